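#' A wavelength-resolved spectroscopic scan at one condition
#'
#' One CD or fluorescence-emission scan recorded at a single perturbant
#' condition: a strictly increasing wavelength grid and the instrument
#' signal (mdeg for CD, counts for fluorescence).
#'
#' @param wavelength Strictly increasing wavelength grid, nm.
#' @param signal Signal values, same length.
#' @param condition List with elements `kind` (`"urea"`, `"gdnhcl"`,
#'   `"temperature"`, or `"none"`) and `value` (numeric).
#' @param excitation Excitation wavelength (nm) or `NULL` for CD.
#' @param replicate_id Replicate label.
#' @param pathlength Cuvette pathlength, cm (needed for MRE conversion).
#' @param concentration Protein concentration, mol/L.
#' @param n_residues Residue count (for per-residue normalization).
#' @return An object of class `spectrum_scan`.
#' @export
spectrum_scan <- function(wavelength, signal,
                          condition = list(kind = "none", value = 0),
                          excitation = NULL, replicate_id = "rep1",
                          pathlength = NA_real_, concentration = NA_real_,
                          n_residues = NA_integer_) {
  stopifnot(is.numeric(wavelength), is.numeric(signal))
  if (length(wavelength) != length(signal))
    stop("wavelength and signal must have the same length", call. = FALSE)
  if (any(diff(wavelength) <= 0))
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  structure(list(wavelength = wavelength, signal = signal,
                 condition = condition, excitation = excitation,
                 replicate_id = as.character(replicate_id),
                 pathlength = pathlength, concentration = concentration,
                 n_residues = n_residues),
            class = "spectrum_scan")
}

#' @export
print.spectrum_scan <- function(x, ...) {
  cat(sprintf("Spectrum scan [%s = %g, %s]: %d points, %g-%g nm\n",
              x$condition$kind, x$condition$value, x$replicate_id,
              length(x$wavelength), min(x$wavelength), max(x$wavelength)))
  invisible(x)
}

## parse a perturbant value out of a wide-table column header like
## "0M", "X2.5M", "urea_4", "2.25"
.parse_condition_header <- function(h) {
  v <- suppressWarnings(as.numeric(gsub("[^0-9.eE+-]", "", h)))
  if (is.na(v))
    stop("cannot parse a perturbant value from column header '", h, "'",
         call. = FALSE)
  v
}

#' Read a delimited table of wavelength scans
#'
#' Two dialects are supported.  `"wide"`: first column is the wavelength
#' grid, each further column one condition (header encodes the perturbant
#' value, e.g. `0M`, `2.5M`).  `"long"`: columns `wavelength`,
#' `condition`, `replicate`, `signal`.  Non-monotone or duplicated
#' wavelength rows are reported with their line numbers.
#'
#' @param path Delimited text file (tab or comma separated, autodetected).
#' @param dialect `"wide"` or `"long"`.
#' @param kind Perturbant kind annotated on every scan.
#' @param pathlength,concentration,n_residues Optional instrument metadata
#'   propagated to every scan (see [ellipticity_to_mre()]).
#' @return A list of [spectrum_scan()] objects, one per condition
#'   (x replicate for the long dialect).
#' @export
read_scan_table <- function(path, dialect = c("wide", "long"),
                            kind = "urea", pathlength = NA_real_,
                            concentration = NA_real_,
                            n_residues = NA_integer_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(first))
    stop("empty scan table: ", path, call. = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  d <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE)
  if (nrow(d) == 0L) stop("empty scan table: ", path, call. = FALSE)

  if (dialect == "wide") {
    if (ncol(d) < 2L)
      stop("wide scan table needs a wavelength column plus at least one ",
           "condition column", call. = FALSE)
    wl <- d[[1L]]
    bad <- which(diff(wl) <= 0)
    if (length(bad))
      stop("non-monotone or duplicated wavelength at line ",
           paste(bad + 2L, collapse = ", "),
           " (data line after header)", call. = FALSE)
    conds <- vapply(names(d)[-1L], .parse_condition_header, numeric(1))
    lapply(seq_along(conds), function(j) {
      spectrum_scan(wl, d[[j + 1L]],
                    condition = list(kind = kind, value = unname(conds[j])),
                    pathlength = pathlength, concentration = concentration,
                    n_residues = n_residues)
    })
  } else {
    need <- c("wavelength", "condition", "replicate", "signal")
    if (!all(need %in% names(d)))
      stop("long scan table must have columns: ",
           paste(need, collapse = ", "), call. = FALSE)
    key <- interaction(d$condition, d$replicate, drop = TRUE)
    out <- lapply(split(seq_len(nrow(d)), key), function(idx) {
      g <- d[idx, ]
      ord <- order(g$wavelength)
      g <- g[ord, ]; idx <- idx[ord]
      bad <- which(diff(g$wavelength) <= 0)
      if (length(bad))
        stop("non-monotone or duplicated wavelength at line ",
             paste(idx[bad + 1L] + 1L, collapse = ", "), call. = FALSE)
      spectrum_scan(g$wavelength, g$signal,
                    condition = list(kind = kind,
                                     value = as.numeric(g$condition[1L])),
                    replicate_id = as.character(g$replicate[1L]),
                    pathlength = pathlength, concentration = concentration,
                    n_residues = n_residues)
    })
    unname(out)
  }
}

#' Convert raw ellipticity to mean residue ellipticity
#'
#' \deqn{MRE = \theta / (10 \, l \, C \, N_{res})}
#' with \eqn{\theta} in millidegrees, pathlength \eqn{l} in cm, molar
#' protein concentration \eqn{C} in mol/L, and the residue count
#' \eqn{N_{res}}; the result is in deg cm^2 dmol^-1 (molar-concentration
#' convention).
#'
#' @param theta Raw ellipticity, mdeg (any sign; vectorized).
#' @param pathlength Pathlength, cm (> 0).
#' @param concentration Protein concentration, mol/L (> 0).
#' @param n_residues Number of residues (> 0).
#' @return Mean residue ellipticity, deg cm^2 dmol^-1.
#' @examples
#' ellipticity_to_mre(-20, 0.1, 3.5e-6, 341)   # ~ -16756
#' @export
ellipticity_to_mre <- function(theta, pathlength, concentration,
                               n_residues) {
  stopifnot(is.numeric(theta))
  if (!is.numeric(pathlength) || pathlength <= 0)
    stop("pathlength must be > 0 cm", call. = FALSE)
  if (!is.numeric(concentration) || concentration <= 0)
    stop("concentration must be > 0 mol/L", call. = FALSE)
  if (!is.numeric(n_residues) || n_residues <= 0)
    stop("n_residues must be > 0", call. = FALSE)
  theta / (10 * pathlength * concentration * n_residues)
}

## signal at one wavelength, linear interpolation between grid neighbors
.signal_at <- function(scan, wavelength) {
  rng <- range(scan$wavelength)
  if (wavelength < rng[1L] || wavelength > rng[2L])
    stop(sprintf("wavelength %g nm outside scan range [%g, %g]",
                 wavelength, rng[1L], rng[2L]), call. = FALSE)
  approx(scan$wavelength, scan$signal, xout = wavelength)$y
}

#' Extract a denaturation curve from a set of wavelength scans
#'
#' Evaluates each scan at a single probe wavelength (linear interpolation
#' between the bracketing grid points) and assembles the per-condition
#' values into a [denaturation_curve()].  For the relative-fluorescence
#' probe (`"fluor340"`), each value has the signal at the maximum
#' perturbant condition subtracted, so the fully denatured condition reads
#' zero.
#'
#' @param scans List of [spectrum_scan()]s, one per condition (a single
#'   replicate series).
#' @param wavelength Probe wavelength, nm; must lie inside every scan.
#' @param probe `"cd222"` (plain lookup) or `"fluor340"` (relative
#'   intensity).
#' @param mre If `TRUE`, convert CD signals to mean residue ellipticity
#'   using each scan's `pathlength`, `concentration`, `n_residues`.
#' @return A [denaturation_curve()] ordered by perturbant value.
#' @export
extract_probe_curve <- function(scans, wavelength,
                                probe = c("cd222", "fluor340"),
                                mre = FALSE) {
  probe <- match.arg(probe)
  stopifnot(is.list(scans),
            all(vapply(scans, inherits, logical(1), "spectrum_scan")))
  if (length(scans) < 2L)
    stop("need at least 2 conditions to build a curve", call. = FALSE)
  vals <- vapply(scans, function(s) s$condition$value, numeric(1))
  sig <- vapply(scans, .signal_at, numeric(1), wavelength = wavelength)
  if (mre) {
    sig <- mapply(function(s, th)
      ellipticity_to_mre(th, s$pathlength, s$concentration, s$n_residues),
      scans, sig)
  }
  kind <- scans[[1L]]$condition$kind
  if (probe == "fluor340") sig <- sig - sig[which.max(vals)]
  denaturation_curve(vals, sig,
                     perturbant = if (kind == "none") "urea" else kind,
                     probe = probe,
                     replicate_id = scans[[1L]]$replicate_id)
}

#' Emission-maximum wavelength of a scan
#'
#' Locates the wavelength of maximal signal, refined by a parabola through
#' the top point and its two neighbors; at a grid edge the raw argmax is
#' returned with attribute `edge = TRUE`.  A flat scan (no peak) is an
#' error.
#'
#' @param scan A [spectrum_scan()] with at least 3 points.
#' @return The peak wavelength (nm), with attribute `edge`.
#' @examples
#' wl <- 300:400
#' sc <- spectrum_scan(wl, exp(-(wl - 352.4)^2 / (2 * 25^2)))
#' emission_maximum(sc)   # ~352.4
#' @export
emission_maximum <- function(scan) {
  stopifnot(inherits(scan, "spectrum_scan"))
  wl <- scan$wavelength; s <- scan$signal
  if (length(wl) < 3L) stop("need at least 3 points", call. = FALSE)
  if (diff(range(s)) == 0)
    stop("flat scan: no emission peak to locate", call. = FALSE)
  i <- which.max(s)
  if (i == 1L || i == length(s))
    return(structure(wl[i], edge = TRUE))
  ## parabolic vertex through (i-1, i, i+1); exact for a quadratic peak
  y1 <- s[i - 1L]; y2 <- s[i]; y3 <- s[i + 1L]
  denom <- y1 - 2 * y2 + y3
  offset <- if (denom == 0) 0 else 0.5 * (y1 - y3) / denom
  h <- (wl[i + 1L] - wl[i - 1L]) / 2
  structure(wl[i] + offset * h, edge = FALSE)
}
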