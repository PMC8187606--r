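#' A denaturation curve: probe signal versus perturbant
#'
#' The unit of fitting: one series of probe signal (MRE at 222 nm, relative
#' fluorescence at 340 nm, or emission-maximum wavelength) against a
#' chemical denaturant concentration or temperature, for one replicate.
#'
#' @param x Perturbant values: molar concentration (urea/GdnHCl, >= 0) or
#'   absolute temperature in kelvin (> 0).
#' @param y Probe signal values, same length as `x`.
#' @param perturbant One of `"urea"`, `"gdnhcl"`, `"temperature"`.
#' @param probe One of `"cd222"`, `"fluor340"`, `"lambda_max"`.
#' @param replicate_id Replicate label (default `"rep1"`).
#' @param metadata Optional named list of free-form condition annotations.
#' @return A data frame of class `denat_curve` with columns `x`, `y` and
#'   attributes `perturbant`, `probe`, `replicate_id`, `metadata`.
#' @examples
#' denaturation_curve(c(0, 2, 4, 6, 8), c(1, 1, .5, 0, 0), "urea", "cd222")
#' @export
denaturation_curve <- function(x, y,
                               perturbant = c("urea", "gdnhcl",
                                              "temperature"),
                               probe = c("cd222", "fluor340", "lambda_max"),
                               replicate_id = "rep1", metadata = list()) {
  perturbant <- match.arg(perturbant)
  probe <- match.arg(probe)
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y))
    stop("x and y must have the same length", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite", call. = FALSE)
  if (perturbant == "temperature") {
    if (any(x <= 0))
      stop("temperatures must be > 0 K (kelvin expected)", call. = FALSE)
  } else if (any(x < 0)) {
    stop("denaturant concentrations must be >= 0 M", call. = FALSE)
  }
  ord <- order(x)
  out <- data.frame(x = x[ord], y = y[ord])
  attr(out, "perturbant") <- perturbant
  attr(out, "probe") <- probe
  attr(out, "replicate_id") <- as.character(replicate_id)
  attr(out, "metadata") <- metadata
  class(out) <- c("denat_curve", "data.frame")
  out
}

#' @export
print.denat_curve <- function(x, ...) {
  cat(sprintf("Denaturation curve [%s, probe %s, %s]: %d points, x in [%g, %g]\n",
              attr(x, "perturbant"), attr(x, "probe"),
              attr(x, "replicate_id"), nrow(x), min(x$x), max(x$x)))
  invisible(x)
}

#' @export
plot.denat_curve <- function(x, ...,
                             xlab = if (attr(x, "perturbant") == "temperature")
                               "temperature (K)" else "denaturant (M)",
                             ylab = attr(x, "probe")) {
  plot(x$x, x$y, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Write denaturation curves to a TSV file
#'
#' Flat long layout with columns `perturbant_kind`, `x`, `probe`,
#' `replicate`, `y` — the same dialect [read_curves_tsv()] reads back.
#'
#' @param curves A `denat_curve` or a list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_curves_tsv <- function(curves, path) {
  if (inherits(curves, "denat_curve")) curves <- list(curves)
  rows <- lapply(curves, function(cv) {
    data.frame(perturbant_kind = attr(cv, "perturbant"), x = cv$x,
               probe = attr(cv, "probe"),
               replicate = attr(cv, "replicate_id"), y = cv$y)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read denaturation curves from a TSV file
#'
#' @param path File written by [write_curves_tsv()] (columns
#'   `perturbant_kind`, `x`, `probe`, `replicate`, `y`).
#' @return A list of `denat_curve` objects, one per probe x replicate.
#' @export
read_curves_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("perturbant_kind", "x", "probe", "replicate", "y")
  if (!all(need %in% names(d)))
    stop("curve table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  key <- interaction(d$perturbant_kind, d$probe, d$replicate, drop = TRUE)
  lapply(split(d, key), function(g) {
    denaturation_curve(g$x, g$y, perturbant = g$perturbant_kind[1L],
                       probe = g$probe[1L], replicate_id = g$replicate[1L])
  })
}
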