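#' Aromatic composition of a protein
#'
#' Holds the counts needed for A280 extinction-coefficient bookkeeping.
#' May be given directly, or derived from a one-letter amino-acid sequence
#' (string or FASTA file), in which case tryptophans (W), tyrosines (Y)
#' and total residues are counted; cystine (disulfide) pairs default to 0
#' for a reduced protein.
#'
#' @param n_trp,n_tyr Tryptophan and tyrosine counts.
#' @param n_cystine Number of disulfide (cystine) pairs, default 0.
#' @param n_residues Total residue count.
#' @param molar_mass Optional molar mass, Da.
#' @param sequence Optional one-letter amino-acid string; overrides the
#'   counts.
#' @param fasta Optional path to a FASTA file (first record used).
#' @return An object of class `protein_composition`.
#' @examples
#' protein_composition(n_trp = 6, n_tyr = 6, n_residues = 341)
#' protein_composition(sequence = "MWWYACK")
#' @export
protein_composition <- function(n_trp = 0, n_tyr = 0, n_cystine = 0,
                                n_residues = NA_integer_, molar_mass = NULL,
                                sequence = NULL, fasta = NULL) {
  if (!is.null(fasta)) {
    recs <- seqinr::read.fasta(fasta, seqtype = "AA", as.string = TRUE)
    if (!length(recs)) stop("no sequences in FASTA file", call. = FALSE)
    sequence <- as.character(recs[[1L]])
  }
  if (!is.null(sequence)) {
    aa <- strsplit(toupper(gsub("[^A-Za-z]", "", sequence)), "")[[1L]]
    n_trp <- sum(aa == "W")
    n_tyr <- sum(aa == "Y")
    n_residues <- length(aa)
  }
  stopifnot(n_trp >= 0, n_tyr >= 0, n_cystine >= 0)
  if (!is.na(n_residues) && n_residues < n_trp + n_tyr)
    stop("n_residues must be >= n_trp + n_tyr", call. = FALSE)
  structure(list(n_trp = n_trp, n_tyr = n_tyr, n_cystine = n_cystine,
                 n_residues = n_residues, molar_mass = molar_mass),
            class = "protein_composition")
}

#' @export
print.protein_composition <- function(x, ...) {
  cat(sprintf("Protein composition: %d Trp, %d Tyr, %d cystine, %s residues\n",
              x$n_trp, x$n_tyr, x$n_cystine,
              ifelse(is.na(x$n_residues), "?", x$n_residues)))
  invisible(x)
}

#' A280 molar extinction coefficient from aromatic composition
#'
#' Pace's additive coefficients:
#' \eqn{\varepsilon_{280} = 5500\,n_{Trp} + 1490\,n_{Tyr} +
#' 125\,n_{cystine}} (M^-1 cm^-1).
#'
#' @param comp A [protein_composition()].
#' @return Extinction coefficient at 280 nm, M^-1 cm^-1.
#' @examples
#' extinction_coefficient_280(protein_composition(6, 6))  # 41940
#' @export
extinction_coefficient_280 <- function(comp) {
  stopifnot(inherits(comp, "protein_composition"))
  5500 * comp$n_trp + 1490 * comp$n_tyr + 125 * comp$n_cystine
}

#' Protein concentration from A280 by Beer-Lambert
#'
#' \eqn{C = A_{280} / (\varepsilon \, l)}.
#'
#' @param a280 Absorbance at 280 nm.
#' @param epsilon Molar extinction coefficient, M^-1 cm^-1 (> 0).
#' @param pathlength Pathlength, cm (> 0, default 1).
#' @return Concentration, mol/L.
#' @examples
#' concentration_from_a280(0.4194, 41940)   # 1e-5 M
#' @export
concentration_from_a280 <- function(a280, epsilon, pathlength = 1) {
  stopifnot(is.numeric(a280))
  if (!is.numeric(epsilon) || epsilon <= 0)
    stop("epsilon must be > 0", call. = FALSE)
  if (!is.numeric(pathlength) || pathlength <= 0)
    stop("pathlength must be > 0", call. = FALSE)
  a280 / (epsilon * pathlength)
}
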