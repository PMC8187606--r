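#' Unfolding free energy at a denaturant concentration
#'
#' Linear extrapolation method: \eqn{\Delta G(c) = \Delta G^{H_2O} - m c}.
#'
#' @param dG0 Free energy of unfolding in water, kcal/mol.
#' @param m m-value, kcal mol^-1 M^-1.
#' @param c Denaturant concentration(s), M; must be >= 0.
#' @return Free energy (kcal/mol), vectorized over `c`.
#' @examples
#' gibbs_at(4.32, 0.8, 0)     # 4.32 (water)
#' gibbs_at(4.7, 1.7, 2.25)   # 0.875
#' @export
gibbs_at <- function(dG0, m, c) {
  stopifnot(is.numeric(c))
  if (any(c < 0)) stop("denaturant concentration must be >= 0", call. = FALSE)
  dG0 - m * c
}

#' Transition midpoint from LEM parameters
#'
#' The denaturant concentration at which half the protein has crossed the
#' transition, \eqn{D_m = \Delta G^{H_2O} / m} (where \eqn{\Delta G(D_m)=0}).
#'
#' @inheritParams gibbs_at
#' @return Midpoint concentration, M.
#' @examples
#' midpoint(1.5, 0.9)   # 1.67 M
#' @export
midpoint <- function(dG0, m) {
  stopifnot(is.numeric(dG0), is.numeric(m))
  if (any(m == 0)) stop("m must be nonzero to define a midpoint",
                        call. = FALSE)
  dG0 / m
}

## logistic fraction unfolded given dG (kcal/mol); saturates cleanly:
## f_U = K/(1+K) with K = exp(-dG/RT)  ==  plogis(-dG/RT)
.frac_unfolded <- function(dG, rt) plogis(-dG / rt)

## softmax over columns of the free-energy matrix (one row per c), with
## max-shift so extreme arguments saturate instead of overflowing; rows sum
## to 1 exactly up to floating point
.softmax <- function(negG_over_RT) {
  shift <- apply(negG_over_RT, 1L, max)
  e <- exp(negG_over_RT - shift)
  e / rowSums(e)
}

#' Species fractions of the two-state model
#'
#' \eqn{K_{NU}(c) = e^{-\Delta G_{NU}(c)/RT}}, \eqn{f_U = K/(1+K)},
#' \eqn{f_N = 1 - f_U}.  Numerically saturating: extreme free energies give
#' exactly (1, 0) or (0, 1) rather than overflowing.
#'
#' @param p A [two_state_params()] object.
#' @param c Denaturant concentration(s), M.
#' @param cond A [conditions()] object.
#' @return A list with numeric vectors `f_N` and `f_U`.
#' @examples
#' p <- two_state_params(4.32, 0.8)
#' two_state_fractions(p, c = midpoint(p$dG0, p$m))$f_U  # exactly 0.5
#' @export
two_state_fractions <- function(p, c, cond = conditions()) {
  stopifnot(inherits(p, "two_state_params"))
  dG <- gibbs_at(p$dG0, p$m, c)
  fU <- .frac_unfolded(dG, .rt(cond))
  list(f_N = 1 - fU, f_U = fU)
}

#' Observed signal of the two-state model
#'
#' \eqn{S_{obs}(c) = S_N(c) f_N(c) + S_U(c) f_U(c)} with linear baselines
#' \eqn{S_N = a_1 + b_1 c} and \eqn{S_U = c_1 + p_1 c}.
#'
#' @inheritParams two_state_fractions
#' @return Numeric vector of signals.
#' @examples
#' p <- two_state_params(4.32, 0.8, a1 = 1, b1 = 0, c1 = 0, p1 = 0)
#' two_state_signal(p, c = 0)   # ~0.99932
#' @export
two_state_signal <- function(p, c, cond = conditions()) {
  f <- two_state_fractions(p, c, cond)
  (p$a1 + p$b1 * c) * f$f_N + (p$c1 + p$p1 * c) * f$f_U
}

#' Species fractions of the three-state model
#'
#' With \eqn{K_{NI} = e^{-\Delta G_{NI}(c)/RT}} and
#' \eqn{K_{NU} = e^{-\Delta G_{NU}(c)/RT}}:
#' \deqn{f_N = \frac{1}{1+K_{NI}+K_{NU}},\;
#'       f_I = \frac{K_{NI}}{1+K_{NI}+K_{NU}},\;
#'       f_U = \frac{K_{NU}}{1+K_{NI}+K_{NU}}.}
#' Computed as a max-shifted softmax so the fractions always sum to 1 and
#' never overflow.
#'
#' @param p A [three_state_params()] object.
#' @inheritParams two_state_fractions
#' @return A list with numeric vectors `f_N`, `f_I`, `f_U`.
#' @examples
#' p <- three_state_params(1.4, 0.8, 4.7, 1.7)
#' three_state_fractions(p, 2.25)   # ~ (0.313, 0.615, 0.072)
#' @export
three_state_fractions <- function(p, c, cond = conditions()) {
  stopifnot(inherits(p, "three_state_params"))
  rt <- .rt(cond)
  x <- cbind(0,
             -gibbs_at(p$dG_NI0, p$m_NI, c) / rt,
             -gibbs_at(p$dG_NU0, p$m_NU, c) / rt)
  f <- .softmax(x)
  list(f_N = f[, 1L], f_I = f[, 2L], f_U = f[, 3L])
}

#' Observed signal of the three-state model
#'
#' \eqn{S_{obs}(c) = S_N f_N + S_I f_I + S_U f_U} with all three baselines
#' linear in denaturant concentration.
#'
#' @inheritParams three_state_fractions
#' @return Numeric vector of signals.
#' @export
three_state_signal <- function(p, c, cond = conditions()) {
  f <- three_state_fractions(p, c, cond)
  (p$a1 + p$b1 * c) * f$f_N +
    (p$c1 + p$p1 * c) * f$f_I +
    (p$e1 + p$g1 * c) * f$f_U
}

#' Fraction unfolded in a thermal melt
#'
#' van't Hoff two-state model with \eqn{\Delta C_p = 0}:
#' \eqn{\Delta G(T) = \Delta H_{vH} (1 - T/T_m)},
#' \eqn{f_U = 1/(1 + e^{\Delta G/RT})}.
#'
#' @param p A [thermal_params()] object.
#' @param temp Absolute temperature(s), kelvin.
#' @return Numeric vector of unfolded fractions.
#' @examples
#' p <- thermal_params(316.45, 70)
#' thermal_fraction_unfolded(p, p$Tm)   # exactly 0.5
#' @export
thermal_fraction_unfolded <- function(p, temp) {
  stopifnot(inherits(p, "thermal_params"), is.numeric(temp))
  if (any(temp <= 0)) stop("temperature must be > 0 K", call. = FALSE)
  dG <- p$dH_vH * (1 - temp / p$Tm)
  .frac_unfolded(dG, 1.987e-3 * temp)
}

#' Observed signal of a thermal melt
#'
#' \eqn{S_{obs}(T) = S_N(T) f_N + S_U(T) f_U} with baselines linear in
#' temperature (kelvin).
#'
#' @inheritParams thermal_fraction_unfolded
#' @return Numeric vector of signals.
#' @export
thermal_signal <- function(p, temp) {
  fU <- thermal_fraction_unfolded(p, temp)
  (p$a1 + p$b1 * temp) * (1 - fU) + (p$c1 + p$p1 * temp) * fU
}

#' Species-population profile over a denaturant grid
#'
#' Evaluates the equilibrium fractions of each species on a grid of
#' denaturant concentrations; for the three-state model also locates the
#' grid point of maximal intermediate population (`argmax_I`).  A
#' two-state parameter set yields a profile with \eqn{f_I \equiv 0}.
#'
#' @param p A [two_state_params()] or [three_state_params()] object.
#' @param grid Non-empty vector of denaturant concentrations, M.
#' @param cond A [conditions()] object.
#' @return A data frame of class `population_profile` with columns
#'   `c`, `f_N`, `f_I`, `f_U`; attributes `argmax_I` (grid value of maximal
#'   f_I, `NA` for two-state) and `max_f_I`.
#' @examples
#' p <- three_state_params(1.4, 0.8, 4.7, 1.7)
#' pp <- population_profile(p, seq(0, 6, 0.05))
#' attr(pp, "argmax_I"); attr(pp, "max_f_I")
#' @export
population_profile <- function(p, grid, cond = conditions()) {
  stopifnot(is.numeric(grid), length(grid) >= 1L)
  if (any(grid < 0)) stop("grid values must be >= 0", call. = FALSE)
  if (inherits(p, "three_state_params")) {
    f <- three_state_fractions(p, grid, cond)
  } else if (inherits(p, "two_state_params")) {
    f2 <- two_state_fractions(p, grid, cond)
    f <- list(f_N = f2$f_N, f_I = rep(0, length(grid)), f_U = f2$f_U)
  } else {
    stop("p must be a two_state_params or three_state_params object",
         call. = FALSE)
  }
  out <- data.frame(c = grid, f_N = f$f_N, f_I = f$f_I, f_U = f$f_U)
  three <- inherits(p, "three_state_params")
  i <- which.max(out$f_I)
  attr(out, "argmax_I") <- if (three) grid[i] else NA_real_
  attr(out, "max_f_I") <- if (three) out$f_I[i] else 0
  class(out) <- c("population_profile", "data.frame")
  out
}

#' @export
print.population_profile <- function(x, ...) {
  cat(sprintf("Population profile: %d grid points, c in [%g, %g] M\n",
              nrow(x), min(x$c), max(x$c)))
  if (!is.na(attr(x, "argmax_I")))
    cat(sprintf("  max f_I = %.3f at c = %g M\n",
                attr(x, "max_f_I"), attr(x, "argmax_I")))
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("  ...\n")
  invisible(x)
}

#' @export
plot.population_profile <- function(x, ...) {
  plot(x$c, x$f_N, type = "l", col = "blue", ylim = c(0, 1),
       xlab = "denaturant (M)", ylab = "fraction", ...)
  lines(x$c, x$f_I, col = "darkgreen")
  lines(x$c, x$f_U, col = "red")
  legend("right", c("N", "I", "U"), lty = 1,
         col = c("blue", "darkgreen", "red"), bty = "n")
  invisible(x)
}
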