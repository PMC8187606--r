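#' Configuration of a synthetic denaturation experiment
#'
#' Defines the forward model, ground-truth parameters, perturbant grid,
#' noise level and replication of a simulated experiment.  Defaults
#' emulate the standard equilibrium protocols: urea titrations 0-8 M in
#' 0.25 M steps, GdnHCl 0-6 M in 0.25 M steps, thermal melts 20-90 degC
#' in 1 degC steps, three replicates, Gaussian noise with a standard
#' deviation of 2% of the transition amplitude.
#'
#' The grid must span both baselines of the truth: at least 3 points where
#' the unfolded species is essentially absent (f_U <= 0.05) and at least 3
#' where the native species is exhausted (f_N <= 0.05; for a two-state
#' truth this is f_U >= 0.95).
#'
#' @param model `"two_state"`, `"three_state"`, or `"thermal"`.
#' @param truth The matching `unfold_params` object (ground truth).
#' @param perturbant For chemical models, `"urea"` or `"gdnhcl"`; fixes
#'   the default grid.  Ignored for thermal.
#' @param grid Optional explicit perturbant grid (M, or kelvin for
#'   thermal).
#' @param noise_sd Gaussian noise SD as a fraction of the transition
#'   amplitude (default 0.02).
#' @param n_replicates Number of replicate curves (default 3).
#' @param seed Integer seed (default 42).
#' @return A list of class `synthetic_config`.
#' @examples
#' truth <- two_state_params(3.44, 0.8, a1 = 1, c1 = 0)
#' cfg <- synthetic_config("two_state", truth, "urea")
#' @export
synthetic_config <- function(model = c("two_state", "three_state",
                                       "thermal"),
                             truth, perturbant = c("urea", "gdnhcl"),
                             grid = NULL, noise_sd = 0.02,
                             n_replicates = 3, seed = 42) {
  model <- match.arg(model)
  perturbant <- match.arg(perturbant)
  cls <- paste0(model, "_params")
  if (!inherits(truth, cls))
    stop("truth must be a ", cls, " object", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  if (is.null(grid)) {
    grid <- switch(model,
                   two_state = ,
                   three_state = if (perturbant == "urea")
                     seq(0, 8, 0.25) else seq(0, 6, 0.25),
                   thermal = seq(293.15, 363.15, 1))
  }
  structure(list(model = model, truth = truth,
                 perturbant = if (model == "thermal") "temperature"
                              else perturbant,
                 grid = grid, noise_sd = noise_sd,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

## fraction unfolded of the truth over the grid (any model)
.truth_fu <- function(cfg, cond) {
  switch(cfg$model,
         two_state = two_state_fractions(cfg$truth, cfg$grid, cond)$f_U,
         three_state = three_state_fractions(cfg$truth, cfg$grid, cond)$f_U,
         thermal = thermal_fraction_unfolded(cfg$truth, cfg$grid))
}

## noise-free signal of the truth over the grid
.truth_signal <- function(cfg, cond) {
  switch(cfg$model,
         two_state = two_state_signal(cfg$truth, cfg$grid, cond),
         three_state = three_state_signal(cfg$truth, cfg$grid, cond),
         thermal = thermal_signal(cfg$truth, cfg$grid))
}

## baseline-to-baseline transition amplitude of the truth
.truth_amplitude <- function(cfg) {
  p <- cfg$truth
  x0 <- min(cfg$grid); x1 <- max(cfg$grid)
  sN <- p$a1 + p$b1 * x0
  sU <- if (cfg$model == "three_state") p$e1 + p$g1 * x1
        else p$c1 + p$p1 * x1
  abs(sN - sU)
}

.check_grid_coverage <- function(cfg, cond) {
  fu <- .truth_fu(cfg, cond)
  fn <- switch(cfg$model,
               three_state = three_state_fractions(cfg$truth, cfg$grid,
                                                   cond)$f_N,
               1 - fu)
  ## native-side baseline: unfolded species absent; unfolded side: native
  ## species exhausted (for two-state these are f_U <= 0.05 / >= 0.95)
  if (sum(fu <= 0.05) < 3L || sum(fn <= 0.05) < 3L)
    stop("grid does not span both baselines of the truth (need >= 3 ",
         "points with f_U <= 0.05 and >= 3 with f_N <= 0.05)",
         call. = FALSE)
  invisible(TRUE)
}

#' Simulate replicate denaturation curves
#'
#' Forward-simulates the configured model on its grid and adds
#' homoscedastic Gaussian noise with standard deviation
#' `noise_sd x amplitude`, where the amplitude is the native-to-unfolded
#' baseline separation \eqn{|S_N(x_{min}) - S_U(x_{max})|}.
#' Deterministic given the seed; the caller's RNG state is untouched.
#'
#' @param cfg A [synthetic_config()].
#' @param cond A [conditions()] object (chemical models).
#' @return A list of `n_replicates` [denaturation_curve()] objects.
#' @examples
#' truth <- two_state_params(3.44, 0.8, a1 = 1, c1 = 0)
#' curves <- simulate_curves(synthetic_config("two_state", truth, "urea"))
#' length(curves)  # 3
#' @export
simulate_curves <- function(cfg, cond = conditions()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  .check_grid_coverage(cfg, cond)
  mu <- .truth_signal(cfg, cond)
  sdv <- cfg$noise_sd * .truth_amplitude(cfg)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(cfg$seed)
  lapply(seq_len(cfg$n_replicates), function(i) {
    denaturation_curve(cfg$grid, mu + rnorm(length(mu), 0, sdv),
                       perturbant = cfg$perturbant, probe = "cd222",
                       replicate_id = paste0("rep", i))
  })
}

#' Simulate tryptophan emission scans along a titration
#'
#' For each grid condition, generates an emission spectrum on a 300-400 nm
#' grid as the fraction-weighted sum of per-species Gaussian bands (sigma
#' 25 nm): the native band at 340 nm, the unfolded band red-shifted to
#' `unfolded_center` (360 nm for GdnHCl; 357 nm available for urea), and
#' for the three-state model a slightly red-shifted intermediate band
#' (345 nm) with near-native quantum yield.  The apparent emission maximum
#' therefore red-shifts continuously from 340 nm toward the unfolded
#' center, and the signal at any fixed wavelength is exactly linear in the
#' species fractions — so zero-noise scans extracted at 340 nm reproduce
#' the closed-form titration signal with flat per-species baselines.
#' Gaussian noise is scaled to the native peak height.
#'
#' @param cfg A chemical-model [synthetic_config()].
#' @param cond A [conditions()] object.
#' @param wavelength Emission wavelength grid, nm.
#' @param unfolded_center Unfolded-band center, nm (default 360).
#' @param centers Named numeric overrides `c(N = , I = , U = )` of the
#'   per-species band centers.
#' @param heights Per-species band heights `c(N = , I = , U = )`.
#' @param bandwidth Gaussian sigma, nm.
#' @return A list of [spectrum_scan()]s, one per grid condition, with the
#'   per-species band constants stored in attribute `band`.
#' @export
simulate_emission_scans <- function(cfg, cond = conditions(),
                                    wavelength = seq(300, 400, 1),
                                    unfolded_center = 360,
                                    centers = NULL, heights = NULL,
                                    bandwidth = 25) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$model == "thermal")
    stop("emission-scan simulation is defined for chemical titrations",
         call. = FALSE)
  .check_grid_coverage(cfg, cond)
  ctr <- c(N = 340, I = 345, U = unfolded_center)
  hgt <- c(N = 1, I = 0.95, U = 0.45)
  if (!is.null(centers)) ctr[names(centers)] <- centers
  if (!is.null(heights)) hgt[names(heights)] <- heights

  fr <- if (cfg$model == "three_state") {
    three_state_fractions(cfg$truth, cfg$grid, cond)
  } else {
    f2 <- two_state_fractions(cfg$truth, cfg$grid, cond)
    list(f_N = f2$f_N, f_I = rep(0, length(cfg$grid)), f_U = f2$f_U)
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(cfg$seed)
  band <- function(center) exp(-(wavelength - center)^2 / (2 * bandwidth^2))
  bN <- hgt["N"] * band(ctr["N"])
  bI <- hgt["I"] * band(ctr["I"])
  bU <- hgt["U"] * band(ctr["U"])
  scans <- lapply(seq_along(cfg$grid), function(i) {
    mu <- fr$f_N[i] * bN + fr$f_I[i] * bI + fr$f_U[i] * bU
    spectrum_scan(wavelength,
                  mu + rnorm(length(wavelength), 0,
                             cfg$noise_sd * hgt["N"]),
                  condition = list(kind = cfg$perturbant,
                                   value = cfg$grid[i]))
  })
  attr(scans, "band") <- list(centers = ctr, heights = hgt,
                              bandwidth = bandwidth)
  scans
}
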