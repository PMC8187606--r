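## ---- fast numeric signal evaluators (reporting parameterizations) -------
## two-state par: (dG0, m, a1, b1, c1, p1)
.sig2 <- function(par, x, rt) {
  fU <- plogis(-(par[1L] - par[2L] * x) / rt)
  (par[3L] + par[4L] * x) * (1 - fU) + (par[5L] + par[6L] * x) * fU
}

## three-state par: (dG_NI0, m_NI, dG_NU0, m_NU, a1, b1, c1, p1, e1, g1)
.sig3 <- function(par, x, rt) {
  q <- cbind(0, -(par[1L] - par[2L] * x) / rt, -(par[3L] - par[4L] * x) / rt)
  f <- .softmax(q)
  (par[5L] + par[6L] * x) * f[, 1L] +
    (par[7L] + par[8L] * x) * f[, 2L] +
    (par[9L] + par[10L] * x) * f[, 3L]
}

## thermal par: (Tm, dH, a1, b1, c1, p1); x in kelvin
.sigT <- function(par, x, rt_unused = NULL) {
  fU <- plogis(-(par[2L] * (1 - x / par[1L])) / (1.987e-3 * x))
  (par[3L] + par[4L] * x) * (1 - fU) + (par[5L] + par[6L] * x) * fU
}

## ---- analytic model Jacobians (d signal / d par) -------------------------
## flat SSR surfaces near noise-free optima need exact derivatives for the
## optimizer to resolve the minimum beyond finite-difference precision
.dsig2 <- function(par, x, rt) {
  f <- plogis(-(par[1L] - par[2L] * x) / rt)
  dB <- (par[5L] + par[6L] * x) - (par[3L] + par[4L] * x)  # S_U - S_N
  w <- f * (1 - f) / rt
  cbind(-dB * w, dB * w * x, 1 - f, x * (1 - f), f, x * f)
}

.dsig3 <- function(par, x, rt) {
  q <- cbind(0, -(par[1L] - par[2L] * x) / rt, -(par[3L] - par[4L] * x) / rt)
  f <- .softmax(q)
  BN <- par[5L] + par[6L] * x
  BI <- par[7L] + par[8L] * x
  BU <- par[9L] + par[10L] * x
  S <- BN * f[, 1L] + BI * f[, 2L] + BU * f[, 3L]
  wI <- f[, 2L] * (BI - S) / rt
  wU <- f[, 3L] * (BU - S) / rt
  cbind(-wI, wI * x, -wU, wU * x,
        f[, 1L], x * f[, 1L], f[, 2L], x * f[, 2L], f[, 3L], x * f[, 3L])
}

.dsigT <- function(par, x) {
  rt <- 1.987e-3 * x
  dG <- par[2L] * (1 - x / par[1L])
  f <- plogis(-dG / rt)
  dB <- (par[5L] + par[6L] * x) - (par[3L] + par[4L] * x)
  w <- -dB * f * (1 - f) / rt           # dS/d(dG)
  cbind(w * par[2L] * x / par[1L]^2,    # d(dG)/dTm = dH * T / Tm^2
        w * (1 - x / par[1L]),
        1 - f, x * (1 - f), f, x * f)
}

## central-difference Jacobian of f(par) (vector-valued) at par
.num_jac <- function(f, par) {
  f0 <- f(par)
  J <- matrix(NA_real_, length(f0), length(par))
  for (j in seq_along(par)) {
    h <- 1e-6 * max(1, abs(par[j]))
    pp <- par; pm <- par
    pp[j] <- pp[j] + h; pm[j] <- pm[j] - h
    J[, j] <- (f(pp) - f(pm)) / (2 * h)
  }
  J
}

## straight line through the first / last k points: c(intercept, slope)
.edge_line <- function(x, y, k = 3L, side = c("head", "tail")) {
  side <- match.arg(side)
  idx <- if (side == "head") seq_len(k) else seq(length(x) - k + 1L, length(x))
  fit <- lm(y[idx] ~ x[idx])
  unname(coef(fit))
}

#' Fitting control settings
#'
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#' @param ftol,ptol Relative SSR / parameter convergence tolerances
#'   (machine-epsilon defaults: noise-free curves are recovered to
#'   optimizer precision).
#' @param min_fraction_span Minimum span of the fitted unfolded fraction
#'   across the data required to accept a fit; smaller spans are reported
#'   as ill-conditioned (transition not spanned by the data).
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(maxiter = 1000, ftol = .Machine$double.eps,
                        ptol = .Machine$double.eps,
                        min_fraction_span = 0.2) {
  structure(list(maxiter = maxiter, ftol = ftol, ptol = ptol,
                 min_fraction_span = min_fraction_span),
            class = "fit_control")
}

## run multi-start Levenberg-Marquardt; returns best nls.lm result + count
.multistart_lm <- function(y, x, fn_fit, starts, lower, upper, control,
                           jac_fit = NULL, tie_key = function(p) p[1L]) {
  best <- NULL
  n_conv <- 0L
  ctl <- minpack.lm::nls.lm.control(maxiter = control$maxiter,
                                    maxfev = 200000,
                                    ftol = control$ftol,
                                    ptol = control$ptol)
  for (s in starts) {
    res <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = s,
        fn = function(p) y - fn_fit(p, x),
        jac = if (is.null(jac_fit)) NULL
              else function(p) -jac_fit(p, x),
        lower = lower, upper = upper,
        control = ctl)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$deviance)) next
    ## info -1: iteration cap reached while polishing at machine-epsilon
    ## tolerances -- the estimate is converged for all practical purposes
    if (res$info %in% c(1:4, -1L)) n_conv <- n_conv + 1L
    ## ties (SSR within 1e-10) go to the smaller stability estimate: the
    ## most conservative interpretation consistent with the data
    if (is.null(best) ||
        res$deviance < best$deviance - 1e-10 ||
        (abs(res$deviance - best$deviance) < 1e-10 &&
         tie_key(res$par) < tie_key(best$par))) {
      best <- res
    }
  }
  if (is.null(best) || n_conv == 0L)
    stop("non-convergence: no optimizer start converged", call. = FALSE)
  list(best = best, n_conv = n_conv)
}

## shared post-processing: vcov, derived quantities, diagnostics
.finish_fit <- function(model, curve, cond, rep_par, par_names, fn_rep,
                        derived_fn, ssr_check, n_conv, n_starts, control,
                        flags = list()) {
  x <- curve$x; y <- curve$y
  n <- length(x); k <- length(rep_par)
  fitted <- fn_rep(rep_par, x)
  res <- y - fitted
  ssr <- sum(res^2)
  sigma2 <- if (n > k) ssr / (n - k) else NA_real_

  J <- .num_jac(function(p) fn_rep(p, x), rep_par)
  vc <- tryCatch({
    V <- sigma2 * chol2inv(chol(crossprod(J)))
    dimnames(V) <- list(par_names, par_names)
    V
  }, error = function(e) NULL)
  if (is.null(vc)) {
    vc <- matrix(NA_real_, k, k, dimnames = list(par_names, par_names))
    flags$singular <- TRUE
  }
  stderr <- sqrt(pmax(diag(vc), 0))

  derived <- derived_fn(rep_par)
  Dg <- .num_jac(function(p) derived_fn(p), rep_par)
  derived_se <- if (all(is.finite(vc))) {
    sqrt(pmax(diag(Dg %*% vc %*% t(Dg)), 0))
  } else rep(NA_real_, length(derived))
  names(derived_se) <- names(derived)

  kk <- k + 1  # + residual variance
  aicc <- if (n - kk - 1 > 0) {
    n * log(max(ssr, .Machine$double.xmin) / n) + 2 * kk +
      2 * kk * (kk + 1) / (n - kk - 1)
  } else Inf

  structure(list(model = model,
                 coefficients = setNames(rep_par, par_names),
                 stderr = setNames(stderr, par_names),
                 vcov = vc,
                 derived = derived, derived_se = derived_se,
                 residuals = res, fitted = fitted,
                 ssr = ssr, sigma = sqrt(sigma2), aicc = aicc, n = n,
                 n_starts = n_starts, n_starts_converged = n_conv,
                 curve = curve, conditions = cond, flags = flags),
            class = "unfold_fit")
}

## ill-conditioning guard: fitted transition must be spanned and resolvable
.check_conditioned <- function(frac_span, amplitude, ssr, n, k, y, control) {
  rmse <- sqrt(ssr / max(1L, n - k))
  amp_tol <- max(1e-7 * (1 + max(abs(y))), 4 * rmse)
  if (frac_span < control$min_fraction_span || amplitude < amp_tol)
    stop("ill-conditioned fit: the unfolding transition is not spanned ",
         "by the data (all points lie on one baseline)", call. = FALSE)
  invisible(TRUE)
}

#' Fit an equilibrium unfolding model to a denaturation curve
#'
#' Nonlinear least-squares estimation (multi-start Levenberg-Marquardt with
#' box bounds) of the two-state or three-state chemical-denaturation model
#' or the van't Hoff thermal-melt model.  Baselines are initialized from
#' straight-line fits through the first and last three points of the curve;
#' transition midpoints are multi-started over quantiles of the x-range
#' (8 starts).  Standard errors come from the numerical Jacobian at the
#' optimum; derived quantities (midpoints, \eqn{\Delta G_{IU}}, Tm in degC)
#' carry delta-method errors.
#'
#' @param curve A [denaturation_curve()].
#' @param model `"two_state"`, `"three_state"`, or `"thermal"`.
#' @param cond A [conditions()] object (chemical models only).
#' @param control A [fit_control()] list.
#' @return An object of class `unfold_fit`; see [summary.unfold_fit()].
#' @examples
#' truth <- two_state_params(3.44, 0.8, a1 = 1, b1 = 0, c1 = 0, p1 = 0)
#' x <- seq(0, 8, 0.25)
#' cv <- denaturation_curve(x, two_state_signal(truth, x), "urea", "cd222")
#' fit <- fit_unfolding(cv, "two_state")
#' coef(fit)[c("dG0", "m")]
#' @export
fit_unfolding <- function(curve,
                          model = c("two_state", "three_state", "thermal"),
                          cond = conditions(), control = fit_control()) {
  model <- match.arg(model)
  switch(model,
         two_state  = fit_two_state(curve, cond, control),
         three_state = fit_three_state(curve, cond, control),
         thermal    = fit_thermal(curve, control))
}

#' @describeIn fit_unfolding Two-state chemical denaturation fit
#'   (requires a urea/GdnHCl curve with at least 7 points).
#' @export
fit_two_state <- function(curve, cond = conditions(),
                          control = fit_control()) {
  stopifnot(inherits(curve, "denat_curve"))
  if (attr(curve, "perturbant") == "temperature")
    stop("two-state chemical fit requires a urea or GdnHCl curve; ",
         "use fit_thermal() for melts", call. = FALSE)
  x <- curve$x; y <- curve$y
  if (length(x) < 7L)
    stop("two-state fit needs at least 7 points spanning both baselines ",
         "and the transition", call. = FALSE)
  rt <- .rt(cond)

  nat <- .edge_line(x, y, side = "head")
  unf <- .edge_line(x, y, side = "tail")
  rng <- range(x)
  dm_q <- rng[1L] + c(0.2, 0.35, 0.5, 0.65, 0.8) * diff(rng)
  starts <- c(
    lapply(dm_q, function(dm) c(min(1.0 * dm, 29), 1.0, nat, unf)),
    lapply(dm_q[2:4], function(dm) c(min(2.5 * dm, 29), 2.5, nat, unf)))
  lower <- c(0, 1e-3, rep(-Inf, 4))
  upper <- c(30, 10, rep(Inf, 4))

  ms <- .multistart_lm(y, x, function(p, x) .sig2(p, x, rt),
                       starts, lower, upper, control,
                       jac_fit = function(p, x) .dsig2(p, x, rt))
  par <- ms$best$par

  fU <- plogis(-(par[1L] - par[2L] * x) / rt)
  dm_hat <- min(max(par[1L] / par[2L], rng[1L]), rng[2L])
  amp <- abs((par[3L] + par[4L] * dm_hat) - (par[5L] + par[6L] * dm_hat))
  .check_conditioned(diff(range(fU)), amp, ms$best$deviance,
                     length(x), 6L, y, control)

  .finish_fit("two_state", curve, cond, par,
              c("dG0", "m", "a1", "b1", "c1", "p1"),
              function(p, x) .sig2(p, x, rt),
              function(p) c(Dm = p[1L] / p[2L]),
              ms$best$deviance, ms$n_conv, length(starts), control)
}

#' @describeIn fit_unfolding Three-state chemical denaturation fit
#'   (at least 11 points).  The stability ordering
#'   \eqn{\Delta G_{NU} \ge \Delta G_{NI}} is enforced by fitting the gap
#'   \eqn{\delta = \Delta G_{NU} - \Delta G_{NI} \ge 0}; an optimum with
#'   \eqn{\delta \approx 0} is reported as a boundary solution with a
#'   warning and `flags$boundary = TRUE`.
#' @export
fit_three_state <- function(curve, cond = conditions(),
                            control = fit_control()) {
  stopifnot(inherits(curve, "denat_curve"))
  if (attr(curve, "perturbant") == "temperature")
    stop("three-state fit requires a chemical denaturation curve",
         call. = FALSE)
  x <- curve$x; y <- curve$y
  if (length(x) < 11L)
    stop("three-state fit needs at least 11 points", call. = FALSE)
  rt <- .rt(cond)

  nat <- .edge_line(x, y, side = "head")
  unf <- .edge_line(x, y, side = "tail")
  rng <- range(x)
  mid <- x > rng[1L] + diff(rng) / 3 & x < rng[2L] - diff(rng) / 3
  imed <- if (any(mid)) median(y[mid]) else median(y)
  int <- c(imed, 0)  # flat intermediate baseline at the mid-plateau level

  ## fitted parameterization: (dG_NI0, m_NI, delta, m_NU, 6 baselines)
  qpairs <- list(c(.2, .5), c(.2, .65), c(.35, .65), c(.35, .8),
                 c(.5, .8), c(.2, .8), c(.35, .5), c(.5, .65))
  starts <- lapply(qpairs, function(q) {
    dm1 <- rng[1L] + q[1L] * diff(rng)
    dm2 <- rng[1L] + q[2L] * diff(rng)
    c(min(dm1, 29), 1.0, max(0.1, dm2 - dm1), 1.0, nat, int, unf)
  })
  ## two intermediate-suppressed starts (m_NI at its floor, delta = 0,
  ## intermediate baseline on the native one): the degenerate two-state
  ## limit reachable under dG_NU0 >= dG_NI0
  for (q in c(0.35, 0.65)) {
    dm <- rng[1L] + q * diff(rng)
    starts <- c(starts, list(c(min(dm, 29), 1e-3, 0, 1.0, nat, nat, unf)))
  }
  lower <- c(0, 1e-3, 0, 1e-3, rep(-Inf, 6))
  upper <- c(30, 10, 30, 10, rep(Inf, 6))

  fitfn <- function(p, x)
    .sig3(c(p[1L], p[2L], p[1L] + p[3L], p[4L], p[5:10]), x, rt)
  ## chain rule into the (dG_NI, m_NI, delta, m_NU, ...) parameterization
  jacfn <- function(p, x) {
    J <- .dsig3(c(p[1L], p[2L], p[1L] + p[3L], p[4L], p[5:10]), x, rt)
    cbind(J[, 1L] + J[, 3L], J[, 2L], J[, 3L], J[, 4L], J[, 5:10])
  }
  ms <- .multistart_lm(y, x, fitfn, starts, lower, upper, control,
                       jac_fit = jacfn,
                       tie_key = function(p) p[1L] + p[3L])  # dG_NU0
  pf <- ms$best$par
  par <- c(pf[1L], pf[2L], pf[1L] + pf[3L], pf[4L], pf[5:10])

  flags <- list()
  if (pf[3L] < 1e-6) {
    flags$boundary <- TRUE
    warning("ordering constraint dG_NU0 >= dG_NI0 is active: ",
            "boundary solution (dG_NU0 = dG_NI0)", call. = FALSE)
  }

  f <- .softmax(cbind(0, -(par[1L] - par[2L] * x) / rt,
                      -(par[3L] - par[4L] * x) / rt))
  ## spanned if the protein leaves the native state (I and U both count:
  ## either transition may carry the signal change)
  ycross <- vapply(seq_along(x), function(i)
    sum(c(par[5L] + par[6L] * x[i], par[7L] + par[8L] * x[i],
          par[9L] + par[10L] * x[i]) * f[i, ]), numeric(1))
  amp <- abs((par[5L] + par[6L] * rng[1L]) - ycross[length(ycross)])
  .check_conditioned(diff(range(1 - f[, 1L])), amp, ms$best$deviance,
                     length(x), 10L, y, control)

  .finish_fit("three_state", curve, cond, par,
              c("dG_NI0", "m_NI", "dG_NU0", "m_NU",
                "a1", "b1", "c1", "p1", "e1", "g1"),
              function(p, x) .sig3(p, x, rt),
              function(p) c(Dm_NI = p[1L] / p[2L], Dm_NU = p[3L] / p[4L],
                            dG_IU0 = p[3L] - p[1L], m_IU = p[4L] - p[2L]),
              ms$best$deviance, ms$n_conv, length(starts), control,
              flags = flags)
}

#' @describeIn fit_unfolding van't Hoff two-state fit of a thermal melt
#'   (temperature curve in kelvin spanning both baselines).  `Tm` is
#'   reported in kelvin among the coefficients and in degC among the
#'   derived values; a fitted `Tm` outside the scanned range is flagged.
#' @export
fit_thermal <- function(curve, control = fit_control()) {
  stopifnot(inherits(curve, "denat_curve"))
  if (attr(curve, "perturbant") != "temperature")
    stop("thermal fit requires a temperature curve", call. = FALSE)
  x <- curve$x; y <- curve$y
  if (length(x) < 7L)
    stop("thermal fit needs at least 7 points", call. = FALSE)

  nat <- .edge_line(x, y, side = "head")
  unf <- .edge_line(x, y, side = "tail")
  rng <- range(x)
  tm_q <- rng[1L] + c(0.2, 0.35, 0.5, 0.65, 0.8) * diff(rng)
  starts <- c(lapply(tm_q, function(tm) c(tm, 60, nat, unf)),
              lapply(tm_q[2:4], function(tm) c(tm, 150, nat, unf)))
  lower <- c(rng[1L] - 100, 1, rep(-Inf, 4))
  upper <- c(rng[2L] + 100, 1000, rep(Inf, 4))

  ms <- .multistart_lm(y, x, .sigT, starts, lower, upper, control,
                       jac_fit = function(p, x) .dsigT(p, x))
  par <- ms$best$par

  fU <- plogis(-(par[2L] * (1 - x / par[1L])) / (1.987e-3 * x))
  tm_hat <- min(max(par[1L], rng[1L]), rng[2L])
  amp <- abs((par[3L] + par[4L] * tm_hat) - (par[5L] + par[6L] * tm_hat))
  .check_conditioned(diff(range(fU)), amp, ms$best$deviance,
                     length(x), 6L, y, control)

  flags <- list()
  if (par[1L] < rng[1L] || par[1L] > rng[2L]) {
    flags$tm_out_of_range <- TRUE
    warning("fitted Tm lies outside the scanned temperature range",
            call. = FALSE)
  }

  .finish_fit("thermal", curve, NULL, par,
              c("Tm", "dH_vH", "a1", "b1", "c1", "p1"),
              .sigT,
              function(p) c(Tm_C = p[1L] - 273.15),
              ms$best$deviance, ms$n_conv, length(starts), control,
              flags = flags)
}

#' Extract the fitted parameter set as an `unfold_params` object
#'
#' @param fit An `unfold_fit`.
#' @return A [two_state_params()], [three_state_params()] or
#'   [thermal_params()] object holding the point estimates.
#' @export
fitted_params <- function(fit) {
  stopifnot(inherits(fit, "unfold_fit"))
  cf <- as.list(fit$coefficients)
  switch(fit$model,
         two_state = two_state_params(cf$dG0, cf$m, cf$a1, cf$b1,
                                      cf$c1, cf$p1),
         three_state = three_state_params(cf$dG_NI0, cf$m_NI, cf$dG_NU0,
                                          cf$m_NU, cf$a1, cf$b1, cf$c1,
                                          cf$p1, cf$e1, cf$g1),
         thermal = thermal_params(cf$Tm, cf$dH_vH, cf$a1, cf$b1,
                                  cf$c1, cf$p1))
}
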