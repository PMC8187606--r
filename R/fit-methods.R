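#' @export
print.unfold_fit <- function(x, ...) {
  cat(sprintf("Equilibrium unfolding fit: %s model, %d points\n",
              x$model, x$n))
  est <- sprintf("%.4g (%.2g)", x$coefficients, x$stderr)
  names(est) <- names(x$coefficients)
  print(noquote(est))
  d <- sprintf("%.4g (%.2g)", x$derived, x$derived_se)
  names(d) <- names(x$derived)
  cat("derived:\n"); print(noquote(d))
  cat(sprintf("SSR = %.4g, sigma = %.4g, AICc = %.4g, starts converged %d/%d\n",
              x$ssr, x$sigma, x$aicc, x$n_starts_converged, x$n_starts))
  if (length(x$flags))
    cat("flags:", paste(names(x$flags), collapse = ", "), "\n")
  invisible(x)
}

#' Summarize an equilibrium unfolding fit
#'
#' @param object An `unfold_fit`.
#' @param ... Unused.
#' @return A `summary.unfold_fit` object: coefficient table (estimate,
#'   std. error), derived-quantity table, and goodness-of-fit scalars.
#' @export
summary.unfold_fit <- function(object, ...) {
  ct <- cbind(Estimate = object$coefficients,
              `Std. Error` = object$stderr)
  dt <- cbind(Estimate = object$derived,
              `Std. Error` = object$derived_se)
  structure(list(model = object$model, coefficients = ct, derived = dt,
                 ssr = object$ssr, sigma = object$sigma,
                 aicc = object$aicc, n = object$n,
                 n_starts_converged = object$n_starts_converged,
                 flags = object$flags),
            class = "summary.unfold_fit")
}

#' @export
print.summary.unfold_fit <- function(x, ...) {
  cat(sprintf("Model: %s (n = %d)\n\nCoefficients:\n", x$model, x$n))
  print(round(x$coefficients, 5))
  cat("\nDerived quantities:\n")
  print(round(x$derived, 5))
  cat(sprintf("\nSSR %.5g on %d points; residual sigma %.4g; AICc %.5g\n",
              x$ssr, x$n, x$sigma, x$aicc))
  invisible(x)
}

#' @export
coef.unfold_fit <- function(object, ...) object$coefficients

#' @export
vcov.unfold_fit <- function(object, ...) object$vcov

#' @export
residuals.unfold_fit <- function(object, ...) object$residuals

#' @export
fitted.unfold_fit <- function(object, ...) object$fitted

#' Predict the model signal at new perturbant values
#'
#' @param object An `unfold_fit`.
#' @param newdata Numeric vector of perturbant values, or a data frame with
#'   column `x`.  Defaults to the fitted curve's x values.
#' @param ... Unused.
#' @return Numeric vector of predicted signals.
#' @export
predict.unfold_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$curve$x
       else if (is.data.frame(newdata)) newdata$x
       else newdata
  stopifnot(is.numeric(x))
  p <- object$coefficients
  switch(object$model,
         two_state = .sig2(p, x, .rt(object$conditions)),
         three_state = .sig3(p, x, .rt(object$conditions)),
         thermal = .sigT(p, x))
}

#' @export
plot.unfold_fit <- function(x, ...) {
  cv <- x$curve
  grid <- seq(min(cv$x), max(cv$x), length.out = 200)
  plot(cv$x, cv$y,
       xlab = if (x$model == "thermal") "temperature (K)"
              else "denaturant (M)",
       ylab = attr(cv, "probe"), ...)
  lines(grid, predict(x, grid), col = "red")
  invisible(x)
}

#' Simulate replicate curves from a fitted model
#'
#' Draws `nsim` synthetic replicates of the fitted curve: the model signal
#' at the original x values plus Gaussian noise with the fit's residual
#' standard deviation.
#'
#' @param object An `unfold_fit`.
#' @param nsim Number of replicates.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @param ... Unused.
#' @return A list of [denaturation_curve()] objects.
#' @export
simulate.unfold_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  cv <- object$curve
  mu <- predict(object)
  lapply(seq_len(nsim), function(i) {
    denaturation_curve(cv$x, mu + rnorm(length(mu), 0, object$sigma),
                       perturbant = attr(cv, "perturbant"),
                       probe = attr(cv, "probe"),
                       replicate_id = paste0("sim", i))
  })
}

## RNG bookkeeping so seeded helpers do not disturb the caller's stream
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
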