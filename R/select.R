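#' Choose between the two-state and three-state chemical models
#'
#' Fits both models to the same curve and recommends the one with the
#' lower corrected Akaike score (AICc); a difference below 2 is reported
#' as ambiguous.  Both fits are returned so the comparison is auditable.
#'
#' @param curve A chemical [denaturation_curve()] with at least 11 points
#'   (the three-state precondition).
#' @param cond A [conditions()] object.
#' @param control A [fit_control()] list.
#' @return An object of class `model_selection`: list with `two_state`,
#'   `three_state` (the `unfold_fit`s), `aicc` (named vector),
#'   `recommended` (`"two_state"`/`"three_state"`), `delta_aicc`,
#'   `ambiguous`.
#' @examples
#' truth <- two_state_params(3.44, 0.8)
#' x <- seq(0, 8, 0.25)
#' cv <- denaturation_curve(x, two_state_signal(truth, x) +
#'                          rnorm(length(x), 0, 0.01), "urea", "cd222")
#' @export
select_model <- function(curve, cond = conditions(),
                         control = fit_control()) {
  stopifnot(inherits(curve, "denat_curve"))
  if (nrow(curve) < 11L)
    stop("insufficient points for three-state comparison (need >= 11)",
         call. = FALSE)
  f2 <- fit_two_state(curve, cond, control)
  f3 <- suppressWarnings(fit_three_state(curve, cond, control))
  aicc <- c(two_state = f2$aicc, three_state = f3$aicc)
  rec <- names(aicc)[which.min(aicc)]
  structure(list(two_state = f2, three_state = f3, aicc = aicc,
                 recommended = rec,
                 delta_aicc = abs(diff(aicc)),
                 ambiguous = abs(diff(aicc)) < 2),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Model selection by AICc:\n")
  print(round(x$aicc, 3))
  cat(sprintf("recommended: %s (delta AICc = %.3g%s)\n", x$recommended,
              x$delta_aicc, if (x$ambiguous) ", ambiguous" else ""))
  invisible(x)
}

#' Aggregate replicate fits into mean +/- SEM parameter estimates
#'
#' Replicate experiments are fitted independently; this summarizes each
#' parameter (and each derived quantity) as the mean across replicates
#' with the standard error of the mean, SEM = SD / sqrt(n) — the
#' convention of stability tables reporting "mean of three measurements
#' along with the standard error of the mean".
#'
#' @param fits A list of at least one `unfold_fit`, all of the same model.
#' @return An object of class `replicate_summary`: `model`,
#'   `n_replicates`, `mean`, `sem` (named vectors over parameters and
#'   derived quantities).  With a single fit the SEM is `NA` and flagged
#'   unavailable.
#' @examples
#' # aggregate_replicates(list(fit1, fit2, fit3))
#' @export
aggregate_replicates <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "unfold_fit")))
  models <- vapply(fits, `[[`, character(1), "model")
  if (length(unique(models)) != 1L)
    stop("all replicate fits must use the same model; got: ",
         paste(unique(models), collapse = ", "), call. = FALSE)
  mat <- do.call(rbind, lapply(fits, function(f) c(coef(f), f$derived)))
  n <- nrow(mat)
  mu <- colMeans(mat)
  sem <- if (n >= 2L) apply(mat, 2L, sd) / sqrt(n)
         else setNames(rep(NA_real_, ncol(mat)), colnames(mat))
  structure(list(model = models[1L], n_replicates = n, mean = mu,
                 sem = sem, sem_available = n >= 2L),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("Replicate summary (%s, n = %d):\n", x$model, x$n_replicates))
  tab <- cbind(mean = x$mean, SEM = x$sem)
  print(round(tab, 4))
  if (!x$sem_available)
    cat("SEM unavailable: a single replicate was supplied\n")
  invisible(x)
}
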