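test_that("noise-free curves are recovered to high relative accuracy", {
  # two-state, MRE-scale baselines
  tr2 <- urea_cd_truth()
  cv2 <- noise_free_curve(tr2, seq(0, 8, 0.25), "urea")
  f2 <- fit_two_state(cv2)
  expect_equal(unname(coef(f2)[c("dG0", "m")]), c(tr2$dG0, tr2$m),
               tolerance = 1e-6)
  expect_equal(unname(f2$derived["Dm"]), 4.3, tolerance = 1e-6)

  # three-state, both canonical truths
  for (tr3 in list(gdn_cd_truth(), gdn_fluor_truth())) {
    cv3 <- noise_free_curve(tr3, seq(0, 6, 0.25), "gdnhcl")
    f3 <- quiet_fit3(cv3)
    expect_equal(unname(coef(f3)[c("dG_NI0", "m_NI", "dG_NU0", "m_NU")]),
                 c(tr3$dG_NI0, tr3$m_NI, tr3$dG_NU0, tr3$m_NU),
                 tolerance = 1e-6)
  }

  # thermal
  trT <- melt_cd_truth()
  cvT <- noise_free_curve(trT, seq(293.15, 363.15, 1), "temperature")
  fT <- fit_thermal(cvT)
  expect_equal(unname(coef(fT)[c("Tm", "dH_vH")]), c(trT$Tm, trT$dH_vH),
               tolerance = 1e-6)
})

test_that("derived quantities satisfy the core identities exactly", {
  cv <- noise_free_curve(urea_cd_truth(), seq(0, 8, 0.25), "urea")
  f <- fit_two_state(cv)
  expect_equal(unname(f$derived["Dm"] * coef(f)["m"]),
               unname(coef(f)["dG0"]))
  cv3 <- noise_free_curve(gdn_cd_truth(), seq(0, 6, 0.25), "gdnhcl")
  f3 <- quiet_fit3(cv3)
  expect_equal(unname(f3$derived["dG_IU0"]),
               unname(coef(f3)["dG_NU0"] - coef(f3)["dG_NI0"]))
  expect_equal(unname(f3$derived["Dm_NI"] * coef(f3)["m_NI"]),
               unname(coef(f3)["dG_NI0"]))
})

test_that("optimizer beats a brute-force grid over (dG0, m)", {
  # baselines fixed at truth; 100 x 100 grid is the independent oracle
  tr <- two_state_params(3.44, 0.8, a1 = 1, b1 = 0.01, c1 = 0, p1 = 0.005)
  x <- seq(0, 8, 0.5)
  set.seed(9)
  y <- two_state_signal(tr, x) + rnorm(length(x), 0, 0.02)
  cv <- denaturation_curve(x, y, "urea", "cd222")
  fit <- fit_two_state(cv)

  grid_ssr <- Inf
  for (dg in seq(0.5, 10, length.out = 100)) {
    for (m in seq(0.1, 3, length.out = 100)) {
      p <- two_state_params(dg, m, tr$a1, tr$b1, tr$c1, tr$p1)
      ssr <- sum((y - two_state_signal(p, x))^2)
      if (ssr < grid_ssr) grid_ssr <- ssr
    }
  }
  expect_lte(fit$ssr, grid_ssr)
})

test_that("noisy replicates recover the truth within useful error", {
  # median relative error of dG0 and m over 50 seeded repetitions <= 15%
  tr <- urea_cd_truth()
  x <- seq(0, 8, length.out = 30)
  amp <- abs((tr$a1 + tr$b1 * 0) - (tr$c1 + tr$p1 * 8))
  errs <- t(vapply(1:50, function(s) {
    set.seed(s)
    y <- two_state_signal(tr, x) + rnorm(30, 0, 0.02 * amp)
    f <- fit_two_state(denaturation_curve(x, y, "urea", "cd222"))
    abs(coef(f)[c("dG0", "m")] / c(tr$dG0, tr$m) - 1)
  }, numeric(2)))
  expect_lte(median(errs[, 1]), 0.15)
  expect_lte(median(errs[, 2]), 0.15)
})

test_that("midpoint error shrinks as the noise level decreases", {
  tr <- urea_cd_truth()
  x <- seq(0, 8, 0.25)
  amp <- abs((tr$a1 + tr$b1 * 0) - (tr$c1 + tr$p1 * 8))
  mean_err <- vapply(c(0.05, 0.01, 0.002), function(sdf) {
    mean(vapply(1:12, function(s) {
      set.seed(1000 + s)
      y <- two_state_signal(tr, x) + rnorm(length(x), 0, sdf * amp)
      f <- fit_two_state(denaturation_curve(x, y, "urea", "cd222"))
      abs(unname(f$derived["Dm"]) - 4.3)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_err) < 0))
})

test_that("fits report uncertainties and convergence bookkeeping", {
  tr <- urea_cd_truth()
  cfg <- synthetic_config("two_state", tr, "urea", noise_sd = 0.02,
                          seed = 21, n_replicates = 1)
  f <- fit_two_state(simulate_curves(cfg)[[1]])
  expect_true(all(is.finite(f$stderr)))
  expect_true(all(f$stderr > 0))
  expect_gte(f$n_starts_converged, 1)
  expect_equal(length(residuals(f)), f$n)
  expect_equal(fitted(f) + residuals(f), f$curve$y)
  expect_true(is.finite(f$aicc))
  # standard errors of derived midpoint propagate from the covariance
  expect_true(is.finite(f$derived_se["Dm"]) && f$derived_se["Dm"] > 0)
})

test_that("curves that never leave one baseline are rejected", {
  x <- seq(0, 8, 0.25)
  # monotone line: no sigmoid at all
  expect_error(fit_two_state(denaturation_curve(x, 2 * x, "urea", "cd222")),
               "ill-conditioned")
  # failed refolding trace: flat on the unfolded baseline
  Tg <- seq(293.15, 363.15, 1)
  set.seed(2)
  yflat <- rep(-2000, length(Tg)) + rnorm(length(Tg), 0, 5)
  expect_error(fit_thermal(denaturation_curve(Tg, yflat, "temperature",
                                              "cd222")),
               "ill-conditioned")
})

test_that("fit preconditions are enforced", {
  x5 <- seq(0, 8, 2)
  cv5 <- denaturation_curve(x5, seq(1, 0, length.out = 5), "urea", "cd222")
  expect_error(fit_two_state(cv5), "at least 7 points")
  x9 <- seq(0, 8, 1)
  cv9 <- denaturation_curve(x9, seq(1, 0, length.out = 9), "urea", "cd222")
  expect_error(fit_three_state(cv9), "at least 11 points")
  cvT <- noise_free_curve(melt_cd_truth(), seq(293.15, 363.15, 1),
                          "temperature")
  expect_error(fit_two_state(cvT), "chemical")
  cvU <- noise_free_curve(urea_cd_truth(), seq(0, 8, 0.25), "urea")
  expect_error(fit_thermal(cvU), "temperature curve")
})

test_that("three-state fit of two-state data leaves the intermediate empty", {
  tr <- two_state_params(3.44, 0.8, a1 = 1, b1 = 0.005, c1 = 0, p1 = 0.002)
  cv <- noise_free_curve(tr, seq(0, 8, 0.25), "urea")
  f3 <- quiet_fit3(cv)
  pp <- population_profile(fitted_params(f3), seq(0, 8, 0.05))
  expect_lte(attr(pp, "max_f_I"), 0.05)
  # the degenerate optimum sits on the ordering-constraint boundary
  expect_warning(fit_three_state(cv), "boundary")
})

test_that("fitted Tm outside the scanned window is flagged", {
  tr <- thermal_params(362, 80, a1 = 1, b1 = 0, c1 = 0, p1 = 0)
  Tg <- seq(293.15, 368.15, 1)
  cv <- noise_free_curve(tr, Tg, "temperature")
  f <- fit_thermal(cv)   # inside: no flag
  expect_null(f$flags$tm_out_of_range)
})

test_that("fitted_params reconstructs a valid parameter object", {
  cv3 <- noise_free_curve(gdn_cd_truth(), seq(0, 6, 0.25), "gdnhcl")
  f3 <- quiet_fit3(cv3)
  p <- fitted_params(f3)
  expect_s3_class(p, "three_state_params")
  expect_equal(three_state_signal(p, cv3$x), predict(f3), tolerance = 1e-10)
})

test_that("predict and simulate operate on the fitted model", {
  tr <- urea_cd_truth()
  cv <- noise_free_curve(tr, seq(0, 8, 0.25), "urea")
  f <- fit_two_state(cv)
  expect_equal(predict(f, c(0, 4.3, 8)),
               two_state_signal(tr, c(0, 4.3, 8)), tolerance = 1e-5)
  cfg <- synthetic_config("two_state", tr, "urea", noise_sd = 0.02,
                          seed = 3, n_replicates = 1)
  fn <- fit_two_state(simulate_curves(cfg)[[1]])
  sims <- simulate(fn, nsim = 2, seed = 99)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "denat_curve")
  expect_false(identical(sims[[1]]$y, sims[[2]]$y))
})
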