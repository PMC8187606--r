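test_that("linear extrapolation of the unfolding free energy", {
  expect_equal(gibbs_at(4.32, 0.8, 0), 4.32)
  expect_equal(gibbs_at(4.7, 1.7, 2.25), 4.7 - 1.7 * 2.25)  # 0.875
  expect_equal(gibbs_at(7.7, 2.2, 0), 7.7)  # zero-denaturant identity
  expect_error(gibbs_at(4, 1, -0.1), "must be >= 0")
})

test_that("midpoint is dG0/m and rejects m = 0", {
  expect_equal(midpoint(1.5, 0.9), 1.5 / 0.9)
  expect_equal(round(midpoint(1.5, 0.9), 1), 1.7)
  expect_equal(round(midpoint(4.3, 1.4), 1), 3.1)
  expect_equal(midpoint(0, 2), 0)
  expect_error(midpoint(1, 0), "nonzero")
})

test_that("two-state fractions: midpoint exactness, water value, limits", {
  p <- two_state_params(4.32, 0.8)
  # at c = Dm the equilibrium constant is 1: f_U = 1/2 exactly
  expect_equal(two_state_fractions(p, midpoint(p$dG0, p$m))$f_U, 0.5,
               tolerance = 1e-12)
  # water value against plain exp arithmetic
  k0 <- exp(-4.32 / RT25)
  expect_equal(two_state_fractions(p, 0)$f_U, k0 / (1 + k0),
               tolerance = 1e-12)
  expect_equal(two_state_fractions(p, 0)$f_U, 6.80e-4, tolerance = 1e-2)
  # saturation, no overflow
  expect_equal(two_state_fractions(p, 1e6)$f_U, 1)
  expect_equal(two_state_fractions(two_state_params(500, 1), 0)$f_U, 0)
})

test_that("two-state signal composes baselines with fractions", {
  p <- two_state_params(4.32, 0.8, a1 = 1, b1 = 0, c1 = 0, p1 = 0)
  expect_equal(two_state_signal(p, midpoint(4.32, 0.8)), 0.5,
               tolerance = 1e-12)
  k0 <- exp(-4.32 / RT25)
  expect_equal(two_state_signal(p, 0), 1 - k0 / (1 + k0), tolerance = 1e-12)
  # sloped baselines against brute-force composition
  p2 <- two_state_params(3.4, 0.9, a1 = -16, b1 = 0.3, c1 = -2, p1 = -0.1)
  c <- seq(0, 8, 0.5)
  k <- exp(-(3.4 - 0.9 * c) / RT25)
  fU <- k / (1 + k)
  expect_equal(two_state_signal(p2, c),
               (-16 + 0.3 * c) * (1 - fU) + (-2 - 0.1 * c) * fU,
               tolerance = 1e-12)
})

test_that("three-state fractions match the closed form and normalize", {
  p <- gdn_fluor_truth()
  f <- three_state_fractions(p, 2.25)
  o <- oracle_three_state_fractions(1.4, 0.8, 4.7, 1.7, 2.25)
  expect_equal(f$f_N, o$f_N, tolerance = 1e-12)
  expect_equal(f$f_I, o$f_I, tolerance = 1e-12)
  expect_equal(f$f_U, o$f_U, tolerance = 1e-12)
  # frozen values: ~60% intermediate at 2.25 M GdnHCl
  expect_equal(f$f_N, 0.313, tolerance = 2e-3)
  expect_equal(f$f_I, 0.615, tolerance = 2e-3)
  expect_equal(f$f_U, 0.072, tolerance = 2e-2)
  # water: residual intermediate population of the fluorescence parameters
  expect_equal(three_state_fractions(p, 0)$f_I, 0.086, tolerance = 1e-2)
  # fully native limit: f_N saturates to 1 in floating point
  ph <- three_state_params(80, 1, 90, 1.5)
  fh <- three_state_fractions(ph, 0)
  expect_identical(fh$f_N, 1)
  expect_lt(fh$f_I + fh$f_U, 1e-50)
})

test_that("fraction normalization holds to 1e-12 over random parameters", {
  set.seed(42)
  for (i in 1:50) {
    dgni <- runif(1, 0.2, 8); mni <- runif(1, 0.2, 3)
    p <- three_state_params(dgni, mni, dgni + runif(1, 0, 8),
                            mni + runif(1, 0.05, 3))
    f <- three_state_fractions(p, seq(0, 10, 0.5))
    expect_true(all(abs(f$f_N + f$f_I + f$f_U - 1) < 1e-12))
    expect_true(all(f$f_N >= 0 & f$f_I >= 0 & f$f_U >= 0))
  }
  # extreme arguments saturate without NaN and still normalize exactly
  pe <- three_state_params(25, 9, 30, 10)
  fe <- three_state_fractions(pe, c(0, 1e5))
  expect_equal(fe$f_N + fe$f_I + fe$f_U, c(1, 1))
})

test_that("three-state signal: composition and two-state degenerate limit", {
  p <- gdn_fluor_truth()
  pf <- three_state_params(1.4, 0.8, 4.7, 1.7,
                           a1 = 1, b1 = 0, c1 = 0.6, p1 = 0, e1 = 0, g1 = 0)
  o <- oracle_three_state_fractions(1.4, 0.8, 4.7, 1.7, 2.25)
  expect_equal(three_state_signal(pf, 2.25),
               o$f_N * 1 + o$f_I * 0.6, tolerance = 1e-12)
  expect_equal(three_state_signal(pf, 2.25), 0.682, tolerance = 1e-3)
  # strongly native: signal is the native baseline
  pn <- three_state_params(40, 1, 50, 1.5, a1 = 1, b1 = 0)
  expect_equal(three_state_signal(pn, 0), 1, tolerance = 1e-12)
  # with the intermediate never populated the model collapses to two-state
  # (the N-U transition must stay steeper so dG_NU0 >= dG_NI0 holds)
  c <- seq(0, 8, 0.1)
  p3 <- three_state_params(50, 0.5, 54, 10,
                           a1 = -16, b1 = 0.3, c1 = 5, p1 = 1,
                           e1 = -2, g1 = -0.1)
  p2 <- two_state_params(54, 10, a1 = -16, b1 = 0.3, c1 = -2, p1 = -0.1)
  expect_equal(three_state_signal(p3, c), two_state_signal(p2, c),
               tolerance = 1e-9)
})

test_that("f_U is non-decreasing in denaturant for positive m", {
  set.seed(7)
  grid <- seq(0, 10, 0.02)
  for (i in 1:20) {
    p <- two_state_params(runif(1, 0.5, 10), runif(1, 0.1, 3))
    expect_true(all(diff(two_state_fractions(p, grid)$f_U) >= 0))
  }
  for (i in 1:20) {
    dgni <- runif(1, 0.3, 6); mni <- runif(1, 0.2, 2)
    p <- three_state_params(dgni, mni, dgni + runif(1, 0.5, 6),
                            mni + runif(1, 0.1, 2))
    expect_true(all(diff(three_state_fractions(p, grid)$f_U) > -1e-14))
  }
})

test_that("derived three-state quantities satisfy the additivity identities", {
  set.seed(11)
  for (i in 1:20) {
    dgni <- runif(1, 0.5, 6); mni <- runif(1, 0.3, 2)
    dgnu <- dgni + runif(1, 0, 6); mnu <- mni + runif(1, 0.05, 2)
    d <- derived_params(three_state_params(dgni, mni, dgnu, mnu))
    expect_equal(unname(d["dG_IU0"]), dgnu - dgni)
    expect_equal(unname(d["m_IU"]), mnu - mni)
    expect_equal(unname(d["Dm_NI"]), dgni / mni)
    expect_equal(unname(d["Dm_NU"]), dgnu / mnu)
  }
  expect_error(three_state_params(5, 1, 4, 1.5), "dG_NU0 must be >=")
})

test_that("thermal model: midpoint exactness, limits, closed form", {
  p <- thermal_params(316.45, 70, a1 = 1, b1 = 0, c1 = 0, p1 = 0)
  expect_equal(thermal_fraction_unfolded(p, 316.45), 0.5, tolerance = 1e-12)
  expect_equal(thermal_signal(p, 316.45), 0.5, tolerance = 1e-12)
  # far below Tm the signal sits on the native baseline
  expect_equal(thermal_signal(p, 200), 1, tolerance = 1e-8)
  # direct evaluation of the van't Hoff expression at Tm - 10
  Tq <- 306.45
  dG <- 70 * (1 - Tq / 316.45)
  fU <- 1 / (1 + exp(dG / (1.987e-3 * Tq)))
  expect_equal(thermal_fraction_unfolded(p, Tq), fU, tolerance = 1e-12)
  expect_equal(thermal_signal(p, Tq), 1 - fU, tolerance = 1e-12)
  expect_error(thermal_params(316, -5), "dH_vH must be > 0")
})

test_that("population profile matches per-point fractions and finds argmax", {
  p <- gdn_fluor_truth()
  grid <- seq(0, 6, 0.05)
  pp <- population_profile(p, grid)
  expect_true(all(abs(pp$f_N + pp$f_I + pp$f_U - 1) < 1e-12))
  # oracle equivalence: brute-force scan over the same grid
  o <- oracle_three_state_fractions(1.4, 0.8, 4.7, 1.7, grid)
  expect_equal(pp$f_I, o$f_I, tolerance = 1e-12)
  expect_equal(attr(pp, "argmax_I"), grid[which.max(o$f_I)])
  expect_equal(attr(pp, "max_f_I"), max(o$f_I), tolerance = 1e-12)
  # single-point grid consistent with three_state_fractions
  p1 <- population_profile(p, 2.25)
  expect_equal(p1$f_I, three_state_fractions(p, 2.25)$f_I)
  # two-state input: f_I identically zero
  p2 <- population_profile(two_state_params(4.3, 1), grid)
  expect_true(all(p2$f_I == 0))
  expect_true(is.na(attr(p2, "argmax_I")))
  expect_error(population_profile(p, numeric(0)))
})

test_that("conditions handle Celsius input and reject nonphysical values", {
  expect_equal(conditions(25, celsius = TRUE)$temperature, 298.15)
  expect_equal(conditions()$R, 1.987e-3)
  expect_error(conditions(-300), "positive")
})
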