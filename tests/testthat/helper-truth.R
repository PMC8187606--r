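# canonical ground-truth parameter sets used across the suite ------------

# gas constant x 25 degC, kcal/mol
RT25 <- 1.987e-3 * 298.15

# urea two-state truth (CD probe): printed midpoint 4.3 M with m = 0.8,
# MRE-scale baselines
urea_cd_truth <- function() {
  two_state_params(dG0 = 0.8 * 4.3, m = 0.8,
                   a1 = -16000, b1 = 100, c1 = -2000, p1 = -50)
}

# GdnHCl three-state truths, flat unit-scale baselines
gdn_cd_truth <- function() {
  three_state_params(1.5, 0.9, 4.3, 1.4,
                     a1 = 1, b1 = 0, c1 = 0.55, p1 = 0, e1 = 0, g1 = 0)
}
gdn_fluor_truth <- function() {
  three_state_params(1.4, 0.8, 4.7, 1.7,
                     a1 = 1, b1 = 0.01, c1 = 1.05, p1 = 0,
                     e1 = 0.45, g1 = 0)
}

# thermal truth at the printed CD melting temperature
melt_cd_truth <- function() {
  thermal_params(Tm = 43.3 + 273.15, dH_vH = 70,
                 a1 = -16000, b1 = 10, c1 = -2000, p1 = -5)
}

# independent closed-form evaluation of the three-state fractions (plain
# exp arithmetic; deliberately not the package's softmax path)
oracle_three_state_fractions <- function(dG_NI0, m_NI, dG_NU0, m_NU, c,
                                         rt = RT25) {
  kNI <- exp(-(dG_NI0 - m_NI * c) / rt)
  kNU <- exp(-(dG_NU0 - m_NU * c) / rt)
  d <- 1 + kNI + kNU
  list(f_N = 1 / d, f_I = kNI / d, f_U = kNU / d)
}

# noise-free curve from any truth
noise_free_curve <- function(truth, x, perturbant, probe = "cd222") {
  y <- if (inherits(truth, "two_state_params")) {
    two_state_signal(truth, x)
  } else if (inherits(truth, "three_state_params")) {
    three_state_signal(truth, x)
  } else {
    thermal_signal(truth, x)
  }
  denaturation_curve(x, y, perturbant = perturbant, probe = probe)
}

quiet_fit3 <- function(...) suppressWarnings(fit_three_state(...))
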