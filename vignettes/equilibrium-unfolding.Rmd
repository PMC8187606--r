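---
title: "Equilibrium unfolding analysis with lemfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equilibrium unfolding analysis with lemfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lemfit)
```

## The models

`lemfit` analyzes equilibrium unfolding experiments in which a protein is
driven from its native state N to its unfolded state U by a chemical
denaturant (urea or guanidine hydrochloride) or by temperature, while a
spectroscopic probe — mean residue ellipticity at 222 nm (secondary
structure) or intrinsic tryptophan fluorescence (tertiary structure) —
reports on the population of each state.

**Two-state chemical unfolding.** Under the linear extrapolation method
(LEM) the unfolding free energy varies linearly with denaturant
concentration $c$:

$$\Delta G_{NU}(c) = \Delta G_{NU}^{H_2O} - m_{NU}\,c ,$$

where $\Delta G_{NU}^{H_2O}$ (kcal/mol) is the stability in water and the
$m$-value (kcal mol$^{-1}$ M$^{-1}$) measures the cooperativity of the
transition and tracks the surface area newly exposed on unfolding.  With
$K_{NU} = e^{-\Delta G_{NU}(c)/RT}$, the unfolded fraction is
$f_U = K_{NU}/(1+K_{NU})$ and the observed signal is

$$S_{obs}(c) = S_N(c)\,f_N(c) + S_U(c)\,f_U(c),$$

with baselines linear in denaturant, $S_N = a_1 + b_1 c$ and
$S_U = c_1 + p_1 c$.  The transition midpoint is
$D_m = \Delta G^{H_2O}/m$, the concentration at which half the protein is
unfolded.

**Three-state chemical unfolding.** When an equilibrium intermediate I is
populated (N $\rightleftharpoons$ I $\rightleftharpoons$ U), two linear
free energies $\Delta G_{NI}(c)$ and $\Delta G_{NU}(c)$, both measured
from the native state, define the species fractions

$$f_N = \frac{1}{1+K_{NI}+K_{NU}},\qquad
  f_I = \frac{K_{NI}}{1+K_{NI}+K_{NU}},\qquad
  f_U = \frac{K_{NU}}{1+K_{NI}+K_{NU}},$$

and the signal adds a linear intermediate baseline.  The
intermediate-to-unfolded step is derived:
$\Delta G_{IU}^{H_2O} = \Delta G_{NU}^{H_2O} - \Delta G_{NI}^{H_2O}$ and
$m_{IU} = m_{NU} - m_{NI}$.  The package enforces
$\Delta G_{NU}^{H_2O} \ge \Delta G_{NI}^{H_2O}$ at the type boundary:
otherwise the intermediate can never be the dominant species between the
transitions and the three-state scheme loses its meaning.

A useful closed-form fact: the intermediate population is maximal at the
concentration where $K_{NU} = m_{NI}/(m_{NU}-m_{NI})$.  For shallow
$m$-values this maximum can sit noticeably *above* the concentration at
which the intermediate first dominates, and the maximal $f_I$ computed
from a fitted parameter set need not coincide with a plateau read off a
population figure by eye.  `population_profile()` therefore reports both
the full profile and the grid argmax, and derived midpoints are always
recomputed from the parameters rather than copied from any table.

**Thermal melts.** A single melt cannot identify the heat-capacity
change, so the package uses the van't Hoff two-state model with
$\Delta C_p = 0$:

$$\Delta G(T) = \Delta H_{vH}\left(1 - \frac{T}{T_m}\right),$$

with baselines linear in temperature.  $T_m$ is the temperature of
half-unfolding and $\Delta H_{vH}$ controls the sharpness of the
transition.  Neglecting $\Delta C_p$ biases extrapolations far from
$T_m$, but $T_m$ itself — the quantity of interest here — is insensitive
to it.

## Conventions and defaults

* Gas constant $R = 1.987\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$.
* Chemical denaturation analyses default to $T = 298.15$ K (25 °C), the
  incubation temperature of the usual equilibrium protocol;
  `conditions()` accepts Celsius.
* Temperatures are kelvin internally; melt interfaces accept and report
  Celsius (`Tm_C` among the derived quantities).
* Mean residue ellipticity uses the molar-concentration convention,
  $MRE = \theta_{mdeg} / (10\,l\,C\,N_{res})$, the dominant convention
  for values quoted in deg cm$^2$ dmol$^{-1}$.  If a lab's convention
  uses mass concentration instead, convert before calling
  `ellipticity_to_mre()`.
* Relative fluorescence at 340 nm subtracts the value at the highest
  denaturant concentration, so the fully denatured condition reads zero.
* A280 extinction coefficients use the Pace additive coefficients
  (5500 Trp / 1490 Tyr / 125 cystine, M$^{-1}$cm$^{-1}$); cystines
  default to zero for proteins kept reduced with DTT.

## Numerical choices

**Saturation, not clipping.** Fractions are computed through the
logistic function (two-state, thermal) and a max-shifted softmax
(three-state).  Both saturate smoothly to 0/1 at extreme free energies
instead of overflowing, sum to 1 at floating-point precision without any
renormalization step, and give exactly $f_U = \tfrac12$ at the midpoint.
This dominates the common alternative of clipping exponent arguments at
some large magnitude: it has no tunable threshold and no discontinuity.

**Optimizer.** Fitting is multi-start Levenberg–Marquardt
(`minpack.lm::nls.lm`) with box bounds
($\Delta G \in [0, 30]$ kcal/mol, $m \in (0, 10]$ kcal mol$^{-1}$
M$^{-1}$) and analytic Jacobians for all three models.  Near a
noise-free optimum the SSR surface is extremely flat; finite-difference
gradients stall around $10^{-6}$ relative parameter error, while the
analytic Jacobians let the optimizer polish to machine precision, which
is what the round-trip tests require.  Convergence tolerances default to
machine epsilon; an iteration-capped polish at those tolerances is
treated as converged.

**Starting values.** Baselines are initialized from straight-line fits
through the first and last three points — the minimum robust
implementation of "intercept and slope of the baselines".  The
three-state intermediate baseline starts flat at the mid-plateau median.
Transition midpoints are multi-started over quantiles of the x-range:
five two-state starts at the 20/35/50/65/80 % quantiles plus three
steeper mid-range starts, eight ordered quantile pairs for the
three-state model, plus two *intermediate-suppressed* starts ($m_{NI}$
at its floor, $\delta = \Delta G_{NU} - \Delta G_{NI} = 0$, intermediate
baseline on the native one).  The suppressed starts matter: they let the
optimizer reach the degenerate two-state limit, so that genuinely
two-state data fitted with the three-state model yields a vestigial
intermediate ($f_I \le 0.05$) at the constraint boundary rather than a
spuriously populated one.

**Tie-breaking.** Sum-of-squares ties (within $10^{-10}$) go to the
solution with the smaller total stability ($\Delta G_{NU}^{H_2O}$): the
most conservative interpretation consistent with the data.

**Ordering constraint.** $\Delta G_{NU} \ge \Delta G_{NI}$ is enforced
by fitting the gap $\delta \ge 0$; an optimum with $\delta \approx 0$ is
reported as a boundary solution with a warning and `flags$boundary`.

**Ill-conditioning.** A fit is rejected with an error when the fitted
transition is not spanned by the data: the fitted fraction of unfolded
(or non-native) protein must span at least 0.2 across the observed
range, and the native/unfolded baseline separation must exceed both
numerical noise and four residual standard deviations.  This catches
monotone drifts with no sigmoid and flat traces such as a failed
(irreversible) refolding branch sitting on the unfolded baseline.

**Uncertainties.** Per-fit standard errors come from the numerical
Jacobian at the optimum (linear approximation,
$\sigma^2 (J^\top J)^{-1}$); derived quantities ($D_m$, $\Delta G_{IU}$,
$T_m$ in °C) carry delta-method errors.  Replicates are aggregated
separately as mean ± SEM (SD/$\sqrt n$) by `aggregate_replicates()`;
the two kinds of uncertainty are deliberately never conflated, because
stability tables conventionally print the replicate SEM.

**Model choice.** `select_model()` fits both chemical models and
recommends the lower corrected Akaike score (AICc), labelling
differences below 2 as ambiguous.  Overlapping transitions with shallow
$m$-values can be statistically indistinguishable from a single
transition at realistic noise; an AICc preference for two-state on such
data is a property of the data, not a failure of the fit.  Each probe is
fitted independently; no baselines are shared across probes.

## The synthetic-experiment generator

`simulate_curves()` forward-simulates a configured truth on its grid and
adds homoscedastic Gaussian noise with standard deviation
`noise_sd` × amplitude, where the amplitude is the native-to-unfolded
baseline separation $|S_N(x_{min}) - S_U(x_{max})|$.  Scaling the noise
to the amplitude makes `noise_sd` unit-free across probes (MRE scales of
$10^4$ and unit-scale fluorescence behave identically).  Defaults follow
the standard protocols: urea 0–8 M and GdnHCl 0–6 M in 0.25 M steps,
melts 20–90 °C in 1 °C steps, three replicates, 2 % noise, seed 42.

The grid-coverage invariant requires at least three points on each
baseline: three with $f_U \le 0.05$ (no unfolded protein yet) and three
with $f_N \le 0.05$ (native protein exhausted).  The unfolded-side
condition is phrased in terms of $f_N$ rather than $f_U$ because a
three-state truth with a slow I $\rightleftharpoons$ U step can have
$f_U$ approach 1 only far beyond any practical grid while the native
baseline is long gone; for a two-state truth the two phrasings coincide.

`simulate_emission_scans()` emulates tryptophan emission spectra as the
fraction-weighted sum of per-species Gaussian bands (σ = 25 nm): native
at 340 nm, unfolded red-shifted to 360 nm (357 nm is the customary urea
endpoint, available via `unfolded_center`), and a slightly red-shifted
intermediate (345 nm) with near-native quantum yield.  The band-sum
construction — rather than a single band with interpolated center —
makes the signal at any fixed wavelength exactly linear in the species
fractions, so zero-noise scans extracted at 340 nm reproduce the
closed-form titration signal exactly (the pipeline-closure property in
the test suite), while the apparent emission maximum still red-shifts
continuously as unfolding proceeds.

The generator does *not* emulate instrument drift, photobleaching,
aggregation artifacts, heteroscedastic noise, or the irreversibility of
thermal refolding (failed refolding is represented simply as a flat
unfolded-baseline trace for failure-mode tests).  Passing
parameter-recovery tests on these simulations therefore demonstrates the
estimator's correctness under the stated error model, not robustness to
every instrumental pathology of real data.

## Validation problem sizes

The test suite validates: exact noise-free round-trips for all three
models (33/25/71-point curves, relative error below $10^{-6}$);
parameter recovery at 2 % noise with triplicates; a median relative
error below 15 % for $\Delta G^{H_2O}$ and $m$ over 50 seeded 30-point
repetitions; midpoint coverage over 50 seeds; and an independent
brute-force SSR grid ($100\times100$ over $\Delta G_0, m$ with baselines
fixed at truth) that the optimizer must never lose to.  These sizes are
the package's validation choices and run in well under a minute.

## Known limitations

* Published stability tables sometimes print $D_m$, $m$ and
  $\Delta G^{H_2O}$ values that are not mutually consistent
  ($D_m \ne \Delta G^{H_2O}/m$ at the printed precision).  The package
  always recomputes derived quantities from the fitted parameters and
  never reconciles inconsistent printed triples; comparisons against
  such tables should pick one parameterization and say so.
* No global multi-probe fitting: CD and fluorescence curves are fitted
  independently.
* No kinetics, no $\Delta C_p$ estimation, no cold denaturation, and no
  mass-action models for oligomer dissociation.
* Uncertainties are linear-approximation standard errors; bootstrap or
  posterior intervals are out of scope.

## A worked example

```{r example, eval = FALSE}
library(lemfit)

# ground truth for a marginally stable protein, urea denaturation
truth <- two_state_params(dG0 = 3.44, m = 0.8,
                          a1 = -16000, b1 = 100, c1 = -2000, p1 = -50)
cfg <- synthetic_config("two_state", truth, "urea",
                        noise_sd = 0.02, n_replicates = 3, seed = 42)
fits <- lapply(simulate_curves(cfg), fit_two_state)
aggregate_replicates(fits)

# three-state GdnHCl unfolding and its population profile
p3 <- three_state_params(1.4, 0.8, 4.7, 1.7)
prof <- population_profile(p3, seq(0, 6, 0.05))
attr(prof, "max_f_I"); attr(prof, "argmax_I")
```
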