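# lemfit

Thermodynamic analysis of protein equilibrium unfolding by the linear
extrapolation method (LEM), for experimentalists who monitor chemical
(urea, GdnHCl) or thermal denaturation by circular dichroism or intrinsic
tryptophan fluorescence and want fitted stability parameters with honest
uncertainties.

## What it computes

Under the LEM the unfolding free energy is linear in denaturant
concentration, ΔG(c) = ΔG<sup>H₂O</sup> − m·c. The package fits, by
multi-start bounded nonlinear least squares:

* the **two-state** model N ⇌ U — observed signal
  S(c) = S_N(c)·f_N + S_U(c)·f_U with f_U = K/(1+K),
  K = exp(−ΔG(c)/RT), and linear baselines; derived midpoint
  D_m = ΔG<sup>H₂O</sup>/m;
* the **three-state** model N ⇌ I ⇌ U — two linear free energies
  (ΔG_NI, m_NI) and (ΔG_NU, m_NU) with
  f_N : f_I : f_U = 1 : K_NI : K_NU, an intermediate baseline, the
  ordering constraint ΔG_NU ≥ ΔG_NI, and derived
  ΔG_IU = ΔG_NU − ΔG_NI, m_IU = m_NU − m_NI, and both midpoints;
* the **van't Hoff thermal** model — ΔG(T) = ΔH_vH(1 − T/T_m) with
  ΔC_p = 0, yielding T_m and ΔH_vH from a melt.

Around the fits it provides species-population profiles f_N/f_I/f_U over
a denaturant grid, AICc model selection, replicate aggregation
(mean ± SEM), probe-signal extraction from wavelength scans (MRE at
222 nm, relative fluorescence at 340 nm, emission-maximum wavelength with
sub-grid parabolic refinement), A280 extinction coefficients (Pace
coefficients), and a seeded synthetic-experiment generator for
parameter-recovery validation.

## Worked example

Simulate a triplicate urea titration (2 % amplitude noise) from a known
truth and recover its parameters:

```r
library(lemfit)

truth <- two_state_params(dG0 = 3.44, m = 0.8,
                          a1 = -16000, b1 = 100, c1 = -2000, p1 = -50)
cfg  <- synthetic_config("two_state", truth, "urea",
                         noise_sd = 0.02, n_replicates = 3, seed = 42)
fits <- lapply(simulate_curves(cfg), fit_two_state)
aggregate_replicates(fits)
#> Replicate summary (two_state, n = 3):
#>            mean       SEM
#> dG0      3.5790    0.1908
#> m        0.8273    0.0445
#> ...
#> Dm       4.3285    0.0834
```

The replicate mean midpoint (4.33 ± 0.08 M) recovers the truth
(D_m = 3.44/0.8 = 4.3 M) within one SEM; `dG0` and `m` are individually
noisier because they are strongly anticorrelated along the transition.

Population profile of a three-state GdnHCl unfolding (fluorescence-probe
parameters ΔG_NI = 1.4, m_NI = 0.8, ΔG_NU = 4.7, m_NU = 1.7):

```r
p3   <- three_state_params(1.4, 0.8, 4.7, 1.7)
prof <- population_profile(p3, seq(0, 6, 0.05))
#> Population profile: 121 grid points, c in [0, 6] M
#>   max f_I = 0.663 at c = 2.7 M
three_state_fractions(p3, 2.25)$f_I
#> [1] 0.615
```

At 2.25 M GdnHCl the intermediate already holds ~62 % of the population;
its true maximum under these parameters (66 %) sits at 2.7 M, where
K_NU = m_NI/(m_NU − m_NI). A280 bookkeeping:

```r
extinction_coefficient_280(protein_composition(n_trp = 6, n_tyr = 6))
#> [1] 41940
```

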