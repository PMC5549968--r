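# mwcfit

Extracting the elementary parameters of the Monod–Wyman–Changeux (MWC)
concerted allosteric model — the conformational equilibrium constant
*L* = [T]/[R] and the state affinities *K*<sub>R</sub> and
*K*<sub>T</sub> — from steady-state ligand saturation curves, with
hemoglobin–oxygen binding as the motivating system.

## The problem

A single tetramer saturation curve fitted to the traditional MWC
isotherm

```
Ȳ(p) = [α(1+α)³ + Lβ(1+β)³] / [(1+α)⁴ + L(1+β)⁴],   α = p/K_R, β = p/K_T
```

does not constrain *L*, *K*<sub>R</sub> and *K*<sub>T</sub>
individually: only the compound combinations *LK*<sub>R</sub>⁴ and
*Lc*⁴ (with *c* = *K*<sub>R</sub>/*K*<sub>T</sub>) are identifiable.
`mwcfit` implements two complementary strategies to recover the
elementary triple anyway:

1. **Three-equation system (TES).** Given reliable estimates of
   *LK*<sub>R</sub>⁴, *Lc*⁴ and the half-saturation pressure
   *P*₅₀, the half-saturation identity supplies a third equation.
   *K*<sub>T</sub> = (*LK*<sub>R</sub>⁴ / *Lc*⁴)^(1/4) follows exactly,
   and the remainder reduces to a quartic in *P*₅₀/*K*<sub>R</sub>,
   typically yielding two real roots: a physiologically sound triple
   (large *L*, small *c*) and a spurious mirror (*L* ≈ 1,
   *c* ≈ 0.1–0.3). `solve_tes()` returns both, classified, with Hill
   coefficients and first-order uncertainties.
2. **Global fitting.** For families of curves measured at different
   concentrations of the same allosteric effector (protons, CO₂,
   2,3-BPG), `global_fit()` fits all curves simultaneously with one
   shared (*K*<sub>R</sub>, *K*<sub>T</sub>) pair and one apparent
   *L*<sub>app</sub> per curve — the MWC picture in which effectors act
   only on the quaternary equilibrium. `fit_lapp()` then fits
   *L*<sub>app</sub>(I) = *L*₀·((1+[I]/*K*<sub>I</sub><sup>T</sup>)/(1+[I]/*K*<sub>I</sub><sup>R</sup>))ⁿ
   to recover the effector's affinities for the two conformations.

Supporting tools: Hill and compound-parameter single-curve fits,
the Hill transformation `hill_coefficient_mwc()` (slope of
log(Ȳ/(1−Ȳ)) vs log p at half saturation), a seeded synthetic-curve
simulator with known ground truth, a packaged reference table of
TES-derived parameters for 27 mammalian hemoglobins, correlation and
monotone-scaling diagnostics, and a CLI (`inst/cli/mwcfit`).

## Worked example

```r
library(mwcfit)

hb <- mwc_params(L = 0.7e5, K_R = 1.6, K_T = 128.8)  # human hemoglobin
p50_mwc(hb)                 # 27.57703 mmHg
hill_coefficient_mwc(hb)    # 2.728924

cp <- compound_params(hb$L * hb$K_R^4, hb$L * hb$c^4, p50_mwc(hb))
solve_tes(cp)
#> Three-equation-system solution
#>   inputs: LK_R^4 = 458752  Lc^4 = 0.00166692  P50 = 27.577 mmHg
#>   shared K_T = 128.8 mmHg; 2 accepted root(s), 0 discarded
#>  root_index             label         L   K_R   K_T       c    nH  residual
#>           1     physiological 70000.000  1.60 128.8 0.01242 2.729 2.220e-16
#>           2 non_physiological     1.818 22.41 128.8 0.17400 1.201 1.301e-16
```

The solver reproduces the generating triple (root 1) and exposes the
spurious mirror solution (root 2) that a naive fit could equally land
on; the classification labels tell them apart.

A physiological curve family, analysed end to end:

```r
m <- effector_model(L0 = 230.3, KI_T = 9.6, KI_R = 140.5, n_sites = 4)
fam <- simulate_effector_family(1.5, 140, m, c(0, 4, 16, 64, 256, 1024),
                                noise_sd = 0.005, seed = 42,
                                effector_name = "H+", conc_unit = "nM")
summary(global_fit(fam))
#> Global MWC fit with shared affinities
#>   K_R = 1.467 +/- 0.02 mmHg
#>   K_T = 139.5 +/- 2.7 mmHg
#>   c   = 0.01052
#>   overall R2 = 0.9998, converged: TRUE
#>  curve_id effector_conc     L_app  se_L_app     r2
#>      H+_0             0     249.7     12.74 0.9998
#>      H+_4             4     909.9     47.29 0.9998
#>     H+_16            16    8133.6    433.02 0.9998
#>     H+_64            64  193859.1  10555.03 0.9998
#>    H+_256           256 2353602.4 130587.85 0.9998
#>   H+_1024          1024 7086390.5 399573.65 0.9997

fit_lapp(global_fit(fam)$L_app, c(0, 4, 16, 64, 256, 1024))
#> Effector linkage fit (non-exclusive binding)
#>   L0   = 250.138
#>   KI_T = 9.58733
#>   KI_R = 140.474
#>   d    = 14.65
#>   sites = 4, R2(log L) = 1.0000
```

The shared affinities, the monotone rise of *L*<sub>app</sub> with
inhibitor concentration, and the recovered effector affinities (true
*d* = 140.5/9.6 = 14.6) all come back from noisy data.

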