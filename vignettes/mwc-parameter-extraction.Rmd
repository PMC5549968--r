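---
title: "Extracting elementary MWC parameters from saturation curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting elementary MWC parameters from saturation curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwcfit)
```

## The model

The concerted two-state (MWC) model describes a tetrameric binding
protein in equilibrium between a tense (T) and a relaxed (R) quaternary
conformation. Three elementary parameters govern steady-state binding:
the conformational equilibrium constant $L = [\mathrm{T}]/[\mathrm{R}]$
in the absence of ligand, and the ligand affinities $K_R$ and $K_T$ of
the two conformations (for oxygen binding these are pressures in mmHg,
identical to Torr; no unit conversions happen anywhere in the package).
The relative affinity $c = K_R/K_T$ is always derived, never stored —
one source of truth. Fractional saturation is

$$\bar Y(p) = \frac{\alpha(1+\alpha)^3 + L\beta(1+\beta)^3}
                   {(1+\alpha)^4 + L(1+\beta)^4},
  \qquad \alpha = p/K_R,\; \beta = p/K_T,$$

a strictly increasing function of $p$ with $\bar Y(0)=0$ and
$\bar Y \to 1$. Cooperativity is summarised by the Hill coefficient at
half saturation, the slope $n_H = \mathrm{d}\log(\bar Y/(1-\bar Y)) /
\mathrm{d}\log p$ at $p = P_{50}$. Key structural facts about $n_H$,
all verified as properties in the test suite:

* $n_H$ depends only on $(L, c)$, never on the pressure scale;
* $n_H = 1$ when $c = 1$, when $L = 0$, and in the $L \to \infty$
  limit (single-conformation hyperbolas);
* as a function of $L$ at fixed $c < 1$, $n_H$ is bell-shaped in
  $\log L$ with its maximum where $Lc^2 = 1$; at that symmetric point
  $P_{50} = \sqrt{K_R K_T}$, and for $c = 0.01$ direct evaluation of
  the Hill transform gives $n_H \approx 3.01$;
* relabelling the conformations, $(L, c) \mapsto (1/L, 1/c)$, leaves
  $n_H$ unchanged.

The assumptions inherited from the model are the usual ones: all four
sites identical within a conformation, concerted (all-or-none)
quaternary switching, no tertiary intermediates, and effectors acting
exclusively on $L$.

## Why elementary parameters are hard to get

A single saturation curve constrains only the compound combinations
$LK_R^4$ (tied to the transition midpoint) and $Lc^4$ (tied to
cooperativity); the third direction — $L$ itself — is nearly flat.
`fit_mwc_modified()` fits a curve in exactly this compound
parameterization and reports the flatness honestly: the standard error
of $\log L$ is typically more than an order of magnitude larger than
that of $\log LK_R^4$, and an `L_fixed` argument profiles the valley
directly (an order of magnitude off in $L$ still fits near the noise
floor). This is the motivation for the two extraction strategies.

### Strategy 1: the three-equation system

Given $(y_1, y_2, P_{50}) = (LK_R^4,\; Lc^4,\; \text{half-saturation
pressure})$, the affinity of the T state follows exactly:
$K_T = (y_1/y_2)^{1/4}$, independent of any root choice. Substituting
$L = y_1/K_R^4$ into the half-saturation identity
$(1+\alpha)^3(\alpha-1) = L(1+\beta)^3(1-\beta)$ reduces the system to
the quartic

$$(1-D)\,\alpha^4 + 2\alpha^3 - 2\alpha - 1 = 0,
  \qquad D = \frac{(1+\beta)^3(1-\beta)\,y_1}{P_{50}^4},$$

in $\alpha = P_{50}/K_R$. This reduction is an implementation device;
its correctness is not taken on faith but enforced by a test that
compares the full root set against an independent brute-force solver
(dense $\log K_R$ scan of the original half-saturation residual with
sign-change bisection) on 200 randomly generated systems, to relative
1e-4. Degenerate special cases are covered analytically: at
$P_{50} = K_T$ the quartic factors as $(\alpha-1)(\alpha+1)^3$, leaving
the single root $K_R = P_{50}$.

Forward-generated systems typically return two real positive roots.
One is the generating triple; the other is a spurious mirror with
$L \approx 1$ and $c \approx 0.1$–$0.3$. `classify_root()` separates
them with configurable thresholds (physiological iff $L > 10^2$ and
$c < 0.05$), chosen midway between the two observed regimes
($L \sim 10^4$–$10^9$, $c \sim 10^{-3}$–$10^{-2}$ for the sound set
versus $L \sim 1$, $c \sim 0.1$–$0.3$ for the mirror set) so that both
classifications hold with wide margin; they are parameters, not
constants, because the underlying evidence is a pair of ranges rather
than a cut point. The label `degenerate` is reserved for $c$ within
1e-6 of 1.

The external validity check for the strategy is the agreement between
model-calculated and independently measured Hill coefficients:
`correlate_nh()` averages replicate groups (the three human and three
elephant entries of the packaged mammalian table) and regresses
observed on calculated $n_H$ with intercept. On the packaged table
this gives slope 0.97 and $R^2$ 0.92 over 13 points. The regression
orientation (observed as response) is a documented package decision —
it is the orientation under which the packaged table reproduces those
reference numbers — with a `transpose` flag for the other convention.

### Strategy 2: global fitting of effector families

When curves are measured at several concentrations of the same
allosteric effector, the MWC reading is that only $L$ changes.
`global_fit()` therefore shares one $(K_R, K_T)$ pair across all
curves and gives each curve its own apparent constant
$L_{\mathrm{app}}$, minimising the pooled sum of squared saturation
residuals. The mechanistic coherence criterion — any genuinely
$L$-mediated effect must make $L_{\mathrm{app}}$ vary monotonically
with concentration — is checked by `scaling_check()` via the Spearman
rank correlation (rank-based because the criterion is monotonicity,
not linearity; the verdict requires $|\rho| = 1$).

The concentration dependence itself is the non-exclusive binding
linkage

$$L_{\mathrm{app}}([I]) = L_0
  \left(\frac{1 + [I]/K_I^T}{1 + [I]/K_I^R}\right)^{n},$$

fitted by `fit_lapp()` on the $\log L_{\mathrm{app}}$ scale with the
site exponent $n$ held fixed: 4 for effectors with one site per
subunit (protons, CO₂), 1 for single-site organophosphates such as
2,3-BPG. An inhibitor binds T more tightly ($K_I^T < K_I^R$, ratio
$d = K_I^R/K_I^T > 1$) and raises $L_{\mathrm{app}}$ with
concentration. When all $L_{\mathrm{app}}$ values coincide there is no
linkage signal; the fit returns $d = 1$ and flags the affinities
unidentifiable rather than reporting noise as structure.

## Numerical choices

* **Root finding.** $P_{50}$ is located by bracketed bisection
  (`uniroot`) on the monotone isotherm over
  $[\min(K_R,K_T)\cdot 10^{-6}, \max(K_R,K_T)\cdot 10^{6}]$, followed
  by secant polish to a residual of at most 1e-10 in $\bar Y$.
  Guaranteed convergence on a monotone function was preferred over a
  faster unbracketed iteration.
* **Hill transform.** Central finite difference on $\log p$ with step
  1e-4. A closed-form derivative exists but is long; the finite
  difference is robust, matches an independent chain-rule oracle to
  1e-5 in tests, and avoids transcription risk. Quartic roots come
  from `polyroot` (companion-matrix method); roots with relative
  imaginary part above 1e-8 are rejected, duplicates merged at
  relative 1e-6, and every accepted root must satisfy all three
  original equations to relative 1e-8 — tolerances sized for
  double-precision quartic conditioning.
* **Fits.** All nonlinear fits run in log-parameter space, which
  enforces positivity without constraint machinery; the global fit
  parameterizes $K_T = K_R e^s$ with $s \ge 0$ so $c \le 1$ holds by
  construction (T is the low-affinity state by convention).
  Optimisation is Nelder–Mead exploration plus BFGS polish (single
  curves) or bounded L-BFGS-B (global fit) from data-driven starts —
  affinities bracketing the observed per-curve midpoints, $L_j$ from
  inverting the half-saturation identity — with seeded jittered
  restarts against local minima. Identical data, configuration and
  seed give identical output; simulation helpers save and restore the
  caller's RNG state.
* **Uncertainties.** Standard errors come from the local quadratic
  approximation at the optimum ($\mathrm{cov} = 2\hat\sigma^2 H^{-1}$
  for an SSR surface). Input uncertainties propagate through the TES
  by first-order expansion with central-difference partials (relative
  step 1e-5) combined as $\sum_i |\partial f/\partial x_i|\,\Delta
  x_i$; absolute values prevent sign cancellation, and a quadrature
  (root-sum-square) mode is available. The linear-absolute sum is the
  conservative reading and cross-checks against the half-range of a
  uniform-perturbation Monte Carlo within a factor of 2.
* **Weighting and adequacy.** Residuals are unweighted on the
  saturation scale (per-point weights can be supplied); $R^2 > 0.97$
  flags adequacy but never silently drops a curve.
* **Degenerate inputs.** $L = 0$ is accepted as the pure-R limit;
  $L = \infty$ is not representable (profile helpers approximate it by
  the T-state hyperbola). Near-hyperbolic data (fitted $n_H < 1.05$)
  set a degeneracy flag on the compound fit.

## The synthetic generator

`simulate_curve()` evaluates the isotherm on 30 log-spaced pressures
covering saturations 0.02–0.98 (so every fit's midpoint requirement is
met) and adds seeded homoscedastic Gaussian noise on the saturation
scale, default sd 0.005 — representative of high-quality oxygenation
measurements, where replicate scatter is a few tenths of a percent to
a percent of full scale. Values are deliberately not clipped to
$[0,1]$, keeping the noise unbiased. `simulate_effector_family()`
builds concentration series in which only $L$ varies, via the linkage
equation, with shared affinities — the exact data-generating process
the global fit assumes.

What the generator does *not* emulate: heteroscedastic or correlated
measurement error, instrument drift, hemoglobin concentration effects,
dimer–tetramer dissociation, temperature variation between curves, or
any tertiary-intermediate kinetics. Passing recovery tests on these
simulations therefore demonstrates correctness of the estimators under
the stated model, not robustness to every failure mode of real
oxygenation data.

Test and acceptance problem sizes are deliberately modest — 30-point
curves, families of 4–6 curves, 200 random systems for the solver
cross-validation, 1e5 Monte-Carlo draws for the error-propagation
check — sizes at which every quantity is stable to well within the
asserted tolerances.

## Design decisions on genuinely open points

* Whether the single-curve compound fit should fix or float the third
  parameter: it floats by default with an identifiability flag, and
  `L_fixed` provides the fixed-parameter profile variant.
* Global fits pool residuals without weighting by curve point count or
  variance; nothing in the problem statement favours a weighting, and
  the per-point `weights` argument covers users who have one.
* Error propagation is linear-absolute by default (conservative,
  sign-cancellation-proof) with quadrature behind a flag.
* The full-range Hill fit of an MWC-generated curve systematically
  under-reads the half-saturation slope (the isotherm's asymptotic
  slope is 1): on a 0.02–0.98 saturation window the fitted $n_H$ for
  the human triple is about 2.49 against a midpoint slope of 2.73,
  converging only as the window narrows to the midpoint. Comparisons
  between Hill-fit $n_H$ and `hill_coefficient_mwc()` should therefore
  be made midpoint-locally; the tests do exactly that.

## Known limitations

The package treats steady-state saturation only: no transient
kinetics, no tertiary two-state extensions, no temperature
corrections. The effector linkage treats protons as a simple ligand
with one apparent site per subunit, an approximation (several residues
contribute to proton linkage in hemoglobin). The packaged mammalian
reference table is a transcription of printed, rounded values;
round-trip reconstructions from it inherit roughly 1–2% rounding
slack. Individual curve datasets for the effector families are not
shipped; the linkage machinery is validated by simulation round trips
with published parameter sets as generators.
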