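---
title: "Deriving leaf photosynthetic traits: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving leaf photosynthetic traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photraits)
```

`photraits` turns raw steady-state gas-exchange and chlorophyll-fluorescence
records into derived photosynthetic traits, with a synthetic-leaf generator
standing in for instrument data.  This vignette explains the models, the
tunable constants, what the generator does and does not emulate, and the
design decisions taken where the underlying methodology is ambiguous.

## The light-response model

Net assimilation against incident light is modelled as

$$A_{net} = A_{max} - A_{max}\,C_0\,e^{-\alpha\,\mathrm{PPFD}/A_{max}}$$

an exponential rise to the light-saturated rate $A_{max}$.  $C_0$ indexes
the dark starting point: the model value at PPFD $=0$ is
$A_{max}(1-C_0)$, so a respiring leaf has $C_0 > 1$ and dark respiration
$R_d = |A_{max} - A_{max} C_0|$.  We report $R_d$ as a non-negative
magnitude: the raw expression $A_{max}-A_{max}C_0$ is the (negative) dark
model value, and the magnitude is what a respiration rate means.

The model surface lets $\alpha$ and $C_0$ trade off against each other near
flat regions, so `fit_light_response()` uses multi-start Levenberg–Marquardt
least squares (9 starts by default) with data-driven initial values:
$A_{max}$ from the observed plateau, $\alpha$ from the low-light OLS slope,
$C_0$ from the dark observation.  On noiseless curves the generating
parameters are recovered to better than $10^{-6}$ relative; the test suite
asserts this over randomised profiles.

The *apparent quantum yield* is reported separately as the OLS slope of
$A_{net}$ over the "linear region" of the curve.  No formal definition of
that region exists; the default threshold PPFD $\le 100$ µmol m⁻² s⁻¹
brackets the lowest four steps of the measurement protocol and is
user-configurable.  Note the analytic initial slope of the exponential model
is $\alpha C_0$, so the regression slope sits slightly below it over any
finite region — the two agree only in the limit of a vanishing region.

## The A–Ci curve: two summaries, two compensation points

The CO₂ response is summarised twice, as is conventional:

1. **Initial linear region** (default $C_i \le 200$ µmol mol⁻¹):
   the OLS slope is the carboxylation efficiency CE, and the $C_i$-intercept
   is the *operational* CO₂ compensation point, reported as `Gamma_star`.
   Treatment-level tabulations in this literature conventionally attach the
   $\Gamma^*$ symbol to this intercept even though, strictly, $\Gamma^*$ is
   the photorespiratory compensation point; with values near 100–125
   µmol mol⁻¹ the tabulated quantity is clearly the operational intercept
   (a true $\Gamma^*$ at 25 °C is ≈ 40 µmol mol⁻¹).  We record it under the
   conventional label and *also* expose the mechanistic value.
2. **Farquhar fit** over the whole curve:
   $A = \min(A_c, A_j) - R_d$ with
   $A_c = V_{cmax}(C_i-\Gamma^*)/(C_i+K_m)$,
   $K_m = K_c(1+O/K_o)$, and
   $A_j = J_{max}(C_i-\Gamma^*)/(4C_i+8\Gamma^*)$.
   Kinetic constants default to 25 °C values ($K_c = 404.9$ µmol mol⁻¹,
   $K_o = 278.4$ mmol mol⁻¹, $O = 210$ mmol mol⁻¹) and are exposed as
   arguments; no temperature corrections are applied because the target
   protocol runs at 25 °C.  The mechanistic $\Gamma^*$ is estimated by
   default (`Gamma_star_photo`) or can be held fixed.  A published
   alternative calibration of $V_{cmax}$/$J_{max}$ requires additional
   measurements under low O₂ and cannot be reproduced from curve data
   alone, so the standard Farquhar fit is the implemented reading.

The fitted minimum-of-two-limitations model is piecewise smooth;
multi-start Levenberg–Marquardt over a 3×3 grid of scaled starts has been
robust in testing (noiseless recovery of $V_{cmax}$ and $J_{max}$ to well
under 1%).  Duplicated driver steps (the protocol revisits 400 µmol mol⁻¹)
are averaged before fitting, which also makes all fits invariant to step
order.

## Fluorescence and electron transport

From dark- and light-adapted yields the standard ratios are
$F_v'/F_m' = (F_m'-F_o')/F_m'$, $\Phi_{PSII} = (F_m'-F_s)/F_m'$,
$qP = (F_m'-F_s)/(F_m'-F_o')$ and $NPQ = (F_m-F_m')/F_m'$.  Total electron
transport is $J_T = \mathrm{PPFD}\cdot\Phi_{PSII}\cdot\alpha_{leaf}\cdot\beta$
with leaf absorptance $\alpha_{leaf}=0.84$ and PSII fraction $\beta=0.5$ —
the conventional fluorometer assumptions, adequate for comparing optically
similar leaves; both are configurable.  The Valentini partition
$J_O = \tfrac23(J_T - 4(A_{net}+R_d))$,
$J_C = \tfrac13(J_T + 8(A_{net}+R_d))$ satisfies $J_C+J_O=J_T$ identically.
$R_d$ is held constant across light steps at the leaf's light-curve value —
whether it should vary with light is genuinely unknowable from this kind of
data, and a constant is the transparent choice.  At dim steps $J_T$ can fall
below $4(A_{net}+R_d)$, making $J_O$ negative; the values are returned with
a warning rather than clipped, because a negative $J_O$ is useful QC signal,
and such steps are excluded from downstream regressions.

## Diffusion traits

The variable-J estimate at one steady-state step is

$$g_m = \frac{A_{net}}{C_i - \Gamma\,\frac{J_T+8(A_{net}+R_d)}{J_T-4(A_{net}+R_d)}}$$

where the bracketed term is the chloroplastic CO₂ implied by fluorescence
(`Cc_variableJ`).  Which step should feed the per-leaf $g_m$ is not
standardised; the default reducer is the highest-PPFD steady state (where
the method is best conditioned), with a mean over admissible steps as the
alternative.  One published formula assigns this same bracketed expression
to the per-chloroplast-surface conductance $C_{lip}$, which is dimensionally
a mole fraction, not a conductance; we therefore keep both quantities
distinct — `Cc_variableJ` as computed, and the tabulated $C_{lip}$
(mol m⁻² s⁻¹) as an independent input used only in
$g_{lip} = C_{lip} \times S_c$.

Specificity follows $S = O/(2\Gamma)$ with $O = 210000$ µmol mol⁻¹ (21% O₂
in $\Gamma$'s unit — the only reading that reproduces tabulated $S$ values
of ~840–1060 mol mol⁻¹ from compensation points of ~100–125 µmol mol⁻¹).
The apparent specificity $S^*$ is the initial slope of $J_C/J_O$ against
$C_i/O$; the regression is not forced through the origin by default and the
initial region defaults to $C_i/O \le 0.5$ (i.e. all points of a typical
curve — the bound exists to allow narrowing).  In the pipeline the
regression points are built across the A–Ci curve from the variable-J
identity $J_C/J_O = C_c/(2\Gamma)$ with $C_c = C_i - A_{net}/g_m$ at the
leaf's estimated $g_m$: this spans a wide $C_i$ range, as an $S^*$
regression must, and yields $S^* < S$ (ratio ≈ 0.87–0.95 for the default
profiles), matching the field's ordering of the two quantities.  Points
from light-curve covariation alone would not: there $C_i$ barely moves while
$A_{net}$ moves a lot, which biases the slope above $S$.

Then $C_c = C_i \cdot S^*/S$, $g_i = A_{max}/(C_i - C_c)$ (domain error when
$C_c \ge C_i$; in the pipeline such leaves get `NA` and remain visible), and
$g_m$/Rubisco is scaled ×1000 — the millimole scaling that matches the
magnitudes conventionally tabulated for this ratio.

## Nitrogen partitioning

$N_C = V_{cmax}/(6.25\,V_{cr})$, $N_B = J_{max}/(8.06\,J_{mc})$,
$N_L = \mathrm{Chl}/C_B$, $N_{photo} = N_C+N_B+N_L$, PNUE $= A_{max}/SLN$,
with $V_{cr} = 20.8$ µmol CO₂ g⁻¹ Rubisco s⁻¹, $J_{mc} = 155.6$ µmol
electrons µmol⁻¹ Cyt f s⁻¹ and $C_B = 2.15$ mmol Chl g⁻¹ N.  The published
pool equations carry SLN in both numerator and denominator; it cancels
algebraically, and we implement the cancelled form — pools depend only on
their driving trait, and SLN enters only the fractional allocations.  PNUE
is implemented as $A_{max}/SLN$, the standard definition (light-saturated
assimilation per unit leaf N).  Chlorophyll arrives as µg cm⁻² and is
converted to mmol m⁻² with a default molar mass of 893.5 g mol⁻¹ (the
Chl a/b average; configurable) — the conversion itself is a design choice,
as the pool equations are defined on a molar basis.

## Pigment indices

V+A+Z, (A+Z)/(V+A+Z) and (V+A+Z)/Chl.  When a pre-tabulated pool is
supplied alongside the components, the tabulated value is preferred for
ratio denominators (configurable): tabulated pools are computed before the
components were rounded, and the ratios printed beside them reproduce only
from the pool itself.  Disagreement beyond 5% between pool and component
sum is flagged.

## The synthetic-leaf generator

The generator's defaults *are* the study conditions: three treatment
profiles (LN/MN/HN) parameterised by the published treatment means and
between-replicate SDs bundled in `reference_traits()` (n = 7 per
treatment), the 11-step light protocol (800 → 0 µmol m⁻² s⁻¹) and the
12-step CO₂ protocol (400 → 50, back to 400, up to 1500 µmol mol⁻¹).  Two
unpublished magnitudes were fixed once: the apparent quantum yield
$\alpha = 0.05$ mol mol⁻¹ (a typical C3 value) and the within-curve noise —
additive Gaussian sd 0.1 µmol m⁻² s⁻¹ on $A_{net}$, relative sd 0.02 on the
fluorescence quenching levels — chosen as typical instrument repeatability,
since the published SDs describe derived traits, not raw channels.

Choices worth knowing about:

- **Replicate draws** are Gaussian around the profile means with the
  published trait SDs, truncated at zero — the simplest model consistent
  with symmetric mean ± SD reporting.
- **Per-leaf streams.** Each leaf's RNG stream derives from the root seed by
  an additive Weyl-increment hash of the leaf index, so datasets are
  byte-reproducible and independent of insertion order.
- **A–Ci forward vs. fitted model.** The generator uses the mechanistic
  Farquhar model while the fitting stage also runs the initial-slope
  summary; the two stages therefore exercise different functional forms,
  which is deliberate.  Because the printed treatment means
  ($V_{cmax}$, $\Gamma$, $R_d$…) were not produced by this forward model,
  they are not exactly mutually consistent — e.g. the LN profile's
  operational compensation point comes out near 170 µmol mol⁻¹ rather than
  the printed 124.  The generator is internally consistent; it does not
  replicate the printed table row by row.
- **Fluorescence consistency.** The qP level of the synthetic fluorescence
  is calibrated so that, at the brightest step, the implied $J_T$ is
  exactly the one the variable-J relation requires for the leaf's
  `gm_true` — a noiseless synthetic leaf returns its own mesophyll
  conductance through the full pipeline (asserted to $10^{-6}$ in tests).
  Full-curve consistency is impossible: at dim steps the Valentini
  relation with constant $R_d$ would demand more electron flux than the
  incident photons can supply, which is exactly why practitioners apply
  variable-J at saturating light.
- **Yield ordering.** Generated series satisfy
  $F_o \le F_o' \le F_s \le F_m' \le F_m$ at every step; $F_o'$ is modelled
  with a mild monotone rise under light.  Under strong non-photochemical
  quenching many real leaves instead show $F_o' < F_o$; the quenching
  ratios are insensitive to the direction, and the monotone ordering gives
  the test suite a single clean invariant.
- **Stomatal coupling.** $g_s = 0.02 + 0.009\,A_{net}$ (plus noise), with
  $C_i = 400 - 1.6 A_{net}/g_s$ — a minimal empirical coupling that makes
  $C_i$ co-vary with light realistically.  It is not a stomatal model.

What the generator does *not* emulate: instrument drift, leaks and match
errors, induction transients, non-steady-state fluorescence, temperature
variation, or any transcript-level biology.  Passing tests therefore
demonstrate that the arithmetic and fitting machinery is correct under the
assumed noise structure — not that the pipeline is robust to every
pathology of field data.

## Statistics

Treatment summaries are means ± sample SD.  Letters come from one-way ANOVA
followed by Tukey's HSD at $\alpha = 0.05$ (no post-hoc test is named in
the source literature; Tukey is the standard choice for all-pairs
contrasts), with the compact letter display computed by the usual
insert–absorb algorithm from the adjusted p-values; the test suite checks
the letter partition against `multcomp`'s independent implementation and
verifies the nominal type-I error by simulation (1000 null datasets,
n = 7 × 3 groups).  Zero-variance degenerate inputs collapse to a single
shared letter.  Percent contrasts are $(ref - x)/ref \times 100$ with MN as
the default reference.  For qPCR follow-ups, relative expression is
$2^{-\Delta\Delta Ct}$; randomisation-test machinery of dedicated qPCR
tools is out of scope.

## Problem sizes and numerics

The shipped tests run the full pipeline at the study's own scale
(3 treatments × 7 leaves, 11 + 12 steps per leaf) and the statistical
checks at 100–1000 replicates — a desk-scale load chosen so the entire
suite completes in well under a minute of fitting time.  Nonlinear fits use
tight convergence tolerances (`ftol = ptol = 1e-15`) so that noiseless
recovery is limited by machine precision, not by the optimiser; all
randomness flows from explicit seeds.

## Known limitations

- The variable-J estimate inherits all the fragility of its inputs; with
  realistic noise, leaves with small $C_i - C_c$ (high-$g_m$ leaves) can
  return wild or negative $g_m$.  These propagate as flagged values rather
  than being silently dropped.
- $S^*$ and $C_c$ depend on the constant-$g_m$ assumption across the A–Ci
  curve.
- The nitrogen pools use literature constants for temperate C3 leaves;
  applying them to other groups is a calibration question, not a software
  one.
- The letter display is defined for the balanced one-way layout used here;
  unbalanced designs fall back to the same machinery via Tukey–Kramer but
  are not specifically tested.
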