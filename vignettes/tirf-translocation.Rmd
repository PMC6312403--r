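---
title: "Quantifying membrane translocation from TIRF footprints"
author: "tirfquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane translocation from TIRF footprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tirfquant)
```

## The problem

In TIRF microscopy only the first few hundred nanometers above the
coverslip are illuminated, so the technique is often treated as a
membrane-selective readout. For a *soluble* biosensor — say a
PH-domain probe that binds 3-phosphoinositides at the plasma membrane —
that shorthand fails quantitatively: the evanescent field reaches far
enough into the cytosol that most of the resting footprint signal comes
from unbound probe. A stimulus that produces, for example, a 1.5-fold
increase in total footprint fluorescence can correspond to a roughly
ten-fold enrichment of the probe at the membrane itself. tirfquant
implements the optics, the inversion model, the trace pipeline and the
cohort statistics needed to make that correction explicit, plus a
seeded simulator so every stage can be validated against ground truth.

## The evanescent field and the layer grid

For light of vacuum wavelength $\lambda_0$ crossing a coverslip
(index $n_3$) / solution (index $n_1$) interface at incidence angle
$\theta$ above the critical angle
$\theta_c = \arcsin(n_1/n_3)$, the illumination decays with height $h$
as $I(h) = e^{-\tau h}$ with

$$ d = \frac{\lambda_0}{4\pi n_3}\left(\sin^2\theta -
  \sin^2\theta_c\right)^{-1/2}, \qquad \tau = 1/d . $$

`penetrationDepth()` computes $\theta_c$ from the configured indices by
default. Published calculations sometimes print a critical angle that
is not exactly $\arcsin(n_1/n_3)$ of their printed indices (small
differences in the assumed solution index move $\theta_c$ by a few
tenths of a degree, and $d$ by around 10 nm near critical incidence).
Rather than silently picking one reading, the function accepts an
explicit `criticalAngleOverride`; both readings round to the same decay
constant $\tau \approx 0.008\ \mathrm{nm}^{-1}$ for the default
447 nm / 1.33 / 1.53 / 63° configuration:

```{r}
cfg <- opticalConfig()
c(computed = decay(penetrationDepth(cfg)),
  override = decay(penetrationDepth(cfg, criticalAngleOverride = 60.8)))
```

The cytosol is discretized into layers of 10 nm — the approximate size
of a PH-domain probe with its fluorescent tag — with the membrane and
its associated proteins occupying layer 0. Each layer is sampled at its
coverslip-proximal edge, so $I_0 = 1$ exactly. Fifty layers reach
500 nm, where under the default optics less than 2 % of the
infinite-series illumination remains; `illuminationProfile()` warns
whenever a requested truncation would discard more than 5 %.

A consequence worth stating plainly: with this grid the membrane layer
contributes $I_0/\sum_i I_i \approx 7.8\%$ of the resting signal —
`membraneFraction()` always reports this computed value, and can flag a
mismatching nominal figure supplied by the user.

## The redistribution model

At rest the probe is assumed homogeneously distributed, $m$ molecules
per layer, and the baseline footprint fluorescence is normalized to 1:

$$ F_{\mathrm{initial}} = B \sum_{i=0}^{N-1} m I_i = 1
   \quad\Rightarrow\quad m = 1/\textstyle\sum_i I_i $$

(the per-molecule brightness $B$ is absorbed by the normalization and
fixed to 1; everything downstream is therefore invariant to absolute
brightness and to each cell's absolute baseline). After stimulation,
$\Delta m$ molecules occupy the membrane layer. Two bookkeeping
scenarios bracket where they came from:

* **fixed_total** — a fixed pool redistributes: each of the $N$ layers
  loses $\Delta m/N$,
  $F = \Delta m I_0 + \sum_i (m - \Delta m/N) I_i$;
* **fixed_cytosol** — molecules are added at the membrane, cytosolic
  layers unchanged,
  $F = (m + \Delta m) I_0 + \sum_{i>0} m I_i$.

Both equations are affine in $\Delta m$, so `solveDeltaM()` uses exact
closed forms (the test suite keeps an independent numeric root-finder
as an oracle and requires agreement to $10^{-10}$). The headline output
is the membrane enrichment ratio $R_m = (m + \Delta m)/m$:

```{r}
rest <- solveRestingDensity(illuminationProfile(0.008))
round(restingDensity(rest), 2)
sapply(c("fixed_total", "fixed_cytosol"), function(sc)
  membraneRatio(rest, solveDeltaM(1.54, rest, sc)))
```

A 1.54-fold footprint change maps to roughly 10-fold (fixed-total) or
8-fold (fixed-cytosol) membrane enrichment — the two scenarios agree
within about 25 %, which is the useful robustness message of the model.

Domain boundaries are enforced rather than extrapolated: $F < 1$
(probe depletion from the field, as seen under kinase inhibition) is
rejected by default because the redistribution model was never meant
for it — `allowDepletion = TRUE` extrapolates to negative $\Delta m$
with a warning — and under fixed_total $F$ may not exceed
$N m I_0$, where the whole pool sits at the membrane.

## The trace pipeline

The measurement chain mirrors standard practice: per-frame arithmetic
mean of the footprint ROI pixels; subtraction of a background-ROI mean
(which removes camera offset and stray light — corrected values at or
below zero are *kept*, since clipping would bias the normalization, but
flagged); division by the mean of the pre-application baseline window;
and a treatment-window mean as the per-cell scalar summary.

Two conventions are deliberately configuration, not constants. The
baseline window defaults to 60 s before application but is a parameter
(`baselineDuration`), because one- and two-minute baselines are both
common and both defensible. Summary windows are half-open
$[\mathrm{start}, \mathrm{end})$ in minutes — half-open so that frames
whose timestamp lands exactly on a boundary are counted
deterministically — and ship as four presets
(`biosensor_early` 4–6 min, `biosensor_late` 6–8 min, `channel_early`
8–10 min, `channel_late` 10–12 min): the biosensor response peaks and
partially relaxes, so it is summarized earlier than the slower,
non-reversing channel-trafficking response. No single placement is
claimed to be canonical; analyses should state which they used.

By construction the normalized trace is invariant to camera gain
(multiplicative) and to any offset shared by the cell and background
ROIs; both invariances are asserted on rendered stacks in the test
suite, as is idempotence of the normalization.

## The synthetic generator

`renderStack()` and `generateCohorts()` exist so that every claim above
is testable without external data. Per-cell recruitment follows a
delayed exponential rise with partial relaxation,

$$ \Delta m(t) = A\,(1 - e^{-(t-t_0)/\tau_r})
   \,(p + (1-p)e^{-(t-t_0)/\tau_d}), $$

the simplest shape consistent with the two response classes the
pipeline must handle (a peaking, partially relaxing biosensor signal,
$p < 1$; monotone channel trafficking, $p = 1$). The fold-change
trajectory is produced by the *forward* redistribution model, so
pipeline output can be compared to model-exact truth. Defaults:
$t_0 = 20$ s, $\tau_r = 60$ s, $\tau_d = 300$ s, $p = 0.7$ for the
biosensor-like responder template.

Condition templates encode the structure of a translocation
experiment. Responder amplitudes are log-normal
($\mu_{\log} = \log 0.75$, $\sigma_{\log} = 0.6$) — translocation
responses are right-skewed in practice, and the family is the simplest
right-skewed choice — calibrated so the cohort window mean lands near a
1.5-fold change; amplitudes are clamped to the fixed-total pool size
$N m$, since more molecules than the pool cannot be recruited. Vehicle
cells have amplitude 0. Inhibitor cells decline mildly below baseline
(direction $-1$, log-normal magnitude with mean $\approx 0.17$,
monotone kinetics), giving window means near 0.9.

Rendering uses an elliptical footprint in a 64×64 frame, a rectangular
background region, footprint pixel mean
$\mathrm{offset} + \mathrm{baseline}\cdot F(t)$, and a standard camera
noise model: scaled-Poisson shot noise (0.15 detected photons per
camera unit) plus Gaussian read noise (sd 1 unit), chosen once to give
a single-frame footprint-mean coefficient of variation of about 1 % at
the default levels — the regime in which window-averaged summaries are
precise to a few tenths of a percent. A seed fully determines every
output, byte for byte. A trace-level fast path
(`method = "trace"`, multiplicative Gaussian noise of sd 0.01 per
frame) skips rendering for statistical experiments and is flagged as
such in the output.

What the generator does *not* emulate — subcellular structure, probe
diffusion and binding kinetics, photobleaching, stage drift, cell-size
variation — bounds what passing tests show: they validate the
extraction, normalization, inversion and statistics against a world in
which the layered model is exactly true, not the model's biological
adequacy on real cells.

## Statistics

Cohorts are summarized as mean ± SEM (sample SD over $\sqrt n$).
Hypothesis tests delegate to R's stats machinery behind a thin,
contract-enforcing surface: `rankSumTest()` runs the two-sided
Wilcoxon–Mann–Whitney test, enumerating the exact null when the smaller
group has ≤ 12 observations and the pooled data are tie-free, and
otherwise using the normal approximation with tie and continuity
correction (exact and approximate p agree within 0.01 by n ≈ 15, and
the empirical type-I error at $\alpha = 0.05$ sits in $0.05 \pm 0.01$;
both are asserted in the suite). `holmBonferroni()` applies the Holm
step-down adjustment; the family of comparisons sharing one adjustment
is always an explicit input, never inferred, because family membership
is a scientific decision. `pairedTTest()` treats identical inputs as
the degenerate null ($t = 0$, $p = 1$) and rejects nonzero
zero-variance differences. `normalizeBlot()` implements the standard
two-step densitometry normalization (band ÷ blot mean, then ÷ the
matching lane of the identically normalized pan-antibody blot), which
makes the result invariant to per-blot exposure.

## Validation problem sizes

The shipped suite validates the chain at deliberately compact sizes:
closed-form vs root-find agreement and forward/inverse round-trips on
grids of up to 200 fold-change values; parameter recovery on 60
rendered responder cells (61 frames of 64×64 pixels each, two-minute
baseline), requiring recovered $F$ and $R_m$ within 5 % of truth for at
least 95 % of cells; rank-test calibration on $10^4$ null replicates of
25-vs-25 cells; and cohort-separation checks at 100-vs-20 cells. These
sizes were chosen as the smallest at which the respective properties
are statistically decisive.

## Known limitations

* The inversion is a static two-compartment redistribution; it says
  nothing about binding kinetics, affinity, or phosphatase dynamics,
  and fold-change measurements feeding it are themselves rough
  estimates once receptor internalization and probe depletion start.
* Polarization, intermediate refractive layers and fluorophore
  orientation are ignored in the optics; the 10 nm layer height is a
  fixed constant, not a fitted quantity.
* ROIs are inputs (masks or polygons); there is no auto-segmentation,
  drift correction, bleach correction or channel registration.
* Cohort statistics pool cells across experiments without batch
  modeling, matching field practice for this assay.
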