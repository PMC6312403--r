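# tirfquant

Quantification of stimulus-induced membrane translocation from total
internal reflection fluorescence (TIRF) time-lapse imaging.

## The problem

TIRF microscopy illuminates only an exponentially decaying sliver of
the cell above the coverslip, and is therefore often read as a
plasma-membrane-selective signal. For a **soluble** biosensor — e.g. a
PH-domain probe for 3-phosphoinositides — that reading is badly
miscalibrated: the evanescent field reaches hundreds of nanometers into
the cytosol, so most of the resting footprint fluorescence comes from
*unbound* probe. A modest stimulus-induced fold-change in total
footprint fluorescence can hide an order-of-magnitude enrichment of the
probe at the membrane.

tirfquant is for imaging labs that measure biosensor or channel
trafficking responses in TIRF footprints and want the whole chain —
optics, inversion model, trace processing, cohort statistics,
simulation-based validation — as tested, reusable code rather than a
spreadsheet.

## The model

With vacuum wavelength λ₀ incident at angle θ above the critical angle
θ_c = arcsin(n₁/n₃), illumination decays as I(h) = e^(−τh), where

    d = λ₀ / (4π n₃) · (sin²θ − sin²θ_c)^(−1/2),   τ = 1/d .

The cytosol is discretized into N layers of 10 nm (layer 0 = membrane,
I₀ = 1). At rest the probe is uniform, m molecules per layer, and the
baseline is normalized: F_initial = B·Σ m·Iᵢ = 1, giving m = 1/ΣIᵢ.
After stimulation Δm molecules occupy the membrane layer; the measured
fold-change F is inverted under either of two scenarios

* fixed total pool: F = Δm·I₀ + Σᵢ (m − Δm/N)·Iᵢ
* fixed cytosol:    F = (m + Δm)·I₀ + Σᵢ₌₁ m·Iᵢ

(both affine in Δm, solved in closed form), and the headline result is
the membrane enrichment ratio **R_m = (m + Δm)/m**.

## Worked example

```r
library(tirfquant)

penetrationDepth(opticalConfig())
#> EvanescentField
#>   critical angle: 60.38 deg
#>   depth d:        118.9 nm
#>   decay tau:      0.00841 per nm

rest <- solveRestingDensity(illuminationProfile(0.008))
rest
#> RestingState: m = 0.0783 molecules/layer (B = 1, 50 layers)

as.data.frame(estimateTranslocation(c(1.08, 1.32, 1.54), rest,
                                    "fixed_total"))
#>   fold_change   delta_m membrane_ratio    scenario
#> 1        1.08 0.1074357       2.371787 fixed_total
#> 2        1.32 0.4297429       6.487147 fixed_total
#> 3        1.54 0.7251912      10.259561 fixed_total
```

Reading: a 63° beam of 447 nm light at a glass/saline interface gives a
~119 nm deep field (τ ≈ 0.008 nm⁻¹); on the 50 × 10 nm grid the resting
probe density is m ≈ 0.08 per layer; and footprint fold-changes of
1.08 / 1.32 / 1.54 correspond to roughly 2.4- / 6.5- / 10-fold
enrichment of the probe at the membrane itself. Under the alternative
fixed-cytosol scenario the 1.54 fold-change gives R_m ≈ 7.9 — the two
bookkeeping extremes agree within ~25 %.

A full simulated experiment, from per-cell kinetics through the trace
pipeline to cohort statistics:

```r
sim <- generateCohorts(defaultExperiment(100, 20, 60), seed = 1)
cohorts <- Map(cohort,
               names(split(sim$summaries$summary_value,
                           sim$summaries$condition)),
               split(sim$summaries$summary_value,
                     sim$summaries$condition))
summarizeCohorts(unname(cohorts))
#>   condition      mean         sem   n
#> 1 inhibitor 0.8695333 0.004615202  60
#> 2 responder 1.5441993 0.030949041 100
#> 3   vehicle 0.9992069 0.001202689  20

compareCohorts(unname(cohorts),
               family = list(c("responder", "vehicle"),
                             c("responder", "inhibitor"),
                             c("vehicle", "inhibitor")))
#>   condition_a condition_b statistic        p_raw   p_adjusted
#> 1   responder     vehicle      2000 1.946454e-12 3.892909e-12
#> 2   responder   inhibitor      6000 4.024826e-26 1.207448e-25
#> 3     vehicle   inhibitor      1200 2.717651e-11 2.717651e-11
```

The responder cohort mean (1.54 ± 0.03) sits far above vehicle
(1.00 ± 0.00) and the inhibitor cohort declines below baseline
(0.87 ± 0.00); the rank-sum comparisons, Holm-adjusted as one family,
separate all three conditions decisively.

A thin command-line wrapper (`inst/scripts/tirfquant-cli.R`) exposes
`optics`, `estimate`, `simulate` and `extract` subcommands for shell
use; see its header for usage.

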