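# parasip

Single-cell stable-isotope probing of fungal (chytrid) parasitism on
N₂-fixing cyanobacteria.

## What this package is for

Bloom-forming, filamentous cyanobacteria such as *Dolichospermum* fix
atmospheric N₂ and inject large amounts of new nitrogen into coastal and
fresh waters. Chytrid fungi parasitize these filaments — a zoospore
encysts on a host cell and matures into a sporangium that drains the
host's carbon and nitrogen — with infections concentrated on storage
cells (akinetes) and N₂-fixing cells (heterocytes). `parasip` is for
researchers who quantify this interaction with dual ¹³C/¹⁵N stable-isotope
labeling read out by SIMS ion imaging. It implements the full chain:

1. **Simulation** — *Dolichospermum*-like populations (filaments,
   differentiated cell types, per-type infection prevalence, sporangia,
   colonizing bacteria) and Poisson ion-count image stacks with known
   ground truth (`simulatePopulation()`, `simulateIonStack()`,
   `simulateBacteriaCounts()`, `simulateBulkSamples()`).
2. **Quantification** — ROI extraction from multi-plane ion-count stacks,
   cumulative-count isotope ratios with Poisson errors
   (σ = R·√(1/N_num + 1/N_den)), plane-level quality control, instrument
   mass-fractionation calibration against non-enriched controls, and
   atom-percent-excess (APE) per cell (`extractRoiCounts()`,
   `computeRatio()`, `qcEvaluate()`, `calibrate()`, `cellMeasurements()`).
3. **Rates** — the bulk tracer mass balance
   rate = (A_PN − A_PN0)/(A_N − A_PN0) · [PN]/Δt, single-cell specific
   rates k = APE_cell/(APE_source·Δt), per-cell incorporation rates via
   cell contents, C:N ratios, and infected vs non-infected group
   contrasts (`bulkFixationRate()`, `specificRate()`, `cellRates()`,
   `summarizeGroups()`).
4. **Transfer** — paired sporangium/host APE ratios, group fold changes,
   origin-constrained trend lines, and zero-inflated Poisson/negative
   binomial colonization models with AIC selection and
   profile-likelihood rate-ratio intervals (`pairHostSporangium()`,
   `groupFoldChanges()`, `zinbFit()`).
5. **Population budget** — weighted infection prevalence, fixation
   retention across a prevalence scan, and the fate partitioning of newly
   fixed nitrogen among host, fungi, bacteria and a residual pool
   (`weightedPrevalence()`, `populationFixation()`, `nitrogenFate()`,
   `budgetScan()`).

`runPipeline()` chains all stages from one seeded configuration and emits
a machine-readable summary.

## Worked example

```r
library(parasip)

cfg <- populationConfig(n_cells = 2000, seed = 1)
pop <- simulatePopulation(cfg)
pop$rois
#> ROISet with 2931 ROIs on a 1 x 1 mask
#>   akinete_I: 33, akinete_II: 10, bacterium: 715, control: 30,
#>   heterocyte_I: 29, heterocyte_II: 119, sporangium: 181, vegetative: 1814

round(computePrevalence(pop$rois)$cell_prevalence_pct, 1)
#> vegetative heterocyte    akinete
#>        4.9       45.9       90.7
```

The realized per-type prevalences scatter around the configured 5/44/82%.
Quantifying the simulated ion images recovers the mass-fractionation
factor (simulated at 0.96, i.e. a correction of 1/0.96 ≈ 1.042) from the
30 control ROIs and yields per-cell rates:

```r
q <- quantifyPopulation(pop, simsConfig(seed = 1))
q$calibration
#>   isotope reference_atom_fraction measured_control_ratio    alpha
#> 1     13C             0.011112329            0.010755661 1.044771
#> 2     15N             0.003663033            0.003563347 1.031755

rates <- cellRates(q$cells, pop$rois)
summarizeGroups(rates, "r_N")$contrasts
#>   category mean_non_infected mean_infected pct_change abs_difference
#>  akinete_I         0.6616104     0.3325637         50      0.3290467
```

Infection halves the akinetes' nitrogen incorporation in this small run
(the generating truth is a 56% reduction, 0.71 → 0.31 pmol N cell⁻¹ d⁻¹;
33 akinetes leave visible sampling noise). The population-level
extrapolation with the observed rate table:

```r
st <- populationState(); bp <- budgetParams()
populationFixation(st, bp, c(0, 9.27, 11.24))
#>  P_total rate_C rate_N retained_C_pct retained_N_pct cn_retained
#>     0.00   0.45   0.05         100.00         100.00        8.71
#>     9.27   0.43   0.05          95.02          86.98        9.52
#>    11.24   0.42   0.04          93.96          84.21        9.72

round(nitrogenFate(st, bp, 9.27)[, c("host_retained_pct", "fungi_pct",
                                     "bacteria_pct", "others_pct")], 1)
#>   host_retained_pct fungi_pct bacteria_pct others_pct
#> 1              45.1      22.1           22       10.8
```

At the 11% epidemic scenario (infections in 100% of akinetes, 54% of
heterocytes, 6% of vegetative cells) population carbon retention drops to
~94% and nitrogen retention to ~84%, while the fungal share of newly
fixed nitrogen rises from ~22% at the observed 9% prevalence to ~27% —
i.e. fungi intercept about as much new nitrogen as the entire
heterotrophic bacterial community.

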