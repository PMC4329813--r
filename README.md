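# cochleostat

Stereological cytocochleograms and simulated cohorts for mouse models of
noise-induced hearing loss (NIHL).

Short exposures to "violet" swept-sine noise — a linear 2–20 kHz (or
9–13 kHz) sweep with amplitude gain proportional to frequency, repeated for
30 min at 105 or 120 dB SPL — produce level- and band-dependent cochlear
damage. Quantifying that damage requires (i) verified exposure stimuli,
(ii) an unbiased estimate of inner and outer hair cell (IHC/OHC) density
along the flattened organ of Corti, and (iii) functional audiometry (ABR and
DPOAE thresholds) that can be correlated with the structural map.
`cochleostat` implements the full chain and, because every stage is driven
by a synthetic cochlea and cohort generator, the whole pipeline is testable
without animal data. It is aimed at auditory neuroscientists designing
NIHL studies and at anyone who needs a tested reference implementation of
fringe-based stereological counting.

## The estimator at the core

Hair bundles are counted in unbiased frames (inclusion edges top/right,
exclusion edges bottom/left) placed by systematic-uniform-random sampling on
the *stereociliary fringe* — the convex region bounding the stereocilia rows
— within each 5% sector of percent distance from the apex. With per-frame
counts `q_i` and corner-count reference areas `a_i` (each of the 4 frame
corners hitting the fringe contributes a quarter of the frame area):

```
N_A = Σq · 1000 / Σa            bundles per 1000 µm²

CE² = (n/(n−1)) · [ Σq²/(Σq)² + Σa²/(Σa)² − 2Σ(q·a)/(Σq·Σa) ]
```

`CE` is Cochran's ratio-estimator coefficient of error. Sector positions
map to characteristic frequency through the log-linear mouse place map
`f = 10^((A − d_base)/B)` kHz (defaults A = 156.5, B = 82.5, giving
~4.8 kHz at the apex and ~79 kHz at the basal extreme; the basal ~20% lost
to dissection carries the 50–80 kHz band). The lesion model places damage
with an in-band component at the exposure band's geometric-mean place plus
a component shifted 1 octave basally, a basal susceptibility gradient, and
level-dependent peak loss — OHCs losing more than IHCs.

## Worked example

Lesion a synthetic control cochlea with the 105 dB SPL 9–13 kHz sweep and
quantify it:

```r
library(cochleostat)

ctrl <- build_control_map(seed = 1)
les  <- apply_lesion(ctrl, stimulus_spec("violet_sweep", 9, 13, level = 105,
                                         sweep_duration = 10,
                                         total_duration = 1800), seed = 2)
cg_ctrl <- estimate_cochleogram(ctrl, sampling_design(seed = 3))
cg_les  <- estimate_cochleogram(les,  sampling_design(seed = 3))
head(subset(as.data.frame(cg_les), class == "OHC"), 8)
#>    sector class sum_q sum_a_um2 n_a_per_1000um2    ce freq_khz
#> 1       5   OHC    41      3125           13.12 0.165     5.19
#> 3      10   OHC    31      3125            9.92 0.312     5.97
#> 5      15   OHC    29      3125            9.28 0.184     6.86
#> 7      20   OHC    24      3125            7.68 0.202     7.89
#> 9      25   OHC     9      3125            2.88 0.324     9.07
#> 11     30   OHC     3      3125            0.96 0.408    10.43
#> 13     35   OHC    12      3125            3.84 0.283    11.99
#> 15     40   OHC    16      3125            5.12 0.117    13.78
```

The narrow-band exposure cuts OHC density from ~10–13 to ~1–4 bundles per
1000 µm² precisely in sectors 25–35, the place of its 9–13 kHz band; the
unexposed control stays above 10 (OHC) and 4 (IHC) everywhere:

```r
region_means(cg_ctrl)
#>   region class mean_n_a pooled_ce n_sectors
#> 1 apical   OHC    11.39     0.212         5
#> 2 apical   IHC     4.35     0.207         5
#> 3 middle   OHC    11.04     0.184         6
#> 4 middle   IHC     4.53     0.212         6
#> 5  basal   OHC    10.88     0.189         5
#> 6  basal   IHC     4.61     0.254         5

loss <- percent_loss(cg_les, cg_ctrl)
rec  <- simulate_cohort(cohort_design(group_sizes = c(vs105_9_13 = 12),
                                      seed = 4))
mean_threshold_shift(rec, "vs105_9_13", day = 2)
#> [1] 50.90909                       # ~50 dB click shift two days post-noise
structure_function_correlation(rec, loss, "vs105_9_13")$rho
#> [1] 0.7142857                      # tonotopic structure-function agreement
```

`run_pipeline(run_config(seed = 1), "out/")` runs everything — stimulus
WAVs with verification reports, maps, cochleograms, audiograms, the
correlation report and a seed manifest — deterministically; a thin CLI
wrapper lives in `inst/cli/cochleostat.R`.

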