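# endmtrack

Serial anterior-segment OCT of a corneal transplant can reveal immune
rejection before it is clinically visible: the endothelium/Descemet membrane
complex (En/DM) — the two most posterior hyperreflective bands of the cornea —
thickens progressively in grafts that go on to reject, while the overall
corneal thickness is too variable to be a reliable early warning.
`endmtrack` is a desk-scale R implementation of the full analysis chain that
turns radial OCT scans into that predictor, for researchers who want to study
or extend threshold-based rejection surveillance without access to clinical
volumes:

1. **Segmental tomography.** Per A-scan band detection, robust per-B-scan
   boundary estimation with RANSAC polynomial fits, bicubic reconstruction of
   the three interface surfaces, and normal-ray-traced thickness maps of the
   En/DM complex (En/DMT) and the full cornea (CCT), averaged over the
   central 2-mm zone.
2. **Rejection-risk modelling.** The longitudinal En/DMT series per graft is
   converted into a time-dependent threshold covariate
   `X(t) = 1{En/DMT has reached c µm by time t}` in counting-process form,
   and the rejection hazard is modelled as

   `λ(t | X) = λ₀(t) · exp(β X(t))`,

   a Cox proportional-hazards model with Breslow tie handling; `exp(β)` is
   the hazard ratio of rejection after the graft first reaches the cutpoint
   `c`. The package sweeps cutpoints (17–21 µm), computes flag rates and
   crossing-to-rejection lead times, runs forward stepwise covariate
   selection around the threshold model, and fits random-intercept
   repeated-measures trend models contrasting En/DMT with CCT.
3. **Synthetic ground truth.** A phantom generator renders radial-scan OCT
   volumes of a layered spherical-cap cornea (Gaussian band profiles,
   multiplicative speckle, saturation artifact, gross outlier columns,
   nodular excrescences) with analytic truth, and a cohort simulator draws
   longitudinal cohorts calibrated to the published study structure
   (60 grafts, 21 rejected, visits at months 1/3/6/9/12).

## Worked example

Measure a synthetic visit, then run the survival stage on the packaged
calibrated cohort:

```r
library(endmtrack)

# imaging chain: phantom -> render -> segment -> surfaces -> ray trace
spec  <- phantom_spec(endmt_true = 15, speckle_sigma = 0.3,
                      outlier_column_fraction = 0.2, seed = 1)
truth <- make_phantom(spec)
vol   <- render_volume(truth, spec)
measure_visit(vol)
#>   endmt_um  cct_um n_valid_endmt n_valid_cct n_flagged_scans zone_diameter_um
#> 1 15.03034 603.196          1257        1257               0             2000
```

The measured central En/DMT (15.03 µm) recovers the constructed 15-µm layer
to within the sub-micron accuracy the test suite enforces, despite 30%
speckle and 20% corrupted A-scan columns.

```r
cohort <- fixture_default()
flag_rates(cohort, cutpoint = 19)
#>   rejected_flagged clear_flagged n_rejected_flagged n_rejected n_clear_flagged n_clear
#> 1        0.8095238     0.1794872                 17         21               7      39

crossing_stats(cohort, cutpoint = 19)
#> <crossing_stats> n = 17, lead time mean 5.29 months (range 2-11)

sweep_cutpoints(cohort)
#>   cutpoint_um hazard.ratio conf.low conf.high  p.value n_events person_time_exposed status
#> 1          17         10.3     3.46      30.7 2.77e-05       21                 160     ok
#> 2          18         11.7     3.90      34.9 1.10e-05       21                 150     ok
#> 3          19         13.0     4.32      39.3 5.25e-06       21                 144     ok
#> 4          20         11.2     4.00      31.6 4.46e-06       21                  60     ok
#> 5          21         10.2     3.80      27.5 4.20e-06       21                  39     ok
```

81% of rejected grafts are flagged by the 19-µm rule at some pre-rejection
visit versus 18% of grafts that stay clear, the first crossing precedes the
clinical diagnosis by 5.3 months on average (range 2–11), and every swept
cutpoint carries a significantly elevated rejection hazard. `tidy()`,
`glance()`, `autoplot()` and `plot_cohort()` give tibble and ggplot views of
each result; `run_pipeline(pipeline_config(), out_dir)` executes the whole
chain and writes a deterministic CSV/JSON report bundle.

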