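# kymoquant

Kymograph-based quantitation of retrograde axonal transport, with a fully
simulated test bed.

## The problem

In neurons cultured in microfluidic chambers, retrogradely transported
signalling endosomes — classically BDNF bound to its receptor and labelled
with a quantum dot — are followed by live imaging along ~450 µm axons
(1 frame/s for 2 minutes). The standard readout is the kymograph: a 2-D
image with position along the axon on one axis and time on the other, in
which each cargo traces a sloped line. Three per-cargo statistics summarise
transport health:

- **average velocity** `v_avg = D / T` — distance travelled `D` over the
  total observation time `T`, pauses included;
- **moving velocity** `v_mov = D / (T − T_pause)` — the speed while
  actually moving;
- **pause percentage** `100 · T_pause / T`.

Direction is classified from the angle θ of each kymograph line (time
increasing downward, soma to the right): retrograde for
θ ∈ [−89.4°, −1°], anterograde for θ ≤ −90.6°, stationary for
θ ∈ −90° ± 0.5° (the two 0.1° slivers left between these bands are closed
into the stationary class).

Because raw movies of such studies are rarely deposited, `kymoquant` pairs
the analysis chain with a generative test bed: a stochastic
run–pause–switch motility model, a microscope-like movie renderer
(Gaussian PSF, Poisson shot noise, calibrated multi-page TIFF), and a
synthetic puncta-image generator for size-distribution analysis
(endosome/soma areas binned at 0.45 and 0.9 µm²). Every stage of the
pipeline can therefore be validated against known ground truth.

The intended users are lab scientists and methods developers who want a
scriptable, auditable replacement for interactive ImageJ kymograph
tracing, and a way to benchmark such pipelines against simulated truth.

## What is in the package

| Stage | Functions |
|---|---|
| Motility simulation | `transport_params()`, `simulate_trajectory()`, `simulate_cohort()`, `expected_metrics()` |
| Movie rendering & I/O | `optics_config()`, `render_stack()`, `write_stack()` / `read_stack()` |
| Kymographs | `axon_path()`, `build_kymograph()`, `write_kymograph()` / `read_kymograph()` |
| Tracing | `detect_per_frame()`, `link_tracks()`, `segment_track()` |
| Transport metrics | `segment_angle()`, `classify_angle()`, `track_metrics()`, `cohort_metrics()` |
| Puncta sizing | `segment_objects()`, `bin_areas()`, `generate_puncta_image()` |
| Group statistics | `t_test_groups()`, `anova_bonferroni()`, `summarize_groups()` |
| Orchestration | `cmd_simulate()`, `cmd_analyze()`, `cmd_compare()`, `cmd_puncta()` (CLI wrapper in `inst/cli/kymoquant`) |

## Worked example

Simulate the built-in two-group experiment — a control profile
(retrograde run speed 1 µm/s, pause entry 0.1/s) against a transport
deficit profile (run speeds × 0.635, pause entry 0.25/s) — with 10 control
and 20 deficit tracks, then quantify and compare:

```r
library(kymoquant)

cfg <- default_pipeline_config(seed = 11)
coh <- simulate_cohort(cohort_spec(cfg$groups, c(control = 10, asyn = 20),
                                   seed = 11), cfg$acq)
met <- analyze_tracks(lapply(coh$trajectories, trajectory_to_track))
res <- cmd_compare(met, control = "control")

print(res$moving_velocity$summary, row.names = FALSE, digits = 3)
#>    group  n  mean     sem n_flag pct_change        p
#>     asyn 20 0.607 0.00440      0       38.1 1.95e-27
#>  control 10 0.981 0.00819      0        0.0       NA
print(res$pause_percent$summary, row.names = FALSE, digits = 3)
#>    group  n mean  sem n_flag pct_change        p
#>     asyn 20 51.6 1.52      0      -99.4 1.15e-10
#>  control 10 25.9 2.04      0        0.0       NA
print(res$moving_velocity$test)
#> student t test: statistic 44.16, df 28, p 1.952e-27 (**)
```

The pipeline recovers a 38.1% moving-velocity reduction against the
injected 36.5% effect (the deficit group's speed factor 0.635), and the
pause percentage roughly doubles (25.9% → 51.6%), both highly significant
by pooled Student t test at these group sizes. The full imaging route —
`cmd_simulate()` to write movies, `cmd_analyze()` to rebuild kymographs
and trace tracks — yields the same tables from the rendered TIFFs.

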