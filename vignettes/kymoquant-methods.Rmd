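---
title: "kymoquant: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{kymoquant: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kymoquant)
```

# Scope

`kymoquant` quantifies single-cargo axonal transport from kymographs the
way the field's live-imaging studies do — per-cargo moving velocity,
average velocity and pause percentage, with angle-based direction
classification — and wraps the analysis in a generative test bed so every
stage can be validated against simulated ground truth. This vignette is
the package's own account of the models, the tunable parameters, the
numerical choices, and what the simulations do and do not establish about
real data.

# The motility model

A cargo moves in one dimension along the axon; position is measured in µm
from the distal end toward the soma, so retrograde motion increases
position. At frame resolution (default 1 s) the cargo is in one of three
states — retrograde run, anterograde run, pause — and evolves as a Markov
chain:

- from a run, a pause begins with per-step probability
  `p_pause * frame_interval`;
- a pause ends with per-step probability `frame_interval / mean_pause`
  (geometric dwell, mean `mean_pause` seconds — the simplest memoryless
  model consistent with 1 s sampling);
- at each pause exit the run resumes **anterogradely with probability
  `p_switch`, retrogradely otherwise**.

Run displacement per step is `±v · frame_interval · max(0, 1 + speed_cv·z)`
with `z ~ N(0,1)`; pauses do not move; a cargo reaching either end of the
axon reflects and resumes inward, which keeps 120 s tracks inside the
field of view.

The switch rule deserves a note. A symmetric rule ("flip direction at each
pause exit with probability `p_switch`") makes the direction a symmetric
random walk whose stationary distribution is 50% anterograde, i.e. the
cargo loses its retrograde bias entirely on long time scales — the
opposite of what signalling-endosome transport looks like. Resampling the
direction at each pause exit instead (anterograde with probability
`p_switch`) produces brief, single-run anterograde excursions embedded in
retrograde-dominant motion, which is the phenomenon the model is meant to
emulate. This is a deliberate design choice of the package.

## Parameters and defaults

| Parameter | Unit | Control default | Why |
|---|---|---|---|
| `v_retro` | µm/s | 1.0 | typical processive retrograde endosome speed |
| `v_antero` | µm/s | 0.8 | excursions slightly slower than retro runs |
| `p_pause` | 1/s | 0.1 | gives ~10 s runs, visibly processive traces |
| `mean_pause` | s | 3 | short pauses; pause fraction 23.1% (below) |
| `p_switch` | — | 0.05 | rare excursions in healthy transport |
| `speed_cv` | — | 0.1 | mild per-step speed variability |
| `axon_length` | µm | 450 | microgroove length of the culture device |

Acquisition defaults: 1 frame/s for 120 s (`n_frames = 120`; the
trajectory has one state label per inter-frame step, so a track spans
119 s of motion), pixel size 0.16 µm/px. No generative model for these
rates exists in the literature this workflow comes from; the values above
are the package's choices of what a practitioner would call realistic,
fixed once and used unchanged everywhere.

The built-in deficit profile (`asyn_like_params()`) scales both run speeds
by **0.635** — injecting a 36.5% moving-velocity reduction, the magnitude
reported for α-synuclein-overexpressing neurons — and raises `p_pause` to
0.25/s with `mean_pause` 4 s and `p_switch` 0.15. The expected pause
fraction rises from 23.1% to 50%, a ≈27 percentage-point increase, chosen
a priori to match the reported pause increase when read as percentage
points. These effect sizes were fixed before any recovery test was run.

## Closed-form expectations

With `p_switch = 0` the model is an alternating renewal process: runs are
geometric with mean `1/p_pause` s, pauses geometric with mean `mean_pause`
s, so the long-run pause-time fraction is

    f = p_pause · mean_pause / (1 + p_pause · mean_pause)

and, per step of the embedded two-state chain, this is exact (the chain's
stationary pause probability equals `f`). Expected moving velocity is
`v_retro` and expected average velocity `v_retro · (1 − f)`.
`expected_metrics()` refuses `p_switch > 0`, where no closed form exists.

Two assumptions matter when using this as a Monte-Carlo oracle: the
formula ignores boundaries (a cargo rattling against the soma-end
reflection loses path length) and assumes the speed while moving is
always `v` (after a reflection the cargo moves at `v_antero`). Oracle
tests therefore use a very long axon and `v_antero = v_retro`; the study
conditions themselves (120 s movies started 10–50% along a 450 µm axon)
never reach a boundary.

# Rendering and kymograph construction

Spots are isotropic Gaussians (σ = 0.2 µm ≈ 1.25 px) truncated at 4σ
(<0.01% mass loss), on a constant background, with optional Poisson shot
noise; frames are written as 16-bit multi-page TIFF with calibration in a
plain-text `key=value` sidecar, and reading a stack without its sidecar is
an error — calibration is never silently defaulted. Camera gain/read
noise, quantum-dot blinking and chromatic channels are deliberately out of
scope; blinking robustness is exercised separately through detection
dropouts (below).

Kymographs sample the stack along a polyline "line ROI" (default: straight
horizontal, matching axons in microgrooves) at 1 px arc steps, reducing
across a transverse window (default 5 px) with `max` by default —
averaging would dilute dim puncta; `mean` is available. Interpolation is
bilinear. Columns are ordered distal→soma, so **retrograde motion always
drifts toward higher column indices**; this orientation contract is what
makes the angle convention below literal.

# Angle convention and classification

For a segment with soma-ward displacement `u` (µm) and duration `d` (s),

    theta = −degrees(atan2(d / row_scale, u / col_scale))

lies in (−180°, 0°): retrograde in (−90°, 0°), anterograde in
(−180°, −90°), exactly −90° for zero displacement (a vertical kymograph
line; the conventional "90 ± 0.5" stationary band is read as −90 ± 0.5 on
this signed scale, since line-angle signs in interactive tools depend on
draw direction — the package always draws time-forward). Classification
uses the standard cut-offs: retrograde [−89.4°, −1°], anterograde
≤ −90.6°, stationary within 0.5° of −90°. The printed cut-offs leave two
0.1°-wide slivers, (−89.5°, −89.4°) and (−90.6°, −90.5°); the package
closes them into the stationary class (they correspond to displacements
of well under a pixel per two minutes, i.e. indistinguishable from
stationary). Angles above −1° would require >57 columns/row — faster than
any real cargo — and are flagged `unclassified`, warned about, and
excluded from metrics. These closure rules are package decisions and are
echoed into output metadata; they are not claims about any original
author's intent.

# Tracing and segmentation

Detection: per kymograph row, local maxima above `median + min_snr·MAD`
(default `min_snr = 3`), refined by 3-point parabolic interpolation.
Linking: greedy nearest-neighbour with gating at `max_jump` (default
2 µm/frame — twice the control run speed), gap bridging up to `max_gap = 3`
frames by linear interpolation, and a `min_track_len = 10` frame minimum.
Greedy (not global) assignment suffices because kymograph tracks are
sparse; the swap rate is tested on two-ridge fixtures. Because a gap is
filled by linear interpolation, its per-step displacement equals the local
mean slope and the gap inherits the enclosing segment's class — a blinking
quantum dot does not register as a pause.

Segmentation labels each inter-frame step stationary when
`|Δposition| < delta`, else by sign, and merges runs of equal labels. The
default `delta = 0.1` µm/frame is half the PSF σ: the literal stationary
band (±0.5° of vertical) corresponds to sub-nanometre per-frame
displacements, far below localisation noise at 1 s sampling, so a spatial
threshold operationalises "stationary". With the default parameters the
probability that a genuine run step falls under `delta` is negligible
(≳8σ event), which is why segment classes agree with ground-truth states
on >95% of frames in the oracle tests.

"Distance travelled" is the cumulative path length over non-stationary
segments (`distance_mode = "path"`), not net displacement — direction
switches would otherwise cancel; `"net"` is available. Percent change is
reported as `100·(1 − treated/control)`, matching the "reduced by X%"
reporting convention. Group comparisons treat each track as the unit of
analysis (per-track default); aggregating per neuron first is possible by
averaging the metrics table before `cmd_compare()`.

# Puncta and soma sizing

Objects are segmented by global Otsu threshold (deterministic and
parameter-free; a manual threshold override exists), labelled with
8-connectivity (4-connected labelling plus a union-find diagonal merge),
filtered at `min_area_px = 4` to suppress single-pixel noise, and
calibrated as `pixels · pixel_size²`. Areas are binned at 0.45 and
0.9 µm² into small/median/large classes; both edges are assigned to the
median class (reading "0.45–0.9" as a closed interval — the open/closed
status of the printed endpoints is ambiguous, so the rule is fixed and
documented here). Frequencies sum to exactly 100% (the last class absorbs
the floating-point remainder). "Soma size" is implemented and labelled as
**area**; other size measures are out of scope. The synthetic fixture
generator places non-overlapping anti-aliased disks with Gaussian edge
blur and additive noise — adequate for testing thresholding and
calibration, but it does not emulate uneven illumination, touching
organelles, or out-of-focus light, so segmentation accuracy on real
micrographs must be established separately.

# Statistics

Pairwise comparisons default to the pooled-variance Student t test
(two-sided), with Welch available; a caveat is emitted when the group
variance ratio exceeds 4. Degenerate zero-variance-in-both-groups input
returns p = 1 for equal means by convention. Frequency-distribution
comparisons across ≥3 groups use one-way ANOVA with a Bonferroni post
test implemented as p-value adjustment, `p_adj = min(1, m·p_raw)` over all
`m` pairs — standard and reportable per pair, rather than α-splitting.
Significance is annotated at 0.05 (\*) and 0.01 (\*\*). Summaries report
mean ± SEM (SD/√n; 0 with an `n_flag` for singletons) and percent change
versus a named control.

# Problem sizes and determinism

All randomness flows through explicit integer seeds; per-track seeds are
derived from (cohort seed, group, index) so cohorts are reproducible
independent of generation order, and re-running any command with the same
configuration reproduces its CSVs byte-identically. The test suite and the
acceptance script use desk-scale sizes chosen by the package: 10 vs 20
tracks of 120 s for effect recovery (the classic control/transgenic group
sizes), a single 10,000-frame trajectory for closed-form cross-checks,
3–4 noiseless movies per group for the imaging-chain oracle, 50 disks for
puncta recovery, and 2,000 null replicates for the t test's type-I error.

# Known limitations

- The motility model is a stand-in: no load-dependent detachment, no
  motor-number dynamics, no spatial heterogeneity along the axon.
- The renderer omits quantum-dot blinking kinetics, EM-gain/read noise and
  multi-channel imaging; detection robustness to blinking is approximated
  by dropout gaps only.
- The tracer is validated as equivalence to simulated ground truth, not to
  manual expert tracing; on crowded or dim real kymographs the greedy
  linker may fragment or swap tracks.
- Published effect magnitudes from undeposited data (velocity reductions,
  endosome mean areas) are used only as injected effect sizes for recovery
  tests; the package makes no claim to reproduce any specific published
  measurement.
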