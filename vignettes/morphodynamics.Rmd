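---
title: "Quantifying microglial morphodynamics with morphodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microglial morphodynamics with morphodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphodyn)
```

Microglia, the resident immune cells of the brain, are ramified and
highly motile: in homeostasis they continuously scan the parenchyma
with their processes, migrate in a saltatory stop-and-go pattern, send
processes toward focal lesions, and phagocytose synaptic material.
`morphodyn` implements the quantitative readouts used to compare these
behaviours between genotypes or treatments: skeleton-based morphology,
a time-lapse surveillance statistic, migration-track analytics, lesion
response speeds, cytometry-style phagocytosis gating, and the matching
statistical tests. Every stage has a synthetic generator that produces
inputs with known ground truth, so the full pipeline is testable
without microscope data.

## Morphology: Sholl profiles and ramification metrics

A reconstructed cell arrives as an SWC file: a rooted tree of nodes
(id, type, x, y, z in µm, radius, parent). `read_swc()` validates the
tree (single root, resolvable parents, no cycles) and `morphometrics()`
reports total process length (the sum of parent–child Euclidean
segment lengths), the number of tips (non-soma nodes without
children), branch points (non-soma nodes with at least two children),
and the peak of the Sholl profile.

`sholl_profile()` counts, for spheres of radius `dr, 2dr, …` centred on
the soma, the parent–child segments crossing each sphere. Three
conventions are fixed deliberately:

* **Crossing rule.** A segment crosses a sphere of radius $r$ when one
  endpoint lies at distance $\le r$ (closed ball) and the other at
  $> r$. The closed-ball tie-break means a branch tip ending *exactly*
  on a sphere does not create a spurious intersection — a star of
  20 µm branches sampled at `dr = 5` yields counts 4, 4, 4, 0 at radii
  5, 10, 15, 20.
* **No resampling.** Sholl is computed on the straight SWC polyline
  segments, matching how tracing software discretizes processes;
  spline smoothing would silently alter counts.
* **Soma choice.** The soma is the node with SWC type code 1 when
  exactly one exists, else the root.

The default radius step is `dr = 1` µm; it is configurable, and the
profile peak (`max_intersections`) is exposed as the ramification
proxy. Cell counts per cortical area come from `cell_density()`
(cells/mm²).

```{r}
sk <- gen_star_skeleton(n_branches = 4, branch_length = 20, soma_radius = 2)
morphometrics(sk)[c("total_length", "n_tips", "n_branch_points")]
```

## Surveillance: scanned area from binarized frame pairs

The imaging chain mirrors common practice for two-photon time series:
per-slice background subtraction (default: the modal grey level)
clamped at zero, a radius-1 median filter, translational drift
registration against the first frame, maximum-intensity projection
over z, and Huang minimal-fuzziness thresholding.

Huang thresholding picks the grey level minimizing a fuzzy-set measure
of fuzziness: for a candidate threshold each level's membership is
$u(g) = 1/(1 + |g - m|/C)$ with $m$ its class mean and $C$ the
occupied grey-level range, and the criterion is the count-weighted sum
of Shannon entropies $-u\log u - (1-u)\log(1-u)$. The search is
exhaustive over occupied levels, ties resolve to the lowest level, and
a constant image raises an error rather than returning an arbitrary
level. Because thresholds must keep *all* processes visible in *all*
frames, `binarize_movie()` defaults to applying the minimum of the
per-frame Huang thresholds to every frame (`mode = "global-min"`); the
per-frame alternative is available since the choice cannot be settled
from a manual-thresholding description.

`surveillance_area()` XORs consecutive mask pairs — the symmetric
difference captures both extension and retraction, which a signed
subtraction would not — and sums changed pixels over a 10 min window
(configurable, with a start offset), scaled by the pixel area. On the
synthetic monotone-growth movie the result is exact:

```{r}
mm <- gen_motility_movie(canvas = c(64, 64), pixel_size = 0.5,
                         n_frames = 11, growth_px_per_frame = 10, seed = 1)
surveillance_area(mm$movie, window = 10)$scanned_area_um2   # truth: 25
```

Registration is translation-only: the normalized cross-correlation
over the overlap region is maximized by exhaustive search over integer
shifts (ties to the smaller displacement). Rotational drift correction
is out of scope; a rigid-body step can be applied upstream and the
contract — exact recovery of known integer shifts, ±1 px under noise
at SNR ≥ 5 — is what the tests enforce.

## Migration tracks: speeds, MSD, idling decomposition

Tracks are long-format tables of positions in µm at a uniform frame
interval. Two normalizations happen on construction: MTrackJ-style
column aliases are harmonized, and tracks with missing frames are
*split* at the gaps rather than interpolated, because displacement
across a gap is not a speed between consecutive time points. 3D
positions are used whenever a z column is present.

Instantaneous speed is $v_i = \lVert p_{i+1} - p_i \rVert / \Delta t$;
average speed is path length over duration (identical to the mean
instantaneous speed at uniform sampling — an identity the tests
assert). `filter_tracks()` implements the inclusion rule that a cell
must remain in view at least 100 min (inclusive boundary).

Idling is defined by a threshold on instantaneous speed: intervals
with $v < \theta$ are idling, the rest active. The default
$\theta = 1.5$ µm/min is the MSD-derived threshold for embryonic
cortical microglia; 15 µm per 10 min is the same quantity in the
10-min-interval spelling, and all thresholds are stored in µm/min to
avoid double bookkeeping. Strict inequalities are used throughout
(a cell exactly at threshold is active; the "high active speed"
classification at 2.5 µm/min likewise requires strictly greater), so
boundary cases fall deterministically to the non-strict side. A phase
that never occurs yields `NA`, never a fabricated zero. Per *cell* —
not per interval — is the unit of downstream statistics;
`motility_metrics()` returns one row per cell and the pooled idling
fraction as an attribute.

`msd_curve()` is the time-averaged MSD with overlapping origins,
pooled across tracks by pair count. `estimate_idling_threshold()` fits
the short-lag MSD to $4D\tau + c$ and converts the fitted one-frame
displacement scale to a candidate threshold; since the original
macro's exact MSD-to-threshold mapping is not published, the estimate
is *advisory* — it is reported next to the configured default and
never silently replaces it, and ballistic curvature
(MSD(2Δt)/MSD(Δt) > 3, against 2 for diffusion and 4 for ballistic
motion) flags it as unreliable.

For the lesion assay, process tips converging on a lesion centre are
analyzed over the first 15 min of each track. Tips are averaged
within their parent cell *after* computing per-tip average speeds
(tips-then-mean; the alternative ordering is not distinguishable from
published descriptions, so one order is fixed and documented), and the
population time course is the per-timepoint mean ± SEM across cells.

## Phagocytosis gating

Single-channel fluorescence event tables are gated against
no-substrate controls: `fit_gate()` places the gate at a high quantile
(default 0.995) of the control distribution, a standard positivity
convention standing in for a manual cytometry gate — the quantile is
configurable precisely because the original gate placement is not
reported. Events strictly above the gate are phagocytic;
`quantify_phagocytosis()` reports their percentage and their MFI. The
MFI is the **median** intensity of positives (the mean is available as
an option): where descriptions of the readout disagree between median
and mean, the median is the deliberate default since it is the robust
choice for log-normal-like fluorescence. `phagocytosis_timecourse()`
gates each timepoint on that timepoint's controls, summarizes
replicates as mean ± SEM per group, and compares groups per timepoint
with the exact Mann–Whitney test, Holm-adjusted across timepoints.

## Statistical toolkit

`compare_groups()` encodes the conventional decision rule: Shapiro–Wilk
on both samples, Student's t-test when both pass, Mann–Whitney
otherwise, two-sided throughout. `mann_whitney_exact()` computes U
from midranks and an exact two-sided p by full enumeration of label
assignments up to combined n = 14 (enumeration is instant there;
beyond it, the normal approximation with tie correction). The
deviation-based two-sided p equals the usual doubled tail under the
symmetric null and, unlike the classical exact network algorithm,
remains exact under ties. `fisher_exact()` and `holm_adjust()` delegate
to the corresponding routines in `stats` (their results are verified
against independent hypergeometric / step-down enumerations in the
test suite); Holm is the default correction for the time course
because the multiple-comparison procedure behind "multiple
Mann–Whitney" outputs of common GUI software is not specified —
Bonferroni and none are available. `fold_change_ddct()` implements
$2^{-\Delta\Delta C_t}$ relative expression.

## What the synthetic generators emulate — and what they do not

| generator | emulates | ground truth |
|---|---|---|
| `gen_star_skeleton` | analytic ramified cell | closed-form Sholl/lengths |
| `gen_random_tree` | varied tree morphologies | construction totals |
| `gen_saltatory_tracks` | stop-and-go soma migration | per-interval phase labels |
| `gen_motility_movie` | process extension/retraction | exact changed-pixel counts |
| `gen_lesion_tracks` | radial process convergence | uniform known speeds |
| `gen_cytometry_events` | two-population uptake mixture | per-event labels |

Choices worth noting:

* The saltatory generator is a stationary two-state chain: each
  interval keeps its phase or, with probability `p_switch`, redraws it
  from Bernoulli(`p_idle`), giving a controllable long-run idle
  fraction with bursty phases — the simplest process reproducing the
  qualitative saltatory pattern. Defaults (50 tracks × 36 frames at
  Δt = 10 min, `v_active` = 3, `v_idle` = 0.3 µm/min, idle fraction
  0.6) represent a realistic 6 h acquisition of an embryonic cohort
  with clear phase separation around the 1.5 µm/min threshold.
  Directions are isotropic in 2D by default (path-length metrics do
  not depend on dimensionality; a 3D flag exists).
* Random trees grow strictly outward (each child is farther from the
  soma than its parent), so each segment crosses a Sholl sphere at
  most once and the dense-resampling oracle and the endpoint rule must
  agree exactly — making the Sholl acceptance check an integer
  equality, not an approximation.
* The movie generator grows the mask monotonically with per-frame
  disjoint change sets, so the XOR ground truth is exact and the
  surveillance check is equality, not tolerance.
* None of the generators simulate microscope physics: no PSF, no shot
  noise beyond optional additive Gaussian, no photobleaching, no ATP
  gradients or chemotaxis, no 3D drift. Passing tests therefore
  validate the *measurement* pipeline on idealized inputs; they do not
  certify segmentation quality or tracking accuracy on real movies,
  which are produced upstream (ROIs and tracks are manual inputs).

## Numerical choices and problem sizes

Degenerate inputs fail loudly: constant images in thresholding,
single-point tracks, empty controls, and structurally invalid SWC
files all raise errors naming the offence. Tie-breaks (closed-ball
Sholl, strict speed thresholds, lowest-level Huang ties, boundary
events negative at the gate) are fixed and covered by boundary tests.

The simulation sizes used by the test-suite and the acceptance script
— 100 random trees for the Sholl oracle, 200 Brownian tracks × 100
frames for diffusion recovery, 50 saltatory tracks × 36 frames, 10⁴
cytometry events × 20 seeds, exhaustive Fisher enumeration up to table
total 40 — were chosen so each property is measured well inside its
stated tolerance while the whole suite completes in about a minute on
a laptop core; they are package defaults, not physical constants, and
every generator accepts larger sizes.

## Limitations

* Registration is translation-only; rotational drift must be corrected
  upstream.
* Surveillance is 2D (post-projection); no per-z-slice variant.
* The control-quantile gate is a stand-in, not a reconstruction of any
  specific cytometry analysis.
* No hierarchical modelling: cells are treated as independent units,
  and mouse-level pseudo-replication is knowingly out of scope.
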