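---
title: "Quantifying direction changes after cell-cell contact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying direction changes after cell-cell contact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clumptrack)
library(dplyr)
```

## The question and the measurement model

In time-lapse movies of migrating cells such as *Drosophila* macrophages,
moments where two cells' microtubule bodies overlap can be read as moments
of cell-cell contact. The hypothesis this package operationalizes is that
such contact changes the direction of migration. The measurement is
deliberately minimal: a cell's heading just before it enters an overlap is
compared with its heading just after it leaves, and the same construction
applied to a contact-free stretch of the same track serves as the matched
control. The package provides the full chain - segmentation, tracking,
contact bookkeeping, angle measurement, paired statistics - plus a seeded
synthetic-movie generator that makes every stage verifiable against ground
truth.

Throughout, coordinates are x = column, y = row, both 0-based with pixel
centers at integers; frame indices are 0-based; angles are radians
internally and degrees in every report.

## Segmentation

Each channel of each frame passes through:

1. **Gaussian low-pass** (`gaussian_lowpass()`, sigma 2 px by default).
2. **Hysteresis thresholding** (`hysteresis_mask()`): foreground is every
   pixel at or above the *low* threshold that is 8-connected to at least one
   pixel at or above *high*. With `low == high` this is plain thresholding.
3. **Morphological opening** with a disc of radius 3 px (`open_mask()`),
   removing noise specks and thin spurs.
4. **8-connected labeling** (`label_mask()`) and per-object centroids/areas.

A microtubule-channel object whose region contains two or more nucleus
centroids (rounded to the nearest pixel) is flagged as a **clump**. Centroid
membership, rather than mask overlap, was chosen as the simplest reading of
"nuclei within the area"; for compact nuclei the two rules differ only when
a nucleus straddles an object boundary.

Thresholds default to per-frame adaptive values (mean + 1 sd and
mean + 3 sd of the smoothed intensities). Adaptive thresholds always chase
the brightest tail of the intensity distribution, which is the right
behaviour on frames that do contain cells and the wrong one on empty
frames; for synthetic movies, where the rendered peak intensities are known
exactly, `synthetic_segment_params()` instead fixes the thresholds at
0.15/0.35 of the nucleus peak (the blurred Gaussian peak halves under the
sigma-2 low-pass) and 0.45/0.70 of the disc level with a gentler sigma-1
low-pass on the microtubule channel, which keeps the fused/apart transition
of neighbouring discs sharp. These fractions were derived from the blurred
edge profiles of the renderer, not fitted to any test outcome.

## Keyhole tracking

Linking works on parent (t-1), present (t), child (t+1) triplets. From the
parent and present positions the child position is extrapolated linearly,
and candidate detections are gated by a keyhole-shaped region: the union of

* a **wedge** centered on the motion direction, half-angle 30 degrees,
  length 3 times the last per-frame displacement - anticipating continued
  motion - and
* a **circle** around the present position of radius
  max(|displacement|, r_min) with r_min = 5 px - tolerating stops and
  reversals. Newborn tracks (no velocity yet) use the circle alone.

The published description of the keyhole gate leaves its exact dimensions
to the original tracking software, so all three parameters are exposed in
`track_params()`; the defaults above are the package's own calibration and
are deliberately conservative. Conflicts where two tracks admit the same
detection are resolved greedily by distance to the predicted position, ties
to the lower track label, so linking is deterministic. A track that misses
one frame is terminated (no gap closing): downstream case selection demands
complete windows anyway, and conservative termination avoids manufacturing
identity switches. Unclaimed detections start new tracks, labeled in order
of creation from 1.

## Clump codes, spans and experiment cases

The member labels of a clump are packed into one integer by writing the
ascending-sorted labels as base-1000 digits (`encode_clump_code()`), e.g.
{1, 2} -> 2001 and {2, 3, 5} -> 5003002; 0 means "not in a clump". The base
must exceed every track label; the encoder refuses labels >= base rather
than corrupting silently. Codes are stored as doubles, exact up to 2^53
(five members at base 1000). A worked-example table in the source material
prints one arithmetic string inconsistent with both its own code column and
the defining formula; the formula is treated as authoritative.

`find_clump_spans()` extracts maximal runs of identical non-zero codes per
track: first frame `t_k0`, last frame `t_kC`, and **time in clump**
TC = t_kC - t_k0 + 1 (an inclusive frame count, since the defining phrase
enumerates the interacting frames). A brief mid-overlap code change (a
third cell touching for one frame) therefore splits the run; such cases are
excluded by the in-and-out criterion below anyway.

`select_cases()` keeps spans with exactly two member labels whose track is
present and clump-free over the 2S frames before `t_k0` (which doubles as
the control window) and the S frames after `t_kC` - the cell enters and
leaves without disappearing or joining another clump. Selection is fully
automated here (the original workflow was semi-automatic); cases whose
partner also qualifies are flagged `partner_valid` rather than filtered, so
per-clump analyses remain possible, and `validate_cases()` re-checks every
emitted case with an independent implementation of the predicates.

## The direction-change angle

With S = 5 (default - the immediate reaction), the entry heading is
`position(t_k0 - 1) - position(t_k0 - S)` and the exit heading
`position(t_kC + S) - position(t_kC + 1)`. `incidence_rotation()` rotates
the coordinates rigidly so the entry heading lies along +x'; theta_x is the
exit heading's angle in that frame, wrapped to [-pi, pi].

**Sign convention.** Positive theta_x is a counter-clockwise turn in the
mathematical orientation of the (x, y) pixel coordinates. Because image
rows grow downward, a positive angle appears clockwise when frames are
displayed with the origin top-left; `plot_tracks()` reverses the y axis so
plots match the image. Mirroring the coordinates negates every angle, and
rigid motions of the whole field leave the angles unchanged - both are
property-tested.

**Controls.** The control angle re-runs the same geometry on the 2S
clump-free frames leading up to the clump, split at `t_k0 - S` into an
entry half `[t_k0 - 2S, t_k0 - S - 1]` and an exit half
`[t_k0 - S, t_k0 - 1]` - i.e. the contact construction with a zero-length
clump. The published description fixes the four marker frames bounding
these windows but not the split itself; the two-halves reading is the one
that makes the control geometrically identical to a TC = 0 contact.

**Degenerate cases.** A zero-length heading (stationary half-window) has no
direction; the case is kept in the angle table with `theta_deg = NA` and a
`degenerate` flag, and dropped pairwise from the statistics.

## Statistics

`compare_groups()` summarises both groups in degrees and runs a paired
Wilcoxon signed-rank test (medians) and a paired t-test (means). Pairing is
the package's reading of per-track controls; an unpaired mode exists for
sensitivity analysis. The signed-rank p-value uses the exact null
distribution for up to 25 effective pairs - via the standard rank-sum
distribution when the absolute differences are untied, and by exact
convolution of the tied ranks otherwise - and a normal approximation with
continuity and tie correction above; zero differences are dropped, and an
all-zero difference vector is reported as degenerate with p = 1. Fewer
than 5 pairs is refused outright. `stratify_by_tc()` filters cases by time
in clump; the combined headline analysis keeps TC < 10, the range in which
contacts are short enough to read as single interactions at 10 s/frame.

## The synthetic generator

`synth_spec()` + `simulate_trajectories()` + `render_movie()` emulate the
study data: frames of 512 x 672 px, bright compact nuclei (Gaussian spots,
sigma = nucleus_radius/2, peak 200) inside dimmer microtubule discs (radius
12 px, level 120), cells moving at 2 px/frame, additive Gaussian noise
(default sd 20, i.e. 10% of the nucleus peak), and scheduled two-cell
contacts after which each cell departs with its entry heading rotated by a
programmed angle. All randomness flows from the single spec seed and runs
are bit-reproducible.

Contact geometry was the one genuinely open design problem. Each scheduled
pair approaches on an antiparallel flyby with 27.4 px lateral separation,
takes a single 3.5 px lateral step into a 20.4 px hold separation
(1.7 x cell radius) for exactly TC frames, steps back out, and departs
along the turned heading; the hold side is chosen so the turned departure
headings diverge. The margins come from the renderer's blurred edge
profiles: at 20.4 px the discs are robustly fused (the neck survives the
r = 3 opening) while the nuclei remain far above separability; at 27.4 px
the discs are robustly separate even under noise. The rendered merge
interval therefore equals the programmed TC exactly, with no ambiguous
partially-fused frames, and the 3.5 px step stays inside the keyhole circle
even after centroid-estimation noise. Holding instead at a fraction *below*
one cell radius - total engulfment - was rejected because at that distance
the two nuclei fuse into a single red object, the nucleus-counting rule can
no longer see the clump, and tracking breaks mid-contact; 1.7 radii is the
package's definition of programmed overlap. The turn is applied
instantaneously at exit, matching the two-point entry/exit measurement.

What the generator does **not** emulate: microtubule arm morphology,
intensity heterogeneity between cells, photobleaching, drift, cell division
and three-plus-cell clumps. Passing the recovery suite therefore
demonstrates the pipeline's correctness on its stated model, not robustness
to every pathology of real movies; on real data the adaptive thresholds and
the keyhole parameters are the knobs to revisit first.

## Problem sizes and verification

The test suite validates each stage against independent oracles
(flood-fill hysteresis, hand-looped morphology, cross/dot angle formula,
brute-force enumeration of all 2^n sign assignments for the signed-rank
null) and the whole pipeline against ground truth: a 40-frame movie with 10
contacts (turn 30 degrees, TC = 3, noise 10% of the nucleus peak) must
yield all 20 cases with TC recovered exactly to +-1 frame, mean contact
angle within 10 degrees of the programmed turn and controls within 10
degrees of zero. Statistical calibration uses 200 replicates at the
combined-analysis configuration (n = 33 pairs) for power and 1000
null replicates for the type-I rate. These sizes were chosen as the
smallest that make the checks statistically meaningful.

## Known limitations

* Clumps of three or more cells are encoded and annotated but never become
  experiment cases; only pairwise contacts are analyzed.
* No gap closing: a single missed detection splits a track and can discard
  an otherwise valid case.
* Overlapping cells are kept as one object; no boundary disambiguation
  inside clumps is attempted.
* The direction change is a two-point measurement; speed, curvature and
  acceleration profiles are out of scope.
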