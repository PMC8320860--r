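# clumptrack

Do migrating cells change direction because they touched another cell?
`clumptrack` is an R toolkit for answering that question from two-channel
fluorescence time-lapse movies of fluorescently labelled cells (for example
macrophages with labelled nuclei and microtubules). It segments both
channels, tracks the nuclei, detects moments of cell–cell contact as
*clumps* — single microtubule-channel objects containing two or more
nuclei — and quantifies each cell's signed change of direction before versus
after the contact, paired with a matched no-contact control window from the
same track. It is aimed at cell-migration labs and image-analysis
practitioners who want the whole chain, from pixels to a paired test, in a
scriptable, fully seeded pipeline.

## What it computes

**Segmentation.** Per frame and channel: Gaussian low-pass, hysteresis
thresholding (foreground = pixels ≥ *low* that are 8-connected to a pixel ≥
*high*), and a morphological opening with a disc of radius 3 px. A
microtubule object containing ≥ 2 nucleus centroids is a clump.

**Tracking.** Nuclei are linked frame to frame with a keyhole-style motion
gate: from a track's positions at *t−1* and *t* the next position is
extrapolated linearly, and a candidate at *t+1* is admissible if it falls in
the union of a narrow forward wedge (half-angle 30°, length 3× the last
displacement) and a tolerance circle around the present position (radius
max(|displacement|, 5 px)), which tolerates stops and reversals.

**Clump codes.** The set of track labels sharing a clump is encoded in one
integer by writing the ascending-sorted labels as base-1000 digits:

    c(r_1, ..., r_m) = sum_i 1000^(i-1) * r_i,   r_1 < ... < r_m

so tracks {1, 2} encode to 2001, {2, 3} to 3002, {2, 3, 5} to 5003002, and
code 24013 decodes to tracks {13, 24}.

**Direction change.** For a clump occupying frames *t_k0 … t_kC* of a track,
the entry heading uses the positions at *t_k0 − S* and *t_k0 − 1* and the
exit heading the positions at *t_kC + 1* and *t_kC + S* (default S = 5
frames, the immediate reaction). The coordinates are rotated so the entry
heading lies along +x′ (the incidence rotation); the direction change
θx ∈ [−π, π] is the exit heading in that frame, positive counter-clockwise.
The control repeats the construction on the 2S clump-free frames before the
clump. Cases (two-cell clumps with complete clump-free windows, both
partners analyzable) are compared contact vs. control with a paired Wilcoxon
signed-rank test (exact null distribution up to n = 25, tied ranks by exact
convolution) and a paired t-test, optionally stratified by time in clump
(TC), e.g. combining only cases with TC < 10.

A fully seeded synthetic-movie generator renders ground-truthed movies
(Gaussian nuclei inside dimmer microtubule discs, programmed contacts with
known TC and turn angles, additive noise) so every stage — and the whole
pipeline — is testable without any imaging data.

## Worked example

Simulate a movie with ten two-cell contacts (turn 30°, TC = 3 frames,
noise at 10% of the nucleus peak), then run the full pipeline:

```r
library(clumptrack)

spec  <- synth_spec(n_frames = 40, n_interactions = 10, turn = 30, TC = 3, seed = 7)
movie <- render_movie(simulate_trajectories(spec))
res   <- run_pipeline(movie, pipeline_config(segment = synthetic_segment_params(spec)))

nrow(res$cases)
#> [1] 20
res$comparison
#> Direction-change comparison (degrees)
#>   filter:    TC < 10
#>   contact:   mean  30.50 (sd   2.13)
#>   control:   mean  -0.08 (sd   2.44)
#>   n:         20 paired
#>   Wilcoxon p: 1.907e-06 (exact signed-rank distribution)
#>   t-test p:   1.373e-18
```

All 20 cases (both partners of each contact) are recovered; the mean contact
angle matches the programmed 30° turn while the matched controls sit at 0°,
and both paired tests reject equality. `tidy()` and `glance()` return the
same numbers as tibbles, and `autoplot(res$comparison)` draws the paired
boxplots. Real movies enter through `read_movie_tiff()`, or an existing
track table through `read_tracks()` / `run_pipeline("tracks.csv", ...)`.
A command-line front end is installed at `inst/cli/clumptrack`.

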