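---
title: "In situ helical reconstruction and sub-tomogram averaging: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In situ helical reconstruction and sub-tomogram averaging: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cytoskeletal filaments observed in situ by cryo-electron tomography are too
noisy to interpret individually: tomograms are recorded over a limited tilt
range (here −60° to +60°), so a wedge-shaped region of Fourier space is never
measured, and the electron dose per tomogram keeps the signal-to-noise ratio
far below one. Two averaging strategies recover structure anyway. For
helical polymers, every subunit is a repeated measurement of the same
molecule: segments cut along a filament every 32.13 Å can be aligned,
projected and back-projected into a single 3D average whose **helical rise**
(axial translation per subunit, Å) and **twist** (azimuthal rotation per
subunit, degrees) are then refined from the map itself. For globular
particles such as ribosomes, many copies at random orientations are aligned
in 3D and averaged (sub-tomogram averaging), and species can be told apart
by classification and by difference densities — for example the enlarged
rRNA expansion segments that mark Asgard archaeal ribosomes.

`tomohelix` implements both workflows generically, together with a
synthetic-tomogram generator that provides exact ground truth, so that every
stage is testable without any experimental data.

## The filament model

A filament is modelled as a 1-start helix: subunit $k$ sits at arc position
$k\,\Delta z$ along the traced centerline with azimuth $k\,\Delta\phi$ about
the local axis, where $\Delta z$ is the rise and $\Delta\phi$ the twist
(negative = left-handed). With `two_strands = TRUE` a second strand is added
at a 180° azimuthal offset with the same parameters — the simplest geometry
consistent with a twisted double-stranded appearance; the true strand
arrangement of the target filament is not known, and this choice gives the
map an exact C2 symmetry about its axis (so azimuths are determined modulo
180°, which the alignment and the tests account for). The F-actin-like
defaults are rise 27.9 Å and twist −167.7°; the alignment prior is the
canonical F-actin textbook pair (27.5 Å, −166.7°), deliberately distinct
from any simulated specimen so that parameter recovery is a real
measurement, not an echo of the prior.

The subunit density is a pseudo-atomic stand-in. The default `two_lobe`
model (two unequal Gaussian lobes, 45 Å across) was chosen over a single
Gaussian for two reasons: a one-lobed isotropic subunit makes the filament
non-polar (flip-symmetric), so polarity estimation would be meaningless, and
its form factor decays so fast that the 27.9 Å lattice reflection would be
invisible — a single Gaussian of realistic size is *smoother* than a real
protein. Subunit centers sit 15 Å off the axis and each copy is tilted 40°
from the tangent toward the radial direction; the resulting ~70–80 Å
filament diameter is a modelling default (no measured value is available).

## What the simulator emulates, and what it does not

`simulate_filament_dataset()` renders each filament into its own
tomogram-sized volume: in-plane orientation at a random angle (filaments in
cellular tomograms lie close to the specimen plane), random azimuthal phase,
gentle random bowing (8 Å amplitude — cytoskeletal filaments are stiff),
random polarity (half the traces run against the helix growth direction,
as manual picking cannot know polarity), the single-axis missing wedge of
the −60..+60° geometry, and additive white Gaussian noise. SNR is defined
as signal variance over noise variance *within the signal support mask*;
conventions differ between packages, so this definition is part of the
package contract. Filaments span the volume (780 Å) so that every retained
segment sees a continuous filament through its box, as micron-long
filaments do in real tomograms.

Deliberately not modelled: electron-optical image formation (CTF, dose
weighting, detector MTF), per-tilt alignment errors, tomographic
reconstruction artifacts beyond the wedge, crowding by other molecules, and
structured (non-white) noise. A single analytic CTF could be multiplied
onto projections but is off by default. Passing tests therefore demonstrate
the correctness and statistical behavior of the algorithms under idealized
image formation — not robustness to every pathology of real data.

## The filament pipeline, stage by stage

1. **Segmentation** (`segment_trace`): segments every 32.13 Å of arc along
   a natural-spline interpolation of the trace, with parallel-transport
   local frames (no artificial frame torsion).
2. **Oriented extraction**: one trilinear resampling takes each segment
   from the tomogram into a cube with the filament along +z. The free
   in-plane azimuth is chosen so that the projection direction coincides
   with the beam axis: the projected central slab is then the fully sampled
   tilt-0 section, and the missing wedge can neither streak the images nor
   bias the twist search. (This is what the classical "rotate to z, rotate
   90°, project along z" recipe achieves for in-plane filaments.)
3. **Cylinder centering** (`center_on_cylinder`): translation-only
   alignment of the z-projection against a soft-edged disc (radius 40 Å by
   default; the reference is featureless so no structural bias enters).
4. **Projection matching** (`align_2d`): reference projections on an
   azimuth grid (4°), in-plane angles ±15° about both polarity branches
   (ψ ≈ 0 and ψ ≈ 180 — a filament viewed with reversed polarity matches
   the 180°-rotated projection at a mirrored azimuth), scored by locally
   normalized cross-correlation over integer shifts with parabolic
   sub-pixel refinement, followed by a 1° local polish. Three numerical
   details matter and were each adopted after the plain implementation
   measurably failed: images and references are apodized (Tukey window) so
   density running off the box faces cannot dominate; the correlation is
   normalized per shift (the norm of the image under the shifted window),
   otherwise zero shift always wins on smooth filament images; and a weak
   Gaussian prior on shifts anchors the degenerate azimuth/axial-shift
   ridge of low-pass filament images at the trace-derived centers.
   Polarity is committed per filament (the branch with the better total
   score), since branch-inconsistent segments would back-project mutually
   flipped copies; per-segment branch preferences are kept for the
   diagnostic vote.
5. **Axial register**: for co-centered back-projection the correct axial
   shift of segment $i$ is its lattice phase $c_f - s_i \bmod \Delta z$
   with a single unknown phase $c_f$ per filament. In the first round the
   60 Å-filtered reference carries no lattice striations, so the measured
   shifts are register noise; they are projected onto a coherent register
   at the prior rise (`estimate_register_rate`, a score-weighted circular
   consensus). Later rounds align against lattice-bearing references and
   their measured shifts are used as-is.
6. **Reconstruction** (`reconstruct_3d`): weighted back-projection of the
   canonicalized images at their azimuths, with transverse Fourier weights
   equal to the local angular sampling density (the exact density
   compensation for the single-axis geometry about the helical axis; the
   classical ramp filter is its uniform-coverage limit). Half-maps are
   split by filament — never by segment — so overlapping segments cannot
   inflate the FSC.
7. **Symmetry refinement** (`refine_helical_params`): grid search over
   (rise, twist) maximizing the mean over $k = 1..K$ of the normalized
   correlation between the map and its $k$-th helical transform, with
   exact Fourier phase shifts along z and a separable cylindrical mask
   whose z-window is shrunk by the largest candidate shift plus one
   subunit (`edge_pad`). Both details are essential: trilinear z-shifts
   bias the search toward integer-voxel rises, and box-face fall-off
   biases it toward small rises. A coarse 0.5 Å/0.5° grid is followed by a
   0.1 Å/0.1° local grid and parabolic peak interpolation. A flat surface
   (featureless cylinder) raises an "unresolved" error instead of
   returning a meaningless argmax.
8. **Reference update**: by default the next reference is a clean
   parametric helix re-rendered at the refined parameters and low-passed
   at the measured FSC resolution (`reference_mode = "model"`). The
   refined parameters remain data-driven — references rendered at
   deliberately wrong parameters still recover the generative values in
   validation — while the reference itself stays noise-free, which proved
   decisive for convergence at SNR 0.1. `reference_mode = "map"` instead
   uses the symmetrized reconstruction itself (the choice appropriate for
   real data, where no parametric density model should be trusted);
   symmetry is imposed with the refined values only once the search shows
   a confident interior peak, and with the prior until then.
9. **Final round**: 2D classification with frozen alignments (k = 8, a
   k-means-style correlation clustering), class selection by an adaptive
   contrast floor (≥ 0.4 × median class contrast) — a fixed "top 70%" cut
   was found to discard well-aligned segments arbitrarily and bias the
   azimuthal coverage — then a fine local re-alignment of the survivors,
   final half-map FSC, symmetry re-optimization, and polarity voting
   (diagnostic only by default, matching the source workflow's decision
   not to apply votes at limited resolution).

## Sub-tomogram averaging and difference densities

`align_subtomograms` searches a quasi-uniform ZYZ Euler grid (φ counts
scaled by sin θ) with translations from 3D FFT cross-correlation, then
halves the angular step in local refinement levels; scores are restricted
to the particle's sampled Fourier region when the acquisition geometry is
given (constrained correlation). `average_subtomograms` rotates each
particle's binary wedge mask with it and normalizes every Fourier voxel by
its coverage, floored so unmeasured voxels stay zero.

`classify_subtomograms` without seed references performs focused difference
classification: per-particle residuals against the wedge-weighted global
mean are formed inside each particle's sampled region and a low-frequency
band (18 Å default), the cross-particle variance map pinpoints where the
population genuinely differs, and particles are clustered on their residual
density inside that focus region, refined by EM with leave-one-out class
means. Three pitfalls shaped this design, each diagnosed on ground-truth
simulations: differently oriented missing wedges of the shared bulk
dominate naive residuals; partially sampled voxels at rotated wedge
boundaries carry large structured errors; and without leave-one-out, a
particle's own contribution to its class average pins weak assignments.

`fit_reference` (coarse Euler grid + Nelder–Mead on the real-space
correlation after matched low-pass filtering) superposes a reference onto
an average, and `difference_density` z-score-normalizes both maps inside
their common support, thresholds the positive difference at
`sigma_threshold` (3 by default, in normalized-map units), and reports
26-connected components above `min_blob_volume` (5 voxel volumes) with
centroids and volumes — the generic form of spotting rRNA expansion
segments as extra densities on a ribosome average.

## Conventions and numerical choices

* Volumes: 3D arrays with isotropic voxel size in Å; physical coordinates
  with the origin at the center of the first voxel. Tables store Å, never
  voxels, so they survive rebinning.
* Angles: intrinsic ZYZ Euler angles in degrees, rotation of the reference
  into the particle; right-handed axes, beam along +z, default tilt axis y.
* Interpolation is trilinear everywhere (documented accuracy/speed
  compromise at the ~20–30 Å target resolutions); operations that would be
  biased by it (the symmetry objective's axial shifts) use exact Fourier
  phase shifts instead.
* FSC threshold 0.143 by default (configurable to 0.5); resolution by
  linear interpolation at the first crossing; identical maps report the
  Nyquist limit.
* The wedge fraction is measured within the Nyquist disc of the plane
  perpendicular to the tilt axis, where "fraction of Fourier space" is
  geometrically meaningful (±60° → exactly 1/3).
* All randomness flows from explicit integer seeds; identical inputs give
  bit-identical outputs.

## Problem sizes

The validation suite runs at desk scale: 20 filaments (~300 segments in
64³ boxes at 5.36 Å) for end-to-end parameter recovery at SNR 0.1;
30 filaments at SNR 0.2 for polarity voting; ~800 segments for the
FSC-vs-count monotonicity check; 40 particles in 48³ boxes at 4.51 Å for
two-species classification. These sizes were chosen so each experiment
carries enough statistics for its tolerance while completing in minutes.

## Known limitations

* The refined twist carries a small systematic bias (≈ −0.7° at the
  validation conditions), a residual echo of the reference's azimuth
  columns in projection matching; it is within the ±1° band used for
  validation but would matter for sub-degree work.
* Axial register across segments leans on accurate traces; with poor
  picking the register consensus (and the `reference_mode = "map"` path)
  degrade gracefully but have not been stress-tested against gross trace
  errors.
* 2D alignment scores ignore the per-segment wedge; this is justified here
  because beam-aligned projections are wedge-free central sections, but
  oblique filaments (steeply tilted out of plane) would reintroduce wedge
  effects that the current scoring does not compensate.
* The model-rendered reference update assumes the subunit stand-in is an
  adequate density model; for real data use `reference_mode = "map"`.
* Image formation is idealized (see the simulator section): no CTF by
  default, white noise, perfect tilt alignment.
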