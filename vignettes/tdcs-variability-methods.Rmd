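---
title: "Modelling interindividual variability in tDCS dosimetry: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling interindividual variability in tDCS dosimetry: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdcsfield)
```

## The physical model

Transcranial direct current stimulation (tDCS) delivers a weak direct
current (typically 1 mA) through pad electrodes on the scalp or body.
At DC the quasi-static approximation applies: capacitive and inductive
effects are negligible, and the electric potential $\phi$ inside the
conductive tissue obeys

$$\nabla \cdot (\sigma \nabla \phi) = 0,$$

where $\sigma$ (S/m) is the local tissue conductivity. The electric
field and current density follow as $\mathbf{E} = -\nabla\phi$ and
$\mathbf{J} = \sigma \mathbf{E}$. Within any region of uniform
conductivity, $|\mathbf{E}|$ and $|\mathbf{J}|$ differ only by the
constant factor $\sigma$, so any scale-invariant statistic (percentile
ratios, focality fractions, coefficients of variability) is identical
for the two fields; the package computes statistics from $|\mathbf{E}|$
and exposes $\mathbf{J}$ alongside.

The exterior boundary (the bounding box of air around the body) is
insulating: the normal component of $\mathbf{J}$ vanishes. In the
finite-volume discretization this needs no special treatment — air has
$\sigma = 0$, so every tissue–air face carries zero conductance, which
simultaneously realizes the insulated box and the condition that the
current density be parallel to the skin at skin–air interfaces. Tissues
with $\sigma = 0$ in the conductivity table (internal air, pharynx,
trachea lumen) are insulators by the same mechanism.

## Discretization and solver

The domain is a uniform voxel grid (cell-centred values, isotropic
spacing $h$). Box integration over each cell gives the standard 7-point
scheme: the face conductance between two adjacent voxels is the
harmonic mean of their conductivities times face area over spacing
($g = \bar\sigma_{\mathrm{harm}}\, h \cdot 10^{-3}$ S with $h$ in mm).
The harmonic mean preserves flux continuity across tissue interfaces,
which matters here because adjacent tissues differ in conductivity by
up to two orders of magnitude (CSF at 2 S/m against skull at 0.02 S/m).

Electrodes are modelled as the clinical construction: a 5 × 7 cm
highly conductive pad ($5.9\times10^{7}$ S/m) on a 7 × 8 cm saline
sponge (0.3 S/m) contacting the skin. Current is injected by fixing
the pad voxels at Dirichlet values (+1 V on all active pads, 0 V on
the reference) and rescaling the solved fields afterwards so that the
summed signed face current through the closed voxel surface enclosing
the active pads equals the target current — valid because the problem
is linear. This mirrors the practice of adjusting the potential
difference between the electrodes until the desired total current
flows. When a montage has two active pads (C3 and C4), both are tied
to the same potential, i.e. wired in parallel, and the 1 mA target is
their summed current.

The reduced symmetric positive-definite system is solved by conjugate
gradients with a symmetric Gauss–Seidel preconditioner (compiled code),
to a relative residual of $10^{-8}$ by default; a sparse direct solver
is available for small grids. The pipeline contains no randomness
anywhere — identical inputs give bit-identical outputs.

$\mathbf{E}$ is evaluated at cell centres by central differences,
falling back to one-sided differences where a neighbour is air or
outside the solved domain (tissue–air faces and electrode-adjacent
voxels), so the gradient is never smeared across a material boundary.
Air voxels carry zero field by definition and are excluded from all
statistics.

Key exact discrete properties, all enforced by tests:

* conservation: the divergence of $\mathbf{J}$ vanishes at every
  non-electrode voxel up to the solver residual, and the current
  through *any* closed surface separating the electrodes equals the
  injected current;
* linearity: fields scale exactly with the injected current;
* current control: scaling every $\sigma$ by $k$ leaves $\mathbf{J}$
  unchanged and scales $\mathbf{E}$ by $1/k$;
* geometric scaling: shrinking all linear dimensions by $k$ at fixed
  current multiplies $|\mathbf{E}|$ by $k^{2}$ — the mechanism behind
  the smallest family member experiencing the highest fields.

## The synthetic phantom family

The original interindividual-variability study used three proprietary
MRI-derived whole-body models (two adults of both genders and one
adolescent, 75–77 segmented tissues each). Those anatomies are not
redistributable, so this package ships an explicit parametric stand-in,
not a reconstruction: a layered-sphere head (scalp skin, skull, CSF,
grey matter, white matter) and a simplified whole body (neck cylinder,
trunk ellipsoid, arm and leg cylinders, each layered
skin/fat/muscle with a bone core). Deep brain regions — thalamus,
midbrain, pons, medulla oblongata, cerebellum — are painted inside the
white-matter sphere at fixed fractional coordinates purely so that the
per-tissue statistics of the study design are computable; their shapes
are schematic. At very coarse resolutions a structure whose analytic
shape captures no voxel centre claims the nearest white-matter voxel,
so every mask is guaranteed non-empty.

The default family is generated by isotropic scaling of one reference
adult (1.75 m stature, 90 mm scalp radius, layers 6/7/3/5 mm) by
stature: an adult female analogue at 1.63 m, an adult male analogue at
1.77 m and an adolescent analogue at 1.47 m, matching the statures of
the models the study emulates. Isotropic scaling is deliberately
simple and controlled: every linear dimension carries the stature
ratio, so the geometric-scaling law above predicts the family ordering
of field strengths exactly, and per-layer overrides
(`scale_profile(..., layer_overrides = )`) allow skull- or
CSF-thickness sensitivity studies, CSF being the structure most often
implicated in shaping current flow. The simplification is also the
main caveat: real adolescent heads are closer to adult size than
stature scaling implies, real heads are not spheres, and real CSF is
not a uniform shell. Passing tests therefore demonstrate correctness
of the machinery and of scale-driven trends, not agreement with any
individual anatomy; the headline focality percentages of MRI-based
models are explicitly out of reach of desk-scale phantoms.

Conductivities come from a shipped low-frequency tissue table in which
grouped tissues are aliases of one canonical label sharing a single
literature value. The skin entry (0.012147 S/m) already embodies a
weighted average of skin and subcutaneous adipose tissue; the weights
behind that average are not published, so the printed value is used
as-is rather than re-derived.

## Electrode placement

Scalp positions use the 10–20 system realized as fixed angles on the
phantom's scalp sphere: 20% steps of the nasion–inion and ear-to-ear
arcs are 18° of inclination from the vertex, 10% of the circumference
circle is 36° of azimuth, and F3/F4 are spherical midpoints of their
arc neighbours (the classical crossing construction). Extracephalic
sites default to a lateral mid-upper-arm patch and an anteromedial
mid-tibia patch on the right limb cylinders; the exact sub-positions
are not prescribed by the study design and are configurable through
the phantom geometry metadata.

Pads and sponges are built as voxel shells that follow the local
surface (radial shells on the sphere, cylindrical shells on a limb),
with footprints measured in azimuthal-equidistant surface coordinates
so the rectangles curve with the anatomy. Thicknesses (sponge 5 mm,
pad 1 mm — typical clinical values, not prescribed by the study) are
realized as whole shells, at least one each. The pad long axis runs
antero-posteriorly by default; orientation is a documented convention,
not a finding.

One genuine geometric conflict arises: on a sphere head scaled to
adolescent stature, two 7 × 8 cm sponges centred on F3 and F4
physically collide. Rather than refusing the montage, placement clips
each electrode to the voxels strictly nearer its own centre with a
one-voxel gap (a warning reports the clipped count). This keeps the
placement mirror-symmetric, deterministic, and free of saline bridges,
at the cost of slightly squeezed sponges — much as a clinician squeezes
pads onto a small head.

## Dose metrics

For each tissue mask the package reports median, 25th/75th
percentiles, minimum, maximum and peak of $|\mathbf{E}|$ (percentiles
by linear interpolation). Focality is quantified as V70 and V50: the
percentage of a tissue's volume where the amplitude strictly exceeds
70% or 50% of its within-tissue peak. These thresholds correspond to
amplitude reductions of $20\log_{10}(1/0.7) \approx 3$ dB and
$20\log_{10}(1/0.5) \approx 6$ dB. The peak is the literal maximum by
default; because voxelization artifacts inflate extreme values, a
robust-peak option (99.9th percentile) is available but off by
default.

Across the family, variability is summarized by the coefficient of
variability (CV = sample standard deviation over mean, $n-1$
denominator as befits three models) of the peak and median amplitudes
per montage and tissue, expressed in decibels. The dB mapping is a
documented interpretation: the source material never writes the
formula. This package uses $20\log_{10}(1 + \mathrm{CV})$, chosen
because it sends identical values to 0 dB, maps CV = 1 to ≈ 6 dB —
consistent with the same amplitude-dB convention that makes the 50%
threshold 6 dB — and reproduces the reported "up to almost 6 dB" range
for CVs of order one. The raw alternative $20\log_{10}(\mathrm{CV})$
is selectable (`convention = "raw"`).

## Statistical testing

Whether the phantom (the *human model* factor, three levels) shifts
V70/V50 is tested with the Kruskal–Wallis one-way analysis of variance
by ranks (midranks, tie correction, chi-square approximation with
$k-1$ df; full-enumeration exact p optionally for total $N \le 10$).
Only when the omnibus test is significant at $\alpha = 0.05$ are
Mann–Whitney pairwise comparisons run, Bonferroni-adjusted over the
three pairs. The Mann–Whitney implementation uses exact enumeration
for small tie-free samples (≤ 8 per group) and the tie-corrected,
continuity-corrected normal approximation otherwise; enumeration
cut-offs are arguments, not magic.

The sampling unit for these tests is the (montage × tissue) cell, so
each family member contributes `montages × 2` values (8 under the full
design) — the only reading consistent with a table of per-montage,
per-tissue focality values; it is configurable by subsetting the
report. V70 and V50 are tested separately rather than pooled, matching
the design's wording of testing "both" percentages.

## The analytic verification oracle

Because no reference solver is bundled, correctness of the Laplace
solver is established against a classical closed-form family: the
potential in a homogeneous or concentric multilayer sphere due to a
point current source and sink on its outer surface, expanded in
Legendre polynomials with per-shell radial coefficients propagated by
a 2 × 2 transfer-matrix recursion and fixed by the insulated outer
boundary. Superposition, reciprocity and the uniform-conductivity
limit are exact properties of the series and are tested as such.

Comparing a voxel solve against the series requires three documented
allowances. First, the series idealizes electrodes as points while the
FD model uses small pads, so a band around each electrode — two voxels
or 1.25 pad edges, whichever is larger — is excluded; a band that
scaled only with the voxel would make the error appear to *grow* under
refinement, because the pad/point mismatch is fixed in physical size.
Second, the outermost one-voxel rim is excluded: those cells see the
staircase boundary, and the series converges arbitrarily slowly as
$r \to R$ (near-surface evaluation uses several hundred terms; the
truncation error is monitored by an explicit tail estimate). Third,
the interior Neumann problem determines $\phi$ only up to a constant,
so the two solutions are gauge-aligned by removing the mean
difference. With these, a three-shell head (brain/skull/skin
conductivities from the shipped table) solved at 2 mm agrees with the
series to better than 5% relative L2 error, improving monotonically
from 4 mm to 2 mm.

## Problem sizes and numerical defaults

The study defaults mirror the emulated design: 1 mm voxels for the
head-only montage and 2 mm for whole-body montages, 1 mA injected
current, solver tolerance $10^{-8}$. Routine verification (the test
suite) exercises the full 3-phantom × 4-montage study at 6 mm (head)
and 8 mm (body), and the acceptance computation uses 2 mm (head) and
4 mm (body) — the current-conservation property it checks is a
property of the normalized discrete solution at any resolution. The
12-case study at full default resolution is the intended production
run (`run_study(study_config())`) and benefits from the built-in
per-case disk cache (`out_dir`), which keys each case by a
configuration hash and makes the study resumable.

Degenerate inputs are handled explicitly: empty tissue masks error;
montages whose electrodes are not bridged by conductive tissue error
at assembly; an open circuit (achieved current ≈ 0) errors at
normalization; a non-convergent conjugate-gradient run errors with the
final residual rather than returning silently.

## Known limitations

* Spherical heads and cylinder/ellipsoid bodies; no gyrification, no
  realistic CSF architecture, no anisotropic white matter.
* Focality percentages are not comparable to MRI-derived anatomies in
  absolute value — only orderings and trends transfer.
* Pad–skin contact impedance and electrochemical effects are not
  modelled; the sponge is a homogeneous saline conductor.
* The dB convention for CV is an interpretation (documented above).
* The 10–20 realization assumes a spherical scalp; on a real head the
  same angles would need a fitted sphere.
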