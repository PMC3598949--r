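---
title: "Bite-force biomechanics of tooth eruption: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bite-force biomechanics of tooth eruption: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Unerupted teeth sit inside a bony crypt, separated from the bone by a soft
connective-tissue dental follicle. Eruption requires resorption of the bone
over the crown and, typically, deposition beneath the root — yet the
signal that orients this remodelling is unresolved: clinical "bony
impactions" (teeth that stop erupting with no obstruction in the way) show
it cannot be a pre-programmed eruptive force. The hypothesis this package
operationalizes is mechanobiological: functional bite forces bend the jaw,
the compliant follicle concentrates the resulting strain, and follicle
cells transduce local *hydrostatic stress* — compression over crowns
promoting resorption, tension under roots promoting apposition — so that
ordinary chewing itself steers the tooth out of the bone.

`eruptsim` provides the quantitative machinery for studying that
hypothesis at desk scale: a linear-elastic tetrahedral finite element
solver, the derived per-element measures, and the follicle "cap" analysis
with its compression/tension accounting.

## The model

### Continuum assumptions

All tissues are homogeneous, isotropic and linearly elastic, each
parameterized by a Young's modulus $E$ (MPa) and Poisson's ratio $\nu$.
Loading is treated as a single quasi-static step at small strain. Units
are fixed system-wide to mm, N and MPa; this self-consistent system makes
the derived stress–volume product come out in N·mm with no conversion
factors.

The default `material_table()` is:

| Tissue | E (MPa) | nu |
|---|---|---|
| Cortical bone & lamina dura | 15,000 | 0.30 |
| Cancellous bone | 1,500 | 0.30 |
| Enamel | 84,100 | 0.20 |
| Dentine | 18,600 | 0.31 |
| Dental pulp | 2 | 0.45 |
| Dental follicle & PDL | 12 | 0.45 |
| Condylar support (anterior) | 44.1 | 0.40 |
| Condylar support (posterior) | 0.49 | 0.49 |

These are literature values for the tissues concerned; every entry can be
overridden per region. The four-order-of-magnitude contrast between
follicle ($E = 12$) and the surrounding hard tissues is the mechanical
heart of the model: the follicle deforms much more than bone under the
same load, which is what makes it a plausible strain sensor.

### Elements and solver

The solver uses 4-node constant-strain tetrahedra (tet4). Dirichlet
conditions are imposed by row/column elimination, so prescribed values are
reproduced exactly in the solution — this makes the patch test a sharp
assertion rather than an approximate one. The reduced symmetric system is
factorized with a direct sparse Cholesky decomposition (`Matrix`); element
integration and assembly triplets are generated in compiled code.

Known limitation: tet4 elements lock volumetrically as $\nu \to 0.5$. The
follicle's $\nu = 0.45$ is below the severely locking regime, and every
claim made of the solved fields here is pattern-level (signs and volume
shares of hydrostatic stress), not point-accurate stress recovery. The
posterior condylar support material ($\nu = 0.49$) is retained in the
material table for completeness but unused by the default scene, which
replaces condylar anatomy with fixed corner supports.

### Derived measures

For each element the package computes:

* **volume** $V = |\det|/6$ of the edge matrix (mm³);
* **hydrostatic stress** $\sigma_h = (\sigma_{xx} + \sigma_{yy} +
  \sigma_{zz})/3$ (MPa), negative = net compression;
* **equivalent strain**
  $S_e = \frac{1}{1+\nu}\sqrt{\tfrac{1}{2}\left[(S_1-S_2)^2 +
  (S_2-S_3)^2 + (S_3-S_1)^2\right]}$
  from the principal strains $S_1 \ge S_2 \ge S_3$ — a von-Mises-type
  deviatoric norm that is zero for purely volumetric deformation and
  homogeneous of degree one. The literature states this measure without a
  machine-readable form in some renditions; the form above follows the
  Mellal convention and is the single point where an equation had to be
  chosen rather than transcribed, so it is flagged here prominently. The
  effective $\nu$ defaults to the element material's ratio and is
  overridable.
* **biological response unit** $\mathrm{BRU} = \sigma_h \times V$
  (N·mm): a dose proxy that weights the stress level by the volume of
  tissue (hence number of cells) experiencing it. Increasingly negative
  BRU = increasingly strong resorptive (compressive) signalling.

### The cap analysis

Per unerupted tooth, two follicle caps are analysed: a **coronal** cap
over the crown and an **apical** cap beneath the roots, each extending
3 mm along the tooth's long axis from the corresponding end of the
follicle towards mid-tooth. The long axis is the dominant principal axis
of the tooth element centroids, oriented crown→apex using the enamel
centroid as the crown marker; an isotropic cloud (no dominant axis within
1%) is an error that demands an explicit axis.

For each cap × load mode, the package reports the relative percentage of
cap volume under compression and the relative percentage of summated
|BRU| under compression. The decision rule is a majority criterion:
compression "dominates" when the percentage exceeds 50. The expected
pattern for actively erupting teeth is compression-dominant coronal caps
and tension-dominant apical caps; entries violating it are *exceptions*,
with a near-miss margin (default 4 percentage points, inclusive) flagging
exceptions that sit close to the 50% line. Second molars are excluded
from aggregate counts: at the developmental stage modelled they are
pre-eruptive, and their deviation from the pattern is the expected
negative control rather than a failure.

Binned distributions use fixed increments: |σ_h| bins of 0.005 MPa from
0.005 to 0.07 MPa, and |BRU| bins of 0.00017 N·mm from 0.00029 to
0.00250 N·mm (coronal) or 0.000045 N·mm from 0.000050 to 0.000630 N·mm
(apical), with everything beyond the extremes summated into
underflow/overflow bins.

## The synthetic-data generator

The original analysis ran on a CT-derived child-mandible mesh of 1.85
million elements that cannot be redistributed; its 64 published cap
percentages are packaged verbatim as `reference_compression_table()`, and
the exception classifier runs identically on that table and on
pipeline-computed summaries. Everything else in the package runs on
synthetic inputs with two tiers:

**Geometric mode** (`geometry_config()` → `build_labelled_grid()` →
`voxels_to_tets()`): an idealized capsule-shaped tooth (enamel hemisphere
over a dentine body with a pulp core) in a rectangular bone block, wrapped
in a follicle shell, a cortical crypt wall, cancellous interior and outer
cortical shell. Voxels are classified by Euclidean distance to the tooth
axis segment, then the follicle and crypt are completed by morphological
dilation so the shells survive voxelization as full 26-connected layers —
the follicle must separate tooth from bone everywhere, since its
compliance is what the analysis measures. Each voxel cube is split into 6
tetrahedra along a globally consistent diagonal (Kuhn subdivision), which
conforms across cube faces without an external mesher and conserves
volume exactly.

The shipped default scene is a 14 × 7 × 10 mm block at 0.5 mm pitch
(47,040 elements, 9,135 nodes — a size chosen so a full two-mode run
completes in about a minute), with a 1.5 mm-radius tooth, 0.6 mm
follicle, 0.5 mm crypt wall. The loading idealization: the block is a
cut-out segment of the mandibular corpus. The elevator muscles act far
from the crypt, so what the segment feels is the flexural couple
transmitted across its cut end faces; that couple is applied as paired
upper/lower force patches on each end face, parameterized through the
standard muscle-force product $M = X_{MI} \cdot K \cdot \mathrm{EMG}$
(cross-sectional area × skeletal-muscle constant × activation in
[0, 1]), with activation 0.4 in incisive mode and 1.0 in unilateral-molar
mode. A transverse load applied directly over the crypt was deliberately
avoided: in a block this deep it "punches" a compressive strut straight
through the crypt and swamps the flexural field, whereas the transmitted
couple produces the clean bending state — occlusal-side fibres in
compression, lower border in tension — that the hypothesis attributes to
the loaded corpus. Supports are the four bottom corner nodes (all three
axes) plus a mode-specific vertical restraint at the bite patch; because
the couples are self-equilibrated these supports carry almost nothing.

**Direct-field mode** (`sample_direct_fields()`): for testing and
calibrating the analysis stages without any solve, per-element records are
drawn from stated distributions — Gaussian hydrostatic stress per cap
(default means ∓0.02 MPa, spread 0.005 MPa, matching the histogram bin
scale) and log-normal volumes (log-mean log 0.01 mm³, log-sd 0.5; the
follicle of an anatomical unstructured mesh, ~2,000 mm³ over ~190,000
elements, has a mean element volume near 0.01 mm³ with a right-skewed
spread). The compressive volume fraction then has the closed form
$\Phi(-\mu/\sigma)$, which the cap statistics must recover within
Monte-Carlo error — a parameter-recovery test with an analytic oracle.

### What the synthetic tests do and do not show

Passing tests establish that the solver satisfies its mathematical
contracts (patch test, closed-form uniaxial states, equilibrium,
linearity, frame objectivity), that the derived measures match independent
oracles, and that the cap accounting is exact bookkeeping. The synthetic
geometry does **not** establish anything about real mandibular anatomy:
it has no curved corpus, no anatomical muscle attachments, no
tooth-to-tooth variation, and its single idealized tooth cannot reproduce
the published per-tooth percentages. The default-scene pattern check
(coronal compression > 50%, apical < 50%) is therefore exploratory — it
demonstrates that the mechanism is coherent under an idealized bending
field, not that the anatomy guarantees it.

## Numerical choices

* **Bin edges are half-open** $[low, high)$; the edge convention is not
  dictated by the source material, and half-open intervals make bin
  membership unambiguous at edge values.
* **The apical |BRU| range is not an exact multiple of its increment**
  ((0.000630 − 0.000050)/0.000045 ≈ 12.9), so the final interior bin is
  closed off at the stated maximum (slightly narrower than the others);
  the stated extremes are honoured exactly.
* **Histogram curves are normalized per curve**: the compression and
  tension curves each sum to 100% of their own mass, which makes shape
  comparisons (e.g. the BRU-weighted right shift) read as distribution
  statements; each curve's share of the cap total is reported alongside
  so dominance information is not lost.
* **Elements with exactly zero hydrostatic stress** count toward neither
  compression nor tension but stay in the denominator — unbiased, and
  measure-zero in practice.
* **Cap membership is by element centroid**; partial elements are not
  split. Caps that would partially overlap mid-tooth (follicle span
  < 2 × depth) are an error to prevent double counting, but a depth at or
  beyond the whole span degenerates cleanly to the entire follicle.
* **The near-miss margin is inclusive** (|x − 50| ≤ 4 by default) and
  exposed as a parameter.
* **Muscle force is split equally across attachment nodes**; the source
  material does not state a distribution scheme, and equal splitting
  keeps the per-muscle force total exact by construction. For
  closed-form verification states the package instead provides
  `traction_loads()`, which applies area-consistent loads over boundary
  triangles.
* **Degeneracy guards**: tetrahedra below 1e−12 mm³, asymmetric tensors
  beyond 1e−8, fixity sets too small to remove rigid-body modes, and
  empty record sets are all hard errors naming the violated constraint.
* **Pooling requires element records**, not bare percentages: a pooled
  percentage is recomputed over concatenated records so the volume
  weighting is preserved.

## Limitations

No contact, no large deformation, no anisotropy, no viscoelasticity, no
time-resolved bite strokes; condylar/TMJ anatomy reduced to corner
supports; single idealized tooth per scene; no locking mitigation for the
nearly incompressible soft tissues. These bound the interpretation of the
solved fields to qualitative pattern statements, which is the level at
which the cap analysis operates.
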