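---
title: "From DICOM RT plans to Monte Carlo input decks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From DICOM RT plans to Monte Carlo input decks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brachydeck)
```

## Scope and model

High-dose-rate (HDR) ¹⁹²Ir brachytherapy delivers dose by stepping a small
sealed source through implanted catheters, pausing at planned *dwell
positions* for planned *dwell times*. Treatment planning systems (TPS)
compute dose either with the water-based TG43 formalism or with advanced
heterogeneity-capable algorithms, and independent Monte Carlo (MC)
recalculation is the reference tool for commissioning either kind.
`brachydeck` automates the conversion of a plan exported in DICOM RT format
into an MCNP-style input deck, and provides the comparison computations used
to benchmark dose grids against each other: percentage-difference maps and
histograms, radial dose function and anisotropy function extraction,
dose-volume histograms, and a morphological skin surrogate.

The pipeline has five stages:

1. **DICOM RT parsing** (`read_ct_series`, `read_rtplan`, `read_rtstruct`,
   `read_rtdose`) normalizes everything into one frame: LPS patient
   coordinates, millimetres, voxel-center addressing.
2. **Material modelling** (`build_material_model`) converts CT Hounsfield
   units into per-voxel mass density and tissue composition.
3. **Source modelling** (`plan_transforms`, `sampling_table`,
   `toy_phase_space`) turns dwell positions into rigid placements of a
   phase-space photon source.
4. **Deck emission** (`write_deck`, `validate_deck`) writes the rectangular
   lattice geometry, material cards, tallies, and the source sidecar
   convention, plus a mini-parser used for structural validation.
5. **Benchmarking** (`diff_map`, `extract_g`, `extract_F`, `compute_dvh`,
   `derive_skin`) compares dose grids.

A TG43 line-source engine (`render_rtdose`) stands in for a TPS TG43 dose
export, so every stage can be exercised end to end on synthetic phantoms
generated in-repo.

## Coordinate conventions

All readers and generators emit geometry in the LPS patient frame in
millimetres, with arrays indexed `[x, y, z]` (x along the in-plane column
direction, z along the slice direction) and positions referring to voxel
*centers*. Only axis-aligned volumes are supported; oblique series are
rejected rather than resampled, because the commissioning fixtures this
package targets are axial. Dose and CT grids are aligned by physical
coordinates, never by indices.

DICOM files are written in explicit-VR little-endian with defined lengths
everywhere, and the reader accepts exactly that dialect. RT Plan channel
encoding is documented in the `read_rtplan` help: path control points
tip-first with constant cumulative time weight, followed by the standard
dwell pairs; dwell times are reconstructed as
`t = (w_after - w_before) / FinalCumulativeTimeWeight * ChannelTotalTime`.
Layouts that violate this pattern (a weight increase between distinct
positions) are flagged as unknown rather than guessed at, since RT plan
encodings are not uniquely transferable between planning systems.

## Material model

Density is assigned per voxel in three steps, in this order:

1. **Calibration**: piecewise-linear HU-to-density curve, clamped at its
   ends. The default anchors (−1000 HU → 0.0012 g/cm³, 0 HU → 1.00 g/cm³,
   plus lung, soft-tissue, and bone anchors up to 3000 HU → 2.70 g/cm³) are
   a conventional single-energy CT curve; a user curve can be supplied as a
   two-column CSV.
2. **Truncation** to two significant digits, toward zero (1.789 → 1.7).
   Truncation rather than rounding is deliberate: it makes the voxel density
   a deterministic coarse label rather than a nearest value.
3. **Binning** (optional, on by default): the density is replaced by the
   representative of its bin in a 54-bin scheme spanning 0.0012–3.0 g/cm³,
   with fine 0.02 g/cm³ bins across the soft-tissue range 0.85–1.15 g/cm³
   and coarser bins elsewhere. Binning keeps the number of distinct
   (material, density) pairs — and hence MC lattice universes — small.
   Density binning at this granularity is known to perturb ¹⁹²Ir dosimetry
   by well under a percent at clinical distances.

Each bin representative is chosen as a two-significant-digit value inside
the bin whenever one exists, so that truncation followed by binning is
idempotent; bins too narrow to contain such a value (possible above
1.15 g/cm³ where bins are finer than the truncation step) are unreachable
through the truncate-first pipeline and take their midpoint.

Tissue composition is looked up from density in a 23-row table following the
Schneider-style density partition (air, inflated/partial lung, adipose
grades, water-equivalent soft tissue, muscle/liver/connective/cartilage,
nine bone rows of increasing mineral content). Ranges are half-open
`[low, high)` with the last range closed; mass fractions sum to one within
10⁻⁶. The shipped table is *constructed* to this pattern — it is a working
default, clearly replaceable by an institutional table via CSV, not a
published consensus dataset.

In-plane down-sampling (factors 2, 4, 8) block-averages HU *before* any
density conversion, mirroring the order a user would apply to imported
images; a matrix not divisible by the factor is padded with air on the
high-index side.

## Source model

The RT plan stores only the source center at each dwell. Orientation is
reconstructed from the two catheter control points nearest the dwell: the
source long axis (local +z) points from the higher-index to the lower-index
point, i.e. toward the catheter tip, since control points are ordered tip
first. Because the source is axisymmetric, rotation about its own axis is
physically irrelevant; the minimal rotation taking +z onto the axis is used
and recorded as a 3×3 orthonormal matrix plus translation. θ = 180° is the
cable side.

The photon source itself is a phase-space file: records of energy, position
and direction in the source-local frame, replayed per history. Each replayed
photon draws its placement transform from the dwell-time distribution
(probability proportional to dwell time over total time) — per-photon
sampling, not a per-dwell partition of the file. The shipped `.phsp` format
is a one-line text header (`PHSP1 <source_id> <n_records> <n_emitted>`)
followed by little-endian float32 septets, chosen for streaming reads; round
trips are bit exact. `toy_phase_space` generates a stand-in file: photons
emitted from the surface of a source-sized cylinder (0.9 mm × 3.6 mm by
default), isotropic directions, energies drawn from the shipped ¹⁹²Ir line
spectrum. It deliberately carries no self-absorption or anisotropy — it
exercises the plumbing (sampling, transforms, deck coupling), not source
dosimetry. Consistently, the emitted geometry contains no source structure,
so backscatter traversing the source volume would not be modelled correctly;
for HDR ¹⁹²Ir sources the affected photon population is small.

## The deck

The computational model is a rectangular lattice whose element size equals
the CT voxel size and whose outer dimensions coincide with the CT volume, so
the lattice element count equals the CT voxel count — the MC geometry is
identical to the geometry available to the TPS. Each distinct
(tissue, density) pair becomes one lattice universe (≤ 23 × 54 by
construction); material cards carry negative mass fractions, densities ride
on the cell entries. The FILL array is written x-fastest with `v nR` repeat
compression, stated in a deck comment, and lines respect the 80-column /
5-space-continuation discipline.

Two tallies are emitted: an F6-type photon heating tally over the lattice
(collisional kerma to medium in medium) and an FMESH4-type photon-fluence
mesh restricted to the RT dose grid extent, weighted by water mass
energy-absorption coefficients to yield water kerma in medium. No variance
reduction cards are written. The phase-space coupling is a documented
sidecar convention (the `.phsp` file plus a CSV of per-dwell transforms and
probabilities referenced from deck comments) rather than inline source
cards: the deck stays human-readable and the large photon file stays
external. `validate_deck` re-parses the emitted text — blocks, lattice
dimensions, FILL cardinality, material mass-fraction sums, tallies — and is
used both in tests and by the `convert` command before anything is written.

## TG43 engine and parameter extraction

The engine implements the line-source formalism:
Ḋ(r,θ) = S_K · Λ · [G_L(r,θ)/G_L(r₀,θ₀)] · g_L(r) · F(r,θ), r₀ = 1 cm,
θ₀ = 90°. The geometry factor uses the two-angle arctangent difference form
for β, switching to the closed on-axis form 1/(r² − L²/4) when
sin θ < 10⁻⁶; the L = 0 limit is exactly 1/r². g_L is interpolated
log-linearly in r, F bilinearly in (r, θ); outside their tables both clamp
with a warning. Plan times are seconds and dose rates per hour; the single
1/3600 conversion lives in `render_rtdose`. Within 2.5 mm of the source
(inside or near the active length, below the tabulated range) rendered
voxels take the clamped-radius value — those voxels are never used by the
extraction, which starts at 5 mm.

The shipped g and F tables are smooth synthetic curves (a gentle quadratic
in r − 1 for g; 1 − a(r)|cos θ|³ for F), normalized exactly at the reference
point. They are test instruments: published consensus tables for a real
source can be dropped in as CSVs but are not bundled.

**Extraction.** `extract_g` and `extract_F` invert the formalism from a dose
grid. A naive implementation samples the dose trilinearly at (r, θ) points
and divides by the geometry factor; but near the source or the long axis the
field is dominated by the steep inverse-square-like G, and trilinear
interpolation across a 1 mm cell incurs errors of several percent (for
1/ρ², interpolating across a cell at ρ = 3.5 mm overestimates mid-cell by
≈ 6%). The default method therefore never interpolates G: it takes the grid
values at voxel centers — where they are exact — divides each by the exact
G at that center, and interpolates the remaining *smooth* residual
(∝ g·F). For g the samples come from a ±5° cone about the transverse plane
(where F ≈ 1 to ~10⁻⁴); for F from a thin spherical shell at the requested
radius, averaged in 1° polar bins. Normalization at r₀ and θ₀ is by
construction exact. On a 1 mm grid with a single dwell this recovers the
input tables to ≈ 0.02% (g) and ≈ 0.14% (F) — comfortably inside the 0.5%
and 1% contracts the test suite enforces. The trilinear variant is kept as
`method = "trilinear"` for sensitivity checks on transverse profiles, where
it is accurate.

Azimuthal handling: extraction averages over all azimuths (the shell/cone
pooling) since the line-source field is axisymmetric; the two-direction
transverse averaging of the trilinear variant is the degenerate case.

## Benchmark computations

- **Difference maps** are 100·(test − ref)/ref on voxels where the reference
  is nonzero, optionally restricted to a body mask and to densities at or
  above 0.05 g/cm³ (the air-exclusion threshold — the policy of excluding
  air and out-of-body voxels is standard; the numeric threshold is this
  package's choice). Voxels inside catheters are *not* excluded. Swapping
  test and reference maps +x% to −100x/(100+x)%, an identity the tests pin.
- **DVHs** rasterize per-slice closed contours at voxel centers with the
  even-odd rule (contours sharing a slice combine by exclusive-or, so nested
  contours cut holes); the cumulative curve starts at 100%, is
  non-increasing, and reaches 0 beyond the maximum dose.
- **Skin**, which is rarely contoured, is derived from the body mask as the
  difference of a one-pass dilation and a one-pass erosion with a 3×3 cross,
  per axial slice (2D, because contours are per-slice planar). Morphology is
  delegated to EBImage.

## Synthetic phantoms: what they do and do not show

`make_water_sphere_ct` builds the classic commissioning phantom — a 15 cm
radius water sphere in air on a 340 mm FOV, 256-matrix, 1 mm-slice grid
(320 slices cover the sphere plus a 1 cm margin; only the in-plane geometry
is dictated by convention, the slice count is this package's choice).
Inside/outside is decided at voxel centers with no partial-volume blending,
matching a mathematical model converted to CT. `make_tg43_conditions`
applies the same binarization to any CT around the dwell centroid, emulating
the standard trick of forcing a patient model into TG43 scatter conditions.
`make_multicatheter_plan` arranges parallel or fanned catheters with
regularly spaced dwells and a 32 Gy prescription, emulating a multicatheter
breast implant at the geometry level; dwell times are uniform or drawn
reproducibly from the seed. All generators are deterministic under a fixed
seed, and their DICOM serializations re-read losslessly.

What passing tests on these phantoms demonstrate: correct parsing and
serialization, correct bookkeeping (voxel counts, dwell times, transforms,
probabilities), correct formalism algebra, and self-consistency of the
render/extract pair. What they do not demonstrate: agreement with any
commercial TPS implementation, real-source dosimetry (the toy phase space is
isotropic), heterogeneity effects, or MC transport accuracy — no transport
code is run in-repo.

## Numerical choices and degenerate inputs

- Slice-position uniformity tolerance 10⁻³ mm; a gapped series is rejected
  with the gap location named.
- RT Dose scaling is max/2³¹ − 1 into signed 32-bit integers (≈ 5·10⁻¹⁰
  relative quantization); an all-zero grid uses unit scaling.
- Densities: calibration clamps outside anchors; binning and tissue lookup
  clamp to their end bins; a dwell exactly on a control point resolves to
  that point and its tip-ward neighbour (the perturbation limit).
- `sampling_table` rejects all-zero dwell times; zero-time dwells get zero
  probability and are skipped by the renderer.
- Truncation uses a 10⁻⁹ epsilon against floating-point droop
  (e.g. 30.000000000000004 from 0.3/0.01); it cannot promote a value across
  a digit boundary.
- Problem sizes in the test suite: unit tests run on 32–64 voxel grids;
  the parameter-recovery check renders a single dwell on a 201³ 1 mm grid
  and the lattice-conservation check builds the full 256×256×320 study —
  both chosen as the smallest sizes that exercise the stated contracts at
  full scale.

## Configuration and CLI

The `brachydeck` executable (in `exec/`) wraps `brachydeck_main()` with
subcommands `phantom`, `convert`, `render`, `extract`, `compare`, `dvh`;
exit codes are 0 (success), 2 (input error), 3 (validation failure). The
config file is YAML with sections `calibration`, `binning`, `tissue`,
`source`, `tallies`, with file paths resolved relative to the config file
(see `inst/extdata/config_example.yaml`). YAML was chosen over other config
dialects because it is the established, already-available config format in
this R stack; the section schema is unchanged by that choice.

## Known limitations

- One DICOM dialect (explicit VR little endian, defined lengths); no
  applicators, no oblique grids, no external-beam or ion objects.
- The toy phase-space generator is not a source model; Λ, L and the g/F
  tables shipped are synthetic defaults, not consensus data.
- No MC transport, no variance reduction, no statistical (type A)
  uncertainty propagation — the deck is the product, not the simulation.
- Skin derivation operates on masks, not on a geometric surface mesh; its
  thickness is fixed by the structuring element (two pixels).
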