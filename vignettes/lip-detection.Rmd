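---
title: "Locating light, polar interfaces in protein structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating light, polar interfaces in protein structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipscan)
```

## The model

Globular protein cores are stabilised by hydrophobic burial, tight packing
and the pairing of the few buried polar groups.  Where these conditions fail
locally — where a contiguous segment is held against the rest of the protein
by an interface that is unusually *polar* and unusually *loosely packed* —
the interface is expected to be thermodynamically weak, and the segment
behind it is a candidate for local unfolding: an unstable foldon, the
unfolded part of an equilibrium intermediate, a late-folding region.

`lipscan` operationalises this idea with two per-window quantities.  A probe
fragment of `L` consecutive residues (default 8) is cut from the chain; the
fragment and the remainder are each treated as rigid, isolated bodies, and
the area buried between them is measured atom by atom:

$$\mathrm{buried}(i) = \max\!\big(0,\ \mathrm{ASA}_{\mathrm{part}}(i)
  - \mathrm{ASA}_{\mathrm{complex}}(i)\big)$$

The **polarity ratio** of the window is the buried area of polar atoms (N,
O; S optionally) over the buried area of apolar atoms (C, and S by default).
The **packing density** is the ratio of standard to actual Voronoi atomic
volumes summed over the interface atoms (those with buried area above a small
threshold).  Both values are assigned to the residue at position
$\lceil L/2\rceil$ of the fragment — the 4th for the default window — and the
scan over all windows yields two per-residue tracks.

A **LIP** is called where the polarity track is organised around at least one
position with PR ≥ 0.8, extended over flanking positions with PR > 0.5, and
the candidate is associated with a packing minimum below the
protein-specific cutoff $\mu_\rho - k\,\sigma_\rho$ (k = 2).  The thresholds
are not free parameters of convenience: 0.5 is the typical core polarity
ratio (folded-state buried area gives ≈ 0.46 on reference protein sets) and
0.8 the typical solvent-exposed surface ratio (≈ 0.75), so a peak above 0.8
marks a buried interface *more polar than an average protein surface*.

## Parameters that matter

| parameter | default | units | meaning |
|---|---|---|---|
| `L` | 8 | residues | probe length; 7–9 give nearly identical profiles on globular structures |
| `probe` | 1.40 | Å | solvent probe radius (water) |
| `n_points` | 960 | – | sphere quadrature points per atom |
| `theta_peak` | 0.8 | – | PR seed threshold (surface-like polarity) |
| `theta_base` | 0.5 | – | PR extension baseline (core polarity) |
| `k_sd` | 2 | – | depth of the packing cutoff below the profile mean |
| `packing_mode` | `"wall"` | – | packing association rule (below) |
| `eps` | 0.1 | Å² | buried-area threshold for interface membership |
| `shell_offset` | 2.8 | Å | solvent pseudo-site distance above the atom radius |

Windows that span a chain break (adjacent CA–CA distance above 4.5 Å, or a
physical gap behind a numbering gap) produce missing values; nothing is ever
interpolated.  Infinite PR (a window burying *no* apolar area) is kept as a
sentinel: it counts as exceeding any peak threshold but is excluded from
means, SDs and correlations.

## Design choices where the design was open

**Packing association (`wall` vs `strict`).**  The literal definition asks
the candidate itself to contain a below-cutoff packing position (`strict`).
Real cases exist, however, where a clearly polar interface sits on the *wall*
of a deep packing minimum rather than at its centre.  The default `wall` rule
formalises that association: a candidate passes if it overlaps a *basin* — a
maximal run of below-mean packing positions containing at least one
below-cutoff position.  `strict` mode is retained; with default settings the
two modes differ only for wall-sitting candidates.

**Radical-plane tessellation.**  Unweighted bisector planes systematically
misallocate volume between atoms of unequal radius (an O–C contact is split
at the midpoint although the carbon is larger).  The default partition
therefore uses radical (power) planes weighted by the van der Waals radii;
`bisector` mode is available, and the two agree exactly when all radii are
equal — a property the tests exploit.

**Solvent capping.**  A tessellation over protein atoms alone leaves surface
cells unbounded.  Pseudo-sites are generated on the accessible surface and
pushed to (atom radius + 2.8 Å), one water diameter above the van der Waals
surface, closing those cells at the first hydration shell.  Cells still
touching the bounding cube afterwards are flagged and excluded from both
packing sums (excluding them from only the denominator would bias ρ).

**The packing scale is conventional.**  With this partition the
whole-protein standard/actual volume ratio of a well-packed globular protein
is ≈ 1.0, and interface packing densities fall around 0.97–1.05 with a
within-protein SD of ~0.02.  Published interface packing values computed
with other Voronoi programs can sit substantially lower (0.65–0.9): surface
treatment and plane conventions shift the absolute scale.  What is robust —
and what the caller uses — is the *shape* of the profile: the positions of
minima and the mean − 2 SD cutoff are insensitive to the scale, and the
PR–ρ anti-correlation holds (−0.28 on hen lysozyme).  Comparisons of ρ
values across programs should not be made at face value.

**Standard volumes and radii.**  The packaged tables
(`inst/extdata/atom_params.tsv`) assign each residue/atom pair a
Chothia-type radius (O 1.40, N 1.65, S 1.85, trigonal C 1.76, tetrahedral C
1.87 Å) and a standard volume from the mean Voronoi volumes of protein
heavy-atom groups in small-molecule crystals (e.g. CH₃ 36.7, CH₂ 23.2,
carbonyl C 9.7, amide N 15.7, carbonyl O 15.9 Å³).  Atoms without a table
entry fall back to element means with a warning and a flag.  Both tables can
be replaced via the `params` argument.

**Reference state for the polarity baselines.**  `reference_polarity()`
needs, for every atom, an ASA in an unfolded reference.  The package uses a
Gly-flanked tripeptide context extracted from the structure itself: the
atom's own residue in its crystallographic conformation plus the backbone
atoms of the two sequence-adjacent residues.  This avoids building rotamers
while keeping the local covalent occlusion realistic.  It is *not* an
unfolded-ensemble average: baselines computed this way are expected to run
somewhat more polar than ensemble-based values, and they inherit the
composition of the input set (a lysozyme-only set gives core ≈ 0.60 and
surface ≈ 0.99, against literature-set values near 0.46 and 0.75).

**Canonical evaluation frame.**  The quadrature point set is fixed in space,
so a naive implementation gives slightly different areas for rotated copies
of the same molecule.  All geometry is therefore evaluated in a canonical
frame (centroid origin, principal axes, signs fixed by chain-order
statistics), making profiles invariant under rigid-body motion — identical
to output precision — and byte-identical under atom-record permutations,
which are sorted to canonical residue/serial order at load time.

## Numerical behaviour

* The surface engine is a deterministic golden-spiral Shrake–Rupley variant;
  no RNG anywhere in the pipeline.  At the default 960 points the per-point
  granularity on a typical expanded sphere is ≈ 0.14 Å².  Convergence is
  ≤ 1 % against 4× resolution for atoms with ASA > 20 Å²; small slivers
  (< 10 Å²) are resolved to ~0.5 Å² absolute.  An independent,
  latitude-band dense-sampling oracle (`sasa_oracle()`) agrees to 2 % on
  exposed atoms; an independent cross-check against another published
  implementation agreed to 0.1 % in total area on a real structure.
* Cell volumes are exact polyhedral volumes from incremental half-space
  clipping (divergence theorem), not sampled: the interior cell of a cubic
  lattice is `spacing³` to 1 × 10⁻⁶, cells clipped to a common box sum to
  the box volume to machine precision, and a nearest-power-site Monte-Carlo
  oracle agrees within 1 % at fixed seeds.
* Degenerate inputs are handled explicitly: coincident centers raise errors
  naming the pair; empty interfaces yield missing PR; zero apolar burial
  yields the +Inf sentinel with a warning; a fully tied rank-sum sample
  returns p = 1; zero-variance tracks make the correlation an error rather
  than NaN.
* The rank-sum test enumerates the exact null for pooled samples ≤ 20
  without ties (verified against complete labeling enumeration and against
  `wilcox.test`), and otherwise uses the tie-corrected normal approximation
  with continuity correction.

## What the synthetic fixtures do and do not show

`make_lattice()` gives analytically solvable geometry (volumes, conservation,
capping); `make_helix()` gives chemically labelled chains whose polar/apolar
contrast is controlled by sequence; `planted_profile()` gives exactly known
PR/ρ tracks for the caller and the statistics.  These fixtures validate every
computational stage without downloads.

They are deliberately *not* miniature proteins.  Helix side chains are single
centroids, so a helix has no packed hydrophobic core, and its probe
interfaces are dominated by the two covalent cut faces.  Consequently the
window-length robustness of real globular structures (PR correlation ≥ 0.93
between L = 7/8/9 on hen lysozyme) does **not** hold on ideal helices, and
helix PR values run higher than globular baselines.  Passing fixture tests
demonstrates the correctness of the machinery; claims about real proteins are
checked on the real structures bundled with the bio3d dependency.

Problem sizes in the test-suite were chosen to keep the full suite in a few
minutes on one CPU: 10–16-residue helices for geometry oracles, a 129-residue
real structure for whole-pipeline checks, 2 × 10⁶–6 × 10⁶ Monte-Carlo samples
per validated cell.

## Known limitations

* Monomeric single chains only: no assemblies, no symmetry expansion, first
  NMR model only, no structure repair.  Cofactors can be admitted to the
  burial/tessellation environment (`het_policy = "environment"`) but never
  join probe fragments.
* Absolute packing densities are convention-bound (above); use profile shape
  and the protein-specific cutoff, not cross-program absolute values.
* The polarity baselines use a tripeptide reference, not an unfolded
  ensemble.
* No smoothing, no multiple-testing correction (one pre-specified contrast
  per protein), no free-energy estimates: the method ranks and delineates
  candidate unstable regions, it does not quantify their stability.
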