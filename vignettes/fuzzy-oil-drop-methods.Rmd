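---
title: "Methods: the fuzzy oil drop model in oildrop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the fuzzy oil drop model in oildrop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oildrop)
```

## The model and its assumptions

The fuzzy oil drop (FOD) model treats a folded, water-soluble protein as an
approximate spherical micelle: hydrophobicity concentrated at the center of
the body and vanishing toward the surface. The idealization is a 3D
Gaussian "drop" spread over the molecular body. The package compares three
per-residue distributions over any structural unit:

* **T** — the Gaussian evaluated at each residue's effective atom and
  normalized to unit sum. The effective atom is the unweighted mean of all
  heavy atoms of the residue (backbone and side chain); hydrogens are never
  used. This treats hydrophobicity as a residue-level, not atom-level,
  property — an assumption of the model itself.
* **O** — each residue's collected intrinsic hydrophobicity from spatial
  neighbours within a cutoff, through Levitt's polynomial distance weight.
  The sum includes the self term (the residue collects its own
  hydrophobicity at distance zero); this can be disabled with
  `include_self = FALSE`, and on normalized profiles the effect is small.
* **R** — the uniform reference `1/N`, the distribution of a body with no
  core at all.

`RD = D_KL(O|T) / (D_KL(O|T) + D_KL(O|R))` locates O between the two
references. The FOD-M extension represents a non-aqueous environment by the
complement field: `M ∝ T + K (T_max − T)`, renormalized, with `T_max` the
maximum of the unit's normalized T. `K` is chosen by minimizing
`D_KL(O|M)` on a grid.

Divergences are computed in bits (`log2`). The base is a convention: RD is
a ratio of divergences, so it cancels there, and K selection only compares
divergences at different K, so the argmin is base-independent as well.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `cutoff` | 9 Å | range of Levitt's weight; pairs beyond it contribute nothing |
| `include_self` | `TRUE` | self term of the observed sum |
| `margin` | 0 Å | additive extent margin in the sigma rule |
| `k_grid` | 0–2 by 0.1 | K candidates; one-decimal reporting convention |
| `rd_low`, `k_low`, `rd_high`, `k_high` | 0.5, 0.5, 0.7, 1.0 | classification boundaries |
| scale | `"aggregate"` | intrinsic hydrophobicity scale |

**The sigma rule.** The Gaussian must be "adjusted to the size and shape"
of the body; that phrase admits several estimators. The package orients the
frame by principal axes of the effective-atom cloud and sets
`sigma_k = (max |projection on axis k| + margin) / 3`, the three-sigma rule:
the entire body lies within three standard deviations along each axis. The
margin is exposed because reproduction of published values depends on this
choice. Near-spherical bodies make the principal axes ill-determined; axis
*order* may then be arbitrary, but every reported statistic is rotation
invariant, so only axis labels are affected. Truly collinear or planar
clouds raise an error rather than returning a degenerate frame.

**The hydrophobicity scale.** Published FOD work does not always state its
intrinsic scale. The default here is an aggregate hydropathy scale: the
mean of the min-max-normalized Kyte–Doolittle, Fauchère–Pliška and
Eisenberg-consensus scales (AAindex `KYTJ820101`, `FAUJ830101`,
`EISD840101`, via the `seqinr` data set), renormalized to [0, 1].
Averaging blunts the idiosyncrasies of any single experimental scale; the
min-max normalization guarantees non-negative observed sums. Individual
scales and user TSV scales (`read_hydro_scale()`) can be swapped in, and
reproduced RD/K values should be read with a tolerance attributable to
scale choice.

**K selection.** The grid spans 0–2 at step 0.1, matching the one-decimal
resolution at which K is conventionally reported; no continuous optimizer
is used. Ties break toward smaller K (the least environmental
modification). If the minimum falls on the upper boundary the grid extends
automatically to 3 with a warning — strongly inverted distributions
genuinely sit there. `T_max` is always taken on the normalized T of the
unit under analysis, so fragment scans recompute it on the
fragment-renormalized T, consistent with per-unit normalization.

## Units, fragments and eliminations

Any selection of residues is a unit. Two views of a fragment are
deliberately different:

* **part of parent** — the parent's raw T and O are restricted to the
  fragment and renormalized; the parent's Gaussian frame is untouched. This
  measures the fragment's role *within* the whole body's field. Raw arrays
  of disjoint fragments concatenate exactly back to the parent's.
* **individual unit** — the frame is refitted on the fragment alone and T
  and O are recomputed within it. A fragment equal to the whole unit
  reproduces the complete analysis bit for bit.

Residue elimination (e.g. removing catalytic residues) is the part-of-parent
restriction to the complement set: the complete unit's field and raw values
are kept, the dropped positions are removed, and T, O, R are renormalized
over the remaining `N − k` residues. K is recomputed after elimination, not
reused, so agreement with the complete-unit K is an observation, not an
assumption. The greedy `scan_eliminate()` removes one residue at a time,
always the current largest `|O_i − T_i|`; since no published stopping rule
exists, it stops at RD < 0.5 (configurable) or a maximum count.

Selections use author numbering with insertion codes throughout, because
catalytic residues and domain boundaries are quoted that way in the
literature. Ranges are inclusive. Overlapping fragments are rejected unless
explicitly allowed — disulfide-delimited segments legitimately overlap.

## The synthetic generator

`generate_structure()` emulates the hydrophobicity *geometry* of the four
canonical folding regimes — aqueous micelle, inverted (non-polar
environment) micelle, spatially random, and polarized — on simple bodies
(ellipsoid cloud, shell, helix, two-domain). The target intrinsic
hydrophobicity of a position follows the Gaussian burial field of the body
(its complement, a shuffle, or a plane split for the other regimes), and
each position is realized as the standard residue whose scale value is
nearest the target. A graded target is used rather than a binary
inside/outside split: a binary split at the median radius makes the
observed field nearly flat over most of the body — closer to uniform than
to the Gaussian — and fails to encode the regime it is meant to represent.
With the graded construction the micelle regime yields RD well below 0.5
with K at most 0.1, and the inverted regime RD above 0.5 with K at least
0.5, which the validation suite checks over 20 seeds each.

Defaults are 120 residues (a typical single-domain chain), body volume
scaled to ~118 Å³ per residue (globular packing at effective-atom
resolution), semi-axes in ratio 1.25 : 1 : 0.8 (mild, generic anisotropy),
and no coordinate noise. A `contrast` knob in [0, 1] flattens the
organization toward unstructured; RD is checked to be non-increasing in
contrast over seeds.

What the generator does **not** emulate: chain connectivity and sterics
(positions are i.i.d. within the body), realistic side-chain packing,
secondary structure, cofactors, or solvent. Passing regime tests therefore
demonstrates correctness of the *field computations and protocols*, not
biological realism of any structure. `generate_profile_with_known_k()`
similarly plants an exact ground-truth K by constructing `O := M(T, K*)`,
optionally perturbed by mean-one gamma noise (a Dirichlet-style
multiplicative perturbation with coefficient of variation equal to the
noise level) and renormalized.

## Numerical choices and degenerate inputs

* Profiles are normalized by their exact sums; tests require unit sums to
  1e-9 and oracle agreement (brute-force pair sums, pointwise Gaussian
  evaluation) to 1e-12 relative on small instances.
* `D_KL(O|T)` and `D_KL(O|R)` are always defined: T is strictly positive
  (a finite Gaussian) and R is constant. `kl_divergence()` still guards
  against zero reference mass for user-supplied distributions, and RD is
  undefined (an error) only when O equals both references exactly.
* Grid values of `seq()` carry floating-point representation error
  (`0.1 * 7 ≠ 0.7` exactly); comparisons against grid K values should use
  a tolerance, as the package's own tests do.
* Alternate locations resolve by highest occupancy, then label order;
  multi-model files use one model; residues with no heavy atoms are
  skipped with a warning; files with no standard amino acids raise an
  error naming the file.
* Units with fewer than 2 residues, empty selections, eliminations that
  empty a unit, unknown residue codes, and exclusions outside the parent
  selection all raise informative errors.

## Validation problem sizes

The shipped suite validates against independent brute-force oracles on
instances of up to 15 residues (100 random cases), parameter recovery on
60-residue profiles (50 exact cases plus noisy-mode studies), regime
separation on 120-residue bodies over 20 seeds per regime, and rigid-motion
invariance over 20 random rotations and translations at a 1e-9 bound.
These sizes give fully deterministic, fast checks while exercising every
code path; the model itself has no size limit beyond memory for the O(N²)
distance matrix.

## Known limitations

* Reproduction of published RD/K values for specific PDB entries depends on
  the (often unstated) intrinsic scale and sigma rule of the original
  implementations; with this package's defaults, agreement should be
  expected within a few hundredths of RD and a grid step or two of K, and
  the published-value test fetches coordinate files over the network.
* Per-residue resolution is intrinsic to the model: no all-atom fields.
* No structure repair, hydrogen placement, or assembly expansion; the file
  is analyzed as deposited.
* Domain boundaries are user inputs; the package does not detect domains
  or protein–protein interfaces.
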