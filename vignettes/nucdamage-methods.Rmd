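---
title: "Geometry of DNA-damage recognition in the nucleosome: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry of DNA-damage recognition in the nucleosome: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucdamage)
```

This vignette is the package's own account of the science it implements:
the geometric model of the nucleosome it uses, the observables and their
exact conventions, what the synthetic generator does and does not emulate,
the numerical choices, and the known limitations. Everything quantitative
stated here is computed by the test suite or the acceptance script; nothing
is quoted from elsewhere.

## 1. The coordinate model of the nucleosome

A nucleosome core particle wraps ~145 bp of DNA in ~1.9 left-handed
superhelical turns. Two geometric frames matter:

* the **double-helical frame** of the duplex itself (rise ~3.4 Å/bp, one
  twist per ~10.4 bp when wrapped, i.e. ~34.6°/bp), and
* the **superhelical frame**: the symmetry axis perpendicular to the two
  nearly parallel circles formed by the gyres, with the origin at their
  center.

The superhelical location (SHL) of a base pair is its signed path distance
from the dyad in units of double-helical turns: SHL = (bp − bp_dyad)/10.4,
reaching ≈ ±6.92 for 145 bp. Because the duplex completes one twist per
10.4 bp *relative to the wrap*, the minor groove faces the histone core
once per turn; with the groove facing outward at the dyad (the orientation
found in nucleosomes), the inward contacts fall at half-integer SHL —
±0.5, ±1.5, …, ±6.5 — which is exactly 14 positions. This count is one of
the two acceptance targets and is reproduced by `contact_points()` on the
synthetic wrap.

### Axis fitting

`fit_superhelix()` seeds the axis with the least-squares plane normal
through the backbone phosphates and then refines it by a cylinder fit (the
axis direction and position minimizing the variance of point-to-axis
distances, Nelder–Mead over 4 parameters). The refinement is not optional:
on a *partial* wrap of ~1.85 turns the raw plane normal is biased by
roughly 13° because the axial drift of the helix correlates with its
incomplete azimuthal coverage; the cylinder fit recovers the generator's
axis to < 0.5°. The axis sign is fixed by handedness: the wrap must appear
left-handed (clockwise with increasing bp index) about +axis.

### Accessibility classes

A lesion is classified by the angle θ between its base's radial vector
(base centroid minus the local double-helical axis point, the latter
estimated as an ~11-bp windowed centroid so the azimuthal placement of any
single atom class averages out) and the outward superhelix radial:
θ < 60° = easy (solvent-facing), θ > 120° = hard (core-facing), medium in
between. The 60°/120° thresholds partition a uniform orientation
distribution into thirds and are configurable; on the synthetic wrap the
observed split is roughly 45 % easy / 33 % medium / 21 % hard because the
coarse base geometry is biased slightly outward. Histone-tail proximity is
a separate boolean: any heavy atom of a configured tail residue range
(defaults: H3 1–44, H4 1–24, H2A 1–16 + 118–129, H2B 1–30) within 5 Å.

## 2. Damage constructs

All constructs are purely geometric; no energy model is applied. Relaxing
a construct is the job of a simulation engine, which this package
deliberately does not contain.

* **Base substitution** (`swap_base`): the base atoms are replaced by an
  idealized planar template (regular-polygon ring geometry, bundled)
  placed on the *existing* glycosidic frame — C1′ position, C1′→N
  direction, and the plane orientation that best matches the old base
  (deterministic mirror disambiguation). T→U removes exactly the C7
  methyl. Because the builder uses the same templates, swap round trips
  (T→U→T) reproduce coordinates to numerical precision.
* **Extrahelical flip** (`flip_base`): the nucleoside (everything except
  the 5′-phosphate group) rotates about the axis through the two flanking
  backbone phosphorus atoms. A P–P axis is the unique well-defined reading
  of a rotation "about the phosphate backbone" that keeps both phosphates
  fixed; the applied angle is recorded in the `DamageSite`. At 180° the
  base centroid moves several Å outward of the helix envelope.
* **Single-strand break** (`make_ssb`): one whole nucleotide is deleted
  (author numbering keeps the gap of exactly 1); the upstream neighbor
  becomes the 3′-OH terminus, the downstream neighbor carries the 5′ cap.
  The default dRP (5′-deoxyribose-phosphate) cap is modeled as abasic
  sugar pseudo-atoms (C1R…O4R) attached to the 5′ neighbor at the deleted
  sugar's coordinates — chemically the remnant the lesion leaves, while
  keeping residue bookkeeping simple. Hydrogens are never synthesized.
  The opposite-strand partner is recorded as unpaired, and the flanking
  base pairs' partners are resolved *before* the deletion breaks index
  pairing. `set_flank_motif()` enforces the G*G / CTC flanking motif
  (idempotent).

## 3. Observables and their conventions

* **dg** is the Euclidean distance between the C3′ atoms of the two break
  termini, reported in nm (internal units are Å throughout; conversion
  happens only at the reporting edge). On an undeformed duplex the
  construct geometry gives dg ≈ 1.23 nm — one double-helical step spanning
  the two-nucleotide gap — matching the closed form
  √[(2r·sin Ω)² + (2·rise)²] with r the C3′ radius and Ω the per-bp twist.
* **Φ** is the dihedral over the ordered C3′ quadruple (5′-flank, its
  partner, the 3′-flank's partner, 3′-flank), mapped to [0°, 180°] since
  only unsigned values are meaningful here. The ordering and the builder's
  backbone geometry were calibrated once so that relaxed B-DNA at
  10.4 bp/turn reads ~65°, i.e. inside the canonical 60–70° band expected
  from twice the per-bp twist; a calibration test pins this. The angle is
  rigid-motion invariant and reflection leaves the reported magnitude
  unchanged.
* **dw** (gyre gaping) is the P–P distance from the break's unpaired
  nucleotide to a partner in the *other* gyre. The partner is chosen once
  — nearest phosphate on frame 0 — and then held fixed, so dw is a proper
  paired time series rather than a running minimum; per-frame re-selection
  within ±1 SHL of the frame-0 partner is available by flag. At the dyad
  there is no adjacent winding and the measurement is refused.
* **Pair distances** offer minimum heavy-atom and mass-weighted centroid
  modes, since published probe distances (e.g. a zinc-finger leucine to a
  3′ terminus) do not always state which was used. The 3′-side anchor
  defaults to C3′ and the 5′-side to P/C5′, both configurable.
* **H-bonds** default to a donor–acceptor heavy-atom cutoff of 3.5 Å with
  no angle test when hydrogens are absent (the bundled typing tables list
  standard donors/acceptors); the distance series is always returned so a
  different criterion can be applied post hoc.
* **RMSD** uses closed-form Kabsch superposition (SVD with determinant
  correction). Superposed RMSD is never larger than raw RMSD; this is
  asserted property-style across random ensembles.

## 4. GROMOS clustering and a caveat worth recording

`gromos_cluster()` implements the greedy neighbor-counting rule: the frame
with the most neighbors within the cutoff (default 0.45 nm) becomes a
center; it and its neighbors are removed; repeat. Ties in neighbor count
resolve to the lowest frame index, cluster ordering is by decreasing size
then lower center index, so the partition is fully deterministic — this is
asserted against an independent brute-force implementation over 100 random
matrices.

One property often attributed to such clustering — that the number of
clusters can only decrease as the cutoff grows — is **not a theorem** of
the greedy rule, and the acceptance suite documents this honestly: with a
larger cutoff the first center can absorb frames that previously held the
remainder together, fragmenting what is left into *more* clusters. The
effect is reproducible both on random symmetric matrices and on genuine
RMSD matrices of diffusive synthetic trajectories (counts going 2→3→2→3
across a fine cutoff sweep). The corresponding acceptance assertion is
therefore expected to fail, and is left failing rather than weakened; the
true guarantees (determinism, complete partition, members within cutoff of
their center, single cluster above max RMSD, all singletons below min
RMSD) are asserted and green.

## 5. Interface descriptors

SASA is Shrake–Rupley-style numerical integration on a deterministic
golden-spiral point set (default 960 points/atom, probe 1.4 Å, bundled
element radii). Determinism makes results exactly reproducible; doubling
the point count changes totals by < 0.5 %. Two degenerate-case choices:
occlusion counts only points *strictly inside* a neighbor, and exactly
coincident equal atoms are owned by the lowest atom index — so two
coincident atoms expose the area of one, and an isolated atom is exact to
the analytic sphere. Buried interface area is
½·[SASA(A)+SASA(B)−SASA(A∪B)], clipped at zero; it matches the two-sphere
spherical-cap closed form within 2 %.

Contact counts use community-default cutoffs — H-bond 3.5 Å
donor/acceptor, salt bridge 4.0 Å between basic nitrogens
(Arg/Lys/His) and phosphate/carboxylate oxygens, hydrophobic 4.5 Å C–C
between apolar moieties counted **once per residue pair** (the published
tables this mirrors do not define the unit; residue pairs are the choice
here and are so documented). Totals come with site-restricted splits
(contacts involving one designated residue, e.g. the flipped nucleotide).
The PISA-style solvation free-energy gain (ΔGS) is **not** recomputed —
its energy model is proprietary-complex and error-prone to imitate — but
the report schema keeps an import-only field for externally computed
values. Consequently, absolute contact counts and areas from other tools
are matched in kind, not asserted numerically.

`table1_report()` averages per-frame reports over a trailing window
(default last 10 ns): areas as means, counts as rounded means clipped so
site ≤ total row-wise.

## 6. The synthetic generator: what a green test establishes

`build_bdna()` places a coarse backbone atom set (P — absent at 5′
termini —, O5′, C5′, C4′, C3′, O3′, C1′) on cylindrical coordinates plus
full idealized heavy-atom bases and a CEN centroid pseudo-atom; geometry
follows the stated rise/twist exactly. The backbone azimuthal
half-separation across the minor groove (45°) is the one calibrated
constant (Section 3). `wrap_superhelix()` maps the duplex axis onto a
left-handed circular helix (defaults radius 41.8 Å, pitch 25.9 Å — canonical
nucleosome crystallography values, **not** fitted to any particular
structure), transporting cross-sections in a proper right-handed radial
frame (an early implementation used a mirror frame, invisible to unsigned
observables; the straight-limit superposition test now guards this) and
registering the dyad minor groove to face outward.

`make_trajectory()` builds each frame independently from the base model by
exact geometric operators: terminus translation along the gap vector (dg),
rigid rotation of the 3′-flank base pair about the flank-pair C3′ axis
(Φ), rigid axial displacement of a ±3-bp gyre segment (dw), rigid probe
translation (probe distances). Noise of the stated σ is added to the
*target value* per frame (seeded; optional AR(1) correlation mimicking MD
autocorrelation) — noise in observable units is the only reading that is
well defined for an angle schedule — and the pre-noise schedule is logged
as ground truth. Several signals sharing atoms are composed by alternating
projection to 10⁻⁶ convergence; non-convergence is a composition error.
Determinism is bit-exact for a fixed seed.

What this emulates: per-frame local deformations of the stated magnitudes
(gap openings ~0.8–3 nm, twists 30–90°, gaping 1–3 nm), probe residues at
prescribed distances, and frame-to-frame noise. What it does **not**
emulate: thermodynamic weights, kinetics, sequence-dependent elasticity,
solvent, histone flexibility, or any force field. A green
parameter-recovery test therefore establishes that the *analysis* is
correct and unit-consistent — never that a biological system behaves this
way.

## 7. Numerical choices and degenerate inputs

* Internal unit Å; reported distances nm, angles degrees; PDB coordinates
  written at 3 decimals (round trips asserted to 10⁻³ Å).
* Atom-name primes (`'`, `*`, Unicode prime) are canonicalized on input.
* Alternate locations: highest occupancy wins, ties to first encountered.
  Waters/ions dropped by default flag.
* Serials > 99999 wrap back to 1 on writing (documented hybrid
  convention); residue numbering is author numbering, never rewritten.
* Straight DNA fed to the nucleosome mapper: the cylinder fit finds the
  duplex's own axis, every base pair then lacks a defined outward radial
  (< 3 Å offset guard), so `contact_points()` correctly returns none.
* The dyad refuses dw (no adjacent winding); chain termini refuse
  flips/breaks; empty selections are anchor errors naming the residue.
* The composition iteration caps at 40 sweeps; 10⁻⁶ tolerance in each
  signal's own units.

## 8. Known limitations

* Base templates are idealized regular-polygon geometry — adequate for
  centroid/anchor observables and bookkeeping, not for base-pair-step
  analysis (roll/slide/tilt are out of scope by design).
* The coarse builder carries no hydrogens, so H-bond detection on
  synthetic structures is always heavy-atom distance only.
* Accessibility thresholds and contact cutoffs are conventions, exposed as
  configuration; absolute agreement with other tools' counts is not a
  goal.
* Binary trajectory formats (XTC/TRR/DCD) enter only through the adapter
  contract (a function returning frames + times); the core parses
  multi-model PDB only.
* The SHL sign convention (positive on the first chain's 3′ side of the
  dyad) is exposed as a flip flag; absolute sign cannot be fixed without
  an external labeling convention.
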