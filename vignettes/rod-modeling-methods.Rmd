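---
title: "Cross-link-guided rod modeling: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-link-guided rod modeling: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smcrod)
```

This vignette is the package's account of the science behind its
functions: what is being modeled, which assumptions the procedures make,
what the tunable parameters mean, and where the design was genuinely open
and a choice had to be made. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The measurement model

An in-vivo cysteine cross-linking screen of a C2-symmetric homodimer
reports, per mutated position, the fraction of protein cross-linked to
its symmetry mate by a short bifunctional thiol reagent (BMOE). Because
the reagent spans only ~8 Å between maleimides, efficient cross-linking
requires the two symmetric copies of a residue to sit close to the
dimer's two-fold axis. Two facts organize everything downstream:

1. **In a C2 dimer, a residue's symmetry-mate Cα–Cα distance equals twice
   its perpendicular distance from the axis.** The docking objective
   exploits this identity: restraints on mate distances are restraints on
   point-to-line distances, which makes the grid stage cheap and exact.
2. **Cross-linking bounds distance only from above.** A position that
   cross-links must be within reach; a position that does not cross-link
   may be far away *or* merely chemically unlucky. Hence the one-sided
   restraint loss, and hence no reward for compressing pairs below the
   reach cutoff in the objective itself.

## Screen representation

Screenable positions are the coiled-coil surface: heptad letters
propagate cyclically (a→b→…→g) from user-supplied anchors, and the
hydrophobic core letters `a`/`d` are excluded — 5 of every 7 residues
remain. Register anchors are configuration, not prediction: the package
deliberately contains no coiled-coil predictor, because screens of this
kind are designed from previously established registers.

*Axial calling* uses a strict threshold: efficiency > 0.20. The
strictness at the boundary follows the "greater than 20 %" convention for
strong cross-linking; a tie at exactly 0.20 is excluded. The four-color
display classes (none/low/medium/high at 0.05/0.20/0.40) are rendering
conventions for surface coloring, chosen so that "strong" spans
medium + high; they are configurable and carry no analysis weight.

Efficiency tables must declare their units (`# units: percent` or
`fraction`, or a unit-suffixed column name). Units are never guessed from
the values: a table whose entries all happen to be below 1 is ambiguous,
and silently mis-scaling by 100 is the classic failure mode.

## Cross-link-restrained C2 docking

`dock_c2()` automates what was historically done by hand: place two
copies of a monomer about a two-fold axis so that axial residues meet
while the backbones do not overlap.

**Objective.**
`score = Σᵢ wᵢ · max(0, dᵢ − reach)² + λ · clashes`, summed over axial
positions with weights `wᵢ` equal to efficiencies. Defaults: reach 14 Å
Cα–Cα (≈ 8 Å BMOE spacer + two ~3 Å cysteine side-chain extents — a
package default, exposed, since the exact side-chain geometry correction
is not standardized), clash cutoff 4 Å Cα-only with intra-chain
neighbors within 2 residues excluded, λ = 1 per clashing pair. Clash
checking is Cα-only because the entire assembly operates at backbone
level; a full-atom steric model would claim a precision the inputs do not
have.

**Search.** Four effective degrees of freedom (axis direction × in-plane
offset; the dimer is invariant to sliding the axis along itself).
Directions come from a nested low-discrepancy (Halton) hemisphere
sequence — nested so that doubling `n_directions` strictly extends the
searched set and the grid-stage optimum is monotone, a property the test
suite checks. Offsets lie on a square grid (2 Å spacing, ±30 Å). The
restraint term is evaluated vectorized on every grid cell; the clash
term, a step function that is zero for every non-overlapping pose, is
evaluated on the best 200 cells by restraint loss before lexicographic
ranking — a scheduling detail, not a change of objective. The best 10
cells seed Nelder–Mead refinement (500 iterations, small seeded start
jitter).

**Tightness stage.** The one-sided loss is satisfied on a whole *set* of
poses whenever every axial pair can be brought within reach, so the
objective alone does not identify a unique pose — it cannot, because the
data only bound distances from above. Among poses whose objective is
within 1e-9 of the optimum, the dock therefore minimizes the total
weighted squared mate distance subject to the clash count not increasing:
the tightest sterically allowed dimer. This mirrors the manual procedure
the method automates — monomers are pulled together until the
cross-linking residues meet and sterics resist — and it is what makes the
planted-axis recovery tests sharp. Internally the optimizer counts
clashes with a 1e-6 Å cutoff buffer so the optimum never sits exactly on
the clash boundary; all reported quantities use the exact cutoffs,
recomputed from the returned dimer.

What the dock does *not* pin down is the axis position along the
compression direction beyond what sterics dictate: with one-sided
restraints, any residual gap between "all pairs in reach" and "first
clash" is genuinely unidentifiable from cross-linking data alone. The
recovered axis *direction* is the robust quantity; position is reported
as found at the steric contact.

## Composite assembly

**Superposition** is Kabsch (SVD with determinant correction, so a
reflection is never returned); degenerate (collinear) selections are
rejected. The suite cross-checks it against an independent
quaternion-based implementation on random instances at 1e-8 Å.

**Stitching** takes rigidly placed fragments in hinge→head order;
consecutive fragments must share ≥ 3 residues. In an overlap the later
fragment donates coordinates and the earlier one is blended out linearly
over the overlap's outer 3 residues — overlap ownership had to be decided
(the source procedure used a guide structure without stating ownership),
and "later donates" keeps each junction local. Every junction's Cα RMSD
is reported; above 5 Å stitching refuses: that is a placement problem the
user must see, not smooth over.

**Coiled-coil bending** (`bend_coiled_coil()`) applies an incremental
rotation per helical turn about an axis perpendicular to the local helix
axis, hinged at one-turn spacings; everything downstream follows rigidly,
so intra-segment geometry is exactly preserved. The bending plane is
intrinsic: each segment residue's radial vector about the local helix
axis is de-rotated by the helical phase implied by its residue number and
averaged. Because that frame is rigid-motion-equivariant and computed
from the already-final upstream segment, applying the negative schedule
restores the input *exactly* — a property the tests assert at 1e-6 Å.
The local axis comes from a total-least-squares line through one
inter-hinge segment (3–4 Cα); with so few points the per-hinge axis
wobbles a few degrees, so the accumulated bend runs ~8 % short of the
nominal schedule (the tests measure ~50° for a 6 × 9° schedule). For
ring-model building the relevant setting is ~9° per six turns
(`angle_per_window = 1.5`), the gentle continuous bend that closes a
rod's arms into a ring; the package checks geometric validity (Cα steps
within [2.9, 4.5] Å) instead of performing force-field minimization,
which is out of scope.

**Transition decomposition** superposes the fixed chains of two dimer
states and expresses the residual motion of the moving selection as a
screw: rotation angle in [0°, 180°] about the right-handed axis plus
translation along it (the translation keeps its sign so the motion
recomposes exactly; an early design that flipped the axis to make the
slide positive broke recomposition and was discarded). Below 1e-6 rad
the axis is degenerate and defaults to the displacement direction. Head
tilt (~85°) and slide (~10 Å) values for real structures depend on the
chain and range conventions chosen, so the function reports, and the
package asserts recovery only on planted transforms.

## Quantitative fits

Subunit exchange is fit as `F(t) = F_eq·(1 − e^(−kt))` with `F(0) = 0`
fixed — the heterodimer fraction starts at zero by the mixing design; a
three-parameter variant with a free intercept exists for data that do
not. The fit is plain nonlinear least squares on fractions
(Levenberg–Marquardt), not a log-linearization, which would weight the
plateau region badly. The half-life is `ln 2 / k`; its uncertainty comes
from a seeded bootstrap over timepoints (default 1000), which is the
honest desk-scale substitute when replicate series are not supplied.
ChIP/input ratios are `α·2^(CT_input − CT_ChIP)` with `α` the
volume/dilution factor — arithmetic, but centralized and tested.

## The synthetic generator and what it does not emulate

`make_monomer_arm()` builds a Cα-only two-helix hairpin from the standard
Crick parameterization: 3.62 residues/turn, 1.51 Å rise, superhelix
radius 4.9 Å, pitch 160 Å — textbook coiled-coil values, not measured
ones. The default arm is 110 residues per helix: long enough to span a
full superhelical pitch turn, so the simulated rod shows the alternating
multi-patch contact pattern that real rod screens show and that the
docking relies on to pin the axis direction; a much shorter arm has a
single contact patch and genuinely under-constrains the axis.
`make_rod_dimer()` plants the C2 axis at a 9.6 Å offset, which puts the
protomers at van-der-Waals Cα contact (minimum mate distance ≈ 4.9 Å) —
rod dimers are tightly packed, and a gap would be both unrealistic and
unidentifiable (see the tightness stage above). Efficiencies follow a
sigmoid of mate distance (midpoint 14 Å, width 2 Å, maximum 0.9) with
clamped additive Gaussian noise; the closed-form threshold
`d₀ + s·ln(E_max/θ − 1)` lets the simulate→call path be checked exactly.

What passing these tests shows: the geometry engine, the calling logic,
the docking search and the fits are correct on data that obey the model.
What it does not show: robustness to the things real screens contain —
position-specific labeling chemistry, expression differences between
mutants, partially disordered regions, helix irregularities at the joint,
or cross-links from transient conformations. Those enter only through
the real deposited structures and published tables, which is why the
acceptance tests against them are kept separate and report their absence
loudly rather than being quietly skipped.

## Problem sizes and numerical conventions

Module tests run on 40–80-residue-per-helix arms; the planted-recovery
checks use the 110-residue default with the full 500-direction grid once
and a 200-direction grid for the five noisy replicates — sizes chosen so
the whole suite exercises every path in a couple of minutes while the
recovery claims still run at the generator's defaults. Tolerances: exact
identities (C2 symmetry, screw recomposition, stitching round-trips) at
1e-6–1e-9 Å; cross-implementation agreement at 1e-8 Å; statistical
recoveries at the 10 % the noise level implies. Ties in axial calling are
excluded by the strict threshold; ties in the dock grid break
lexicographically by (objective, clash count, grid index); alternate
conformers in crystal files keep the highest occupancy, label-order on
ties, with a message.

## Known limitations

- Cα-only sterics and reach: no side-chain rotamers, no Sγ–Sγ geometry;
  the reach cutoff is a tunable surrogate.
- The dock explores rigid monomers only; backbone flexibility during
  rod formation is outside the model.
- Collinearity significance uses residue sets drawn uniformly from the
  chain as the permutation baseline; it does not condition on surface
  exposure.
- The exchange model assumes a single first-order process; biphasic
  exchange will show in the residuals but is not fit.
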