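---
title: "Rigidity and cooperativity analysis of RNA ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rigidity and cooperativity analysis of RNA ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Purine riboswitches regulate transcription through an aptamer domain built
around a three-way junction of paired regions P1, P2 and P3. Two loops, L2
and L3, cap P2 and P3 and form tertiary "kissing" contacts through two base
quadruples; the ligand binds at the junction core formed by the joining
strands J1/2, J2/3 and J3/1; and part of P1 belongs to the switching
sequence that decides between terminator and antiterminator folds. The
question this package addresses quantitatively is how *two* distal
interaction sets — the loop–loop quadruples and the ligand contacts —
jointly stabilize the terminal base pairs of P1, and whether their joint
effect exceeds the sum of their separate effects (cooperativity).

The approach is mechanical rather than thermodynamic. Each conformation is
converted into a constraint network; a combinatorial rigidity analysis
decomposes the network into rigid clusters and flexible links; and
ensemble statistics over many snapshots turn cluster membership into
probabilities. Because the ligand is modeled purely as extra constraints
on fixed coordinates, any effect detected is an effect of *interactions*,
never of conformational change.

## The constraint network

`build_network()` maps a structure onto a body-bar multigraph:

* **Bodies.** One body per heavy atom, with bonded hydrogens absorbed into
  their parent atom. A free body has 6 degrees of freedom.
* **Covalent bars.** Bonds come from internal residue templates for
  A/C/G/U (plus inter-residue O3'–P links), not from distance inference,
  which is reserved for residues outside the templates (< 1.8 Å between
  heavy atoms). Rotatable single bonds contribute 5 bars (they remove all
  relative freedom except torsion); bonds with hindered rotation — ring
  bonds and partial-double exocyclic bonds — contribute 6 bars and weld a
  rigid unit.
* **Hydrogen bonds.** Detected geometrically (donor–acceptor distance
  ≤ 3.5 Å and donor–H–acceptor angle ≥ 120° by default), scored with a
  Mayo-style energy: a 12–10 radial well of depth 8 kcal/mol at an optimal
  donor–acceptor separation of 2.8 Å, clamped at the optimum, multiplied
  by `cos^4` of the deviation from linearity. Only bonds with energy at or
  below the cutoff `e_cut` (−0.6 kcal/mol by default, −1.0 as a
  sensitivity setting) contribute 5 bars each. Salt bridges carry a fixed
  −10 kcal/mol so they survive any cutoff.
* **Hydrophobic tethers.** Carbon/sulfur pairs whose surfaces approach
  within 0.25 Å of the summed van-der-Waals radii contribute 2 bars. Only
  the closest such contact per residue pair is kept: a tether stands in
  for a stacking-type association, and counting every close carbon pair in
  a packed structure would grossly overconstrain the network.
* **Magnesium.** Mg–water-oxygen and Mg–RNA contacts within 3.5 Å become
  covalent-strength (6-bar) coordination bars; only first-shell waters are
  retained in the network, and water–RNA contacts enter through the
  ordinary hydrogen-bond machinery.
* **Ligand constraints.** `add_ligand_constraints()` connects the base N1
  atoms of the binding triplet (47, 51, 74) pairwise with locked-strength
  bars. Because each nucleobase is internally rigid through its ring
  bars, this places the three binding nucleobases in one rigid cluster —
  the validation contract for the bound-site model — without adding any
  stacking constraints (a deliberately weak coupling).

### Hydrogen placement

Crystal structures and generated structures lack hydrogens, so donors get
ideal-geometry hydrogens at detection time: ring N–H along the bisector
away from the two ring neighbours; amino groups two in-plane hydrogens at
±60° from the C–N extension; hydroxyls (2'-OH) a single hydrogen at the
tetrahedral angle with torsion anti to C1'. Shell waters, which tumble
freely, are oriented toward the candidate acceptor. The fixed hydroxyl
torsion matters: treating 2'-OH as freely orientable makes essentially
every close sugar–sugar contact a bond and rigidifies entire strands.
Intra-residue donor–acceptor pairs are excluded altogether — at this
resolution they reflect sugar geometry, not interactions that should
constrain the network.

## The pebble game and its oracle

`pebble_game_decompose()` runs the (6,6) body-bar pebble game: every body
holds six pebbles, and a bar is independent exactly when seven pebbles can
be gathered on its two endpoints before placement. After all bars are
processed, two bodies are mutually rigid when a virtual seventh-pebble
test between them fails; rigid clusters are maximal mutually-rigid sets,
found by pinning six pebbles on a seed body and collecting every body that
can no longer reach a free pebble. Bars are processed in the network's
canonical sorted order, so results are reproducible; the decomposition is
invariant to input order by the matroid property of the underlying count.

Floppy modes are reported per connected component as
`6V − 6 − independent bars` (the six global rigid-body motions
subtracted), summed into a total. Note a consequence checked in the test
suite: adding a bar *within* a component never increases the mode count,
but a bar *bridging* two components converts their six relative rigid-body
motions into internal modes, so the total can rise.

The implementation is validated against an independent brute-force
oracle (`brute_force_rank()`, `brute_force_clusters()`): bodies receive
random generic placements, each bar becomes one row of the body-bar
rigidity matrix (bar direction and moment, six columns per incident
body), and the numeric rank — singular values below 1e-8 of the largest
treated as zero, maximum over two seeds as a genericity guard — must
equal the pebble count. Mutual rigidity is cross-checked by adding six
generic bars between a body pair and asking whether the rank grows. The
suite requires exact agreement on both counts and partitions over 100
random networks of up to 8 bodies with multiplicities 1–6.

## Ensemble statistics

For an ensemble of N snapshots, `plrc_profile()` computes per nucleotide
`p_lrc(i) = n1(i)/N`, the fraction of snapshots in which the nucleotide's
base N1 atom belongs to the largest rigid cluster (ties between equally
large clusters break toward the cluster containing the smallest body
index; real inputs are unambiguous). The N1 value is projected onto the
whole nucleotide. `delta_plrc()` is the elementwise difference between
ligand-constrained and apo profiles.

The cooperativity statistic compares four conditions — wildtype (`apt`)
and loop-mutant (`loop`) variants, each with and without ligand
constraints — referenced to the mutant apo state, which lacks both
interaction sets:

Coop(i) = ln(p_lig^apt / p_apo^loop) − ln(p_apo^apt / p_apo^loop)
        − ln(p_lig^loop / p_apo^loop)
        = ln[(p_lig^apt · p_apo^loop) / (p_apo^apt · p_lig^loop)]

Coop(i) > 0 means the two interaction sets together stabilize nucleotide
i more than the sum of their separate effects. Uncertainty is propagated
from the four terms, `SEM² = Σ (SEM_p / p)²`, with each probability's SEM
taken as the standard error over independent trajectories (the
alternative, a binomial SEM per condition, ignores between-trajectory
variability and was not adopted). Zero probabilities yield an explicit
`undefined` flag rather than a silent pseudocount; an optional
`(n1 + ½)/(N + 1)` continuity correction is available behind a flag.
`coop_ttest()` applies a two-sided one-sample t-test of Coop = 0; the
degrees of freedom default to the number of independent trajectories
minus one (2 for a three-trajectory design) — the natural choice when the
SEM itself comes from the trajectory spread — and are configurable
because other conventions are defensible.

Hydrogen-bond occupancies are per-frame geometric indicators averaged to
a percentage; within a trajectory the uncertainty comes from means over
consecutive 10-ns blocks (block averaging absorbs autocorrelation), and
across trajectories from the spread of trajectory occupancies. Base-pair
occupancy averages the member bonds with SEM propagated as
`sqrt(Σ SEM²)/k`.

## Trajectory metrics

All superpositions are mass-weighted least-squares fits (Kabsch/SVD).
RMSF fits each frame to the reference over a fit selection, computes
per-atom fluctuations about the mean fitted structure and averages them
per nucleotide over all atoms (heavy-only is a switch). `select_core()`
keeps the `round(0.8 n)` least-fluctuating nucleotides — 54 of 67 for
this aptamer — with ties toward the lower id. RMSD fits on the core
selection and measures over any region; substructure-internal deviations
fit on the substructure itself. The radius of gyration is mass-weighted
and by convention omits the P1 region (the mobile terminal helix would
otherwise dominate compactness). RAC(w) averages coordinates over running
windows of w frames, refits, and reports the mean RMSD against the first
post-discard frame; the variant against the average structure (smaller
values) sits behind a flag. PCA pools the covariance of phosphorus
coordinates over all supplied trajectories after fitting to a common
reference and exposes per-trajectory and per-half projections for overlap
checks. Mg2+ ions are hexahydrated when exactly six water oxygens lie
within 3.5 Å and no RNA atom does (the same cutoff flags chelation).
Occupancy grids use 0.4 Å cells and count frames with any ion in a cell;
site occupancy uses a separate 3 Å radius because the 5 Å value used for
nucleotide-proximity comparisons answers a different question. χ
dihedrals (O4'–C1'–N9–C4 for purines, O4'–C1'–N1–C2 for pyrimidines) are
histogrammed over [0°, 360°) in 5° bins, normalized per nucleotide.

## The synthetic data generators

The generators define the study conditions for every test; nothing is
downloaded.

* `make_fixture_network()` produces networks with known rigidity
  (braced pair, hinge, chain, ring, seeded random) for the pebble-game
  oracle suite.
* `make_toy_aptamer()` builds a fully synthetic 67-nucleotide miniature
  of the aptamer architecture with author numbering 15–81: three helices
  around a junction, loop quadruples whose designed hydrogen-bond sets
  number seven (wildtype) and five (loop mutant) in the upper quadruple,
  and a spatially separated binding triplet. Bases are idealized regular
  polygons; pair geometry is solved by small placement optimizations so
  every designed bond satisfies the detection criteria; the sugar
  backbone is a fixed offset template with sensible bond lengths but
  schematic pucker. No coordinates derive from any deposited structure.
* `simulate_condition_ensembles()` draws four-condition ensembles on a
  coarse five-body topology in which the focal body joins the largest
  rigid cluster with an exactly known probability q per condition, so the
  analytic Coop of the design, `ln[(q1 q4)/(q2 q3)]`, is available for
  recovery tests.
* `simulate_trajectory()` adds per-region Gaussian displacements,
  optional global rigid-body motion, two-state Markov (telegraph)
  hydrogen-bond switching with a prescribed stationary on-fraction, and
  fixed, diffusing or water-shedding hexahydrated ions.

All generators take mandatory seeds, use R's default generator, and
attach their parameters to the output. What they emulate is the
*statistical* structure the analyses assume — fluctuation amplitudes,
bond on/off dynamics, shell composition — not force-field physics: a
passing test shows the estimators recover designed truth under those
statistics, not that any particular simulation of the real aptamer is
converged.

## Problem sizes and numerical choices

The test and acceptance runs use deliberately small ensembles chosen to
exercise every code path at comfortable statistical margins: 10–80 frames
for trajectory metrics, 18 frames for the energy-cutoff comparison of
ligand-response profiles, 1000 snapshots × 3 pseudo-trajectories per
condition for cooperativity recovery (with 100 seeded replicates of the
null design), and 100 random networks for the rigidity oracle. Rank
tolerance is 1e-8 of the largest singular value; Coop identities are
checked to 1e-12; PDB round trips to the format's 1e-3 Å precision.
Degenerate inputs fail loudly: empty networks, empty selections,
non-negative energy cutoffs, block lengths exceeding the trajectory,
missing binding nucleotides and region-table gaps are all errors, and a
donor without a placeable hydrogen is skipped with a warning.

## Known limitations

* The default region table is a reconstruction anchored at published
  landmarks (terminal P1 = 15–19/77–81, upper quadruple 34/37/61/65,
  lower 33/38/60/66, binding 47/51/74); helix boundaries in between are
  conventional, and any authoritative assignment should be supplied as a
  user table.
* The hydrophobic-tether and bar-multiplicity parameters follow the
  standard body-bar convention with an RNA-flavoured tether rule; all are
  configurable, and analyses near the rigidity transition should check
  sensitivity to them alongside the documented `e_cut` sensitivity.
* The toy aptamer is a geometric analog. Its quadruple bond counts and
  binding-site behaviour mirror the real system by construction, but
  absolute p_lrc values on it say nothing about the real aptamer.
* Crystal-structure checks (radius of gyration of the ligand-stripped
  wildtype and mutant structures; their quadruple bond counts) run only
  when the user supplies the corresponding PDB files, which the package
  does not redistribute.
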