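# riborigid

Rigidity and cooperativity analysis of RNA conformational ensembles.

Purine riboswitch aptamers fold into a three-way junction of helices P1,
P2 and P3, with loops L2/L3 forming tertiary base quadruples and the
ligand binding at the junction core. `riborigid` asks a mechanical
question about such systems: how do the loop–loop interactions and the
ligand contacts jointly stabilize the terminal base pairs of P1, and is
their joint effect larger than the sum of their separate effects?

The package is for structural bioinformaticians who have conformational
ensembles (multi-model PDB or frame tables sharing a topology) and want
constraint-network rigidity analyses and the accompanying trajectory
metrics without external tooling.

## The method

Each conformation becomes a **body-bar constraint network**: one body
(6 degrees of freedom) per heavy atom; 5 bars for rotatable covalent
bonds, 6 for locked ones; 5 bars per hydrogen bond that passes a
Mayo-style energy filter (cutoff *E*<sub>cut</sub> = −0.6 kcal/mol by
default); 2 bars per hydrophobic tether; 6-bar coordination for Mg²⁺ and
its first hydration shell. The **(6,6) pebble game** decomposes the
network into rigid clusters and flexible links, validated in the test
suite against a brute-force generic rigidity-matrix rank oracle.

Over an ensemble of *N* snapshots, the per-nucleotide probability of
belonging to the largest rigid cluster is

> *p*<sub>lrc</sub>(*i*) = *n*₁(*i*) / *N*,

evaluated at each nucleotide's base N1 atom. A bound ligand is modeled
as pairwise constraints between the binding nucleobases (47, 51, 74), so
Δ*p*<sub>lrc</sub>(*i*) = *p*<sub>lrc</sub>(*i*)<sub>lig</sub> −
*p*<sub>lrc</sub>(*i*)<sub>apo</sub> isolates the pure interaction
effect. Cooperativity between the loop and ligand interaction sets is
the four-condition log-odds statistic

> Coop(*i*) = ln[(*p*<sub>lig</sub><sup>apt</sup> ·
> *p*<sub>apo</sub><sup>loop</sup>) / (*p*<sub>apo</sub><sup>apt</sup> ·
> *p*<sub>lig</sub><sup>loop</sup>)],

referenced to the loop-mutant apo state, with SEM propagated from the
four terms and a one-sample t-test per nucleotide. Trajectory metrics
(RMSF with 80 % core-nucleotide fitting, RMSD variants, radius of
gyration omitting P1, RMSD average correlation, phosphorus-atom PCA,
Mg²⁺ hydration tracking, occupancy grids, χ histograms) round out the
analyses. Seeded synthetic generators — fixture networks, a fully
synthetic toy aptamer, four-condition ensembles with analytically known
Coop, and coordinate trajectories with prescribed statistics — make
every stage testable offline.

## Worked example

```r
library(riborigid)

# a synthetic 67-nt three-way-junction aptamer (numbering 15-81)
toy <- make_toy_aptamer()
net <- build_network(toy$structure, e_cut = -0.6)
net
#> <constraint_network> 1428 bodies, 1777 bar groups (9459 bars)
#>   e_cut: -0.6 kcal/mol
#>   COVALENT_LOCKED:793  COVALENT_ROTATABLE:803  HBOND:108  HYDROPHOBIC:73

pebble_game_decompose(net)
#> <rigidity_result> 1428 bodies in 326 rigid clusters
#>   largest cluster: id 110 (260 bodies)
#>   independent bars: 8453, redundant: 1006, internal floppy modes: 109

# four-condition ensembles with a designed cooperativity of
# ln(0.45/0.42) = 0.069 at the focal nucleotide
des <- coop_design(0.9, 0.6, 0.7, 0.5, n_snapshots = 1000, n_traj = 3,
                   seed = 42)
cc <- coop_ttest(estimate_coop(simulate_condition_ensembles(des)))
cc[, c("resid", "coop", "sem", "t", "p", "signif")]
#>   resid   coop    sem    t     p signif
#> 1     5 0.0862 0.0182 4.73 0.042      *
```

The network summary counts bodies (heavy atoms) and bars by provenance;
the decomposition reports how many bars were independent versus
redundant and how many internal floppy modes remain. In the Coop table,
the estimate 0.086 ± 0.018 brackets the designed value 0.069 within its
propagated SEM, and the t-test (2 degrees of freedom for three
trajectories) classifies it significant at the 0.05 level.

For real data the entry points are `read_structure()` /
`read_ensemble()`, then `run_rigidity_pipeline()` for p_lrc / Δp_lrc /
Coop tables and `run_traj_metrics()` for the trajectory metrics; every
result type has `autoplot()`, and rigidity results have `tidy()` /
`glance()` methods.

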