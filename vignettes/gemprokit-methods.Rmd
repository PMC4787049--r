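---
title: "Methods: structure-aware genome-scale models with gemprokit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-aware genome-scale models with gemprokit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemprokit)
```

# Overview

`gemprokit` links a genome-scale metabolic model (GEM) to per-gene protein
structural data and runs the downstream analyses that such a GEM-PRO
resource enables: quality scoring and ranking of candidate structures,
sequence reversion of minimally mutated crystal structures, a 29-feature
structural property profile per protein, comparative proteome clustering,
complex-stoichiometry abundance prediction, co-crystallised ligand
diversity, and temperature-constrained growth simulation. Every stage can
be exercised on synthetic fixtures generated in code, so the whole pipeline
runs without any external download.

This vignette records the models and procedures implemented, the tunable
parameters with their defaults and rationale, the numerical choices, and
what the synthetic fixtures do and do not establish about real data.

# Structure mapping and quality control

Candidate structures for a gene are parsed from PDB text (ATOM/SEQRES via
`bio3d`; the `REMARK 2` resolution, `EXPDTA` method and an optional
TM-score annotation are scanned directly). The chain whose ATOM-derived
sequence best matches the gene's wild-type sequence represents the gene;
other chains are ignored for QC.

**Alignment.** The structure sequence is aligned globally to the wild type
(Needleman–Wunsch via `Biostrings::pairwiseAlignment`) with match +1,
mismatch 0, gap open −2, gap extension −0.5. These values are a
design choice: with mismatch at 0 the aligner prefers a substitution over a
gap pair, which matches how point mutations appear in crystal structures,
and the heavy opening penalty keeps unresolved stretches as single runs.
Two fractions summarise the alignment over the wild-type length *L*:

* **identity** `S_SI` — exact matches / *L*;
* **completeness** — aligned (resolved) positions / *L*, mismatches
  included, so identity ≤ completeness always.

**Scoring.** Experimental structures score

$$S = 0.5\,S_{SI} + 0.3\,\text{completeness} + 0.2\,S_{res},$$

clamped into (0, 1], with the resolution term
$S_{res} = \max(0, 1 - (\text{res} - 1)/4)$ (1.0 Å → 1, ≥ 5.0 Å → 0) and
NMR entries fixed at $S_{res} = 0.7$. The weights are exposed as a
parameter of `scoreStructure()`; they encode the view that sequence
fidelity matters more than completeness, which matters more than nominal
resolution. Homology models score $0.5\,\mathrm{TM} + 0.5\,S_{comp}$ where
$S_{comp} = 1 - \tfrac12\sum_c |f_{model}(c) - f_{ref}(c)|$ over the eight
secondary-structure classes; without a reference composition the term
exerts no penalty.

**Groups.** Group I: no mutations, no interior gaps, resolution ≤ 3.0 Å
(NMR/model entries pass the resolution test vacuously). Group II tolerates
small, fixable damage: mutation runs of at most 2 consecutive positions, at
most 5 mutated positions in total, interior gaps of at most 3 residues each
and 5 in total. The run bound of 2 is the structural criterion; the total
bounds are this package's codification and are arguments of
`classifyGroup()`. Terminal truncations reduce completeness but never
affect the group: the concern is the interior of the protein. Everything
else is group III and is routed to homology modelling.

**Ranking** sorts by combined score, then higher identity, experimental
before model, lower resolution, and finally structure id — a total order,
so ranking is deterministic under input permutation.

# Sequence reversion of group-II structures

A group-II structure is reverted to the wild type in three stages. For each
mutated residue (found by alignment): (i) the side chain is stripped to the
backbone atoms N, CA, C, O; (ii) an idealised wild-type side chain is grown
by internal-coordinate (NeRF) construction from a shipped geometry table
(CB at 1.521 Å from CA, N–CA–CB 110.5°, L-configuration improper
C–N–CA–CB +122.55°, chi angles extended at 180°, branches at ±120°,
planar rings); (iii) bad contacts are relieved by steepest descent on a
purely repulsive harmonic clash potential

$$E = \sum_{r_{ij} < r_0} k\,(r_0 - r_{ij})^2, \qquad
  r_0 = s\,(r^{vdW}_i + r^{vdW}_j),$$

with scale $s = 0.8$, $k = 1$, base step 0.01 Å, gradient tolerance
10⁻⁴ and at most 5000 iterations; step halving guarantees a monotone
non-increasing energy. Only the grafted atoms move, so the backbone RMSD
between input and output is exactly zero. vdW radii: C 1.70, N 1.55,
O 1.52, S 1.80, default 1.70 Å; pairs within one residue and 1-2/1-3
backbone-bonded pairs are excluded from the clash term.

The harmonic clash potential is a deliberate simplification relative to a
molecular-mechanics force field: the goal of this stage is only to remove
steric overlap introduced by grafting, not to produce a physically
minimised conformation. Because the extended rotamer can jam against
neighbouring side chains in ways a repulsive-only potential cannot escape,
grafting tries chi1 in the deterministic order 180°, −60°, +60° and keeps
the least-clashing start before minimising.

Residual clashes are counted over pairs involving grafted atoms: the
contract of the stage is that the *added* atoms introduce no bad contacts.
A reverted mutation-only structure re-classifies as group I; structures
with interior gaps keep their gaps (loop modelling is out of scope), so
reversion alone cannot promote a gapped entry to group I.

# Structural properties

`propertyVector()` assembles 29 features per protein:

* **SASA** by a deterministic probe-sphere point lattice: each heavy atom
  carries a fixed golden-spiral lattice of 960 points on its sphere of
  radius $r^{vdW} + 1.4$ Å; a point is accessible iff it lies inside no
  other expanded sphere. This is a seed-free numerical stand-in for the
  classical solvent-accessible-surface construction; an isolated atom
  recovers $4\pi r^2$ to well under 2 %, and doubling the lattice moves
  fixture totals by < 1 %. A residue is **surface** iff its summed SASA
  exceeds 3 Å² (strict), else **buried**.
* **Secondary structure** from backbone hydrogen bonds with the
  Kabsch–Sander electrostatic energy
  $E = 27.888\,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})$ kcal/mol
  (bond iff $E < -0.5$; amide H reconstructed along the bisector of
  C(i−1)→N and CA→N when absent). A residue is labelled H when it lies
  strictly between donor and acceptor of at least two distinct i→i+4
  bonds; G and I analogously for i+3 and i+5. Bridges follow the
  parallel/antiparallel patterns (ladders → E, isolated → B); remaining
  turn residues → T; a CA-trace kink above 70° → S; else "-". On a
  12-residue ideal helix (φ = −57°, ψ = −47°) this labels residues 3–10 H.
  Chains are assessed jointly, so inter-chain sheets are detected.
* **Contacts**: heavy-atom pairs within 4.5 Å between residues at sequence
  separation ≥ 3 (cross-chain pairs always qualify). **Disulfides**:
  CYS SG–SG pairs within 5.0 Å, greedily paired so each SG counts once.
* **Residue depth**: mean over a residue's heavy atoms of the minimum
  distance to any accessible surface sample point — accessible-surface
  samples, not a solvent-excluded surface, so monotonicity (core deeper
  than periphery, isometry invariance) rather than absolute agreement with
  other tools is the contract.
* **Ovality** $= \mathrm{SASA}/N_{res}^{2/3}$, and residue-class
  percentages (nonpolar A V L I M F W P G; polar S T N Q Y C; positive
  K R H; negative D E) over all, surface and buried residues.

The named feature list is fixed by `propertyFeatureNames()`. Three of the
29 (`pct_bridge_B`, `n_res`, `mean_residue_sasa`) round out the canonical
set alongside the classical descriptors. Class percentages over an empty
subset (e.g. no buried residues in a small peptide) are NA and are
mean-imputed by the comparison stage, which flags imputed cells.

# Comparative proteome clustering

Feature matrices (rows = proteins tagged by organism) are column z-scored
(sample sd; constant columns dropped with a warning), analysed by PCA on
the scaled matrix (covariance of z-scores ≡ correlation PCA; component
signs fixed so the dominant loading is positive), and clustered by K-means
with k-means++ initialisation from a stated seed, 50 restarts, Lloyd
iterations (≤ 300) and lowest-WCSS selection — deterministic given the
seed. The number of clusters is chosen by a codified elbow rule on
$\mathrm{explained}(k) = 1 - \mathrm{WCSS}(k)/\mathrm{WCSS}(1)$: the
smallest k with explained ≥ 0.75 and marginal gain < 0.05. The two
conditions cannot both hold at k = 1, so structureless data fall back to
the smallest k whose marginal gain is below 0.05 (k = 1 for a single
blob), and failing both the largest candidate k is returned. Both
thresholds are arguments.

# Complex stoichiometry and abundances

GPR rules (`and`/`or`, case-insensitive, genes `[A-Za-z0-9_.-]+`, no
negation — it does not occur in GEMs) parse to an AST and expand to
disjunctive normal form: each conjunction is a candidate enzyme complex,
with a gene's multiplicity within the conjunction as its default copy
number; a curated table overrides copy numbers by subunit set. Complex
identity is the multiset of (gene, copies), and the model-wide census
deduplicates on it, which is what makes "genes in ≥ 2 complexes" a
well-defined count. Isozyme fractions use reactions with a non-empty GPR
as denominator; gene fractions use all model genes.

The protein stoichiometric matrix **P** (proteins × enzymes, copy-number
entries) links measured peptide abundances *p* to enzyme abundances *e*
and free peptide *f* through the accounting identity
$P e + f = p,\; e, f \ge 0$. `fitAbundances()` minimises unweighted
$\sum f$ (molecular-weight weights are an option); the optimum is always
feasible ($e = 0, f = p$) and the optimal total is unique even when
individual abundances are degenerate. `fvaEnzymes()` reports per-enzyme
min/max at the free-peptide optimum held within a relative 10⁻⁶ plus
absolute 10⁻⁹ slack — strict equality is numerically brittle in LP
solvers, and degenerate alternate optima are reported as ranges rather
than an arbitrary vertex. All linear programs (including flux balance
analysis) are solved with the two-phase tableau simplex in the `boot`
package after a small presolve (fixed-variable elimination, removal of
vacuous rows, and fixing of variables forced to zero by same-sign
zero-rhs balance rows), which the problems here — tens of variables —
are comfortably within.

# Temperature-constrained growth

The stability model is a binary step: a gene is functional iff
$T \le T_M$, with the boundary $T = T_M$ functional. A reaction is
disabled (bounds zeroed) iff its GPR evaluates false under the functional
set; reactions without a GPR are never disabled. Genes without a $T_M$
default to functional — coverage of melting data is always partial, and
disabling unknowns would zero every prediction; `strict = TRUE` flips the
default. Because raising the temperature only shrinks the functional set,
constraint sets are nested and the growth curve is monotone
non-increasing; `growthCurve()` asserts this. A continuous
capacity-scaling variant (enzyme capacity proportional to folded fraction)
would require an unfolding model and is intentionally not implemented;
binary gating is the documented choice.

# Ligand diversity

Ligand graphs (atoms with element, formal charge, chirality flag; bonds
with order 1/2/3/aromatic) are deduplicated by a Morgan-style canonical
key: atom invariants start from element, charge, chirality, degree and
valence and are refined by sorted neighbour invariants for a fixed number
of rounds equal to the atom count (a label-invariant stopping rule); the
key is the sorted multiset of final signatures plus the bond-class
multiset, with per-component keys joined by "." for disconnected graphs.
The key is a fast heuristic, not a complete isomorphism certificate:
highly symmetric counterexamples can collide, but relabelled copies of a
graph always map to equal keys, and on all test graphs key equality
coincides with brute-force isomorphism.

Fingerprints enumerate all simple paths of 0–7 bonds from every atom and
hash each element/bond-order string into 1024 bits with a fixed
polynomial hash; similarity is the Tanimoto coefficient
$|A \cap B| / |A \cup B|$ (two empty sets: 1; one empty: 0). Per-protein
diversity reports the distinct-ligand count (canonical-key dedup), the
maximum pairwise distance $1 - \min \mathrm{Tanimoto}$, and a flag for
proteins binding more than six distinct ligands. The shipped non-metabolic
exclusion list (waters, glycerol, PEGs, detergents, buffers, precipitant
ions) is a reconstruction of common crystallisation additives; metal
cofactors are kept by default and removable by flag. Superclass
assignment (lipids, sugars, ...) is supported through a user-supplied
code→class table rather than a shipped taxonomy.

# Synthetic fixtures: what they do and do not show

All fixtures are built by `make*` generators from ideal internal
coordinates (N–CA 1.458, CA–C 1.525, C–N 1.329 Å — one table shared with
the grafting code) and fixed seeds; identical calls are byte-identical and
every generator emits its planted ground truth.

* `makeHelixPdb` / `makeHairpinPdb`: ideal poly-Ala helix and an
  antiparallel two-strand sheet whose second strand is a flipped, offset
  copy of the first; the offset constants were fitted once against the
  hydrogen-bond energy and frozen.
* `makeMutantPdb` / `makeGappedPdb`: extended-conformation structures
  with planted point mutations and interior deletions, numbering
  preserved across gaps. Gap fixtures use a non-periodic sequence so a
  deletion cannot re-align as a terminal truncation.
* `makeToyModel`: viable linear pathways with sampled GPR patterns
  (single genes, homomers, heterocomplexes, isozymes) and ~30 % gene
  reuse; the truth is recorded at construction, independent of the
  parser.
* `makeClusterBlobs`: unit-variance Gaussian blobs whose centres sit a
  stated separation apart along random orthonormal directions, spreading
  the signal across all 29 features so column scaling preserves it. Blob
  sizes of 50 (structured cases) and 200 (the structureless case) keep
  the elbow statistics in their asymptotic regime at desk scale.
* `makeAbundanceSet` / `makeTmTable` / `makeLigandSet`: seeded abundance,
  melting-temperature and ligand-set tables with planted truths.

Fixtures establish internal correctness — exact recovery of planted
truths, invariances, boundary behaviour — not field realism: real crystal
structures have alternate conformations, heteroatoms, non-ideal geometry
and disordered regions; real proteomes have correlated features rather
than isotropic blobs; real abundance data carry structured,
non-half-normal noise. Passing this suite therefore validates the
machinery, while headline statistics of any real organism (coverage
percentages, cluster sizes, homomer fractions) depend on the full
structural corpus and curated databases and are outside what desk-scale
fixtures can reproduce.

# Numerical choices and limitations

* Problem sizes throughout (tens of residues, 10–20 reactions, 20 × 10
  stoichiometric systems, 200-row feature matrices) were chosen as the
  smallest sizes at which each statistic is stable; all are package
  defaults, overridable by argument.
* The simplex solver is exact on these sizes but not intended for
  genome-scale LPs with thousands of reactions; swapping in a sparse LP
  backend would be a contained change inside one internal function.
* The SASA lattice is orientation-dependent at the sub-percent level;
  tests allow 1–1.5 % drift under rigid rotation at 960 points.
* Ties in nearest-centroid assignment resolve to the lowest centroid
  index (the behaviour of Lloyd's algorithm as implemented in
  `stats::kmeans`).
* `parse_pdb` keeps the first alternate location, ignores hydrogens for
  SASA/contacts/depth, and treats entries without resolution or method
  records as NMR.
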