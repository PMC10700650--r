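---
title: "Conservation-guided stabilization design: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conservation-guided stabilization design: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(stabdesign)
```

`stabdesign` turns a well-established enzyme-stabilization recipe into a
small, fully deterministic toolchain: conservation-guided candidate
nomination, ddG screening, geometric exclusion rules, combinatorial
rotamer-packing design, and RMSD/energy selection. This vignette is the
package's own account of the models behind each stage, the tunable
parameters and their defaults, the design choices made where the recipe
leaves choices open, and what the validation suite does and does not
establish.

## The candidate pool: PSSM with Laplace smoothing

The conservation scan models each alignment column independently. For
column `c` (kept only when the reference sequence is ungapped there) and
amino acid `a`, the score in bits is

$$ S(c,a) \;=\; \log_2 \frac{(n_{ca} + k) / (N_c + 20k)}{b_a}, $$

with `n_ca` the (optionally weighted) count of `a` in the column, `N_c` the
ungapped non-X count, `k` the additive pseudocount (default 1), and `b_a` the
background frequency. Candidates are all (position, substitution) pairs with
`S > 0` and a substitution differing from the wild type.

Two deliberate simplifications:

* **Uniform background (1/20) by default.** This makes the zero-score case
  exact — a column whose empirical frequencies equal the background scores
  exactly 0 in every cell — which in turn makes the scan testable to machine
  precision. A 20-vector can be supplied to mimic database-derived
  backgrounds.
* **No sequence weighting by default.** PSI-BLAST-style PSSMs down-weight
  redundant sequences; this implementation exposes a per-sequence weight
  vector as a hook but applies none by default. On alignments with heavily
  duplicated clades the positive pool will therefore over-represent those
  clades' preferences.

The positive pool is counted both as (position, substitution) pairs and as
distinct positions, since the two conventions are easy to conflate when
comparing pool sizes across tools; the pipeline manifest reports both.

## The surrogate energy

Every stage that needs an energy (the ddG scan, packing, relaxation, final
ranking) shares one surrogate function:

$$ E = w_{cl} \sum_{\text{pairs}} \max(0,\; r_i + r_j - d_{ij})^2
  \;-\; w_{ct}\,\#\{\text{hydrophobic center pairs} \le R_{ct}\}
  \;-\; w_{hb}\,\#\{\text{H-bonds}\}
  \;+\; \sum_r E_{ref}(aa_r)
  \;-\; w_{p} \sum_r S(r, aa_r). $$

Defaults: `w_cl = 10`, `w_ct = 0.5`, `R_ct = 8` Å, `w_hb = 1`, `w_p = 1`,
reference energies all zero; van der Waals radii C 1.70, N 1.55, O 1.52,
S 1.80 Å. Units are "kcal/mol-like" surrogate units: the protocol only needs
a ranking-competent energy, and each term is simple enough to be verified in
isolation by the test suite (a 1.4 Å overlap between two carbons contributes
exactly `10 * 1.4^2`; one hydrophobic contact pair contributes exactly
`-0.5`; and so on). No parity with any all-atom force field is claimed — which
is also why the package accepts an external per-mutation ddG table as a
drop-in replacement for its own scorer, and why the stabilizing cutoff
(strictly below −0.5, applied to whichever method produced the record) warns
when surrogate and external records are mixed in one run.

Covalent geometry is excluded from the steric term by a residue-adjacency
rule: intra-residue pairs always, and backbone/Cβ pairs of
sequence-adjacent residues. Ligand (HETATM) atoms take part in the steric
term and in distance tests only — they have no assigned chemistry, so they
neither donate hydrogen bonds nor count as hydrophobic contacts. This is a deliberate
resolution of a genuinely open modelling question (how much a bound ligand
should participate in a design energy): clashes with the ligand are always
penalized, but no attraction to it is modelled.

## Reduced side-chain representation

Designed positions are not rebuilt atom by atom. A designed side chain is a
single interaction center placed at a rotamer-specific offset in the local
Cβ frame (origin at Cβ — the actual Cβ when present, an ideally placed one
otherwise; first axis along CA→Cβ). The shipped library
(`inst/extdata/rotamers.tsv`) provides 1–3 centers per amino acid with
uniform priors, with offsets growing with side-chain size; it is a plain TSV
and fully replaceable.

The trade-off is explicit: packing decisions (bulky vs small, buried vs
exposed, clash vs contact) are preserved, while atomic detail — real
chi-angle rotamers, side-chain H-bond formation by designed residues — is
not. Two consequences worth knowing:

* The wild-type side chains of *undesigned* residues keep their full atoms,
  so the unsatisfied-H-bond rule is evaluated on the input structure only
  (mutant side chains are never rebuilt for that rule).
* A designed glycine carries a phantom center at the ideal Cβ position;
  this slightly overstates glycine's bulk but keeps every position's state
  space uniform.

In output PDB models the centers are written as CB-named pseudo-atoms.

## ddG: matched local repacks

`surrogate_ddg()` mirrors the local-optimization spirit of single-mutation
ddG scanners: the mutated position plus every residue with a heavy atom
within the contact radius is repacked twice — once with the substitution
forced, once with the wild type — under identical seeds, and the ddG is the
difference of the two best energies. A self-substitution is exactly 0 by
construction, the quantity is invariant under rigid motion of the input, and
on enumerable toys it equals the exhaustive-enumeration difference (all three
properties are tests). Scoring is single-conformer; averaging over an
ensemble of relaxed conformers would be a straightforward extension hook but
is not implemented.

## Structural exclusion rules

Exclusion criteria of this kind are traditionally applied by visual
inspection in a molecular viewer. Committing them to deterministic geometry
requires thresholds that inspection never makes explicit, so every threshold
below is configuration-exposed; the 5 Å active-site radius is the one
conventional, widely quoted value:

| rule | test | default |
|---|---|---|
| active site | min heavy-atom distance to any catalytic residue ≤ radius | 5.0 Å |
| unsatisfied H-bond | wild-type side chain donates/accepts, mutant chemistry cannot fill that role | — |
| exposed hydrophobic | mutant ∈ {A,V,L,I,M,F,W,C} and relative SASA > threshold | 0.25 |
| loop flexibility | loop position gaining G or losing P | — |
| proline in helix | mutant P at an 'H' position | — |
| cavity creation | relative SASA < burial threshold and side-chain volume loss > threshold | 0.10 / 40 Å³ |

Decisions embedded here:

* The 5 Å exclusion is measured from **any** heavy atom of the mutated
  residue — the more conservative reading of "within a radius of the active
  residues". The catalytic list is a **required** configuration field (for
  the stevia glycosyltransferase, for example, His25 and Asp124) precisely
  so the rule can never silently run empty: catalytic annotations are
  inconsistent often enough that the responsibility for naming them must sit
  with the user, visibly, in the run configuration.
* "Cavity creation" is proxied by buried large-to-small volume loss
  (standard residue volumes; L→A loses 78.1 Å³) rather than explicit void
  detection, which would drag in a cavity-finding dependency without making
  the rule more testable.
* Relative SASA normalizes by theoretical Gly-X-Gly maxima and clips to
  [0, 1.2]; a fully isolated residue legitimately exceeds 1.0 because it
  lacks even its tripeptide context, hence the clip rather than an error.

SASA itself is Shrake–Rupley on a deterministic Fibonacci sphere lattice
(default 960 points, probe 1.4 Å). The estimated quantity is each atom's
exposed *fraction*; at 960 points that fraction is reproducible against a
10,000-point dense sampling to within 3 % (validated on random clusters).
Because the lattice is fixed in space, SASA is exactly invariant under
translation but only sampling-invariant under rotation — the suite asserts
both, at their respective tolerances.

Secondary structure uses a dihedral rule (helix: φ ∈ [−100, −30], ψ ∈
[−80, −5], runs ≥ 4; strand: φ ∈ [−170, −70], ψ ∈ [90, 180], runs ≥ 3;
else loop), which is deliberately coarser than DSSP but exact on the ideal
helices the fixtures generate and free of external binaries. Hydrogen bonds
are donor/acceptor heavy-atom pairs from a per-residue chemistry table at
≤ 3.5 Å with an antecedent–donor–acceptor angle ≥ 120°; hydrogens are never
placed.

## Design loop

Packing is simulated annealing over discrete (amino acid, rotamer) states.
Because designed side chains are single centers on a fixed backbone, the
surrogate energy decomposes **exactly** into a constant plus one-body plus
two-body terms; the annealer (`anneal_states()`) therefore optimizes on
precomputed tables, and the identity `E(assembled model) = fixed + Σ
one-body + Σ two-body` is itself a test. Defaults: 2000 Metropolis steps per
run, geometric cooling kT 5 → 0.3, greedy one-body initialization, ties
broken toward the lexicographically smallest (position, amino acid, rotamer)
assignment so that equal-energy runs are reproducible. On enumerable
instances (≤ 3 positions × ≤ 5 states) the annealer attains the exhaustive
optimum on 100/100 seeded instances.

Relaxation then perturbs the interaction centers (≤ 0.3 Å per move) plus a
smaller backbone jitter (one fifth of the step size), accepting by
Metropolis under a second cooling schedule and returning the best model
visited — so relaxation can never raise the reported energy. One
pack-then-relax cycle is the default; the cycle count is configurable, since
how often packing and relaxation should alternate has no canonical answer.

`generate_variants()` draws a designable subset of m positions from the
filtered pool, m uniform in [⌈0.02 L⌉, ⌊0.20 L⌋] for a design region of L
residues. The fraction window is interpreted against the truncated design
region and enforced as a sampling bound — two choices a different
implementation could reasonably make otherwise, so both are stated here.
The wild type stays allowed at every sampled position, so the realized
mutation count can fall below m; variants outside the window are rejected
and redrawn within a bounded attempt budget.

**Energy comparability.** A variant lives in the reduced representation at
its designed positions, so comparing its energy against the full-atom wild
type would conflate representation with substitution. The wild-type
reference is therefore computed on the *same* reduced representation: an
identity repack and relax over the same positions with the same seeds,
exactly mirroring the ddG construction. A variant is kept only if its energy
is strictly below that matched reference, and selection ranks by this energy
gap. When all variants share one reference (or a scalar wild-type energy is
supplied), the ranking coincides with a plain ascending-energy sort.

## Selection

Cα RMSD uses closed-form Kabsch superposition (proper rotation enforced by
sign-correcting the smallest singular direction; collinear inputs rejected)
over residues matched by chain, author number and insertion code. The RMSD
screening cutoff defaults to 1.0 Å — there is no single standard threshold
for "structurally similar to the wild type", so the cutoff is
configuration-exposed and echoed in every report; it is implemented as a
hard gate rather than a soft ranking. The
report includes the mutation-overlap table (how many selected variants share
each mutation, flagged when more than 5 do).

## Synthetic fixtures and what validation shows

`write_demo_inputs()` wires the generators into a runnable input set: an
ideal α-helix (NeRF-built backbone at φ −57°, ψ −47°, 3.6 residues/turn,
Cα–Cα 3.8 Å) over a hydrophilic-leaning random sequence, and a toy
alignment whose reference row is the helix sequence with planted conserved
substitutions (frequency 0.9) at interior positions. Catalytic residues
default to two interior positions of the truncated region. The validation
scale — 60 residues, 50 homologs, 12 planted signals, 10 variants — was
chosen as the smallest problem on which every stage has non-trivial work to
do: the scan must separate planted signal from sampling noise, the battery
prunes on every rule, and the design loop has a pool wide enough for 2–20 %
subsets.

Choices fixed inside the generators: toy-alignment background columns are
uniform over the 20 amino acids (matching the PSSM's default background, so
expected scores are computable in closed form), and at a planted column with
frequency < 1 the reference row is forced to differ from the planted amino
acid so that the planted substitution is a well-defined recovery target; at
frequency 1 the column is monomorphic, reference included.

What a passing suite establishes: the geometric and statistical primitives
are correct against independent oracles (analytic spheres, dense sampling,
exhaustive enumeration, numerical minimization, hand-applied rules), the
protocol's contracts hold end to end (monotone pool counts, per-variant
bounds, strict energy improvement, RMSD gate, bit-identical reruns under one
seed), and planted conservation signal is recovered in full. What it does
**not** establish: fidelity on real proteins. Toy helices have no tertiary
packing, no buried cores (burial must be constructed artificially to
exercise the cavity rule), uniform-background alignments are far more
permissive than real homolog families, and the surrogate energy is not a
force field. On real inputs the pipeline's value is the ranking and the
audit trail, not the absolute numbers.

## Known limitations

* Single-chain design; multi-chain structures are read but only one chain is
  designed per run.
* Single-conformer ddG; no ensemble averaging.
* The reduced representation cannot model designed side-chain hydrogen
  bonds or chi-angle-specific packing.
* Secondary structure is a dihedral heuristic, not DSSP.
* No explicit cavity detection; volume loss at buried positions is the
  proxy.
* mmCIF, multi-model ensembles and ligand chemistry beyond steric
  pass-through are out of scope.
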