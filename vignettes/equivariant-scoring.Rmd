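---
title: "Equivariant scoring, attribution and hotspot mapping: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equivariant scoring, attribution and hotspot mapping: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(eqscore)
library(dplyr)
```

## The model

`eqscore` scores a protein--ligand complex with an E(n)-equivariant graph
neural network. The input is a point cloud of typed atoms: the ligand plus
the binding pocket, defined as every protein atom within 6 Å of any ligand
atom. Each atom becomes a node with a 12-wide binary feature row — one bit
over an 11-element vocabulary (C, N, O, S, P, F, Cl, Br, I, B, other) plus
one bit flagging ligand versus receptor. Edges connect atoms within a
distance cutoff that depends on the pair class: 10 Å for ligand--protein
pairs, 2 Å for ligand--ligand and protein--protein pairs, so that
intramolecular connectivity closely tracks covalent structure while
intermolecular edges capture the wider interaction neighborhood. Edges carry
a 3-wide one-hot over {LL, LP, PP} and are stored in both directions.

A linear layer projects the 12 features to a hidden width of 32, followed by
a stack of equivariant message-passing layers. Per directed edge $(i, j)$
the message network reads $(f_i, f_j, \lVert x_i - x_j \rVert^2, e_a)$ and
produces an edge embedding $m_{ij}$; a shallow attention network (one hidden
layer, sigmoid output) maps $m_{ij}$ to a weight $e_{ij} \in [0, 1]$, and
each node aggregates

$$ m_i = \sum_{j \in N(i)} e_{ij}\, m_{ij}. $$

Node features update through a residual (skip) connection,
$f_i' = f_i + \phi_h(f_i, m_i)$. Positions update equivariantly along
relative-position directions, $x_i' = x_i + \sum_j (x_i - x_j)\,
e_{ij}\, s_{ij}$ with a scalar weight $s_{ij}$ computed from $m_{ij}$ and a
smooth clamp on the displacement norm for stability. Because every
coordinate-dependent quantity enters only through squared distances, scalar
outputs are exactly invariant under rotations, translations, reflections and
atom relabeling; the test suite asserts this to far better than the 1e-4
contract in double precision. After the final layer, global average pooling
over node features feeds the task head: a sigmoid unit for pose
classification ($y \in [0,1]$) or, after head replacement for affinity
finetuning, a fully connected unit with ReLU activation ($y \ge 0$).

Weighting the coordinate update by $e_{ij}$ (not only the scalar $s_{ij}$)
is a deliberate choice: it makes "attention zero" exactly equivalent to
deleting the edge everywhere it acts, which is the formal link between
edge-attention attribution and bond masking, and the package asserts that
equivalence numerically rather than assuming it.

Two profiles exist: the full-scale architecture (48 layers, width 32) and
the desk-scale default used throughout the tests (4 layers, width 32).
Training, attribution and all statistics are profile-agnostic.

## Training

Training is two-stage. Stage one is pose classification (binder versus
decoy) under binary cross-entropy — learning the geometry of binding before
any affinity value is seen. Stage two replaces the sigmoid head with a
freshly initialized ReLU head and finetunes under squared error on
nonnegative affinity labels. Because the losses, optimizer and schedule are
implementation choices, we use standard ones and record them in
`train_config()`: Adam (step size 5e-3), minibatches of 32 graphs batched as
disjoint unions, a group-aware 80/20 validation split (all poses of one
system stay on one side, mirroring the leakage concern that motivates the
debiasing filters), and early stopping on validation loss with a patience of
25 epochs. The patience is deliberately long: on the synthetic task the
optimizer commonly sits on a majority-class plateau for 20--30 epochs before
finding the geometric solution. Gradients are computed by a hand-derived
reverse pass through every layer, including the coordinate updates, and are
verified against central finite differences in the test suite. All
randomness is seeded; training is bit-reproducible on one machine.

## Attribution

Three procedures assign importance to the input:

* **Atom masking** — score(i) = prediction(intact) − prediction(without
  atom *i*), where removal deletes the atom and its incident edges.
* **Bond masking** — the same difference for removal of one edge (both
  directions together). By convention only intermolecular edges shorter
  than 4 Å are scored, the range where hydrogen bonds and close contacts
  live.
* **Edge attention** — reads the final layer's $e_{ij}$ for
  ligand--protein edges directly; directed duplicates are averaged, and a
  protein atom's score is its best incident edge score. Whether attention
  should be read from one layer or averaged over layers is genuinely open;
  we read the final layer, whose weights act on the most processed
  representation, and expose everything needed to do otherwise.

The distance-rank diagnostic asks whether high scores fall on protein atoms
close to polar ligand atoms: for the top-k protein atoms it computes
Spearman's rank correlation between score and negated distance to the
nearest polar ligand atom (N/O or any atom with a hydrogen-bond role),
average ranks on ties. We rank protein atoms by their atom-level scores
rather than by raw edge lists because the top-ten *edges* frequently touch
fewer than three distinct protein atoms, which would leave the correlation
undefined; the "nearest polar ligand atom" convention is the default, with
the nearest-any-atom alternative behind a flag.

## Hotspot maps

Attribution on one structure scores one pocket. Over a fragment screen —
many bound structures of one rigid target — per-atom scores are averaged by
(chain, residue index, atom name) key, each atom over the structures in
which it was actually scored: pockets are ligand-dependent, and zero-filling
absent atoms would punish atoms merely for sitting at the pocket rim.
Ranked atoms become donor or acceptor hotspots according to their
hydrogen-bond role; atoms typed "both" resolve to the role with the higher
sub-score against complementary ligand partners, ties to donor. Per-structure
scores enter raw by default (a min--max normalization flag exists, since
nothing in the method fixes this).

The geometric baseline counts, per protein atom, the structures in which a
complementary-role polar ligand atom lies within 3.5 Å; atoms highlighted in
strictly more than five structures become baseline hotspots. This is a
declared simplification of full interaction-profiling rules — no angle
criteria — sufficient as a counting control.

The stability analysis subsamples the screen (40 repeats per size),
recomputes the top-5 set each time, and reports per-atom inclusion
frequencies and the mean Jaccard overlap with the full-data top-5. Larger
screens should produce more consistent maps.

Aggregation is attribution-method agnostic: any `attribution_result` with
per-atom scores can drive it. The shipped end-to-end tests drive it with
atom masking, whose causal score-drop is reliable at the 4-layer desk
profile and scores every protein atom in every structure, giving the
across-screen averaging full support; attention-driven maps are produced
identically and are the natural choice for deep full-scale models, where
masking becomes expensive.

## Debiasing filters

Two one-sided filters remove training items too similar to a test set:
ligands whose 2048-bit circular-fingerprint Tanimoto similarity to any test
ligand exceeds 0.8 (strict), and proteins whose global-alignment sequence
identity to any test protein exceeds 0.8 (strict). "Greater than 0.8" is
read as a strict inequality. The fingerprint is an ECFP-style circular
fingerprint authored in this package (radius 2, atom invariants of element,
degree, total bond order and charge, iterative neighborhood hashing folded
to 2048 bits). Sequence identity uses a global alignment with match 1,
mismatch 0 and affine gaps (opening 10, extension 0.5); identity is
matches over alignment length including gaps, with matches-over-shorter
-sequence behind a flag, and multi-chain entries take the maximum over chain
pairs. Because co-optimal alignments can differ in their match count, the
test oracle asserts exact agreement on the (unique) optimal score and on
the kept/removed decision, not on the identity's tenth decimal.
Size-matched random subsets (uniform, seeded) provide the control that
separates debiasing from mere data reduction.

## Fragment-elaboration statistics

Docked elaborations of a fragment are summarized by ligand efficiency
LE = docking score / heavy atoms. Within a (fragment, hotspot) pool — the
elaborations plus the ground-truth molecule the fragment was cut from — LEs
are standardized to zero mean and unit variance; we use the population
variance (the pool is the entire population of interest; a sample-variance
flag exists). ΔSLE₍α₎ is the mean of the top α = 20 standardized elaboration
LEs minus the ground truth's standardized LE. Zero-variance pools yield
ΔSLE = 0 with a warning rather than an error so that batch reports complete.
Per hotspot, the report averages ΔSLE over fragments with at least one
elaboration and counts successes; hotspots nobody could elaborate toward
appear with n = 0 and a missing mean. Fragment enumeration cuts every
acyclic single bond outside protected functional groups (amide, ester,
sulfonamide, nitro — the protected set is configurable since no canonical
list exists), emitting both sides of each cut with a dummy atom marking the
exit vector. The quasi-active distance conventions (2 Å for pocket-grid
hotspots, 3 Å for protein-atom hotspots) are recorded as metadata columns;
the docking and generative steps that apply them are external tools.

## The synthetic data generator

Real training corpora (hundreds of thousands of redocked poses) are far
beyond a desk-scale test, so every pipeline stage is exercised on synthetic
complexes with planted ground truth. A ligand is a compact cluster — an
apolar carbon core inside a 0.5 Å ball plus one polar atom per planted
contact at 2.5 Å from the center — and the pocket is a surrounding carbon
shell at 5.05--5.45 Å. Planted contacts are complementary donor--acceptor
pairs at 2.9 ± 0.1 Å (a typical hydrogen bond); every non-planted
ligand--protein pair is kept at least 4.5 Å apart, and contact sites sit on
icosahedral directions so these constraints can hold simultaneously. An
exhaustive distance audit validates each generated complex. Defaults: 8
ligand atoms, 16 pocket atoms, 3 planted contacts, decoy displacement 3 Å,
binder label for ≥ 2 intact contacts, affinity noise σ = 0.1.

Pose datasets pair each binder with a rigid-body decoy; the label re-applies
the planted-contact rule to the emitted coordinates, so labels are always
recomputable. The pocket is extracted once from the reference pose and
shared by both poses of a system — as with a fixed set of binding-site
residues — so binder and decoy present identical atom sets and only
geometry separates the classes. (An earlier design re-extracted the decoy's
pocket after the perturbation; the resulting atom-count difference was a
shortcut signal that let the classifier succeed without reading geometry —
a small-scale reenactment of the dataset-bias problem the debiasing filters
exist for.) Affinity datasets vary the planted contact count from 0 to 3
and set the label to count plus noise, floored at zero. Fragment screens fix
one protein (identical shell and contact-site atoms across structures, so
cross-structure keys match) and bind a different ligand per structure, with
one dominant site contacted everywhere and others at 35% probability.

What the generator does *not* emulate: conformational flexibility, solvent,
protonation states, realistic docking-score physics, or chemically valid
ligands. Passing the desk-scale suite therefore shows that the machinery —
representation, equivariance, optimization, attribution arithmetic,
aggregation and statistics — behaves correctly on data whose answer is
known; it does not certify performance on crystallographic data.

## Numerical choices and degenerate inputs

* Squared edge lengths are scaled by 0.1 before entering the message
  network (they reach 100 Å² at the LP cutoff; the scale keeps the inputs
  in tanh's responsive range).
* Position displacements are soft-clamped to at most 2 Å per layer via
  $\gamma / (\gamma + \lVert \Delta \rVert)$, which is smooth and
  direction-preserving.
* Distance boundaries are closed (a pair exactly at a cutoff forms an
  edge; a protein atom exactly at the pocket radius is kept).
* Ties break deterministically by atom id or key everywhere a ranking is
  produced.
* Parameter initialization, data generation, splitting, shuffling and
  subsampling all derive from explicit seeds; seeded RNG streams are warmed
  up before use because Mersenne-Twister states seeded from consecutive
  integers are poorly mixed in their first draws.
* Graphs with no edges, pools with zero variance, hotspots with no
  elaborated fragments, and screens with no eligible edges all degrade to
  documented results (empty aggregates, zeros with warnings, n = 0 rows)
  rather than errors, except where an error is the contract (empty ligand,
  empty pocket, single-class labels).

## Problem sizes in the test suite

The shipped tests train the 4-layer desk profile on 200-example pose sets
and 200-example affinity sets, run the attribution-recovery contrast over
five seeds of 100-example models, aggregate hotspots over a 90-structure
synthetic screen with the 10/30/80 stability ladder at 40 repeats, and run
the ΔSLE recovery (20 seeds) and null (100 seeds) simulations. These sizes
were chosen so the full suite demonstrates every claim end-to-end on a
single CPU core in well under half an hour.

## Known limitations

* The attention-localization results are desk-scale analogues: with 4
  layers and small pockets, attention sometimes concentrates on a subset
  of the planted contacts rather than all of them.
* The geometric hotspot baseline has no angular terms, so it is more
  permissive than full interaction profilers.
* The sequence-identity filter reports the identity of one optimal
  alignment; co-optimal alignments could differ slightly (the kept/removed
  decision at 0.8 is insensitive to this in practice).
* No GPU path exists; the 48-layer profile is functional but slow in pure
  R, and is exercised only at reduced depth in the tests.
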