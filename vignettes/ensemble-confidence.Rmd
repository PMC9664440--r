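---
title: "Alignment ensembles and confidence metrics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment ensembles and confidence metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msaensemble)
```

# The problem

A multiple sequence alignment (MSA) asserts, column by column, which residues
of a set of protein or nucleotide sequences are homologous.  Every downstream
inference — conserved motifs, secondary structure, and above all phylogeny —
inherits the errors of that alignment.  Standard practice builds one MSA with
one program and one parameter set and treats it as correct, although current
aligners get a substantial fraction of columns wrong on structure-based
benchmarks, and progressive alignment is known to bias an estimated phylogeny
towards its own guide tree.

`msaensemble` takes the ensemble view: instead of one alignment it constructs
a collection of *replicates*, all of comparable expected accuracy but with
deliberately diversified biases, and measures the confidence of any inference
as the fraction of replicates that supports it.  If all replicates agree, the
inference is robust to the arbitrary choices hidden in the aligner; if they
disagree, the disagreement itself is the signal, because two different
alignments of the same sequences cannot both be correct.

# The alignment model

## Pair hidden Markov model

Each replicate is built from posterior probabilities of residue pairing
computed under a pair hidden Markov model with *double-affine* gaps: besides
the match state M there are two tiers of insert states, short-gap states
I~x~/I~y~ and long-gap states J~x~/J~y~, giving a two-regime gap length
distribution (frequent short gaps, rarer long gaps with slower decay).
Symmetry between the two sequences and between a sequence and its reversal
is enforced, which reduces the model to five independent sets of mutually
exclusive probabilities:

1. transitions from the start state S,
2. transitions out of M,
3. transitions out of the I states,
4. transitions out of the J states,
5. the joint letter-pair emission distribution of M.

Each set sums to one; each set also contains an explicit end-state
probability, so the total probability of a sequence pair is properly
normalised over alignments of all lengths (for two empty sequences it reduces
to the direct start-to-end probability).  Insert states emit single letters
according to the *marginals* of the joint emission matrix, so the
marginalisation identity `insert(a) = sum_b joint(a, b)` holds exactly, and
is maintained exactly under perturbation.

Amino-acid emissions are the joint-probability form of BLOSUM62.  Because
only the rounded half-bit log-odds scores `s_ij` of BLOSUM62 are distributed
with R (in `Biostrings`), the joint form is reconstructed at load time from
the defining relation `q_ij = c · p_i p_j · 2^(s_ij/2)` together with the
self-consistency requirement that the background frequencies `p` be the
marginals of `q`.  Writing `M_ij = 2^(s_ij/2)`, that requirement is the
linear condition `M p ∝ 1`, solved directly and normalised.  The recovered
backgrounds match the published BLOSUM62 values to the precision the rounded
scores permit (e.g. `p_A ≈ 0.082`, `p_W ≈ 0.012`).  Nucleotide emissions are
a simple uniform-marginal match/mismatch matrix (60% of the probability mass
on identities); this is flagged experimental, since no trained nucleotide
parameterisation is reproduced here.

Transition probabilities are deliberately plain round numbers (short-gap
open 0.02 and extend 0.80; long-gap open 0.01 and extend 0.90; end
probability 0.01 per set; start transitions 0.85/0.04/0.02/0.03 for
M/I/J/end).  They are not trained: the premise of the ensemble approach is
that alignment quality is insensitive to small changes in these values, and
any nearby round numbers are equally admissible.  All constants live in one
place (`R/params.R`) and parameter sets can be serialised to a plain-text
`key=value` file for inspection.

## Perturbation rule

Replicate diversity on the model side comes from perturbing every
probability by the rule P → (1 + αδ)P, with amplitude α (default 0.25, i.e.
changes up to ±25%) and δ drawn independently per probability, uniformly on
[−1, 1].  After all probabilities are perturbed, each mutually exclusive set
is renormalised to sum to one.  Seed `s = 0` is reserved: it means *no*
perturbation, bit-exactly.

Determinism matters here, because a replicate's identity is its label
`perm.s`: the generator is R's Mersenne-Twister run in an isolated,
state-restoring scope, and the draw order over probabilities is fixed
(start, match, short-gap, long-gap transitions, then the emission upper
triangle — including the diagonal — in column-major order).  The emission
matrix is perturbed on its upper triangle only and mirrored, so its symmetry
survives; insert marginals are recomputed from the perturbed joint.
Amplitudes ≥ 1 are rejected, since a draw of δ = −1 would then produce a
non-positive probability.

## Posterior decoding, consistency, progressive alignment

For every sequence pair, forward–backward over the five emitting states
(in log space, implemented in C++) yields the posterior probability
P(x~i~ ∼ y~j~) that residue i of x pairs with residue j of y.  Posteriors
below a sparsity cutoff (0.01, the convention of the ProbCons lineage) are
dropped; the cutoff is re-applied after each consistency round.

The consistency transformation re-estimates each pairwise posterior matrix
through third sequences, P~xy~ ← (1/K) Σ~z~ P~xz~ P~zy~, including z = x and
z = y via identity self-posteriors (the standard formulation; an
exclude-self variant would only rescale the diagonal terms and is not
offered).  Two rounds are the default.  No renormalisation beyond the matrix
product is applied.  Since all row sums of the factors are at most one, the
transformation preserves the substochastic row/column bound.

The final MSA is built by maximum expected accuracy (MEA) alignment: the
pairwise alignment maximising the summed posteriors of its matched pairs
(gaps score zero), extended to profiles by scoring a column pair as the sum
of posteriors over all inter-profile residue pairs, with no position
weighting.  Profiles are merged bottom-up along a guide tree built by greedy
agglomeration on the pairwise expected accuracies (UPGMA-style average
linkage on similarity, size-weighted).  Deterministic tie-breaks are fixed
everywhere: cluster ties lexicographically by member ids, dynamic-programming
traceback prefers match, then gap in x, then gap in y.  All-gap columns
produced by a merge are removed immediately.

Optional refinement by randomised partitioning draws a random row
bipartition (each row to either side with probability 1/2, redrawn if a side
is empty), re-aligns the two induced profiles, and accepts the result iff
the sum-of-pairs expected-accuracy objective does not decrease; the
objective is therefore monotone in the number of rounds.  `refine()`
defaults to 100 rounds.  Ensemble generation (`diversified_ensemble()`,
`stratified_ensemble()`) defaults to `refine_rounds = 0`: at the problem
sizes this package targets, progressive alignment on consistency-transformed
posteriors is already at or near the exhaustive optimum (the test suite
verifies this on small cases), and refinement is exposed as an explicit
knob rather than silently spent compute.

## Guide-tree permutations and ensembles

Diversity on the guide-tree side comes from permuting the joining order of
large subgroups near the root, where progressive alignment bias originates,
while preserving the joining order near the leaves, where accuracy is made.
The tree is split by finding the edge whose subtree holds as close to one
third of the leaves as achievable (subset *a*), then splitting the remaining
tree as evenly as possible into *b* and *c*.  Because guide trees here are
rooted, every edge subtends exactly one clade, so "over all edges" means
"over all proper subtrees"; the complement of a clade is not a candidate
since it is not a join-order-preserving subtree.  Ties go to the smaller
subtree, then lexicographically by contained leaf ids.  The four variants
`none`, `abc` ((a,b),c), `acb` ((a,c),b) and `bca` ((b,c),a) are the
permutation labels.

A *diversified* ensemble maximises variation: replicate i uses seed s = i
while the permutation cycles through the four variants, so replicate 0 is
the default alignment `none.0`, and n replicates use seeds 0..n−1 (the
count is taken literally; the alternative reading "seeds 0..N" giving N+1
replicates is ambiguous in prose, so the unambiguous convention is fixed
here).  A *stratified* ensemble holds some parameters fixed per stratum —
for example, two strata with permutations `abc` and `bca` over the same
seeds isolate guide-tree bias, since members `abc.k` and `bca.k` differ in
nothing but the guide tree.  The guide tree (and its split) is recomputed
for every seed, because perturbation changes the posteriors and hence the
expected accuracies the tree is built from.

A convergence heuristic is provided but opt-in: generation is fixed-N by
default, and `convergence_check()` reports n1 (column signatures seen in
exactly one replicate) versus n2 (seen in two or more), declaring the
diversity sampled when n2 > n1 or when the ensemble has reached the cap of
m replicates, m being the median column count.  The "two or more" reading
is deliberate: an ensemble of identical replicates must report n1 = 0,
n2 > 0, converged.

# Confidence metrics

## Alignment side: CC, AC, MAC

Two columns in different alignments of the same sequences are *the same
column* when every sequence contributes the same residue ordinal — or a gap
— to both.  This is made precise by the column signature: per sequence id
(sorted), the 1-based count of residues consumed up to that column, or 0
for a gap.  The default identity test includes the gap pattern (the
strictest reading); `ignore_gaps = TRUE` relaxes it to the non-gap cells
only, for sensitivity analysis, since either convention is defensible.

* **CC** (column confidence) of a reference replicate's column is the
  fraction of ensemble replicates containing an equal-signature column (the
  reference counts; a signature counts at most once per replicate).  Unlike
  conservation scores, a gappy or biochemically mixed column earns CC = 1 if
  it is consistently reproduced.
* **AC** (alignment confidence) is the mean CC over a replicate's columns;
  `max_ac_replicate()` returns the replicate most representative of the
  ensemble (ties to the first).
* **MAC** is the mean AC over the ensemble; MAC = 1 exactly when all
  replicates are column-identical, and lower MAC necessarily means a higher
  error rate in a typical replicate.

## Tree side: EC, EM, TC

Replicate trees (one per replicate MSA, estimated by any external phylogeny
program and read back as Newick) are compared with three metrics:

* **EC** (edge confidence): an internal edge is identified with its unrooted
  leaf bipartition, and EC is the fraction of replicate trees containing
  that bipartition.  Pendant edges are excluded as trivially shared.
  Unrooted bipartitions are the default currency (rooted-clade comparison
  would double-count the root placement, which is usually itself an
  inference).
* **EM** (ensemble monophyly): for a leaf category C, the best-fit subtree
  is the node minimising FP + FN (leaves under the node not in C, plus
  leaves of C not under it; ties to larger TP, then preorder position);
  monophyly is m = TP/(TP+FP+FN), equal to 1 iff C is a clade; EM is the
  mean m over the tree ensemble.  Unlabelled leaves under the node count as
  FP by default — they are not in C — with `ignore_unlabelled = TRUE` as the
  permissive alternative.
* **TC** (topology confidence): each tree is reduced to its *condensed
  tree* — category best-fit nodes become leaves, only edges on their root
  paths survive, and unary chains collapse with lengths summed and the
  larger support kept — and TC is the relative frequency of each distinct
  condensed branching order, canonicalised by sorting children on their
  smallest contained category name.

Outgroup rooting follows the same best-fit machinery: all non-outgroup
leaves form a second category, the best-fit side for the outgroup is found
over every edge of the unrooted tree (which handles polyphyletic outgroups),
and the root is placed at the midpoint of that edge.  The 50/50 length
split is a convention; nothing downstream depends on it beyond the two root
child edge lengths.

Condensation can fail honestly: if one category's best-fit node is an
ancestor of another's (heavily intermixed categories), the branching order
of those categories is not representable and `condensed_tree()` raises a
diagnostic rather than guessing; `topology_confidence(on_error = "drop")`
can exclude such trees explicitly.  Notably, under the larger-TP tie-break
two distinct categories can never share the same best-fit node, so the
ancestor case is the only reachable degeneracy.  Supports of collapsed
pendant edges cannot be expressed in Newick node-label convention and are
returned in the `"leaf_support"` attribute instead.

# The synthetic-data generator

`evolve_family()` exists to make every pipeline stage testable without
downloads: it evolves a root sequence down a tree, with per-site
substitution and indel probabilities `1 − exp(−rate · branch_length)`,
geometric indel lengths (insertions and deletions equiprobable), and full
column-homology bookkeeping through indels, so the *true* alignment is known
exactly and every leaf sequence degaps from it.  `make_labelled_tree()`
builds trees with perfectly monophyletic category clades and then plants a
controlled number of random leaf re-grafts, giving known monophyly
violations.  Both are deterministic per seed.

What these fixtures do *not* emulate: rate heterogeneity across sites,
indel hotspots, composition drift, domain shuffling — the features that make
real deep homology hard.  Passing tests on these fixtures demonstrates that
the code computes its definitions correctly and that the pipeline behaves
sensibly as divergence rises; it does not certify accuracy on real
sequences, which in the source tradition is established on structure-based
benchmarks, deliberately not by simulation.

# Numerical and design notes

* Forward–backward runs in log space with a five-state per-cell recursion
  and no banding; inputs are desk-scale (tens of sequences, hundreds of
  columns).  The exact double-affine recursion is reconstructed from the
  stated state topology; it disallows direct I↔J and x↔y insert chaining,
  so e.g. the all-gap "alignment" of two length-1 sequences has probability
  zero, as in the lineage this model follows.
* The end-to-end checks in the test suite use families of 8 sequences of
  length ≈ 60 with a 16-replicate diversified ensemble, and NJ trees (a
  deliberately minimal estimator, `nj_from_msa()`, offered for fixtures
  only) for the tree-side metrics; these sizes keep the whole suite around
  half a minute while exercising every stage.
* Low-divergence test families use substitution rate 0.03 and indel rate
  0.005 per site per unit length on unit branches (leaf identities ≈ 85%);
  high-divergence families use 0.45 and 0.06 (identities ≈ 35–45%), values
  chosen once as representative of easy and hard alignment regimes.
* Known limitations: no divide-and-conquer scaling (input sizes are bounded
  by the dense all-pairs posterior computation); no ensemble bootstrap
  (resampling columns from the ensemble rather than one MSA) — the ensemble
  container and `column_signatures()` are the extension point for it; no
  per-residue-pair confidence, only per-column.
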