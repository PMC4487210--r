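---
title: "Models and methods: distance networks, fossil placement, and root-conflict scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: distance networks, fossil placement, and root-conflict scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fossilgraft)
```

This vignette is the package's own account of the science it implements:
the models and procedures, their assumptions, the parameters that
matter, what the synthetic-data generators do and do not emulate, and
the numerical and design choices made where the methods leave room.

## The problem

Fossils of small, anatomically well-preserved clades — the motivating
case is royal-fern (Osmundaceae) rhizomes — can be scored for the same
categorical characters as living species, but they rarely fit neatly
into molecular phylogenies of the extant taxa. Two distinct questions
arise. First, *where does a fossil attach* on a backbone whose topology
is fixed by molecular data, and does the answer depend on how characters
are weighted? Second, *is the backbone's own root trustworthy*, given
that outgroup-inferred root placements can be driven by a minority of
gene partitions (and distorted by long outgroup branches)? The package
treats both questions as placement problems: a query taxon — fossil or
outgroup — is attached to every branch of a reference topology and the
per-branch support is examined, rather than forced into a single tree.

## Mean character distances and neighbour-nets

For a taxa-by-characters matrix with cell *state sets* (polymorphism
`{ab}`, missing `?`), the distance between two taxa is the proportion of
characters scored in both whose state sets are *disjoint*; overlapping
sets count as a match, and missing cells are dropped pairwise rather
than case-wise, which keeps sparsely scored fossil rows usable. The
matrix is a premetric (symmetric, zero diagonal, bounded by \[0,1\]);
the triangle inequality is *not* guaranteed under pairwise deletion, and
no method here assumes it. Pairs sharing no scored character are left
undefined and abort the network with an explicit error — imputation
would silently manufacture signal. The disjointness rule for polymorphic
cells is a convention (the usual one in splits-graph software); a
fractional-overlap alternative would shrink distances slightly but the
package deliberately implements the common rule.

The neighbour-net generalizes neighbor joining to conflicting signal: an
agglomerative pass (clusters holding one or two "active" nodes; the
rate-adjusted selection criterion picks first a cluster pair, then the
junction nodes; fused paths are reduced by the standard three-to-two
node formulas) yields a *circular ordering* of the taxa, and every split
whose side is an arc of that ordering gets a weight by non-negative
least squares against the observed distances:

$$\min_{w \ge 0} \sum_{i<j} \Big( d_{ij} - \sum_s w_s\,\delta_s(i,j) \Big)^2 .$$

There are $n(n-1)/2$ candidate splits, so the system is square; any
distance matrix that *is* a non-negative combination of splits of some
circular ordering is represented exactly (and additive tree metrics
recover the tree's splits and branch lengths). Agglomeration ties are
broken deterministically toward the lowest cluster-index pair, so runs
are reproducible across platforms; fitted weights below `1e-8` are
reported as zero — that threshold suppresses optimizer noise and is a
declared choice, not an attempt to match any particular viewer's
post-filtering. Support comes from elsewhere: bootstrap or posterior
tree samples are reduced to canonical bipartition frequencies and
overlaid on the network's splits, with sample-only splits reported
separately rather than dropped.

## Parsimony: generalized Fitch and the insertion scan

Step counting uses generalized Fitch on binary-resolved topologies:
polymorphic leaves enter as their state set (taken as-is, the standard
treatment), missing cells as the full alphabet. Scores are invariant to
root placement — which is exactly why two competing rooting scenarios of
one backbone topology must tie, a property the tests assert across all
rootings. The insertion scan attaches the query to every branch
(pendant branches included), recording the incremental steps
$S_b$; *all* tied minimal attachments are reported, never broken, since
tied placements are a finding (ancestral-grade fossils produce them),
not a nuisance. Per-character consistency indices (minimum over observed
steps, 1 for invariant characters) feed the parsimony weighting scheme
of the placement module.

NNI hill climbing under parsimony or likelihood is a steepest-ascent
loop over all nearest-neighbour interchanges. NNI landscapes have
genuine strict local optima even for homoplasy-free five-taxon matrices
(the tests construct one and verify it by enumerating all fifteen
topologies), so searches are seeded from the BioNJ tree of the data
being scored — in the bootstrap, from each replicate's own BioNJ tree —
and the tests assert monotonicity and local optimality of endpoints
rather than pretending NNI is a global optimizer.

## Likelihoods

All models are time-reversible and normalized to one expected
substitution per unit branch length.

* **Mk** (categorical): Lewis' symmetric *k*-state chain, with the
  closed form $P_{\text{same}}(t) = 1/k + \frac{k-1}{k}
  e^{-kt/(k-1)}$. Each character uses its own observed state count
  ($k \ge 2$), the standard morphological convention.
* **Frequency-augmented multistate** (`mk_freq`): equal
  exchangeabilities with empirical state frequencies — the categorical
  analogue of the GTR option in common ML software. This is a declared
  reconstruction: the multistate "GTR" parameterization for morphology
  is not published, and full exchangeability estimation on 23 characters
  would be hopelessly overparameterized. Frequencies get a +0.5
  pseudocount per observed state so padded or rare states never produce
  degenerate rates. Its transitions also have a closed form (an F81-type
  chain), so categorical pruning never exponentiates a matrix.
* **GTR+Γ** (nucleotide): eigendecomposition via the symmetrizing
  similarity transform; discrete Gamma with four categories
  (category means by the incomplete-gamma construction). Base
  frequencies are empirical with fractional counting of IUPAC
  ambiguities; shape and exchangeabilities are fitted by the same
  bounded scalar coordinate search as branch lengths.

Felsenstein pruning runs over compressed column patterns (nucleotide)
or per-character local alphabets vectorized by state count
(categorical), with lazy rescaling of partial likelihoods; likelihood is
root-invariant under reversibility, asserted to $10^{-9}$ across random
rerootings. Lewis' variable-characters-only (Mkv) conditioning is
available but off by default — the original analyses cite Lewis' model
without stating the conditioning, so both modes are exposed. Note the
correction *raises* each variable character's log-likelihood (division
by $1 - P(\text{constant}) < 1$).

Branch-length optimization is coordinate-wise bounded scalar search
(branch lengths in $[10^{-8}, 100]$, convergence when a sweep gains less
than the tolerance, at most 20 sweeps; the log-likelihood never
decreases). Plain golden-section search fails on the long flat plateau
of the likelihood in $t$, so each one-dimensional step first brackets
the maximum on a log-spaced grid — and, after the first sweep, on a
local grid around the current value — before refining. The two-taxon
closed form $\hat t = -\tfrac12 \ln(1 - 2x/n)$ anchors the tests.

## Evolutionary placement and character weighting

A query is attached at the midpoint of each backbone branch; the pendant
branch length is optimized and the branch's score is the weighted
log-likelihood (or the weighted Fitch step increase under MP). ML
per-branch weights are the softmax of the attachment log-likelihoods, so
they sum to one and read as placement probabilities; MP reports ranks
and tie sets. Pendant-only optimization is the default economy.
"Local" (pendant plus the two halves of the subdivided branch),
"two-stage" (thorough re-evaluation of the top candidates) and "full"
re-optimization are available behind the `optimize` flag, but fuller
optimization is *not* uniformly better: re-fitting all branch lengths
lets a wrong attachment absorb signal that the fixed backbone lengths
carry, and in the package's recovery simulations the pendant economy was
the most accurate mode. An entirely unscored query yields a uniform
table with a warning, not an error.

The three character-weighting schemes calibrate per-character weights
against the backbone of extant taxa before a fossil is placed: MP uses
the consistency index; ML_MK and ML_GTR use
$w_c = \exp(\ell_c - \max_{c'} \ell_{c'})$ from the per-character
log-likelihoods on the optimized backbone, rescaled to mean one. These
calibrations are declared reconstructions of the original software's
weight-calibration feature, whose numeric mapping is unpublished; what
matters downstream is only the induced ranking of branches per scheme
and whether the schemes' best branches disagree (the "swap" report).

## Outgroup root scans and gene jackknifing

Root hypotheses are branch classes: a root on the branch separating
taxon set $X$ from everything else implies the corresponding basal
arrangement. For Osmundaceae: H1 (root on the *Osmundastrum* branch —
paraphyletic *Osmunda*), H2 (root on the *Leptopteris*+*Todea* stem —
monophyletic *Osmunda*), H3 (root on the *Osmunda s.str.* stem — an
*Osmundastrum*–*Leptopteris*–*Todea* clade). Clade membership is
supplied as taxon lists, so the machinery generalizes beyond ferns.

Per partition, the ingroup branch lengths and the GTR+Γ4 model are
refit (partitions differ strongly in rate), each outgroup taxon is
placed as an ML query on every ingroup branch, per-branch likelihood
weights are averaged over outgroups — outgroups enter one at a time by
default; the ordering is irrelevant by construction — and then summed
within branch classes, so H1 + H2 + H3 + other = 1 per partition.
Partitions with fewer than four variable columns are flagged
low-information but still reported. The jackknife repeats the scan on
the concatenation, each partition alone, and each leave-one-out
concatenation ($2P+1$ subsets), and `split_support_scan()` tracks
bootstrap support for named focal splits across the same subsets.

## What the generators emulate — and what they do not

`simulate_mk_matrix()` mirrors the study scale: ~23 characters with 2–4
states, ~15 % missing cells, Mk evolution along a given tree.
`make_fossil_query()` either evolves a query from a recorded attachment
point (so the true branch is known) or builds a "mosaic" row mixing two
clades' consensus states — the caricature of an ancestral-grade fossil.
`simulate_dna_conflict()` fixes an eight-taxon royal-fern-like ingroup
and attaches the outgroup pair at the H1 branch for "coding" partitions
(atpA 900, rbcL 1200 columns, rate 0.8) and at the H2 branch for three
"spacer" partitions (350–400 columns, rate 1.2), with a configurable
long outgroup stem (default 0.2 substitutions/site) emulating the
long-branch pressure real outgroups exert. Conflict is engineered by
generating-branch assignment, not by simulating convergent evolution —
simpler, and sufficient to exercise the scan. None of the generators
model correlated characters, among-character rate variation in
morphology, or fossilization-biased missingness; passing recovery tests
therefore demonstrates that the *machinery* identifies signal that is
present, not that real matrices contain such signal.

Validation scale, chosen once: placement recovery uses 50 replicates of
a 10-taxon Yule backbone of depth 2 (about two expected changes per
character from root to tip, giving consistency indices in the range
typical of published morphological matrices), 30 characters, pendant
length 0.1, no missing data on the query; root-conflict recovery uses 20
seeds of a half-length spacer configuration (coding 450/600, spacers
300 each) with a zero-length outgroup stem — the regime in which
per-partition recovery is a fair test, since the long-stem default
deliberately degrades spacer signal; the jackknife flip runs at the
generator's full default proportions, where the coding signal dominates
the concatenation as engineered. Under these conditions the placement
recovery rate measures around ninety percent but varies substantially
between seed families (individual 50-replicate batches have landed
between the high seventies and mid nineties), because recovery depends
strongly on the drawn backbone: trees with short pendant branches near
the attachment are intrinsically harder. The misses are adjacent-branch
confusions whose log-likelihood margins are fractions of a unit —
information-limited at 30 characters, not an optimizer artifact (the
engine is verified against closed forms, brute-force state summation,
and an independent pruning implementation).

## Numerical and interface choices

* Partition ranges are 1-based inclusive on input (the common partition
  file convention) and stored as 1-based R index vectors — R's native
  indexing; a zero-based internal representation would buy nothing here.
* Gaps `-` in categorical matrices are missing data by default
  (`gap_as_state` reverses this); the source analyses do not state a
  gap policy.
* Newick output keeps 12 significant digits; quoted labels and
  square-bracket comments are accepted on input.
* Bootstrap default is 1,000 replicates with a flag to match the
  original 10,000 — desk-scale analyses do not need the larger count to
  stabilize the frequencies that matter here.
* The posterior sampler is a deliberately small single-chain
  Metropolis–Hastings over (topology, branch lengths): NNI and
  single-branch log-multiplier proposals with probability ½ each,
  uniform topology prior, iid exponential (mean 0.1) branch-length
  prior. It targets matrices of a few dozen taxa, has no heated chains,
  and its correctness check is prior recovery on a constant matrix — a
  no-data run must reproduce the uniform topology prior (each quartet
  split at frequency ⅓). It replaces full Bayesian machinery by design.
* The scan refits per-partition models with a short coordinate-descent
  budget (one alternation, two branch-length sweeps); placement ranking
  is insensitive to the residual tolerance, and the budget keeps a full
  five-partition scan in the tens of seconds.

## Known limitations

Rooted/non-reversible models, formal topology tests (AU/SH), Sankoff
parsimony with step matrices, network layout/drawing, and divergence
dating are all out of scope. The MCMC provides no convergence
diagnostics beyond the acceptance rate and split-frequency stability;
for publication-grade posteriors use dedicated samplers. Placement
accuracy is bounded by the information in the character matrix — with
few characters, adjacent branches are genuinely indistinguishable, and
the per-branch weight tables (not just the best branch) are the honest
output to report.
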