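---
title: "Embedding protein sequences and interrogating annotation structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Embedding protein sequences and interrogating annotation structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protspace)
```

## The problem

Bacterial protein function is organized in curated ontologies (SEED-style:
superclass → class → subclass → subsystem), but the ontology's partition of
sequence space reflects expert curation, not the geometry of the sequences
themselves. `protspace` embeds amino acid sequences as numeric vectors and
then asks structural questions: how many clusters does the embedded set
contain, does the embedding's hierarchy agree with the annotation
hierarchy, and do unannotated sequences form coherent groups that are not
simply homology artifacts?

The package implements two embeddings, a cluster-number estimator, a
tanglegram comparison, an unknown-sequence clustering workflow, and a
synthetic corpus generator that makes the entire pipeline testable without
any external database.

## Sequence filtering

Input sets are filtered before any embedding: sequences containing the
ambiguity character `X` are removed first, then sequences shorter than 30
residues (unlikely to form a domain) or longer than 1024 residues
(uncommon). The bounds are inclusive — only strictly shorter/longer
sequences are dropped — and the two reasons are counted separately.
Non-`X` ambiguity codes (B, Z, J, U, O) are rejected at parse time rather
than silently filtered, because silently guessing a policy for characters
the pipeline was never designed around is worse than surfacing them.

## Skip-gram 3-mer vectors and the summation embedding

For training, each sequence is decomposed into three "sentences" of
shifted, non-overlapping 3-mers (frames 0, 1, 2); jointly the frames cover
every 3-mer start position exactly once, so a sequence of length $L$
contributes $L-2$ tokens. A skip-gram model with negative sampling is
trained on these sentences with the standard configuration: vector size
$d = 100$, symmetric context window of 25 tokens each side. The remaining
word2vec hyperparameters are not dictated by the method and are set to the
common defaults: 5 negative samples, 5 epochs, initial learning rate 0.025
with linear decay, minimum token count 1 (keeping the full 3-mer
vocabulary), and no frequent-token subsampling. Negative samples are drawn
from the unigram distribution raised to $3/4$. Training is single-threaded
with a dedicated deterministic generator, so a fixed seed reproduces the
vectors bit-for-bit.

A sequence is embedded by summing the vectors of its *overlapping* 3-mers.
3-mers absent from the model's vocabulary — unavoidable when embedding
held-out sequences — contribute the zero vector, and the per-sequence
out-of-vocabulary fraction is recorded so downstream analyses can detect
poorly covered sequences. Embedded matrices are standardized column-wise
(Z-score) before clustering; the population standard deviation is used,
matching the default of the standard machine-learning toolkits, and
constant columns are set to zero with a warning rather than producing
non-finite values.

The learned space can be audited directly: the Euclidean norm of each
3-mer vector measures its influence on where sequences land, the norm
distribution is summarized by a Gaussian kernel density estimate (R's
rule-of-thumb bandwidth, `bw = "nrd"`), and the residue composition of the
100 longest vectors can be compared against the BLOSUM62 diagonal — in a
well-trained model the rarely substituted residues (W, C) dominate the
tail. Because absolute norms are not transferable across trainings, the
tail is defined by top-$n$ rank by default, with an absolute threshold
mode also available; ties in norm are broken lexicographically by token so
results are deterministic.

## Reduced-alphabet k-mer frequency embedding

The second embedding needs no training: sequences are first mapped into
the Murphy 10-letter reduced alphabet (classes LVIM, C, A, G, ST, P, FYW,
EDNQ, KR, H, each written as its representative letter), which shrinks the
3-mer space from $20^3 = 8000$ to $10^3 = 1000$ coordinates. Each sequence
becomes the vector of its overlapping reduced 3-mer counts divided by its
length $L$; coordinates are indexed by the lexicographic enumeration of
all 1000 reduced 3-mers, fixed so vectors are comparable across runs.
Every row sums to $(L-2)/L$.

A consequence worth understanding: with count-over-length normalization a
row's squared norm scales approximately as $1/L$, so sets with a broad
length distribution carry a strong length gradient in this embedding (see
*Limitations*).

## How many clusters? The bootstrapped Calinski–Harabasz profile

Cluster structure is scored on agglomerative dendrogram cuts. For a
partition of $n$ rows into $K$ clusters with cluster means
$\bar{x}_k$ and grand mean $\bar{x}$:

$$WSS(K) = \sum_{k=1}^{K}\sum_{i=1}^{n_k} \lVert x_{ik} - \bar{x}_k \rVert^2,
\qquad
BSS(K) = \sum_{k=1}^{K} n_k \lVert \bar{x}_k - \bar{x} \rVert^2,$$

$$CH(K) = \frac{BSS(K)}{WSS(K)} \cdot \frac{n-K}{K-1}.$$

$WSS + BSS$ equals the total scatter for every partition, which the test
suite checks as an invariant. The profile resamples the rows with
replacement $B$ times (default 500), builds one Ward dendrogram per
replicate, cuts it at every $K$ in the range (default 2–150), and records
$WSS$, $BSS$ and $CH$; the estimate of the cluster count is the $K$
maximizing the mean CH, together with a flag for whether that optimum is
an *interior peak* (strictly exceeding both neighbors). A monotone
profile — no $K$ at which between-cluster variance comes to dominate — is
reported as "no interior peak" rather than as a spurious boundary
estimate.

Design choices here were genuinely open and are fixed as follows. The
linkage is Ward (on Euclidean distances, i.e. `hclust` method
`"ward.D2"`) by default because the CH criterion is itself a variance
ratio, with average and complete linkage selectable. The bootstrap
resampling unit is the row (case resampling), with one dendrogram per
replicate cut at all $K$ — re-scoring fixed full-data labels on resampled
rows is an alternative reading of "bootstrapping each K"; replicate-level
values are retained so other summaries can be computed. Resamples with
fewer than two distinct rows are redrawn (at most 10 times, counted). A
seeded subsample (default cap 5000 rows) bounds the $O(n^2)$ dendrogram
cost on large sets. Ties in the optimal $K$ go to the smallest $K$.

## Comparing an embedding's hierarchy with the ontology

The annotation table is turned into a fixed-depth tree (labels nested
coarse→fine, leaves = sequence ids, depth-ordinal heights since the
ontology has no branch lengths), and the embedding side is a Ward
dendrogram over the same sequences. The two trees form a tanglegram, and
disagreement is quantified by entanglement: with $u_i, v_i$ the ranks of
leaf $i$ in the two leaf orders,

$$E = \frac{\sum_i |u_i - v_i|^{L}}{\sum_i |u_i - u_{n+1-i}|^{L}},$$

the denominator being the value attained when one order is the exact
reverse of the other, so $E \in [0,1]$. The exponent defaults to
$L = 1.5$, the conventional tanglegram setting. Entanglement is minimized
with the alternating *step2side* heuristic: hold one side fixed, walk the
other side's internal nodes depth-first left-to-right, reverse a node's
children whenever that strictly decreases $E$ (strictness prevents
cycles), then swap sides; stop when a full round changes nothing. The
result is flip-locally optimal — the tests verify by exhaustive
neighborhood search on small instances — but not necessarily globally
optimal, since exact entanglement minimization is intractable in general.

A complementary report counts, for each finest-level label, the number of
maximal contiguous blocks its sequences occupy in the dendrogram's leaf
order: labels with two or more blocks are functional categories that the
embedding splits across distant clades.

## Clustering unknowns

Unannotated sequences are embedded with a model trained on unannotated
sequences, then clustered with k-means (k-means++ initialization, Lloyd
iterations, best of 10 seeded restarts by inertia; k is a user choice, not
a package constant). Per cluster, the members nearest the centroid (ties
by row order) are the natural experimental representatives. To check that
clusters are not homology artifacts, within-cluster mean percent identity
is computed from Needleman–Wunsch global alignments under BLOSUM62 with
gap opening 10 and gap extension 1; identity uses the full alignment
length (gap columns included) as denominator — conventions differ, so
this is fixed and documented. Clusters with many members are summarized
over a seeded sample of at most 10,000 pairs.

## The synthetic corpus generator

Real corpora (GTDB/PATRIC-scale collections with SEED annotations) are
too large and too external for a test suite, so the generator emulates
their relevant structure: `F` families, each defined by a random
30-residue motif planted at a random offset in otherwise uniform random
background, per-position motif conservation `p_cons` (default 0.9),
lengths uniform in 30–300 (inside the filter bounds), and a balanced mock
4-level ontology built by pairing families into subsystems and so on
upward. Motifs are redrawn whenever two families would share more than
50% positional identity. A fraction of whole families can be held out as
the "unknown" set — held-out families, rather than random sequences,
because real unannotated proteins tend to come from functions missing
from the ontology entirely. Uniform background was chosen over natural
residue frequencies to keep recovery tests sharp and assumption-free; the
background is swappable. Label perturbation (reassigning finest-level
labels of a random subset) manufactures controlled embedding-vs-ontology
disagreement for entanglement tests.

What the generator does *not* emulate: indel processes, phylogenetic
autocorrelation within families, domain architecture, or natural length
and composition biases. Tests that pass on synthetic corpora demonstrate
that the machinery is correct and that its statistical behavior matches
the planted truth under the generator's assumptions — not that any
particular biological corpus will show the same cluster counts.

## Numerical and degenerate-input policy

Z-scoring of constant columns yields zeros plus a warning; the CH index
refuses $WSS = 0$ (perfect separation makes the ratio undefined) and
$K < 2$; KDE is skipped with a warning for single-token models; k-means
restarts that produce an empty cluster are re-initialized from the seeded
stream; t-SNE input affinities fall back to uniform for coincident
points, so degenerate projections stay finite. PCA axes are sign-fixed
(largest-magnitude loading positive). All stochastic steps take explicit
seeds, and every documented tie (norm ranking, optimal-K, centroid
distance) is broken deterministically.

The t-SNE engine shipped with the package is a compact exact
$O(n^2)$ implementation (perplexity calibration by bisection, early
exaggeration, momentum gradient descent) intended for the set sizes this
package visualizes; `project()` accepts any drop-in replacement function
for larger problems.

## Problem sizes used by the tests

The suite exercises the pipeline at deliberately small scale: toy corpora
of tens of sequences for skip-gram contracts, 200-sequence synthetic
corpora (5 families × 40) for profiling, 8-leaf trees for exhaustive
untangling oracles, and bootstrap counts of 20–50 where the full default
is 500. These sizes were chosen so the whole suite completes in well under
a minute while still covering every code path; the statistical properties
checked (scatter conservation, oracle equivalence, sign tests over seeds)
do not depend on scale.

## Limitations

* **Cluster recoverability vs CH-peak detectability.** With
  motif-planted families at realistic motif fractions (30 conserved
  positions in sequences of 30–300 residues), Ward clustering of the
  k-mer frequency embedding can recover the planted families almost
  perfectly while the CH profile still declines monotonically in $K$:
  the between-family share of total scatter stays far below the level at
  which the variance ratio peaks, and under count-over-length
  normalization the $1/\sqrt{L}$ norm gradient adds within-cluster
  spread that the family signal cannot offset. A CH interior peak
  requires strongly separated clusters, not merely recoverable ones.
  This is the same qualitative behavior as on real corpora, where the
  k-mer frequency embedding's profile never reaches a peak; the
  acceptance script reports both the profile's optimum and the Ward-cut
  family purity so the two notions can be compared directly.
* The step2side heuristic finds flip-local optima only.
* Percent identity uses one fixed alignment parameterization; it is a
  homology screen, not a substitute for a profile-based search.
* Skip-gram vectors are reproducible for a fixed seed *within* this
  implementation; they are not numerically portable across different
  word2vec implementations.
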