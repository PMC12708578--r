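---
title: "Federated LSH with blinded outsourcing: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Federated LSH with blinded outsourcing: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedlsh)
```

## The problem

Germplasm collections, breeding companies and national gene banks each hold
genomic data they will not pool, yet cross-institutional questions — "who
else holds a fragment similar to this one?" — are exactly the questions that
make joint breeding programmes work. `fedlsh` implements a three-role
protocol for answering k-candidate similarity queries over data that never
leaves its owner in raw form:

* **Clients** hold private feature matrices $X \in \mathbb{R}^{m \times d}$
  (for genomes, numericized fixed-length sequence slices).
* A **cloud server** maintains the global locality-sensitive hashing (LSH)
  ensemble and performs the heavy projection product on *blinded* inputs.
* A **data server** aggregates integer-quantized hash tables from all
  clients and ranks candidates for queries. It never sees raw data or
  real-valued projections, only bucket integers.

## The hashing model

Each of $L$ hash tables is a classical 2-stable random projection: a matrix
$W \in \mathbb{R}^{t \times d}$ with i.i.d. $N(0,1)$ entries, per-row
offsets $b_i \sim U[0, r)$ and a bucket width $r$, quantizing item $x$ as

$$h_i(x) = \left\lfloor \frac{w_i \cdot x + b_i}{r} \right\rfloor,
  \qquad i = 1, \dots, t.$$

Because the projections are Gaussian, the probability that two items agree
on a row decreases monotonically with their Euclidean distance — the
property `collision_profile()` measures directly, and the reason Euclidean
ranking of candidates is meaningful. The full $t$-tuple per table is the
bucket key; near misses are handled by distance ranking over stored bucket
vectors rather than multiprobe, because the data server only holds bucket
integers.

Two notational choices deserve a note. The hash size of the default
configuration is written $40 \times 3$: we read this as $t = 40$ hash rows
per table and $L = 3$ tables, and expose both as ordinary configuration.
The quantizer's divisor is the bucket width $r$ (default 4.0, a standard
choice for roughly unit-variance features); the historical name `num_hash`
for this quantity is kept as an alias in the documentation only.

## Blinded outsourcing

Computing $W X^\top$ for every client is the expensive step
($t \cdot d \cdot m$ multiplications), so clients may outsource it. A
client's secret key is
$SK = \{\alpha,\ P_1 \dots P_l,\ Q_1 \dots Q_l\}$: a scalar and $2l$ random
Givens (elementary) rotations, the $P_k$ acting on the item dimension $m$,
the $Q_k$ on the feature dimension $d$. The client ships

$$X' = P_1 \cdots P_l\,(\alpha X)\,Q_1 \cdots Q_l, \qquad
  W' = (\alpha W)\,Q_1 \cdots Q_l,$$

the cloud returns $H' = W' X'^\top$, and the client recovers

$$H = \tfrac{1}{\alpha^2}\,H' P_1 \cdots P_l = W X^\top$$

exactly, because the orthogonal factors cancel
($Q Q^\top = I$, $P^\top P = I$). Each Givens factor touches only two rows
or columns (4 multiplications per touched element), so blinding costs
$O(l(m + d + t))$ element updates against the $t d m$ the cloud performs —
the entire point of outsourcing.

Keys are stored and serialized as rotation parameter triples $(i, j,
\theta)$, never as dense matrices, and are used only locally.

### Parameter choices in the key

* $\theta$ is sampled as a **real** uniform on $(0, 2\pi)$. An
  integer-valued angle would admit only six distinct rotations per pair and
  substantially weaken the blinding, so the continuous reading is the only
  defensible one.
* Index pairs $(i, j)$ are drawn uniformly and independently per rotation;
  repeats are harmless (products of rotations remain orthogonal).
* $\alpha$ is log-uniform on $[0.5, 2]$. It only needs to be nonzero, but
  bounding it away from $0$ and $\infty$ keeps the $1/\alpha^2$ recovery
  well conditioned; log-uniformity makes $\alpha$ and $1/\alpha$
  equidistributed.
* $l$ defaults to 8 rotations per side. More rotations mix more but cost
  linearly; 8 already gives every guessing argument its exponent while
  staying negligible next to the projection cost.
* Factor order: the left product applies $P_l$ first and $P_1$ last, the
  right product applies $Q_1$ first and $Q_l$ last, and recovery
  right-multiplies by $P_1$ first. Any consistent convention yields the
  cancellation; this one matches the written factor order above.

### Verifying the cloud

The cloud is untrusted, so every returned table is checked with a
Freivalds-style contraction: draw $r \sim N(0, I_t)$ as a row vector and
compare $V_1 = (r W') X'^\top$ with $V_2 = r H'$ at cost
$td + dm + tm$ — linear in the matrix sizes. Honest tables satisfy
$V_1 = V_2$ identically; for a tampered table the discrepancy is a nonzero
linear functional of a continuous Gaussian, so false acceptance has measure
zero up to the tolerance.

Exact equality is meaningless in floating point, so acceptance is
$\lVert V_1 - V_2 \rVert_\infty \le \varepsilon\,(1 + \lVert V_1
\rVert_\infty)$ with $\varepsilon = 10^{-10}$ by default. The choice is
deliberate and asymmetric: honest rounding discrepancy is of order
$10^{-13}$ relative for the dimensions this package targets, while a
single-entry perturbation of magnitude $\delta$ survives only when the
matching $|r_i| < \varepsilon(1 + \lVert V_1\rVert_\infty)/\delta$. At
$\varepsilon = 10^{-6}$ and table magnitudes in the hundreds that miss
probability is a few percent for $\delta = 10^{-3}$; at $10^{-10}$ it drops
to $\sim 10^{-5}$ per trial while completeness retains three orders of
magnitude of slack. A client that sees verification fail raises a
`fedlsh_verification` error and discards the table, so a dishonest cloud
can deny service but never plant a wrong table in the index.

## Federation and query modes

`orchestrate()` runs broadcast → (per client) keygen → outsource → cloud
product → verify → recover → bucketize → submit → aggregate, entirely in
process with serializable messages; there is no real transport layer
because the protocol is defined by its message contents, not its wires.
Three query paths differ only in *where* $W X_q^\top$ is computed: on the
data server from raw vectors (`raw`, no privacy), on the querying client
(`local-hash`), or on the cloud via the blinded path (`cloud-assisted`).
Recovery is exact to $\sim 10^{-12}$, far below the bucket width, so the
three modes produce identical bucket vectors and identical ranked results —
an equivalence the test suite asserts rather than assumes.

Quantization happens client-side by default, so the data server holds
integers only; a `submit_hashtables(..., at_server = TRUE)` variant ships
real-valued tables for server-side quantization where that weaker reading
is wanted. One encrypted data matrix $X'$ is reused across the $L$ tables'
$W'$ encryptions under the same key: the blinding acts on the feature side,
which all tables share. Each client draws a fresh key per run.

Candidate generation takes the union of exact bucket-key matches over
tables; since exact $t$-tuple collisions are rare at $t = 40$, the lookup
falls back to ranking all indexed items by mean per-table L1 distance
between bucket vectors and pads the candidate set to `num_results`. Final
ranking supports Euclidean, cosine (as $1 - $ similarity) and L1 distances
over the stored bucket vectors, with lexicographic id tie-breaks for
reproducibility.

## Genomic front-end

Nucleotides are numericized A→0, T→1, C→2, G→3; any other symbol (N, IUPAC
codes, gaps) maps to the same −1 sentinel used for padding, keeping the
value set minimal. Sequences are sliced into windows of `sequence_length`
(default 3072) with `overlap` (default 100) shared bases between
consecutive windows — stride $= 3072 - 100$ — and the final window is
right-padded with −1. Each slice carries its source ordinal and a
deterministic content hash (xxhash64 of the integer vector) as UUID, so
identical fragments deduplicate across clients without coordination.

Two caveats are documented rather than hidden. First, the ordinal codes
$\{0,1,2,3\}$ feed the Euclidean LSH directly as a $d = 3072$ feature
vector; this imposes an artificial A<T<C<G geometry (a substitution A→T
moves the vector less than A→G). It is implemented this way because that is
the pipeline's definition; users wanting a metric-faithful embedding should
one-hot encode upstream. Second, the slicer is frame-sensitive: an
insertion or deletion shifts all downstream windows.

## Synthetic benchmarks

The package tests itself on generated data with known ground truth:

* `gen_clusters()` — 10 classes × 500 points in $d = 64$, class centers
  $N(0, 0.55^2 I)$, unit within-class noise. The separation 0.55 was
  calibrated once so that a leave-one-out 1-nearest-neighbour classifier
  attains ≈ 0.9 accuracy at the default size (the suite recomputes this),
  i.e. the data carry strong but imperfect class signal.
* `gen_genomes()` — random ACGT sequences with planted variant copies at a
  per-base substitution rate (default 1%), substitution-only so planted
  pairs stay frame-aligned. Provenance is returned as truth.
* `shard_clients()` — balanced seed-shuffled partition across clients; the
  reference topology is 10 clients × 1,000 items.

What these fixtures do **not** emulate: real image or genome statistics
(correlated pixels, codon structure, repeats, indels), heterogeneous client
distributions, or adversarial clients. Passing tests demonstrate that the
protocol machinery is exact and that retrieval recovers planted structure;
absolute hit rates on real collections will differ.

`hit_rate()` scores a query as a hit when at least one of its top-k
candidates shares the query's label (clusters) or base sequence (genomes),
with the query item excluded from its own candidates — without
self-exclusion every indexed query is a trivial hit. When evaluating at
$k$, the benchmark fetches $k + 1$ results so each query still has $k$
candidates besides itself; the chance level for a balanced 10-class set at
$k = 4$ is then $1 - 0.9^4 \approx 0.344$, which `permutation_null()`
estimates exactly for the actual candidate structure by label permutation.

## Cost accounting

Scalar multiplications (SM) are the protocol's cost unit; additions are
ignored. Every operation tallies its algorithmic SM count into a per-phase
counter (`sm_counts()`). Two phases have exact closed forms that the
implementation reproduces multiplication-for-multiplication:
verification $td + dm + tm$ and the cloud product $tdm$; both are asserted
exactly in the tests. The model's encryption ($md + td + 2ml + 4dl$) and
recovery ($tm + 2ml$) expressions do not match a direct count of Givens
applications — left-multiplying an $m \times d$ matrix by one rotation
costs $4d$ multiplications, right-multiplying $4m$, and recovery's right
products on a $t \times m$ table cost $4t$ each, giving
$md + 4dl + 4ml (+\, td + 4tl$ per table$)$ for encryption and $tm + 4tl$
for recovery. `sm_formulas()` prints the model verbatim,
`sm_account()` sets it beside the measured and exact implementation counts,
and the tests assert the implementation's own bound rather than the
model expressions.

## Problem sizes used by the checks

The automated checks run at the scales the protocol is specified for:
100 random round-trip instances ($m, t \le 64$, $d \le 128$, $l \le 16$);
1,000 verification trials per arm; rotation products up to dimension 256
with 64 factors; 2,000 distance-controlled pairs for the collision profile;
the full 5,000-point cluster benchmark behind a 10-client federation with
300 queries (10 seed repetitions in the acceptance script); and an
end-to-end genomic run of 10 clients × 1,000 slices at $d = 3072$,
$t = 40$, $L = 3$ with 100 queries. Timings are reported but never
asserted.

## Known limitations

* The blinding is a lightweight masking scheme, not lattice-grade
  cryptography: it hides values behind a secret orthogonal conjugation and
  scalar, and the guessing-probability argument for its strength is
  documented, not mechanized. No attack code is included by design.
* No multiprobe or learned hashing; candidate padding is a linear scan of
  bucket vectors, which is exact but $O(n)$ per query on the index.
* The data server learns bucket-vector geometry (it must, to rank); an
  adversary there can estimate pairwise similarities between indexed items,
  though not feature values.
* Cosine and L1 ranking operate on quantized bucket vectors, a coarser
  proxy than the real projections; `project()` output can be ranked instead
  where the privacy budget allows.
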