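---
title: "Methods: from bibliographic records to themes and emerging biomarker nodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from bibliographic records to themes and emerging biomarker nodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litkg)
```

This vignette documents the models and procedures `litkg` implements,
the assumptions behind them, the parameters that matter, and what the
synthetic test bed does and does not demonstrate about real corpora.

## 1. The analysis pipeline

The package turns a set of bibliographic records into three artifacts:

1. a **keyword map** sending raw keyword variants to canonical terms;
2. a **theme map**: communities of the keyword co-occurrence network
   placed on a Callon strategic diagram;
3. a **classified knowledge graph** of subject–predicate–object triples
   with hub, bridge, and emerging-node flags.

Stages communicate through plain-text artifacts (JSON Lines and CSV)
written deterministically, so any run is reproducible byte-for-byte from
its seed and config.

## 2. Semantic keyword standardization

**Model.** Keyword variants naming one concept lie close together in a
sentence-embedding space, while distinct concepts are farther apart.
Formally: if the within-concept minimum pairwise cosine exceeds a
threshold $\tau$ that the between-concept maximum stays below, then the
graph joining pairs with $\cos \ge \tau$ has the concepts as its
connected components.

**Procedure.** Terms are case-folded, whitespace-normalized, and
stripped of trailing punctuation before lookup; vectors are re-normalized
to unit length; clusters are connected components of the threshold graph
(single linkage); each cluster's canonical term is its most frequent
member, ties broken by shorter then lexicographically smaller term.

**Choices.**

* $\tau = 0.85$ by default, exposed as a parameter. Raising $\tau$ only
  refines the partition (a property the tests check), so a user can
  trade merge aggressiveness against fragmentation monotonically.
* Single linkage is the literal reading of "pairs above threshold are
  grouped": it is deterministic and order-independent. Its known failure
  mode is chaining through borderline pairs; complete linkage is
  available as an option for vocabularies where chaining is a concern.
* Embedding acquisition is behind a provider contract (a function from
  terms to a row matrix). The package never calls a hosted service; a
  file-backed provider reads a JSONL table, and a hash provider gives
  deterministic, near-orthogonal vectors for plumbing tests.

## 3. Co-occurrence network and centralities

Each record contributes its *set* of unique canonical keywords: every
unordered pair gains one unit of edge weight. Using the set (not the
multiset) means a record mentioning five variants of one concept creates
no self-affinity artifact. Analysis runs on the giant component;
removed node counts are reported.

Centralities follow the classical normalized definitions: degree
$\deg(v)/(N{-}1)$; betweenness by Brandes' exact algorithm normalized by
$(N{-}1)(N{-}2)/2$ with shortest-path ties split proportionally;
closeness $(N{-}1)/\sum_u d(v,u)$; eigenvector centrality by power
iteration scaled to maximum entry 1. Two numerical choices deserve
note:

* **Identity shift.** Power iteration runs on $A + I$ rather than $A$.
  On bipartite graphs (stars, paths) the adjacency has a $\pm\lambda$
  eigenvalue pair and the plain iteration oscillates forever; the shift
  makes the iteration convergent while leaving the principal eigenvector
  of a connected graph unchanged. Tolerance is $10^{-10}$ (L2 change per
  step), at most 1000 iterations, with a hard error on non-convergence.
  A graph made of several near-identical, weakly coupled clusters has an
  almost-degenerate leading eigenpair and will legitimately hit that
  error; the centrality functions therefore let the caller request only
  the metrics a given analysis needs.
* **Weighted variant.** When requested, betweenness and closeness use
  edge length $1/w$ (strong co-occurrence = short distance); degree
  remains the unweighted connection count so that "number of distinct
  partners" keeps its meaning.

## 4. Walktrap theme detection

A length-$t$ random walk started inside a dense community tends to stay
inside it, so the $t$-step visit distribution $P^t_{i\cdot}$
characterizes node $i$'s community. Walktrap defines

$$ r^2(C_1, C_2) \;=\; \sum_k \frac{(\hat P^t_{C_1 k} - \hat P^t_{C_2 k})^2}{d(k)} $$

with $\hat P^t_C$ the community-averaged distribution and $d(k)$ the
walk degree of $k$, and greedily merges the *adjacent* pair minimizing
the mean squared-distance increase
$\Delta\sigma = \frac{1}{N}\frac{|C_1||C_2|}{|C_1|+|C_2|} r^2(C_1,C_2)$.
After $N-1$ merges the dendrogram is cut at the level maximizing the
weighted modularity $Q = \sum_c \left( w_c/m - (d_c/2m)^2 \right)$.

Implementation notes:

* Following the algorithm authors' reference implementation, the walk
  runs on the graph with a **unit self-loop per node**. Without it the
  walk is periodic on bipartite subgraphs and the $t$-step distribution
  carries a parity artifact that measurably degrades the dendrogram;
  with it, the package reproduces the reference implementation's
  partitions exactly on random graphs (a test cross-checks this against
  igraph). Modularity is always computed on the graph as given.
  `transition_powers()` exposes both walks; the plain walk is the
  default there so the matrix itself matches the textbook definition.
* Community distributions are updated by exact size-weighted averaging,
  not an approximate update — networks at this scale (tens to hundreds
  of keywords) do not need the speedup.
* Ties in $\Delta\sigma$ break on the smaller (then larger) community
  id, making the procedure fully deterministic. Greedy agglomeration is
  inherently tie-sensitive: two exact implementations that break a
  near-tie differently can produce different dendrograms, with no
  guarantee which cut scores higher $Q$. The cross-check test therefore
  expects identical partitions on the vast majority of random graphs and
  comparable cut quality on the remainder.
* $t = 4$ by default (the classic choice; short enough to stay local,
  long enough to mix within a community), exposed as `walk_t`.

## 5. Callon strategic diagram

For each theme $C$: density $= 100 \cdot \sum w_{\text{int}} / |C|$
(internal link strength per member — maturity) and centrality
$= 10 \cdot \sum w_{\text{ext}}$ (total link strength to other themes —
relevance to the field). These are the classic Callon conventions used
by strategic-diagram tools; the constants only scale axes and cancel in
quadrant assignment, which is invariant under positive rescaling of
either axis (tested).

Themes split at the **median** of each axis by default ("high" meaning
$\ge$ the split); the mean is available for parity with tools that use
it. The median is robust to the heavy-tailed theme sizes typical of
keyword networks. Quadrant 4 — high centrality, low density — marks
*basic/future themes*: directions strongly tied to the field's core that
have not yet developed internal structure.

A `min_theme_size` filter (default 3 in the pipeline config) suppresses
noise themes in real corpora. Note the interaction with the synthetic
test bed: planted future themes are single canonical keywords and
surface as singleton communities, so end-to-end synthetic runs use
`min_theme_size = 1`. The Q4 count of a real corpus is sensitive to this
filter, which is why it is a visible config parameter rather than a
constant.

## 6. Knowledge graph and node classification

Triples arrive from any extractor honoring a minimal contract (a
function from text to subject/predicate/object items). The bundled mock
extractor implements deterministic pattern rules over a closed verb
lexicon ("increases", "decreases", "inhibits", "promotes", "is
associated with"), inheriting the subject across conjoined clauses.
Malformed items (missing or empty fields) are dropped and *counted*: the
noise tally mirrors the manual filtering step a human-in-the-loop
validation applies to real extractor output.

Entities pass through the keyword map, duplicates merge with
multiplicity, and the graph is undirected for topology: bridging and
gatekeeping are symmetric notions even though predicates are directed.

Per entity, three independent flags:

* **hub** — among the top `hub_k` (default 10) nodes by degree
  centrality, ties at the boundary included;
* **bridge** — domain tags of incident triples span $\ge 2$ domains;
* **emerging** — degree centrality *strictly below the median* and
  betweenness centrality in the top `emerging_q` quantile (default
  0.25), and positive: a node carrying no shortest paths is never a
  gatekeeper, however degenerate the quantile. "Top-ranked betweenness"
  is quantified as the top quartile by default; the strict-median degree
  condition keeps the emerging and top-degree sets disjoint.

Validation support implements stratified sampling —
$\lceil f \cdot n_s \rceil$ per stratum at $f = 0.05$, so every
non-empty stratum contributes at least one item — and Cohen's
$\kappa = (p_o - p_e)/(1 - p_e)$, with $\kappa \equiv 1$ when both
raters are constant and equal.

## 7. The synthetic test bed

The generator plants, under a single hierarchical seed, exactly the
structures the stages assume. Its defaults are the package's study
conditions; they were chosen for identifiability and stay fixed.

* **Vocabulary**: 42 synonym groups of 2–4 terms; each group's canonical
  term receives a strictly maximal planted frequency (canonicals draw
  from 30–45, variants from 1–10), so canonical election is
  deterministic.
* **Embeddings**: one random unit base vector per group (a random
  orthonormal frame when the dimension allows, which keeps between-group
  cosines small); members are normalized $base + \sigma\,\text{noise}$
  with $\sigma$ set from the target within-group cosine. Generation
  verifies the realized geometry (min within $\ge 0.9$, max between
  $\le 0.6$) and retries within a bound, so recovery at $\tau = 0.85$
  is a property of the *stated* bounds, not of luck.
* **Corpus**: 500 records over 10 core themes and 2 future themes, 3–6
  keywords per record surfaced as variants, 5% cross-theme leakage,
  linearly increasing annual counts over 20 years, geometric citation
  counts.
* **Future themes** are planted per the fourth-quadrant signature: a
  future-theme record pairs the theme's single keyword with two donor
  keywords from two *core* themes — never with another future keyword —
  so the future keyword has zero internal and large external
  co-occurrence. Two design conditions make this signature survive the
  modularity cut rather than being absorbed into a core community:
  (i) donor themes follow a balanced tournament schedule, spreading the
  future keyword's attachment evenly over core communities — an evenly
  attached node is modularity-neutral to first order, so the
  second-order penalty dominates; and (ii) future themes are a small
  minority of themes (here 2 of 12; the penalty is positive whenever
  future themes number fewer than half the core themes). Future themes
  are sampled at twice the per-theme record rate — a fourth-quadrant
  theme is by definition strongly tied to the core — which gives the
  penalty enough weight to dominate sampling noise. Under these
  conditions the planted future keyword surfaces as a singleton
  community (density 0, top centrality) in the large majority of seeded
  runs.
* **Triples**: per domain, a hub wired to a 10-entity core clique and 3
  leaves (strictly maximal degree); a 4-entity satellite clique
  reachable only through a degree-2 emerging entity (the sole cut
  vertex, hence below-median degree with top betweenness); bridge
  entities joining consecutive domains.
* **Annotation pairs**: rater A reports a balanced latent truth; rater B
  agrees independently with probability $a$; the expected $\kappa$ is
  $2a - 1$.

**What passing tests show — and what they do not.** The synthetic bed
demonstrates algorithmic correctness (exact centralities, exact
agglomeration, correct cut, correct classification rules) and
recoverability under the stated geometric and structural assumptions. It
does not demonstrate that real embeddings satisfy a clean
within/between cosine separation, that real themes are as balanced, or
that real extractor noise is as benign as dropped fields; on real
corpora, $\tau$, `min_theme_size`, and `emerging_q` deserve sensitivity
checks.

## 8. Problem sizes and determinism

All randomness flows from one integer seed through named child streams
(one per generator), so each stage can be regenerated independently.
Test and acceptance workloads use desk-scale sizes — co-occurrence
networks of ~40 nodes, planted-partition graphs of 80 nodes, 100-graph
oracle sweeps, 20-seed recovery studies — which exercise every code path
while keeping a full run in the order of a minute. Exact (non-sampled)
betweenness is the only super-linear step and is comfortable at the
hundreds-of-nodes scale this package targets; approximate betweenness is
deliberately out of scope.

## 9. Known limitations

* Single-linkage threshold clustering can chain borderline synonym
  pairs; inspect large clusters or switch to complete linkage.
* The modularity cut inherits modularity's resolution limit; very small
  genuine themes can be absorbed (the planted-future-theme design in
  §7 works around exactly this).
* TGCS is approximated by summed per-record citation counts from the
  source exports; a dedicated citation index would differ.
* Country extraction relies on the last address token plus a small alias
  table; affiliation disambiguation beyond that is out of scope.
* The mock extractor is a test instrument, not an information-extraction
  system; real deployments wire an LLM or rule engine behind the
  extractor contract and validate with the sampling + $\kappa$ tools.
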