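---
title: "Methods: consensus voting, network integration, path search and the expression statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus voting, network integration, path search and the expression statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regpath)
```

# The problem

During vascular calcification, smooth-muscle cells trans-differentiate
toward an osteoblast-like phenotype. TGF-β1 sits upstream of this process,
CTGF (CCN2) is a downstream effector, and miR-378a-3p represses CTGF
indirectly. The mechanistic question is which molecular chains can carry a
signal from a *source* (TGF-β1) to a *target* (CTGF): direct interactions,
TF-mediated induction of the miRNA, or longer mixed chains. `regpath`
answers the computational half of that question: it integrates three
heterogeneous interaction layers into one directed network and enumerates
every bounded-length simple path from source to target, together with the
quantitative statistics used to read out the wet-lab and cohort evidence.

# Consensus miRNA-target voting

Sequence-based target predictors disagree; the standard defence is a vote.
With records from $n$ tools, a pair (miRNA $m$, gene $g$) is retained iff

$$\left|\{\,t : t \text{ predicts } (m, g)\,\}\right| \ge k,$$

with $k = 3$ of five tools by default, and the per-miRNA target set is the
union of retained pairs. Votes count **distinct tools** — duplicate rows
within one tool's table count once, because the criterion is a tool-level
one. Two consequences are worth stating: the rule is monotone (raising $k$
never adds a target; $k = 1$ is the plain union) and idempotent (re-feeding
a consensus as a single pseudo-tool with $k = 1$ reproduces it); both are
enforced as property tests.

Tool-native scores are carried through unchanged but never combined: the
rule is a vote, not a rank aggregation. No score cutoffs are applied before
voting — tool-specific thresholds vary wildly in scale, and applying none
is the only choice that needs no per-tool calibration. Identifier matching
is case-insensitive exact string matching; no ortholog or alias mapping is
attempted, so mixed human/rodent symbol conventions must be resolved
upstream by the user.

# Network integration

The integrated object is a typed directed multigraph over three node types
(miRNA, TF, gene) and three edge types:

* `ppi` — undirected protein–protein pairs, materialised as **two directed
  arcs** so that a single traversal engine serves all layers. PPI edges are
  allowed anywhere in a path (they act as a bridging layer between gene/TF
  nodes); an edge-type filter is exposed for analyses that want to restrict
  them.
* `tf_mirna` — directed TF→miRNA regulation.
* `mirna_target` — directed miRNA→gene edges from the consensus vote.

Node types are inferred from usage, and one id has exactly one type: a
declared TF stays a TF even where it appears in the PPI layer, while
source/target status is a *role* overlay rather than a type (the path
source is simultaneously an ordinary gene node). Contradictory usage — an
id appearing both as a miRNA and as a PPI protein — is an error rather
than a silent coercion, because every such case we could construct was a
data bug. Self-loops are dropped with a warning. Edges carry no sign or
weight: the repression-versus-activation character of an interaction is a
biological annotation this network deliberately does not encode, and no
confidence scoring is attempted.

The directed edge count therefore obeys an exact conservation law —
$2\,|\text{PPI pairs}| + |\text{TF rows}| + |\text{consensus pairs}|$
after deduplication — which the pipeline checks on every run and the test
suite verifies against brute-force counting on random fixtures.

# Depth-first path search

All search primitives operate on the directed multigraph under a depth
bound `max_depth` (edges per path):

* `reachable_nodes()` — nodes within `max_depth` edges of the source,
  computed by breadth-first expansion; equal, by construction and by test,
  to the depth-truncated transitive closure from boolean adjacency-matrix
  powers.
* `enumerate_paths()` — every **simple** directed source→target path with
  at most `max_depth` edges, each exactly once, ordered by (depth,
  lexicographic node sequence).
* `build_search_tree()` — the hierarchical DFS expansion tree; flattening
  its root-to-target branches reproduces `enumerate_paths()` exactly,
  which is asserted as a cross-operation consistency test.

Design choices that were genuinely open:

* **Depth default 4.** Known mechanistic chains run through one to three
  mediators; four edges covers them all while bounding the combinatorial
  growth of simple-path enumeration. The bound is a parameter, not a
  constant.
* **Simple paths only.** Without the no-revisit constraint, cyclic
  networks admit unbounded walks; biological path interpretations are
  acyclic chains anyway.
* **`source == target` returns an empty list** rather than a zero-length
  path: the analysis is about mediators between distinct molecules.
* **Lexicographic tie-breaking** (radix order, locale-independent) for
  children at every expansion makes outputs byte-reproducible across
  platforms and independent of input row order.

The search engine is hand-written recursion; igraph serves as an
*independent* implementation in the test suite (`all_simple_paths` with a
cutoff), alongside a pure-R permutation brute force on small graphs and
the matrix-power oracle for reachability.

# Expression and cohort statistics

**ΔΔCt.** Replicate wells within a sample are averaged; each sample
contributes $\Delta Ct = Ct_\text{gene} - Ct_\text{reference}$; groups are
summarised by the mean of per-sample ΔCt (not the difference of mean Cts —
the two agree for balanced data, but the per-sample form is the standard
and degrades more gracefully with dropped samples); then
$\Delta\Delta Ct = \overline{\Delta Ct}_\text{treated} -
\overline{\Delta Ct}_\text{control}$ and relative expression is
$2^{-\Delta\Delta Ct}$. Swapping the contrast inverts the fold exactly.
Efficiency-corrected (Pfaffl) quantification is out of scope.

**Percentages.** Reported suppression follows the *reduced-by* convention,
$100\,(1 - \text{fold})$, so fold 0.42 reads as 58 % suppression; the
alternative *reduced-to* reading is one call away
(`suppression_to_fold()` / `induction_to_fold()` expose both directions).

**Pooled *t*-test.** Group comparisons use the equal-variance Student form
with $df = n_1 + n_2 - 2$. The choice matters: from the printed summaries
of the serum cohort (24 versus 11 subjects), the pooled form reproduces
all three published p-values, while the Welch form does not. The raw-data
entry point delegates to `stats::t.test(var.equal = TRUE)`; the
summary-statistic form implements the closed form
$t = (m_1 - m_2)\big/\sqrt{s_p^2 (1/n_1 + 1/n_2)}$ and is tested to agree
with the raw form to $10^{-10}$ on random data. Zero pooled variance with
equal means returns $t = 0, p = 1$; with unequal means it is rejected as
degenerate. p-values in summary reports are rounded to three decimals; no
multiple-testing correction is applied, matching the original analysis
scale of three biomarkers.

# What the synthetic generators emulate

The generators exist so that every downstream stage has a ground truth.

**Interaction databases.** Planted paths are node sequences whose
consecutive pairs must form legal layer transitions (gene/TF–gene/TF →
PPI; TF→miRNA; miRNA→gene); anything else is rejected naming the edge.
Decoys are added around them: Erdős–Rényi PPI (the simplest null with
tunable density; scale-free topology is deliberately not modelled),
random TF→miRNA regulation, and per-tool prediction tables in which each
tool emits a true miRNA-target pair with probability 0.8 (resampled until
at least `min_tools` tools emit it, so the default consensus always
retains planted targets) and each decoy pair with probability 0.1.
**Safety rule:** every decoy edge points *into* a decoy node, and
undirected decoy PPI touches only decoy genes and the declared sources
(arcs into a source cannot extend a simple path that starts there). This
makes the no-shortcut guarantee structural: any source→target path must
end in a planted edge, hence inductively consist of planted edges — no
post-hoc filtering, no rejection loop over whole graphs. With zero decoys
the output contains exactly the planted edges.

**qPCR.** Expected Ct is $\text{baseline} - \log_2(\text{fold})$ with
i.i.d. Gaussian replicate noise (default SD 0.25 cycles, a typical
technical spread; baseline 24 cycles, mid dynamic range and arbitrary).
At SD 0 the ΔΔCt pipeline recovers planted folds exactly; at SD 0.25 with
6 replicates/group the estimator carries a small convexity bias
($\mathbb{E}\,2^{-X} = 2^{-\mu}e^{(\ln 2)^2\sigma^2/2} \approx 1.005$
times the planted fold), well inside the two-percentage-point recovery
band checked by the tests.

**Cohort.** Two groups of 24 and 11 subjects with per-biomarker mean ± SD
(serum TGF-β1 9.62 ± 8.25 vs 1.85 ± 3.36 ng/mL, CTGF 24.93 ± 6.39 vs
19.98 ± 7.11 ng/mL, miR-378a-3p 0.55 ± 0.763 vs 0.134 ± 0.207 relative
units), age 75.8 ± 6.0 years, 37.1 % in the reported sex category. Values
are normal draws, optionally clipped at zero — a deliberate
simplification: an SD larger than the mean implies right skew that a
clipped normal only approximates, so simulated group means sit slightly
above nominal for those biomarkers. Group sizes and the sex count are
exact by construction, not sampled.

What passing tests on this synthetic data do **not** show: real prediction
tools are correlated (they share seed-match logic), real PPI networks are
scale-free and orders of magnitude larger, real Ct noise has sample- and
plate-level structure, and real serum concentrations are skewed. The
generators probe correctness of the algorithms, not realism of the noise.

# Numerical and degenerate-input conventions

* All orderings are radix (byte) order, independent of locale.
* Seeds fix all randomness; generators save and restore the caller's RNG
  state. The pipeline derives per-stage seeds (`seed`, `seed + 1`,
  `seed + 2`) so stages stay independently reproducible.
* Empty prediction files warn and contribute nothing; unknown columns are
  an error naming the file.
* Samples lacking a reference Ct are dropped with a warning; a group left
  empty is an error.
* `fold ≤ 0` is rejected wherever a fold is consumed.

# Problem sizes

The bundled demo plants three 3-edge paths among 20 decoy genes, 3 decoy
TFs and 2 decoy miRNAs; the test suite uses random digraphs of up to 10
nodes (where brute-force path enumeration is exact and fast) and 500-seed
Monte-Carlo runs for the qPCR recovery checks. These sizes were chosen so
that exhaustive oracles remain feasible; all engine code is written for
networks orders of magnitude larger (the only super-linear step is
simple-path enumeration itself, bounded by `max_depth`).

# Known limitations

* No regulatory signs: a path asserts connectivity, not net activation or
  repression.
* No path significance testing or network-randomisation nulls — path
  existence under a depth bound is the reported statistic.
* No ortholog/alias identifier mapping.
* The clipped-normal cohort model under-represents skew (see above).
* Consensus voting treats tools as exchangeable and independent; the
  synthetic emission model does too, which is optimistic for correlated
  real tools.
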