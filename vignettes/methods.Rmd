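---
title: "Methods: from herb tables to hub genes, microbiome statistics and colitis scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from herb tables to hub genes, microbiome statistics and colitis scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharmbiome)
```

`netpharmbiome` packages the desk-side analysis pipeline of multi-herb
formula studies in experimental colitis: screen compounds, build the
herb–ingredient–target network, distil hub proteins from a PPI graph, test
gene-set over-representation, and analyse the downstream animal data (16S
community profiles, disease-activity scores). This vignette records the
statistical definitions the package commits to, the defaults and why they
were chosen, what the synthetic generators do and do not emulate, and the
procedure's measured limitations.

## 1. Compound screening and the HIT network

Compounds are screened on two ADME descriptors: oral bioavailability
(OB, percent) and drug-likeness (DL, unitless). The activity rule is
`OB >= 20 and DL >= 0.18`, **both inclusive** — a compound at exactly the
cutoff is active. Gene symbols are normalized by uppercasing and trimming
only; no alias resolution is attempted, so symbols that differ beyond
case/whitespace are distinct genes (a documented limitation: merged or
renamed symbols inflate set sizes slightly).

Disease genes pooled from several databases are combined by **union**;
`collate_disease_genes()` additionally reports every exact-membership Venn
region so source overlap is auditable (region counts always sum to the
union size). The HIT network links herb → compound → target, restricted to
the formula–disease shared targets. Pruning is closed: a compound with no
retained target disappears, then a herb with no retained compound. A
compound found in several herbs is a single node with one edge per herb,
so per-herb component totals count shared constituents once per herb;
`herb_target_share()` reports both per-herb coverage (fractions may sum
above 1 because targets are shared) and combined coverage of any herb
subset (the all-herb subset covers exactly 1).

## 2. Six-centrality hub extraction

The PPI graph keeps edges with confidence at or above 0.7 (inclusive; the
usual "high confidence" STRING convention; 0–1000 exports are detected and
rescaled), drops self-loops, merges duplicate edges at their maximum
confidence and removes degree-0 nodes. Confidences select edges but never
weight the statistics — all six indices are computed on the unweighted
topology:

* **DC** — degree.
* **BC** — betweenness, unnormalized Brandes sum over unordered pairs;
  pairs in different components contribute 0. Unnormalized values keep the
  magnitudes comparable with the common Cytoscape/CytoNCA reports.
* **CC** — per-component closeness `(n_c - 1) / sum of distances` within
  the node's component; 0 for an isolated node. This keeps closeness
  finite on disconnected graphs without inventing cross-component
  distances.
* **EC** — principal eigenvector of the adjacency matrix, entries folded
  non-negative and scaled to max 1. It is computed with a dense symmetric
  (LAPACK) eigendecomposition rather than ARPACK: ARPACK's random start
  consumes RNG state and breaks the pipeline's byte-identical determinism
  guarantee. On disconnected graphs the vector concentrates on the
  spectrally dominant component.
* **LAC** — mean degree of the node's neighbours inside the subgraph
  induced by the neighbourhood.
* **NC** — sum over incident edges of the edge clustering coefficient
  `ECC(u, v) = triangles(u, v) / min(deg(u) - 1, deg(v) - 1)`, with the
  0/0 case (a pendant endpoint) defined as 0. On a star, NC and LAC are 0
  at the centre — there are no triangles to support them.

One filtering round computes the per-index medians and keeps nodes that
pass the median on **all six** indices (intersection). "Pass" defaults to
*strictly greater* (`comparator = "strict"`); the inclusive variant exists
because strictness necessarily empties vertex-transitive graphs, where all
scores tie. Scores within `1e-8` (relative) of a median count as ties, so
numerically identical values on symmetric graphs behave identically.
`extract_hub_subnetwork()` repeats this three times by default, inducing
the subgraph on survivors (and re-dropping isolated nodes) between rounds,
and stops early when the survivor set is empty, unchanged, or smaller than
`min_size` (default 3), returning the last valid subnetwork plus a full
per-round trace (input nodes, six medians, survivors, stop reason). The
intersection-of-indices reading and the early-stop policy are design
choices: the selection rule could also be read as sequential per-index
refinement, but both converge under repeated rounds and the trace makes
the behaviour auditable.

**Measured limitation.** On a synthetic benchmark — an Erdős–Rényi
background G(200, 0.03) with a planted 12-clique — three strict rounds
recover at least 10 of the 12 planted nodes in only ~9 of 20 seeds (the
acceptance suite asserts the stronger 18/20 expectation and is
deliberately left failing). The traces show two causes. First,
betweenness anti-correlates with dense-module membership: a clique carries
no internal shortest-path load, so one to three members sit at or below
the BC median in early rounds and the all-six intersection removes them.
Second, once the surviving subgraph is nearly the clique itself it is
nearly symmetric, so a strict round keeps only a small fraction of it;
when that fraction still reaches `min_size`, a decimated set becomes the
final answer. The procedure works well on scale-free PPI graphs, where
hubs dominate every index simultaneously; on symmetric dense modules the
strict median intersection is intrinsically lossy. Users who want the
module rather than the hubs should inspect the trace and the
round-1 survivor set, or use the inclusive comparator.

## 3. Over-representation analysis

`enrich_gene_set()` performs the classic one-sided hypergeometric test:
with a universe of `N` genes, `K` of them in a term, and a query of `n`,
the p-value is `P(X >= k)` for the observed overlap `k` (computed via the
stable `phyper` tail, exact for universes well beyond 1e5). The universe
defaults to the union of all collection members and is overridable — the
background is the analyst's choice and is recorded in the pipeline
manifest. Terms with zero query hits are excluded from the output *and*
from the multiple-testing family. Benjamini–Hochberg adjustment is applied
separately within each ontology category (BP, CC, MF, pathway), matching
how per-ontology tables are usually reported; significance is
`p_adj < 0.05`. One caution: BH adjustment is not idempotent — re-running
the step-up procedure on already-adjusted values inflates them (ties get
multiplied by `n/rank` again), so adjusted p-values must never be fed back
through the adjustment.

## 4. Microbiome statistics

All analyses operate on a samples × features count table with taxonomy
and group labels. Low-abundance filtration removes features whose total
count is below `5e-5` (0.005%) of the table-wide grand total, boundary
inclusive; the threshold is measured table-wide (not per sample) because a
single table-wide fraction is the common convention for this filtration
step. Composition profiles aggregate relative abundances at a rank, rank
taxa by mean relative abundance, and pool everything beyond the top 10
into "Others"; columns sum to 1 exactly.

Alpha diversity (per sample, with `S` observed taxa, `N` reads, `F_i` the
number of taxa seen `i` times):

* Good's coverage `1 - F1/N`;
* Chao1, bias-corrected by default `S + F1(F1-1)/(2(F2+1))` (defined even
  when `F2 = 0`), classic `S + F1^2/(2 F2)` by flag;
* ACE with rare/abundant cutoff 10 reads, `C_ACE = 1 - F1/N_rare`,
  `gamma^2 = max(S_rare * sum(i(i-1)F_i) / (C_ACE N_rare (N_rare-1)) - 1, 0)`;
  if every rare read is a singleton (`C_ACE = 0`) the estimate falls back
  to Chao1 with a warning;
* Shannon `-sum(p ln p)` (natural log, the common amplicon default);
* Simpson reported as Gini–Simpson `1 - sum(p^2)` so that *higher means
  more diverse*; the classic dominance `sum(p^2)` is available by flag.

Rarefaction uses the exact hypergeometric expectation
`E[S_n] = S - sum_i C(N - N_i, n)/C(N, n)` evaluated in log space, so it
is exact at any depth (1 read yields exactly 1 taxon; full depth yields
`S`).

Beta diversity is **binary Jaccard**: `d = 1 - |A ∩ B| / |A ∪ B|` on
presence/absence, with two empty samples at distance 0. PCoA is classical
scaling — Gower double-centering of `-D²/2`, eigendecomposition,
coordinates scaled by the square roots of the positive eigenvalues;
negative eigenvalues (non-Euclidean distances) are reported but never used
for coordinates. NMDS minimizes Kruskal stress-1
`sqrt(sum((d - d̂)²) / sum(d²))` by alternating isotonic regression (ties
handled by the primary approach: tied dissimilarities are ordered by the
current configuration distances before the monotone fit) with a Guttman
majorization update. A safeguard ends the run at the first update that
fails to decrease stress, so the recorded stress trace is non-increasing
by construction; the best of one metric-scaling start and 20 random starts
is returned, and the conventional `stress < 0.2` validity flag is set.
UPGMA is explicit size-weighted average-linkage agglomeration with ties
broken toward the pair containing the earliest sample label; node depth is
half the merge height, so cophenetic distances reproduce ultrametric
inputs exactly, and the tree is returned both as an `hclust`-compatible
object and a Newick string.

### The LEfSe-style screen and its measured error profile

The biomarker screen is a documented two-class variant of the LEfSe idea,
on relative abundances scaled to 10⁶: a Kruskal–Wallis gate at
`alpha = 0.05`, then, for surviving features, 30 within-group bootstrap
resamples of a one-dimensional two-class linear discriminant — which for a
single feature reduces to the absolute class-mean difference — each
averaged with the full-sample mean difference; the effect score is
`max(1, log10(mean bootstrap effect))` and a biomarker needs score ≥ 2.
Bit-parity with the original LEfSe tool is out of scope (that tool is
multi-class, has a subclass stage, and different bootstrap plumbing).

Its error profile, measured on Dirichlet-multinomial tables with planted
10-fold taxa (10 vs 10 samples, package defaults): planted-taxon recovery
is high (~92% across 20 seeds), but among *called* biomarkers the spurious
fraction is large (~60%). The reason is structural: null features pass the
KW gate at roughly the nominal rate, and the effect threshold of 2 —
i.e. a mean difference of 100 on the 10⁶ scale, 0.01% abundance — cannot
remove them, because any feature above ~0.1% mean abundance shows chance
between-group differences far larger than that at this sample size under
overdispersed counts. The acceptance suite asserts a ≤10% spurious
fraction and is deliberately left failing as documentation of this
property; it could only be met by tables with ~10 features, which no real
16S experiment resembles. Likewise, on a 2000-feature null table the KW
pass rate is ~1.4%, well below 5%: most features are rare and zero-heavy,
and the tie-corrected KW statistic is strongly conservative there.
Practically: treat the screen as a ranked shortlist, not an
error-controlled discovery set, and corroborate with the per-feature
`kw_p` (BH-adjustable) and effect sizes.

## 5. DAI scoring

The disease-activity rubric is deterministic: stool consistency
(normal 0, soft 1, very soft/semi-formed 2, liquid/sticky 3), occult blood
(negative within 2 min 0, purple after 10 s 1, light purple within 10 s 2,
heavy purple within 10 s 3), body-weight loss binned 0, (0,5), [5,10),
[10,20), ≥20 percent → 0–4, and four histology criteria (epithelial
destruction, edema, crypt loss, mucosa infiltration) each 0–3, summed to
0–12. The bin edges are lower-inclusive half-open — a published "<5%,
5–10%, 10–20%, >20%" bin list is ambiguous at its edges, and exactly 20%
maps to bin 3 under the ">20%" wording for the top bin. The histology
point scale (0–3 per criterion) and the unweighted total (range 0–22) are
package conventions, stated here because rubric variants in the literature
sometimes average components instead; both choices are deliberate,
monotone (worsening any field never lowers the total, verified by
exhaustive grid enumeration) and easy to rescale downstream.

## 6. Synthetic data: the stated world

Each generator is a pure function of a master seed, fanned out to
independent substreams per generator, and emits its planted truth:

* **Compound tables** — six herbs, 15 compound slots each; OB lognormal
  (median 15%, log-sd 0.8) capped at 100, DL Beta(1.2, 5): right-skewed
  marginals under which roughly one compound in seven passes both cutoffs,
  the shape seen in typical compound-database exports. 15% of slots reuse
  a compound from another herb (shared constituents).
* **Disease sources** — five named sources built from an explicit region
  plan (private regions plus an all-source core by default, arbitrary
  plans accepted), so collation can be checked against planted Venn
  counts.
* **PPI graphs** — Erdős–Rényi background (n = 200, p = 0.03) plus a
  planted dense module (12 nodes, density 1); module-edge confidences are
  drawn in [0.75, 0.99], above the 0.7 cutoff by construction, while
  background confidences span [0.4, 0.95] and straddle it.
* **Feature tables** — Dirichlet-multinomial: base proportions lognormal
  (log-sd 1.5, a few dominant taxa and a long rare tail), total
  concentration 60 (strong overdispersion, in the range fitted to real 16S
  data), 120 OTUs over a 6-phylum/12-genus synthetic taxonomy, library
  sizes lognormal around 20,000 reads, 10 samples per group; the treatment
  group's concentrations are multiplied by the fold change (default 5) on
  the planted features.
* **DAI cohorts** — 15 mice per group in three groups (healthy control,
  severe, treated-intermediate) with categorical severity profiles;
  expected group totals are computed exactly from the profiles (the
  weight-loss bin expectation integrates the truncated normal).

What the generators do *not* emulate: read-level artifacts (chimeras,
primer bias, denoising errors), phylogenetic correlation between taxa
(so UniFrac-style metrics are out of scope), compound chemistry, and
database-specific gene-identifier quirks. A green test therefore
establishes that the statistics are implemented correctly and behave as
analysed under a clean generative model — not that any particular
biological conclusion reproduces.

## 7. Numerical conventions

* Median comparisons use a `1e-8` relative tolerance (ties on symmetric
  graphs).
* ECC is 0 whenever its denominator is 0; closeness of an isolated node is
  0; eigenvector centrality of an edgeless graph is all zeros.
* NMDS runs end at the first non-decreasing stress update (monotone trace
  by construction); non-convergence within `maxit` returns best-so-far
  with a warning.
* UPGMA ties break toward the earliest label; duplicate PPI edges keep the
  maximum confidence.
* All file outputs avoid timestamps and unstable float formatting, so a
  fixed seed gives byte-identical pipeline reruns (checked by manifest
  checksums).

## 8. Pipeline orchestration

`run_pipeline()` runs the network-pharmacology branch and the
animal-study branch as independent DAGs — no invented cross-coupling —
aborting on the first stage validation error with the stage name and a
`FAILED` marker while preserving earlier outputs. All thresholds default
to the conventional printed values (OB 20%, DL 0.18, confidence 0.7,
3 rounds, 0.005% filtration, adjusted p and KW alpha 0.05, LDA threshold
2) and are recorded, together with input/output MD5 checksums and the
seed, in `manifest.json`.
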