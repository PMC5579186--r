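---
title: "Methods: ceRNA network inference, comparison and pathway cross-talk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ceRNA network inference, comparison and pathway cross-talk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernascape)
```

## The model

Competing endogenous RNAs (ceRNAs) are transcripts that regulate each other
indirectly: two mRNAs carrying response elements for the same miRNAs draw
on a shared, limited miRNA pool, so up-regulation of one de-represses the
other. Two observable consequences drive the inference:

* genuine ceRNA partners share an unexpectedly large number of targeting
  miRNAs, and
* their expression is **positively** correlated across samples.

Stage one scores the first signal. With a miRNA universe of size $m$, a
gene targeted by $t$ miRNAs, a partner targeted by $n$, and $r$ miRNAs in
common, the probability of an overlap at least $r$ under independent
uniform target sets is the hypergeometric upper tail

$$p \;=\; 1-\sum_{i=0}^{r-1}
  \frac{\binom{t}{i}\binom{m-t}{n-i}}{\binom{m}{n}} .$$

Pairs sharing fewer than 3 miRNAs are removed before any testing — a
pair-level floor, not a statistical correction — and the surviving
p-values receive one Holm (step-down, family-wise) adjustment across the
entire candidate universe. The universe is profile-independent, so the
correction is applied once, not per profile. Candidates are declared at
Holm-adjusted $p < 0.01$.

Stage two scores the second signal, per expression profile: the sample
Pearson correlation and its two-sided p-value from the $t$ distribution
with $n_\text{samples}-2$ degrees of freedom. An edge is retained when
$R > 0$ and $p < 0.01$. Benjamini–Hochberg q-values over all pairs tested
in the profile are stored on every retained edge; `filter_on_q = TRUE`
switches the threshold to the q-value for users who prefer an
FDR-controlled second stage. We filter on the raw p-value by default
because the adjusted-versus-raw reading of the second stage is genuinely
ambiguous in the literature this design follows, and the stored q-values
make the stricter reading reproducible after the fact.

Assumptions worth stating: expression is treated as approximately Gaussian
on the log2 scale (Pearson, not rank, correlation); the miRNA universe
$m$ is taken as the number of distinct miRNAs in the supplied interaction
table unless overridden — using a genome-wide miRNA count instead makes
every tail probability smaller and the test more liberal; and target sets
are treated as fixed and binary (no binding-strength weighting).

## Downstream analyses

**Topology.** Degree sequences are fitted with the continuity-corrected
discrete maximum-likelihood power-law estimator
$\hat\alpha = 1 + N\big/\sum_i \ln\!\big(d_i/(x_{\min}-\tfrac12)\big)$,
scanning $x_{\min}$ to minimize the Kolmogorov–Smirnov distance between
the empirical and fitted tail CCDFs. This estimator is slightly biased
low at $x_{\min}=1$ (about $-0.05$ at $\alpha=2.5$, $n=10^4$), which the
test suite's $\pm 0.1$ recovery band absorbs; users comparing exponents
across networks should keep $x_{\min}$ handling consistent.
Degree/co-expression trends are summarized over degree deciles with a
Spearman rank statistic; pair-degree (sum of endpoint degrees — a
documented choice, the max or min would serve too) and shared-miRNA-count
comparisons use one-sided Mann–Whitney tests. Whenever a trend is
undefined (constant correlations, too few bins) the statistic is reported
as 0 with a `degenerate` flag rather than NA, so tabulations over many
networks stay rectangular.

**Communities.** Modularity communities come from igraph's multi-level
(Louvain) optimizer on the unweighted graph; only communities with more
than 3 and fewer than 300 members are retained, reflecting the view that
ceRNAs act in small functional groups and that giant communities in dense
co-expression graphs are artifacts of resolution. The optimizer is
stochastic; `detect_communities(seed = )` pins its RNG stream, and reruns
with the same seed are bit-identical.

**Dicer stratification.** Because miRNA abundance limits cross-talk,
co-expression of ceRNA pairs should be stronger when the miRNA-processing
enzyme Dicer is low. Samples are split at the median Dicer-proxy
expression (ties to the low group — a fixed, documented rule), pair
correlations are recomputed within each group, and a one-sided
Mann–Whitney tests $r_\text{low} > r_\text{high}$. Recomputation within
groups (rather than comparing edge presence) is used because it measures
the quantity of interest directly and stays defined for every edge.

**Cross-network comparison.** Network similarity is the Simpson (overlap)
index of edge sets, $|A\cap B|/\min(|A|,|B|)$, which is robust to the
large density differences between profiles; significance, when requested,
comes from resampling each network's edge count uniformly from the shared
candidate universe ($p = (1+\#\{\text{perm} \ge \text{obs}\})/(1+B)$) — a
documented substitute, since no analytic null is standard for this
statistic. The conserved core keeps edges recurring in at least 16 of the
supplied networks ("more than 15"), configurable. Hubs are the top 10% of
nodes by degree, implemented as the $k$-th largest degree with inclusive
ties ($k=\lceil 0.1\,n\rceil$): deterministic, and degenerate inputs
(all degrees equal) make every node a hub rather than none. Hubs present
in one network are *specific*; otherwise the Simpson index of the hub's
neighbor sets is computed for every pair of networks in which it is a
hub, and any value above 0.8 makes it *common*, else *differential*. The
three categories partition the hub universe by construction.

**Pathway cross-talk.** Pathway-mapped subnetworks keep edges whose both
endpoints are pathway-annotated. Modules among common hubs use k-clique
percolation: communities are connected components of the graph whose
vertices are the network's $k$-cliques, adjacent when sharing $k-1$
nodes. $k=3$ by default — the smallest $k$ for which percolation is
meaningful, chosen because the analysis targets small, dense modules;
larger $k$ only shrinks communities. Pairs are CPWP when some pathway
contains both genes ("within"), CPBP when both genes are annotated but
never co-annotated ("between"), and unclassified when at most one gene is
annotated; a gene belonging to several pathways therefore cannot force a
pair into CPBP if any single pathway holds both. Normalized pathway
degree divides a gene's degree by the maximum degree of its network,
giving a $[0,1]$ quantity comparable across diseases. Gene-set enrichment
is the one-sided hypergeometric tail with BH correction, with the
interaction table's gene set as the default universe.

## The synthetic-data generator

The generator exists so every stage has a ground truth. Its defaults are
the study conditions used throughout the package's validation: 21
profiles over 8 disease labels (assigned round-robin), 2,000 genes, 386
miRNAs with 30 targets per gene, 100 samples per profile, 150 planted
pairs plus one planted 12-gene clique, planted correlation $\rho = 0.8$,
16 pathway sets of 62 genes. These mirror a multi-disease microarray
compendium at desk scale: hundreds of candidate interactions per profile,
thousands of background pairs sharing $\ge 3$ miRNAs by chance.

Planted structure is generated in groups. Each group (a pair, or a clique
of 12) receives a shared block of miRNAs first — two thirds of the
per-gene target count, at least 3 — guaranteeing every within-group pair
passes the shared-miRNA floor and scores an extreme hypergeometric tail;
the rest of each target set, and all non-planted target sets, are uniform
draws. Expression uses a latent-factor model: within a group, each gene is
$\sqrt{\rho_\text{eff}}\,z + \sqrt{1-\rho_\text{eff}}\,\varepsilon$ with
one shared $z$ per group, the simplest construction with exact population
correlation $\rho_\text{eff}$. Samples carry a bimodal Dicer-proxy gene;
in Dicer-high samples $\rho_\text{eff} = \rho(1-\text{dicer\_effect})$,
a generative choice (the attenuation mechanism itself is not modeled
mechanistically). Each generator draws from its own RNG stream derived
from the seed plus a stage offset, so adding a generator never perturbs
earlier outputs and every output is reproducible bit-for-bit.

The planted clique deserves a note: disjoint planted pairs alone produce
networks of isolated edges — no triangles, hence nothing for clique
percolation or modularity analysis to find. One planted clique of 12
(configurable) provides a recoverable module and a realistic hub group.

What the generator does **not** emulate: platform and batch effects,
probe-level noise, missing values, count-based (RNA-seq) error models,
correlated background structure, or miRNA expression itself. Passing
tests therefore demonstrate correctness of the statistical machinery and
the pipeline's recovery behavior under its stated model — not robustness
to the messiness of real GEO series. In particular, real profiles from
different platforms share only part of their gene space, whereas
generated profiles are fully aligned.

## Numerical choices and degenerate inputs

* Hypergeometric tails are evaluated through the survival function of the
  hypergeometric distribution (log-space internally), stable far beyond
  $m = 10^4$; the validity domain $0 \le r \le \min(t,n)$, $t,n\le m$ is
  enforced with errors.
* `log2(x+1)` is the ingestion transform for raw-scale profiles (the +1
  keeps zeros finite); duplicate probe rows are collapsed by mean after
  transformation. Probe-to-gene mapping is out of scope — ids are opaque,
  case-sensitive strings.
* Zero-variance genes and genes absent from a profile skip the pair (with
  a message) instead of erroring, so one degenerate probe cannot abort a
  21-profile run. Correlations are clamped to $[-1,1]$ before the t
  transform; $|r|=1$ maps to $p=0$.
* Edge lists are canonicalized (`gene_a < gene_b` lexicographically,
  self-loops rejected, duplicates dropped), so edge-set comparisons are
  order-independent. Merges keep, per duplicated edge, the statistics of
  the constituent network with the smallest Pearson p-value.
* Network TSV round trips preserve attributes to at least 6 significant
  digits.

## Problem sizes used in validation

The test suite exercises most operations on studies of ~300 genes, 6
profiles and 60 samples (seconds each), and the recovery/core/partition
properties on the full default conditions above; the acceptance script
runs the default study once end to end. The Monte-Carlo check of the
hypergeometric tail uses $10^5$ draws per parameter set on universes up
to $m = 30$; clique percolation is checked against brute-force
enumeration on 50 random graphs of up to 15 nodes for $k \in \{3,4\}$.

## Known limitations

* Pearson correlation captures linear co-expression only, and the
  two-stage filter inherits the false-positive behavior of marginal
  correlation screens; partial-correlation or conditional approaches are
  deliberately out of scope.
* The Holm correction over candidate universes of ~$10^6$ pairs is very
  conservative; with the default $m$ equal to the observed miRNA count
  this is partly offset by the liberal universe choice.
* Disease-level networks are unions over profiles; no meta-analytic
  weighting of per-profile evidence is attempted.
* The similarity permutation scheme conditions only on edge counts, not
  on degree sequences.
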