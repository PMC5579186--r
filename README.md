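# cernascape

Inference and cross-disease comparison of miRNA-mediated competing
endogenous RNA (ceRNA) networks.

## The problem

Transcripts that share miRNA response elements compete for the same pool of
miRNAs: when one ceRNA is over-expressed it sequesters shared miRNAs and
de-represses its partners, so the expression of a genuine ceRNA pair is
*positively* correlated. `cernascape` is for computational biologists who
want to map this mRNA–mRNA cross-talk across many expression profiles and
diseases from three plain-text inputs — a miRNA→target interaction table, a
set of genes × samples expression matrices with disease labels, and pathway
gene sets (GMT) — and then ask which parts of the cross-talk map are shared
between diseases, which genes act as conserved hubs, and how ceRNA pairs
relate to pathway membership.

## The method

Inference is two-staged, per expression profile:

1. **Shared-miRNA test.** For genes targeted by *t* and *n* miRNAs out of a
   universe of *m*, sharing *r* miRNAs, the null probability of an overlap
   at least as large is the hypergeometric tail

   p = 1 − Σ_{i=0}^{r−1} C(t,i) C(m−t, n−i) / C(m,n).

   Pairs sharing fewer than 3 miRNAs are discarded before testing; the
   remaining p-values receive a single Holm correction across the whole
   candidate universe, with candidates declared at adjusted p < 0.01.

2. **Co-expression filter.** Each candidate pair is tested for positive
   co-expression in a profile: Pearson R > 0 and p < 0.01 (two-sided t
   test, n−2 df) retains the edge; BH q-values over all tested pairs are
   stored on every edge.

Downstream analyses operate on the resulting networks: discrete power-law
degree fits (continuity-corrected MLE with KS-minimizing x_min), Louvain
modularity communities filtered to sizes in (3, 300), Dicer-stratified
co-expression (median split on a Dicer-proxy gene, one-sided Mann–Whitney),
Simpson/overlap similarity |A∩B| / min(|A|,|B|) between edge sets, a
conserved core of edges recurring in more than 15 profiles, hubs as the top
10% of nodes by degree with a common / differential / specific taxonomy
(neighbor-set Simpson > 0.8 across networks), k-clique percolation modules
among pathway-mapped common hubs, and classification of pairs as
within-pathway (CPWP) or between-pathway (CPBP) cross-talks.

A synthetic-data module (`synthetic_config()`, `generate_study()`) plants
ceRNA pairs and cliques with known correlation structure — including a
Dicer-proxy gene that attenuates planted correlations in Dicer-high
samples — so the whole pipeline can be validated against ground truth
without any external downloads.

## Worked example

```r
library(cernascape)

cfg <- synthetic_config(seed = 42, n_genes = 500, n_mirnas = 150,
                        n_samples = 80, n_profiles = 6, n_diseases = 3,
                        targets_per_gene = 15, n_planted_pairs = 60)
study <- generate_study(cfg)
study$interactions
#> interaction_table: 7500 miRNA-gene pairs, 150 miRNAs (m = 150), 500 genes

cand <- candidate_pairs(study$interactions, min_shared = 3, alpha_holm = 0.01)
nrow(cand)            # gene pairs sharing >= 3 miRNAs
#> [1] 22039
sum(cand$candidate)   # Holm-significant candidate ceRNA pairs
#> [1] 126

net <- build_profile_network(study$profiles[[1]], cand)
net
#> cerna_network 'profile01' (profile level): 132 nodes, 126 edges

nets  <- lapply(study$profiles, build_profile_network, candidates = cand)
dnets <- merge_by_disease(nets, vapply(study$profiles, `[[`, "", "disease"))
hubs  <- classify_hubs(dnets)
table(hubs$category)
#> common
#>    132

core <- extract_core_network(nets, min_profiles = 6)
core
#> cerna_network 'core' (global level): 132 nodes, 126 edges

global <- merge_networks(nets, "global", "global")
mods <- common_modules(global, study$gene_sets,
                       hubs$gene[hubs$category == "common"], k = 3)
lengths(mods$modules)
#> [1] 12

cls <- classify_pairs(global$edges, study$gene_sets)
table(cls$class)
#> CPBP CPWP
#>   29   97
```

The 126 Holm-significant candidates are exactly the planted structure (60
pairs plus one 12-gene clique contributing 66 pairwise edges); all are
recovered in each profile, every edge recurs in all 6 profiles (hence the
identical core), the planted clique is found as one 12-member module, and
the pathway classification splits the edges into within- and
between-pathway cross-talks.

For a full run — per-profile and disease networks, similarity matrix, hub
table, core, modules, pair classes and a `summary.json` of all counts —
use `run_pipeline(run_config(seed = 1, out_dir = "report",
simulate = list()))`, or the wrapper script `inst/scripts/cerna.R`.

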