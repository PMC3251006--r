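# cdep — consistent differential expression across heterogeneous studies

`cdep` is an R package for meta-analysis of two-condition gene expression
studies (e.g. primary vs. metastatic tumours profiled by different labs on
different platforms). It identifies genes that are **consistently** up- or
down-regulated across all datasets, rather than genes driven by a single
large study — the failure mode of pooled rank-product meta-analysis — or
genes that merely clear a fixed per-study cutoff, as in signature-counting
approaches.

## The method in brief

For each dataset *i* (mᵢ cases, nᵢ controls) and gene *g*:

1. **Rank product.** Over all Hᵢ = mᵢnᵢ case–control pairs, the geometric
   mean fold-change rank γ̄₍gi₎ = (∏ₕ γ₍gih₎)^(1/Hᵢ) is computed per
   direction; permutation of sample labels gives pooled p-values, and the
   per-dataset FDR is F₍gi₎ = p·Gᵢ/rank(γ̄). Genes absent from a platform
   receive the dataset's median FDR.
2. **Beta mixture.** A 3-component Beta mixture (Dirichlet(1, 18, 1) prior
   on the weights; anchored skewed components) fitted to each dataset's
   one-sided p-values by Gibbs sampling estimates M̄ᵢ, the number of genes
   *not* regulated — rank-product p-values are not uniform under the null,
   so a uniform-null model would be misspecified.
3. **Bernoulli evidence over FDR thresholds.** At threshold *l*, dataset
   *i* declares d₍il₎ genes, implying a false-positive rate
   r̂₍il₎ = l·d₍il₎/M̄ᵢ for unregulated genes. The minus log likelihood of a
   gene's cross-dataset significance pattern under pure false positives,
   Q₍gl₎ = −Σᵢ [δ ln r̂ + (1−δ) ln(1−r̂)], is averaged over the threshold
   density p(l) = −2l + 2 (100-bin rectangular rule):
   ELg = ∫ Q₍gl₎ p(l) dl.
4. **Permutation FDR.** Shuffling FDR values over genes within each
   dataset B times gives the null EL distribution and
   FDRg = (1/B)·Σ_b #{g′: ELg ≤ EL₍bg′₎} / #{g′: ELg ≤ EL₍g′₎};
   genes with FDRg at or below the call threshold are reported per
   direction.

The package also implements the two comparator methods the approach is
evaluated against (`meta_profile`, signature counting; `meta_rankprod`,
pooled cross-dataset rank product), a multi-dataset simulator with planted
consistent and dataset-specific genes (`simulate_panel`,
`default_table2_shapes`), and power / Type-I-error scoring
(`score_calls`, `table1_grid`).

## Worked example

```r
library(cdep)

cfg <- default_table2_shapes(genes = 500, p = 0.1, q = 0.1, delta = 1)
sim <- simulate_panel(cfg, seed = 1)
res <- run_cdep(sim$datasets, n_perm = 50, B = 50, seed = 2,
                sampler = list(chains = 2, iter = 1200, burnin = 400))
res
#> cdep_result: 500 genes, 28 up / 24 down at FDR_g <= 0.05 (B = 50)
score_calls(called_genes(res), sim$truth, threshold = 0.05, method = "cdep")
#>   method fdr_threshold    power     type1 n_true_gm n_called n_false
#> 1   cdep          0.05 61.11111 0.0426009        54       52      19
```

The six simulated datasets mimic the published cancer panel's shapes
(12/21, 25/65, 15/7, 3/3, 19/8, 10/22 cases/controls; nested platforms,
largest rescaled to 500 genes here). Of the 54 planted consistently
regulated genes, 33 are recovered at meta-level FDR ≤ 0.05 (power 61%);
19 other genes — mostly dataset-specific genes that happened to draw the
same direction nearly everywhere — are also called (Type I error 0.043).
The top-ranked genes separate cleanly by direction:

```r
head(as.data.frame(res)[order(-pmax(res$EL_up, res$EL_down)), ], 3)
#>       gene      EL_up   EL_down fdr_g_up fdr_g_down call
#> 30  g00030  0.2323112 19.876254        1     0.0000 down
#> 75  g00075 19.7388474  0.171258        0     0.4382   up
#> 95  g00095  0.2323112 19.253724        1     0.0000 down
```

An EL near 20 means the gene's significance pattern is about e⁻²⁰ times
likelier under consistent regulation than under independent false
positives; unregulated genes sit near 0.

A thin command-line front end is installed under `inst/cli/cdep.R`
(`run`, `simulate`, `evaluate` subcommands over YAML configs).

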