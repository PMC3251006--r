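---
title: "Consistent differential expression across heterogeneous studies: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consistent differential expression across heterogeneous studies: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdep)
```

## The problem

Public repositories hold many small two-condition expression studies — for
example, primary versus metastatic tumours profiled by different
laboratories on different platforms. A meta-analysis that simply pools
samples, or pools test statistics, tends to be dominated by the largest
study and by genes regulated in only one dataset. The method implemented
here asks a different question: *for which genes is the pattern of
significance across all datasets unlikely to be an accident of per-dataset
false positives?* Genes answering that description are "consistently
differentially expressed": up- (or down-) regulated in every dataset in
which they are measured.

## The pipeline, stage by stage

### Per-dataset evidence: rank products

For dataset $i$ with $m_i$ cases and $n_i$ controls, every case–control
pair $h = 1, \dots, H_i = m_i n_i$ yields a fold-change ranking of the
$G_i$ genes. The per-gene statistic is the geometric mean rank

$$\bar\gamma_{gi}^{up} = \Big(\prod_{h=1}^{H_i} \gamma_{gih}^{up}\Big)^{1/H_i},$$

with ranks taken ascending in $-$fold-change for up-regulation (rank 1 =
strongest increase) and ascending in fold-change for down-regulation. Ties
get average ranks; with average ranks the two directions satisfy
$\gamma^{up} + \gamma^{down} = G_i + 1$ exactly, so one ranking pass serves
both. Significance comes from label permutations (preserving $m_i$ and
$n_i$): the p-value of a gene counts how often permutation rank products
across *all* genes fall at or below its observed value, with add-one
smoothing so no p-value is exactly zero (the Beta-mixture likelihood below
needs p-values strictly inside $(0,1)$). When the number of distinct label
assignments is at most the requested permutation count the enumeration is
exhaustive. The per-dataset FDR divides the p-value by the rank of the rank
product,

$$F_{gi} = p_{gi}\, G_i / \mathrm{rank}(\bar\gamma_{gi}),$$

reported uncapped by default (the estimator exceeds 1 for weak genes; a
`cap_fdr` flag truncates at 1). Genes missing from a dataset's platform
receive that dataset's median FDR, flagged as imputed.

### How many genes are *not* regulated: a Beta mixture

The false-positive rate below needs $\bar M_i$, the number of genes not
up- (down-) regulated in dataset $i$. Permutation p-values from the rank
product are **not** uniform for unregulated genes when real signal is
present — the pooled permutation null absorbs the planted effects, pushing
null genes' p-values away from 0 and 1 — so a uniform-null mixture would be
misspecified. Instead the one-sided p-values are modelled as a
three-component Beta mixture: a left-skewed component for the significant
genes (shape $a_1 = 1$ fixed, $b_1$ with a tight prior of mean 20), a free
Beta$(a_2, b_2)$ bulk, and a mirrored right-skewed component
($b_3 = 1$ fixed). The priors are
$\theta \sim \mathrm{Dir}(1, 18, 1)$ (mean $0.05, 0.90, 0.05$),
$a_2 \sim \Gamma(4, 2)$, $b_2 \sim \Gamma(1, 1)$ and
$a_3, b_1 \sim \Gamma(400, 20)$, with $\Gamma(\alpha,\beta)$ parameterised
so the mean is $\alpha/\beta$. Fitting is by Gibbs sampling with data
augmentation over component memberships. Because $a_1$ and $b_3$ are fixed
at 1, the $b_1$ and $a_3$ updates are conjugate Gamma draws; only
$(a_2, b_2)$ needs a Metropolis step (random walk on the log scale,
proposal sd 0.05, chosen for a ~25% acceptance rate). The fixed shapes
anchor the component labels, which is what prevents label switching.
Defaults are 2 chains of 4,000 sweeps with 2,000 burn-in; convergence is
monitored by split-$\hat R$ on the weights ($\hat R < 1.1$). Posterior
means are used as point estimates, and
$\bar M_i = \mathrm{round}\!\big(G_i(\theta_2 + \theta_3)\big)$, floored at
1 so rates stay finite.

One behaviour worth knowing about: on rank-product p-values whose
significant spike is very sharp, the free bulk component can drift to a
U-shape ($a_2 < 1$) and absorb both tails, driving $\theta_1$ toward zero
(the $\hat R$ warning fires when chains disagree on this). The downstream
effect is small — $\bar M_i$ moves by at most $\theta_1 G_i$ and rescales
every gene's rates equally — and the priors are kept exactly as stated
rather than adding constraints the model does not define.

### Combining datasets: Bernoulli likelihood over an FDR-threshold density

Fix an FDR threshold $l \in (0,1)$. In dataset $i$,
$d_{il} = \sum_g I(F_{gi} < l)$ genes are declared significant, of which
about $l \cdot d_{il}$ are false positives, so a *non-regulated* gene is
falsely declared with probability
$\hat r_{il} = l\, d_{il} / \bar M_i$, clamped into
$[10^{-8}, 1 - 10^{-8}]$ (the plug-in estimate can hit 0 or exceed 1; the
clamp keeps the log-likelihood finite). Writing
$\delta_{gil} = I(F_{gi} < l)$ for gene $g$'s significance pattern, the
probability of that pattern arising from false positives alone is a product
of independent Bernoullis, and its minus log,

$$Q_{gl} = -\sum_{i=1}^{D} \big[\delta_{gil}\ln \hat r_{il} +
  (1-\delta_{gil})\ln(1-\hat r_{il})\big],$$

is large when the pattern is hard to explain away. Rather than fixing one
threshold, $Q$ is averaged over $l$ with the linearly decreasing density
$p(l) = -2l + 2$, which emphasises small thresholds (where declared genes
are mostly true positives) without the hard filtering a convex density
would reintroduce:

$$EL_g = \int_0^1 Q_{gl}\, p(l)\, dl
  \approx \sum_{j=1}^{100} Q_{g l_j}\, p(l_j)\, \tfrac{1}{100},$$

a rectangular rule on 100 equal bins evaluated at midpoints
$l_j = (j - 0.5)/100$. Midpoints avoid the degenerate endpoints ($l = 0$
declares nothing; at $l = 1$ everything is declared and $Q \equiv 0$) and
integrate the linear density exactly. Because $\delta_{gil}$ is a step
function of $l$, each dataset's contribution to $EL_g$ is a single lookup
into cumulative bin sums; the per-(dataset, bin) counts and rates are
computed once and shared across genes. A brute-force per-gene loop
reproduces the shared computation to $10^{-10}$ (it is one of the tests).

### Gene-level significance: permutation FDR

The null distribution of $EL$ shuffles each dataset's FDR column over genes
independently ($B$ times; imputed cells shuffle like any other value). The
per-dataset rates depend only on the counts $d_{il}$, which such shuffles
leave unchanged, so rates are held fixed. For gene $g$,

$$FDR_g = \frac{\tfrac1B \sum_b \#\{g' : EL_g \le EL_{bg'}\}}
  {\#\{g' : EL_g \le EL_{g'}\}},$$

with inclusive ties (the denominator counts $g$ itself, so it is never
zero), reported capped at 1. A gene is called up (down) when the
corresponding $FDR_g$ is at or below the call threshold (default 0.05); if
both directions pass, the smaller $FDR_g$ wins and the larger $EL$ breaks
ties — the direction conflict is not defined by the model, so the rule is
stated here as a package choice.

A granularity note: for the top-ranked gene the denominator is 1, so a
call at threshold $t$ requires its $EL$ to beat all but
$\lfloor tB \rfloor$ of the $B \cdot G$ pooled null values. Under a pure
null, exchangeability makes that happen with probability about
$(tB + 1)/(B + 1)$ per direction — roughly 6% at $t = 0.05$, independent
of $B$. Occasional single-gene calls on null data are therefore expected
behaviour of this estimator, not a bug; the suite's null-calibration check
measures exactly this.

## Comparator methods

Two comparators are implemented behind the same data structures:

* **Signature counting** (`meta_profile`): per dataset, the "signature" is
  the set of genes with $F_{gi} < l$ (default $l = 0.05$); a gene's score
  is the number of signatures containing it. The gene-level FDR applies the
  same permutation counting rule as above to the count statistic. The
  score ignores how far below $l$ an FDR lies, which is why the approach is
  conservative and comparatively underpowered.
* **Pooled rank product** (`meta_rankprod`): the geometric mean of a gene's
  fold-change ranks across *all* $\sum_i H_i$ comparisons of all datasets,
  with absent genes contributing their dataset's median per-gene rank
  product once per comparison. The null permutes expression values within
  each single array. Since every comparison carries equal weight, a large
  study dominates: a gene regulated only in the largest dataset can outrank
  genuinely consistent genes (one of the tests constructs exactly this
  situation), and the within-array null under-estimates the gene-level FDR,
  inflating the Type I error.

## The simulator

Synthetic panels follow an additive model per dataset:

$$y = \mu + L_i + G_{gi} + \alpha_g T + \beta_g M + \varepsilon,$$

with universal background $\mu$, laboratory effect
$L_i \sim N(0, b_2)$, per-gene per-dataset baseline
$G_{gi} \sim N(0, b_{3i})$ and noise $\varepsilon \sim N(0, e_i)$. Case
samples of regulated genes additionally receive a per-sample effect
$N(\pm\Delta, \psi)$. Genes are dataset-specifically regulated
($\alpha_g = 1$, rate $p$, direction re-drawn per dataset), consistently
regulated ($\beta_g = 1$, rate $q$, one panel-wide direction), or null; a
gene belongs to at most one category, enforced by drawing $\alpha$ first
and then $\beta$ at rate $q/(1-p)$ among the remainder so the marginal
rates are exactly $p$ and $q$. Platforms are nested: dataset $i$ carries
the first $G_i$ genes of the largest platform (the overlap structure of the
real platforms is not published; nesting is the documented assumption, and
it exercises the median-FDR imputation path).

`default_table2_shapes()` reproduces the six-study cancer panel the method
was demonstrated on: case/control splits (12/21, 25/65, 15/7, 3/3, 19/8,
10/22) — 84 metastatic and 126 primary samples — and gene counts 20,271 /
9,000 / 5,526 / 13,069 / 13,069 / 13,069, optionally rescaled
proportionally.

The variance parameters were estimated from real data in the original
study but never published. The package fixes, once:
$\mu = 8$, $\sqrt{b_2} = 0.5$, $\sqrt{b_{3i}} = 1$, $\psi = 0.25$,
$\sqrt{e_i} = 0.5$ — values typical of log2-scale summarised oligonucleotide
arrays (backgrounds near 8, per-gene spreads near 1, residual noise around
0.5). These defaults are deliberately *not* calibrated against the
published power table; with them the planted effect $|\Delta| = 1$ is
roughly twice as detectable per sample pair as in the original operating
point, so absolute power and Type-I-error levels come out higher than the
published ones, while every qualitative ordering (main method above
signature counting in power; effect-size monotonicity; the pooled rank
product's Type-I inflation relative to its own power) is preserved. The
simulation checks therefore treat orderings as hard gates and absolute
levels as wide bands.

What the simulator does *not* emulate: probe-level artifacts, correlated
gene blocks, batch structure beyond the scalar laboratory shift,
platform-specific dynamic range, and partially consistent genes (regulated
in a strict subset of datasets with a common direction). Passing tests on
this generator show the machinery is correct under the stated model, not
that real-data operating characteristics are reproduced.

## Problem sizes and numerical choices

* Simulation study: six datasets with the shapes above scaled to a
  2,000-gene largest platform, 10 replicate panels per scenario, 50
  rank-product permutations, $B = 50$, 100 threshold bins. The per-panel
  mixture fits use 2 chains × 1,200 sweeps (400 burn-in): at
  $G \approx 2{,}000$ the posterior mean of $\theta$ is stable well before
  the standalone default of 2 × 4,000/2,000, and twelve fits per panel make
  the shorter chains the pragmatic choice.
* p-values are clamped to $[10^{-6}, 1 - 10^{-6}]$ before the mixture fit;
  rates to $[10^{-8}, 1 - 10^{-8}]$ before the Bernoulli likelihood.
* All permutation streams are seeded; per-stage seeds derive
  deterministically from one master seed, so every result in the package
  reproduces bit-for-bit from that one integer.
* Rank assignment uses average ties throughout; the fold-change ranking
  inner loop is compiled (an order-preserving integer key sort), which is
  what makes the full study tractable on one core.

## A small worked example

```{r example, eval = FALSE}
cfg <- default_table2_shapes(genes = 500, p = 0.1, q = 0.1, delta = 1)
sim <- simulate_panel(cfg, seed = 1)
res <- run_cdep(sim$datasets, n_perm = 50, B = 50, seed = 2,
                sampler = list(chains = 2, iter = 1200, burnin = 400))
res
score_calls(called_genes(res), sim$truth, threshold = 0.05, method = "cdep")
```

## Known limitations

* The per-dataset FDR floor is $G_i/(1 + n_\mathrm{perm} G_i) \cdot
  G_i/\mathrm{rank}$; with 50 permutations the smallest attainable FDR is
  about 0.02, so the first two threshold bins are usually empty. More
  permutations sharpen the grid at linear cost.
* The meta-level FDR inherits the conservatism discussed above for
  genes regulated in single datasets, and its top-rank granularity allows
  occasional null calls.
* Direction calls for genes significant both ways rely on a tie-break rule
  the model itself does not specify.
* Paired designs, covariates and more than two conditions are out of scope.
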