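# ktscreen

Comprehensive evaluation of low-potassium (low-K) tolerance in crop
germplasm panels, with the downstream multi-omics screens used to compare
contrasting genotypes. The package is aimed at plant-phenomics and
breeding researchers who need to rank hundreds of genotypes by stress
tolerance from replicated multi-trait data, and to screen ionome,
metabolome and transcriptome responses of selected contrasting lines.

## The method

For a panel of genotypes measured for traits $t$ under control (CK) and
low-K (LK) treatments, each genotype gets a per-trait **tolerance
coefficient** $TC_{g,t} = \bar{x}^{LK}_{g,t}/\bar{x}^{CK}_{g,t}$
(replicate means first, then the ratio). The standardized coefficient
matrix is decomposed by PCA; retained component scores $X_j$
("comprehensive indices", contribution rates $P_j$) are min–max rescaled
to fuzzy membership values

$$U_{g,j} = \frac{X_{g,j} - X_{j,\min}}{X_{j,\max} - X_{j,\min}},
\qquad W_j = \frac{P_j}{\sum_k P_k}, \qquad
D_g = \sum_j U_{g,j}\,W_j ,$$

so every genotype receives a single evaluation value $D \in [0,1]$
(higher = more tolerant). Genotypes are then classified by hierarchical
clustering of D into tolerant / moderately tolerant / moderately
sensitive / sensitive, and extreme genotypes selected by D percentile
(99th/1st), optionally intersected across growth stages.

Companion stages:

- **Ionome**: element-wise percent change $(LK-CK)/CK \times 100$ per
  tissue and genotype, genotype contrasts ("greater decrease in ..."),
  K content and K-utilization-efficiency ($DW^2/K$) arithmetic.
- **Metabolomics**: OPLS-DA (NIPALS, closed-form single-response fit)
  with VIP scoring implemented from first principles; differential gate
  VIP ≥ 1 and fold-change ≥ 2 or ≤ 0.5.
- **Transcriptomics**: direction calls at |log2FC| ≥ 1 and p < 0.05,
  cross-genotype Venn partition, and the tolerance-pattern gene
  selection (up/down, up/unchanged, unchanged/down).
- **Synthetic data**: generators for every input with planted ground
  truth (latent tolerance, tiers, differential features, direction
  patterns), so the whole pipeline is testable end to end.

## Worked example

```r
library(ktscreen)

# --- ionome: packaged elemental-concentration table, two genotypes ---
t5 <- read_ionome_table(system.file("extdata", "wheat_ionome_contrast.csv",
                                    package = "ktscreen"))
resp <- percent_change(t5)
subset(resp, element == "K", select = c(tissue, genotype, ck, lk, pct_change_2dp))
#>  tissue genotype    ck   lk pct_change_2dp
#>   Shoot   KN9204 29.58 7.05         -76.17
#>   Shoot    BN207 26.60 5.62         -78.87
#>    Root   KN9204  9.25 4.81         -48.00
#>    Root    BN207  7.00 1.40         -80.00
```

Shoot K collapses by about three quarters in both genotypes, slightly
more in the sensitive BN207; root K drops far more in BN207 (−80%) than
in the tolerant KN9204 (−48%) — the tolerant line holds on to root K
under starvation.

```r
# --- screening: 543 synthetic genotypes with planted tolerance tiers ---
spec <- trait_gen_spec(n_genotypes = 543,
                       tiers = list(sizes = c(7L, 50L, 238L, 248L)),
                       seed = 101)
g  <- generate_trait_panel(spec)
ev <- evaluate_tolerance(g$panel)
ev
#> Comprehensive PCA: 543 genotypes, 13 traits
#> Retained 1 component(s) [ kaiser rule ]
#> Contribution rates (%): 59.41
#> Cumulative contribution: 59.41%
#> D values: n = 543, mean = 0.339, range = [0.000, 1.000]

classify_tolerance(ev$D)
#> Tolerance classification (k = 4 , linkage = average )
#>                 class   n mean_D
#>              tolerant   7  0.946
#>   moderately tolerant  50  0.673
#>  moderately sensitive 231  0.429
#>             sensitive 255  0.175

cor(ev$D, g$truth$latent_tolerance, method = "spearman")
#> [1] 0.93
```

The D ranking tracks the planted latent tolerance (Spearman 0.93), and
the four recovered classes match the planted tier sizes almost exactly
(7/50 recovered; the two sensitive tiers trade a handful of borderline
genotypes).

A full synthetic demo of all five stages, with CSV/JSON artifacts, a run
manifest and a markdown report:

```r
run_pipeline("demo_out", seed = 1)
```

or from a shell: `Rscript inst/scripts/ktscreen.R demo --seed 1 --out demo_out`.

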