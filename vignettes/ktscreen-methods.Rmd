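---
title: "Comprehensive low-K tolerance evaluation and multi-omics screens: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comprehensive low-K tolerance evaluation and multi-omics screens: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ktscreen)
```

# The screening problem

Potassium-deficient soils are widespread, and breeding crops that keep
growing under low potassium (low-K) supply requires screening large
germplasm panels for tolerance. A single trait is a poor yardstick: low-K
stress touches growth, biomass partitioning, tissue K concentration and K
utilization efficiency in different directions and magnitudes, and the
traits are correlated with one another. `ktscreen` implements the
comprehensive-evaluation workflow used for this kind of screen, plus the
downstream multi-omics response analyses that compare a tolerant and a
sensitive genotype: ionome percent-change contrasts, an OPLS-DA/VIP
differential-metabolite screen, and threshold-based differential-gene set
algebra.

# The comprehensive evaluation chain

The screening stage transforms a replicated trait panel (genotype x trait
x treatment x replicate) into a single tolerance score per genotype in
five steps.

**Tolerance coefficients.** For genotype $g$ and trait $t$, replicate
means are taken per treatment and the coefficient is the stress/control
ratio of means,

$$ TC_{g,t} = \bar{x}^{LK}_{g,t} \, / \, \bar{x}^{CK}_{g,t}. $$

Coefficients above 1 are legitimate and are *not* inverted: utilization
efficiency indices characteristically rise under K starvation (a typical
panel moves from about 1.0 to about 2.6 for the shoot index), and
inverting them would discard exactly the signal the screen is after.

**Comprehensive indices.** The coefficient matrix is standardized per
trait and eigen-decomposed via its correlation matrix. Retained principal
component scores are the "comprehensive indices" $X_j$; each carries a
contribution rate $P_j = 100\,\lambda_j / \sum_k \lambda_k$. The default
retention rule is Kaiser's eigenvalue > 1, with a cumulative-contribution
alternative (`retention = "cumulative"`), since reported analyses of this
type retain five or six components without stating their rule.

Principal component signs are arbitrary in the decomposition but *not* in
what follows — the membership step is not sign-invariant. We fix each
loading vector so its largest-magnitude element is positive, with a 1e-8
tolerance on the magnitude comparison so ties (exact at two traits) break
identically across numerically equivalent decompositions. The convention
is recorded in the run manifest.

**Membership, weights, D.** Each index is min–max rescaled over genotypes
to a fuzzy membership value

$$ U_{g,j} = \frac{X_{g,j} - \min_g X_{g,j}}{\max_g X_{g,j} - \min_g X_{g,j}} \in [0, 1], $$

weights are normalized contribution rates $W_j = P_j / \sum_k P_k$, and
the evaluation value is the weighted sum $D_g = \sum_j U_{g,j} W_j$.
By construction $\sum_j W_j = 1$ and $D \in [0,1]$; larger D = more
tolerant. These identities, plus dominance monotonicity (componentwise
larger membership can never lower D), are asserted property-style in the
test suite over a thousand random draws.

**Classification and extremes.** Genotypes are clustered on the
one-dimensional D values by agglomerative hierarchical clustering
(Euclidean distance, average linkage by default, emulating the defaults
of the statistical packages traditionally used for this step; Ward
available), cut at $k = 4$, and classes labeled by descending mean D:
tolerant, moderately tolerant, moderately sensitive, sensitive. Extremes
are selected by empirical percentile of D (type-7 quantiles, linear
interpolation — the convention must be pinned for reproducibility and is
recorded in the manifest) with *strict* inequality, defaults 99th/1st.
`cross_stage_consensus()` intersects per-stage selections, flagging
genotypes extreme in two or more growth stages.

An open design question is whether clustering should run on D alone or on
the comprehensive indices; the text ordering of typical reports implies D,
which is the default here.

# What the synthetic generator emulates

`generate_trait_panel()` emits panels with the statistical structure the
evaluation assumes:

- **Thirteen seedling traits** with control means, control CVs and
  population-mean LK/CK ratios matching the scale of a large hydroponic
  wheat panel (leaf length/area, shoot length, shoot/root/total dry
  weight, root:shoot ratio, shoot/root K concentration and content, and
  the two utilization-efficiency indices). Growth and K-accumulation
  traits shrink under LK (ratios 0.27–0.83); efficiency indices rise
  (1.8–2.6).
- **A latent tolerance score** $z_g$, standard normal by default, linked
  to the per-trait ratio through an affine-then-clip map
  $r_{g,t} = \bar{r}_t (1 + \ell_t \, \delta_t \, z_g)$ with loading
  $\ell_t \in [-1,1]$ and dispersion $\delta_t = 0.15$. Affine keeps the
  link monotone and identifiable for recovery tests; clipping at 0.01
  keeps ratios positive.
- **Genotype-level control baselines** drawn with the trait's control CV,
  so population descriptive statistics look like a real panel; baselines
  cancel in the ratio.
- **Replicate noise** Gaussian on the measurement scale with sd equal to
  `noise_sd` (default 10%) of the genotype's control mean, truncated at
  zero by clipping. At the default noise level the truncation never
  fires; a resampling scheme would be unbounded for adversarial
  parameter choices.
- **Optional planted tiers**: discrete tolerance classes (default sizes
  7/50/238/248, mirroring a published seedling-stage classification) with
  tier means spaced 1.5 latent units at within-tier sd 0.2. The spacing
  is deliberately wide — 7.5 within-tier sd — so that adjacent tiers stay
  separated even at the order statistics of a 543-genotype panel, and a
  recovery failure indicates a pipeline defect rather than sampling
  overlap.

What the generator does **not** emulate: genotype-by-trait interaction
beyond the single latent factor, trait-specific error variances,
measurement-scale skew, missing cells, or any genetic structure among
genotypes. Passing recovery tests therefore shows the chain is correct
and well-conditioned under the assumed one-factor structure, not that
real panels carry that structure.

A consequence worth knowing: because weights are proportional to variance
contributions, the principal components that carry no tolerance signal
still receive substantial weight (often over half in total), so D is a
deliberately diluted estimator of the latent score. On full-size
synthetic panels Spearman(D, latent) is typically 0.92–0.95 at the
default noise, while the tier membership of individual borderline
genotypes fluctuates between adjacent classes across replicates — the
median top-tier recovery across seeds is the stable quantity, not any
single run.

# Ionome arithmetic

`percent_change()` computes $100\,(LK - CK)/CK$ per tissue, genotype and
element at full precision (a 2-decimal column is provided for reporting,
matching the narrative precision conventional in this literature), labels
directions, and ranks magnitudes within each tissue x genotype block.
Zero-control and missing-pair cells are flagged, never fabricated. The
swap identity $(1 + pc_{fwd}/100)(1 + pc_{rev}/100) = 1$ is asserted in
tests — percent change is not antisymmetric, and this is the correct
invariant under exchanging the two treatments.

K content is dry weight (mg/plant) x concentration (g/kg) x $10^{-3}$
(mg/plant). The utilization-efficiency index defaults to the
squared-biomass form $KUE = DW^2 / K\text{-content}$ (mg² DW per ug K) —
the only form consistent with the units printed alongside such traits —
with the simple ratio $DW/K$ behind `formula = "ratio"` because the
primary sources leave the constant factors in supplementary material.
Population means of such products are not products of population means,
so per-genotype computation before averaging is assumed throughout.

# OPLS-DA and VIP

The metabolite screen regresses a preprocessed intensity matrix against a
centered ±1 class vector. Preprocessing defaults to `log(x+1)` then unit
variance scaling with mean centering — standard for MS intensities,
bounding the influence of high-abundance features; Pareto scaling is
available. Orthogonal components (default 1) are estimated
Trygg–Wold-style: the class-predictive weight vector is computed, the
loading's component orthogonal to it extracted, and that variation
deflated from X before the final one-component predictive fit. With a
single response the NIPALS weight vector has the closed form
$w \propto X^T y$, so the fit is exact, deterministic, and needs no
iteration or convergence tolerance.

VIP uses the predictive component only (the common OPLS-DA convention;
orthogonal variation is by construction class-irrelevant):
$VIP_j = \sqrt{p}\,|w_j|$ for a single component, which makes
$\mathrm{mean}(VIP^2) = 1$ an exact identity — asserted to 1e-6 on every
fit. The differential gate is VIP ≥ 1 together with raw-scale
fold-change ≥ 2 or ≤ 0.5; fold change is a ratio of raw group means, so
an 8-fold induction reads as 8.

`permutation_check()` refits under shuffled labels. Note a small-n
caveat: at 3 samples/group with hundreds of features a one-component
latent fit can track *any* labeling (permuted R2Y stays high); the
diagnostic is informative once samples outnumber what a single component
can fit by chance, and the test suite exercises it at 10/group.

# Differential-gene set algebra

`call_directions()` applies the gate |log2FC| ≥ 1 and p < 0.05 (both
configurable). The boundary is *included* by default — method statements
of this screen conventionally write "≥" while result narrations write
">"; we follow the methods convention and expose
`include_boundary = FALSE`. Raw p-values are the default (`adjust =
"none"`) to match the screen as practiced; BH adjustment is a flag away.
Genes absent from one contrast are treated as unchanged there, with a
reported count. `venn_partition()` builds the full 3 x 3 direction-pair
table (its cells always sum to the gene universe) and the six Venn
counts; `select_pattern_genes()` returns the union of the
(up, down), (up, unchanged) and (unchanged, down) patterns — genes
induced or maintained in the tolerant genotype while repressed or silent
in the sensitive one — the set this kind of study carries into
enrichment analysis.

# Numerical and testing choices

- Problem sizes in the test suite: full-size 543-genotype panels for
  recovery (medians over 20 seeds), 150-metabolite matrices over 50
  seeds for screen sensitivity/FDP, 10,000-gene tables over 100 seeds
  against brute-force enumeration oracles. The oracles (SVD-based PCA,
  closed-form one-component PLS, per-pair set enumeration) are
  independent code paths living in the test helpers.
- All generators take explicit seeds and restore the caller's RNG state;
  the pipeline derives per-stage substreams from one global seed so
  stages can be rerun independently.
- Degenerate inputs fail loudly with named culprits: zero-variance
  traits, zero control means, max = min components, all-equal D, empty
  universes.
- The run manifest records every defaulted parameter and every
  convention choice (sign fix, percentile type, boundary rule, KUE form,
  scaling) so a run is reproducible from the manifest plus inputs.

# Limitations

Headline counts from any particular study (total differential
transcripts or metabolites, exact class sizes, cumulative contribution
percentages) depend on raw data that is not redistributable at this
scale; the package validates the *machinery* on synthetic ground truth
and on the published elemental-concentration worked example it ships as
a fixture. The comprehensive evaluation inherits the method's own
dilution of signal across variance-ranked components; users screening
real panels should treat class boundaries as soft and prefer the D
ranking (and cross-stage consensus) over single-run class membership for
borderline genotypes.
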