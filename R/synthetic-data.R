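# Synthetic-data generators for every pipeline input. Each generator emits
# the data together with a ground-truth object (never mixed into the data)
# so downstream stages can be validated by parameter recovery.

#' Default trait descriptors for a seedling-stage low-K panel
#'
#' Thirteen K-utilization-efficiency-related seedling traits with control
#' means, control coefficients of variation, the direction of the low-K
#' response, and the population-mean LK/CK ratio. Values reflect the scale
#' of typical hydroponic wheat seedling panels: growth and K-accumulation
#' traits shrink under low K while the two utilization-efficiency indices
#' (biomass per unit plant K) rise.
#'
#' @param ratio_dispersion Genotype-to-genotype dispersion of the LK/CK
#'   ratio (sd of the multiplicative spread; default 0.15).
#' @return Data frame with columns `name`, `control_mean`, `control_cv`,
#'   `direction`, `mean_ratio`, `ratio_dispersion`.
#' @export
default_lowk_traits <- function(ratio_dispersion = 0.15) {
  d <- data.frame(
    name = c("LL", "LA", "SL", "SDW", "RDW", "TDW", "RSDW",
             "SKCe", "RKCe", "SKC", "RKC", "SKUE", "RKUE"),
    control_mean = c(13.07, 2.99, 18.01, 21.36, 11.35, 32.41, 0.53,
                     24.44, 7.72, 1.02, 0.08, 0.99, 1.95),
    control_cv = c(32.46, 36.67, 26.71, 27.09, 33.20, 26.25, 30.00,
                   34.31, 51.89, 46.02, 53.79, 50.33, 65.50),
    direction = c("decrease", "decrease", "decrease", "decrease",
                  "decrease", "decrease", "increase", "decrease",
                  "decrease", "decrease", "decrease", "increase",
                  "increase"),
    mean_ratio = c(0.781, 0.699, 0.827, 0.806, 0.809, 0.814, 1.00,
                   0.284, 0.395, 0.275, 0.375, 2.636, 1.805),
    stringsAsFactors = FALSE
  )
  d$ratio_dispersion <- ratio_dispersion
  d
}

#' Specification for a synthetic trait panel
#'
#' @param n_genotypes Number of genotypes (default 543, the size of a large
#'   germplasm panel).
#' @param traits Trait descriptor data frame (see [default_lowk_traits()]).
#' @param n_replicates Replicates per genotype x treatment (default 3, a
#'   completely randomized design with three replicates).
#' @param tolerance_loading Per-trait weight in `[-1, 1]` (recycled from a
#'   scalar) linking the latent tolerance score to the genotype's LK/CK
#'   ratio: `ratio(g, t) = mean_ratio_t * (1 + loading_t *
#'   ratio_dispersion_t * z_g)`, clipped below at 0.01.
#' @param noise_sd Replicate noise sd as a fraction of the genotype's
#'   control mean (default 0.10); noise is Gaussian on the measurement
#'   scale, truncated at 0.
#' @param tiers Optional list with `sizes` (integer vector summing to
#'   `n_genotypes`) and optionally `means` / `sd`, planting discrete
#'   tolerance tiers in the latent score instead of a standard normal.
#'   Defaults when only `sizes` is given: equally spaced tier means
#'   descending from `1.5 * (k - 1)` to 0 in steps of 1.5, within-tier
#'   sd 0.2 (widely separated tiers, so recovery failures indicate a
#'   pipeline defect rather than sampling overlap).
#' @param seed Integer RNG seed.
#' @return Object of class `trait_gen_spec`.
#' @export
trait_gen_spec <- function(n_genotypes = 543, traits = default_lowk_traits(),
                           n_replicates = 3, tolerance_loading = 0.8,
                           noise_sd = 0.10, tiers = NULL, seed = 1) {
  if (n_genotypes < 1) stop_ktscreen("n_genotypes must be >= 1")
  if (n_replicates < 1) stop_ktscreen("n_replicates must be >= 1")
  if (any(traits$control_mean <= 0)) {
    stop_ktscreen("control means must be positive")
  }
  if (any(traits$mean_ratio <= 0)) {
    stop_ktscreen("mean LK/CK ratios must be positive")
  }
  if (noise_sd < 0) stop_ktscreen("noise_sd must be nonnegative")
  loading <- rep_len(tolerance_loading, nrow(traits))
  if (any(abs(loading) > 1)) {
    stop_ktscreen("tolerance_loading must lie in [-1, 1]")
  }
  if (!is.null(tiers)) {
    if (sum(tiers$sizes) != n_genotypes) {
      stop_ktscreen("tier sizes must sum to n_genotypes")
    }
    k <- length(tiers$sizes)
    # tiers exist to make recovery unambiguous by construction: spacing of
    # 7.5 within-tier sd keeps adjacent tiers separated even at the order
    # statistics of a 543-genotype panel
    tiers$means <- tiers$means %||% (1.5 * (k - seq_len(k)))
    tiers$sd <- tiers$sd %||% 0.2
  }
  structure(
    list(n_genotypes = as.integer(n_genotypes), traits = traits,
         n_replicates = as.integer(n_replicates),
         tolerance_loading = loading, noise_sd = noise_sd,
         tiers = tiers, seed = as.integer(seed)),
    class = "trait_gen_spec"
  )
}

#' Generate a synthetic trait panel with known tolerance structure
#'
#' Draws a latent tolerance score per genotype (standard normal, or tiered
#' when the spec plants tiers), maps it to per-trait LK/CK ratios through
#' the affine link in [trait_gen_spec()], and emits replicate-level CK and
#' LK measurements with Gaussian noise truncated at zero. Identical specs
#' (including seed) give bitwise-identical output.
#'
#' @param spec A [trait_gen_spec()].
#' @return List with `panel` (a [trait_panel()]) and `truth` (data frame
#'   `genotype`, `latent_tolerance`, and `tier` when tiers were planted;
#'   plus attribute-free `ratios` matrix genotypes x traits of the
#'   noise-free planted LK/CK ratios).
#' @export
generate_trait_panel <- function(spec) {
  stopifnot(inherits(spec, "trait_gen_spec"))
  with_seed(spec$seed, {
    n_g <- spec$n_genotypes
    genotypes <- sprintf("G%04d", seq_len(n_g))
    if (is.null(spec$tiers)) {
      z <- stats::rnorm(n_g)
      tier <- NULL
    } else {
      tier <- rep(seq_along(spec$tiers$sizes), spec$tiers$sizes)
      z <- stats::rnorm(n_g, mean = spec$tiers$means[tier],
                        sd = spec$tiers$sd)
    }

    tr <- spec$traits
    n_t <- nrow(tr)
    # planted noise-free LK/CK ratio per genotype x trait
    ratios <- outer(z, seq_len(n_t), function(zz, j) {
      pmax(tr$mean_ratio[j] *
             (1 + spec$tolerance_loading[j] * tr$ratio_dispersion[j] * zz),
           0.01)
    })
    dimnames(ratios) <- list(genotypes, tr$name)

    # genotype-level control baselines: the population control CV is mostly
    # genuine genotype variation, which cancels in the LK/CK ratio
    baseline <- outer(seq_len(n_g), seq_len(n_t), function(i, j) {
      tr$control_mean[j]
    }) * pmax(1 + stats::rnorm(n_g * n_t) *
                rep(tr$control_cv / 100, each = n_g), 0.05)
    dimnames(baseline) <- list(genotypes, tr$name)

    n_r <- spec$n_replicates
    grid <- expand.grid(
      replicate = seq_len(n_r), treatment = c("CK", "LK"),
      trait = tr$name, genotype = genotypes,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    trait_idx <- match(grid$trait, tr$name)
    geno_idx <- match(grid$genotype, genotypes)
    base_gt <- baseline[cbind(geno_idx, trait_idx)]
    mu <- ifelse(grid$treatment == "CK", base_gt,
                 base_gt * ratios[cbind(geno_idx, trait_idx)])
    sdv <- spec$noise_sd * base_gt
    value <- pmax(stats::rnorm(nrow(grid), mean = mu, sd = sdv), 0)
    panel <- trait_panel(data.frame(
      genotype = grid$genotype, trait = grid$trait,
      treatment = grid$treatment, replicate = grid$replicate,
      value = value, stringsAsFactors = FALSE
    ))
    truth <- data.frame(genotype = genotypes, latent_tolerance = z,
                        stringsAsFactors = FALSE)
    if (!is.null(tier)) truth$tier <- tier
    list(panel = panel, truth = truth, ratios = ratios)
  })
}

#' Generate a synthetic ionome table
#'
#' Control concentrations are drawn from a log-normal spread around
#' per-element baseline levels; the low-K concentration is the control value
#' times the supplied multiplicative effect.
#'
#' @param elements Character vector of element names (defaults to the ten
#'   macro- and micronutrients N, P, K, Ca, Mg, Na, Fe, Mn, Cu, Zn).
#' @param tissues,genotypes Character vectors (defaults: shoot/root and two
#'   genotypes).
#' @param effect_map Either a single positive number applied everywhere, or
#'   a data frame with columns `tissue`, `genotype`, `element`, `effect`
#'   supplying the LK/CK multiplier per cell (missing cells default to 1).
#' @param baseline Optional named vector of control-level means per element;
#'   defaults to typical shoot concentrations.
#' @param cv Log-scale spread of the control draw (default 0.2).
#' @param seed Integer RNG seed.
#' @return A long ionome data frame (see [read_ionome_table()]) plus a
#'   `truth` attribute holding the effect map actually applied.
#' @export
generate_ionome_table <- function(elements = IONOME_ELEMENTS,
                                  tissues = c("Shoot", "Root"),
                                  genotypes = c("G1", "G2"),
                                  effect_map = 1, baseline = NULL, cv = 0.2,
                                  seed = 1) {
  base_default <- c(N = 26, P = 8, K = 28, Ca = 4, Mg = 1.7, Na = 2.6,
                    Fe = 12, Mn = 9, Cu = 3, Zn = 32)
  baseline <- baseline %||% base_default[elements]
  baseline[is.na(baseline)] <- 10
  names(baseline) <- elements

  grid <- expand.grid(tissue = tissues, genotype = genotypes,
                      element = elements, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  if (is.data.frame(effect_map)) {
    key <- function(d) paste(d$tissue, d$genotype, d$element, sep = "\r")
    eff <- effect_map$effect[match(key(grid), key(effect_map))]
    eff[is.na(eff)] <- 1
  } else {
    eff <- rep_len(effect_map, nrow(grid))
  }
  if (any(eff <= 0)) stop_ktscreen("LK effects must be positive multipliers")

  with_seed(seed, {
    ck <- baseline[grid$element] *
      stats::rlnorm(nrow(grid), meanlog = 0, sdlog = cv)
    lk <- ck * eff
    unit <- unname(IONOME_UNITS[grid$element])
    unit[is.na(unit)] <- "g/kg"
    out <- rbind(
      data.frame(tissue = grid$tissue, treatment = "CK",
                 genotype = grid$genotype, element = grid$element,
                 concentration = ck, unit = unit, stringsAsFactors = FALSE),
      data.frame(tissue = grid$tissue, treatment = "LK",
                 genotype = grid$genotype, element = grid$element,
                 concentration = lk, unit = unit, stringsAsFactors = FALSE)
    )
    rownames(out) <- NULL
    attr(out, "truth") <- cbind(grid, effect = eff)
    out
  })
}

#' Generate a synthetic two-class metabolite intensity matrix
#'
#' Log-normal intensities with a planted group shift on the log scale for a
#' chosen subset of features, so the planted fold change is exact in
#' expectation. Planted fold changes are drawn uniformly from `fc_range`
#' and inverted (1/FC) with probability 1/2 so both induced and repressed
#' metabolites occur.
#'
#' @param n_samples_per_group Samples per class (>= 2; default 3).
#' @param n_features Number of metabolites (default 200).
#' @param n_differential Number of planted differential features
#'   (default 20).
#' @param fc_range Range the planted fold changes are drawn from; must not
#'   overlap the (0.5, 2) non-differential band (default `c(2, 8)`).
#' @param noise_sdlog Log-scale replicate noise sd (default 0.2).
#' @param seed Integer RNG seed.
#' @return List with `matrix` (samples x metabolites), `groups` (factor
#'   CK/LK), and `truth` (data frame `metabolite`, `true_fc` for the
#'   planted features).
#' @export
generate_metabolite_matrix <- function(n_samples_per_group = 3,
                                       n_features = 200,
                                       n_differential = 20,
                                       fc_range = c(2, 8),
                                       noise_sdlog = 0.2, seed = 1) {
  if (n_samples_per_group < 2) {
    stop_ktscreen("need >= 2 samples per group (the discriminant fit is ",
                  "undefined below that)")
  }
  if (n_differential > n_features) {
    stop_ktscreen("n_differential cannot exceed n_features")
  }
  if (n_differential > 0 &&
      !(all(fc_range >= 2) || all(fc_range <= 0.5))) {
    stop_ktscreen("fc_range must avoid the (0.5, 2) non-differential band")
  }
  with_seed(seed, {
    ids <- sprintf("M%04d", seq_len(n_features))
    base_log <- stats::rnorm(n_features, mean = log(1e5), sd = 1)
    planted <- if (n_differential > 0) {
      sort(sample(n_features, n_differential))
    } else {
      integer(0)
    }
    fc <- rep(1, n_features)
    if (n_differential > 0) {
      mag <- stats::runif(n_differential, fc_range[1], fc_range[2])
      flip <- stats::runif(n_differential) < 0.5
      fc[planted] <- ifelse(flip, 1 / mag, mag)
    }
    n <- 2 * n_samples_per_group
    groups <- factor(rep(c("CK", "LK"), each = n_samples_per_group),
                     levels = c("CK", "LK"))
    mean_log <- matrix(base_log, n, n_features, byrow = TRUE)
    mean_log[groups == "LK", ] <- sweep(
      mean_log[groups == "LK", , drop = FALSE], 2, log(fc), "+"
    )
    mat <- exp(mean_log + matrix(stats::rnorm(n * n_features,
                                              sd = noise_sdlog),
                                 n, n_features))
    dimnames(mat) <- list(paste0(groups, rep(seq_len(n_samples_per_group),
                                             2)), ids)
    truth <- data.frame(metabolite = ids[planted], true_fc = fc[planted],
                        stringsAsFactors = FALSE)
    list(matrix = mat, groups = groups, truth = truth)
  })
}

#' Generate paired synthetic differential-gene tables
#'
#' Draws a direction pattern (up/down/unchanged in contrast A, same in
#' contrast B) per gene from `pattern_probabilities` and emits two per-gene
#' statistics tables whose log2 fold-changes and p-values are consistent
#' with the planted pattern under the default thresholds: changed genes get
#' `|log2fc|` in `lfc_range` and p uniform on `[0, 0.04]`; unchanged genes
#' get `|log2fc| < 0.5` and p uniform on `[0.1, 1]`.
#'
#' @param n_genes Number of genes (default 10000).
#' @param pattern_probabilities Numeric 3 x 3 matrix (rows = contrast A
#'   direction up/down/unchanged, columns = contrast B) or length-9 vector
#'   in row-major order; must sum to 1 (tolerance 1e-9).
#' @param lfc_range Range of the planted absolute log2 fold-change for
#'   changed genes (default `c(1.5, 4)`).
#' @param seed Integer RNG seed.
#' @return List with `table_a`, `table_b` (data frames gene / log2fc /
#'   pvalue) and `truth` (data frame `gene`, `pattern_a`, `pattern_b`).
#' @export
generate_deg_table <- function(n_genes = 10000,
                               pattern_probabilities = NULL,
                               lfc_range = c(1.5, 4), seed = 1) {
  if (is.null(pattern_probabilities)) {
    pattern_probabilities <- matrix(
      c(0.02, 0.01, 0.03,
        0.01, 0.03, 0.03,
        0.02, 0.04, 0.81), 3, 3, byrow = TRUE
    )
  }
  p <- as.numeric(pattern_probabilities)
  if (length(p) != 9) {
    stop_ktscreen("pattern_probabilities must have 9 entries")
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop_ktscreen("pattern probabilities must sum to 1 (got ", sum(p), ")")
  }
  if (any(p < 0)) stop_ktscreen("pattern probabilities must be nonnegative")
  pat_mat <- matrix(p, 3, 3,
                    dimnames = list(DIRECTIONS, DIRECTIONS))
  pairs <- expand.grid(a = DIRECTIONS, b = DIRECTIONS,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  probs <- pat_mat[cbind(pairs$a, pairs$b)]

  with_seed(seed, {
    ids <- sprintf("gene%05d", seq_len(n_genes))
    draw <- sample(nrow(pairs), n_genes, replace = TRUE, prob = probs)
    simulate_contrast <- function(direction) {
      changed <- direction != "unchanged"
      lfc <- stats::runif(n_genes, -0.5 + 1e-6, 0.5 - 1e-6)
      mag <- stats::runif(n_genes, lfc_range[1], lfc_range[2])
      lfc[direction == "up"] <- mag[direction == "up"]
      lfc[direction == "down"] <- -mag[direction == "down"]
      pval <- ifelse(changed, stats::runif(n_genes, 0, 0.04),
                     stats::runif(n_genes, 0.1, 1))
      data.frame(gene = ids, log2fc = lfc, pvalue = pval,
                 stringsAsFactors = FALSE)
    }
    truth <- data.frame(gene = ids, pattern_a = pairs$a[draw],
                        pattern_b = pairs$b[draw], stringsAsFactors = FALSE)
    list(table_a = simulate_contrast(truth$pattern_a),
         table_b = simulate_contrast(truth$pattern_b),
         truth = truth)
  })
}
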