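#' Descriptive statistics per trait and treatment
#'
#' Summarizes a trait panel across genotypes: for each trait x treatment cell
#' the mean, maximum, minimum, standard deviation (n - 1 denominator) and
#' coefficient of variation (CV% = 100 * SD / mean) of the genotype-level
#' means. This mirrors the descriptive tables conventionally reported for
#' germplasm panels under control and stress treatments.
#'
#' @param panel A [trait_panel()].
#' @param trait_order Optional character vector fixing the row order of
#'   traits; defaults to order of first appearance.
#' @return A data frame with columns `trait`, `treatment`, `mean`, `max`,
#'   `min`, `sd`, `cv`. A zero mean yields `NA` CV with a warning.
#' @export
summarize_traits <- function(panel, trait_order = NULL) {
  panel <- trait_panel(panel)
  gm <- genotype_means(panel)
  if (is.null(trait_order)) trait_order <- unique(panel$trait)

  split_key <- interaction(gm$trait, gm$treatment, drop = TRUE)
  rows <- lapply(split(gm, split_key), function(cell) {
    if (length(unique(cell$genotype)) < 2) {
      stop_ktscreen(
        "summarize_traits needs >= 2 genotypes for trait '",
        cell$trait[1], "' under ", cell$treatment[1]
      )
    }
    m <- mean(cell$value)
    s <- stats::sd(cell$value)
    cv <- if (m == 0) NA_real_ else 100 * s / m
    data.frame(
      trait = cell$trait[1], treatment = cell$treatment[1],
      mean = m, max = max(cell$value), min = min(cell$value),
      sd = s, cv = cv
    )
  })
  out <- do.call(rbind, rows)
  if (anyNA(out$cv)) {
    warning("CV undefined (zero mean) for some trait/treatment cells",
            call. = FALSE)
  }
  out <- out[order(match(out$trait, trait_order), out$treatment), ]
  rownames(out) <- NULL
  out
}

#' Low-K tolerance coefficients
#'
#' For each genotype and trait, the tolerance coefficient is the ratio of the
#' mean measured value under low-K stress to the mean measured value under
#' control conditions. Replicate means are taken per genotype first; the
#' ratio is then formed from the two means.
#'
#' @param panel A [trait_panel()] in which every genotype has both CK and LK
#'   observations for every trait.
#' @return A numeric matrix (genotypes x traits) of class
#'   `tolerance_coefficients`, with genotype row names and trait column names.
#' @examples
#' spec <- trait_gen_spec(n_genotypes = 5, seed = 1)
#' panel <- generate_trait_panel(spec)$panel
#' coef <- tolerance_coefficients(panel)
#' @export
tolerance_coefficients <- function(panel) {
  panel <- trait_panel(panel)
  gm <- genotype_means(panel)
  genotypes <- unique(gm$genotype)
  traits <- unique(gm$trait)

  ck <- gm[gm$treatment == "CK", ]
  lk <- gm[gm$treatment == "LK", ]
  key <- function(d) paste(d$genotype, d$trait, sep = "\r")
  ck_map <- stats::setNames(ck$value, key(ck))
  lk_map <- stats::setNames(lk$value, key(lk))

  out <- matrix(NA_real_, nrow = length(genotypes), ncol = length(traits),
                dimnames = list(genotypes, traits))
  for (g in genotypes) {
    for (t in traits) {
      k <- paste(g, t, sep = "\r")
      ck_v <- unname(ck_map[k])
      lk_v <- unname(lk_map[k])
      if (is.na(ck_v) || is.na(lk_v)) {
        stop_ktscreen(
          "missing CK or LK mean for genotype '", g, "', trait '", t, "'"
        )
      }
      if (ck_v == 0) {
        stop_ktscreen(
          "control mean is zero for genotype '", g, "', trait '", t,
          "': tolerance coefficient undefined"
        )
      }
      out[g, t] <- lk_v / ck_v
    }
  }
  class(out) <- c("tolerance_coefficients", class(out))
  out
}

#' Principal-component comprehensive indices
#'
#' Standardizes the tolerance-coefficient matrix (zero mean, unit variance
#' per trait over genotypes), eigen-decomposes the trait correlation matrix,
#' and projects genotypes onto the retained components. Each retained
#' component is a "comprehensive index"; its contribution rate is
#' `100 * eigenvalue / sum(eigenvalues)`.
#'
#' Component signs are fixed so that the largest-magnitude element of every
#' loading vector is positive. The downstream membership step is not
#' sign-invariant, so a deterministic convention is required; this one makes
#' the dominant trait load positively on its component.
#'
#' @param coef A genotypes x traits matrix of tolerance coefficients.
#' @param retention Retention rule: `"kaiser"` keeps components with
#'   eigenvalue > 1; `"cumulative"` keeps the smallest leading set whose
#'   cumulative contribution reaches `cum_threshold`.
#' @param cum_threshold Cumulative contribution (%) for
#'   `retention = "cumulative"`.
#' @param n_components Optional integer overriding the retention rule.
#' @return An object of class `comprehensive_pca`: a list with `loadings`
#'   (traits x n), `scores` (genotypes x n), `eigenvalues`, `contribution`
#'   (% per retained component), `cumulative` (% summed over retained
#'   components), `n_components`, and `retention`.
#' @export
comprehensive_pca <- function(coef, retention = c("kaiser", "cumulative"),
                              cum_threshold = 85, n_components = NULL) {
  retention <- match.arg(retention)
  x <- unclass(coef)
  if (!is.matrix(x) || ncol(x) < 2) {
    stop_ktscreen("comprehensive_pca needs a matrix with >= 2 traits")
  }
  if (anyNA(x)) {
    dropped <- rownames(x)[apply(x, 1, anyNA)]
    warning(
      "dropping ", length(dropped),
      " genotype(s) with missing coefficients: ",
      paste(utils::head(dropped, 5), collapse = ", "),
      if (length(dropped) > 5) ", ..." else "",
      call. = FALSE
    )
    x <- x[!apply(x, 1, anyNA), , drop = FALSE]
  }
  if (nrow(x) <= ncol(x)) {
    warning("fewer genotypes than traits + 1; PCA may be unstable",
            call. = FALSE)
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop_ktscreen(
      "constant trait column(s): ",
      paste(colnames(x)[sds == 0], collapse = ", ")
    )
  }

  z <- scale(x, center = TRUE, scale = TRUE)
  ev <- eigen(stats::cor(x), symmetric = TRUE)
  values <- ev$values
  vectors <- ev$vectors
  # sign convention: dominant loading element positive per component; ties
  # in magnitude broken by first index, with a tolerance so the choice is
  # stable across numerically equivalent decompositions
  for (j in seq_len(ncol(vectors))) {
    dom <- which(abs(vectors[, j]) >= max(abs(vectors[, j])) - 1e-8)[1]
    if (vectors[dom, j] < 0) vectors[, j] <- -vectors[, j]
  }

  contribution_all <- 100 * values / sum(values)
  n <- if (!is.null(n_components)) {
    as.integer(n_components)
  } else if (retention == "kaiser") {
    max(1L, sum(values > 1))
  } else {
    which(cumsum(contribution_all) >= cum_threshold - 1e-9)[1]
  }
  if (is.na(n) || n < 1 || n > ncol(x)) {
    stop_ktscreen("invalid number of retained components: ", n)
  }

  loadings <- vectors[, seq_len(n), drop = FALSE]
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(n)))
  scores <- z %*% loadings
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(n)))

  structure(
    list(
      loadings = loadings,
      scores = scores,
      eigenvalues = values,
      contribution = contribution_all[seq_len(n)],
      contribution_all = contribution_all,
      cumulative = sum(contribution_all[seq_len(n)]),
      n_components = n,
      retention = if (!is.null(n_components)) "fixed" else retention
    ),
    class = "comprehensive_pca"
  )
}

#' @export
print.comprehensive_pca <- function(x, ...) {
  cat("Comprehensive PCA:", nrow(x$scores), "genotypes,",
      nrow(x$loadings), "traits\n")
  cat("Retained", x$n_components, "component(s) [", x$retention, "rule ]\n")
  cat("Contribution rates (%):",
      paste(sprintf("%.2f", x$contribution), collapse = ", "), "\n")
  cat(sprintf("Cumulative contribution: %.2f%%\n", x$cumulative))
  invisible(x)
}

#' Fuzzy membership values of comprehensive indices
#'
#' Min-max rescaling of each comprehensive index over genotypes:
#' `U(g, j) = (X_j(g) - min_j) / (max_j - min_j)`, so the genotype attaining
#' a component's minimum maps to 0 and the maximum to 1.
#'
#' @param scores A genotypes x components numeric matrix of comprehensive
#'   indices (e.g. `comprehensive_pca(...)$scores`).
#' @return A matrix of the same shape with entries in `[0, 1]`.
#' @export
membership <- function(scores) {
  scores <- as.matrix(scores)
  rng <- apply(scores, 2, range)
  span <- rng[2, ] - rng[1, ]
  if (any(span == 0)) {
    stop_ktscreen(
      "degenerate component(s) with max = min: ",
      paste(colnames(scores)[span == 0] %||% which(span == 0),
            collapse = ", ")
    )
  }
  sweep(sweep(scores, 2, rng[1, ], "-"), 2, span, "/")
}

#' Contribution-rate weights
#'
#' Normalizes the retained components' contribution rates to weights summing
#' to one: `W_j = P_j / sum(P)`.
#'
#' @param contribution Positive contribution rates (%) of the retained
#'   components.
#' @return A numeric weight vector summing to 1.
#' @examples
#' contribution_weights(c(24.21, 21.85, 17.27, 16.53, 9.83))
#' @export
contribution_weights <- function(contribution) {
  if (length(contribution) == 0 || any(!is.finite(contribution)) ||
      any(contribution <= 0)) {
    stop_ktscreen("contribution rates must be positive and non-empty")
  }
  contribution / sum(contribution)
}

#' Comprehensive tolerance evaluation value (D)
#'
#' The weighted sum of membership values over retained components:
#' `D(g) = sum_j U(g, j) * W_j`. Higher D means more tolerant. Because each
#' U column lies in `[0, 1]` and the weights sum to 1, D lies in `[0, 1]`.
#'
#' @param U Membership matrix from [membership()].
#' @param w Weights from [contribution_weights()]; length must equal
#'   `ncol(U)`.
#' @return Named numeric vector of per-genotype D values.
#' @export
d_value <- function(U, w) {
  U <- as.matrix(U)
  if (ncol(U) != length(w)) {
    stop_ktscreen(
      "dimension mismatch: ", ncol(U), " membership columns vs ",
      length(w), " weights"
    )
  }
  drop(U %*% w)
}

#' Full comprehensive evaluation of a trait panel
#'
#' Convenience wrapper chaining [tolerance_coefficients()],
#' [comprehensive_pca()], [membership()], [contribution_weights()] and
#' [d_value()].
#'
#' @inheritParams comprehensive_pca
#' @param panel A [trait_panel()].
#' @return An object of class `comprehensive_evaluation`: list with `coef`,
#'   `pca`, `U`, `weights`, `D`.
#' @export
evaluate_tolerance <- function(panel, retention = "kaiser",
                               cum_threshold = 85, n_components = NULL) {
  coef <- tolerance_coefficients(panel)
  pca <- comprehensive_pca(coef, retention = retention,
                           cum_threshold = cum_threshold,
                           n_components = n_components)
  U <- membership(pca$scores)
  w <- contribution_weights(pca$contribution)
  D <- d_value(U, w)
  structure(
    list(coef = coef, pca = pca, U = U, weights = w, D = D),
    class = "comprehensive_evaluation"
  )
}

#' @export
print.comprehensive_evaluation <- function(x, ...) {
  print(x$pca)
  cat(sprintf("D values: n = %d, mean = %.3f, range = [%.3f, %.3f]\n",
              length(x$D), mean(x$D), min(x$D), max(x$D)))
  invisible(x)
}

#' Classify genotypes into tolerance classes
#'
#' Hierarchical agglomerative clustering of the one-dimensional D values
#' (Euclidean distance), cut at `k` clusters. Clusters are labeled by
#' descending mean D: tolerant, moderately tolerant, moderately sensitive,
#' sensitive (for `k = 4`; `"class_i"` labels otherwise).
#'
#' @param D Named numeric vector of D values.
#' @param k Number of classes (default 4).
#' @param method Agglomeration method passed to [stats::hclust()]
#'   (`"average"` emulates common statistical-package defaults;
#'   `"ward.D2"` available).
#' @return Object of class `tolerance_classification`: list with
#'   `class` (named factor, levels ordered tolerant first), `counts`,
#'   `class_means`, `k`, `method`.
#' @export
classify_tolerance <- function(D, k = 4, method = c("average", "ward.D2")) {
  method <- match.arg(method)
  if (k > length(D)) {
    stop_ktscreen("k = ", k, " exceeds the number of genotypes (", length(D), ")")
  }
  if (stats::sd(D) == 0) {
    stop_ktscreen("all D values identical: classification is degenerate")
  }
  hc <- stats::hclust(stats::dist(D), method = method)
  raw <- stats::cutree(hc, k = k)
  cluster_means <- tapply(D, raw, mean)
  ord <- order(cluster_means, decreasing = TRUE)
  labels <- if (k == 4) {
    c("tolerant", "moderately tolerant", "moderately sensitive", "sensitive")
  } else {
    paste0("class_", seq_len(k))
  }
  relabel <- stats::setNames(labels, names(cluster_means)[ord])
  cls <- factor(relabel[as.character(raw)], levels = labels)
  names(cls) <- names(D)
  structure(
    list(
      class = cls,
      counts = table(cls),
      class_means = stats::setNames(as.numeric(cluster_means[ord]), labels),
      k = k,
      method = method
    ),
    class = "tolerance_classification"
  )
}

#' @export
print.tolerance_classification <- function(x, ...) {
  cat("Tolerance classification (k =", x$k, ", linkage =", x$method, ")\n")
  out <- data.frame(
    class = names(x$class_means),
    n = as.integer(x$counts[names(x$class_means)]),
    mean_D = round(x$class_means, 3)
  )
  print(out, row.names = FALSE)
  invisible(x)
}

#' Select extreme genotypes by D-value percentile
#'
#' Returns the genotypes strictly above the upper percentile and strictly
#' below the lower percentile of the empirical D distribution (type-7
#' quantiles, the linear-interpolation default).
#'
#' @param D Named numeric vector of D values.
#' @param upper_pct,lower_pct Percentile cutoffs (defaults 99 and 1).
#' @return List with character vectors `tolerant` and `sensitive`.
#' @export
select_extremes <- function(D, upper_pct = 99, lower_pct = 1) {
  if (upper_pct <= lower_pct) {
    stop_ktscreen("upper_pct must exceed lower_pct")
  }
  if (length(D) < 100) {
    warning("percentile selection on fewer than 100 genotypes is coarse",
            call. = FALSE)
  }
  hi <- stats::quantile(D, upper_pct / 100, type = 7, names = FALSE)
  lo <- stats::quantile(D, lower_pct / 100, type = 7, names = FALSE)
  list(
    tolerant = names(D)[D > hi],
    sensitive = names(D)[D < lo]
  )
}

#' Cross-stage consensus of extreme genotypes
#'
#' Given per-stage selections (e.g. seedling and mature stage), returns the
#' genotypes selected in at least `min_stages` stages, with per-stage
#' membership flags.
#'
#' @param selections Named list of character vectors, one per stage.
#' @param min_stages Minimum number of stages (default 2).
#' @return Data frame with columns `genotype`, one logical column per stage,
#'   `n_stages`, filtered to `n_stages >= min_stages`; ordered by decreasing
#'   `n_stages` then genotype.
#' @examples
#' cross_stage_consensus(list(seedling = c("A", "B"), mature = c("B", "C")))
#' @export
cross_stage_consensus <- function(selections, min_stages = 2) {
  if (length(selections) < 2) {
    stop_ktscreen("need selections from >= 2 stages")
  }
  if (is.null(names(selections))) {
    names(selections) <- paste0("stage", seq_along(selections))
  }
  universe <- sort(unique(unlist(selections)))
  flags <- vapply(selections, function(s) universe %in% s,
                  logical(length(universe)))
  flags <- matrix(flags, nrow = length(universe),
                  dimnames = list(NULL, names(selections)))
  n_stages <- rowSums(flags)
  out <- data.frame(genotype = universe, flags, n_stages = n_stages,
                    check.names = FALSE)
  out <- out[out$n_stages >= min_stages, , drop = FALSE]
  out <- out[order(-out$n_stages, out$genotype), , drop = FALSE]
  rownames(out) <- NULL
  out
}
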