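# Orthogonal projections to latent structures discriminant analysis
# (OPLS-DA) with VIP scoring, implemented from first principles.
#
# The model regresses a preprocessed intensity matrix X against a centered
# +/-1 class vector y. Orthogonal (class-uncorrelated) components are
# stripped from X first; a single predictive component is then fitted to the
# filtered matrix. With a single response vector the NIPALS weight vector is
# available in closed form (w proportional to X'y), so the fit is exact and
# deterministic -- no iterative refinement is needed.

#' Fit an OPLS-DA model
#'
#' Preprocessing (recorded in the returned model): optional log transform
#' (`log(x + 1)`, appropriate for nonnegative MS intensities), mean
#' centering, then unit-variance or Pareto scaling of each metabolite
#' column. The class vector is coded +1 / -1 and centered.
#'
#' @param x Numeric samples x metabolites matrix (nonnegative intensities).
#' @param groups Factor or vector with exactly two levels giving the class
#'   of each row; each class needs >= 2 samples.
#' @param n_orthogonal Number of orthogonal components to remove before the
#'   predictive fit (default 1; 0 gives a one-component PLS-DA).
#' @param scale Column scaling: `"uv"` (unit variance, default) or
#'   `"pareto"` (square-root of the standard deviation).
#' @param log_transform Apply `log(x + 1)` first (default `TRUE`).
#' @return Object of class `oplsda`: list with `scores` / `loadings` /
#'   `weights` for the predictive component, `ortho_scores` /
#'   `ortho_loadings` / `ortho_weights` matrices (0 columns when
#'   `n_orthogonal = 0`), `vip` (per metabolite), `r2y` (fraction of class
#'   variance explained by the predictive component), `groups`, `levels`,
#'   and a `preprocess` record.
#' @examples
#' sim <- generate_metabolite_matrix(n_samples_per_group = 3,
#'                                   n_features = 30, n_differential = 3,
#'                                   seed = 1)
#' fit <- fit_oplsda(sim$matrix, sim$groups)
#' head(sort(fit$vip, decreasing = TRUE))
#' @export
fit_oplsda <- function(x, groups, n_orthogonal = 1,
                       scale = c("uv", "pareto"), log_transform = TRUE) {
  scale <- match.arg(scale)
  x <- as.matrix(x)
  groups <- factor(groups)
  if (nlevels(groups) != 2) {
    stop_ktscreen("OPLS-DA requires exactly two classes; got ",
                  nlevels(groups))
  }
  if (any(table(groups) < 2)) {
    stop_ktscreen("each class needs >= 2 samples")
  }
  if (n_orthogonal < 0) stop_ktscreen("n_orthogonal must be >= 0")
  rank_bound <- min(nrow(x) - 1, ncol(x))
  if (n_orthogonal >= rank_bound) {
    stop_ktscreen("n_orthogonal = ", n_orthogonal,
                  " leaves no predictive variation for a matrix of rank <= ",
                  rank_bound)
  }

  xp <- if (log_transform) log1p(x) else x
  centers <- colMeans(xp)
  sds <- apply(xp, 2, stats::sd)
  scales <- switch(scale, uv = sds, pareto = sqrt(sds))
  scales[scales == 0] <- 1  # constant columns carry no information
  xs <- sweep(sweep(xp, 2, centers, "-"), 2, scales, "/")

  y <- ifelse(groups == levels(groups)[2], 1, -1)
  yc <- y - mean(y)

  p_feat <- ncol(xs)
  ortho_w <- matrix(0, p_feat, 0)
  ortho_p <- matrix(0, p_feat, 0)
  ortho_t <- matrix(0, nrow(xs), 0)
  xf <- xs
  for (a in seq_len(n_orthogonal)) {
    w <- drop(crossprod(xf, yc)) / sum(yc^2)
    w <- w / sqrt(sum(w^2))
    t_pred <- drop(xf %*% w)
    p_load <- drop(crossprod(xf, t_pred)) / sum(t_pred^2)
    wo <- p_load - drop(crossprod(w, p_load)) * w
    nrm <- sqrt(sum(wo^2))
    if (nrm < 1e-12) break  # no orthogonal variation left
    wo <- wo / nrm
    to <- drop(xf %*% wo)
    po <- drop(crossprod(xf, to)) / sum(to^2)
    xf <- xf - tcrossprod(to, po)
    ortho_w <- cbind(ortho_w, wo)
    ortho_p <- cbind(ortho_p, po)
    ortho_t <- cbind(ortho_t, to)
  }

  w <- drop(crossprod(xf, yc)) / sum(yc^2)
  wn <- sqrt(sum(w^2))
  if (wn < 1e-12) {
    stop_ktscreen("degenerate model: no class-predictive variation")
  }
  w <- w / wn
  t_pred <- drop(xf %*% w)
  p_load <- drop(crossprod(xf, t_pred)) / sum(t_pred^2)
  q <- sum(yc * t_pred) / sum(t_pred^2)
  r2y <- sum((t_pred * q)^2) / sum(yc^2)

  names(w) <- colnames(x)
  vip <- sqrt(p_feat) * abs(w)  # single predictive component

  structure(
    list(
      weights = w, scores = t_pred, loadings = p_load, q = q,
      ortho_weights = ortho_w, ortho_scores = ortho_t,
      ortho_loadings = ortho_p,
      n_orthogonal = ncol(ortho_t),
      vip = vip, r2y = r2y,
      groups = groups, levels = levels(groups),
      preprocess = list(log_transform = log_transform, scale = scale,
                        centers = centers, scales = scales)
    ),
    class = "oplsda"
  )
}

#' @export
print.oplsda <- function(x, ...) {
  cat("OPLS-DA:", length(x$scores), "samples x", length(x$vip),
      "metabolites\n")
  cat("1 predictive +", x$n_orthogonal, "orthogonal component(s)\n")
  cat(sprintf("R2Y (predictive) = %.3f\n", x$r2y))
  invisible(x)
}

#' Variable importance in projection
#'
#' VIP scores of a fitted model:
#' `VIP_j = sqrt(p * sum_a w_ja^2 SSY_a / sum_a SSY_a)` over the predictive
#' component(s), where `p` is the metabolite count and `SSY_a` the class
#' variance explained by component `a`. With a single predictive component
#' this reduces to `sqrt(p) * |w_j|`, and the mean of the squared VIPs is
#' exactly 1 (the usual normalization gated at VIP >= 1).
#'
#' @param model A fitted [fit_oplsda()] model.
#' @return Named numeric vector of VIP scores.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "oplsda"))
  if (model$r2y <= 0) {
    stop_ktscreen("degenerate model: zero explained class variance")
  }
  model$vip
}

#' Fold change of group means
#'
#' `FC = mean(treated) / mean(control)` on the raw intensity scale, matching
#' the convention in which an 8-fold induction is reported as FC = 8 and a
#' halving as FC = 0.5.
#'
#' @param x Samples x metabolites intensity matrix.
#' @param groups Two-class vector for the rows of `x`.
#' @param control Level of `groups` to use as the denominator (default: the
#'   first level).
#' @return Named numeric vector of fold changes; a zero control mean yields
#'   `Inf` with a warning.
#' @export
fold_change <- function(x, groups, control = NULL) {
  x <- as.matrix(x)
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop_ktscreen("fold_change requires two groups")
  control <- control %||% levels(groups)[1]
  if (!control %in% levels(groups)) {
    stop_ktscreen("control level '", control, "' not found")
  }
  treated <- setdiff(levels(groups), control)
  m_ctrl <- colMeans(x[groups == control, , drop = FALSE])
  m_trt <- colMeans(x[groups == treated, , drop = FALSE])
  if (any(m_ctrl == 0)) {
    warning("zero control mean for some metabolites: infinite fold change",
            call. = FALSE)
  }
  fc <- m_trt / m_ctrl
  names(fc) <- colnames(x)
  fc
}

#' Screen metabolites by VIP and fold change
#'
#' Applies the differential-metabolite gate: a metabolite is called `"up"`
#' when `FC >= fc_up` and `VIP >= vip_threshold`, `"down"` when
#' `FC <= fc_down` and `VIP >= vip_threshold`, otherwise
#' `"not-differential"`.
#'
#' @param vip Named VIP vector (or a fitted `oplsda` model).
#' @param fc Named fold-change vector over the same metabolites.
#' @param vip_threshold VIP gate (default 1).
#' @param fc_up,fc_down Fold-change gates (defaults 2 and 0.5).
#' @param annotation Optional named character vector mapping metabolite ids
#'   to compound classes (amino acid, lipid, ...); adds per-class direction
#'   counts to the result.
#' @return Object of class `metabolite_screen`: list with `table` (data
#'   frame: metabolite, fc, vip, verdict), `counts` (up/down totals), and
#'   `class_counts` when an annotation is supplied.
#' @export
screen_metabolites <- function(vip, fc, vip_threshold = 1, fc_up = 2,
                               fc_down = 0.5, annotation = NULL) {
  if (inherits(vip, "oplsda")) vip <- vip_scores(vip)
  ids <- names(vip) %||% as.character(seq_along(vip))
  if (!is.null(names(fc))) {
    if (!setequal(ids, names(fc))) {
      stop_ktscreen("VIP and fold-change metabolite sets differ")
    }
    fc <- fc[ids]
  }
  verdict <- ifelse(vip >= vip_threshold & fc >= fc_up, "up",
                    ifelse(vip >= vip_threshold & fc <= fc_down, "down",
                           "not-differential"))
  tab <- data.frame(metabolite = ids, fc = unname(fc), vip = unname(vip),
                    verdict = verdict, stringsAsFactors = FALSE)
  counts <- c(up = sum(verdict == "up"), down = sum(verdict == "down"),
              `not-differential` = sum(verdict == "not-differential"))
  res <- list(table = tab, counts = counts)
  if (!is.null(annotation)) {
    tab$class <- unname(annotation[tab$metabolite])
    res$table <- tab
    diff_tab <- tab[tab$verdict != "not-differential", ]
    res$class_counts <- table(class = diff_tab$class,
                              verdict = diff_tab$verdict)
  }
  class(res) <- "metabolite_screen"
  res
}

#' @export
print.metabolite_screen <- function(x, ...) {
  cat("Metabolite screen:", nrow(x$table), "metabolites;",
      x$counts["up"], "up,", x$counts["down"], "down\n")
  invisible(x)
}

#' Permutation diagnostic for an OPLS-DA fit
#'
#' Refits the model under random permutations of the class labels and
#' returns the predictive R2Y of each permuted fit. For a real class
#' structure the permuted R2Y values should fall well below the observed
#' one.
#'
#' @param x,groups,n_orthogonal,scale,log_transform As in [fit_oplsda()].
#' @param n_perm Number of permutations (default 100).
#' @param seed RNG seed.
#' @return List with `observed` R2Y and the vector `permuted`.
#' @export
permutation_check <- function(x, groups, n_orthogonal = 0, n_perm = 100,
                              scale = "uv", log_transform = TRUE, seed = 1) {
  observed <- fit_oplsda(x, groups, n_orthogonal, scale, log_transform)$r2y
  permuted <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      g <- sample(groups)
      while (length(unique(g)) < 2 || min(table(g)) < 2) g <- sample(groups)
      tryCatch(
        fit_oplsda(x, g, n_orthogonal, scale, log_transform)$r2y,
        error = function(e) 0
      )
    }, numeric(1))
  })
  list(observed = observed, permuted = permuted)
}
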