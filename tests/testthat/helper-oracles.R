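# Independent brute-force oracles. These deliberately take different code
# paths from the package implementation so that agreement is evidence, not
# tautology.

# PCA oracle via SVD of the standardized matrix (the package uses
# eigen() on the correlation matrix).
oracle_pca <- function(x, n_components) {
  z <- scale(x, center = TRUE, scale = TRUE)
  sv <- svd(z)
  values <- sv$d^2 / (nrow(x) - 1)
  vectors <- sv$v
  for (j in seq_len(ncol(vectors))) {
    dom <- which(abs(vectors[, j]) >= max(abs(vectors[, j])) - 1e-8)[1]
    if (vectors[dom, j] < 0) vectors[, j] <- -vectors[, j]
  }
  list(
    eigenvalues = values,
    contribution = 100 * values / sum(values),
    scores = z %*% vectors[, seq_len(n_components), drop = FALSE]
  )
}

# One-component PLS-DA with VIP, written straight from the defining
# equations on the preprocessed matrix.
oracle_pls1 <- function(x, groups, scale = "uv", log_transform = TRUE) {
  xp <- if (log_transform) log1p(x) else x
  s <- apply(xp, 2, sd)
  s <- switch(scale, uv = s, pareto = sqrt(s))
  s[s == 0] <- 1
  xs <- sweep(sweep(xp, 2, colMeans(xp), "-"), 2, s, "/")
  y <- ifelse(groups == levels(factor(groups))[2], 1, -1)
  yc <- y - mean(y)
  w <- unname(drop(t(xs) %*% yc))
  w <- w / sqrt(sum(w^2))
  t1 <- drop(xs %*% w)
  q <- sum(yc * t1) / sum(t1^2)
  ssy_total <- sum(yc^2)
  ssy_expl <- sum((t1 * q)^2)
  p <- ncol(x)
  # single component: the SSY weighting collapses
  vip <- sqrt(p * w^2 * ssy_expl / ssy_expl)
  list(weights = w, scores = t1, r2y = ssy_expl / ssy_total, vip = vip)
}

# Venn partition by explicit per-gene enumeration.
oracle_venn <- function(dir_a, dir_b) {
  stopifnot(length(dir_a) == length(dir_b))
  counts <- c(up_only_a = 0, up_only_b = 0, up_common = 0,
              down_only_a = 0, down_only_b = 0, down_common = 0)
  tab <- matrix(0L, 3, 3, dimnames = list(c("up", "down", "unchanged"),
                                          c("up", "down", "unchanged")))
  for (i in seq_along(dir_a)) {
    a <- dir_a[i]; b <- dir_b[i]
    tab[a, b] <- tab[a, b] + 1L
    if (a == "up" && b == "up") counts["up_common"] <- counts["up_common"] + 1
    if (a == "up" && b != "up") counts["up_only_a"] <- counts["up_only_a"] + 1
    if (b == "up" && a != "up") counts["up_only_b"] <- counts["up_only_b"] + 1
    if (a == "down" && b == "down") counts["down_common"] <- counts["down_common"] + 1
    if (a == "down" && b != "down") counts["down_only_a"] <- counts["down_only_a"] + 1
    if (b == "down" && a != "down") counts["down_only_b"] <- counts["down_only_b"] + 1
  }
  list(venn = counts, table = tab)
}

# Same enumeration, vectorized over the nine direction pairs (for large
# inputs where the per-gene loop is too slow).
oracle_venn_fast <- function(dir_a, dir_b) {
  venn <- c(
    up_only_a = sum(dir_a == "up" & dir_b != "up"),
    up_only_b = sum(dir_b == "up" & dir_a != "up"),
    up_common = sum(dir_a == "up" & dir_b == "up"),
    down_only_a = sum(dir_a == "down" & dir_b != "down"),
    down_only_b = sum(dir_b == "down" & dir_a != "down"),
    down_common = sum(dir_a == "down" & dir_b == "down")
  )
  list(venn = venn)
}

oracle_pattern_fast <- function(genes, dir_a, dir_b) {
  keep <- (dir_a == "up" & dir_b == "down") |
    (dir_a == "up" & dir_b == "unchanged") |
    (dir_a == "unchanged" & dir_b == "down")
  sort(genes[keep])
}

# Pattern selection by explicit set comprehension.
oracle_pattern <- function(genes, dir_a, dir_b) {
  sel <- character(0)
  for (i in seq_along(genes)) {
    a <- dir_a[i]; b <- dir_b[i]
    if ((a == "up" && b == "down") || (a == "up" && b == "unchanged") ||
        (a == "unchanged" && b == "down")) {
      sel <- c(sel, genes[i])
    }
  }
  sort(sel)
}

# Small handmade trait panel: two genotypes, one trait, exact means.
tiny_panel <- function() {
  trait_panel(data.frame(
    genotype = rep(c("A", "B"), each = 4),
    trait = "SL",
    treatment = rep(c("CK", "CK", "LK", "LK"), 2),
    replicate = rep(1:2, 4),
    value = c(10, 10, 8, 8, 20, 20, 10, 10)
  ))
}

ionome_fixture_path <- function() {
  system.file("extdata", "wheat_ionome_contrast.csv", package = "ktscreen")
}
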