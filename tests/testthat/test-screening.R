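test_that("trait summaries use the n-1 denominator and CV% = 100*SD/mean", {
  panel <- trait_panel(data.frame(
    genotype = c("A", "B"), trait = "SL", treatment = "CK",
    replicate = 1L, value = c(8, 12)
  ))
  s <- summarize_traits(panel)
  expect_equal(s$mean, 10)
  expect_equal(s$sd, sqrt(8), tolerance = 1e-12)
  expect_equal(s$cv, 100 * sqrt(8) / 10, tolerance = 1e-12)

  flat <- trait_panel(data.frame(
    genotype = c("A", "B", "C"), trait = "SL", treatment = "CK",
    replicate = 1L, value = 10
  ))
  s2 <- summarize_traits(flat)
  expect_equal(s2$sd, 0)
  expect_equal(s2$cv, 0)
})

test_that("a panel matching published SL control statistics reproduces its CV", {
  # mean 18.01, SD 4.81 -> CV 26.71% from its own numbers
  expect_equal(round(100 * 4.81 / 18.01, 2), 26.71)
  # two-point panel with exactly that mean and SD
  delta <- 4.81 / sqrt(2)
  panel <- trait_panel(data.frame(
    genotype = c("A", "B"), trait = "SL", treatment = "CK",
    replicate = 1L, value = c(18.01 - delta, 18.01 + delta)
  ))
  s <- summarize_traits(panel)
  expect_equal(s$cv, 100 * 4.81 / 18.01, tolerance = 1e-10)
})

test_that("tolerance coefficients are LK mean over CK mean, replicates first", {
  coef <- tolerance_coefficients(tiny_panel())
  expect_equal(coef["A", "SL"], 0.8)
  expect_equal(coef["B", "SL"], 0.5)

  # population pseudo-genotype from published means: 14.89 / 18.01
  pseudo <- trait_panel(data.frame(
    genotype = "pop", trait = "SL", treatment = c("CK", "LK"),
    replicate = 1L, value = c(18.01, 14.89)
  ))
  expect_equal(unclass(tolerance_coefficients(pseudo))[1, 1],
               14.89 / 18.01, tolerance = 1e-12)
  # coefficients above 1 are legitimate (utilization-efficiency traits)
  expect_gt(2.61 / 0.99, 1)

  zero_ck <- trait_panel(data.frame(
    genotype = "A", trait = "SL", treatment = c("CK", "LK"),
    replicate = 1L, value = c(0, 1)
  ))
  expect_error(tolerance_coefficients(zero_ck), "genotype 'A'.*'SL'")
  missing_lk <- trait_panel(data.frame(
    genotype = "A", trait = "SL", treatment = "CK",
    replicate = 1L, value = 1
  ))
  expect_error(tolerance_coefficients(missing_lk), "missing")
})

test_that("comprehensive PCA agrees with an SVD oracle on random matrices", {
  set.seed(101)
  for (i in 1:10) {
    n <- sample(8:20, 1)
    p <- sample(3:7, 1)
    x <- matrix(rexp(n * p, rate = 1), n, p,
                dimnames = list(paste0("g", 1:n), paste0("t", 1:p)))
    fit <- comprehensive_pca(x, n_components = p)
    orc <- oracle_pca(x, p)
    expect_equal(fit$eigenvalues, orc$eigenvalues, tolerance = 1e-8)
    expect_equal(fit$contribution, orc$contribution[1:p], tolerance = 1e-8)
    expect_equal(unname(fit$scores), unname(orc$scores), tolerance = 1e-8)
  }
})

test_that("PCA degenerate and structured cases behave as the model implies", {
  # two perfectly correlated traits: first component carries everything
  x <- cbind(t1 = c(1, 2, 3, 4, 5), t2 = 2 * c(1, 2, 3, 4, 5) + 3)
  fit <- comprehensive_pca(x, n_components = 2)
  expect_equal(fit$contribution[1], 100, tolerance = 1e-8)
  expect_equal(fit$n_components, 2)

  # near-identity correlation: contributions approach 100/p
  set.seed(7)
  xi <- matrix(rnorm(4000 * 4), ncol = 4)
  fi <- comprehensive_pca(xi, n_components = 4)
  expect_true(all(abs(fi$contribution - 25) < 5))

  const <- cbind(a = c(1, 1, 1), b = c(1, 2, 3))
  expect_error(comprehensive_pca(const), "constant trait")
})

test_that("membership maps min to 0, max to 1, midpoint to 0.5, affine-invariantly", {
  scores <- cbind(c(0, 5, 10), c(-2, 0, 6))
  U <- membership(scores)
  expect_equal(U[, 1], c(0, 0.5, 1))
  expect_equal(U[1, 2], 0)
  expect_equal(U[3, 2], 1)
  expect_true(all(U >= 0 & U <= 1))
  # affine transforms of a component leave U unchanged
  U2 <- membership(cbind(3 * scores[, 1] + 7, scores[, 2] / 2 - 1))
  expect_equal(U, U2, tolerance = 1e-12)
  expect_error(membership(cbind(c(1, 1, 1))), "degenerate")
})

test_that("weights normalize contribution rates; D is their weighted sum", {
  expect_equal(contribution_weights(c(30, 30, 30)), rep(1 / 3, 3))
  expect_equal(contribution_weights(42), 1)
  expect_error(contribution_weights(numeric(0)), "positive")
  expect_error(contribution_weights(c(10, -1)), "positive")

  expect_equal(d_value(cbind(0.2, 0.4), c(0.5, 0.5)), 0.3)
  expect_equal(d_value(cbind(1, 1, 1), rep(1 / 3, 3)), 1)
  expect_equal(d_value(cbind(0, 0), c(0.4, 0.6)), 0)
  expect_error(d_value(cbind(1, 1), c(1)), "mismatch")
})

test_that("D respects dominance: componentwise larger membership gives larger D", {
  set.seed(33)
  for (i in 1:200) {
    k <- sample(2:6, 1)
    w <- contribution_weights(runif(k, 1, 40))
    ua <- runif(k)
    ub <- pmin(ua + runif(k, 0, 0.5), 1)  # ub dominates ua
    expect_gte(d_value(rbind(ub), w), d_value(rbind(ua), w))
  }
})

test_that("classification recovers well-separated groups and orders class means", {
  D <- c(rep(0.9, 5), rep(0.7, 8), rep(0.4, 10), rep(0.1, 7))
  names(D) <- paste0("g", seq_along(D))
  cl <- classify_tolerance(D)
  expect_equal(as.integer(cl$counts), c(5, 8, 10, 7))
  expect_true(all(diff(cl$class_means) < 0))
  expect_true(all(cl$class[1:5] == "tolerant"))
  expect_true(all(cl$class[24:30] == "sensitive"))

  expect_error(classify_tolerance(rep(0.5, 10)), "degenerate")
  expect_error(classify_tolerance(c(a = 0.1, b = 0.2), k = 4), "exceeds")
})

test_that("percentile extremes follow the type-7 convention with strict inequality", {
  D <- seq_len(100) / 100
  names(D) <- paste0("g", 1:100)
  sel <- suppressWarnings(select_extremes(D, 99, 1))
  hi <- quantile(D, 0.99, type = 7, names = FALSE)
  lo <- quantile(D, 0.01, type = 7, names = FALSE)
  expect_setequal(sel$tolerant, names(D)[D > hi])
  expect_setequal(sel$sensitive, names(D)[D < lo])
  expect_equal(sel$tolerant, "g100")

  # n = 543 at the 99th percentile returns at most ceiling(543 * 0.01)
  set.seed(12)
  D543 <- runif(543)
  names(D543) <- paste0("g", 1:543)
  sel543 <- select_extremes(D543, 99, 1)
  expect_lte(length(sel543$tolerant), ceiling(543 * 0.01))

  expect_equal(suppressWarnings(select_extremes(D, 99, 0))$sensitive,
               character(0))
  expect_error(select_extremes(D, 50, 60), "exceed")
})

test_that("cross-stage consensus intersects per-stage selections", {
  cons <- cross_stage_consensus(list(seedling = c("A", "B"),
                                     mature = c("B", "C")))
  expect_equal(cons$genotype, "B")
  expect_true(cons$seedling[1] && cons$mature[1])

  empty <- cross_stage_consensus(list(s = c("A"), m = c("B")))
  expect_equal(nrow(empty), 0)
  expect_error(cross_stage_consensus(list(s = "A")), ">= 2 stages")

  # published-style fixture: two genotypes flagged at both stages
  seedling <- c("Kenong9204", "Henong6119", "Han6172", "Jimai38", "Heng7228")
  mature <- c("Kenong9204", "Henong6119", "Cangmai119", "Henong2552",
              "Henong9204")
  both <- cross_stage_consensus(list(seedling = seedling, mature = mature))
  expect_setequal(both$genotype, c("Kenong9204", "Henong6119"))
})

test_that("pipeline outputs are invariant to genotype row order", {
  spec <- trait_gen_spec(n_genotypes = 40, seed = 21)
  panel <- generate_trait_panel(spec)$panel
  ev1 <- evaluate_tolerance(panel)
  perm <- sample(nrow(panel))
  ev2 <- evaluate_tolerance(panel[perm, ])
  expect_equal(ev1$D[sort(names(ev1$D))], ev2$D[sort(names(ev2$D))],
               tolerance = 1e-10)
})
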