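test_that("with no orthogonal components the fit equals the one-component PLS oracle", {
  set.seed(51)
  for (i in 1:5) {
    x <- matrix(rlnorm(6 * 20, meanlog = 8, sdlog = 1), 6, 20,
                dimnames = list(NULL, paste0("m", 1:20)))
    groups <- factor(rep(c("CK", "LK"), each = 3))
    fit <- fit_oplsda(x, groups, n_orthogonal = 0)
    orc <- oracle_pls1(x, groups)
    expect_equal(unname(fit$weights), orc$weights, tolerance = 1e-8)
    expect_equal(fit$scores, orc$scores, tolerance = 1e-8)
    expect_equal(fit$r2y, orc$r2y, tolerance = 1e-8)
    expect_equal(unname(fit$vip), unname(orc$vip), tolerance = 1e-8)
  }
})

test_that("VIP normalization and score orthogonality hold on every fit", {
  set.seed(52)
  for (i in 1:10) {
    n_per <- sample(3:5, 1)
    p <- sample(15:40, 1)
    n_orth <- sample(0:2, 1)
    x <- matrix(rlnorm(2 * n_per * p, meanlog = 8), 2 * n_per, p)
    groups <- factor(rep(c("CK", "LK"), each = n_per))
    fit <- fit_oplsda(x, groups, n_orthogonal = n_orth)
    expect_equal(mean(vip_scores(fit)^2), 1, tolerance = 1e-6)
    if (ncol(fit$ortho_scores) > 0) {
      for (j in seq_len(ncol(fit$ortho_scores))) {
        expect_lt(abs(sum(fit$scores * fit$ortho_scores[, j])) /
                    (sqrt(sum(fit$scores^2)) *
                       sqrt(sum(fit$ortho_scores[, j]^2))), 1e-8)
      }
    }
  }
})

test_that("VIP degenerate cases follow the normalization identity", {
  # p = 1: VIP is exactly 1
  set.seed(53)
  x1 <- matrix(c(rlnorm(3, 5), rlnorm(3, 7)), ncol = 1)
  fit1 <- fit_oplsda(x1, rep(c("CK", "LK"), each = 3), n_orthogonal = 0)
  expect_equal(unname(fit1$vip), 1, tolerance = 1e-12)

  # perfectly symmetric informative features share equal VIP = 1
  base <- c(1, 1, 1, 3, 3, 3)
  x_eq <- cbind(a = base, b = base, c = base) *
    matrix(1 + rnorm(18, sd = 1e-6), 6, 3)
  fit_eq <- fit_oplsda(x_eq, rep(c("CK", "LK"), each = 3), n_orthogonal = 0,
                       log_transform = FALSE)
  expect_equal(unname(fit_eq$vip), rep(1, 3), tolerance = 1e-3)
})

test_that("class-label permutation collapses the explained class variance", {
  # enough samples per group that a single latent component cannot fit
  # arbitrary labels by chance
  sim <- generate_metabolite_matrix(n_samples_per_group = 10,
                                    n_features = 20, n_differential = 5,
                                    fc_range = c(3, 6), noise_sdlog = 0.3,
                                    seed = 15)
  pc <- permutation_check(sim$matrix, sim$groups, n_orthogonal = 0,
                          n_perm = 50, seed = 16)
  expect_gt(pc$observed, 0.9)
  expect_lt(mean(pc$permuted), pc$observed / 2)
})

test_that("fold change is a ratio of raw group means with reciprocal symmetry", {
  x <- rbind(matrix(2, 3, 4), matrix(6, 3, 4))
  colnames(x) <- paste0("m", 1:4)
  g <- rep(c("CK", "LK"), each = 3)
  expect_equal(unname(fold_change(x, g)), rep(3, 4))
  expect_equal(unname(fold_change(x, g, control = "LK")), rep(1 / 3, 4))
  expect_equal(unname(fold_change(x[, 1, drop = FALSE] * 0 + 5, g)), 1)
  x0 <- x; x0[1:3, 1] <- 0
  expect_warning(fc0 <- fold_change(x0, g), "zero control")
  expect_equal(unname(fc0[1]), Inf)
})

test_that("the screen gate combines VIP and fold-change thresholds", {
  vip <- c(a = 1.5, b = 1.2, c = 0.9, d = 1.1)
  fc <- c(a = 7.12, b = 0.47, c = 3.0, d = 1.2)
  res <- screen_metabolites(vip, fc)
  expect_equal(res$table$verdict, c("up", "down", "not-differential",
                                    "not-differential"))
  expect_equal(unname(res$counts["up"]), 1L)

  ann <- c(a = "amino acid", b = "amino acid", c = "lipid", d = "lipid")
  res2 <- screen_metabolites(vip, fc, annotation = ann)
  expect_equal(sum(res2$class_counts), 2)
  expect_error(screen_metabolites(vip, fc[1:3]), "differ")
})

test_that("no planted differentials gives an (almost) empty screen", {
  sim <- generate_metabolite_matrix(n_samples_per_group = 3,
                                    n_features = 150, n_differential = 0,
                                    noise_sdlog = 0.2, seed = 31)
  fit <- fit_oplsda(sim$matrix, sim$groups)
  fc <- fold_change(sim$matrix, sim$groups)
  res <- screen_metabolites(fit, fc)
  fpr <- sum(res$counts[c("up", "down")]) / 150
  expect_lte(fpr, 0.02)
})

test_that("degenerate inputs are rejected with clear messages", {
  x <- matrix(rlnorm(12 * 5), 12, 5)
  expect_error(fit_oplsda(x, rep("CK", 12)), "two classes")
  expect_error(fit_oplsda(x[1:4, ], c("CK", "CK", "CK", "LK")),
               ">= 2 samples")
  expect_error(fit_oplsda(x[1:6, ], rep(c("CK", "LK"), each = 3),
                          n_orthogonal = 10), "predictive variation")
})
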