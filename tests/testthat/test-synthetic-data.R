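test_that("zero noise and zero loading give the exact planted ratio", {
  traits <- default_lowk_traits()
  traits$mean_ratio <- 0.8
  spec <- trait_gen_spec(n_genotypes = 10, traits = traits,
                         tolerance_loading = 0, noise_sd = 0, seed = 42)
  coef <- tolerance_coefficients(generate_trait_panel(spec)$panel)
  expect_true(all(abs(coef - 0.8) < 1e-12))
})

test_that("trait panel has full factorial structure and is seed-deterministic", {
  spec <- trait_gen_spec(n_genotypes = 25, n_replicates = 3, seed = 1)
  g1 <- generate_trait_panel(spec)
  g2 <- generate_trait_panel(spec)
  expect_identical(g1, g2)
  expect_equal(nrow(g1$panel), 25 * 13 * 2 * 3)
  counts <- table(g1$panel$genotype, g1$panel$treatment)
  expect_true(all(counts == 13 * 3))
  # different seed changes the draw
  g3 <- generate_trait_panel(trait_gen_spec(n_genotypes = 25, seed = 2))
  expect_false(identical(g1$panel$value, g3$panel$value))
})

test_that("latent tolerance drives the genotype-mean LK/CK ratio", {
  traits <- default_lowk_traits()
  dec <- traits$direction == "decrease"
  loading <- ifelse(dec, 0.9, 0)
  spec <- trait_gen_spec(n_genotypes = 150, traits = traits,
                         tolerance_loading = loading, noise_sd = 0.10,
                         seed = 11)
  g <- generate_trait_panel(spec)
  coef <- tolerance_coefficients(g$panel)
  mean_ratio <- rowMeans(coef[, dec])
  rho <- cor(g$truth$latent_tolerance, mean_ratio, method = "spearman")
  expect_gte(rho, 0.8)
})

test_that("trait generator rejects invalid specifications", {
  bad <- default_lowk_traits()
  bad$control_mean[1] <- -1
  expect_error(trait_gen_spec(traits = bad), "positive")
  expect_error(trait_gen_spec(n_replicates = 0), "n_replicates")
  expect_error(trait_gen_spec(tolerance_loading = 1.5), "\\[-1, 1\\]")
  expect_error(trait_gen_spec(n_genotypes = 10,
                              tiers = list(sizes = c(5, 4))), "sum")
})

test_that("ionome generator plants exact multiplicative effects", {
  null_tab <- generate_ionome_table(effect_map = 1, seed = 3)
  pc <- percent_change(null_tab)
  expect_true(all(abs(pc$pct_change) < 1e-12))

  eff <- data.frame(tissue = "Shoot", genotype = "G1", element = "K",
                    effect = 0.5)
  tab <- generate_ionome_table(effect_map = eff, seed = 3)
  pc <- percent_change(tab)
  hit <- pc[pc$tissue == "Shoot" & pc$genotype == "G1" & pc$element == "K", ]
  expect_equal(hit$pct_change, -50)
  expect_true(all(abs(pc$pct_change[!(pc$tissue == "Shoot" &
                                        pc$genotype == "G1" &
                                        pc$element == "K")]) < 1e-12))
  expect_error(generate_ionome_table(effect_map = -1), "positive")
})

test_that("metabolite generator plants recoverable fold changes", {
  sim <- generate_metabolite_matrix(n_samples_per_group = 3,
                                    n_features = 50, n_differential = 5,
                                    fc_range = c(4, 8), noise_sdlog = 0.05,
                                    seed = 9)
  expect_identical(sim, generate_metabolite_matrix(
    n_samples_per_group = 3, n_features = 50, n_differential = 5,
    fc_range = c(4, 8), noise_sdlog = 0.05, seed = 9))
  expect_true(all(sim$truth$metabolite %in% colnames(sim$matrix)))
  fc <- fold_change(sim$matrix, sim$groups)
  est <- fc[sim$truth$metabolite]
  expect_true(all(abs(log2(est) - log2(sim$truth$true_fc)) < 0.5))
  expect_error(generate_metabolite_matrix(n_samples_per_group = 1),
               ">= 2 samples")
  expect_error(generate_metabolite_matrix(fc_range = c(0.8, 1.5)),
               "band")
})

test_that("single strong planted metabolite attains the maximum VIP", {
  sim <- generate_metabolite_matrix(n_samples_per_group = 3,
                                    n_features = 40, n_differential = 1,
                                    fc_range = c(8, 8), noise_sdlog = 0.05,
                                    seed = 4)
  fit <- fit_oplsda(sim$matrix, sim$groups, n_orthogonal = 0)
  expect_equal(names(which.max(fit$vip)), sim$truth$metabolite)
})

test_that("DEG generator respects pattern probabilities and thresholds", {
  # all mass on (unchanged, unchanged): both screens empty
  p0 <- matrix(0, 3, 3); p0[3, 3] <- 1
  sim <- generate_deg_table(n_genes = 500, pattern_probabilities = p0,
                            seed = 2)
  ca <- call_directions(sim$table_a)
  cb <- call_directions(sim$table_b)
  expect_true(all(ca$direction == "unchanged"))
  expect_true(all(cb$direction == "unchanged"))

  # planted (up, down) pattern recovered exactly
  p1 <- matrix(0, 3, 3); p1[1, 2] <- 0.2; p1[3, 3] <- 0.8
  sim <- generate_deg_table(n_genes = 1000, pattern_probabilities = p1,
                            seed = 5)
  ca <- call_directions(sim$table_a)
  cb <- call_directions(sim$table_b)
  planted <- sim$truth$gene[sim$truth$pattern_a == "up"]
  sel <- select_pattern_genes(ca, cb)
  expect_setequal(sel$genes, planted)

  expect_error(generate_deg_table(pattern_probabilities = rep(0.2, 9)),
               "sum to 1")
})

test_that("venn partition of planted patterns equals the planted draw", {
  sim <- generate_deg_table(n_genes = 3000, seed = 7)
  v <- venn_partition(call_directions(sim$table_a),
                      call_directions(sim$table_b))
  truth_tab <- table(factor(sim$truth$pattern_a,
                            c("up", "down", "unchanged")),
                     factor(sim$truth$pattern_b,
                            c("up", "down", "unchanged")))
  expect_equal(unclass(v$table), unclass(truth_tab),
               ignore_attr = TRUE)
})
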