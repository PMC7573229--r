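# End-to-end orchestration: synthetic generation -> screening -> ionome ->
# metabolite screen -> DEG screen, with a run manifest and a markdown
# report. All outputs are plain CSV/JSON/markdown for diffability.

#' Default pipeline configuration
#'
#' Every tunable parameter of every stage, with its default. Unknown keys in
#' a user-supplied configuration are rejected; every defaulted value is
#' echoed into the run manifest so no decision is silent.
#'
#' @return Named list of stage parameter lists.
#' @export
default_config <- function() {
  list(
    stages = c("synthetic", "screening", "ionome", "metabolites", "degs"),
    screening = list(
      n_genotypes = 543L, n_replicates = 3L, tolerance_loading = 0.8,
      noise_sd = 0.10, tier_sizes = c(7L, 50L, 238L, 248L),
      retention = "kaiser", k = 4L, cluster_method = "average",
      upper_pct = 99, lower_pct = 1
    ),
    ionome = list(contrast = c("G1", "G2")),
    metabolites = list(
      n_samples_per_group = 3L, n_features = 200L, n_differential = 20L,
      fc_range = c(2, 8), noise_sdlog = 0.2, n_orthogonal = 1L,
      scale = "uv", vip_threshold = 1, fc_up = 2, fc_down = 0.5
    ),
    degs = list(n_genes = 10000L, lfc = 1, alpha = 0.05,
                include_boundary = TRUE, adjust = "none")
  )
}

merge_config <- function(user, defaults) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop_ktscreen("unknown configuration key(s): ",
                  paste(unknown, collapse = ", "))
  }
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(user[[k]]) && is.list(defaults[[k]])) {
      merge_config(user[[k]], defaults[[k]])
    } else {
      user[[k]]
    }
  }
  defaults
}

#' Run the full synthetic-demo pipeline
#'
#' Generates all inputs with the synthetic module, runs every analysis
#' stage, and writes CSV artifacts, a JSON manifest (configuration, package
#' version, per-stage decisions, seeds) and a markdown report into
#' `out_dir`. A single global seed fans out to per-stage substreams so each
#' stage can be rerun independently with stable results.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Global integer seed (default 1).
#' @param config Optional configuration: a named list overriding
#'   [default_config()] entries, or a path to a YAML file with the same
#'   structure.
#' @return Invisibly, a list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(out_dir, seed = 1, config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(config, default_config())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()

  if ("screening" %in% cfg$stages || "synthetic" %in% cfg$stages) {
    sc <- cfg$screening
    spec <- trait_gen_spec(
      n_genotypes = sc$n_genotypes, n_replicates = sc$n_replicates,
      tolerance_loading = sc$tolerance_loading, noise_sd = sc$noise_sd,
      tiers = if (!is.null(sc$tier_sizes)) list(sizes = sc$tier_sizes),
      seed = derive_seed(seed, 1L)
    )
    gen <- generate_trait_panel(spec)
    write_trait_panel(gen$panel, file.path(out_dir, "trait_panel.csv"))
    utils::write.csv(gen$truth, file.path(out_dir, "trait_truth.csv"),
                     row.names = FALSE)

    eval_res <- evaluate_tolerance(gen$panel, retention = sc$retention)
    cls <- classify_tolerance(eval_res$D, k = sc$k,
                              method = sc$cluster_method)
    extremes <- select_extremes(eval_res$D, sc$upper_pct, sc$lower_pct)
    ev_out <- data.frame(
      genotype = rownames(eval_res$U), eval_res$pca$scores, eval_res$U,
      D = eval_res$D, class = as.character(cls$class),
      check.names = FALSE
    )
    names(ev_out) <- c("genotype",
                       paste0("X", seq_len(ncol(eval_res$pca$scores))),
                       paste0("U", seq_len(ncol(eval_res$U))), "D", "class")
    utils::write.csv(ev_out, file.path(out_dir, "evaluation.csv"),
                     row.names = FALSE)
    results$screening <- list(spec = spec, truth = gen$truth,
                              evaluation = eval_res, classification = cls,
                              extremes = extremes)
  }

  if ("ionome" %in% cfg$stages) {
    io <- cfg$ionome
    tab <- generate_ionome_table(genotypes = io$contrast,
                                 effect_map = default_ionome_effects(io$contrast),
                                 seed = derive_seed(seed, 2L))
    resp <- percent_change(tab)
    contrast <- genotype_contrast(resp, io$contrast[1], io$contrast[2])
    utils::write.csv(resp, file.path(out_dir, "ionome_response.csv"),
                     row.names = FALSE)
    utils::write.csv(contrast, file.path(out_dir, "ionome_contrast.csv"),
                     row.names = FALSE)
    results$ionome <- list(table = tab, response = resp,
                           contrast = contrast)
  }

  if ("metabolites" %in% cfg$stages) {
    mb <- cfg$metabolites
    sim <- generate_metabolite_matrix(
      n_samples_per_group = mb$n_samples_per_group,
      n_features = mb$n_features, n_differential = mb$n_differential,
      fc_range = mb$fc_range, noise_sdlog = mb$noise_sdlog,
      seed = derive_seed(seed, 3L)
    )
    fit <- fit_oplsda(sim$matrix, sim$groups,
                      n_orthogonal = mb$n_orthogonal, scale = mb$scale)
    fc <- fold_change(sim$matrix, sim$groups, control = "CK")
    screen <- screen_metabolites(fit, fc, vip_threshold = mb$vip_threshold,
                                 fc_up = mb$fc_up, fc_down = mb$fc_down)
    utils::write.csv(screen$table, file.path(out_dir, "metabolite_screen.csv"),
                     row.names = FALSE)
    results$metabolites <- list(sim = sim, fit = fit, screen = screen)
  }

  if ("degs" %in% cfg$stages) {
    dg <- cfg$degs
    sim <- generate_deg_table(n_genes = dg$n_genes,
                              seed = derive_seed(seed, 4L))
    calls_a <- call_directions(sim$table_a, lfc = dg$lfc, alpha = dg$alpha,
                               include_boundary = dg$include_boundary,
                               adjust = dg$adjust)
    calls_b <- call_directions(sim$table_b, lfc = dg$lfc, alpha = dg$alpha,
                               include_boundary = dg$include_boundary,
                               adjust = dg$adjust)
    venn <- venn_partition(calls_a, calls_b)
    selected <- select_pattern_genes(calls_a, calls_b)
    jsonlite::write_json(as.list(venn$venn),
                         file.path(out_dir, "venn_counts.json"),
                         auto_unbox = TRUE)
    writeLines(selected$genes, file.path(out_dir, "selected_genes.txt"))
    results$degs <- list(sim = sim, venn = venn, selected = selected)
  }

  manifest <- list(
    package = "ktscreen",
    version = as.character(utils::packageVersion("ktscreen")),
    seed = seed,
    stage_seeds = stats::setNames(
      as.list(vapply(1:4, function(i) derive_seed(seed, i), integer(1))),
      c("screening", "ionome", "metabolites", "degs")
    ),
    config = cfg,
    decisions = list(
      pca_sign_convention = "largest-magnitude loading element positive",
      retention_rule = cfg$screening$retention,
      percentile_type = 7,
      deg_boundary = if (cfg$degs$include_boundary) ">=" else ">",
      kue_formula = "squared (DW^2 / K content)",
      oplsda_scaling = cfg$metabolites$scale,
      vip_components = "predictive only"
    ),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  render_report(out_dir, results)
  invisible(list(results = results, manifest = manifest))
}

# LK/CK multipliers emulating a tolerant first genotype (moderate K loss)
# and a sensitive second genotype (severe K and P loss, strong Ca influx).
default_ionome_effects <- function(genotypes) {
  g1 <- genotypes[1]
  g2 <- genotypes[2]
  rbind(
    data.frame(tissue = "Shoot", genotype = g1, element = "K",
               effect = 0.24, stringsAsFactors = FALSE),
    data.frame(tissue = "Root", genotype = g1, element = "K", effect = 0.52),
    data.frame(tissue = "Shoot", genotype = g2, element = "K", effect = 0.21),
    data.frame(tissue = "Root", genotype = g2, element = "K", effect = 0.20),
    data.frame(tissue = "Root", genotype = g2, element = "P", effect = 0.16),
    data.frame(tissue = "Shoot", genotype = g1, element = "Ca", effect = 1.18),
    data.frame(tissue = "Shoot", genotype = g2, element = "Ca", effect = 1.51),
    data.frame(tissue = "Root", genotype = g2, element = "Ca", effect = 2.21),
    data.frame(tissue = "Shoot", genotype = g1, element = "Na", effect = 1.11),
    data.frame(tissue = "Shoot", genotype = g2, element = "Na", effect = 1.10)
  )
}

#' Render a markdown report from pipeline results
#'
#' Writes `report.md` summarizing whichever stages are present: trait
#' descriptive statistics, classification counts and class mean D,
#' percentile-extreme genotypes, the strongest ionome responses, the
#' metabolite screen counts, and the DEG Venn partition. Regenerating the
#' report from the same results is idempotent.
#'
#' @param out_dir Directory to write `report.md` into.
#' @param results Per-stage result list as produced by [run_pipeline()].
#' @return Path to the report, invisibly.
#' @export
render_report <- function(out_dir, results) {
  if (length(results) == 0) stop_ktscreen("no stage results to report")
  lines <- c("# ktscreen run report", "")

  if (!is.null(results$screening)) {
    sc <- results$screening
    lines <- c(lines, "## Comprehensive tolerance evaluation", "",
               sprintf("- Genotypes: %d", length(sc$evaluation$D)),
               sprintf("- Retained components: %d (cumulative contribution %.2f%%)",
                       sc$evaluation$pca$n_components,
                       sc$evaluation$pca$cumulative),
               sprintf("- Contribution rates (%%): %s",
                       paste(sprintf("%.2f", sc$evaluation$pca$contribution),
                             collapse = ", ")),
               sprintf("- D: mean %.3f, range [%.3f, %.3f]",
                       mean(sc$evaluation$D), min(sc$evaluation$D),
                       max(sc$evaluation$D)),
               "", "| class | n | mean D |", "|---|---|---|")
    cm <- sc$classification$class_means
    cn <- sc$classification$counts
    for (cl in names(cm)) {
      lines <- c(lines, sprintf("| %s | %d | %.3f |", cl, cn[[cl]], cm[[cl]]))
    }
    lines <- c(lines, "",
               sprintf("- Tolerant extremes (> %gth pct): %s",
                       99, paste(sc$extremes$tolerant, collapse = ", ")),
               sprintf("- Sensitive extremes (< %gth pct): %s",
                       1, paste(sc$extremes$sensitive, collapse = ", ")), "")
  }

  if (!is.null(results$ionome)) {
    resp <- results$ionome$response
    top <- resp[order(resp$pct_change), ]
    lines <- c(lines, "## Ionome response", "",
               "| tissue | genotype | element | % change |",
               "|---|---|---|---|")
    show <- utils::head(top[!is.na(top$pct_change), ], 6)
    for (i in seq_len(nrow(show))) {
      lines <- c(lines, sprintf("| %s | %s | %s | %.2f |",
                                show$tissue[i], show$genotype[i],
                                show$element[i], show$pct_change[i]))
    }
    lines <- c(lines, "")
  }

  if (!is.null(results$metabolites)) {
    mc <- results$metabolites$screen$counts
    lines <- c(lines, "## Metabolite screen", "",
               sprintf("- %d up, %d down, %d not differential (VIP >= 1, FC >= 2 or <= 0.5)",
                       mc[["up"]], mc[["down"]], mc[["not-differential"]]),
               sprintf("- Predictive R2Y: %.3f", results$metabolites$fit$r2y),
               "")
  }

  if (!is.null(results$degs)) {
    v <- results$degs$venn$venn
    lines <- c(lines, "## DEG screen", "",
               sprintf("- Up: %d only A, %d common, %d only B",
                       v[["up_only_a"]], v[["up_common"]], v[["up_only_b"]]),
               sprintf("- Down: %d only A, %d common, %d only B",
                       v[["down_only_a"]], v[["down_common"]],
                       v[["down_only_b"]]),
               sprintf("- Pattern-selected genes: %d",
                       length(results$degs$selected$genes)),
               "")
  }

  path <- file.path(out_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
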