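# Threshold-based differential-gene screening and cross-genotype set
# algebra. The module consumes per-gene differential statistics tables
# (gene, log2 fold-change, p-value) -- how they were fitted is out of scope.

DIRECTIONS <- c("up", "down", "unchanged")

#' Call per-gene expression directions
#'
#' A gene is `"up"` when `log2fc >= lfc` and `p < alpha`, `"down"` when
#' `log2fc <= -lfc` and `p < alpha`, otherwise `"unchanged"`. The
#' fold-change boundary is included by default (`>=`); set
#' `include_boundary = FALSE` for the strict `>` convention.
#'
#' @param table Data frame with columns `gene`, `log2fc`, `pvalue`
#'   (one row per gene).
#' @param lfc Absolute log2 fold-change threshold (default 1).
#' @param alpha P-value threshold (default 0.05).
#' @param include_boundary Include `|log2fc| == lfc` (default `TRUE`).
#' @param adjust Optional p-value adjustment method passed to
#'   [stats::p.adjust()] (e.g. `"BH"`); default `"none"`, matching a raw
#'   p-value gate.
#' @return Data frame `gene`, `direction` with `direction` a factor over
#'   up/down/unchanged.
#' @export
call_directions <- function(table, lfc = 1, alpha = 0.05,
                            include_boundary = TRUE, adjust = "none") {
  required <- c("gene", "log2fc", "pvalue")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols) > 0) {
    stop_ktscreen("differential table is missing column(s): ",
                  paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(table$gene)) {
    stop_ktscreen("duplicate gene records: ",
                  paste(utils::head(unique(
                    table$gene[duplicated(table$gene)]), 5),
                    collapse = ", "))
  }
  if (any(table$pvalue < 0 | table$pvalue > 1, na.rm = TRUE)) {
    stop_ktscreen("p-values must lie in [0, 1]")
  }
  p <- stats::p.adjust(table$pvalue, method = adjust)
  sig <- p < alpha
  hit_up <- if (include_boundary) table$log2fc >= lfc else table$log2fc > lfc
  hit_dn <- if (include_boundary) table$log2fc <= -lfc else table$log2fc < -lfc
  direction <- ifelse(sig & hit_up, "up",
                      ifelse(sig & hit_dn, "down", "unchanged"))
  data.frame(gene = as.character(table$gene),
             direction = factor(direction, levels = DIRECTIONS),
             stringsAsFactors = FALSE)
}

# Align two call tables on the union of their gene universes; genes absent
# from one contrast are treated as unchanged there (count reported via a
# message when any exist).
align_calls <- function(calls_a, calls_b) {
  universe <- union(calls_a$gene, calls_b$gene)
  if (length(universe) == 0) stop_ktscreen("empty gene universe")
  fill <- function(calls, who) {
    idx <- match(universe, calls$gene)
    n_absent <- sum(is.na(idx))
    if (n_absent > 0) {
      message(n_absent, " gene(s) absent from contrast ", who,
              " treated as unchanged")
    }
    d <- as.character(calls$direction)[idx]
    d[is.na(d)] <- "unchanged"
    factor(d, levels = DIRECTIONS)
  }
  data.frame(gene = universe,
             a = fill(calls_a, "A"), b = fill(calls_b, "B"),
             stringsAsFactors = FALSE)
}

#' Cross-genotype Venn partition of direction calls
#'
#' Crosses the direction calls of two contrasts (e.g. the tolerant and the
#' sensitive genotype, each LK vs CK) into the full 3 x 3 contingency table
#' and the six Venn counts for the up- and down-regulated sets.
#'
#' @param calls_a,calls_b Call tables from [call_directions()]. The gene
#'   universe is the union; genes absent from one contrast count as
#'   unchanged there.
#' @return Object of class `venn_partition`: list with `table` (3 x 3
#'   contingency, rows = contrast A), `venn` (named counts `up_only_a`,
#'   `up_only_b`, `up_common`, `down_only_a`, `down_only_b`,
#'   `down_common`), `universe_size`, and `genes` (the aligned per-gene
#'   direction pairs).
#' @export
venn_partition <- function(calls_a, calls_b) {
  aligned <- align_calls(calls_a, calls_b)
  tab <- table(a = aligned$a, b = aligned$b)
  venn <- c(
    up_only_a = sum(aligned$a == "up" & aligned$b != "up"),
    up_only_b = sum(aligned$b == "up" & aligned$a != "up"),
    up_common = sum(aligned$a == "up" & aligned$b == "up"),
    down_only_a = sum(aligned$a == "down" & aligned$b != "down"),
    down_only_b = sum(aligned$b == "down" & aligned$a != "down"),
    down_common = sum(aligned$a == "down" & aligned$b == "down")
  )
  structure(
    list(table = tab, venn = venn, universe_size = nrow(aligned),
         genes = aligned),
    class = "venn_partition"
  )
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Venn partition over", x$universe_size, "genes\n")
  print(x$table)
  cat("\nUp:  ", x$venn["up_only_a"], "only A,", x$venn["up_common"],
      "common,", x$venn["up_only_b"], "only B\n")
  cat("Down:", x$venn["down_only_a"], "only A,", x$venn["down_common"],
      "common,", x$venn["down_only_b"], "only B\n")
  invisible(x)
}

#' Select genes with tolerance-associated expression patterns
#'
#' Returns the genes whose direction pair (tolerant contrast, sensitive
#' contrast) matches any of the selected patterns; the default set --
#' (up, down), (up, unchanged), (unchanged, down) -- captures genes induced
#' (or at least maintained) in the tolerant genotype while repressed or
#' silent in the sensitive one.
#'
#' @param calls_tolerant,calls_sensitive Call tables from
#'   [call_directions()].
#' @param patterns List of length-2 character vectors
#'   `c(tolerant_direction, sensitive_direction)`.
#' @return List with `genes` (character vector, sorted) and
#'   `pattern_counts` (named integer vector, one entry per pattern,
#'   names like `"up/down"`).
#' @export
select_pattern_genes <- function(calls_tolerant, calls_sensitive,
                                 patterns = list(c("up", "down"),
                                                 c("up", "unchanged"),
                                                 c("unchanged", "down"))) {
  for (p in patterns) {
    if (length(p) != 2 || !all(p %in% DIRECTIONS)) {
      stop_ktscreen("each pattern must be two of up/down/unchanged")
    }
  }
  aligned <- align_calls(calls_tolerant, calls_sensitive)
  pair <- paste(aligned$a, aligned$b, sep = "/")
  wanted <- vapply(patterns, paste, character(1), collapse = "/")
  counts <- vapply(wanted, function(w) sum(pair == w), integer(1))
  list(
    genes = sort(aligned$gene[pair %in% wanted]),
    pattern_counts = counts
  )
}
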