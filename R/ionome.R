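# Ionome responses and K-utilization-efficiency arithmetic.
#
# Elemental concentration tables are long data frames with columns tissue,
# treatment (CK/LK), genotype, element, concentration, unit, and optionally
# `letters` carrying significance annotations parsed from published tables
# (never computed here).

IONOME_ELEMENTS <- c("N", "P", "K", "Ca", "Mg", "Na", "Fe", "Mn", "Cu", "Zn")
IONOME_UNITS <- c(N = "g/kg", P = "g/kg", K = "g/kg", Ca = "g/kg",
                  Mg = "g/kg", Na = "g/kg", Fe = "mg/kg", Mn = "mg/kg",
                  Cu = "mg/kg", Zn = "mg/kg")

validate_ionome_table <- function(table) {
  required <- c("tissue", "treatment", "genotype", "element", "concentration")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols) > 0) {
    stop_ktscreen("ionome table is missing column(s): ",
                  paste(missing_cols, collapse = ", "))
  }
  if (any(table$concentration < 0, na.rm = TRUE)) {
    stop_ktscreen("concentrations must be nonnegative")
  }
  if ("unit" %in% names(table)) {
    per_elem <- tapply(table$unit, table$element,
                       function(u) length(unique(u)))
    if (any(per_elem > 1)) {
      stop_ktscreen("each element must carry exactly one unit across the table")
    }
  }
  table
}

#' Read an ionome table from a wide CSV
#'
#' Reads the published-table layout: columns `tissue`, `treatment`,
#' `genotype`, then one column per element named `<element>_<unit>` with `/`
#' written as `.` (e.g. `K_g.kg`, `Fe_mg.kg`). Cell values may carry trailing
#' significance letters (e.g. `29.58Aa`), which are split off into a
#' `letters` column.
#'
#' @param path CSV path.
#' @return A long ionome data frame with columns `tissue`, `treatment`,
#'   `genotype`, `element`, `concentration`, `unit`, `letters`.
#' @export
read_ionome_table <- function(path) {
  wide <- utils::read.csv(path, stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  id_cols <- c("tissue", "treatment", "genotype")
  elem_cols <- setdiff(names(wide), id_cols)
  rows <- lapply(elem_cols, function(col) {
    parts <- strsplit(col, "_", fixed = TRUE)[[1]]
    element <- parts[1]
    unit <- gsub(".", "/", paste(parts[-1], collapse = "_"), fixed = TRUE)
    raw <- wide[[col]]
    num <- as.numeric(sub("([0-9.]+).*", "\\1", raw))
    letters <- sub("^[0-9.]+", "", raw)
    data.frame(
      tissue = wide$tissue, treatment = wide$treatment,
      genotype = wide$genotype, element = element,
      concentration = num, unit = unit, letters = letters,
      stringsAsFactors = FALSE
    )
  })
  validate_ionome_table(do.call(rbind, rows))
}

#' Write an ionome table to a wide CSV
#'
#' Inverse of [read_ionome_table()]: emits one column per element with the
#' unit suffix, significance letters re-appended to the values.
#'
#' @param table Long ionome data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ionome_table <- function(table, path) {
  table <- validate_ionome_table(table)
  if (!"letters" %in% names(table)) table$letters <- ""
  if (!"unit" %in% names(table)) {
    table$unit <- IONOME_UNITS[table$element]
  }
  elements <- unique(table$element)
  ids <- unique(table[, c("tissue", "treatment", "genotype")])
  wide <- ids
  for (e in elements) {
    sub_t <- table[table$element == e, ]
    unit <- sub_t$unit[1]
    col <- paste0(e, "_", gsub("/", ".", unit, fixed = TRUE))
    key_ids <- paste(ids$tissue, ids$treatment, ids$genotype, sep = "\r")
    key_sub <- paste(sub_t$tissue, sub_t$treatment, sub_t$genotype, sep = "\r")
    idx <- match(key_ids, key_sub)
    wide[[col]] <- paste0(
      format(sub_t$concentration[idx], trim = TRUE, scientific = FALSE),
      sub_t$letters[idx]
    )
  }
  utils::write.csv(wide, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Percent change of elemental concentrations under low-K stress
#'
#' For each (tissue, genotype, element) present under both treatments,
#' computes `100 * (LK - CK) / CK`, labels the direction, and ranks the
#' response magnitudes within each (tissue, genotype). Comparisons are done
#' at full precision; a rounded 2-decimal column is provided for reporting.
#'
#' @param table Long ionome data frame (see [read_ionome_table()]).
#' @return Data frame with columns `tissue`, `genotype`, `element`, `ck`,
#'   `lk`, `pct_change`, `pct_change_2dp`, `direction`
#'   (increase/decrease/unchanged), and `magnitude_rank` (1 = largest
#'   absolute change within the tissue x genotype block). Cells with CK = 0
#'   or a missing treatment are flagged in the `flag` column and carry `NA`
#'   percent change.
#' @examples
#' t5 <- read_ionome_table(
#'   system.file("extdata", "wheat_ionome_contrast.csv", package = "ktscreen")
#' )
#' resp <- percent_change(t5)
#' subset(resp, genotype == "KN9204" & element == "K")
#' @export
percent_change <- function(table) {
  table <- validate_ionome_table(table)
  ck <- table[table$treatment == "CK", ]
  lk <- table[table$treatment == "LK", ]
  key <- function(d) paste(d$tissue, d$genotype, d$element, sep = "\r")
  all_keys <- union(key(ck), key(lk))
  ck_idx <- match(all_keys, key(ck))
  lk_idx <- match(all_keys, key(lk))
  parts <- do.call(rbind, strsplit(all_keys, "\r", fixed = TRUE))

  out <- data.frame(
    tissue = parts[, 1], genotype = parts[, 2], element = parts[, 3],
    ck = ck$concentration[ck_idx], lk = lk$concentration[lk_idx],
    stringsAsFactors = FALSE
  )
  out$flag <- ifelse(is.na(out$ck) | is.na(out$lk), "missing_pair",
                     ifelse(out$ck == 0, "zero_control", ""))
  out$pct_change <- ifelse(out$flag == "", 100 * (out$lk - out$ck) / out$ck,
                           NA_real_)
  out$pct_change_2dp <- round(out$pct_change, 2)
  out$direction <- ifelse(is.na(out$pct_change), NA_character_,
                          ifelse(out$pct_change > 0, "increase",
                                 ifelse(out$pct_change < 0, "decrease",
                                        "unchanged")))
  blocks <- interaction(out$tissue, out$genotype, drop = TRUE)
  out$magnitude_rank <- stats::ave(
    abs(out$pct_change), blocks,
    FUN = function(v) rank(-v, ties.method = "min", na.last = "keep")
  )
  rownames(out) <- NULL
  out
}

#' Potassium content from dry weight and concentration
#'
#' `content (mg/plant) = dry weight (mg/plant) x concentration (g/kg) x 1e-3`
#' (g/kg is mg/g, so a 1000 mg plant at 1 g/kg holds 1 mg K).
#'
#' @param dry_weight_mg Dry weight in mg per plant (nonnegative).
#' @param k_concentration_g_kg K concentration in g/kg (nonnegative).
#' @return K content in mg per plant.
#' @examples
#' k_content(1000, 1)  # 1 mg
#' @export
k_content <- function(dry_weight_mg, k_concentration_g_kg) {
  if (any(dry_weight_mg < 0) || any(k_concentration_g_kg < 0)) {
    stop_ktscreen("dry weight and K concentration must be nonnegative")
  }
  dry_weight_mg * k_concentration_g_kg * 1e-3
}

#' K utilization efficiency
#'
#' Biomass produced per unit plant K, in the squared-dry-weight form whose
#' units are mg^2 dry weight per ug K content:
#' `KUE = (dry weight in mg)^2 / (K content in ug)`. The simple-ratio
#' alternative `dry weight / K content` (mg/ug) is available via `formula`.
#'
#' @param dry_weight_mg Dry weight, mg per plant.
#' @param k_content_mg K content, mg per plant (> 0).
#' @param formula `"squared"` (default) or `"ratio"`.
#' @return KUE (mg^2/ug for `"squared"`, mg/ug for `"ratio"`).
#' @export
kue <- function(dry_weight_mg, k_content_mg, formula = c("squared", "ratio")) {
  formula <- match.arg(formula)
  if (any(k_content_mg <= 0)) {
    stop_ktscreen("K content must be positive to form a KUE index")
  }
  k_content_ug <- k_content_mg * 1e3
  switch(formula,
    squared = dry_weight_mg^2 / k_content_ug,
    ratio = dry_weight_mg / k_content_ug
  )
}

#' Contrast element responses between two genotypes
#'
#' For every tissue x element, compares the percent changes of a tolerant
#' and a sensitive genotype and reports which changed more, by signed and
#' absolute magnitude.
#'
#' @param resp A response table from [percent_change()].
#' @param tolerant,sensitive Genotype identifiers present in `resp`.
#' @return Data frame with per-(tissue, element) percent changes for both
#'   genotypes, their difference, and a `verdict` naming the genotype with
#'   the greater decrease (or increase), `"tie"` when equal.
#' @export
genotype_contrast <- function(resp, tolerant, sensitive) {
  for (g in c(tolerant, sensitive)) {
    if (!g %in% resp$genotype) {
      stop_ktscreen("genotype '", g, "' not present in the response table")
    }
  }
  a <- resp[resp$genotype == tolerant, ]
  b <- resp[resp$genotype == sensitive, ]
  key <- function(d) paste(d$tissue, d$element, sep = "\r")
  common <- intersect(key(a), key(b))
  a <- a[match(common, key(a)), ]
  b <- b[match(common, key(b)), ]
  verdict <- ifelse(
    a$pct_change == b$pct_change, "tie",
    ifelse(abs(b$pct_change) > abs(a$pct_change),
           paste0(sensitive, ifelse(b$pct_change < 0,
                                    " greater decrease", " greater increase")),
           paste0(tolerant, ifelse(a$pct_change < 0,
                                   " greater decrease", " greater increase")))
  )
  data.frame(
    tissue = a$tissue, element = a$element,
    pct_change_tolerant = a$pct_change,
    pct_change_sensitive = b$pct_change,
    abs_diff = abs(abs(b$pct_change) - abs(a$pct_change)),
    verdict = verdict,
    stringsAsFactors = FALSE
  )
}
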