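#' Construct and validate a trait panel
#'
#' A trait panel holds replicate-level phenotype measurements in long format:
#' one row per genotype x trait x treatment x replicate. Treatments follow the
#' control / low-potassium convention used throughout the package: `"CK"` for
#' control potassium supply and `"LK"` for the low-K stress treatment.
#'
#' @param data A data frame with columns `genotype`, `trait`, `treatment`,
#'   `replicate`, `value` (and optionally `units`).
#' @return The validated data frame with class `trait_panel` prepended.
#' @examples
#' panel <- trait_panel(data.frame(
#'   genotype = "G1", trait = "SL", treatment = c("CK", "LK"),
#'   replicate = 1L, value = c(18, 15)
#' ))
#' @export
trait_panel <- function(data) {
  required <- c("genotype", "trait", "treatment", "replicate", "value")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop_ktscreen(
      "trait panel is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    )
  }
  if (!all(data$treatment %in% c("CK", "LK"))) {
    bad <- unique(setdiff(data$treatment, c("CK", "LK")))
    stop_ktscreen(
      "treatment labels must be 'CK' or 'LK'; found: ",
      paste(bad, collapse = ", ")
    )
  }
  if (!is.numeric(data$value) || any(!is.finite(data$value))) {
    stop_ktscreen("trait values must be finite numbers")
  }
  data$genotype <- as.character(data$genotype)
  data$trait <- as.character(data$trait)
  class(data) <- unique(c("trait_panel", class(data)))
  data
}

#' Read a trait panel from CSV
#'
#' Expects the long layout written by [write_trait_panel()]: columns
#' `genotype`, `trait`, `treatment`, `replicate`, `value`.
#'
#' @param path Path to a CSV file.
#' @return A [trait_panel()].
#' @export
read_trait_panel <- function(path) {
  trait_panel(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a trait panel to CSV
#'
#' @param panel A [trait_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trait_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(unclass(panel)), path, row.names = FALSE)
  invisible(path)
}

# Genotype-level means over replicates, one row per
# genotype x trait x treatment.
genotype_means <- function(panel) {
  stats::aggregate(
    value ~ genotype + trait + treatment,
    data = as.data.frame(unclass(panel)),
    FUN = mean
  )
}
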