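#' Write association results to a tab-separated table
#'
#' One row per trait x marker with columns `trait`, `marker`, `n`, `lod`,
#' `pve`, `p_value`, `threshold`, `significant` (mirroring the layout of a
#' published association summary table).  Missing fields (e.g. no
#' permutation p-value yet) are written as `NA`.
#'
#' @param results data frame, e.g. an `association_scan`, optionally with
#'   `p_value`, `threshold`, `significant` columns.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_association_results <- function(results, path) {
  results <- as.data.frame(results)
  if (nrow(results) == 0L) warning("writing header-only results file")
  cols <- c("trait", "marker", "n", "lod", "pve", "p_value", "threshold",
            "significant")
  for (cc in setdiff(cols, names(results))) results[[cc]] <- NA
  utils::write.table(results[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read association results written by [write_association_results()]
#' @param path file path.
#' @return Data frame with the standard result columns.
#' @export
read_association_results <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(trait = "character", marker = "character"))
}
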