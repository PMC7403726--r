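#' Read a phenotype/covariate table
#'
#' Tab-separated with a header row; one row per individual.  Columns named
#' in `factors` are read as factors, `fraction_traits` are numeric traits
#' constrained to \[0, 1\], `count_traits` to non-negative integers, and the
#' conventional covariate columns (`sex`, `standard_length_mm`,
#' `staining_quality`, `days_held`, ...) are typed when present.
#'
#' Rows violating a range invariant (a fraction outside \[0, 1\], a
#' staining-quality score outside 1-7, a negative count) are *flagged*, not
#' dropped: the returned table carries a `flags` attribute (data frame with
#' columns `id`, `column`, `issue`) so curation can decide their fate.
#'
#' @param path file path.
#' @param id_column name of the individual-ID column (default first column).
#' @param factors extra column names to treat as categorical.
#' @param fraction_traits,count_traits trait columns with range invariants.
#' @return A data frame of class `phenotype_table` with attribute `flags`.
#' @export
read_phenotypes <- function(path, id_column = NULL, factors = character(),
                            fraction_traits = character(),
                            count_traits = character()) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(id_column)) id_column <- names(tab)[1L]
  if (!id_column %in% names(tab)) stop("missing ID column: ", id_column)
  names(tab)[names(tab) == id_column] <- "id"
  tab$id <- as.character(tab$id)
  if (anyDuplicated(tab$id)) stop("duplicate individual IDs in ", path)
  phenotype_table(tab, factors = factors, fraction_traits = fraction_traits,
                  count_traits = count_traits)
}

#' Type and validate a phenotype table built in memory
#'
#' @param tab data frame with an `id` column.
#' @inheritParams read_phenotypes
#' @return A `phenotype_table` (see [read_phenotypes()]).
#' @export
phenotype_table <- function(tab, factors = character(),
                            fraction_traits = character(),
                            count_traits = character()) {
  default_factors <- c("sex", "family", "month", "tank", "staining_method")
  for (f in intersect(c(default_factors, factors), names(tab))) {
    tab[[f]] <- factor(tab[[f]])
  }
  flags <- list()
  flag <- function(rows, column, issue) {
    if (any(rows, na.rm = TRUE)) {
      flags[[length(flags) + 1L]] <<- data.frame(
        id = tab$id[which(rows)], column = column, issue = issue,
        stringsAsFactors = FALSE)
    }
  }
  if ("staining_quality" %in% names(tab)) {
    sq <- suppressWarnings(as.integer(tab$staining_quality))
    flag(!is.na(sq) & (sq < 1L | sq > 7L), "staining_quality", "outside 1-7")
    tab$staining_quality <- sq
  }
  if ("days_held" %in% names(tab)) {
    dh <- suppressWarnings(as.integer(tab$days_held))
    flag(!is.na(dh) & dh < 0L, "days_held", "negative")
    tab$days_held <- dh
  }
  for (tr in intersect(fraction_traits, names(tab))) {
    v <- suppressWarnings(as.numeric(tab[[tr]]))
    flag(!is.na(v) & (v < 0 | v > 1), tr, "fraction outside [0,1]")
    tab[[tr]] <- v
  }
  for (tr in intersect(count_traits, names(tab))) {
    v <- suppressWarnings(as.numeric(tab[[tr]]))
    flag(!is.na(v) & (v < 0 | v != round(v)), tr, "not a non-negative integer")
    tab[[tr]] <- v
  }
  attr(tab, "flags") <- if (length(flags)) {
    do.call(rbind, flags)
  } else {
    data.frame(id = character(), column = character(), issue = character(),
               stringsAsFactors = FALSE)
  }
  class(tab) <- c("phenotype_table", "data.frame")
  tab
}

#' Write a phenotype table
#' @param pheno a `phenotype_table` or data frame with an `id` column.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(as.data.frame(pheno), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
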