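#' Normalize diploid genotype tokens
#'
#' Genotypes are unordered pairs of the two marker alleles C (completely
#' plated / marine-associated) and L (low-plated / freshwater-associated).
#' Tokens are upper-cased and allele order is canonicalised, so `"LC"`
#' becomes `"CL"`.  Anything that is not a pair over \{C, L\} (including
#' `"NA"`, `""`, `"."`) becomes `NA`.
#'
#' @param x character vector of raw genotype tokens.
#' @return character vector over `"CC"`, `"CL"`, `"LL"`, `NA`.
#' @export
normalize_genotype <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[x %in% c("", "NA", ".", "--", "N")] <- NA_character_
  ok <- !is.na(x) & grepl("^[CL][CL]$", x)
  # canonical allele order: C before L
  x[ok] <- vapply(strsplit(x[ok], ""), function(a) paste(sort(a), collapse = ""),
                  character(1))
  x[!ok & !is.na(x)] <- NA_character_
  x
}

#' Construct a genotype matrix
#'
#' Individuals x markers grid of unordered diploid genotype calls, with a
#' parallel logical matrix flagging calls filled in by [impute_genotypes()].
#'
#' @param calls character matrix (or data frame) of genotype tokens; row
#'   names are individual IDs, column names are marker names.
#' @param map optional [marker_map]; when given, columns must be a subset of
#'   the panel and are reordered into panel order.
#' @param imputed optional logical matrix of the same shape marking imputed
#'   calls; defaults to all-`FALSE`.
#' @param normalize normalize tokens via [normalize_genotype()]?
#' @return An object of class `genotype_matrix`: a character matrix with an
#'   `imputed` attribute.
#' @export
genotype_matrix <- function(calls, map = NULL, imputed = NULL, normalize = TRUE) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls))) stop("calls must have individual IDs as row names")
  if (is.null(colnames(calls))) stop("calls must have marker names as column names")
  if (anyDuplicated(rownames(calls))) stop("duplicate individual IDs")
  if (!is.null(map)) {
    extra <- setdiff(colnames(calls), map$name)
    if (length(extra)) {
      stop("markers not in map: ", paste(extra, collapse = ", "))
    }
    calls <- calls[, intersect(map$name, colnames(calls)), drop = FALSE]
  }
  storage.mode(calls) <- "character"
  if (normalize) {
    norm <- normalize_genotype(calls)
    n_bad <- sum(is.na(norm) & !is.na(calls) &
                   !toupper(trimws(calls)) %in% c("", "NA", ".", "--", "N"))
    if (n_bad > 0) {
      warning(n_bad, " unrecognised genotype token(s) set to missing")
    }
    calls[] <- norm
  }
  if (is.null(imputed)) {
    imputed <- matrix(FALSE, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  }
  stopifnot(identical(dim(imputed), dim(calls)))
  attr(calls, "imputed") <- imputed
  class(calls) <- c("genotype_matrix", class(calls))
  calls
}

#' Read genotypes from a tab-separated file
#'
#' First column is the individual ID; remaining columns must be marker names
#' present in `map`.  Tokens are normalized; unknown tokens are converted to
#' missing with a warning giving the count.
#'
#' @param path file path.
#' @param map a [marker_map].
#' @return A [genotype_matrix].
#' @export
read_genotypes <- function(path, map) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  if (ncol(tab) < 2L) stop("genotype file must have an ID column plus markers")
  ids <- tab[[1L]]
  calls <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(calls) <- ids
  genotype_matrix(calls, map = map)
}

#' Write genotypes to a tab-separated file
#'
#' Inverse of [read_genotypes()]: missing calls are written as `NA`.
#'
#' @param G a [genotype_matrix].
#' @param path file path.
#' @param id_column header name for the ID column.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(G, path, id_column = "id") {
  out <- data.frame(id = rownames(G), unclass(G)[, , drop = FALSE],
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out)[1L] <- id_column
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d markers (%.1f%% missing, %d imputed)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x)), sum(attr(x, "imputed"))))
  invisible(x)
}

# L-allele dosage coding: CC=0, CL=1, LL=2, missing=NA
.dosage <- function(g) {
  d <- rep(NA_integer_, length(g))
  d[g == "CC"] <- 0L
  d[g == "CL"] <- 1L
  d[g == "LL"] <- 2L
  d
}
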