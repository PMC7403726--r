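#' Classify an individual's haplotype carriage from unphased genotypes
#'
#' Chromosomes in this system come in three non-recombinant forms: all-C
#' (marine), all-L (full freshwater haplotype), and "short-L" — an L block
#' anchored at the 5' end of the region with C beyond.  Any unordered pair
#' of such chromosomes yields an L-allele dosage (CC=0, CL=1, LL=2) that is
#' monotone non-increasing along the region, and conversely every monotone
#' non-increasing dosage vector decomposes into two such chromosomes.  An
#' individual whose observed region dosages *increase* anywhere therefore
#' carries at least one historically recombined chromosome and is classed
#' `recombinant`.  Missing calls are wildcards: they are consistent with,
#' never evidence of, recombination.
#'
#' Classes:
#' \describe{
#'   \item{hom_C}{CC at every observed region marker.}
#'   \item{het_full_L}{CL at every observed region marker (the NAKA SNP is
#'     exempt from this requirement, since the L allele at that single site
#'     also segregates on completely plated backgrounds).}
#'   \item{hom_full_L}{LL at every observed region marker (NAKA exempt).}
#'   \item{het_short_L}{one short-L chromosome: a CL block anchored at the
#'     5' region edge, CC beyond.}
#'   \item{hom_short_L}{two L-bearing chromosomes of which at least one is
#'     short: dosage starts at 2 and steps down 5' to 3'.}
#'   \item{recombinant}{observed dosage increases somewhere along the
#'     region; `breakpoint_intervals` brackets each increase.}
#'   \item{unclassifiable}{no region marker observed.}
#' }
#'
#' @param gvec named character vector of genotype calls covering (at least)
#'   the region markers of `map`.
#' @param map a [marker_map].
#' @param naka_marker name of the NAKA SNP (exempt from full-L checks);
#'   `NULL` if the panel has none.
#' @return A `haplotype_call` list: `class`, `short_L_extent` (last region
#'   marker of the L block, or `NA`), `breakpoint_intervals` (data frame
#'   with columns `left`, `right`).
#' @export
classify_carrier <- function(gvec, map, naka_marker = "NAKA") {
  rm_names <- region_markers(map)
  missing_m <- setdiff(rm_names, names(gvec))
  if (length(missing_m)) stop("genotype vector lacks region markers: ",
                              paste(missing_m, collapse = ", "))
  g <- gvec[rm_names]
  d <- .dosage(g)
  obs <- which(!is.na(d))
  no_bp <- data.frame(left = character(), right = character(),
                      stringsAsFactors = FALSE)
  call <- function(class, extent = NA_character_, bp = no_bp) {
    structure(list(class = class, short_L_extent = extent,
                   breakpoint_intervals = bp), class = "haplotype_call")
  }
  if (length(obs) == 0L) return(call("unclassifiable"))
  non_naka <- if (is.null(naka_marker)) obs else obs[rm_names[obs] != naka_marker]
  if (all(d[obs] == 0L)) return(call("hom_C"))
  if (length(non_naka) && all(d[non_naka] == 1L)) return(call("het_full_L"))
  if (length(non_naka) && all(d[non_naka] == 2L)) return(call("hom_full_L"))
  dd <- d[obs]
  if (all(diff(dd) <= 0L)) {
    extent <- rm_names[obs[max(which(dd >= 1L))]]
    if (max(dd) == 1L) return(call("het_short_L", extent))
    return(call("hom_short_L", extent))
  }
  up <- which(diff(dd) > 0L)
  bp <- data.frame(left = rm_names[obs[up]], right = rm_names[obs[up + 1L]],
                   stringsAsFactors = FALSE)
  call("recombinant", bp = bp)
}

#' Detect historical recombinants across a genotype matrix
#'
#' Applies [classify_carrier()] to every individual over the region markers
#' and summarises the recombinant fraction among classifiable individuals.
#'
#' @param G a [genotype_matrix].
#' @param map a [marker_map].
#' @param naka_marker see [classify_carrier()].
#' @return Data frame of class `haplotype_calls`: `id`, `class`,
#'   `short_L_extent`, `n_breakpoints`, `breakpoints` (intervals encoded
#'   `"left|right"`, `;`-separated).  Attributes: `fraction_recombinant`
#'   (recombinants / classifiable), `n_classifiable`, `n_unclassifiable`,
#'   and `calls` (the full list of `haplotype_call` objects).
#' @export
detect_recombinants <- function(G, map, naka_marker = "NAKA") {
  calls <- lapply(rownames(G), function(i) {
    classify_carrier(unclass(G)[i, ], map, naka_marker = naka_marker)
  })
  names(calls) <- rownames(G)
  cls <- vapply(calls, `[[`, character(1), "class")
  out <- data.frame(
    id = rownames(G), class = cls,
    short_L_extent = vapply(calls, `[[`, character(1), "short_L_extent"),
    n_breakpoints = vapply(calls, function(x) nrow(x$breakpoint_intervals),
                           integer(1)),
    breakpoints = vapply(calls, function(x) {
      paste(paste(x$breakpoint_intervals$left, x$breakpoint_intervals$right,
                  sep = "|"), collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  n_class <- sum(cls != "unclassifiable")
  attr(out, "fraction_recombinant") <-
    if (n_class > 0) sum(cls == "recombinant") / n_class else NA_real_
  attr(out, "n_classifiable") <- n_class
  attr(out, "n_unclassifiable") <- sum(cls == "unclassifiable")
  attr(out, "calls") <- calls
  class(out) <- c("haplotype_calls", "data.frame")
  out
}

#' L-allele frequency at a marker
#'
#' `freq_L = (2 * #LL + #CL) / (2 * #observed)`; individuals missing at the
#' marker are excluded from the denominator.
#'
#' @param G a [genotype_matrix].
#' @param marker marker name.
#' @return List with `freq_L`, `n_L` (L alleles) and `n_chromosomes`
#'   (observed chromosomes, i.e. twice the observed individuals).
#' @export
allele_frequency <- function(G, marker) {
  if (!marker %in% colnames(G)) stop("no such marker: ", marker)
  d <- .dosage(unclass(G)[, marker])
  n_obs <- sum(!is.na(d))
  if (n_obs == 0L) stop("no observed genotypes at ", marker)
  list(freq_L = sum(d, na.rm = TRUE) / (2 * n_obs),
       n_L = sum(d, na.rm = TRUE), n_chromosomes = 2L * n_obs)
}

#' Export a sorted visual-genotype text matrix
#'
#' One row per individual, one character per marker (`C` = CC, `H` = CL,
#' `L` = LL, `.` = missing), grouped by haplotype class with all
#' non-recombinant classes first, sorted within class by the 3' extent of
#' the L block and then by first breakpoint position.
#'
#' @param calls `haplotype_calls` from [detect_recombinants()].
#' @param G the [genotype_matrix] the calls came from.
#' @param map a [marker_map].
#' @param path file path.
#' @return The ordered data frame written (invisibly): `id`, `class`,
#'   `pattern`.
#' @export
export_visual_genotypes <- function(calls, G, map, path) {
  sym <- c(CC = "C", CL = "H", LL = "L")
  panel <- intersect(map$name, colnames(G))
  pat <- apply(unclass(G)[calls$id, panel, drop = FALSE], 1, function(r) {
    paste(ifelse(is.na(r), ".", sym[r]), collapse = "")
  })
  class_order <- c("hom_C", "het_full_L", "hom_full_L", "het_short_L",
                   "hom_short_L", "recombinant", "unclassifiable")
  extent_idx <- match(calls$short_L_extent, map$name)
  first_bp <- vapply(attr(calls, "calls")[calls$id], function(x) {
    if (nrow(x$breakpoint_intervals)) {
      match(x$breakpoint_intervals$left[1L], map$name)
    } else NA_integer_
  }, integer(1))
  ord <- order(match(calls$class, class_order), extent_idx, first_bp,
               calls$id)
  out <- data.frame(id = calls$id[ord], class = calls$class[ord],
                    pattern = unname(pat[ord]), stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#markers\t", paste(panel, collapse = ",")), con)
  writeLines(sprintf("%s\t%s\t%s", out$id, out$class, out$pattern), con)
  invisible(out)
}
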