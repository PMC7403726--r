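#' Impute missing genotypes from matching flanking markers
#'
#' A conservative, rule-based fill for short runs of missing calls.  For
#' each maximal run of missing genotypes of length at most `max_run` in an
#' individual, let `a` be the genotype at the nearest observed marker to the
#' left and `b` at the nearest observed marker to the right.  The run is
#' filled with `a` only when:
#' \enumerate{
#'   \item both flanks are observed (runs touching the panel edge are never
#'     filled) and `a == b`;
#'   \item the congruence check passes at every marker in the run: no other
#'     individual observed at that marker, whose genotypes at the *same two
#'     flanking markers* are both `a`, carries a genotype different from `a`
#'     there.  Such an individual would be direct evidence of a breakpoint
#'     between the flanks, voiding the no-double-recombination assumption
#'     the rule rests on.
#' }
#' Uncertain calls are left missing; observed calls are never altered.  The
#' procedure is deterministic and invariant to row order.
#'
#' @param G a [genotype_matrix] with markers in map order.
#' @param map a [marker_map]; columns of `G` must be in panel order.
#' @param max_run longest missing run eligible for filling (default 3).
#' @return List with elements `genotypes` (the filled [genotype_matrix],
#'   imputed flags set) and `report` (an `imputation_report`): per-marker
#'   counts of observed / imputed / left-missing calls plus a per-call trace
#'   (`individual`, `marker`, `value`, `left_flank`, `right_flank`).
#' @export
impute_genotypes <- function(G, map, max_run = 3L) {
  stopifnot(max_run >= 1L)
  panel <- intersect(map$name, colnames(G))
  if (!identical(colnames(G), panel)) {
    stop("genotype columns must be in map order; reorder via genotype_matrix(..., map)")
  }
  M <- unclass(G)
  imp <- attr(G, "imputed")
  trace <- list()
  n_ind <- nrow(M)
  for (i in seq_len(n_ind)) {
    miss <- is.na(M[i, ])
    if (!any(miss)) next
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      len <- r$lengths[k]
      if (len > max_run) next
      s <- starts[k]; e <- ends[k]
      if (s == 1L || e == ncol(M)) next            # panel edge: one flank only
      left <- s - 1L; right <- e + 1L
      a <- M[i, left]; b <- M[i, right]
      if (is.na(a) || is.na(b) || a != b) next
      # congruence: any sample observed at a run marker with both flanks == a
      # but a different genotype there blocks the whole run
      flank_match <- !is.na(M[, left]) & M[, left] == a &
        !is.na(M[, right]) & M[, right] == a
      incongruous <- FALSE
      for (m in s:e) {
        gm <- M[flank_match, m]
        if (any(!is.na(gm) & gm != a)) { incongruous <- TRUE; break }
      }
      if (incongruous) next
      for (m in s:e) {
        M[i, m] <- a
        imp[i, m] <- TRUE
        trace[[length(trace) + 1L]] <- data.frame(
          individual = rownames(M)[i], marker = colnames(M)[m], value = a,
          left_flank = colnames(M)[left], right_flank = colnames(M)[right],
          stringsAsFactors = FALSE)
      }
    }
  }
  filled <- genotype_matrix(M, imputed = imp, normalize = FALSE)
  per_marker <- data.frame(
    marker = colnames(M),
    observed = colSums(!is.na(M)) - colSums(imp),
    imputed = colSums(imp),
    left_missing = colSums(is.na(M)),
    row.names = NULL, stringsAsFactors = FALSE)
  report <- structure(list(
    per_marker = per_marker,
    trace = if (length(trace)) do.call(rbind, trace) else data.frame(
      individual = character(), marker = character(), value = character(),
      left_flank = character(), right_flank = character(),
      stringsAsFactors = FALSE),
    max_run = max_run,
    congruence = "conditional on identical flanking genotypes"),
    class = "imputation_report")
  list(genotypes = filled, report = report)
}

#' @export
print.imputation_report <- function(x, ...) {
  cat(sprintf("imputation_report: %d calls imputed (max run %d)\n",
              nrow(x$trace), x$max_run))
  print(x$per_marker, ...)
  invisible(x)
}

#' Trim a genotype matrix for the conservative analysis file
#'
#' Markers whose missing fraction exceeds `marker_missing_frac_max` are
#' deleted entirely (they carry too little information and their imputed
#' values would dominate).  Optionally, individuals still carrying any
#' missing call at the retained markers are then removed, so the analysis
#' view is fully observed; the per-trait analyses are in any case listwise
#' per marker.
#'
#' @param G a [genotype_matrix].
#' @param marker_missing_frac_max drop markers missing in more than this
#'   fraction of individuals (default 0.5).
#' @param drop_incomplete_individuals remove individuals with remaining
#'   missing calls (default `TRUE`, the conservative file).
#' @return The trimmed [genotype_matrix]; attribute `trim` records dropped
#'   markers and individuals.
#' @export
trim_genotypes <- function(G, marker_missing_frac_max = 0.5,
                           drop_incomplete_individuals = TRUE) {
  M <- unclass(G)
  frac <- colMeans(is.na(M))
  drop_m <- colnames(M)[frac > marker_missing_frac_max]
  keep_m <- setdiff(colnames(M), drop_m)
  if (length(keep_m) == 0L) stop("all markers exceed the missingness threshold")
  M <- M[, keep_m, drop = FALSE]
  imp <- attr(G, "imputed")[, keep_m, drop = FALSE]
  drop_i <- character()
  if (drop_incomplete_individuals) {
    bad <- rowSums(is.na(M)) > 0L
    drop_i <- rownames(M)[bad]
    M <- M[!bad, , drop = FALSE]
    imp <- imp[!bad, , drop = FALSE]
    if (nrow(M) == 0L) stop("no individuals remain after trimming")
  }
  out <- genotype_matrix(M, imputed = imp, normalize = FALSE)
  attr(out, "trim") <- list(dropped_markers = drop_m,
                            dropped_individuals = drop_i,
                            marker_missing_frac_max = marker_missing_frac_max)
  out
}
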