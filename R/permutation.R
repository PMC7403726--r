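#' Bonferroni-adjusted significance level
#'
#' @param alpha family-wise level (default 0.05).
#' @param n_traits number of traits tested.
#' @return `alpha / n_traits`.
#' @export
bonferroni_alpha <- function(alpha = 0.05, n_traits) {
  if (n_traits < 1) stop("n_traits must be >= 1")
  alpha / n_traits
}

#' Empirical LOD threshold from a permutation distribution
#'
#' Nearest-rank upper quantile: the `ceil((1 - alpha) * N)`-th order
#' statistic of the permuted LODs — deterministic and conservative.
#'
#' @param perm_lods numeric vector of permuted LOD scores.
#' @param alpha_adjusted the (Bonferroni-adjusted) significance level.
#' @return LOD threshold.
#' @export
lod_threshold <- function(perm_lods, alpha_adjusted) {
  stopifnot(length(perm_lods) > 0, alpha_adjusted > 0, alpha_adjusted <= 1)
  s <- sort(perm_lods)
  s[max(1L, ceiling((1 - alpha_adjusted) * length(s)))]
}

#' Stratified permutation test of marker-trait association
#'
#' Significance of observed LOD scores is assessed by permuting whole
#' genotype rows (all markers jointly, preserving each individual's
#' within-haplotype structure) among individuals *within strata* — families
#' with comparable haplotype sizes in a cross design, collection months in
#' a wild-caught sample — so that stratum-level allele-frequency structure
#' is preserved under the null of no genotype effect.  Trait and covariates
#' stay fixed, so the covariate model holds in every permutation.
#'
#' P-values use the add-one estimator `p = (1 + #\{perm >= obs\}) / (1 +
#' n_perm)`, which can never be zero.  In `"max"` mode the null
#' distribution is the per-permutation maximum LOD over the scanned
#' markers, controlling family-wise error across the panel; `"per_marker"`
#' mode tests each marker against its own permutation distribution.
#'
#' @param view analysis view with `id` and the spec's columns; rows with
#'   incomplete trait/covariates are dropped.
#' @param spec a [model_spec] (its `strata` is used unless `strata` is
#'   given).
#' @param G a [genotype_matrix].
#' @param markers markers to scan (default all columns of `G`).
#' @param strata name of the categorical stratification column in `view`.
#' @param n_perm number of permutations (default 5000).
#' @param seed RNG seed; results are bit-reproducible given
#'   `(seed, n_perm, mode)`.
#' @param mode `"max"` (max-over-markers, default) or `"per_marker"`.
#' @param alpha family-wise significance level before trait correction.
#' @param n_traits number of traits tested, for the Bonferroni adjustment.
#' @return A `permutation_result` list: `observed` (the observed
#'   [scan_markers()] table with `p_value` and `significant` columns),
#'   `perm_lods` (matrix `n_perm` x markers), `perm_max` (in max mode),
#'   `lod_threshold`, `alpha_adjusted`, `mode`, `n_perm`, `seed`, `strata`.
#' @export
stratified_permutation_test <- function(view, spec, G,
                                        markers = colnames(G),
                                        strata = spec$strata,
                                        n_perm = 5000L, seed = 1L,
                                        mode = c("max", "per_marker"),
                                        alpha = 0.05, n_traits = 1L) {
  mode <- match.arg(mode)
  if (is.null(strata)) stop("a strata column is required")
  stopifnot("id" %in% names(view), strata %in% names(view))
  .check_spec(spec, view)
  ids <- intersect(view$id, rownames(G))
  view <- view[match(ids, view$id), , drop = FALSE]
  used <- setdiff(.spec_columns(spec), strata)
  keep <- stats::complete.cases(view[, used, drop = FALSE]) &
    !is.na(view[[strata]])
  view <- droplevels(view[keep, , drop = FALSE])
  strat <- factor(view[[strata]])
  sizes <- table(strat)
  if (any(sizes < 2L)) {
    stop("strata of size 1: ", paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  Gm <- unclass(G)[view$id, markers, drop = FALSE]
  y <- view[[spec$trait]]
  X0 <- stats::model.matrix(.spec_formula(spec), data = view)
  n <- nrow(view)
  global_nf <- .null_fit_fast(y, X0)

  lod_for_rows <- function(row_order) {
    vapply(seq_along(markers), function(j) {
      g <- Gm[row_order, j]
      obs <- !is.na(g)
      if (all(obs)) {
        .lod_fast(global_nf, g)
      } else {
        if (sum(obs) < 4L) return(0)
        nf <- .null_fit_fast(y[obs], X0[obs, , drop = FALSE])
        .lod_fast(nf, g[obs])
      }
    }, numeric(1))
  }

  observed_lod <- lod_for_rows(seq_len(n))
  strata_idx <- split(seq_len(n), strat)
  set.seed(seed)
  perm_lods <- matrix(NA_real_, n_perm, length(markers),
                      dimnames = list(NULL, markers))
  for (b in seq_len(n_perm)) {
    ord <- seq_len(n)
    for (s in strata_idx) {
      if (length(s) > 1L) ord[s] <- s[sample.int(length(s))]
    }
    stopifnot(identical(sort(ord), seq_len(n)))   # stratum multisets preserved
    perm_lods[b, ] <- lod_for_rows(ord)
  }
  alpha_adj <- bonferroni_alpha(alpha, n_traits)
  if (mode == "max") {
    perm_max <- apply(perm_lods, 1, max)
    p_value <- (1 + vapply(observed_lod,
                           function(l) sum(perm_max >= l), numeric(1))) /
      (1 + n_perm)
    thr <- lod_threshold(perm_max, alpha_adj)
  } else {
    perm_max <- NULL
    p_value <- (1 + colSums(sweep(perm_lods, 2, observed_lod, `>=`))) /
      (1 + n_perm)
    thr <- lod_threshold(as.numeric(perm_lods), alpha_adj)
  }
  observed <- data.frame(trait = spec$trait, marker = markers,
                         n = colSums(!is.na(Gm)), lod = observed_lod,
                         pve = pve_from_lod(observed_lod, colSums(!is.na(Gm))),
                         p_value = as.numeric(p_value),
                         threshold = thr,
                         significant = as.numeric(p_value) <= alpha_adj,
                         stringsAsFactors = FALSE, row.names = NULL)
  structure(list(observed = observed, perm_lods = perm_lods,
                 perm_max = perm_max, lod_threshold = thr,
                 alpha_adjusted = alpha_adj, mode = mode,
                 n_perm = as.integer(n_perm), seed = seed, strata = strata,
                 n = n),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation_result: %d permutations, mode=%s, strata=%s, LOD threshold %.3g (alpha=%.4g)\n",
              x$n_perm, x$mode, x$strata, x$lod_threshold, x$alpha_adjusted))
  print(x$observed, ...)
  invisible(x)
}
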