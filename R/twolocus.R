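#' Pooled-variance two-sample contrast between genotype-class groups
#'
#' Student's t with pooled variance and `df = nA + nB - 2`, two-sided
#' p-value — the classical contrast for comparing covariate-adjusted trait
#' means between genotype classes.
#'
#' @param adjusted numeric vector of (adjusted) trait values.
#' @param maskA,maskB logical vectors selecting the two groups (disjoint).
#' @return List with `t`, `df`, `p`, `mean_A`, `mean_B`, `n_A`, `n_B`.
#' @export
class_contrast <- function(adjusted, maskA, maskB) {
  stopifnot(length(maskA) == length(adjusted),
            length(maskB) == length(adjusted))
  if (any(maskA & maskB)) stop("contrast groups overlap")
  a <- adjusted[maskA & !is.na(adjusted)]
  b <- adjusted[maskB & !is.na(adjusted)]
  nA <- length(a); nB <- length(b)
  if (nA < 2L || nB < 2L) stop("both groups need n >= 2")
  sp2 <- ((nA - 1) * stats::var(a) + (nB - 1) * stats::var(b)) / (nA + nB - 2)
  if (sp2 == 0) stop("zero pooled variance")
  tval <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / nA + 1 / nB))
  df <- nA + nB - 2L
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df),
       mean_A = mean(a), mean_B = mean(b), n_A = nA, n_B = nB)
}

#' Two-locus genotype-class decomposition of adjusted trait values
#'
#' Cross-tabulates adjusted trait values over the up-to-9 genotype
#' combinations at two markers (cells labelled `"g1:g2"`, e.g. `"LL:CL"`)
#' and evaluates declaratively specified cell-set contrasts — the device
#' used to expose dominance at the major locus and an epistatic 3' effect
#' visible only on the LL background.
#'
#' @param adjusted data frame from [adjusted_trait_values()], or a numeric
#'   vector.
#' @param g1,g2 genotype call vectors at the two markers, aligned with
#'   `adjusted`.
#' @param contrasts named list of `list(A = cells, B = cells)` entries,
#'   each cell set a character vector of `"g1:g2"` labels (or bare `g1`
#'   labels, which select all cells with that first-marker genotype).
#' @return A `two_locus_table`: `cells` (data frame `g1`, `g2`, `cell`,
#'   `n`, `mean`, `sd`; empty cells have `n = 0`) and `contrasts` (data
#'   frame with `t`, `df`, `p` and group sizes).
#' @export
two_locus_table <- function(adjusted, g1, g2, contrasts = list()) {
  vals <- if (is.data.frame(adjusted)) adjusted$adjusted else as.numeric(adjusted)
  stopifnot(length(g1) == length(vals), length(g2) == length(vals))
  lev <- c("CC", "CL", "LL")
  keep <- !is.na(vals) & g1 %in% lev & g2 %in% lev
  vals <- vals[keep]; g1 <- g1[keep]; g2 <- g2[keep]
  cell <- paste(g1, g2, sep = ":")
  grid <- expand.grid(g1 = lev, g2 = lev, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid$cell <- paste(grid$g1, grid$g2, sep = ":")
  grid$n <- vapply(grid$cell, function(cl) sum(cell == cl), integer(1))
  grid$mean <- vapply(grid$cell, function(cl) {
    if (any(cell == cl)) mean(vals[cell == cl]) else NA_real_
  }, numeric(1))
  grid$sd <- vapply(grid$cell, function(cl) {
    if (sum(cell == cl) > 1) stats::sd(vals[cell == cl]) else NA_real_
  }, numeric(1))
  expand_cells <- function(cl) {
    unlist(lapply(cl, function(x) {
      if (grepl(":", x, fixed = TRUE)) x else grid$cell[grid$g1 == x]
    }))
  }
  ctr <- lapply(contrasts, function(ct) {
    A <- cell %in% expand_cells(ct$A)
    B <- cell %in% expand_cells(ct$B)
    cc <- class_contrast(vals, A, B)
    data.frame(cells_A = paste(ct$A, collapse = ","),
               cells_B = paste(ct$B, collapse = ","),
               n_A = cc$n_A, n_B = cc$n_B, t = cc$t, df = cc$df, p = cc$p,
               stringsAsFactors = FALSE)
  })
  structure(list(
    cells = grid,
    contrasts = if (length(ctr)) {
      out <- do.call(rbind, ctr)
      out$name <- names(contrasts) %||% rep(NA_character_, nrow(out))
      out
    } else NULL,
    n = length(vals)), class = "two_locus_table")
}

#' @export
print.two_locus_table <- function(x, ...) {
  cat(sprintf("two_locus_table: %d individuals\n", x$n))
  print(x$cells, ...)
  if (!is.null(x$contrasts)) {
    cat("contrasts:\n")
    print(x$contrasts, ...)
  }
  invisible(x)
}
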