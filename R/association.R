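#' LOD score from nested residual sums of squares
#'
#' The strength of association between a marker and a trait is measured as
#' the log10 likelihood ratio of two nested ordinary-least-squares models:
#' a null model with covariates only (residual sum of squares `rss0`) and an
#' alternate model adding the marker genotype (`rss1`),
#' \deqn{LOD = (n/2)\,\log_{10}(RSS_0 / RSS_1)}
#' where `n` is the number of samples entering both fits.
#'
#' @param rss0,rss1 residual sums of squares of the null and alternate
#'   models; the models must be nested so `rss1 <= rss0`.
#' @param n sample size.
#' @return LOD score (non-negative).
#' @export
lod_score <- function(rss0, rss1, n) {
  if (rss1 <= 0) stop("perfect fit: rss1 must be > 0")
  if (rss1 > rss0 * (1 + 1e-12)) stop("models not nested: rss1 > rss0")
  max(0, (n / 2) * log10(rss0 / rss1))
}

#' Percent variance explained from a LOD score
#'
#' The share of phenotypic variance explained by the marker after the
#' covariates, on the percent scale:
#' \deqn{PVE = 100\,(1 - 10^{-2\,LOD/n})}
#' which by the LOD identity equals `100 * (1 - rss1/rss0)`.
#'
#' @param lod LOD score (>= 0).
#' @param n sample size used to compute the LOD.
#' @return PVE in percent (0-100).
#' @export
pve_from_lod <- function(lod, n) {
  stopifnot(all(lod >= 0), all(n >= 1))
  100 * (1 - 10^(-2 * lod / n))
}

#' Curate a trait for analysis
#'
#' Two-stage outlier handling applied before model fitting: first rows are
#' removed by declarative category predicates (e.g. poor staining quality,
#' out-of-season size classes), then trait values more than `k_sd` standard
#' deviations from the post-filter mean are removed in a single pass.
#' Rows with a missing trait value are dropped from the analysis view.
#'
#' @param pheno a `phenotype_table` (or data frame with an `id` column).
#' @param trait trait column name.
#' @param exclude list of one-sided formulas over phenotype columns; rows
#'   where a predicate evaluates `TRUE` are removed
#'   (e.g. `~ staining_quality < 3`, `~ month == "October" &
#'   standard_length_mm > 65`).  `NA` predicate values keep the row.
#' @param k_sd standard-deviation cutoff for the outlier pass (default 4).
#' @return The curated analysis view (data frame) with attribute
#'   `curation`, a list of removal counts and IDs.
#' @export
curate_trait <- function(pheno, trait, exclude = list(), k_sd = 4) {
  if (!trait %in% names(pheno)) stop("no such trait column: ", trait)
  view <- as.data.frame(pheno)
  n0 <- nrow(view)
  cat_removed <- character()
  for (f in exclude) {
    pred <- eval(f[[length(f)]], envir = view, enclos = environment(f))
    pred[is.na(pred)] <- FALSE
    cat_removed <- c(cat_removed, view$id[pred])
    view <- view[!pred, , drop = FALSE]
  }
  miss <- is.na(view[[trait]])
  view <- view[!miss, , drop = FALSE]
  y <- view[[trait]]
  s <- stats::sd(y)
  out <- if (is.na(s) || s == 0) rep(FALSE, length(y)) else abs(y - mean(y)) > k_sd * s
  outlier_ids <- view$id[out]
  view <- view[!out, , drop = FALSE]
  if (nrow(view) < 3L) stop("fewer than 3 rows remain after curation")
  attr(view, "curation") <- list(
    trait = trait, n_input = n0,
    n_category_removed = length(unique(cat_removed)),
    n_missing_trait = sum(miss),
    n_outlier_removed = length(outlier_ids),
    outlier_ids = outlier_ids, k_sd = k_sd)
  view
}

#' Fit the null or alternate linear model for a trait
#'
#' Ordinary least squares of the trait on the model-spec covariates,
#' optionally plus a marker genotype entered as an unordered 3-level factor
#' (up to 2 df; fewer if a genotype class is absent).  Rows with missing
#' values in any used column (or missing genotype) are dropped listwise.
#'
#' @param view analysis view from [curate_trait()] (any data frame with the
#'   spec's columns).
#' @param spec a [model_spec].
#' @param genotype optional character vector of genotype calls aligned with
#'   the rows of `view` (`"CC"/"CL"/"LL"/NA`); when supplied the alternate
#'   model is fitted.
#' @param marker optional marker name recorded in the result.
#' @return A `fit_result` list: `rss`, `n`, `p` (fitted parameters excluding
#'   the intercept), `coefficients`, `residuals`, `fitted`, `lm` (the
#'   underlying fit), `data` (model data including `id`), `genotype_term`.
#' @export
fit_linear_model <- function(view, spec, genotype = NULL, marker = NULL) {
  .check_spec(spec, view)
  dat <- as.data.frame(view)
  has_g <- !is.null(genotype)
  if (has_g) {
    stopifnot(length(genotype) == nrow(dat))
    dat$.genotype <- factor(genotype, levels = c("CC", "CL", "LL"))
  }
  used <- c(.spec_columns(spec), if (has_g) ".genotype")
  used <- setdiff(intersect(used, names(dat)), spec$strata)
  keep <- stats::complete.cases(dat[, used, drop = FALSE])
  dat <- droplevels(dat[keep, , drop = FALSE])
  form <- .spec_formula(spec, genotype = has_g)
  fit <- stats::lm(form, data = dat)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design; aliased term(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  res <- stats::residuals(fit)
  n <- length(res)
  p <- length(cf) - 1L
  if (n <= p + 1L) stop("too few rows (n <= p + 1) for trait ", spec$trait)
  structure(list(rss = sum(res^2), n = n, p = p, coefficients = cf,
                 residuals = res, fitted = stats::fitted(fit), lm = fit,
                 data = dat, spec = spec,
                 genotype_term = if (has_g) marker %||% ".genotype" else NULL),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: %s, n=%d, p=%d, rss=%.4g%s\n", x$spec$trait, x$n,
              x$p, x$rss,
              if (is.null(x$genotype_term)) " (null model)"
              else paste0(" (+ genotype at ", x$genotype_term, ")")))
  invisible(x)
}

#' Per-marker LOD/PVE association scan
#'
#' For each marker, the trait rows with an observed genotype at that marker
#' (and complete covariates) are kept, the null and alternate models are
#' fitted on that same subset, and the LOD score and PVE are computed.
#' Markers with fewer than two genotype classes contribute 0 genotype df and
#' are reported with LOD 0 and flagged `skipped`.
#'
#' @param view analysis view with an `id` column matching `G`'s row names.
#' @param spec a [model_spec].
#' @param G a [genotype_matrix].
#' @param markers marker names to scan (default: all columns of `G`), in map
#'   order if a map ordered `G`.
#' @return Data frame of class `association_scan`: one row per marker with
#'   `trait`, `marker`, `n`, `lod`, `pve`, `skipped`.
#' @export
scan_markers <- function(view, spec, G, markers = colnames(G)) {
  stopifnot("id" %in% names(view))
  missing_m <- setdiff(markers, colnames(G))
  if (length(missing_m)) stop("markers absent from genotype matrix: ",
                              paste(missing_m, collapse = ", "))
  ids <- intersect(view$id, rownames(G))
  view <- view[match(ids, view$id), , drop = FALSE]
  rows <- lapply(markers, function(m) {
    g <- unclass(G)[ids, m]
    obs <- !is.na(g)
    sub <- view[obs, , drop = FALSE]
    gsub <- g[obs]
    if (length(unique(gsub)) < 2L || nrow(sub) < 4L) {
      return(data.frame(trait = spec$trait, marker = m, n = sum(obs),
                        lod = 0, pve = 0, skipped = TRUE,
                        stringsAsFactors = FALSE))
    }
    alt <- fit_linear_model(sub, spec, genotype = gsub, marker = m)
    # null refitted on the rows the alternate model kept
    null <- fit_linear_model(alt$data[, setdiff(names(alt$data), ".genotype"),
                                      drop = FALSE], spec)
    lod <- lod_score(null$rss, alt$rss, alt$n)
    data.frame(trait = spec$trait, marker = m, n = alt$n, lod = lod,
               pve = pve_from_lod(lod, alt$n), skipped = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("association_scan", "data.frame")
  out
}

#' Covariate-adjusted trait values
#'
#' Adjusted values are each individual's residual from the genotype model
#' plus the model prediction for that individual's genotype when all
#' covariates are held equal: factors at their reference levels and
#' continuous covariates at their reference values (sample mean unless the
#' model spec says otherwise).  Within a genotype class this shifts all
#' values by a common constant, so class contrasts are unaffected by the
#' reference choice.
#'
#' @param fit a `fit_result` from [fit_linear_model()] that includes the
#'   genotype term.
#' @param spec the [model_spec] used for the fit (defaults to the one stored
#'   in `fit`).
#' @return Data frame with columns `id`, `genotype`, `adjusted`.
#' @export
adjusted_trait_values <- function(fit, spec = fit$spec) {
  if (is.null(fit$genotype_term)) stop("fit has no genotype term")
  dat <- fit$data
  newdata <- dat
  covariate_cols <- setdiff(intersect(.spec_columns(spec), names(dat)),
                            c(spec$trait, spec$strata))
  for (cc in covariate_cols) {
    col <- dat[[cc]]
    if (is.factor(col)) {
      ref <- spec$reference_levels[[cc]] %||% levels(col)[1L]
      if (!ref %in% levels(col)) {
        stop("reference level '", ref, "' absent from fitted levels of ", cc)
      }
      newdata[[cc]] <- factor(rep(ref, nrow(dat)), levels = levels(col))
    } else {
      newdata[[cc]] <- rep(spec$continuous_reference[[cc]] %||% mean(col),
                           nrow(dat))
    }
  }
  pred <- stats::predict(fit$lm, newdata = newdata)
  data.frame(id = if ("id" %in% names(dat)) dat$id else seq_len(nrow(dat)),
             genotype = as.character(dat$.genotype),
             adjusted = as.numeric(fit$residuals + pred),
             stringsAsFactors = FALSE)
}

# ---- fast LOD path used by the permutation engine -------------------------
# Null fit via QR once; genotype df added by residualising the dummy block
# against the null design (Frisch-Waugh).  Agrees with the lm path to 1e-10.

.null_fit_fast <- function(y, X0) {
  qr0 <- qr(X0)
  e0 <- qr.resid(qr0, y)
  list(qr = qr0, e0 = e0, rss0 = sum(e0^2), n = length(y))
}

.lod_fast <- function(nf, g) {
  f <- factor(g)
  if (nlevels(f) < 2L) return(0)
  Z <- stats::model.matrix(~ f)[, -1L, drop = FALSE]
  Zt <- qr.resid(nf$qr, Z)
  qz <- qr(Zt)
  r <- qz$rank
  if (r == 0L) return(0)
  u <- qr.qty(qz, nf$e0)[seq_len(r)]
  rss1 <- nf$rss0 - sum(u^2)
  if (rss1 <= 0) stop("perfect fit in fast LOD path")
  max(0, (nf$n / 2) * log10(nf$rss0 / rss1))
}
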