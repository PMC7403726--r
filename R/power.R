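#' Residual error variance of a fitted model
#'
#' `sigma^2 = RSS1 / (n - p - 1)`, with `p` the number of fitted parameters
#' (covariates plus genotype) excluding the intercept.
#'
#' @param fit a `fit_result` from [fit_linear_model()].
#' @return Error variance (trait units squared).
#' @export
error_variance <- function(fit) {
  if (fit$n <= fit$p + 1L) stop("n must exceed p + 1")
  fit$rss / (fit$n - fit$p - 1L)
}

#' Analytic power of the LOD test at a given variance share
#'
#' Under a true marker variance share `q`, the likelihood-ratio statistic
#' `2 ln(10) * LOD = n * ln(RSS0/RSS1)` is approximately non-central
#' chi-square with `df_genotype` degrees of freedom and non-centrality
#' `2 ln(10) * ELOD`, where `ELOD = -(n/2) log10(1 - q)` is the expected
#' LOD.  Power is the upper tail of that distribution at the LOD threshold.
#'
#' @param q variance share in `[0, 1)`.
#' @param n sample size.
#' @param lod_threshold significance threshold on the LOD scale.
#' @param df_genotype genotype degrees of freedom (2 for a 3-level factor).
#' @return Power in `[0, 1]`.
#' @export
lod_power <- function(q, n, lod_threshold, df_genotype = 2) {
  stopifnot(q >= 0, q < 1, lod_threshold > 0)
  ncp <- 2 * log(10) * (-(n / 2) * log10(1 - q))
  stats::pchisq(2 * log(10) * lod_threshold, df = df_genotype, ncp = ncp,
                lower.tail = FALSE)
}

#' Minimum detectable variance share at a given power
#'
#' The smallest variance share `q` such that the probability of the LOD
#' score exceeding `lod_threshold` is at least `power`, under the
#' non-central chi-square approximation of [lod_power()].  Solved by
#' bisection (power is monotone increasing in `q`) to a tolerance of 1e-6
#' on `q`, returning the upper bracket so the recomputed power is >= the
#' target.
#'
#' @param n sample size.
#' @param sigma2 residual error variance of the trait model (from
#'   [error_variance()]); on the variance-share scale it does not change
#'   the detectable PVE, but it is used to report the corresponding
#'   absolute genotype-class offset.
#' @param lod_threshold permutation-derived LOD threshold.
#' @param power target power (default 0.90).
#' @param df_genotype genotype degrees of freedom (default 2).
#' @return A `power_result` list: `detectable_pve` (percent),
#'   `detectable_offset` (absolute effect in trait units for a balanced
#'   two-class contrast, when `sigma2` is given), `n`, `sigma2`,
#'   `lod_threshold`, `power_target`, `achieved_power`, `df_genotype`.
#' @export
detectable_pve <- function(n, sigma2 = NULL, lod_threshold, power = 0.90,
                           df_genotype = 2) {
  stopifnot(n > df_genotype + 1, lod_threshold > 0, power > 0, power < 1)
  f <- function(q) lod_power(q, n, lod_threshold, df_genotype) - power
  hi <- 1 - 1e-12
  if (f(hi) < 0) stop("undetectable at this n: no variance share < 1 reaches the target power")
  lo <- 0
  if (f(lo) >= 0) {
    hi <- 0
  } else {
    while (hi - lo > 1e-9) {
      mid <- (lo + hi) / 2
      if (f(mid) >= 0) hi <- mid else lo <- mid
    }
  }
  q <- hi                                   # power at q is >= target
  offset <- if (!is.null(sigma2)) {
    # balanced two-class offset d with share q: q = (d/2)^2 / ((d/2)^2 + sigma2)
    2 * sqrt(sigma2 * q / (1 - q))
  } else NA_real_
  structure(list(detectable_pve = 100 * q, detectable_offset = offset,
                 n = n, sigma2 = sigma2, lod_threshold = lod_threshold,
                 power_target = power,
                 achieved_power = lod_power(q, n, lod_threshold, df_genotype),
                 df_genotype = df_genotype),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("power_result: detectable PVE %.2f%% at n=%d, LOD threshold %.3g, power %.0f%%\n",
              x$detectable_pve, x$n, x$lod_threshold, 100 * x$power_target))
  invisible(x)
}
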