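#' Declare a trait's null (covariate) model
#'
#' A declarative description of the covariate structure used throughout the
#' association, permutation and power stages: the null model regresses the
#' trait on `covariates`; the alternate model adds the focal marker's
#' genotype as an unordered 3-level factor.
#'
#' @param trait trait column name.
#' @param covariates character vector of model terms over phenotype columns,
#'   e.g. `c("family", "standard_length_mm", "sex",
#'   "standard_length_mm:family", "sex:family")`.  May be empty for a
#'   marginal (intercept-only null) analysis.
#' @param strata column used to stratify permutations (family for crosses,
#'   collection month for wild-caught samples); must be categorical.
#' @param reference_levels named list mapping factor covariates to the
#'   reference category used when computing covariate-adjusted trait values;
#'   factors not listed default to their first observed level.
#' @param continuous_reference named list mapping continuous covariates to
#'   the reference value for adjusted trait values; unlisted continuous
#'   covariates default to their sample mean.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(trait, covariates = character(), strata = NULL,
                       reference_levels = list(),
                       continuous_reference = list()) {
  stopifnot(is.character(trait), length(trait) == 1L)
  spec <- list(trait = trait, covariates = as.character(covariates),
               strata = strata,
               reference_levels = reference_levels,
               continuous_reference = continuous_reference)
  class(spec) <- "model_spec"
  spec
}

# columns a spec touches (terms split on ':' for interactions)
.spec_columns <- function(spec) {
  unique(c(spec$trait, unlist(strsplit(spec$covariates, ":", fixed = TRUE)),
           spec$strata))
}

# validate spec against a phenotype table
.check_spec <- function(spec, pheno) {
  missing_cols <- setdiff(.spec_columns(spec), names(pheno))
  if (length(missing_cols)) {
    stop("model_spec references absent column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!is.null(spec$strata) && !is.factor(pheno[[spec$strata]]) &&
      !is.character(pheno[[spec$strata]])) {
    stop("strata variable must be categorical: ", spec$strata)
  }
  invisible(TRUE)
}

# null-model formula; genotype term appended for the alternate model
.spec_formula <- function(spec, genotype = FALSE) {
  rhs <- if (length(spec$covariates)) spec$covariates else "1"
  if (genotype) rhs <- c(rhs, ".genotype")
  stats::reformulate(rhs, response = spec$trait)
}

#' Read per-trait model specifications from a YAML config file
#'
#' The file maps trait names to entries with keys `covariates`, `strata`,
#' `reference_levels` and `continuous_reference` (all optional).
#'
#' @param path YAML file path.
#' @return Named list of [model_spec] objects.
#' @export
read_model_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read config files")
  }
  cfg <- yaml::read_yaml(path)
  out <- lapply(names(cfg), function(tr) {
    e <- cfg[[tr]]
    model_spec(trait = tr,
               covariates = as.character(e$covariates %||% character()),
               strata = e$strata %||% NULL,
               reference_levels = e$reference_levels %||% list(),
               continuous_reference = e$continuous_reference %||% list())
  })
  names(out) <- names(cfg)
  out
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec:", x$trait, "~",
      if (length(x$covariates)) paste(x$covariates, collapse = " + ") else "1",
      "\n")
  if (!is.null(x$strata)) cat("  permutation strata:", x$strata, "\n")
  invisible(x)
}
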