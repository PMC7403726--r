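#' Declare a simulated locus effect
#'
#' Effect architecture for the trait generator.  Effects are offsets applied
#' to a genotype-defined cell, with magnitude solved at generation time so
#' the locus's realized marginal variance share matches `target_pve`.
#'
#' @param focal_marker marker carrying the effect.
#' @param mode effect mode:
#'   \describe{
#'     \item{dominant_C / recessive_L}{offset applied to LL individuals only
#'       (the marine C allele is dominant, equivalently the freshwater L
#'       allele recessive): CC and CL share a mean distinct from LL.}
#'     \item{additive}{effect proportional to L-allele dosage.}
#'     \item{epistatic_on_LL_background}{offset applied only to individuals
#'       LL at `focal_marker` *and* LL at `conditioning_marker` — a minor 3'
#'       locus expressed only on the freshwater background at the major
#'       locus.}
#'   }
#' @param target_pve marginal variance share in the simulated population,
#'   in `[0, 1)`.
#' @param conditioning_marker required for the epistatic mode.
#' @param direction sign of the offset (default `-1`: the freshwater allele
#'   lowers meristic trait values).
#' @return A `locus_effect` list.
#' @export
locus_effect <- function(focal_marker,
                         mode = c("dominant_C", "additive", "recessive_L",
                                  "epistatic_on_LL_background"),
                         target_pve, conditioning_marker = NULL,
                         direction = -1) {
  mode <- match.arg(mode)
  stopifnot(target_pve >= 0, target_pve < 1)
  if (mode == "epistatic_on_LL_background" && is.null(conditioning_marker)) {
    stop("epistatic mode requires a conditioning_marker")
  }
  structure(list(focal_marker = focal_marker, mode = mode,
                 target_pve = target_pve,
                 conditioning_marker = conditioning_marker,
                 direction = sign(direction)),
            class = "locus_effect")
}

#' Default haplotype pool for the simulator
#'
#' Three standing chromosome classes: the marine all-C haplotype, the full
#' 16-kb freshwater (all-L) haplotype, and a short-L haplotype whose L block
#' is anchored at the 5' region edge and ends at `short_extent_bp`.
#'
#' @param map a [marker_map].
#' @param freq_C,freq_full_L,freq_short_L pool frequencies (must sum to 1).
#' @param short_extent_bp 3' physical extent of the short-L block.
#' @return List of `list(haplotype = named allele vector, frequency)`.
#' @export
default_haplotype_pool <- function(map, freq_C = 0.55, freq_full_L = 0.30,
                                   freq_short_L = 0.15,
                                   short_extent_bp = 11000L) {
  alleles <- function(v) stats::setNames(v, map$name)
  list(
    list(haplotype = alleles(rep("C", nrow(map))), frequency = freq_C),
    list(haplotype = alleles(rep("L", nrow(map))), frequency = freq_full_L),
    list(haplotype = alleles(ifelse(map$position_bp <= short_extent_bp,
                                    "L", "C")),
         frequency = freq_short_L)
  )
}

#' Default covariate model for the simulator
#'
#' Distributions and effect sizes for the covariates the analysis adjusts
#' for: sex, standard length, family (cross design) and collection month
#' (wild-caught design), plus effect-free collection covariates (tank,
#' staining method and quality, days held) used to exercise curation rules.
#' Family and month effects are drawn once per population from centred
#' normals with the stated spread.
#'
#' @param sex_effect trait offset for males.
#' @param length_mean,length_sd standard length distribution (mm).
#' @param length_slope trait change per mm of standard length.
#' @param n_families,family_sd number of families and spread of their
#'   effects.
#' @param months,month_sd collection months and spread of their effects.
#' @param n_tanks number of holding tanks.
#' @return A `covariate_model` list.
#' @export
default_covariate_model <- function(sex_effect = 0.3, length_mean = 55,
                                    length_sd = 6, length_slope = 0.05,
                                    n_families = 6, family_sd = 0.3,
                                    months = c("May", "June", "September",
                                               "October"),
                                    month_sd = 0.3, n_tanks = 3) {
  structure(list(sex_effect = sex_effect, length_mean = length_mean,
                 length_sd = length_sd, length_slope = length_slope,
                 n_families = n_families, family_sd = family_sd,
                 months = months, month_sd = month_sd, n_tanks = n_tanks),
            class = "covariate_model")
}

#' Full parameterisation of a synthetic population
#'
#' @param n_individuals number of individuals.
#' @param map a [marker_map].
#' @param haplotype_pool list of `(haplotype, frequency)` entries; the
#'   frequencies must sum to 1 (tolerance 1e-9) and each haplotype must
#'   cover every marker of `map`.
#' @param recombinant_fraction probability an individual carries a
#'   chromosome recombined at a uniformly chosen inter-marker breakpoint.
#' @param architecture list of [locus_effect]s; their `target_pve` values
#'   must sum to < 1.
#' @param covariate_model a [default_covariate_model()]-style list.
#' @param missing_rate per-call missingness probability (runs capped at 3).
#' @param noise_sd residual (environmental) standard deviation.
#' @param intercept trait intercept.
#' @param trait_name trait column name.
#' @param trait_type `"gaussian"` or `"count"` (rounded, truncated at 0).
#' @param seed RNG seed used by [generate_population()].
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_individuals, map = default_marker_map(),
                              haplotype_pool = default_haplotype_pool(map),
                              recombinant_fraction = 0.22,
                              architecture = list(
                                locus_effect("Stn382", "dominant_C", 0.90),
                                locus_effect("SNP13",
                                             "epistatic_on_LL_background",
                                             0.02,
                                             conditioning_marker = "Stn382")),
                              covariate_model = default_covariate_model(),
                              missing_rate = 0.02, noise_sd = 1,
                              intercept = 30,
                              trait_name = "left_plate_count",
                              trait_type = c("gaussian", "count"),
                              seed = 1L) {
  trait_type <- match.arg(trait_type)
  freqs <- vapply(haplotype_pool, `[[`, numeric(1), "frequency")
  if (abs(sum(freqs) - 1) > 1e-9) stop("pool frequencies must sum to 1")
  for (h in haplotype_pool) {
    if (!all(map$name %in% names(h$haplotype))) {
      stop("each pool haplotype needs one allele per marker")
    }
    if (!all(h$haplotype[map$name] %in% c("C", "L"))) {
      stop("pool alleles must be C or L")
    }
  }
  stopifnot(recombinant_fraction >= 0, recombinant_fraction <= 1,
            missing_rate >= 0, missing_rate <= 1, noise_sd >= 0)
  q_total <- sum(vapply(architecture, `[[`, numeric(1), "target_pve"))
  if (q_total >= 1) stop("infeasible variance budget: locus shares sum to >= 1")
  structure(list(n_individuals = as.integer(n_individuals), map = map,
                 haplotype_pool = haplotype_pool,
                 recombinant_fraction = recombinant_fraction,
                 architecture = architecture,
                 covariate_model = covariate_model,
                 missing_rate = missing_rate, noise_sd = noise_sd,
                 intercept = intercept, trait_name = trait_name,
                 trait_type = trait_type, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a synthetic population
#'
#' Draws two chromosomes per individual from the haplotype pool; with
#' probability `recombinant_fraction` one of them is replaced by a
#' historically recombined chromosome — a marine-5'/freshwater-3' chimera
#' with a uniformly chosen inter-marker breakpoint.  (The complementary
#' orientation, freshwater-5'/marine-3', is indistinguishable from a
#' standing short-L haplotype on unphased genotypes, so generating it would
#' conflate the recombinant and short-L carrier classes.)  The trait is
#' `intercept + covariate effects + locus effects + Gaussian noise`, with
#' each locus-effect magnitude solved from the variance-share identity
#' `a = sqrt(q * T / var(z))`, where `z` is the realized affected-cell
#' indicator (or dosage) and `T = (noise + covariate variance) / (1 - sum q)`
#' is the implied total variance, so realized marginal shares match
#' `target_pve` in expectation.
#'
#' @param cfg a [simulation_config].
#' @return A `simulated_population` list: `genotypes` (masked
#'   [genotype_matrix]), `phenotypes` (phenotype table), and `truth` — the
#'   full unmasked genotypes, each individual's two chromosome allele
#'   vectors, recombination flags and breakpoint intervals, solved effect
#'   coefficients, per-individual covariate and locus contributions, and the
#'   noise draw.
#' @export
generate_population <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  n <- cfg$n_individuals
  map <- cfg$map
  m <- nrow(map)
  ids <- sprintf("ind%05d", seq_len(n))
  hap_alleles <- t(vapply(cfg$haplotype_pool,
                          function(h) h$haplotype[map$name], character(m)))
  freqs <- vapply(cfg$haplotype_pool, `[[`, numeric(1), "frequency")
  idx1 <- sample.int(nrow(hap_alleles), n, replace = TRUE, prob = freqs)
  idx2 <- sample.int(nrow(hap_alleles), n, replace = TRUE, prob = freqs)
  A <- hap_alleles[idx1, , drop = FALSE]
  B <- hap_alleles[idx2, , drop = FALSE]
  is_rec <- stats::runif(n) < cfg$recombinant_fraction
  breakpoint <- rep(NA_integer_, n)
  rec_slot <- rep(NA_integer_, n)
  for (i in which(is_rec)) {
    j <- sample.int(m - 1L, 1L)            # chimera: C for 1..j, L beyond
    chim <- c(rep("C", j), rep("L", m - j))
    if (stats::runif(1) < 0.5) A[i, ] <- chim else B[i, ] <- chim
    breakpoint[i] <- j
    rec_slot[i] <- ifelse(identical(A[i, ], chim), 1L, 2L)
  }
  dos <- (A == "L") + (B == "L")
  geno <- matrix(c("CC", "CL", "LL")[dos + 1L], n, m,
                 dimnames = list(ids, map$name))
  cm <- cfg$covariate_model
  sex <- sample(c("M", "F"), n, replace = TRUE)
  std_len <- stats::rnorm(n, cm$length_mean, cm$length_sd)
  family <- sample(sprintf("fam%02d", seq_len(cm$n_families)), n,
                   replace = TRUE)
  month <- sample(cm$months, n, replace = TRUE)
  tank <- sample(sprintf("tank%d", seq_len(cm$n_tanks)), n, replace = TRUE)
  staining_method <- sample(c("daspei", "alkphos"), n, replace = TRUE)
  staining_quality <- sample(1:7, n, replace = TRUE,
                             prob = c(1, 2, 4, 7, 7, 4, 2))
  days_held <- stats::rpois(n, 10)
  fam_eff <- stats::setNames(stats::rnorm(cm$n_families, 0, cm$family_sd),
                             sprintf("fam%02d", seq_len(cm$n_families)))
  month_eff <- stats::setNames(stats::rnorm(length(cm$months), 0, cm$month_sd),
                               cm$months)
  cov_contrib <- cm$sex_effect * (sex == "M") +
    cm$length_slope * (std_len - cm$length_mean) +
    fam_eff[family] + month_eff[month]
  q_total <- sum(vapply(cfg$architecture, `[[`, numeric(1), "target_pve"))
  total_var <- (cfg$noise_sd^2 + stats::var(cov_contrib)) / (1 - q_total)
  locus_contrib <- numeric(n)
  effects <- list()
  for (le in cfg$architecture) {
    fm <- match(le$focal_marker, map$name)
    if (is.na(fm)) stop("architecture marker not in map: ", le$focal_marker)
    z <- switch(le$mode,
      dominant_C = ,
      recessive_L = as.numeric(dos[, fm] == 2L),
      additive = as.numeric(dos[, fm]),
      epistatic_on_LL_background = {
        cmk <- match(le$conditioning_marker, map$name)
        if (is.na(cmk)) stop("conditioning marker not in map: ",
                             le$conditioning_marker)
        as.numeric(dos[, fm] == 2L & dos[, cmk] == 2L)
      })
    vz <- stats::var(z)
    if (le$target_pve > 0 && vz == 0) {
      stop("affected genotype cell absent; cannot realize effect at ",
           le$focal_marker)
    }
    a <- if (le$target_pve == 0) 0 else
      le$direction * sqrt(le$target_pve * total_var / vz)
    locus_contrib <- locus_contrib + a * z
    effects[[length(effects) + 1L]] <-
      list(focal_marker = le$focal_marker, mode = le$mode,
           target_pve = le$target_pve, coefficient = a, indicator = z)
  }
  noise <- stats::rnorm(n, 0, cfg$noise_sd)
  trait <- cfg$intercept + cov_contrib + locus_contrib + noise
  if (cfg$trait_type == "count") trait <- pmax(0, round(trait))
  pheno <- phenotype_table(data.frame(
    id = ids, trait = trait, sex = sex, standard_length_mm = std_len,
    family = family, month = month, tank = tank,
    staining_method = staining_method, staining_quality = staining_quality,
    days_held = days_held, stringsAsFactors = FALSE))
  names(pheno)[names(pheno) == "trait"] <- cfg$trait_name
  full <- genotype_matrix(geno, map = map, normalize = FALSE)
  masked <- if (cfg$missing_rate > 0) {
    .apply_mask(full, cfg$missing_rate, max_run = 3L)
  } else full
  truth <- list(genotypes_full = full, chrom1 = A, chrom2 = B,
                recombinant = is_rec, breakpoint_interval = breakpoint,
                recombined_slot = rec_slot, effects = effects,
                covariate_contrib = as.numeric(cov_contrib),
                locus_contrib = locus_contrib, noise = noise,
                family_effects = fam_eff, month_effects = month_eff,
                total_var = total_var, config = cfg)
  structure(list(genotypes = masked, phenotypes = pheno, truth = truth),
            class = "simulated_population")
}

#' @export
print.simulated_population <- function(x, ...) {
  cat(sprintf("simulated_population: %d individuals x %d markers, %.0f%% recombinant carriers\n",
              nrow(x$genotypes), ncol(x$genotypes),
              100 * mean(x$truth$recombinant)))
  invisible(x)
}

#' Generate a genotype-independent null trait
#'
#' The trait is covariate effects plus Gaussian noise, independent of every
#' genotype — the null under which permutation type-I error is assessed.
#'
#' @param pheno phenotype table providing the covariates.
#' @param covariate_model a [default_covariate_model()]-style list.
#' @param noise_sd residual standard deviation.
#' @param seed optional RNG seed (bit-identical trait for a fixed seed).
#' @return Numeric trait column aligned with `pheno` rows.
#' @export
generate_null_trait <- function(pheno, covariate_model = default_covariate_model(),
                                noise_sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cm <- covariate_model
  n <- nrow(pheno)
  contrib <- numeric(n)
  if ("sex" %in% names(pheno)) {
    contrib <- contrib + cm$sex_effect * (as.character(pheno$sex) == "M")
  }
  if ("standard_length_mm" %in% names(pheno)) {
    contrib <- contrib +
      cm$length_slope * (pheno$standard_length_mm - cm$length_mean)
  }
  for (col in c("family", "month")) {
    if (col %in% names(pheno)) {
      lev <- levels(factor(pheno[[col]]))
      sd_col <- if (col == "family") cm$family_sd else cm$month_sd
      eff <- stats::setNames(stats::rnorm(length(lev), 0, sd_col), lev)
      contrib <- contrib + eff[as.character(pheno[[col]])]
    }
  }
  as.numeric(contrib + stats::rnorm(n, 0, noise_sd))
}

#' Mask observed genotypes in short missing runs
#'
#' Test fixture generator for the imputation rule: sets calls missing with
#' per-call probability `rate`, then truncates any missing run longer than
#' `max_run` (the tail of the run is restored), so no introduced run exceeds
#' `max_run`.
#'
#' @param G a fully observed [genotype_matrix].
#' @param rate per-call masking probability in `[0, 1]`.
#' @param max_run maximum introduced run length.
#' @param seed optional RNG seed.
#' @return The masked [genotype_matrix].
#' @export
mask_genotypes <- function(G, rate, max_run = 3L, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  if (anyNA(unclass(G))) stop("G must be fully observed")
  if (!is.null(seed)) set.seed(seed)
  .apply_mask(G, rate, max_run)
}

.apply_mask <- function(G, rate, max_run) {
  M <- unclass(G)
  if (rate > 0) {
    mask <- matrix(stats::runif(length(M)) < rate, nrow(M), ncol(M))
    for (i in seq_len(nrow(M))) {
      r <- rle(mask[i, ])
      ends <- cumsum(r$lengths)
      for (k in which(r$values & r$lengths > max_run)) {
        keep_from <- ends[k] - (r$lengths[k] - max_run) + 1L
        mask[i, keep_from:ends[k]] <- FALSE
      }
    }
    M[mask] <- NA_character_
  }
  genotype_matrix(M, imputed = attr(G, "imputed"), normalize = FALSE)
}
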