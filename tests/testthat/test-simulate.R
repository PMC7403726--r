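test_that("generation is bit-reproducible for a fixed seed", {
  cfg <- simulation_config(150, seed = 51)
  a <- generate_population(cfg)
  b <- generate_population(cfg)
  expect_identical(unclass(a$genotypes), unclass(b$genotypes))
  expect_identical(a$phenotypes$left_plate_count, b$phenotypes$left_plate_count)
  c <- generate_population(simulation_config(150, seed = 52))
  expect_false(identical(a$phenotypes$left_plate_count,
                         c$phenotypes$left_plate_count))
})

test_that("config invariants are enforced", {
  map <- default_marker_map()
  pool <- default_haplotype_pool(map, freq_C = 0.6, freq_full_L = 0.3,
                                 freq_short_L = 0.2)          # sums to 1.1
  expect_error(simulation_config(10, haplotype_pool = pool), "sum to 1")
  expect_error(simulation_config(10, architecture = list(
    locus_effect("Stn382", "dominant_C", 0.7),
    locus_effect("SNP13", "dominant_C", 0.4))), "variance budget")
  expect_error(locus_effect("x", "epistatic_on_LL_background", 0.1),
               "conditioning_marker")
})

test_that("allele frequencies match the pool-implied expectation", {
  cfg <- simulation_config(2000, recombinant_fraction = 0, missing_rate = 0,
                           seed = 53)
  pop <- generate_population(cfg)
  # pool L frequency at the 5' marker: full-L 0.30 + short-L 0.15
  af <- allele_frequency(pop$genotypes, "Stn382")
  ci <- qbinom(c(0.025, 0.975), af$n_chromosomes, 0.45) / af$n_chromosomes
  expect_gte(af$freq_L, ci[1])
  expect_lte(af$freq_L, ci[2])
  # 3' of the short-L extent only full-L contributes
  af3 <- allele_frequency(pop$genotypes, "SNP13")
  ci3 <- qbinom(c(0.025, 0.975), af3$n_chromosomes, 0.30) / af3$n_chromosomes
  expect_gte(af3$freq_L, ci3[1])
  expect_lte(af3$freq_L, ci3[2])
})

test_that("dominant architecture yields the CC~CL != LL mean pattern", {
  cfg <- simulation_config(700, architecture = list(
    locus_effect("Stn382", "dominant_C", 0.9)), missing_rate = 0, seed = 54)
  pop <- generate_population(cfg)
  y <- pop$phenotypes$left_plate_count
  g <- unclass(pop$genotypes)[, "Stn382"]
  m <- tapply(y, g, mean)
  expect_lt(abs(m["CC"] - m["CL"]), 0.5)
  expect_gt(abs(m["CC"] - m["LL"]), 3)
})

test_that("realized marginal variance shares converge to target_pve", {
  # single-locus architectures: the marginal decomposition is the locus's
  # own term.  (With several loci on one haplotype the indicators are in LD
  # and marginal shares also absorb cross-locus covariance, as in the real
  # system; the generator matches each term's own variance share.)
  for (arch in list(locus_effect("Stn382", "dominant_C", 0.5),
                    locus_effect("Cnv770", "additive", 0.3))) {
    cfg <- simulation_config(10000, architecture = list(arch),
                             missing_rate = 0, seed = 55)
    pop <- generate_population(cfg)
    y <- pop$phenotypes$left_plate_count
    z <- pop$truth$effects[[1]]$indicator
    share <- summary(stats::lm(y ~ z))$r.squared    # one-way decomposition
    expect_lt(abs(share - arch$target_pve), 0.01)
  }
})

test_that("the epistatic locus acts only on the LL major-locus background", {
  cfg <- simulation_config(4000, architecture = list(
    locus_effect("Stn382", "dominant_C", 0.6),
    locus_effect("SNP13", "epistatic_on_LL_background", 0.05,
                 conditioning_marker = "Stn382")),
    missing_rate = 0, seed = 56)
  pop <- generate_population(cfg)
  y <- pop$phenotypes$left_plate_count
  G <- unclass(pop$genotypes)
  on_LL <- G[, "Stn382"] == "LL"
  gap_LL <- mean(y[on_LL & G[, "SNP13"] == "LL"]) -
    mean(y[on_LL & G[, "SNP13"] != "LL"])
  gap_C <- mean(y[!on_LL & G[, "SNP13"] == "LL"]) -
    mean(y[!on_LL & G[, "SNP13"] != "LL"])
  expect_lt(gap_LL, -0.5)          # expressed on the freshwater background
  expect_lt(abs(gap_C), 0.4)       # silent elsewhere
})

test_that("null traits are genotype-independent with calibrated rejection", {
  cfg <- simulation_config(200, architecture = list(), missing_rate = 0,
                           seed = 57)
  pop <- generate_population(cfg)
  t1 <- generate_null_trait(pop$phenotypes, seed = 58)
  t2 <- generate_null_trait(pop$phenotypes, seed = 58)
  expect_identical(t1, t2)                       # bit-identical under a seed
  # anova F-test of genotype after covariates rejects at ~nominal rate
  spec <- model_spec("null_trait", covariates = c("sex", "standard_length_mm"))
  reps <- 200
  pvals <- numeric(reps)
  view <- as.data.frame(pop$phenotypes)
  g <- unclass(pop$genotypes)[view$id, "Stn382"]
  for (r in seq_len(reps)) {
    view$null_trait <- generate_null_trait(pop$phenotypes, seed = 1000 + r)
    alt <- fit_linear_model(view, spec, genotype = g)
    null <- fit_linear_model(view, spec)
    pvals[r] <- anova(null$lm, alt$lm)[2, "Pr(>F)"]
  }
  rate <- mean(pvals <= 0.05)
  ci <- qbinom(c(0.025, 0.975), reps, 0.05) / reps
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})
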