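test_that("LOD and PVE follow the model-comparison formulas exactly", {
  expect_equal(lod_score(2, 2, 10), 0)
  expect_equal(lod_score(2, 1, 10), 5 * log10(2))
  # inverse identity: the printed left-plate result implies this rss ratio
  expect_equal(lod_score(10^(2 * 344.3 / 578), 1, 578), 344.3)
  expect_error(lod_score(2, 0, 10), "perfect fit")
  expect_error(lod_score(1, 2, 10), "nested")
  expect_equal(pve_from_lod(0, 100), 0)
  # exact algebra: pve == 100 * (1 - rss1/rss0) for any nested pair
  set.seed(1)
  for (i in 1:50) {
    r1 <- runif(1, 0.1, 5); r0 <- r1 * runif(1, 1, 20); n <- sample(5:900, 1)
    expect_equal(pve_from_lod(lod_score(r0, r1, n), n), 100 * (1 - r1 / r0),
                 tolerance = 1e-12)
  }
})

test_that("curation removes category-rule rows then single-pass outliers", {
  set.seed(47)
  ph <- phenotype_table(data.frame(
    id = sprintf("f%02d", 1:40),
    plates = c(80, rnorm(39, 30, 1)),                  # one gross outlier
    staining_quality = c(rep(5, 35), rep(2, 5)),
    stringsAsFactors = FALSE))
  view <- curate_trait(ph, "plates",
                       exclude = list(~ staining_quality < 3), k_sd = 4)
  cur <- attr(view, "curation")
  expect_equal(cur$n_category_removed, 5L)
  expect_equal(cur$n_outlier_removed, 1L)
  expect_false("f01" %in% view$id)
  # constant trait: sd is 0, no outliers removed
  ph$plates <- 30
  v2 <- curate_trait(ph, "plates")
  expect_equal(attr(v2, "curation")$n_outlier_removed, 0L)
  expect_error(curate_trait(ph, "nope"), "no such trait")
})

test_that("null-model fit reproduces the closed-form variance identity", {
  set.seed(42)
  y <- rnorm(200)
  view <- data.frame(id = as.character(1:200), y = y)
  spec <- model_spec("y")
  fit <- fit_linear_model(view, spec)
  expect_equal(fit$rss, (200 - 1) * var(y), tolerance = 1e-10)
  expect_equal(fit$p, 0L)
})

test_that("adding the causal genotype reduces RSS and the scan finds it", {
  cfg <- simulation_config(400, architecture = list(
    locus_effect("Stn382", "dominant_C", 0.6)), missing_rate = 0, seed = 43)
  pop <- generate_population(cfg)
  spec <- model_spec("left_plate_count",
                     covariates = c("sex", "standard_length_mm"))
  view <- curate_trait(pop$phenotypes, "left_plate_count")
  g <- unclass(pop$genotypes)[view$id, "Stn382"]
  null <- fit_linear_model(view, spec)
  alt <- fit_linear_model(view, spec, genotype = g, marker = "Stn382")
  expect_lt(alt$rss, null$rss)
  sc <- scan_markers(view, spec, pop$genotypes)
  expect_equal(sc$marker, colnames(pop$genotypes))    # map order preserved
  expect_equal(sc$marker[which.max(sc$lod)], "Stn382")
  expect_true(all(sc$lod >= 0))
  # pve column satisfies the identity at 1e-9
  expect_equal(sc$pve, pve_from_lod(sc$lod, sc$n), tolerance = 1e-9)
})

test_that("monomorphic markers contribute no degrees of freedom", {
  map <- tiny_map(2)
  G <- make_G(replicate(30, c("CC", "CL"), simplify = FALSE), map)
  rownames(G) <- as.character(1:30)
  set.seed(2)
  view <- data.frame(id = as.character(1:30), y = rnorm(30))
  sc <- scan_markers(view, model_spec("y"), G)
  expect_true(sc$skipped[sc$marker == "m1"])
  expect_equal(sc$lod[sc$marker == "m1"], 0)
})

test_that("LOD from the model-comparison path matches a naive reimplementation", {
  set.seed(44)
  for (i in 1:10) {
    n <- 40
    view <- data.frame(id = as.character(1:n), y = rnorm(n),
                       x = rnorm(n), f = sample(c("u", "v"), n, TRUE))
    g <- sample(c("CC", "CL", "LL"), n, TRUE)
    spec <- model_spec("y", covariates = c("x", "f"))
    alt <- fit_linear_model(view, spec, genotype = g)
    null <- fit_linear_model(view, spec)
    lod_pkg <- lod_score(null$rss, alt$rss, alt$n)
    # naive: explicit normal equations and accumulated squared residuals
    X0 <- model.matrix(~ x + f, view)
    X1 <- model.matrix(~ x + f + factor(g, levels = c("CC", "CL", "LL")),
                       view)
    rss <- function(X, y) {
      beta <- solve(crossprod(X), crossprod(X, y))
      r <- y - X %*% beta
      s <- 0
      for (e in r) s <- s + e * e
      s
    }
    lod_naive <- (n / 2) * log10(rss(X0, view$y) / rss(X1, view$y))
    expect_equal(lod_pkg, lod_naive, tolerance = 1e-10)
  }
})

test_that("rank-deficient designs fail loudly, naming the aliased terms", {
  set.seed(45)
  view <- data.frame(id = as.character(1:30), y = rnorm(30), x = rnorm(30))
  view$z <- 2 * view$x                                  # aliased
  expect_error(fit_linear_model(view, model_spec("y", c("x", "z"))),
               "aliased")
})

test_that("adjusted trait values equalise covariates but keep residual spread", {
  cfg <- simulation_config(500, architecture = list(
    locus_effect("Stn382", "dominant_C", 0.7)), missing_rate = 0, seed = 46)
  pop <- generate_population(cfg)
  spec <- model_spec("left_plate_count",
                     covariates = c("sex", "standard_length_mm", "family"))
  view <- curate_trait(pop$phenotypes, "left_plate_count")
  g <- unclass(pop$genotypes)[view$id, "Stn382"]
  fit <- fit_linear_model(view, spec, genotype = g, marker = "Stn382")
  adj <- adjusted_trait_values(fit)
  # within a genotype class, adjusted values are residuals plus a constant
  for (cl in unique(adj$genotype)) {
    idx <- adj$genotype == cl
    expect_equal(var(adj$adjusted[idx]), var(fit$residuals[idx]),
                 tolerance = 1e-9)
  }
  # class mean differences recover the simulated dominant offset
  a_true <- pop$truth$effects[[1]]$coefficient
  gap <- mean(adj$adjusted[adj$genotype == "LL"]) -
    mean(adj$adjusted[adj$genotype == "CC"])
  expect_lt(abs(gap - a_true) / abs(a_true), 0.1)
  cc_cl <- mean(adj$adjusted[adj$genotype == "CC"]) -
    mean(adj$adjusted[adj$genotype == "CL"])
  expect_lt(abs(cc_cl), 0.35 * abs(a_true))

  # a model with no covariates adjusts nothing
  fit0 <- fit_linear_model(view, model_spec("left_plate_count"), genotype = g)
  adj0 <- adjusted_trait_values(fit0)
  expect_equal(adj0$adjusted, fit0$data$left_plate_count, tolerance = 1e-10)
  expect_error(adjusted_trait_values(fit_linear_model(view, spec)),
               "no genotype term")
})
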