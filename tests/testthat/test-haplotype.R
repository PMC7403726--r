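test_that("carrier classes follow the dosage rules, with the NAKA exemption", {
  map <- default_marker_map()
  rm_names <- region_markers(map)
  k <- length(rm_names)
  gv <- function(...) stats::setNames(c(...), rm_names)

  full_het <- gv(rep("CL", k))
  full_het["NAKA"] <- "CC"                       # NAKA exempt from full-L
  expect_equal(classify_carrier(full_het, map)$class, "het_full_L")
  expect_equal(classify_carrier(gv(rep("CC", k)), map)$class, "hom_C")
  expect_equal(classify_carrier(gv(rep("LL", k)), map)$class, "hom_full_L")

  short <- gv(c(rep("CL", 5), rep("CC", k - 5)))
  call <- classify_carrier(short, map)
  expect_equal(call$class, "het_short_L")
  expect_equal(call$short_L_extent, rm_names[5])

  hom_short <- gv(c(rep("LL", 4), rep("CL", 3), rep("CC", k - 7)))
  expect_equal(classify_carrier(hom_short, map)$class, "hom_short_L")

  # phase-forced double transition: CC,CC,LL,... is a recombinant with the
  # breakpoint bracketed between markers 2 and 3
  rec <- gv(c("CC", "CC", rep("LL", k - 2)))
  call <- classify_carrier(rec, map)
  expect_equal(call$class, "recombinant")
  expect_equal(call$breakpoint_intervals$left[1], rm_names[2])
  expect_equal(call$breakpoint_intervals$right[1], rm_names[3])

  # LL at 5', CL between, CC at 3': two short-L chromosomes of different
  # extents (L dosage steps down monotonically), not a recombinant
  sandwich <- gv(c("LL", rep("CL", k - 2), "CC"))
  expect_equal(classify_carrier(sandwich, map)$class, "hom_short_L")
  # the mirror pattern (dosage stepping up 5' to 3') forces a recombinant
  mirror <- gv(c("CC", rep("CL", k - 2), "LL"))
  expect_equal(classify_carrier(mirror, map)$class, "recombinant")

  # missing calls are wildcards, never evidence of recombination
  wild <- gv(c("CL", rep(NA, k - 2), "CC"))
  expect_equal(classify_carrier(wild, map)$class, "het_short_L")
  expect_equal(classify_carrier(gv(rep(NA, k)), map)$class, "unclassifiable")
})

test_that("recombinant calls agree with the exhaustive two-chromosome oracle", {
  k <- 6
  map <- tiny_map(k)
  ok_set <- oracle_nonrecombinant_set(k)
  vecs <- all_genotype_vectors(k)
  got <- apply(vecs, 1, function(g) {
    classify_carrier(stats::setNames(g, map$name), map,
                     naka_marker = NULL)$class
  })
  want_rec <- !(apply(vecs, 1, paste, collapse = ",") %in% ok_set)
  expect_identical(unname(got == "recombinant"), unname(want_rec))
  # every recombinant call carries at least one breakpoint interval
  some_rec <- which(want_rec)[seq(1, sum(want_rec), length.out = 25)]
  for (i in some_rec) {
    call <- classify_carrier(stats::setNames(vecs[i, ], map$name), map,
                             naka_marker = NULL)
    expect_gt(nrow(call$breakpoint_intervals), 0)
  }
})

test_that("allele frequencies match printed worked examples and invariants", {
  map <- tiny_map(2)
  # 86 L alleles among 1938 chromosomes: 86 CL carriers + 883 CC
  rows <- c(replicate(86, c("CL", "CC"), simplify = FALSE),
            replicate(883, c("CC", "CC"), simplify = FALSE))
  G <- make_G(rows, map)
  af <- allele_frequency(G, "m1")
  expect_equal(af$n_chromosomes, 1938L)
  expect_equal(round(100 * af$freq_L, 1), 4.4)
  expect_equal(allele_frequency(G, "m2")$freq_L, 0)

  # invariant to row order and to fully-missing individuals
  Gperm <- genotype_matrix(unclass(G)[rev(seq_len(nrow(G))), ], map = map)
  expect_equal(allele_frequency(Gperm, "m1"), af)
  Gext <- genotype_matrix(rbind(unclass(G),
                                matrix(NA_character_, 5, 2,
                                       dimnames = list(paste0("x", 1:5),
                                                       map$name))),
                          map = map)
  expect_equal(allele_frequency(Gext, "m1"), af)
  expect_error(allele_frequency(Gext, "nope"), "no such marker")
})

test_that("visual genotype export groups non-recombinants before recombinants", {
  map <- tiny_map(4)
  G <- make_G(list(h = rep("CC", 4),
                   r = c("CC", "LL", "CC", "CC"),
                   s = c("CL", "CL", "CC", "CC"),
                   m = c("CC", NA, "CC", "CC")), map)
  calls <- detect_recombinants(G, map, naka_marker = NULL)
  path <- withr::local_tempfile(fileext = ".txt")
  out <- export_visual_genotypes(calls, G, map, path)
  expect_equal(out$pattern[out$id == "h"], "CCCC")
  expect_equal(out$pattern[out$id == "m"], "C.CC")
  expect_lt(which(out$id == "s"), which(out$id == "r"))
  expect_true(max(which(out$class != "recombinant")) <
                min(which(out$class == "recombinant")))
  expect_true(file.exists(path))
})

test_that("recombinant fraction is recovered on synthetic truth", {
  cfg <- simulation_config(600, recombinant_fraction = 0, missing_rate = 0.02,
                           seed = 21)
  pop <- generate_population(cfg)
  calls <- detect_recombinants(pop$genotypes, cfg$map)
  expect_equal(attr(calls, "fraction_recombinant"), 0)

  cfg <- simulation_config(885, recombinant_fraction = 0.22, seed = 22)
  pop <- generate_population(cfg)
  calls <- detect_recombinants(pop$genotypes, cfg$map)
  est <- attr(calls, "fraction_recombinant")
  ci <- qbinom(c(0.025, 0.975), 885, 0.22) / 885
  expect_gte(est, ci[1])
  expect_lte(est, ci[2])
})
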