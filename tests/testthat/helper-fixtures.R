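# small in-code fixtures shared across test files

# evenly spaced panel named m1..mk spanning ~16 kb
tiny_map <- function(k = 5) {
  marker_map(paste0("m", seq_len(k)), seq(1000L, by = 3000L, length.out = k),
             region_start_bp = 1L, region_end_bp = 3000L * k)
}

# genotype matrix from per-individual call vectors (list or character rows)
make_G <- function(rows, map, normalize = TRUE) {
  M <- do.call(rbind, rows)
  if (is.null(rownames(M))) rownames(M) <- sprintf("i%02d", seq_len(nrow(M)))
  colnames(M) <- map$name[seq_len(ncol(M))]
  genotype_matrix(M, map = map, normalize = normalize)
}

# exhaustive two-chromosome decomposition oracle: an individual is
# non-recombinant iff its unphased genotypes match some unordered pair of
# chromosomes drawn from {all-C, all-L, every 5'-anchored L-prefix chimera}
oracle_nonrecombinant_set <- function(k) {
  chroms <- c(list(rep("C", k), rep("L", k)),
              lapply(seq_len(k - 1), function(j) {
                c(rep("L", j), rep("C", k - j))
              }))
  combos <- expand.grid(a = seq_along(chroms), b = seq_along(chroms))
  combos <- combos[combos$a <= combos$b, ]
  unique(apply(combos, 1, function(idx) {
    c1 <- chroms[[idx[1]]]; c2 <- chroms[[idx[2]]]
    paste(ifelse(c1 == c2, ifelse(c1 == "C", "CC", "LL"), "CL"),
          collapse = ",")
  }))
}

# all genotype vectors of length k over CC/CL/LL as a character matrix
all_genotype_vectors <- function(k) {
  as.matrix(expand.grid(rep(list(c("CC", "CL", "LL")), k),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
}
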