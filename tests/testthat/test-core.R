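mk_matrix <- function(df, samples = sort(unique(df$sample_id))) {
  df$present <- as.integer(is_present(df$max_cov, df$covered_len))
  structure(df, samples = samples, class = c("coverage_matrix", "data.frame"))
}

test_that("core calling is inclusive at the boundary and strict across samples", {
  df <- expand.grid(contig_id = c("in", "out"), sample_id = paste0("S", 1:4),
                    stringsAsFactors = FALSE)
  df$max_cov <- ifelse(df$contig_id == "in", 5L,
                       c(5L, 5L, 5L, 4L)[match(df$sample_id, paste0("S", 1:4))])
  df$covered_len <- 120L
  core <- call_core(mk_matrix(df))
  expect_equal(core$contig_ids, "in")
  expect_error(call_core(mk_matrix(df), samples = c("S1", "S9")), "unknown sample")
})

test_that("core calling matches a brute-force double loop on random matrices", {
  set.seed(5)
  for (rep in 1:8) {
    n <- 1000
    samples <- paste0("S", 1:4)
    df <- expand.grid(contig_id = sprintf("c%04d", 1:n), sample_id = samples,
                      stringsAsFactors = FALSE)
    df$max_cov <- sample(0:8, nrow(df), replace = TRUE)
    df$covered_len <- sample(c(0, 50, 100, 150), nrow(df), replace = TRUE)
    # drop some rows entirely: absent pairs mean zero coverage
    df <- df[runif(nrow(df)) > 0.1, ]
    mat <- mk_matrix(df, samples)
    got <- call_core(mat)$contig_ids
    expect_setequal(got, oracle_core(df, 5, 100, samples))
  }
})

test_that("core calling is antitone in thresholds and in the sample set", {
  tr <- small_truth(n_contigs = 200, seed = 17)
  mat <- truth_coverage_matrix(tr)
  base <- call_core(mat, 5, 100)$contig_ids
  expect_true(all(call_core(mat, 6, 100)$contig_ids %in% base))
  expect_true(all(call_core(mat, 5, 150)$contig_ids %in% base))
  two <- call_core(mat, samples = tr$samples[1:2])$contig_ids
  expect_true(all(base %in% two))
})

test_that("core recovery on synthetic fixtures is exact", {
  tr <- small_truth(n_contigs = 250, seed = 23)
  mat <- truth_coverage_matrix(tr)
  expect_setequal(call_core(mat)$contig_ids, tr$core_ids)
})

test_that("core_fraction rounds half-up to the requested precision", {
  expect_equal(core_fraction(0, 100), 0)
  expect_equal(core_fraction(226887, 226887), 100)
  expect_equal(core_fraction(5, 1000), 0.5)     # 0.5 exactly
  expect_equal(core_fraction(45, 10000), 0.5)   # 0.45 rounds up, not to even
  expect_equal(core_fraction(25, 1000, 2), 2.5)
  expect_error(core_fraction(1, 0), "positive")
  expect_error(core_fraction(5, 4), "core_size")
})

test_that("k-mer core fraction is 1 for identical read sets and 0 for disjoint ones", {
  reads <- c("ACGTACGTACGTACG", "TTGCATTGCATTGCA")
  same <- kmer_core_fraction(list(a = reads, b = reads, c = reads), k = 8,
                             subset_size = 2, n_boot = 3, seed = 1)
  expect_equal(same$core_fraction_per_boot, rep(1, 3))
  disjoint <- kmer_core_fraction(list(a = "AAAAAAAAAAAA", b = "CCCCCCCCCCCC"),
                                 k = 8, subset_size = 1, n_boot = 2, seed = 1)
  expect_equal(disjoint$core_fraction_per_boot, rep(0, 2))
})

test_that("k-mer core fraction equals a naive set computation on the same subsampled reads", {
  set.seed(404)
  pool_shared <- vapply(1:30, function(i) paste(sample(c("A", "C", "G", "T"), 30,
                                                       replace = TRUE),
                                                collapse = ""), character(1))
  mk_sample <- function() {
    own <- vapply(1:120, function(i) paste(sample(c("A", "C", "G", "T"), 30,
                                                  replace = TRUE),
                                           collapse = ""), character(1))
    c(sample(pool_shared, 80, replace = TRUE), own)  # ~40% from the shared pool
  }
  sets <- list(s1 = mk_sample(), s2 = mk_sample(), s3 = mk_sample())
  est <- kmer_core_fraction(sets, k = 8, subset_size = 150, n_boot = 3, seed = 6)
  for (b in seq_len(est$n_boot)) {
    km <- lapply(names(est$sorted_reads), function(s)
      oracle_kmer_set(est$sorted_reads[[s]][est$read_indices[[b]][[s]]], 8))
    core <- Reduce(intersect, km)
    uni <- Reduce(union, km)
    expect_equal(est$core_fraction_per_boot[b], length(core) / length(uni))
    expect_equal(unname(est$unique_kmer_counts[b, ]),
                 vapply(km, length, integer(1)))
  }
  expect_true(all(est$core_fraction_per_boot > 0 &
                    est$core_fraction_per_boot < 1))
})

test_that("k-mer estimation is invariant to sample and read order, and validates inputs", {
  sets <- list(s1 = c("ACGTTGCAACGT", "GGGTTTCCCAAA", "ACACACACACAC"),
               s2 = c("ACGTTGCAACGT", "TGCATGCATGCA", "GGGTTTCCCAAA"))
  e1 <- kmer_core_fraction(sets, k = 6, subset_size = 2, n_boot = 2, seed = 9)
  e2 <- kmer_core_fraction(rev(lapply(sets, rev)), k = 6, subset_size = 2,
                           n_boot = 2, seed = 9)
  expect_equal(e1$core_fraction_per_boot, e2$core_fraction_per_boot)
  expect_error(kmer_core_fraction(sets, k = 6, subset_size = 10, seed = 1),
               "subset_size")
  expect_message(kmer_core_fraction(list(a = c("ACGTACGTACGT", "ACG"),
                                         b = "ACGTACGTACGT"),
                                    k = 6, subset_size = 1, n_boot = 1, seed = 1),
                 "shorter than k")
})
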