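mk_cov <- function(df) {
  df$present <- as.integer(is_present(df$max_cov, df$covered_len))
  structure(df, samples = sort(unique(df$sample_id)),
            class = c("coverage_matrix", "data.frame"))
}

test_that("normalization divides max coverage by the sample recA count", {
  df <- data.frame(contig_id = c("c1", "c1", "c2"),
                   sample_id = c("S1", "S2", "S1"),
                   max_cov = c(8L, 3L, 0L), covered_len = c(120L, 120L, 0L))
  ab <- normalize_abundance(mk_cov(df), c(S1 = 4L, S2 = 1L))
  expect_equal(nrow(ab), 2)  # zero-coverage pair dropped
  expect_equal(ab$copies_per_recA[ab$sample_id == "S1"], 2.0)
  expect_equal(ab$copies_per_recA[ab$sample_id == "S2"], 3.0)  # recA 1 => identity
  expect_error(normalize_abundance(mk_cov(df), c(S1 = 4L, S2 = 0L)), "S2")
  expect_error(normalize_abundance(mk_cov(df), c(S1 = 4L)), "S2")
})

test_that("normalization matches elementwise recomputation on random inputs", {
  set.seed(33)
  n <- 200
  df <- data.frame(contig_id = sprintf("c%03d", 1:n),
                   sample_id = sample(paste0("S", 1:4), n, replace = TRUE),
                   max_cov = sample(1:50, n, replace = TRUE),
                   covered_len = 200L)
  reca <- c(S1 = 7L, S2 = 13L, S3 = 99L, S4 = 101L)
  ab <- normalize_abundance(mk_cov(df), reca)
  for (i in seq_len(nrow(ab))) {
    j <- which(df$contig_id == ab$contig_id[i] & df$sample_id == ab$sample_id[i])
    expect_equal(ab$copies_per_recA[i], df$max_cov[j] / reca[[df$sample_id[j]]])
  }
})

ann4 <- data.frame(
  contig_id = c("c1", "c2", "c3", "c4"),
  cazy_family = c("GT2", "GT4", "GH13", "unknown"),
  cazy_class = c("GT", "GT", "GH", "unknown"),
  phylum = c("Proteobacteria", "Actinobacteria", "Proteobacteria", "unknown"),
  domain = c("Bacteria", "Bacteria", "Bacteria", "Bacteria"),
  stringsAsFactors = FALSE)

mk_ab <- function(sums_by_contig) {
  # sums_by_contig: named list contig -> named per-sample abundance
  do.call(rbind, lapply(names(sums_by_contig), function(cid) {
    v <- sums_by_contig[[cid]]
    data.frame(contig_id = cid, sample_id = names(v), copies_per_recA = unname(v),
               stringsAsFactors = FALSE)
  }))
}

test_that("replicate aggregation gives the closed-form mean, SE and t-based 95% CI", {
  s <- paste0("S", 1:4)
  ab <- mk_ab(list(c1 = setNames(c(1, 2, 3, 4), s)))
  pr <- profile_abundance("c1", ann4, ab, by = "class", samples = s)
  expect_equal(pr$mean, 2.5)
  expect_equal(pr$se, sd(1:4) / 2)
  tq <- qt(0.975, df = 3)
  expect_equal(pr$ci_low, 2.5 - tq * sd(1:4) / 2)
  expect_equal(pr$ci_high, 2.5 + tq * sd(1:4) / 2)
  expect_equal(pr$ci_low, 0.4457, tolerance = 1e-4)
  expect_equal(pr$ci_high, 4.5543, tolerance = 1e-4)
  # zero variance
  ab0 <- mk_ab(list(c1 = setNames(c(2, 2, 2, 2), s)))
  pr0 <- profile_abundance("c1", ann4, ab0, by = "class", samples = s)
  expect_equal(c(pr0$mean, pr0$se, pr0$ci_low, pr0$ci_high), c(2, 0, 2, 2))
})

test_that("a single replicate reports missing SE and CI, not zero", {
  ab <- mk_ab(list(c1 = c(S1 = 3)))
  pr <- profile_abundance("c1", ann4, ab, by = "class", samples = "S1")
  expect_equal(pr$mean, 3)
  expect_true(is.na(pr$se) && is.na(pr$ci_low) && is.na(pr$ci_high))
})

test_that("family-level profiles aggregate exactly to the class-level profile", {
  tr <- small_truth(n_contigs = 300, seed = 77)
  mat <- truth_coverage_matrix(tr)
  core <- call_core(mat)
  reca <- setNames(tr$config$recA_per_sample, tr$samples)
  ab <- normalize_abundance(mat, reca)
  prf <- profile_abundance(core, tr$annotations, ab, by = "family",
                           samples = tr$samples)
  prc <- profile_abundance(core, tr$annotations, ab, by = "class",
                           samples = tr$samples)
  fam_ps <- attr(prf, "per_sample")
  cls_ps <- attr(prc, "per_sample")
  fam_cls <- cazy_class(rownames(fam_ps))
  for (cl in rownames(cls_ps)) {
    expect_equal(colSums(fam_ps[fam_cls == cl, , drop = FALSE]),
                 cls_ps[cl, ])
  }
  expect_equal(sum(prf$prevalence), length(core$contig_ids))
})

test_that("group abundances conserve the total core abundance and prevalence at every level", {
  tr <- small_truth(n_contigs = 300, seed = 78)
  mat <- truth_coverage_matrix(tr)
  core <- call_core(mat)
  reca <- setNames(tr$config$recA_per_sample, tr$samples)
  ab <- normalize_abundance(mat, reca)
  core_ab <- ab[ab$contig_id %in% core$contig_ids, ]
  totals <- vapply(tr$samples, function(s)
    sum(core_ab$copies_per_recA[core_ab$sample_id == s]), numeric(1))
  for (lev in c("class", "family", "phylum", "family_phylum")) {
    pr <- profile_abundance(core, tr$annotations, ab, by = lev,
                            samples = tr$samples)
    ps <- attr(pr, "per_sample")
    expect_equal(colSums(ps), totals)
    expect_equal(sum(pr$prevalence), length(core$contig_ids))
  }
})

test_that("aggregation is invariant to replicate ordering and demands full annotation", {
  s <- paste0("S", 1:4)
  ab <- mk_ab(list(c1 = setNames(c(1, 2, 3, 4), s),
                   c3 = setNames(c(4, 3, 2, 1), s)))
  p1 <- profile_abundance(c("c1", "c3"), ann4, ab, by = "class", samples = s)
  p2 <- profile_abundance(c("c1", "c3"), ann4, ab, by = "class", samples = rev(s))
  expect_equal(p1$mean, p2$mean)
  expect_equal(p1$se, p2$se)
  expect_error(profile_abundance(c("c1", "cX"), ann4, ab, by = "class",
                                 samples = s), "lack an annotation")
})
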