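mk_cov2 <- function(df) {
  df$present <- as.integer(is_present(df$max_cov, df$covered_len))
  structure(df, samples = sort(unique(df$sample_id)),
            class = c("coverage_matrix", "data.frame"))
}

sharing_record_df <- function(id, grp, n) {
  data.frame(metagenome_id = id, group_label = grp, n_shared = as.integer(n),
             mode = "coverage", stringsAsFactors = FALSE)
}

mk_share_hits <- function(qseqid, evalue, length, pident, bitscore = 100) {
  data.frame(qseqid = qseqid, sseqid = "target_read", pident = pident,
             length = length, mismatch = 0L, gapopen = 0L, qstart = 1L,
             qend = length, sstart = 1L, send = length,
             evalue = evalue, bitscore = bitscore, stringsAsFactors = FALSE)
}

test_that("coverage sharing against the source matrix recovers the whole core", {
  tr <- small_truth(n_contigs = 200, seed = 55)
  mat <- truth_coverage_matrix(tr)
  core <- call_core(mat)
  rec <- shared_by_coverage(core, mat, metagenome_id = "self")
  expect_equal(rec$n_shared, length(core$contig_ids))
  zero <- mat
  zero$max_cov <- 0L
  zero$covered_len <- 0L
  expect_equal(shared_by_coverage(core, zero)$n_shared, 0L)
  expect_warning(out <- shared_by_coverage(character(), mat), "empty core")
  expect_equal(out$n_shared, 0L)
})

test_that("coverage sharing counts presence in at least min_samples replicates", {
  df <- data.frame(contig_id = rep(c("c1", "c2"), each = 2),
                   sample_id = rep(c("S1", "S2"), 2),
                   max_cov = c(9L, 9L, 9L, 1L), covered_len = 200L)
  mat <- mk_cov2(df)
  expect_equal(shared_by_coverage(c("c1", "c2"), mat, min_samples = 1)$n_shared, 2L)
  expect_equal(shared_by_coverage(c("c1", "c2"), mat, min_samples = 2)$n_shared, 1L)
  # brute-force check on a random fixture
  set.seed(61)
  for (rep in 1:20) {
    rdf <- data.frame(contig_id = sprintf("c%02d", sample.int(25, 60, TRUE)),
                      sample_id = sample(paste0("S", 1:3), 60, TRUE),
                      max_cov = sample(0:9, 60, TRUE),
                      covered_len = sample(c(50L, 100L, 200L), 60, TRUE))
    rdf <- rdf[!duplicated(rdf[c("contig_id", "sample_id")]), ]
    rmat <- mk_cov2(rdf)
    ids <- sprintf("c%02d", 1:25)
    for (ms in 1:3) {
      exp_n <- sum(vapply(ids, function(cid) {
        r <- rdf[rdf$contig_id == cid, ]
        sum(r$max_cov >= 5 & r$covered_len >= 100) >= ms
      }, logical(1)))
      expect_equal(shared_by_coverage(ids, rmat, min_samples = ms)$n_shared,
                   exp_n)
    }
  }
})

test_that("alignment sharing gates on E-value, length and identity together", {
  core <- c("c1")
  expect_equal(shared_by_alignment(core, NULL)$n_shared, 0L)
  expect_equal(shared_by_alignment(core, mk_share_hits("c1", 1e-4, 100, 90))$n_shared, 0L)
  expect_equal(shared_by_alignment(core, mk_share_hits("c1", 1e-6, 100, 90))$n_shared, 1L)
  expect_equal(shared_by_alignment(core, mk_share_hits("c1", 1e-6, 69, 90))$n_shared, 0L)
  expect_equal(shared_by_alignment(core, mk_share_hits("c1", 1e-6, 70, 69.9))$n_shared, 0L)
  expect_equal(shared_by_alignment(core, mk_share_hits("c1", 1e-5, 70, 70))$n_shared, 1L)
  expect_message(
    out <- shared_by_alignment(core, mk_share_hits(c("c1", "zz"), 1e-6, 100, 90)),
    "non-core")
  expect_equal(out$n_shared, 1L)
})

test_that("alignment sharing matches a brute-force any-pass scan and is antitone", {
  set.seed(71)
  core_ids <- sprintf("core%03d", 1:200)
  for (rep in 1:10) {
    hits <- mk_share_hits(sample(core_ids, 1000, replace = TRUE),
                          10^-sample.int(9, 1000, replace = TRUE),
                          sample(40:150, 1000, replace = TRUE),
                          runif(1000, 40, 100))
    got <- shared_by_alignment(core_ids, hits)$n_shared
    expect_equal(got, oracle_shared_alignment(core_ids, hits, 1e-5, 70, 70))
    expect_lte(shared_by_alignment(core_ids, hits, max_evalue = 1e-7)$n_shared, got)
    expect_lte(shared_by_alignment(core_ids, hits, min_length = 100)$n_shared, got)
    expect_lte(shared_by_alignment(core_ids, hits, min_pident = 90)$n_shared, got)
  }
})

test_that("group summaries give per-group mean and SE, NA for singletons", {
  recs <- rbind(
    sharing_record_df("m1", "grass", 40), sharing_record_df("m2", "grass", 40),
    sharing_record_df("m3", "tundra", 78),
    sharing_record_df("m4", "agri", 300), sharing_record_df("m5", "agri", 510))
  s <- summarize_groups(recs)
  expect_equal(s$mean_shared[s$group_label == "grass"], 40)
  expect_equal(s$se_shared[s$group_label == "grass"], 0)
  expect_true(is.na(s$se_shared[s$group_label == "tundra"]))
  expect_equal(s$mean_shared[s$group_label == "agri"], 405)
  expect_equal(s$se_shared[s$group_label == "agri"], sd(c(300, 510)) / sqrt(2))
  expect_equal(s$se_shared[s$group_label == "agri"], 105)
  # invariant to record order
  s2 <- summarize_groups(recs[sample.int(nrow(recs)), ])
  expect_equal(s, s2)
})
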