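# Independent brute-force oracles. These deliberately avoid the package's
# code paths: full per-position vectors, double loops, naive set algebra.

# coverage oracle: materialize a full depth vector per contig, take max and
# count of nonzero positions (duplicated positions keep the max depth)
oracle_coverage <- function(rows) {
  out <- list()
  for (cid in sort(unique(rows$contig_id))) {
    r <- rows[rows$contig_id == cid, ]
    vec <- integer(max(r$pos))
    for (i in seq_len(nrow(r))) {
      vec[r$pos[i]] <- max(vec[r$pos[i]], r$depth[i])
    }
    out[[cid]] <- c(max_cov = max(vec, 0L), covered_len = sum(vec >= 1))
  }
  out
}

# core-calling oracle: explicit double loop over contigs and samples
oracle_core <- function(mat, min_cov, min_len, samples) {
  ids <- sort(unique(mat$contig_id))
  core <- character()
  for (cid in ids) {
    ok <- TRUE
    for (s in samples) {
      row <- mat[mat$contig_id == cid & mat$sample_id == s, ]
      if (nrow(row) == 0 || row$max_cov < min_cov || row$covered_len < min_len) {
        ok <- FALSE
        break
      }
    }
    if (ok) core <- c(core, cid)
  }
  core
}

# recA-count oracle: distinct-query scan
oracle_recA <- function(hits, max_evalue, strict) {
  seen <- character()
  for (i in seq_len(nrow(hits))) {
    pass <- if (strict) hits$evalue[i] < max_evalue else hits$evalue[i] <= max_evalue
    if (pass && !(hits$qseqid[i] %in% seen)) seen <- c(seen, hits$qseqid[i])
  }
  length(seen)
}

# alignment-sharing oracle: per-contig any-qualifying-hit scan
oracle_shared_alignment <- function(core_ids, hits, max_evalue, min_length,
                                    min_pident) {
  n <- 0L
  for (cid in core_ids) {
    h <- hits[hits$qseqid == cid, ]
    any_pass <- FALSE
    for (i in seq_len(nrow(h))) {
      if (h$evalue[i] <= max_evalue && h$length[i] >= min_length &&
          h$pident[i] >= min_pident) {
        any_pass <- TRUE
        break
      }
    }
    if (any_pass) n <- n + 1L
  }
  n
}

# naive canonical k-mer set of a read vector: character-by-character reverse
# complement, no Biostrings
oracle_kmer_set <- function(reads, k) {
  rc1 <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  out <- character()
  for (r in reads) {
    if (nchar(r) < k) next
    for (i in seq_len(nchar(r) - k + 1)) {
      km <- substr(r, i, i + k - 1)
      rc <- rc1(km)
      out <- c(out, if (km <= rc) km else rc)
    }
  }
  unique(out)
}

# random small coverage-row tables for property tests
random_depth_rows <- function(n_rows, n_contigs, max_pos = 50, max_depth = 10) {
  data.frame(
    contig_id = sprintf("c%02d", sample.int(n_contigs, n_rows, replace = TRUE)),
    pos = sample.int(max_pos, n_rows, replace = TRUE),
    depth = sample.int(max_depth + 1, n_rows, replace = TRUE) - 1L,
    stringsAsFactors = FALSE)
}

small_truth <- function(n_contigs = 120, seed = 42, ...) {
  generate_community(community_config(n_contigs = n_contigs, seed = seed, ...))
}
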