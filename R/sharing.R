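#' Core sharing with a target metagenome by coverage
#'
#' Counts how many core contigs are detectable in a target sample set: a
#' contig counts as shared when it satisfies the presence rule (depth and
#' covered-length thresholds) in at least `min_samples` of the target
#' samples.
#'
#' @param core A `core_set` or character vector of core contig identifiers.
#' @param matrix `coverage_matrix` over the target samples.
#' @param min_cov,min_len Presence thresholds (defaults 5 and 100).
#' @param min_samples Minimum number of target samples in which the contig
#'   must be present (default 1, "at least one field replicate").
#' @param metagenome_id,group_label Identifiers carried into the record.
#' @return One-row data.frame (class `sharing_record`): `metagenome_id`,
#'   `group_label`, `n_shared`, `mode`.
#' @export
shared_by_coverage <- function(core, matrix, min_cov = 5L, min_len = 100L,
                               min_samples = 1L, metagenome_id = "target",
                               group_label = NA_character_) {
  ids <- if (inherits(core, "core_set")) core$contig_ids else as.character(core)
  if (length(ids) == 0L) {
    warning("empty core set; n_shared is 0")
    return(sharing_record(metagenome_id, group_label, 0L, "coverage"))
  }
  m <- matrix[matrix$contig_id %in% ids, , drop = FALSE]
  pres <- is_present(m$max_cov, m$covered_len, min_cov, min_len)
  tab <- table(m$contig_id[pres])
  sharing_record(metagenome_id, group_label,
                 sum(tab >= min_samples), "coverage")
}

#' Core sharing with a remote metagenome by alignment
#'
#' A core contig counts as shared when at least one of its alignment hits
#' against the target passes all three gates: E-value at most `max_evalue`,
#' alignment length at least `min_length` columns, and percent identity at
#' least `min_pident`. With `best_hit_only = TRUE` only each contig's
#' top-bitscore hits are eligible.
#'
#' @param core A `core_set` or character vector of core contig identifiers.
#' @param hits 12-column tabular hits of core contigs vs. target reads.
#' @param max_evalue E-value gate (default 1e-5, inclusive).
#' @param min_length Alignment-length gate in columns (default 70).
#' @param min_pident Percent-identity gate (default 70).
#' @param best_hit_only Restrict to top-bitscore hits per contig.
#' @param metagenome_id,group_label Identifiers carried into the record.
#' @return One-row `sharing_record` data.frame. Hits whose query is not a
#'   core contig are ignored (their count is reported via a message).
#' @export
shared_by_alignment <- function(core, hits, max_evalue = 1e-5,
                                min_length = 70L, min_pident = 70,
                                best_hit_only = FALSE,
                                metagenome_id = "target",
                                group_label = NA_character_) {
  ids <- if (inherits(core, "core_set")) core$contig_ids else as.character(core)
  if (is.null(hits) || nrow(hits) == 0L) {
    return(sharing_record(metagenome_id, group_label, 0L, "alignment"))
  }
  foreign <- !(hits$qseqid %in% ids)
  if (any(foreign)) {
    message(sprintf("shared_by_alignment: ignored %d hit(s) from non-core queries",
                    sum(foreign)))
    hits <- hits[!foreign, , drop = FALSE]
  }
  if (best_hit_only && nrow(hits)) {
    dt <- data.table::as.data.table(hits)
    hits <- as.data.frame(dt[, .SD[bitscore == max(bitscore)], by = "qseqid"])
  }
  pass <- hits$evalue <= max_evalue & hits$length >= min_length &
    hits$pident >= min_pident
  sharing_record(metagenome_id, group_label,
                 length(unique(hits$qseqid[pass])), "alignment")
}

sharing_record <- function(metagenome_id, group_label, n_shared, mode) {
  structure(data.frame(metagenome_id = metagenome_id,
                       group_label = group_label,
                       n_shared = as.integer(n_shared), mode = mode,
                       stringsAsFactors = FALSE),
            class = c("sharing_record", "data.frame"))
}

#' Summarize sharing counts by metagenome group
#'
#' Per group (grassland, agricultural, forest, ...), the mean and dispersion
#' of the number of shared core contigs across member metagenomes. Both the
#' standard error and the standard deviation are reported, labelled
#' explicitly; single-member groups have `NA` dispersion.
#'
#' @param records data.frame of sharing records (rows from
#'   [shared_by_coverage()] / [shared_by_alignment()], rbind-ed).
#' @return data.frame with `group_label`, `n_metagenomes`, `mean_shared`,
#'   `se_shared`, `sd_shared`, sorted by group.
#' @export
summarize_groups <- function(records) {
  records <- as.data.frame(records)
  groups <- sort(unique(records$group_label))
  rows <- lapply(groups, function(g) {
    x <- records$n_shared[records$group_label %in% g]
    n <- length(x)
    sdev <- if (n > 1L) stats::sd(x) else NA_real_
    data.frame(group_label = g, n_metagenomes = n, mean_shared = mean(x),
               se_shared = sdev / sqrt(n), sd_shared = sdev,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
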