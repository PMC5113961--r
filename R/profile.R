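#' Normalize contig coverage to copies per recA
#'
#' Divides each contig's maximum base-pair coverage by the sample's estimated
#' recA gene count, standardizing samples of different sequencing depth. One
#' record is emitted per (contig, sample) with nonzero coverage.
#'
#' @param matrix A `coverage_matrix`.
#' @param recA_counts Named integer vector (names are sample identifiers) or
#'   a data.frame with columns `sample_id`, `recA_count`.
#' @return data.frame with `contig_id`, `sample_id`, `copies_per_recA`.
#' @export
normalize_abundance <- function(matrix, recA_counts) {
  if (is.data.frame(recA_counts)) {
    recA_counts <- stats::setNames(recA_counts$recA_count, recA_counts$sample_id)
  }
  samples <- unique(matrix$sample_id)
  missing <- setdiff(samples, names(recA_counts))
  if (length(missing)) {
    stopf("no recA count for sample(s): %s", paste(missing, collapse = ", "))
  }
  zero <- names(recA_counts)[recA_counts <= 0]
  if (length(zero)) {
    stopf("recA count must be >= 1; offending sample(s): %s",
          paste(zero, collapse = ", "))
  }
  m <- matrix[matrix$max_cov > 0, , drop = FALSE]
  data.frame(contig_id = m$contig_id, sample_id = m$sample_id,
             copies_per_recA = m$max_cov / as.numeric(recA_counts[m$sample_id]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Profile core abundance by CAZy class, family, phylum
#'
#' Aggregates copies-per-recA abundances of core contigs into groups at the
#' requested level. Within each replicate sample the group abundance is the
#' sum over its core contigs; across replicates the profile reports the mean,
#' the standard error (sd / sqrt(n)) and the 95% confidence interval using
#' the t distribution with n - 1 degrees of freedom (n = 4 replicates gives
#' t = 3.1824). Prevalence is the number of distinct core contigs in the
#' group. Contigs without a recognized category fall in an explicit
#' `"unknown"` group, so group abundances always sum to the total core
#' abundance and prevalences to the core size.
#'
#' @param core A `core_set` or character vector of core contig identifiers.
#' @param annotations Annotation data.frame covering every core contig.
#' @param abundances Output of [normalize_abundance()].
#' @param by Grouping level: `"class"`, `"family"`, `"phylum"` or
#'   `"family_phylum"`.
#' @param samples Replicate sample identifiers; defaults to those observed in
#'   `abundances`.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return data.frame of class `abundance_profile` with columns `level`,
#'   `label`, `prevalence`, `mean`, `se`, `ci_low`, `ci_high`; the per-sample
#'   group sums are kept in `attr(, "per_sample")` (groups x samples matrix).
#'   With a single replicate `se` and the interval are `NA`.
#' @export
profile_abundance <- function(core, annotations, abundances,
                              by = c("class", "family", "phylum", "family_phylum"),
                              samples = NULL, conf_level = 0.95) {
  by <- match.arg(by)
  ids <- if (inherits(core, "core_set")) core$contig_ids else as.character(core)
  if (is.null(samples)) samples <- sort(unique(abundances$sample_id))
  n <- length(samples)
  if (n < 1L) stopf("at least one replicate sample is required")
  m <- match(ids, annotations$contig_id)
  if (anyNA(m)) {
    stopf("%d core contig(s) lack an annotation, e.g. %s",
          sum(is.na(m)), ids[which(is.na(m))[1]])
  }
  ann <- annotations[m, , drop = FALSE]
  lab <- switch(by,
                class = ann$cazy_class,
                family = ann$cazy_family,
                phylum = ann$phylum,
                family_phylum = paste(ann$cazy_family, ann$phylum, sep = "×"))
  lab[is.na(lab) | !nzchar(lab)] <- "unknown"
  group_of <- stats::setNames(lab, ids)
  groups <- sort(unique(lab))

  ab <- abundances[abundances$contig_id %in% ids &
                     abundances$sample_id %in% samples, , drop = FALSE]
  per_sample <- matrix(0, nrow = length(groups), ncol = n,
                       dimnames = list(groups, samples))
  if (nrow(ab)) {
    agg <- stats::aggregate(copies_per_recA ~ g + sample_id,
                            data = data.frame(g = group_of[ab$contig_id],
                                              sample_id = ab$sample_id,
                                              copies_per_recA = ab$copies_per_recA),
                            FUN = sum)
    per_sample[cbind(agg$g, agg$sample_id)] <- agg$copies_per_recA
  }
  prevalence <- as.integer(table(factor(lab, levels = groups)))
  mu <- rowMeans(per_sample)
  if (n > 1L) {
    se <- apply(per_sample, 1, stats::sd) / sqrt(n)
    tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1L)
    ci_low <- mu - tq * se
    ci_high <- mu + tq * se
  } else {
    se <- ci_low <- ci_high <- rep(NA_real_, length(groups))
  }
  out <- data.frame(level = by, label = groups, prevalence = prevalence,
                    mean = mu, se = se, ci_low = ci_low, ci_high = ci_high,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, per_sample = per_sample, n_replicates = n,
            class = c("abundance_profile", "data.frame"))
}

#' Bar chart of an abundance profile
#'
#' Mean abundance per group with standard-error bars, in the style of the
#' class- and phylum-level core profiles.
#'
#' @param x An `abundance_profile`.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
plot.abundance_profile <- function(x, ...) {
  o <- order(-x$mean)
  mids <- graphics::barplot(x$mean[o], names.arg = x$label[o],
                            las = 2, ylab = "copies per recA (mean ± SE)",
                            ylim = c(0, max(x$mean + ifelse(is.na(x$se), 0, x$se)) * 1.1),
                            ...)
  ok <- !is.na(x$se[o]) & x$se[o] > 0
  if (any(ok)) {
    graphics::arrows(mids[ok], x$mean[o][ok] - x$se[o][ok],
                     mids[ok], x$mean[o][ok] + x$se[o][ok],
                     angle = 90, code = 3, length = 0.04)
  }
  invisible(mids)
}

#' Write a long-format profile TSV
#'
#' @param profile An `abundance_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  data.table::fwrite(as.data.frame(profile), path, sep = "\t")
  invisible(path)
}
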