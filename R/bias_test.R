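#' Category distribution of a label set
#'
#' @param x Character vector of category labels, or a named integer vector of
#'   counts.
#' @param categories Optional category universe (ordered); labels outside it
#'   are an error, categories without observations get zero counts.
#' @return Object of class `category_distribution`: `categories`, `counts`,
#'   `freqs`.
#' @export
category_distribution <- function(x, categories = NULL) {
  if (is.numeric(x)) {
    if (is.null(names(x))) stopf("numeric input must be a named count vector")
    counts <- x
  } else {
    x <- as.character(x)
    if (length(x) == 0L) stopf("empty category set")
    counts <- table(x)
  }
  if (is.null(categories)) categories <- sort(names(counts))
  extra <- setdiff(names(counts), categories)
  if (length(extra)) stopf("labels outside the category universe: %s",
                           paste(extra, collapse = ", "))
  cnt <- stats::setNames(rep(0, length(categories)), categories)
  cnt[names(counts)] <- as.numeric(counts)
  structure(list(categories = categories, counts = cnt,
                 freqs = cnt / sum(cnt)),
            class = "category_distribution")
}

#' Null category distributions by resampling a reference pool
#'
#' Repeatedly draws `n_draw` labels from a reference pool (e.g. the CAZy
#' classes or phyla of all proteins in the reference database or the
#' cumulative metagenome) and reduces each draw to a category distribution.
#' Sampling is without replacement by default — drawing distinct proteins
#' from a finite catalogue.
#'
#' @param pool Character vector of category labels, one per pool member.
#' @param n_draw Labels per draw (default 50000).
#' @param n_rep Number of draws (default 1000).
#' @param seed Integer seed.
#' @param replace Sample with replacement (default `FALSE`).
#' @return Object of class `null_draws`: `categories`, `counts` (an
#'   `n_rep` x categories matrix), `freqs`, `n_draw`. Row r of `freqs` is the
#'   r-th null category distribution.
#' @export
draw_null <- function(pool, n_draw = 50000L, n_rep = 1000L, seed = 1L,
                      replace = FALSE) {
  pool <- as.character(pool)
  if (n_rep < 1L) stopf("n_rep must be >= 1")
  if (!replace && length(pool) < n_draw) {
    stopf("pool (%d) smaller than n_draw (%d); use replace = TRUE to sample with replacement",
          length(pool), n_draw)
  }
  categories <- sort(unique(pool))
  codes <- match(pool, categories)
  K <- length(categories)
  counts <- matrix(0L, nrow = n_rep, ncol = K,
                   dimnames = list(NULL, categories))
  with_seed(seed, for (r in seq_len(n_rep)) {
    idx <- sample.int(length(codes), n_draw, replace = replace)
    counts[r, ] <- tabulate(codes[idx], nbins = K)
  })
  structure(list(categories = categories, counts = counts,
                 freqs = counts / n_draw, n_draw = as.integer(n_draw)),
            class = "null_draws")
}

# chi-square distance of frequency rows `p` (matrix or vector) from a
# reference frequency vector m; categories where m == 0 contribute nothing
chisq_distance <- function(p, m) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  use <- m > 0
  d <- sweep(p[, use, drop = FALSE], 2, m[use])
  as.numeric(d^2 %*% (1 / m[use]))
}

#' Empirical-null test for annotation-database bias
#'
#' Compares an observed category distribution (the CAZy classes or phyla of
#' the core) against null distributions from [draw_null()]. The default
#' statistic is the chi-square distance of a distribution's frequencies from
#' the null-mean frequencies; the empirical p-value is
#' `(1 + #draws with statistic >= observed) / (n_rep + 1)`, never exactly
#' zero. Per-category z-scores against the null mean and sd are always
#' reported. `statistic = "ftest"` adds per-category empirical two-sided
#' p-values (Bonferroni-corrected), an analysis-of-variance-style
#' category-by-category comparison.
#'
#' @param observed A `category_distribution` or character vector of labels.
#' @param nulls A `null_draws` object.
#' @param statistic `"chi2"` (default) or `"ftest"`.
#' @return Object of class `bias_test`: `observed`, `observed_statistic`,
#'   `statistic_per_draw`, `p_empirical`, `per_category` (data.frame with
#'   observed frequency, null mean, null sd, z, and — in ftest mode —
#'   `p_cat`, `p_cat_bonf`), `statistic`.
#' @export
bias_compare <- function(observed, nulls, statistic = c("chi2", "ftest")) {
  statistic <- match.arg(statistic)
  if (!inherits(nulls, "null_draws")) stopf("nulls must come from draw_null()")
  if (!inherits(observed, "category_distribution")) {
    observed <- category_distribution(observed)
  }
  if (sum(observed$counts) == 0) stopf("observed distribution is empty")
  categories <- sort(union(observed$categories, nulls$categories))
  obs <- category_distribution(observed$counts, categories)
  K <- length(categories)
  R <- nrow(nulls$counts)
  nf <- matrix(0, nrow = R, ncol = K, dimnames = list(NULL, categories))
  nf[, nulls$categories] <- nulls$freqs
  m <- colMeans(nf)
  s <- apply(nf, 2, stats::sd)
  stat_draws <- chisq_distance(nf, m)
  stat_obs <- chisq_distance(obs$freqs, m)
  p_emp <- (1 + sum(stat_draws >= stat_obs)) / (R + 1)
  z <- ifelse(s > 0, (obs$freqs - m) / s, ifelse(obs$freqs == m, 0, Inf))
  per_cat <- data.frame(category = categories, observed_freq = unname(obs$freqs),
                        null_mean = unname(m), null_sd = unname(s),
                        z = unname(z), stringsAsFactors = FALSE)
  if (statistic == "ftest") {
    dev_obs <- abs(obs$freqs - m)
    dev_null <- abs(sweep(nf, 2, m))
    p_cat <- (1 + colSums(dev_null >= rep(dev_obs, each = R))) / (R + 1)
    per_cat$p_cat <- unname(p_cat)
    per_cat$p_cat_bonf <- unname(stats::p.adjust(p_cat, method = "bonferroni"))
  }
  structure(list(observed = obs, observed_statistic = stat_obs,
                 statistic_per_draw = stat_draws, p_empirical = p_emp,
                 per_category = per_cat, statistic = statistic),
            class = "bias_test")
}

#' @export
print.bias_test <- function(x, ...) {
  cat(sprintf("Bias test (%s statistic, %d null draws)\n",
              x$statistic, length(x$statistic_per_draw)))
  cat(sprintf("  observed statistic: %.4g; empirical p = %.4g\n",
              x$observed_statistic, x$p_empirical))
  top <- x$per_category[order(-abs(x$per_category$z)), ]
  cat("  largest |z| categories:\n")
  print(utils::head(top, 5), row.names = FALSE, digits = 3)
  invisible(x)
}
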