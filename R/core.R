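#' Call the core contig set from a coverage matrix
#'
#' A contig belongs to the core when it is present — maximum per-base depth
#' at least `min_cov` over a covered length of at least `min_len` bp — in
#' every one of the required samples. Contigs with no coverage row for a
#' sample are absent there.
#'
#' @param matrix A `coverage_matrix` (see [coverage_matrix()]).
#' @param min_cov Minimum maximum-depth threshold (default 5).
#' @param min_len Minimum covered length in bp (default 100).
#' @param samples Sample identifiers that must all contain the contig;
#'   defaults to every sample in the matrix.
#' @param annotations Optional annotation data.frame; when supplied, the core
#'   is restricted to annotated contigs (the carbohydrate-active subset).
#' @return An object of class `core_set`: a list with `contig_ids` (sorted),
#'   `min_cov`, `min_len`, `samples`, `annotation_filtered`.
#' @export
call_core <- function(matrix, min_cov = 5L, min_len = 100L, samples = NULL,
                      annotations = NULL) {
  all_samples <- attr(matrix, "samples") %||% unique(matrix$sample_id)
  if (is.null(samples)) samples <- all_samples
  unknown <- setdiff(samples, all_samples)
  if (length(unknown)) {
    stopf("unknown sample name(s): %s", paste(unknown, collapse = ", "))
  }
  m <- matrix[matrix$sample_id %in% samples, , drop = FALSE]
  pres <- is_present(m$max_cov, m$covered_len, min_cov, min_len)
  hit <- m$contig_id[pres]
  # present in every required sample <=> number of distinct present samples
  # equals the number of required samples
  tab <- table(unique(data.frame(contig_id = hit,
                                 sample_id = m$sample_id[pres]))$contig_id)
  ids <- sort(as.character(names(tab)[tab == length(unique(samples))]))
  filtered <- FALSE
  if (!is.null(annotations)) {
    ids <- intersect(ids, annotations$contig_id)
    filtered <- TRUE
  }
  structure(list(contig_ids = sort(ids), min_cov = as.integer(min_cov),
                 min_len = as.integer(min_len), samples = samples,
                 annotation_filtered = filtered),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("Core set: %d contigs (max depth >= %d over >= %d bp in all %d samples%s)\n",
              length(x$contig_ids), x$min_cov, x$min_len, length(x$samples),
              if (x$annotation_filtered) "; annotation-restricted" else ""))
  invisible(x)
}

#' @export
length.core_set <- function(x) length(x$contig_ids)

#' Core fraction as a printed percentage
#'
#' Returns `100 * core_size / total_size` rounded half-up to `decimals`
#' digits — the convention used when quoting what share of a cumulative
#' catalogue the core represents.
#'
#' @param core_size Number of core sequences.
#' @param total_size Total number of sequences in the catalogue.
#' @param decimals Digits after the decimal point (default 1).
#' @return Numeric percentage.
#' @examples
#' core_fraction(843, 226887) # 0.4
#' @export
core_fraction <- function(core_size, total_size, decimals = 1L) {
  if (length(total_size) != 1L || total_size <= 0) {
    stopf("total_size must be a single positive count")
  }
  if (any(core_size < 0) || any(core_size > total_size)) {
    stopf("core_size must lie in [0, total_size]")
  }
  x <- 100 * core_size / total_size
  f <- 10^decimals
  floor(x * f + 0.5) / f
}

#' Write / read a core contig list (one identifier per line)
#'
#' @param core A `core_set` or character vector of contig identifiers.
#' @param path File path.
#' @return `read_core()` returns a character vector of contig identifiers.
#' @export
write_core <- function(core, path) {
  ids <- if (inherits(core, "core_set")) core$contig_ids else as.character(core)
  writeLines(ids, path)
  invisible(path)
}

#' @rdname write_core
#' @export
read_core <- function(path) {
  ids <- readLines(path)
  ids[nzchar(ids)]
}

# ---- k-mer core ------------------------------------------------------------

# canonical form: lexicographic min of a k-mer and its reverse complement
canonical_kmers <- function(kmers) {
  if (length(kmers) == 0L) return(character())
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  ifelse(kmers <= rc, kmers, rc)
}

# unique canonical k-mers over a character vector of reads; reads shorter
# than k contribute nothing
kmer_set <- function(reads, k) {
  reads <- toupper(reads)
  keep <- nchar(reads) >= k
  reads <- reads[keep]
  if (length(reads) == 0L) return(character())
  km <- unlist(lapply(reads, function(r) {
    n <- nchar(r) - k + 1L
    substring(r, 1:n, k:(k + n - 1L))
  }), use.names = FALSE)
  unique(canonical_kmers(unique(km)))
}

#' Estimate the k-mer-level core fraction across samples
#'
#' Bootstraps the fraction of unique canonical k-mers shared by *all*
#' samples. Each bootstrap subsamples `subset_size` reads per sample without
#' replacement (seeded; reads are put in lexicographic order first, so the
#' estimate does not depend on read order), enumerates canonical k-mers per
#' sample, and reports `|intersection across samples| / |union across
#' samples|` (or the mean per-sample count as denominator with
#' `denominator = "mean"`).
#'
#' @param read_sets Named list, one element per sample: a character vector of
#'   read sequences, or a path to a FASTA/FASTQ file.
#' @param k K-mer length (default 20).
#' @param subset_size Reads subsampled per sample per bootstrap.
#' @param n_boot Number of bootstraps (default 4).
#' @param seed Integer seed.
#' @param denominator `"union"` (default) or `"mean"`.
#' @return Object of class `kmer_core_estimate`: `k`, `subset_size`,
#'   `n_boot`, `core_fraction_per_boot`, `unique_kmer_counts` (bootstraps x
#'   samples matrix), `n_short_skipped`, plus an audit trail of each
#'   bootstrap's subsample (`read_indices` into the sorted reads,
#'   `sorted_reads`) so any estimate can be recomputed independently.
#' @export
kmer_core_fraction <- function(read_sets, k = 20L, subset_size, n_boot = 4L,
                               seed = 1L, denominator = c("union", "mean")) {
  denominator <- match.arg(denominator)
  if (k < 1L) stopf("k must be >= 1")
  if (is.null(names(read_sets)) || anyDuplicated(names(read_sets))) {
    stopf("read_sets must be uniquely named by sample")
  }
  reads <- lapply(read_sets, function(x) {
    if (is.character(x) && length(x) == 1L && file.exists(x)) read_reads(x)
    else as.character(x)
  })
  n_reads <- vapply(reads, length, integer(1))
  if (any(n_reads < subset_size)) {
    stopf("subset_size (%d) exceeds available reads in sample(s): %s",
          subset_size,
          paste(names(reads)[n_reads < subset_size], collapse = ", "))
  }
  n_short <- sum(vapply(reads, function(r) sum(nchar(r) < k), integer(1)))
  if (n_short > 0) {
    message(sprintf("kmer_core_fraction: %d read(s) shorter than k = %d skipped",
                    n_short, k))
  }
  # read-order invariance: subsample indices against sorted reads
  reads <- lapply(reads, sort)
  samples <- sort(names(reads))
  fracs <- numeric(n_boot)
  counts <- matrix(0L, nrow = n_boot, ncol = length(samples),
                   dimnames = list(NULL, samples))
  read_indices <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    idxs <- with_seed(derive_seed(seed, b), lapply(samples, function(s)
      sample.int(length(reads[[s]]), subset_size)))
    names(idxs) <- samples
    read_indices[[b]] <- idxs
    sets <- lapply(samples, function(s) kmer_set(reads[[s]][idxs[[s]]], k))
    counts[b, ] <- vapply(sets, length, integer(1))
    core <- Reduce(intersect, sets)
    denom <- switch(denominator,
                    union = length(Reduce(union, sets)),
                    mean = mean(counts[b, ]))
    fracs[b] <- if (denom == 0) 0 else length(core) / denom
  }
  structure(list(k = as.integer(k), subset_size = as.integer(subset_size),
                 n_boot = as.integer(n_boot), core_fraction_per_boot = fracs,
                 unique_kmer_counts = counts, n_short_skipped = n_short,
                 denominator = denominator, read_indices = read_indices,
                 sorted_reads = reads),
            class = "kmer_core_estimate")
}

#' @export
print.kmer_core_estimate <- function(x, ...) {
  cat(sprintf("k-mer core estimate (k = %d, %d reads/sample, %d bootstraps)\n",
              x$k, x$subset_size, x$n_boot))
  cat(sprintf("  core fraction: %.3f to %.3f (mean %.3f of %s unique k-mers)\n",
              min(x$core_fraction_per_boot), max(x$core_fraction_per_boot),
              mean(x$core_fraction_per_boot),
              if (x$denominator == "union") "total (union)" else "mean per-sample"))
  invisible(x)
}

# read sequences from FASTA or FASTQ as a character vector
read_reads <- function(path) {
  fq <- grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE)
  ss <- Biostrings::readDNAStringSet(path, format = if (fq) "fastq" else "fasta")
  unname(as.character(ss))
}
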