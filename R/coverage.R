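#' Summarize per-base depth into per-contig coverage
#'
#' Reduces a per-base depth table (samtools-depth dialect: contig, 1-based
#' position, depth) to one row per contig with the two coverage statistics
#' downstream presence calls use: the maximum per-base depth (`max_cov`) and
#' the number of positions with depth at least 1 (`covered_len`).
#'
#' Rows may arrive in any order. Duplicated (contig, position) rows keep the
#' maximum depth, so a duplicated row never double-counts covered length.
#'
#' @param depth A data.frame with columns `contig_id`, `pos`, `depth`
#'   (as produced by [read_depth()]).
#' @param contiguous If `TRUE`, `covered_len` is the length of the longest run
#'   of consecutive covered positions rather than the count of all covered
#'   positions (the stricter reading of a minimum coverage-length rule).
#' @return A data.frame with columns `contig_id`, `max_cov`, `covered_len`,
#'   one row per contig appearing in the input, sorted by `contig_id`.
#' @examples
#' d <- data.frame(contig_id = "c1", pos = 1:3, depth = c(3L, 7L, 0L))
#' contig_coverage(d) # max_cov 7, covered_len 2
#' @export
contig_coverage <- function(depth, contiguous = FALSE) {
  depth <- as.data.frame(depth)
  need <- c("contig_id", "pos", "depth")
  if (!all(need %in% names(depth))) {
    stopf("depth table must have columns %s", paste(need, collapse = ", "))
  }
  if (nrow(depth) == 0L) {
    return(data.frame(contig_id = character(), max_cov = integer(),
                      covered_len = integer(), stringsAsFactors = FALSE))
  }
  bad <- which(depth$depth < 0 | depth$pos < 1)[1]
  if (!is.na(bad)) {
    stopf("invalid depth row %d: position %s, depth %s (positions must be >= 1, depths >= 0)",
          bad, depth$pos[bad], depth$depth[bad])
  }
  dt <- data.table::as.data.table(depth[need])
  # duplicated (contig, pos) keep the max depth
  dt <- dt[, list(depth = max(depth)), by = c("contig_id", "pos")]
  if (contiguous) {
    cov <- dt[, {
      p <- sort(pos[depth >= 1])
      len <- if (length(p) == 0L) 0L else max(rle_run_lengths(p))
      list(max_cov = as.integer(max(depth)), covered_len = as.integer(len))
    }, by = "contig_id"]
  } else {
    cov <- dt[, list(max_cov = as.integer(max(depth)),
                     covered_len = as.integer(sum(depth >= 1))),
              by = "contig_id"]
  }
  data.table::setorderv(cov, "contig_id")
  as.data.frame(cov)
}

# lengths of maximal runs of consecutive integers in a sorted vector
rle_run_lengths <- function(p) {
  if (length(p) == 1L) return(1L)
  breaks <- which(diff(p) != 1L)
  diff(c(0L, breaks, length(p)))
}

#' Presence call for a contig in one sample
#'
#' A contig is called present when its maximum per-base depth reaches
#' `min_cov` AND its covered length reaches `min_len` base pairs. Both
#' comparisons are inclusive (a contig at exactly 5x over exactly 100 bp is
#' present under the defaults).
#'
#' @param max_cov Integer vector of maximum per-base depths.
#' @param covered_len Integer vector of covered lengths (bp).
#' @param min_cov Minimum maximum-depth threshold (default 5).
#' @param min_len Minimum covered length in bp (default 100).
#' @return Logical vector.
#' @export
is_present <- function(max_cov, covered_len, min_cov = 5L, min_len = 100L) {
  if (min_cov < 0 || min_len < 0) stopf("presence thresholds must be >= 0")
  max_cov >= min_cov & covered_len >= min_len
}

#' Read a per-base depth table
#'
#' Reads the 3-column samtools-depth dialect: contig identifier, 1-based
#' position, depth; tab-separated, no header.
#'
#' @param path Path to the depth TSV.
#' @return data.frame with columns `contig_id`, `pos`, `depth`.
#' @export
read_depth <- function(path) {
  if (!file.exists(path)) stopf("depth file not found: %s", path)
  if (file.size(path) == 0L) {
    return(data.frame(contig_id = character(), pos = integer(),
                      depth = integer(), stringsAsFactors = FALSE))
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("contig_id", "pos", "depth"),
                          colClasses = list(character = 1, integer = 2:3))
  bad <- which(dt$depth < 0 | dt$pos < 1)[1]
  if (!is.na(bad)) {
    stopf("%s line %d: position %s, depth %s (positions must be >= 1, depths >= 0)",
          path, bad, dt$pos[bad], dt$depth[bad])
  }
  as.data.frame(dt)
}

#' Build a coverage matrix across samples
#'
#' Combines per-sample depth tables into the long coverage table the core rule
#' operates on: one row per (contig, sample) with `max_cov`, `covered_len`
#' and a presence flag. Pairs absent from the table have zero coverage.
#'
#' @param depths Either a named list of depth data.frames (names are sample
#'   identifiers) or a character vector of depth TSV paths.
#' @param sample_names Sample identifiers when `depths` is a vector of paths;
#'   defaults to the file base names.
#' @param min_cov,min_len Presence thresholds, see [is_present()].
#' @param contiguous Passed to [contig_coverage()].
#' @return A data.frame of class `coverage_matrix` with columns `contig_id`,
#'   `sample_id`, `max_cov`, `covered_len`, `present`; the ordered sample
#'   identifiers are kept in `attr(, "samples")`.
#' @export
coverage_matrix <- function(depths, sample_names = NULL, min_cov = 5L,
                            min_len = 100L, contiguous = FALSE) {
  if (is.character(depths)) {
    paths <- depths
    if (is.null(sample_names)) {
      sample_names <- tools::file_path_sans_ext(basename(paths))
    }
    if (length(sample_names) != length(paths)) {
      stopf("need one sample name per depth file")
    }
    depths <- lapply(paths, read_depth)
    names(depths) <- sample_names
  }
  if (is.null(names(depths)) || anyDuplicated(names(depths))) {
    stopf("depth tables must be uniquely named by sample")
  }
  per <- lapply(names(depths), function(s) {
    cov <- contig_coverage(depths[[s]], contiguous = contiguous)
    if (nrow(cov)) cov$sample_id <- s else cov$sample_id <- character()
    cov
  })
  mat <- as.data.frame(data.table::rbindlist(per))
  mat <- mat[, c("contig_id", "sample_id", "max_cov", "covered_len")]
  mat$present <- as.integer(is_present(mat$max_cov, mat$covered_len,
                                       min_cov, min_len))
  structure(mat, samples = names(depths), min_cov = min_cov, min_len = min_len,
            class = c("coverage_matrix", "data.frame"))
}

#' Write a coverage summary TSV
#'
#' @param matrix A `coverage_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(matrix, path) {
  data.table::fwrite(as.data.frame(matrix), path, sep = "\t")
  invisible(path)
}

#' Read a coverage summary TSV written by [write_coverage()]
#'
#' @param path Path to the summary TSV.
#' @return A `coverage_matrix` data.frame.
#' @export
read_coverage <- function(path) {
  dt <- as.data.frame(data.table::fread(path, sep = "\t"))
  structure(dt, samples = unique(dt$sample_id),
            class = c("coverage_matrix", "data.frame"))
}
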