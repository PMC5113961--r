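#' Derive a CAZy class from a family label
#'
#' Classes are taken from the family-label prefix: `GH13` is a glycoside
#' hydrolase (GH), `GT2` a glycosyltransferase (GT), `CE10` a carbohydrate
#' esterase (CE), `PL*` a polysaccharide lyase, `CB*`/`CBM*` a
#' carbohydrate-binding module. Anything else maps to `"unknown"`.
#'
#' @param family Character vector of CAZy family labels.
#' @return Character vector of classes in
#'   `{GT, GH, CE, CB, PL, unknown}`.
#' @export
cazy_class <- function(family) {
  cls <- rep("unknown", length(family))
  family <- as.character(family)
  pref2 <- toupper(substr(family, 1, 2))
  known <- c("GT", "GH", "CE", "CB", "PL")
  hit <- pref2 %in% known & grepl("^[A-Za-z]{2,3}[0-9]*$", family)
  cls[hit] <- pref2[hit]
  cls
}

#' Read a 12-column tabular alignment file
#'
#' BLAST outfmt-6 dialect: qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore; tab-separated, no header.
#'
#' @param path Path to the hits file.
#' @return data.frame with the 12 standard columns.
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) stopf("hits file not found: %s", path)
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (file.size(path) == 0L) {
    out <- data.frame(qseqid = character(), sseqid = character(),
                      pident = numeric(), length = integer(),
                      mismatch = integer(), gapopen = integer(),
                      qstart = integer(), qend = integer(),
                      sstart = integer(), send = integer(),
                      evalue = numeric(), bitscore = numeric(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  as.data.frame(data.table::fread(path, header = FALSE, sep = "\t",
                                  col.names = cols))
}

#' Best-scoring hit for a single query, with seeded tie-breaking
#'
#' Hits above the E-value cutoff are discarded; among survivors the hit with
#' the maximal bitscore wins. When several hits tie exactly on bitscore, one
#' is chosen uniformly at random; the tied candidates are sorted by subject
#' identifier before the seeded draw so the choice does not depend on input
#' row order.
#'
#' @param hits data.frame of alignment hits for one query (columns `qseqid`,
#'   `sseqid`, `evalue`, `bitscore` required).
#' @param max_evalue E-value cutoff; hits with `evalue > max_evalue` are
#'   dropped (default 1e-5, inclusive).
#' @param seed Integer seed for tie resolution.
#' @return One-row data.frame with `qseqid`, `sseqid`, `evalue`, `bitscore`,
#'   `tie_broken`, or `NULL` if no hit survives the cutoff.
#' @export
best_hit <- function(hits, max_evalue = 1e-5, seed = 1L) {
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  if (length(unique(hits$qseqid)) > 1L) {
    stopf("best_hit() expects hits for a single query; got %d distinct queries",
          length(unique(hits$qseqid)))
  }
  keep <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  if (nrow(keep) == 0L) return(NULL)
  top <- keep[keep$bitscore == max(keep$bitscore), , drop = FALSE]
  top <- top[order(top$sseqid), , drop = FALSE]
  idx <- if (nrow(top) > 1L) with_seed(seed, sample.int(nrow(top), 1L)) else 1L
  out <- top[idx, c("qseqid", "sseqid", "evalue", "bitscore"), drop = FALSE]
  out$tie_broken <- nrow(top) > 1L
  rownames(out) <- NULL
  out
}

#' Annotate contigs from alignment hits and subject metadata
#'
#' Applies the best-hit rule of [best_hit()] to every query in a hit table
#' and joins the winning subject's CAZy family and taxonomy from a sidecar
#' metadata table. The CAZy class is derived from the family label prefix.
#' Tie resolution draws from one seeded stream over queries taken in sorted
#' order, with tied candidates sorted by subject identifier first, so results
#' are reproducible and independent of input row order.
#'
#' @param hits data.frame of 12-column tabular hits (see [read_hits()]).
#' @param subject_meta data.frame mapping `subject_id` to `cazy_family`,
#'   `phylum`, `domain`.
#' @param max_evalue E-value cutoff, inclusive (default 1e-5).
#' @param seed Integer seed for tie-breaking.
#' @return data.frame with columns `contig_id`, `cazy_family`, `cazy_class`,
#'   `phylum`, `domain`, `best_evalue`, `best_bitscore`, `tie_broken`; one
#'   row per query with at least one qualifying hit.
#' @export
annotate_contigs <- function(hits, subject_meta, max_evalue = 1e-5, seed = 1L) {
  empty <- data.frame(contig_id = character(), cazy_family = character(),
                      cazy_class = character(), phylum = character(),
                      domain = character(), best_evalue = numeric(),
                      best_bitscore = numeric(), tie_broken = logical(),
                      stringsAsFactors = FALSE)
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  h <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  if (nrow(h) == 0L) return(empty)
  dt <- data.table::as.data.table(h[, c("qseqid", "sseqid", "evalue", "bitscore")])
  top <- dt[, .SD[bitscore == max(bitscore)], by = "qseqid"]
  data.table::setorderv(top, c("qseqid", "sseqid"))
  nt <- top[, list(n = .N), by = "qseqid"]  # qseqid sorted
  picks <- with_seed(seed, vapply(nt$n, function(n)
    if (n > 1L) sample.int(n, 1L) else 1L, integer(1)))
  offs <- cumsum(c(0L, nt$n[-nrow(nt)]))
  chosen <- top[offs + picks]
  ann <- data.frame(contig_id = chosen$qseqid,
                    subject_id = chosen$sseqid,
                    best_evalue = chosen$evalue,
                    best_bitscore = chosen$bitscore,
                    tie_broken = nt$n > 1L,
                    stringsAsFactors = FALSE)
  m <- match(ann$subject_id, subject_meta$subject_id)
  if (anyNA(m)) {
    stopf("subject metadata missing for %d subject(s), e.g. %s",
          sum(is.na(m)), ann$subject_id[which(is.na(m))[1]])
  }
  ann$cazy_family <- as.character(subject_meta$cazy_family[m])
  ann$cazy_class <- cazy_class(ann$cazy_family)
  ann$phylum <- as.character(subject_meta$phylum[m])
  ann$domain <- as.character(subject_meta$domain[m])
  ann[, c("contig_id", "cazy_family", "cazy_class", "phylum", "domain",
          "best_evalue", "best_bitscore", "tie_broken")]
}

#' Restrict annotations to cellular / viral / fungal taxa
#'
#' Keeps annotations whose best-hit taxonomy falls in the retained domains
#' (bacteria, archaea, viruses and fungi by default), dropping e.g.
#' plant-derived reference proteins. Order is preserved and the filter is
#' idempotent.
#'
#' @param annotations Annotation data.frame with a `domain` column.
#' @param keep_domains Character vector of domains to retain.
#' @return The filtered annotation data.frame.
#' @export
filter_taxa <- function(annotations,
                        keep_domains = c("Bacteria", "Archaea", "Viruses", "Fungi")) {
  annotations[annotations$domain %in% keep_domains, , drop = FALSE]
}

#' Count recA-bearing sequences in one sample
#'
#' Counts distinct query sequences with a qualifying alignment to the recA
#' single-copy marker; the count is the per-sample normalizer for
#' copies-per-recA abundances. The recA cutoff is strict (`evalue <
#' max_evalue`) by default.
#'
#' @param hits data.frame of alignment hits against recA for one sample
#'   (columns `qseqid`, `evalue`).
#' @param max_evalue E-value cutoff (default 1e-5).
#' @param strict If `TRUE` (default) require `evalue < max_evalue`; otherwise
#'   `evalue <= max_evalue`.
#' @return Integer count of distinct qualifying queries (0 when none).
#' @export
count_recA <- function(hits, max_evalue = 1e-5, strict = TRUE) {
  if (is.null(hits) || nrow(hits) == 0L) return(0L)
  ok <- if (strict) hits$evalue < max_evalue else hits$evalue <= max_evalue
  length(unique(hits$qseqid[ok]))
}

#' Read / write the contig annotation table
#'
#' Tab-separated with a header; columns `contig_id`, `cazy_family`,
#' `cazy_class`, `phylum`, `domain` (plus any extra columns present).
#'
#' @param path File path.
#' @return `read_annotations()` returns the annotation data.frame.
#' @export
read_annotations <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' @rdname read_annotations
#' @param annotations Annotation data.frame to write.
#' @export
write_annotations <- function(annotations, path) {
  data.table::fwrite(as.data.frame(annotations), path, sep = "\t")
  invisible(path)
}
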