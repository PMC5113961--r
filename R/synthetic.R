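# Built-in taxonomy used by the default community: phylum -> domain.
default_phylum_domains <- c(
  Proteobacteria = "Bacteria", Actinobacteria = "Bacteria",
  Firmicutes = "Bacteria", Bacteroidetes = "Bacteria",
  Verrucomicrobia = "Bacteria", Planctomycetes = "Bacteria",
  Acidobacteria = "Bacteria", Euryarchaeota = "Archaea",
  Ascomycota = "Fungi", Basidiomycota = "Fungi",
  Streptophyta = "Eukaryota", Uroviricota = "Viruses")

default_class_freqs <- c(GT = 0.30, GH = 0.30, CE = 0.15, CB = 0.10,
                         PL = 0.05, unknown = 0.10)

default_family_freqs <- list(
  GT = c(GT2 = 0.45, GT4 = 0.35, GT87 = 0.20),
  GH = c(GH13 = 0.40, GH76 = 0.20, GH94 = 0.20, GH3 = 0.20),
  CE = c(CE10 = 0.60, CE1 = 0.40),
  CB = c(CB32 = 0.60, CB50 = 0.40),
  PL = c(PL1 = 0.70, PL9 = 0.30),
  unknown = c(unknown = 1))

default_phylum_freqs <- c(
  Proteobacteria = 0.28, Actinobacteria = 0.17, Firmicutes = 0.10,
  Bacteroidetes = 0.07, Verrucomicrobia = 0.05, Planctomycetes = 0.05,
  Acidobacteria = 0.05, Euryarchaeota = 0.05, Ascomycota = 0.07,
  Basidiomycota = 0.03, Streptophyta = 0.05, Uroviricota = 0.03)

#' Configuration for a synthetic replicated soil community
#'
#' Describes a replicated metagenome experiment with a planted core: a set of
#' contigs of which a fixed fraction is guaranteed, by construction, to pass
#' the presence rule (max depth >= `presence_min_cov` over >=
#' `presence_min_len` covered bp) in every replicate, while every non-core
#' contig fails it in at least one replicate (forced dropout or depth capped
#' just below the threshold). Per-contig mean depth is lognormal; per-base
#' depth is the rounded mean with unit jitter — the only coverage features
#' downstream analysis uses are the maximum and the covered length, so no
#' read-level simulation is needed.
#'
#' @param n_samples Replicate metagenomes (default 4, as in a replicated
#'   field-block design).
#' @param n_contigs Total distinct contigs.
#' @param core_fraction Fraction of contigs planted as core.
#' @param contig_length_range Integer pair, contig length bounds in bp; the
#'   lower bound must be at least `presence_min_len`.
#' @param coverage_model List with `meanlog`, `sdlog` of the lognormal
#'   per-contig mean depth.
#' @param presence_min_cov,presence_min_len Presence thresholds (defaults 5
#'   and 100).
#' @param class_freqs Probability vector over CAZy classes
#'   (GT, GH, CE, CB, PL, unknown).
#' @param family_freqs_per_class Named list of probability vectors over
#'   families within each class.
#' @param phylum_freqs Probability vector over phyla.
#' @param phylum_domains Named map phylum -> domain.
#' @param recA_per_sample Integer vector of per-sample recA counts (length
#'   `n_samples`, entries >= 1).
#' @param dropout_rate Probability a non-core contig is absent from a given
#'   sample (default 0.3).
#' @param tie_fraction Fraction of contigs given an exactly score-tied
#'   duplicate hit in the synthetic alignment files, to exercise random
#'   tie-breaking (default 0.15).
#' @param seed Integer seed; the whole community is a deterministic function
#'   of the configuration including the seed.
#' @return Validated list of class `community_config`.
#' @export
community_config <- function(n_samples = 4L, n_contigs = 500L,
                             core_fraction = 0.1,
                             contig_length_range = c(150L, 800L),
                             coverage_model = list(meanlog = 0.8, sdlog = 0.9),
                             presence_min_cov = 5L, presence_min_len = 100L,
                             class_freqs = default_class_freqs,
                             family_freqs_per_class = default_family_freqs,
                             phylum_freqs = default_phylum_freqs,
                             phylum_domains = default_phylum_domains,
                             recA_per_sample = NULL,
                             dropout_rate = 0.3, tie_fraction = 0.15,
                             seed = 1L) {
  if (is.null(recA_per_sample)) {
    recA_per_sample <- 100L + 10L * (seq_len(n_samples) - 1L)
  }
  cfg <- list(n_samples = as.integer(n_samples),
              n_contigs = as.integer(n_contigs),
              core_fraction = core_fraction,
              contig_length_range = as.integer(contig_length_range),
              coverage_model = coverage_model,
              presence_min_cov = as.integer(presence_min_cov),
              presence_min_len = as.integer(presence_min_len),
              class_freqs = class_freqs,
              family_freqs_per_class = family_freqs_per_class,
              phylum_freqs = phylum_freqs,
              phylum_domains = phylum_domains,
              recA_per_sample = as.integer(recA_per_sample),
              dropout_rate = dropout_rate,
              tie_fraction = tie_fraction,
              seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "community_config")
}

validate_config <- function(cfg) {
  chk_prob <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stopf("%s must be a probability vector summing to 1 (got sum %.12f)",
            what, sum(p))
    }
  }
  chk_prob(cfg$class_freqs, "class_freqs")
  chk_prob(cfg$phylum_freqs, "phylum_freqs")
  for (cl in names(cfg$family_freqs_per_class)) {
    chk_prob(cfg$family_freqs_per_class[[cl]],
             sprintf("family_freqs_per_class[%s]", cl))
  }
  if (cfg$core_fraction < 0 || cfg$core_fraction > 1) {
    stopf("core_fraction must lie in [0, 1]")
  }
  if (any(cfg$recA_per_sample < 1)) stopf("recA_per_sample entries must be >= 1")
  if (length(cfg$recA_per_sample) != cfg$n_samples) {
    stopf("recA_per_sample must have one entry per sample")
  }
  if (cfg$contig_length_range[1] < cfg$presence_min_len) {
    stopf("minimum contig length (%d) must be >= presence_min_len (%d) so planted core contigs can satisfy the length rule",
          cfg$contig_length_range[1], cfg$presence_min_len)
  }
  if (cfg$dropout_rate < 0 || cfg$dropout_rate > 1) {
    stopf("dropout_rate must lie in [0, 1]")
  }
  missing_dom <- setdiff(names(cfg$phylum_freqs), names(cfg$phylum_domains))
  if (length(missing_dom)) {
    stopf("phylum_domains missing entries for: %s",
          paste(missing_dom, collapse = ", "))
  }
  invisible(cfg)
}

#' Generate a synthetic replicated community with a planted core
#'
#' Deterministic given the configuration (which includes the seed). Core
#' contigs satisfy both presence thresholds in every sample; non-core
#' contigs fail the presence rule in at least one sample by construction
#' (forced dropout or per-base depth capped at `presence_min_cov - 1`), so
#' the planted truth is unambiguous and downstream core calling can be
#' checked by set equality.
#'
#' @param config A `community_config`.
#' @return Object of class `synthetic_truth`: `core_ids` (character),
#'   `per_sample_depth` (list contig -> length x samples integer matrix),
#'   `annotations` (data.frame), `contig_lengths`, `samples`, `config`.
#' @export
generate_community <- function(config) {
  validate_config(config)
  cfg <- config
  n <- cfg$n_contigs
  S <- cfg$n_samples
  samples <- sprintf("S%d", seq_len(S))
  with_seed(cfg$seed, {
    ids <- sprintf("contig_%05d", seq_len(n))
    n_core <- as.integer(round(cfg$core_fraction * n))
    core_ids <- if (n_core > 0L) sort(sample(ids, n_core)) else character()
    is_core <- ids %in% core_ids
    lens <- if (n > 0L) {
      sample(cfg$contig_length_range[1]:cfg$contig_length_range[2], n,
             replace = TRUE)
    } else integer()

    # annotations
    cls <- if (n > 0L) sample(names(cfg$class_freqs), n, replace = TRUE,
                              prob = cfg$class_freqs) else character()
    fam <- vapply(cls, function(cl) {
      fr <- cfg$family_freqs_per_class[[cl]]
      sample(names(fr), 1L, prob = fr)
    }, character(1), USE.NAMES = FALSE)
    phy <- if (n > 0L) sample(names(cfg$phylum_freqs), n, replace = TRUE,
                              prob = cfg$phylum_freqs) else character()
    dom <- unname(cfg$phylum_domains[phy])
    annotations <- data.frame(contig_id = ids, cazy_family = fam,
                              cazy_class = cls, phylum = phy, domain = dom,
                              stringsAsFactors = FALSE)

    mc <- cfg$presence_min_cov
    ml <- cfg$coverage_model$meanlog
    sl <- cfg$coverage_model$sdlog
    per_sample_depth <- vector("list", n)
    names(per_sample_depth) <- ids
    for (i in seq_len(n)) {
      L <- lens[i]
      depth <- matrix(0L, nrow = L, ncol = S, dimnames = list(NULL, samples))
      if (is_core[i]) {
        for (s in seq_len(S)) {
          base <- as.integer(round(mc + stats::rlnorm(1, ml, sl)))
          d <- pmax(0L, base + sample(c(-1L, 0L, 1L), L, replace = TRUE))
          if (max(d) < mc) d[1L] <- mc   # jitter never hides a planted core
          depth[, s] <- d
        }
      } else {
        fails <- stats::runif(S) < cfg$dropout_rate
        if (!any(fails)) fails[sample.int(S, 1L)] <- TRUE
        for (s in seq_len(S)) {
          if (fails[s]) {
            # fail the presence rule: dropout, or depth capped below threshold
            if (stats::runif(1) < 0.5) next
            base <- min(as.integer(round(stats::rlnorm(1, ml, sl))), mc - 1L)
            d <- pmax(0L, base + sample(c(-1L, 0L, 1L), L, replace = TRUE))
            depth[, s] <- pmin(d, mc - 1L)
          } else {
            base <- as.integer(round(stats::rlnorm(1, ml, sl)))
            depth[, s] <- pmax(0L, base + sample(c(-1L, 0L, 1L), L, replace = TRUE))
          }
        }
      }
      per_sample_depth[[i]] <- depth
    }
    structure(list(core_ids = core_ids, per_sample_depth = per_sample_depth,
                   annotations = annotations, contig_lengths = lens,
                   samples = samples, config = cfg),
              class = "synthetic_truth")
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("Synthetic community: %d contigs x %d samples, %d planted core\n",
              x$config$n_contigs, x$config$n_samples, length(x$core_ids)))
  invisible(x)
}

#' Extract the coverage matrix implied by a synthetic truth
#'
#' Convenience for in-memory pipelines: equivalent to writing depth fixtures
#' and re-reading them.
#'
#' @param truth A `synthetic_truth`.
#' @param ... Passed to [coverage_matrix()] (thresholds).
#' @return A `coverage_matrix`.
#' @export
truth_coverage_matrix <- function(truth, ...) {
  depths <- lapply(truth$samples, function(s) {
    rows <- lapply(names(truth$per_sample_depth), function(cid) {
      d <- truth$per_sample_depth[[cid]][, s]
      keep <- which(d >= 1L)
      if (length(keep) == 0L) return(NULL)
      data.frame(contig_id = cid, pos = keep, depth = d[keep],
                 stringsAsFactors = FALSE)
    })
    as.data.frame(data.table::rbindlist(rows))
  })
  names(depths) <- truth$samples
  coverage_matrix(depths, ...)
}

#' Write a synthetic community to plain-text fixture files
#'
#' Emits, per sample, a depth TSV (samtools-depth dialect, covered positions
#' only), a 12-column tabular alignment-hit file whose hits are consistent
#' with the planted annotations (score-tied duplicate subjects planted for a
#' configurable fraction of contigs share the winning annotation, so
#' tie-breaking never changes the truth), and a recA hit file sized to the
#' configured per-sample recA counts; plus one annotation TSV, a subject
#' metadata TSV, a FASTA of contig sequences, a recA count TSV, and a truth
#' file listing the planted core identifiers. Fixtures are byte-identical
#' for identical (config, seed).
#'
#' @param truth A `synthetic_truth`.
#' @param out_dir Output directory (created if needed).
#' @return Named list of written paths (the manifest), invisibly.
#' @export
write_fixture <- function(truth, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok || file.access(out_dir, 2L) != 0L) {
    stopf("cannot write to directory: %s", out_dir)
  }
  cfg <- truth$config
  samples <- truth$samples
  ids <- names(truth$per_sample_depth)
  manifest <- list(depth = character(), hits = character(),
                   reca_hits = character())

  for (s in samples) {
    rows <- lapply(ids, function(cid) {
      d <- truth$per_sample_depth[[cid]][, s]
      keep <- which(d >= 1L)
      if (length(keep) == 0L) return(NULL)
      data.frame(contig_id = cid, pos = keep, depth = d[keep])
    })
    dt <- data.table::rbindlist(rows)
    p <- file.path(out_dir, sprintf("depth_%s.tsv", s))
    if (nrow(dt) == 0L) file.create(p) else {
      data.table::fwrite(dt, p, sep = "\t", col.names = FALSE)
    }
    manifest$depth[s] <- p
  }

  ann <- truth$annotations
  ann_path <- file.path(out_dir, "annotations.tsv")
  write_annotations(ann, ann_path)
  manifest$annotations <- ann_path

  # subject metadata + per-sample CAZy hit files, seeded off the config seed
  with_seed(derive_seed(cfg$seed, 7L), {
    n <- nrow(ann)
    subj1 <- sprintf("caz|%s|%s|%04d", ann$cazy_family, ann$phylum, seq_len(n))
    tie <- if (n > 0L) stats::runif(n) < cfg$tie_fraction else logical()
    subj2 <- sprintf("caz|%s|%s|%04d_dup", ann$cazy_family, ann$phylum, seq_len(n))
    meta <- data.frame(subject_id = c(subj1, subj2[tie]),
                       cazy_family = c(ann$cazy_family, ann$cazy_family[tie]),
                       phylum = c(ann$phylum, ann$phylum[tie]),
                       domain = c(ann$domain, ann$domain[tie]),
                       stringsAsFactors = FALSE)
    meta_path <- file.path(out_dir, "subject_meta.tsv")
    data.table::fwrite(meta, meta_path, sep = "\t")
    manifest$subject_meta <- meta_path

    top_bits <- if (n > 0L) round(stats::runif(n, 80, 300), 1) else numeric()
    for (s in samples) {
      covered <- vapply(ids, function(cid)
        any(truth$per_sample_depth[[cid]][, s] >= 1L), logical(1))
      idx <- which(covered)
      mk_hit <- function(i, sseq, bits, ev) {
        data.frame(qseqid = ann$contig_id[i], sseqid = sseq, pident = 85.0,
                   length = 150L, mismatch = 10L, gapopen = 1L, qstart = 1L,
                   qend = 150L, sstart = 1L, send = 150L, evalue = ev,
                   bitscore = bits, stringsAsFactors = FALSE)
      }
      rows <- lapply(idx, function(i) {
        h <- mk_hit(i, subj1[i], top_bits[i], 1e-20)
        if (tie[i]) h <- rbind(h, mk_hit(i, subj2[i], top_bits[i], 1e-20))
        # a decoy below the best score, and one failing the E-value gate
        h <- rbind(h,
                   mk_hit(i, subj1[i], top_bits[i] - 15, 1e-10),
                   mk_hit(i, subj1[i], top_bits[i] + 50, 1e-3))
        h
      })
      dt <- data.table::rbindlist(rows)
      p <- file.path(out_dir, sprintf("cazy_hits_%s.tsv", s))
      if (nrow(dt) == 0L) file.create(p) else {
        data.table::fwrite(dt, p, sep = "\t", col.names = FALSE)
      }
      manifest$hits[s] <- p
    }

    # recA hit files: one qualifying query per planted recA gene, plus one
    # non-qualifying hit at exactly the cutoff (recA uses a strict cutoff)
    for (si in seq_along(samples)) {
      s <- samples[si]
      nr <- cfg$recA_per_sample[si]
      q <- sprintf("%s_read_%05d", s, seq_len(nr + 1L))
      dt <- data.frame(qseqid = q, sseqid = "recA|SS04542", pident = 90.0,
                       length = 120L, mismatch = 12L, gapopen = 0L,
                       qstart = 1L, qend = 120L, sstart = 1L, send = 120L,
                       evalue = c(rep(1e-10, nr), 1e-5), bitscore = 200.0,
                       stringsAsFactors = FALSE)
      p <- file.path(out_dir, sprintf("recA_hits_%s.tsv", s))
      data.table::fwrite(dt, p, sep = "\t", col.names = FALSE)
      manifest$reca_hits[s] <- p
    }
  })

  reca_path <- file.path(out_dir, "recA_counts.tsv")
  data.table::fwrite(data.frame(sample_id = samples,
                                recA_count = cfg$recA_per_sample),
                     reca_path, sep = "\t")
  manifest$reca_counts <- reca_path

  # contig sequences
  fa_path <- file.path(out_dir, "contigs.fasta")
  seqs <- with_seed(derive_seed(cfg$seed, 13L), vapply(truth$contig_lengths,
    function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                      collapse = ""), character(1)))
  if (length(seqs)) {
    ss <- Biostrings::DNAStringSet(seqs)
    names(ss) <- ids
    Biostrings::writeXStringSet(ss, fa_path)
  } else {
    file.create(fa_path)
  }
  manifest$fasta <- fa_path

  truth_path <- file.path(out_dir, "core_truth.txt")
  writeLines(truth$core_ids, truth_path)
  manifest$core_truth <- truth_path

  # manifest JSON carries paths relative to the fixture directory, so two
  # fixtures from the same (config, seed) are byte-identical wherever written
  manifest_rel <- rapply(manifest, function(x) {
    stats::setNames(basename(x), names(x))
  }, classes = "character", how = "replace")
  manifest_path <- file.path(out_dir, "fixture_manifest.json")
  jsonlite::write_json(manifest_rel, manifest_path, auto_unbox = FALSE,
                       pretty = TRUE)
  manifest$manifest <- manifest_path
  invisible(manifest)
}
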