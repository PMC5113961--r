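#' Run configuration for the end-to-end pipeline
#'
#' Collects the stage input paths and every threshold, with the standard
#' defaults: presence at max depth >= 5 over >= 100 covered bp in all
#' replicates, CAZy hits at E <= 1e-5, recA at strict E < 1e-5,
#' remote-sharing gates E <= 1e-5 / length >= 70 / identity >= 70%, and the
#' 50,000 x 1,000 resampling null. The configuration round-trips through
#' YAML unchanged.
#'
#' @param depth_paths Per-sample depth TSVs (samtools-depth dialect).
#' @param sample_names Sample identifiers, one per depth file.
#' @param cazy_hits_paths Per-sample 12-column tabular CAZy hit files (their
#'   union is annotated).
#' @param subject_meta_path Subject metadata TSV (subject_id, cazy_family,
#'   phylum, domain).
#' @param reca_hits_paths Optional per-sample recA hit files (counted with
#'   the strict cutoff); alternatively `reca_counts_path`.
#' @param reca_counts_path Optional recA counts TSV (sample_id, recA_count).
#' @param bias_pool_path Optional single-column category pool for the bias
#'   test; by default the cumulative annotations serve as the pool.
#' @param bias_field Category field for the bias test: `"class"` or
#'   `"phylum"`.
#' @param share_targets Optional named list of target coverage sources for
#'   the sharing stage: each element a list with `depth_paths`,
#'   `sample_names`, and optionally `group_label`.
#' @param out_dir Output directory.
#' @param min_cov,min_len Presence thresholds.
#' @param max_evalue CAZy / sharing E-value cutoff.
#' @param share_min_length,share_min_pident Remote-sharing gates.
#' @param n_draw,n_rep Bias-test draw size and repetitions.
#' @param seed Global seed; per-stage seeds are derived by a fixed scheme.
#' @return List of class `run_config`.
#' @export
run_config <- function(depth_paths = NULL, sample_names = NULL,
                       cazy_hits_paths = NULL, subject_meta_path = NULL,
                       reca_hits_paths = NULL, reca_counts_path = NULL,
                       bias_pool_path = NULL, bias_field = "class",
                       share_targets = NULL, out_dir = ".",
                       min_cov = 5L, min_len = 100L, max_evalue = 1e-5,
                       share_min_length = 70L, share_min_pident = 70,
                       n_draw = 50000L, n_rep = 1000L, seed = 1L) {
  structure(list(depth_paths = depth_paths, sample_names = sample_names,
                 cazy_hits_paths = cazy_hits_paths,
                 subject_meta_path = subject_meta_path,
                 reca_hits_paths = reca_hits_paths,
                 reca_counts_path = reca_counts_path,
                 bias_pool_path = bias_pool_path, bias_field = bias_field,
                 share_targets = share_targets, out_dir = out_dir,
                 min_cov = as.integer(min_cov), min_len = as.integer(min_len),
                 max_evalue = max_evalue,
                 share_min_length = as.integer(share_min_length),
                 share_min_pident = share_min_pident,
                 n_draw = as.integer(n_draw), n_rep = as.integer(n_rep),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full core-identification pipeline
#'
#' Executes coverage summarization, annotation (+ recA counting), core
#' calling, abundance profiling, the database-bias test and core sharing, in
#' order, skipping any stage whose inputs are absent from the configuration.
#' Stages communicate only through the written TSV/JSON files, so each is
#' independently re-runnable; a JSON manifest records parameters, input
#' checksums, per-stage record counts and output paths, and suffices to
#' reproduce the run. Given identical inputs, configuration and seed, every
#' output is byte-identical across runs.
#'
#' @param config A `run_config` (or path to a YAML file).
#' @return The manifest, invisibly (also written to
#'   `<out_dir>/run_manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- config
  if (is.null(cfg$depth_paths)) {
    stopf("pipeline requires depth_paths (coverage stage is mandatory)")
  }
  missing <- cfg$depth_paths[!file.exists(cfg$depth_paths)]
  for (p in c(cfg$cazy_hits_paths, cfg$subject_meta_path,
              cfg$reca_hits_paths, cfg$reca_counts_path, cfg$bias_pool_path)) {
    if (!is.null(p) && !file.exists(p)) missing <- c(missing, p)
  }
  if (length(missing)) {
    stopf("missing input file(s): %s", paste(missing, collapse = ", "))
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(cfg$out_dir, ...)
  inputs <- unlist(c(cfg$depth_paths, cfg$cazy_hits_paths,
                     cfg$subject_meta_path, cfg$reca_hits_paths,
                     cfg$reca_counts_path, cfg$bias_pool_path))
  manifest <- list(
    package_version = as.character(utils::packageVersion("corecazyome")),
    parameters = cfg[c("min_cov", "min_len", "max_evalue", "share_min_length",
                       "share_min_pident", "n_draw", "n_rep", "seed",
                       "bias_field")],
    input_md5 = as.list(tools::md5sum(inputs)),
    stages = list(), skipped = character())

  # stage 1: coverage
  mat <- coverage_matrix(cfg$depth_paths, cfg$sample_names,
                         min_cov = cfg$min_cov, min_len = cfg$min_len)
  cov_path <- out("coverage_summary.tsv")
  write_coverage(mat, cov_path)
  manifest$stages$coverage <- list(output = cov_path, n_records = nrow(mat))

  # stage 2: annotation (+ recA counts)
  annotations <- NULL
  reca <- NULL
  if (!is.null(cfg$cazy_hits_paths) && !is.null(cfg$subject_meta_path)) {
    hits <- unique(as.data.frame(
      data.table::rbindlist(lapply(cfg$cazy_hits_paths, read_hits))))
    meta <- as.data.frame(data.table::fread(cfg$subject_meta_path, sep = "\t"))
    annotations <- annotate_contigs(hits, meta, max_evalue = cfg$max_evalue,
                                    seed = derive_seed(cfg$seed, 2L))
    ann_path <- out("annotations.tsv")
    write_annotations(annotations, ann_path)
    manifest$stages$annotate <- list(output = ann_path,
                                     n_records = nrow(annotations))
  } else manifest$skipped <- c(manifest$skipped, "annotate")
  if (!is.null(cfg$reca_hits_paths)) {
    samples <- cfg$sample_names %||% attr(mat, "samples")
    reca <- data.frame(sample_id = samples,
                       recA_count = vapply(cfg$reca_hits_paths, function(p)
                         count_recA(read_hits(p), max_evalue = cfg$max_evalue),
                         integer(1)))
    reca_path <- out("recA_counts.tsv")
    data.table::fwrite(reca, reca_path, sep = "\t")
    manifest$stages$recA <- list(output = reca_path,
                                 n_records = nrow(reca))
  } else if (!is.null(cfg$reca_counts_path)) {
    reca <- as.data.frame(data.table::fread(cfg$reca_counts_path, sep = "\t"))
  }

  # stage 3: core calling (restricted to annotated contigs when available)
  core <- call_core(mat, min_cov = cfg$min_cov, min_len = cfg$min_len,
                    annotations = annotations)
  core_path <- out("core_contigs.txt")
  write_core(core, core_path)
  jsonlite::write_json(
    list(n_core = length(core$contig_ids), min_cov = core$min_cov,
         min_len = core$min_len, samples = core$samples,
         annotation_filtered = core$annotation_filtered),
    out("core_report.json"), auto_unbox = TRUE, pretty = TRUE)
  manifest$stages$core <- list(output = core_path,
                               n_records = length(core$contig_ids))

  # stage 4: abundance profiling
  if (!is.null(annotations) && !is.null(reca) && length(core$contig_ids)) {
    ab <- normalize_abundance(mat, reca)
    prof_paths <- character()
    for (lev in c("class", "family", "phylum")) {
      pr <- profile_abundance(core, annotations, ab, by = lev,
                              samples = attr(mat, "samples"))
      p <- out(sprintf("profile_%s.tsv", lev))
      write_profile(pr, p)
      prof_paths[lev] <- p
    }
    manifest$stages$profile <- list(output = as.list(prof_paths),
                                    n_records = length(core$contig_ids))
  } else manifest$skipped <- c(manifest$skipped, "profile")

  # stage 5: bias test (core categories vs. cumulative pool)
  if (!is.null(annotations) && length(core$contig_ids)) {
    field <- if (cfg$bias_field == "phylum") "phylum" else "cazy_class"
    pool <- if (!is.null(cfg$bias_pool_path)) {
      readLines(cfg$bias_pool_path)
    } else annotations[[field]]
    obs_labels <- annotations[[field]][annotations$contig_id %in% core$contig_ids]
    n_draw <- min(cfg$n_draw, length(pool))
    nulls <- draw_null(pool, n_draw = n_draw, n_rep = cfg$n_rep,
                       seed = derive_seed(cfg$seed, 5L))
    bt <- bias_compare(category_distribution(obs_labels,
                                             categories = sort(unique(c(obs_labels, pool)))),
                       nulls)
    bias_path <- out("bias_test.json")
    jsonlite::write_json(
      list(statistic = bt$statistic, observed_statistic = bt$observed_statistic,
           p_empirical = bt$p_empirical, n_draw = n_draw, n_rep = cfg$n_rep,
           per_category = bt$per_category),
      bias_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    manifest$stages$bias_test <- list(output = bias_path,
                                      n_records = cfg$n_rep)
  } else manifest$skipped <- c(manifest$skipped, "bias_test")

  # stage 6: sharing with target metagenomes
  if (!is.null(cfg$share_targets) && length(core$contig_ids)) {
    recs <- lapply(names(cfg$share_targets), function(nm) {
      tg <- cfg$share_targets[[nm]]
      tmat <- coverage_matrix(tg$depth_paths, tg$sample_names,
                              min_cov = cfg$min_cov, min_len = cfg$min_len)
      shared_by_coverage(core, tmat, min_cov = cfg$min_cov,
                         min_len = cfg$min_len, metagenome_id = nm,
                         group_label = tg$group_label %||% NA_character_)
    })
    sharing <- do.call(rbind, recs)
    share_path <- out("sharing.tsv")
    data.table::fwrite(sharing, share_path, sep = "\t")
    grp_path <- out("sharing_groups.tsv")
    data.table::fwrite(summarize_groups(sharing), grp_path, sep = "\t")
    manifest$stages$share <- list(output = share_path,
                                  n_records = nrow(sharing))
  } else manifest$skipped <- c(manifest$skipped, "share")

  if (length(manifest$skipped)) {
    warning(sprintf("skipped stage(s) with absent inputs: %s",
                    paste(manifest$skipped, collapse = ", ")))
  }
  manifest_path <- out("run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
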