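# End-to-end orchestration from a YAML config: synthesize or load inputs,
# run target curation, ROI identification, robustness checks, matching and
# cohort statistics, and write stage outputs plus a JSON run manifest.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    alpha = 0.05,
    min_freq = 5L,
    min_donors = 5L,
    split_half = TRUE,
    false_positives = list(run = FALSE, list_sizes = c(30L, 100L),
                           n_lists = 20L),
    cohort = list(run = TRUE)
  )
}

read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config '%s' does not exist.", path))
  cfg <- yaml::read_yaml(path)
  defaults <- pipeline_defaults()
  cfg <- utils::modifyList(defaults, cfg)
  has_atlas_files <- !is.null(cfg$atlas_manifest)
  has_synth <- !is.null(cfg$synthetic_atlas)
  if (!has_atlas_files && !has_synth) {
    abort(paste("Config must provide either 'atlas_manifest' (file input)",
                "or 'synthetic_atlas' (generator settings)."))
  }
  cfg
}

#' Run the full pipeline from a YAML config
#'
#' Stages: obtain the atlas and gene set (from files, or from the
#' synthetic generator), normalise, identify ROIs, optionally run the
#' split-half and random-list robustness checks, optionally generate and
#' analyse a synthetic cohort.  Every stage writes its table under
#' `out_dir`, and `manifest.json` records the config snapshot, seeds,
#' package version, design-decision settings in force, and timestamps.
#'
#' @param config Path to a YAML config.  Recognised keys: `seed`, `alpha`,
#'   `min_freq`, `min_donors`, `split_half` (logical), `false_positives`
#'   (`run`, `list_sizes`, `n_lists`), `synthetic_atlas` (arguments of
#'   [synthetic_atlas_config()]), `atlas_manifest` + `gene_list` (file
#'   inputs), `targetscan` (`file`, `mirna_family`, `threshold`), `cohort`
#'   (`run`, plus arguments of [synthetic_cohort_config()], or
#'   `participants` CSV + `roi` column name).
#' @param out_dir Output directory (created; default `"pgl_run"`).
#' @return Invisibly, a list with the stage results (`rois`,
#'   `split_half`, `false_positives`, `match`, `stats`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir = "pgl_run") {
  cfg <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- assert_seed(cfg$seed)
  results <- list()
  log_line <- function(...) inform(sprintf(...))

  # --- stage: gene set -----------------------------------------------------
  gs <- if (!is.null(cfg$targetscan)) {
    recs <- read_targetscan(cfg$targetscan$file, cfg$targetscan$mirna_family)
    log_line("targets: %d records parsed", nrow(recs))
    filter_by_pct(recs, cfg$targetscan$threshold %||% 0.99)
  } else if (!is.null(cfg$gene_list)) {
    read_gene_set(cfg$gene_list)
  } else NULL

  # --- stage: atlas --------------------------------------------------------
  if (!is.null(cfg$synthetic_atlas)) {
    ac <- do.call(synthetic_atlas_config,
                  utils::modifyList(cfg$synthetic_atlas, list(seed = seed)))
    sim <- make_atlas(ac)
    atlas <- sim$atlas
    gs <- gs %||% sim$gene_set
    yaml::write_yaml(sim$truth, file.path(out_dir, "atlas_truth.yaml"))
  } else {
    atlas <- read_atlas(cfg$atlas_manifest)
  }
  if (is.null(gs)) {
    abort("Config must provide a gene set ('targetscan' or 'gene_list').")
  }
  write_gene_set(gs, file.path(out_dir, "gene_set.txt"))
  atlas <- normalize_within_donor(atlas)
  log_line("atlas: %d donors, %d genes; gene set: %d genes",
           length(atlas$donors), length(atlas$gene_universe), nrow(gs))

  # --- stage: ROIs ---------------------------------------------------------
  rois <- get_rois(atlas, gs, alpha = cfg$alpha, min_freq = cfg$min_freq,
                   min_donors = cfg$min_donors)
  readr::write_tsv(
    dplyr::select(rois, -"per_donor"), file.path(out_dir, "rois.tsv"),
    progress = FALSE)
  log_line("get_rois: %d region(s) at frequency >= %d (universe m = %d)",
           nrow(rois), as.integer(cfg$min_freq), attr(rois, "m_tests"))
  results$rois <- rois

  # --- stage: robustness ---------------------------------------------------
  if (isTRUE(cfg$split_half) && nrow(gs) >= 4) {
    sh <- split_half_validation(atlas, gs, seed = seed, alpha = cfg$alpha,
                                min_freq = cfg$min_freq,
                                min_donors = cfg$min_donors)
    readr::write_tsv(
      tibble::tibble(region = sh$overlap),
      file.path(out_dir, "split_half_overlap.tsv"), progress = FALSE)
    results$split_half <- sh
  }
  if (isTRUE(cfg$false_positives$run)) {
    fp <- false_positive_simulation(
      atlas, list_sizes = cfg$false_positives$list_sizes,
      n_lists = cfg$false_positives$n_lists, seed = seed,
      alpha = cfg$alpha, min_freq = cfg$min_freq,
      min_donors = cfg$min_donors)
    readr::write_tsv(fp, file.path(out_dir, "false_positives.tsv"),
                     progress = FALSE)
    results$false_positives <- fp
  }

  # --- stage: cohort -------------------------------------------------------
  if (isTRUE(cfg$cohort$run)) {
    participants <- if (!is.null(cfg$cohort$participants)) {
      readr::read_csv(cfg$cohort$participants, col_types = readr::cols(),
                      progress = FALSE)
    } else {
      cohort_args <- cfg$cohort[setdiff(names(cfg$cohort),
                                        c("run", "participants", "roi"))]
      make_cohort(do.call(synthetic_cohort_config,
                          utils::modifyList(cohort_args,
                                            list(seed = seed + 1L))))
    }
    stats_tbl <- cohort_stats(participants, roi = cfg$cohort$roi %||%
                                "vol_roi")
    readr::write_tsv(stats_tbl, file.path(out_dir, "cohort_stats.tsv"),
                     progress = FALSE)
    results$stats <- stats_tbl
  }

  manifest <- list(
    config = cfg,
    seed = seed,
    package_version = as.character(utils::packageVersion("pglr")),
    settings = list(
      test = "two-sided Wilcoxon rank-sum, positive direction required",
      bonferroni_m = "shared region universe size",
      ranking = "frequency desc, mean -log10 adjusted p desc, region asc",
      probe_collapse = "mean",
      normalization = "per-gene z-score across regions, population SD",
      matching = "greedy global minimum Euclidean distance",
      recovery_score = "admission - discharge (positive = improvement)"
    ),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  results$manifest <- manifest
  invisible(results)
}
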