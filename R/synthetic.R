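# Synthetic atlas and cohort generators: fixtures with the statistical
# structure the analysis assumes, so every stage is testable without
# external downloads.  Defaults emulate the study conditions: 6 donor
# brains, ~250 regions, 20,000 genes, a 93-gene target set, and two
# clinical groups of 111 participants each.

#' Configuration for a synthetic expression atlas
#'
#' @param n_donors,n_regions,n_genes Atlas dimensions (defaults 6, 250,
#'   20,000 — the shape of the six-donor Allen-style reference).
#' @param target_set_size Size of the ground-truth gene set (default 93).
#' @param planted_regions Region identifiers receiving the expression
#'   shift for target genes (default: the first region).
#' @param planted_shift Added expression for target genes in planted
#'   regions, in units of the background SD (z-units); `>= 0`.
#' @param region_sampling_rate Probability that a region is sampled in any
#'   given donor (default 1, i.e. all donors sample all regions).
#' @param background Background value distribution: `"gaussian"`
#'   (standard normal) or `"lognormal"` (exp of a standard normal; the
#'   planted shift is then applied on the log scale).
#' @param seed Integer seed; generation is fully deterministic given the
#'   config.
#' @return A `pgl_atlas_config` list.
#' @export
synthetic_atlas_config <- function(n_donors = 6L, n_regions = 250L,
                                   n_genes = 20000L, target_set_size = 93L,
                                   planted_regions = NULL,
                                   planted_shift = 1.0,
                                   region_sampling_rate = 1.0,
                                   background = c("gaussian", "lognormal"),
                                   seed = 1L) {
  background <- match.arg(background)
  regions <- sprintf("region_%03d", seq_len(n_regions))
  planted_regions <- planted_regions %||% regions[1]
  if (!all(planted_regions %in% regions)) {
    abort(sprintf("Planted region(s) not in the region list: %s",
                  paste(setdiff(planted_regions, regions), collapse = ", ")))
  }
  if (target_set_size >= n_genes) {
    abort("`target_set_size` must be smaller than `n_genes`.")
  }
  if (planted_shift < 0) abort("`planted_shift` must be >= 0.")
  if (region_sampling_rate <= 0 || region_sampling_rate > 1) {
    abort("`region_sampling_rate` must be in (0, 1].")
  }
  structure(list(
    n_donors = as.integer(n_donors), n_regions = as.integer(n_regions),
    n_genes = as.integer(n_genes),
    target_set_size = as.integer(target_set_size),
    regions = regions, planted_regions = planted_regions,
    planted_shift = planted_shift,
    region_sampling_rate = region_sampling_rate,
    background = background, seed = assert_seed(seed)
  ), class = "pgl_atlas_config")
}

#' Generate a synthetic multi-donor expression atlas
#'
#' Per donor, every gene-by-region value is drawn from the background
#' distribution; the ground-truth target set receives `planted_shift` in
#' each planted region for every donor; each region is kept in a donor
#' with probability `region_sampling_rate`.  Returns the raw (not yet
#' normalised) atlas, the ground-truth gene set, and a `truth` record —
#' ground truth is never embedded in the atlas matrices themselves.
#'
#' @param config A [synthetic_atlas_config()].
#' @return List: `atlas` (`pgl_atlas`), `gene_set` ([gene_set()]),
#'   `truth` (planted regions, shift, seed).
#' @export
make_atlas <- function(config) {
  stopifnot(inherits(config, "pgl_atlas_config"))
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  null_blocks <- list()
  withr::with_seed(config$seed, {
    target_genes <- sort(sample(genes, config$target_set_size))
    target_idx <- match(target_genes, genes)
    planted_cols <- config$planted_regions
    exprs <- lapply(seq_len(config$n_donors), function(d) {
      keep <- if (config$region_sampling_rate < 1) {
        runif(config$n_regions) <= config$region_sampling_rate
      } else rep(TRUE, config$n_regions)
      # every donor keeps the planted regions so the planted signal is
      # interpretable at any sampling rate
      keep[match(planted_cols, config$regions)] <- TRUE
      cols <- config$regions[keep]
      m <- matrix(rnorm(config$n_genes * length(cols)),
                  nrow = config$n_genes,
                  dimnames = list(genes, cols))
      block0 <- m[target_idx, planted_cols, drop = FALSE]
      if (config$planted_shift > 0) {
        m[target_idx, planted_cols] <- block0 + config$planted_shift
      }
      if (config$background == "lognormal") {
        m <- exp(m)
        block0 <- exp(block0)
      }
      # pristine (shift-free) planted block, kept with the ground truth so a
      # bit-exact matched null atlas can be reconstructed
      null_blocks[[d]] <<- block0
      m
    })
    names(exprs) <- sprintf("donor%d", seq_len(config$n_donors))
    names(null_blocks) <- names(exprs)
    list(
      atlas = new_atlas(exprs),
      gene_set = gene_set(target_genes, provenance = list(
        source = "synthetic", target_set_size = config$target_set_size,
        seed = config$seed)),
      truth = list(planted_regions = config$planted_regions,
                   planted_shift = config$planted_shift,
                   target_genes = target_genes,
                   background = config$background, seed = config$seed,
                   null_blocks = null_blocks)
    )
  })
}

# Per-variable natural scales for the planted covariate relations:
# intercepts per group and residual SD (multiplied by `noise_sd`).
COHORT_SCALES <- list(
  bfi_agreeableness = list(case = 3.0, control = 3.5, sd = 0.6),
  age = list(case = 27, control = 27, sd = 9),
  delta_ideation = list(case = 7, control = 3, sd = 6)
)

#' Configuration for a synthetic clinical cohort
#'
#' Defaults mirror the published demographics: two groups of 111, planted
#' volume deficit in cases of 0.8 SD, planted within-case regressions of
#' agreeableness, age and ideation recovery on normalised ROI volume, and
#' comorbidity prevalences from the published demographics table.
#'
#' @param n_per_group Participants per group (default 111).
#' @param volume_effect Standardised mean difference in the focal ROI
#'   volume/ICV ratio (cases lower; default 0.8).
#' @param slopes Named numeric vector of planted slopes (native units per
#'   z of normalised ROI volume) for `bfi_agreeableness`, `age`,
#'   `delta_ideation`; applied in cases only.
#' @param noise_sd Residual-noise multiplier for the planted relations
#'   (default 1; each variable keeps its natural scale).
#' @param diagnosis_prevalences Named list mapping diagnosis name to
#'   `c(case_rate, control_rate)` for a current diagnosis.
#' @param seed Integer seed.
#' @return A `pgl_cohort_config` list.
#' @export
synthetic_cohort_config <- function(
    n_per_group = 111L,
    volume_effect = 0.8,
    slopes = c(bfi_agreeableness = -0.13, age = -3.7, delta_ideation = -1.2),
    noise_sd = 1,
    diagnosis_prevalences = list(
      depression = c(0.66, 0.54), anxiety = c(0.29, 0.22),
      ptsd = c(0.19, 0.20), bipolar = c(0.24, 0.26),
      avoidant = c(0.30, 0.18), obsessive_compulsive = c(0.22, 0.07),
      narcissistic = c(0.05, 0.03), antisocial = c(0.07, 0.02)
    ),
    seed = 1L) {
  rates <- unlist(diagnosis_prevalences)
  if (any(rates < 0 | rates > 1)) abort("Prevalences must lie in [0, 1].")
  if (n_per_group < 3) abort("`n_per_group` must be >= 3.")
  if (noise_sd <= 0) abort("`noise_sd` must be positive.")
  structure(list(
    n_per_group = as.integer(n_per_group), volume_effect = volume_effect,
    slopes = slopes, noise_sd = noise_sd,
    diagnosis_prevalences = diagnosis_prevalences,
    seed = assert_seed(seed)
  ), class = "pgl_cohort_config")
}

draw_dx <- function(n, current_rate, past_rate = 0.10) {
  current <- rbinom(n, 1, current_rate) == 1
  past <- !current & rbinom(n, 1, past_rate) == 1
  ifelse(current, "current", ifelse(past, "past", "absent"))
}

#' Generate a synthetic clinical cohort
#'
#' Cases and controls of `n_per_group` each.  The focal ROI volume/ICV
#' ratio is normal with a standardised case deficit of `volume_effect`;
#' ICV is normal with mean 1.5e6 mm^3 and SD 1e5; in cases only, the
#' configured covariates follow planted linear relations to the
#' standardised normalised volume; binary diagnoses are drawn at the
#' configured prevalences.  Deterministic under the config seed.
#'
#' @param config A [synthetic_cohort_config()].
#' @return Participant tibble: `id`, `group` (`case`/`control`), `age`,
#'   `sex`, `race`, `dx_*` status columns, `vol_roi`, `icv`, `bfi_*`,
#'   `ideation_*`, `mir_level`.
#' @export
make_cohort <- function(config) {
  stopifnot(inherits(config, "pgl_cohort_config"))
  n <- config$n_per_group
  withr::with_seed(config$seed, {
    per_group <- lapply(c(case = "case", control = "control"), function(g) {
      is_case <- g == "case"
      zvol <- rnorm(n) - if (is_case) config$volume_effect else 0
      ratio <- 1e-3 + 1e-4 * zvol
      icv <- pmax(rnorm(n, 1.5e6, 1e5), 5e5)
      planted <- function(var) {
        sc <- COHORT_SCALES[[var]]
        slope <- if (is_case) (config$slopes[[var]] %||% 0) else 0
        # slope acts on the standardised volume; in cases zvol is shifted,
        # so centre it before applying the planted relation
        z <- zvol + if (is_case) config$volume_effect else 0
        sc[[g]] + slope * z + rnorm(n, 0, config$noise_sd * sc$sd)
      }
      agree <- planted("bfi_agreeableness")
      age <- pmax(planted("age"), 1)
      delta <- planted("delta_ideation")
      admission <- rnorm(n, if (is_case) 15 else 10, 5)
      dx <- lapply(config$diagnosis_prevalences, function(rates) {
        draw_dx(n, rates[if (is_case) 1 else 2])
      })
      tibble::tibble(
        id = sprintf("%s%03d", if (is_case) "c" else "p", seq_len(n)),
        group = g,
        age = age,
        sex = sample(c("female", "male"), n, replace = TRUE,
                     prob = if (is_case) c(0.46, 0.54) else c(0.54, 0.46)),
        race = sample(c("white", "black", "hispanic", "asian"), n,
                      replace = TRUE, prob = c(0.60, 0.15, 0.15, 0.10)),
        !!!setNames(dx, paste0("dx_", names(dx))),
        vol_roi = ratio * icv,
        icv = icv,
        bfi_openness = rnorm(n, 3.4, 0.6),
        bfi_conscientiousness = rnorm(n, 3.2, 0.6),
        bfi_extraversion = rnorm(n, 3.1, 0.6),
        bfi_agreeableness = agree,
        bfi_neuroticism = rnorm(n, if (is_case) 3.8 else 3.4, 0.6),
        ideation_lifetime = rnorm(n, if (is_case) 18 else 13, 4),
        ideation_admission = admission,
        ideation_discharge = admission - delta,
        mir_level = exp(rnorm(n, if (is_case) 0.3 else 0, 0.5))
      )
    })
    dplyr::bind_rows(per_group)
  })
}

#' Generate a matching problem: cases plus a covariate-shifted pool
#'
#' Produces a case group and a larger control pool whose age, sex and
#' diagnosis distributions are deliberately shifted, for exercising
#' [euclidean_match()] and its balance diagnostics.
#'
#' @param n_cases Number of cases (default 111).
#' @param pool_size Pool size (default 333).
#' @param case_rates,pool_rates Named current-diagnosis prevalences.
#' @param age_mean_case,age_mean_pool,age_sd_case,age_sd_pool Age
#'   distributions.
#' @param seed Integer seed.
#' @return Tibble with `group` of `case` / `pool`.
#' @export
make_match_pool <- function(n_cases = 111L, pool_size = 333L,
                            case_rates = c(depression = 0.66, anxiety = 0.29,
                                           obsessive_compulsive = 0.22,
                                           avoidant = 0.30),
                            pool_rates = c(depression = 0.45, anxiety = 0.15,
                                           obsessive_compulsive = 0.07,
                                           avoidant = 0.12),
                            age_mean_case = 27.6, age_mean_pool = 24,
                            age_sd_case = 9.7, age_sd_pool = 7,
                            seed = 1L) {
  stopifnot(identical(sort(names(case_rates)), sort(names(pool_rates))))
  withr::with_seed(assert_seed(seed), {
    mk <- function(g, n, age_mean, age_sd, rates, female_p) {
      dx <- lapply(names(case_rates), function(d) draw_dx(n, rates[[d]]))
      names(dx) <- paste0("dx_", names(case_rates))
      tibble::tibble(
        id = sprintf("%s%04d", if (g == "case") "c" else "p", seq_len(n)),
        group = g,
        age = pmax(rnorm(n, age_mean, age_sd), 18),
        sex = sample(c("female", "male"), n, replace = TRUE,
                     prob = c(female_p, 1 - female_p)),
        race = sample(c("white", "black", "hispanic", "asian"), n,
                      replace = TRUE, prob = c(0.60, 0.15, 0.15, 0.10)),
        !!!dx
      )
    }
    dplyr::bind_rows(
      mk("case", n_cases, age_mean_case, age_sd_case, case_rates, 0.46),
      mk("pool", pool_size, age_mean_pool, age_sd_pool, pool_rates, 0.60)
    )
  })
}

#' Parameter-recovery summary across simulation replicates
#'
#' Runs the full pipeline on fresh synthetic data `n_replicates` times and
#' summarises: planted-region recovery rate (planted region returned at
#' rank 1 with full donor frequency), false-positive rate on matched null
#' atlases (same config, shift 0), slope bias and RMSE for each planted
#' cohort relation, and empirical power of the case-control volume
#' comparison at `p < 1e-4`.
#'
#' @param atlas_config A [synthetic_atlas_config()] (its seed is
#'   overridden per replicate).
#' @param cohort_config A [synthetic_cohort_config()] (likewise).
#' @param n_replicates Number of replicates (`>= 10`).
#' @param seed Master seed spawning per-replicate child seeds.
#' @param alpha,min_freq,min_donors Passed to [get_rois()].
#' @return Tibble of summary metrics (`metric`, `value`, `n_replicates`).
#' @export
recovery_suite <- function(atlas_config, cohort_config, n_replicates = 20L,
                           seed = 1L, alpha = 0.05, min_freq = NULL,
                           min_donors = NULL) {
  if (n_replicates < 10) abort("`n_replicates` must be >= 10.")
  min_freq <- min_freq %||% min(5L, atlas_config$n_donors)
  min_donors <- min_donors %||% min(5L, atlas_config$n_donors)
  seeds <- child_seeds(assert_seed(seed), n_replicates)
  null_config <- atlas_config
  null_config$planted_shift <- 0

  rec <- fp <- pow <- logical(n_replicates)
  slopes_est <- matrix(NA_real_, n_replicates, length(cohort_config$slopes),
                       dimnames = list(NULL, names(cohort_config$slopes)))
  for (i in seq_len(n_replicates)) {
    ac <- atlas_config; ac$seed <- seeds[i]
    sim <- make_atlas(ac)
    rois <- suppressMessages(get_rois(
      normalize_within_donor(sim$atlas), sim$gene_set, alpha = alpha,
      min_freq = min_freq, min_donors = min_donors))
    rec[i] <- nrow(rois) > 0 &&
      rois$region[rois$rank == 1] %in% sim$truth$planted_regions &&
      all(rois$frequency[rois$rank == 1] == atlas_config$n_donors)

    nc <- null_config; nc$seed <- seeds[i] + 1L
    nsim <- make_atlas(nc)
    nrois <- suppressMessages(get_rois(
      normalize_within_donor(nsim$atlas), nsim$gene_set, alpha = alpha,
      min_freq = min_freq, min_donors = min_donors))
    fp[i] <- nrow(nrois) > 0

    cc <- cohort_config; cc$seed <- seeds[i]
    coh <- make_cohort(cc)
    cases <- coh[coh$group == "case", ]
    ctrls <- coh[coh$group == "control", ]
    ratio_c <- icv_normalize(cases$vol_roi, cases$icv)
    z <- (ratio_c - mean(ratio_c)) / sd(ratio_c)
    for (v in names(cohort_config$slopes)) {
      y <- if (v == "delta_ideation") {
        delta_ideation(cases$ideation_admission, cases$ideation_discharge)
      } else cases[[v]]
      slopes_est[i, v] <- linear_fit(z, y)$slope
    }
    pow[i] <- rank_sum_compare(
      ratio_c, icv_normalize(ctrls$vol_roi, ctrls$icv))$p < 1e-4
  }

  bias <- colMeans(slopes_est) - cohort_config$slopes
  rmse <- sqrt(colMeans(
    (slopes_est - rep(cohort_config$slopes,
                      each = n_replicates))^2))
  mcse <- apply(slopes_est, 2, sd) / sqrt(n_replicates)
  dplyr::bind_rows(
    tibble::tibble(metric = "planted_region_recovery_rate",
                   value = mean(rec)),
    tibble::tibble(metric = "null_false_positive_rate", value = mean(fp)),
    tibble::tibble(metric = "volume_rank_sum_power_p1e4",
                   value = mean(pow)),
    tibble::tibble(metric = paste0("slope_bias_", colnames(slopes_est)),
                   value = unname(bias)),
    tibble::tibble(metric = paste0("slope_rmse_", colnames(slopes_est)),
                   value = unname(rmse)),
    tibble::tibble(metric = paste0("slope_mcse_", colnames(slopes_est)),
                   value = unname(mcse))
  ) |>
    dplyr::mutate(n_replicates = n_replicates)
}

#' Matched null counterpart of a synthetic atlas draw
#'
#' Returns the same noise realisation with the planted expression shift
#' removed: exactly the atlas that [make_atlas()] would produce from the
#' same config with `planted_shift = 0` (the generators consume the random
#' stream identically), without re-drawing the 20,000-gene matrices.
#' Useful for paired signal/null comparisons across replicates.
#'
#' @param sim The list returned by [make_atlas()].
#' @return A list of the same shape (`atlas`, `gene_set`, `truth`) with
#'   `planted_shift = 0`.
#' @export
make_null_counterpart <- function(sim) {
  stopifnot(is.list(sim), inherits(sim$atlas, "pgl_atlas"))
  shift <- sim$truth$planted_shift
  if (shift == 0) return(sim)
  target_idx <- match(sim$truth$target_genes, sim$atlas$gene_universe)
  planted <- sim$truth$planted_regions
  exprs <- lapply(names(sim$atlas$exprs), function(d) {
    m <- sim$atlas$exprs[[d]]
    m[target_idx, planted] <- sim$truth$null_blocks[[d]]
    m
  })
  names(exprs) <- names(sim$atlas$exprs)
  truth <- sim$truth
  truth$planted_shift <- 0
  list(atlas = new_atlas(exprs), gene_set = sim$gene_set, truth = truth)
}

# Row-wise z-scoring of a small block (population SD), mirroring
# normalize_within_donor for the override path.
zscore_rows <- function(m) {
  zs <- .row_zscore_cpp(m)
  zs$z
}

#' Matched-null ROI analysis via common random numbers
#'
#' Evaluates [get_rois()] for the ground-truth gene set on the matched
#' null counterpart of a synthetic draw (same noise, planted shift
#' removed) without materialising or re-normalising the null atlas:
#' background gene rows have identical normalised values in the signal and
#' null atlases, so only the target-gene rows are re-standardised and
#' substituted into the enrichment sweep.  Numerically identical to
#' `get_rois(normalize_within_donor(make_null_counterpart(sim)$atlas),
#' sim$gene_set, ...)`.
#'
#' @param sim The list returned by [make_atlas()] (raw atlas + truth).
#' @param atlas The normalised signal atlas
#'   (`normalize_within_donor(sim$atlas)`).
#' @param ... Passed to [get_rois()] (`alpha`, `min_freq`, `min_donors`).
#' @return A `pgl_rois` tibble for the null counterpart.
#' @export
get_rois_matched_null <- function(sim, atlas, ...) {
  stopifnot(inherits(atlas, "pgl_atlas"), atlas$normalized)
  target_idx <- match(sim$truth$target_genes, atlas$gene_universe)
  values <- lapply(atlas$donors, function(d) {
    raw <- sim$atlas$exprs[[d]][target_idx, , drop = FALSE]
    cols <- intersect(sim$truth$planted_regions, colnames(raw))
    raw[, cols] <- sim$truth$null_blocks[[d]]
    zscore_rows(raw)
  })
  names(values) <- atlas$donors
  get_rois_sets(atlas, list(sim$gene_set), ...,
                null_override = list(rows = target_idx,
                                     values = values))[[1]]
}
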