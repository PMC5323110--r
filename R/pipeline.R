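# End-to-end orchestration: synthetic cohort -> preprocessing -> ReHo and
# seed discovery -> seed-based connectivity -> group statistics ->
# behaviour -> mediation, with one top-level seed driving every stage.

#' Build a pipeline configuration
#'
#' All numeric defaults are the analysis-chain defaults used throughout the
#' package: 10 discarded volumes, 0.01-0.08 Hz band, 0.5 mm dRMS scrub
#' threshold, 2 mm / 2 degree exclusion, 8 mm FWHM smoothing, 27-voxel ReHo
#' neighbourhood, group cluster rule {p < 0.005, >= 74 voxels (1,998 mm^3)},
#' behaviour cluster rule {p < 0.05, >= 389 voxels (10,503 mm^3)},
#' one-sample FWE p < 0.01, alpha = 0.05. Cohort sizes and volume counts
#' are desk-scale defaults chosen so a full run stays interactive.
#'
#' @param seed master RNG seed
#' @param n_patient,n_control cohort sizes
#' @param n_volumes volumes per subject
#' @param tr_s repetition time (s)
#' @param ... overrides for any other config entry
#' @return a named list of resolved settings
#' @export
pipeline_config <- function(seed = 1, n_patient = 12, n_control = 12,
                            n_volumes = 120, tr_s = 2, ...) {
  cfg <- list(
    seed = seed, n_patient = n_patient, n_control = n_control,
    n_volumes = n_volumes, tr_s = tr_s,
    n_discard = 10, low_hz = 0.01, high_hz = 0.08,
    drms_threshold_mm = 0.5, exclusion_mm = 2, exclusion_deg = 2,
    fwhm_mm = 8, neighborhood = 27,
    voxel_p_group = 0.005, min_extent_group = 74,
    voxel_p_behavior = 0.05, min_extent_behavior = 389,
    seed_min_extent = 30,
    fwe_p = 0.01, alpha = 0.05,
    global_signal = TRUE, seed_source = "reho",
    run_clustersim = FALSE, clustersim_iter = 1000,
    calibrate = TRUE, spike_prob = 0.25, atrophy_effect = 0.05)
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown))
    stop("unknown config entries: ", paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  cfg
}

# regenerate + preprocess one subject; returns pieces both branches need
process_subject <- function(cohort, i, cfg, wm, csf) {
  bold <- generate_bold(cohort$subjects[i, ], cohort$atlas, cohort$truth,
                        cohort$n_volumes, cohort$tr_s)
  preprocess_subject(bold, cohort$motion[[i]], wm, csf,
                     n_discard = cfg$n_discard, low_hz = cfg$low_hz,
                     high_hz = cfg$high_hz,
                     global_signal = cfg$global_signal)
}

#' Run the full analysis chain on a synthetic cohort
#'
#' Executes cohort generation, per-subject preprocessing and motion QA,
#' ReHo mapping with seed discovery from the ReHo group difference,
#' seed-based Fisher-z connectivity on the scrubbed and smoothed series,
#' one-sample network maps with the positive-connectivity restriction,
#' the covariate-and-GM-adjusted group GLM with cluster tabulation,
#' behaviour-connectivity regressions with conjunction (patients), and the
#' three-step mediation of EF on EM through connectivity strength. The
#' returned summary contains numbers only and is byte-reproducible for a
#' fixed seed.
#'
#' @param config a [pipeline_config()]
#' @param out_dir optional directory: writes `summary.json` and the fully
#'   resolved `config.json`
#' @param atlas,truth optional [atlas_spec()] / [ground_truth()] overrides
#' @param verbose print per-stage progress
#' @return the summary list, invisibly
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         atlas = default_atlas(), truth = ground_truth(),
                         verbose = interactive()) {
  cfg <- config
  say <- function(...) if (verbose) message(sprintf(...))
  say("stage synth: cohort %d/%d, %d volumes",
      cfg$n_patient, cfg$n_control, cfg$n_volumes)
  cohort <- generate_cohort(cfg$n_patient, cfg$n_control, atlas, truth,
                            seed = cfg$seed, n_volumes = cfg$n_volumes,
                            tr_s = cfg$tr_s, calibrate = cfg$calibrate,
                            spike_prob = cfg$spike_prob,
                            atrophy_effect = cfg$atrophy_effect)
  excluded <- vapply(cohort$motion, exclusion_check, logical(1),
                     max_mm = cfg$exclusion_mm, max_deg = cfg$exclusion_deg)
  if (any(excluded)) {
    say("excluding %d subject(s) for gross motion", sum(excluded))
    cohort$subjects <- cohort$subjects[!excluded, , drop = FALSE]
    cohort$motion <- cohort$motion[!excluded]
    cohort$gm <- cohort$gm[!excluded]
  }
  n <- nrow(cohort$subjects)
  group <- cohort$subjects$group
  mask <- gm_mask(atlas)
  wm <- array(FALSE, atlas$grid_shape); wm[atlas$regions$wm] <- TRUE
  csf <- array(FALSE, atlas$grid_shape); csf[atlas$regions$csf] <- TRUE

  say("stage preprocess + reho: %d subjects", n)
  reho_maps <- vector("list", n)
  mean_drms <- numeric(n)
  flagged_frac <- numeric(n)
  for (i in seq_len(n)) {
    pp <- process_subject(cohort, i, cfg, wm, csf)
    mean_drms[i] <- mean(pp$drms)
    flagged_frac[i] <- {
      later <- which(pp$drms > cfg$drms_threshold_mm) + 1L
      fl <- unique(as.vector(outer(later, -1:2, `+`)))
      t <- n_volumes(pp$series)
      length(fl[fl >= 1 & fl <= t]) / t
    }
    rh <- reho_map(pp$series, mask, cfg$neighborhood)
    rh <- normalize_reho(rh)
    reho_maps[[i]] <- smooth_map(rh$values, cfg$fwhm_mm,
                                 atlas$voxel_size_mm, mask)
  }
  qa <- motion_group_qa(mean_drms, group)

  say("stage seed discovery")
  covars <- cohort$subjects[, c("age", "gender", "education")]
  reho_diff <- behavior_regression(reho_maps,
                                   score = as.integer(group == "patient"),
                                   covariates = covars, mask = mask,
                                   contrast = "ReHo group difference")
  seeds <- if (cfg$seed_source == "reho")
    select_seeds(reho_diff, atlas, cfg$voxel_p_group, cfg$seed_min_extent)
  else list()
  seed_fallback <- FALSE
  if (!length(seeds)) {
    seed_fallback <- cfg$seed_source == "reho"
    if (seed_fallback)
      warning("no ReHo-difference seeds survive; falling back to atlas seeds")
    seeds <- lapply(names(truth$networks), function(nm)
      seed_roi(nm, atlas$regions[[nm]], "sphere"))
  }
  seed_names <- vapply(seeds, `[[`, character(1), "name")

  say("stage connectivity: %d seed(s)", length(seeds))
  zmaps <- lapply(seeds, function(s) vector("list", n))
  for (i in seq_len(n)) {
    pp <- process_subject(cohort, i, cfg, wm, csf)
    sc <- scrub(pp$series, pp$drms, cfg$drms_threshold_mm)
    sm <- smooth_series(sc$series, cfg$fwhm_mm)
    for (s in seq_along(seeds))
      zmaps[[s]][[i]] <- fc_zmap(sm, seeds[[s]], mask)
  }

  say("stage group statistics")
  gm_cov <- lapply(cohort$gm, logit_gm, voxel_size_mm = atlas$voxel_size_mm,
                   fwhm_mm = cfg$fwhm_mm, mask = atlas$brain_mask)
  min_extent_group <- cfg$min_extent_group
  clustersim <- NULL
  if (cfg$run_clustersim) {
    cs <- estimate_extent_threshold(mask, cfg$fwhm_mm,
                                    atlas$voxel_size_mm,
                                    voxel_p = cfg$voxel_p_group,
                                    alpha = cfg$fwe_p,
                                    n_iter = cfg$clustersim_iter,
                                    seed = derive_seed(cfg$seed, 999))
    min_extent_group <- cs$extent_threshold_voxels
    clustersim <- list(extent_threshold_voxels = cs$extent_threshold_voxels,
                       extent_threshold_mm3 = cs$extent_threshold_mm3,
                       n_iterations = cs$n_iterations)
  }
  group_tables <- list()
  behav <- list()
  patients <- group == "patient"
  pheno <- add_composites(cohort$subjects)
  for (s in seq_along(seeds)) {
    nm <- seed_names[s]
    os_p <- one_sample_map(zmaps[[s]][patients], mask, cfg$fwe_p)
    os_c <- one_sample_map(zmaps[[s]][!patients], mask, cfg$fwe_p)
    pos <- positive_mask(os_p) | positive_mask(os_c)
    amask <- if (any(pos)) pos else mask
    gd <- group_glm(zmaps[[s]], group, covars, gm_cov, amask)
    ct <- cluster_table(gd, cfg$voxel_p_group, min_extent_group, atlas,
                        network = nm)
    group_tables[[nm]] <- ct
    sig_set <- function(map) {
      cb <- cluster_table(map, cfg$voxel_p_behavior,
                          cfg$min_extent_behavior, atlas, network = nm)
      sig <- array(FALSE, atlas$grid_shape)
      for (vx in cb$clusters) sig[vx] <- TRUE
      list(sig = sig, table = cb$table)
    }
    em_map <- behavior_regression(zmaps[[s]][patients], pheno$EM[patients],
                                  covars[patients, ], amask, "EM")
    ef_map <- behavior_regression(zmaps[[s]][patients], pheno$EF[patients],
                                  covars[patients, ], amask, "EF")
    em_sig <- sig_set(em_map); ef_sig <- sig_set(ef_map)
    conj <- conjunction(em_sig$sig, ef_sig$sig, atlas, em_map, ef_map,
                        network = nm)
    behav[[nm]] <- list(em = em_sig$table, ef = ef_sig$table,
                        conjunction = conj$table,
                        conj_clusters = conj$clusters)
  }

  say("stage mediation")
  dlpfc <- if ("seed_DLPFC" %in% seed_names) "seed_DLPFC" else seed_names[1]
  mediator_cluster <- NULL; mediator_source <- "atlas_target_MCC"
  if (length(behav[[dlpfc]]$conj_clusters)) {
    mediator_cluster <- behav[[dlpfc]]$conj_clusters[[1]]
    mediator_source <- "behavior_conjunction"
  } else if (length(group_tables[[dlpfc]]$clusters)) {
    mediator_cluster <- group_tables[[dlpfc]]$clusters[[1]]
    mediator_source <- "group_difference_cluster"
  } else {
    mediator_cluster <- atlas$regions$target_MCC
  }
  si <- which(seed_names == dlpfc)
  strengths <- extract_mediator(zmaps[[si]][patients], mediator_cluster)
  med <- if (sum(patients) >= 10)
    fit_mediation(pheno$EF[patients], strengths, pheno$EM[patients],
                  alpha = cfg$alpha)
  else NULL
  if (is.null(med))
    warning("fewer than 10 patients; mediation stage skipped")

  tab_list <- function(tb) lapply(seq_len(nrow(tb)), function(i)
    as.list(tb[i, , drop = FALSE]))
  summary <- list(
    config = cfg,
    n_patient = sum(patients), n_control = sum(!patients),
    n_excluded = sum(excluded),
    motion_qa = qa,
    mean_flagged_fraction = mean(flagged_frac),
    seeds = lapply(seeds, function(s)
      list(name = s$name, n_voxels = length(s$voxels), source = s$source)),
    seed_fallback = seed_fallback,
    clustersim = clustersim,
    composites = list(
      em_mean = tapply(pheno$EM, group, mean),
      ef_mean = tapply(pheno$EF, group, mean),
      em_ef_corr = stats::cor(pheno$EM, pheno$EF)),
    group_difference = lapply(group_tables, function(ct)
      tab_list(ct$table)),
    behavior = lapply(behav, function(b)
      list(em = tab_list(b$em), ef = tab_list(b$ef),
           conjunction = tab_list(b$conjunction))),
    mediation = if (is.null(med)) list(skipped = TRUE) else list(
      a = as.list(med$a), b = as.list(med$b), c = as.list(med$c),
      c_prime = as.list(med$c_prime), indirect = med$indirect,
      indirect_ratio = med$indirect_ratio,
      classification = med$classification,
      mediator_source = mediator_source,
      n = med$n))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(summary)
}
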