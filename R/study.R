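# Multi-subject phantom study: the study configuration, per-subject
# simulation + first-level analysis, and the in-memory end-to-end engine the
# pipeline stages are built from.

#' Default phantom-study configuration
#'
#' Describes a two-network phantom: each network is three spheres on a common
#' grid, localized by a two-condition blocked task (each network responds to
#' one condition), with a main event-related picture-naming task run once per
#' preceding-language condition. A condition effect is planted in network A
#' and absent in network B, emulating an after-effect confined to one
#' functional network.
#'
#' @param n_subjects Number of synthetic subjects.
#' @param grid_shape Grid dimensions (voxels).
#' @param effect_a Planted condition effect in network A, percent signal
#'   change (L1-after-L2 minus L1-after-L1).
#' @return Nested configuration list (YAML-serializable; see
#'   [read_study_config()]).
#' @export
demo_study_config <- function(n_subjects = 12, grid_shape = c(24, 24, 24),
                              effect_a = 0.07) {
  list(
    grid = list(shape = as.integer(grid_shape), voxel_size_mm = c(2, 2, 2)),
    n_subjects = as.integer(n_subjects),
    tr_s = 1.4,
    baseline = 100,
    conditions = c("L1_after_L1", "L1_after_L2"),
    main_response = 1.0,
    effects = list(network_a = effect_a, network_b = 0),
    localizer_response = 1.5,
    amplitude_sd = 0.03,
    networks = list(
      network_a = list(centers = list(c(7, 7, 7), c(7, 17, 7), c(17, 7, 7)),
                       radius_vox = 4, localizer_condition = "taskA"),
      network_b = list(centers = list(c(7, 7, 18), c(7, 17, 18), c(17, 7, 18)),
                       radius_vox = 4, localizer_condition = "taskB")),
    topography = list(max_shift_vox = 1, morph_steps = 1, min_overlap = 0.5),
    localizer = list(n_runs = 2, n_blocks_per_condition = 6, block_s = 18,
                     n_fixation = 4, fixation_s = 12),
    main_task = list(n_trials = 55),
    noise = list(white_sd = 1, ar1 = 0.3, drift = 2),
    gss = list(top_fraction = 0.05, min_subjects = 6, smoothing_fwhm_mm = 8,
               min_mean_parcel_size_vox = 10, validation_z = 2,
               validation_min_cluster_vox = 5, restrict_to_overlap = TRUE),
    froi = list(top_fraction = 0.10, min_voxels = 1),
    write_bold = FALSE
  )
}

study_grid <- function(config) {
  volume_grid(config$grid$shape, config$grid$voxel_size_mm)
}

study_subjects <- function(config) sprintf("sub-%02d", seq_len(config$n_subjects))

# Network specs with the study's localizer + main-task amplitudes attached.
study_network_specs <- function(config) {
  conds <- config$conditions
  nets <- names(config$networks)
  lapply(stats::setNames(nets, nets), function(nm) {
    net <- config$networks[[nm]]
    eff <- config$effects[[nm]] %||% 0
    amp <- c(stats::setNames(config$main_response + c(-0.5, 0.5) * eff, conds),
             stats::setNames(config$localizer_response, net$localizer_condition))
    network_spec(nm, do.call(rbind, net$centers), net$radius_vox, amp,
                 amplitude_sd = config$amplitude_sd)
  })
}

#' Build the ground truth of a phantom study
#'
#' @param config Study configuration (see [demo_study_config()]).
#' @param seed Integer seed (amplitude draws).
#' @return List of `network_truth` objects, disjointness enforced.
#' @export
study_truths <- function(config, seed) {
  make_phantom(study_grid(config), study_network_specs(config),
               n_subjects = config$n_subjects, seed = seed, disjoint = TRUE)
}

# Localizer schedule for one run (two task conditions, blocked).
study_localizer_schedule <- function(config, seed) {
  p <- config$localizer
  nb <- p$n_blocks_per_condition
  task <- rep(c("taskA", "taskB"), each = nb)
  task <- with_seed(seed, sample(task))
  order <- interleave_fixation(task, p$n_fixation)
  durs <- ifelse(order == "fixation", p$fixation_s, p$block_s)
  blocks_to_schedule(order, durs)
}

# Simulate and fit one subject's runs; returns only the derived maps.
analyze_subject <- function(config, truths, topographies, subject_index,
                            seed, run_writer = NULL) {
  grid <- study_grid(config)
  subj <- study_subjects(config)[subject_index]
  responsive <- lapply(topographies, `[[`, "mask")
  nets <- names(truths)
  contrasts <- lapply(stats::setNames(nets, nets), function(nm) {
    own <- config$networks[[nm]]$localizer_condition
    other <- setdiff(c("taskA", "taskB"), own)
    stats::setNames(c(1, -1), c(own, other))
  })

  # --- localizer runs ---
  loc_runs <- list()
  for (r in seq_len(config$localizer$n_runs)) {
    sched <- study_localizer_schedule(config, derive_seed(seed, subj, "locsched", r))
    amps <- lapply(stats::setNames(nets, nets), function(nm)
      truths[[nm]]$subject_amplitudes[subject_index, ])
    run <- simulate_bold_run(grid, responsive, amps, sched,
                             tr_s = config$tr_s, noise_params = config$noise,
                             baseline = config$baseline,
                             subject_id = subj, run_id = sprintf("loc%d", r),
                             seed = derive_seed(seed, subj, "locrun", r))
    if (!is.null(run_writer)) run_writer(run)
    design <- build_design_matrix(sched, config$tr_s, nrow(run$data))
    glm <- fit_glm(run, design)
    loc_runs[[r]] <- list(
      z = lapply(contrasts, function(w) contrast_z_map(glm, w)),
      con = lapply(contrasts, function(w) contrast_effect_map(glm, w)),
      psc = list(taskA = percent_signal_change(glm, "taskA"),
                 taskB = percent_signal_change(glm, "taskB")))
  }
  combined_z <- lapply(stats::setNames(nets, nets), function(nm) {
    fe <- fixed_effects_combine(lapply(loc_runs, function(r) r$con[[nm]]$effect),
                                lapply(loc_runs, function(r) r$con[[nm]]$variance))
    fe$z
  })

  # --- main task: one event-related run per preceding-language condition ---
  main_psc <- list()
  for (cond in config$conditions) {
    sched <- make_picture_naming_schedule(
      n_trials = config$main_task$n_trials, condition = "naming",
      seed = derive_seed(seed, subj, "mainsched", cond))
    amps <- lapply(stats::setNames(nets, nets), function(nm) {
      a <- truths[[nm]]$subject_amplitudes[subject_index, cond]
      stats::setNames(a, "naming")
    })
    run <- simulate_bold_run(grid, responsive, amps, sched,
                             tr_s = config$tr_s, noise_params = config$noise,
                             baseline = config$baseline,
                             subject_id = subj, run_id = cond,
                             seed = derive_seed(seed, subj, "mainrun", cond))
    if (!is.null(run_writer)) run_writer(run)
    design <- build_design_matrix(sched, config$tr_s, nrow(run$data))
    glm <- fit_glm(run, design)
    main_psc[[cond]] <- percent_signal_change(glm, "naming")
  }

  list(subject = subj,
       run_z = lapply(loc_runs, `[[`, "z"),
       run_psc = lapply(loc_runs, `[[`, "psc"),
       combined_z = combined_z,
       main_psc = main_psc)
}

study_topographies <- function(config, truths, seed) {
  subjects <- study_subjects(config)
  lapply(stats::setNames(seq_along(subjects), subjects), function(i) {
    lapply(truths, function(tr)
      sample_subject_topography(tr, jitter = config$topography,
                                subject_id = subjects[i], seed = seed,
                                min_overlap = config$topography$min_overlap))
  })
}

study_gss_config <- function(config) do.call(gss_config, config$gss)

#' Run a phantom study end to end in memory
#'
#' Simulates every subject's runs, fits the first-level models, runs GSS
#' parcellation per network, defines fROIs, extracts the PSC table, and fits
#' the network-level, interaction, and per-ROI models.
#'
#' @param config Study configuration (see [demo_study_config()]).
#' @param seed Integer master seed; every stochastic step derives its own
#'   sub-seed from it.
#' @return List with `truths`, `atlases`, `psc_tables`, `fits`,
#'   `interaction`, `roi_fits`, `overlap`, `dice_truth`, and the per-subject
#'   `maps`.
#' @export
run_study <- function(config = demo_study_config(), seed = 1) {
  truths <- study_truths(config, derive_seed(seed, "phantom"))
  topo <- study_topographies(config, truths, derive_seed(seed, "topo"))
  subjects <- study_subjects(config)
  maps <- lapply(seq_along(subjects), function(i)
    analyze_subject(config, truths, topo[[i]], i, derive_seed(seed, "subject", i)))
  names(maps) <- subjects
  study_group_analysis(config, truths, maps)
}

# Group stages shared by run_study() and the disk-based pipeline.
study_group_analysis <- function(config, truths, maps) {
  nets <- names(truths) %||% names(config$networks)
  grid <- study_grid(config)
  gssc <- study_gss_config(config)
  atlases <- lapply(stats::setNames(nets, nets), function(nm) {
    gss_parcellate(lapply(maps, function(m) m$combined_z[[nm]]),
                   config = gssc, voxel_size_mm = config$grid$voxel_size_mm)
  })
  psc_tables <- lapply(stats::setNames(nets, nets), function(nm) {
    froi_masks <- lapply(maps, function(m) {
      ids <- atlases[[nm]]$table$id
      fr <- lapply(ids, function(pid)
        define_subject_froi(atlases[[nm]]$labels == pid, m$combined_z[[nm]],
                            config$froi$top_fraction, config$froi$min_voxels))
      stats::setNames(fr, sprintf("parcel-%02d", ids))
    })
    psc_maps <- lapply(maps, `[[`, "main_psc")
    tab <- extract_psc_table(froi_masks, psc_maps, network = nm)
    deviation_code(tab, levels = config$conditions)
  })
  fits <- lapply(psc_tables, fit_network_lmm)
  interaction <- if (length(nets) >= 2)
    fit_interaction_lmm(psc_tables[[1]], psc_tables[[2]]) else NULL
  roi_fits <- fit_roi_models(do.call(rbind, psc_tables))
  overlap <- if (length(nets) >= 2)
    network_overlap(atlases[[1]], atlases[[2]]) else NULL
  dice_truth <- if (!is.null(truths))
    mapply(function(at, tr) network_overlap(at, array(as.integer(tr$mask),
                                                      dim(tr$mask)))$dice,
           atlases, truths)
  else NULL
  list(config = config, truths = truths, maps = maps, atlases = atlases,
       psc_tables = psc_tables, fits = fits, interaction = interaction,
       roi_fits = roi_fits, overlap = overlap, dice_truth = dice_truth,
       grid = grid)
}
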