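# Reproducible pipeline orchestration: staged execution with on-disk
# artifacts, content-hash manifests, and a plain-text report.

#' Read a study configuration from YAML (or JSON)
#'
#' The file holds the same nested structure as [demo_study_config()]; missing
#' entries fall back to the defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Configuration list.
#' @export
read_study_config <- function(path) {
  cfg <- if (grepl("[.]json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  out <- modifyList(demo_study_config(), cfg, keep.null = TRUE)
  # structural lists are replaced wholesale, not merged element-wise
  for (nm in c("networks", "conditions", "effects"))
    if (!is.null(cfg[[nm]])) out[[nm]] <- cfg[[nm]]
  out
}

#' Write a study configuration as YAML
#' @param config Configuration list.
#' @param path Output path.
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

stage_order <- c("simulate", "glm", "parcellate", "extract", "analyze")

pipeline_paths <- function(outdir, config) {
  nets <- names(config$networks)
  subjects <- study_subjects(config)
  list(
    truth = file.path(outdir, "truth", paste0(nets, "_mask.nii")),
    amplitudes = file.path(outdir, "truth", "amplitudes.tsv"),
    topo = file.path(outdir, "truth",
                     as.vector(outer(subjects, nets,
                                     function(s, n) paste0(s, "_", n, "_topography.nii")))),
    z = file.path(outdir, "maps",
                  as.vector(outer(subjects, nets,
                                  function(s, n) paste0(s, "_", n, "_z.nii")))),
    psc = file.path(outdir, "maps",
                    as.vector(outer(subjects, config$conditions,
                                    function(s, cn) paste0(s, "_psc_", cn, ".nii")))),
    atlas = file.path(outdir, "group", paste0("atlas_", nets, ".nii")),
    parcels = file.path(outdir, "group", paste0("atlas_", nets, "_parcels.tsv")),
    table = file.path(outdir, "tables", "psc_table.tsv"),
    analysis = file.path(outdir, "reports", "analysis.json"),
    manifest = file.path(outdir, "manifest.json"))
}

hash_files <- function(files) {
  h <- tools::md5sum(files)
  stats::setNames(as.vector(h), basename(files))
}

#' Run the phantom-study pipeline with on-disk artifacts
#'
#' Executes the stages `simulate` (ground-truth masks, subject topographies,
#' amplitude table), `glm` (per-subject z and PSC maps; runs are regenerated
#' deterministically from the seed, and optionally written as 4-D NIfTI when
#' `config$write_bold`), `parcellate` (GSS atlases per network), `extract`
#' (fROIs + PSC table) and `analyze` (mixed models, overlap, recovery
#' statistics). A stage whose output files already exist is skipped, so any
#' contiguous suffix of stages can start from cached artifacts; a stage whose
#' *inputs* are missing stops with an error naming the stage to rerun. A
#' manifest with the MD5 hash of every artifact is written at the end;
#' rerunning with identical inputs reproduces it bit for bit.
#'
#' @param config Configuration list or path to a YAML/JSON file (see
#'   [demo_study_config()], [read_study_config()]).
#' @param outdir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param stages Character vector of stages to run (a contiguous subsequence
#'   of simulate, glm, parcellate, extract, analyze).
#' @param force Rerun stages even when their outputs exist.
#' @return The manifest (named list), invisibly written to
#'   `<outdir>/manifest.json`.
#' @export
run_pipeline <- function(config = demo_study_config(), outdir, seed = 1,
                         stages = stage_order, force = FALSE) {
  if (is.character(config)) config <- read_study_config(config)
  stopifnot(all(stages %in% stage_order))
  stages <- stage_order[stage_order %in% stages]
  paths <- pipeline_paths(outdir, config)
  for (d in c("truth", "maps", "group", "tables", "reports"))
    dir.create(file.path(outdir, d), recursive = TRUE, showWarnings = FALSE)
  grid <- study_grid(config)
  subjects <- study_subjects(config)
  nets <- names(config$networks)

  need <- function(files, producer) {
    missing <- files[!file.exists(files)]
    if (length(missing))
      stop(sprintf("missing artifact(s) %s; rerun stage '%s'",
                   paste(basename(missing), collapse = ", "), producer))
  }
  done <- function(files) !force && all(file.exists(files))

  truths <- NULL
  load_truths <- function() {
    need(c(paths$truth, paths$amplitudes), "simulate")
    amp <- utils::read.delim(paths$amplitudes)
    lapply(stats::setNames(nets, nets), function(nm) {
      mask <- read_volume(file.path(outdir, "truth", paste0(nm, "_mask.nii")))$data > 0
      a <- amp[amp$network == nm, ]
      amps <- stats::xtabs(amplitude ~ subject + condition, a)
      amps <- matrix(amps, nrow(amps), ncol(amps),
                     dimnames = list(rownames(amps), colnames(amps)))
      structure(list(name = nm, mask = mask,
                     subject_amplitudes = amps[subjects, , drop = FALSE]),
                class = "network_truth")
    })
  }

  if ("simulate" %in% stages && !done(c(paths$truth, paths$topo, paths$amplitudes))) {
    truths <- study_truths(config, derive_seed(seed, "phantom"))
    topo <- study_topographies(config, truths, derive_seed(seed, "topo"))
    for (nm in nets)
      write_volume(truths[[nm]]$mask, grid,
                   file.path(outdir, "truth", paste0(nm, "_mask.nii")), "int32")
    amp <- do.call(rbind, lapply(nets, function(nm) {
      a <- truths[[nm]]$subject_amplitudes
      data.frame(network = nm, subject = rep(subjects, ncol(a)),
                 condition = rep(colnames(a), each = nrow(a)),
                 amplitude = as.vector(a))
    }))
    utils::write.table(amp, paths$amplitudes, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    for (s in seq_along(subjects)) for (nm in nets)
      write_volume(topo[[s]][[nm]]$mask, grid,
                   file.path(outdir, "truth",
                             paste0(subjects[s], "_", nm, "_topography.nii")),
                   "int32")
  }

  if ("glm" %in% stages && !done(c(paths$z, paths$psc))) {
    need(c(paths$truth, paths$topo, paths$amplitudes), "simulate")
    if (is.null(truths)) truths <- load_truths()
    writer <- if (isTRUE(config$write_bold)) {
      dir.create(file.path(outdir, "bold"), showWarnings = FALSE)
      function(run) write_bold_run(run, file.path(outdir, "bold",
        paste0(run$subject_id, "_", run$run_id, "_bold.nii")))
    } else NULL
    for (s in seq_along(subjects)) {
      topo_s <- lapply(stats::setNames(nets, nets), function(nm) {
        mask <- read_volume(file.path(outdir, "truth",
          paste0(subjects[s], "_", nm, "_topography.nii")))$data > 0
        list(mask = mask)
      })
      m <- analyze_subject(config, truths, topo_s, s,
                           derive_seed(seed, "subject", s), run_writer = writer)
      for (nm in nets)
        write_volume(m$combined_z[[nm]], grid,
                     file.path(outdir, "maps",
                               paste0(subjects[s], "_", nm, "_z.nii")))
      for (cn in config$conditions)
        write_volume(m$main_psc[[cn]], grid,
                     file.path(outdir, "maps",
                               paste0(subjects[s], "_psc_", cn, ".nii")))
    }
  }

  load_z <- function(nm) lapply(subjects, function(s)
    read_volume(file.path(outdir, "maps", paste0(s, "_", nm, "_z.nii")))$data)

  if ("parcellate" %in% stages && !done(c(paths$atlas, paths$parcels))) {
    need(paths$z, "glm")
    gssc <- study_gss_config(config)
    for (nm in nets) {
      atlas <- gss_parcellate(load_z(nm), config = gssc,
                              voxel_size_mm = config$grid$voxel_size_mm)
      write_parcel_atlas(atlas, grid, file.path(outdir, "group",
                                                paste0("atlas_", nm)))
    }
  }

  if ("extract" %in% stages && !done(paths$table)) {
    need(c(paths$z, paths$psc, paths$atlas), if (all(file.exists(paths$z))) "parcellate" else "glm")
    tabs <- lapply(nets, function(nm) {
      labels <- read_volume(file.path(outdir, "group",
                                      paste0("atlas_", nm, ".nii")))$data
      labels <- array(as.integer(round(labels)), dim(labels))
      ids <- sort(unique(labels[labels > 0]))
      z_maps <- load_z(nm)
      froi_masks <- lapply(stats::setNames(seq_along(subjects), subjects),
        function(s) {
          fr <- lapply(ids, function(pid)
            define_subject_froi(labels == pid, z_maps[[s]],
                                config$froi$top_fraction, config$froi$min_voxels))
          stats::setNames(fr, sprintf("parcel-%02d", ids))
        })
      psc_maps <- lapply(stats::setNames(subjects, subjects), function(s) {
        lapply(stats::setNames(config$conditions, config$conditions), function(cn)
          read_volume(file.path(outdir, "maps",
                                paste0(s, "_psc_", cn, ".nii")))$data)
      })
      deviation_code(extract_psc_table(froi_masks, psc_maps, network = nm),
                     levels = config$conditions)
    })
    utils::write.table(do.call(rbind, tabs), paths$table, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  if ("analyze" %in% stages && !done(paths$analysis)) {
    need(c(paths$table, paths$atlas), "extract")
    tab <- utils::read.delim(paths$table)
    tabs <- split(tab, tab$network)[nets]
    fits <- lapply(tabs, fit_network_lmm)
    interaction <- if (length(nets) >= 2)
      fit_interaction_lmm(tabs[[1]], tabs[[2]]) else NULL
    roi_fits <- fit_roi_models(tab)
    atlases <- lapply(nets, function(nm)
      read_volume(file.path(outdir, "group", paste0("atlas_", nm, ".nii")))$data)
    overlap <- if (length(nets) >= 2)
      network_overlap(array(as.integer(round(atlases[[1]])), dim(atlases[[1]])),
                      array(as.integer(round(atlases[[2]])), dim(atlases[[2]])))
      else NULL
    dice_truth <- if (all(file.exists(paths$truth))) {
      vapply(seq_along(nets), function(i) {
        tr <- read_volume(file.path(outdir, "truth",
                                    paste0(nets[i], "_mask.nii")))$data
        network_overlap(array(as.integer(round(atlases[[i]])), dim(atlases[[i]])),
                        array(as.integer(tr > 0), dim(tr)))$dice
      }, numeric(1))
    } else NULL
    analysis <- list(
      networks = lapply(stats::setNames(nets, nets), function(nm)
        fit_to_list(fits[[nm]])),
      interaction = if (!is.null(interaction)) fit_to_list(interaction),
      roi_fits = roi_fits,
      overlap = if (!is.null(overlap))
        overlap[c("dice", "jaccard", "n_shared", "n_a", "n_b")],
      dice_truth = if (!is.null(dice_truth)) stats::setNames(as.list(dice_truth), nets),
      n_records = nrow(tab))
    jsonlite::write_json(analysis, paths$analysis, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  }

  all_files <- unlist(paths[c("truth", "amplitudes", "topo", "z", "psc",
                              "atlas", "parcels", "table", "analysis")])
  manifest <- list(seed = seed,
                   config = config,
                   stages = stages,
                   files = hash_files(all_files[file.exists(all_files)]))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

fit_to_list <- function(fit) {
  fit[c("term", "beta", "se", "t", "df", "p", "effect_size_dz", "structure",
        "trace", "note")]
}

#' Summarize a completed pipeline run
#'
#' Reads the analyze-stage artifacts and writes a human-readable summary
#' (`reports/summary.txt`) plus simple figures (`reports/figures.pdf`: atlas
#' slices and PSC by condition). Values are reported exactly as stored in
#' `reports/analysis.json`.
#'
#' @param outdir The pipeline output directory (or a manifest list returned
#'   by [run_pipeline()], whose artifacts live next to the manifest).
#' @param figures Write the PDF figures (default TRUE).
#' @return The summary text, invisibly; also printed.
#' @export
report_pipeline <- function(outdir, figures = TRUE) {
  if (is.list(outdir)) stop("pass the pipeline output directory")
  analysis_path <- file.path(outdir, "reports", "analysis.json")
  if (!file.exists(analysis_path))
    stop("missing reports/analysis.json; rerun stage 'analyze'")
  an <- jsonlite::read_json(analysis_path, simplifyVector = TRUE)
  tab_path <- file.path(outdir, "tables", "psc_table.tsv")
  tab <- if (file.exists(tab_path)) utils::read.delim(tab_path) else NULL
  lines <- c("Phantom-study pipeline report", strrep("=", 29), "")
  if (is.null(tab) || nrow(tab) == 0) {
    lines <- c(lines, "no records in the PSC table")
  } else {
    lines <- c(lines, sprintf("PSC records: %d", nrow(tab)), "")
  }
  for (nm in names(an$networks)) {
    f <- an$networks[[nm]]
    ci <- f$beta + c(-1, 1) * stats::qt(0.975, f$df) * f$se
    lines <- c(lines, sprintf(
      "%s: beta = %.4f [%.4f, %.4f], t(%.1f) = %.3f, p = %.4g (structure: %s)",
      nm, f$beta, ci[1], ci[2], f$df, f$t, f$p, f$structure))
  }
  if (!is.null(an$interaction))
    lines <- c(lines, sprintf(
      "condition x network interaction: beta = %.4f, t(%.1f) = %.3f, p = %.4g",
      an$interaction$beta, an$interaction$df, an$interaction$t,
      an$interaction$p))
  if (!is.null(an$overlap))
    lines <- c(lines, sprintf("atlas overlap: Dice = %.3f, Jaccard = %.3f",
                              an$overlap$dice, an$overlap$jaccard))
  if (!is.null(an$dice_truth))
    lines <- c(lines, paste0("Dice vs truth: ",
      paste(sprintf("%s = %.3f", names(an$dice_truth),
                    unlist(an$dice_truth)), collapse = ", ")))
  txt <- paste(lines, collapse = "\n")
  writeLines(txt, file.path(outdir, "reports", "summary.txt"))
  if (figures && !is.null(tab) && nrow(tab) > 0) {
    grDevices::pdf(file.path(outdir, "reports", "figures.pdf"), width = 8,
                   height = 4)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::par(mfrow = c(1, 2))
    graphics::boxplot(psc ~ condition + network, data = tab, las = 2,
                      cex.axis = 0.6, main = "PSC by condition and network",
                      ylab = "% signal change")
    atlas_files <- list.files(file.path(outdir, "group"),
                              pattern = "^atlas_.*[.]nii$", full.names = TRUE)
    if (length(atlas_files)) {
      lab <- read_volume(atlas_files[1])$data
      mid <- ceiling(dim(lab)[3] / 2)
      graphics::image(lab[, , mid], main = basename(atlas_files[1]),
                      col = grDevices::hcl.colors(max(lab) + 1, "viridis"))
    }
  }
  cat(txt, "\n")
  invisible(txt)
}
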