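# Subject-specific fROIs: top-fraction selection inside group parcels,
# across-run cross-validated percent-signal-change extraction, and the long
# PSC table consumed by the mixed models.

#' fROI configuration
#'
#' @param top_fraction Fraction of parcel voxels selected (default 0.10, the
#'   top 10% most responsive voxels).
#' @param min_voxels Minimum fROI size; selection is
#'   `max(min_voxels, floor(top_fraction * |parcel|))`.
#' @return List of class `froi_config`.
#' @export
froi_config <- function(top_fraction = 0.10, min_voxels = 1) {
  stopifnot(top_fraction > 0, top_fraction <= 1, min_voxels >= 1)
  structure(list(top_fraction = top_fraction, min_voxels = min_voxels),
            class = "froi_config")
}

#' Define a subject's fROI within a parcel
#'
#' Selects the `k = max(min_voxels, floor(top_fraction * |parcel|))` voxels
#' with the highest z inside the parcel; ties are broken by the fixed
#' linear-index voxel order. The selection is always nonempty: even when a
#' subject's supra-threshold activation misses the parcel, the k best voxels
#' are taken (and the caller may flag this from the returned statistics).
#'
#' @param parcel_mask Logical array (nonempty).
#' @param z_map Subject z array on the same grid.
#' @param top_fraction Fraction of parcel voxels to select.
#' @param min_voxels Minimum selection size.
#' @return A `subject_froi`: list with `mask`, `n_voxels`, `parcel_size`,
#'   `max_z`.
#' @export
define_subject_froi <- function(parcel_mask, z_map, top_fraction = 0.10,
                                min_voxels = 1) {
  stop_if_grid_mismatch(parcel_mask, z_map, "parcel/z map")
  idx <- which(parcel_mask)
  if (length(idx) == 0) stop("empty parcel")
  k <- max(min_voxels, floor(top_fraction * length(idx)))
  k <- min(k, length(idx))
  v <- z_map[idx]
  v[!is.finite(v)] <- -Inf
  sel <- idx[order(-v, idx)][seq_len(k)]
  mask <- array(FALSE, dim(parcel_mask))
  mask[sel] <- TRUE
  structure(list(mask = mask, n_voxels = k, parcel_size = length(idx),
                 max_z = max(v)),
            class = "subject_froi")
}

# Stouffer combination of run z-maps, used to pool defining runs in
# cross-validation folds.
pool_z_maps <- function(z_list) {
  if (length(z_list) == 1) return(z_list[[1]])
  Reduce(`+`, z_list) / sqrt(length(z_list))
}

#' Cross-validated percent-signal-change extraction
#'
#' For each fold (one held-out run), the fROI is defined from the *other*
#' runs' pooled z-map and the held-out run's PSC estimate is averaged inside
#' it; folds are then averaged. This keeps the voxel-selection statistic and
#' the extracted estimate on independent data, removing the selection
#' (circularity) bias. With `circular = TRUE` the fROI is instead defined and
#' estimated on the same run — the biased estimator, kept for comparisons.
#'
#' @param runs List of runs; each run is a list with elements `z` (defining z
#'   array) and `psc` (named list of per-condition PSC arrays).
#' @param parcel_mask Logical parcel array.
#' @param config A [froi_config()].
#' @param circular If TRUE, define and estimate on the same run (no
#'   cross-validation).
#' @return data.frame with columns `condition`, `psc` (across-fold means);
#'   per-fold values in attribute `folds`.
#' @export
crossvalidated_psc <- function(runs, parcel_mask, config = froi_config(),
                               circular = FALSE) {
  stopifnot(length(runs) >= 1)
  if (!circular && length(runs) < 2)
    stop("cross-validation requires at least two runs; pass circular = TRUE to override explicitly")
  conds <- names(runs[[1]]$psc)
  folds <- lapply(seq_along(runs), function(i) {
    def_z <- if (circular) runs[[i]]$z
             else pool_z_maps(lapply(runs[-i], `[[`, "z"))
    froi <- define_subject_froi(parcel_mask, def_z, config$top_fraction,
                                config$min_voxels)
    vapply(conds, function(cn) mean(runs[[i]]$psc[[cn]][froi$mask], na.rm = TRUE),
           numeric(1))
  })
  m <- colMeans(do.call(rbind, folds))
  structure(data.frame(condition = conds, psc = as.numeric(m),
                       row.names = NULL),
            folds = folds)
}

#' Build the long PSC table for mixed modelling
#'
#' One record per subject x parcel x condition: the mean PSC over the
#' subject's fROI voxels. Subjects with an empty fROI for a parcel are
#' skipped with a message.
#'
#' @param froi_masks Named list: subject -> named list parcel id -> logical
#'   fROI array (as returned by [define_subject_froi()], or plain masks).
#' @param psc_maps Named list: subject -> named list condition -> PSC array.
#' @param network Network label attached to every record.
#' @return data.frame with columns `subject`, `roi`, `network`, `condition`,
#'   `psc`.
#' @export
extract_psc_table <- function(froi_masks, psc_maps, network = "network") {
  records <- list()
  for (subj in names(froi_masks)) {
    if (!subj %in% names(psc_maps)) stop(sprintf("missing PSC maps for %s", subj))
    for (roi in names(froi_masks[[subj]])) {
      froi <- froi_masks[[subj]][[roi]]
      mask <- if (inherits(froi, "subject_froi")) froi$mask else froi
      if (!any(mask)) {
        message(sprintf("skipping empty fROI: subject %s, roi %s", subj, roi))
        next
      }
      for (cond in names(psc_maps[[subj]])) {
        records[[length(records) + 1]] <-
          data.frame(subject = subj, roi = roi, network = network,
                     condition = cond,
                     psc = mean(psc_maps[[subj]][[cond]][mask], na.rm = TRUE))
      }
    }
  }
  if (length(records) == 0)
    return(data.frame(subject = character(0), roi = character(0),
                      network = character(0), condition = character(0),
                      psc = numeric(0)))
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  out
}
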