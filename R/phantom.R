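# Ground-truth networks and per-subject activation topographies.

#' Specify a synthetic network geometry
#'
#' A network is a union of spheres/ellipsoids on the analysis grid, together
#' with its condition response amplitudes (percent of baseline signal) and
#' optional between-subject amplitude variability.
#'
#' @param name Network label.
#' @param centers n x 3 matrix of sphere centres in 1-based voxel coordinates.
#' @param radii_vox Radius in voxels; a scalar, a per-sphere vector, or an
#'   n x 3 matrix of per-axis semi-axes for ellipsoids.
#' @param amplitudes Named numeric vector: condition label -> mean response
#'   amplitude (percent signal change at the response peak).
#' @param amplitude_sd Between-subject SD of every amplitude (same units).
#' @return A list of class `network_spec`.
#' @export
network_spec <- function(name, centers, radii_vox, amplitudes,
                         amplitude_sd = 0) {
  centers <- matrix(as.numeric(centers), ncol = 3)
  if (is.matrix(radii_vox)) {
    radii <- matrix(as.numeric(radii_vox), ncol = 3)
  } else {
    radii <- matrix(rep(as.numeric(radii_vox), length.out = nrow(centers) * 3),
                    ncol = 3)
  }
  stopifnot(nrow(radii) == nrow(centers) || nrow(radii) == 1)
  if (nrow(radii) == 1) radii <- radii[rep(1, nrow(centers)), , drop = FALSE]
  stopifnot(all(radii > 0), length(names(amplitudes)) == length(amplitudes))
  structure(list(name = name, centers = centers, radii = radii,
                 amplitudes = amplitudes, amplitude_sd = amplitude_sd),
            class = "network_spec")
}

# Discrete ellipsoid membership by voxel-centre distance (no partial volumes).
ellipsoid_mask <- function(grid, center, radii) {
  shape <- grid$shape
  if (any(center - radii < 1 - 1e-9) || any(center + radii > shape + 1e-9))
    stop(sprintf("network geometry at (%s) with radii (%s) exceeds the grid bounds",
                 paste(center, collapse = ","), paste(radii, collapse = ",")))
  i <- seq_len(shape[1]); j <- seq_len(shape[2]); k <- seq_len(shape[3])
  d2 <- outer(outer(((i - center[1]) / radii[1])^2,
                    ((j - center[2]) / radii[2])^2, `+`),
              ((k - center[3]) / radii[3])^2, `+`)
  d2 <= 1 + 1e-12
}

#' Generate ground-truth networks on a grid
#'
#' Builds the binary truth mask of each network (union of its ellipsoids) and
#' draws per-subject response amplitudes for every condition.
#'
#' @param grid A [volume_grid()].
#' @param specs List of [network_spec()] objects (may be empty).
#' @param n_subjects Number of subjects for which to draw amplitudes.
#' @param seed Integer seed for the amplitude draws.
#' @param disjoint If TRUE, error when any two network masks intersect.
#' @return List of `network_truth` objects with fields `name`, `mask`
#'   (logical array) and `subject_amplitudes` (n_subjects x conditions matrix).
#' @export
make_phantom <- function(grid, specs, n_subjects = 1, seed = 1,
                         disjoint = FALSE) {
  stopifnot(is_volume_grid(grid))
  truths <- lapply(specs, function(sp) {
    mask <- array(FALSE, grid$shape)
    for (s in seq_len(nrow(sp$centers)))
      mask <- mask | ellipsoid_mask(grid, sp$centers[s, ], sp$radii[s, ])
    if (!any(mask)) stop(sprintf("network '%s' has an empty mask", sp$name))
    conds <- names(sp$amplitudes)
    amps <- matrix(rep(sp$amplitudes, each = n_subjects), nrow = n_subjects,
                   dimnames = list(NULL, conds))
    if (sp$amplitude_sd > 0) {
      amps <- amps + with_seed(derive_seed(seed, sp$name),
                               matrix(stats::rnorm(n_subjects * length(conds),
                                                   0, sp$amplitude_sd),
                                      nrow = n_subjects))
    }
    structure(list(name = sp$name, mask = mask, subject_amplitudes = amps),
              class = "network_truth")
  })
  if (disjoint && length(truths) > 1) {
    for (a in seq_len(length(truths) - 1)) for (b in seq((a + 1), length(truths))) {
      if (any(truths[[a]]$mask & truths[[b]]$mask))
        stop(sprintf("networks '%s' and '%s' overlap but disjoint = TRUE",
                     truths[[a]]$name, truths[[b]]$name))
    }
  }
  truths
}

# Shift a logical volume by an integer voxel offset (voxels shifted off the
# grid are lost; vacated voxels are FALSE).
shift_mask <- function(mask, shift) {
  dims <- dim(mask)
  out <- array(FALSE, dims)
  src <- lapply(1:3, function(a) {
    s <- seq_len(dims[a]) - shift[a]
    s[s >= 1 & s <= dims[a]]
  })
  dst <- lapply(1:3, function(a) src[[a]] + shift[a])
  out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
  out
}

# One step of 6-connected dilation or erosion (out-of-grid voxels count as
# background, so erosion also shrinks masks touching the grid boundary).
morph_step <- function(mask, grow = TRUE) {
  acc <- mask
  for (off in asplit(neighbor_offsets(6), 1)) {
    sh <- shift_mask(mask, as.integer(off))
    acc <- if (grow) acc | sh else acc & sh
  }
  acc
}

#' Draw a subject-specific activation topography
#'
#' Emulates cross-subject variability in functional topography by applying a
#' random integer voxel shift and a random dilation/erosion to the network
#' truth mask. The draw is rejected and retried (with a derived sub-seed)
#' until the subject mask overlaps the truth mask by at least `min_overlap`
#' of the truth volume.
#'
#' @param truth A `network_truth` from [make_phantom()].
#' @param jitter List with `max_shift_vox` (maximum absolute shift per axis)
#'   and `morph_steps` (maximum dilation (+) / erosion (-) steps).
#' @param subject_id Subject label (enters the derived seed).
#' @param seed Integer master seed.
#' @param min_overlap Minimum |subject mask intersect truth| / |truth|.
#' @param max_tries Rejection-sampling budget before erroring.
#' @return List of class `subject_topography` with fields `subject_id`,
#'   `mask`, `shift_vox`, `morph_steps`.
#' @export
sample_subject_topography <- function(truth, jitter = list(max_shift_vox = 1,
                                                           morph_steps = 1),
                                      subject_id = "sub-01", seed = 1,
                                      min_overlap = 0.5, max_tries = 25) {
  s_max <- jitter$max_shift_vox %||% 0
  m_max <- jitter$morph_steps %||% 0
  n_truth <- sum(truth$mask)
  for (try in seq_len(max_tries)) {
    draw <- with_seed(derive_seed(seed, truth$name, subject_id, try), {
      list(shift = if (s_max > 0) sample(seq(-s_max, s_max), 3, replace = TRUE)
                   else c(0L, 0L, 0L),
           morph = if (m_max > 0) sample(seq(-m_max, m_max), 1) else 0L)
    })
    mask <- shift_mask(truth$mask, draw$shift)
    if (draw$morph != 0) {
      for (i in seq_len(abs(draw$morph)))
        mask <- morph_step(mask, grow = draw$morph > 0)
    }
    if (sum(mask & truth$mask) / n_truth >= min_overlap) {
      return(structure(list(subject_id = subject_id, mask = mask,
                            shift_vox = draw$shift, morph_steps = draw$morph),
                       class = "subject_topography"))
    }
  }
  stop(sprintf("could not satisfy the minimum-overlap constraint (%.2f) for %s/%s in %d tries",
               min_overlap, truth$name, subject_id, max_tries))
}
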