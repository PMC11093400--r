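# Forward BOLD model: HRF-convolved condition regressors and noisy 4-D runs.

# Convolve each condition's boxcar with the HRF on a fine time grid and sample
# at volume acquisition times. Also returns, per condition, the peak of the
# regressor for one isolated event of that condition's median duration: the
# scale that converts a regressor beta into percent signal change.
condition_regressors <- function(schedule, tr_s, n_vols, hrf = hrf_params(),
                                 dt = 0.02) {
  conds <- sort(unique(schedule$condition))
  n_fine <- ceiling(schedule_duration(schedule) / dt) + 1
  kernel <- double_gamma_hrf(dt, hrf)
  X <- matrix(0, n_vols, length(conds), dimnames = list(NULL, conds))
  peak <- stats::setNames(numeric(length(conds)), conds)
  samp <- pmin(round((0:(n_vols - 1)) * tr_s / dt) + 1, n_fine)
  for (c in seq_along(conds)) {
    rows <- which(schedule$condition == conds[c])
    box <- numeric(n_fine)
    for (r in rows) {
      i0 <- round(schedule$onset[r] / dt) + 1
      i1 <- min(round((schedule$onset[r] + schedule$duration[r]) / dt), n_fine)
      box[i0:i1] <- 1
    }
    conv <- fine_convolve(box, kernel, dt)
    X[, c] <- conv[samp]
    peak[c] <- isolated_event_peak(stats::median(schedule$duration[rows]),
                                   kernel, dt)
  }
  list(X = X, peak_scale = peak, conditions = conds)
}

# Discrete approximation of the continuous convolution (hence the dt factor):
# regressor amplitudes are invariant to the oversampling resolution.
fine_convolve <- function(box, kernel, dt) {
  n <- length(box)
  full <- stats::convolve(box, rev(kernel), type = "open")
  full[seq_len(n)] * dt
}

# Peak of the HRF-convolved boxcar for a single isolated event.
isolated_event_peak <- function(duration_s, kernel, dt) {
  nb <- max(1, round(duration_s / dt))
  box <- c(rep(1, nb), numeric(length(kernel)))
  max(fine_convolve(box, kernel, dt))
}

#' Simulate one BOLD run
#'
#' Forward model: within each network's responsive voxels the signal is
#' `baseline * (1 + sum_c amplitude_c / 100 * X_c(t))`, where `X_c` is the
#' HRF-convolved boxcar of condition `c`, normalized by the peak of an
#' isolated event, so that `amplitude_c` is the planted percent signal change
#' at the response peak. A linear drift and AR(1) Gaussian noise are added
#' everywhere.
#'
#' @param grid A [volume_grid()].
#' @param responsive Named list (network -> logical array) of responsive
#'   voxels, e.g. subject topography masks.
#' @param amplitudes Named list (network -> named numeric vector
#'   condition -> amplitude in percent). Conditions absent from a network
#'   contribute nothing there.
#' @param schedule A [design_schedule()].
#' @param tr_s Repetition time in seconds (> 0); number of volumes is
#'   `ceiling(total_duration / tr_s)`.
#' @param noise_params List: `white_sd` (innovation SD, signal units), `ar1`
#'   (AR(1) coefficient in `[0, 1)`), `drift` (peak-to-peak linear drift,
#'   signal units).
#' @param baseline Baseline signal level (> 0).
#' @param hrf [hrf_params()].
#' @param subject_id,run_id Labels carried in the result.
#' @param seed Integer seed; the run is a pure function of its arguments.
#' @return A `bold_run`: list with `data` (volumes x voxels matrix), `grid`,
#'   `tr_s`, `schedule`, `subject_id`, `run_id`, `seed`.
#' @export
simulate_bold_run <- function(grid, responsive, amplitudes, schedule,
                              tr_s = 1.4,
                              noise_params = list(white_sd = 1, ar1 = 0.3,
                                                  drift = 2),
                              baseline = 100, hrf = hrf_params(),
                              subject_id = "sub-01", run_id = "run-01",
                              seed = 1) {
  if (tr_s <= 0) stop("tr_s must be positive")
  if (baseline <= 0) stop("baseline must be positive")
  ar1 <- noise_params$ar1 %||% 0
  if (ar1 < 0 || ar1 >= 1) stop("AR(1) coefficient must lie in [0, 1)")
  n_vols <- ceiling(schedule_duration(schedule) / tr_s)
  n_vox <- prod(grid$shape)
  reg <- condition_regressors(schedule, tr_s, n_vols, hrf)
  Xs <- sweep(reg$X, 2, reg$peak_scale, "/")
  Y <- matrix(baseline, n_vols, n_vox)
  for (net in names(responsive)) {
    amp <- amplitudes[[net]]
    amp <- amp[names(amp) %in% reg$conditions]
    if (length(amp) == 0) next
    vox <- which(responsive[[net]])
    sig <- baseline / 100 * (Xs[, names(amp), drop = FALSE] %*% amp)
    Y[, vox] <- Y[, vox] + as.vector(sig)
  }
  drift <- noise_params$drift %||% 0
  if (drift != 0) Y <- Y + drift * seq(-0.5, 0.5, length.out = n_vols)
  sd <- noise_params$white_sd %||% 0
  if (sd > 0) {
    E <- with_seed(seed, matrix(stats::rnorm(n_vols * n_vox, 0, sd), n_vols, n_vox))
    if (ar1 > 0) E <- apply_ar1(E, ar1)
    Y <- Y + E
  }
  structure(list(data = Y, grid = grid, tr_s = tr_s, schedule = schedule,
                 subject_id = subject_id, run_id = run_id, seed = seed),
            class = "bold_run")
}

# Recursive AR(1) filter applied down each column.
apply_ar1 <- function(E, phi) {
  out <- stats::filter(E, phi, method = "recursive")
  matrix(as.numeric(out), nrow(E), ncol(E))
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("bold_run %s/%s: %d volumes x %d voxels, TR %.3f s\n",
              x$subject_id, x$run_id, nrow(x$data), ncol(x$data), x$tr_s))
  invisible(x)
}

#' Reshape a run (or one volume per timepoint) to a 4-D array
#' @param run A `bold_run`.
#' @return 4-D array (x, y, z, t).
#' @export
bold_as_array <- function(run) {
  array(t(run$data), c(run$grid$shape, nrow(run$data)))
}

#' Write a BOLD run as 4-D NIfTI-1
#' @param run A `bold_run`.
#' @param file Output `.nii` path.
#' @export
write_bold_run <- function(run, file) {
  img <- RNifti::asNifti(bold_as_array(run))
  img <- RNifti::`pixdim<-`(img, c(run$grid$voxel_size_mm, run$tr_s))
  img <- RNifti::`sform<-`(img, structure(run$grid$affine, code = 2L))
  RNifti::writeNifti(img, file, datatype = "double")
  invisible(file)
}
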