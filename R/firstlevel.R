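# First-level GLM: design construction, voxelwise OLS, contrast z-maps,
# percent signal change, and within-subject fixed-effects run combination.

#' Build a first-level design matrix
#'
#' One HRF-convolved regressor per condition, an intercept, a discrete-cosine
#' high-pass basis up to the cutoff frequency, and optional nuisance columns
#' appended unmodified. High-pass filtering lives inside the design so the
#' residual degrees of freedom stay explicit.
#'
#' @param schedule A [design_schedule()].
#' @param tr_s Repetition time (s).
#' @param n_vols Number of volumes; must cover the schedule.
#' @param hrf [hrf_params()].
#' @param highpass_cutoff_s High-pass cutoff in seconds (default 100); the
#'   number of cosine basis functions is `floor(2 * T / cutoff)`. Use `Inf`
#'   to disable.
#' @param nuisance Optional matrix of nuisance columns (e.g. motion), one row
#'   per volume.
#' @return A `design_matrix`: the numeric matrix with attributes
#'   `condition_cols`, `dct_cols`, `nuisance_cols`, `peak_scale`, `tr_s`.
#' @export
build_design_matrix <- function(schedule, tr_s, n_vols, hrf = hrf_params(),
                                highpass_cutoff_s = 100, nuisance = NULL) {
  stopifnot(tr_s > 0, n_vols >= 1)
  if (n_vols * tr_s < schedule_duration(schedule) - tr_s)
    stop("n_vols inconsistent with the schedule duration")
  if (nrow(schedule) > 0) {
    reg <- condition_regressors(schedule, tr_s, n_vols, hrf)
    Xc <- reg$X
    peak <- reg$peak_scale
  } else {
    Xc <- matrix(numeric(0), n_vols, 0)
    peak <- numeric(0)
  }
  total_s <- n_vols * tr_s
  K <- if (is.finite(highpass_cutoff_s) && highpass_cutoff_s > 0)
    floor(2 * total_s / highpass_cutoff_s) else 0L
  D <- dct_basis(n_vols, K)
  X <- cbind(intercept = 1, Xc, D)
  cn <- c("intercept", colnames(Xc),
          if (K > 0) paste0("dct", seq_len(K)))
  nuis_cols <- integer(0)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    stopifnot(nrow(nuisance) == n_vols)
    nn <- colnames(nuisance) %||% paste0("nuisance", seq_len(ncol(nuisance)))
    nuis_cols <- ncol(X) + seq_len(ncol(nuisance))
    X <- cbind(X, nuisance)
    cn <- c(cn, nn)
  }
  colnames(X) <- cn
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- cn[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("design matrix is rank deficient; collinear column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  structure(X,
            condition_cols = which(cn %in% colnames(Xc)),
            dct_cols = if (K > 0) which(grepl("^dct", cn)) else integer(0),
            nuisance_cols = nuis_cols,
            peak_scale = peak, tr_s = tr_s,
            class = c("design_matrix", "matrix"))
}

# Zero-mean discrete cosine high-pass basis (k = 1..K).
dct_basis <- function(n, K) {
  if (K <= 0) return(matrix(numeric(0), n, 0))
  i <- 0:(n - 1)
  sapply(seq_len(K), function(k) cos(pi * k * (2 * i + 1) / (2 * n)))
}

#' Fit a voxelwise ordinary-least-squares GLM
#'
#' @param run A `bold_run`, or a volumes x voxels numeric matrix.
#' @param design A [build_design_matrix()] result with `nrow(design)` equal to
#'   the number of volumes.
#' @param grid Optional [volume_grid()] (taken from the run when available);
#'   required to return maps as 3-D arrays.
#' @return A `glm_result`: betas (regressors x voxels), residual variance,
#'   residual degrees of freedom (n - rank), the unscaled covariance
#'   `(X'X)^-1`, voxel means, and the design.
#' @export
fit_glm <- function(run, design, grid = NULL) {
  Y <- if (inherits(run, "bold_run")) run$data else as.matrix(run)
  if (is.null(grid) && inherits(run, "bold_run")) grid <- run$grid
  X <- unclass(design)
  if (nrow(X) != nrow(Y)) stop("design rows must equal run volumes")
  qrX <- qr(X)
  betas <- qr.coef(qrX, Y)
  betas[is.na(betas)] <- 0
  fitted <- X %*% betas
  res <- Y - fitted
  dof <- nrow(Y) - qrX$rank
  if (dof <= 0) stop("no residual degrees of freedom")
  sigma2 <- colSums(res^2) / dof
  structure(list(betas = betas, sigma2 = sigma2, dof = dof,
                 xtx_inv = chol2inv(chol(crossprod(X))),
                 voxel_mean = colMeans(Y),
                 design = design, grid = grid),
            class = "glm_result")
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf("glm_result: %d regressors x %d voxels, dof = %d\n",
              nrow(x$betas), ncol(x$betas), x$dof))
  invisible(x)
}

as_map <- function(values, grid) {
  if (is.null(grid)) return(values)
  array(values, grid$shape)
}

# Contrast effect and variance (shared by z-maps and run combination).
contrast_effect <- function(glm, weights) {
  cc <- attr(glm$design, "condition_cols")
  conds <- colnames(glm$design)[cc]
  if (!is.null(names(weights))) {
    w <- stats::setNames(numeric(length(conds)), conds)
    w[names(weights)] <- weights
  } else {
    if (length(weights) != length(conds))
      stop("contrast weight vector length must equal the number of condition regressors")
    w <- stats::setNames(as.numeric(weights), conds)
  }
  wfull <- numeric(ncol(glm$design))
  wfull[cc] <- w
  effect <- as.vector(t(wfull) %*% glm$betas)
  var_scale <- as.numeric(t(wfull) %*% glm$xtx_inv %*% wfull)
  list(effect = effect, variance = glm$sigma2 * var_scale)
}

#' Contrast z-map from a fitted GLM
#'
#' Computes `t = effect / sqrt(variance)` voxelwise and maps t to a z score
#' through the distribution functions at the model's residual degrees of
#' freedom. Zero-variance voxels are masked (`NA`).
#'
#' @param glm A [fit_glm()] result.
#' @param weights Contrast weights over the condition regressors, either
#'   named (condition -> weight; omitted conditions get 0) or a full vector
#'   in sorted-condition order.
#' @return 3-D z array (or vector when the GLM has no grid).
#' @export
contrast_z_map <- function(glm, weights) {
  ce <- contrast_effect(glm, weights)
  z <- ifelse(ce$variance > 0, t_to_z(ce$effect / sqrt(ce$variance), glm$dof),
              NA_real_)
  as_map(z, glm$grid)
}

#' Convert t statistics to z scores
#'
#' Distribution-function mapping at finite degrees of freedom, computed on the
#' log scale so extreme tails stay finite; above 1000 dof the identity is
#' used.
#'
#' @param t Numeric vector of t values.
#' @param df Degrees of freedom.
#' @return z scores.
#' @export
t_to_z <- function(t, df) {
  if (df > 1000) return(t)
  sign(t) * stats::qnorm(stats::pt(abs(t), df, lower.tail = FALSE, log.p = TRUE),
                         lower.tail = FALSE, log.p = TRUE)
}

#' Percent-signal-change map for one condition
#'
#' `psc = 100 * beta * peak / baseline`, where `peak` is the height of the
#' condition's HRF-convolved regressor for one isolated event (so the value is
#' the peak percent change an isolated event evokes) and `baseline` is the
#' voxelwise intercept (default) or mean signal. Nonpositive baselines are
#' masked.
#'
#' @param glm A [fit_glm()] result.
#' @param condition Condition label.
#' @param baseline "intercept" or "mean".
#' @return 3-D psc array (or vector when the GLM has no grid).
#' @export
percent_signal_change <- function(glm, condition,
                                  baseline = c("intercept", "mean")) {
  baseline <- match.arg(baseline)
  peak <- attr(glm$design, "peak_scale")
  if (!condition %in% names(peak)) stop(sprintf("unknown condition '%s'", condition))
  beta <- glm$betas[condition, ]
  base <- if (baseline == "intercept") glm$betas["intercept", ] else glm$voxel_mean
  psc <- ifelse(base > 0, 100 * beta * peak[[condition]] / base, NA_real_)
  as_map(psc, glm$grid)
}

#' Combine runs within subject by fixed effects
#'
#' Inverse-variance-weighted combination of per-run contrast effects; the
#' combined z is the combined effect over its standard error. Runs with
#' infinite (or zero-weight) variance drop out of the combination.
#'
#' @param effects List of per-run effect arrays/vectors (same grid).
#' @param variances List of matching variance arrays/vectors.
#' @return List with `effect`, `variance` and `z` (same shape as the inputs).
#' @export
fixed_effects_combine <- function(effects, variances) {
  stopifnot(length(effects) == length(variances), length(effects) >= 1)
  dims <- dim(effects[[1]])
  for (i in seq_along(effects)) {
    stop_if_grid_mismatch(effects[[1]], effects[[i]], "runs")
    stop_if_grid_mismatch(effects[[i]], variances[[i]], "effect/variance")
  }
  wsum <- 0; esum <- 0
  for (i in seq_along(effects)) {
    w <- 1 / variances[[i]]
    w[!is.finite(w) | w < 0] <- 0
    e <- effects[[i]]
    e[w == 0] <- 0
    wsum <- wsum + w
    esum <- esum + w * e
  }
  effect <- ifelse(wsum > 0, esum / wsum, NA_real_)
  variance <- ifelse(wsum > 0, 1 / wsum, NA_real_)
  z <- ifelse(wsum > 0, effect / sqrt(variance), NA_real_)
  shape_all <- function(x) { dim(x) <- dims; x }
  list(effect = shape_all(effect), variance = shape_all(variance),
       z = shape_all(z))
}

#' Per-run contrast effect and variance maps
#'
#' Convenience accessor for [fixed_effects_combine()]: returns the contrast
#' effect and its estimation variance as maps.
#'
#' @inheritParams contrast_z_map
#' @return List with `effect` and `variance`.
#' @export
contrast_effect_map <- function(glm, weights) {
  ce <- contrast_effect(glm, weights)
  list(effect = as_map(ce$effect, glm$grid),
       variance = as_map(ce$variance, glm$grid))
}
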