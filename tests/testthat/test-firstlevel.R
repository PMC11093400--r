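test_that("double-gamma kernel has the canonical shape", {
  h <- double_gamma_hrf(0.1)
  t_peak <- (which.max(h) - 1) * 0.1
  expect_gte(t_peak, 4); expect_lte(t_peak, 7)
  expect_lt(min(h), 0)                       # undershoot
  expect_equal(max(h), 1, tolerance = 1e-6)  # peak-normalized
  h0 <- double_gamma_hrf(0.1, hrf_params(undershoot_ratio = 0))
  expect_true(all(h0 >= 0))
  expect_error(double_gamma_hrf(0), "positive")
})

test_that("a coarse kernel equals the decimated fine kernel", {
  fine <- double_gamma_hrf(0.1)
  coarse <- double_gamma_hrf(1.4)
  dec <- fine[seq(1, length(fine), by = 14)][seq_along(coarse)]
  expect_equal(coarse, dec, tolerance = 1e-10)
})

test_that("design matrix holds convolved conditions, DCT basis and nuisance", {
  sched <- make_localizer_schedule("language", seed = 1)
  n_vols <- ceiling(264 / 1.4)
  d <- build_design_matrix(sched, 1.4, n_vols)
  expect_equal(length(attr(d, "dct_cols")), floor(2 * n_vols * 1.4 / 100))
  expect_setequal(colnames(d)[attr(d, "condition_cols")], c("intact", "degraded"))
  # empty schedule: intercept + high-pass only
  empty <- design_schedule(data.frame(onset = numeric(0), duration = numeric(0),
                                      condition = character(0)), 140, "blocked")
  d0 <- build_design_matrix(empty, 1.4, 100)
  expect_equal(ncol(d0), 1 + length(attr(d0, "dct_cols")))
  # nuisance appended unmodified
  nuis <- matrix(rnorm(n_vols * 2), ncol = 2, dimnames = list(NULL, c("mx", "my")))
  dn <- build_design_matrix(sched, 1.4, n_vols, nuisance = nuis)
  expect_equal(unname(unclass(dn)[, attr(dn, "nuisance_cols")]), unname(nuis))
  # collinearity is named
  expect_error(build_design_matrix(sched, 1.4, n_vols,
                                   nuisance = cbind(dup = rep(1, n_vols))),
               "rank deficient.*dup|dup.*rank deficient|collinear")
})

test_that("the convolved regressor integrates to duration x HRF integral", {
  s <- design_schedule(data.frame(onset = 20, duration = 18, condition = "a"),
                       300, "blocked")
  d <- build_design_matrix(s, 0.1, 3000, highpass_cutoff_s = Inf)
  integral <- sum(unclass(d)[, "a"]) * 0.1
  h <- double_gamma_hrf(0.001)                # quadrature oracle (peak = 1)
  expect_equal(integral, 18 * sum(h) * 0.001, tolerance = 1e-3)
})

test_that("noiseless simulation round-trips through the GLM exactly", {
  g <- volume_grid(c(4, 4, 4))
  mask <- array(FALSE, c(4, 4, 4)); mask[2:3, 2:3, 2:3] <- TRUE
  sched <- make_picture_naming_schedule(n_trials = 12, seed = 1)
  run <- simulate_bold_run(g, list(n = mask), list(n = c(naming = 1.0)), sched,
                           noise_params = list(white_sd = 0, ar1 = 0, drift = 0),
                           seed = 1)
  glm <- fit_glm(run, build_design_matrix(sched, 1.4, nrow(run$data)))
  psc <- percent_signal_change(glm, "naming")
  expect_equal(unname(psc[mask]), rep(1, sum(mask)), tolerance = 1e-6)
  expect_equal(unname(psc[!mask]), rep(0, sum(!mask)), tolerance = 1e-6)
  # and the raw signal is flat at baseline when nothing responds
  run0 <- simulate_bold_run(g, list(n = mask), list(n = c(naming = 0)), sched,
                            noise_params = list(white_sd = 0, ar1 = 0, drift = 0),
                            baseline = 50, seed = 1)
  expect_true(all(run0$data == 50))
})

test_that("intercept-only design estimates the time-series mean", {
  y <- matrix(rnorm(200), 100, 2) + 5
  empty <- design_schedule(data.frame(onset = numeric(0), duration = numeric(0),
                                      condition = character(0)), 140, "blocked")
  d <- build_design_matrix(empty, 1.4, 100, highpass_cutoff_s = Inf)
  glm <- fit_glm(y, d)
  expect_equal(unname(glm$betas["intercept", ]), colMeans(y))
})

test_that("contrast z-maps match an independent per-voxel regression oracle", {
  set.seed(33)
  sched <- make_localizer_schedule("language", seed = 2)
  n_vols <- ceiling(264 / 1.4)
  d <- build_design_matrix(sched, 1.4, n_vols)
  X <- unclass(d)
  y <- X %*% rnorm(ncol(X)) + rnorm(n_vols)
  glm <- fit_glm(matrix(y, ncol = 1), d)
  z <- contrast_z_map(glm, c(degraded = -1, intact = 1))
  fit <- lm(y ~ X - 1)
  w <- numeric(ncol(X)); w[match(c("intact", "degraded"), colnames(X))] <- c(1, -1)
  eff <- sum(w * coef(fit))
  se <- sqrt(sum(w * (vcov(fit) %*% w)))
  t_or <- eff / se
  expect_equal(unname(z), t_to_z(t_or, df.residual(fit)), tolerance = 1e-8)
})

test_that("t-to-z conversion behaves at the limits", {
  expect_equal(t_to_z(1.96, 5000), 1.96)
  expect_equal(t_to_z(1.96, 1e5), 1.96, tolerance = 0.01)
  expect_equal(t_to_z(0, 10), 0)
  expect_equal(t_to_z(-3, 20), -t_to_z(3, 20))
  # huge t stays finite through the log-scale mapping
  expect_true(is.finite(t_to_z(50, 100)))
})

test_that("identical regressor betas give zero contrast", {
  sched <- design_schedule(data.frame(onset = c(10, 60), duration = 10,
                                      condition = c("a", "b")), 120, "blocked")
  d <- build_design_matrix(sched, 1, 120, highpass_cutoff_s = Inf)
  X <- unclass(d)
  # noise orthogonal to the design: fitted betas are exact, variance > 0
  e <- qr.resid(qr(X), withr::with_seed(12, rnorm(120)))
  y <- 10 + 2 * X[, "a"] + 2 * X[, "b"] + e
  glm <- fit_glm(matrix(y, ncol = 1), d)
  expect_equal(unname(contrast_z_map(glm, c(a = 1, b = -1))), 0,
               tolerance = 1e-8)
})

test_that("PSC scales as beta and inversely with baseline", {
  g <- volume_grid(c(3, 3, 3))
  mask <- array(TRUE, c(3, 3, 3))
  sched <- make_picture_naming_schedule(n_trials = 8, seed = 4)
  run <- simulate_bold_run(g, list(n = mask), list(n = c(naming = 2)), sched,
                           noise_params = list(white_sd = 0, ar1 = 0, drift = 0),
                           seed = 1)
  d <- build_design_matrix(sched, 1.4, nrow(run$data))
  psc1 <- percent_signal_change(fit_glm(run, d, g), "naming")
  # adding a constant doubles the intercept but not beta -> PSC halves
  run$data <- run$data + 100
  psc2 <- percent_signal_change(fit_glm(run, d, g), "naming")
  expect_equal(unname(psc2), unname(psc1) / 2, tolerance = 1e-6)
  # zero response -> zero PSC
  run0 <- simulate_bold_run(g, list(n = mask), list(n = c(naming = 0)), sched,
                            noise_params = list(white_sd = 0, ar1 = 0, drift = 0),
                            seed = 1)
  expect_equal(as.vector(percent_signal_change(fit_glm(run0, d, g), "naming")),
               rep(0, 27), tolerance = 1e-9)
})

test_that("fixed-effects run combination equals the closed-form weighted mean", {
  e <- list(array(1, c(2, 2, 2)), array(1, c(2, 2, 2)))
  v <- list(array(4, c(2, 2, 2)), array(4, c(2, 2, 2)))
  fe <- fixed_effects_combine(e, v)
  expect_equal(unname(fe$effect[1]), 1)
  expect_equal(unname(fe$variance[1]), 2)     # s^2 / 2
  # degenerate run drops out
  v2 <- list(array(4, c(2, 2, 2)), array(Inf, c(2, 2, 2)))
  e2 <- list(array(1, c(2, 2, 2)), array(99, c(2, 2, 2)))
  fe2 <- fixed_effects_combine(e2, v2)
  expect_equal(unname(fe2$effect[1]), 1)
  expect_equal(unname(fe2$variance[1]), 4)
  # three unequal-variance runs vs oracle
  effs <- c(0.5, 1.2, -0.3); vars <- c(0.2, 1.5, 0.7)
  fe3 <- fixed_effects_combine(lapply(effs, function(x) array(x, c(1, 1, 1))),
                               lapply(vars, function(x) array(x, c(1, 1, 1))))
  orc <- oracle_ivw(effs, vars)
  expect_equal(as.numeric(fe3$effect), orc$effect)
  expect_equal(as.numeric(fe3$variance), orc$variance)
  expect_error(fixed_effects_combine(list(array(0, c(2, 2, 2))),
                                     list(array(1, c(3, 3, 3)))), "mismatch")
})

test_that("AR(1) noise reproduces its lag-1 autocorrelation", {
  g <- volume_grid(c(5, 5, 4))
  sched <- design_schedule(data.frame(onset = numeric(0), duration = numeric(0),
                                      condition = character(0)), 2800, "blocked")
  run <- simulate_bold_run(g, list(), list(), sched, tr_s = 1.4,
                           noise_params = list(white_sd = 1, ar1 = 0.5, drift = 0),
                           seed = 21)
  ac <- apply(run$data, 2, function(y) {
    y <- y - mean(y); sum(y[-1] * y[-length(y)]) / sum(y^2)
  })
  expect_equal(mean(ac), 0.5, tolerance = 0.05 / 0.5)
})

test_that("the OLS estimator is unbiased under noise", {
  # 200 noisy voxel simulations of a known 0.8% response
  g <- volume_grid(c(10, 5, 4))
  mask <- array(TRUE, c(10, 5, 4))
  sched <- make_picture_naming_schedule(n_trials = 20, seed = 3)
  run <- simulate_bold_run(g, list(n = mask), list(n = c(naming = 0.8)), sched,
                           noise_params = list(white_sd = 1, ar1 = 0, drift = 0),
                           seed = 8)
  glm <- fit_glm(run, build_design_matrix(sched, 1.4, nrow(run$data)))
  psc <- as.vector(percent_signal_change(glm, "naming"))
  err <- psc - 0.8
  expect_lt(abs(mean(err)), 2 * sd(err) / sqrt(length(err)))
})

test_that("z statistics are calibrated under pure noise", {
  g <- volume_grid(c(14, 14, 14))
  sched <- make_localizer_schedule("language", seed = 6)
  run <- simulate_bold_run(g, list(), list(), sched, tr_s = 1.4,
                           noise_params = list(white_sd = 1, ar1 = 0, drift = 0),
                           seed = 19)
  glm <- fit_glm(run, build_design_matrix(sched, 1.4, nrow(run$data)))
  z <- as.vector(contrast_z_map(glm, c(intact = 1, degraded = -1)))
  expect_equal(mean(z), 0, tolerance = 0.05)
  expect_equal(sd(z), 1, tolerance = 0.1)
})
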