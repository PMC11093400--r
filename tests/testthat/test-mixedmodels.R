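test_that("deviation coding maps the two conditions to -0.5 / +0.5", {
  df <- data.frame(condition = rep(c("L1_after_L1", "L1_after_L2"), 4))
  coded <- deviation_code(df, levels = c("L1_after_L1", "L1_after_L2"))
  expect_equal(coded$condition_code[coded$condition == "L1_after_L1"],
               rep(-0.5, 4))
  expect_equal(coded$condition_code[coded$condition == "L1_after_L2"],
               rep(0.5, 4))
  expect_equal(mean(coded$condition_code), 0)       # balanced data
  bad <- data.frame(condition = c("a", "b", "c"))
  expect_error(deviation_code(bad), "exactly two")
})

test_that("balanced noiseless data recovers the condition difference exactly", {
  tab <- simulate_psc_table(n_subjects = 8, n_rois = 5, beta = 0.3, mu = 1,
                            subject_int_sd = 0.2, subject_slope_sd = 0,
                            roi_int_sd = 0.15, roi_slope_sd = 0, resid_sd = 0,
                            seed = 6)
  fit <- fit_network_lmm(tab)
  expect_equal(fit$beta, 0.3, tolerance = 1e-9)
  # deviation-coding identity: slope = mean(+0.5 cells) - mean(-0.5 cells)
  expect_equal(fit$beta,
               mean(tab$psc[tab$condition_code > 0]) -
                 mean(tab$psc[tab$condition_code < 0]), tolerance = 1e-9)
})

test_that("the intercept under deviation coding is the grand mean", {
  tab <- simulate_psc_table(n_subjects = 10, n_rois = 4, beta = 0.2, mu = 0.8,
                            resid_sd = 0.05, seed = 9)
  fit <- fit_network_lmm(tab)
  est <- lme4::fixef(fit$fit)
  expect_equal(unname(est["(Intercept)"]), mean(
    tapply(tab$psc, paste(tab$roi, tab$condition), mean)), tolerance = 0.02)
})

test_that("the deviation-coding identity is robust to the random structure", {
  # balanced data: the fixed effect equals the cell-mean difference no matter
  # which rung of the simplification ladder is used
  tab <- simulate_psc_table(n_subjects = 12, n_rois = 6, beta = 0.1,
                            resid_sd = 0.08, seed = 11)
  celldiff <- mean(tab$psc[tab$condition_code > 0]) -
    mean(tab$psc[tab$condition_code < 0])
  fit <- fit_network_lmm(tab)
  expect_equal(fit$beta, celldiff, tolerance = 1e-6)
})

test_that("parameter recovery on the paper-scale crossed design", {
  betas <- vapply(1:25, function(i)
    fit_network_lmm(simulate_psc_table(n_subjects = 41, n_rois = 15,
                                       beta = 0.07, seed = 1000 + i))$beta,
    numeric(1))
  mc_se <- sd(betas) / sqrt(length(betas))
  expect_lt(abs(mean(betas) - 0.07), 2 * mc_se + 0.0035)
})

test_that("the simplification trace is deterministic and recorded", {
  tab <- simulate_psc_table(n_subjects = 15, n_rois = 8, beta = 0.05,
                            roi_slope_sd = 0, seed = 21)
  f1 <- fit_network_lmm(tab)
  f2 <- fit_network_lmm(tab)
  expect_identical(f1$structure, f2$structure)
  expect_identical(f1$trace, f2$trace)
  expect_equal(f1$beta, f2$beta)
  expect_match(f1$trace[1], "maximal")
})

test_that("degenerate single-ROI tables reduce to the paired comparison", {
  tab <- simulate_psc_table(n_subjects = 12, n_rois = 1, beta = 0.2,
                            roi_int_sd = 0, roi_slope_sd = 0, resid_sd = 0.1,
                            seed = 3)
  fit <- localizer_scope_effect(tab)
  agg <- tapply(tab$psc, list(tab$subject, tab$condition_code), mean)
  diffs <- agg[, "0.5"] - agg[, "-0.5"]
  expect_equal(fit$beta, mean(diffs), tolerance = 1e-9)
  tt <- t.test(diffs)
  expect_equal(unname(fit$t), unname(tt$statistic), tolerance = 1e-6)
  expect_equal(fit$p, tt$p.value, tolerance = 1e-6)
})

test_that("interaction models recover a network-specific effect with its sign", {
  ta <- simulate_psc_table(beta = 0.08, n_subjects = 25, n_rois = 8, seed = 31)
  ta$network <- "A"; ta$roi <- paste0("A", ta$roi)
  tb <- simulate_psc_table(beta = 0, n_subjects = 25, n_rois = 8, seed = 32)
  tb$network <- "B"; tb$roi <- paste0("B", tb$roi)
  fi <- fit_interaction_lmm(ta, tb)
  expect_gt(fi$beta, 0)                       # effect in A -> positive
  expect_lt(abs(fi$beta - 0.08), 3 * fi$se)
  # identical planted effects -> interaction about zero
  tb2 <- simulate_psc_table(beta = 0.08, n_subjects = 25, n_rois = 8, seed = 33)
  tb2$network <- "B"
  fi0 <- fit_interaction_lmm(ta, tb2)
  expect_lt(abs(fi0$beta), 3 * fi0$se)
  expect_error(fit_interaction_lmm(ta, ta), "different network")
})

test_that("permuting network labels centres the interaction on zero", {
  ta <- simulate_psc_table(beta = 0.06, n_subjects = 12, n_rois = 4, seed = 41)
  tb <- simulate_psc_table(beta = 0.06, n_subjects = 12, n_rois = 4, seed = 42)
  ta$network <- "A"; tb$network <- "B"
  stacked <- rbind(ta, tb)
  est <- vapply(1:30, function(p) {
    perm <- withr::with_seed(p, sample(stacked$network))
    a <- stacked[perm == "A", ]; a$network <- "A"
    b <- stacked[perm == "B", ]; b$network <- "B"
    fit_interaction_lmm(a, b)$beta
  }, numeric(1))
  expect_lt(abs(mean(est)), 2 * sd(est) / sqrt(length(est)) + 0.01)
})

test_that("per-ROI paired tests match the closed form and control FDR", {
  tab <- simulate_psc_table(n_subjects = 14, n_rois = 6, beta = 0.1, seed = 8)
  rois <- fit_roi_models(tab)
  expect_equal(nrow(rois), 6)
  r1 <- rois$roi[1]
  d <- tab[tab$roi == r1, ]
  agg <- tapply(d$psc, list(d$subject, d$condition_code), mean)
  tt <- t.test(agg[, "0.5"], agg[, "-0.5"], paired = TRUE)
  expect_equal(rois$t[rois$roi == r1], unname(tt$statistic), tolerance = 1e-9)
  expect_equal(rois$p[rois$roi == r1], tt$p.value, tolerance = 1e-9)
  expect_equal(rois$p_fdr, p.adjust(rois$p, "BH"))
  # zero within-subject difference everywhere -> t = 0, p = 1
  flat <- tab; flat$psc <- ave(flat$psc, flat$subject, flat$roi)
  rf <- fit_roi_models(flat)
  expect_true(all(rf$t == 0))
  expect_true(all(rf$p == 1))
})

test_that("strong planted effects are discovered at FDR 0.05", {
  hits <- vapply(1:20, function(i) {
    tab <- simulate_psc_table(n_subjects = 20, n_rois = 10, beta = 0,
                              subject_slope_sd = 0.02, roi_slope_sd = 0,
                              resid_sd = 0.05, seed = 500 + i)
    planted <- tab$roi %in% sprintf("roi-%02d", 1:4)
    tab$psc <- tab$psc + ifelse(planted, 0.3 * tab$condition_code, 0)
    rois <- fit_roi_models(tab)
    all(rois$p_fdr[rois$roi %in% sprintf("roi-%02d", 1:4)] < 0.05)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("atlas overlap statistics match their set-theoretic definitions", {
  dims <- c(8, 8, 8)
  a <- array(0L, dims); a[1:4, , ] <- 1L
  expect_equal(network_overlap(a, a)$dice, 1)
  b <- array(0L, dims); b[5:8, , ] <- 2L
  expect_equal(network_overlap(a, b)$dice, 0)
  r1 <- withr::with_seed(1, array(rbinom(prod(dims), 1, 0.4), dims))
  r2 <- withr::with_seed(2, array(rbinom(prod(dims), 1, 0.4), dims))
  ov <- network_overlap(r1, r2)
  expect_equal(ov$dice, 2 * sum(r1 > 0 & r2 > 0) / (sum(r1 > 0) + sum(r2 > 0)))
  expect_equal(ov$jaccard, sum(r1 > 0 & r2 > 0) / sum(r1 > 0 | r2 > 0))
  expect_error(network_overlap(a, array(0L, c(2, 2, 2))), "mismatch")
})

test_that("localizer-scope effects recover a planted contrast", {
  tab <- simulate_psc_table(n_subjects = 20, n_rois = 6, beta = 0.5, mu = 0.6,
                            seed = 77,
                            conditions = c("degraded", "intact"))
  fit <- localizer_scope_effect(tab, levels = c("degraded", "intact"))
  expect_equal(fit$beta, 0.5, tolerance = 0.1)
  expect_lt(fit$p, 0.001)
})
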