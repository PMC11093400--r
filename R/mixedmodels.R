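# Network-level mixed-effects inference: deviation coding, the crossed
# subject x ROI model, the condition-by-network interaction, per-ROI tests
# with FDR control, and atlas overlap descriptives.

#' Apply deviation coding to a two-level condition
#'
#' Adds a `condition_code` column mapping the two condition labels to -0.5
#' and +0.5, so the fixed-effect slope is the condition difference and the
#' intercept the grand mean. By default the *second* element of `levels` is
#' coded +0.5 (for the main task: L1-after-L1 = -0.5, L1-after-L2 = +0.5).
#'
#' @param records data.frame with a `condition` column carrying exactly two
#'   labels.
#' @param levels Character vector of length 2 giving the (-0.5, +0.5) order;
#'   defaults to the sorted unique labels.
#' @return The data.frame with a `condition_code` column.
#' @export
deviation_code <- function(records, levels = NULL) {
  labs <- sort(unique(as.character(records$condition)))
  if (length(labs) != 2)
    stop(sprintf("deviation coding requires exactly two condition labels, got %d",
                 length(labs)))
  if (is.null(levels)) levels <- labs
  stopifnot(length(levels) == 2, setequal(levels, labs))
  records$condition_code <- ifelse(records$condition == levels[2], 0.5, -0.5)
  records
}

# Random-effects simplification ladder for the crossed design, from maximal
# downward: drop correlations first, then the ROI slope, then the subject
# slope (keeping the by-subject structure as long as possible).
lmm_formulas <- function() {
  c(maximal = "psc ~ condition_code + (1 + condition_code | subject) + (1 + condition_code | roi)",
    no_correlations = "psc ~ condition_code + (1 + condition_code || subject) + (1 + condition_code || roi)",
    no_roi_slope = "psc ~ condition_code + (1 + condition_code || subject) + (1 | roi)",
    no_subject_slope = "psc ~ condition_code + (1 | subject) + (1 | roi)")
}

# Fit one lmer formula, capturing convergence and singularity status.
fit_one_lmm <- function(formula_str, data) {
  msgs <- character(0)
  fit <- withCallingHandlers(
    tryCatch(lmerTest::lmer(stats::as.formula(formula_str), data = data,
                            REML = TRUE),
             error = function(e) e),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  if (inherits(fit, "error"))
    return(list(fit = NULL, ok = FALSE, singular = NA,
                status = paste("error:", conditionMessage(fit))))
  singular <- lme4::isSingular(fit, tol = 1e-4)
  converged <- !any(grepl("failed to converge|unable to evaluate|degenerate",
                          msgs, ignore.case = TRUE))
  list(fit = fit, ok = converged && !singular, singular = singular,
       status = if (length(msgs)) paste(msgs, collapse = "; ") else "ok")
}

# Cohen's d_z on subject-level condition-difference means.
cohens_dz <- function(data) {
  agg <- stats::aggregate(psc ~ subject + condition_code, data, mean)
  wide <- merge(agg[agg$condition_code > 0, c("subject", "psc")],
                agg[agg$condition_code < 0, c("subject", "psc")],
                by = "subject", suffixes = c("_pos", "_neg"))
  d <- wide$psc_pos - wide$psc_neg
  if (length(d) < 2 || stats::sd(d) == 0) return(list(dz = NA_real_, diffs = d))
  list(dz = mean(d) / stats::sd(d), diffs = d)
}

mixed_fit_result <- function(term, beta, se, t, df, p, fit, structure_name,
                             trace, dz, note = NULL) {
  vc <- if (!is.null(fit)) as.data.frame(lme4::VarCorr(fit)) else NULL
  structure(list(term = term, beta = beta, se = se, t = t, df = df, p = p,
                 effect_size_dz = dz, random_effects = vc,
                 structure = structure_name, trace = trace, fit = fit,
                 note = note),
            class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf("mixed_fit [%s]: %s\n", x$structure, x$term))
  cat(sprintf("  beta = %.4f, SE = %.4f, t(%.1f) = %.3f, p = %.4g",
              x$beta, x$se, x$df, x$t, x$p))
  if (is.finite(x$effect_size_dz))
    cat(sprintf(", d_z = %.2f", x$effect_size_dz))
  cat("\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

# Shared fitting engine: walk the simplification ladder, fall back to a
# subject-level paired test when no mixed model is estimable (degenerate,
# e.g. noiseless, data).
fit_lmm_ladder <- function(data, term = "condition_code",
                           formulas = lmm_formulas()) {
  trace <- character(0)
  last_usable <- NULL
  for (nm in names(formulas)) {
    res <- fit_one_lmm(formulas[[nm]], data)
    trace <- c(trace, sprintf("%s: %s", nm,
                              if (res$ok) "accepted"
                              else if (is.null(res$fit)) res$status
                              else if (isTRUE(res$singular)) "singular"
                              else res$status))
    if (!is.null(res$fit)) last_usable <- list(name = nm, fit = res$fit)
    if (res$ok) {
      return(extract_fixed(res$fit, term, nm, trace, data))
    }
  }
  if (!is.null(last_usable)) {
    out <- extract_fixed(last_usable$fit, term, last_usable$name, trace, data,
                         note = "no structure converged non-singular; reporting the most simplified estimable fit")
    if (is.finite(out$se) && out$se > 0 && is.finite(out$df) && out$df >= 1 &&
        is.finite(out$p)) return(out)
  }
  paired_fallback(data, term, trace)
}

extract_fixed <- function(fit, term, structure_name, trace, data, note = NULL) {
  co <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
  dz <- if (term == "condition_code") cohens_dz(data)$dz else NA_real_
  if (is.null(co) || !term %in% rownames(co) || ncol(co) < 5) {
    return(mixed_fit_result(term, NA_real_, NA_real_, NA_real_, NA_real_,
                            NA_real_, fit, structure_name, trace, dz,
                            note = "could not extract Satterthwaite summary"))
  }
  r <- co[term, ]
  mixed_fit_result(term, unname(r["Estimate"]), unname(r["Std. Error"]),
                   unname(r["t value"]), unname(r["df"]),
                   unname(r["Pr(>|t|)"]), fit, structure_name, trace, dz,
                   note = note)
}

# Degenerate-data fallback: paired comparison on subject-level condition
# means (exact in balanced data; variance components are then zero).
paired_fallback <- function(data, term, trace) {
  dzi <- cohens_dz(data)
  d <- dzi$diffs
  beta <- mean(d)
  n <- length(d)
  sdd <- if (n > 1) stats::sd(d) else NA_real_
  if (!is.finite(sdd) || sdd == 0) {
    t <- if (beta == 0) 0 else Inf * sign(beta)
    p <- if (beta == 0) 1 else 0
    se <- 0
  } else {
    se <- sdd / sqrt(n)
    t <- beta / se
    p <- 2 * stats::pt(-abs(t), n - 1)
  }
  mixed_fit_result(term, beta, se, t, n - 1, p, NULL, "paired_fallback",
                   c(trace, "paired_fallback: accepted"), dzi$dz,
                   note = "mixed model not estimable; subject-level paired comparison")
}

#' Fit the network-level mixed-effects model
#'
#' Restricted-likelihood fit of
#' `psc ~ condition_code + (1 + condition_code | subject) + (1 + condition_code | roi)`,
#' the crossed random-effects model treating ROIs within a functional network
#' as exchangeable units. On convergence failure or a singular fit, the
#' random-effects structure is simplified in a fixed order (drop the
#' correlations, then the ROI slope, then the subject slope), recording the
#' trace. Degrees of freedom are Satterthwaite approximations; the effect
#' size is Cohen's d_z on subject-level condition-difference means (the
#' metric is always reported by name).
#'
#' @param psc_table data.frame with columns `subject`, `roi`, `psc` and
#'   either `condition_code` or a two-level `condition`.
#' @param levels Optional condition order passed to [deviation_code()] when
#'   `condition_code` is absent.
#' @return A `mixed_fit` with beta, SE, t, Satterthwaite df, p, d_z, the
#'   random-effect variances, and the simplification trace.
#' @export
fit_network_lmm <- function(psc_table, levels = NULL) {
  data <- prepare_lmm_data(psc_table, levels)
  if (length(unique(data$roi)) < 2) {
    # single-ROI network: the crossed model is unidentifiable; use the
    # subject-level paired comparison directly
    return(paired_fallback(data, "condition_code", "single ROI: paired comparison"))
  }
  fit_lmm_ladder(data)
}

prepare_lmm_data <- function(psc_table, levels = NULL) {
  data <- as.data.frame(psc_table)
  if (!"condition_code" %in% names(data)) data <- deviation_code(data, levels)
  if (!all(sort(unique(data$condition_code)) == c(-0.5, 0.5)))
    stop("condition_code must be deviation-coded (-0.5, +0.5) with both levels present")
  if (length(unique(data$subject)) < 2) stop("need at least two subjects")
  data$subject <- factor(data$subject)
  data$roi <- factor(data$roi)
  data
}

#' Condition-by-network interaction model
#'
#' Stacks the PSC tables of two networks, deviation-codes the network label
#' (-0.5/+0.5 in the order given), and fits
#' `psc ~ condition_code * network_code + (1 + condition_code | subject) + (1 + condition_code | roi)`
#' with the same simplification policy; the reported term is the
#' condition x network interaction. ROI labels are made unique within
#' network. The *first* table's network is coded +0.5, so the interaction
#' estimate equals the condition effect in network A minus the condition
#' effect in network B.
#'
#' @param table_a,table_b PSC tables of the two networks (see
#'   [fit_network_lmm()]); subjects must be shared.
#' @param levels Optional condition order for [deviation_code()].
#' @return A `mixed_fit` for the interaction term.
#' @export
fit_interaction_lmm <- function(table_a, table_b, levels = NULL) {
  a <- as.data.frame(table_a); b <- as.data.frame(table_b)
  if (nrow(a) == 0 || nrow(b) == 0) stop("interaction model needs two networks")
  net_a <- unique(a$network) %||% "A"; net_b <- unique(b$network) %||% "B"
  if (identical(net_a, net_b)) stop("the two tables must carry different network labels")
  a$roi <- paste0(net_a, ":", a$roi); b$roi <- paste0(net_b, ":", b$roi)
  data <- rbind(a, b)
  data$network_code <- ifelse(data$network == net_a[1], 0.5, -0.5)
  data <- prepare_lmm_data(data, levels)
  formulas <- c(
    maximal = "psc ~ condition_code * network_code + (1 + condition_code | subject) + (1 + condition_code | roi)",
    no_correlations = "psc ~ condition_code * network_code + (1 + condition_code || subject) + (1 + condition_code || roi)",
    no_roi_slope = "psc ~ condition_code * network_code + (1 + condition_code || subject) + (1 | roi)",
    no_subject_slope = "psc ~ condition_code * network_code + (1 | subject) + (1 | roi)")
  fit_lmm_ladder(data, term = "condition_code:network_code", formulas = formulas)
}

#' Per-ROI condition tests with FDR control
#'
#' For each ROI, a paired comparison of subject-level condition means
#' (positive-coded minus negative-coded condition); p-values are
#' Benjamini-Hochberg adjusted across the ROIs of each network.
#'
#' @param psc_table PSC table with columns `subject`, `roi`, `network`,
#'   `psc` and `condition_code` (or a two-level `condition`).
#' @param levels Optional condition order for [deviation_code()].
#' @return data.frame: network, roi, beta (mean paired difference), t, df,
#'   p, p_fdr.
#' @export
fit_roi_models <- function(psc_table, levels = NULL) {
  data <- prepare_lmm_data(psc_table, levels)
  if (!"network" %in% names(data)) data$network <- "network"
  out <- do.call(rbind, lapply(split(data, data[c("roi", "network")], drop = TRUE),
    function(d) {
      dzi <- cohens_dz(d)
      dd <- dzi$diffs
      n <- length(dd)
      if (n < 2) return(NULL)
      sdd <- stats::sd(dd)
      if (sdd == 0) {
        t <- if (mean(dd) == 0) 0 else Inf * sign(mean(dd))
        p <- if (mean(dd) == 0) 1 else 0
      } else {
        t <- mean(dd) / (sdd / sqrt(n))
        p <- 2 * stats::pt(-abs(t), n - 1)
      }
      data.frame(network = d$network[1], roi = as.character(d$roi[1]),
                 beta = mean(dd), t = t, df = n - 1, p = p)
    }))
  rownames(out) <- NULL
  out$p_fdr <- stats::ave(out$p, out$network,
                          FUN = function(p) stats::p.adjust(p, "BH"))
  out
}

#' Overlap statistics between two parcel atlases
#'
#' Standard set-overlap measures on the binarized atlases, plus the fraction
#' of each parcel of `atlas_a` covered by `atlas_b`.
#'
#' @param atlas_a,atlas_b `parcel_atlas` objects (or integer label arrays) on
#'   one grid.
#' @return List with `dice`, `jaccard`, `n_shared`, `n_a`, `n_b`, and
#'   `per_parcel` (data.frame id, n_vox, overlap_fraction for `atlas_a`).
#' @export
network_overlap <- function(atlas_a, atlas_b) {
  la <- if (inherits(atlas_a, "parcel_atlas")) atlas_a$labels else atlas_a
  lb <- if (inherits(atlas_b, "parcel_atlas")) atlas_b$labels else atlas_b
  stop_if_grid_mismatch(la, lb, "atlases")
  a <- la > 0; b <- lb > 0
  n_a <- sum(a); n_b <- sum(b); n_shared <- sum(a & b)
  dice <- if (n_a + n_b > 0) 2 * n_shared / (n_a + n_b) else NA_real_
  jaccard <- if (sum(a | b) > 0) n_shared / sum(a | b) else NA_real_
  ids <- sort(unique(la[la > 0]))
  per_parcel <- data.frame(
    id = ids,
    n_vox = vapply(ids, function(i) sum(la == i), numeric(1)),
    overlap_fraction = vapply(ids, function(i) {
      n <- sum(la == i); if (n == 0) NA_real_ else sum(la == i & b) / n
    }, numeric(1)))
  list(dice = dice, jaccard = jaccard, n_shared = n_shared, n_a = n_a,
       n_b = n_b, per_parcel = per_parcel)
}

#' Localizer-scope contrast model
#'
#' Applies the network-level mixed model machinery to a cross-validated
#' localizer PSC table, testing the localizer's own contrast (e.g. intact
#' vs. degraded speech). With a single ROI the model reduces to the
#' subject-level paired comparison.
#'
#' @param cv_psc_table PSC table (see [fit_network_lmm()]) whose `condition`
#'   holds the localizer's two conditions.
#' @param levels Condition order: `levels[2]` is coded +0.5 (the "task"/hard
#'   condition).
#' @return A `mixed_fit`.
#' @export
localizer_scope_effect <- function(cv_psc_table, levels = NULL) {
  fit_network_lmm(cv_psc_table, levels = levels)
}

#' Simulate a PSC table from the crossed generative model
#'
#' Draws records from
#' `psc = mu + beta * code + a_subject + b_subject * code + a_roi + b_roi * code + noise`,
#' the generative counterpart of the network-level model; used for
#' calibration and parameter-recovery studies.
#'
#' @param n_subjects,n_rois Design size.
#' @param beta True condition effect.
#' @param mu Grand mean.
#' @param subject_int_sd,subject_slope_sd,roi_int_sd,roi_slope_sd Random
#'   effect SDs.
#' @param resid_sd Residual SD.
#' @param seed Integer seed.
#' @param conditions Labels coded (-0.5, +0.5) in order.
#' @return data.frame with subject, roi, network, condition, condition_code,
#'   psc.
#' @export
simulate_psc_table <- function(n_subjects = 40, n_rois = 20, beta = 0.07,
                               mu = 0.5, subject_int_sd = 0.1,
                               subject_slope_sd = 0.05, roi_int_sd = 0.1,
                               roi_slope_sd = 0.03, resid_sd = 0.1, seed = 1,
                               conditions = c("L1_after_L1", "L1_after_L2")) {
  with_seed(seed, {
    subj <- sprintf("sub-%02d", seq_len(n_subjects))
    roi <- sprintf("roi-%02d", seq_len(n_rois))
    grid <- expand.grid(subject = subj, roi = roi, condition = conditions,
                        stringsAsFactors = FALSE)
    grid$condition_code <- ifelse(grid$condition == conditions[2], 0.5, -0.5)
    a_s <- stats::setNames(stats::rnorm(n_subjects, 0, subject_int_sd), subj)
    b_s <- stats::setNames(stats::rnorm(n_subjects, 0, subject_slope_sd), subj)
    a_r <- stats::setNames(stats::rnorm(n_rois, 0, roi_int_sd), roi)
    b_r <- stats::setNames(stats::rnorm(n_rois, 0, roi_slope_sd), roi)
    grid$psc <- mu + beta * grid$condition_code +
      a_s[grid$subject] + b_s[grid$subject] * grid$condition_code +
      a_r[grid$roi] + b_r[grid$roi] * grid$condition_code +
      stats::rnorm(nrow(grid), 0, resid_sd)
    grid$network <- "network"
    grid[c("subject", "roi", "network", "condition", "condition_code", "psc")]
  })
}
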