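# Experiment schedules: blocked localizers and the event-related picture
# naming task, plus BIDS-style events-table I/O.

#' Construct a design schedule
#'
#' @param events data.frame with columns `onset`, `duration`, `condition`
#'   (seconds; onsets nondecreasing, events non-overlapping).
#' @param total_duration_s Total run duration, >= last onset + last duration.
#' @param design_kind "blocked" or "event_related".
#' @return An object of class `design_schedule` (the events data.frame with
#'   attributes `total_duration_s` and `design_kind`).
#' @export
design_schedule <- function(events, total_duration_s,
                            design_kind = c("blocked", "event_related")) {
  design_kind <- match.arg(design_kind)
  stopifnot(is.data.frame(events),
            all(c("onset", "duration", "condition") %in% names(events)))
  if (nrow(events) > 0) {
    if (is.unsorted(events$onset)) stop("event onsets must be nondecreasing")
    ends <- events$onset + events$duration
    if (nrow(events) > 1 && any(ends[-nrow(events)] > events$onset[-1] + 1e-9))
      stop("events must not overlap")
    if (total_duration_s < ends[nrow(events)] - 1e-9)
      stop("total_duration_s shorter than the last event")
  }
  structure(events, total_duration_s = as.numeric(total_duration_s),
            design_kind = design_kind,
            class = c("design_schedule", "data.frame"))
}

#' @export
print.design_schedule <- function(x, ...) {
  cat(sprintf("design_schedule (%s): %d events, %d condition(s), %.3f s total\n",
              attr(x, "design_kind"), nrow(x),
              length(unique(x$condition)), attr(x, "total_duration_s")))
  invisible(x)
}

#' Total duration of a schedule in seconds
#' @param schedule A [design_schedule()].
#' @export
schedule_duration <- function(schedule) attr(schedule, "total_duration_s")

# Assemble a blocked schedule from an ordered vector of block conditions
# ("fixation" blocks contribute time but no event row).
blocks_to_schedule <- function(conditions, durations, lead_s = 0, tail_s = 0) {
  onset <- lead_s + c(0, cumsum(durations))[seq_along(durations)]
  keep <- conditions != "fixation"
  events <- data.frame(onset = onset[keep], duration = durations[keep],
                       condition = conditions[keep])
  design_schedule(events, lead_s + sum(durations) + tail_s, "blocked")
}

#' Build a blocked localizer schedule
#'
#' Generates one functional run of the named localizer with the published
#' block structure; block counts and durations can be overridden through
#' `params`. Task-block order is a seed-controlled permutation; fixation
#' blocks occupy fixed, evenly spaced slots.
#'
#' Defaults per design:
#' \describe{
#'   \item{language}{6 intact + 6 degraded speech blocks of 18 s, 4 fixation
#'     blocks of 12 s; 264 s per run.}
#'   \item{articulation}{6 syllable + 6 finger-tapping blocks of 18 s, 4
#'     fixation blocks of 12 s; 264 s.}
#'   \item{md}{5 easy + 5 hard spatial working-memory blocks; each block is 4
#'     trials of 0.5 s fixation + 4 x 1 s grids + 4 s response/feedback
#'     window, i.e. 34 s; 6 fixation blocks of 16 s.}
#'   \item{stroop}{8 easy + 8 hard colour-naming blocks of 18 s, 5 fixation
#'     blocks of 18 s, 8 s lead-in and 8 s tail; 394 s.}
#'   \item{verbal_fluency}{6 semantic + 6 phonemic fluency blocks and 5
#'     automated-speech baseline blocks of 10 s, each followed by a jittered
#'     7-13 s fixation rescaled so the run totals 348 s.}
#' }
#'
#' @param design_name One of "language", "md", "stroop", "articulation",
#'   "verbal_fluency".
#' @param params Named list of overrides (see Details in the source; e.g.
#'   `n_blocks_per_condition`, `block_s`, `n_fixation`, `fixation_s`).
#' @param seed Integer seed controlling block-order counterbalancing.
#' @return A [design_schedule()].
#' @export
make_localizer_schedule <- function(design_name, params = list(), seed = 1) {
  known <- c("language", "md", "stroop", "articulation", "verbal_fluency")
  if (!design_name %in% known)
    stop(sprintf("unknown design name '%s' (expected one of: %s)",
                 design_name, paste(known, collapse = ", ")))
  p <- function(name, default) params[[name]] %||% default

  if (design_name %in% c("language", "articulation")) {
    conds <- if (design_name == "language") c("intact", "degraded")
             else c("articulation", "motor")
    nb <- p("n_blocks_per_condition", 6)
    block_s <- p("block_s", 18)
    nf <- p("n_fixation", 4)
    fix_s <- p("fixation_s", 12)
    task <- rep(conds, each = nb)
    task <- with_seed(seed, sample(task))
    order <- interleave_fixation(task, nf)
    durs <- ifelse(order == "fixation", fix_s, block_s)
    return(blocks_to_schedule(order, durs))
  }

  if (design_name == "md") {
    nb <- p("n_blocks_per_condition", 5)
    trials <- p("trials_per_block", 4)
    trial_s <- p("trial_fixation_s", 0.5) + p("n_grids", 4) * p("grid_s", 1) +
      p("response_feedback_s", 4)
    block_s <- trials * trial_s
    nf <- p("n_fixation", 6)
    fix_s <- p("fixation_s", 16)
    task <- rep(c("easy", "hard"), each = nb)
    task <- with_seed(seed, sample(task))
    order <- interleave_fixation(task, nf)
    durs <- ifelse(order == "fixation", fix_s, block_s)
    return(blocks_to_schedule(order, durs))
  }

  if (design_name == "stroop") {
    nb <- p("n_blocks_per_condition", 8)
    block_s <- p("block_s", 18)
    nf <- p("n_fixation", 5)
    fix_s <- p("fixation_s", 18)
    task <- rep(c("easy", "hard"), each = nb)
    task <- with_seed(seed, sample(task))
    order <- interleave_fixation(task, nf)
    durs <- ifelse(order == "fixation", fix_s, block_s)
    return(blocks_to_schedule(order, durs, lead_s = p("lead_in_s", 8),
                              tail_s = p("tail_s", 8)))
  }

  # verbal_fluency
  nb <- p("n_blocks_per_condition", 6)
  block_s <- p("block_s", 10)
  nbase <- p("n_baseline", 5)
  fix_min <- p("fixation_min_s", 7)
  fix_max <- p("fixation_max_s", 13)
  total_s <- p("total_s", 348)
  task <- c(rep(c("semantic", "phonemic"), each = nb), rep("baseline", nbase))
  task <- with_seed(seed, sample(task))
  nfix <- length(task)
  fix_total <- total_s - nfix * block_s
  stopifnot(fix_total >= nfix * fix_min - 1e-9, fix_total <= nfix * fix_max + 1e-9)
  fix <- with_seed(derive_seed(seed, 2), stats::runif(nfix, fix_min, fix_max))
  fix <- rescale_to_mean(fix, fix_total / nfix, fix_min, fix_max)
  conditions <- as.vector(rbind(task, "fixation"))
  durs <- as.vector(rbind(rep(block_s, nfix), fix))
  blocks_to_schedule(conditions, durs)
}

# Place `n_fix` fixation blocks at (approximately) evenly spaced fixed slots
# among the task blocks, including the first and last slot.
interleave_fixation <- function(task, n_fix) {
  if (n_fix == 0) return(task)
  n_total <- length(task) + n_fix
  slots <- round(seq(1, n_total, length.out = n_fix))
  out <- character(n_total)
  out[slots] <- "fixation"
  out[-slots] <- task
  out
}

# Affinely shrink a sample toward its target mean without leaving [lo, hi];
# the realized mean equals `target` exactly.
rescale_to_mean <- function(x, target, lo, hi) {
  m <- mean(x)
  if (length(x) == 1L || isTRUE(all.equal(m, target))) return(rep(target, length(x)) + (x - m) * 0)
  k <- 1
  if (min(x) < m) k <- min(k, (target - lo) / (m - min(x)))
  if (max(x) > m) k <- min(k, (hi - target) / (max(x) - m))
  target + (x - m) * k
}

#' Build the event-related picture-naming schedule
#'
#' One run of the main task: a 7 s lead-in fixation, `n_trials` picture events
#' of 2 s each followed by a jittered inter-stimulus interval, and an 8 s tail
#' fixation. ISIs are drawn from a truncated exponential on
#' `[isi$min_s, isi$max_s]` and affinely rescaled so their realized mean equals
#' `isi$mean_s` (within 1 ms). With the defaults a run totals 295 s.
#'
#' @param n_trials Number of naming trials (default 55).
#' @param isi List with `min_s`, `max_s`, `mean_s` (defaults 0.607, 10.144,
#'   3.091).
#' @param condition Condition label attached to every trial (the run-level
#'   preceding-language condition in the main task).
#' @param trial_s Picture presentation time (2 s).
#' @param lead_in_s,tail_s Fixation before the first and after the last trial.
#' @param seed Integer seed for the ISI sample.
#' @return A [design_schedule()] of kind "event_related".
#' @export
make_picture_naming_schedule <- function(n_trials = 55,
                                         isi = list(min_s = 0.607,
                                                    max_s = 10.144,
                                                    mean_s = 3.091),
                                         condition = "naming",
                                         trial_s = 2, lead_in_s = 7,
                                         tail_s = 8, seed = 1) {
  stopifnot(n_trials >= 1)
  if (isi$mean_s < isi$min_s || isi$mean_s > isi$max_s)
    stop("infeasible ISI parameters: mean outside [min, max]")
  isis <- with_seed(seed, rtrunc_exp(n_trials, isi$min_s, isi$max_s, isi$mean_s))
  isis <- rescale_to_mean(isis, isi$mean_s, isi$min_s, isi$max_s)
  onsets <- lead_in_s + c(0, cumsum(trial_s + isis))[seq_len(n_trials)]
  events <- data.frame(onset = onsets, duration = trial_s, condition = condition)
  total <- lead_in_s + sum(trial_s + isis) + tail_s
  design_schedule(events, total, "event_related")
}

# Truncated exponential on [a, b] with the rate chosen so the distribution
# mean matches `target`; inverse-CDF sampling.
rtrunc_exp <- function(n, a, b, target) {
  mean_fun <- function(lambda) {
    w <- b - a
    a + 1 / lambda - w * exp(-lambda * w) / (1 - exp(-lambda * w))
  }
  mid <- (a + b) / 2
  if (abs(target - mid) < 1e-9) {
    lambda <- 1e-8          # degenerate toward uniform
  } else if (target < mid) {
    lambda <- stats::uniroot(function(l) mean_fun(l) - target,
                             interval = c(1e-6, 50), tol = 1e-10)$root
  } else {
    # mean above the midpoint needs a negative rate (increasing density)
    lambda <- stats::uniroot(function(l) mean_fun(l) - target,
                             interval = c(-50, -1e-6), tol = 1e-10)$root
  }
  u <- stats::runif(n)
  w <- b - a
  a - log(1 - u * (1 - exp(-lambda * w))) / lambda
}

#' Write a schedule as a BIDS-style events table
#'
#' Tab-separated columns `onset`, `duration`, `trial_type`.
#' @param schedule A [design_schedule()].
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_events_tsv <- function(schedule, file) {
  df <- data.frame(onset = schedule$onset, duration = schedule$duration,
                   trial_type = schedule$condition)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a BIDS-style events table as a design schedule
#'
#' @param file Path to a TSV with `onset`, `duration`, `trial_type` columns.
#' @param total_duration_s Run duration; defaults to the last event end.
#' @param design_kind "blocked" or "event_related".
#' @return A [design_schedule()].
#' @export
read_events_tsv <- function(file, total_duration_s = NULL,
                            design_kind = "event_related") {
  df <- utils::read.delim(file)
  events <- data.frame(onset = df$onset, duration = df$duration,
                       condition = df$trial_type)
  if (is.null(total_duration_s))
    total_duration_s <- max(events$onset + events$duration, 0)
  design_schedule(events, total_duration_s, design_kind)
}
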