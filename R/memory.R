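#' Score recognition-memory behavior in a session
#'
#' Operates on the recognition-phase trials of a trial table. Trials with
#' outlier reaction times (longer than 5 s, or above the session mean plus 3
#' SD) are excluded before scoring. A *hit* is an old trial answered with
#' response >= 4 ("old" side of the 1-6 confidence scale); *accuracy* counts
#' hits and correct rejections among all surviving recognition trials;
#' *confidence* is the mean numeric response over old trials judged old
#' (range 4-6), or over all old trials with `confidence_scope = "all_old"`.
#'
#' @param trials A `trial_table` data.frame (columns `stimulus_id`, `phase`,
#'   `old_flag`, `response`, `rt_s`).
#' @param confidence_scope `"judged_old"` (default) or `"all_old"`.
#' @param rt_max Absolute RT cutoff, seconds (default 5).
#' @param rt_sd_factor SD multiplier for the relative RT cutoff (default 3).
#' @return A `recognition_outcome`: `trials` (surviving recognition trials
#'   with `hit`/`correct` flags), `hit_rate`, `accuracy`, `confidence`,
#'   `n_excluded`.
#' @export
score_recognition <- function(trials,
                              confidence_scope = c("judged_old", "all_old"),
                              rt_max = 5, rt_sd_factor = 3) {
  confidence_scope <- match.arg(confidence_scope)
  rec <- trials[trials$phase == "recognition", , drop = FALSE]
  if (nrow(rec) == 0) stop("no recognition trials")
  cut <- mean(rec$rt_s) + rt_sd_factor * stats::sd(rec$rt_s)
  keep <- rec$rt_s <= rt_max & rec$rt_s <= cut
  n_excluded <- sum(!keep)
  rec <- rec[keep, , drop = FALSE]
  if (nrow(rec) == 0) {
    warning("no recognition trials survive the RT filter")
    return(structure(list(trials = rec, hit_rate = NA_real_,
                          accuracy = NA_real_, confidence = NA_real_,
                          n_excluded = n_excluded),
                     class = "recognition_outcome"))
  }
  rec$said_old <- rec$response >= 4
  rec$hit <- rec$old_flag & rec$said_old
  rec$correct <- rec$said_old == rec$old_flag
  old <- rec[rec$old_flag, , drop = FALSE]
  conf_trials <- if (confidence_scope == "judged_old")
    old[old$said_old, , drop = FALSE] else old
  structure(list(
    trials = rec,
    hit_rate = if (nrow(old)) mean(old$hit) else NA_real_,
    accuracy = mean(rec$correct),
    confidence = if (nrow(conf_trials)) mean(conf_trials$response)
                 else NA_real_,
    n_excluded = n_excluded),
    class = "recognition_outcome")
}

#' @export
print.recognition_outcome <- function(x, ...) {
  cat(sprintf(
    "recognition_outcome: %d trials (%d RT-excluded), hit rate %.3f, accuracy %.3f, confidence %.2f\n",
    nrow(x$trials), x$n_excluded, x$hit_rate, x$accuracy, x$confidence))
  invisible(x)
}

# hit rate / confidence restricted to a stimulus subset; NA when no old
# trials fall in the subset
subset_memory_metrics <- function(outcome, ids,
                                  confidence_scope = "judged_old") {
  old <- outcome$trials[outcome$trials$old_flag &
                          outcome$trials$stimulus_id %in% ids, ,
                        drop = FALSE]
  if (nrow(old) == 0)
    return(list(hit_rate = NA_real_, confidence = NA_real_, n_old = 0L))
  conf <- if (confidence_scope == "judged_old")
    old[old$said_old, , drop = FALSE] else old
  list(hit_rate = mean(old$hit),
       confidence = if (nrow(conf)) mean(conf$response) else NA_real_,
       n_old = nrow(old))
}

#' Compare memory for in-region versus out-region stimuli
#'
#' Each analysis unit pairs a recognition outcome with a partition of the
#' stimuli into in-region and out-region sets — a single feature neuron's
#' tuning region, or the aggregated (union) regions of a session's feature
#' neurons. Units from sessions with hit rate at or below `min_hit_rate` are
#' excluded (low-performance sessions are unreliable), as are units with no
#' in-region or no out-region old stimuli after filtering. Hit rate and
#' confidence are compared with paired two-tailed t-tests across units.
#'
#' @param units List of lists, each with elements `outcome`
#'   (a `recognition_outcome`), `in_ids`, `out_ids` (stimulus id vectors).
#' @param min_hit_rate Session hit-rate inclusion threshold (default 0.6,
#'   strict).
#' @param confidence_scope Passed through to the per-subset metrics.
#' @return List with `per_unit` (data.frame of paired metrics), `hit_test`
#'   and `confidence_test` (paired `test_result`s), `n_excluded`.
#' @export
in_out_memory_comparison <- function(units, min_hit_rate = 0.6,
                                     confidence_scope = "judged_old") {
  rows <- lapply(units, function(u) {
    if (is.na(u$outcome$hit_rate) || u$outcome$hit_rate <= min_hit_rate)
      return(NULL)
    m_in <- subset_memory_metrics(u$outcome, u$in_ids, confidence_scope)
    m_out <- subset_memory_metrics(u$outcome, u$out_ids, confidence_scope)
    if (m_in$n_old == 0 || m_out$n_old == 0) {
      message("unit dropped: no old stimuli on one side of the region")
      return(NULL)
    }
    data.frame(hit_in = m_in$hit_rate, hit_out = m_out$hit_rate,
               conf_in = m_in$confidence, conf_out = m_out$confidence,
               n_in = m_in$n_old, n_out = m_out$n_old)
  })
  per_unit <- do.call(rbind, rows)
  if (is.null(per_unit) || nrow(per_unit) < 2)
    stop("fewer than 2 usable units")
  n_excluded <- length(units) - nrow(per_unit)
  list(per_unit = per_unit,
       hit_test = paired_samples_test(per_unit$hit_in, per_unit$hit_out),
       confidence_test = paired_samples_test(per_unit$conf_in,
                                             per_unit$conf_out),
       n_excluded = n_excluded)
}

#' Compare behavior between high- and low-memorability stimuli
#'
#' Stimuli are split by memorability score into a high group (top
#' `group_fraction`, default 30%) and a low group (bottom 30%), with
#' thresholds computed over all scored stimuli. Per session, accuracy,
#' confidence, reaction time and hit rate are computed for each group;
#' sessions need more than `min_trials` surviving recognition trials in both
#' groups. Groups are compared with paired two-tailed t-tests across
#' sessions.
#'
#' @param outcomes List of `recognition_outcome`s, one per session.
#' @param scores Named numeric vector of memorability scores in \[0, 1\]
#'   (names = stimulus ids).
#' @param group_fraction Fraction defining the top/bottom groups.
#' @param min_trials Minimum trials per group per session (strict, default
#'   10).
#' @return List with `per_session` data.frame, paired `test_result`s
#'   `accuracy_test`, `confidence_test`, `rt_test`, `hit_test`, and
#'   `n_excluded`.
#' @export
memorability_behavior_comparison <- function(outcomes, scores,
                                             group_fraction = 0.3,
                                             min_trials = 10) {
  if (length(unique(scores)) < 2)
    stop("memorability groups undefined: all scores identical")
  lo <- stats::quantile(scores, group_fraction, names = FALSE)
  hi <- stats::quantile(scores, 1 - group_fraction, names = FALSE)
  high_ids <- names(scores)[scores >= hi]
  low_ids <- names(scores)[scores <= lo]
  grp <- function(outcome, ids) {
    tr <- outcome$trials[outcome$trials$stimulus_id %in% ids, , drop = FALSE]
    old <- tr[tr$old_flag, , drop = FALSE]
    conf <- old[old$said_old, , drop = FALSE]
    list(n = nrow(tr), accuracy = mean(tr$correct),
         confidence = if (nrow(conf)) mean(conf$response) else NA_real_,
         rt = mean(tr$rt_s),
         hit_rate = if (nrow(old)) mean(old$hit) else NA_real_)
  }
  rows <- lapply(outcomes, function(o) {
    h <- grp(o, high_ids); l <- grp(o, low_ids)
    if (h$n <= min_trials || l$n <= min_trials) return(NULL)
    data.frame(acc_high = h$accuracy, acc_low = l$accuracy,
               conf_high = h$confidence, conf_low = l$confidence,
               rt_high = h$rt, rt_low = l$rt,
               hit_high = h$hit_rate, hit_low = l$hit_rate)
  })
  per_session <- do.call(rbind, rows)
  if (is.null(per_session) || nrow(per_session) < 2)
    stop("fewer than 2 usable sessions")
  list(per_session = per_session,
       accuracy_test = paired_samples_test(per_session$acc_high,
                                           per_session$acc_low),
       confidence_test = paired_samples_test(per_session$conf_high,
                                             per_session$conf_low),
       rt_test = paired_samples_test(per_session$rt_high,
                                     per_session$rt_low),
       hit_test = paired_samples_test(per_session$hit_high,
                                      per_session$hit_low),
       n_excluded = length(outcomes) - nrow(per_session))
}

#' Select neurons whose firing rate tracks image memorability
#'
#' A neuron encodes memorability when the Pearson correlation between its
#' per-stimulus firing rate and the memorability score is significant
#' (two-sided p < alpha). Both signs carry information (some neurons fire
#' more, others less, for memorable images), so the sign is recorded rather
#' than filtered on.
#'
#' @param rates Neurons x stimuli matrix of firing rates.
#' @param scores Memorability score per stimulus (>= 10 stimuli).
#' @param alpha Significance level (default 0.05).
#' @return Data.frame with `neuron`, `r`, `p`, `selected`, `sign`.
#' @export
select_memorability_neurons <- function(rates, scores, alpha = 0.05) {
  rates <- as.matrix(rates)
  if (ncol(rates) != length(scores)) stop("one score per stimulus required")
  if (length(scores) < 10) stop("need >= 10 scored stimuli")
  res <- t(apply(rates, 1, function(r) {
    if (stats::sd(r) == 0) {
      message("constant-rate neuron: not selectable")
      return(c(NA_real_, NA_real_))
    }
    ct <- stats::cor.test(r, scores)
    c(ct$estimate, ct$p.value)
  }))
  data.frame(neuron = seq_len(nrow(rates)), r = res[, 1], p = res[, 2],
             selected = !is.na(res[, 2]) & res[, 2] < alpha,
             sign = sign(res[, 1]))
}

#' Memorability-matched in-region versus out-region memory comparison
#'
#' Controls the in/out memory comparison for memorability: per unit, the
#' out-region set is restricted to stimuli whose memorability score lies
#' within `sd_factor` (2) SDs of the mean score of the in-region stimuli
#' before running [in_out_memory_comparison()]. Units whose matched
#' out-region set is empty are dropped.
#'
#' @param units As in [in_out_memory_comparison()].
#' @param scores Named memorability vector (names = stimulus ids).
#' @param sd_factor Matching half-width in in-region SDs (default 2).
#' @param ... Passed to [in_out_memory_comparison()].
#' @return As [in_out_memory_comparison()].
#' @export
matched_memorability_comparison <- function(units, scores, sd_factor = 2,
                                            ...) {
  matched <- lapply(units, function(u) {
    s_in <- scores[u$in_ids]
    if (length(s_in) == 0) return(NULL)
    mu <- mean(s_in, na.rm = TRUE)
    sd <- stats::sd(s_in)
    if (is.na(sd)) sd <- 0
    s_out <- scores[u$out_ids]
    keep <- !is.na(s_out) & abs(s_out - mu) <= sd_factor * sd
    if (!any(keep)) {
      message("unit dropped: matched out-region set is empty")
      return(NULL)
    }
    u$out_ids <- u$out_ids[keep]
    u
  })
  in_out_memory_comparison(matched[!vapply(matched, is.null, TRUE)], ...)
}

#' Cross-phase analysis of tuning regions
#'
#' Tests whether tuning regions identified in the learning phase predict
#' responses in the recognition phase. For each feature neuron with a
#' learning-phase region, the mean recognition-phase response to in-region
#' versus out-region stimuli is compared (paired t-test across neurons), for
#' all stimuli and for the old/new subsets. When recognition-phase regions
#' are supplied, the per-neuron region overlap (intersection over smaller
#' region) is reported, and neurons with overlap above 0.5 are flagged as
#' invariant across phases.
#'
#' @param learning_regions Named list of `tuning_region`s (one per feature
#'   neuron, learning phase).
#' @param recog_rates Neurons x stimuli matrix of recognition-phase mean
#'   rates (rows matching `names(learning_regions)`, columns matching
#'   `set$stimulus_id`).
#' @param set The `stimulus_set` of the recognition phase.
#' @param old_ids,new_ids Stimulus ids shown as old / new.
#' @param recognition_regions Optional named list of recognition-phase
#'   `tuning_region`s for the same neurons.
#' @return List with `per_neuron` data.frame (mean in/out responses per
#'   subset), `tests` (paired `test_result` per subset), and when available
#'   `overlap` plus logical `invariant`.
#' @export
cross_phase_analysis <- function(learning_regions, recog_rates, set,
                                 old_ids, new_ids,
                                 recognition_regions = NULL) {
  recog_rates <- as.matrix(recog_rates)
  stopifnot(nrow(recog_rates) == length(learning_regions))
  ids <- set$stimulus_id[!set$anchor]
  stopifnot(ncol(recog_rates) == length(ids))
  subsets <- list(all = ids, old = intersect(ids, old_ids),
                  new = intersect(ids, new_ids))
  rows <- lapply(seq_along(learning_regions), function(i) {
    part <- stimuli_in_region(learning_regions[[i]], set)
    vals <- lapply(subsets, function(ss) {
      inn <- intersect(part$in_ids, ss)
      out <- intersect(part$out_ids, ss)
      c(mean_in = if (length(inn)) mean(recog_rates[i, match(inn, ids)])
                  else NA_real_,
        mean_out = if (length(out)) mean(recog_rates[i, match(out, ids)])
                   else NA_real_)
    })
    data.frame(neuron = i, t(unlist(vals)))
  })
  per_neuron <- do.call(rbind, rows)
  tests <- lapply(c(all = "all", old = "old", new = "new"), function(s)
    paired_samples_test(per_neuron[[paste0(s, ".mean_in")]],
                        per_neuron[[paste0(s, ".mean_out")]]))
  out <- list(per_neuron = per_neuron, tests = tests)
  if (!is.null(recognition_regions)) {
    stopifnot(length(recognition_regions) == length(learning_regions))
    ov <- mapply(region_overlap, learning_regions, recognition_regions)
    out$overlap <- ov
    out$invariant <- ov > 0.5
  }
  out
}

#' Detect saccades and fixations in a gaze trace
#'
#' A sample is a saccade candidate when its instantaneous velocity exceeds
#' `min_velocity` or its absolute acceleration exceeds `min_acceleration`
#' (the standard video-oculography parser rule). Runs of candidate samples
#' lasting at least `min_duration` with a total deflection (start-to-end
#' displacement) above `min_deflection` are saccades; fixations are the
#' complementary intervals. Consecutive fixations are kept as discrete
#' intervals even when they land on the same object.
#'
#' @param gaze Data.frame with columns `t_s`, `x_deg`, `y_deg`, uniformly
#'   sampled (>= 3 samples).
#' @param min_velocity Degrees/s (default 30).
#' @param min_acceleration Degrees/s^2 (default 8000).
#' @param min_duration Seconds (default 0.004).
#' @param min_deflection Degrees (default 0.1).
#' @return List with `saccades` and `fixations` data.frames (`onset`,
#'   `offset` in seconds).
#' @export
detect_saccades <- function(gaze, min_velocity = 30,
                            min_acceleration = 8000,
                            min_duration = 0.004, min_deflection = 0.1) {
  n <- nrow(gaze)
  if (n < 3) stop("need at least 3 gaze samples")
  dt <- stats::median(diff(gaze$t_s))
  vx <- c(0, diff(gaze$x_deg)) / dt
  vy <- c(0, diff(gaze$y_deg)) / dt
  speed <- sqrt(vx^2 + vy^2)
  accel <- c(0, diff(speed)) / dt
  cand <- speed > min_velocity | abs(accel) > min_acceleration
  r <- rle(cand)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  sacc <- data.frame(onset = numeric(0), offset = numeric(0))
  for (k in which(r$values)) {
    i1 <- starts[k]; i2 <- ends[k]
    dur <- (i2 - i1 + 1) * dt
    defl <- sqrt((gaze$x_deg[i2] - gaze$x_deg[max(i1 - 1, 1)])^2 +
                   (gaze$y_deg[i2] - gaze$y_deg[max(i1 - 1, 1)])^2)
    if (dur >= min_duration && defl > min_deflection)
      sacc <- rbind(sacc, data.frame(onset = gaze$t_s[i1],
                                     offset = gaze$t_s[i2] + dt))
  }
  t_end <- gaze$t_s[n] + dt
  if (nrow(sacc) == 0) {
    fix <- data.frame(onset = gaze$t_s[1], offset = t_end)
  } else {
    bounds <- c(gaze$t_s[1], t(as.matrix(sacc)), t_end)
    fix <- data.frame(onset = bounds[seq(1, length(bounds) - 1, by = 2)],
                      offset = bounds[seq(2, length(bounds), by = 2)])
    fix <- fix[fix$offset - fix$onset > dt / 2, , drop = FALSE]
  }
  list(saccades = sacc, fixations = fix)
}
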