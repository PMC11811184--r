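test_that("recognition scoring matches hand counts and the RT filter", {
  tt <- toy_trial_table()   # old: 6,5,4,3,2,6; new: 1,1,5,2
  o <- score_recognition(tt)
  expect_equal(o$hit_rate, 4 / 6)
  expect_equal(o$accuracy, 7 / 10)
  expect_equal(o$confidence, mean(c(6, 5, 4, 6)))
  expect_equal(score_recognition(tt,
                                 confidence_scope = "all_old")$confidence,
               mean(c(6, 5, 4, 3, 2, 6)))
  # all old trials answered 6
  tt6 <- toy_trial_table(responses_old = rep(6, 6))
  expect_equal(score_recognition(tt6)$hit_rate, 1)
  expect_equal(score_recognition(tt6)$confidence, 6)
  # a 6 s RT trial is excluded before scoring
  tt$rt_s[1] <- 6
  o2 <- score_recognition(tt)
  expect_equal(o2$n_excluded, 1)
  expect_equal(o2$hit_rate, 3 / 5)
  # hit + miss = 1 on old trials after filtering
  old <- o2$trials[o2$trials$old_flag, ]
  expect_equal(mean(old$hit) + mean(!old$hit), 1)
  expect_error(score_recognition(toy_trial_table()[0, ]), "no recognition")
})

test_that("in/out comparison pairs units and applies the session filter", {
  set <- small_set()
  cfg1 <- small_cfg(beta_region = 1)
  nr <- generate_neuron(set, "region", cfg1, seed = 41)
  ids_in <- set$stimulus_id[nr$truth$in_region]
  ids_out <- set$stimulus_id[!nr$truth$in_region]
  units <- lapply(1:50, function(s) {
    tt <- generate_memory_session(set, cfg1, in_region = nr$truth$in_region,
                                  seed = 2000 + s)
    list(outcome = score_recognition(tt), in_ids = ids_in,
         out_ids = ids_out)
  })
  cmp <- in_out_memory_comparison(units)
  expect_gt(mean(cmp$per_unit$hit_in), mean(cmp$per_unit$hit_out))
  expect_lt(cmp$hit_test$p_value, 0.01)
  # a unit covering every stimulus is dropped as undefined
  degen <- units[1:3]
  degen[[1]]$in_ids <- set$stimulus_id
  degen[[1]]$out_ids <- character(0)
  expect_message(cmp2 <- in_out_memory_comparison(degen), "dropped")
  expect_equal(nrow(cmp2$per_unit), 2)
  # the 60% hit-rate session filter removes weak sessions
  strong <- toy_trial_table(responses_old = rep(6, 12),
                            responses_new = rep(1, 4))
  weak <- toy_trial_table(responses_old = rep(c(6, 1), 6),
                          responses_new = rep(1, 4))
  in3 <- strong$stimulus_id[1:6]; out3 <- strong$stimulus_id[7:12]
  toy_units <- list(
    list(outcome = score_recognition(strong), in_ids = in3, out_ids = out3),
    list(outcome = score_recognition(strong), in_ids = in3, out_ids = out3),
    list(outcome = score_recognition(weak), in_ids = in3, out_ids = out3))
  cmp3 <- in_out_memory_comparison(toy_units)
  expect_equal(nrow(cmp3$per_unit), 2)
  expect_equal(cmp3$n_excluded, 1)
})

test_that("memorability groups predict behavior when planted", {
  set <- small_set()
  scores <- setNames(set$memorability, set$stimulus_id)
  mk_outcomes <- function(cfg, n = 40, seed0 = 0)
    lapply(seq_len(n), function(s)
      score_recognition(generate_memory_session(set, cfg,
                                                seed = seed0 + s)))
  cmp <- memorability_behavior_comparison(
    mk_outcomes(small_cfg(beta_mem = 2), seed0 = 3000), scores)
  expect_lt(cmp$hit_test$p_value, 0.01)
  expect_gt(mean(cmp$per_session$hit_high), mean(cmp$per_session$hit_low))
  # no planted effect: no systematic difference
  cmp0 <- memorability_behavior_comparison(
    mk_outcomes(small_cfg(), seed0 = 4000), scores)
  expect_gt(cmp0$hit_test$p_value, 0.01)
  expect_error(
    memorability_behavior_comparison(mk_outcomes(small_cfg(), n = 3),
                                     scores * 0 + 0.5), "identical")
})

test_that("sessions lacking enough trials in a group are excluded", {
  set <- small_set()
  scores <- setNames(set$memorability, set$stimulus_id)
  outs <- lapply(1:5, function(s)
    score_recognition(generate_memory_session(set, small_cfg(),
                                              seed = 5000 + s)))
  # keep only a handful of trials in the first session: it must drop out
  outs[[1]]$trials <- outs[[1]]$trials[1:12, ]
  cmp <- memorability_behavior_comparison(outs, scores)
  expect_equal(nrow(cmp$per_session), 4)
  expect_equal(cmp$n_excluded, 1)
})

test_that("memorability-neuron selection recovers sign and stays calibrated", {
  set.seed(31)
  scores <- rbeta(120, 4, 4)
  up <- 5 + 8 * scores + rnorm(120, sd = 0.5)
  down <- 5 - 8 * scores + rnorm(120, sd = 0.5)
  nulls <- matrix(rnorm(300 * 120, 5), 300, 120)
  sel <- select_memorability_neurons(rbind(up, down, nulls), scores)
  expect_true(sel$selected[1]); expect_equal(sel$sign[1], 1)
  expect_true(sel$selected[2]); expect_equal(sel$sign[2], -1)
  null_rate <- mean(sel$selected[-(1:2)])
  expect_lt(abs(null_rate - 0.05), 3 * sqrt(0.05 * 0.95 / 300) + 0.01)
  # constant-rate neurons are not selectable
  expect_message(sel0 <- select_memorability_neurons(
    matrix(2, 1, 120), scores), "constant")
  expect_false(sel0$selected[1])
})

test_that("memorability matching restricts the out-region set as specified", {
  # in-region scores 0.45/0.50/0.55 (mean 0.5, SD 0.05): the 2 SD window is
  # [0.4, 0.6], so an out-region score of 0.9 is excluded and 0.45 kept
  tt <- toy_trial_table(responses_old = c(6, 6, 5, 4, 2, 6),
                        responses_new = c(1, 1, 1, 1))
  o <- score_recognition(tt)
  scores <- setNames(c(0.45, 0.50, 0.55, 0.45, 0.90, 0.50,
                       0.5, 0.5, 0.5, 0.5),
                     tt$stimulus_id)
  units <- list(
    list(outcome = o, in_ids = tt$stimulus_id[1:3],
         out_ids = tt$stimulus_id[4:6]),
    list(outcome = o, in_ids = tt$stimulus_id[c(1, 2, 6)],
         out_ids = tt$stimulus_id[3:5]))
  cmp <- matched_memorability_comparison(units, scores, min_hit_rate = 0)
  # unit 1: out scores 0.45/0.90/0.50 against window [0.4, 0.6] -> 0.9 out
  # unit 2: in mean 0.483, 2 SD window [0.426, 0.541] -> 0.55 and 0.9 out
  expect_equal(cmp$per_unit$n_out, c(2, 1))
  # all scores equal: matching keeps the full out-region set
  cmp2 <- matched_memorability_comparison(units, scores * 0 + 0.5,
                                          min_hit_rate = 0)
  expect_equal(cmp2$per_unit$n_out, c(3, 3))
})

test_that("learning-phase regions predict recognition responses", {
  set <- small_set()
  cfg <- small_cfg()
  g <- small_grid()
  regions <- lapply(41:44, function(s) {
    nr <- generate_neuron(set, "region", cfg, seed = s)
    detect_tuning_region(responses =
                           neuron_stimulus_rates(nr, set$stimulus_id),
                         grid = g)
  })
  # fresh recognition-phase recordings of the same planted neurons
  recog <- t(vapply(41:44, function(s) {
    nr <- generate_neuron(set, "region", cfg, seed = 10000 + s)
    neuron_stimulus_rates(nr, set$stimulus_id)
  }, numeric(n_stimuli(set))))
  old_ids <- set$stimulus_id[1:96]
  new_ids <- set$stimulus_id[97:192]
  # recognition-phase regions from the fresh recordings
  rec_regions <- lapply(41:44, function(s) {
    nr <- generate_neuron(set, "region", cfg, seed = 10000 + s)
    detect_tuning_region(responses =
                           neuron_stimulus_rates(nr, set$stimulus_id),
                         grid = g)
  })
  res <- cross_phase_analysis(regions, recog, set, old_ids, new_ids,
                              recognition_regions = rec_regions)
  for (s in c("all", "old", "new"))
    expect_true(all(res$per_neuron[[paste0(s, ".mean_in")]] >
                      res$per_neuron[[paste0(s, ".mean_out")]]))
  expect_lt(res$tests$all$p_value, 0.05)
  # identical planted tuning in both phases: overlap near 1, invariant
  expect_true(all(res$overlap > 0.5))
  expect_true(all(res$invariant))
})

test_that("saccade detection matches threshold arithmetic and round-trips", {
  fs <- 500; dt <- 1 / fs
  # constant gaze: no saccade, one fixation spanning the trace
  gz <- data.frame(t_s = (0:99) * dt, x_deg = 1, y_deg = 1)
  det <- detect_saccades(gz)
  expect_equal(nrow(det$saccades), 0)
  expect_equal(nrow(det$fixations), 1)
  # 2 degree displacement over 10 ms (200 deg/s): exactly one saccade
  x <- c(rep(0, 50), seq(0, 2, length.out = 5), rep(2, 50))
  gz2 <- data.frame(t_s = seq_along(x) * dt, x_deg = x, y_deg = 0)
  det2 <- detect_saccades(gz2)
  expect_equal(nrow(det2$saccades), 1)
  expect_equal(nrow(det2$fixations), 2)
  # a 0.05 degree micro-step fails the deflection threshold
  x3 <- c(rep(0, 50), rep(0.05, 50))
  gz3 <- data.frame(t_s = seq_along(x3) * dt, x_deg = x3, y_deg = 0)
  expect_equal(nrow(detect_saccades(gz3)$saccades), 0)
  expect_error(detect_saccades(gz[1:2, ]), "3 gaze samples")

  # planted trace round-trips with >= 90% sample agreement
  cfg <- small_cfg()
  tr <- generate_gaze_trace(data.frame(x = c(0, 3, 1), y = c(0, 2, 4)),
                            durations = c(0.3, 0.25, 0.3), config = cfg,
                            seed = 6)
  det4 <- detect_saccades(tr$gaze)
  expect_equal(nrow(det4$saccades), tr$truth$n_saccades)
  expect_gte(interval_agreement(det4$fixations, tr$truth$fixations,
                                tr$gaze$t_s), 0.9)
})

test_that("trial tables and regions round-trip through TSV/JSON", {
  set <- small_set()
  tdir <- withr::local_tempdir()
  p1 <- file.path(tdir, "stim.tsv")
  write_stimulus_tsv(set, p1)
  back <- read_stimulus_tsv(p1)
  expect_equal(back$stimulus_id, set$stimulus_id)
  expect_equal(back$coords, set$coords, tolerance = 1e-12,
               ignore_attr = TRUE)
  tt <- generate_memory_session(set, small_cfg(), seed = 8)
  p2 <- file.path(tdir, "trials.tsv")
  write_trials_tsv(tt, p2)
  tt2 <- read_trials_tsv(p2)
  expect_equal(tt2$response, tt$response)
  expect_equal(tt2$old_flag, tt$old_flag)
  nr <- generate_neuron(set, "region", small_cfg(), seed = 9)
  reg <- detect_tuning_region(responses =
                                neuron_stimulus_rates(nr, set$stimulus_id),
                              grid = small_grid())
  p3 <- file.path(tdir, "region.json")
  write_region_json(reg, p3)
  reg2 <- read_region_json(p3)
  expect_equal(reg2$pixels, reg$pixels)
  expect_equal(reg2$area_fraction, reg$area_fraction)
})
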