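test_that("stimulus sets have the configured structure", {
  cfg <- synthetic_config(seed = 1)
  set <- generate_stimulus_set(cfg)
  expect_equal(n_stimuli(set), 500)
  expect_equal(length(unique(set$category)), 50)
  expect_true(all(set$coords >= 0 & set$coords <= 1))
  expect_true(all(set$memorability >= 0 & set$memorability <= 1))
  # same-category stimuli cluster: within < between mean pairwise distance
  d <- as.matrix(dist(set$coords))
  same <- outer(set$category, set$category, `==`)
  diag(same) <- NA
  expect_lt(mean(d[same & !is.na(same)]), mean(d[!same & !is.na(same)]))
  # degenerate: one category, two stimuli
  tiny <- generate_stimulus_set(synthetic_config(n_categories = 1,
                                                 n_per_category = 2))
  expect_equal(n_stimuli(tiny), 2)
  expect_equal(length(unique(tiny$category)), 1)
  expect_error(synthetic_config(n_categories = 0), "invalid config")
  expect_error(synthetic_config(n_categories = 1, n_per_category = 1),
               "invalid config")
  expect_error(synthetic_config(cluster_spread = 0), "invalid config")
})

test_that("generation is fully deterministic under a fixed seed", {
  cfg <- small_cfg()
  expect_identical(generate_stimulus_set(cfg), generate_stimulus_set(cfg))
  set <- small_set()
  expect_identical(generate_neuron(set, "region", cfg, seed = 3),
                   generate_neuron(set, "region", cfg, seed = 3))
  expect_identical(generate_memory_session(set, cfg, seed = 4),
                   generate_memory_session(set, cfg, seed = 4))
  # and the seed matters
  expect_false(identical(generate_neuron(set, "null", cfg, seed = 3),
                         generate_neuron(set, "null", cfg, seed = 4)))
})

test_that("null neurons fire at baseline and planted tuning is visible", {
  cfg <- study_cfg()
  set <- study_set()
  nn <- generate_neuron(set, "null", cfg, seed = 31)
  r <- neuron_trial_rates(nn, c(0, 1))
  se <- sd(r) / sqrt(length(r))
  expect_lt(abs(mean(r) - cfg$baseline_rate), 3 * se)

  nr <- generate_neuron(set, "region", cfg, seed = 32)
  rs <- neuron_stimulus_rates(nr, set$stimulus_id)
  d <- sqrt(rowSums(sweep(set$coords, 2, cfg$region_center)^2))
  expect_gt(mean(rs[d <= cfg$region_width]),
            mean(rs[d > 3 * cfg$region_width]))

  na <- generate_neuron(set, "axis", cfg, seed = 33)
  ra <- neuron_stimulus_rates(na, set$stimulus_id)
  proj <- drop(set$features %*% na$truth$weights)
  ct <- cor.test(ra, proj)
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.001)
})

test_that("memory generator honors its logistic hit model", {
  set <- small_set()
  nr <- generate_neuron(set, "region", small_cfg(), seed = 41)
  inr <- nr$truth$in_region

  # null model: the paired in/out comparison has calibrated type-I error
  cfg0 <- small_cfg()
  session_hits <- function(s) {
    tt <- generate_memory_session(set, cfg0, in_region = inr, seed = s)
    o <- score_recognition(tt)
    old <- o$trials[o$trials$old_flag, ]
    c(mean(old$hit[old$stimulus_id %in% set$stimulus_id[inr]]),
      mean(old$hit[!old$stimulus_id %in% set$stimulus_id[inr]]))
  }
  pvals <- vapply(1:30, function(rep) {
    hits <- t(vapply(1:10, function(s) session_hits(700 + rep * 100 + s),
                     numeric(2)))
    hits <- hits[complete.cases(hits), , drop = FALSE]
    paired_samples_test(hits[, 1], hits[, 2])$p_value
  }, 0)
  expect_lte(mean(pvals < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 30))

  # planted region benefit: paired in > out across 50 sessions
  cfg1 <- small_cfg(beta_region = 1)
  hits1 <- t(vapply(1:50, function(s) {
    tt <- generate_memory_session(set, cfg1, in_region = inr, seed = 800 + s)
    o <- score_recognition(tt)
    old <- o$trials[o$trials$old_flag, ]
    c(mean(old$hit[old$stimulus_id %in% set$stimulus_id[inr]]),
      mean(old$hit[!old$stimulus_id %in% set$stimulus_id[inr]]))
  }, numeric(2)))
  hits1 <- hits1[complete.cases(hits1), ]
  expect_lt(paired_samples_test(hits1[, 1], hits1[, 2],
                                alternative = "greater")$p_value, 0.01)
})

test_that("logistic coefficients are recoverable by refitting", {
  cfg <- synthetic_config(beta_mem = 2, beta_region = 1, seed = 9)
  set <- generate_stimulus_set(cfg)
  nr <- generate_neuron(set, "region", cfg, seed = 42)
  inr <- setNames(nr$truth$in_region, set$stimulus_id)
  mem <- setNames(set$memorability, set$stimulus_id)
  rows <- do.call(rbind, lapply(1:120, function(s) {
    tt <- generate_memory_session(set, cfg, in_region = unname(inr),
                                  seed = 1000 + s)
    rec <- tt[tt$phase == "recognition" & tt$old_flag, ]
    data.frame(y = rec$response >= 4, mem = mem[rec$stimulus_id],
               inr = inr[rec$stimulus_id])
  }))
  fit <- glm(y ~ mem + inr, family = binomial, data = rows)
  co <- summary(fit)$coefficients
  expect_lt(abs(co["mem", 1] - 2), 2 * co["mem", 2])
  expect_lt(abs(co["inrTRUE", 1] - 1), 2 * co["inrTRUE", 2])
  expect_lt(abs(co["(Intercept)", 1] - cfg$memory_beta0),
            2 * co["(Intercept)", 2])
})

test_that("trial table structure matches the phased task", {
  set <- small_set()
  tt <- generate_memory_session(set, small_cfg(), seed = 5)
  learn <- tt[tt$phase == "learning", ]
  rec <- tt[tt$phase == "recognition", ]
  expect_equal(anyDuplicated(learn$stimulus_id), 0)
  expect_true(all(rec$stimulus_id[rec$old_flag] %in% learn$stimulus_id))
  expect_false(any(rec$stimulus_id[!rec$old_flag] %in% learn$stimulus_id))
  expect_true(all(rec$response %in% 1:6))
  expect_true(all(tt$rt_s > 0))
  expect_true(all(is.na(learn$response)))
})

test_that("gaze traces plant the advertised fixation/saccade structure", {
  cfg <- small_cfg()
  # one stationary segment: no saccade
  g1 <- generate_gaze_trace(data.frame(x = 1, y = 1), durations = 0.4,
                            config = cfg, seed = 2)
  expect_equal(g1$truth$n_saccades, 0)
  det1 <- detect_saccades(g1$gaze)
  expect_equal(nrow(det1$saccades), 0)
  expect_equal(nrow(det1$fixations), 1)
  # two segments joined by a 2-degree jump: exactly one planted saccade
  g2 <- generate_gaze_trace(data.frame(x = c(0, 2), y = c(0, 0)),
                            durations = c(0.3, 0.3), config = cfg, seed = 3)
  expect_equal(g2$truth$n_saccades, 1)
  expect_error(generate_gaze_trace(data.frame(x = 1, y = 1), durations = 0,
                                   config = cfg), "positive duration")
})
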