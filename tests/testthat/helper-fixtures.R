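# shared fixtures, memoized so expensive grids are built once per run
.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

# small, dense stimulus set for fast region-detection tests
small_cfg <- function(...) {
  synthetic_config(n_categories = 16, n_per_category = 12,
                   cluster_spread = 0.05, region_width = 0.1, seed = 7, ...)
}

small_set <- function() memo("small_set", generate_stimulus_set(small_cfg()))

small_rcfg <- function(...) {
  region_config(resolution = 60, sq = 0.04, n_permutations = 100,
                seed = 5, ...)
}

small_grid <- function() memo("small_grid",
                              region_grid(small_set(), small_rcfg()))

# study-scale set (50 categories x 10) shared by the heavier checks
study_cfg <- function(...) synthetic_config(seed = 2, ...)
study_set <- function() memo("study_set", generate_stimulus_set(study_cfg()))
study_grid <- function(n_permutations = 200) {
  memo(paste0("study_grid_", n_permutations),
       region_grid(study_set(),
                   region_config(n_permutations = n_permutations, seed = 3)))
}

# Jaccard overlap between a detected region and the planted disc of radius
# 2 * width around the planted center (restricted to the mask)
planted_disc_jaccard <- function(region, truth, grid) {
  res <- grid$config$resolution
  centers <- (seq_len(res) - 0.5) / res
  pix <- grid$pixel_index
  d2 <- (centers[(pix - 1) %% res + 1] - truth$center[1])^2 +
    (centers[(pix - 1) %/% res + 1] - truth$center[2])^2
  disc <- pix[d2 <= (2 * truth$width)^2]
  length(intersect(region$pixels, disc)) /
    length(union(region$pixels, disc))
}

# hand-built recognition trial table
toy_trial_table <- function(responses_old = c(6, 5, 4, 3, 2, 6),
                            responses_new = c(1, 1, 5, 2),
                            rt = 1) {
  n_old <- length(responses_old); n_new <- length(responses_new)
  n <- n_old + n_new
  data.frame(trial_id = seq_len(n),
             stimulus_id = sprintf("s%02d", seq_len(n)),
             phase = "recognition",
             old_flag = rep(c(TRUE, FALSE), c(n_old, n_new)),
             response = c(responses_old, responses_new),
             rt_s = rep_len(rt, n),
             onset_s = 2.5 * (seq_len(n) - 1))
}

# fraction of time samples on which two saccade/fixation segmentations agree
interval_agreement <- function(fix_a, fix_b, t) {
  in_fix <- function(fix, t) {
    out <- rep(FALSE, length(t))
    for (k in seq_len(nrow(fix)))
      out <- out | (t >= fix$onset[k] & t < fix$offset[k])
    out
  }
  mean(in_fix(fix_a, t) == in_fix(fix_b, t))
}
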