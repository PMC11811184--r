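test_that("response map is the Gaussian-kernel sum and is linear", {
  set <- stimulus_set(c("a", "b"), c("x", "y"),
                      rbind(c(0.3, 0.4), c(0.7, 0.6)))
  r <- c(2, 5)
  m <- response_map(set, r, kernel_sd = 0.08, resolution = 25)
  # brute force over every pixel
  centers <- (1:25 - 0.5) / 25
  brute <- matrix(0, 25, 25)
  for (i in 1:25) for (j in 1:25)
    brute[i, j] <- sum(r * exp(-((centers[i] - set$coords[, 1])^2 +
                                   (centers[j] - set$coords[, 2])^2) /
                                 (2 * 0.08^2)))
  expect_equal(m, brute, tolerance = 1e-12)
  expect_equal(response_map(set, c(0, 0), 0.08, 25), matrix(0, 25, 25))
  expect_equal(response_map(set, 2 * r, 0.08, 25), 2 * m, tolerance = 1e-12)
  # single stimulus: peak at that stimulus pixel
  s1 <- stimulus_set("a", "x", matrix(c(0.53, 0.47), 1))
  m1 <- response_map(s1, 1, 0.05, 25)
  expect_equal(which(m1 == max(m1)), coord_to_pixel(s1$coords, 25))
  expect_error(response_map(set, r, kernel_sd = -1), "positive")
})

test_that("constant responses yield no region, all p-values 1", {
  g <- small_grid()
  expect_message(reg <- detect_tuning_region(responses = rep(3, 192),
                                             grid = g), "constant")
  expect_false(reg$detected)
  expect_equal(reg$area_fraction, 0)
  expect_true(all(reg$p_values[g$pixel_index] == 1))
})

test_that("planted region neurons are recovered where null neurons are not", {
  set <- small_set()
  g <- small_grid()
  cfg <- small_cfg()
  jac <- det <- numeric(6)
  for (s in 1:6) {
    nr <- generate_neuron(set, "region", cfg, seed = 500 + s)
    reg <- detect_tuning_region(
      responses = neuron_stimulus_rates(nr, set$stimulus_id), grid = g)
    det[s] <- reg$detected
    jac[s] <- planted_disc_jaccard(reg, nr$truth, g)
    if (reg$detected) {
      # planted center pixel inside the region
      expect_true(coord_to_pixel(matrix(nr$truth$center, 1),
                                 g$config$resolution) %in% reg$pixels)
      # in-region stimuli mostly within 2 planted widths of the center
      part <- stimuli_in_region(reg, set)
      d <- sqrt(rowSums(sweep(set$coords, 2, nr$truth$center)^2))
      expect_gt(mean(d[part$in_region] <= 2 * nr$truth$width), 0.5)
    }
  }
  expect_true(all(det == 1))
  expect_gt(median(jac), 0.3)
  flags <- vapply(1:8, function(s) {
    nn <- generate_neuron(set, "null", cfg, seed = 600 + s)
    detect_tuning_region(
      responses = neuron_stimulus_rates(nn, set$stimulus_id),
      grid = g)$detected
  }, TRUE)
  expect_lte(mean(flags), 0.25)
})

test_that("null permutation p-values are super-uniform on masked pixels", {
  set <- small_set()
  g <- small_grid()
  cfg <- small_cfg()
  nn <- generate_neuron(set, "null", cfg, seed = 901)
  reg <- detect_tuning_region(
    responses = neuron_stimulus_rates(nn, set$stimulus_id), grid = g)
  pv <- reg$p_values[g$pixel_index]
  for (alpha in c(0.05, 0.1, 0.25))
    expect_lte(mean(pv <= alpha), alpha + 3 * sqrt(alpha / length(pv)) + 0.02)
})

test_that("detection is invariant to positive scaling of responses", {
  set <- small_set()
  g <- small_grid()
  nr <- generate_neuron(set, "region", small_cfg(), seed = 505)
  r <- neuron_stimulus_rates(nr, set$stimulus_id)
  a <- detect_tuning_region(responses = r, grid = g)
  b <- detect_tuning_region(responses = 7.3 * r, grid = g)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$clusters, b$clusters)
})

test_that("raising the minimum cluster size only prunes pixels", {
  set <- small_set()
  nr <- generate_neuron(set, "region", small_cfg(), seed = 507)
  r <- neuron_stimulus_rates(nr, set$stimulus_id)
  prev <- NULL
  for (f in c(0, 0.01, 0.025, 0.1, 0.3)) {
    cfg <- small_rcfg(min_cluster_fraction = f)
    reg <- detect_tuning_region(set, r, cfg)
    if (!is.null(prev)) expect_true(all(reg$pixels %in% prev))
    prev <- reg$pixels
  }
})

test_that("region overlap and coverage follow set arithmetic", {
  g <- small_grid()
  mk <- function(pixels) {
    structure(list(pixels = as.integer(pixels),
                   clusters = list(as.integer(pixels)),
                   area_fraction = length(pixels) / g$mask$n_valid,
                   mask = g$mask, resolution = g$config$resolution,
                   detected = length(pixels) > 0),
              class = "tuning_region")
  }
  px <- g$pixel_index
  a <- mk(px[1:100]); b <- mk(px[51:250]); e <- mk(integer(0))
  expect_equal(region_overlap(a, a), 1)
  expect_equal(region_overlap(a, mk(px[101:200])), 0)
  expect_equal(region_overlap(a, b), 0.5)   # 50 shared / min(100, 200)
  expect_equal(region_overlap(a, e), 0)
  expect_equal(region_coverage(list()), 0)
  expect_equal(region_coverage(list(a)), 100 / g$mask$n_valid)
  # union semantics: duplicated region adds nothing
  expect_equal(region_coverage(list(a, a)), region_coverage(list(a)))
  expect_equal(region_coverage(list(a, b)), 250 / g$mask$n_valid)
})

test_that("stimuli_in_region partitions by pixel membership", {
  set <- small_set()
  g <- small_grid()
  all_reg <- structure(list(pixels = g$pixel_index, clusters =
                              list(g$pixel_index),
                            mask = g$mask, resolution = 60, detected = TRUE),
                       class = "tuning_region")
  part <- stimuli_in_region(all_reg, set)
  expect_length(part$out_ids, 0)
  empty <- structure(list(pixels = integer(0), clusters = list(),
                          mask = g$mask, resolution = 60, detected = FALSE),
                     class = "tuning_region")
  expect_length(stimuli_in_region(empty, set)$in_ids, 0)
})

test_that("connected-component labelling respects connectivity", {
  # two diagonal pixels: separate under 4-connectivity, joined under 8
  res <- 10
  px <- c(coord_to_pixel(matrix(c(0.15, 0.15), 1), res),
          coord_to_pixel(matrix(c(0.25, 0.25), 1), res))
  expect_equal(length(unique(
    regiontune:::label_grid_components(px, res, 4))), 2)
  expect_equal(length(unique(
    regiontune:::label_grid_components(px, res, 8))), 1)
})
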