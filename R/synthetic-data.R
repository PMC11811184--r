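#' Configuration of the synthetic recording generator
#'
#' Defaults emulate the study conditions the pipeline is designed for:
#' 50 object categories with 10 exemplars each laid out as compact clusters
#' in a 2D feature space, baseline-Poisson neurons at 5 Hz with planted
#' Gaussian tuning regions (peak gain 20 Hz, tuning SD 0.08 of the space
#' side), 1 s stimulus presentations shown once each, and recognition-memory
#' sessions with 100 learning images and 50 old + 50 new recognition images
#' rated on the 1-6 confidence scale.
#'
#' @param n_categories,n_per_category Stimulus-set structure.
#' @param cluster_spread SD of the isotropic Gaussian category cluster, in
#'   feature-space units (must be > 0).
#' @param n_features Dimensionality of the synthetic high-D feature vectors
#'   (>= 2; the first two dimensions carry the 2D layout).
#' @param baseline_rate Baseline firing rate, Hz (>= 0).
#' @param region_gain Peak rate increase inside a planted tuning region, Hz.
#' @param region_center 2D coordinate of the planted region center.
#' @param region_width SD of the planted Gaussian tuning profile (the planted
#'   region proper is the disc of radius `2 * region_width`).
#' @param axis_weights Optional weight vector over feature dimensions for
#'   axis-tuned neurons; `NULL` draws a random unit vector per neuron.
#' @param trial_duration Stimulus presentation length, seconds.
#' @param n_trials_per_stimulus Presentations per stimulus (default 1: each
#'   image is shown once).
#' @param n_learning,n_old,n_new Memory-session structure: learning-phase
#'   stimuli, and old/new stimuli in the recognition phase.
#' @param memory_beta0,beta_mem,beta_region Log-odds coefficients of the
#'   hit-probability model: for an old stimulus,
#'   `P(response >= 4) = plogis(beta0 + beta_mem * memorability +
#'   beta_region * in_region)`. Defaults are the neutral null
#'   (`beta_mem = beta_region = 0`) with `beta0 = 0.85` (~70% hit rate).
#' @param new_bias Log-odds penalty applied to new stimuli (false-alarm rate
#'   `plogis(beta0 + beta_mem * memorability - new_bias)`).
#' @param confidence_noise SD of the latent confidence strength mapping
#'   decisions onto the 1-6 scale.
#' @param rt_shift,rt_meanlog,rt_sdlog Shifted-lognormal reaction-time model
#'   (seconds); positive and right-skewed, median ~1 s.
#' @param sampling_rate Gaze sampling rate, Hz (for [generate_gaze_trace()]).
#' @param seed Integer; fully determines all generated outputs.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_categories = 50, n_per_category = 10,
                             cluster_spread = 0.03, n_features = 32,
                             baseline_rate = 5, region_gain = 20,
                             region_center = c(0.5, 0.5), region_width = 0.08,
                             axis_weights = NULL, trial_duration = 1,
                             n_trials_per_stimulus = 1,
                             n_learning = 100, n_old = 50, n_new = 50,
                             memory_beta0 = 0.85, beta_mem = 0,
                             beta_region = 0, new_bias = 1.7,
                             confidence_noise = 1,
                             rt_shift = 0.3, rt_meanlog = -0.35,
                             rt_sdlog = 0.4,
                             sampling_rate = 500, seed = 1) {
  if (n_categories < 1 || n_per_category < 1)
    stop("invalid config: counts must be positive")
  if (n_categories * n_per_category < 2)
    stop("invalid config: need at least 2 stimuli")
  if (cluster_spread <= 0) stop("invalid config: cluster_spread must be > 0")
  if (baseline_rate < 0 || region_gain < 0)
    stop("invalid config: rates must be >= 0")
  if (n_features < 2) stop("invalid config: n_features must be >= 2")
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate a clustered synthetic stimulus set
#'
#' Category centroids are placed on a randomly jittered grid covering the
#' space (emulating a feature embedding tuned so that objects are spread
#' approximately homogeneously); exemplars are drawn isotropically around
#' their centroid with SD `cluster_spread`, and all coordinates are min-max
#' normalized into the unit square. High-dimensional feature vectors are
#' built so that their first two dimensions carry the 2D layout and the
#' remaining dimensions add category-structured low-variance directions, so
#' the 2D projection of the features matches the coordinates. Per-stimulus
#' memorability scores are drawn from Beta(4, 4) (unimodal on \[0, 1\]).
#'
#' @param config A [synthetic_config()].
#' @return A [stimulus_set()] with `features` and `memorability` filled in,
#'   plus attribute `"centroids"` (category centroid matrix, normalized).
#' @export
generate_stimulus_set <- function(config = synthetic_config()) {
  with_seed(config$seed, {
    nc <- config$n_categories
    npc <- config$n_per_category
    g <- ceiling(sqrt(nc))
    cells <- sample.int(g * g, nc)
    cx <- ((cells - 1) %% g + 0.5) / g
    cy <- ((cells - 1) %/% g + 0.5) / g
    jit <- 0.25 / g
    centroids <- cbind(cx + stats::runif(nc, -jit, jit),
                       cy + stats::runif(nc, -jit, jit))
    category <- rep(sprintf("cat%02d", seq_len(nc)), each = npc)
    coords <- centroids[rep(seq_len(nc), each = npc), , drop = FALSE] +
      matrix(stats::rnorm(nc * npc * 2, sd = config$cluster_spread), ncol = 2)
    n <- nrow(coords)
    if (n > 1) {
      rng <- apply(coords, 2, range)
      coords <- normalize_coords(coords)
      centroids <- vapply(1:2, function(a)
        if (rng[2, a] == rng[1, a]) rep(0.5, nc) else
          (centroids[, a] - rng[1, a]) / (rng[2, a] - rng[1, a]),
        numeric(nc))
    }
    d <- config$n_features
    cat_dirs <- matrix(stats::rnorm(nc * (d - 2), sd = 0.08), nc, d - 2)
    features <- cbind(coords,
                      cat_dirs[rep(seq_len(nc), each = npc), , drop = FALSE] +
                        matrix(stats::rnorm(n * (d - 2), sd = 0.03), n, d - 2))
    colnames(features) <- sprintf("f%02d", seq_len(d))
    set <- stimulus_set(stimulus_id = sprintf("stim%04d", seq_len(n)),
                        category = category, coords = coords,
                        features = features,
                        memorability = stats::rbeta(n, 4, 4))
    attr(set, "centroids") <- centroids
    set
  })
}

#' Category centroids of a stimulus set
#' @param set A `stimulus_set`.
#' @return Matrix of mean 2D coordinates, one row per category.
#' @export
category_centroids <- function(set) {
  keep <- !set$anchor
  cats <- unique(set$category[keep])
  out <- t(vapply(cats, function(cc)
    colMeans(set$coords[keep & set$category == cc, , drop = FALSE]),
    numeric(2)))
  rownames(out) <- cats
  out
}

#' Pick selected categories for a planted multi-category neuron
#'
#' `"adjacent"` picks the `n` category centroids nearest to a randomly chosen
#' seed category (categories contiguous in feature space, the feature-MC
#' layout); `"dispersed"` greedily picks approximately maximally separated
#' centroids (the non-feature-MC layout).
#'
#' @param set A `stimulus_set`.
#' @param n Number of categories to select.
#' @param mode `"adjacent"` or `"dispersed"`.
#' @param seed Integer seed.
#' @return Character vector of category labels.
#' @export
choose_categories <- function(set, n = 3, mode = c("adjacent", "dispersed"),
                              seed = 1) {
  mode <- match.arg(mode)
  cen <- category_centroids(set)
  if (n > nrow(cen)) stop("more categories requested than available")
  with_seed(seed, {
    if (mode == "adjacent") {
      s <- sample.int(nrow(cen), 1)
      d <- sqrt(colSums((t(cen) - cen[s, ])^2))
      rownames(cen)[order(d)[seq_len(n)]]
    } else {
      picked <- sample.int(nrow(cen), 1)
      while (length(picked) < n) {
        d <- apply(cen, 1, function(p)
          min(sqrt(colSums((t(cen[picked, , drop = FALSE]) - p)^2))))
        d[picked] <- -Inf
        picked <- c(picked, which.max(d))
      }
      rownames(cen)[picked]
    }
  })
}

#' Simulate a neuron recording with planted tuning
#'
#' Spikes are drawn from a piecewise-homogeneous Poisson process: baseline
#' rate before stimulus onset (from -0.5 s) and a stimulus-driven rate from
#' onset until 0.5 s after offset. The driven rate per stimulus is
#' `baseline + bump`, with the bump set by the neuron kind:
#' \describe{
#'   \item{null}{no bump.}
#'   \item{region}{`gain * exp(-d^2 / (2 width^2))`, `d` the distance of the
#'     stimulus coordinate from the planted center.}
#'   \item{axis}{`gain` times the min-max-normalized projection of the
#'     stimulus features on the planted weight vector.}
#'   \item{single_category / multi_category}{`gain` for stimuli of the
#'     planted selected categories.}
#' }
#' Rates are clipped at 0. All output is deterministic given `seed`.
#'
#' @param set A `stimulus_set` (non-empty).
#' @param kind One of `"null"`, `"region"`, `"axis"`, `"single_category"`,
#'   `"multi_category"`.
#' @param config A [synthetic_config()].
#' @param selected_categories Planted categories for the category kinds
#'   (default: 1 or 3 categories chosen adjacently with the neuron's seed).
#' @param region_center Planted region center for `kind = "region"`
#'   (default `config$region_center`). Receptive fields are only observable
#'   where stimuli exist, so recovery studies typically plant each neuron's
#'   center at a (randomly chosen) stimulus coordinate.
#' @param neuron_id Identifier string.
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A `neuron_recording`: `trials` (data.frame trial_id, stimulus_id,
#'   category, rate), `spikes` (data.frame trial_id, t; t relative to onset),
#'   `truth` (kind, planted parameters, per-stimulus expected rate and
#'   in-region flag), `trial_duration`.
#' @export
generate_neuron <- function(set, kind = c("null", "region", "axis",
                                          "single_category",
                                          "multi_category"),
                            config = synthetic_config(),
                            selected_categories = NULL,
                            region_center = config$region_center,
                            neuron_id = "n1", seed = config$seed) {
  kind <- match.arg(kind)
  keep <- !set$anchor
  n <- sum(keep)
  if (n == 0) stop("stimulus set is empty")
  xy <- set$coords[keep, , drop = FALSE]
  with_seed(seed, {
    truth <- list(kind = kind, neuron_id = neuron_id)
    bump <- numeric(n)
    if (kind == "region") {
      d2 <- (xy[, 1] - region_center[1])^2 +
        (xy[, 2] - region_center[2])^2
      bump <- config$region_gain * exp(-d2 / (2 * config$region_width^2))
      truth$center <- region_center
      truth$width <- config$region_width
      truth$in_region <- d2 <= (2 * config$region_width)^2
    } else if (kind == "axis") {
      if (is.null(set$features)) stop("axis neuron needs stimulus features")
      w <- config$axis_weights
      if (is.null(w)) w <- stats::rnorm(ncol(set$features))
      w <- w / sqrt(sum(w^2))
      s <- drop(set$features[keep, , drop = FALSE] %*% w)
      s <- if (max(s) > min(s)) (s - min(s)) / (max(s) - min(s)) else s * 0
      bump <- config$region_gain * s
      truth$weights <- w
    } else if (kind %in% c("single_category", "multi_category")) {
      if (is.null(selected_categories))
        selected_categories <- choose_categories(
          set, n = if (kind == "single_category") 1 else 3,
          mode = "adjacent", seed = seed)
      bump <- config$region_gain *
        (set$category[keep] %in% selected_categories)
      truth$selected_categories <- selected_categories
    }
    rate <- pmax(config$baseline_rate + bump, 0)
    if (any(config$baseline_rate + bump < 0))
      message("negative rates clipped to 0")
    truth$rate <- rate
    truth$memorability <- set$memorability[keep]

    reps <- config$n_trials_per_stimulus
    stim_idx <- rep(seq_len(n), reps)
    stim_idx <- sample(stim_idx)          # shuffled presentation order
    ntr <- length(stim_idx)
    dur <- config$trial_duration
    pre <- 0.5; post <- 0.5
    base_counts <- stats::rpois(ntr, config$baseline_rate * pre)
    drive_counts <- stats::rpois(ntr, rate[stim_idx] * (dur + post))
    spikes <- data.frame(
      trial_id = c(rep(seq_len(ntr), base_counts),
                   rep(seq_len(ntr), drive_counts)),
      t = c(stats::runif(sum(base_counts), -pre, 0),
            stats::runif(sum(drive_counts), 0, dur + post)))
    spikes <- spikes[order(spikes$trial_id, spikes$t), ]
    rownames(spikes) <- NULL
    structure(list(
      neuron_id = neuron_id,
      trials = data.frame(trial_id = seq_len(ntr),
                          stimulus_id = set$stimulus_id[keep][stim_idx],
                          category = set$category[keep][stim_idx],
                          rate = rate[stim_idx]),
      spikes = spikes, truth = truth, trial_duration = dur),
      class = "neuron_recording")
  })
}

#' Mean firing rate of a spike train in a time window
#'
#' Spike count in the half-open window `[start, end)` divided by the window
#' length, in Hz.
#'
#' @param spike_times Numeric spike times (seconds, trial-aligned).
#' @param window Length-2 numeric `c(start, end)`, `end > start`.
#' @return Rate in Hz.
#' @export
trial_firing_rate <- function(spike_times, window) {
  if (diff(window) <= 0) stop("window must have positive length")
  sum(spike_times >= window[1] & spike_times < window[2]) / diff(window)
}

#' Per-trial firing rates of a recorded neuron
#'
#' @param neuron A `neuron_recording`.
#' @param window Length-2 analysis window in seconds relative to onset
#'   (default the 0.25-1.25 s response window; use `c(-0.5, 0)` for the
#'   baseline window).
#' @return Numeric vector of rates, one per trial (in trial order).
#' @export
neuron_trial_rates <- function(neuron, window = c(0.25, 1.25)) {
  if (diff(window) <= 0) stop("window must have positive length")
  tid <- neuron$spikes$t >= window[1] & neuron$spikes$t < window[2]
  counts <- tabulate(neuron$spikes$trial_id[tid],
                     nbins = nrow(neuron$trials))
  counts / diff(window)
}

#' Per-stimulus mean firing rates of a recorded neuron
#'
#' Averages per-trial rates over repeated presentations and returns them in
#' the order of `stimulus_ids`.
#'
#' @param neuron A `neuron_recording`.
#' @param stimulus_ids Stimulus ids defining the output order.
#' @param window Analysis window (see [neuron_trial_rates()]).
#' @return Numeric vector, one mean rate per stimulus.
#' @export
neuron_stimulus_rates <- function(neuron, stimulus_ids,
                                  window = c(0.25, 1.25)) {
  r <- neuron_trial_rates(neuron, window)
  means <- tapply(r, neuron$trials$stimulus_id, mean)
  out <- as.numeric(means[stimulus_ids])
  if (anyNA(out)) stop("some stimulus_ids were never presented")
  out
}

#' Simulate a recognition-memory session
#'
#' A learning phase shows each learning stimulus once (animal/no-animal cover
#' task; no memory response), then a recognition phase mixes old and new
#' stimuli. For each recognition trial the probability of an "old" response
#' (response >= 4) is `plogis(beta0 + beta_mem * memorability +
#' beta_region * in_region)` for old stimuli, with `new_bias` subtracted for
#' new stimuli. Confidence grades within the chosen side come from a latent
#' strength with SD `confidence_noise`; reaction times are shifted-lognormal.
#'
#' @param set A `stimulus_set` with memorability scores.
#' @param config A [synthetic_config()].
#' @param in_region Logical per (non-anchor) stimulus: inside a planted
#'   tuning region? Default all `FALSE`.
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A data.frame of class `trial_table` with columns `trial_id`,
#'   `stimulus_id`, `phase` ("learning"/"recognition"), `old_flag`
#'   (NA in learning), `response` (1-6; NA in learning), `rt_s`, `onset_s`.
#' @export
generate_memory_session <- function(set, config = synthetic_config(),
                                    in_region = NULL, seed = config$seed) {
  keep <- !set$anchor
  n <- sum(keep)
  ids <- set$stimulus_id[keep]
  mem <- set$memorability[keep]
  if (is.null(mem)) stop("stimulus set lacks memorability scores")
  if (is.null(in_region)) in_region <- rep(FALSE, n)
  stopifnot(length(in_region) == n)
  n_learn <- min(config$n_learning, n - 1)
  if (n_learn < 1) stop("invalid config: empty learning set")
  n_old <- min(config$n_old, n_learn)
  n_new <- min(config$n_new, n - n_learn)
  if (n_new < 1) stop("invalid config: no new stimuli available")
  with_seed(seed, {
    learn_idx <- sample.int(n, n_learn)
    old_idx <- sample(learn_idx, n_old)
    new_idx <- sample(setdiff(seq_len(n), learn_idx), n_new)
    rec_idx <- sample(c(old_idx, new_idx))
    old_flag <- rec_idx %in% old_idx
    lin <- config$memory_beta0 + config$beta_mem * mem[rec_idx] +
      config$beta_region * in_region[rec_idx] -
      config$new_bias * !old_flag
    said_old <- stats::runif(length(rec_idx)) < stats::plogis(lin)
    strength <- abs(lin) + abs(stats::rnorm(length(rec_idx),
                                            sd = config$confidence_noise))
    grade <- findInterval(strength, c(0.8, 1.6))        # 0,1,2
    response <- ifelse(said_old, 4 + grade, 3 - grade)
    nrec <- length(rec_idx)
    rt <- config$rt_shift +
      stats::rlnorm(n_learn + nrec, config$rt_meanlog, config$rt_sdlog)
    iti <- 2.5
    out <- data.frame(
      trial_id = seq_len(n_learn + nrec),
      stimulus_id = c(ids[learn_idx], ids[rec_idx]),
      phase = rep(c("learning", "recognition"), c(n_learn, nrec)),
      old_flag = c(rep(NA, n_learn), old_flag),
      response = c(rep(NA_real_, n_learn), response),
      rt_s = rt,
      onset_s = iti * (seq_len(n_learn + nrec) - 1))
    class(out) <- c("trial_table", "data.frame")
    out
  })
}

#' Simulate a gaze trace over a sequence of fixated objects
#'
#' Produces piecewise-stationary gaze (small isotropic jitter around each
#' object position) joined by ballistic saccadic jumps of fixed duration.
#'
#' @param objects Data.frame with columns `x`, `y` (positions in degrees),
#'   one row per fixated object, in fixation order.
#' @param durations Fixation duration per object, seconds (all > 0).
#' @param config A [synthetic_config()] (`sampling_rate` is used).
#' @param jump_duration Saccade flight time, seconds (default 0.01).
#' @param jitter_sd Fixational jitter SD, degrees (default 0.01; small
#'   relative to the 0.1 degree saccade deflection threshold).
#' @param seed Integer seed.
#' @return List with `gaze` (data.frame `t_s`, `x_deg`, `y_deg`) and
#'   `truth` (planted fixation intervals and saccade count).
#' @export
generate_gaze_trace <- function(objects, durations,
                                config = synthetic_config(),
                                jump_duration = 0.01, jitter_sd = 0.01,
                                seed = config$seed) {
  if (nrow(objects) < 1) stop("need at least one object")
  if (length(durations) != nrow(objects) || any(durations <= 0))
    stop("invalid config: each segment needs a positive duration")
  fs <- config$sampling_rate
  dt <- 1 / fs
  with_seed(seed, {
    t <- numeric(0); x <- numeric(0); y <- numeric(0)
    t0 <- 0
    fix <- data.frame(onset = numeric(0), offset = numeric(0))
    for (k in seq_len(nrow(objects))) {
      nk <- max(2L, round(durations[k] * fs))
      tk <- t0 + (seq_len(nk) - 1) * dt
      x <- c(x, objects$x[k] + stats::rnorm(nk, sd = jitter_sd))
      y <- c(y, objects$y[k] + stats::rnorm(nk, sd = jitter_sd))
      t <- c(t, tk)
      fix <- rbind(fix, data.frame(onset = t0, offset = tk[nk] + dt))
      t0 <- tk[nk] + dt
      if (k < nrow(objects)) {          # ballistic jump to the next object
        nj <- max(2L, round(jump_duration * fs))
        frac <- seq_len(nj) / (nj + 1)
        # smooth (cosine) velocity profile
        s <- (1 - cos(pi * frac)) / 2
        x <- c(x, objects$x[k] + s * (objects$x[k + 1] - objects$x[k]))
        y <- c(y, objects$y[k] + s * (objects$y[k + 1] - objects$y[k]))
        t <- c(t, t0 + (seq_len(nj) - 1) * dt)
        t0 <- t0 + nj * dt
      }
    }
    list(gaze = data.frame(t_s = t, x_deg = x, y_deg = y),
         truth = list(fixations = fix, n_saccades = nrow(objects) - 1L))
  })
}
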