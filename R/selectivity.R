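#' Classify a neuron's category selectivity
#'
#' Two-step procedure. A one-way ANOVA across categories on response-window
#' firing rates identifies neurons with significantly unequal responses
#' (`anova_p < alpha`). The *selected categories* are those whose mean
#' response is at least `sd_factor` (1.5) standard deviations above the mean
#' baseline-window rate; baseline mean and SD are computed across all trials'
#' baseline rates. Neurons passing both screens are single-category (SC) if
#' exactly one category is selected and multiple-category (MC) otherwise.
#' MC neurons are subtyped by where their selected categories live in the 2D
#' feature space: if every selected category's centroid falls inside one
#' connected cluster of the neuron's significant-pixel map (computed without
#' the minimum-cluster-size threshold, so that narrow single peaks are not
#' discarded), the neuron is a *feature MC* neuron; otherwise *non-feature
#' MC*.
#'
#' @param rates Response-window rate per trial (Hz).
#' @param baseline_rates Baseline-window rate per trial (Hz).
#' @param categories Category label per trial (>= 2 categories, each with
#'   >= 2 trials).
#' @param set Optional `stimulus_set`; needed (or `region`) to subtype MC
#'   neurons.
#' @param stimulus_ids Stimulus id per trial (to aggregate repeated
#'   presentations before region detection); defaults to one trial per
#'   stimulus in `set` order when omitted and sizes match.
#' @param region Optional precomputed `tuning_region` obtained with
#'   `min_cluster_fraction = 0`; skips the internal detection.
#' @param config `region_config` for the internal detection (its
#'   `min_cluster_fraction` is forced to 0).
#' @param alpha ANOVA significance level (default 0.05).
#' @param sd_factor Baseline-SD multiplier for the selected-category screen
#'   (default 1.5).
#' @return A `selectivity_profile`: `anova_p`, `selected_categories`,
#'   `class` in `{"SC", "feature-MC", "non-feature-MC", "none"}`, `dprime`,
#'   `dos`, `response_ratio_curve`, `category_means`.
#' @export
classify_selectivity <- function(rates, baseline_rates, categories,
                                 set = NULL, stimulus_ids = NULL,
                                 region = NULL, config = region_config(),
                                 alpha = 0.05, sd_factor = 1.5) {
  categories <- as.character(categories)
  stopifnot(length(rates) == length(categories),
            length(baseline_rates) == length(rates))
  tab <- table(categories)
  if (length(tab) < 2 || any(tab < 2))
    stop("need >= 2 categories with >= 2 trials each")

  cat_means <- tapply(rates, categories, mean)
  anova_p <- if (stats::var(rates) == 0) 1 else
    stats::oneway.test(rates ~ factor(categories), var.equal = TRUE)$p.value

  base_mu <- mean(baseline_rates)
  base_sd <- stats::sd(baseline_rates)
  if (base_sd == 0 && base_mu == 0) {
    message("degenerate baseline (all zero): selecting categories with ",
            "positive mean response")
    selected <- names(cat_means)[cat_means > 0]
  } else {
    selected <- names(cat_means)[cat_means >= base_mu + sd_factor * base_sd]
  }

  class <- "none"
  if (anova_p < alpha && length(selected) >= 1) {
    if (length(selected) == 1) {
      class <- "SC"
    } else {
      class <- mc_subtype(rates, categories, selected, set, stimulus_ids,
                          region, config)
    }
  }
  structure(list(anova_p = anova_p,
                 selected_categories = if (class == "none") character(0)
                                       else selected,
                 class = class,
                 dprime = selectivity_dprime(rates, categories),
                 dos = depth_of_selectivity(cat_means),
                 response_ratio_curve = response_ratio_curve(cat_means),
                 category_means = cat_means),
            class = "selectivity_profile")
}

# feature-MC iff all selected-category centroids fall in a single connected
# cluster of the unthresholded significant-pixel map
mc_subtype <- function(rates, categories, selected, set, stimulus_ids,
                       region, config) {
  if (is.null(set)) {
    warning("MC subtype needs `set` (category centroids); ",
            "returning non-feature-MC")
    return("non-feature-MC")
  }
  if (is.null(region)) {
    if (is.null(stimulus_ids)) {
      if (length(rates) != n_stimuli(set))
        stop("supply stimulus_ids when trials != stimuli")
      stim_rates <- rates
    } else {
      stim_rates <- as.numeric(
        tapply(rates, stimulus_ids, mean)[set$stimulus_id[!set$anchor]])
    }
    cfg <- config
    cfg$min_cluster_fraction <- 0
    region <- detect_tuning_region(set, stim_rates, cfg)
  }
  if (length(region$clusters) == 0) return("non-feature-MC")
  cen <- category_centroids(set)[selected, , drop = FALSE]
  px <- coord_to_pixel(cen, region$resolution)
  membership <- vapply(px, function(p) {
    hit <- which(vapply(region$clusters, function(cl) p %in% cl, TRUE))
    if (length(hit)) hit[1] else NA_integer_
  }, 0L)
  if (anyNA(membership) || length(unique(membership)) != 1)
    "non-feature-MC" else "feature-MC"
}

#' @export
print.selectivity_profile <- function(x, ...) {
  cat(sprintf("selectivity_profile: class %s (ANOVA p = %.3g)\n",
              x$class, x$anova_p))
  if (length(x$selected_categories))
    cat("  selected:", paste(x$selected_categories, collapse = ", "), "\n")
  cat(sprintf("  d' = %.3g, DOS = %.3g\n", x$dprime, x$dos))
  invisible(x)
}

#' Category selectivity index (d-prime)
#'
#' Standardized mean difference between the most-preferred and
#' least-preferred categories:
#' `(mu_best - mu_least) / sqrt((var_best + var_least) / 2)`,
#' with per-category means and population (divide-by-n) variances across
#' exemplars/trials. Non-negative by construction since "best" is the
#' category with the largest mean.
#'
#' @param rates Rate per trial.
#' @param categories Category per trial.
#' @return d-prime, or `NA` when both extreme categories have zero variance.
#' @export
selectivity_dprime <- function(rates, categories) {
  mu <- tapply(rates, categories, mean)
  if (length(mu) < 2) stop("need >= 2 categories")
  pop_var <- function(x) mean((x - mean(x))^2)
  v <- tapply(rates, categories, pop_var)
  b <- which.max(mu); w <- which.min(mu)
  denom <- sqrt((v[b] + v[w]) / 2)
  if (denom == 0) {
    message("d-prime undefined: zero variance in extreme categories")
    return(NA_real_)
  }
  unname((mu[b] - mu[w]) / denom)
}

#' Depth of selectivity (DOS) index
#'
#' `(n - sum(r) / r_max) / (n - 1)` over per-category mean rates; 0 for an
#' equal response to all categories, 1 for an exclusive response to one.
#'
#' @param mean_rates Mean rate per category (length >= 2).
#' @return DOS in \[0, 1\], or `NA` when all rates are 0.
#' @export
depth_of_selectivity <- function(mean_rates) {
  n <- length(mean_rates)
  if (n < 2) stop("need >= 2 categories")
  rmax <- max(mean_rates)
  if (rmax <= 0) {
    message("DOS undefined: all rates zero")
    return(NA_real_)
  }
  (n - sum(mean_rates) / rmax) / (n - 1)
}

#' Ordered response-ratio curve
#'
#' Per-category mean rates divided by the most-preferred category's rate and
#' sorted from most to least preferred; the first entry is 1 and the curve is
#' non-increasing. Steeper decay indicates stronger category selectivity.
#'
#' @param mean_rates Mean rate per category.
#' @return Numeric vector of fractions, descending.
#' @export
response_ratio_curve <- function(mean_rates) {
  rmax <- max(mean_rates)
  if (rmax <= 0) stop("max rate must be positive")
  sort(mean_rates / rmax, decreasing = TRUE)
}

#' Test an axis-coding model for a neuron
#'
#' Fits a cross-validated partial least squares (PLS) regression of the
#' neuron's responses on the high-dimensional stimulus features. The observed
#' statistic is the Pearson correlation between held-out predictions and
#' actual responses for a random 50/50 train/test split. The null
#' distribution comes from `n_permutations` runs in which responses are
#' shuffled before a fresh split/fit/predict cycle; the model is significant
#' when the observed correlation exceeds the 95th percentile of the null.
#' The default of one observed split keeps the observed statistic
#' exchangeable with the null draws under the null hypothesis (so the
#' selection rate is calibrated at 5%); `n_splits > 1` averages splits for a
#' more stable correlation estimate at the price of a conservative test.
#'
#' @param features n x d numeric feature matrix.
#' @param responses Numeric response per stimulus.
#' @param n_components PLS components (default 10); reduced with a warning
#'   when the training set is too small.
#' @param n_permutations Null permutations (default 1000).
#' @param split_fraction Training fraction (default 0.5).
#' @param n_splits Random splits averaged for the observed statistic
#'   (default 1; see above).
#' @param seed Integer seed.
#' @return An `axis_model` list: `observed_r`, `null_r`, `significant`,
#'   `threshold` (null 95th percentile), `n_components`.
#' @export
fit_axis_model <- function(features, responses, n_components = 10,
                           n_permutations = 1000, split_fraction = 0.5,
                           n_splits = 1, seed = 1) {
  features <- as.matrix(features)
  n <- nrow(features)
  stopifnot(length(responses) == n)
  if (n <= 2 * n_components)
    stop("need more than 2 * n_components stimuli")
  ntrain <- round(split_fraction * n)
  ncomp <- min(n_components, ntrain - 1, ncol(features))
  if (ncomp < n_components)
    warning("reduced n_components to ", ncomp)
  split_r <- function(y) {
    tr <- sample.int(n, ntrain)
    fit <- simpls_fit(features[tr, , drop = FALSE], y[tr], ncomp)
    pred <- simpls_predict(fit, features[-tr, , drop = FALSE])
    if (stats::sd(pred) == 0 || stats::sd(y[-tr]) == 0) 0 else
      stats::cor(pred, y[-tr])
  }
  with_seed(seed, {
    observed_r <- mean(vapply(seq_len(n_splits), function(i)
      split_r(responses), 0))
    null_r <- vapply(seq_len(n_permutations), function(i)
      split_r(sample(responses)), 0)
  })
  threshold <- stats::quantile(null_r, 0.95, names = FALSE)
  structure(list(observed_r = observed_r, null_r = null_r,
                 significant = observed_r > threshold,
                 threshold = threshold, n_components = ncomp),
            class = "axis_model")
}

#' @export
print.axis_model <- function(x, ...) {
  cat(sprintf(
    "axis_model: r = %.3f (null 95th pct %.3f) -> %ssignificant\n",
    x$observed_r, x$threshold, if (x$significant) "" else "not "))
  invisible(x)
}

# SIMPLS partial least squares with a univariate response.
# Small and allocation-light because the permutation engine refits it
# thousands of times per neuron.
simpls_fit <- function(X, y, ncomp) {
  mx <- colMeans(X)
  Xc <- sweep(X, 2, mx)
  my <- mean(y)
  y0 <- y - my
  p <- ncol(X)
  W <- matrix(0, p, ncomp)
  V <- matrix(0, p, ncomp)
  Q <- numeric(ncomp)
  s <- crossprod(Xc, y0)
  a <- 0L
  for (k in seq_len(ncomp)) {
    r <- s
    t <- drop(Xc %*% r)
    nt <- sqrt(sum(t^2))
    if (nt < 1e-12) break
    t <- t / nt
    r <- r / nt
    pv <- crossprod(Xc, t)
    v <- pv
    if (k > 1) {
      Vk <- V[, seq_len(k - 1), drop = FALSE]
      v <- v - Vk %*% crossprod(Vk, pv)
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) break
    v <- v / nv
    a <- k
    W[, k] <- r
    V[, k] <- v
    Q[k] <- sum(y0 * t)
    s <- s - v * drop(crossprod(v, s))
  }
  if (a == 0L) return(list(coef = rep(0, p), x_center = mx, y_center = my))
  list(coef = drop(W[, seq_len(a), drop = FALSE] %*% Q[seq_len(a)]),
       x_center = mx, y_center = my)
}

simpls_predict <- function(fit, Xnew) {
  drop(sweep(as.matrix(Xnew), 2, fit$x_center) %*% fit$coef) + fit$y_center
}
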