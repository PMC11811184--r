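#' Configuration for sliding-window population decoding
#'
#' Defaults follow the standard protocol: 500 ms bins advanced in 50 ms
#' steps, the first bin starting 500 ms before stimulus onset, 31 consecutive
#' bins (the last covering 1000-1500 ms post-onset), 8-fold cross-validation
#' repeated 50 times with fresh random partitions.
#'
#' @param bin_width Bin size, seconds.
#' @param step Bin step, seconds.
#' @param first_start Start of the first bin relative to onset, seconds.
#' @param n_bins Number of bins (>= 1).
#' @param folds Cross-validation folds (>= 2).
#' @param repeats Cross-validation repetitions.
#' @param seed Integer seed for fold assignment.
#' @return A list of class `decoding_config`.
#' @export
decoding_config <- function(bin_width = 0.5, step = 0.05,
                            first_start = -0.5, n_bins = 31,
                            folds = 8, repeats = 50, seed = 1) {
  stopifnot(folds >= 2, n_bins >= 1, bin_width > 0, repeats >= 1)
  structure(as.list(environment()), class = "decoding_config")
}

#' Assemble a pseudo-population rate tensor
#'
#' Stacks a list of neuron recordings that share the same trial structure
#' (same stimuli in the same order, as produced by simulating a session) into
#' a trial x neuron x bin firing-rate array with one category label per
#' trial. Neurons recorded in separate sessions can be pooled this way
#' because the classifier only uses per-class means.
#'
#' @param neurons List of `neuron_recording` objects.
#' @param config A [decoding_config()].
#' @return A `pseudo_population`: `rates` (trial x neuron x bin array),
#'   `labels` (factor), `bin_centers` (seconds).
#' @export
build_pseudo_population <- function(neurons, config = decoding_config()) {
  stopifnot(length(neurons) >= 1)
  # align trials across neurons by stimulus identity (k-th presentation of
  # each stimulus), so that neurons recorded with independently shuffled
  # presentation orders can be pooled
  align <- lapply(neurons, function(nr) {
    occ <- stats::ave(seq_len(nrow(nr$trials)), nr$trials$stimulus_id,
                      FUN = seq_along)
    order(nr$trials$stimulus_id, occ)
  })
  ref <- neurons[[1]]$trials$stimulus_id[align[[1]]]
  for (j in seq_along(neurons))
    if (!identical(neurons[[j]]$trials$stimulus_id[align[[j]]], ref))
      stop("all neurons must share the same stimulus x presentation set")
  starts <- config$first_start + config$step * (seq_len(config$n_bins) - 1)
  ntr <- length(ref)
  rates <- array(0, dim = c(ntr, length(neurons), config$n_bins))
  for (j in seq_along(neurons)) {
    sp <- neurons[[j]]$spikes
    for (b in seq_len(config$n_bins)) {
      inb <- sp$t >= starts[b] & sp$t < starts[b] + config$bin_width
      rates[, j, b] <- (tabulate(sp$trial_id[inb], nbins = ntr) /
                          config$bin_width)[align[[j]]]
    }
  }
  structure(list(rates = rates,
                 labels = factor(neurons[[1]]$trials$category[align[[1]]]),
                 bin_centers = starts + config$bin_width / 2),
            class = "pseudo_population")
}

#' Maximum-correlation-coefficient classifier
#'
#' Estimates a mean activity template per class from the training trials and
#' assigns each test trial to the class whose template has the highest
#' Pearson correlation (across neurons) with the test activity vector. Ties
#' and undefined correlations (zero-variance vectors) fall back to the
#' lowest class index.
#'
#' @param train Training matrix, trials x neurons.
#' @param labels Class label per training trial (every class >= 1 trial).
#' @param test Test matrix, trials x neurons.
#' @return Character vector of predicted labels, one per test trial.
#' @export
mcc_classify <- function(train, labels, test) {
  train <- as.matrix(train); test <- as.matrix(test)
  labels <- factor(labels)
  if (any(table(labels) < 1)) stop("every class needs a training trial")
  templates <- rowsum(train, labels) / as.vector(table(labels))
  C <- suppressWarnings(stats::cor(t(test), t(templates)))
  if (anyNA(C)) {
    message("zero-variance vector(s): undefined correlations broken by ",
            "lowest class index")
    C[is.na(C)] <- -Inf
  }
  levels(labels)[max.col(C, ties.method = "first")]
}

#' Sliding-window decoding of object category from a pseudo-population
#'
#' For each time bin, stratified k-fold cross-validated MCC accuracy, with
#' the whole procedure repeated with fresh random partitions. Each neuron is
#' z-scored using means/SDs estimated on the training folds only (applied
#' unchanged to the test fold). Per-bin significance against chance is the
#' fraction of repeats with accuracy at or below chance, thresholded at 0.05
#' and FDR-corrected across bins.
#'
#' @param pop A `pseudo_population`.
#' @param config A [decoding_config()].
#' @return A `decoding_result`: `bin_centers`, `accuracy` (mean per bin),
#'   `repeat_accuracy` (repeats x bins matrix), `chance`, `p_below_chance`,
#'   `significant` (FDR mask), `n_trials`, `n_classes`.
#' @export
sliding_decoding <- function(pop, config = decoding_config()) {
  rates <- pop$rates
  labels <- droplevels(factor(pop$labels))
  tab <- table(labels)
  if (any(tab < config$folds)) {
    drop <- names(tab)[tab < config$folds]
    warning("dropping classes with fewer trials than folds: ",
            paste(drop, collapse = ", "))
    keep <- !(labels %in% drop)
    rates <- rates[keep, , , drop = FALSE]
    labels <- droplevels(labels[keep])
  }
  n <- length(labels)
  nb <- dim(rates)[3]
  acc <- matrix(NA_real_, config$repeats, nb)
  with_seed(config$seed, {
    for (rep in seq_len(config$repeats)) {
      fold <- stratified_folds(labels, config$folds)
      for (b in seq_len(nb)) {
        X <- rates[, , b, drop = FALSE]
        dim(X) <- dim(rates)[1:2]
        pred <- character(n)
        for (f in seq_len(config$folds)) {
          tr <- fold != f
          mu <- colMeans(X[tr, , drop = FALSE])
          sd <- apply(X[tr, , drop = FALSE], 2, stats::sd)
          sd[sd == 0] <- 1
          Z <- sweep(sweep(X, 2, mu), 2, sd, `/`)
          pred[!tr] <- mcc_classify(Z[tr, , drop = FALSE], labels[tr],
                                    Z[!tr, , drop = FALSE])
        }
        acc[rep, b] <- mean(pred == as.character(labels))
      }
    }
  })
  chance <- 1 / nlevels(labels)
  p_below <- colMeans(acc <= chance)
  structure(list(bin_centers = pop$bin_centers, accuracy = colMeans(acc),
                 repeat_accuracy = acc, chance = chance,
                 p_below_chance = p_below,
                 significant = p_below < 0.05 & bh_fdr(p_below, 0.05),
                 n_trials = n, n_classes = nlevels(labels)),
            class = "decoding_result")
}

# balanced fold labels within each class
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(sample.int(k), length(idx)))
  }
  fold
}

#' Compare decoding accuracy between two neuron groups
#'
#' Per-bin significance is the fraction of paired cross-validation repeats in
#' which group A does not exceed group B, thresholded at 0.05 and
#' FDR-corrected across bins.
#'
#' @param a,b `decoding_result` objects with equal repeats and bins.
#' @return List with `p_a_not_greater` per bin and `significant` mask.
#' @export
compare_decoding <- function(a, b) {
  stopifnot(all(dim(a$repeat_accuracy) == dim(b$repeat_accuracy)))
  p <- colMeans(a$repeat_accuracy <= b$repeat_accuracy)
  list(p_a_not_greater = p, significant = p < 0.05 & bh_fdr(p, 0.05))
}

#' Subsample neurons from a pseudo-population
#'
#' Used to match neuron counts when comparing decoding between groups of
#' different sizes.
#'
#' @param pop A `pseudo_population`.
#' @param n Number of neurons to keep.
#' @param seed Integer seed.
#' @return A `pseudo_population` with `n` neurons.
#' @export
subsample_neurons <- function(pop, n, seed = 1) {
  stopifnot(n >= 1, n <= dim(pop$rates)[2])
  keep <- with_seed(seed, sample.int(dim(pop$rates)[2], n))
  structure(list(rates = pop$rates[, keep, , drop = FALSE],
                 labels = pop$labels, bin_centers = pop$bin_centers),
            class = "pseudo_population")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf(
    "decoding_result: %d classes, %d trials, %d bins; peak accuracy %.3f (chance %.3f)\n",
    x$n_classes, x$n_trials, length(x$accuracy), max(x$accuracy), x$chance))
  invisible(x)
}
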