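#' Construct a stimulus set
#'
#' Bundles stimulus identifiers, category labels, 2D feature-space coordinates
#' and (optionally) the high-dimensional feature vectors the coordinates were
#' derived from. Coordinates are expected in the unit square; use
#' [embed_features()] or [normalize_coords()] to get there.
#'
#' @param stimulus_id Character vector of unique ids.
#' @param category Character vector of category labels (non-empty strings).
#' @param coords n x 2 numeric matrix of feature-space positions.
#' @param features Optional n x d numeric matrix of high-dimensional features.
#' @param memorability Optional numeric vector in \[0, 1\].
#' @param anchor Optional logical vector flagging corner pseudo-stimuli that
#'   anchor the space but are excluded from statistics.
#' @return An object of class `stimulus_set`.
#' @export
stimulus_set <- function(stimulus_id, category, coords, features = NULL,
                         memorability = NULL, anchor = NULL) {
  stimulus_id <- as.character(stimulus_id)
  category <- as.character(category)
  coords <- as.matrix(coords)
  n <- length(stimulus_id)
  if (anyDuplicated(stimulus_id)) stop("stimulus ids must be unique")
  if (length(category) == 1) category <- rep(category, n)
  if (length(category) != n) stop("category must match stimulus_id length")
  if (any(!nzchar(category))) stop("category labels must be non-empty")
  if (nrow(coords) != n || ncol(coords) != 2)
    stop("coords must be an n x 2 matrix")
  if (!is.null(features)) {
    features <- as.matrix(features)
    if (nrow(features) != n) stop("features must have one row per stimulus")
  }
  if (!is.null(memorability)) {
    stopifnot(length(memorability) == n,
              all(memorability >= 0 & memorability <= 1, na.rm = TRUE))
  }
  if (is.null(anchor)) anchor <- rep(FALSE, n)
  structure(list(stimulus_id = stimulus_id, category = category,
                 coords = coords, features = features,
                 memorability = memorability, anchor = anchor),
            class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("stimulus_set: %d stimuli, %d categories%s%s\n",
              n_stimuli(x), length(unique(x$category[!x$anchor])),
              if (is.null(x$features)) "" else
                sprintf(", %d-D features", ncol(x$features)),
              if (any(x$anchor)) sprintf(", %d anchors", sum(x$anchor)) else ""))
  invisible(x)
}

#' Number of (real, non-anchor) stimuli in a set
#' @param set A `stimulus_set`.
#' @export
n_stimuli <- function(set) sum(!set$anchor)

#' Min-max normalize 2D coordinates into the unit square
#'
#' Each axis is rescaled so that its minimum maps to 0 and its maximum to 1.
#' Idempotent on already-normalized input.
#'
#' @param coords n x 2 numeric matrix.
#' @return n x 2 matrix with per-axis range \[0, 1\].
#' @export
normalize_coords <- function(coords) {
  coords <- as.matrix(coords)
  apply(coords, 2, function(v) {
    r <- range(v)
    if (r[2] == r[1]) rep(0.5, length(v)) else (v - r[1]) / (r[2] - r[1])
  })
}

#' Embed high-dimensional stimulus features into a 2D feature space
#'
#' Delegates dimensionality reduction to a configurable method and min-max
#' rescales the result into the unit square. The analysis pipeline is
#' deliberately agnostic to the reducer: region detection operates on the 2D
#' coordinates only, and results should be qualitatively robust across
#' reduction methods.
#'
#' * `"none"`: input must already be 2D; only min-max normalization is applied
#'   (the reference path for testing, and for data with precomputed layouts).
#' * `"pca"`: first two principal components via [stats::prcomp()].
#' * `"tsne"` / `"umap"`: dispatched to `Rtsne::Rtsne` / `uwot::umap` when
#'   those packages are installed; otherwise an informative error.
#'
#' @param features n x d numeric matrix (finite values).
#' @param method One of `"none"`, `"pca"`, `"tsne"`, `"umap"`.
#' @param params Named list of extra arguments for the reducer (e.g.
#'   `perplexity` for t-SNE).
#' @param seed Integer seed; reduction is deterministic given the seed.
#' @param corner_anchored If `TRUE`, four pseudo-stimulus rows are appended at
#'   the corners of the unit square after normalization. These anchor the
#'   space so that it stays comparable across stimulus subsets (e.g. task
#'   phases) and must be excluded from all downstream statistics; the returned
#'   `anchor` flag marks them.
#' @return A list of class `feature_space` with elements `coords` (m x 2,
#'   in \[0,1\]^2), `anchor` (logical), `method`, `params`.
#' @export
embed_features <- function(features, method = c("none", "pca", "tsne", "umap"),
                           params = list(), seed = 1,
                           corner_anchored = FALSE) {
  method <- match.arg(method)
  features <- as.matrix(features)
  if (nrow(features) < 3) stop("need at least 3 stimuli to build a space")
  if (!all(is.finite(features))) stop("features must be finite")
  coords <- switch(method,
    none = {
      if (ncol(features) != 2)
        stop("method 'none' requires 2D input coordinates")
      features
    },
    pca = with_seed(seed, {
      stats::prcomp(features, center = TRUE, scale. = FALSE)$x[, 1:2]
    }),
    tsne = {
      if (!requireNamespace("Rtsne", quietly = TRUE))
        stop("method 'tsne' requires the Rtsne package; ",
             "use method 'pca' or 'none', or install Rtsne")
      with_seed(seed, do.call(Rtsne::Rtsne,
        c(list(X = features, dims = 2), params))$Y)
    },
    umap = {
      if (!requireNamespace("uwot", quietly = TRUE))
        stop("method 'umap' requires the uwot package; ",
             "use method 'pca' or 'none', or install uwot")
      with_seed(seed, do.call(uwot::umap, c(list(X = features), params)))
    })
  coords <- normalize_coords(coords)
  anchor <- rep(FALSE, nrow(coords))
  if (corner_anchored) {
    corners <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
    coords <- rbind(coords, corners)
    anchor <- c(anchor, rep(TRUE, 4))
  }
  rownames(coords) <- NULL
  structure(list(coords = coords, anchor = anchor, method = method,
                 params = params), class = "feature_space")
}

#' Build the valid-pixel mask of the analysis grid
#'
#' Density estimates at pixels far from every stimulus are dominated by the
#' tails of the smoothing kernel and are prone to false positives, so edge and
#' corner pixels with no nearby stimuli are masked out. A pixel is valid iff
#' its center lies within `mask_radius_factor * kernel_sd` of at least one
#' (non-anchor) stimulus coordinate.
#'
#' @param set A `stimulus_set` (or any list with `$coords` and `$anchor`).
#' @param kernel_sd Smoothing-kernel SD in unit-square units (> 0).
#' @param resolution Pixels per axis (default 100).
#' @param mask_radius_factor Multiple of `kernel_sd` defining "near" (default 2).
#' @return A `grid_mask`: list with `valid` (resolution x resolution logical
#'   matrix, rows = x index, cols = y index), `resolution`, `kernel_sd`,
#'   `mask_radius_factor`, `n_valid`.
#' @export
build_grid_mask <- function(set, kernel_sd, resolution = 100,
                            mask_radius_factor = 2) {
  if (kernel_sd <= 0) stop("kernel_sd must be positive")
  if (resolution < 2) stop("resolution must be at least 2")
  xy <- set$coords[!set$anchor, , drop = FALSE]
  centers <- (seq_len(resolution) - 0.5) / resolution
  # squared distance from every pixel center to its nearest stimulus
  dx2 <- outer(centers, xy[, 1], `-`)^2   # res x n
  dy2 <- outer(centers, xy[, 2], `-`)^2
  r2 <- (mask_radius_factor * kernel_sd)^2
  valid <- matrix(FALSE, resolution, resolution)
  for (j in seq_len(resolution)) {
    # pixel (i, j): min_i' dx2[i, i'] + dy2[j, i']
    valid[, j] <- matrixStats_rowMins(sweep(dx2, 2, dy2[j, ], `+`)) <= r2
  }
  if (!any(valid)) stop("mask is empty: kernel_sd/mask_radius_factor too small")
  structure(list(valid = valid, resolution = resolution,
                 kernel_sd = kernel_sd,
                 mask_radius_factor = mask_radius_factor,
                 n_valid = sum(valid)),
            class = "grid_mask")
}

# row minima without extra deps
matrixStats_rowMins <- function(m) do.call(pmin, as.data.frame(m))

#' Normalized feature-space distance between two category centroids
#'
#' Euclidean distance between the mean 2D coordinates of the two categories,
#' divided by the unit-square diagonal (sqrt(2)) so that the result lies in
#' \[0, 1\].
#'
#' @param set A `stimulus_set`.
#' @param cat_a,cat_b Category labels.
#' @return Scalar in \[0, 1\]; symmetric in its arguments.
#' @export
normalized_category_distance <- function(set, cat_a, cat_b) {
  keep <- !set$anchor
  for (cc in c(cat_a, cat_b))
    if (!any(set$category[keep] == cc)) stop("unknown category: ", cc)
  ca <- colMeans(set$coords[keep & set$category == cat_a, , drop = FALSE])
  cb <- colMeans(set$coords[keep & set$category == cat_b, , drop = FALSE])
  sqrt(sum((ca - cb)^2)) / sqrt(2)
}

#' Mean full-feature distances among selected and non-selected categories
#'
#' For a neuron with a set of selected categories, computes the mean
#' normalized Euclidean distance between category-mean high-dimensional
#' feature vectors over all selected-selected (S-S) pairs and over all
#' selected-nonselected (S-NS) pairs. Distances are normalized by the maximum
#' pairwise distance between category means, so values lie in \[0, 1\].
#' Neurons whose selected categories cluster in feature space have S-S < S-NS.
#'
#' @param features n x d matrix of stimulus features.
#' @param category Category label per stimulus.
#' @param selected Character vector of the neuron's selected categories
#'   (>= 2), all present in `category`.
#' @return List with `ss` and `sns` mean normalized distances.
#' @export
full_feature_distance <- function(features, category, selected) {
  selected <- unique(as.character(selected))
  if (length(selected) < 2) stop("need >= 2 selected categories")
  cats <- unique(category)
  if (!all(selected %in% cats)) stop("selected categories must be present")
  if (length(setdiff(cats, selected)) < 1)
    stop("need >= 1 non-selected category")
  means <- t(vapply(cats, function(cc)
    colMeans(features[category == cc, , drop = FALSE]),
    numeric(ncol(features))))
  dmat <- as.matrix(stats::dist(means))
  dimnames(dmat) <- list(cats, cats)
  dmax <- max(dmat)
  if (dmax == 0) return(list(ss = 0, sns = 0))
  dmat <- dmat / dmax
  ns <- setdiff(cats, selected)
  ss_pairs <- utils::combn(selected, 2)
  ss <- mean(dmat[cbind(ss_pairs[1, ], ss_pairs[2, ])])
  sns <- mean(dmat[selected, ns])
  list(ss = ss, sns = sns)
}

# run expr under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}
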