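#' Configuration for tuning-region detection
#'
#' @param resolution Grid pixels per axis (default 100).
#' @param sq Empirical kernel scaling factor; the smoothing-kernel SD is
#'   `sq` times the unit-square side. Published per-dataset presets are in
#'   [sq_presets].
#' @param n_permutations Label permutations for the per-pixel null
#'   (default 1000).
#' @param pixel_alpha Per-pixel significance level (default 0.01).
#' @param min_cluster_fraction Minimum cluster size as a fraction of masked
#'   pixels (default 0.025); clusters must be strictly larger to survive.
#'   Set to 0 to keep all significant pixels (used when comparing
#'   category-selective subtypes).
#' @param connectivity Pixel adjacency for clustering, 4 or 8 (default 4).
#' @param mask_radius_factor Passed to [build_grid_mask()].
#' @param cluster_correction If `TRUE`, an additional cluster-level correction
#'   is applied: surviving clusters must have summed observed density
#'   exceeding the 95th percentile of the largest null-cluster mass across
#'   permutations. Off by default.
#' @param seed Integer seed for the permutations.
#' @return A list of class `region_config`.
#' @export
region_config <- function(resolution = 100, sq = 0.021,
                          n_permutations = 1000, pixel_alpha = 0.01,
                          min_cluster_fraction = 0.025, connectivity = 4,
                          mask_radius_factor = 2,
                          cluster_correction = FALSE, seed = 1) {
  stopifnot(pixel_alpha > 0, pixel_alpha < 1,
            n_permutations >= 1,
            min_cluster_fraction >= 0, min_cluster_fraction < 1,
            connectivity %in% c(4, 8), sq > 0)
  structure(list(resolution = resolution, sq = sq,
                 n_permutations = n_permutations, pixel_alpha = pixel_alpha,
                 min_cluster_fraction = min_cluster_fraction,
                 connectivity = connectivity,
                 mask_radius_factor = mask_radius_factor,
                 cluster_correction = cluster_correction, seed = seed),
            class = "region_config")
}

#' Published kernel scaling factors per feature space
#'
#' Empirical `sq` values for the four stimulus sets the method was developed
#' on: 500 ImageNet objects, 500 COCO objects, the phased recognition-memory
#' stimuli and the continuous recognition-memory scenes.
#' @export
sq_presets <- c(imagenet = 0.021, coco = 0.05, phased = 0.11,
                continuous = 0.03)

#' Precompute the smoothing grid for a stimulus set
#'
#' Builds the grid mask and the kernel weight matrix mapping per-stimulus
#' responses to masked-pixel density values. Detection for many neurons on
#' the same stimulus set should reuse this object: it is by far the most
#' expensive part of the setup.
#'
#' @param set A `stimulus_set`.
#' @param config A `region_config`.
#' @return A list of class `region_grid` with `mask`, `kernel` (n_valid x n
#'   matrix), `pixel_index` (linear indices of masked pixels, column-major),
#'   `stim_pixel` (linear pixel index per stimulus), `config`.
#' @export
region_grid <- function(set, config = region_config()) {
  sd <- config$sq                       # kernel SD in unit-square units
  mask <- build_grid_mask(set, kernel_sd = sd,
                          resolution = config$resolution,
                          mask_radius_factor = config$mask_radius_factor)
  res <- config$resolution
  keep <- !set$anchor
  xy <- set$coords[keep, , drop = FALSE]
  centers <- (seq_len(res) - 0.5) / res
  pix <- which(mask$valid)              # linear, column-major
  px <- centers[(pix - 1) %% res + 1]
  py <- centers[(pix - 1) %/% res + 1]
  # unnormalized isotropic Gaussian weights, pixel x stimulus
  kernel <- exp(-(outer(px, xy[, 1], `-`)^2 + outer(py, xy[, 2], `-`)^2) /
                  (2 * sd^2))
  structure(list(mask = mask, kernel = kernel, pixel_index = pix,
                 stim_pixel = coord_to_pixel(xy, res), config = config,
                 stimulus_id = set$stimulus_id[keep],
                 category = set$category[keep]),
            class = "region_grid")
}

#' Map unit-square coordinates to linear pixel indices
#'
#' Pixel `(i, j)` covers the half-open square `[(i-1)/R, i/R) x [(j-1)/R, j/R)`
#' per axis; coordinates exactly at 1 are assigned to the last pixel.
#'
#' @param coords n x 2 matrix in \[0, 1\]^2.
#' @param resolution Pixels per axis.
#' @return Integer vector of column-major linear indices.
#' @export
coord_to_pixel <- function(coords, resolution) {
  ij <- pmin(pmax(floor(coords * resolution), 0), resolution - 1)
  as.integer(ij[, 1] + 1 + ij[, 2] * resolution)
}

#' Smoothed response density map
#'
#' The discrete firing-rate map (one response at each stimulus coordinate) is
#' smoothed with an isotropic 2D Gaussian kernel:
#' `map(p) = sum_i r_i * exp(-||p - x_i||^2 / (2 sd^2))`.
#' The map is linear in the responses and is reported on the full grid
#' (masking happens at detection time).
#'
#' @param set A `stimulus_set`.
#' @param responses Numeric response per (non-anchor) stimulus.
#' @param kernel_sd Kernel SD in unit-square units.
#' @param resolution Pixels per axis (default 100).
#' @return resolution x resolution numeric matrix (rows = x, cols = y).
#' @export
response_map <- function(set, responses, kernel_sd, resolution = 100) {
  if (kernel_sd <= 0) stop("kernel_sd must be positive")
  xy <- set$coords[!set$anchor, , drop = FALSE]
  if (length(responses) != nrow(xy))
    stop("need one response per stimulus")
  if (!all(is.finite(responses))) stop("responses must be finite")
  centers <- (seq_len(resolution) - 0.5) / resolution
  gx <- exp(-outer(centers, xy[, 1], `-`)^2 / (2 * kernel_sd^2))
  gy <- exp(-outer(centers, xy[, 2], `-`)^2 / (2 * kernel_sd^2))
  gx %*% (responses * t(gy))            # separable kernel
}

#' Detect a neuron's tuning region in the 2D feature space
#'
#' The observed smoothed density map is compared, pixel by pixel, to a null
#' ensemble obtained by randomly permuting the responses across stimulus
#' coordinates (breaking any relation between response and feature-space
#' position while keeping the response distribution and the stimulus layout).
#' Per-pixel p-values use the add-one estimator
#' `p = (1 + #\{null >= observed\}) / (1 + n_permutations)`, so constant
#' response vectors get p = 1 everywhere. Pixels with `p < pixel_alpha`
#' inside the mask are grouped into connected clusters; clusters not larger
#' than `min_cluster_fraction` of the masked pixels are discarded. A neuron
#' with at least one surviving cluster is a *feature neuron* and the union of
#' surviving clusters is its *tuning region*.
#'
#' @param set A `stimulus_set` (ignored when `grid` is supplied).
#' @param responses Numeric response per stimulus (e.g. mean firing rate
#'   250-1250 ms post-onset).
#' @param config A `region_config`.
#' @param grid Optional precomputed [region_grid()] to reuse across neurons.
#' @return A `tuning_region` object: `pixels` (linear indices of the tuning
#'   region), `clusters` (list of pixel-index vectors), `area_fraction`
#'   (region size / masked pixels), `member_ids` / `categories` (stimuli and
#'   categories inside the region), `p_values` (full-grid matrix, NA outside
#'   the mask), `detected` flag, `mask`, `resolution`.
#' @export
detect_tuning_region <- function(set = NULL, responses,
                                 config = region_config(), grid = NULL) {
  if (is.null(grid)) grid <- region_grid(set, config)
  cfg <- grid$config
  n <- ncol(grid$kernel)
  responses <- as.numeric(responses)
  if (length(responses) != n) stop("need one response per stimulus")
  if (!all(is.finite(responses))) stop("responses must be finite")

  observed <- drop(grid$kernel %*% responses)
  if (max(responses) == min(responses)) {
    message("constant responses: permutation-invariant map, no region")
    pvals <- rep(1, length(observed))
    return(new_tuning_region(integer(0), list(), grid, pvals))
  }
  nperm <- cfg$n_permutations
  perm <- with_seed(cfg$seed,
    matrix(responses[vapply(seq_len(nperm), function(i) sample.int(n),
                            integer(n))], nrow = n))
  null_maps <- grid$kernel %*% perm     # n_valid x nperm
  exceed <- rowSums(null_maps >= observed)
  pvals <- (1 + exceed) / (1 + nperm)

  sig <- pvals < cfg$pixel_alpha
  clusters <- list()
  if (any(sig)) {
    labels <- label_grid_components(grid$pixel_index[sig], cfg$resolution,
                                    cfg$connectivity)
    clusters <- split(grid$pixel_index[sig], labels)
    min_size <- cfg$min_cluster_fraction * grid$mask$n_valid
    clusters <- clusters[vapply(clusters, length, 0L) > min_size]
    if (cfg$cluster_correction && length(clusters)) {
      clusters <- cluster_mass_filter(clusters, observed, null_maps, grid, cfg)
    }
    names(clusters) <- NULL
  }
  new_tuning_region(sort(unlist(clusters, use.names = FALSE)), clusters,
                    grid, pvals)
}

# optional cluster-level correction: observed cluster mass must exceed the
# 95th percentile of the maximum null-cluster mass
cluster_mass_filter <- function(clusters, observed, null_maps, grid, cfg) {
  obs_mass <- vapply(clusters, function(px)
    sum(observed[match(px, grid$pixel_index)]), 0)
  null_max <- apply(null_maps, 2, function(nm) {
    thr <- stats::quantile(nm, 1 - cfg$pixel_alpha, names = FALSE)
    sig <- nm > thr
    if (!any(sig)) return(0)
    lab <- label_grid_components(grid$pixel_index[sig], cfg$resolution,
                                 cfg$connectivity)
    max(vapply(split(nm[sig], lab), sum, 0))
  })
  clusters[obs_mass > stats::quantile(null_max, 0.95, names = FALSE)]
}

new_tuning_region <- function(pixels, clusters, grid, pvals) {
  pmat <- matrix(NA_real_, grid$config$resolution, grid$config$resolution)
  pmat[grid$pixel_index] <- pvals
  inside <- grid$stim_pixel %in% pixels
  structure(list(
    pixels = as.integer(pixels), clusters = clusters,
    area_fraction = length(pixels) / grid$mask$n_valid,
    member_ids = grid$stimulus_id[inside],
    categories = unique(grid$category[inside]),
    p_values = pmat, detected = length(clusters) > 0,
    mask = grid$mask, resolution = grid$config$resolution),
    class = "tuning_region")
}

#' @export
print.tuning_region <- function(x, ...) {
  if (!x$detected) {
    cat("tuning_region: none detected\n")
  } else {
    cat(sprintf(
      "tuning_region: %d cluster(s), %d pixels (%.1f%% of mask), %d stimuli, %d categories\n",
      length(x$clusters), length(x$pixels), 100 * x$area_fraction,
      length(x$member_ids), length(x$categories)))
  }
  invisible(x)
}

# connected-component labels for a set of linear pixel indices on an R x R
# grid; BFS with 4- or 8-neighborhood
label_grid_components <- function(pixels, resolution, connectivity = 4) {
  np <- length(pixels)
  if (np == 0) return(integer(0))
  idx <- integer(resolution * resolution)
  idx[pixels] <- seq_len(np)            # position of each pixel in `pixels`
  ix <- (pixels - 1) %% resolution + 1
  iy <- (pixels - 1) %/% resolution + 1
  off <- if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(rep(c(-1, 0, 1), 3), rep(c(-1, 0, 1), each = 3))[-5, ]
  }
  labels <- integer(np)
  current <- 0L
  queue <- integer(np)
  for (s in seq_len(np)) {
    if (labels[s] > 0L) next
    current <- current + 1L
    labels[s] <- current
    queue[1] <- s; head <- 1L; tail <- 1L
    while (head <= tail) {
      k <- queue[head]; head <- head + 1L
      nx <- ix[k] + off[, 1]; ny <- iy[k] + off[, 2]
      ok <- nx >= 1 & nx <= resolution & ny >= 1 & ny <= resolution
      nb <- idx[nx[ok] + (ny[ok] - 1) * resolution]
      nb <- nb[nb > 0L]
      nb <- nb[labels[nb] == 0L]
      if (length(nb)) {
        labels[nb] <- current
        queue[(tail + 1L):(tail + length(nb))] <- nb
        tail <- tail + length(nb)
      }
    }
  }
  labels
}

#' Partition stimuli by tuning-region membership
#'
#' @param region A `tuning_region`.
#' @param set A `stimulus_set` on the same grid/space.
#' @return List with `in_ids` and `out_ids` (character vectors of stimulus
#'   ids) and logical `in_region` aligned with the non-anchor stimuli.
#' @export
stimuli_in_region <- function(region, set) {
  keep <- !set$anchor
  px <- coord_to_pixel(set$coords[keep, , drop = FALSE], region$resolution)
  inside <- px %in% region$pixels
  list(in_ids = set$stimulus_id[keep][inside],
       out_ids = set$stimulus_id[keep][!inside],
       in_region = inside)
}

#' Overlap fraction between two tuning regions
#'
#' Intersection size divided by the size of the smaller region; 0 when either
#' region is empty. Regions with overlap above 0.5 are conventionally treated
#' as invariant across conditions.
#'
#' @param a,b `tuning_region` objects on the same grid.
#' @return Scalar in \[0, 1\].
#' @export
region_overlap <- function(a, b) {
  if (a$resolution != b$resolution)
    stop("regions live on different grids")
  na <- length(a$pixels); nb <- length(b$pixels)
  if (na == 0 || nb == 0) return(0)
  length(intersect(a$pixels, b$pixels)) / min(na, nb)
}

#' Fraction of the masked feature space covered by a set of tuning regions
#'
#' @param regions List of `tuning_region` objects on the same grid.
#' @param mask A `grid_mask` (defaults to the first region's mask).
#' @return Scalar in \[0, 1\]: size of the union of region pixels (within the
#'   mask) over the number of masked pixels.
#' @export
region_coverage <- function(regions, mask = NULL) {
  if (length(regions) == 0) return(0)
  res <- unique(vapply(regions, `[[`, 0, "resolution"))
  if (length(res) != 1) stop("regions live on different grids")
  if (is.null(mask)) mask <- regions[[1]]$mask
  px <- unique(unlist(lapply(regions, `[[`, "pixels")))
  px <- px[mask$valid[px]]
  length(px) / mask$n_valid
}
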