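#' Write / read a stimulus set as TSV
#'
#' Columns `stimulus_id`, `category`, `x`, `y` (plus `memorability` and
#' `anchor` when present). High-dimensional features travel separately via
#' [write_features_tsv()].
#'
#' @param set A `stimulus_set`.
#' @param path Output file path.
#' @export
write_stimulus_tsv <- function(set, path) {
  df <- data.frame(stimulus_id = set$stimulus_id, category = set$category,
                   x = set$coords[, 1], y = set$coords[, 2])
  if (!is.null(set$memorability)) df$memorability <- set$memorability
  if (any(set$anchor)) df$anchor <- set$anchor
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stimulus_tsv
#' @param path Input file path.
#' @return A `stimulus_set` (without features).
#' @export
read_stimulus_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stimulus_set(df$stimulus_id, df$category, cbind(df$x, df$y),
               memorability = df$memorability,
               anchor = if (!is.null(df$anchor)) as.logical(df$anchor))
}

#' Write / read a feature matrix as TSV
#'
#' Dense numeric matrix with a `stimulus_id` index column.
#' @param features Numeric matrix, rows aligned with `stimulus_id`.
#' @param stimulus_id Row identifiers.
#' @param path File path.
#' @export
write_features_tsv <- function(features, stimulus_id, path) {
  df <- data.frame(stimulus_id = stimulus_id, features,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_tsv
#' @return List with `features` matrix and `stimulus_id`.
#' @export
read_features_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  list(stimulus_id = df$stimulus_id,
       features = as.matrix(df[, -1, drop = FALSE]))
}

#' Write / read a trial table as TSV
#'
#' Columns `trial_id`, `stimulus_id`, `phase`, `old_flag`, `response`,
#' `rt_s`, `onset_s`.
#' @param trials A `trial_table` data.frame.
#' @param path File path.
#' @export
write_trials_tsv <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials_tsv
#' @export
read_trials_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$old_flag <- as.logical(df$old_flag)
  class(df) <- c("trial_table", "data.frame")
  df
}

#' Write spike times as TSV
#'
#' Long format: `neuron_id`, `trial_id`, `spike_time_s`.
#' @param neurons List of `neuron_recording`s.
#' @param path File path.
#' @export
write_spikes_tsv <- function(neurons, path) {
  df <- do.call(rbind, lapply(neurons, function(nr)
    data.frame(neuron_id = nr$neuron_id, trial_id = nr$spikes$trial_id,
               spike_time_s = nr$spikes$t)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a tuning region as JSON
#'
#' Pixel indices (column-major on the detection grid), cluster membership,
#' area fraction and member stimuli; round-trips via [read_region_json()]
#' for downstream overlap/coverage computations.
#'
#' @param region A `tuning_region`.
#' @param path File path.
#' @export
write_region_json <- function(region, path) {
  jsonlite::write_json(list(
    resolution = region$resolution,
    n_masked = region$mask$n_valid,
    detected = region$detected,
    area_fraction = region$area_fraction,
    pixels = region$pixels,
    clusters = lapply(region$clusters, identity),
    member_ids = region$member_ids,
    categories = region$categories), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_region_json
#' @return A list with the stored region fields (not a full `tuning_region`:
#'   p-value maps are not serialized).
#' @export
read_region_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$pixels <- as.integer(x$pixels)
  x$clusters <- lapply(x$clusters, as.integer)
  x
}
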