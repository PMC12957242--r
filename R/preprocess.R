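#' Preprocessing configuration
#'
#' @param percentile per-sample normalization percentile (percent, default
#'   75).
#' @param frequency_threshold fraction of a group's samples a metabolite must
#'   be present in (default 0.25).
#' @param area_floor pseudo-area added before log transform; `NULL` (default)
#'   means half the smallest positive area in the table.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(percentile = 75, frequency_threshold = 0.25,
                              area_floor = NULL) {
  stopifnot(percentile > 0, percentile < 100,
            frequency_threshold >= 0, frequency_threshold <= 1)
  structure(list(percentile = percentile,
                 frequency_threshold = frequency_threshold,
                 area_floor = area_floor),
            class = "preprocess_config")
}

#' Percentile normalization
#'
#' Divides each sample's areas by that sample's `percentile`-th percentile
#' (linear-interpolation quantile), then rescales by the median of those
#' percentiles across samples so the output stays on the input scale. This
#' removes per-sample loading/injection differences: multiplying any sample
#' by a positive constant leaves its normalized profile unchanged. QC rows
#' are normalized identically. Idempotent.
#'
#' @param table a [feature_table()].
#' @param config a [preprocess_config()].
#' @return The normalized `feature_table`.
#' @export
percentile_normalize <- function(table, config = preprocess_config()) {
  stopifnot(inherits(table, "feature_table"))
  q <- apply(table$areas, 1, stats::quantile,
             probs = config$percentile / 100, names = FALSE, type = 7)
  if (any(q <= 0))
    stop("sample(s) with a non-positive ", config$percentile,
         "th percentile area: ",
         paste(table$sample_id[q <= 0], collapse = ", "))
  areas <- table$areas / q * stats::median(q)
  feature_table(areas, group = table$group, batch = table$batch_id)
}

#' Frequency (presence) filter
#'
#' Keeps a metabolite iff it is present (area strictly positive, or above
#' `presence_floor`) in at least `frequency_threshold` of the samples of at
#' least one origin group. QC samples are excluded from the tally.
#'
#' @param table a [feature_table()].
#' @param config a [preprocess_config()].
#' @param presence_floor detectability floor; areas above it count as
#'   present (default 0: any positive area).
#' @return The filtered `feature_table` (metabolite subset of the input).
#' @export
frequency_filter <- function(table, config = preprocess_config(),
                             presence_floor = 0) {
  stopifnot(inherits(table, "feature_table"))
  grp <- table$group[table$group != "QC"]
  if (!length(grp)) stop("no non-QC samples to tally")
  areas <- table$areas[table$group != "QC", , drop = FALSE]
  keep <- vapply(seq_len(ncol(areas)), function(j) {
    frac <- tapply(areas[, j] > presence_floor, grp, mean)
    any(frac >= config$frequency_threshold)
  }, logical(1))
  subset_metabolites(table, which(keep))
}

#' Log2 transform of peak areas
#'
#' `log2(area + floor)`; the default floor is 0 when every area is positive
#' (so the transform is exact) and otherwise half the smallest positive
#' area, so exact zeros map to a finite value.
#'
#' @param table a [feature_table()].
#' @param config a [preprocess_config()] (supplies `area_floor`).
#' @return A `feature_table` whose `areas` hold log2 values. Note the
#'   non-negativity invariant still applies, which is satisfied whenever
#'   areas are >= 1; for general matrices use the returned matrix of
#'   [log_areas()] instead.
#' @export
log_transform <- function(table, config = preprocess_config()) {
  la <- log_areas(table, config)
  feature_table(la, group = table$group, batch = table$batch_id)
}

#' Log2 area matrix
#'
#' Matrix-returning variant of [log_transform()].
#'
#' @inheritParams log_transform
#' @return samples x metabolites matrix of `log2(area + floor)`.
#' @export
log_areas <- function(table, config = preprocess_config()) {
  stopifnot(inherits(table, "feature_table"), all(table$areas >= 0))
  floor <- config$area_floor
  if (is.null(floor)) {
    floor <- if (all(table$areas > 0)) 0 else {
      pos <- table$areas[table$areas > 0]
      if (length(pos)) min(pos) / 2 else 1
    }
  }
  log2(table$areas + floor)
}

#' QC repeatability metrics
#'
#' Relative standard deviations of peak area and retention time over
#' replicate QC runs (sample SD, n-1 denominator, as a percent of the mean),
#' and the mass difference in ppm between the mean detected m/z and the
#' calculated m/z.
#'
#' @param area numeric vector of per-run peak areas (length >= 2).
#' @param rt optional vector of per-run retention times.
#' @param detected_mz optional vector of per-run detected m/z.
#' @param calculated_mz calculated m/z (required with `detected_mz`).
#' @return A list with `rsd_area_pct`, `rsd_rt_pct`, `mass_difference_ppm`
#'   (the latter two `NA` when their inputs are absent).
#' @examples
#' qc_metrics(c(8, 10, 12))  # RSD 20%
#' @export
qc_metrics <- function(area, rt = NULL, detected_mz = NULL,
                       calculated_mz = NULL) {
  rsd <- function(x) {
    if (length(x) < 2) stop("need at least 2 QC runs")
    m <- mean(x)
    if (m == 0) stop("zero mean in QC series")
    100 * stats::sd(x) / m
  }
  list(
    rsd_area_pct = rsd(area),
    rsd_rt_pct = if (is.null(rt)) NA_real_ else rsd(rt),
    mass_difference_ppm = if (is.null(detected_mz)) NA_real_ else {
      stopifnot(!is.null(calculated_mz))
      ppm_error(mean(detected_mz), calculated_mz)
    })
}
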