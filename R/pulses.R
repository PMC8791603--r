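# Pulse detection: threshold "strong intensity" pixels in the kymograph,
# group adjacent pixels into connected components (8-connectivity, so a
# one-pixel positional jitter between frames does not split a focus),
# measure event durations, and pool consecutive measurements.

#' Threshold strong-intensity pixels in a kymograph
#'
#' Builds the binary mask of "strong" pixels used for pulse segmentation.
#' Methods: `"mad"` (robust; threshold = median + k * MAD, with the MAD
#' scaled to be consistent with the standard deviation), `"otsu"`
#' (two-class histogram threshold maximizing between-class variance) and
#' `"absolute"` (user-supplied value).  The mask is strict:
#' `intensity > threshold`.
#'
#' @param kymo a [kymograph].
#' @param method `"mad"`, `"otsu"` or `"absolute"`.
#' @param k multiplier for the MAD method (> 0); default 3.
#' @param value threshold for the absolute method.
#' @param n_bins histogram bins for the Otsu method.
#' @return An object of class `binary_kymograph`: the logical `mask`, the
#'   `threshold_value`, the `method`, and the parent kymograph's
#'   coordinates and labels.
#' @details With the MAD method an all-equal kymograph has MAD 0, so the
#'   mask is empty; a warning is emitted since no scale is estimable.
#' @export
threshold_kymograph <- function(kymo, method = c("mad", "otsu", "absolute"),
                                k = 3, value = NULL, n_bins = 256L) {
  stopifnot(inherits(kymo, "kymograph"))
  method <- match.arg(method)
  x <- kymo$data
  if (length(x) == 0L) stop("empty kymograph")
  thr <- switch(method,
    mad = {
      if (!isTRUE(k > 0)) stop("k must be > 0")
      s <- mad(x)
      if (s == 0)
        warning("MAD of kymograph is 0 (constant or near-constant ",
                "intensities); mask will be empty or unreliable")
      median(x) + k * s
    },
    otsu = otsu_threshold(x, n_bins = n_bins),
    absolute = {
      if (is.null(value) || !is.numeric(value))
        stop("method = 'absolute' requires a numeric `value`")
      as.numeric(value)
    })
  structure(list(mask = x > thr, threshold_value = thr, method = method,
                 arc_um = kymo$arc_um, region_labels = kymo$region_labels,
                 frame_interval_s = kymo$frame_interval_s,
                 pixel_size_um = kymo$pixel_size_um),
            class = "binary_kymograph")
}

#' @export
print.binary_kymograph <- function(x, ...) {
  cat(sprintf("binary_kymograph: %d x %d, %s threshold = %.4g, %d strong pixels (%.1f%%)\n",
              nrow(x$mask), ncol(x$mask), x$method, x$threshold_value,
              sum(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

# Otsu's method on an n_bins histogram over the data range: pick the bin
# edge maximizing between-class variance.  Invariant under affine
# intensity rescaling because the bins scale with the range.
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(pmin(findInterval(x, breaks, rightmost.closed = TRUE), n_bins),
                nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  bcv <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  best <- which.max(bcv[-n_bins])
  breaks[best + 1L]
}

#' Segment pulses as 8-connected components of the strong-pixel mask
#'
#' Adjacent strong pixels (sharing an edge or a corner) are grouped into
#' connected components, each one candidate pulse event.  Component ids
#' are deterministic: sorted by (first frame, then lowest arc row).
#'
#' @param binary a `binary_kymograph` from [threshold_kymograph()].
#' @return An object of class `pulse_components`: an integer `labels`
#'   matrix (0 = background) plus `n` components and the parent metadata.
#' @export
segment_pulses <- function(binary) {
  stopifnot(inherits(binary, "binary_kymograph"))
  lab <- label_components_8(binary$mask)
  n <- max(lab)
  if (n > 0L) {
    idx <- which(lab > 0L)
    ids <- lab[idx]
    rows <- (idx - 1L) %% nrow(lab) + 1L
    cols <- (idx - 1L) %/% nrow(lab) + 1L
    fmin <- tapply(cols, ids, min)
    rmin <- tapply(rows, ids, min)
    ord <- order(fmin, rmin)
    remap <- integer(n)
    remap[as.integer(names(fmin))[ord]] <- seq_len(n)
    lab[idx] <- remap[ids]
  }
  structure(list(labels = lab, n = n, arc_um = binary$arc_um,
                 region_labels = binary$region_labels,
                 frame_interval_s = binary$frame_interval_s,
                 pixel_size_um = binary$pixel_size_um),
            class = "pulse_components")
}

#' @export
print.pulse_components <- function(x, ...) {
  cat("pulse_components:", x$n, "connected components\n")
  invisible(x)
}

#' Measure pulse events from segmented components
#'
#' Computes, per component: temporal extent and duration (an event seen in
#' frames `f_min ... f_max` lasted `(f_max - f_min + 1) * frame_interval_s`
#' -- an event visible in a single frame lasted at most one interval),
#' pixel count, peak intensity, positional drift (range of the per-frame
#' intensity-weighted centroid arc position) and region (majority region
#' label of the member rows, pixel-weighted).
#'
#' Components smaller than `min_pixels` are discarded as noise; components
#' whose majority label is `"unassigned"` are dropped; events touching the
#' first or last frame are flagged `censored` (true duration unknown);
#' events drifting more than `max_drift_um` are flagged non-`stationary`
#' (e.g. merged neighbours).  Censored and non-stationary events are kept
#' in the table -- downstream statistics exclude them by default.
#'
#' @param components a `pulse_components` from [segment_pulses()].
#' @param kymo the [kymograph] the mask was computed from.
#' @param min_pixels minimum component size in pixels (default 4).
#' @param max_drift_um maximum centroid drift (um) for an event to count
#'   as stationary (default 2).
#' @param verbose log discard counts with `message()`.
#' @return A data frame of class `pulse_events`, one row per retained
#'   event, with columns `component_id`, `region`, `frame_min`,
#'   `frame_max` (0-based frames), `duration_s`, `n_pixels`,
#'   `peak_intensity`, `centroid_arc_um`, `centroid_drift_um`,
#'   `censored`, `stationary`.
#' @export
measure_pulses <- function(components, kymo, min_pixels = 4,
                           max_drift_um = 2, verbose = FALSE) {
  stopifnot(inherits(components, "pulse_components"),
            inherits(kymo, "kymograph"))
  if (!identical(dim(components$labels), dim(kymo$data)))
    stop("components and kymograph dimensions do not match")
  lab <- components$labels
  n_frames <- ncol(lab)
  dt <- components$frame_interval_s
  empty <- data.frame(component_id = integer(0), region = character(0),
                      frame_min = integer(0), frame_max = integer(0),
                      duration_s = numeric(0), n_pixels = integer(0),
                      peak_intensity = numeric(0),
                      centroid_arc_um = numeric(0),
                      centroid_drift_um = numeric(0),
                      censored = logical(0), stationary = logical(0))
  if (components$n == 0L)
    return(structure(empty, class = c("pulse_events", "data.frame")))
  idx <- which(lab > 0L)
  ids <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  w <- kymo$data[idx]
  arc <- components$arc_um[rows]
  regs <- components$region_labels[rows]

  per <- split(seq_along(idx), ids)
  num <- vapply(per, function(ii) {
    fr <- cols[ii]
    fmin <- min(fr); fmax <- max(fr)
    # per-frame intensity-weighted centroid arc position
    ws <- rowsum(cbind(w[ii] * arc[ii], w[ii]), fr)
    cw <- ws[, 1] / ws[, 2]
    c(fmin, fmax, length(ii), max(w[ii]),
      sum(w[ii] * arc[ii]) / sum(w[ii]), max(cw) - min(cw))
  }, numeric(6))
  region <- vapply(per, function(ii) {
    cnt <- table(regs[ii])
    names(cnt)[which.max(cnt)]
  }, character(1))
  fmin <- num[1, ]; fmax <- num[2, ]
  ev <- data.frame(
    region = region,
    frame_min = as.integer(fmin - 1L), frame_max = as.integer(fmax - 1L),
    duration_s = (fmax - fmin + 1) * dt,
    n_pixels = as.integer(num[3, ]),
    peak_intensity = num[4, ],
    centroid_arc_um = num[5, ],
    centroid_drift_um = num[6, ],
    censored = fmin == 1 | fmax == n_frames)
  ev$component_id <- as.integer(names(per))
  ev$stationary <- ev$centroid_drift_um <= max_drift_um
  too_small <- ev$n_pixels < min_pixels
  no_region <- ev$region == "unassigned"
  if (verbose)
    message(sprintf(
      "measure_pulses: %d components; discarded %d < %d px, %d unassigned; %d censored, %d non-stationary flagged",
      nrow(ev), sum(too_small), min_pixels, sum(!too_small & no_region),
      sum(ev$censored[!too_small & !no_region]),
      sum(!ev$stationary[!too_small & !no_region])))
  ev <- ev[!too_small & !no_region, , drop = FALSE]
  ev <- ev[order(ev$component_id),
           c("component_id", "region", "frame_min", "frame_max",
             "duration_s", "n_pixels", "peak_intensity", "centroid_arc_um",
             "centroid_drift_um", "censored", "stationary")]
  rownames(ev) <- NULL
  structure(ev, class = c("pulse_events", "data.frame"))
}

#' @export
print.pulse_events <- function(x, ...) {
  cat("pulse_events:", nrow(x), "events\n")
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

# Filter events the way duration statistics see them.
usable_events <- function(events, include_censored = FALSE,
                          stationary_only = TRUE) {
  keep <- rep(TRUE, nrow(events))
  if (!include_censored) keep <- keep & !events$censored
  if (stationary_only) keep <- keep & events$stationary
  events[keep, , drop = FALSE]
}

#' Pool consecutive pulse durations
#'
#' Within each region, events are ordered by onset frame and grouped into
#' non-overlapping blocks of `window` consecutive measurements; each
#' complete block is averaged into one pooled mean (the classical "pool 25
#' consecutive measurements" summary).  Leftover events (fewer than
#' `window`) contribute to `n_events` and the raw summary statistics but
#' not to the pooled means.  Censored and non-stationary events are
#' excluded by default.
#'
#' @param events a `pulse_events` data frame.
#' @param window block size (>= 1); default 25.
#' @param include_censored include censored events (default FALSE).
#' @param stationary_only keep only stationary events (default TRUE).
#' @return An object of class `pulse_summary`: `pooled` (named list,
#'   region -> numeric vector of pooled means, seconds), `stats` (data
#'   frame with per-region `n_events`, `mean_s`, `sd_s` over the raw
#'   retained durations) and `window`.
#' @export
pool_durations <- function(events, window = 25, include_censored = FALSE,
                           stationary_only = TRUE) {
  if (!is.numeric(window) || window < 1) stop("window must be >= 1")
  window <- as.integer(window)
  ev <- usable_events(events, include_censored, stationary_only)
  regions <- sort(unique(ev$region))
  pooled <- list()
  stats <- data.frame(region = character(0), n_events = integer(0),
                      mean_s = numeric(0), sd_s = numeric(0))
  for (r in regions) {
    d <- ev$duration_s[ev$region == r][order(ev$frame_min[ev$region == r])]
    n_blocks <- length(d) %/% window
    pooled[[r]] <- if (n_blocks > 0)
      vapply(seq_len(n_blocks), function(b)
        mean(d[((b - 1L) * window + 1L):(b * window)]), numeric(1))
    else numeric(0)
    stats <- rbind(stats, data.frame(region = r, n_events = length(d),
                                     mean_s = mean(d), sd_s = sd(d)))
  }
  structure(list(pooled = pooled, stats = stats, window = window),
            class = "pulse_summary")
}

#' @export
print.pulse_summary <- function(x, ...) {
  cat("pulse_summary (pooling window", x$window, "events):\n")
  for (i in seq_len(nrow(x$stats))) {
    r <- x$stats$region[i]
    cat(sprintf("  %-3s n=%3d  mean %6.1f s  sd %5.1f s  pooled means: %s\n",
                r, x$stats$n_events[i], x$stats$mean_s[i], x$stats$sd_s[i],
                if (length(x$pooled[[r]]))
                  paste(round(x$pooled[[r]], 1), collapse = ", ")
                else "(fewer than window events)"))
  }
  invisible(x)
}

#' Run the full pulse-detection pipeline on a kymograph
#'
#' Convenience wrapper: threshold, segment, measure.
#'
#' @param kymo a [kymograph] with region labels assigned.
#' @inheritParams threshold_kymograph
#' @inheritParams measure_pulses
#' @return A `pulse_events` data frame.
#' @export
detect_pulses <- function(kymo, method = "mad", k = 3, value = NULL,
                          min_pixels = 4, max_drift_um = 2,
                          verbose = FALSE) {
  binary <- threshold_kymograph(kymo, method = method, k = k, value = value)
  comps <- segment_pulses(binary)
  measure_pulses(comps, kymo, min_pixels = min_pixels,
                 max_drift_um = max_drift_um, verbose = verbose)
}
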