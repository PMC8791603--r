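# Crescent quantification: band-averaged cortical intensity profiles
# normalized to a follicle-cell reference band, per-profile crescent
# metrics, and group aggregation onto a common arc grid.

#' Band-averaged intensity profile along a cortical path
#'
#' Same sampling contract as [extract_kymograph()] applied to a single 2D
#' image: for each arc sample the intensity is the mean of bilinear
#' samples across the band normal to the path.
#'
#' @param image numeric matrix (single-channel image).
#' @param path a [cortical_path].
#' @param band_halfwidth_px band half-width in pixels.
#' @param pixel_size_um pixel size; defaults to the path's.
#' @return A data frame with columns `arc_um`, `intensity`.
#' @export
profile_along_cortex <- function(image, path, band_halfwidth_px = 1,
                                 pixel_size_um = NULL) {
  stopifnot(is.matrix(image), inherits(path, "cortical_path"))
  px <- pixel_size_um %||% path$pixel_size_um
  fs <- frame_stack(array(image, dim = c(dim(image), 1L)),
                    frame_interval_s = 1, pixel_size_um = px)
  kymo <- extract_kymograph(fs, path, band_halfwidth_px = band_halfwidth_px)
  data.frame(arc_um = kymo$arc_um, intensity = kymo$data[, 1])
}

#' Normalize a cortical profile to a reference signal
#'
#' Divides the raw cortical profile by the mean of a reference band --
#' typically the lateral follicle-cell signal -- so that profiles from
#' different samples (with different illumination or expression levels)
#' are comparable.
#'
#' @param profile data frame from [profile_along_cortex()].
#' @param reference either a scalar, a numeric vector of reference band
#'   intensities, or a profile data frame with an `intensity` column.
#' @param sample_id identifier stored with the profile.
#' @param summary `"mean"` (default) or `"median"` summary of the
#'   reference band.
#' @return A data frame of class `crescent_profile` with columns
#'   `arc_um`, `ratio`, `sample_id`.
#' @export
normalize_profile <- function(profile, reference, sample_id = "sample_1",
                              summary = c("mean", "median")) {
  summary <- match.arg(summary)
  ref <- if (is.data.frame(reference)) reference$intensity else reference
  ref_val <- if (length(ref) == 1L) as.numeric(ref)
             else if (summary == "mean") mean(ref) else median(ref)
  if (!isTRUE(ref_val > 0))
    stop("reference summary must be > 0 (got ", format(ref_val),
         "); cannot normalize")
  out <- data.frame(arc_um = profile$arc_um,
                    ratio = profile$intensity / ref_val,
                    sample_id = sample_id)
  structure(out, class = c("crescent_profile", "data.frame"))
}

# Per-profile crescent metrics: peak ratio, full width at half of
# (peak - lateral baseline), and posterior:lateral mean ratio.
profile_metrics <- function(profile, regions = region_spec()) {
  s <- profile$arc_um
  y <- profile$ratio
  lateral <- (s >= regions$L1[1] & s <= regions$L1[2]) |
             (s >= regions$L2[1] & s <= regions$L2[2])
  posterior <- s >= regions$P[1] & s <= regions$P[2]
  baseline <- mean(y[lateral])
  i_pk <- which.max(y)
  peak <- y[i_pk]
  half <- baseline + (peak - baseline) / 2
  # full width at half maximum above baseline, by linear interpolation of
  # the outermost crossings around the peak
  left <- s[1]; right <- s[length(s)]
  below <- y < half
  li <- rev(which(below[seq_len(i_pk)]))
  if (length(li)) {
    i <- li[1]
    left <- s[i] + (half - y[i]) / (y[i + 1] - y[i]) * (s[i + 1] - s[i])
  }
  ri <- which(below) [which(below) > i_pk]
  if (length(ri)) {
    i <- ri[1]
    right <- s[i - 1] + (half - y[i - 1]) / (y[i] - y[i - 1]) * (s[i] - s[i - 1])
  }
  data.frame(sample_id = profile$sample_id[1],
             peak_ratio = peak,
             peak_arc_um = s[i_pk],
             width_um = right - left,
             posterior_lateral_ratio = mean(y[posterior]) / baseline)
}

#' Aggregate crescent profiles across samples
#'
#' Interpolates each profile onto a shared arc grid covering the common
#' arc range and computes the group mean and standard error per grid
#' point, plus per-profile crescent metrics: peak ratio, full width at
#' half of (peak - lateral baseline), and the posterior:lateral ratio
#' (mean over the posterior window divided by the mean over the lateral
#' windows).
#'
#' @param profiles list of `crescent_profile` data frames (>= 2).
#' @param grid_um grid spacing in micrometres (default 1).
#' @param regions a [region_spec()] defining the posterior and lateral
#'   windows used by the metrics.
#' @return A list of class `crescent_group` with `curve` (data frame
#'   `arc_um`, `mean`, `sem`, `n`) and `metrics` (one row per profile).
#' @export
aggregate_profiles <- function(profiles, grid_um = 1,
                               regions = region_spec()) {
  if (!is.list(profiles) || length(profiles) < 2L)
    stop("need at least 2 profiles")
  lo <- max(vapply(profiles, function(p) min(p$arc_um), numeric(1)))
  hi <- min(vapply(profiles, function(p) max(p$arc_um), numeric(1)))
  if (lo >= hi) stop("profiles have disjoint arc ranges; nothing to aggregate")
  grid <- seq(ceiling(lo / grid_um) * grid_um, floor(hi / grid_um) * grid_um,
              by = grid_um)
  mat <- vapply(profiles, function(p)
    approx(p$arc_um, p$ratio, xout = grid)$y, numeric(length(grid)))
  n <- length(profiles)
  mu <- rowMeans(mat)
  sem <- apply(mat, 1, sd) / sqrt(n)
  metrics <- do.call(rbind, lapply(profiles, profile_metrics,
                                   regions = regions))
  rownames(metrics) <- NULL
  structure(list(curve = data.frame(arc_um = grid, mean = mu, sem = sem,
                                    n = n),
                 metrics = metrics),
            class = "crescent_group")
}

#' @export
print.crescent_group <- function(x, ...) {
  cat(sprintf("crescent_group: %d profiles on %d grid points (%+.0f ... %+.0f um)\n",
              x$curve$n[1], nrow(x$curve), min(x$curve$arc_um),
              max(x$curve$arc_um)))
  cat(sprintf("  peak ratio %.2f +- %.2f, width %.1f +- %.1f um, P:L ratio %.2f +- %.2f\n",
              mean(x$metrics$peak_ratio), sd(x$metrics$peak_ratio),
              mean(x$metrics$width_um), sd(x$metrics$width_um),
              mean(x$metrics$posterior_lateral_ratio),
              sd(x$metrics$posterior_lateral_ratio)))
  invisible(x)
}

#' Plot an aggregated crescent profile
#'
#' @param x a `crescent_group` from [aggregate_profiles()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.crescent_group <- function(x, ...) {
  cv <- x$curve
  graphics::plot(cv$arc_um, cv$mean, type = "l",
                 xlab = "arc distance from posterior pole (um)",
                 ylab = "normalized intensity ratio", ...)
  graphics::polygon(c(cv$arc_um, rev(cv$arc_um)),
                    c(cv$mean - cv$sem, rev(cv$mean + cv$sem)),
                    border = NA, col = grDevices::adjustcolor("grey40", 0.3))
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}
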