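# Synthetic imaging generator: stationary, intensity-oscillating cortical
# foci with region-specific gamma-distributed lifetimes, painted either
# directly into a kymograph or along a semicircular cortex in a 2D movie,
# plus single-frame crescent scenes with a follicle reference band.

# Uniform arc-length grid of the simulated cortex; spacing = one pixel,
# guaranteed to contain 0 (the posterior pole) exactly.
arc_grid <- function(cfg) {
  n_pos <- max(2L, round(cfg$cortex_length_um / cfg$pixel_size_um))
  k0 <- floor(n_pos / 2)
  (seq_len(n_pos) - 1L - k0) * cfg$pixel_size_um
}

frame_times <- function(cfg) (seq_len(cfg$n_frames) - 1L) * cfg$frame_interval_s

# Raised-cosine intensity envelope on [onset, offset]: smooth rise and fall,
# zero slope at both ends, peak 1 at mid-pulse.
pulse_envelope <- function(t, onset, offset) {
  tau <- (t - onset) / (offset - onset)
  ifelse(tau >= 0 & tau <= 1, 0.5 - 0.5 * cos(2 * pi * tau), 0)
}

# Draw focus birth events: homogeneous Poisson process in (position, time)
# within each region window, lifetimes gamma(shape, mean per region).
# Consumes RNG; caller controls seeding.
sample_foci <- function(cfg) {
  t_total <- (cfg$n_frames - 1L) * cfg$frame_interval_s
  out <- lapply(names(cfg$regions), function(nm) {
    w <- cfg$regions[[nm]]
    width <- w[2] - w[1]
    n <- rpois(1L, cfg$focus_rate_per_um_per_s * width * t_total)
    if (n == 0L)
      return(data.frame(region = character(0), arc_um = numeric(0),
                        onset_s = numeric(0), offset_s = numeric(0),
                        duration_s = numeric(0)))
    pos <- runif(n, w[1], w[2])
    onset <- runif(n, 0, t_total)
    dur <- rgamma(n, shape = cfg$duration_shape,
                  rate = cfg$duration_shape / cfg$duration_mean_s[[nm]])
    data.frame(region = rep(nm, n), arc_um = pos, onset_s = onset,
               offset_s = onset + dur, duration_s = dur)
  })
  foci <- do.call(rbind, out)
  rownames(foci) <- NULL
  foci[order(foci$onset_s, foci$arc_um), , drop = FALSE]
}

new_ground_truth <- function(foci, cfg, crescent_truth = NULL) {
  rownames(foci) <- NULL
  structure(list(
    foci = foci,
    per_region_true_mean_s = cfg$duration_mean_s[names(cfg$regions)],
    crescent_truth = crescent_truth
  ), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Synthetic ground truth:", nrow(x$foci), "foci\n")
  if (nrow(x$foci)) {
    tab <- table(x$foci$region)
    cat("  per region:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
    cat("  configured mean durations (s):",
        paste(sprintf("%s=%g", names(x$per_region_true_mean_s),
                      x$per_region_true_mean_s), collapse = ", "), "\n")
  }
  if (!is.null(x$crescent_truth))
    cat("  crescent truth profile over",
        nrow(x$crescent_truth), "arc samples\n")
  invisible(x)
}

# Paint foci onto the (position x time) grid.  Without positional jitter
# each focus is a rank-one outer product (spatial Gaussian x temporal
# envelope), which keeps generation fast.
render_foci <- function(foci, cfg, arc, times) {
  mat <- matrix(cfg$background_level, nrow = length(arc), ncol = length(times))
  if (nrow(foci) == 0L || cfg$focus_sigma_um == 0) return(mat)
  sig <- cfg$focus_sigma_um
  for (i in seq_len(nrow(foci))) {
    f <- foci[i, ]
    cols <- which(times >= f$onset_s & times <= f$offset_s)
    if (!length(cols)) next
    h <- pulse_envelope(times[cols], f$onset_s, f$offset_s)
    if (cfg$drift_sd_um > 0) {
      centres <- f$arc_um + rnorm(length(cols), 0, cfg$drift_sd_um)
      for (k in seq_along(cols)) {
        rows <- which(abs(arc - centres[k]) <= 5 * sig)
        mat[rows, cols[k]] <- mat[rows, cols[k]] +
          cfg$focus_amplitude * exp(-(arc[rows] - centres[k])^2 / (2 * sig^2)) * h[k]
      }
    } else {
      rows <- which(abs(arc - f$arc_um) <= 5 * sig)
      g <- exp(-(arc[rows] - f$arc_um)^2 / (2 * sig^2))
      mat[rows, cols] <- mat[rows, cols] +
        cfg$focus_amplitude * tcrossprod(g, h)
    }
  }
  mat
}

apply_noise <- function(x, cfg) {
  switch(cfg$noise_model,
         none = x,
         gaussian = pmax(x + rnorm(length(x), 0, cfg$gaussian_sd), 0),
         poisson = array(rpois(length(x), pmax(x, 0)), dim = dim(x)))
}

#' Generate a synthetic cortical kymograph with ground truth
#'
#' Simulates the position-by-time intensity map of a pulsing cortex: foci
#' are born as a Poisson process inside each region window, remain
#' stationary, and rise and fall in intensity over a gamma-distributed
#' lifetime.  Overlapping foci superpose additively; noise is added last.
#'
#' @param cfg a [scenario_config()].
#' @return A list with components `kymograph` (a [kymograph] with region
#'   labels already assigned) and `truth` (a `ground_truth`: one row per
#'   focus with region, arc position, onset, offset and duration).
#' @examples
#' sim <- generate_kymograph(scenario_config(seed = 7))
#' sim$kymograph
#' head(sim$truth$foci)
#' @export
generate_kymograph <- function(cfg) {
  validate_scenario(cfg)
  arc <- arc_grid(cfg)
  times <- frame_times(cfg)
  with_seed(cfg$seed, {
    foci <- sample_foci(cfg)
    data <- render_foci(foci, cfg, arc, times)
    data <- apply_noise(data, cfg)
    kymo <- new_kymograph(data, arc_um = arc,
                          frame_interval_s = cfg$frame_interval_s,
                          pixel_size_um = cfg$pixel_size_um)
    kymo <- assign_regions(kymo, cfg$regions)
    list(kymograph = kymo, truth = new_ground_truth(foci, cfg))
  })
}

#' Generate a synthetic movie with the cortex on a semicircular path
#'
#' Embeds the 1D cortical signal of [generate_kymograph()] along a
#' semicircular path (radius `cortex_length_um / pi`) as a band of width
#' `2 * band_halfwidth_px + 1` pixels in a 2D frame stack, so that
#' [extract_kymograph()] on the returned path recovers the 1D signal.
#' With the same seed, the ground truth is identical to that of
#' [generate_kymograph()].
#'
#' @param cfg a [scenario_config()].
#' @param band_halfwidth_px half-width of the painted band in pixels.
#' @param frame_shape optional `c(rows, cols)`; by default the frame is
#'   sized to fit the path.  If supplied and the path does not fit, an
#'   error is raised.
#' @return A list with `movie` (a [frame_stack]), `path` (a
#'   [cortical_path] along the band centreline, pole at arc 0) and
#'   `truth` (as in [generate_kymograph()]).
#' @export
generate_movie <- function(cfg, band_halfwidth_px = 1, frame_shape = NULL) {
  validate_scenario(cfg)
  arc <- arc_grid(cfg)
  times <- frame_times(cfg)
  r_px <- (cfg$cortex_length_um / pi) / cfg$pixel_size_um
  margin <- band_halfwidth_px + 4
  if (is.null(frame_shape)) {
    nr <- ceiling(2 * r_px + 2 * margin)
    nc <- ceiling(r_px + 2 * margin)
  } else {
    nr <- frame_shape[1]; nc <- frame_shape[2]
    if (2 * (r_px + margin) > sqrt(nr^2 + nc^2))
      stop("cortical path does not fit: arc length ", cfg$cortex_length_um,
           " um exceeds the frame diagonal")
  }
  r0 <- (nr + 1) / 2
  c0 <- margin
  # band membership and arc coordinate of every frame pixel (static geometry)
  dr <- matrix(seq_len(nr) - r0, nr, nc)
  dc <- matrix(rep(seq_len(nc) - c0, each = nr), nr, nc)
  rad <- sqrt(dr^2 + dc^2)
  theta <- atan2(dr, dc)
  in_band <- abs(rad - r_px) <= band_halfwidth_px + 0.5 &
    abs(theta) <= pi / 2
  band_idx <- which(in_band)
  s_band <- r_px * theta[band_idx] * cfg$pixel_size_um
  s_band <- pmin(pmax(s_band, min(arc)), max(arc))

  with_seed(cfg$seed, {
    foci <- sample_foci(cfg)
    signal <- render_foci(foci, cfg, arc, times)
    data <- array(cfg$background_level, dim = c(nr, nc, cfg$n_frames))
    for (t in seq_len(cfg$n_frames)) {
      frame <- matrix(cfg$background_level, nr, nc)
      frame[band_idx] <- approx(arc, signal[, t], xout = s_band,
                                rule = 2)$y
      data[, , t] <- frame
    }
    data <- apply_noise(data, cfg)
    movie <- frame_stack(data, frame_interval_s = cfg$frame_interval_s,
                         pixel_size_um = cfg$pixel_size_um)
    th <- arc / (r_px * cfg$pixel_size_um)
    verts <- cbind(row = r0 + r_px * sin(th), col = c0 + r_px * cos(th))
    path <- new_cortical_path(verts, pole_index = which(arc == 0),
                              arc_um = arc,
                              pixel_size_um = cfg$pixel_size_um)
    list(movie = movie, path = path, truth = new_ground_truth(foci, cfg))
  })
}

#' Generate a synthetic crescent scene with a follicle reference band
#'
#' Produces a single 2D image containing (i) an oocyte cortical band whose
#' intensity follows `base + amplitude * exp(-s^2 / (2 w^2))` in the signed
#' arc coordinate `s` (0 at the posterior pole) and (ii) a parallel
#' follicle-cell reference band of constant intensity, together with the
#' polylines tracing both bands and the analytic normalized-ratio profile.
#'
#' @param cfg a [scenario_config()]; supplies calibration, background
#'   (`background_level`, the off-peak cortical level) and noise settings.
#' @param crescent_amplitude peak crescent intensity above the base level.
#' @param crescent_halfwidth_um Gaussian half-width `w` (sd, um) of the
#'   crescent; must be > 0.
#' @param reference_level intensity of the follicle reference band;
#'   defaults to `cfg$background_level`.
#' @return A list with `image` (matrix), `oocyte_path`, `follicle_path`
#'   (both [cortical_path]s), `truth` (a `ground_truth` whose
#'   `crescent_truth` is a data frame of `arc_um`, `ratio`), and
#'   `reference_level`.
#' @examples
#' sc <- generate_crescent_image(scenario_config(noise_model = "none"))
#' plot(sc$truth$crescent_truth, type = "l")
#' @export
generate_crescent_image <- function(cfg, crescent_amplitude = 80,
                                    crescent_halfwidth_um = 10,
                                    reference_level = NULL) {
  validate_scenario(cfg)
  if (!is.numeric(crescent_halfwidth_um) || crescent_halfwidth_um <= 0)
    stop("crescent_halfwidth_um must be > 0")
  reference_level <- reference_level %||% cfg$background_level
  if (reference_level <= 0) stop("reference_level must be > 0")
  arc <- arc_grid(cfg)
  n_arc <- length(arc)
  margin <- 4L
  nr <- 41L
  nc <- n_arc + 2L * margin
  oo_row <- 15L
  fc_row <- 27L
  base <- cfg$background_level
  crescent <- base + crescent_amplitude * exp(-arc^2 / (2 * crescent_halfwidth_um^2))
  img <- matrix(base, nr, nc)
  cols <- margin + seq_len(n_arc)
  for (d in -1:1) {
    img[oo_row + d, cols] <- crescent
    img[fc_row + d, cols] <- reference_level
  }
  img <- with_seed(cfg$seed, apply_noise(img, cfg))
  mk_path <- function(row) new_cortical_path(
    cbind(row = rep(row, n_arc), col = cols),
    pole_index = which(arc == 0), arc_um = arc,
    pixel_size_um = cfg$pixel_size_um)
  truth <- data.frame(arc_um = arc, ratio = crescent / reference_level)
  no_foci <- data.frame(region = character(0), arc_um = numeric(0),
                        onset_s = numeric(0), offset_s = numeric(0),
                        duration_s = numeric(0))
  gt <- new_ground_truth(no_foci, cfg, crescent_truth = truth)
  list(image = img, oocyte_path = mk_path(oo_row),
       follicle_path = mk_path(fc_row), truth = gt,
       reference_level = reference_level)
}
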