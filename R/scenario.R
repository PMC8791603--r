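#' Cortical analysis windows
#'
#' Defines the arc-length windows (in micrometres, signed, 0 at the posterior
#' pole) used to compare pulse behaviour between cortical regions: two lateral
#' windows `L1` (negative arc) and `L2` (positive arc) flanking a posterior
#' window `P` that must contain the pole.  The defaults leave a 10 um guard
#' gap between the posterior and lateral windows so that events are never
#' ambiguous about the region they belong to.
#'
#' @param L1,P,L2 numeric length-2 vectors `c(arc_min_um, arc_max_um)`.
#' @return An object of class `region_spec`: a named list of windows.
#' @examples
#' region_spec()
#' region_spec(L1 = c(-30, -15), P = c(-8, 8), L2 = c(15, 30))
#' @export
region_spec <- function(L1 = c(-40, -20), P = c(-10, 10), L2 = c(20, 40)) {
  windows <- list(L1 = as.numeric(L1), P = as.numeric(P), L2 = as.numeric(L2))
  for (nm in names(windows)) {
    w <- windows[[nm]]
    if (length(w) != 2L || !all(is.finite(w)) || w[1] >= w[2])
      stop("region window '", nm, "' must be c(min, max) with min < max")
  }
  if (!(windows$P[1] < 0 && windows$P[2] > 0))
    stop("posterior window P must contain the pole (arc 0)")
  if (windows$L1[2] > 0)
    stop("lateral window L1 must be entirely negative")
  if (windows$L2[1] < 0)
    stop("lateral window L2 must be entirely positive")
  ord <- order(vapply(windows, `[`, numeric(1), 1L))
  sorted <- windows[ord]
  for (i in seq_len(length(sorted) - 1L))
    if (sorted[[i]][2] > sorted[[i + 1L]][1])
      stop("region windows '", names(sorted)[i], "' and '",
           names(sorted)[i + 1L], "' overlap")
  structure(windows, class = "region_spec")
}

#' @export
print.region_spec <- function(x, ...) {
  cat("Cortical region windows (arc um, 0 = posterior pole):\n")
  for (nm in names(x))
    cat(sprintf("  %-3s [%+7.2f, %+7.2f]\n", nm, x[[nm]][1], x[[nm]][2]))
  invisible(x)
}

#' Synthetic imaging scenario
#'
#' Parameters of the synthetic time-lapse generator.  The calibration
#' defaults (101 frames at 15 s, i.e. a 25 min movie, 0.198 um pixels)
#' mirror typical confocal imaging of cortical myosin in the Drosophila
#' oocyte.  Foci are born as a homogeneous Poisson process within each
#' region window, stay spatially stationary (optionally jittered), and
#' oscillate in intensity following a raised-cosine envelope over a
#' gamma-distributed lifetime whose mean is region specific.
#'
#' @param n_frames number of frames (>= 2); frame `k` is at time `k *
#'   frame_interval_s`, `k = 0 ... n_frames - 1`.
#' @param frame_interval_s frame interval in seconds.
#' @param pixel_size_um pixel size in micrometres.
#' @param cortex_length_um total arc length of the simulated cortex; the
#'   arc coordinate spans approximately `[-cortex_length_um/2,
#'   +cortex_length_um/2]` with 0 on the grid.
#' @param regions a [region_spec()]; foci are only born inside its windows.
#' @param focus_rate_per_um_per_s Poisson birth intensity of new foci, per
#'   micrometre of cortex per second.
#' @param duration_mean_s named numeric, mean pulse duration (s) per region;
#'   names must match `regions`.
#' @param duration_shape gamma shape parameter shared by all regions
#'   (coefficient of variation `1/sqrt(shape)`).
#' @param focus_amplitude peak focus intensity above background (a.u.).
#' @param focus_sigma_um spatial Gaussian half-width (sd) of a focus.
#' @param background_level baseline intensity (a.u., >= 0).
#' @param noise_model one of `"gaussian"`, `"poisson"`, `"none"`.
#' @param gaussian_sd sd of additive Gaussian noise (used when
#'   `noise_model = "gaussian"`).
#' @param drift_sd_um per-frame positional jitter (sd, um) of focus centres;
#'   0 gives perfectly stationary foci.
#' @param seed integer seed; identical configurations with identical seeds
#'   produce bit-identical output.
#' @return An object of class `scenario_config` (validated named list).
#' @seealso [symmetric_scenario()], [generate_kymograph()]
#' @examples
#' cfg <- scenario_config(seed = 1)
#' cfg$duration_mean_s
#' @export
scenario_config <- function(n_frames = 101,
                            frame_interval_s = 15,
                            pixel_size_um = 0.198,
                            cortex_length_um = 120,
                            regions = region_spec(),
                            focus_rate_per_um_per_s = 6e-5,
                            duration_mean_s = c(L1 = 40, P = 100, L2 = 40),
                            duration_shape = 10,
                            focus_amplitude = 400,
                            focus_sigma_um = 1.0,
                            background_level = 40,
                            noise_model = c("gaussian", "poisson", "none"),
                            gaussian_sd = 4,
                            drift_sd_um = 0,
                            seed = NULL) {
  noise_model <- match.arg(noise_model)
  cfg <- structure(list(
    n_frames = as.integer(n_frames),
    frame_interval_s = as.numeric(frame_interval_s),
    pixel_size_um = as.numeric(pixel_size_um),
    cortex_length_um = as.numeric(cortex_length_um),
    regions = regions,
    focus_rate_per_um_per_s = as.numeric(focus_rate_per_um_per_s),
    duration_mean_s = duration_mean_s,
    duration_shape = as.numeric(duration_shape),
    focus_amplitude = as.numeric(focus_amplitude),
    focus_sigma_um = as.numeric(focus_sigma_um),
    background_level = as.numeric(background_level),
    noise_model = noise_model,
    gaussian_sd = as.numeric(gaussian_sd),
    drift_sd_um = as.numeric(drift_sd_um),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "scenario_config")
  validate_scenario(cfg)
  cfg
}

#' Symmetric (kinase-inhibited-like) scenario
#'
#' The same generator with no posterior enrichment: all region means equal
#' the lateral mean, emulating a cortex in which myosin-light-chain-kinase
#' inhibition has abolished the posterior-specific long pulses.
#'
#' @param duration_s common mean pulse duration (s) for all regions.
#' @param ... passed on to [scenario_config()].
#' @return A `scenario_config`.
#' @export
symmetric_scenario <- function(duration_s = 40, ...) {
  scenario_config(duration_mean_s = c(L1 = duration_s, P = duration_s,
                                      L2 = duration_s), ...)
}

#' Validate a scenario configuration
#'
#' Checks every invariant of the scenario and fails with a single error
#' listing all offending fields.
#'
#' @param cfg a `scenario_config`.
#' @return `cfg`, invisibly, if valid.
#' @export
validate_scenario <- function(cfg) {
  bad <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) bad <<- c(bad, msg)
  chk(is.numeric(cfg$n_frames) && cfg$n_frames >= 2,
      "n_frames: must be >= 2")
  chk(cfg$frame_interval_s > 0, "frame_interval_s: must be > 0")
  chk(cfg$pixel_size_um > 0, "pixel_size_um: must be > 0")
  chk(cfg$cortex_length_um > 0, "cortex_length_um: must be > 0")
  chk(inherits(cfg$regions, "region_spec"), "regions: not a region_spec")
  chk(cfg$focus_rate_per_um_per_s >= 0,
      "focus_rate_per_um_per_s: must be >= 0")
  chk(cfg$duration_shape > 0, "duration_shape: must be > 0")
  chk(cfg$focus_sigma_um >= 0, "focus_sigma_um: must be >= 0")
  chk(cfg$background_level >= 0, "background_level: must be >= 0")
  chk(cfg$focus_amplitude > cfg$background_level,
      "focus_amplitude: must exceed background_level")
  chk(cfg$gaussian_sd >= 0, "gaussian_sd: must be >= 0")
  chk(cfg$drift_sd_um >= 0, "drift_sd_um: must be >= 0")
  if (inherits(cfg$regions, "region_spec")) {
    rn <- names(cfg$regions)
    chk(all(rn %in% names(cfg$duration_mean_s)),
        "duration_mean_s: missing a mean for some region")
    chk(all(cfg$duration_mean_s[names(cfg$duration_mean_s) %in% rn] > 0),
        "duration_mean_s: all means must be > 0")
    half <- cfg$cortex_length_um / 2
    inside <- vapply(cfg$regions, function(w)
      w[1] >= -half - 1e-9 && w[2] <= half + 1e-9, logical(1))
    chk(all(inside),
        "regions: windows must lie within [-cortex_length_um/2, +cortex_length_um/2]")
  }
  if (length(bad))
    stop("invalid scenario_config:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  invisible(cfg)
}

#' @export
print.scenario_config <- function(x, ...) {
  mins <- (x$n_frames - 1) * x$frame_interval_s / 60
  cat(sprintf("Synthetic imaging scenario: %d frames @ %gs (%.1f min), %g um/px\n",
              x$n_frames, x$frame_interval_s, mins, x$pixel_size_um))
  cat(sprintf("  cortex %g um; focus rate %g /um/s; amplitude %g over background %g\n",
              x$cortex_length_um, x$focus_rate_per_um_per_s,
              x$focus_amplitude, x$background_level))
  cat("  mean pulse duration (s):",
      paste(sprintf("%s=%g", names(x$duration_mean_s), x$duration_mean_s),
            collapse = ", "),
      sprintf("(gamma shape %g)\n", x$duration_shape))
  cat(sprintf("  noise: %s%s; drift sd %g um; seed %s\n", x$noise_model,
              if (x$noise_model == "gaussian") sprintf(" (sd %g)", x$gaussian_sd) else "",
              x$drift_sd_um,
              if (is.null(x$seed)) "unset" else format(x$seed)))
  invisible(x)
}

# Read/write scenario configurations as flat YAML or JSON.

#' Read or write a scenario configuration file
#'
#' Configurations are stored flat (field names as in [scenario_config()]),
#' with region windows under a `regions:` mapping.  Format is chosen by
#' file extension: `.yaml`/`.yml` or `.json`.
#'
#' @param path file path.
#' @return `read_scenario()` returns a `scenario_config`.
#' @export
read_scenario <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  args <- raw
  if (!is.null(raw$regions))
    args$regions <- do.call(region_spec, lapply(raw$regions, as.numeric))
  if (!is.null(raw$duration_mean_s))
    args$duration_mean_s <- unlist(raw$duration_mean_s)
  do.call(scenario_config, args)
}

#' @rdname read_scenario
#' @param cfg a `scenario_config`.
#' @export
write_scenario <- function(cfg, path) {
  out <- unclass(cfg)
  out$regions <- lapply(unclass(cfg$regions), as.numeric)
  out$duration_mean_s <- as.list(cfg$duration_mean_s)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  else yaml::write_yaml(out, path)
  invisible(path)
}
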