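# Standard-format readers/writers and the four pipeline entry points
# (simulate / pulses / crescent / compare).  TIFFs are written as 32-bit
# float with the calibration in a JSON sidecar; CSVs are
# comma-separated, UTF-8, header row, '.' decimal.

# tiff stores [0,1] floats; the intensity scale and the calibration
# travel in a JSON sidecar (<path>.json) so they survive any TIFF writer.
write_calibrated_tiff <- function(frames, path, frame_interval_s,
                                  pixel_size_um) {
  mx <- max(vapply(frames, max, numeric(1)), 1)
  tiff::writeTIFF(lapply(frames, function(f) f / mx), path,
                  bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(frame_interval_s = frame_interval_s,
                            pixel_size_um = pixel_size_um,
                            intensity_scale = mx),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

read_calibrated_tiff <- function(path, frame_interval_s = NULL,
                                 pixel_size_um = NULL) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  meta_file <- paste0(path, ".json")
  meta <- if (file.exists(meta_file))
    tryCatch(jsonlite::read_json(meta_file), error = function(e) NULL)
  else NULL
  scale <- 1
  if (!is.null(meta)) {
    frame_interval_s <- frame_interval_s %||% meta$frame_interval_s
    pixel_size_um <- pixel_size_um %||% meta$pixel_size_um
    scale <- meta$intensity_scale %||% 1
  }
  if (is.null(frame_interval_s) || is.null(pixel_size_um))
    stop("no calibration metadata in '", path, "'; supply frame_interval_s ",
         "and pixel_size_um explicitly (CLI: --frame-interval / --pixel-size)")
  list(frames = lapply(frames, function(f) {
         if (length(dim(f)) == 3L) f <- f[, , 1]   # tolerate RGB exports
         f * scale
       }),
       frame_interval_s = frame_interval_s, pixel_size_um = pixel_size_um)
}

#' Read and write calibrated movies as multi-page TIFF
#'
#' Frames are stored as 32-bit float pages; the frame interval, pixel
#' size and intensity scale live in a JSON sidecar (`<path>.json`) and
#' are restored on read (explicit arguments override).
#'
#' @param movie a [frame_stack()].
#' @param path TIFF file path.
#' @return `read_movie_tiff()` returns a `frame_stack`.
#' @export
write_movie_tiff <- function(movie, path) {
  stopifnot(inherits(movie, "frame_stack"))
  d <- dim(movie$data)
  frames <- lapply(seq_len(d[3]), function(t) movie$data[, , t])
  write_calibrated_tiff(frames, path, movie$frame_interval_s,
                        movie$pixel_size_um)
}

#' @rdname write_movie_tiff
#' @param frame_interval_s,pixel_size_um calibration overrides (required
#'   if the file carries no metadata).
#' @export
read_movie_tiff <- function(path, frame_interval_s = NULL,
                            pixel_size_um = NULL) {
  r <- read_calibrated_tiff(path, frame_interval_s, pixel_size_um)
  d <- dim(r$frames[[1]])
  data <- array(0, dim = c(d[1], d[2], length(r$frames)))
  for (t in seq_along(r$frames)) data[, , t] <- r$frames[[t]]
  frame_stack(data, r$frame_interval_s, r$pixel_size_um)
}

#' Read and write kymographs as TIFF plus a sidecar CSV
#'
#' The intensity matrix (positions x frames) goes to `path`; arc
#' coordinates and region labels go to a sidecar `<path>.csv` with
#' columns `arc_um`, `region`.
#'
#' @param kymo a [kymograph].
#' @param path TIFF file path.
#' @return `read_kymograph_tiff()` returns a [kymograph].
#' @export
write_kymograph_tiff <- function(kymo, path) {
  stopifnot(inherits(kymo, "kymograph"))
  write_calibrated_tiff(list(kymo$data), path, kymo$frame_interval_s,
                        kymo$pixel_size_um)
  write.csv(data.frame(arc_um = kymo$arc_um, region = kymo$region_labels),
            paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_kymograph_tiff
#' @inheritParams read_movie_tiff
#' @export
read_kymograph_tiff <- function(path, frame_interval_s = NULL,
                                pixel_size_um = NULL) {
  r <- read_calibrated_tiff(path, frame_interval_s, pixel_size_um)
  side <- read.csv(paste0(path, ".csv"))
  new_kymograph(r$frames[[1]], arc_um = side$arc_um,
                frame_interval_s = r$frame_interval_s,
                pixel_size_um = r$pixel_size_um,
                region_labels = as.character(side$region))
}

#' Read a traced polyline from CSV
#'
#' Accepts a plain two-column CSV (`row`, `col`, pixel coordinates, e.g.
#' an ImageJ point list export saved with those headers).  The posterior
#' pole is marked either by an optional `pole` column (1 on the pole
#' vertex) or by passing `pole_point`.
#'
#' @param path CSV path.
#' @param pole_point optional `(row, col)` overriding any `pole` column.
#' @return A list with `vertices` (matrix) and `pole_point`.
#' @export
read_path_csv <- function(path, pole_point = NULL) {
  df <- read.csv(path)
  if (!all(c("row", "col") %in% names(df)))
    stop("path CSV needs columns 'row' and 'col': ", path)
  v <- cbind(row = df$row, col = df$col)
  if (is.null(pole_point)) {
    if ("pole" %in% names(df) && any(df$pole == 1))
      pole_point <- v[which(df$pole == 1)[1], ]
    else stop("no pole marked: add a 'pole' column or pass pole_point")
  }
  list(vertices = v, pole_point = as.numeric(pole_point))
}

#' Write pulse events / ground truth / summaries as CSV
#'
#' @param x the object to write.
#' @param path CSV path.
#' @name cortexpulse-csv
NULL

#' @rdname cortexpulse-csv
#' @export
write_events_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname cortexpulse-csv
#' @export
write_ground_truth_csv <- function(x, path) {
  foci <- if (inherits(x, "ground_truth")) x$foci else x
  write.csv(foci, path, row.names = FALSE)
  invisible(path)
}

#' @rdname cortexpulse-csv
#' @export
write_summary_csv <- function(x, path) {
  stopifnot(inherits(x, "pulse_summary"))
  pooled <- do.call(rbind, lapply(names(x$pooled), function(r) {
    if (!length(x$pooled[[r]])) return(NULL)
    data.frame(region = r, block = seq_along(x$pooled[[r]]),
               pooled_mean_s = x$pooled[[r]])
  }))
  write.csv(merge(x$stats, pooled %||% data.frame(region = character(0),
                                                  block = integer(0),
                                                  pooled_mean_s = numeric(0)),
                  by = "region", all.x = TRUE),
            path, row.names = FALSE)
  invisible(path)
}

# Run manifest: inputs, config hash, seed, package/R versions.  No
# timestamp, so reruns with the same seed are byte-identical.
write_manifest <- function(dir, cfg, seed, inputs = list()) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  if (inherits(cfg, "scenario_config")) write_scenario(cfg, tmp)
  else yaml::write_yaml(cfg, tmp)
  manifest <- list(
    package = "cortexpulse",
    version = as.character(utils::packageVersion("cortexpulse")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config_md5 = unname(tools::md5sum(tmp)),
    inputs = inputs)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Pipeline entry points
#'
#' The four stages of the reproducible pipeline, as called by the
#' `inst/cli/cortexpulse` command-line script.  Each writes its declared
#' files into `out_dir` together with a `manifest.json` (inputs, config
#' hash, seed, versions) and returns the paths invisibly.
#'
#' * `run_simulate()`: synthetic kymograph TIFF (+ sidecar CSV) and
#'   ground-truth CSV; optionally the full movie TIFF and path CSV.
#' * `run_pulses()`: extract -> threshold -> segment -> measure -> pool;
#'   writes kymograph TIFF, mask TIFF, events CSV and summary CSV.
#' * `run_crescent()`: profile + metrics CSV from an image and two paths.
#' * `run_compare()`: ANOVA/ratio comparison as JSON and flat CSV.
#'
#' @param cfg a [scenario_config()] (or path to its YAML/JSON file).
#' @param out_dir output directory (created if missing).
#' @param seed integer seed recorded in the manifest; overrides the
#'   config seed when given.
#' @param write_movie also write the (large) movie TIFF and its cortical
#'   path CSV.
#' @return Invisibly, a named list of written file paths.
#' @name pipeline
NULL

as_scenario <- function(cfg) {
  if (inherits(cfg, "scenario_config")) cfg else read_scenario(cfg)
}

#' @rdname pipeline
#' @export
run_simulate <- function(cfg, out_dir, seed = NULL, write_movie = FALSE) {
  cfg <- as_scenario(cfg)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (is.null(cfg$seed)) stop("a seed is required for reproducible output")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- generate_kymograph(cfg)
  paths <- list(kymograph = file.path(out_dir, "kymograph.tif"),
                ground_truth = file.path(out_dir, "ground_truth.csv"))
  write_kymograph_tiff(sim$kymograph, paths$kymograph)
  write_ground_truth_csv(sim$truth, paths$ground_truth)
  if (write_movie) {
    mv <- generate_movie(cfg)
    paths$movie <- file.path(out_dir, "movie.tif")
    paths$path <- file.path(out_dir, "cortex_path.csv")
    write_movie_tiff(mv$movie, paths$movie)
    v <- mv$path$vertices
    write.csv(data.frame(row = v[, 1], col = v[, 2],
                         pole = as.integer(seq_len(nrow(v)) ==
                                             mv$path$pole_index)),
              paths$path, row.names = FALSE)
  }
  write_manifest(out_dir, cfg, cfg$seed)
  invisible(paths)
}

#' @rdname pipeline
#' @param movie path to a movie TIFF (or a [frame_stack()]).
#' @param path path to a traced-polyline CSV (or a list as returned by
#'   [read_path_csv()]).
#' @param frame_interval_s,pixel_size_um calibration overrides.
#' @param band_halfwidth_px kymograph band half-width.
#' @param regions a [region_spec()].
#' @param method,k thresholding settings ([threshold_kymograph()]).
#' @param min_pixels,max_drift_um event filters ([measure_pulses()]).
#' @param window pooling window ([pool_durations()]).
#' @export
run_pulses <- function(movie, path, out_dir, seed = 0L,
                       frame_interval_s = NULL, pixel_size_um = NULL,
                       band_halfwidth_px = 1, regions = region_spec(),
                       method = "mad", k = 3, min_pixels = 4,
                       max_drift_um = 2, window = 25) {
  if (is.character(movie))
    movie <- read_movie_tiff(movie, frame_interval_s, pixel_size_um)
  if (is.character(path)) path <- read_path_csv(path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cpath <- resample_path(path$vertices, path$pole_point,
                         movie$pixel_size_um)
  kymo <- extract_kymograph(movie, cpath,
                            band_halfwidth_px = band_halfwidth_px)
  kymo <- assign_regions(kymo, regions)
  binary <- threshold_kymograph(kymo, method = method, k = k)
  comps <- segment_pulses(binary)
  events <- measure_pulses(comps, kymo, min_pixels = min_pixels,
                           max_drift_um = max_drift_um, verbose = TRUE)
  summary <- pool_durations(events, window = window)
  paths <- list(kymograph = file.path(out_dir, "kymograph.tif"),
                mask = file.path(out_dir, "mask.tif"),
                events = file.path(out_dir, "events.csv"),
                summary = file.path(out_dir, "summary.csv"))
  write_kymograph_tiff(kymo, paths$kymograph)
  write_calibrated_tiff(list(binary$mask * 1), paths$mask,
                        kymo$frame_interval_s, kymo$pixel_size_um)
  write_events_csv(events, paths$events)
  write_summary_csv(summary, paths$summary)
  write_manifest(out_dir,
                 list(band_halfwidth_px = band_halfwidth_px,
                      method = method, k = k, min_pixels = min_pixels,
                      max_drift_um = max_drift_um, window = window),
                 seed)
  invisible(paths)
}

#' @rdname pipeline
#' @param image path to a single-frame TIFF (or a matrix).
#' @param oocyte_path,follicle_path polyline CSVs (or [read_path_csv()]
#'   lists) tracing the oocyte cortex and the follicle reference band.
#' @export
run_crescent <- function(image, oocyte_path, follicle_path, out_dir,
                         seed = 0L, pixel_size_um = NULL,
                         band_halfwidth_px = 1, regions = region_spec()) {
  if (is.character(image)) {
    r <- read_calibrated_tiff(image, frame_interval_s = 1,
                              pixel_size_um = pixel_size_um)
    pixel_size_um <- r$pixel_size_um
    image <- r$frames[[1]]
  }
  if (is.null(pixel_size_um)) stop("pixel_size_um required")
  if (is.character(oocyte_path)) oocyte_path <- read_path_csv(oocyte_path)
  if (is.character(follicle_path))
    follicle_path <- read_path_csv(follicle_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  oo <- resample_path(oocyte_path$vertices, oocyte_path$pole_point,
                      pixel_size_um)
  fc <- resample_path(follicle_path$vertices, follicle_path$pole_point,
                      pixel_size_um)
  raw <- profile_along_cortex(image, oo, band_halfwidth_px)
  ref <- profile_along_cortex(image, fc, band_halfwidth_px)
  prof <- normalize_profile(raw, ref)
  metrics <- profile_metrics(prof, regions = regions)
  paths <- list(profile = file.path(out_dir, "profile.csv"),
                metrics = file.path(out_dir, "metrics.csv"))
  write.csv(as.data.frame(prof), paths$profile, row.names = FALSE)
  write.csv(metrics, paths$metrics, row.names = FALSE)
  write_manifest(out_dir, list(band_halfwidth_px = band_halfwidth_px),
                 seed)
  invisible(paths)
}

#' @rdname pipeline
#' @param events one or more events CSVs (or `pulse_events` data frames)
#'   whose events are pooled before comparison.
#' @param n_boot bootstrap resamples for the ratio CI.
#' @export
run_compare <- function(events, out_dir, seed = 0L, n_boot = 2000) {
  if (!is.list(events) || is.data.frame(events)) events <- list(events)
  evs <- lapply(events, function(e)
    if (is.character(e)) read.csv(e) else as.data.frame(e))
  ev <- do.call(rbind, evs)
  class(ev) <- c("pulse_events", "data.frame")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cmp <- compare_regions(ev, n_boot = n_boot, seed = seed)
  paths <- list(json = file.path(out_dir, "comparison.json"),
                csv = file.path(out_dir, "comparison.csv"))
  jsonlite::write_json(unclass(cmp), paths$json, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  write.csv(data.frame(group = cmp$groups, n = as.integer(cmp$n),
                       mean_s = as.numeric(cmp$means_s),
                       F_statistic = cmp$F_statistic,
                       p_value = cmp$p_value,
                       posterior_lateral_ratio = cmp$posterior_lateral_ratio,
                       ratio_ci_lo = cmp$ratio_ci_95[1],
                       ratio_ci_hi = cmp$ratio_ci_95[2]),
            paths$csv, row.names = FALSE)
  write_manifest(out_dir, list(n_boot = n_boot), seed)
  invisible(paths)
}
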