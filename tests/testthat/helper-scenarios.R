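# Shared fixtures: scaled-down scenarios so unit tests run in seconds.

`%||%` <- function(a, b) if (is.null(a)) b else a

small_regions <- function() {
  region_spec(L1 = c(-15, -8), P = c(-4, 4), L2 = c(8, 15))
}

small_config <- function(...) {
  args <- utils::modifyList(
    list(n_frames = 41, cortex_length_um = 40, regions = small_regions(),
         duration_mean_s = c(L1 = 40, P = 100, L2 = 40)),
    list(...))
  do.call(scenario_config, args)
}

# A single hand-placed focus, bypassing the Poisson sampler.
forced_focus <- function(region = "P", arc_um = 0, onset_s = 60,
                         offset_s = 150) {
  data.frame(region = region, arc_um = arc_um, onset_s = onset_s,
             offset_s = offset_s, duration_s = offset_s - onset_s)
}

# Render a kymograph from hand-placed foci (no Poisson draw, no noise).
render_forced <- function(foci, cfg) {
  arc <- cortexpulse:::arc_grid(cfg)
  times <- cortexpulse:::frame_times(cfg)
  data <- cortexpulse:::render_foci(foci, cfg, arc, times)
  kymo <- cortexpulse:::new_kymograph(data, arc_um = arc,
                                      frame_interval_s = cfg$frame_interval_s,
                                      pixel_size_um = cfg$pixel_size_um)
  assign_regions(kymo, cfg$regions)
}

# Straight horizontal path through a synthetic frame.
straight_path <- function(row, col_from, col_to, pixel_size_um,
                          pole = c(row, col_from)) {
  resample_path(rbind(c(row, col_from), c(row, col_to)),
                pole_point = pole, pixel_size_um = pixel_size_um)
}
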