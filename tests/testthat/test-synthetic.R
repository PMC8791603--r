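test_that("zero focus rate with no noise gives a flat background and empty truth", {
  cfg <- small_config(focus_rate_per_um_per_s = 0, noise_model = "none",
                      seed = 1)
  sim <- generate_kymograph(cfg)
  expect_equal(nrow(sim$truth$foci), 0)
  expect_true(all(sim$kymograph$data == cfg$background_level))
})

test_that("a forced pulse contributes intensity only within its envelope support", {
  cfg <- small_config(noise_model = "none")
  kymo <- render_forced(forced_focus(onset_s = 60, offset_s = 150), cfg)
  excess <- colSums(kymo$data - cfg$background_level)
  frames <- seq_len(ncol(kymo$data)) - 1L          # 0-based
  # support is t in [60, 150] s = frames 4..10; the raised-cosine envelope
  # is exactly zero at its endpoints, so strictly positive only inside
  expect_true(all(excess[frames < 4 | frames > 10] == 0))
  expect_true(all(excess[frames >= 5 & frames <= 9] > 0))
})

test_that("identical config and seed give bit-identical output", {
  cfg <- small_config(seed = 99)
  a <- generate_kymograph(cfg)
  b <- generate_kymograph(cfg)
  expect_identical(a$kymograph$data, b$kymograph$data)
  expect_identical(a$truth$foci, b$truth$foci)
  c <- generate_kymograph(small_config(seed = 100))
  expect_false(identical(a$kymograph$data, c$kymograph$data))
})

test_that("ground-truth foci land inside their region windows with offset > onset", {
  cfg <- small_config(focus_rate_per_um_per_s = 5e-3, seed = 5)
  foci <- generate_kymograph(cfg)$truth$foci
  expect_gt(nrow(foci), 30)
  expect_true(all(foci$offset_s > foci$onset_s))
  expect_equal(foci$duration_s, foci$offset_s - foci$onset_s)
  for (nm in names(cfg$regions)) {
    w <- cfg$regions[[nm]]
    pos <- foci$arc_um[foci$region == nm]
    expect_true(all(pos >= w[1] & pos <= w[2]))
  }
})

test_that("sampled durations match the configured gamma law (vs naive re-draw)", {
  # boost the rate so a single draw yields >= 2000 foci
  cfg <- scenario_config(focus_rate_per_um_per_s = 3e-2, seed = 21)
  foci <- generate_kymograph(cfg)$truth$foci
  expect_gt(nrow(foci), 2000)
  cv <- 1 / sqrt(cfg$duration_shape)
  for (nm in names(cfg$regions)) {
    d <- foci$duration_s[foci$region == nm]
    mu <- cfg$duration_mean_s[[nm]]
    sem <- mu * cv / sqrt(length(d))
    expect_lt(abs(mean(d) - mu), 3 * sem)
    # independent re-draw with a naive inverse-CDF gamma sampler
    set.seed(1000 + match(nm, names(cfg$regions)))
    ref <- naive_gamma(length(d), mu, cfg$duration_shape)
    expect_lt(abs(mean(d) - mean(ref)), 3 * sqrt(2) * sem)
    expect_lt(abs(sd(d) / mean(d) - cv), 3 * cv / sqrt(length(d)))
  }
})

test_that("foci are spatially stationary when drift is zero", {
  cfg <- small_config(noise_model = "none")
  kymo <- render_forced(forced_focus(arc_um = 1.3, onset_s = 60,
                                     offset_s = 300), cfg)
  excess <- kymo$data - cfg$background_level
  live <- which(colSums(excess) > 0)
  centroids <- vapply(live, function(j)
    sum(kymo$arc_um * excess[, j]) / sum(excess[, j]), numeric(1))
  expect_lt(diff(range(centroids)), cfg$pixel_size_um)
})

test_that("noise-free total intensity equals the analytic space-time integral", {
  cfg <- scenario_config(focus_rate_per_um_per_s = 3e-4,
                         noise_model = "none", seed = 13)
  sim <- generate_kymograph(cfg)
  foci <- sim$truth$foci
  # clip each pulse to the recorded time span before integrating h(t)
  t_total <- (cfg$n_frames - 1) * cfg$frame_interval_s
  h_int <- vapply(seq_len(nrow(foci)), function(i) {
    f <- foci[i, ]
    integrate(function(t) cortexpulse:::pulse_envelope(t, f$onset_s,
                                                       f$offset_s),
              max(f$onset_s, 0), min(f$offset_s, t_total))$value
  }, numeric(1))
  analytic <- sum(cfg$focus_amplitude * sqrt(2 * pi) * cfg$focus_sigma_um *
                    h_int)
  measured <- sum(sim$kymograph$data - cfg$background_level) *
    cfg$pixel_size_um * cfg$frame_interval_s
  expect_lt(abs(measured - analytic) / analytic, 0.01)
})

test_that("a movie embeds the cortex so extraction recovers the kymograph", {
  cfg <- small_config(focus_rate_per_um_per_s = 4e-4, noise_model = "none",
                      seed = 31)
  mv <- generate_movie(cfg)
  ky <- generate_kymograph(cfg)
  expect_identical(mv$truth$foci, ky$truth$foci)   # same seed, same truth
  # centreline extraction keeps the bilinear support inside the 3 px band
  rec <- extract_kymograph(mv$movie, mv$path, band_halfwidth_px = 0)
  expect_equal(rec$arc_um, ky$kymograph$arc_um)
  rel <- abs(rec$data - ky$kymograph$data) / ky$kymograph$data
  expect_lt(max(rel), 0.05)
  # a wider painted band admits the default +-1 px sampling band
  mv5 <- generate_movie(cfg, band_halfwidth_px = 2)
  rec5 <- extract_kymograph(mv5$movie, mv5$path, band_halfwidth_px = 1)
  rel5 <- abs(rec5$data - ky$kymograph$data) / ky$kymograph$data
  expect_lt(max(rel5), 0.05)
})

test_that("the default movie spans 25 minutes and fails when the frame is too small", {
  cfg <- scenario_config(seed = 1)
  expect_equal((cfg$n_frames - 1) * cfg$frame_interval_s, 1500)
  expect_error(generate_movie(small_config(seed = 1),
                              frame_shape = c(30, 30)),
               "does not fit")
})

test_that("crescent scenes expose the analytic ratio profile", {
  cfg0 <- small_config(noise_model = "none")
  flat <- generate_crescent_image(cfg0, crescent_amplitude = 0)
  expect_equal(diff(range(flat$truth$crescent_truth$ratio)), 0)

  sc <- generate_crescent_image(cfg0, crescent_amplitude = 80,
                                crescent_halfwidth_um = 3)
  tr <- sc$truth$crescent_truth
  base <- cfg0$background_level
  expect_equal(tr$ratio[tr$arc_um == 0], (base + 80) / sc$reference_level)
  far <- abs(tr$arc_um) > 5 * 3
  expect_gt(sum(far), 10)
  expect_lt(max(abs(tr$ratio[far] - base / sc$reference_level)), 1e-4)
  expect_error(generate_crescent_image(cfg0, crescent_halfwidth_um = 0),
               "crescent_halfwidth_um")
})
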