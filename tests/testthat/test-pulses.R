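mini_kymo <- function(data, dt = 15, px = 0.5, labels = NULL) {
  cortexpulse:::new_kymograph(data, arc_um = (seq_len(nrow(data)) - 1) * px,
                              frame_interval_s = dt, pixel_size_um = px,
                              region_labels = labels)
}

test_that("thresholding follows the declared rule for each method", {
  k <- mini_kymo(matrix(c(4, 5, 6), 1))
  b <- threshold_kymograph(k, method = "absolute", value = 5)
  expect_identical(as.vector(b$mask), c(FALSE, FALSE, TRUE))

  expect_warning(bc <- threshold_kymograph(mini_kymo(matrix(3, 5, 5))),
                 "MAD")
  expect_false(any(bc$mask))

  expect_error(threshold_kymograph(k, k = 0), "k must be > 0")
  expect_error(threshold_kymograph(k, method = "absolute"), "value")

  set.seed(4)
  x <- matrix(c(rnorm(500, 10, 1), rnorm(60, 40, 1)), 28)
  b2 <- threshold_kymograph(mini_kymo(x), method = "mad", k = 3)
  expect_equal(b2$threshold_value, median(x) + 3 * mad(x))
  expect_identical(b2$mask, x > b2$threshold_value)
})

test_that("Otsu separates a two-level image and agrees with exhaustive search", {
  x <- matrix(c(rep(10, 100), rep(100, 100)), 20)
  b <- threshold_kymograph(mini_kymo(x), method = "otsu")
  expect_true(b$threshold_value > 10 && b$threshold_value < 100)
  expect_identical(b$mask, x > 10)

  set.seed(11)
  for (i in 1:5) {
    y <- matrix(c(rnorm(300, 20, 4), rnorm(120, 70, 8)), 20)
    got <- threshold_kymograph(mini_kymo(y), method = "otsu")$threshold_value
    want <- otsu_oracle(y)
    # the histogram-based threshold must achieve (essentially) the same
    # between-class variance as the exhaustive optimum, and split the
    # sample almost identically
    bcv <- function(th) {
      lo <- y[y <= th]; hi <- y[y > th]
      w0 <- length(lo) / length(y)
      w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    }
    expect_gte(bcv(got), 0.995 * bcv(want))
    expect_lt(abs(sum(y > got) - sum(y > want)), 5)
  }
})

test_that("detection masks are invariant under affine intensity rescaling", {
  cfg <- small_config(seed = 17)
  kymo <- generate_kymograph(cfg)$kymograph
  scaled <- kymo
  scaled$data <- 2.5 * kymo$data + 30
  for (m in c("mad", "otsu")) {
    b1 <- threshold_kymograph(kymo, method = m)
    b2 <- threshold_kymograph(scaled, method = m)
    expect_identical(b1$mask, b2$mask)
    e1 <- measure_pulses(segment_pulses(b1), kymo)
    e2 <- measure_pulses(segment_pulses(b2), scaled)
    expect_equal(e1$duration_s, e2$duration_s)
    expect_equal(e1$frame_min, e2$frame_min)
  }
})

test_that("segmentation groups 8-connected pixels into deterministic components", {
  m <- matrix(FALSE, 10, 10)
  m[2:3, 2:3] <- TRUE          # block A, frames 2-3
  m[7:8, 6:7] <- TRUE          # block B, frames 6-7
  b <- structure(list(mask = m, arc_um = seq_len(10) * 0.5,
                      region_labels = rep("P", 10),
                      frame_interval_s = 15, pixel_size_um = 0.5),
                 class = "binary_kymograph")
  comps <- segment_pulses(b)
  expect_equal(comps$n, 2)
  expect_equal(as.integer(table(comps$labels[comps$labels > 0])), c(4, 4))
  # ids ordered by first frame
  expect_equal(unique(as.vector(comps$labels[2:3, 2:3])), 1L)

  # diagonal contact joins under 8-connectivity
  d <- matrix(FALSE, 4, 4); d[1, 1] <- TRUE; d[2, 2] <- TRUE
  b$mask <- d
  b$arc_um <- seq_len(4) * 0.5; b$region_labels <- rep("P", 4)
  expect_equal(segment_pulses(b)$n, 1)
})

test_that("component partition matches a brute-force flood fill on random masks", {
  set.seed(42)
  for (i in 1:25) {
    m <- matrix(runif(400) < 0.3, 20, 20)
    b <- structure(list(mask = m, arc_um = seq_len(20) * 0.5,
                        region_labels = rep("P", 20),
                        frame_interval_s = 15, pixel_size_um = 0.5),
                   class = "binary_kymograph")
    got <- segment_pulses(b)$labels
    want <- flood_fill_oracle(m, connectivity = 8)
    expect_true(same_partition(got, want))
    # partition property: component sizes sum to the mask count
    expect_equal(sum(got > 0), sum(m))
  }
})

test_that("durations, censoring and drift flags follow the event definitions", {
  data <- matrix(1, 20, 12)
  data[8:10, 4:8] <- 50        # frames 3..7 (0-based), rows 8-10
  data[2:3, 1:2] <- 50         # touches frame 0 -> censored
  kymo <- mini_kymo(data, dt = 15, labels = rep(c("L1", "P"), each = 10))
  ev <- detect_pulses(kymo, method = "absolute", value = 10, min_pixels = 4)
  ev <- ev[order(ev$frame_min), ]
  expect_equal(nrow(ev), 2)
  expect_equal(ev$censored, c(TRUE, FALSE))
  expect_equal(ev$duration_s[2], 75)     # 5 frames x 15 s
  expect_equal(ev$frame_min[2], 3)
  expect_equal(ev$frame_max[2], 7)
  expect_equal(ev$region, c("L1", "L1"))
  expect_true(all(ev$stationary))

  # a component walking along the cortex is flagged non-stationary
  walk <- matrix(1, 30, 10)
  for (j in 1:8) walk[(2 * j):(2 * j + 1), j] <- 50
  kw <- mini_kymo(walk, labels = rep("P", 30))
  evw <- detect_pulses(kw, method = "absolute", value = 10)
  expect_equal(nrow(evw), 1)
  expect_false(evw$stationary)
  expect_gt(evw$centroid_drift_um, 2)

  # min_pixels filter and unassigned-region drop
  tiny <- matrix(1, 10, 6); tiny[5, 3] <- 50
  expect_equal(nrow(detect_pulses(mini_kymo(tiny, labels = rep("P", 10)),
                                  method = "absolute", value = 10)), 0)
  una <- matrix(1, 10, 6); una[4:6, 3:4] <- 50
  expect_equal(nrow(detect_pulses(mini_kymo(una,
                                            labels = rep("unassigned", 10)),
                                  method = "absolute", value = 10)), 0)
})

test_that("shifting the kymograph in time shifts events without changing durations", {
  cfg <- small_config(focus_rate_per_um_per_s = 3e-4, noise_model = "none",
                      seed = 23)
  kymo <- generate_kymograph(cfg)$kymograph
  shift <- 7L
  shifted <- kymo
  n <- ncol(kymo$data)
  shifted$data <- kymo$data[, c((n - shift + 1):n, 1:(n - shift))]
  thr <- cfg$background_level + 0.01 * cfg$focus_amplitude
  e0 <- detect_pulses(kymo, method = "absolute", value = thr)
  e1 <- detect_pulses(shifted, method = "absolute", value = thr)
  # compare events that are whole (non-censored) in both versions
  k0 <- e0[!e0$censored & e0$frame_max + shift < n, ]
  k1 <- e1[!e1$censored & e1$frame_min > shift, ]
  k1 <- k1[order(k1$frame_min, k1$centroid_arc_um), ]
  k0 <- k0[order(k0$frame_min, k0$centroid_arc_um), ]
  expect_equal(k1$frame_min, k0$frame_min + shift)
  expect_equal(k1$duration_s, k0$duration_s)
  expect_equal(k1$centroid_arc_um, k0$centroid_arc_um, tolerance = 1e-9)
})

test_that("pooling averages exact blocks of consecutive measurements", {
  ev <- data.frame(component_id = 1:50, region = "P", frame_min = 1:50,
                   frame_max = 2:51, duration_s = rep(30, 50),
                   n_pixels = 10, peak_intensity = 1,
                   centroid_arc_um = 0, centroid_drift_um = 0,
                   censored = FALSE, stationary = TRUE)
  class(ev) <- c("pulse_events", "data.frame")
  ps <- pool_durations(ev, window = 25)
  expect_equal(ps$pooled$P, c(30, 30))

  ev60 <- ev[rep(1:50, length.out = 60), ]
  ev60$frame_min <- 1:60
  ev60$duration_s <- seq(15, by = 15, length.out = 60)
  ps60 <- pool_durations(ev60, window = 25)
  expect_equal(length(ps60$pooled$P), 2)
  expect_equal(ps60$stats$n_events, 60)   # remainder retained in the count
  expect_equal(ps60$pooled$P, naive_pooled_means(ev60$duration_s, 25))

  set.seed(6)
  evr <- ev60
  evr$duration_s <- rgamma(60, 4, 1 / 10)
  for (w in c(1, 7, 25)) {
    expect_equal(pool_durations(evr, window = w)$pooled$P,
                 naive_pooled_means(evr$duration_s, w))
  }
  expect_error(pool_durations(ev, window = 0), "window")
})

test_that("censored and non-stationary events are excluded from pooled statistics", {
  ev <- data.frame(component_id = 1:4, region = "P", frame_min = c(0, 5, 9, 13),
                   frame_max = c(2, 7, 11, 20), duration_s = c(45, 45, 45, 120),
                   n_pixels = 10, peak_intensity = 1, centroid_arc_um = 0,
                   centroid_drift_um = c(0, 0, 5, 0),
                   censored = c(TRUE, FALSE, FALSE, FALSE),
                   stationary = c(TRUE, TRUE, FALSE, TRUE))
  class(ev) <- c("pulse_events", "data.frame")
  ps <- pool_durations(ev, window = 2)
  expect_equal(ps$stats$n_events, 2)
  expect_equal(ps$pooled$P, mean(c(45, 120)))
  ps_all <- pool_durations(ev, window = 2, include_censored = TRUE,
                           stationary_only = FALSE)
  expect_equal(ps_all$stats$n_events, 4)
})

test_that("measured durations recover ground truth for isolated foci", {
  # noise-free movies at the default focus density; low absolute
  # threshold so the envelope support is nearly fully captured
  nfail <- 0; ntot <- 0
  for (i in 1:100) {
    cfg <- scenario_config(seed = 300 + i, noise_model = "none")
    sim <- generate_kymograph(cfg)
    ev <- detect_pulses(sim$kymograph, method = "absolute",
                        value = cfg$background_level +
                          0.005 * cfg$focus_amplitude)
    g <- sim$truth$foci
    whole <- which(g$offset_s <= 1500)
    m <- match_events(ev, sim$truth, cfg$frame_interval_s)
    ok <- m$focus[abs(m$true_duration_s - m$measured_duration_s) <=
                    cfg$frame_interval_s]
    ntot <- ntot + length(whole)
    nfail <- nfail + sum(!(whole %in% ok))
  }
  expect_gt(ntot, 500)
  expect_gte(1 - nfail / ntot, 0.9)
})
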