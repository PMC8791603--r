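# Cortical path resampling and kymograph extraction.
#
# Continuous pixel coordinates follow the R convention: the centre of
# pixel data[i, j] is at (row = i, col = j).  Arc-length coordinates are
# signed micrometres with 0 at the posterior pole; frames are indexed from
# 0 so frame k is at time k * frame_interval_s.

#' Calibrated single-channel movie
#'
#' @param data numeric array `rows x cols x frames` (a single matrix is
#'   accepted as a one-frame movie); all intensities must be >= 0.
#' @param frame_interval_s frame interval in seconds (> 0).
#' @param pixel_size_um pixel size in micrometres (> 0).
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(data, frame_interval_s, pixel_size_um) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a rows x cols x frames array")
  if (any(data < 0)) stop("all intensities must be >= 0")
  if (!isTRUE(frame_interval_s > 0) || !isTRUE(pixel_size_um > 0))
    stop("calibration values frame_interval_s and pixel_size_um must be > 0")
  structure(list(data = data,
                 frame_interval_s = as.numeric(frame_interval_s),
                 pixel_size_um = as.numeric(pixel_size_um)),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("frame_stack: %d x %d px, %d frame(s) @ %gs, %g um/px (%.1f min)\n",
              d[1], d[2], d[3], x$frame_interval_s, x$pixel_size_um,
              (d[3] - 1) * x$frame_interval_s / 60))
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$data)

new_cortical_path <- function(vertices, pole_index, arc_um, pixel_size_um) {
  structure(list(vertices = vertices, pole_index = as.integer(pole_index),
                 arc_um = as.numeric(arc_um),
                 pixel_size_um = as.numeric(pixel_size_um)),
            class = "cortical_path")
}

#' @export
print.cortical_path <- function(x, ...) {
  cat(sprintf("cortical_path: %d samples, arc %+.2f ... %+.2f um (pole at sample %d)\n",
              nrow(x$vertices), min(x$arc_um), max(x$arc_um), x$pole_index))
  invisible(x)
}

#' Resample a traced cortical polyline to uniform arc length
#'
#' Re-parameterizes a user-traced polyline at uniform arc spacing equal to
#' one pixel, by linear interpolation, and anchors the signed arc
#' coordinate at the projection of the posterior-pole point onto the path.
#' Samples are placed at integer multiples of the spacing on both sides of
#' the pole, so arc 0 falls exactly on a sample.
#'
#' @param vertices numeric matrix (or data frame) with columns `row`, `col`
#'   in pixel coordinates; at least 2 distinct vertices.  Duplicate
#'   consecutive vertices are collapsed.
#' @param pole_point length-2 numeric `(row, col)`; must lie within one
#'   pixel of the polyline.
#' @param pixel_size_um pixel size, used both as arc spacing (one pixel)
#'   and to express arc coordinates in micrometres.
#' @return A `cortical_path`: resampled `vertices`, `pole_index`,
#'   signed `arc_um` (strictly increasing, 0 at the pole), `pixel_size_um`.
#' @examples
#' p <- resample_path(rbind(c(10, 10), c(10, 60)), pole_point = c(10, 10),
#'                    pixel_size_um = 0.198)
#' range(p$arc_um)
#' @export
resample_path <- function(vertices, pole_point, pixel_size_um) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L) stop("vertices must have two columns (row, col)")
  storage.mode(v) <- "double"
  keep <- c(TRUE, rowSums(abs(diff(v))) > 0)
  v <- v[keep, , drop = FALSE]
  if (nrow(v) < 2L) stop("need at least 2 distinct vertices")
  if (!isTRUE(pixel_size_um > 0)) stop("pixel_size_um must be > 0")
  seg <- sqrt(rowSums(diff(v)^2))            # segment lengths, px
  cum_px <- c(0, cumsum(seg))
  total_um <- cum_px[length(cum_px)] * pixel_size_um

  # project the pole point onto the polyline
  pole <- as.numeric(pole_point)
  best <- list(dist = Inf, arc_px = NA_real_)
  for (i in seq_len(nrow(v) - 1L)) {
    a <- v[i, ]; b <- v[i + 1L, ]
    ab <- b - a
    t <- sum((pole - a) * ab) / sum(ab^2)
    t <- min(max(t, 0), 1)
    p <- a + t * ab
    d <- sqrt(sum((pole - p)^2))
    if (d < best$dist) best <- list(dist = d, arc_px = cum_px[i] + t * seg[i])
  }
  if (best$dist > 1)
    stop("pole_point is ", format(best$dist, digits = 3),
         " px from the path; it must lie within 1 px")
  pole_um <- best$arc_px * pixel_size_um

  eps <- 1e-9
  n_neg <- floor(pole_um / pixel_size_um + eps)
  n_pos <- floor((total_um - pole_um) / pixel_size_um + eps)
  arc <- (-n_neg:n_pos) * pixel_size_um
  at_px <- (pole_um + arc) / pixel_size_um   # positions along path, px
  at_px <- pmin(pmax(at_px, 0), cum_px[length(cum_px)])
  rows <- approx(cum_px, v[, 1], xout = at_px)$y
  cols <- approx(cum_px, v[, 2], xout = at_px)$y
  new_cortical_path(cbind(row = rows, col = cols),
                    pole_index = n_neg + 1L, arc_um = arc,
                    pixel_size_um = pixel_size_um)
}

# Vectorized bilinear interpolation of matrix `m` at continuous (r, c);
# coordinates are clamped to the matrix extent.
bilinear_sample <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(r, 1), nr)
  c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- r0 + (c0 - 1) * nr
  m[i00] * (1 - fr) * (1 - fc) + m[i00 + 1] * fr * (1 - fc) +
    m[i00 + nr] * (1 - fr) * fc + m[i00 + nr + 1] * fr * fc
}

new_kymograph <- function(data, arc_um, frame_interval_s, pixel_size_um,
                          region_labels = NULL) {
  stopifnot(nrow(data) == length(arc_um))
  if (is.null(region_labels))
    region_labels <- rep("unassigned", nrow(data))
  structure(list(data = data, arc_um = as.numeric(arc_um),
                 frame_interval_s = as.numeric(frame_interval_s),
                 pixel_size_um = as.numeric(pixel_size_um),
                 region_labels = region_labels),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph: %d positions x %d frames (arc %+.1f ... %+.1f um, %gs/frame)\n",
              nrow(x$data), ncol(x$data), min(x$arc_um), max(x$arc_um),
              x$frame_interval_s))
  lab <- table(x$region_labels)
  cat("  region rows:",
      paste(sprintf("%s=%d", names(lab), as.integer(lab)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.kymograph <- function(x) dim(x$data)

#' Display a kymograph
#'
#' @param x a [kymograph].
#' @param ... passed to [graphics::image()].
#' @export
plot.kymograph <- function(x, ...) {
  t_min <- (seq_len(ncol(x$data)) - 1L) * x$frame_interval_s / 60
  graphics::image(x = t_min, y = x$arc_um, z = t(x$data),
                  col = grDevices::hcl.colors(64, "inferno"),
                  xlab = "time (min)", ylab = "arc position (um)", ...)
  invisible(x)
}

#' Extract a kymograph from a movie along a cortical path
#'
#' For every path sample and frame, the intensity is the mean of bilinear
#' samples taken at the path point and at offsets +-1 ... +-band_halfwidth
#' pixels along the local normal to the path (a band of `2 *
#' band_halfwidth_px + 1` samples).
#'
#' @param movie a [frame_stack()].
#' @param path a [cortical_path], e.g. from [resample_path()].
#' @param band_halfwidth_px band half-width in pixels (>= 0).
#' @return A [kymograph]: positions x frames intensity matrix with the
#'   path's arc coordinates; region labels are `"unassigned"` until
#'   [assign_regions()] is called.
#' @details If part of the sampling band falls outside the frame, the
#'   coordinates are clamped to the image border and a warning reports the
#'   affected rows.
#' @export
extract_kymograph <- function(movie, path, band_halfwidth_px = 1) {
  stopifnot(inherits(movie, "frame_stack"), inherits(path, "cortical_path"))
  d <- dim(movie$data)
  if (d[3] < 1L || prod(d) == 0L) stop("empty movie")
  v <- path$vertices
  n <- nrow(v)
  # unit normals from central-difference tangents
  tg <- rbind(v[2, ] - v[1, ],
              (v[-(1:2), , drop = FALSE] - v[seq_len(n - 2L), , drop = FALSE]) / 2,
              v[n, ] - v[n - 1L, ])
  len <- sqrt(rowSums(tg^2))
  nrm <- cbind(-tg[, 2], tg[, 1]) / len
  offs <- -band_halfwidth_px:band_halfwidth_px
  rr <- outer(v[, 1], rep(1, length(offs))) + outer(nrm[, 1], offs)
  cc <- outer(v[, 2], rep(1, length(offs))) + outer(nrm[, 2], offs)
  out_of_bounds <- rr < 1 | rr > d[1] | cc < 1 | cc > d[2]
  if (any(out_of_bounds)) {
    bad_rows <- which(rowSums(out_of_bounds) > 0)
    warning("sampling band exits image bounds at ", length(bad_rows),
            " path row(s) (", paste(head(bad_rows, 5), collapse = ", "),
            if (length(bad_rows) > 5) ", ..." else "",
            "); coordinates clamped to the border")
  }
  kdata <- matrix(0, n, d[3])
  for (t in seq_len(d[3])) {
    s <- bilinear_sample(movie$data[, , t], as.vector(rr), as.vector(cc))
    kdata[, t] <- rowMeans(matrix(s, n, length(offs)))
  }
  new_kymograph(kdata, arc_um = path$arc_um,
                frame_interval_s = movie$frame_interval_s,
                pixel_size_um = path$pixel_size_um)
}

#' Label kymograph rows with cortical regions
#'
#' @param kymo a [kymograph].
#' @param spec a [region_spec()]; every window must lie within the
#'   kymograph's arc range.
#' @return The kymograph with `region_labels` set per row (rows outside
#'   all windows are `"unassigned"`).
#' @export
assign_regions <- function(kymo, spec) {
  stopifnot(inherits(kymo, "kymograph"), inherits(spec, "region_spec"))
  rng <- range(kymo$arc_um)
  for (nm in names(spec)) {
    w <- spec[[nm]]
    if (w[1] < rng[1] - 1e-9 || w[2] > rng[2] + 1e-9)
      stop("region window '", nm, "' [", w[1], ", ", w[2],
           "] lies outside the kymograph arc range [",
           round(rng[1], 3), ", ", round(rng[2], 3), "]")
  }
  labels <- rep("unassigned", length(kymo$arc_um))
  for (nm in names(spec)) {
    w <- spec[[nm]]
    labels[kymo$arc_um >= w[1] & kymo$arc_um <= w[2]] <- nm
  }
  kymo$region_labels <- labels
  kymo
}
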