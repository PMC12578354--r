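#' Bin cell centroids into a density field
#'
#' Counts nuclear centroids in half-open square (2D) or interval (1D) bins
#' tiling the declared domain and divides by bin area to obtain a density
#' field in cells/um^2. Binning conserves counts exactly: the sum of
#' `C * bin area` over bins equals the number of centroids at each frame.
#'
#' @param table centroid data.frame (`x1`, `x2`, `t`, `replicate`); see
#'   [read_centroids()].
#' @param bin_size bin edge length (um), > 0.
#' @param domain list with elements `x1 = c(lo, hi)` and `x2 = c(lo, hi)`
#'   bounding all centroids; each extent must be an integer multiple of
#'   `bin_size`.
#' @param dims 1 or 2. With `dims = 1` counts are collected along x1 only and
#'   converted to areal density with the strip width `diff(domain$x2)`.
#' @return a [density_field()] (raw, unsmoothed).
#' @export
bin_centroids <- function(table, bin_size, domain, dims = 1) {
  stopifnot(bin_size > 0, dims %in% c(1, 2))
  lo1 <- domain$x1[1]; hi1 <- domain$x1[2]
  lo2 <- domain$x2[1]; hi2 <- domain$x2[2]
  n1 <- (hi1 - lo1) / bin_size
  n2 <- (hi2 - lo2) / bin_size
  if (abs(n1 - round(n1)) > 1e-8 || (dims == 2 && abs(n2 - round(n2)) > 1e-8))
    stop("domain extent must be an integer multiple of bin_size")
  n1 <- round(n1); n2 <- round(n2)
  strip <- hi2 - lo2

  if (nrow(table) == 0) {
    warning("empty centroid table: returning all-zero field")
    tf <- 0
  } else {
    bad <- which(table$x1 < lo1 | table$x1 >= hi1 |
                 table$x2 < lo2 | table$x2 >= hi2)
    if (length(bad))
      stop("centroids outside declared domain at rows: ",
           paste(utils::head(bad, 10), collapse = ", "),
           if (length(bad) > 10) " ..." else "")
    tf <- sort(unique(table$t))
  }
  x1c <- lo1 + (seq_len(n1) - 0.5) * bin_size

  if (dims == 1) {
    C <- matrix(0, n1, length(tf))
    if (nrow(table) > 0) {
      i1 <- floor((table$x1 - lo1) / bin_size) + 1
      it <- match(table$t, tf)
      counts <- table(factor(i1, levels = seq_len(n1)),
                      factor(it, levels = seq_along(tf)))
      C <- matrix(as.numeric(counts), n1, length(tf)) / (bin_size * strip)
    }
    density_field(x1 = x1c, t = tf, C = C, bin_size = bin_size,
                  strip_width = strip)
  } else {
    x2c <- lo2 + (seq_len(n2) - 0.5) * bin_size
    C <- array(0, dim = c(n1, n2, length(tf)))
    if (nrow(table) > 0) {
      i1 <- floor((table$x1 - lo1) / bin_size) + 1
      i2 <- floor((table$x2 - lo2) / bin_size) + 1
      it <- match(table$t, tf)
      for (k in seq_along(tf)) {
        sel <- it == k
        if (any(sel)) {
          counts <- table(factor(i1[sel], levels = seq_len(n1)),
                          factor(i2[sel], levels = seq_len(n2)))
          C[, , k] <- matrix(as.numeric(counts), n1, n2) / bin_size^2
        }
      }
    }
    density_field(x1 = x1c, t = tf, C = C, x2 = x2c, bin_size = bin_size,
                  strip_width = strip)
  }
}

# centered moving average with the window shrunk at the boundaries
# (mean over available samples); k = half-width in samples
running_mean <- function(v, k) {
  if (k == 0) return(v)
  n <- length(v)
  cs <- c(0, cumsum(v))
  i <- seq_len(n)
  lo <- pmax(1, i - k); hi <- pmin(n, i + k)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

window_half <- function(window, spacing, axis) {
  if (is.null(window) || window < spacing) {
    if (!is.null(window))
      warning(sprintf("%s window (%g) smaller than grid spacing (%g): identity",
                      axis, window, spacing))
    return(0L)
  }
  w <- round(window / spacing)
  if (w %% 2 == 0) w <- w + 1  # force odd so the average is centered
  as.integer((w - 1) / 2)
}

#' Smooth a density field with separable moving averages
#'
#' Applies a centered moving-average filter along each spatial axis and then
#' along time. Window sizes are given in physical units and converted to an
#' odd number of grid samples (`round(window / spacing)`, forced odd). At
#' domain boundaries the window shrinks to the available samples, so no data
#' are fabricated outside the observed domain. A window smaller than one grid
#' spacing leaves that axis untouched (with a warning).
#'
#' @param field a [density_field()].
#' @param spatial_window spatial window (um); the reference pipeline value is
#'   150 um.
#' @param temporal_window temporal window (hr); the reference pipeline value
#'   is 3 hr 40 min (about 3.667 hr).
#' @return the smoothed [density_field()] with window metadata recorded.
#' @export
smooth_field <- function(field, spatial_window = 150, temporal_window = 11 / 3) {
  C <- field$C
  dx <- if (length(field$x1) > 1) field$x1[2] - field$x1[1] else Inf
  dt <- if (length(field$t) > 1) field$t[2] - field$t[1] else Inf
  ks <- window_half(spatial_window, dx, "spatial")
  kt <- window_half(temporal_window, dt, "temporal")

  if (is_1d_field(field)) {
    if (ks > 0) C <- apply(C, 2, running_mean, k = ks)
    if (kt > 0) C <- t(apply(C, 1, running_mean, k = kt))
    C <- matrix(C, nrow = length(field$x1))
  } else {
    dd <- dim(C)
    if (ks > 0) {
      for (j in seq_len(dd[2])) for (k in seq_len(dd[3]))
        C[, j, k] <- running_mean(C[, j, k], ks)
      for (i in seq_len(dd[1])) for (k in seq_len(dd[3]))
        C[i, , k] <- running_mean(C[i, , k], ks)
    }
    if (kt > 0)
      for (i in seq_len(dd[1])) for (j in seq_len(dd[2]))
        C[i, j, ] <- running_mean(C[i, j, ], kt)
  }
  density_field(x1 = field$x1, t = field$t, C = C, x2 = field$x2,
                bin_size = field$bin_size, strip_width = field$strip_width,
                smooth = list(spatial_um = spatial_window,
                              temporal_hr = temporal_window))
}

#' Collapse a 2D field to a 1D profile
#'
#' Averages the density along the x2 direction (parallel to the scratch),
#' yielding a one-dimensional profile along x1 (perpendicular to the wound).
#' A field that is already 1D is returned unchanged.
#'
#' @param field a [density_field()].
#' @return a 1D [density_field()] with `strip_width` set to the x2 extent.
#' @export
collapse_to_1d <- function(field) {
  if (is_1d_field(field)) return(field)
  C1 <- apply(field$C, c(1, 3), mean)
  strip <- length(field$x2) * field$bin_size
  density_field(x1 = field$x1, t = field$t, C = C1,
                bin_size = field$bin_size, strip_width = strip,
                smooth = field$smooth)
}

#' Locate wound edges in a 1D density profile
#'
#' Finds the innermost crossings of `C = threshold_fraction * plateau`, where
#' the plateau density is the mean over the outer 20% of bins (10% on each
#' side). Crossings are linearly interpolated between bin centers. If the
#' trough never drops below the threshold the wound is flagged closed and
#' both edges coincide at the trough center.
#'
#' @param field a 1D [density_field()].
#' @param t frame time (hr); the nearest frame is used.
#' @param threshold_fraction fraction of the plateau density defining the
#'   edge, in (0, 1); default 0.5 (half-maximum).
#' @return list with `left`, `right` (um), `width` (um), `closed` flag and
#'   the frame time used.
#' @export
detect_wound_edges <- function(field, t, threshold_fraction = 0.5) {
  stopifnot(is_1d_field(field), threshold_fraction > 0, threshold_fraction < 1)
  j <- which.min(abs(field$t - t))
  prof <- field$C[, j]
  x <- field$x1
  n <- length(x)
  n_out <- max(1L, ceiling(0.1 * n))
  plateau <- mean(c(prof[seq_len(n_out)], prof[seq(n - n_out + 1, n)]))
  thr <- threshold_fraction * plateau
  i0 <- which.min(prof)
  if (prof[i0] >= thr || plateau <= 0) {
    return(list(left = x[i0], right = x[i0], width = 0,
                closed = TRUE, t = field$t[j]))
  }
  interp <- function(ia, ib) {
    # crossing between bins ia (>= thr) and ib (< thr)
    x[ia] + (thr - prof[ia]) / (prof[ib] - prof[ia]) * (x[ib] - x[ia])
  }
  left <- x[1]
  for (i in seq(i0 - 1, 1)) {
    if (i0 == 1) break
    if (prof[i] >= thr) { left <- interp(i, i + 1); break }
  }
  right <- x[n]
  if (i0 < n) {
    for (i in seq(i0 + 1, n)) {
      if (prof[i] >= thr) { right <- interp(i, i - 1); break }
    }
  }
  list(left = left, right = right, width = right - left,
       closed = FALSE, t = field$t[j])
}

#' Fractional wound closure
#'
#' `|d_start - d_end| / d_start` for wound widths measured at the first and
#' last frames.
#'
#' @param d_start wound width at the start (um), > 0.
#' @param d_end wound width at the end (um).
#' @return closure fraction (dimensionless).
#' @export
wound_closure <- function(d_start, d_end) {
  if (d_start <= 0) stop("d_start must be positive (no wound to close)")
  abs(d_start - d_end) / d_start
}

#' Wound metrics for a 1D density field
#'
#' Convenience wrapper: detects wound edges at the first and last frames and
#' reports the widths and the fractional closure.
#'
#' @inheritParams detect_wound_edges
#' @return list with `d_start`, `d_end` (um) and `closure`.
#' @export
closure_metrics <- function(field, threshold_fraction = 0.5) {
  e0 <- detect_wound_edges(field, field$t[1], threshold_fraction)
  e1 <- detect_wound_edges(field, field$t[length(field$t)], threshold_fraction)
  list(d_start = e0$width, d_end = e1$width,
       closure = wound_closure(e0$width, e1$width))
}
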