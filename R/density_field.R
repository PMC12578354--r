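#' Binned cell-density field
#'
#' Container for a cell density field \eqn{C(x, t)} (units cells/\eqn{\mu m^2})
#' on a regular space-time grid, as produced by binning nuclear-centroid
#' tables. 1D fields hold a profile along the axis perpendicular to the
#' wound; 2D fields hold the full imaged plane.
#'
#' @param x1 numeric vector of bin-center coordinates along x1 (um), uniform
#'   spacing.
#' @param t numeric vector of frame times (hr), strictly increasing.
#' @param C density array, cells/um^2: `length(x1) x length(t)` matrix for 1D,
#'   `length(x1) x length(x2) x length(t)` array for 2D. Nonnegative, finite.
#' @param x2 bin centers along x2 (um) for 2D fields, `NULL` for 1D.
#' @param bin_size bin edge length (um).
#' @param strip_width x2 extent (um) used to convert 1D counts to areal
#'   density; required for 1D fields.
#' @param smooth list of smoothing metadata (`spatial_um`, `temporal_hr`) or
#'   `NULL` if the field is raw.
#' @return An object of class `density_field`.
#' @export
density_field <- function(x1, t, C, x2 = NULL, bin_size = NULL,
                          strip_width = NULL, smooth = NULL) {
  x1 <- as.numeric(x1); t <- as.numeric(t)
  stopifnot(length(x1) >= 1, length(t) >= 1)
  if (is.unsorted(t, strictly = TRUE)) stop("frame times must be strictly increasing")
  check_uniform(x1, "x1")
  if (!is.null(x2)) {
    x2 <- as.numeric(x2)
    check_uniform(x2, "x2")
    C <- array(as.numeric(C), dim = c(length(x1), length(x2), length(t)))
  } else {
    C <- matrix(as.numeric(C), nrow = length(x1), ncol = length(t))
  }
  if (any(!is.finite(C))) stop("density values must be finite")
  if (any(C < -1e-12)) stop("density values must be nonnegative")
  C[C < 0] <- 0
  structure(list(x1 = x1, x2 = x2, t = t, C = C,
                 bin_size = bin_size, strip_width = strip_width,
                 smooth = smooth),
            class = "density_field")
}

check_uniform <- function(x, name) {
  if (length(x) > 1) {
    dx <- diff(x)
    if (any(dx <= 0)) stop(name, " coordinates must be strictly increasing")
    if (diff(range(dx)) > 1e-8 * mean(dx))
      stop(name, " grid spacing must be uniform")
  }
  invisible(x)
}

#' @export
print.density_field <- function(x, ...) {
  d <- if (is.null(x$x2)) "1D" else "2D"
  cat(sprintf("<density_field> %s, %d x1-bins%s, %d frames (t = %g..%g hr)\n",
              d, length(x$x1),
              if (is.null(x$x2)) "" else sprintf(" x %d x2-bins", length(x$x2)),
              length(x$t), min(x$t), max(x$t)))
  cat(sprintf("  C range: [%.3g, %.3g] cells/um^2%s\n", min(x$C), max(x$C),
              if (is.null(x$smooth)) "" else "  (smoothed)"))
  invisible(x)
}

is_1d_field <- function(field) is.null(field$x2)

#' Read a centroid table from CSV
#'
#' Expects columns `x1_um`, `x2_um`, `t_hr`, `replicate` (header required), as
#' produced by nuclear-marker image processing.
#'
#' @param path CSV file path.
#' @return data.frame with columns `x1`, `x2`, `t`, `replicate`.
#' @export
read_centroids <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x1_um", "x2_um", "t_hr", "replicate")
  if (!all(need %in% names(df)))
    stop("centroid CSV must have columns: ", paste(need, collapse = ", "))
  data.frame(x1 = as.numeric(df$x1_um), x2 = as.numeric(df$x2_um),
             t = as.numeric(df$t_hr), replicate = df$replicate)
}

#' Write a centroid table to CSV
#' @param table data.frame with columns `x1`, `x2`, `t`, `replicate`.
#' @param path output path.
#' @export
write_centroids <- function(table, path) {
  utils::write.csv(data.frame(x1_um = table$x1, x2_um = table$x2,
                              t_hr = table$t, replicate = table$replicate),
                   path, row.names = FALSE, quote = FALSE)
}

#' Serialize a density field to a JSON container
#'
#' Stores the datasets `x1`, `x2` (optional), `t`, `C` and the attributes
#' `bin_size_um`, `strip_width_um`, `smooth_spatial_um`, `smooth_temporal_hr`
#' in a single JSON document.
#'
#' @param field a [density_field()].
#' @param path output path.
#' @export
write_density_field <- function(field, path) {
  obj <- list(x1 = field$x1, t = field$t,
              C = as.vector(field$C), C_dim = dim(field$C),
              bin_size_um = field$bin_size,
              strip_width_um = field$strip_width,
              smooth_spatial_um = field$smooth$spatial_um,
              smooth_temporal_hr = field$smooth$temporal_hr)
  if (!is.null(field$x2)) obj$x2 <- field$x2
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a density field from its JSON container
#' @param path path written by [write_density_field()].
#' @return a [density_field()].
#' @export
read_density_field <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  smooth <- NULL
  if (!is.null(obj$smooth_spatial_um) || !is.null(obj$smooth_temporal_hr))
    smooth <- list(spatial_um = obj$smooth_spatial_um,
                   temporal_hr = obj$smooth_temporal_hr)
  density_field(x1 = obj$x1, t = obj$t,
                C = array(obj$C, dim = obj$C_dim),
                x2 = obj$x2, bin_size = obj$bin_size_um,
                strip_width = obj$strip_width_um, smooth = smooth)
}
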