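# S3 containers for raw data, signals, images and model fields.

#' Acquisition geometry
#'
#' Describes the image grid shared by k-space data, images, coil maps and
#' motion-model coefficient maps.
#'
#' @param matrix_size integer length-2, \code{c(Ny, Nx)} image matrix size.
#' @param pixel_spacing numeric length-2, \code{c(dy, dx)} in mm.
#' @param slice_thickness slice thickness in mm.
#' @param n_slices number of slices.
#' @return An object of class \code{acq_geometry}: a list with the fields
#'   above plus \code{fov} (field of view in mm).
#' @export
acq_geometry <- function(matrix_size, pixel_spacing = c(1, 1),
                         slice_thickness = 3, n_slices = 1L) {
  matrix_size <- as.integer(matrix_size)
  stopifnot(length(matrix_size) == 2, all(matrix_size >= 2),
            length(pixel_spacing) == 2, all(pixel_spacing > 0),
            slice_thickness > 0, n_slices >= 1)
  structure(list(matrix_size = matrix_size,
                 pixel_spacing = as.numeric(pixel_spacing),
                 slice_thickness = as.numeric(slice_thickness),
                 n_slices = as.integer(n_slices),
                 fov = matrix_size * as.numeric(pixel_spacing)),
            class = "acq_geometry")
}

#' Multi-coil Cartesian k-space container
#'
#' Holds the acquired complex samples \code{m} together with per-line
#' acquisition metadata. Samples are indexed \code{[coil, line, readout]};
#' each line carries a 0-based phase-encode index, a 0-based slice index and
#' an acquisition timestamp in seconds from sequence start. Shots are
#' recovered by grouping lines with equal timestamps.
#'
#' @param samples complex array \code{[n_coils, n_lines, Nx]}.
#' @param line_meta data.frame with columns \code{phase_encode_index},
#'   \code{slice_index}, \code{timestamp} (one row per line). Timestamps must
#'   be non-decreasing within each slice.
#' @param geometry an [acq_geometry()].
#' @param acceleration integer uniform undersampling factor (>= 1).
#' @param n_center_calibration_lines number of fully sampled central
#'   calibration lines when \code{acceleration > 1}.
#' @return An object of class \code{kspace_data}.
#' @export
kspace_data <- function(samples, line_meta, geometry, acceleration = 1L,
                        n_center_calibration_lines = 0L) {
  stopifnot(is.array(samples), length(dim(samples)) == 3)
  if (!is.complex(samples)) storage.mode(samples) <- "complex"
  req <- c("phase_encode_index", "slice_index", "timestamp")
  miss <- setdiff(req, names(line_meta))
  if (length(miss) > 0)
    stop("line_meta is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(line_meta) != dim(samples)[2])
    stop("every k-space line needs exactly one line_meta record (",
         dim(samples)[2], " lines vs ", nrow(line_meta), " records)")
  ny <- geometry$matrix_size[1]
  if (any(line_meta$phase_encode_index < 0 | line_meta$phase_encode_index >= ny))
    stop("phase_encode_index out of [0, Ny)")
  for (sl in unique(line_meta$slice_index)) {
    ts <- line_meta$timestamp[line_meta$slice_index == sl]
    if (is.unsorted(ts)) stop("timestamps must be non-decreasing within a slice")
  }
  acceleration <- as.integer(acceleration)
  stopifnot(acceleration >= 1)
  obj <- structure(list(samples = samples,
                        line_meta = as.data.frame(line_meta),
                        geometry = geometry,
                        n_coils = dim(samples)[1],
                        acceleration = acceleration,
                        n_center_calibration_lines =
                          as.integer(n_center_calibration_lines)),
                   class = "kspace_data")
  if (acceleration > 1) check_sampling_pattern(obj)
  obj
}

# With acceleration > 1, sampled indices outside the calibration band must
# form an arithmetic progression with stride = acceleration.
#' @noRd
check_sampling_pattern <- function(ks) {
  ny <- ks$geometry$matrix_size[1]
  ctr <- ny %/% 2
  half <- ks$n_center_calibration_lines / 2
  pe <- sort(unique(ks$line_meta$phase_encode_index))
  outside <- pe[pe < ctr - floor(half) | pe >= ctr + ceiling(half)]
  # the calibration band interrupts the progression, so test membership of a
  # single stride-R progression (all gaps multiples of the acceleration)
  if (length(outside) > 1 &&
      any(diff(outside) %% ks$acceleration != 0))
    stop("sampled phase-encode indices outside the calibration band must ",
         "have stride = acceleration (", ks$acceleration, ")")
  invisible(TRUE)
}

#' Respiratory sensor signal
#'
#' A uniformly sampled scalar respiratory-belt series \code{s(t)}, optionally
#' carrying per-sample motion-state labels after binning.
#'
#' @param values numeric vector of sensor samples (length >= 2).
#' @param sample_rate sampling rate in Hz (> 0).
#' @param t0 time of the first sample in seconds.
#' @param state_labels optional integer vector of 0-based motion-state labels,
#'   one per sample.
#' @param state_values optional numeric vector of representative sensor values
#'   per state (strictly increasing).
#' @return An object of class \code{resp_signal}.
#' @export
resp_signal <- function(values, sample_rate, t0 = 0,
                        state_labels = NULL, state_values = NULL) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("a respiratory signal needs at least 2 samples")
  if (!is.finite(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be positive")
  if (!is.null(state_labels)) {
    stopifnot(length(state_labels) == length(values))
    ns <- length(state_values)
    if (any(state_labels < 0 | state_labels >= ns))
      stop("state labels must lie in [0, n_states)")
  }
  structure(list(values = values, sample_rate = as.numeric(sample_rate),
                 t0 = as.numeric(t0),
                 state_labels = state_labels, state_values = state_values),
            class = "resp_signal")
}

#' @export
print.resp_signal <- function(x, ...) {
  cat(sprintf("<resp_signal> %d samples @ %g Hz, span %.2f s",
              length(x$values), x$sample_rate,
              (length(x$values) - 1) / x$sample_rate))
  if (!is.null(x$state_labels))
    cat(sprintf(", %d motion states", length(x$state_values)))
  cat("\n")
  invisible(x)
}

#' @noRd
resp_times <- function(sig) {
  sig$t0 + (seq_along(sig$values) - 1) / sig$sample_rate
}

#' Image volume
#'
#' Real or complex image stack indexed \code{[y, x, slice]}.
#'
#' @param data 2D matrix or 3D array; a matrix is promoted to one slice.
#' @param geometry an [acq_geometry()]; defaults to unit 1 mm pixels.
#' @return An object of class \code{image_volume}.
#' @export
image_volume <- function(data, geometry = NULL) {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 3)
  if (is.null(geometry))
    geometry <- acq_geometry(dim(data)[1:2], n_slices = dim(data)[3])
  if (!all(dim(data)[1:2] == geometry$matrix_size))
    stop("image shape inconsistent with geometry matrix size")
  structure(list(data = data, geometry = geometry), class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %d x %d x %d (%s), pixel %g x %g mm\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              if (is.complex(x$data)) "complex" else "real",
              x$geometry$pixel_spacing[1], x$geometry$pixel_spacing[2]))
  invisible(x)
}

#' Extract one slice of an image volume as a matrix
#' @param img an [image_volume()].
#' @param slice 1-based slice number.
#' @return A matrix \code{[y, x]}.
#' @export
slice_matrix <- function(img, slice = 1L) img$data[, , slice]

#' Motion-model coefficient maps
#'
#' Per-pixel coefficients \eqn{\alpha(x,y)} of the linear motion model
#' \eqn{u(x,y,t) = \alpha(x,y) s(t)}: one (y, x) displacement pair per pixel,
#' in pixels per unit sensor amplitude.
#'
#' @param coeff real array \code{[2, Ny, Nx]}; \code{coeff[1,,]} is the y
#'   (row) coefficient, \code{coeff[2,,]} the x (column) coefficient.
#' @param geometry an [acq_geometry()].
#' @return An object of class \code{alpha_maps}.
#' @export
alpha_maps <- function(coeff, geometry) {
  stopifnot(is.array(coeff), length(dim(coeff)) == 3, dim(coeff)[1] == 2)
  if (!all(is.finite(coeff))) stop("alpha coefficients must be finite")
  if (!all(dim(coeff)[2:3] == geometry$matrix_size))
    stop("alpha shape inconsistent with geometry")
  structure(list(coeff = coeff, geometry = geometry), class = "alpha_maps")
}

#' Zero motion-model maps for a geometry
#' @param geometry an [acq_geometry()].
#' @return An all-zero [alpha_maps()].
#' @export
alpha_zero <- function(geometry) {
  alpha_maps(array(0, c(2, geometry$matrix_size)), geometry)
}

#' Displacement field
#'
#' A per-pixel in-plane displacement \code{u} in pixels, indexed
#' \code{[component, y, x]} with component 1 = y, 2 = x.
#'
#' @param u real array \code{[2, Ny, Nx]}.
#' @return An object of class \code{displacement_field}.
#' @export
displacement_field <- function(u) {
  stopifnot(is.array(u), length(dim(u)) == 3, dim(u)[1] == 2)
  if (!all(is.finite(u))) stop("displacements must be finite")
  structure(list(u = u), class = "displacement_field")
}

#' Coil sensitivity maps
#'
#' @param maps complex array \code{[coil, Ny, Nx]}.
#' @param n_center_lines_used number of central k-space lines the estimate
#'   was computed from.
#' @param smoothing_coeff roughness weight of the smoothing spline.
#' @return An object of class \code{coil_maps}.
#' @export
coil_maps <- function(maps, n_center_lines_used = NA_integer_,
                      smoothing_coeff = NA_real_) {
  stopifnot(is.array(maps), length(dim(maps)) == 3)
  if (!is.complex(maps)) storage.mode(maps) <- "complex"
  if (!all(is.finite(Re(maps)) & is.finite(Im(maps))))
    stop("coil maps must be finite")
  structure(list(maps = maps,
                 n_center_lines_used = as.integer(n_center_lines_used),
                 smoothing_coeff = as.numeric(smoothing_coeff)),
            class = "coil_maps")
}

#' @export
print.kspace_data <- function(x, ...) {
  cat(sprintf(paste0("<kspace_data> %d coils, %d lines x %d readout, ",
                     "matrix %dx%d, R=%d\n"),
              x$n_coils, dim(x$samples)[2], dim(x$samples)[3],
              x$geometry$matrix_size[1], x$geometry$matrix_size[2],
              x$acceleration))
  invisible(x)
}

# Subset a multi-slice kspace_data to a single slice (slice index 0-based).
#' @noRd
kspace_slice <- function(ks, slice_index) {
  keep <- ks$line_meta$slice_index == slice_index
  if (!any(keep)) stop("no lines for slice ", slice_index)
  g <- ks$geometry
  g1 <- acq_geometry(g$matrix_size, g$pixel_spacing, g$slice_thickness, 1L)
  kspace_data(ks$samples[, keep, , drop = FALSE],
              ks$line_meta[keep, , drop = FALSE], g1,
              ks$acceleration, ks$n_center_calibration_lines)
}
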