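# On-disk formats: HDF5 raw-data container, CSV sensor signals, NIfTI images.
#
# HDF5 layout (ISMRMRD-flavoured naming):
#   /kspace/samples_real, /kspace/samples_imag   float64 [coil, line, readout]
#   /kspace/line_meta/{phase_encode_index, slice_index, timestamp}
#   /kspace/geometry/{matrix_size, pixel_spacing, slice_thickness, n_slices}
#   /kspace/acceleration, /kspace/n_center_calibration_lines
#   /resp/values, /resp/sample_rate, /resp/t0            (optional group)
#   /alpha/coeff, /alpha/{pixel_spacing, slice_thickness} (optional group)
# Complex samples are stored as a real/imaginary dataset pair (float64), which
# round-trips bit-exactly.

#' @noRd
h5_must_read <- function(path, name) {
  ls <- rhdf5::h5ls(path)
  present <- gsub("^/+", "", paste(ls$group, ls$name, sep = "/"))
  if (!(name %in% present))
    stop(sprintf("k-space container '%s' lacks required dataset '%s'",
                 path, name), call. = FALSE)
  rhdf5::h5read(path, name)
}

#' Write a k-space container to HDF5
#'
#' @param data a [kspace_data()], optionally with a \code{resp} attribute.
#' @param path output file path (overwritten if present).
#' @param resp optional [resp_signal()] stored alongside under \code{/resp}.
#' @param alpha optional [alpha_maps()] stored under \code{/alpha}.
#' @return \code{path}, invisibly.
#' @export
write_kspace <- function(data, path, resp = NULL, alpha = NULL) {
  stopifnot(inherits(data, "kspace_data"))
  if (!all(is.finite(Re(data$samples)) & is.finite(Im(data$samples))))
    stop("refusing to write non-finite k-space samples")
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "kspace")
  rhdf5::h5createGroup(path, "kspace/line_meta")
  rhdf5::h5createGroup(path, "kspace/geometry")
  rhdf5::h5write(Re(data$samples), path, "kspace/samples_real")
  rhdf5::h5write(Im(data$samples), path, "kspace/samples_imag")
  rhdf5::h5write(as.integer(data$line_meta$phase_encode_index), path,
                 "kspace/line_meta/phase_encode_index")
  rhdf5::h5write(as.integer(data$line_meta$slice_index), path,
                 "kspace/line_meta/slice_index")
  rhdf5::h5write(as.numeric(data$line_meta$timestamp), path,
                 "kspace/line_meta/timestamp")
  g <- data$geometry
  rhdf5::h5write(g$matrix_size, path, "kspace/geometry/matrix_size")
  rhdf5::h5write(g$pixel_spacing, path, "kspace/geometry/pixel_spacing")
  rhdf5::h5write(g$slice_thickness, path, "kspace/geometry/slice_thickness")
  rhdf5::h5write(g$n_slices, path, "kspace/geometry/n_slices")
  rhdf5::h5write(data$acceleration, path, "kspace/acceleration")
  rhdf5::h5write(data$n_center_calibration_lines, path,
                 "kspace/n_center_calibration_lines")
  if (!is.null(resp)) {
    rhdf5::h5createGroup(path, "resp")
    rhdf5::h5write(resp$values, path, "resp/values")
    rhdf5::h5write(resp$sample_rate, path, "resp/sample_rate")
    rhdf5::h5write(resp$t0, path, "resp/t0")
  }
  if (!is.null(alpha)) {
    rhdf5::h5createGroup(path, "alpha")
    rhdf5::h5write(alpha$coeff, path, "alpha/coeff")
    rhdf5::h5write(alpha$geometry$pixel_spacing, path, "alpha/pixel_spacing")
    rhdf5::h5write(alpha$geometry$slice_thickness, path,
                   "alpha/slice_thickness")
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a k-space container from HDF5
#'
#' @param path file written by [write_kspace()] (or following its layout).
#' @return A [kspace_data()]; if the file carries a \code{/resp} group the
#'   signal is attached as attribute \code{"resp"}, and a \code{/alpha} group
#'   as attribute \code{"alpha"}.
#' @export
read_kspace <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  re <- h5_must_read(path, "kspace/samples_real")
  im <- h5_must_read(path, "kspace/samples_imag")
  pe <- h5_must_read(path, "kspace/line_meta/phase_encode_index")
  sl <- h5_must_read(path, "kspace/line_meta/slice_index")
  ts <- h5_must_read(path, "kspace/line_meta/timestamp")
  ms <- h5_must_read(path, "kspace/geometry/matrix_size")
  px <- h5_must_read(path, "kspace/geometry/pixel_spacing")
  th <- h5_must_read(path, "kspace/geometry/slice_thickness")
  nsl <- h5_must_read(path, "kspace/geometry/n_slices")
  acc <- h5_must_read(path, "kspace/acceleration")
  ncc <- h5_must_read(path, "kspace/n_center_calibration_lines")
  ls <- rhdf5::h5ls(path)
  present <- gsub("^/+", "", paste(ls$group, ls$name, sep = "/"))
  ks <- kspace_data(
    samples = re + 1i * im,
    line_meta = data.frame(phase_encode_index = as.integer(pe),
                           slice_index = as.integer(sl),
                           timestamp = as.numeric(ts)),
    geometry = acq_geometry(ms, px, th, nsl),
    acceleration = acc, n_center_calibration_lines = ncc)
  if ("resp/values" %in% present) {
    attr(ks, "resp") <- resp_signal(
      rhdf5::h5read(path, "resp/values"),
      as.numeric(rhdf5::h5read(path, "resp/sample_rate")),
      as.numeric(rhdf5::h5read(path, "resp/t0")))
  }
  if ("alpha/coeff" %in% present) {
    co <- rhdf5::h5read(path, "alpha/coeff")
    apx <- rhdf5::h5read(path, "alpha/pixel_spacing")
    ath <- rhdf5::h5read(path, "alpha/slice_thickness")
    attr(ks, "alpha") <- alpha_maps(
      co, acq_geometry(dim(co)[2:3], apx, ath))
  }
  rhdf5::h5closeAll()
  ks
}

#' Write motion-model coefficient maps to HDF5
#' @param alpha an [alpha_maps()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_alpha <- function(alpha, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "alpha")
  rhdf5::h5write(alpha$coeff, path, "alpha/coeff")
  rhdf5::h5write(alpha$geometry$pixel_spacing, path, "alpha/pixel_spacing")
  rhdf5::h5write(alpha$geometry$slice_thickness, path, "alpha/slice_thickness")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read motion-model coefficient maps from HDF5
#' @param path file written by [write_alpha()].
#' @return An [alpha_maps()].
#' @export
read_alpha <- function(path) {
  co <- h5_must_read(path, "alpha/coeff")
  px <- h5_must_read(path, "alpha/pixel_spacing")
  th <- h5_must_read(path, "alpha/slice_thickness")
  rhdf5::h5closeAll()
  alpha_maps(co, acq_geometry(dim(co)[2:3], px, th))
}

#' Read a respiratory signal from CSV
#'
#' Expects two columns \code{time_s,value} with a header row and uniform
#' sampling.
#'
#' @param path CSV file path.
#' @return A [resp_signal()].
#' @export
read_resp_csv <- function(path) {
  df <- utils::read.csv(path)
  if (nrow(df) == 0) stop("no samples in ", path)
  if (!all(c("time_s", "value") %in% names(df)))
    stop("respiratory CSV needs columns 'time_s' and 'value'")
  if (nrow(df) < 2) stop("a respiratory signal needs at least 2 samples")
  dt <- diff(df$time_s)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop("respiratory CSV is not uniformly sampled")
  resp_signal(df$value, sample_rate = 1 / dt[1], t0 = df$time_s[1])
}

#' Write a respiratory signal to CSV
#' @param sig a [resp_signal()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_resp_csv <- function(sig, path) {
  df <- data.frame(time_s = resp_times(sig), value = sig$values)
  utils::write.csv(format(df, digits = 17, scientific = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an image volume as NIfTI-1
#'
#' Complex volumes are written as their magnitude. Pixel spacing and slice
#' thickness from the geometry populate the NIfTI pixdim.
#'
#' @param img an [image_volume()].
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @return \code{path}, invisibly.
#' @export
write_image_nifti <- function(img, path) {
  stopifnot(inherits(img, "image_volume"))
  dat <- if (is.complex(img$data)) Mod(img$data) else img$data
  if (!all(is.finite(dat))) stop("refusing to write non-finite image data")
  nif <- RNifti::asNifti(dat)
  RNifti::pixdim(nif) <- c(img$geometry$pixel_spacing,
                           img$geometry$slice_thickness)
  RNifti::writeNifti(nif, path)
  invisible(path)
}

#' Read a NIfTI image as an image volume
#' @param path NIfTI file path.
#' @return An [image_volume()].
#' @export
read_image_nifti <- function(path) {
  nif <- RNifti::readNifti(path)
  d <- dim(nif)
  if (length(d) == 2) d <- c(d, 1L)
  pd <- RNifti::pixdim(nif)
  image_volume(array(as.numeric(nif), d),
               acq_geometry(d[1:2], pd[1:2],
                            if (length(pd) >= 3) pd[3] else 1, d[3]))
}
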