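# Coil sensitivities: estimation from the central calibration band of
# k-space, 2D penalized-spline smoothing of magnitude and phase, and
# sum-of-squares intensity normalization.

# 2D smoothing spline (Whittaker/P-spline form): minimizes
# ||x - y||^2 + lambda * ||d^2 x / d(mm)^2||^2 with second differences
# expressed in physical (mm) coordinates, solved with a sparse Cholesky
# factorization. Penalizing the physical curvature makes the smoothing
# length resolution-invariant, so the same lambda yields the same physical
# smoothness at every pyramid level. lambda = 0 returns the input,
# lambda -> Inf a plane.
#' @noRd
smooth2d <- function(y, lambda, spacing = c(1, 1)) {
  if (lambda <= 0) return(y)
  ny <- nrow(y); nx <- ncol(y)
  d2 <- function(n, h) {
    if (n < 3) return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                           x = numeric(0), dims = c(0, n)))
    Matrix::sparseMatrix(i = rep(seq_len(n - 2), 3),
                         j = c(seq_len(n - 2), seq_len(n - 2) + 1,
                               seq_len(n - 2) + 2),
                         x = rep(c(1, -2, 1) / h^2, each = n - 2),
                         dims = c(n - 2, n))
  }
  Iy <- Matrix::Diagonal(ny); Ix <- Matrix::Diagonal(nx)
  Dy <- d2(ny, spacing[1]); Dx <- d2(nx, spacing[2])
  P <- Matrix::kronecker(Ix, Matrix::crossprod(Dy)) +
    Matrix::kronecker(Matrix::crossprod(Dx), Iy)
  A <- Matrix::Diagonal(ny * nx) + lambda * P
  out <- as.vector(Matrix::solve(A, as.vector(y)))
  matrix(out, ny, nx)
}

#' @noRd
smooth2d_complex <- function(z, lambda, spacing = c(1, 1)) {
  smooth2d(Re(z), lambda, spacing) + 1i * smooth2d(Im(z), lambda, spacing)
}

# Shared tail of the coil-map estimators: RSS ratio, magnitude/phase spline
# smoothing in physical coordinates.
#' @noRd
finish_coil_maps <- function(low, spacing, n_center_lines, smoothing_coeff) {
  nc <- dim(low)[1]
  rss <- sqrt(apply(Mod(low)^2, c(2, 3), sum))
  floor_eps <- 1e-6 * max(rss)
  maps <- array(0i, dim(low))
  for (c in seq_len(nc)) {
    raw <- low[c, , ] / pmax(rss, floor_eps)
    mag <- smooth2d(Mod(raw), smoothing_coeff, spacing)
    unit <- low[c, , ] / pmax(Mod(low[c, , ]), 1e-12 * max(Mod(low[c, , ])))
    unit_s <- smooth2d_complex(unit, smoothing_coeff, spacing)
    mu <- Mod(unit_s); mu[mu < 1e-12] <- 1
    maps[c, , ] <- mag * (unit_s / mu)
  }
  coil_maps(maps, n_center_lines_used = n_center_lines,
            smoothing_coeff = smoothing_coeff)
}

# Central-band lines, Hann weights and per-line row indices for a container.
#' @noRd
center_band <- function(ks, n_center_lines) {
  ny <- ks$geometry$matrix_size[1]
  if (n_center_lines > ny)
    stop("requested central band (", n_center_lines,
         " lines) is wider than the sampled lines")
  ctr <- ny %/% 2
  half_lo <- floor(n_center_lines / 2); half_hi <- ceiling(n_center_lines / 2)
  band <- seq(ctr - half_lo, ctr + half_hi - 1)
  band <- band[band >= 0 & band < ny]
  have <- unique(ks$line_meta$phase_encode_index)
  if (!all(band %in% have))
    stop("requested central band (", n_center_lines,
         " lines) is wider than the sampled lines")
  list(band = band,
       hann = sin(pi * seq_along(band) / (length(band) + 1))^2)
}

#' Estimate coil sensitivity maps from central k-space
#'
#' Per coil: keep only the central phase-encode band (zero-fill the rest),
#' apodize the band with a Hann window to suppress truncation ringing,
#' inverse Fourier transform, divide by the root-sum-of-squares across coils,
#' and smooth magnitude and phase with a 2D smoothing spline of roughness
#' weight \code{smoothing_coeff}. Phase is smoothed through the real and
#' imaginary parts of the unit-phase field (no unwrapping needed).
#'
#' @param ks a [kspace_data()] (single slice).
#' @param n_center_lines width of the central band; 32 lines is the default
#'   for the fully sampled protocol, 24 calibration lines for the accelerated
#'   one.
#' @param smoothing_coeff spline roughness weight \eqn{\lambda_{smooth}}
#'   (default 1000), applied to both magnitude and phase.
#' @return A [coil_maps()] whose root-sum-of-squares is ~1 inside the object
#'   support.
#' @export
estimate_coil_maps <- function(ks, n_center_lines = 32L,
                               smoothing_coeff = 1000) {
  stopifnot(inherits(ks, "kspace_data"))
  ny <- ks$geometry$matrix_size[1]; nx <- ks$geometry$matrix_size[2]
  cb <- center_band(ks, n_center_lines)
  nc <- ks$n_coils
  low <- array(0i, c(nc, ny, nx))
  for (c in seq_len(nc)) {
    grid <- matrix(0i, ny, nx)
    for (b in seq_along(cb$band)) {
      pe <- cb$band[b]
      row <- which(ks$line_meta$phase_encode_index == pe)[1]
      grid[pe + 1, ] <- ks$samples[c, row, ] * cb$hann[b]
    }
    low[c, , ] <- ifft2u(grid)
  }
  finish_coil_maps(low, ks$geometry$pixel_spacing, length(cb$band),
                   smoothing_coeff)
}

#' Motion-consistent coil sensitivity refinement
#'
#' Re-estimates the coil maps given the current image and motion-model
#' estimates -- the third block of the joint data model. For each coil the
#' linear system \eqn{m_c = S F \,\mathrm{diag}(W_s\hat\rho)\, c} (sampling,
#' unitary FFT, pointwise multiplication with the state-warped image) is
#' solved for the sensitivity \eqn{c} by Tikhonov-regularized CG over all
#' acquired lines, the magnitude gauge is pinned by pixelwise
#' root-sum-of-squares normalization (the joint problem is only identifiable
#' up to a smooth multiplicative field), and magnitude and phase are
#' spline-smoothed as in [estimate_coil_maps()].
#'
#' Maps estimated from the raw central calibration lines inherit motion
#' ghosting, which flattens the joint problem's sensitivity to the
#' displacement amplitude; refreshing them with this estimator as the motion
#' model improves removes that bias.
#'
#' @inheritParams estimate_coil_maps
#' @param alpha current [alpha_maps()] on the container's geometry.
#' @param rho current complex image estimate at the container's resolution.
#' @param line_states integer 0-based motion state per k-space line.
#' @param state_values sensor value per state.
#' @param maxit CG iterations for the per-coil solves.
#' @return A [coil_maps()].
#' @export
refine_coil_maps <- function(ks, alpha, rho, line_states, state_values,
                             smoothing_coeff = 1000, maxit = 10L) {
  stopifnot(inherits(ks, "kspace_data"), inherits(alpha, "alpha_maps"))
  ny <- ks$geometry$matrix_size[1]; nx <- ks$geometry$matrix_size[2]
  stopifnot(all(dim(rho) == c(ny, nx)))
  if (!is.complex(rho)) storage.mode(rho) <- "complex"
  states <- sort(unique(line_states))
  ws <- lapply(states, function(s)
    warp_image(rho, predict_displacement(alpha, state_values[s + 1])))
  names(ws) <- as.character(states)
  pe <- ks$line_meta$phase_encode_index
  nc <- ks$n_coils
  reg <- 1e-2 * mean(vapply(ws, function(w) mean(Mod(w)^2), 0))
  fwd <- function(cimg) {
    out <- array(0i, c(length(pe), nx))
    for (s in states) {
      rows <- which(line_states == s)
      kspc <- fft2u(cimg * ws[[as.character(s)]])
      out[rows, ] <- kspc[pe[rows] + 1, , drop = FALSE]
    }
    out
  }
  adj <- function(r) {
    acc <- matrix(0i, ny, nx)
    for (s in states) {
      rows <- which(line_states == s)
      grid <- matrix(0i, ny, nx)
      grid[pe[rows] + 1, ] <- r[rows, ]
      acc <- acc + Conj(ws[[as.character(s)]]) * ifft2u(grid)
    }
    acc
  }
  raws <- array(0i, c(nc, ny, nx))
  for (c in seq_len(nc)) {
    sol <- cg_solve(function(x) adj(fwd(x)) + reg * x,
                    adj(ks$samples[c, , ]), maxit = maxit, tol = 1e-3)
    raws[c, , ] <- sol$x
  }
  finish_coil_maps(raws, ks$geometry$pixel_spacing,
                   ks$n_coils * 0L + NA_integer_, smoothing_coeff)
}

# Bilinear resampling of smooth coil maps between geometries (real and
# imaginary parts separately), FOV centers aligned.
#' @noRd
resample_coil_maps <- function(cm, src_geom, dst_geom) {
  nc <- dim(cm$maps)[1]
  out <- array(0i, c(nc, dst_geom$matrix_size))
  for (c in seq_len(nc)) {
    out[c, , ] <- resample_field(Re(cm$maps[c, , ]), src_geom, dst_geom) +
      1i * resample_field(Im(cm$maps[c, , ]), src_geom, dst_geom)
  }
  coil_maps(out, cm$n_center_lines_used, cm$smoothing_coeff)
}

#' Sum-of-squares intensity normalization
#'
#' Pixelwise division of an image by the sum of squared coil-sensitivity
#' magnitudes, guarded below a small floor to avoid division by ~0 outside
#' the coil coverage.
#'
#' @param img an [image_volume()] (or a 2D matrix).
#' @param maps a [coil_maps()] matching the image matrix size.
#' @param eps_rel relative floor on the sum of squares (default \code{1e-6}
#'   of its maximum).
#' @return The normalized image, same class as the input.
#' @export
sos_normalize <- function(img, maps, eps_rel = 1e-6) {
  is_vol <- inherits(img, "image_volume")
  dat <- if (is_vol) img$data else img
  d2 <- if (is.matrix(dat)) dim(dat) else dim(dat)[1:2]
  if (!all(dim(maps$maps)[2:3] == d2))
    stop("image / coil map shape mismatch")
  ss <- apply(Mod(maps$maps)^2, c(2, 3), sum)
  ss <- pmax(ss, eps_rel * max(ss))
  if (is.matrix(dat)) {
    out <- dat / ss
  } else {
    out <- dat
    for (z in seq_len(dim(dat)[3])) out[, , z] <- dat[, , z] / ss
  }
  if (is_vol) image_volume(out, img$geometry) else out
}
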