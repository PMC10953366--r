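# Motion model: displacement prediction u = alpha * s, backward bilinear
# warping with an exact transpose adjoint, geometry interpolation of alpha,
# and frame-to-frame displacement differences.

#' Predict a displacement field from the motion model
#'
#' Evaluates \eqn{u(x, y) = \alpha(x, y)\,s} for a sensor value \code{s}.
#'
#' @param alpha an [alpha_maps()].
#' @param s_value scalar sensor amplitude.
#' @return A [displacement_field()] in pixels.
#' @export
predict_displacement <- function(alpha, s_value) {
  stopifnot(inherits(alpha, "alpha_maps"), length(s_value) == 1)
  displacement_field(alpha$coeff * s_value)
}

# Sparse matrix of the backward bilinear warp: output(p) = input sampled at
# p + u(p); samples outside the FOV contribute zero. Pixels are 0-based
# (iy, ix); the linear index follows R's column-major matrix layout.
#' @noRd
warp_matrix <- function(u, ny, nx) {
  stopifnot(all(dim(u) == c(2, ny, nx)))
  iy <- rep(seq_len(ny) - 1L, times = nx)
  ix <- rep(seq_len(nx) - 1L, each = ny)
  sy <- iy + as.vector(u[1, , ])
  sx <- ix + as.vector(u[2, , ])
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0;   fx <- sx - x0
  n <- ny * nx
  row <- seq_len(n)
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  for (dy in 0:1) for (dx in 0:1) {
    yy <- y0 + dy; xx <- x0 + dx
    w <- (if (dy == 0) 1 - fy else fy) * (if (dx == 0) 1 - fx else fx)
    ok <- yy >= 0 & yy < ny & xx >= 0 & xx < nx & w != 0
    ii <- c(ii, row[ok])
    jj <- c(jj, yy[ok] + ny * xx[ok] + 1L)
    ww <- c(ww, w[ok])
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(n, n))
}

#' @noRd
apply_warp_matrix <- function(W, img) {
  d <- dim(img)
  v <- as.vector(img)
  if (is.complex(img)) {
    out <- as.vector(W %*% Re(v)) + 1i * as.vector(W %*% Im(v))
  } else {
    out <- as.vector(W %*% v)
  }
  dim(out) <- d
  out
}

#' Warp an image by a displacement field
#'
#' Backward (pull) warp with bilinear interpolation:
#' \code{output(p) = input(p + u(p))}; samples falling outside the field of
#' view contribute zero. The map is linear in the image.
#'
#' @param img 2D (complex or real) image matrix.
#' @param u a [displacement_field()] matching the image shape.
#' @return The warped image matrix.
#' @export
warp_image <- function(img, u) {
  if (inherits(u, "displacement_field")) u <- u$u
  if (!all(dim(u)[2:3] == dim(img))) stop("image / displacement shape mismatch")
  apply_warp_matrix(warp_matrix(u, nrow(img), ncol(img)), img)
}

#' Adjoint of the bilinear warp
#'
#' The exact transpose of the linear map of [warp_image()] for the same
#' displacement field (a scatter of bilinear weights, not the inverse warp),
#' so that \eqn{\langle Wf, g\rangle = \langle f, W^T g\rangle} holds to
#' machine precision. This is what conjugate-gradient on the normal equations
#' requires.
#'
#' @inheritParams warp_image
#' @return The adjoint-warped image matrix.
#' @export
warp_adjoint <- function(img, u) {
  if (inherits(u, "displacement_field")) u <- u$u
  if (!all(dim(u)[2:3] == dim(img))) stop("image / displacement shape mismatch")
  W <- warp_matrix(u, nrow(img), ncol(img))
  d <- dim(img)
  v <- as.vector(img)
  if (is.complex(img)) {
    out <- as.vector(Matrix::crossprod(W, Re(v))) +
      1i * as.vector(Matrix::crossprod(W, Im(v)))
  } else {
    out <- as.vector(Matrix::crossprod(W, v))
  }
  dim(out) <- d
  out
}

# Bilinear resampling of one scalar field from src geometry to dst geometry
# in physical (mm) coordinates. Grids are aligned at the DC pixel (0-based
# index n %/% 2, the package-wide fftshift convention), which is exactly how
# a central k-space crop relates a dyadic image pyramid.
#' @noRd
resample_field <- function(field, src_geom, dst_geom) {
  ny_s <- src_geom$matrix_size[1]; nx_s <- src_geom$matrix_size[2]
  ny_d <- dst_geom$matrix_size[1]; nx_d <- dst_geom$matrix_size[2]
  # physical coordinate of pixel i (0-based): (i - n %/% 2) * spacing
  py <- (seq_len(ny_d) - 1 - ny_d %/% 2) * dst_geom$pixel_spacing[1]
  px <- (seq_len(nx_d) - 1 - nx_d %/% 2) * dst_geom$pixel_spacing[2]
  sy <- py / src_geom$pixel_spacing[1] + ny_s %/% 2
  sx <- px / src_geom$pixel_spacing[2] + nx_s %/% 2
  # clamp to the source grid (geometries must overlap; checked by caller)
  sy <- pmin(pmax(sy, 0), ny_s - 1)
  sx <- pmin(pmax(sx, 0), nx_s - 1)
  y0 <- pmin(floor(sy), ny_s - 2); fy <- sy - y0
  x0 <- pmin(floor(sx), nx_s - 2); fx <- sx - x0
  FY <- matrix(fy, ny_d, nx_d); FX <- matrix(fx, ny_d, nx_d, byrow = TRUE)
  i0 <- y0 + 1; j0 <- x0 + 1
  f11 <- field[i0, j0, drop = FALSE];     f21 <- field[i0 + 1, j0, drop = FALSE]
  f12 <- field[i0, j0 + 1, drop = FALSE]; f22 <- field[i0 + 1, j0 + 1, drop = FALSE]
  (1 - FY) * (1 - FX) * f11 + FY * (1 - FX) * f21 +
    (1 - FY) * FX * f12 + FY * FX * f22
}

#' Resample motion-model maps to a new geometry
#'
#' Bilinear resampling in physical (mm) coordinates. Because the
#' coefficients are expressed in pixels per unit sensor amplitude, each
#' component is rescaled by the pixel-size ratio so the predicted *physical*
#' displacement is preserved (the motion-model reuse pathway between
#' acquisitions with different matrices).
#'
#' @param alpha an [alpha_maps()].
#' @param dst_geometry target [acq_geometry()]; its field of view must
#'   overlap the source's.
#' @return An [alpha_maps()] on the destination geometry.
#' @export
interpolate_alpha <- function(alpha, dst_geometry) {
  sg <- alpha$geometry; dg <- dst_geometry
  if (any(pmin(sg$fov, dg$fov) <= 0) ||
      all(dg$fov / 2 > sg$fov / 2 + sg$pixel_spacing * sg$matrix_size))
    stop("source and destination fields of view do not overlap")
  scale_y <- sg$pixel_spacing[1] / dg$pixel_spacing[1]
  scale_x <- sg$pixel_spacing[2] / dg$pixel_spacing[2]
  co <- array(0, c(2, dg$matrix_size))
  co[1, , ] <- resample_field(alpha$coeff[1, , ], sg, dg) * scale_y
  co[2, , ] <- resample_field(alpha$coeff[2, , ], sg, dg) * scale_x
  alpha_maps(co, dg)
}

#' Frame-to-frame displacement change
#'
#' The motion direction/amplitude between consecutive frames,
#' \code{du = u_curr - u_prev}. When the fields carry a slice dimension
#' (arrays \code{[2, Ny, Nx, Nz]}), a moving-average filter of the given
#' window is applied along the slice direction.
#'
#' @param u_curr,u_prev displacement fields ([displacement_field()] or arrays
#'   \code{[2, Ny, Nx(, Nz)]}) of matching shape.
#' @param smooth_window moving-average window along slices (default 3;
#'   \code{1} disables smoothing).
#' @return The difference field, same class/shape as the inputs.
#' @export
frame_displacement_delta <- function(u_curr, u_prev, smooth_window = 3L) {
  wrap <- inherits(u_curr, "displacement_field")
  a <- if (wrap) u_curr$u else u_curr
  b <- if (inherits(u_prev, "displacement_field")) u_prev$u else u_prev
  if (!all(dim(a) == dim(b))) stop("displacement field shape mismatch")
  du <- a - b
  if (length(dim(du)) == 4 && smooth_window > 1) {
    nz <- dim(du)[4]
    h <- smooth_window %/% 2
    sm <- du
    for (z in seq_len(nz)) {
      zz <- max(1, z - h):min(nz, z + h)
      sm[, , , z] <- apply(du[, , , zz, drop = FALSE], 1:3, mean)
    }
    du <- sm
  }
  if (wrap && length(dim(du)) == 3) displacement_field(du) else du
}
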