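# No-reference image quality metrics: sharpness index (SI), average edge
# strength (AES), symmetric enhancement ratios (SE/AEE), and k-means
# background masking.

# Circular (periodic) finite differences used by the sharpness index; the
# phase-randomized null field of the same image is stationary under exactly
# these differences, which keeps the null statistics closed-form.
#' @noRd
circ_diff <- function(img, dim) {
  if (dim == 1) img[c(2:nrow(img), 1), ] - img
  else img[, c(2:ncol(img), 1)] - img
}

#' Sharpness index
#'
#' A no-reference sharpness measure based on Fourier phase coherence: the
#' image is compared with its phase-randomized null field \eqn{W} (same
#' power spectrum, random phases), whose anisotropic total variation
#' \eqn{TV(W) = \sum |\partial_x W| + |\partial_y W|} is asymptotically
#' Gaussian with mean and variance available in closed form from the
#' autocorrelations of the image derivatives. The index is
#' \deqn{SI = -\log_{10}\Phi\!\left(\frac{TV(u) - E[TV(W)]}
#'   {\sqrt{\mathrm{Var}[TV(W)]}}\right),}
#' i.e. minus the log-probability that the null field has total variation
#' below the observed one. Sharp, phase-coherent images have
#' \eqn{TV(u) \ll E[TV(W)]} and hence a large index; the measure is invariant
#' to global intensity scaling.
#'
#' @param img real 2D image matrix (magnitude image).
#' @return The sharpness index (non-negative scalar).
#' @export
sharpness_index <- function(img) {
  stopifnot(is.matrix(img), is.numeric(img))
  if (max(img) - min(img) <= 0)
    stop("undefined SI: constant image")
  img <- img - mean(img)
  n <- length(img)
  dx <- circ_diff(img, 2)
  dy <- circ_diff(img, 1)
  tv <- sum(abs(dx)) + sum(abs(dy))
  vx <- mean(dx^2); vy <- mean(dy^2)
  mu <- n * sqrt(2 / pi) * (sqrt(vx) + sqrt(vy))
  # covariance of |X|,|Y| for jointly Gaussian pairs with correlation r:
  # (2/pi) * sx * sy * (sqrt(1 - r^2) + r*asin(r) - 1)
  omega <- function(r) {
    r <- pmin(pmax(r, -1), 1)
    sqrt(1 - r^2) + r * asin(r) - 1
  }
  Fx <- stats::fft(dx); Fy <- stats::fft(dy)
  # circular autocorrelations of the derivative fields (per-pixel scale)
  gxx <- Re(stats::fft(Mod(Fx)^2, inverse = TRUE)) / n^2
  gyy <- Re(stats::fft(Mod(Fy)^2, inverse = TRUE)) / n^2
  gxy <- Re(stats::fft(Fx * Conj(Fy), inverse = TRUE)) / n^2
  v <- (2 / pi) * n * (vx * sum(omega(gxx / vx)) +
                         vy * sum(omega(gyy / vy)) +
                         2 * sqrt(vx * vy) *
                           sum(omega(gxy / sqrt(vx * vy))))
  if (v <= 0) return(0)
  z <- (tv - mu) / sqrt(v)
  -stats::pnorm(z, log.p = TRUE) / log(10)
}

#' @noRd
gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable convolution with edge replication.
#' @noRd
conv_sep <- function(img, k) {
  r <- (length(k) - 1) / 2
  ny <- nrow(img); nx <- ncol(img)
  pad_idx <- function(n) pmin(pmax(seq(1 - r, n + r), 1), n)
  tmp <- img[pad_idx(ny), ]
  tmp <- apply(tmp, 2, function(col) stats::filter(col, k, sides = 2))
  tmp <- tmp[(r + 1):(r + ny), , drop = FALSE]
  tmp2 <- tmp[, pad_idx(nx)]
  tmp2 <- t(apply(tmp2, 1, function(row) stats::filter(row, k, sides = 2)))
  tmp2[, (r + 1):(r + nx), drop = FALSE]
}

# Canny edge detector: Gaussian smoothing, Sobel gradients, non-maximum
# suppression along the quantized gradient direction, hysteresis with
# thresholds at the given gradient-magnitude percentiles.
#' @noRd
canny_edges <- function(img, sigma = 1, low_q = 0.7, high_q = 0.9) {
  sm <- conv_sep(img, gauss_kernel(sigma))
  ny <- nrow(sm); nx <- ncol(sm)
  pad <- function(m) m[pmin(pmax(0:(ny + 1), 1), ny),
                       pmin(pmax(0:(nx + 1), 1), nx)]
  p <- pad(sm)
  ix <- function(dy, dx) p[(2 + dy):(ny + 1 + dy), (2 + dx):(nx + 1 + dx)]
  gx <- (ix(-1, 1) + 2 * ix(0, 1) + ix(1, 1)) -
    (ix(-1, -1) + 2 * ix(0, -1) + ix(1, -1))
  gy <- (ix(1, -1) + 2 * ix(1, 0) + ix(1, 1)) -
    (ix(-1, -1) + 2 * ix(-1, 0) + ix(-1, 1))
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) == 0) return(matrix(FALSE, ny, nx))
  ang <- atan2(gy, gx) %% pi
  sector <- as.integer(floor((ang + pi / 8) / (pi / 4))) %% 4
  mp <- matrix(0, ny + 2, nx + 2); mp[2:(ny + 1), 2:(nx + 1)] <- mag
  off <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))  # E, SE, S, SW
  iy <- row(mag); jx <- col(mag)
  n1 <- n2 <- matrix(0, ny, nx)
  for (s in 0:3) {
    sel <- sector == s
    o <- off[[s + 1]]
    n1[sel] <- mp[cbind(iy[sel] + 1 + o[1], jx[sel] + 1 + o[2])]
    n2[sel] <- mp[cbind(iy[sel] + 1 - o[1], jx[sel] + 1 - o[2])]
  }
  keep <- mag >= n1 & mag >= n2 & mag > 0
  pos <- mag[mag > 0]
  thr_hi <- stats::quantile(pos, high_q, names = FALSE)
  thr_lo <- stats::quantile(pos, low_q, names = FALSE)
  strong <- keep & mag >= thr_hi
  weak <- keep & mag >= thr_lo
  if (!any(strong)) return(strong)
  # hysteresis: keep weak-edge components connected to a strong pixel
  lab <- EBImage::bwlabel(weak * 1)
  keep_labels <- unique(lab[strong])
  weak & (lab %in% keep_labels[keep_labels > 0])
}

#' Average edge strength
#'
#' Mean gradient magnitude over the pixels of a binary edge map (Canny
#' detector with Gaussian sigma 1 px and hysteresis thresholds at the 70th /
#' 90th gradient-magnitude percentiles by default). Returns 0 when no edges
#' are detected.
#'
#' @param img real 2D image matrix.
#' @param sigma Gaussian smoothing (px) of the edge detector.
#' @param low_q,high_q hysteresis threshold percentiles.
#' @return The average edge strength (>= 0).
#' @export
average_edge_strength <- function(img, sigma = 1, low_q = 0.7, high_q = 0.9) {
  stopifnot(is.matrix(img), is.numeric(img))
  if (max(img) - min(img) <= 0) return(0)
  edges <- canny_edges(img, sigma, low_q, high_q)
  if (!any(edges)) return(0)
  # gradient magnitude on the unsmoothed image (central differences)
  ny <- nrow(img); nx <- ncol(img)
  gy <- img * 0; gx <- img * 0
  gy[2:(ny - 1), ] <- (img[3:ny, ] - img[1:(ny - 2), ]) / 2
  gx[, 2:(nx - 1)] <- (img[, 3:nx] - img[, 1:(nx - 2)]) / 2
  mag <- sqrt(gy^2 + gx^2)
  mean(mag[edges])
}

#' Symmetric enhancement ratio
#'
#' \code{2 * (a - b) / (a + b)}: the relative improvement of a quality metric
#' between a corrected (\code{a}) and an uncorrected (\code{b}) image.
#' Antisymmetric in its arguments and bounded in (-2, 2) for non-negative
#' metrics. Used for both SE (sharpness enhancement) and AEE (average edge
#' enhancement).
#'
#' @param metric_corrected,metric_uncorrected metric values (sum must be
#'   positive).
#' @return The enhancement as a fraction (1.0 = 100%).
#' @export
enhancement <- function(metric_corrected, metric_uncorrected) {
  if (metric_corrected + metric_uncorrected <= 0)
    stop("enhancement undefined: non-positive metric sum")
  2 * (metric_corrected - metric_uncorrected) /
    (metric_corrected + metric_uncorrected)
}

#' Background mask via k-means segmentation
#'
#' Segments a magnitude image into \code{k} intensity clusters (k-means on
#' Gaussian-smoothed intensities with deterministic quantile-based
#' initialization), discards the lowest-intensity cluster as background, and
#' closes small holes morphologically.
#'
#' If the lowest-intensity cluster is not clearly separated from the rest
#' (its centroid above half of the largest centroid), the image is treated as
#' all-foreground: k-means always produces k clusters, even on pure noise,
#' and an unseparated "background" would just shave off the darker half of
#' the tissue.
#'
#' @param img real 2D image matrix (non-constant).
#' @param k number of intensity clusters (default 3).
#' @param sigma Gaussian smoothing (px) before clustering.
#' @return A logical matrix (TRUE = retained foreground) with the retained
#'   fraction in attribute \code{"mask_coverage"}.
#' @export
background_mask <- function(img, k = 3L, sigma = 1) {
  stopifnot(is.matrix(img), is.numeric(img))
  if (max(img) - min(img) <= 0) stop("cannot segment a constant image")
  sm <- conv_sep(img, gauss_kernel(sigma))
  centers <- stats::quantile(sm, probs = seq(0.05, 0.95, length.out = k),
                             names = FALSE)
  centers <- unique(centers)
  km <- stats::kmeans(as.vector(sm), centers = matrix(centers, ncol = 1),
                      iter.max = 50)
  bg_cluster <- which.min(km$centers)
  separated <- min(km$centers) < 0.5 * max(km$centers)
  mask <- matrix(!separated | km$cluster != bg_cluster,
                 nrow(img), ncol(img))
  closed <- EBImage::closing(EBImage::Image(mask * 1),
                             EBImage::makeBrush(5, shape = "disc"))
  out <- matrix(as.numeric(closed) > 0.5, nrow(img), ncol(img))
  attr(out, "mask_coverage") <- mean(out)
  out
}

#' Paired quality evaluation of corrected vs uncorrected volumes
#'
#' Computes SI and AES per slice on both volumes (magnitudes), then the
#' symmetric enhancements SE and AEE per slice and their means. With
#' \code{use_mask = TRUE}, both metrics are evaluated inside the bounding box
#' of a shared background mask (computed on the mean of the two magnitudes),
#' which suppresses the influence of residual aliasing outside the object.
#'
#' @param corrected,uncorrected [image_volume()]s with identical geometry.
#' @param use_mask mask out the background first?
#' @param k clusters for [background_mask()].
#' @return A \code{quality_report}: list with a per-slice data.frame
#'   (\code{si_corr, si_uncorr, aes_corr, aes_uncorr, se, aee}), mean
#'   \code{se} and \code{aee}, and \code{mask_coverage}.
#' @export
evaluate_pair <- function(corrected, uncorrected, use_mask = FALSE, k = 3L) {
  stopifnot(inherits(corrected, "image_volume"),
            inherits(uncorrected, "image_volume"))
  if (!all(corrected$geometry$matrix_size == uncorrected$geometry$matrix_size)
      || dim(corrected$data)[3] != dim(uncorrected$data)[3])
    stop("geometry mismatch between corrected and uncorrected volumes")
  nz <- dim(corrected$data)[3]
  rows <- vector("list", nz)
  coverage <- NA_real_
  for (z in seq_len(nz)) {
    a <- Mod(corrected$data[, , z])
    b <- Mod(uncorrected$data[, , z])
    if (use_mask) {
      msk <- background_mask((a + b) / 2, k = k)
      coverage <- attr(msk, "mask_coverage")
      idx <- which(msk, arr.ind = TRUE)
      yr <- range(idx[, 1]); xr <- range(idx[, 2])
      a <- a[yr[1]:yr[2], xr[1]:xr[2]]
      b <- b[yr[1]:yr[2], xr[1]:xr[2]]
    }
    si_a <- sharpness_index(a); si_b <- sharpness_index(b)
    aes_a <- average_edge_strength(a); aes_b <- average_edge_strength(b)
    rows[[z]] <- data.frame(slice = z, si_corr = si_a, si_uncorr = si_b,
                            aes_corr = aes_a, aes_uncorr = aes_b,
                            se = enhancement(si_a, si_b),
                            aee = enhancement(aes_a, aes_b))
  }
  per_slice <- do.call(rbind, rows)
  structure(list(per_slice = per_slice,
                 se = mean(per_slice$se), aee = mean(per_slice$aee),
                 si = mean(per_slice$si_corr),
                 aes = mean(per_slice$aes_corr),
                 mask_coverage = coverage),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> %d slice(s): SE = %.1f%%, AEE = %.1f%%\n",
              nrow(x$per_slice), 100 * x$se, 100 * x$aee))
  invisible(x)
}

#' Write a quality report as JSON
#' @param report a [evaluate_pair()] result.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_quality_report <- function(report, path) {
  jsonlite::write_json(list(per_slice = report$per_slice,
                            se = report$se, aee = report$aee,
                            mask_coverage = report$mask_coverage),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a quality report from JSON
#' @param path file written by [write_quality_report()].
#' @return A \code{quality_report}.
#' @export
read_quality_report <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(per_slice = as.data.frame(j$per_slice), se = j$se,
                 aee = j$aee, si = mean(j$per_slice$si_corr),
                 aes = mean(j$per_slice$aes_corr),
                 mask_coverage = j$mask_coverage %||% NA_real_),
            class = "quality_report")
}
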