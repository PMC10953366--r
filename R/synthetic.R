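# Synthetic test bed: deforming breast-like phantom, quasi-periodic
# respiration, smooth motion-model fields, coil profiles, and a shot-by-shot
# multi-coil Cartesian acquisition simulator with full ground truth.

#' Breast-like 2D phantom
#'
#' Two half-elliptical bright regions ("breasts") on a dark background,
#' attached to a chest-wall band along the posterior (low-y) edge, with
#' smooth internal texture and a few ellipsoidal glandular structures.
#' Intensities are normalized to [0, 1]. Deterministic per seed.
#'
#' @param size matrix size (square, >= 32).
#' @param seed RNG seed.
#' @param pixel_spacing pixel size in mm.
#' @return An [image_volume()] with the object support mask in attribute
#'   \code{"support"}.
#' @export
make_phantom <- function(size = 64L, seed = 1L, pixel_spacing = c(2, 2)) {
  size <- as.integer(size)
  if (size < 32) stop("phantom size must be >= 32")
  with_seed(seed, {
    y <- matrix(rep(seq_len(size), size), size, size)        # row = y
    x <- matrix(rep(seq_len(size), each = size), size, size) # col = x
    yn <- (y - 1) / (size - 1); xn <- (x - 1) / (size - 1)
    img <- matrix(0, size, size)
    # chest wall band along low y
    chest <- 0.55 * exp(-((yn - 0.08) / 0.06)^2) * (yn < 0.2)
    # two half-elliptical breasts anchored on the chest wall
    breast <- function(cx, ry, rx) {
      d <- ((yn - 0.12) / ry)^2 + ((xn - cx) / rx)^2
      (d < 1 & yn >= 0.10) * (0.75 + 0.25 * sqrt(pmax(0, 1 - d)))
    }
    b1 <- breast(0.30, 0.62, 0.21)
    b2 <- breast(0.70, 0.58, 0.22)
    breasts <- pmax(b1, b2)
    # smooth internal texture (band-limited random field)
    tex <- matrix(stats::rnorm(size^2), size, size)
    tex <- Re(ifft2u(fft2u(tex) *
                       fftshift2(outer(
                         exp(-((seq_len(size) - size / 2 - 1) / (size / 10))^2),
                         exp(-((seq_len(size) - size / 2 - 1) / (size / 10))^2)))))
    tex <- 0.15 * tex / max(abs(tex))
    # glandular ellipsoids
    gl <- matrix(0, size, size)
    for (i in 1:6) {
      cy <- stats::runif(1, 0.25, 0.55); cx <- stats::runif(1, 0.18, 0.82)
      ry <- stats::runif(1, 0.03, 0.08); rx <- stats::runif(1, 0.03, 0.08)
      amp <- stats::runif(1, 0.1, 0.25)
      d <- ((yn - cy) / ry)^2 + ((xn - cx) / rx)^2
      gl <- gl + amp * pmax(0, 1 - d)
    }
    img <- chest + breasts * (1 + tex) + gl * (breasts > 0)
    img <- img / max(img)
    support <- img > 0.1
    vol <- image_volume(img, acq_geometry(c(size, size), pixel_spacing))
    attr(vol, "support") <- support
    vol
  })
}

#' Synthetic respiratory-belt trace
#'
#' Quasi-periodic breathing: a raised-cosine waveform with inhale/exhale
#' asymmetry and slow random phase modulation, plus a quadratic baseline
#' drift and white measurement noise. The belt extends during inspiration,
#' so the waveform is non-negative before drift/noise. Deterministic per
#' seed.
#'
#' @param duration_s trace duration in seconds.
#' @param rate_hz sampling rate (>= 10 Hz).
#' @param period_s mean respiratory period (default 4 s).
#' @param drift_coeffs quadratic drift coefficients \code{c(a, b, c)} in
#'   \code{a + b t + c t^2}.
#' @param noise_sd white-noise standard deviation.
#' @param asymmetry exponent of the raised cosine (> 1 sharpens inhalation).
#' @param jitter_sd sd of the slow phase modulation (fraction of a cycle).
#' @param seed RNG seed.
#' @return A [resp_signal()].
#' @export
make_resp <- function(duration_s = 180, rate_hz = 50, period_s = 4,
                      drift_coeffs = c(0, 0, 0), noise_sd = 0,
                      asymmetry = 1.7, jitter_sd = 0.02, seed = 1L) {
  if (rate_hz < 10) stop("sampling rate must be >= 10 Hz")
  with_seed(seed, {
    t <- seq(0, duration_s, by = 1 / rate_hz)
    phase_noise <- 0
    if (jitter_sd > 0) {
      raw <- stats::rnorm(length(t))
      k <- exp(-((-100:100) / 40)^2); k <- k / sum(k)
      sm <- stats::filter(c(rev(raw[1:100]), raw, rev(raw[(length(raw) - 99):
                                                            length(raw)])),
                          k, sides = 2)
      phase_noise <- jitter_sd * as.numeric(sm[101:(100 + length(t))]) * 40
    }
    phase <- t / period_s + phase_noise
    breath <- (0.5 - 0.5 * cos(2 * pi * phase))^asymmetry
    drift <- drift_coeffs[1] + drift_coeffs[2] * t + drift_coeffs[3] * t^2
    noise <- if (noise_sd > 0) stats::rnorm(length(t), sd = noise_sd) else 0
    resp_signal(breath + drift + noise, rate_hz, t0 = 0)
  })
}

#' Synthetic motion-model coefficient fields
#'
#' Smooth coefficient maps mimicking observed breast-motion regimes:
#' \describe{
#'   \item{vertical}{dominant y-displacement growing with distance from the
#'     chest wall (anterior tissue moves most).}
#'   \item{expansion}{radial outward field centered on the object.}
#'   \item{shear}{x-displacement growing with y.}
#' }
#' All patterns vanish outside a chest-attached smooth support taper, so the
#' chest wall stays put and the field is C1-smooth.
#'
#' @param geometry an [acq_geometry()].
#' @param pattern one of \code{"vertical"}, \code{"expansion"},
#'   \code{"shear"}.
#' @param amplitude_px peak coefficient magnitude, in pixels per unit sensor
#'   amplitude (<= 8).
#' @param seed RNG seed (small smooth perturbation only).
#' @return An [alpha_maps()].
#' @export
make_alpha <- function(geometry, pattern = c("vertical", "expansion", "shear"),
                       amplitude_px = 3, seed = 1L) {
  pattern <- match.arg(pattern)
  if (amplitude_px > 8) stop("amplitude must be <= 8 px per unit signal")
  ny <- geometry$matrix_size[1]; nx <- geometry$matrix_size[2]
  yn <- matrix(rep(seq_len(ny) - 1, nx), ny, nx) / (ny - 1)
  xn <- matrix(rep(seq_len(nx) - 1, each = ny), ny, nx) / (nx - 1)
  # smooth taper: 0 at the chest wall (y=0) and at the far/side FOV edges
  taper <- sin(pi * pmin(pmax(yn, 0), 1))^1 *
    (0.5 - 0.5 * cos(2 * pi * pmin(pmax(xn, 0), 1)))^0.5
  taper <- taper * (yn > 0.02)
  co <- array(0, c(2, ny, nx))
  if (pattern == "vertical") {
    co[1, , ] <- yn * taper
    co[2, , ] <- 0.15 * sin(pi * xn) * yn * taper
  } else if (pattern == "expansion") {
    cy <- 0.45; cx <- 0.5
    r <- sqrt((yn - cy)^2 + (xn - cx)^2) + 1e-9
    co[1, , ] <- (yn - cy) / r * pmin(r * 3, 1) * taper
    co[2, , ] <- (xn - cx) / r * pmin(r * 3, 1) * taper
  } else {
    co[2, , ] <- yn * taper
    co[1, , ] <- 0.1 * yn * taper
  }
  peak <- max(sqrt(co[1, , ]^2 + co[2, , ]^2))
  if (peak > 0) co <- co * amplitude_px / peak
  alpha_maps(co, geometry)
}

#' Synthetic coil sensitivity profiles
#'
#' Smooth complex Gaussian-lobe sensitivities with lobe centers around the
#' FOV and gentle phase ramps, normalized so the root-sum-of-squares is
#' exactly 1 everywhere. Deterministic per seed.
#'
#' @param n_coils number of coils (>= 1).
#' @param geometry an [acq_geometry()].
#' @param seed RNG seed.
#' @return A [coil_maps()] (ground truth).
#' @export
make_coils <- function(n_coils, geometry, seed = 1L) {
  stopifnot(n_coils >= 1)
  ny <- geometry$matrix_size[1]; nx <- geometry$matrix_size[2]
  if (n_coils == 1) {
    return(coil_maps(array(1 + 0i, c(1, ny, nx))))
  }
  with_seed(seed, {
    yn <- matrix(rep(seq_len(ny) - 1, nx), ny, nx) / (ny - 1)
    xn <- matrix(rep(seq_len(nx) - 1, each = ny), ny, nx) / (nx - 1)
    maps <- array(0i, c(n_coils, ny, nx))
    ang0 <- stats::runif(1, 0, 2 * pi)
    for (c in seq_len(n_coils)) {
      a <- ang0 + 2 * pi * (c - 1) / n_coils
      cy <- 0.5 + 0.55 * sin(a) + stats::rnorm(1, 0, 0.05)
      cx <- 0.5 + 0.55 * cos(a) + stats::rnorm(1, 0, 0.05)
      w <- stats::runif(1, 0.5, 0.8)
      mag <- exp(-(((yn - cy)^2 + (xn - cx)^2)) / (2 * w^2))
      ph <- 2 * pi * (stats::runif(1, -0.2, 0.2) * yn +
                        stats::runif(1, -0.2, 0.2) * xn)
      maps[c, , ] <- mag * exp(1i * ph)
    }
    rss <- sqrt(apply(Mod(maps)^2, c(2, 3), sum))
    for (c in seq_len(n_coils)) maps[c, , ] <- maps[c, , ] / rss
    coil_maps(maps)
  })
}

#' Simulate a multi-coil Cartesian acquisition of a deforming object
#'
#' The phase-encode lines (optionally uniformly undersampled outside a fully
#' sampled central calibration band) are grouped into shots of
#' \code{lines_per_shot} lines acquired \code{shot_interval_s} apart; all
#' lines of a shot share one timestamp. The respiratory trace is conditioned
#' exactly as the reconstruction conditions it (low-pass + quadratic drift
#' removal), the conditioned amplitude at each shot time drives the motion
#' \code{u = alpha * s}, the warped phantom is weighted by each coil map and
#' transformed with a unitary centered FFT, and the shot's lines are stored.
#' With \code{binned = TRUE} the sensor amplitude is first quantized to
#' \code{n_states} state values (the reconstruction's model, useful as an
#' exact consistency oracle); continuous mode injects the model mismatch of
#' real acquisitions. Complex white Gaussian noise is added at the requested
#' image-domain SNR (relative to the mean support intensity).
#'
#' The ground-truth image is the phantom itself: the conditioned signal is
#' zero-mean by construction of the drift fit, so the phantom is the
#' \code{s = 0} reference frame that the joint reconstruction estimates.
#'
#' @param phantom an [image_volume()] from [make_phantom()].
#' @param alpha an [alpha_maps()] (ground-truth motion model).
#' @param resp a raw [resp_signal()] spanning the acquisition.
#' @param coils a [coil_maps()].
#' @param lines_per_shot k-space lines per shot.
#' @param shot_interval_s time between shots (s).
#' @param acceleration uniform undersampling factor (1 = fully sampled).
#' @param n_center_lines fully sampled central calibration lines (used when
#'   \code{acceleration > 1}).
#' @param ordering \code{"interleaved"} (default; shot j takes every S-th
#'   line) or \code{"sequential"}.
#' @param snr image-domain signal-to-noise ratio (\code{Inf} = noiseless).
#' @param binned quantize the drive signal to \code{n_states} state values?
#' @param n_states states for \code{binned} mode.
#' @param seed RNG seed (noise).
#' @return A [kspace_data()] with attributes \code{"ground_truth"} (the
#'   phantom volume), \code{"alpha_true"}, \code{"resp"} (the raw trace),
#'   \code{"s_shot"} (conditioned amplitude per shot) and \code{"line_s"}
#'   (per line).
#' @export
simulate_acquisition <- function(phantom, alpha, resp, coils,
                                 lines_per_shot = 2L, shot_interval_s = 4.7,
                                 acceleration = 1L, n_center_lines = 24L,
                                 ordering = c("interleaved", "sequential"),
                                 snr = Inf, binned = FALSE, n_states = 12L,
                                 seed = 1L) {
  ordering <- match.arg(ordering)
  g <- phantom$geometry
  ny <- g$matrix_size[1]; nx <- g$matrix_size[2]
  img <- slice_matrix(phantom)
  if (!is.complex(img)) storage.mode(img) <- "complex"
  ctr <- ny %/% 2
  if (acceleration > 1) {
    half_lo <- floor(n_center_lines / 2); half_hi <- ceiling(n_center_lines / 2)
    band <- seq(ctr - half_lo, ctr + half_hi - 1)
    outside <- setdiff(seq(0, ny - 1), band)
    outside <- outside[(outside - min(outside)) %% acceleration == 0]
    pe_all <- sort(c(band, outside))
  } else {
    pe_all <- seq(0, ny - 1)
    n_center_lines <- 0L
  }
  n_lines <- length(pe_all)
  if (n_lines %% lines_per_shot != 0)
    stop("protocol inconsistent with matrix size: ", n_lines,
         " sampled lines not divisible into shots of ", lines_per_shot)
  n_shots <- n_lines %/% lines_per_shot
  # shot composition
  shot_of <- if (ordering == "interleaved") {
    rep(seq_len(n_shots), times = lines_per_shot)
  } else {
    rep(seq_len(n_shots), each = lines_per_shot)
  }
  t_shot <- (seq_len(n_shots) - 1) * shot_interval_s
  total_t <- max(t_shot)
  if (total_t > max(resp_times(resp)))
    stop("respiratory trace does not cover the acquisition span")
  # condition the trace as the reconstruction will
  cond <- correct_drift(
    if (resp$sample_rate > 6) lowpass_filter(resp, 3) else resp)
  s_shot <- cond$values[
    vapply(t_shot, function(tt) which.min(abs(resp_times(cond) - tt)), 1L)]
  if (binned) {
    binned_sig <- bin_motion_states(cond, n_states)
    s_shot <- binned_sig$state_values[
      state_for_line(binned_sig, t_shot) + 1]
  }
  nc <- dim(coils$maps)[1]
  samples <- array(0i, c(nc, n_lines, nx))
  pe_line <- integer(n_lines); ts_line <- numeric(n_lines)
  s_line <- numeric(n_lines)
  pos <- 1L
  for (j in seq_len(n_shots)) {
    pe_j <- pe_all[shot_of == j]
    u <- alpha$coeff * s_shot[j]
    warped <- warp_image(img, displacement_field(u))
    for (c in seq_len(nc)) {
      ksp <- fft2u(coils$maps[c, , ] * warped)
      samples[c, pos:(pos + length(pe_j) - 1), ] <-
        ksp[pe_j + 1, , drop = FALSE]
    }
    pe_line[pos:(pos + length(pe_j) - 1)] <- pe_j
    ts_line[pos:(pos + length(pe_j) - 1)] <- t_shot[j]
    s_line[pos:(pos + length(pe_j) - 1)] <- s_shot[j]
    pos <- pos + length(pe_j)
  }
  if (is.finite(snr)) {
    support <- attr(phantom, "support")
    sig_level <- if (!is.null(support)) mean(Mod(img)[support])
                 else mean(Mod(img))
    sdn <- sig_level / snr / sqrt(2)
    noise <- with_seed(seed, array(complex(real = stats::rnorm(length(samples),
                                                               sd = sdn),
                                           imaginary = stats::rnorm(
                                             length(samples), sd = sdn)),
                                   dim(samples)))
    samples <- samples + noise
  }
  ks <- kspace_data(samples,
                    data.frame(phase_encode_index = pe_line,
                               slice_index = 0L, timestamp = ts_line),
                    g, acceleration = acceleration,
                    n_center_calibration_lines = n_center_lines)
  attr(ks, "ground_truth") <- phantom
  attr(ks, "alpha_true") <- alpha
  attr(ks, "resp") <- resp
  attr(ks, "s_shot") <- s_shot
  attr(ks, "line_s") <- s_line
  ks
}
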