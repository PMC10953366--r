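# The coupled inversion: Tikhonov-regularized image reconstruction and
# linearized motion-model updates, alternated on a multiresolution pyramid.

#' GRICS solver configuration
#'
#' Defaults are the operating point selected for online use: \eqn{\lambda=1}
#' for the generalized reconstruction, \eqn{\mu=0.5} for the model
#' optimization, CG tolerances \code{1e-3} (reconstruction) and \code{1e-2}
#' (motion), 4 fixed-point iterations, 10 CG iterations per solver, 12 motion
#' states and 32 central calibration lines, on a dyadic pyramid.
#'
#' \code{lambda_recon} and \code{mu_motion} are interpreted under the
#' conventional unnormalized-DFT data scale; internally they are multiplied
#' by \code{nu = 1/(Nx*Ny)} at each pyramid level because this package uses
#' unitary Fourier transforms (set \code{nu_scale} to override).
#'
#' @param lambda_recon Tikhonov weight of the image subproblem.
#' @param mu_motion Tikhonov weight (on the coefficient gradient) of the
#'   motion subproblem.
#' @param n_fixed_point alternations of the two solvers per pyramid level.
#' @param maxit_recon,maxit_motion CG iteration caps.
#' @param tol_recon,tol_motion CG relative-residual tolerances.
#' @param n_states number of respiratory motion states \code{Ns}.
#' @param n_levels pyramid levels (level \code{n_levels} is native resolution
#'   and runs the reconstruction step only). \code{NULL} (default) adapts the
#'   depth so the coarsest level is ~8 pixels, where any plausible
#'   displacement is sub-pixel and the warp linearization is accurate.
#' @param smoothing_coeff coil-map spline roughness weight.
#' @param n_center_lines central lines used for coil-map estimation.
#' @param nu_scale optional override of the per-level \code{nu} factor.
#' @param nu_motion_scale extra factor on \code{nu} for the motion system's
#'   gradient penalty (default 10). The paper's \eqn{\mu = 0.5} is expressed
#'   on its (unstated) raw-data intensity scale, so the conversion to the
#'   unitary-FFT scale carries a free factor; the default was calibrated once
#'   on simulations so the smoothness prior suppresses noise-driven
#'   coefficients while leaving smooth fields intact.
#' @param omega_motion over-relaxation of the motion increment
#'   (\eqn{\alpha \gets \alpha + \omega\,\delta\alpha}, default 2). The
#'   alternating scheme is a contractive fixed-point iteration whose steps
#'   are systematically damped by the image re-fit; moderate over-relaxation
#'   roughly halves the iterations needed, and the scheme stays stable for
#'   \eqn{\omega \le 2}.
#' @param mc_coil_refresh when to refresh coil maps with the
#'   motion-compensated estimator [estimate_coil_maps_mc()]:
#'   \code{"iteration"} (before every fixed-point iteration, default),
#'   \code{"level"} (at the start of each pyramid level) or \code{"off"}.
#' @param n_passes number of sweeps through the coarse-to-fine schedule
#'   (default 2). The joint problem is bilinear: the first pass estimates the
#'   motion model from coil maps and coarse images that are still biased by
#'   motion; the second pass restarts the schedule with the
#'   motion-compensated maps and the converged model, which removes most of
#'   the remaining amplitude bias.
#' @return A \code{grics_config} list.
#' @export
grics_config <- function(lambda_recon = 1, mu_motion = 0.5,
                         n_fixed_point = 4L, maxit_recon = 10L,
                         maxit_motion = 10L, tol_recon = 1e-3,
                         tol_motion = 1e-2, n_states = 12L, n_levels = NULL,
                         smoothing_coeff = 1000, n_center_lines = 32L,
                         nu_scale = NULL, nu_motion_scale = 10,
                         omega_motion = 2,
                         mc_coil_refresh = c("iteration", "level", "off"),
                         n_passes = 2L) {
  mc_coil_refresh <- match.arg(mc_coil_refresh)
  cfg <- list(lambda_recon = lambda_recon, mu_motion = mu_motion,
              n_fixed_point = as.integer(n_fixed_point),
              maxit_recon = as.integer(maxit_recon),
              maxit_motion = as.integer(maxit_motion),
              tol_recon = tol_recon, tol_motion = tol_motion,
              n_states = as.integer(n_states),
              n_levels = if (is.null(n_levels)) NULL else as.integer(n_levels),
              smoothing_coeff = smoothing_coeff,
              n_center_lines = as.integer(n_center_lines),
              nu_scale = nu_scale, nu_motion_scale = nu_motion_scale,
              omega_motion = omega_motion,
              mc_coil_refresh = mc_coil_refresh,
              n_passes = as.integer(n_passes))
  stopifnot(cfg$lambda_recon >= 0, cfg$mu_motion >= 0, cfg$n_fixed_point >= 1,
            cfg$maxit_recon >= 1, cfg$maxit_motion >= 1, cfg$tol_recon > 0,
            cfg$tol_motion > 0, cfg$n_states >= 1,
            is.null(cfg$n_levels) || cfg$n_levels >= 1,
            cfg$nu_motion_scale > 0, cfg$omega_motion > 0,
            cfg$omega_motion <= 2, cfg$n_passes >= 1)
  structure(cfg, class = "grics_config")
}

#' @noRd
nu_for <- function(cfg, ny, nx) cfg$nu_scale %||% (1 / (ny * nx))

#' Tikhonov-regularized image reconstruction
#'
#' Conjugate gradient on the normal equations
#' \eqn{(E^H E + \lambda\nu I)\rho = E^H m}, stopping at \code{maxit}
#' iterations or relative residual below \code{tol}.
#'
#' @param op an [encoding_operator()].
#' @param m k-space samples \code{[coil, line, readout]}.
#' @param lambda_recon Tikhonov weight (see [grics_config()] for the
#'   \code{nu} normalization).
#' @param maxit,tol CG controls.
#' @param nu data-scale normalization of \code{lambda_recon}; defaults to
#'   \code{1/(Nx*Ny)}.
#' @return The reconstructed complex image matrix, with the CG iteration
#'   count and final relative residual in attributes \code{"iterations"} and
#'   \code{"relres"}.
#' @export
solve_reconstruction <- function(op, m, lambda_recon = 1, maxit = 10L,
                                 tol = 1e-3, nu = NULL) {
  if (!all(is.finite(Re(m)) & is.finite(Im(m)))) stop("non-finite k-space data")
  nu <- nu %||% (1 / (op$ny * op$nx))
  lam <- lambda_recon * nu
  rhs <- encode_adjoint(op, m)
  sol <- cg_solve(function(x) encode_normal(op, x) + lam * x,
                  rhs, maxit = maxit, tol = tol)
  structure(sol$x, iterations = sol$iterations, relres = sol$relres)
}

# Linearized motion operator. Perturbing alpha by d_alpha shifts the state-s
# displacement by state_value[s] * d_alpha; to first order the warped image
# changes by grad(W_s rho) . du. L maps d_alpha (real [2, Ny, Nx]) to k-space
# samples through coil weighting, unitary FFT and line sampling.
#' @noRd
motion_linear_parts <- function(op, rho) {
  lapply(op$states, function(s) {
    w <- op_apply_warp(op, s, rho)
    # central-difference spatial gradient (zero at the FOV edge)
    gy <- w * 0; gx <- w * 0
    ny <- nrow(w); nx <- ncol(w)
    gy[2:(ny - 1), ] <- (w[3:ny, ] - w[1:(ny - 2), ]) / 2
    gx[, 2:(nx - 1)] <- (w[, 3:nx] - w[, 1:(nx - 2)]) / 2
    list(state = s, gy = gy, gx = gx, sval = op$state_values[s + 1])
  })
}

#' @noRd
motion_forward <- function(op, parts, da) {
  out <- array(0i, c(op$nc, length(op$line_pe), op$nx))
  for (p in parts) {
    rows <- which(op$line_states == p$state)
    pert <- p$sval * (p$gy * da[1, , ] + p$gx * da[2, , ])
    for (c in seq_len(op$nc)) {
      ksp <- fft2u(op$coil_maps$maps[c, , ] * pert)
      out[c, rows, ] <- ksp[op$line_pe[rows] + 1, , drop = FALSE]
    }
  }
  out
}

#' @noRd
motion_adjoint <- function(op, parts, r) {
  da <- array(0, c(2, op$ny, op$nx))
  for (p in parts) {
    rows <- which(op$line_states == p$state)
    q <- matrix(0i, op$ny, op$nx)
    for (c in seq_len(op$nc)) {
      grid <- matrix(0i, op$ny, op$nx)
      grid[op$line_pe[rows] + 1, ] <- r[c, rows, ]
      q <- q + Conj(op$coil_maps$maps[c, , ]) * ifft2u(grid)
    }
    da[1, , ] <- da[1, , ] + p$sval * Re(Conj(p$gy) * q)
    da[2, , ] <- da[2, , ] + p$sval * Re(Conj(p$gx) * q)
  }
  da
}

# Gradient-penalty normal operator: (grad^T grad) applied to each coefficient
# component with forward differences and Neumann boundaries.
#' @noRd
grad_penalty <- function(da) {
  out <- da * 0
  for (k in 1:2) {
    f <- da[k, , ]
    ny <- nrow(f); nx <- ncol(f)
    dy <- f[c(2:ny, ny), ] - f          # forward diff, replicated edge
    dx <- f[, c(2:nx, nx)] - f
    # adjoint of forward difference (negative divergence)
    oy <- -dy; oy[2:ny, ] <- oy[2:ny, ] + dy[1:(ny - 1), ]
    ox <- -dx; ox[, 2:nx] <- ox[, 2:nx] + dx[, 1:(nx - 1)]
    out[k, , ] <- oy + ox
  }
  out
}

#' Linearized motion-model update
#'
#' Solves the Gauss-Newton subproblem for the coefficient increment
#' \eqn{\delta\alpha}: the data residual \eqn{\epsilon = m - E(u)\rho} is
#' modeled as \eqn{L\,\delta\alpha} with \eqn{L} the spatial-gradient
#' linearization of the warp, regularized by
#' \eqn{\mu\|\nabla(\alpha + \delta\alpha)\|^2}, and solved by CG on
#' \eqn{(L^H L + \mu\nu G)\,\delta\alpha = L^H\epsilon - \mu\nu G\alpha}.
#'
#' @param op an [encoding_operator()] built from the current \code{alpha}.
#' @param m acquired k-space samples.
#' @param rho current image estimate (complex matrix).
#' @param alpha current [alpha_maps()].
#' @param mu_motion Tikhonov weight on the coefficient gradient.
#' @param maxit,tol CG controls.
#' @param nu data-scale normalization (default \code{1/(Nx*Ny)}).
#' @return The increment as an [alpha_maps()], with CG diagnostics in
#'   attributes.
#' @export
solve_motion_update <- function(op, m, rho, alpha, mu_motion = 0.5,
                                maxit = 10L, tol = 1e-2, nu = NULL) {
  if (all(Mod(rho) == 0)) stop("cannot linearize the warp on an empty image")
  nu <- nu %||% (1 / (op$ny * op$nx))
  mu <- mu_motion * nu
  parts <- motion_linear_parts(op, rho)
  eps <- m - encode_forward(op, rho)
  rhs <- motion_adjoint(op, parts, eps) - mu * grad_penalty(alpha$coeff)
  sol <- cg_solve(function(x) {
    motion_adjoint(op, parts, motion_forward(op, parts, x)) +
      mu * grad_penalty(x)
  }, rhs, maxit = maxit, tol = tol)
  structure(alpha_maps(sol$x, alpha$geometry),
            iterations = sol$iterations, relres = sol$relres)
}

# Central crop of k-space to a coarser dyadic level. Lines whose
# phase-encode index falls outside the coarse band are dropped; readout is
# cropped around DC. Indices are remapped to the coarse grid.
#' @noRd
crop_kspace <- function(ks, n) {
  g <- ks$geometry
  ny <- g$matrix_size[1]; nx <- g$matrix_size[2]
  if (n > ny || n > nx) stop("crop size exceeds matrix")
  y_lo <- ny %/% 2 - n %/% 2          # 0-based first kept pe index
  x_lo <- nx %/% 2 - n %/% 2
  keep <- ks$line_meta$phase_encode_index >= y_lo &
    ks$line_meta$phase_encode_index < y_lo + n
  lm <- ks$line_meta[keep, , drop = FALSE]
  lm$phase_encode_index <- lm$phase_encode_index - y_lo
  samp <- ks$samples[, keep, (x_lo + 1):(x_lo + n), drop = FALSE]
  gg <- acq_geometry(c(n, n), g$pixel_spacing * g$matrix_size / n,
                     g$slice_thickness, 1L)
  kspace_data(samp, lm, gg, acceleration = 1L,
              n_center_calibration_lines = 0L)
}

#' Joint motion-corrected reconstruction (GRICS)
#'
#' Runs the alternating optimization on a dyadic multiresolution pyramid,
#' coarsest level first. At every level below the native resolution,
#' \code{n_fixed_point} alternations of [solve_reconstruction()] and
#' [solve_motion_update()] are performed (\eqn{\alpha \gets \alpha +
#' \delta\alpha}), then \eqn{\alpha} is upsampled with pixel-unit rescaling.
#' At the native level only the reconstruction step runs. The uncorrected
#' comparator (same solver with zero motion and a single state) is computed
#' alongside.
#'
#' The respiratory trace is conditioned internally (3 Hz zero-phase low-pass,
#' quadratic drift removal, equal-width binning into \code{cfg$n_states})
#' unless it already carries state labels. A constant trace collapses to a
#' single zero-valued state, in which case the pipeline reduces exactly to
#' plain regularized parallel-imaging reconstruction.
#'
#' @param ks single-slice [kspace_data()].
#' @param resp the [resp_signal()] covering the acquisition span.
#' @param cfg a [grics_config()].
#' @param alpha_init optional initial [alpha_maps()] (required when
#'   \code{motion_update = FALSE}).
#' @param motion_update logical; \code{FALSE} omits the motion optimization
#'   step and reconstructs with \code{alpha_init} (the model-reuse pathway
#'   for a follow-up acquisition).
#' @param coil_maps optional precomputed [coil_maps()] at native resolution;
#'   by default maps are estimated per level from the central lines.
#' @return A \code{recon_result}: list with \code{corrected} and
#'   \code{uncorrected} [image_volume()]s (SoS-normalized magnitude-ready
#'   complex data), \code{alpha}, \code{residual_history} (relative
#'   data-consistency norm per fixed-point iteration and level),
#'   \code{config}, and the conditioned \code{resp}.
#' @export
run_grics <- function(ks, resp, cfg = grics_config(), alpha_init = NULL,
                      motion_update = TRUE, coil_maps = NULL) {
  stopifnot(inherits(ks, "kspace_data"), inherits(resp, "resp_signal"))
  if (!motion_update && is.null(alpha_init))
    stop("recon-only mode requires alpha_init")
  g <- ks$geometry
  ny <- g$matrix_size[1]; nx <- g$matrix_size[2]
  if (ny != nx) stop("square matrices are assumed for the dyadic pyramid")
  if (is.null(resp$state_labels)) {
    resp <- condition_resp(resp, cfg$n_states)
  }
  n_states <- length(resp$state_values)
  line_states <- state_for_line(resp, ks$line_meta$timestamp)
  empty <- setdiff(seq_len(n_states) - 1L, unique(line_states))
  if (length(empty) > 0)
    message("motion state(s) with no acquired lines skipped: ",
            paste(empty, collapse = ", "))

  n_levels <- cfg$n_levels %||% max(1L, as.integer(floor(log2(ny / 8))) + 1L)
  sizes <- ny / 2^((n_levels - 1):0)
  if (any(sizes != round(sizes)))
    stop("matrix size not divisible for ", n_levels, " dyadic levels")
  # with the motion step omitted nothing couples the levels: go straight to
  # the native-resolution reconstruction
  if (!motion_update) sizes <- ny
  alpha <- NULL
  residual_history <- list()

  # coil maps are estimated once at native resolution (from the central
  # calibration lines) and resampled to each pyramid level; they are smooth,
  # so bilinear resampling in physical coordinates is accurate
  cm_native <- if (!is.null(coil_maps)) coil_maps
               else estimate_coil_maps(ks, min(cfg$n_center_lines, ny),
                                       cfg$smoothing_coeff)
  cm_plain <- cm_native  # uncompensated estimate, for the uncorrected recon

  line_states_native <- state_for_line(resp, ks$line_meta$timestamp)
  n_passes <- if (!motion_update) 1L else (cfg$n_passes %||% 1L)

  for (pass in seq_len(n_passes)) for (li in seq_along(sizes)) {
    n <- sizes[li]
    ksl <- if (n < ny) crop_kspace(ks, n) else ks
    gl <- ksl$geometry
    if (is.null(alpha)) {
      alpha <- if (!is.null(alpha_init)) interpolate_alpha(alpha_init, gl)
               else alpha_zero(gl)
    } else {
      alpha <- interpolate_alpha(alpha, gl)
    }
    ls <- state_for_line(resp, ksl$line_meta$timestamp)
    cm_level <- if (n == ny) cm_native else resample_coil_maps(cm_native, g, gl)
    build_op <- function(a) encoding_operator(cm_level, ls,
                                              ksl$line_meta$phase_encode_index,
                                              resp$state_values, a, gl)
    m <- ksl$samples
    nm <- sqrt(sum(Mod(m)^2))
    final_level <- li == length(sizes)
    res_lv <- numeric(0)
    # motion-consistent coil refresh, once a motion model and image exist.
    # The refinement runs at the level's resolution; only the correction it
    # implies (refined minus current, a field of the level's bandwidth) is
    # propagated to the native maps, preserving their finer-scale content.
    may_refresh <- cfg$mc_coil_refresh != "off" && is.null(coil_maps)
    refresh_maps <- function(rho_cur, a_cur) {
      if (max(abs(a_cur$coeff)) <= 1e-12) return(FALSE)
      refined <- refine_coil_maps(ksl, a_cur,
                                  matrix(as.complex(rho_cur), n, n),
                                  ls, resp$state_values,
                                  cfg$smoothing_coeff)
      delta <- coil_maps(refined$maps - cm_level$maps)
      cm_native <<- coil_maps(cm_native$maps +
                                resample_coil_maps(delta, gl, g)$maps)
      cm_level <<- refined
      TRUE
    }
    if (final_level) {
      op <- build_op(alpha)
      rho <- solve_reconstruction(op, m, cfg$lambda_recon, cfg$maxit_recon,
                                  cfg$tol_recon, nu_for(cfg, n, n))
      if (may_refresh && refresh_maps(rho, alpha)) {
        op <- build_op(alpha)
        rho <- solve_reconstruction(op, m, cfg$lambda_recon, cfg$maxit_recon,
                                    cfg$tol_recon, nu_for(cfg, n, n))
      }
      res_lv <- sqrt(sum(Mod(encode_forward(op, rho) - m)^2)) / nm
      cm_native <- cm_level
    } else {
      rho <- NULL
      for (it in seq_len(cfg$n_fixed_point)) {
        # refresh maps with the previous iterate, BEFORE re-fitting the
        # image, so the motion step sees a map-consistent residual
        if (!is.null(rho) && may_refresh &&
            (cfg$mc_coil_refresh == "iteration" || it == 2)) {
          refresh_maps(rho, alpha)
        }
        op <- build_op(alpha)
        rho <- solve_reconstruction(op, m, cfg$lambda_recon, cfg$maxit_recon,
                                    cfg$tol_recon, nu_for(cfg, n, n))
        res_lv <- c(res_lv, sqrt(sum(Mod(encode_forward(op, rho) - m)^2)) / nm)
        # a single motion state (or an all-but-zero sensor) carries no
        # motion information: the model is unidentifiable and alpha stays put
        informative <- length(resp$state_values) >= 2 &&
          max(abs(resp$state_values)) > 1e-9 * max(1, max(abs(resp$values)))
        if (motion_update && informative && any(Mod(rho) > 0)) {
          da <- solve_motion_update(op, m, rho, alpha, cfg$mu_motion,
                                    cfg$maxit_motion, cfg$tol_motion,
                                    cfg$nu_motion_scale * nu_for(cfg, n, n))
          # safeguarded over-relaxation: halve the step until the
          # data-consistency residual (at the current image) stops growing
          res_cur <- sqrt(sum(Mod(encode_forward(op, rho) - m)^2)) / nm
          omega <- cfg$omega_motion
          for (try in 1:3) {
            cand <- alpha_maps(alpha$coeff + omega * da$coeff, gl)
            opc <- build_op(cand)
            res_cand <- sqrt(sum(Mod(encode_forward(opc, rho) - m)^2)) / nm
            if (res_cand <= res_cur * 1.10) break
            omega <- omega / 2
            cand <- NULL
          }
          if (!is.null(cand)) alpha <- cand
        }
      }
    }
    residual_history[[paste0("pass", pass, "_level_", n)]] <- res_lv
  }

  # uncorrected comparator: identical solver, zero motion, single state,
  # plain (uncompensated) coil maps -- the standard reconstruction
  op0 <- encoding_operator(cm_plain, rep(0L, nrow(ks$line_meta)),
                           ks$line_meta$phase_encode_index, 0,
                           alpha_zero(g), g)
  rho0 <- solve_reconstruction(op0, ks$samples, cfg$lambda_recon,
                               cfg$maxit_recon, cfg$tol_recon,
                               nu_for(cfg, ny, nx))

  corr <- sos_normalize(matrix(as.complex(rho), ny, nx), cm_native)
  unc <- sos_normalize(matrix(as.complex(rho0), ny, nx), cm_plain)
  structure(list(corrected = image_volume(corr, g),
                 uncorrected = image_volume(unc, g),
                 raw_corrected = matrix(as.complex(rho), ny, nx),
                 raw_uncorrected = matrix(as.complex(rho0), ny, nx),
                 alpha = alpha, coil_maps = cm_native,
                 residual_history = residual_history,
                 resp = resp, config = cfg),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  g <- x$corrected$geometry
  n_passes <- length(unique(sub("_level.*", "", names(x$residual_history))))
  cat(sprintf(
    "<recon_result> %dx%d, %d motion states, %d pyramid levels x %d pass(es)\n",
    g$matrix_size[1], g$matrix_size[2], length(x$resp$state_values),
    length(x$residual_history) / n_passes, n_passes))
  fr <- x$residual_history[[length(x$residual_history)]]
  cat(sprintf("final data-consistency residual: %.4g\n", fr[length(fr)]))
  invisible(x)
}

#' Reconstruct all slices of a multi-slice acquisition
#'
#' Each slice is reconstructed independently with [run_grics()]; with
#' \code{n_workers > 1} slices run in parallel worker processes. Results are
#' bit-identical to sequential execution for any worker count (the solvers
#' are deterministic and slices share no state).
#'
#' @param ks multi-slice [kspace_data()].
#' @param resp the [resp_signal()].
#' @param cfg a [grics_config()].
#' @param n_workers number of parallel workers (forked; falls back to
#'   sequential on platforms without fork).
#' @param ... passed through to [run_grics()].
#' @return A list of \code{recon_result}, one per slice (ascending 0-based
#'   slice index).
#' @export
reconstruct_slices_parallel <- function(ks, resp, cfg = grics_config(),
                                        n_workers = 1L, ...) {
  slices <- sort(unique(ks$line_meta$slice_index))
  fun <- function(sl) run_grics(kspace_slice(ks, sl), resp, cfg, ...)
  if (n_workers > 1 && .Platform$OS.type == "unix") {
    parallel::mclapply(slices, fun, mc.cores = n_workers)
  } else {
    lapply(slices, fun)
  }
}
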