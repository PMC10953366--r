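# The encoding operator E(u) of the coupled system: per motion state,
# spatial warp -> coil weighting -> unitary FFT -> phase-encode line
# sampling; and its exact adjoint. Motion is piecewise constant per state.

#' Build the encoding operator
#'
#' Assembles \eqn{E(u)} for one slice: every acquired k-space line belongs to
#' exactly one motion state; all lines of a state share the displacement
#' field \code{alpha * state_value}. The forward map warps the image by the
#' state displacement, multiplies by each coil sensitivity, applies a unitary
#' centered 2D FFT and extracts the acquired phase-encode rows. Output
#' samples are ordered exactly like the \code{kspace_data} container:
#' \code{[coil, line, readout]} with lines in acquisition order.
#'
#' @param coil_maps a [coil_maps()].
#' @param line_states integer 0-based motion-state label per acquired line.
#' @param line_pe integer 0-based phase-encode index per acquired line.
#' @param state_values numeric sensor value per state (length = number of
#'   states).
#' @param alpha an [alpha_maps()] (use [alpha_zero()] for no motion).
#' @param geometry an [acq_geometry()].
#' @return An object of class \code{encoding_operator} with precomputed
#'   per-state warp matrices.
#' @export
encoding_operator <- function(coil_maps, line_states, line_pe, state_values,
                              alpha, geometry) {
  ny <- geometry$matrix_size[1]; nx <- geometry$matrix_size[2]
  stopifnot(length(line_states) == length(line_pe))
  if (any(line_states < 0 | line_states >= length(state_values)))
    stop("every acquired line must be assigned to exactly one state")
  if (any(line_pe < 0 | line_pe >= ny)) stop("phase-encode index out of range")
  states <- sort(unique(line_states))
  warps <- lapply(states, function(s) {
    u <- alpha$coeff * state_values[s + 1]
    W <- warp_matrix(u, ny, nx)
    list(W = W, Wt = Matrix::t(W))
  })
  names(warps) <- as.character(states)
  structure(list(coil_maps = coil_maps, line_states = as.integer(line_states),
                 line_pe = as.integer(line_pe),
                 state_values = as.numeric(state_values),
                 alpha = alpha, geometry = geometry,
                 states = states, warps = warps,
                 ny = ny, nx = nx, nc = dim(coil_maps$maps)[1]),
            class = "encoding_operator")
}

#' @noRd
op_apply_warp <- function(op, state, img, adjoint = FALSE) {
  w <- op$warps[[as.character(state)]]
  apply_warp_matrix(if (adjoint) w$Wt else w$W, img)
}

#' Forward encoding: image to k-space samples
#'
#' @param op an [encoding_operator()].
#' @param rho 2D complex image matrix.
#' @return Complex array \code{[coil, line, readout]} over the acquired
#'   lines, matching the container ordering.
#' @export
encode_forward <- function(op, rho) {
  if (!all(dim(rho) == c(op$ny, op$nx))) stop("image shape mismatch")
  if (!is.complex(rho)) storage.mode(rho) <- "complex"
  out <- array(0i, c(op$nc, length(op$line_pe), op$nx))
  for (s in op$states) {
    rows <- which(op$line_states == s)
    warped <- op_apply_warp(op, s, rho)
    for (c in seq_len(op$nc)) {
      ksp <- fft2u(op$coil_maps$maps[c, , ] * warped)
      out[c, rows, ] <- ksp[op$line_pe[rows] + 1, , drop = FALSE]
    }
  }
  out
}

#' Adjoint encoding: k-space samples to image
#'
#' Exact adjoint of [encode_forward()]: zero-fill the acquired lines onto the
#' k-space grid, inverse unitary FFT, conjugate coil weighting, adjoint warp,
#' and sum over coils and states.
#'
#' @param op an [encoding_operator()].
#' @param m complex array \code{[coil, line, readout]} as produced by
#'   [encode_forward()].
#' @return 2D complex image matrix.
#' @export
encode_adjoint <- function(op, m) {
  if (!all(dim(m) == c(op$nc, length(op$line_pe), op$nx)))
    stop("k-space sample shape mismatch")
  acc <- matrix(0i, op$ny, op$nx)
  for (s in op$states) {
    rows <- which(op$line_states == s)
    coilsum <- matrix(0i, op$ny, op$nx)
    for (c in seq_len(op$nc)) {
      grid <- matrix(0i, op$ny, op$nx)
      grid[op$line_pe[rows] + 1, ] <- m[c, rows, ]
      coilsum <- coilsum + Conj(op$coil_maps$maps[c, , ]) * ifft2u(grid)
    }
    acc <- acc + op_apply_warp(op, s, coilsum, adjoint = TRUE)
  }
  acc
}

# Normal-equations operator E^H E applied to an image.
#' @noRd
encode_normal <- function(op, rho) encode_adjoint(op, encode_forward(op, rho))

#' Largest singular value of the encoding operator (power iteration)
#'
#' Useful for verifying the operator-norm bound
#' \eqn{\|E\| \le \sqrt{\max \mathrm{RSS}}} under full sampling.
#'
#' @param op an [encoding_operator()].
#' @param iters power-iteration count.
#' @param seed RNG seed for the start vector.
#' @return Estimated operator 2-norm.
#' @export
encode_opnorm <- function(op, iters = 30L, seed = 1L) {
  x <- with_seed(seed, matrix(stats::rnorm(op$ny * op$nx), op$ny, op$nx)) + 0i
  for (i in seq_len(iters)) {
    y <- encode_normal(op, x)
    x <- y / sqrt(Re(sum(Conj(y) * y)))
  }
  sqrt(sqrt(Re(sum(Conj(encode_normal(op, x)) * encode_normal(op, x)))))
}
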