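# Shared numerical helpers: shifted unitary FFTs, seeded RNG scope, CG.

#' @noRd
fftshift2 <- function(x) {
  d <- dim(x)
  x[c(seq(d[1] %/% 2 + 1, d[1]), seq_len(d[1] %/% 2)),
    c(seq(d[2] %/% 2 + 1, d[2]), seq_len(d[2] %/% 2)), drop = FALSE]
}

#' @noRd
ifftshift2 <- function(x) {
  d <- dim(x)
  x[c(seq(d[1] - d[1] %/% 2 + 1, d[1]), seq_len(d[1] - d[1] %/% 2)),
    c(seq(d[2] - d[2] %/% 2 + 1, d[2]), seq_len(d[2] - d[2] %/% 2)),
    drop = FALSE]
}

# Unitary centered 2D FFT pair. DC of the k-space grid sits at
# (Ny/2, Nx/2) in 0-based indexing. The pair is exactly adjoint/unitary.
#' @noRd
fft2u <- function(img) {
  fftshift2(stats::fft(ifftshift2(img))) / sqrt(length(img))
}

#' @noRd
ifft2u <- function(ks) {
  fftshift2(stats::fft(ifftshift2(ks), inverse = TRUE)) / sqrt(length(ks))
}

# Run expr with a fixed RNG seed, restoring the caller's RNG state after.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Conjugate gradient for Hermitian positive (semi)definite A given as a
# function handle. Works for real or complex vectors; inner products use
# Re(<a, b>) which is exact for Hermitian A. Stops on relative residual
# ||r|| / ||b|| < tol or after maxit iterations.
#' @noRd
cg_solve <- function(Afun, b, x0 = NULL, maxit = 10L, tol = 1e-3) {
  x <- if (is.null(x0)) b * 0 else x0
  r <- b - Afun(x)
  p <- r
  nb <- sqrt(Re(sum(Conj(b) * b)))
  if (nb == 0) {
    return(list(x = x * 0, iterations = 0L, relres = 0))
  }
  rs <- Re(sum(Conj(r) * r))
  it <- 0L
  while (it < maxit && sqrt(rs) / nb >= tol) {
    Ap <- Afun(p)
    denom <- Re(sum(Conj(p) * Ap))
    if (denom <= 0) break  # numerically singular direction
    a <- rs / denom
    x <- x + a * p
    r <- r - a * Ap
    rs_new <- Re(sum(Conj(r) * r))
    p <- r + (rs_new / rs) * p
    rs <- rs_new
    it <- it + 1L
  }
  list(x = x, iterations = it, relres = sqrt(rs) / nb)
}

#' @noRd
rmse <- function(a, b) sqrt(mean(Mod(a - b)^2))

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
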