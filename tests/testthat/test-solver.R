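# The coupled solver: CG-vs-dense oracles, reductions, recovery, parallelism.

# Assemble the dense matrix of a linear complex operator column by column.
dense_matrix <- function(apply_fun, n_in, dim_in) {
  first <- apply_fun(array(c(1 + 0i, rep(0i, n_in - 1)), dim_in))
  A <- matrix(0i, length(first), n_in)
  A[, 1] <- as.vector(first)
  for (j in 2:n_in) {
    e <- array(0i, dim_in); e[j] <- 1 + 0i
    A[, j] <- as.vector(apply_fun(e))
  }
  A
}

test_that("CG reconstruction matches a dense normal-equations solve", {
  ny <- 12
  g <- acq_geometry(c(ny, ny))
  coils <- make_coils(3, g, seed = 11)
  a <- make_alpha(g, "vertical", 2.5, seed = 11)
  sv <- c(-0.4, 0.5)
  ls <- rep(c(0L, 1L), length.out = ny)
  op <- encoding_operator(coils, ls, 0:(ny - 1), sv, a, g)
  m <- array(rand_cplx(3 * ny * ny, 12), c(3, ny, ny))
  lam <- 1 / (ny * ny)
  E <- dense_matrix(function(x) encode_forward(op, x), ny * ny, c(ny, ny))
  dense <- solve(Conj(t(E)) %*% E + lam * diag(ny * ny),
                 Conj(t(E)) %*% as.vector(m))
  cg <- solve_reconstruction(op, m, lambda_recon = 1, maxit = 2000,
                             tol = 1e-8)
  relerr <- sqrt(sum(Mod(as.vector(cg) - dense)^2)) / sqrt(sum(Mod(dense)^2))
  expect_lt(relerr, 1e-3)
  # trivial cases
  expect_equal(as.complex(solve_reconstruction(op, m * 0)),
               rep(0i, ny * ny))
  flat <- make_coils(1, g)
  op_flat <- encoding_operator(flat, rep(0L, ny), 0:(ny - 1), 0,
                               alpha_zero(g), g)
  m1 <- array(rand_cplx(ny * ny, 13), c(1, ny, ny))
  rec <- solve_reconstruction(op_flat, m1, lambda_recon = 1e-10, maxit = 50,
                              tol = 1e-10)
  expect_equal(matrix(as.complex(rec), ny, ny), gricsr:::ifft2u(m1[1, , ]),
               tolerance = 1e-6)
})

test_that("the linearized motion update matches a dense least-squares solve", {
  ny <- 8
  g <- acq_geometry(c(ny, ny))
  coils <- make_coils(2, g, seed = 21)
  a0 <- alpha_zero(g)
  sv <- c(-0.5, 0.5)
  ls <- rep(c(0L, 1L), length.out = ny)
  op <- encoding_operator(coils, ls, 0:(ny - 1), sv, a0, g)
  rho <- slice_matrix(make_phantom(32, seed = 21))[1:ny, 1:ny] + 0i
  m <- array(rand_cplx(2 * ny * ny, 22), c(2, ny, ny)) * 0.05 +
    encode_forward(op, rho)
  mu <- 0.5 * 10 / (ny * ny)
  parts <- gricsr:::motion_linear_parts(op, rho)
  # dense L (real coefficients -> complex data) and dense gradient penalty
  n_a <- 2 * ny * ny
  Lfirst <- gricsr:::motion_forward(op, parts,
                                    array(c(1, rep(0, n_a - 1)), c(2, ny, ny)))
  L <- matrix(0i, length(Lfirst), n_a)
  G <- matrix(0, n_a, n_a)
  for (j in seq_len(n_a)) {
    e <- array(0, c(2, ny, ny)); e[j] <- 1
    L[, j] <- as.vector(gricsr:::motion_forward(op, parts, e))
    G[, j] <- as.vector(gricsr:::grad_penalty(e))
  }
  eps <- m - encode_forward(op, rho)
  A <- Re(Conj(t(L)) %*% L) + mu * G
  b <- Re(Conj(t(L)) %*% as.vector(eps))
  dense <- solve(A, b)
  da <- solve_motion_update(op, m, rho, a0, mu_motion = 0.5, maxit = 2000,
                            tol = 1e-6, nu = 10 / (ny * ny))
  relerr <- sqrt(sum((as.vector(da$coeff) - dense)^2)) / sqrt(sum(dense^2))
  expect_lt(relerr, 1e-2)
  # consistent data gives a zero update
  da0 <- solve_motion_update(op, encode_forward(op, rho), rho, a0)
  expect_equal(max(abs(da0$coeff)), 0)
  expect_error(solve_motion_update(op, m, rho * 0, a0), "empty image")
})

test_that("a global translation proportional to the sensor is recovered", {
  # pure x-translation: alpha_x constant, alpha_y zero, vs a 1-parameter
  # grid-search oracle over constant translations
  ny <- 32
  g <- acq_geometry(c(ny, ny))
  phantom <- make_phantom(ny, seed = 31)
  img <- slice_matrix(phantom) + 0i
  coils <- make_coils(4, g, seed = 31)
  a_true <- alpha_maps(array(c(0, 2), c(2, ny, ny)) * 0 +
                         rep(c(0, 2), ny * ny), g)  # alpha_x = 2 px/unit
  sv <- c(-0.5, 0, 0.5)
  ls <- rep(0:2, length.out = ny)
  op_t <- encoding_operator(coils, ls, 0:(ny - 1), sv, a_true, g)
  m <- encode_forward(op_t, img)
  # grid-search oracle: best constant alpha_x by exhaustive residual scan
  scan <- vapply(seq(0, 4, by = 0.25), function(ax) {
    a <- alpha_maps(array(rep(c(0, ax), ny * ny), c(2, ny, ny)), g)
    opx <- encoding_operator(coils, ls, 0:(ny - 1), sv, a, g)
    sqrt(sum(Mod(encode_forward(opx, img) - m)^2))
  }, 0)
  expect_equal(seq(0, 4, by = 0.25)[which.min(scan)], 2)
  # a few Gauss-Newton updates from alpha = 0 on the true image
  a <- alpha_zero(g)
  sup <- attr(phantom, "support")
  for (it in 1:4) {
    opk <- encoding_operator(coils, ls, 0:(ny - 1), sv, a, g)
    da <- solve_motion_update(opk, m, img, a, maxit = 50)
    a <- alpha_maps(a$coeff + da$coeff, g)
  }
  ax_rec <- mean(a$coeff[2, , ][sup])
  ay_rec <- mean(abs(a$coeff[1, , ][sup]))
  expect_lt(abs(ax_rec - 2) / 2, 0.10)     # constant component within 10%
  expect_lt(ay_rec, 0.10 * abs(ax_rec))    # y component <= 10% of x
})

test_that("constant sensor signal reduces to plain regularized reconstruction", {
  phantom <- make_phantom(64, seed = 41)
  g <- phantom$geometry
  resp_const <- resp_signal(rep(3.7, 8000), 50)
  coils <- make_coils(4, g, seed = 41)
  alpha_any <- make_alpha(g, "vertical", 4, seed = 41)
  ks <- simulate_acquisition(phantom, alpha_any, resp_const, coils, 2, 4.7,
                             snr = Inf, seed = 41)
  res <- run_grics(ks, resp_const, grics_config(n_states = 6))
  expect_equal(res$raw_corrected, res$raw_uncorrected, tolerance = 1e-6)
  expect_lt(max(abs(res$alpha$coeff)), 0.01)  # < 1% of a 1-px reference
})

test_that("the full joint solver halves the error of a moving-phantom recon", {
  rec <- scene_recon()
  sc <- rec$scene; res <- rec$res
  r_corr <- sqrt(mean((Mod(res$raw_corrected) - sc$truth)^2))
  r_unc <- sqrt(mean((Mod(res$raw_uncorrected) - sc$truth)^2))
  expect_lt(r_corr / r_unc, 0.5)
  # data-consistency residuals non-increasing (<=1% jitter) across the
  # fixed-point iterations of the finest level that runs the motion step
  rh <- res$residual_history
  finest <- rh[grep("level_32$", names(rh))]
  for (r in finest) expect_true(all(diff(r) <= 0.01 * r[-length(r)]))
})

test_that("recon-only mode reproduces the full run from its own motion model", {
  rec <- scene_recon()
  sc <- rec$scene; res <- rec$res
  reuse <- run_grics(sc$ks, sc$resp, grics_config(n_states = 6),
                     alpha_init = res$alpha, motion_update = FALSE,
                     coil_maps = sc$coils)
  dev <- sqrt(mean(Mod(reuse$raw_corrected - res$raw_corrected)^2)) /
    sqrt(mean(Mod(res$raw_corrected)^2))
  expect_lt(dev, 0.05)
  expect_error(run_grics(sc$ks, sc$resp, grics_config(n_states = 6),
                         motion_update = FALSE), "alpha_init")
})

test_that("multi-slice reconstruction is identical across worker counts", {
  # two slices with distinct phantoms, stacked into one container
  mk <- function(seed) {
    p <- make_phantom(32, seed = seed)
    r <- make_resp(160, 50, 4, seed = 99)
    c4 <- make_coils(3, p$geometry, seed = 98)
    a <- make_alpha(p$geometry, "vertical", 3, seed = seed)
    simulate_acquisition(p, a, r, c4, 2, 4.7, snr = Inf, binned = TRUE,
                         n_states = 4, seed = seed)
  }
  ks1 <- mk(51); ks2 <- mk(52)
  lm <- rbind(ks1$line_meta,
              transform(ks2$line_meta, slice_index = 1L))
  samp <- array(0i, c(3, 64, 32))
  samp[, 1:32, ] <- ks1$samples
  samp[, 33:64, ] <- ks2$samples
  g3 <- acq_geometry(c(32, 32), c(2, 2), n_slices = 2)
  ks <- kspace_data(samp, lm, g3)
  resp <- make_resp(160, 50, 4, seed = 99)
  cfg <- grics_config(n_states = 4, n_fixed_point = 2L, n_passes = 1L)
  seq1 <- reconstruct_slices_parallel(ks, resp, cfg, n_workers = 1)
  par4 <- reconstruct_slices_parallel(ks, resp, cfg, n_workers = 4)
  expect_equal(length(seq1), 2)
  for (i in 1:2) {
    expect_identical(seq1[[i]]$raw_corrected, par4[[i]]$raw_corrected)
    expect_identical(seq1[[i]]$alpha$coeff, par4[[i]]$alpha$coeff)
  }
  # each slice matches its own single-slice run
  solo <- run_grics(ks1, resp, cfg)
  expect_identical(seq1[[1]]$raw_corrected, solo$raw_corrected)
})
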