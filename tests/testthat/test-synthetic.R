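# Synthetic data generators and the simulator/encoding consistency oracle.

test_that("phantoms are deterministic, normalized and plausibly supported", {
  p1 <- make_phantom(64, seed = 11)
  p2 <- make_phantom(64, seed = 11)
  expect_identical(p1$data, p2$data)
  expect_false(identical(p1$data, make_phantom(64, seed = 12)$data))
  expect_equal(range(p1$data)[2], 1)
  expect_gte(min(p1$data), 0)
  frac <- mean(attr(p1, "support"))
  expect_gt(frac, 0.2); expect_lt(frac, 0.6)
  expect_error(make_phantom(16), ">= 32")
})

test_that("the respiratory generator has the requested period, drift and determinism", {
  r <- make_resp(120, 50, period_s = 4, noise_sd = 0, jitter_sd = 0, seed = 2)
  expect_identical(r$values, make_resp(120, 50, period_s = 4, noise_sd = 0,
                                       jitter_sd = 0, seed = 2)$values)
  # exact periodicity without noise/drift/jitter
  n_per <- 4 * 50
  expect_lt(max(abs(r$values[1:200] - r$values[(n_per + 1):(n_per + 200)])),
            1e-10)
  # periodogram peak at 1/period
  sp <- stats::spec.pgram(r$values, plot = FALSE, taper = 0)
  f_peak <- sp$freq[which.max(sp$spec)] * 50
  expect_equal(f_peak, 0.25, tolerance = 0.02)
  # quadratic drift recovered by the conditioning chain
  rd <- make_resp(120, 50, period_s = 4, drift_coeffs = c(0, 0.01, 5e-4),
                  noise_sd = 0, jitter_sd = 0, seed = 2)
  cleaned <- correct_drift(rd)
  ref <- correct_drift(r)
  rms <- sqrt(mean((cleaned$values - ref$values)^2)) / sd(ref$values)
  expect_lt(rms, 0.02)
})

test_that("motion-model patterns are smooth, scaled and chest-anchored", {
  g <- acq_geometry(c(64, 64))
  expect_equal(make_alpha(g, "vertical", 0)$coeff, array(0, c(2, 64, 64)))
  v <- make_alpha(g, "vertical", 5, seed = 1)
  expect_equal(max(sqrt(v$coeff[1, , ]^2 + v$coeff[2, , ]^2)), 5)
  expect_gt(mean(abs(v$coeff[1, , ])), 3 * mean(abs(v$coeff[2, , ])))
  # C1 smoothness: bounded finite-difference gradient (taper-width bound)
  fd <- max(abs(diff(v$coeff[1, , ])), abs(t(diff(t(v$coeff[1, , ])))))
  expect_lt(fd, 5 * pi / 64 * 2)
  for (p in c("expansion", "shear")) {
    a <- make_alpha(g, p, 4, seed = 2)
    expect_equal(max(sqrt(a$coeff[1, , ]^2 + a$coeff[2, , ]^2)), 4)
  }
  expect_error(make_alpha(g, "vertical", 9), "<= 8")
  expect_error(make_alpha(g, "twist", 3))
})

test_that("synthetic coil profiles are RSS-1 and seed-dependent", {
  g <- acq_geometry(c(32, 32))
  one <- make_coils(1, g)
  expect_true(all(one$maps == 1 + 0i))
  c4 <- make_coils(4, g, seed = 3)
  rss <- sqrt(apply(Mod(c4$maps)^2, c(2, 3), sum))
  expect_lt(max(abs(rss - 1)), 1e-6)
  expect_false(identical(c4$maps, make_coils(4, g, seed = 4)$maps))
})

test_that("a static acquisition reconstructs the phantom exactly", {
  phantom <- make_phantom(32, seed = 6)
  flat <- make_coils(1, phantom$geometry)
  resp <- make_resp(160, 50, 4, seed = 6)
  ks <- simulate_acquisition(phantom, alpha_zero(phantom$geometry), resp,
                             flat, 2, 4.7, snr = Inf, seed = 6)
  grid <- matrix(0i, 32, 32)
  grid[ks$line_meta$phase_encode_index + 1, ] <- ks$samples[1, , ]
  rec <- gricsr:::ifft2u(grid)
  expect_lt(max(Mod(rec - slice_matrix(phantom))), 1e-6)
})

test_that("the simulator and the encoding operator agree in binned mode", {
  sc <- cached("scene", make_scene(seed = 1L))
  cond <- condition_resp(sc$resp, 6)
  ls <- state_for_line(cond, sc$ks$line_meta$timestamp)
  op <- encoding_operator(sc$coils, ls, sc$ks$line_meta$phase_encode_index,
                          cond$state_values, sc$alpha_true, sc$geometry)
  pred <- encode_forward(op, slice_matrix(sc$phantom) + 0i)
  relerr <- sqrt(sum(Mod(pred - sc$ks$samples)^2)) /
    sqrt(sum(Mod(sc$ks$samples)^2))
  expect_lt(relerr, 1e-10)
})

test_that("motion corrupts the zero-motion reconstruction measurably", {
  sc <- cached("scene", make_scene(seed = 1L))
  static <- simulate_acquisition(sc$phantom, alpha_zero(sc$geometry),
                                 sc$resp, sc$coils, 2, 4.7, snr = Inf,
                                 seed = 1)
  recon0 <- function(ks) {
    acc <- matrix(0, 32 * 2, 32 * 2) * 0i
    acc <- matrix(0i, 64, 64)
    for (c in seq_len(ks$n_coils)) {
      grid <- matrix(0i, 64, 64)
      grid[ks$line_meta$phase_encode_index + 1, ] <- ks$samples[c, , ]
      acc <- acc + Conj(sc$coils$maps[c, , ]) * gricsr:::ifft2u(grid)
    }
    Mod(acc)
  }
  si_static <- sharpness_index(recon0(static))
  si_moving <- sharpness_index(recon0(sc$ks))
  expect_lt(si_moving, si_static)
})

test_that("acquisitions and noise are deterministic per seed", {
  sc1 <- make_scene(seed = 2, snr = 20)
  sc2 <- make_scene(seed = 2, snr = 20)
  expect_identical(sc1$ks$samples, sc2$ks$samples)
  expect_identical(sc1$ks$line_meta, sc2$ks$line_meta)
})
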