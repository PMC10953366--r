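# Coil-map estimation, smoothing and SoS normalization.

static_scene <- function() {
  cached("coil_static_scene", {
    phantom <- make_phantom(64, seed = 5)
    resp <- make_resp(160, 50, 4, seed = 6)
    coils <- make_coils(4, phantom$geometry, seed = 7)
    ks <- simulate_acquisition(phantom, alpha_zero(phantom$geometry), resp,
                               coils, 2, 4.7, snr = Inf, seed = 5)
    list(phantom = phantom, coils = coils, ks = ks,
         support = attr(phantom, "support"))
  })
}

test_that("a single flat coil estimates to ~1 inside the object support", {
  phantom <- make_phantom(32, seed = 3)
  resp <- make_resp(160, 50, 4, seed = 3)
  flat <- make_coils(1, phantom$geometry)
  ks <- simulate_acquisition(phantom, alpha_zero(phantom$geometry), resp,
                             flat, 2, 4.7, snr = Inf, seed = 3)
  cm <- estimate_coil_maps(ks, 16)
  sup <- attr(phantom, "support")
  expect_lt(max(abs(Mod(cm$maps[1, , ])[sup] - 1)), 0.05)
})

test_that("Gaussian coil profiles are recovered within 5% inside the support", {
  sc <- static_scene()
  cm <- estimate_coil_maps(sc$ks, 32, 1000)
  # erode the support to stay clear of the object boundary
  sup <- as.matrix(EBImage::erode(EBImage::Image(sc$support * 1),
                                  EBImage::makeBrush(7, "disc"))) > 0.5
  for (c in 1:4) {
    rel <- Mod(cm$maps[c, , ] - sc$coils$maps[c, , ]) /
      max(Mod(sc$coils$maps[c, , ]))
    expect_lt(max(rel[sup]), 0.05)
  }
  expect_equal(cm$n_center_lines_used, 32)
  expect_error(estimate_coil_maps(sc$ks, 128), "wider than")
})

test_that("estimation is equivariant to global complex scaling of the data", {
  sc <- static_scene()
  cm1 <- estimate_coil_maps(sc$ks, 32)
  ks2 <- sc$ks
  ks2$samples <- ks2$samples * (2 * exp(1i * 0.7))
  cm2 <- estimate_coil_maps(ks2, 32)
  # maps are RSS-ratio based: identical up to the global phase
  expect_equal(Mod(cm2$maps), Mod(cm1$maps), tolerance = 1e-8)
})

test_that("spline smoothing shrinks total variation", {
  with_seed(4, {
    rough <- matrix(rnorm(32 * 32), 32, 32)
    sm <- gricsr:::smooth2d(rough, 1000)
    tv <- function(m) sum(abs(diff(m))) + sum(abs(t(diff(t(m)))))
    expect_lt(tv(sm), tv(rough))
    expect_equal(gricsr:::smooth2d(rough, 0), rough)
  })
})

test_that("SoS normalization inverts the coil weighting algebraically", {
  sc <- static_scene()
  img <- matrix(rand_cplx(64 * 64, 9), 64, 64)
  # uniform unit maps: division by the coil count
  unit <- coil_maps(array(1 + 0i, c(4, 64, 64)))
  expect_equal(sos_normalize(img, unit), img / 4)
  # RSS-1 maps: identity
  expect_equal(sos_normalize(img, sc$coils), img, tolerance = 1e-10)
  # algebraic inversion where the RSS is above the floor
  rnd <- coil_maps(array(rand_cplx(4 * 64 * 64, 10), c(4, 64, 64)))
  ss <- apply(Mod(rnd$maps)^2, c(2, 3), sum)
  out <- sos_normalize(img, rnd)
  ok <- ss > 1e-6 * max(ss)
  expect_equal((out * ss)[ok], img[ok], tolerance = 1e-12)
})

test_that("motion-consistent refinement explains the data where plain calibration cannot", {
  sc <- cached("scene", make_scene(seed = 1L))
  cond <- condition_resp(sc$resp, 6)
  lsn <- state_for_line(cond, sc$ks$line_meta$timestamp)
  truth_img <- slice_matrix(sc$phantom) + 0i
  pred_err <- function(cm) {
    o <- encoding_operator(cm, lsn, sc$ks$line_meta$phase_encode_index,
                           cond$state_values, sc$alpha_true, sc$geometry)
    sqrt(sum(Mod(encode_forward(o, truth_img) - sc$ks$samples)^2)) /
      sqrt(sum(Mod(sc$ks$samples)^2))
  }
  # at a mild smoothing weight the per-coil solve is nearly exact on
  # model-consistent data, unlike the motion-ghosted central-band estimate
  cm_plain <- estimate_coil_maps(sc$ks, 32, 10)
  cm_ref <- refine_coil_maps(sc$ks, sc$alpha_true, truth_img, lsn,
                             cond$state_values, 10)
  expect_lt(pred_err(cm_ref), 0.75 * pred_err(cm_plain))
  # end-to-end: the self-calibrated joint solver still corrects motion
  res <- suppressMessages(run_grics(sc$ks, sc$resp, grics_config(n_states = 6)))
  r1 <- sqrt(mean((Mod(res$raw_corrected) - sc$truth)^2))
  r0 <- sqrt(mean((Mod(res$raw_uncorrected) - sc$truth)^2))
  expect_lt(r1 / r0, 0.9)
  sup <- sc$support
  expect_gt(cor(c(res$alpha$coeff[1, , ][sup], res$alpha$coeff[2, , ][sup]),
                c(sc$alpha_true$coeff[1, , ][sup],
                  sc$alpha_true$coeff[2, , ][sup])), 0.9)
})
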