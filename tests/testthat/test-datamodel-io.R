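# Containers and on-disk round-trips.

test_that("k-space container validates its metadata contracts", {
  g <- acq_geometry(c(16, 16))
  samp <- array(rand_cplx(4 * 16 * 16, 1), c(4, 16, 16))
  lm <- data.frame(phase_encode_index = 0:15, slice_index = 0L,
                   timestamp = seq(0, 15))
  ks <- kspace_data(samp, lm, g)
  expect_s3_class(ks, "kspace_data")
  expect_equal(ks$n_coils, 4)
  # one meta record per line
  expect_error(kspace_data(samp, lm[1:10, ], g), "exactly one")
  # phase-encode range
  lm_bad <- lm; lm_bad$phase_encode_index[1] <- 16L
  expect_error(kspace_data(samp, lm_bad, g), "phase_encode_index")
  # timestamps non-decreasing within a slice
  lm_bad <- lm; lm_bad$timestamp <- rev(lm$timestamp)
  expect_error(kspace_data(samp, lm_bad, g), "non-decreasing")
})

test_that("undersampled acquisitions have stride = acceleration outside the calibration band", {
  sc <- cached("accel_scene", {
    phantom <- make_phantom(64, seed = 4)
    resp <- make_resp(160, 50, 4, seed = 5)
    coils <- make_coils(4, phantom$geometry, seed = 6)
    simulate_acquisition(phantom, alpha_zero(phantom$geometry), resp, coils,
                         lines_per_shot = 2, shot_interval_s = 4.7,
                         acceleration = 2, n_center_lines = 24, seed = 4)
  })
  pe <- sort(unique(sc$line_meta$phase_encode_index))
  band <- 32 + seq(-12, 11)
  outside <- pe[!(pe %in% band)]
  # one stride-2 progression on each side of the calibration band
  lo <- outside[outside < min(band)]; hi <- outside[outside > max(band)]
  expect_true(all(diff(lo) == 2) && all(diff(hi) == 2))
  expect_true(all(diff(outside) %% 2 == 0))
  # 64/2 + extra central lines in total
  expect_equal(length(pe), 32 + sum(band %% 2 == 1))
  expect_error(check <- kspace_data(sc$samples, sc$line_meta, sc$geometry,
                                    acceleration = 3,
                                    n_center_calibration_lines = 24),
               "stride")
})

test_that("HDF5 k-space round-trip is bit-exact and errors name missing keys", {
  g <- acq_geometry(c(16, 16), c(2, 2), 3)
  samp <- array(rand_cplx(4 * 16 * 16, 2), c(4, 16, 16))
  lm <- data.frame(phase_encode_index = 0:15, slice_index = 0L,
                   timestamp = as.numeric(0:15))
  ks <- kspace_data(samp, lm, g)
  resp <- resp_signal(sin(1:100), 50)
  path <- tempfile(fileext = ".h5")
  write_kspace(ks, path, resp = resp)
  back <- read_kspace(path)
  expect_identical(Re(back$samples), Re(ks$samples))
  expect_identical(Im(back$samples), Im(ks$samples))
  expect_identical(back$line_meta, ks$line_meta)
  expect_equal(back$geometry$pixel_spacing, c(2, 2))
  r2 <- attr(back, "resp")
  expect_identical(r2$values, resp$values)
  expect_equal(r2$sample_rate, 50)
  # a file missing a required dataset reports the absent key by name
  rhdf5::h5delete(path, "kspace/line_meta/timestamp")
  expect_error(read_kspace(path), "kspace/line_meta/timestamp")
  unlink(path)
})

test_that("respiratory CSV and alpha HDF5 round-trips are lossless", {
  sig <- resp_signal(c(0.1, 0.25, -0.3, 1.7, 0.9, 0.33, 0.1, 0, 2, 1), 100)
  path <- tempfile(fileext = ".csv")
  write_resp_csv(sig, path)
  back <- read_resp_csv(path)
  expect_equal(back$values, sig$values, tolerance = 1e-15)
  expect_equal(back$sample_rate, 100)
  expect_equal(length(back$values), 10)
  # empty CSV errors
  empty <- tempfile(fileext = ".csv")
  writeLines("time_s,value", empty)
  expect_error(read_resp_csv(empty), "no samples")

  a <- make_alpha(acq_geometry(c(32, 32), c(2, 2)), "expansion", 3)
  ap <- tempfile(fileext = ".h5")
  write_alpha(a, ap)
  a2 <- read_alpha(ap)
  expect_identical(a2$coeff, a$coeff)
  expect_equal(a2$geometry$pixel_spacing, c(2, 2))
  unlink(c(path, empty, ap))
})

test_that("NIfTI output preserves geometry and is readable", {
  img <- image_volume(array(runif(16 * 16 * 3), c(16, 16, 3)),
                      acq_geometry(c(16, 16), c(0.72, 0.72),
                                   slice_thickness = 3, n_slices = 3))
  path <- tempfile(fileext = ".nii")
  write_image_nifti(img, path)
  nif <- RNifti::readNifti(path)
  expect_equal(RNifti::pixdim(nif), c(0.72, 0.72, 3), tolerance = 1e-6)
  back <- read_image_nifti(path)
  expect_equal(back$data, img$data, tolerance = 1e-6)
  expect_error(write_image_nifti(
    image_volume(matrix(c(NaN, runif(255)), 16, 16)), path), "non-finite")
  unlink(path)
})
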