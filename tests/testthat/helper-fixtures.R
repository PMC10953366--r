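# Shared fixtures: a small deterministic motion-correction scene and a cache
# so expensive reconstructions are computed once per session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# The reference motion-correction scene: 64x64 phantom, 4 coils, vertical
# motion pattern scaled to a 5 px peak displacement over the acquisition,
# 2-line shots every 4.7 s (a 2.5-minute acquisition), Ns = 6.
make_scene <- function(seed = 1L, size = 64L, binned = TRUE, snr = Inf,
                       n_states = 6L) {
  phantom <- make_phantom(size, seed = seed)
  g <- phantom$geometry
  resp <- make_resp(160, 50, 4, seed = seed + 100L)
  coils <- make_coils(4, g, seed = seed + 200L)
  probe <- make_alpha(g, "vertical", amplitude_px = 1, seed = seed)
  ks0 <- simulate_acquisition(phantom, probe, resp, coils,
                              lines_per_shot = 2, shot_interval_s = 4.7,
                              snr = Inf, seed = seed)
  smax <- max(abs(attr(ks0, "s_shot")))
  alpha_true <- make_alpha(g, "vertical", amplitude_px = min(8, 5 / smax),
                           seed = seed)
  ks <- simulate_acquisition(phantom, alpha_true, resp, coils,
                             lines_per_shot = 2, shot_interval_s = 4.7,
                             snr = snr, binned = binned, n_states = n_states,
                             seed = seed)
  list(phantom = phantom, geometry = g, resp = resp, coils = coils,
       alpha_true = alpha_true, ks = ks,
       truth = Mod(slice_matrix(phantom)),
       support = attr(phantom, "support"))
}

# Full joint reconstruction of the reference scene at the convergent
# operating point, with the simulator's coil profiles (isolates the motion
# solver; coil estimation has its own tests).
scene_recon <- function() {
  cached("scene_recon", {
    sc <- cached("scene", make_scene(seed = 1L))
    res <- suppressMessages(run_grics(sc$ks, sc$resp,
                                      grics_config(n_states = 6L,
                                                   n_fixed_point = 6L),
                                      coil_maps = sc$coils))
    list(scene = sc, res = res)
  })
}

# Small random smooth displacement field (<= max_px peak), deterministic.
# Smoothing by dense Gaussian kernel matrices, size-safe for tiny grids.
random_smooth_u <- function(ny, nx, max_px, seed) {
  with_seed(seed, {
    u <- array(stats::rnorm(2 * ny * nx), c(2, ny, nx))
    kmat <- function(n) {
      K <- exp(-outer(seq_len(n), seq_len(n), "-")^2 / (2 * 2.5^2))
      K / rowSums(K)
    }
    Ky <- kmat(ny); Kx <- kmat(nx)
    u[1, , ] <- Ky %*% u[1, , ] %*% t(Kx)
    u[2, , ] <- Ky %*% u[2, , ] %*% t(Kx)
    u * max_px / max(abs(u))
  })
}

rand_cplx <- function(n, seed) {
  with_seed(seed, complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)))
}

with_seed <- gricsr:::with_seed
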