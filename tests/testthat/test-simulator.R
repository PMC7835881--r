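test_that("projection at zero tilt equals the beam-axis sum exactly", {
  vol <- array(rnorm(16 * 12 * 10)^2, c(16, 12, 10))
  ts <- project_tilt_series(vol, 0)
  expect_equal(ts$images[, , 1], apply(vol, c(1, 2), sum), tolerance = 1e-12)
})

test_that("ball projection matches the analytic chord-length profile", {
  # uniform unit ball: line integral at offset d is the chord 2*sqrt(r^2-d^2)
  r <- 10; g <- 48
  m <- make_phantom(list(type = "sphere", radius = r), g)
  for (ang in c(-37, 0, 52)) {
    ts <- project_tilt_series(m$grid, ang)
    c0 <- floor((g - 1) / 2)
    profile <- ts$images[, c0 + 1, 1]   # central row through the ball
    d <- abs(seq_len(g) - 1 - c0)
    chord <- 2 * sqrt(pmax(r^2 - d^2, 0))
    # voxelization error peaks at the rim where the chord slope diverges,
    # so bound the interior pointwise and the rim through the mean
    expect_lt(max(abs(profile - chord)[d <= r - 3]), 0.12 * 2 * r)
    expect_lt(mean(abs(profile - chord)), 0.05 * 2 * r)
    # and mass conservation within 1%
    expect_lt(abs(sum(ts$images) - sum(m$grid)) / sum(m$grid), 0.01)
  }
})

test_that("tilt series invariants are enforced", {
  vol <- array(1, c(8, 8, 8))
  expect_error(project_tilt_series(vol, c(0, 95)), "inside")
  expect_error(project_tilt_series(vol, c(10, 10)), "increasing")
})

test_that("optical factors: disabled pass-through, convolution oracle, low-pass", {
  img <- matrix(rnorm(256), 16, 16)
  ts <- tomoshot:::tilt_series(array(img, c(16, 16, 1)), 0)
  off <- apply_ctf_mtf(ts, optics_params(enabled = FALSE))
  expect_identical(off$images, ts$images)
  # frequency multiplication equals direct circular spatial convolution
  op <- optics_params(pixel_size = 10)
  filt <- tomoshot:::ctf_mtf_filter(16, 16, op)
  ker <- Re(stats::fft(filt, inverse = TRUE)) / 256
  direct <- matrix(0, 16, 16)
  for (i in 0:15) for (j in 0:15) {
    acc <- 0
    for (a in 0:15) for (b in 0:15)
      acc <- acc + img[a + 1, b + 1] * ker[(i - a) %% 16 + 1, (j - b) %% 16 + 1]
    direct[i + 1, j + 1] <- acc
  }
  out <- apply_ctf_mtf(ts, op)$images[, , 1]
  expect_lt(max(abs(out - direct)), 1e-6)
  # power above 0.8 Nyquist strictly decreases under the MTF envelope
  fr <- sqrt(outer(fft_freqs(16)^2, fft_freqs(16)^2, "+"))
  hi <- fr > 0.8 * 0.5
  expect_lt(sum(Mod(stats::fft(out))[hi]^2),
            sum(Mod(stats::fft(img))[hi]^2))
})

test_that("noise injection hits the target SNR and is seeded", {
  img <- array(rnorm(600 * 600), c(600, 600, 1))
  ts <- tomoshot:::tilt_series(img, 0)
  expect_identical(add_noise_to_snr(ts, Inf)$images, img)
  no <- add_noise_to_snr(ts, 0.5, seed = 4)
  achieved <- var(as.vector(img)) / var(as.vector(no$images - img))
  expect_lt(abs(achieved - 0.5) / 0.5, 0.05)
  no2 <- add_noise_to_snr(ts, 0.5, seed = 4)
  expect_identical(no$images, no2$images)
  expect_error(add_noise_to_snr(ts, -1), "positive")
})

test_that("weighted back-projection reconstructs and shows the missing wedge", {
  expect_true(all(reconstruct_wbp(
    tomoshot:::tilt_series(array(0, c(16, 16, 5)), seq(-20, 20, 10)),
    c(16, 16, 16)) == 0))
  sph <- make_phantom(list(type = "sphere", radius = 8), 48)$grid
  # near-full angular coverage: faithful reconstruction
  rec <- reconstruct_wbp(project_tilt_series(sph, seq(-89, 89, 1)),
                         c(48, 48, 48))
  expect_gt(cor(as.vector(rec), as.vector(sph)), 0.9)
  # +/-60 degrees: Fourier amplitudes inside the wedge are suppressed
  rec60 <- reconstruct_wbp(project_tilt_series(sph, seq(-60, 60, 2)),
                           c(48, 48, 48))
  F <- Mod(stats::fft(rec60))
  fx <- fft_freqs(48)
  ang <- array(0, c(48, 48, 48))
  for (i in 1:48) for (k in 1:48)
    ang[i, , k] <- atan2(abs(fx[i]), abs(fx[k])) * 180 / pi
  mag <- sqrt(outer(outer(fx^2, fx^2, "+"), fx^2, "+"))
  shell <- mag > 0.05 & mag < 0.45
  wedge_amp <- mean(F[ang < 25 & shell])     # around the beam axis
  sampled_amp <- mean(F[ang > 35 & shell])
  expect_lt(wedge_amp, 0.2 * sampled_amp)
})

test_that("single-projection reconstruction warns but works", {
  ts <- tomoshot:::tilt_series(array(1, c(8, 8, 1)), 0)
  expect_warning(v <- reconstruct_wbp(ts, c(8, 8, 8)), "ill-posed")
  expect_equal(dim(v), c(8, 8, 8))
})

test_that("projection and unfiltered back-projection are exact adjoints", {
  angs <- seq(-60, 60, 15)
  v <- array(rnorm(20 * 18 * 16), c(20, 18, 16))
  P <- project_tilt_series(v, angs)
  g <- array(rnorm(length(P$images)), dim(P$images))
  bt <- reconstruct_wbp(tomoshot:::tilt_series(g, angs), c(20, 18, 16),
                        filter = "none")
  # reconstruct_wbp scales by pi/(2 nA); undo for the raw adjoint
  bt <- bt / (pi / (2 * length(angs)))
  lhs <- sum(P$images * g)
  rhs <- sum(v * bt)
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-4)
})

test_that("packing places non-overlapping particles inside bounds", {
  expect_equal(length(pack_volume(phantom_library()[1], 0,
                                  c(64, 64, 64))$placements), 0)
  m <- make_phantom(list(type = "sphere", radius = 4), 16)
  one <- pack_volume(list(m), 1, c(64, 64, 64), seed = 3)
  expect_lt(abs(sum(one$volume) - sum(m$grid)) / sum(m$grid), 0.05)
  many <- pack_volume(list(m), 50, c(100, 100, 100), seed = 5)
  centers <- t(vapply(many$placements, function(p) p$center, numeric(3)))
  dd <- as.matrix(dist(centers))
  diag(dd) <- Inf
  expect_gt(min(dd), 8)
})

test_that("packing warns when the volume cannot hold all particles", {
  m <- make_phantom(list(type = "sphere", radius = 4), 16)
  expect_warning(res <- pack_volume(list(m), 100, c(24, 24, 24), seed = 1),
                 "placed only")
  expect_lt(length(res$placements), 100)
})

test_that("subtomogram extraction crops, skips out-of-bounds, and counts", {
  m <- make_phantom(list(type = "sphere", radius = 5), 32)
  tomo <- array(0, c(64, 64, 64))
  placements <- list(
    list(class = "sphere", map_index = 1, center = c(32, 32, 32),
         pose = pose(diag(3))),
    list(class = "sphere", map_index = 1, center = c(3, 32, 32),
         pose = pose(diag(3))))
  tomo[17:48, 17:48, 17:48] <- m$grid
  recs <- extract_subtomograms(tomo, placements, 32, list(m))
  expect_length(recs, 1)
  expect_equal(attr(recs, "n_skipped"), 1L)
  expect_equal(recs[[1]]$volume, m$grid)
  expect_equal(recs[[1]]$gt_mask, m$grid > 0)
})

test_that("dataset building splits classes disjointly and is deterministic", {
  maps <- phantom_library()[1:4]
  cfg <- sim_config(tomogram_shape = c(96, 96, 64), n_particles = 12,
                    tilt_step = 10, seed = 21)
  ds <- build_dataset(cfg, maps, n_train_classes = 2)
  expect_setequal(unique(ds$manifest$split), c("train", "test"))
  train_cls <- unique(ds$manifest$class[ds$manifest$split == "train"])
  test_cls <- unique(ds$manifest$class[ds$manifest$split == "test"])
  expect_length(intersect(train_cls, test_cls), 0)
  ds2 <- build_dataset(cfg, maps, n_train_classes = 2)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(ds$records[[1]]$volume, ds2$records[[1]]$volume)
  expect_error(build_dataset(cfg, maps, 4), "split")
})

test_that("simulation is linear in the input volume (noiseless, fixed optics)", {
  angs <- seq(-60, 60, 20)
  v1 <- array(rnorm(16^3)^2, c(16, 16, 16))
  v2 <- array(rnorm(16^3)^2, c(16, 16, 16))
  sim <- function(v) {
    ts <- apply_ctf_mtf(project_tilt_series(v, angs),
                        optics_params(pixel_size = 10))
    reconstruct_wbp(ts, c(16, 16, 16))
  }
  lhs <- sim(v1 + v2)
  rhs <- sim(v1) + sim(v2)
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-5)
})

test_that("reconstruction error grows as SNR decreases", {
  sph <- make_phantom(list(type = "sphere", radius = 6), 32)$grid
  angs <- seq(-60, 60, 5)
  ts <- project_tilt_series(sph, angs)
  clean <- reconstruct_wbp(ts, c(32, 32, 32))
  mse <- vapply(c(Inf, 1000, 0.5), function(snr) {
    noisy <- add_noise_to_snr(ts, snr, seed = 9)
    mean((reconstruct_wbp(noisy, c(32, 32, 32)) - clean)^2)
  }, numeric(1))
  expect_true(all(diff(mse) > 0))
})
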