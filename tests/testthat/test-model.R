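tiny_cfg <- model_config(channels = c(2, 4, 8), input_size = 8,
                         embedding_dim = 16, duse_reduction = 2, seed = 9)

test_that("both Siamese streams share one parameter set", {
  model <- init_model(tiny_cfg)
  x <- array(rnorm(512), c(8, 8, 8))
  lat_support <- volume_encode(model, x)
  lat_target <- volume_encode(model, x)
  expect_identical(lat_support, lat_target)
  expect_identical(volume_decode(model, lat_support),
                   volume_decode(model, lat_target))
  expect_identical(feature_encode(model, lat_support),
                   feature_encode(model, lat_target))
})

test_that("encoding a batch preserves order and rejects wrong sizes", {
  model <- init_model(tiny_cfg)
  vols <- lapply(1:3, function(i) array(rnorm(512, mean = i), c(8, 8, 8)))
  lats <- volume_encode(model, vols)
  expect_length(lats, 3)
  expect_identical(lats[[2]], volume_encode(model, vols[[2]]))
  expect_error(volume_encode(model, array(0, c(16, 16, 16))),
               "does not match")
})

test_that("model construction is deterministic under a fixed seed", {
  m1 <- init_model(tiny_cfg)
  m2 <- init_model(tiny_cfg)
  expect_identical(m1$par, m2$par)
  x <- array(rnorm(512), c(8, 8, 8))
  s1 <- match_scores(m1, list(pairwise_distance(
    feature_encode(m1, volume_encode(m1, x)),
    feature_encode(m1, volume_encode(m1, x * 2)))))
  s2 <- match_scores(m2, list(pairwise_distance(
    feature_encode(m2, volume_encode(m2, x)),
    feature_encode(m2, volume_encode(m2, x * 2)))))
  expect_identical(s1, s2)
})

test_that("channel squeeze-excitation follows its defining equations", {
  C <- 4
  F <- array(rnorm(2 * 3 * 4 * C), c(2, 3, 4, C))
  # constant channel pools to exactly that constant
  Fc <- F
  Fc[, , , 2] <- 0.7
  N <- prod(dim(F)[1:3])
  xm <- Fc; dim(xm) <- c(N, C)
  expect_equal(colMeans(xm)[2], 0.7)
  # zero weights: sigmoid(0) = 0.5 scaling
  z1 <- matrix(0, 2, C); z2 <- matrix(0, C, 2)
  expect_equal(channel_squeeze_excite(F, z1, z2), 0.5 * F)
})

test_that("spatial squeeze-excitation follows its defining equations", {
  C <- 3
  F <- array(rnorm(4^3 * C), c(4, 4, 4, C))
  expect_equal(spatial_squeeze_excite(F, numeric(C)), 0.5 * F)
  # large positive single-channel weight saturates to the identity
  Fp <- array(abs(rnorm(4^3)) + 1, c(4, 4, 4, 1))
  expect_equal(spatial_squeeze_excite(Fp, 50), Fp, tolerance = 1e-6)
  # per-voxel dot-product oracle
  w3 <- rnorm(C)
  out <- spatial_squeeze_excite(F, w3)
  for (i in c(1, 3)) for (j in c(2, 4)) for (k in c(1, 4)) {
    m <- sum(F[i, j, k, ] * w3)
    expect_equal(out[i, j, k, ], F[i, j, k, ] / (1 + exp(-m)),
                 tolerance = 1e-12)
  }
})

test_that("DuSE equals the brute-force scalar oracle on random maps", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      C <- sample(c(2, 4, 6), 1)
      H <- sample(2:6, 1); W <- sample(2:6, 1); D <- sample(2:6, 1)
      F <- array(rnorm(H * W * D * C), c(H, W, D, C))
      w1 <- matrix(rnorm(C / 2 * C), C / 2, C)
      w2 <- matrix(rnorm(C * C / 2), C, C / 2)
      w3 <- rnorm(C)
      got <- duse_block(F, list(w1 = w1, w2 = w2, w3 = w3))
      expect_lt(max(abs(got - duse_oracle(F, w1, w2, w3))), 1e-5)
    }
  })
  # all-zero SE weights: both branches halve the input, so DuSE = F
  F <- array(rnorm(3^3 * 2), c(3, 3, 3, 2))
  expect_equal(duse_block(F, list(w1 = matrix(0, 1, 2),
                                  w2 = matrix(0, 2, 1), w3 = c(0, 0))), F)
  # definitional decomposition
  w <- list(w1 = matrix(rnorm(2), 1, 2), w2 = matrix(rnorm(2), 2, 1),
            w3 = rnorm(2))
  expect_equal(duse_block(F, w),
               channel_squeeze_excite(F, w$w1, w$w2) +
                 spatial_squeeze_excite(F, w$w3))
})

test_that("decoder output is a probability map of the input shape", {
  model <- init_model(tiny_cfg)
  for (i in 1:3) {
    p <- volume_decode(model, volume_encode(model,
                                            array(rnorm(512) * i, c(8, 8, 8))))
    expect_equal(dim(p), c(8, 8, 8))
    expect_gte(min(p), 0)
    expect_lte(max(p), 1)
  }
})

test_that("feature encoder emits embeddings of the configured length", {
  model <- init_model(tiny_cfg)
  lat <- volume_encode(model, array(rnorm(512), c(8, 8, 8)))
  expect_length(feature_encode(model, lat), 16)
  m512 <- init_model(model_config(channels = c(2, 2, 2), input_size = 8,
                                  duse_reduction = 2, seed = 1))
  lat2 <- volume_encode(m512, array(rnorm(512), c(8, 8, 8)))
  expect_length(feature_encode(m512, lat2), 512)
})

test_that("pairwise distance is the elementwise absolute difference", {
  a <- c(1, 3, -2); b <- c(2, 1, -2)
  expect_equal(pairwise_distance(a, b), c(1, 2, 0))
  expect_equal(pairwise_distance(a, b), pairwise_distance(b, a))
  expect_equal(pairwise_distance(a, a), c(0, 0, 0))
  expect_error(pairwise_distance(a, c(1, 2)), "lengths differ")
})

test_that("match scores normalize over the support set", {
  model <- init_model(tiny_cfg)
  d <- rep(list(rep(0.3, 16)), 4)   # identical distances, n = 4
  s <- match_scores(model, d)
  expect_equal(s, rep(0.25, 4))
  withr::with_seed(2, {
    dr <- lapply(1:5, function(i) abs(rnorm(16)))
    expect_equal(sum(match_scores(model, dr)), 1, tolerance = 1e-6)
  })
  # zero distance with a zero-bias head scores sigmoid(0) = 0.5
  expect_equal(match_scores(model, list(numeric(16)),
                            mode = "pairwise-sigmoid"), 0.5)
  expect_error(match_scores(model, list()), "at least one")
})

test_that("analytic gradients match central finite differences", {
  cfg <- model_config(channels = c(2, 3, 4), input_size = 8,
                      embedding_dim = 6, duse_reduction = 1, seed = 5)
  model <- init_model(cfg)
  par <- model$par
  ep <- fake_episode()
  st <- tomoshot:::episode_step(par, cfg, ep)
  lossf <- function(p)
    tomoshot:::episode_step(p, cfg, ep, compute_grads = FALSE)$loss
  withr::with_seed(13, {
    for (nm in names(par)) {
      i <- sample(length(par[[nm]]), 1)
      h <- 1e-6
      p2 <- par; p2[[nm]][i] <- p2[[nm]][i] + h
      p3 <- par; p3[[nm]][i] <- p3[[nm]][i] - h
      nd <- (lossf(p2) - lossf(p3)) / (2 * h)
      # finite differences cross rectifier kinks occasionally (a bias
      # perturbs every voxel of a level), so allow a small absolute
      # floor on top of the relative tolerance
      expect_lt(abs(st$grads[[nm]][i] - nd), 5e-4 + 5e-3 * abs(nd),
                label = sprintf("gradient error of %s[%d]", nm, i))
    }
  })
})

test_that("checkpoints round-trip the model", {
  model <- init_model(tiny_cfg)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_identical(back$par, model$par)
  x <- array(rnorm(512), c(8, 8, 8))
  expect_identical(volume_encode(back, x), volume_encode(model, x))
  saveRDS(list(format = "other"), path)
  expect_error(load_checkpoint(path), "not a tomoshot checkpoint")
})
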