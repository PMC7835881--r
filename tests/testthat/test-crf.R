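test_that("the CRF energy matches a hand evaluation on a two-voxel instance", {
  # voxels at p = (0,0,0) and (1,0,0), labels (0,1), equal intensities,
  # w1 = w2 = 1, all sigma = 1: each ordered pair contributes
  # exp(-1/2) (appearance) + exp(-1/2) (smoothness), both pairs -> 4 e^-1/2
  lab <- array(c(0, 1), c(2, 1, 1))
  probs <- array(c(0.3, 0.8), c(2, 1, 1))
  inten <- array(c(0, 0), c(2, 1, 1))
  pp <- crf_params(w1 = 1, w2 = 1, sigma_alpha = 1, sigma_beta = 1,
                   sigma_gamma = 1)
  unary <- -log(1 - 0.3) - log(0.8)
  expect_equal(crf_energy(lab, probs, inten, pp),
               unary + 4 * exp(-0.5), tolerance = 1e-9)
})

test_that("the pairwise energy term is label-symmetric and monotone in w1", {
  withr::with_seed(4, {
    lab <- array(rbinom(27, 1, 0.5), c(3, 3, 3))
    probs <- array(runif(27, 0.1, 0.9), c(3, 3, 3))
    inten <- array(rnorm(27), c(3, 3, 3))
    pp <- crf_params()
    e <- crf_energy(lab, probs, inten, pp)
    # flipping all labels leaves the pairwise term unchanged: subtract the
    # unaries to isolate it
    unary <- function(l) sum(ifelse(l == 1, -log(pmax(probs, 1e-8)),
                                    -log(pmax(1 - probs, 1e-8))))
    e_flip <- crf_energy(1 - lab, probs, inten, pp)
    expect_equal(e - unary(lab), e_flip - unary(1 - lab), tolerance = 1e-9)
    # increasing w1 with differing-label pairs strictly increases energy
    pp2 <- crf_params(w1 = 5)
    expect_gt(crf_energy(lab, probs, inten, pp2), e)
  })
})

test_that("without pairwise coupling mean field reduces to thresholding", {
  probs <- array(0, c(4, 4, 4))
  probs[2:3, 2:3, 2:3] <- 1
  inten <- array(rnorm(64), c(4, 4, 4))
  # zero-weight kernels are disallowed negative; use tiny sigmas + w = 0
  pp <- crf_params(w1 = 0, w2 = 0)
  out <- mean_field_refine(probs, inten, pp)
  expect_identical(out, probs > 0.5)
})

test_that("mean-field marginals stay normalized across iterations", {
  # binary marginals are stored as the foreground probability; the dense
  # reference keeps them in [0, 1] at every step by construction of the
  # softmax update -- verify the outputs are valid probabilities
  withr::with_seed(5, {
    probs <- array(runif(27), c(3, 3, 3))
    inten <- array(rnorm(27), c(3, 3, 3))
    q <- tomoshot:::mean_field_dense(probs, inten, crf_params())
    expect_true(all(q >= 0 & q <= 1))
  })
})

test_that("truncated pairwise messages agree with the dense all-pairs reference", {
  # the net pairwise message of one synchronous update is recovered from
  # the updated marginal: M = Ksum - 2 S = logit(1 - Q') - (u1 - u0)
  net_message <- function(q, probs) {
    p <- pmin(pmax(as.vector(probs), 1e-8), 1 - 1e-8)
    du <- -log(p) + log(1 - p)
    log((1 - q) / q) - du
  }
  withr::with_seed(6, {
    for (rep in 1:3) {
      probs <- array(runif(1000, 0.05, 0.95), c(10, 10, 10))
      inten <- array(rnorm(1000), c(10, 10, 10))
      pp <- crf_params(w1 = 1, w2 = 1, sigma_alpha = 1.5, sigma_beta = 0.5,
                       sigma_gamma = 1, n_iterations = 1)
      ii <- standardize_volume(inten)
      q_fast <- tomoshot:::crf_meanfield_cpp(probs, ii, dim(probs),
                                             1, 1, 1.5, 0.5, 1, 1L)
      q_dense <- tomoshot:::mean_field_dense(probs, ii, pp)
      m_fast <- net_message(as.vector(q_fast), probs)
      m_dense <- net_message(as.vector(q_dense), probs)
      expect_lt(max(abs(m_fast - m_dense)) / max(abs(m_dense)), 0.05)
      # and the refined masks coincide almost everywhere after full
      # inference
      pp5 <- crf_params(w1 = 1, w2 = 1, sigma_alpha = 1.5, sigma_beta = 0.5,
                        sigma_gamma = 1, n_iterations = 5)
      mask_fast <- mean_field_refine(probs, inten, pp5)
      mask_dense <- tomoshot:::mean_field_dense(probs, ii, pp5) > 0.5
      expect_gt(mean(mask_fast == mask_dense), 0.98)
    }
  })
})

test_that("refinement does not increase the CRF energy over the unary argmax", {
  withr::with_seed(7, {
    wins <- 0
    for (rep in 1:50) {
      base <- array(runif(512, 0.05, 0.45), c(8, 8, 8))
      blob <- sample(512, 40)
      base[blob] <- runif(40, 0.55, 0.95)
      inten <- array(rnorm(512, sd = 0.3), c(8, 8, 8)) + (base > 0.5)
      pp <- crf_params(w1 = 1, w2 = 1, sigma_alpha = 1.5, sigma_beta = 0.5,
                       sigma_gamma = 1, n_iterations = 5)
      ii <- standardize_volume(inten)
      refined <- mean_field_refine(base, inten, pp)
      e_ref <- crf_energy(refined * 1, base, ii, pp)
      e_un <- crf_energy((base > 0.5) * 1, base, ii, pp)
      if (e_ref <= e_un + 1e-9) wins <- wins + 1
    }
    expect_gte(wins, 45)
  })
})

test_that("the CRF removes salt-and-pepper noise while keeping the sphere", {
  g <- 16; c0 <- (g - 1) / 2
  ax <- seq_len(g) - 1 - c0
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  clean <- r2 <= 4.5^2
  probs <- ifelse(clean, 0.9, 0.1)
  withr::with_seed(8, {
    flips <- sample(g^3, round(0.02 * g^3))
    probs[flips] <- 1 - probs[flips]
    inten <- clean + array(rnorm(g^3, sd = 0.1), c(g, g, g))
  })
  refined <- mean_field_refine(array(probs, c(g, g, g)), inten,
                               crf_params(w1 = 3, w2 = 1, sigma_alpha = 2,
                                          sigma_beta = 0.5, sigma_gamma = 1))
  dsc_unary <- dsc_metric(probs > 0.5, clean)
  dsc_ref <- dsc_metric(refined, clean)
  expect_gt(dsc_ref, dsc_unary)
  # at least 80% of the flipped voxels are restored
  flipped_mask <- array(FALSE, c(g, g, g)); flipped_mask[flips] <- TRUE
  wrong_before <- sum((probs > 0.5) != clean & flipped_mask)
  wrong_after <- sum((refined != clean) & flipped_mask)
  expect_lte(wrong_after, 0.2 * wrong_before)
})

test_that("DSC matches its closed forms and symmetry", {
  a <- array(FALSE, c(4, 4, 4)); a[1:3, 1, 1] <- TRUE
  expect_equal(dsc_metric(a, a), 1)
  b <- array(FALSE, c(4, 4, 4)); b[1, 2, 1] <- TRUE
  expect_equal(dsc_metric(a, b), 0)
  # |I| = 2, |pred| = 3, |gt| = 4 -> 4/7
  gt <- array(FALSE, c(4, 4, 4)); gt[2:3, 1, 1] <- TRUE; gt[1:2, 2, 2] <- TRUE
  expect_equal(dsc_metric(a, gt), 4 / 7)
  expect_equal(dsc_metric(a, gt), dsc_metric(gt, a))
  expect_equal(dsc_metric(array(FALSE, c(2, 2, 2)),
                          array(FALSE, c(2, 2, 2))), 1)
  expect_error(dsc_metric(a, array(FALSE, c(2, 2, 2))), "shapes differ")
})

test_that("segment_target yields deterministic masks and a bounded DSC", {
  model <- init_model(model_config(channels = c(2, 2, 4), input_size = 8,
                                   embedding_dim = 8, duse_reduction = 2,
                                   seed = 2))
  rec <- fake_record("a", size = 8)
  pp <- crf_params(n_iterations = 1)
  s1 <- segment_target(model, rec, pp)
  s2 <- segment_target(model, rec, pp)
  expect_identical(s1$mask, s2$mask)
  expect_equal(dim(s1$mask), c(8, 8, 8))
  expect_gte(s1$dsc, 0)
  expect_lte(s1$dsc, 1)
  expect_error(crf_params(n_iterations = 0), "at least 1")
  nodec <- init_model(model_config(channels = c(2, 2, 2), input_size = 8,
                                   duse_reduction = 2, use_decoder = FALSE))
  expect_error(segment_target(nodec, rec), "decoder")
})
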