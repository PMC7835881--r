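# Shared fixtures and brute-force oracles. Heavy artifacts (the desk-scale
# dataset) are built once per test run and memoised here.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# a synthetic subtomogram record with a blob of the given centre offset
fake_record <- function(class_label, offset = c(0, 0, 0), size = 8,
                        radius = 2.5, noise_sd = 0.05, seed = 1) {
  c0 <- (size - 1) / 2
  ax <- seq_len(size) - 1 - c0
  r2 <- outer(outer((ax - offset[1])^2, (ax - offset[2])^2, "+"),
              (ax - offset[3])^2, "+")
  vol <- array(exp(-r2 / (2 * (radius / 2)^2)), rep(size, 3))
  mask <- r2 <= radius^2
  vol <- vol + array(withr::with_seed(seed, rnorm(size^3, sd = noise_sd)),
                     rep(size, 3))
  structure(list(volume = vol, class_label = class_label, gt_mask = mask,
                 pose = pose(diag(3)), snr = Inf),
            class = "subtomo_record")
}

# a tiny in-memory split: n_rec records per class, blob centres per class
fake_split <- function(classes = c("a", "b", "c"), n_rec = 3, size = 8) {
  offs <- list(c(0, 0, 0), c(1.5, 0, 0), c(0, 1.5, 0), c(0, 0, 1.5),
               c(-1.5, 0, 0), c(0, -1.5, 0))
  records <- list()
  for (ci in seq_along(classes)) {
    for (k in seq_len(n_rec)) {
      records[[length(records) + 1]] <-
        fake_record(classes[ci], offs[[ci]], size = size, seed = ci * 100 + k)
    }
  }
  list(records = records, classes = classes)
}

# deterministic two-class episode over 8-cube records
fake_episode <- function(size = 8, seed = 1) {
  sp <- fake_split(c("a", "b"), n_rec = 2, size = size)
  structure(list(set_a = sp$records[c(1, 3)], set_b = sp$records[c(2, 4)],
                 classes = c("a", "b"), labels = diag(2)),
            class = "episode")
}

# scalar triple-loop oracle for the DuSE block (channel + spatial branch)
duse_oracle <- function(F, w1, w2, w3) {
  d <- dim(F)
  H <- d[1]; W <- d[2]; D <- d[3]; C <- d[4]
  sig <- function(x) 1 / (1 + exp(-x))
  v <- numeric(C)
  for (z in seq_len(C)) {
    s <- 0
    for (i in 1:H) for (j in 1:W) for (k in 1:D) s <- s + F[i, j, k, z]
    v[z] <- s / (H * W * D)
  }
  vhat <- sig(as.numeric(w2 %*% pmax(as.numeric(w1 %*% v), 0)))
  out <- array(0, d)
  for (i in 1:H) for (j in 1:W) for (k in 1:D) {
    m <- 0
    for (c in seq_len(C)) m <- m + w3[c] * F[i, j, k, c]
    mh <- sig(m)
    for (z in seq_len(C)) out[i, j, k, z] <- F[i, j, k, z] * vhat[z] +
        F[i, j, k, z] * mh
  }
  out
}

# fft-layout radial frequency grid
fft_freqs <- function(n) c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1)) / n

# The desk-scale simulated dataset shared by training/eval tests:
# 6 phantom classes, 4 training / 2 held-out, SNR Inf. The hold-out pair
# (sphere, torus) is resolvable without subtomogram alignment.
desk_dataset <- function() {
  memo("desk_dataset", function() {
    suppressWarnings(build_dataset(
      sim_config(tomogram_shape = c(170, 170, 110), n_particles = 150,
                 snr = Inf, seed = 11),
      phantom_library()[c("shell", "dumbbell", "lshape", "cross",
                          "sphere", "torus")],
      n_train_classes = 4))
  })
}

desk_model_config <- function(use_decoder = TRUE, use_duse = TRUE,
                              seed = 101) {
  model_config(channels = c(2, 4, 8), use_decoder = use_decoder,
               use_duse = use_duse, fe_adapter = "flatten",
               head_monotone = TRUE, seed = seed)
}

desk_train_config <- function(seed = 202) {
  train_config(n_way = 2, epochs = 30, episodes_per_epoch = 20,
               lr = 1e-3, seed = seed)
}

# trained desk-scale models, memoised per (decoder, seed)
desk_fit <- function(use_decoder = TRUE, seed = 202) {
  memo(sprintf("desk_fit_%d_%d", use_decoder, seed), function() {
    train_oneshot(desk_dataset(),
                  desk_model_config(use_decoder = use_decoder,
                                    seed = seed - 101),
                  desk_train_config(seed = seed))
  })
}
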