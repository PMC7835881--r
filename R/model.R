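# The Siamese one-shot network. One shared parameter set serves both
# streams: a 3-level volume encoder (two 3x3x3 convolutions + ReLU + DuSE
# + 2x max-pool per level), a mirrored volume decoder ending in a
# 1-channel sigmoid convolution (the probability map), and a feature
# encoder (global average pool -> linear adapter to 512 -> 512x512 fully
# connected layer). Embeddings of support and target are compared by
# elementwise L1 distance; a final linear head maps the distance vector to
# one logit per support class (sigmoid per pair in training, softmax over
# the support set at inference).

#' Model configuration
#'
#' @param channels integer length-3 channel widths of the three encoder
#'   levels (the decoder mirrors them).
#' @param input_size subtomogram cube edge; must be divisible by 8.
#' @param embedding_dim embedding length (512 by default).
#' @param duse_reduction reduction ratio of the DuSE channel branch; must
#'   divide every channel width.
#' @param use_duse include the DuSE attention blocks.
#' @param use_decoder include the volume decoder (the segmentation and
#'   attention-guidance branch).
#' @param fe_adapter how the latent grid is reduced before the fully
#'   connected feature encoder: `"pool"` applies global average pooling
#'   (one value per channel), `"flatten"` keeps the full spatial layout.
#'   Pooling discards the latent's spatial structure, which at small
#'   channel counts can carry most of the class signal; flattening keeps
#'   it at the cost of less built-in pose invariance.
#' @param head_monotone constrain the matching head's distance weights to
#'   be nonpositive, so the match score is monotonically decreasing in
#'   every coordinate of the L1 distance vector. A structural prior for
#'   distance-based matching that aids generalization to unseen classes
#'   when few training classes are available; note that it makes even an
#'   untrained model mildly informative (nearest-neighbour-like), whereas
#'   the unconstrained default scores at chance until trained.
#' @param seed integer seed for weight initialization.
#' @return A `model_config` object.
#' @export
model_config <- function(channels = c(32, 64, 128), input_size = 32,
                         embedding_dim = 512, duse_reduction = 2,
                         use_duse = TRUE, use_decoder = TRUE,
                         fe_adapter = c("pool", "flatten"),
                         head_monotone = FALSE, seed = 0) {
  fe_adapter <- match.arg(fe_adapter)
  channels <- as.integer(channels)
  if (length(channels) != 3 || any(channels < 1))
    stopf("channels must be three positive integers")
  if (input_size %% 8 != 0)
    stopf("input_size must be divisible by 8 (three pooling levels)")
  if (any(channels %% duse_reduction != 0))
    stopf("duse_reduction must divide every channel width")
  structure(list(channels = channels, input_size = as.integer(input_size),
                 embedding_dim = as.integer(embedding_dim),
                 duse_reduction = duse_reduction,
                 use_duse = isTRUE(use_duse),
                 use_decoder = isTRUE(use_decoder),
                 fe_adapter = fe_adapter,
                 head_monotone = isTRUE(head_monotone),
                 seed = as.integer(seed)),
            class = "model_config")
}

he_mat <- function(nout, nin) {
  matrix(rnorm(nout * nin, sd = sqrt(2 / nin)), nout, nin)
}

init_duse <- function(C, r) {
  list(w1 = he_mat(C %/% r, C), w2 = he_mat(C, C %/% r),
       w3 = rnorm(C, sd = sqrt(2 / C)))
}

#' Initialize a model
#'
#' Weights are He-normal with zero biases, fully determined by the
#' configuration seed. The same parameter set serves both Siamese streams.
#'
#' @param config a [model_config].
#' @return A `oneshot_model` object (fields `par`, `config`).
#' @export
init_model <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  ch <- config$channels
  r <- config$duse_reduction
  E <- config$embedding_dim
  with_seed(substream_seed(config$seed, "init"), {
    par <- list()
    cin <- 1L
    for (l in 1:3) {
      par[[paste0("enc", l, "_conv1_W")]] <- he_mat(ch[l], cin * 27)
      par[[paste0("enc", l, "_conv1_b")]] <- numeric(ch[l])
      par[[paste0("enc", l, "_conv2_W")]] <- he_mat(ch[l], ch[l] * 27)
      par[[paste0("enc", l, "_conv2_b")]] <- numeric(ch[l])
      if (config$use_duse) {
        d <- init_duse(ch[l], r)
        par[[paste0("enc", l, "_duse_w1")]] <- d$w1
        par[[paste0("enc", l, "_duse_w2")]] <- d$w2
        par[[paste0("enc", l, "_duse_w3")]] <- d$w3
      }
      cin <- ch[l]
    }
    if (config$use_decoder) {
      dch <- c(ch[2], ch[1], ch[1])  # widths after each upsampling level
      cin <- ch[3]
      for (l in 1:3) {
        par[[paste0("dec", l, "_conv1_W")]] <- he_mat(dch[l], cin * 27)
        par[[paste0("dec", l, "_conv1_b")]] <- numeric(dch[l])
        par[[paste0("dec", l, "_conv2_W")]] <- he_mat(dch[l], dch[l] * 27)
        par[[paste0("dec", l, "_conv2_b")]] <- numeric(dch[l])
        if (config$use_duse) {
          d <- init_duse(dch[l], r)
          par[[paste0("dec", l, "_duse_w1")]] <- d$w1
          par[[paste0("dec", l, "_duse_w2")]] <- d$w2
          par[[paste0("dec", l, "_duse_w3")]] <- d$w3
        }
        cin <- dch[l]
      }
      par$dec_final_W <- he_mat(1, ch[1] * 27)
      par$dec_final_b <- 0
    }
    pre_in <- if (config$fe_adapter == "flatten")
      ch[3] * (config$input_size %/% 8)^3 else ch[3]
    par$fe_pre_W <- he_mat(E, pre_in)
    par$fe_pre_b <- numeric(E)
    par$fe_fc_W <- he_mat(E, E)
    par$fe_fc_b <- numeric(E)
    par$head_w <- rnorm(E, sd = sqrt(2 / E))
    # under the monotone prior the head starts as a (random) nonpositive
    # weighting of the distance coordinates
    if (config$head_monotone) par$head_w <- -abs(par$head_w)
    par$head_b <- 0
    structure(list(par = par, config = config), class = "oneshot_model")
  })
}

#' @export
print.oneshot_model <- function(x, ...) {
  np <- sum(vapply(x$par, length, numeric(1)))
  cat(sprintf("<oneshot_model> channels %s, %s decoder, %s DuSE, %d parameters\n",
              paste(x$config$channels, collapse = "/"),
              if (x$config$use_decoder) "with" else "without",
              if (x$config$use_duse) "with" else "without", np))
  invisible(x)
}

# ---- forward / backward with caches (internal) ----

encoder_fwd <- function(par, cfg, x) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  if (dim(x)[1] != cfg$input_size)
    stopf("input cube edge %d does not match configured size %d",
          dim(x)[1], cfg$input_size)
  caches <- vector("list", 3)
  for (l in 1:3) {
    p <- function(nm) par[[paste0("enc", l, "_", nm)]]
    c1 <- conv_fwd(x, p("conv1_W"), p("conv1_b"))
    r1 <- lrelu_fwd(c1$out)
    c2 <- conv_fwd(r1$out, p("conv2_W"), p("conv2_b"))
    r2 <- lrelu_fwd(c2$out)
    if (cfg$use_duse) {
      du <- duse_fwd(r2$out, p("duse_w1"), p("duse_w2"), p("duse_w3"))
      dd <- du$out
    } else {
      du <- NULL
      dd <- r2$out
    }
    po <- maxpool_fwd(dd)
    caches[[l]] <- list(c1 = c1, r1 = r1, c2 = c2, r2 = r2, du = du,
                        po = po)
    x <- po$out
  }
  list(latent = x, caches = caches)
}

encoder_bwd <- function(par, cfg, caches, dlat, grads) {
  dx <- dlat
  for (l in 3:1) {
    ca <- caches[[l]]
    nm <- function(s) paste0("enc", l, "_", s)
    dx <- maxpool_bwd(ca$po$cache, dx)
    if (cfg$use_duse) {
      g <- duse_bwd(ca$du$cache, dx)
      grads[[nm("duse_w1")]] <- grads[[nm("duse_w1")]] + g$dw1
      grads[[nm("duse_w2")]] <- grads[[nm("duse_w2")]] + g$dw2
      grads[[nm("duse_w3")]] <- grads[[nm("duse_w3")]] + g$dw3
      dx <- g$dx
    }
    dx <- lrelu_bwd(ca$r2$cache, dx)
    g <- conv_bwd(ca$c2$cache, dx)
    grads[[nm("conv2_W")]] <- grads[[nm("conv2_W")]] + g$dW
    grads[[nm("conv2_b")]] <- grads[[nm("conv2_b")]] + g$db
    dx <- lrelu_bwd(ca$r1$cache, g$dx)
    g <- conv_bwd(ca$c1$cache, dx)
    grads[[nm("conv1_W")]] <- grads[[nm("conv1_W")]] + g$dW
    grads[[nm("conv1_b")]] <- grads[[nm("conv1_b")]] + g$db
    dx <- g$dx
  }
  grads
}

decoder_fwd <- function(par, cfg, latent) {
  caches <- vector("list", 3)
  x <- latent
  for (l in 1:3) {
    p <- function(nm) par[[paste0("dec", l, "_", nm)]]
    up <- upsample_fwd(x)
    c1 <- conv_fwd(up$out, p("conv1_W"), p("conv1_b"))
    r1 <- lrelu_fwd(c1$out)
    c2 <- conv_fwd(r1$out, p("conv2_W"), p("conv2_b"))
    r2 <- lrelu_fwd(c2$out)
    if (cfg$use_duse) {
      du <- duse_fwd(r2$out, p("duse_w1"), p("duse_w2"), p("duse_w3"))
      x <- du$out
    } else { du <- NULL; x <- r2$out }
    caches[[l]] <- list(up = up, c1 = c1, r1 = r1, c2 = c2, r2 = r2,
                        du = du)
  }
  cf <- conv_fwd(x, par$dec_final_W, par$dec_final_b)
  pm <- sigmoid(cf$out)
  dim(pm) <- dim(pm)[1:3]
  list(prob = pm, caches = caches, cf = cf)
}

decoder_bwd <- function(par, cfg, dec, dprob, grads) {
  pm <- dec$prob
  dpre <- dprob * pm * (1 - pm)
  dim(dpre) <- c(dim(pm), 1L)
  g <- conv_bwd(dec$cf$cache, dpre)
  grads$dec_final_W <- grads$dec_final_W + g$dW
  grads$dec_final_b <- grads$dec_final_b + g$db
  dx <- g$dx
  for (l in 3:1) {
    ca <- dec$caches[[l]]
    nm <- function(s) paste0("dec", l, "_", s)
    if (cfg$use_duse) {
      gd <- duse_bwd(ca$du$cache, dx)
      grads[[nm("duse_w1")]] <- grads[[nm("duse_w1")]] + gd$dw1
      grads[[nm("duse_w2")]] <- grads[[nm("duse_w2")]] + gd$dw2
      grads[[nm("duse_w3")]] <- grads[[nm("duse_w3")]] + gd$dw3
      dx <- gd$dx
    }
    dx <- lrelu_bwd(ca$r2$cache, dx)
    g <- conv_bwd(ca$c2$cache, dx)
    grads[[nm("conv2_W")]] <- grads[[nm("conv2_W")]] + g$dW
    grads[[nm("conv2_b")]] <- grads[[nm("conv2_b")]] + g$db
    dx <- lrelu_bwd(ca$r1$cache, g$dx)
    g <- conv_bwd(ca$c1$cache, dx)
    grads[[nm("conv1_W")]] <- grads[[nm("conv1_W")]] + g$dW
    grads[[nm("conv1_b")]] <- grads[[nm("conv1_b")]] + g$db
    dx <- upsample_bwd(ca$up$cache, g$dx)
  }
  list(grads = grads, dlatent = dx)
}

feature_fwd <- function(par, cfg, latent) {
  d <- dim(latent)
  N <- prod(d[1:3])
  g <- if (cfg$fe_adapter == "flatten") {
    as.numeric(latent)
  } else {
    lm <- latent
    dim(lm) <- c(N, d[4])
    colMeans(lm)
  }
  l1 <- linear_fwd(g, par$fe_pre_W, par$fe_pre_b)
  r1 <- relu_fwd(l1$out)
  l2 <- linear_fwd(r1$out, par$fe_fc_W, par$fe_fc_b)
  # project onto the unit sphere: embedding comparisons then live on a
  # fixed scale regardless of the encoder's activation magnitudes
  nrm <- sqrt(sum(l2$out^2)) + 1e-12
  emb <- l2$out / nrm
  list(emb = emb,
       cache = list(dims = d, N = N, l1 = l1, r1 = r1, l2 = l2,
                    nrm = nrm, emb = emb))
}

feature_bwd <- function(par, cfg, ca, demb, grads) {
  # through the normalization: dv = (demb - (demb . e) e) / ||v||
  dv <- (demb - sum(demb * ca$emb) * ca$emb) / ca$nrm
  g2 <- linear_bwd(ca$l2$cache, dv)
  grads$fe_fc_W <- grads$fe_fc_W + g2$dW
  grads$fe_fc_b <- grads$fe_fc_b + g2$db
  dh <- relu_bwd(ca$r1$cache, g2$dx)
  g1 <- linear_bwd(ca$l1$cache, dh)
  grads$fe_pre_W <- grads$fe_pre_W + g1$dW
  grads$fe_pre_b <- grads$fe_pre_b + g1$db
  dg <- g1$dx
  d <- ca$dims
  dlat <- if (cfg$fe_adapter == "flatten") array(dg, dim = d)
          else array(rep(dg, each = ca$N) / ca$N, dim = d)
  list(grads = grads, dlatent = dlat)
}

zero_grads <- function(par) {
  lapply(par, function(p) if (is.matrix(p)) matrix(0, nrow(p), ncol(p))
         else numeric(length(p)))
}

# ---- public module operations ----

#' Encode subtomogram volumes into latent representations
#'
#' The shared volume encoder of both Siamese streams: for any input the
#' support and target paths produce bit-identical latents because they use
#' the same parameter set.
#'
#' @param model a `oneshot_model`.
#' @param x a 3D volume of the configured input size, or a list of them.
#' @return A rank-4 latent array (or list of them, order preserved).
#' @export
volume_encode <- function(model, x) {
  if (is.list(x)) return(lapply(x, function(v) volume_encode(model, v)))
  encoder_fwd(model$par, model$config, x)$latent
}

#' Decode a latent representation into a foreground probability map
#'
#' @param model a `oneshot_model` built with `use_decoder = TRUE`.
#' @param latent a latent array from [volume_encode()], or a list.
#' @return 3D array of per-voxel foreground probabilities in `[0, 1]`.
#' @export
volume_decode <- function(model, latent) {
  if (!model$config$use_decoder)
    stopf("this model was built without a volume decoder")
  if (is.list(latent)) return(lapply(latent, function(l) volume_decode(model, l)))
  decoder_fwd(model$par, model$config, latent)$prob
}

#' Encode a latent representation into a 512-dimensional embedding
#'
#' Global average pooling over the latent grid, a linear adapter to the
#' embedding width, the 512x512 fully connected layer, and projection
#' onto the unit sphere (so embedding distances live on a fixed scale).
#'
#' @param model a `oneshot_model`.
#' @param latent a latent array from [volume_encode()], or a list.
#' @return Numeric embedding vector of length `embedding_dim`.
#' @export
feature_encode <- function(model, latent) {
  if (is.list(latent)) return(lapply(latent, function(l) feature_encode(model, l)))
  feature_fwd(model$par, model$config, latent)$emb
}

#' Elementwise L1 distance between two embeddings
#'
#' @param a,b numeric vectors of equal length.
#' @return `abs(a - b)`.
#' @export
pairwise_distance <- function(a, b) {
  if (length(a) != length(b))
    stopf("embedding lengths differ: %d vs %d", length(a), length(b))
  abs(a - b)
}

#' Score support-target distance vectors
#'
#' In `"pairwise-sigmoid"` mode (training) each distance vector yields an
#' independent match probability in (0, 1). In `"softmax-over-support"`
#' mode (inference) the per-class logits are normalized across the support
#' set; the predicted class is the argmax, ties broken towards the lowest
#' index.
#'
#' @param model a `oneshot_model`.
#' @param distances a single distance vector or a list of them (one per
#'   support class).
#' @param mode scoring mode, see above.
#' @return Numeric vector of scores (sums to 1 in softmax mode).
#' @export
match_scores <- function(model,
                         distances,
                         mode = c("softmax-over-support",
                                  "pairwise-sigmoid")) {
  mode <- match.arg(mode)
  if (!is.list(distances)) distances <- list(distances)
  if (length(distances) == 0) stopf("at least one distance vector required")
  logits <- vapply(distances, function(d)
    sum(model$par$head_w * d) + model$par$head_b, numeric(1))
  if (mode == "pairwise-sigmoid") {
    sigmoid(logits)
  } else {
    e <- exp(logits - max(logits))
    e / sum(e)
  }
}

#' Channel squeeze-and-excitation recalibration
#'
#' Squeezes each channel by global average pooling, passes the pooled
#' vector through a bottleneck (`w1`, ReLU, `w2`, sigmoid) and rescales
#' every channel by its calibration weight.
#'
#' @param F rank-4 feature map (H, W, D, C).
#' @param w1 matrix (C/r x C); @param w2 matrix (C x C/r).
#' @return Recalibrated feature map of the same shape.
#' @export
channel_squeeze_excite <- function(F, w1, w2) {
  d <- dim(F)
  N <- prod(d[1:3])
  xm <- F
  dim(xm) <- c(N, d[4])
  v <- colMeans(xm)
  vhat <- sigmoid(as.numeric(w2 %*% pmax(as.numeric(w1 %*% v), 0)))
  out <- sweep(xm, 2, vhat, "*")
  dim(out) <- d
  out
}

#' Spatial squeeze-and-excitation recalibration
#'
#' Squeezes the channel axis with a 1x1x1 convolution `w3`, applies a
#' sigmoid, and rescales every voxel by its calibration weight.
#'
#' @param F rank-4 feature map (H, W, D, C).
#' @param w3 numeric vector of length C.
#' @return Recalibrated feature map of the same shape.
#' @export
spatial_squeeze_excite <- function(F, w3) {
  d <- dim(F)
  N <- prod(d[1:3])
  xm <- F
  dim(xm) <- c(N, d[4])
  mhat <- sigmoid(as.numeric(xm %*% w3))
  out <- xm * mhat
  dim(out) <- d
  out
}

#' Dual squeeze-and-excitation block
#'
#' Elementwise sum of the channel and spatial recalibration branches.
#'
#' @param F rank-4 feature map.
#' @param weights list with fields `w1`, `w2`, `w3` as in
#'   [channel_squeeze_excite()] and [spatial_squeeze_excite()].
#' @return Recalibrated feature map of the same shape.
#' @export
duse_block <- function(F, weights) {
  channel_squeeze_excite(F, weights$w1, weights$w2) +
    spatial_squeeze_excite(F, weights$w3)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS file with the configuration embedded.
#'
#' @param model a `oneshot_model`.
#' @param path file path.
#' @return `path` invisibly / the restored model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "oneshot_model"))
  saveRDS(list(format = "tomoshot-checkpoint-v1",
               config = unclass(model$config), par = model$par), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "tomoshot-checkpoint-v1"))
    stopf("%s is not a tomoshot checkpoint", path)
  structure(list(par = ck$par,
                 config = structure(ck$config, class = "model_config")),
            class = "oneshot_model")
}
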