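# Episodic one-shot training and evaluation. Each training episode draws
# two n-class single-sample support sets over the same classes; the n^2
# ordered pairs carry binary match labels. The objective is the sum of a
# Dice segmentation loss on the decoder maps of both sets and the mean
# pairwise binary cross-entropy of the matching head. At test time one
# support set is replaced by a single target subtomogram and the predicted
# class is the softmax argmax over the support logits.

#' Training configuration
#'
#' @param n_way classes per episode (at least 2).
#' @param epochs training epochs.
#' @param episodes_per_epoch episodes sampled per epoch.
#' @param lr Adam learning rate.
#' @param beta1,beta2,adam_eps Adam moment decays and stabilizer.
#' @param augment_poses pose augmentation of episode records (volume and
#'   mask together) before the forward pass: `"inplane"` (default)
#'   rotates by a uniform angle about the beam axis, which preserves the
#'   missing-wedge geometry that real and simulated subtomograms share;
#'   `"so3"` rotates uniformly in 3D (also randomizing the wedge
#'   direction); `"none"` disables augmentation. `TRUE`/`FALSE` are
#'   accepted aliases for `"so3"`/`"none"`.
#' @param seed integer seed controlling episode sampling.
#' @return A `train_config` object.
#' @export
train_config <- function(n_way = 2, epochs = 30, episodes_per_epoch = 6,
                         lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         adam_eps = 1e-8, augment_poses = "inplane",
                         seed = 0) {
  if (n_way < 2) stopf("n_way must be at least 2")
  if (isTRUE(augment_poses)) augment_poses <- "so3"
  if (isFALSE(augment_poses)) augment_poses <- "none"
  augment_poses <- match.arg(augment_poses, c("inplane", "so3", "none"))
  structure(list(n_way = as.integer(n_way), epochs = as.integer(epochs),
                 episodes_per_epoch = as.integer(episodes_per_epoch),
                 lr = lr, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps, augment_poses = augment_poses,
                 seed = as.integer(seed)),
            class = "train_config")
}

# rotate a record's volume and mask by one fresh random rotation; mode
# "inplane" rotates about the beam (z) axis only, preserving the
# missing-wedge geometry
augment_record <- function(rec, mode) {
  R <- if (mode == "inplane") {
    th <- runif(1, 0, 2 * pi)
    matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
           3, 3, byrow = TRUE)
  } else random_pose()$rotation
  rec$volume <- resample_affine_cpp(rec$volume, dim(rec$volume), R,
                                    c(0, 0, 0))
  rec$gt_mask <- resample_affine_cpp(rec$gt_mask * 1, dim(rec$gt_mask),
                                     R, c(0, 0, 0)) > 0.5
  rec
}

#' Sample a training episode
#'
#' Draws `n_way` classes without replacement from the training split, then
#' one record per class for each of the two support sets; within a class
#' the two sets use different records whenever the class has at least two
#' (otherwise the record is reused with a warning). The label matrix
#' `F_gt[i, j]` is 1 exactly when the i-th record of set A and the j-th
#' record of set B share a class.
#'
#' @param dataset a `subtomo_dataset` or a split from it.
#' @param n_way number of classes in the episode.
#' @param seed optional integer seed.
#' @param split which split to draw from when `dataset` is a full dataset.
#' @return An `episode`: list with `set_a`, `set_b` (lists of records),
#'   `classes`, and `labels` (n x n binary matrix).
#' @export
sample_episode <- function(dataset, n_way, seed = NULL, split = "train") {
  recs <- if (!is.null(dataset$manifest)) dataset_split(dataset, split)
          else dataset
  by_class <- split(seq_along(recs$records),
                    vapply(recs$records, function(r) r$class_label,
                           character(1)))
  if (length(by_class) < n_way)
    stopf("episode needs %d classes but the split has only %d",
          n_way, length(by_class))
  with_seed(seed, {
    classes <- sample(names(by_class), n_way)
    ia <- integer(n_way); ib <- integer(n_way)
    for (q in seq_len(n_way)) {
      idx <- by_class[[classes[q]]]
      if (length(idx) >= 2) {
        pick <- sample(idx, 2)
        ia[q] <- pick[1]; ib[q] <- pick[2]
      } else {
        warnf("class '%s' has a single record; reusing it in both support sets",
              classes[q])
        ia[q] <- ib[q] <- idx
      }
    }
    labels <- outer(classes, classes, "==") * 1
    structure(list(set_a = recs$records[ia], set_b = recs$records[ib],
                   classes = classes, labels = labels),
              class = "episode")
  })
}

#' Binary cross-entropy of a match score
#'
#' `-label * log(score) - (1 - label) * log(1 - score)` with scores
#' clipped to `[1e-7, 1 - 1e-7]`. Vectorized; returns the mean over
#' elements.
#'
#' @param score predicted probabilities in (0, 1).
#' @param label binary labels.
#' @return Nonnegative scalar.
#' @export
bce_loss <- function(score, label) {
  s <- pmin(pmax(score, 1e-7), 1 - 1e-7)
  mean(-label * log(s) - (1 - label) * log(1 - s))
}

soft_dice <- function(pred, gt, eps = 1e-6) {
  (2 * sum(pred * gt) + eps) / (sum(pred) + sum(gt) + eps)
}

#' Dice segmentation loss over the two support sets
#'
#' Soft Dice on probabilities (product intersection, sum cardinality,
#' epsilon-smoothed): `2 - mean(DSC(set A)) - mean(DSC(set B))`, in
#' `[0, 2]`. An all-zero prediction paired with an all-zero mask counts as
#' perfect.
#'
#' @param ms1,ms2 probability map (3D array) or list of maps, one per set.
#' @param gt1,gt2 matching ground-truth masks.
#' @return Scalar in `[0, 2]`.
#' @export
dice_loss <- function(ms1, ms2, gt1, gt2) {
  as_list <- function(x) if (is.list(x)) x else list(x)
  ms1 <- as_list(ms1); ms2 <- as_list(ms2)
  gt1 <- as_list(gt1); gt2 <- as_list(gt2)
  d1 <- mean(mapply(function(p, g) soft_dice(p, g * 1), ms1, gt1))
  d2 <- mean(mapply(function(p, g) soft_dice(p, g * 1), ms2, gt2))
  2 - d1 - d2
}

#' Total episode loss
#'
#' Unit-weighted sum of the Dice and BCE components.
#'
#' @param l_dsc,l_bce nonnegative loss components.
#' @return Their sum.
#' @export
total_loss <- function(l_dsc, l_bce) l_dsc + l_bce

# full forward pass for one volume: latent (+caches), optional decoder
# map, embedding
forward_volume <- function(par, cfg, vol) {
  x <- standardize_volume(vol)
  enc <- encoder_fwd(par, cfg, x)
  dec <- if (cfg$use_decoder) decoder_fwd(par, cfg, enc$latent) else NULL
  fe <- feature_fwd(par, cfg, enc$latent)
  list(enc = enc, dec = dec, fe = fe)
}

# gradient of the soft-Dice loss term -dsc/n_set w.r.t. the probability map
soft_dice_grad <- function(pred, gt, scale, eps = 1e-6) {
  den <- sum(pred) + sum(gt) + eps
  num <- 2 * sum(pred * gt) + eps
  -scale * (2 * gt / den - num / den^2)
}

# One episode: loss, components, and parameter gradients.
episode_step <- function(par, cfg, episode, compute_grads = TRUE) {
  n <- length(episode$set_a)
  fa <- lapply(episode$set_a, function(r) forward_volume(par, cfg, r$volume))
  fb <- lapply(episode$set_b, function(r) forward_volume(par, cfg, r$volume))
  # pairwise BCE over all ordered (a_i, b_j) pairs
  npair <- n * n
  dlogit <- matrix(0, n, n)
  l_bce <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d <- abs(fa[[i]]$fe$emb - fb[[j]]$fe$emb)
    logit <- sum(par$head_w * d) + par$head_b
    p <- sigmoid(logit)
    y <- episode$labels[i, j]
    pc <- min(max(p, 1e-7), 1 - 1e-7)
    l_bce <- l_bce + (-y * log(pc) - (1 - y) * log(1 - pc)) / npair
    dlogit[i, j] <- (p - y) / npair
  }
  # Dice on the decoder maps of both support sets
  l_dsc <- 0
  if (cfg$use_decoder) {
    ga <- lapply(episode$set_a, function(r) r$gt_mask * 1)
    gb <- lapply(episode$set_b, function(r) r$gt_mask * 1)
    l_dsc <- dice_loss(lapply(fa, function(f) f$dec$prob),
                       lapply(fb, function(f) f$dec$prob), ga, gb)
  }
  loss <- total_loss(l_dsc, l_bce)
  if (!compute_grads)
    return(list(loss = loss, l_dsc = l_dsc, l_bce = l_bce))
  grads <- zero_grads(par)
  demb_a <- lapply(seq_len(n), function(i) numeric(length(par$head_w)))
  demb_b <- demb_a
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d <- fa[[i]]$fe$emb - fb[[j]]$fe$emb
    ad <- abs(d)
    sg <- sign(d)
    grads$head_w <- grads$head_w + dlogit[i, j] * ad
    grads$head_b <- grads$head_b + dlogit[i, j]
    dd <- dlogit[i, j] * par$head_w
    demb_a[[i]] <- demb_a[[i]] + dd * sg
    demb_b[[j]] <- demb_b[[j]] - dd * sg
  }
  backward_one <- function(f, rec, demb, n_set) {
    dlat_fe <- feature_bwd(par, cfg, f$fe$cache, demb, grads)
    grads <<- dlat_fe$grads
    dlat <- dlat_fe$dlatent
    if (cfg$use_decoder) {
      dprob <- soft_dice_grad(f$dec$prob, rec$gt_mask * 1, 1 / n_set)
      db <- decoder_bwd(par, cfg, f$dec, dprob, grads)
      grads <<- db$grads
      dlat <- dlat + db$dlatent
    }
    grads <<- encoder_bwd(par, cfg, f$enc$caches, dlat, grads)
  }
  for (i in seq_len(n)) backward_one(fa[[i]], episode$set_a[[i]],
                                     demb_a[[i]], n)
  for (j in seq_len(n)) backward_one(fb[[j]], episode$set_b[[j]],
                                     demb_b[[j]], n)
  list(loss = loss, l_dsc = l_dsc, l_bce = l_bce, grads = grads)
}

adam_init <- function(par) {
  list(m = zero_grads(par), v = zero_grads(par), t = 0)
}

adam_step <- function(par, grads, state, tc) {
  state$t <- state$t + 1
  bc1 <- 1 - tc$beta1^state$t
  bc2 <- 1 - tc$beta2^state$t
  for (nm in names(par)) {
    g <- grads[[nm]]
    state$m[[nm]] <- tc$beta1 * state$m[[nm]] + (1 - tc$beta1) * g
    state$v[[nm]] <- tc$beta2 * state$v[[nm]] + (1 - tc$beta2) * g^2
    par[[nm]] <- par[[nm]] - tc$lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + tc$adam_eps)
  }
  list(par = par, state = state)
}

#' Train the one-shot network
#'
#' Episodic training on the training split only: per episode the total
#' loss (Dice + mean pairwise BCE) is minimized with Adam. Aborts with a
#' diagnostic if the loss turns non-finite.
#'
#' @param dataset a `subtomo_dataset`.
#' @param model_config a [model_config].
#' @param tc a [train_config].
#' @param verbose print per-epoch losses.
#' @return List with `model` (trained `oneshot_model`) and `history`
#'   (data frame of per-epoch mean loss and components).
#' @export
train_oneshot <- function(dataset, model_config, tc = train_config(),
                          verbose = FALSE) {
  model <- init_model(model_config)
  par <- model$par
  cfg <- model$config
  state <- adam_init(par)
  ep_seed <- substream_seed(tc$seed, "episodes")
  history <- data.frame(epoch = integer(), loss = numeric(),
                        l_dsc = numeric(), l_bce = numeric())
  for (ep in seq_len(tc$epochs)) {
    losses <- matrix(0, tc$episodes_per_epoch, 3)
    for (it in seq_len(tc$episodes_per_epoch)) {
      episode <- sample_episode(dataset, tc$n_way,
                                seed = ep_seed + ep * 10007L + it)
      if (tc$augment_poses != "none") {
        with_seed(ep_seed + ep * 20011L + it, {
          episode$set_a <- lapply(episode$set_a, augment_record,
                                  mode = tc$augment_poses)
          episode$set_b <- lapply(episode$set_b, augment_record,
                                  mode = tc$augment_poses)
        })
      }
      st <- episode_step(par, cfg, episode, compute_grads = tc$lr > 0)
      if (!is.finite(st$loss))
        stopf("training diverged: non-finite loss at epoch %d episode %d (l_dsc=%g, l_bce=%g)",
              ep, it, st$l_dsc, st$l_bce)
      losses[it, ] <- c(st$loss, st$l_dsc, st$l_bce)
      if (tc$lr > 0) {
        upd <- adam_step(par, st$grads, state, tc)
        par <- upd$par
        state <- upd$state
        if (cfg$head_monotone) par$head_w <- pmin(par$head_w, 0)
      }
    }
    history <- rbind(history, data.frame(
      epoch = ep, loss = mean(losses[, 1]), l_dsc = mean(losses[, 2]),
      l_bce = mean(losses[, 3])))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  (dice %.4f, bce %.4f)",
                      ep, mean(losses[, 1]), mean(losses[, 2]),
                      mean(losses[, 3])))
  }
  model$par <- par
  list(model = model, history = history)
}

#' Evaluate n-way one-shot classification on the test split
#'
#' Every unique test record is embedded once; each episode then draws
#' `n_way` classes, one support record per class, and one target record of
#' a support class (a record distinct from its support whenever the class
#' has at least two). The prediction is the softmax argmax over support
#' logits. Optionally computes CRF-refined segmentation DSC per class over
#' the distinct test records.
#'
#' @param model a trained `oneshot_model`.
#' @param dataset a `subtomo_dataset` (its test split is used) or a split.
#' @param n_way support classes per episode.
#' @param n_episodes number of evaluation episodes.
#' @param seed integer seed.
#' @param score_fn optional override: function(list of support embeddings,
#'   target embedding) returning per-class scores. Used for protocol
#'   checks (oracle / random scorers); default uses the model's head.
#' @param crf segmentation refinement parameters ([crf_params]) when
#'   per-class DSC is wanted, otherwise `NULL`.
#' @return An `eval_report`: list with `n_way`, `n_episodes`, `accuracy`,
#'   and `per_class_dsc` (data frame with `class`, `dsc_mean`, `dsc_sd`,
#'   `n`, or NULL).
#' @export
evaluate_nway <- function(model, dataset, n_way, n_episodes = 200,
                          seed = 0, score_fn = NULL, crf = NULL) {
  recs <- if (!is.null(dataset$manifest)) dataset_split(dataset, "test")
          else dataset
  labels <- vapply(recs$records, function(r) r$class_label, character(1))
  by_class <- split(seq_along(recs$records), labels)
  if (length(by_class) < n_way)
    stopf("n_way = %d exceeds the %d available test classes", n_way,
          length(by_class))
  embs <- NULL
  if (is.null(score_fn)) {
    embs <- lapply(recs$records, function(r)
      feature_fwd(model$par, model$config,
                  encoder_fwd(model$par, model$config,
                              standardize_volume(r$volume))$latent)$emb)
    score_fn <- function(support_embs, target_emb) {
      dists <- lapply(support_embs, pairwise_distance, b = target_emb)
      match_scores(model, dists, mode = "softmax-over-support")
    }
  }
  correct <- logical(n_episodes)
  with_seed(substream_seed(seed, "eval"), {
    for (e in seq_len(n_episodes)) {
      classes <- sample(names(by_class), n_way)
      support <- vapply(classes, function(cl)
        if (length(by_class[[cl]]) == 1) by_class[[cl]] else
          sample(by_class[[cl]], 1), integer(1))
      tgt_class <- sample.int(n_way, 1)
      pool <- setdiff(by_class[[classes[tgt_class]]], support[tgt_class])
      target <- if (length(pool) == 0) support[tgt_class] else
        if (length(pool) == 1) pool else sample(pool, 1)
      scores <- if (is.null(embs))
        score_fn(recs$records[support], recs$records[[target]])
      else score_fn(embs[support], embs[[target]])
      pred <- which.max(scores)   # ties -> lowest index
      correct[e] <- pred == tgt_class
    }
  })
  per_class_dsc <- NULL
  if (!is.null(crf)) {
    if (!model$config$use_decoder)
      stopf("per-class DSC needs a model with a volume decoder")
    dscs <- vapply(recs$records, function(r)
      segment_target(model, r, crf)$dsc, numeric(1))
    agg <- tapply(dscs, labels, function(x)
      c(mean = mean(x), sd = stats::sd(x), n = length(x)))
    per_class_dsc <- data.frame(
      class = names(agg),
      dsc_mean = vapply(agg, `[[`, numeric(1), "mean"),
      dsc_sd = vapply(agg, `[[`, numeric(1), "sd"),
      n = vapply(agg, `[[`, numeric(1), "n"),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(list(n_way = n_way, n_episodes = n_episodes,
                 accuracy = mean(correct), per_class_dsc = per_class_dsc),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d-way 1-shot: accuracy %.3f over %d episodes\n",
              x$n_way, x$accuracy, x$n_episodes))
  if (!is.null(x$per_class_dsc)) {
    cat("per-class CRF-refined DSC:\n")
    print(x$per_class_dsc, digits = 3)
  }
  invisible(x)
}
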