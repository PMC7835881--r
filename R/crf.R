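# Fully connected binary CRF over subtomogram voxels. The unary term ties
# the labeling to the decoder's probability map; the pairwise term couples
# every ordered voxel pair through an appearance kernel (position +
# intensity) and a smoothness kernel (position only), gated by a Potts
# compatibility that penalizes differing labels. Inference is iterative
# mean field with truncated Gaussian neighbourhoods (radius 3 sigma); the
# dense all-pairs versions below serve as test oracles on small instances.

#' CRF parameters
#'
#' @param w1 appearance kernel weight (position + intensity).
#' @param w2 smoothness kernel weight (position only).
#' @param sigma_alpha spatial bandwidth of the appearance kernel, voxels.
#' @param sigma_beta intensity bandwidth of the appearance kernel, in
#'   units of the (standardized) subtomogram intensity.
#' @param sigma_gamma spatial bandwidth of the smoothness kernel, voxels.
#' @param n_iterations mean-field iterations, at least 1.
#' @return A `crf_params` object.
#' @export
crf_params <- function(w1 = 1, w2 = 1, sigma_alpha = 2, sigma_beta = 0.5,
                       sigma_gamma = 1, n_iterations = 5) {
  if (w1 < 0 || w2 < 0) stopf("kernel weights must be nonnegative")
  if (sigma_alpha <= 0 || sigma_beta <= 0 || sigma_gamma <= 0)
    stopf("kernel bandwidths must be positive")
  if (n_iterations < 1) stopf("n_iterations must be at least 1")
  structure(list(w1 = w1, w2 = w2, sigma_alpha = sigma_alpha,
                 sigma_beta = sigma_beta, sigma_gamma = sigma_gamma,
                 n_iterations = as.integer(n_iterations)),
            class = "crf_params")
}

# pairwise kernel matrix over all ordered voxel pairs (dense; small
# instances only)
crf_kernel_matrix <- function(intensity, params) {
  d <- dim(intensity)
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  D2 <- as.matrix(stats::dist(idx))^2
  dI2 <- outer(as.vector(intensity), as.vector(intensity), "-")^2
  K <- params$w1 * exp(-D2 / (2 * params$sigma_alpha^2) -
                         dI2 / (2 * params$sigma_beta^2)) +
    params$w2 * exp(-D2 / (2 * params$sigma_gamma^2))
  diag(K) <- 0
  K
}

#' Evaluate the CRF energy of a labeling
#'
#' Exact evaluation over all ordered voxel pairs: the unary term is the
#' negative log of the (clipped) decoder probability of each voxel's
#' label; the pairwise term applies the appearance and smoothness kernels
#' wherever two labels differ. Quadratic in the voxel count — intended for
#' small instances and as a test oracle.
#'
#' @param labeling binary 3D array (0/1 per voxel).
#' @param unary_probs foreground probability map in `[0, 1]`, same shape.
#' @param intensity intensity volume, same shape.
#' @param params a [crf_params].
#' @return Scalar energy.
#' @export
crf_energy <- function(labeling, unary_probs, intensity, params) {
  if (!all(dim(labeling) == dim(unary_probs)) ||
      !all(dim(labeling) == dim(intensity)))
    stopf("labeling, unary_probs and intensity must share a shape")
  x <- as.vector(labeling) * 1
  p <- pmin(pmax(as.vector(unary_probs), 1e-8), 1 - 1e-8)
  unary <- sum(ifelse(x == 1, -log(p), -log(1 - p)))
  K <- crf_kernel_matrix(intensity, params)
  mu <- outer(x, x, "!=") * 1
  unary + sum(K * mu)
}

# dense-matrix mean field (test oracle for the truncated implementation)
mean_field_dense <- function(unary_probs, intensity, params) {
  p <- pmin(pmax(as.vector(unary_probs), 1e-8), 1 - 1e-8)
  u1 <- -log(p); u0 <- -log(1 - p)
  K <- crf_kernel_matrix(intensity, params)
  q1 <- p
  for (it in seq_len(params$n_iterations)) {
    s <- as.numeric(K %*% q1)
    ksum <- rowSums(K)
    e1 <- u1 + (ksum - s)
    e0 <- u0 + s
    q1 <- 1 / (1 + exp(e1 - e0))
  }
  array(q1, dim(unary_probs))
}

#' Refine a probability map by mean-field CRF inference
#'
#' Runs synchronous mean-field updates with the two Gaussian kernels and
#' returns the argmax labeling of the converged marginals. Deterministic.
#'
#' @param unary_probs foreground probability map in `[0, 1]`.
#' @param intensity intensity volume of the same shape (standardized
#'   internally to zero mean, unit variance).
#' @param params a [crf_params].
#' @return Logical mask of the same shape.
#' @export
mean_field_refine <- function(unary_probs, intensity, params = crf_params()) {
  stopifnot(inherits(params, "crf_params"))
  if (!all(dim(unary_probs) == dim(intensity)))
    stopf("unary_probs and intensity must share a shape")
  ii <- standardize_volume(intensity)
  q1 <- crf_meanfield_cpp(unary_probs, ii, dim(unary_probs),
                          params$w1, params$w2, params$sigma_alpha,
                          params$sigma_beta, params$sigma_gamma,
                          params$n_iterations)
  q1 > 0.5
}

#' Dice similarity coefficient of two binary masks
#'
#' `2 |A and B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param pred,gt binary arrays of identical shape.
#' @return Scalar in `[0, 1]`.
#' @export
dsc_metric <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt)))
    stopf("mask shapes differ: %s vs %s",
          paste(dim(pred), collapse = "x"), paste(dim(gt), collapse = "x"))
  p <- as.vector(pred) != 0
  g <- as.vector(gt) != 0
  tot <- sum(p) + sum(g)
  if (tot == 0) return(1)
  2 * sum(p & g) / tot
}

#' Segment a target subtomogram
#'
#' Runs the target through the shared encoder and the volume decoder,
#' refines the decoder's probability map with the mean-field CRF (the
#' subtomogram's own intensities drive the appearance kernel), and returns
#' the final mask plus its DSC against the record's ground truth when
#' present.
#'
#' @param model a trained `oneshot_model` with a decoder.
#' @param record a `subtomo_record` (or plain 3D volume).
#' @param params a [crf_params]; `NULL` skips refinement and thresholds
#'   the decoder map at 0.5.
#' @return List with `mask`, `prob` (decoder map), and `dsc` (or NA).
#' @export
segment_target <- function(model, record, params = crf_params()) {
  if (!model$config$use_decoder)
    stopf("segmentation requires a model with a volume decoder")
  vol <- if (inherits(record, "subtomo_record")) record$volume else record
  x <- standardize_volume(vol)
  lat <- encoder_fwd(model$par, model$config, x)$latent
  prob <- decoder_fwd(model$par, model$config, lat)$prob
  mask <- if (is.null(params)) prob > 0.5 else
    mean_field_refine(prob, vol, params)
  dsc <- if (inherits(record, "subtomo_record") && !is.null(record$gt_mask))
    dsc_metric(mask, record$gt_mask) else NA_real_
  list(mask = mask, prob = prob, dsc = dsc)
}

#' Grid search for CRF parameters
#'
#' Scores every combination of the supplied parameter values by mean
#' refined DSC over a set of validation records and returns the best
#' [crf_params].
#'
#' @param model a trained `oneshot_model` with a decoder.
#' @param records list of `subtomo_record`s with ground-truth masks.
#' @param w1,w2,sigma_alpha,sigma_beta,sigma_gamma,n_iterations candidate
#'   values.
#' @return List with `params` (best [crf_params]) and `results` (data
#'   frame of all combinations and their mean DSC).
#' @export
crf_grid_search <- function(model, records, w1 = c(1, 3, 10),
                            w2 = c(1, 3, 10), sigma_alpha = c(1, 3),
                            sigma_beta = c(0.1, 0.5), sigma_gamma = c(1, 3),
                            n_iterations = 5) {
  grid <- expand.grid(w1 = w1, w2 = w2, sigma_alpha = sigma_alpha,
                      sigma_beta = sigma_beta, sigma_gamma = sigma_gamma)
  grid$dsc <- NA_real_
  for (g in seq_len(nrow(grid))) {
    pp <- crf_params(grid$w1[g], grid$w2[g], grid$sigma_alpha[g],
                     grid$sigma_beta[g], grid$sigma_gamma[g], n_iterations)
    grid$dsc[g] <- mean(vapply(records, function(r)
      segment_target(model, r, pp)$dsc, numeric(1)))
  }
  best <- which.max(grid$dsc)
  list(params = crf_params(grid$w1[best], grid$w2[best],
                           grid$sigma_alpha[best], grid$sigma_beta[best],
                           grid$sigma_gamma[best], n_iterations),
       results = grid)
}
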