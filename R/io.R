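# Dataset manifests, configuration files, and the end-to-end pipeline
# wiring simulate -> train -> eval -> segment. Every artifact embeds the
# seed and a hash of the configuration that produced it.

pose_to_quaternion <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- 0.25 * s
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  q / sqrt(sum(q^2))
}

#' Write a dataset to disk
#'
#' Each record's volume (and mask) is written as MRC2014; a JSON manifest
#' records paths, classes, the class-level split, SNR, poses (as
#' quaternion + translation), the creation seed and the config hash.
#'
#' @param dataset a `subtomo_dataset`.
#' @param dir output directory (created if missing).
#' @param write_volumes also write per-record MRC files (otherwise only
#'   the manifest is written).
#' @return Path to the manifest JSON, invisibly.
#' @export
write_dataset <- function(dataset, dir, write_volumes = TRUE) {
  stopifnot(inherits(dataset, "subtomo_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  recs <- lapply(seq_along(dataset$records), function(i) {
    r <- dataset$records[[i]]
    path <- file.path(dir, sprintf("subtomo_%04d.mrc", i))
    mpath <- file.path(dir, sprintf("mask_%04d.mrc", i))
    if (write_volumes) {
      write_mrc(r$volume, path, dataset$config$voxel_size)
      write_mrc(r$gt_mask * 1, mpath, dataset$config$voxel_size)
    }
    list(path = basename(path), mask_path = basename(mpath),
         class_label = r$class_label,
         split = unname(dataset$split[r$class_label]),
         snr = if (is.infinite(r$snr)) "Inf" else r$snr,
         pose_quaternion = pose_to_quaternion(r$pose$rotation),
         pose_translation = r$pose$translation)
  })
  manifest <- list(format = "tomoshot-manifest-v1",
                   seed = dataset$config$seed,
                   config_hash = dataset$config_hash,
                   classes = as.list(dataset$split),
                   records = recs)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a dataset manifest
#'
#' @param path path to a manifest JSON file.
#' @return The parsed manifest (list).
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(m$format, "tomoshot-manifest-v1"))
    stopf("%s is not a tomoshot manifest", path)
  m
}

#' Validate a dataset manifest
#'
#' Checks that the manifest has records, that the train/test assignment
#' is a partition of the classes (class-disjoint), that each record's
#' split matches its class's split, and (optionally) that the referenced
#' files exist.
#'
#' @param m a manifest from [load_manifest()].
#' @param dir directory for resolving record paths; `NULL` skips file
#'   existence checks.
#' @return List with `ok` (logical), `errors` (character), `classes`
#'   (data frame of class, split, n_records).
#' @export
validate_manifest <- function(m, dir = NULL) {
  errors <- character()
  if (length(m$records) == 0) errors <- c(errors, "no records")
  cls_split <- unlist(m$classes)
  bad <- setdiff(unique(cls_split), c("train", "test"))
  if (length(bad) > 0)
    errors <- c(errors, sprintf("invalid split labels: %s",
                                paste(bad, collapse = ", ")))
  rec_class <- vapply(m$records, function(r) r$class_label, character(1))
  rec_split <- vapply(m$records, function(r) r$split, character(1))
  for (cl in unique(rec_class)) {
    sp <- unique(rec_split[rec_class == cl])
    if (length(sp) > 1)
      errors <- c(errors,
                  sprintf("class '%s' appears in both splits: %s", cl,
                          paste(sp, collapse = ", ")))
    if (!is.null(cls_split[[cl]]) && length(sp) == 1 &&
        sp != cls_split[[cl]])
      errors <- c(errors,
                  sprintf("class '%s' split '%s' disagrees with registry '%s'",
                          cl, sp, cls_split[[cl]]))
  }
  missing <- setdiff(rec_class, names(cls_split))
  if (length(missing) > 0)
    errors <- c(errors, sprintf("classes absent from registry: %s",
                                paste(missing, collapse = ", ")))
  if (!is.null(dir)) {
    paths <- vapply(m$records, function(r) r$path, character(1))
    gone <- paths[!file.exists(file.path(dir, paths))]
    if (length(gone) > 0)
      errors <- c(errors, sprintf("%d record files missing (first: %s)",
                                  length(gone), gone[1]))
  }
  classes <- if (length(rec_class) == 0) {
    data.frame(class = character(), n_records = integer(),
               split = character(), stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(table(class = rec_class), stringsAsFactors = FALSE)
    names(df) <- c("class", "n_records")
    df$split <- rec_split[match(df$class, rec_class)]
    df
  }
  list(ok = length(errors) == 0, errors = errors, classes = classes)
}

#' Top-level pipeline configuration
#'
#' @param sim a [sim_config].
#' @param model a [model_config].
#' @param train a [train_config].
#' @param crf a [crf_params] (or `NULL` to skip CRF refinement).
#' @param n_train_classes classes assigned to the training split.
#' @param eval_n_way n-way settings to evaluate.
#' @param eval_episodes episodes per evaluation cell.
#' @param seed top-level seed; overrides the stage seeds through named
#'   sub-streams.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(sim = sim_config(), model = model_config(),
                            train = train_config(), crf = crf_params(),
                            n_train_classes = 4, eval_n_way = 2,
                            eval_episodes = 200, seed = 0) {
  sim$seed <- substream_seed(seed, "sim")
  model$seed <- substream_seed(seed, "init")
  train$seed <- substream_seed(seed, "episodes")
  structure(list(sim = sim, model = model, train = train, crf = crf,
                 n_train_classes = n_train_classes,
                 eval_n_way = eval_n_way, eval_episodes = eval_episodes,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Simulates a phantom dataset, trains the one-shot network, evaluates
#' n-way-1-shot accuracy on the unseen test classes, segments the test
#' records with CRF refinement, and writes metrics CSVs (an accuracy
#' table with columns snr, variant, n_way, accuracy, and a DSC table with
#' columns variant, n_way, class, dsc_mean, dsc_sd) plus a checkpoint
#' into `out_dir`.
#'
#' @param config a [pipeline_config].
#' @param out_dir output directory.
#' @param class_maps density maps to simulate; defaults to the built-in
#'   phantom library.
#' @param verbose print progress.
#' @return List with `dataset`, `model`, `history`, `reports` (one
#'   `eval_report` per n-way), and the artifact paths.
#' @export
run_pipeline <- function(config, out_dir, class_maps = phantom_library(),
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  dataset <- stage("simulate",
                   build_dataset(config$sim, class_maps,
                                 config$n_train_classes))
  manifest_path <- stage("simulate",
                         write_dataset(dataset, file.path(out_dir, "data"),
                                       write_volumes = FALSE))
  fit <- stage("train", train_oneshot(dataset, config$model, config$train,
                                      verbose = verbose))
  ckpt <- file.path(out_dir, "checkpoint.rds")
  save_checkpoint(fit$model, ckpt)
  variant <- sprintf("%s%s",
                     if (config$model$use_duse) "DuSE-SCNN" else "SCNN",
                     if (config$model$use_decoder) " w Decoder"
                     else " w/o Decoder")
  acc_rows <- list(); reports <- list()
  for (nw in config$eval_n_way) {
    rep <- stage("eval",
                 evaluate_nway(fit$model, dataset, nw,
                               n_episodes = config$eval_episodes,
                               seed = substream_seed(config$seed, "eval"),
                               crf = if (config$model$use_decoder)
                                 config$crf else NULL))
    reports[[as.character(nw)]] <- rep
    acc_rows[[length(acc_rows) + 1]] <- data.frame(
      snr = format(config$sim$snr), variant = variant, n_way = nw,
      accuracy = rep$accuracy)
  }
  acc <- do.call(rbind, acc_rows)
  acc$seed <- config$seed
  acc$config_hash <- config_hash(config)
  acc_path <- file.path(out_dir, "accuracy.csv")
  utils::write.csv(acc, acc_path, row.names = FALSE)
  dsc_path <- NULL
  if (config$model$use_decoder) {
    dsc_rows <- do.call(rbind, lapply(names(reports), function(nw) {
      df <- reports[[nw]]$per_class_dsc
      if (is.null(df)) return(NULL)
      data.frame(variant = variant, n_way = as.integer(nw), df)
    }))
    if (!is.null(dsc_rows)) {
      dsc_rows$seed <- config$seed
      dsc_rows$config_hash <- config_hash(config)
      dsc_path <- file.path(out_dir, "dsc.csv")
      utils::write.csv(dsc_rows, dsc_path, row.names = FALSE)
    }
  }
  history_path <- file.path(out_dir, "loss_history.csv")
  utils::write.csv(cbind(fit$history, seed = config$seed), history_path,
                   row.names = FALSE)
  list(dataset = dataset, model = fit$model, history = fit$history,
       reports = reports,
       paths = list(manifest = manifest_path, checkpoint = ckpt,
                    accuracy = acc_path, dsc = dsc_path,
                    history = history_path))
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Recognized top-level keys: `seed`, `n_train_classes`, `eval_n_way`,
#' `eval_episodes`, and the nested sections `sim`, `optics`, `model`,
#' `train`, `crf`, each holding the arguments of the matching
#' constructor. Unknown keys raise an error naming the key.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A [pipeline_config].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("seed", "n_train_classes", "eval_n_way", "eval_episodes",
             "sim", "optics", "model", "train", "crf")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0)
    stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  build <- function(ctor, args, extra = list()) {
    if (is.null(args)) args <- list()
    ok <- names(formals(ctor))
    bad <- setdiff(names(args), ok)
    if (length(bad) > 0)
      stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
    do.call(ctor, c(args, extra))
  }
  optics <- build(optics_params, raw$optics)
  sim_args <- raw$sim
  sim_args$optics <- NULL   # optics live in their own section
  if (!is.null(sim_args$snr) && is.character(sim_args$snr))
    sim_args$snr <- as.numeric(sim_args$snr)  # "Inf" -> Inf
  sim <- build(sim_config, sim_args, list(optics = optics))
  pipeline_config(
    sim = sim,
    model = build(model_config, raw$model),
    train = build(train_config, raw$train),
    crf = build(crf_params, raw$crf),
    n_train_classes = raw$n_train_classes %||% 4,
    eval_n_way = raw$eval_n_way %||% 2,
    eval_episodes = raw$eval_episodes %||% 200,
    seed = raw$seed %||% 0)
}
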