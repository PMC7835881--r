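# Subtomogram simulation pipeline: pack posed structures into a volume,
# project a single-axis tilt series (missing wedge), convolve CTF/MTF
# optical factors, add Gaussian noise to a target SNR, reconstruct by
# weighted back-projection, and extract 32-cube subtomograms with
# ground-truth masks.

#' Electron-optics parameters for CTF/MTF simulation
#'
#' @param voltage acceleration voltage in kV.
#' @param defocus defocus in micrometres (negative = underfocus).
#' @param spherical_aberration Cs in mm.
#' @param amplitude_contrast amplitude contrast fraction in `[0, 1]`.
#' @param mtf_cutoff Gaussian MTF envelope width as a fraction of Nyquist.
#' @param pixel_size detector pixel size in Angstrom.
#' @param enabled when `FALSE`, [apply_ctf_mtf()] is a pass-through.
#' @return An `optics_params` object.
#' @export
optics_params <- function(voltage = 300, defocus = -5,
                          spherical_aberration = 2,
                          amplitude_contrast = 0.07, mtf_cutoff = 0.4,
                          pixel_size = 10, enabled = TRUE) {
  if (voltage <= 0) stopf("voltage must be positive")
  if (amplitude_contrast < 0 || amplitude_contrast > 1)
    stopf("amplitude_contrast must be in [0, 1]")
  structure(list(voltage = voltage, defocus = defocus,
                 spherical_aberration = spherical_aberration,
                 amplitude_contrast = amplitude_contrast,
                 mtf_cutoff = mtf_cutoff, pixel_size = pixel_size,
                 enabled = enabled),
            class = "optics_params")
}

#' Simulation configuration
#'
#' Defaults describe a desk-scale tomogram; the full-scale setting of the
#' reference experiments (600 x 600 x 300 voxels, 10,000 particles) is
#' reached by overriding `tomogram_shape` and `n_particles`.
#'
#' @param tilt_min,tilt_max tilt range in degrees (the +/-60 degree default
#'   is the canonical cryo-ET missing-wedge condition).
#' @param tilt_step tilt increment in degrees.
#' @param snr signal-to-noise ratio (variance of signal over variance of
#'   added noise in projection images); `Inf` for noiseless.
#' @param tomogram_shape integer length-3 volume shape in voxels.
#' @param n_particles number of particles to pack.
#' @param subtomo_size subtomogram cube edge in voxels.
#' @param optics an [optics_params] object.
#' @param voxel_size voxel edge in Angstrom.
#' @param seed integer seed from which all simulation sub-streams derive.
#' @return A `sim_config` object.
#' @export
sim_config <- function(tilt_min = -60, tilt_max = 60, tilt_step = 2,
                       snr = Inf, tomogram_shape = c(150, 150, 100),
                       n_particles = 100, subtomo_size = 32,
                       optics = optics_params(enabled = FALSE),
                       voxel_size = 10, seed = 0) {
  if (tilt_min >= tilt_max) stopf("tilt_min must be < tilt_max")
  if (tilt_step <= 0) stopf("tilt_step must be positive")
  if (!is.infinite(snr) && snr <= 0) stopf("snr must be positive or Inf")
  if (subtomo_size > min(tomogram_shape))
    stopf("subtomo_size exceeds the tomogram")
  structure(list(tilt_min = tilt_min, tilt_max = tilt_max,
                 tilt_step = tilt_step, snr = snr,
                 tomogram_shape = as.integer(tomogram_shape),
                 n_particles = as.integer(n_particles),
                 subtomo_size = as.integer(subtomo_size), optics = optics,
                 voxel_size = voxel_size, seed = as.integer(seed)),
            class = "sim_config")
}

tilt_series <- function(images, angles) {
  if (dim(images)[3] != length(angles))
    stopf("one image per angle required")
  if (any(diff(angles) <= 0)) stopf("angles must be strictly increasing")
  if (max(angles) - min(angles) >= 180) stopf("angle span must be < 180")
  structure(list(images = images, angles = angles), class = "tilt_series")
}

#' Project a volume into a single-axis tilt series
#'
#' Each image is the line integral of the volume along the beam direction
#' after tilting about the second (y) axis; at 0 degrees the projection is
#' exactly the sum over the z axis.
#'
#' @param volume numeric 3D array.
#' @param angles tilt angles in degrees, strictly increasing, inside
#'   (-90, 90).
#' @return A `tilt_series` (fields `images`, an H x W x n_angles array,
#'   and `angles`).
#' @export
project_tilt_series <- function(volume, angles) {
  if (any(angles <= -90 | angles >= 90))
    stopf("tilt angles must lie inside (-90, 90) degrees")
  imgs <- project_tilt_cpp(volume, dim(volume), as.numeric(angles))
  tilt_series(imgs, as.numeric(angles))
}

# CTF * MTF frequency-domain multiplier for an H x W image, in the same
# (wrapped) frequency layout as stats::fft.
ctf_mtf_filter <- function(H, W, optics) {
  V <- optics$voltage * 1e3
  lambda <- 12.2643 / sqrt(V * (1 + 0.978466e-6 * V))       # Angstrom
  dz <- optics$defocus * 1e4                                # um -> Angstrom
  cs <- optics$spherical_aberration * 1e7                   # mm -> Angstrom
  fx <- c(0:floor((H - 1) / 2), -(ceiling((H - 1) / 2):1)) / H
  fy <- c(0:floor((W - 1) / 2), -(ceiling((W - 1) / 2):1)) / W
  f2 <- outer(fx^2, fy^2, "+") / optics$pixel_size^2        # 1/A^2
  gamma <- pi * lambda * dz * f2 - (pi / 2) * cs * lambda^3 * f2^2
  A <- optics$amplitude_contrast
  ctf <- -(sqrt(1 - A^2) * sin(gamma) + A * cos(gamma))
  f_nyq <- 0.5 / optics$pixel_size
  mtf <- exp(-f2 / (2 * (optics$mtf_cutoff * f_nyq)^2))
  ctf * mtf
}

#' Convolve a tilt series with the electron-optical factors
#'
#' Multiplies every projection image in the frequency domain by the
#' contrast transfer function and a Gaussian modulation-transfer envelope,
#' which equals circular convolution with the corresponding point-spread
#' function.
#'
#' @param ts a `tilt_series`.
#' @param optics an [optics_params]; with `enabled = FALSE` the series is
#'   returned unchanged.
#' @return A `tilt_series`.
#' @export
apply_ctf_mtf <- function(ts, optics = optics_params()) {
  stopifnot(inherits(ts, "tilt_series"))
  if (!optics$enabled) return(ts)
  d <- dim(ts$images)
  filt <- ctf_mtf_filter(d[1], d[2], optics)
  out <- ts$images
  for (a in seq_len(d[3])) {
    F <- stats::fft(ts$images[, , a])
    out[, , a] <- Re(stats::fft(F * filt, inverse = TRUE)) / (d[1] * d[2])
  }
  tilt_series(out, ts$angles)
}

#' Add Gaussian noise to reach a target SNR
#'
#' SNR is defined as var(signal) / var(noise) per projection image; the
#' injected noise is zero-mean Gaussian with variance `var(image) / snr`.
#'
#' @param ts a `tilt_series`.
#' @param snr positive SNR, or `Inf` to return the input unchanged.
#' @param seed optional integer seed for a reproducible noise field.
#' @return A `tilt_series`.
#' @export
add_noise_to_snr <- function(ts, snr, seed = NULL) {
  stopifnot(inherits(ts, "tilt_series"))
  if (is.infinite(snr)) return(ts)
  if (snr <= 0) stopf("snr must be positive or Inf, got %g", snr)
  d <- dim(ts$images)
  out <- ts$images
  with_seed(seed, {
    for (a in seq_len(d[3])) {
      s2 <- stats::var(as.vector(ts$images[, , a]))
      out[, , a] <- ts$images[, , a] +
        rnorm(d[1] * d[2], sd = sqrt(s2 / snr))
    }
  })
  tilt_series(out, ts$angles)
}

#' Reconstruct a volume by weighted back-projection
#'
#' Applies a ramp filter to each projection along the axis perpendicular
#' to the tilt axis, then back-projects with the exact adjoint of the
#' projector. With a limited tilt range the reconstruction carries the
#' expected missing-wedge artifacts.
#'
#' @param ts a `tilt_series`.
#' @param shape length-3 output shape; the first two entries must match
#'   the projection image size.
#' @param filter `"ramp"` (default) or `"none"` (plain adjoint
#'   back-projection, used for adjointness checks).
#' @return Numeric 3D array.
#' @export
reconstruct_wbp <- function(ts, shape, filter = c("ramp", "none")) {
  stopifnot(inherits(ts, "tilt_series"))
  filter <- match.arg(filter)
  d <- dim(ts$images)
  if (d[1] != shape[1] || d[2] != shape[2])
    stopf("projection size %dx%d does not match target shape", d[1], d[2])
  nA <- d[3]
  if (nA == 1) warnf("reconstructing from a single projection is severely ill-posed")
  imgs <- ts$images
  if (filter == "ramp") {
    ramp <- abs(c(0:floor((d[1] - 1) / 2), -(ceiling((d[1] - 1) / 2):1)) / d[1])
    for (a in seq_len(nA)) {
      F <- stats::mvfft(imgs[, , a]) * ramp
      imgs[, , a] <- Re(stats::mvfft(F, inverse = TRUE)) / d[1]
    }
  }
  vol <- backproject_tilt_cpp(imgs, d, ts$angles, as.integer(shape[3]))
  vol * (pi / (2 * nA))
}

map_bounding_radius <- function(map) {
  grid <- if (inherits(map, "density_map")) map$grid else map
  idx <- which(grid > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0)
  c0 <- (dim(grid) - 1) / 2
  sqrt(max(rowSums(sweep(idx - 1, 2, c0)^2)))
}

#' Pack posed structures into a volume
#'
#' Places `n_particles` randomly posed copies of the class maps at uniform
#' random positions, using bounding-sphere rejection sampling (up to 1000
#' retries per particle) so that no two particles overlap. Classes are
#' assigned uniformly at random.
#'
#' @param maps list of [density_map] objects (one per class).
#' @param n_particles number of particles to place.
#' @param shape length-3 tomogram shape in voxels.
#' @param seed integer seed.
#' @param margin minimum clearance of particle centres from the volume
#'   faces in voxels (at least the bounding radius is always enforced; set
#'   to half the subtomogram size so that every particle can be cropped).
#' @return List with `volume` (3D array) and `placements` (list of
#'   records: `class`, `map_index`, `center` (1-based voxel coordinates),
#'   `pose`).
#' @export
pack_volume <- function(maps, n_particles, shape, seed = NULL, margin = 0) {
  shape <- as.integer(shape)
  vol <- array(0, dim = shape)
  placements <- list()
  if (n_particles == 0) return(list(volume = vol, placements = placements))
  radii <- vapply(maps, map_bounding_radius, numeric(1))
  if (any(2 * radii + 1 > min(shape)))
    stopf("a class map does not fit inside the tomogram")
  with_seed(seed, {
    centers <- matrix(0, nrow = 0, ncol = 3)
    rads <- numeric(0)
    for (p in seq_len(n_particles)) {
      ci <- sample.int(length(maps), 1)
      r <- radii[ci]
      clear <- max(r, margin)   # clearance of the centre from every face
      lo <- clear + 1
      hi <- shape - clear
      if (any(hi < lo)) stopf("margin %g leaves no room to place particles", margin)
      placed <- FALSE
      for (try in seq_len(1000)) {
        cen <- runif(3, lo, hi)
        if (nrow(centers) > 0 &&
            any(rowSums(sweep(centers, 2, cen)^2) < (rads + r)^2)) next
        placed <- TRUE
        break
      }
      if (!placed) {
        warnf("placed only %d of %d particles after max retries",
              length(placements), n_particles)
        break
      }
      centers <- rbind(centers, cen)
      rads <- c(rads, r)
      po <- random_pose(max_shift = 0)
      g <- dim(maps[[ci]]$grid)[1]
      cint <- round(cen)
      frac <- cen - cint
      posed <- resample_affine_cpp(maps[[ci]]$grid, dim(maps[[ci]]$grid),
                                   po$rotation, frac)
      half <- g %/% 2
      i0 <- cint[1] - half; j0 <- cint[2] - half; k0 <- cint[3] - half
      is <- max(1, i0 + 1):min(shape[1], i0 + g)
      js <- max(1, j0 + 1):min(shape[2], j0 + g)
      ks <- max(1, k0 + 1):min(shape[3], k0 + g)
      vol[is, js, ks] <- vol[is, js, ks] +
        posed[is - i0, js - j0, ks - k0]
      placements[[length(placements) + 1]] <- list(
        class = maps[[ci]]$name, map_index = ci, center = as.numeric(cen),
        pose = pose(po$rotation, frac))
    }
  })
  list(volume = vol, placements = placements)
}

#' Extract subtomograms and ground-truth masks from a tomogram
#'
#' Crops a cube of side `subtomo_size` around each placement whose full
#' cube lies inside the tomogram (out-of-bounds placements are skipped and
#' counted). The ground-truth mask is the support of the identically posed
#' source map, cropped the same way.
#'
#' @param tomogram numeric 3D array.
#' @param placements placement list from [pack_volume()].
#' @param subtomo_size even cube edge in voxels.
#' @param gt_maps the class [density_map] list given to [pack_volume()].
#' @param snr SNR annotation stored on each record.
#' @return List of `subtomo_record` objects (fields `volume`,
#'   `class_label`, `gt_mask`, `pose`, `snr`). The number of skipped
#'   placements is attached as attribute `n_skipped`.
#' @export
extract_subtomograms <- function(tomogram, placements, subtomo_size,
                                 gt_maps, snr = Inf) {
  if (subtomo_size %% 2 != 0) stopf("subtomo_size must be even")
  shape <- dim(tomogram)
  half <- subtomo_size %/% 2
  records <- list()
  skipped <- 0L
  for (pl in placements) {
    cint <- round(pl$center)
    i0 <- cint[1] - half; j0 <- cint[2] - half; k0 <- cint[3] - half
    if (i0 < 0 || j0 < 0 || k0 < 0 || i0 + subtomo_size > shape[1] ||
        j0 + subtomo_size > shape[2] || k0 + subtomo_size > shape[3]) {
      skipped <- skipped + 1L
      next
    }
    volume <- tomogram[i0 + seq_len(subtomo_size),
                       j0 + seq_len(subtomo_size),
                       k0 + seq_len(subtomo_size)]
    src <- gt_maps[[pl$map_index]]
    posed <- resample_affine_cpp(src$grid, dim(src$grid),
                                 pl$pose$rotation, pl$pose$translation)
    g <- dim(src$grid)[1]
    mask <- array(FALSE, rep(subtomo_size, 3))
    # centre the posed map's support in the subtomogram cube
    off <- (subtomo_size - g) %/% 2
    gs <- max(1, 1 - off):min(g, subtomo_size - off)
    mask[gs + off, gs + off, gs + off] <- posed[gs, gs, gs] > 0
    records[[length(records) + 1]] <- structure(
      list(volume = volume, class_label = pl$class, gt_mask = mask,
           pose = pl$pose, snr = snr),
      class = "subtomo_record")
  }
  attr(records, "n_skipped") <- skipped
  records
}

#' Run the full simulation pipeline and build a class-split dataset
#'
#' Packs the class maps into a tomogram, projects the tilt series, applies
#' the optical factors, adds noise to the configured SNR, reconstructs by
#' weighted back-projection, extracts subtomograms, and splits the classes
#' (not the records) into train and test sets, so that test classes are
#' never seen in training.
#'
#' @param config a [sim_config].
#' @param class_maps list of [density_map] objects, at least 2.
#' @param n_train_classes number of classes assigned to the training
#'   split; the remainder form the test split.
#' @return A `subtomo_dataset`: list with `records`, `classes`, `split`
#'   (named character vector `"train"`/`"test"` per class), `config`,
#'   `config_hash`, and `manifest` (data frame).
#' @export
build_dataset <- function(config, class_maps, n_train_classes) {
  stopifnot(inherits(config, "sim_config"))
  if (length(class_maps) < 2) stopf("need at least 2 classes")
  if (n_train_classes < 1 || n_train_classes >= length(class_maps))
    stopf("n_train_classes must leave at least one class in each split (got %d of %d classes)",
          n_train_classes, length(class_maps))
  seed <- config$seed
  packed <- pack_volume(class_maps, config$n_particles,
                        config$tomogram_shape,
                        seed = substream_seed(seed, "pack"),
                        margin = config$subtomo_size / 2)
  angles <- seq(config$tilt_min, config$tilt_max, by = config$tilt_step)
  ts <- project_tilt_series(packed$volume, angles)
  ts <- apply_ctf_mtf(ts, config$optics)
  ts <- add_noise_to_snr(ts, config$snr,
                         seed = substream_seed(seed, "noise"))
  tomo <- reconstruct_wbp(ts, config$tomogram_shape)
  records <- extract_subtomograms(tomo, packed$placements,
                                  config$subtomo_size, class_maps,
                                  snr = config$snr)
  classes <- vapply(class_maps, function(m) m$name, character(1))
  split <- c(rep("train", n_train_classes),
             rep("test", length(classes) - n_train_classes))
  names(split) <- classes
  manifest <- data.frame(
    record = seq_along(records),
    class = vapply(records, function(r) r$class_label, character(1)),
    snr = config$snr,
    stringsAsFactors = FALSE)
  manifest$split <- unname(split[manifest$class])
  structure(list(records = records, classes = classes, split = split,
                 config = config, config_hash = config_hash(config),
                 manifest = manifest),
            class = "subtomo_dataset")
}

#' @export
print.subtomo_dataset <- function(x, ...) {
  cat(sprintf("<subtomo_dataset> %d records, %d classes (%d train / %d test), SNR %s\n",
              length(x$records), length(x$classes),
              sum(x$split == "train"), sum(x$split == "test"),
              format(x$config$snr)))
  print(table(x$manifest$class, x$manifest$split))
  invisible(x)
}

# records of one split as a sub-dataset
dataset_split <- function(dataset, which = c("train", "test")) {
  which <- match.arg(which)
  keep <- dataset$manifest$split == which
  list(records = dataset$records[keep],
       classes = names(dataset$split)[dataset$split == which])
}
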