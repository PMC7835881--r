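# Minimal MRC2014 volume I/O (little-endian, modes 0/1/2/6). MRC stores
# the x index fastest, which matches R's column-major (H, W, D) arrays, so
# no axis permutation is needed.

#' Write a volume to an MRC2014 file
#'
#' Data are written as 32-bit floats (mode 2) with the voxel size recorded
#' in the cell dimensions.
#'
#' @param volume numeric 3D array.
#' @param path output path.
#' @param voxel_size voxel edge in Angstrom (scalar or length 3).
#' @return `path`, invisibly.
#' @export
write_mrc <- function(volume, path, voxel_size = 1) {
  if (!is.array(volume) || length(dim(volume)) != 3)
    stopf("volume must be a 3D array")
  d <- dim(volume)
  vs <- rep(as.numeric(voxel_size), length.out = 3)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  v <- as.numeric(volume)
  wi(d)                      # nx ny nz
  wi(2)                      # mode 2: float32
  wi(c(0, 0, 0))             # nxstart nystart nzstart
  wi(d)                      # mx my mz
  wf(d * vs)                 # cella
  wf(c(90, 90, 90))          # cellb
  wi(c(1, 2, 3))             # mapc mapr maps
  wf(c(min(v), max(v), mean(v)))  # dmin dmax dmean
  wi(1)                      # ispg: volume
  wi(0)                      # nsymbt
  wi(rep(0, 25))             # extra
  wf(c(0, 0, 0))             # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(v))           # rms
  wi(0)                      # nlabl
  writeBin(raw(800), con)    # labels
  writeBin(v, con, size = 4, endian = "little")
  invisible(path)
}

#' Read a volume from an MRC2014 file
#'
#' @param path path to an MRC file.
#' @return List with `volume` (3D array) and `voxel_size` (Angstrom per
#'   voxel; mean of the three axes, with a warning when anisotropic).
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  if (any(d <= 0) || length(d) < 3)
    stopf("malformed MRC header in %s: bad dimensions at offset 0", path)
  ri(3)                       # nxstart..
  m <- ri(3)                  # mx my mz
  cella <- rf(3)
  invisible(rf(3)); invisible(ri(3)); invisible(rf(3))
  invisible(ri(1))
  nsymbt <- ri(1)
  seek(con, 1024 + nsymbt)
  n <- prod(d)
  v <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n, size = 2, endian = "little")),
    "2" = rf(n),
    "6" = as.numeric(readBin(con, "integer", n, size = 2, signed = FALSE,
                             endian = "little")),
    stopf("unsupported MRC mode %d in %s", mode, path))
  if (length(v) < n)
    stopf("malformed MRC file %s: expected %d voxels, read %d at offset %d",
          path, n, length(v), 1024 + nsymbt)
  vs <- ifelse(m > 0, cella / m, 1)
  if (max(vs) - min(vs) > 1e-4 * max(vs))
    warnf("anisotropic voxel sizes in %s: %s", path,
          paste(signif(vs, 4), collapse = ", "))
  list(volume = array(v, dim = d), voxel_size = mean(vs))
}
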