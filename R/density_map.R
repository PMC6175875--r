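#' 3D density map
#'
#' The universal volume container of the pipeline: a 3D numeric array with an
#' isotropic voxel size in Angstrom and an origin offset (Angstrom) of voxel
#' `(0,0,0)`. Tomograms, subvolumes, references, averages and difference maps
#' are all `density_map` objects.
#'
#' @param data 3D numeric array, finite values, each dimension >= 2.
#' @param voxel_size voxel edge length in Angstrom (> 0).
#' @param origin numeric length-3, Angstrom offset of voxel `(0,0,0)`.
#' @return A `density_map` object.
#' @export
density_map <- function(data, voxel_size = 1, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (any(dim(data) < 2L))
    stop("grid dimensions must be >= 2 in each axis", call. = FALSE)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number", call. = FALSE)
  if (!all(is.finite(data)))
    stop("density values must be finite", call. = FALSE)
  structure(
    list(data = data, voxel_size = as.numeric(voxel_size),
         origin = as.numeric(origin)),
    class = "density_map"
  )
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<density_map> %d x %d x %d voxels @ %.4g A/voxel\n",
              d[1], d[2], d[3], x$voxel_size))
  cat(sprintf("  range [%.4g, %.4g], mean %.4g\n",
              min(x$data), max(x$data), mean(x$data)))
  invisible(x)
}

#' @export
dim.density_map <- function(x) dim(x$data)

is_density_map <- function(x) inherits(x, "density_map")

as_map_like <- function(data, template) {
  density_map(data, voxel_size = template$voxel_size, origin = template$origin)
}

#' Read an MRC2014 density map
#'
#' Reads mode-2 (float32) MRC files written by this package or by standard
#' cryo-EM software. The voxel size is recovered from the cell dimensions.
#'
#' @param path file path.
#' @return A [density_map()].
#' @export
read_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 1024L)
  if (length(hdr_raw) < 1024L)
    stop("malformed MRC header: file shorter than 1024-byte header", call. = FALSE)
  ints <- readBin(hdr_raw, "integer", n = 10L, size = 4L, endian = "little")
  nx <- ints[1]; ny <- ints[2]; nz <- ints[3]; mode <- ints[4]
  if (mode != 2L)
    stop(sprintf("malformed MRC header: mode %d unsupported (expect 2, float32)",
                 mode), call. = FALSE)
  if (nx < 1 || ny < 1 || nz < 1)
    stop(sprintf("malformed MRC header: bad dimensions nx=%d ny=%d nz=%d",
                 nx, ny, nz), call. = FALSE)
  mxyz <- readBin(hdr_raw[29:40], "integer", n = 3L, size = 4L, endian = "little")
  cella <- readBin(hdr_raw[41:52], "numeric", n = 3L, size = 4L, endian = "little")
  nsymbt <- readBin(hdr_raw[93:96], "integer", n = 1L, size = 4L, endian = "little")
  orig <- readBin(hdr_raw[197:208], "numeric", n = 3L, size = 4L, endian = "little")
  if (nsymbt > 0) readBin(con, "raw", n = nsymbt)
  n_expect <- as.numeric(nx) * ny * nz
  vals <- readBin(con, "numeric", n = n_expect, size = 4L, endian = "little")
  if (length(vals) < n_expect)
    stop(sprintf(
      "malformed MRC payload: expected %d voxels (%d bytes), read %d",
      n_expect, 4 * n_expect, length(vals)), call. = FALSE)
  vs <- if (mxyz[1] > 0 && cella[1] > 0) cella[1] / mxyz[1] else 1
  density_map(array(vals, dim = c(nx, ny, nz)), voxel_size = vs, origin = orig)
}

#' Write an MRC2014 density map
#'
#' Writes mode-2 (float32) little-endian MRC2014. Round-trips written by
#' [read_map()] preserve values bit-exactly at float32 precision.
#'
#' @param map a [density_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(is_density_map(map))
  d <- dim(map$data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(d)                      # nx ny nz
  wi(2L)                     # mode 2: float32
  wi(c(0L, 0L, 0L))          # nxstart
  wi(d)                      # mx my mz
  wf(d * map$voxel_size)     # cella
  wf(c(90, 90, 90))          # cellb
  wi(c(1L, 2L, 3L))          # mapc mapr maps
  wf(c(min(map$data), max(map$data), mean(map$data)))
  wi(c(0L, 0L))              # ispg, nsymbt
  wi(integer(25))            # extra (incl. exttyp/nversion slots left 0)
  wf(map$origin)             # origin (MRC2014)
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst: little-endian
  wf(stats::sd(map$data))    # rms
  wi(0L)                     # nlabl
  writeBin(raw(800L), con)   # labels
  writeBin(as.numeric(map$data), con, size = 4L, endian = "little")
  invisible(path)
}

#' Write / read a tilt-series stack as MRC
#'
#' A tilt series is stored as an `nx * ny * ntilt` MRC stack; per-tilt
#' metadata travels separately (see [write_tilt_metadata()]).
#' @param images 3D array (`nx * ny * ntilt`).
#' @param pixel_size Angstrom per pixel.
#' @param path file path.
#' @return `path` invisibly for the writer; a list with `images` (array) and
#'   `pixel_size` for the reader.
#' @export
write_tilt_stack <- function(images, pixel_size, path) {
  write_map(density_map(images, voxel_size = pixel_size), path)
}

#' @rdname write_tilt_stack
#' @export
read_tilt_stack <- function(path) {
  m <- read_map(path)
  list(images = m$data, pixel_size = m$voxel_size)
}

#' Bin a density map by integer block averaging
#'
#' @param map a [density_map()].
#' @param factor integer binning factor (1 = no-op).
#' @return A [density_map()] with `factor`-fold larger voxels.
#' @export
bin_map <- function(map, factor) {
  stopifnot(is_density_map(map), factor >= 1)
  factor <- as.integer(factor)
  if (factor == 1L) return(map)
  d <- dim(map$data)
  nd <- d %/% factor
  if (any(nd < 2L)) stop("binning factor too large for this map", call. = FALSE)
  x <- map$data[seq_len(nd[1] * factor), seq_len(nd[2] * factor),
                seq_len(nd[3] * factor), drop = FALSE]
  dim(x) <- c(factor, nd[1], factor, nd[2], factor, nd[3])
  binned <- apply(x, c(2, 4, 6), mean)
  density_map(binned, voxel_size = map$voxel_size * factor, origin = map$origin)
}
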