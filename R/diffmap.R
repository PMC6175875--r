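#' Pseudo-atomic model
#'
#' A pre-positioned coarse model: weighted Gaussian scattering centers.
#' Stands in for a fitted atomic model when generating model-derived maps.
#'
#' @param centers numeric `n x 3` matrix of Angstrom coordinates.
#' @param weights per-center mass (> 0); recycled.
#' @param label component name(s); recycled.
#' @return A tibble with columns `x`, `y`, `z`, `weight`, `label` of class
#'   `pseudo_model`.
#' @export
pseudo_model <- function(centers, weights = 1, label = "model") {
  centers <- as.matrix(centers)
  if (nrow(centers) < 1 || ncol(centers) != 3)
    stop("centers must be an n x 3 matrix with n >= 1", call. = FALSE)
  if (any(weights <= 0)) stop("weights must be > 0", call. = FALSE)
  out <- tibble::tibble(x = centers[, 1], y = centers[, 2], z = centers[, 3],
                        weight = rep_len(weights, nrow(centers)),
                        label = rep_len(label, nrow(centers)))
  structure(out, class = c("pseudo_model", class(out)))
}

#' Read / write pseudo-models
#'
#' TSV with columns `x`, `y`, `z` (Angstrom), `weight`, `label`.
#' @param model a [pseudo_model()].
#' @param path file path.
#' @return The model (reader) or `path` invisibly (writer).
#' @export
write_model <- function(model, path) {
  readr::write_tsv(model, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("x", "y", "z", "weight", "label")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0)
    stop("model table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  pseudo_model(cbind(tab$x, tab$y, tab$z), tab$weight, tab$label)
}

#' Render a model-derived map
#'
#' Sums a Gaussian kernel per scattering center (real-space sd
#' `lowpass / (pi sqrt(2))`, so the kernel's Fourier amplitude falls to
#' about 1/e at the stated resolution), then applies a hard low-pass at
#' `lowpass`. Integrated density is proportional to the summed weights.
#'
#' @param model a [pseudo_model()]; coordinates in Angstrom.
#' @param shape output dimensions in voxels.
#' @param voxel_size Angstrom per voxel.
#' @param lowpass resolution in Angstrom (default 5; must be
#'   >= 2 voxel).
#' @return A [density_map()].
#' @export
model_to_map <- function(model, shape, voxel_size, lowpass = 5) {
  if (lowpass < 2 * voxel_size)
    stop("lowpass below the Nyquist limit of this grid", call. = FALSE)
  pos_vox <- cbind(model$x, model$y, model$z) / voxel_size
  bad <- which(pos_vox[, 1] < 0 | pos_vox[, 1] > shape[1] - 1 |
               pos_vox[, 2] < 0 | pos_vox[, 2] > shape[2] - 1 |
               pos_vox[, 3] < 0 | pos_vox[, 3] > shape[3] - 1)
  if (length(bad) > 0)
    stop("model centers outside the box: rows ",
         paste(bad, collapse = ", "), call. = FALSE)
  sd_A <- lowpass / (pi * sqrt(2))
  sd_vox <- sd_A / voxel_size
  vol <- array(0, shape)
  kr <- ceiling(4 * sd_vox)
  kn <- 2 * kr + 1
  co <- seq(-kr, kr)
  kern <- exp(-0.5 * (outer(outer(co^2, co^2, `+`), co^2, `+`)) / sd_vox^2)
  kern <- kern / sum(kern)
  kd <- as.integer(c(kn, kn, kn))
  for (i in seq_len(nrow(model))) {
    cpp_stamp_kernel(vol, as.integer(shape), as.numeric(kern), kd,
                     as.numeric(diag(3)), pos_vox[i, ], model$weight[i],
                     FALSE)
  }
  m <- density_map(vol, voxel_size = voxel_size)
  lowpass_map(m, lowpass, edge_frac = 0)
}

#' Support mask of a model-derived map
#'
#' Threshold at a fraction of the map maximum, dilated by a few voxels —
#' the normalization region for [normalize_map()].
#'
#' @param model_map a [density_map()].
#' @param threshold_frac fraction of the maximum.
#' @param dilate_vox dilation radius in voxels.
#' @return 0/1 array.
#' @export
model_support_mask <- function(model_map, threshold_frac = 0.1,
                               dilate_vox = 5) {
  core <- model_map$data >= threshold_frac * max(model_map$data)
  d <- dim(core)
  lab <- array(as.numeric(core), d)
  # dilation via Gaussian blur thresholded at the radius-equivalent level
  sm <- lowpass_map(lab, cutoff_A = 2 * dilate_vox * model_map$voxel_size,
                    voxel_size = model_map$voxel_size)
  out <- array(0, d)
  out[core | sm > 0.05] <- 1
  out
}

#' Normalize a map within a mask
#'
#' Affine rescaling to zero mean and unit standard deviation over the
#' masked region (weights in `[0, 1]` allowed).
#'
#' @param map a [density_map()].
#' @param mask region mask (array or [density_map()]); `NULL` uses the
#'   whole box.
#' @return Normalized [density_map()].
#' @export
normalize_map <- function(map, mask = NULL) {
  stopifnot(is_density_map(map))
  m <- if (is.null(mask)) array(1, dim(map$data))
       else if (is_density_map(mask)) mask$data else mask
  w <- sum(m)
  mu <- sum(map$data * m) / w
  v <- sum((map$data - mu)^2 * m) / w
  if (v <= 0) stop("zero variance within the mask", call. = FALSE)
  as_map_like((map$data - mu) / sqrt(v), map)
}

#' Normalized difference map
#'
#' `(em - model)` convolved with an isotropic Gaussian (default sd 3
#' voxels). Both inputs should already be normalized on the same mask (see
#' [normalize_map()]). Swapping the inputs negates the output exactly.
#'
#' @param em_map,model_map [density_map()]s of identical shape.
#' @param gaussian_sd filter sd in voxels.
#' @return A [density_map()] of the filtered difference.
#' @export
difference_map <- function(em_map, model_map, gaussian_sd = 3) {
  stopifnot(is_density_map(em_map), is_density_map(model_map))
  if (!all(dim(em_map$data) == dim(model_map$data)))
    stop("maps have mismatched shapes", call. = FALSE)
  diff <- em_map$data - model_map$data
  if (gaussian_sd > 0) {
    d <- dim(diff)
    # Gaussian transfer in Fourier space (sd in voxels -> cycles/voxel)
    gx <- exp(-2 * pi^2 * gaussian_sd^2 * fft_freq(d[1])^2)
    gy <- exp(-2 * pi^2 * gaussian_sd^2 * fft_freq(d[2])^2)
    gz <- exp(-2 * pi^2 * gaussian_sd^2 * fft_freq(d[3])^2)
    h <- outer(outer(gx, gy), gz)
    diff <- Re(ifftn(fftn(diff) * h))
  }
  as_map_like(diff, em_map)
}

#' Detect difference-density blobs
#'
#' Thresholds the difference map at `threshold_sigmas` times its standard
#' deviation, labels 26-connected components, drops those below
#' `min_voxels`, and returns them sorted by descending volume.
#'
#' @param diff a [density_map()] difference map.
#' @param threshold_sigmas threshold in units of the map sd.
#' @param min_voxels minimum blob volume in voxels.
#' @return Tibble with `label`, `centroid_x/y/z` (voxels), `volume`
#'   (voxels), `peak`; zero rows when nothing passes.
#' @export
detect_blobs <- function(diff, threshold_sigmas = 3, min_voxels = 20) {
  stopifnot(is_density_map(diff))
  d <- dim(diff$data)
  thr <- threshold_sigmas * stats::sd(diff$data)
  maskv <- diff$data > thr
  lab <- cpp_label_components(as.logical(maskv), as.integer(d))
  lab <- array(lab, d)
  if (max(lab) == 0)
    return(tibble::tibble(label = integer(0), centroid_x = numeric(0),
                          centroid_y = numeric(0), centroid_z = numeric(0),
                          volume = integer(0), peak = numeric(0)))
  idx <- which(lab > 0)
  ai <- arrayInd(idx, d)
  tab <- tibble::tibble(lab = lab[idx],
                        x = ai[, 1] - 1, y = ai[, 2] - 1, z = ai[, 3] - 1,
                        v = diff$data[idx]) |>
    dplyr::group_by(.data$lab) |>
    dplyr::summarise(centroid_x = mean(.data$x), centroid_y = mean(.data$y),
                     centroid_z = mean(.data$z),
                     volume = dplyr::n(), peak = max(.data$v)) |>
    dplyr::filter(.data$volume >= min_voxels) |>
    dplyr::arrange(dplyr::desc(.data$volume))
  tab$label <- seq_len(nrow(tab))
  tab[, c("label", "centroid_x", "centroid_y", "centroid_z", "volume",
          "peak")]
}
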