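#' Particle tables
#'
#' One row per subtomogram. The canonical columns are:
#' \describe{
#'   \item{tomo_id, tube_id}{identifiers (character).}
#'   \item{x, y, z}{position in 0-based, continuous voxel coordinates.}
#'   \item{phi, theta, psi}{intrinsic ZYZ Euler angles in degrees (see
#'     [euler()]).}
#'   \item{shift_x, shift_y, shift_z}{residual offset in Angstrom.}
#'   \item{cc}{raw constrained cross-correlation in `[-1, 1]`.}
#'   \item{cc_weighted}{curated score after azimuth-dependent weighting.}
#'   \item{half_set}{`"A"`, `"B"` or `"unassigned"`.}
#' }
#' Unknown extra columns are carried along untouched.
#'
#' @param n number of blank records.
#' @return A tibble with the canonical columns.
#' @export
particle_table <- function(n = 0) {
  tibble::tibble(
    tomo_id = rep("tomo1", n), tube_id = rep("tube1", n),
    x = numeric(n), y = numeric(n), z = numeric(n),
    phi = numeric(n), theta = numeric(n), psi = numeric(n),
    shift_x = numeric(n), shift_y = numeric(n), shift_z = numeric(n),
    cc = rep(NA_real_, n), cc_weighted = rep(NA_real_, n),
    half_set = rep("unassigned", n)
  )
}

particle_columns <- function() {
  c("tomo_id", "tube_id", "x", "y", "z", "phi", "theta", "psi",
    "shift_x", "shift_y", "shift_z", "cc", "cc_weighted", "half_set")
}

validate_particles <- function(table, tomo_dims = NULL) {
  missing_cols <- setdiff(particle_columns(), names(table))
  if (length(missing_cols) > 0)
    stop("particle table missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  cc <- table$cc[!is.na(table$cc)]
  if (any(cc < -1 | cc > 1))
    stop("cc values must lie in [-1, 1]", call. = FALSE)
  if (!all(table$half_set %in% c("A", "B", "unassigned")))
    stop("half_set must be one of 'A', 'B', 'unassigned'", call. = FALSE)
  if (!is.null(tomo_dims)) {
    bad <- table$x < 0 | table$x > tomo_dims[1] - 1 |
           table$y < 0 | table$y > tomo_dims[2] - 1 |
           table$z < 0 | table$z > tomo_dims[3] - 1
    if (any(bad))
      stop(sum(bad), " particle position(s) outside tomogram bounds",
           call. = FALSE)
  }
  invisible(table)
}

#' Read / write particle tables
#'
#' Plain tab-separated text with a fixed header (see [particle_table()] for
#' the schema). Round-trips are lossless and unknown columns are preserved.
#'
#' @param path file path.
#' @param table a particle tibble.
#' @return `read_particles()` returns a validated tibble;
#'   `write_particles()` returns `path` invisibly.
#' @export
read_particles <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  for (col in intersect(c("tomo_id", "tube_id", "half_set"), names(tab)))
    tab[[col]] <- as.character(tab[[col]])
  validate_particles(tab)
  tab
}

#' @rdname read_particles
#' @export
write_particles <- function(table, path) {
  validate_particles(table)
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}

euler_of_row <- function(row) euler(row$phi, row$theta, row$psi)

set_euler_cols <- function(table, eulers) {
  table$phi <- vapply(eulers, function(e) e[["phi"]], numeric(1))
  table$theta <- vapply(eulers, function(e) e[["theta"]], numeric(1))
  table$psi <- vapply(eulers, function(e) e[["psi"]], numeric(1))
  table
}

#' Split particles into independent half sets
#'
#' Random assignment to halves A and B, stratified by tube so both halves
#' see every tube, with a fixed seed for reproducibility.
#'
#' @param table particle tibble.
#' @param seed integer seed governing the split.
#' @return The table with `half_set` filled in.
#' @export
split_half_sets <- function(table, seed = 1) {
  validate_particles(table)
  with_seed(seed, {
    table |>
      dplyr::group_by(.data$tube_id) |>
      dplyr::mutate(half_set = {
        n <- dplyr::n()
        lab <- rep(c("A", "B"), length.out = n)
        sample(lab, n)
      }) |>
      dplyr::ungroup()
  })
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
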