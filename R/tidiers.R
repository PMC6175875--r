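#' Tidy an FSC curve
#'
#' @param x an `fsc_curve` from [fsc()].
#' @param ... unused.
#' @return A plain tibble with `shell`, `freq`, `resolution`, `fsc`,
#'   `n_terms` and the curve `variant`.
#' @export
tidy.fsc_curve <- function(x, ...) {
  tibble::tibble(shell = x$shell, freq = x$freq,
                 resolution = ifelse(x$freq > 0, 1 / x$freq, Inf),
                 fsc = x$fsc, n_terms = x$n_terms,
                 variant = attr(x, "variant"))
}

#' Summarize an FSC curve
#'
#' @param x an `fsc_curve`.
#' @param ... unused.
#' @return One-row tibble with the 0.143 and 0.5 resolutions and whether
#'   each threshold was crossed.
#' @export
glance.fsc_curve <- function(x, ...) {
  r143 <- resolution_at(x, 0.143)
  r50 <- resolution_at(x, 0.5)
  tibble::tibble(resolution_0143 = r143$resolution,
                 crossed_0143 = r143$crossed,
                 resolution_05 = r50$resolution,
                 crossed_05 = r50$crossed,
                 n_shells = nrow(x))
}

#' Plot an FSC curve
#'
#' @param object an `fsc_curve`.
#' @param thresholds horizontal reference lines.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.fsc_curve <- function(object, thresholds = c(0.143, 0.5), ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$fsc)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_hline(yintercept = thresholds, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = expression(spatial~frequency~(ring(A)^-1)),
                  y = "FSC",
                  title = attr(object, "variant")) +
    ggplot2::theme_minimal()
}

#' Plot a mask-corrected FSC table
#'
#' @param object an `fsc_table` from [mask_corrected_fsc()].
#' @param ... unused.
#' @return A ggplot with all four curve variants.
#' @export
autoplot.fsc_table <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            c("unmasked", "masked", "randomized",
                              "corrected"),
                            names_to = "variant", values_to = "fsc")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$fsc,
                                   colour = .data$variant)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = 0.143, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = expression(spatial~frequency~(ring(A)^-1)),
                  y = "FSC") +
    ggplot2::theme_minimal()
}

#' Central slice of a density map
#'
#' @param map a [density_map()].
#' @param axis slicing axis (1, 2 or 3).
#' @param index slice index (default: center).
#' @return A ggplot raster of the slice.
#' @export
plot_slice <- function(map, axis = 3, index = NULL) {
  stopifnot(is_density_map(map))
  d <- dim(map$data)
  if (is.null(index)) index <- ceiling(d[axis] / 2)
  sl <- switch(axis,
               map$data[index, , ],
               map$data[, index, ],
               map$data[, , index])
  df <- tidyr::expand_grid(i = seq_len(nrow(sl)), j = seq_len(ncol(sl)))
  df$value <- as.numeric(sl)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Plot particle curation scores against tube azimuth
#'
#' Visualizes the missing-wedge CC bias and its removal: raw and weighted
#' scores against the azimuthal Euler angle phi.
#'
#' @param table particle tibble with `cc` (and optionally `cc_weighted`).
#' @return A ggplot.
#' @export
plot_cc_phi <- function(table) {
  df <- tidyr::pivot_longer(
    table[, c("phi", "cc", "cc_weighted")],
    c("cc", "cc_weighted"), names_to = "score", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phi, y = .data$value,
                                   colour = .data$score)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "phi (degrees)", y = "CC") +
    ggplot2::theme_minimal()
}
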