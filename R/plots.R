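# ggplot2 views of the main result objects.

#' Plot an axial slice of a volume or mask
#'
#' @param v an [nv_volume] or [nv_mask].
#' @param z slice index (default: middle slice).
#' @param mask optional [nv_mask] overlaid as contour-less highlight.
#' @return A ggplot object.
#' @export
plot_slice <- function(v, z = NULL, mask = NULL) {
  stopifnot(inherits(v, "nv_volume"))
  d <- dim(v$data)
  if (is.null(z)) z <- ceiling(d[3] / 2)
  df <- data.frame(
    x = rep(seq_len(d[1]), d[2]),
    y = rep(seq_len(d[2]), each = d[1]),
    intensity = as.vector(v$data[, , z] * 1.0))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("axial slice z = %d", z)) +
    ggplot2::theme_minimal()
  if (!is.null(mask)) {
    dm <- data.frame(df[, 1:2], m = as.vector(mask$data[, , z]))
    p <- p + ggplot2::geom_raster(
      data = dm[dm$m, , drop = FALSE],
      ggplot2::aes(x = .data$x, y = .data$y), fill = "red", alpha = 0.4,
      inherit.aes = FALSE)
  }
  p
}

#' Plot an inflation trace
#'
#' Enclosed volume and frozen-vertex fraction against iteration, the audit
#' view of [inflate] convergence.
#'
#' @param trace tibble from `inflate(..., trace = TRUE)` (attribute
#'   `"trace"`) or `negative_volume()$trace`.
#' @return A ggplot object.
#' @export
plot_inflation_trace <- function(trace) {
  stopifnot(all(c("iteration", "volume", "frozen_fraction") %in% names(trace)))
  vmax <- max(trace$volume)
  ggplot2::ggplot(trace, ggplot2::aes(x = .data$iteration)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$volume, colour = "volume (mm^3)")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$frozen_fraction * vmax,
                                    colour = "frozen fraction")) +
    ggplot2::scale_y_continuous(
      sec.axis = ggplot2::sec_axis(~ . / vmax, name = "frozen fraction")) +
    ggplot2::labs(x = "iteration", y = "enclosed volume (mm^3)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.nv_symmetry_report <- function(object, ...) {
  df <- data.frame(side = c("left", "right"),
                   area = c(object$S_L, object$S_R),
                   volume = c(object$V_L, object$V_R))
  dl <- data.frame(side = rep(df$side, 2),
                   quantity = rep(c("surface area (mm^2)", "volume (mm^3)"),
                                  each = 2),
                   value = c(df$area, df$volume))
  ggplot2::ggplot(dl, ggplot2::aes(x = .data$side, y = .data$value,
                                   fill = .data$side)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~ .data$quantity, scales = "free_y") +
    ggplot2::labs(
      title = sprintf("S_LR = %.3f, H_LR = %.2f mm%s", object$S_LR,
                      object$H_LR,
                      if (object$asymmetric) " (flagged asymmetric)" else ""),
      x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.nv_phantom <- function(object, ...) {
  plot_slice(object$volume, mask = object$gap_mask)
}
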