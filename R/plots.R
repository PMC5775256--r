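#' Plot a feature-centred methylation profile
#'
#' @param object A `meth_profile` from [profile_at_features()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot meth_profile
#' @export
autoplot.meth_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$offset, .data$level)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(
      x = "distance from feature centre (bp)",
      y = "weighted methylation level"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a TSS-distance enrichment curve with its control band
#'
#' @param object An `enrichment_curve`, optionally carrying
#'   band_lower/band_upper columns from [matched_control_band()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot enrichment_curve
#' @export
autoplot.enrichment_curve <- function(object, ...) {
  d <- as_tibble(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$bin_mid / 1e3, .data$score))
  if (all(c("band_lower", "band_upper") %in% names(d))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$band_lower, ymax = .data$band_upper),
      fill = "grey80"
    )
  }
  p +
    ggplot2::geom_line(colour = "darkgreen") +
    ggplot2::labs(
      x = "distance from TSS (kb)",
      y = "DMRs per gene per Mb"
    ) +
    ggplot2::theme_minimal()
}

#' Plot sample principal components
#'
#' @param object A `sample_pca` from [sample_structure()].
#' @param colour Optional metadata column to colour by (string).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sample_pca
#' @export
autoplot.sample_pca <- function(object, colour = NULL, ...) {
  d <- as_tibble(object)
  ve <- attr(object, "var_explained")
  aes <- if (!is.null(colour) && colour %in% names(d)) {
    ggplot2::aes(.data$PC1, .data$PC2, colour = .data[[colour]])
  } else {
    ggplot2::aes(.data$PC1, .data$PC2)
  }
  ggplot2::ggplot(d, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", 100 * ve[1]),
      y = sprintf("PC2 (%.0f%%)", 100 * ve[2])
    ) +
    ggplot2::theme_minimal()
}

#' Bar plot of global methylation levels per context and sample group
#'
#' @param levels Tibble from [global_level()] calls (rows per
#'   sample/group and context).
#' @param x Column mapped to the x axis (string; default "context").
#' @param fill Optional column mapped to fill.
#' @return A ggplot.
#' @export
plot_context_levels <- function(levels, x = "context", fill = NULL) {
  aes <- if (!is.null(fill) && fill %in% names(levels)) {
    ggplot2::aes(.data[[x]], .data$level, fill = .data[[fill]])
  } else {
    ggplot2::aes(.data[[x]], .data$level)
  }
  ggplot2::ggplot(levels, aes) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(y = "weighted methylation level") +
    ggplot2::theme_minimal()
}
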