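#' Tidy calibration rates
#'
#' @param x A `calibration_rates` tibble.
#' @param ... Unused.
#' @return A plain tibble with one row per rate.
#' @method tidy calibration_rates
#' @export
tidy.calibration_rates <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' One-row summary of calibration rates
#'
#' @param x A `calibration_rates` tibble.
#' @param ... Unused.
#' @method glance calibration_rates
#' @export
glance.calibration_rates <- function(x, ...) {
  wide <- setNames(as.list(x$estimate), x$rate)
  out <- as_tibble(wide)
  a <- attr(x, "hmc_abundance")
  if (!is.null(a)) out$hmc_abundance <- a
  out
}

#' Tidy a DMR set
#'
#' @param x A `dmr_set`.
#' @param ... Unused.
#' @method tidy dmr_set
#' @export
tidy.dmr_set <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' Headline summary of a DMR set: count, genomic extent and mean
#' methylation difference magnitude
#'
#' @param x A `dmr_set`.
#' @param ... Unused.
#' @method glance dmr_set
#' @export
glance.dmr_set <- function(x, ...) {
  s <- attr(x, "summary")
  tibble(
    n_dmrs = s$n, total_bp = s$total_bp, mean_abs_diff = s$mean_abs_diff,
    n_a_hypo = sum(x$direction == "A_hypo"),
    n_b_hypo = sum(x$direction == "B_hypo")
  )
}

#' Summary of a differential expression result
#'
#' @param x A `de_result` from [de_test()].
#' @param ... Unused.
#' @method glance de_result
#' @export
glance.de_result <- function(x, ...) {
  tibble(
    contrast = x$contrast[1],
    n_genes = nrow(x),
    n_tested = sum(x$passes_filters),
    n_de = sum(x$de),
    alpha = attr(x, "alpha"),
    min_fold_change = attr(x, "min_fold_change")
  )
}

#' Variance explained by sample principal components
#'
#' @param x A `sample_pca` from [sample_structure()].
#' @param ... Unused.
#' @method glance sample_pca
#' @export
glance.sample_pca <- function(x, ...) {
  ve <- attr(x, "var_explained")
  as_tibble(setNames(as.list(ve), paste0("var_explained_pc", seq_along(ve))))
}
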