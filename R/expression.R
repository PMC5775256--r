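#' Filter lowly expressed genes
#'
#' Default rule retains genes with counts strictly greater than 10 in at
#' least two samples; the alternative retains genes with TPM > 1 in at
#' least three samples (requires gene lengths).
#'
#' @param counts Integer matrix, genes x samples.
#' @param method `"counts"` or `"tpm"`.
#' @param min_count,min_count_samples Thresholds for the count rule.
#' @param min_tpm,min_tpm_samples Thresholds for the TPM rule.
#' @param gene_lengths Named numeric vector of effective (exonic) lengths
#'   in bp, required for the TPM rule.
#' @return Tibble: gene_id, retained; attribute `n_dropped`.
#' @export
#' @examples
#' m <- rbind(a = c(11, 11, 0), b = c(11, 0, 0))
#' filter_genes(m)
filter_genes <- function(counts, method = c("counts", "tpm"),
                         min_count = 10, min_count_samples = 2,
                         min_tpm = 1, min_tpm_samples = 3,
                         gene_lengths = NULL) {
  method <- match.arg(method)
  if (method == "counts") {
    retained <- rowSums(counts > min_count) >= min_count_samples
  } else {
    if (is.null(gene_lengths)) abort("the TPM rule requires gene_lengths")
    len <- gene_lengths[rownames(counts)]
    if (any(is.na(len))) abort("gene_lengths missing for some genes")
    rpk <- counts / (len / 1e3)
    tpm <- t(t(rpk) / colSums(rpk)) * 1e6
    retained <- rowSums(tpm > min_tpm) >= min_tpm_samples
  }
  out <- tibble(gene_id = rownames(counts), retained = unname(retained))
  attr(out, "n_dropped") <- sum(!retained)
  out
}

#' Flag samples with aberrant expression of a sex-specific marker
#'
#' Computes counts-per-million of the marker gene and flags samples whose
#' marker CPM exceeds median + k * MAD across samples — the rule used to
#' exclude, e.g., a female sample betrayed by high Xist in a male cohort.
#' Exclusion is reported, never silent.
#'
#' @param counts Integer matrix, genes x samples.
#' @param marker_gene Row name of the marker (default "Xist").
#' @param k MAD multiplier.
#' @return Tibble: sample, marker_cpm, flagged.
#' @export
xist_qc <- function(counts, marker_gene = "Xist", k = 5) {
  if (!marker_gene %in% rownames(counts)) {
    warn(sprintf("marker gene '%s' not found; no samples flagged", marker_gene))
    return(tibble(
      sample = colnames(counts), marker_cpm = NA_real_, flagged = FALSE
    ))
  }
  cpm <- counts[marker_gene, ] / colSums(counts) * 1e6
  thr <- median(cpm) + k * mad(cpm)
  flagged <- cpm > thr
  if (any(flagged)) {
    inform(sprintf(
      "xist_qc: flagging %s (marker CPM %s; threshold %.2f)",
      paste(colnames(counts)[flagged], collapse = ", "),
      paste(sprintf("%.1f", cpm[flagged]), collapse = ", "), thr
    ))
  }
  tibble(
    sample = colnames(counts), marker_cpm = unname(cpm),
    flagged = unname(flagged)
  )
}

# median-of-ratios size factors (reference = geometric mean over samples)
size_factors <- function(counts) {
  logg <- rowMeans(log(counts))
  use <- is.finite(logg)
  if (!any(use)) abort("no gene has positive counts in every sample")
  apply(counts, 2L, function(x) exp(median(log(x[use]) - logg[use])))
}

normalized_log2 <- function(counts) {
  sf <- size_factors(counts)
  log2(t(t(counts) / sf) + 0.5)
}

#' Differential expression by region/condition contrast
#'
#' A fully specified substitute for a negative-binomial GLM workflow:
#' counts are normalised with median-of-ratios size factors, transformed
#' to log2(normalised + 0.5), and each gene is tested with a Welch t-type
#' statistic on the contrast's linear combination of group means.
#' Contrasts follow the three study null hypotheses: `"region"` tests
#' Dorsal SH - Ventral SH = Dorsal EE - Ventral EE (the
#' difference-of-differences, with variance summed across all four
#' cells and Welch-Satterthwaite degrees of freedom), `"ee_dorsal"` tests
#' Dorsal EE = Dorsal SH, and `"ee_ventral"` tests Ventral EE =
#' Ventral SH. P-values are BH-adjusted across the retained genes of the
#' contrast; a DE call requires q below `alpha` and at least a
#' `min_fold_change`-fold change on the linear scale.
#'
#' @param counts Integer matrix, genes x samples (after any QC
#'   exclusions).
#' @param samples Tibble with sample, region (dorsal/ventral), condition
#'   (SH/EE) matching the matrix columns.
#' @param contrast `"region"`, `"ee_dorsal"` or `"ee_ventral"`.
#' @param retained Optional tibble from [filter_genes()]; genes failing
#'   the filter are reported with `passes_filters = FALSE` and excluded
#'   from testing and BH adjustment.
#' @param alpha FDR threshold for the DE call.
#' @param min_fold_change Linear fold-change threshold for the DE call
#'   (1.2 = at least a 20% change).
#' @return Tibble of class `de_result`: gene_id, log2fc, p, q, contrast,
#'   passes_filters, de.
#' @export
de_test <- function(counts, samples, contrast = c("region", "ee_dorsal", "ee_ventral"),
                    retained = NULL, alpha = 0.05, min_fold_change = 1.2) {
  contrast <- match.arg(contrast)
  stopifnot(identical(colnames(counts), samples$sample))
  cells <- list(
    d_sh = samples$region == "dorsal" & samples$condition == "SH",
    d_ee = samples$region == "dorsal" & samples$condition == "EE",
    v_sh = samples$region == "ventral" & samples$condition == "SH",
    v_ee = samples$region == "ventral" & samples$condition == "EE"
  )
  needed <- switch(contrast,
    region = c("d_sh", "d_ee", "v_sh", "v_ee"),
    ee_dorsal = c("d_sh", "d_ee"),
    ee_ventral = c("v_sh", "v_ee")
  )
  for (cell in needed) {
    if (sum(cells[[cell]]) < 2L) {
      abort(sprintf("design cell '%s' has fewer than 2 samples", cell))
    }
  }
  y <- normalized_log2(counts)
  if (is.null(retained)) {
    retained <- tibble(gene_id = rownames(counts), retained = TRUE)
  }
  keep <- retained$retained[match(rownames(counts), retained$gene_id)]
  keep[is.na(keep)] <- FALSE

  stats_for <- function(sel) {
    m <- y[, sel, drop = FALSE]
    list(mean = rowMeans(m), var = apply(m, 1L, var), n = ncol(m))
  }
  st <- lapply(cells[needed], stats_for)
  if (contrast == "region") {
    # (D_SH - V_SH) - (D_EE - V_EE)
    est <- st$d_sh$mean - st$v_sh$mean - st$d_ee$mean + st$v_ee$mean
    vterms <- lapply(st, function(s) s$var / s$n)
    se2 <- Reduce(`+`, vterms)
    df <- se2^2 / Reduce(`+`, lapply(st, function(s) {
      (s$var / s$n)^2 / (s$n - 1)
    }))
  } else {
    a <- st[[2]]; b <- st[[1]] # EE minus SH
    est <- a$mean - b$mean
    se2 <- a$var / a$n + b$var / b$n
    df <- se2^2 / ((a$var / a$n)^2 / (a$n - 1) + (b$var / b$n)^2 / (b$n - 1))
  }
  tstat <- est / sqrt(se2)
  p <- 2 * pt(-abs(tstat), df)
  p[!is.finite(p)] <- 1
  q <- rep(NA_real_, length(p))
  q[keep] <- p.adjust(p[keep], method = "BH")
  out <- tibble(
    gene_id = rownames(counts),
    log2fc = unname(est),
    p = ifelse(keep, unname(p), NA_real_),
    q = unname(q),
    contrast = contrast,
    passes_filters = unname(keep),
    de = !is.na(q) & q < alpha & abs(est) >= log2(min_fold_change)
  )
  structure(out, class = c("de_result", class(tibble())),
    alpha = alpha, min_fold_change = min_fold_change
  )
}

#' Principal-component projection of samples
#'
#' Projects samples onto the top principal components of centred log-CPM
#' expression, the standard QC view in which regional identity should
#' dominate the first component.
#'
#' @param counts Integer matrix, genes x samples.
#' @param n_components Number of components to keep.
#' @param samples Optional sample tibble joined onto the output.
#' @return Tibble of class `sample_pca` with sample, PC columns and a
#'   `var_explained` attribute (fractions, sums to <= 1).
#' @export
sample_structure <- function(counts, n_components = 2, samples = NULL) {
  if (ncol(counts) < 3L) abort("need at least 3 samples")
  cpm <- t(t(counts) / colSums(counts)) * 1e6
  y <- log2(cpm + 1)
  y <- y[apply(y, 1L, sd) > 0, , drop = FALSE]
  pc <- prcomp(t(y), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  out <- as_tibble(pc$x[, seq_len(k), drop = FALSE])
  out <- bind_cols(tibble(sample = colnames(counts)), out)
  if (!is.null(samples)) out <- left_join(out, samples, by = "sample")
  structure(out, class = c("sample_pca", class(tibble())),
    var_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  )
}
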