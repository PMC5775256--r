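#' Signed, strand-oriented distance from a gene's TSS to a DMR midpoint
#'
#' Upstream distances are negative; for minus-strand genes upstream lies
#' at larger coordinates, so the sign flips. Pairs on different
#' chromosomes are excluded (NA).
#'
#' @param dmrs Tibble with chrom, start, end (0-based half-open).
#' @param genes Tibble with chrom, tss, strand (and gene_id).
#' @return Tibble of pairs: gene_id, dmr index, distance (bp).
#' @export
#' @examples
#' tss_distance(tibble::tibble(chrom = "chr1", start = 1400, end = 1600),
#'              tibble::tibble(gene_id = "g1", chrom = "chr1", tss = 1000,
#'                             strand = "+"))
tss_distance <- function(dmrs, genes) {
  if (!"gene_id" %in% names(genes)) {
    genes$gene_id <- sprintf("gene%04d", seq_len(nrow(genes)))
  }
  dmrs <- mutate(dmrs, .dmr = dplyr::row_number(),
    mid = (.data$start + .data$end) / 2
  )
  inner_join(
    select(genes, "gene_id", "chrom", "tss", "strand"),
    select(dmrs, "chrom", ".dmr", "mid"),
    by = "chrom", relationship = "many-to-many"
  ) |>
    mutate(
      distance = (.data$mid - .data$tss) *
        ifelse(.data$strand == "-", -1, 1)
    ) |>
    select("gene_id", dmr = ".dmr", "distance")
}

#' DMR density around transcription start sites
#'
#' For a gene set, counts DMR-gene pairs by signed TSS distance bin and
#' normalises to a density of DMRs per gene per megabase. Every gene
#' within the window of a DMR contributes a pair (not only the nearest
#' gene), matching the per-gene normalisation.
#'
#' @param dmrs Tibble with chrom, start, end.
#' @param genes Gene tibble (chrom, tss, strand).
#' @param window Half-width of the distance window in bp.
#' @param bin_width Distance bin width in bp.
#' @return Tibble of class `enrichment_curve`: bin_start, bin_end,
#'   bin_mid, n_pairs, score (DMRs per gene per Mb).
#' @export
enrichment_curve <- function(dmrs, genes, window = 1e6, bin_width = 1e5) {
  if (nrow(genes) == 0L) abort("gene set is empty")
  if (bin_width <= 0) abort("bin_width must be > 0")
  edges <- seq(-window, window, by = bin_width)
  d <- tss_distance(dmrs, genes) |>
    filter(.data$distance >= -window, .data$distance < window)
  bin <- findInterval(d$distance, edges)
  counts <- tabulate(bin, nbins = length(edges) - 1L)
  out <- tibble(
    bin_start = head(edges, -1), bin_end = tail(edges, -1),
    bin_mid = (head(edges, -1) + tail(edges, -1)) / 2,
    n_pairs = counts,
    score = counts / (nrow(genes) * bin_width / 1e6)
  )
  structure(out, class = c("enrichment_curve", class(tibble())))
}

#' Expression-matched control band for a TSS enrichment curve
#'
#' Stratifies all genes into deciles of mean expression and repeatedly
#' draws control gene sets (without replacement, excluding the targets)
#' matching the target set's per-decile composition; the band is the
#' per-bin 2.5th/97.5th percentile of the control curves. When a decile
#' has too few non-target genes the deficit is drawn from neighbouring
#' deciles with a warning.
#'
#' @param dmrs,window,bin_width As in [enrichment_curve()].
#' @param target_genes Gene tibble for the set of interest.
#' @param all_genes Gene tibble for the whole universe (must include the
#'   targets).
#' @param expression Tibble with gene_id and mean_expr, or a counts matrix
#'   whose row means are used.
#' @param n_resamples Number of control draws.
#' @param seed Seed for the resampling.
#' @return An `enrichment_curve` tibble for the target set with extra
#'   columns band_lower/band_upper and attribute `n_resamples`.
#' @export
matched_control_band <- function(dmrs, target_genes, all_genes, expression,
                                 window = 1e6, bin_width = 1e5,
                                 n_resamples = 1000, seed = 1) {
  if (nrow(all_genes) <= nrow(target_genes)) {
    abort("all_genes must be larger than target_genes")
  }
  if (is.matrix(expression)) {
    expression <- tibble(
      gene_id = rownames(expression), mean_expr = rowMeans(expression)
    )
  }
  missing <- setdiff(all_genes$gene_id, expression$gene_id)
  if (length(missing)) {
    abort(sprintf("expression missing for %d genes", length(missing)))
  }
  universe <- all_genes |>
    left_join(select(expression, "gene_id", "mean_expr"), by = "gene_id") |>
    mutate(decile = dplyr::ntile(.data$mean_expr, 10))
  is_target <- universe$gene_id %in% target_genes$gene_id
  need <- universe |>
    filter(is_target) |>
    count(.data$decile, name = "need")
  pool <- universe[!is_target, ]

  target_curve <- enrichment_curve(dmrs, target_genes, window, bin_width)
  scores <- withr::with_seed(seed, {
    vapply(seq_len(n_resamples), function(i) {
      ctrl_idx <- draw_matched(pool$decile, need)
      enrichment_curve(dmrs, pool[ctrl_idx, ], window, bin_width)$score
    }, numeric(nrow(target_curve)))
  })
  # order-statistic (type 1) quantiles: per-bin scores are scaled counts,
  # and interpolated quantiles under-cover on discrete distributions
  target_curve$band_lower <- apply(scores, 1L, quantile, probs = 0.025, type = 1)
  target_curve$band_upper <- apply(scores, 1L, quantile, probs = 0.975, type = 1)
  attr(target_curve, "n_resamples") <- n_resamples
  target_curve
}

# sample indices of `deciles` matching the per-decile `need` counts,
# borrowing from neighbouring deciles when one is exhausted
draw_matched <- function(deciles, need) {
  taken <- logical(length(deciles))
  out <- integer(0)
  for (j in seq_len(nrow(need))) {
    want <- need$need[j]
    dec <- need$decile[j]
    avail <- which(deciles == dec & !taken)
    if (length(avail) < want) {
      warn(sprintf(
        "expression decile %d has only %d control genes for %d targets; borrowing from neighbours",
        dec, length(avail), want
      ))
      shift <- 1L
      while (length(avail) < want && shift <= 9L) {
        avail <- c(avail, which(deciles %in% c(dec - shift, dec + shift) & !taken))
        shift <- shift + 1L
      }
    }
    pick <- if (length(avail) <= want) avail else avail[sample.int(length(avail), want)]
    taken[pick] <- TRUE
    out <- c(out, pick)
  }
  out
}

#' Hypergeometric test for DMR-containing genes in a target set
#'
#' Urn model: the population is all genes, successes are genes carrying at
#' least one DMR (within the chosen span), and the sample is the target
#' set; the upper-tail p-value asks whether target genes carry DMRs more
#' often than expected.
#'
#' @param target_genes Character vector of target gene ids.
#' @param all_genes Character vector of all gene ids.
#' @param gene_has_dmr Logical vector named by gene id (or tibble with
#'   gene_id and has_dmr), defined for every gene.
#' @return One-row tibble: population, successes, sample_size, hits, p.
#' @export
dmr_gene_hypergeom <- function(target_genes, all_genes, gene_has_dmr) {
  if (length(target_genes) == 0L) abort("target gene set is empty")
  if (is.data.frame(gene_has_dmr)) {
    gene_has_dmr <- setNames(gene_has_dmr$has_dmr, gene_has_dmr$gene_id)
  }
  if (!all(all_genes %in% names(gene_has_dmr))) {
    abort("gene_has_dmr must be defined for every gene in all_genes")
  }
  flags <- gene_has_dmr[all_genes]
  pop <- length(all_genes)
  succ <- sum(flags)
  samp <- length(target_genes)
  hits <- sum(gene_has_dmr[target_genes])
  tibble(
    population = pop, successes = succ, sample_size = samp, hits = hits,
    p = phyper(hits - 1, succ, pop - succ, samp, lower.tail = FALSE)
  )
}

#' Fraction of genes carrying at least one DMR
#'
#' A gene carries a DMR when any DMR overlaps its body extended by `span`
#' bp on each side (0-based half-open arithmetic).
#'
#' @param genes Gene tibble (gene_id, chrom, start, end).
#' @param dmrs DMR tibble (chrom, start, end).
#' @param span Flank added to each gene body in bp.
#' @return List with `fraction` and `flags` (tibble gene_id, has_dmr).
#' @export
gene_dmr_fraction <- function(genes, dmrs, span = 1e4) {
  ext <- mutate(genes,
    start = pmax(.data$start - span, 0), end = .data$end + span
  )
  flags <- tibble(
    gene_id = genes$gene_id,
    has_dmr = overlaps_any(ext, dmrs)
  )
  list(
    fraction = if (nrow(flags)) mean(flags$has_dmr) else NA_real_,
    flags = flags
  )
}

#' Peak-DMR colocalization with a hypergeometric window universe
#'
#' A peak "hits" when its midpoint lies within `max_dist` bp of a DMR edge
#' (closed convention: a midpoint exactly `max_dist` away, or exactly at
#' an edge with `max_dist = 0`, counts). The urn population is the set of
#' fixed-width windows tiling the genome, successes are windows whose
#' midpoints hit under the same rule, the sample size is the number of
#' peaks, and the upper-tail hypergeometric p-value measures excess
#' colocalization.
#'
#' @param peaks Tibble with chrom, start, end (0-based half-open).
#' @param dmrs Tibble with chrom, start, end.
#' @param chrom_sizes Tibble with chrom, size describing the genome.
#' @param max_dist Maximum midpoint-to-edge distance in bp.
#' @param window_size Width of the universe windows in bp.
#' @return One-row tibble of class `colocalization_result`: n_peaks,
#'   n_peaks_near_dmr, max_dist, universe, successes, p; the per-peak hit
#'   flags are attached as attribute `hits`.
#' @export
peak_dmr_colocalization <- function(peaks, dmrs, chrom_sizes,
                                    max_dist = 500, window_size = 1000) {
  if (nrow(peaks) == 0L) abort("peak set is empty")
  hit_flags <- midpoint_near(peaks, dmrs, max_dist)
  windows <- purrr::map_dfr(seq_len(nrow(chrom_sizes)), function(i) {
    k <- floor(chrom_sizes$size[i] / window_size)
    tibble(
      chrom = chrom_sizes$chrom[i],
      start = (seq_len(k) - 1) * window_size
    )
  }) |>
    mutate(end = .data$start + window_size)
  succ <- sum(midpoint_near(windows, dmrs, max_dist))
  hits <- sum(hit_flags)
  out <- tibble(
    n_peaks = nrow(peaks), n_peaks_near_dmr = hits, max_dist = max_dist,
    universe = nrow(windows), successes = succ,
    p = phyper(hits - 1, succ, nrow(windows) - succ, nrow(peaks),
      lower.tail = FALSE
    )
  )
  attr(out, "hits") <- hit_flags
  structure(out, class = c("colocalization_result", class(tibble())))
}

# TRUE where the interval midpoint lies within max_dist of any target
# interval (distance 0 inside; closed at max_dist)
midpoint_near <- function(x, targets, max_dist) {
  mids <- (x$start + x$end) / 2
  out <- rep(FALSE, nrow(x))
  for (ch in unique(x$chrom)) {
    sel <- x$chrom == ch
    tsel <- targets$chrom == ch
    d <- point_interval_dist(mids[sel], targets$start[tsel], targets$end[tsel])
    out[sel] <- d <= max_dist
  }
  out
}
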