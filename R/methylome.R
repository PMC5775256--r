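#' Global weighted methylation level per context
#'
#' Computes the coverage-weighted level sum(mc)/sum(cov) over qualifying
#' sites, the standard weighted methylation level, optionally corrected
#' for bisulfite non-conversion at the aggregate level via [correct_mc()].
#' `context = "CH"` pools the CA, CC and CT classes. When the table has a
#' `sample` (and/or `group`) column, one row per sample/group is returned.
#'
#' @param table Allc-style tibble.
#' @param context One of "CG", "CH", "CA", "CC", "CT".
#' @param min_coverage Minimum per-site coverage to qualify.
#' @param ncr Non-conversion rate applied to the pooled level (0 = raw).
#' @param weighted Use the pooled ratio of sums (default). With
#'   `weighted = FALSE` the unweighted mean of per-site fractions is
#'   returned instead.
#' @return Tibble: (sample/group columns,) context, level, n_sites,
#'   total_coverage. Zero qualifying sites give an empty tibble.
#' @export
#' @examples
#' tbl <- tibble::tibble(chrom = "chr1", pos = c(2, 10), strand = "+",
#'                       context = c("CGA", "CGT"), mc = c(3, 7), cov = 10)
#' global_level(tbl, "CG")
global_level <- function(table, context = "CG", min_coverage = 1, ncr = 0,
                         weighted = TRUE) {
  assert_allc(table)
  context <- match.arg(context, c("CG", "CH", "CA", "CC", "CT"))
  keep <- if (context == "CH") c("CA", "CC", "CT") else context
  x <- table |>
    mutate(.ctx = context_class(.data$context)) |>
    filter(.data$.ctx %in% keep, .data$cov >= min_coverage)
  if (nrow(x) == 0L) {
    return(tibble(
      context = character(), level = numeric(),
      n_sites = integer(), total_coverage = numeric()
    ))
  }
  ctx_label <- context
  grp <- intersect(c("sample", "group", "assay"), names(x))
  x |>
    group_by(across(all_of(grp))) |>
    summarise(
      context = .env$ctx_label,
      level = if (weighted) sum(.data$mc) / sum(.data$cov) else mean(.data$mc / .data$cov),
      n_sites = n(),
      total_coverage = sum(.data$cov),
      .groups = "drop"
    ) |>
    mutate(level = if (ncr > 0) correct_mc(
      .data$level * .data$total_coverage, .data$total_coverage, ncr
    ) else .data$level)
}

#' Pooled methylation levels in fixed genomic bins
#'
#' Partitions each chromosome into fixed 0-based half-open bins of
#' `bin_size` bp and pools counts per bin (and per sample/group column if
#' present). Bin numerators and denominators sum exactly to the global
#' values, so no site is lost or double-counted.
#'
#' @param table Allc-style tibble.
#' @param bin_size Bin width in bp.
#' @param contexts Context classes to include (default CG).
#' @return Tibble: (sample/group,) chrom, bin_start, bin_end, mc, cov,
#'   level, n_sites.
#' @export
binned_levels <- function(table, bin_size = 1000, contexts = "CG") {
  assert_allc(table)
  if (bin_size <= 0) abort("bin_size must be > 0")
  grp <- intersect(c("sample", "group"), names(table))
  table |>
    mutate(.ctx = context_class(.data$context)) |>
    filter(.data$.ctx %in% contexts) |>
    mutate(bin_start = floor((.data$pos - 1) / bin_size) * bin_size) |>
    group_by(across(all_of(c(grp, "chrom", "bin_start")))) |>
    summarise(
      mc = sum(.data$mc), cov = sum(.data$cov), n_sites = n(),
      .groups = "drop"
    ) |>
    mutate(
      bin_end = .data$bin_start + bin_size,
      level = ifelse(.data$cov > 0, .data$mc / .data$cov, NA_real_)
    ) |>
    select(all_of(grp), "chrom", "bin_start", "bin_end", "mc", "cov",
      "n_sites", "level"
    )
}

#' Median condition effect per stratum of regional methylation difference
#'
#' Implements the binned stratification view: genomic bins are stratified
#' by their dorsal-ventral (regional) methylation difference, and the
#' median condition difference (e.g. EE - SH) is reported per stratum.
#' Only bins where EE-responsive methylation coincides with a regional
#' difference produce nonzero stratified medians.
#'
#' @param bins Tibble with one row per genomic bin carrying the two
#'   difference columns.
#' @param region_diff,condition_diff Column names (strings) of the
#'   regional and condition differences.
#' @param edges Stratum edges on the regional difference.
#' @return Tibble: stratum (factor interval label), stratum_mid, n_bins,
#'   median_condition_diff.
#' @export
stratify_bin_diffs <- function(bins, region_diff = "region_diff",
                               condition_diff = "condition_diff",
                               edges = seq(-0.6, 0.6, by = 0.1)) {
  stopifnot(all(c(region_diff, condition_diff) %in% names(bins)))
  bins |>
    mutate(stratum = cut(.data[[region_diff]], breaks = edges, include.lowest = TRUE)) |>
    filter(!is.na(.data$stratum)) |>
    group_by(.data$stratum) |>
    summarise(
      n_bins = n(),
      median_condition_diff = median(.data[[condition_diff]], na.rm = TRUE),
      .groups = "drop"
    ) |>
    mutate(
      stratum_mid = ((head(edges, -1) + tail(edges, -1)) / 2)[as.integer(.data$stratum)]
    )
}

#' Mean methylation profile centered on genomic features
#'
#' Assigns sites to offset bins relative to each feature's midpoint
#' (strand-oriented: offsets of minus-strand features are negated) and
#' reports the pooled, coverage-weighted level per offset bin. Bins with
#' fewer than `min_sites` contributing site-feature pairs are masked.
#'
#' @param table Allc-style tibble.
#' @param features Tibble of 0-based half-open intervals (chrom, start,
#'   end, optional strand).
#' @param flank_bp Half-width of the window around feature midpoints.
#' @param step_bp Offset bin width.
#' @param contexts Context classes to include.
#' @param min_sites Minimum site-feature pairs per reported bin.
#' @return Tibble of class `meth_profile`: offset (bin center), mc, cov,
#'   n_sites, level.
#' @export
profile_at_features <- function(table, features, flank_bp = 2000,
                                step_bp = 100, contexts = "CG",
                                min_sites = 3) {
  assert_allc(table)
  edges <- seq(-flank_bp, flank_bp, by = step_bp)
  empty <- tibble(
    offset = numeric(), mc = numeric(), cov = numeric(),
    n_sites = integer(), level = numeric()
  )
  if (is.null(features) || nrow(features) == 0L) {
    return(structure(empty, class = c("meth_profile", class(tibble()))))
  }
  if (!"strand" %in% names(features)) features$strand <- "+"
  feats <- features |>
    mutate(
      mid = (.data$start + .data$end) / 2,
      lo = .data$mid - flank_bp, hi = .data$mid + flank_bp + 1
    )
  x <- table |>
    mutate(.ctx = context_class(.data$context)) |>
    filter(.data$.ctx %in% contexts, .data$cov > 0)
  pairs <- inner_join(
    select(x, "chrom", "pos", "mc", "cov"),
    select(feats, "chrom", "mid", "lo", "hi", feat_strand = "strand"),
    by = join_by(chrom, between(pos, lo, hi))
  ) |>
    mutate(
      # pos is 1-based; convert to the 0-based midpoint frame
      offset = (.data$pos - 0.5 - .data$mid) *
        ifelse(.data$feat_strand == "-", -1, 1)
    ) |>
    filter(.data$offset >= -flank_bp, .data$offset < flank_bp)
  out <- pairs |>
    mutate(bin = findInterval(.data$offset, edges)) |>
    group_by(.data$bin) |>
    summarise(
      mc = sum(.data$mc), cov = sum(.data$cov), n_sites = n(),
      .groups = "drop"
    ) |>
    mutate(
      offset = (edges[.data$bin] + edges[.data$bin + 1L]) / 2,
      level = ifelse(.data$n_sites >= min_sites, .data$mc / .data$cov, NA_real_)
    ) |>
    select("offset", "mc", "cov", "n_sites", "level") |>
    arrange(.data$offset)
  structure(out, class = c("meth_profile", class(tibble())))
}
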