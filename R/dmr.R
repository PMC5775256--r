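#' Per-site two-group methylation test
#'
#' Pools counts across replicates within each group and tests equality of
#' methylation per site: a two-sided Fisher exact test on the pooled 2x2
#' table when total coverage is below `fisher_max_coverage`, otherwise a
#' normal approximation on the difference of pooled proportions. A
#' replicate-aware over-dispersion guard flags sites where the range of
#' per-replicate fractions within either group exceeds the absolute
#' between-group difference while the replicate counts are significantly
#' over-dispersed relative to binomial sampling; flagged sites are
#' excluded from DMR candidacy by [call_dmrs()].
#'
#' @param m_a,c_a Methylated and total counts for group A: vectors (one
#'   replicate) or matrices with one column per replicate (rows = sites).
#' @param m_b,c_b Same for group B.
#' @param fisher_max_coverage Total-coverage switch point between the
#'   exact and approximate test.
#' @return Tibble: level_a, level_b, diff (A - B), p, flagged, cov_a,
#'   cov_b. Sites with zero coverage in a group get `NA` p and diff.
#' @export
#' @examples
#' site_test(2, 20, 16, 20) # strong difference, Fisher exact
site_test <- function(m_a, c_a, m_b, c_b, fisher_max_coverage = 200) {
  m_a <- as.matrix(m_a); c_a <- as.matrix(c_a)
  m_b <- as.matrix(m_b); c_b <- as.matrix(c_b)
  stopifnot(
    nrow(m_a) == nrow(m_b), all(dim(m_a) == dim(c_a)),
    all(dim(m_b) == dim(c_b))
  )
  ma <- rowSums(m_a); ca <- rowSums(c_a)
  mb <- rowSums(m_b); cb <- rowSums(c_b)
  pa <- ifelse(ca > 0, ma / ca, NA_real_)
  pb <- ifelse(cb > 0, mb / cb, NA_real_)
  diff <- pa - pb
  p <- two_group_p(ma, ca, mb, cb, fisher_max_coverage)
  flagged <- !is.na(diff) &
    (dispersion_flag(m_a, c_a, diff) | dispersion_flag(m_b, c_b, diff))
  tibble(
    level_a = pa, level_b = pb, diff = diff, p = p,
    flagged = flagged, cov_a = ca, cov_b = cb
  )
}

# over-dispersion guard: a site is flagged when the between-replicate range
# of methylation fractions within the group exceeds the absolute
# between-group difference AND the replicate counts are significantly
# over-dispersed relative to binomial sampling at the pooled level
# (chi-square upper p < 0.01). The second condition keeps pure sampling
# noise at low coverage from masquerading as replicate inconsistency; the
# guard targets biologically inconsistent replicates, standing in for a
# beta-binomial dispersion fit.
dispersion_flag <- function(m, c, diff, chisq_alpha = 0.01) {
  m <- as.matrix(m)
  c <- as.matrix(c)
  n <- nrow(m)
  out <- rep(FALSE, n)
  if (ncol(m) < 2L) return(out)
  f <- m / c
  f[c == 0] <- NA
  rng <- apply(f, 1L, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) 0 else max(x) - min(x)
  })
  pooled <- rowSums(m) / pmax(rowSums(c), 1)
  ev <- c * rep(pooled, ncol(c))
  chisq <- rowSums(
    ifelse(c > 0 & pooled > 0 & pooled < 1,
      (m - ev)^2 / pmax(ev * (1 - rep(pooled, ncol(c))), 1e-12), 0
    ),
    na.rm = TRUE
  )
  df <- rowSums(c > 0) - 1L
  over <- df >= 1L & stats::pchisq(chisq, df, lower.tail = FALSE) < chisq_alpha
  rng > abs(diff) & over & !is.na(diff)
}

# vectorised two-sided p for pooled 2x2 tables
two_group_p <- function(ma, ca, mb, cb, fisher_max_coverage = 200) {
  n <- length(ma)
  p <- rep(NA_real_, n)
  ok <- ca > 0 & cb > 0
  tot <- ca + cb
  use_fisher <- ok & tot < fisher_max_coverage
  if (any(use_fisher)) {
    idx <- which(use_fisher)
    p[idx] <- vapply(
      idx,
      function(i) fisher_p2(ma[i], ca[i], mb[i], cb[i]),
      numeric(1)
    )
  }
  use_z <- ok & !use_fisher
  if (any(use_z)) {
    i <- which(use_z)
    phat <- (ma[i] + mb[i]) / tot[i]
    se <- sqrt(phat * (1 - phat) * (1 / ca[i] + 1 / cb[i]))
    z <- (ma[i] / ca[i] - mb[i] / cb[i]) / se
    pv <- 2 * pnorm(-abs(z))
    pv[se == 0] <- 1
    p[i] <- pmin(pv, 1)
  }
  p
}

# two-sided Fisher exact p for one 2x2 table via hypergeometric enumeration
# (sum of outcome probabilities not exceeding the observed one, the same
# rule stats::fisher.test uses)
fisher_p2 <- function(m1, c1, m2, c2) {
  k <- m1 + m2
  lo <- max(0, k - c2)
  hi <- min(k, c1)
  d <- dhyper(lo:hi, c1, c2, k)
  sum(d[d <= dhyper(m1, c1, c2, k) * (1 + 1e-7)])
}

#' Call differentially methylated regions between two groups
#'
#' Candidate CG sites (site p below `alpha`, absolute pooled difference at
#' least `min_diff`, consistent sign, not dispersion-flagged) are merged
#' into regions when separated by at most `max_gap_bp` and by at most
#' `max_intervening` covered non-candidate sites. Region statistics —
#' the pooled methylation difference and a signed Stouffer-combined p —
#' are then computed over every covered site in the region span, and
#' regions are kept when they hold at least `min_sites` candidate sites,
#' their span difference is at least `min_diff` in absolute value, and the
#' span p is below `alpha`. The defaults encode the classic DMR
#' thresholds: at least a 15% methylation difference at p < 0.05.
#'
#' @param tables_a,tables_b Allc tibbles (with a `sample` column for
#'   replicates) or lists of per-replicate allc tibbles.
#' @param min_diff Minimum absolute methylation difference.
#' @param alpha Site and region significance threshold.
#' @param max_gap_bp Maximum gap between candidate sites within a region.
#' @param min_sites Minimum candidate sites per region.
#' @param max_intervening Maximum number of covered non-candidate sites
#'   tolerated between two merged candidates.
#' @param contexts Context classes tested (CG by default; DMRs are defined
#'   at CG dinucleotides).
#' @param fisher_max_coverage Passed to the site test.
#' @return Tibble of class `dmr_set` (chrom, start, end 0-based half-open,
#'   n_sites, level_a, level_b, diff, p, direction) sorted by coordinate,
#'   with a `summary` attribute (n, total_bp, mean_abs_diff) and the call
#'   parameters.
#' @export
call_dmrs <- function(tables_a, tables_b, min_diff = 0.15, alpha = 0.05,
                      max_gap_bp = 250, min_sites = 3, max_intervening = 2,
                      contexts = "CG", fisher_max_coverage = 200) {
  wide_a <- replicate_wide(tables_a, contexts)
  wide_b <- replicate_wide(tables_b, contexts)
  empty <- dmr_set_tbl(tibble(
    chrom = character(), start = numeric(), end = numeric(),
    n_sites = integer(), n_sites_span = integer(), level_a = numeric(),
    level_b = numeric(), diff = numeric(), p = numeric(),
    direction = character()
  ), min_diff, alpha, max_gap_bp, min_sites)
  if (nrow(wide_a$sites) == 0L || nrow(wide_b$sites) == 0L) {
    warn("empty input table(s); returning no DMRs")
    return(empty)
  }
  sites <- inner_join(
    wide_a$sites, wide_b$sites,
    by = c("chrom", "pos", "strand"), suffix = c("_a", "_b")
  ) |> arrange(.data$chrom, .data$pos, .data$strand)
  if (nrow(sites) == 0L) {
    warn("groups share no covered sites; returning no DMRs")
    return(empty)
  }
  ma <- wide_a$mc[sites$idx_a, , drop = FALSE]
  ca <- wide_a$cov[sites$idx_a, , drop = FALSE]
  mb <- wide_b$mc[sites$idx_b, , drop = FALSE]
  cb <- wide_b$cov[sites$idx_b, , drop = FALSE]
  pma <- rowSums(ma); pca <- rowSums(ca)
  pmb <- rowSums(mb); pcb <- rowSums(cb)
  covered <- pca > 0 & pcb > 0
  diff <- ifelse(covered, pma / pca - pmb / pcb, NA_real_)

  # p-values are only needed where the difference threshold can be met
  cand <- covered & abs(diff) >= min_diff
  p <- rep(NA_real_, length(diff))
  p[cand] <- two_group_p(
    pma[cand], pca[cand], pmb[cand], pcb[cand], fisher_max_coverage
  )
  keep <- which(cand & p < alpha)
  if (length(keep)) {
    disp <- dispersion_flag(ma[keep, , drop = FALSE], ca[keep, , drop = FALSE], diff[keep]) |
      dispersion_flag(mb[keep, , drop = FALSE], cb[keep, , drop = FALSE], diff[keep])
    keep <- keep[!disp]
  }
  if (length(keep) == 0L) {
    return(empty)
  }
  # merge consecutive same-sign candidates when the gap is small AND only a
  # few covered non-candidate sites sit between them: a lone noise
  # candidate near a true region would otherwise drag the region span over
  # null sites and dilute its pooled difference below threshold
  cov_pos <- split(sites$pos[covered], sites$chrom[covered])
  cov_pos <- lapply(cov_pos, sort)
  cand <- tibble(
    row = keep, chrom = sites$chrom[keep], pos = sites$pos[keep],
    sgn = sign(diff[keep])
  ) |>
    arrange(.data$chrom, .data$sgn, .data$pos) |>
    group_by(.data$chrom, .data$sgn) |>
    mutate(
      gap = .data$pos - dplyr::lag(.data$pos),
      prev_pos = dplyr::lag(.data$pos)
    ) |>
    ungroup()
  n_between <- rep(0L, nrow(cand))
  has_prev <- !is.na(cand$prev_pos)
  for (ch in unique(cand$chrom[has_prev])) {
    sel <- has_prev & cand$chrom == ch
    v <- cov_pos[[ch]]
    n_between[sel] <- findInterval(cand$pos[sel] - 0.5, v) -
      findInterval(cand$prev_pos[sel] + 0.5, v)
  }
  # consecutive same-sign candidates have no same-sign candidate strictly
  # between them, so n_between counts exactly the covered sites that argue
  # against continuity (non-candidates and opposite-sign candidates)
  new_run <- !has_prev | cand$gap > max_gap_bp | n_between > max_intervening
  runs <- cand |>
    mutate(run = cumsum(new_run)) |>
    group_by(.data$chrom, .data$sgn, .data$run) |>
    summarise(
      pos_min = min(.data$pos), pos_max = max(.data$pos),
      n_cand = n(), .groups = "drop"
    ) |>
    rename(sign = "sgn") |>
    filter(.data$n_cand >= min_sites)
  if (nrow(runs) == 0L) return(empty)

  # region statistics pool over EVERY site in the span, not just the
  # candidates that seeded it: candidate-only pooling is selection-biased
  # (all seeds were picked for large, significant differences) and would
  # let short runs of coincidental noise sites through.
  regions <- purrr::map_dfr(seq_len(nrow(runs)), function(k) {
    on_chrom <- which(sites$chrom == runs$chrom[k])
    span <- on_chrom[
      sites$pos[on_chrom] >= runs$pos_min[k] &
        sites$pos[on_chrom] <= runs$pos_max[k]
    ]
    need <- span[is.na(p[span]) & covered[span]]
    if (length(need)) {
      p[need] <<- two_group_p(
        pma[need], pca[need], pmb[need], pcb[need], fisher_max_coverage
      )
    }
    use <- span[covered[span]]
    z <- sign(runs$sign[k]) * sign(diff[use]) *
      qnorm(pmax(p[use], 1e-300) / 2, lower.tail = FALSE)
    la <- sum(pma[use]) / sum(pca[use])
    lb <- sum(pmb[use]) / sum(pcb[use])
    tibble(
      chrom = runs$chrom[k],
      start = runs$pos_min[k] - 1, end = as.numeric(runs$pos_max[k]),
      n_sites = runs$n_cand[k], n_sites_span = length(use),
      level_a = la, level_b = lb, diff = la - lb,
      p = 2 * pnorm(-sum(z) / sqrt(length(z)))
    )
  }) |>
    filter(abs(.data$diff) >= min_diff, .data$p < alpha) |>
    mutate(direction = ifelse(.data$diff < 0, "A_hypo", "B_hypo")) |>
    select(
      "chrom", "start", "end", "n_sites", "n_sites_span", "level_a",
      "level_b", "diff", "p", "direction"
    ) |>
    arrange(.data$chrom, .data$start)
  dmr_set_tbl(regions, min_diff, alpha, max_gap_bp, min_sites)
}

dmr_set_tbl <- function(x, min_diff, alpha, max_gap_bp, min_sites) {
  structure(
    x,
    class = c("dmr_set", class(tibble())),
    summary = list(
      n = nrow(x),
      total_bp = sum(x$end - x$start),
      mean_abs_diff = if (nrow(x)) mean(abs(x$diff)) else NA_real_
    ),
    params = list(
      min_diff = min_diff, alpha = alpha,
      max_gap_bp = max_gap_bp, min_sites = min_sites
    )
  )
}

# normalise replicate input to aligned site table + count matrices
replicate_wide <- function(tables, contexts) {
  if (is.data.frame(tables)) {
    tbl <- tables
    if (!"sample" %in% names(tbl)) tbl$sample <- "rep1"
  } else {
    tbl <- purrr::imap_dfr(tables, function(x, i) {
      x$sample <- paste0("rep", i)
      x
    })
  }
  assert_allc(tbl)
  tbl <- tbl |>
    mutate(.ctx = context_class(.data$context)) |>
    filter(.data$.ctx %in% contexts)
  if (nrow(tbl) == 0L) {
    return(list(
      sites = tibble(
        chrom = character(), pos = numeric(), strand = character(),
        idx = integer()
      ),
      mc = matrix(0, 0, 0), cov = matrix(0, 0, 0)
    ))
  }
  samples <- unique(tbl$sample)
  key <- paste(tbl$chrom, tbl$pos, tbl$strand, sep = "\r")
  ukey <- unique(key)
  row <- match(key, ukey)
  col <- match(tbl$sample, samples)
  mc <- matrix(0, length(ukey), length(samples))
  cv <- matrix(0, length(ukey), length(samples))
  mc[cbind(row, col)] <- tbl$mc
  cv[cbind(row, col)] <- tbl$cov
  first <- !duplicated(key)
  sites <- tibble(
    chrom = tbl$chrom[first], pos = tbl$pos[first],
    strand = tbl$strand[first], idx = seq_along(ukey)
  )
  list(sites = sites, mc = mc, cov = cv)
}

#' Compare two DMR sets
#'
#' Reports set-specific and shared (>= 1 bp overlap) region counts and the
#' base-pair Jaccard index between the two sets, the machinery used to
#' contrast DMRs called under different conditions.
#'
#' @param dmrs_1,dmrs_2 Tibbles with chrom, start, end (0-based
#'   half-open).
#' @return One-row tibble: n_1, n_2, shared_1, shared_2, specific_1,
#'   specific_2, bp_1, bp_2, bp_intersect, bp_union, jaccard_bp.
#' @export
compare_dmr_sets <- function(dmrs_1, dmrs_2) {
  bp <- function(x) sum(x$end - x$start)
  inter_bp <- interval_intersect_bp(dmrs_1, dmrs_2)
  union_bp <- bp(merge_intervals(dmrs_1)) + bp(merge_intervals(dmrs_2)) - inter_bp
  ov1 <- overlaps_any(dmrs_1, dmrs_2)
  ov2 <- overlaps_any(dmrs_2, dmrs_1)
  tibble(
    n_1 = nrow(dmrs_1), n_2 = nrow(dmrs_2),
    shared_1 = sum(ov1), shared_2 = sum(ov2),
    specific_1 = sum(!ov1), specific_2 = sum(!ov2),
    bp_1 = bp(dmrs_1), bp_2 = bp(dmrs_2),
    bp_intersect = inter_bp, bp_union = union_bp,
    jaccard_bp = if (union_bp > 0) inter_bp / union_bp else NA_real_
  )
}

# merge overlapping 0-based half-open intervals per chromosome
merge_intervals <- function(x) {
  if (nrow(x) == 0L) return(tibble(chrom = character(), start = numeric(), end = numeric()))
  x |>
    mutate(start = as.numeric(.data$start), end = as.numeric(.data$end)) |>
    arrange(.data$chrom, .data$start) |>
    group_by(.data$chrom) |>
    mutate(grp = cumsum(.data$start > cummax(dplyr::lag(.data$end, default = -Inf)))) |>
    group_by(.data$chrom, .data$grp) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
    select("chrom", "start", "end")
}

interval_intersect_bp <- function(a, b) {
  a <- merge_intervals(a)
  b <- merge_intervals(b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  pairs <- inner_join(a, b, by = "chrom", suffix = c("_a", "_b"),
    relationship = "many-to-many"
  )
  sum(pmax(
    pmin(pairs$end_a, pairs$end_b) - pmax(pairs$start_a, pairs$start_b), 0
  ))
}

overlaps_any <- function(a, b) {
  if (nrow(a) == 0L) return(logical(0))
  if (nrow(b) == 0L) return(rep(FALSE, nrow(a)))
  vapply(seq_len(nrow(a)), function(i) {
    sel <- b$chrom == a$chrom[i]
    any(b$start[sel] < a$end[i] & b$end[sel] > a$start[i])
  }, logical(1))
}

#' @method print dmr_set
#' @export
print.dmr_set <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf(
    "<dmr_set> %d regions, %.0f bp total, mean |diff| %.3f\n",
    s$n, s$total_bp, s$mean_abs_diff
  ))
  NextMethod()
}
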