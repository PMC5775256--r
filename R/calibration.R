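#' Assemble a set of calibration rates
#'
#' @param ncr,r_tab,s_tab,t_tab Point estimates in `[0, 1)` (NCR:
#'   bisulfite non-conversion in the BS assay; r/s/t: non-conversion,
#'   non-oxidation and non-protection in the TAB assay).
#' @return A tibble of class `calibration_rates` with one row per rate
#'   (columns: rate, estimate, conf_low, conf_high, numerator,
#'   denominator).
#' @export
#' @examples
#' calibration_rates(ncr = 0.005, r_tab = 0.003, s_tab = 0.02, t_tab = 0.08)
calibration_rates <- function(ncr = NA_real_, r_tab = NA_real_,
                              s_tab = NA_real_, t_tab = NA_real_) {
  new_calibration_rates(tibble(
    rate = c("ncr", "r_tab", "s_tab", "t_tab"),
    estimate = c(ncr, r_tab, s_tab, t_tab),
    conf_low = NA_real_, conf_high = NA_real_,
    numerator = NA_real_, denominator = NA_real_
  ))
}

new_calibration_rates <- function(x) {
  structure(x, class = c("calibration_rates", class(tibble())))
}

rate_value <- function(rates, name) {
  if (is.data.frame(rates)) {
    v <- rates$estimate[match(name, rates$rate)]
  } else {
    v <- rates[[name]]
  }
  if (is.null(v) || length(v) != 1L || is.na(v)) {
    abort(sprintf("rate `%s` is missing", name))
  }
  v
}

# pooled ratio-of-sums rate with Clopper-Pearson interval
pooled_rate_row <- function(name, m, c) {
  if (c <= 0) abort(sprintf("zero total coverage when estimating %s", name))
  ci <- cp_interval(m, c)
  tibble(
    rate = name, estimate = m / c, conf_low = ci[1], conf_high = ci[2],
    numerator = m, denominator = c
  )
}

#' Estimate the bisulfite non-conversion rate from an unmethylated spike-in
#'
#' Pools methylated and total calls over every cytosine of the fully
#' unmethylated control contig (ratio of sums, the maximum-likelihood
#' estimate weighting sites by coverage) and attaches a Clopper-Pearson
#' 95% interval.
#'
#' @param spikein_bs Allc-style tibble of BS-assay spike-in counts.
#' @param contig Name of the unmethylated control contig.
#' @param known_contigs Contigs that may legitimately appear alongside it
#'   (methylated calls on any other contig draw a warning).
#' @return One-row `calibration_rates` tibble (rate = "ncr").
#' @export
#' @examples
#' tbl <- tibble::tibble(chrom = "spike_unmeth", pos = 1:4, strand = "+",
#'                       context = "CGA", mc = c(0, 1, 0, 0), cov = 25)
#' estimate_ncr(tbl)
estimate_ncr <- function(spikein_bs, contig = "spike_unmeth",
                         known_contigs = c(
                           "spike_unmeth", "spike_meth_cg", "spike_hmc"
                         )) {
  assert_allc(spikein_bs, "spikein_bs")
  unknown <- !spikein_bs$chrom %in% c(contig, known_contigs)
  if (any(unknown & spikein_bs$mc > 0)) {
    warn("spike-in BS table has nonzero methylated calls on unknown contigs; they are ignored")
  }
  x <- filter(spikein_bs, .data$chrom == contig)
  if (nrow(x) == 0L || sum(x$cov) == 0) {
    abort(sprintf("no coverage on contig '%s' for NCR estimation", contig))
  }
  new_calibration_rates(pooled_rate_row("ncr", sum(x$mc), sum(x$cov)))
}

#' Correct a methylation fraction for bisulfite non-conversion
#'
#' Maximum-likelihood correction `g[((m/c) - NCR) / (1 - NCR)]` with
#' `g[x] = max(x, 0)`; estimates are additionally capped at 1 so corrected
#' values stay probabilities (sampling noise can push the raw ratio above
#' the ceiling). Vectorised over sites; `c = 0` yields `NA` (undefined,
#' distinct from a true 0).
#'
#' @param m Methylated call counts.
#' @param c Total call counts.
#' @param ncr Non-conversion rate in `[0, 1)`.
#' @return Corrected methylation fractions in `[0, 1]`.
#' @export
#' @examples
#' correct_mc(30, 100, 0.1) # (0.3 - 0.1) / 0.9
correct_mc <- function(m, c, ncr) {
  if (length(ncr) != 1L || !is.finite(ncr) || ncr < 0 || ncr >= 1) {
    abort("`ncr` must be a single value in [0, 1)")
  }
  if (any(m < 0 | m > c, na.rm = TRUE)) abort("need 0 <= m <= c")
  out <- ((m / c) - ncr) / (1 - ncr)
  out[c == 0] <- NA_real_
  pmin(pmax(out, 0), 1)
}

#' Estimate TAB-Seq error rates from the three spike-in contigs
#'
#' `r_tab` is the pooled unconverted fraction over all cytosines of the
#' unmethylated contig; `s_tab` the pooled unconverted fraction at CG sites
#' of the fully methylated contig. `t_tab` comes from the
#' hydroxymethylated contig, whose true per-site 5hmC abundance `a` is
#' first measured from its matched BS-assay table (NCR-corrected), because
#' real 5hmC spike-ins are not 100% hydroxymethylated. The TAB unconverted
#' fraction on that contig follows
#' `q_C = (1 - t) a + s a + r (1 - a)` under the assay model, which is
#' solved for `t` and clamped to `[0, 1]`. Confidence limits for `t`
#' propagate the Clopper-Pearson interval of `q_C` at fixed `a`, `r`, `s`.
#'
#' @param spikein_tab Allc tibble of TAB-assay counts for all three
#'   contigs.
#' @param spikein_c_bs Allc tibble of BS-assay counts for the
#'   hydroxymethylated contig (matched batch).
#' @param ncr NCR of the BS assay used for `spikein_c_bs` (corrects the
#'   abundance measurement).
#' @param contigs Named character vector mapping roles `unmeth`, `meth`,
#'   `hmc` to contig names.
#' @return A `calibration_rates` tibble with rows r_tab, s_tab, t_tab and
#'   attribute `hmc_abundance`.
#' @export
estimate_tab_rates <- function(spikein_tab, spikein_c_bs, ncr = 0,
                               contigs = c(
                                 unmeth = "spike_unmeth",
                                 meth = "spike_meth_cg",
                                 hmc = "spike_hmc"
                               )) {
  assert_allc(spikein_tab, "spikein_tab")
  assert_allc(spikein_c_bs, "spikein_c_bs")
  for (role in c("unmeth", "meth", "hmc")) {
    if (!any(spikein_tab$chrom == contigs[[role]])) {
      abort(sprintf("TAB table lacks the '%s' contig (%s)", role, contigs[[role]]))
    }
  }
  un <- filter(spikein_tab, .data$chrom == contigs[["unmeth"]])
  r_row <- pooled_rate_row("r_tab", sum(un$mc), sum(un$cov))

  me <- filter(
    spikein_tab,
    .data$chrom == contigs[["meth"]], context_class(.data$context) == "CG"
  )
  s_row <- pooled_rate_row("s_tab", sum(me$mc), sum(me$cov))

  hm_bs <- filter(
    spikein_c_bs,
    .data$chrom == contigs[["hmc"]], context_class(.data$context) == "CG"
  )
  if (nrow(hm_bs) == 0L || sum(hm_bs$cov) == 0) {
    abort("matched BS table has no CG coverage on the hmC contig")
  }
  a <- correct_mc(sum(hm_bs$mc), sum(hm_bs$cov), ncr)

  hm <- filter(
    spikein_tab,
    .data$chrom == contigs[["hmc"]], context_class(.data$context) == "CG"
  )
  q_row <- pooled_rate_row("q_hmc", sum(hm$mc), sum(hm$cov))
  r <- r_row$estimate
  s <- s_row$estimate
  if (a <= r) {
    abort(sprintf(
      "hmC spike-in abundance (%.4f) does not exceed the non-conversion rate (%.4f); t is unidentifiable",
      a, r
    ))
  }
  solve_t <- function(q) min(max(1 - (q - s * a - r * (1 - a)) / a, 0), 1)
  t_hat <- solve_t(q_row$estimate)
  # delta-method s.e. over all binomial components:
  # t = 1 - (q - s*a - r*(1-a))/a, so dt/dq = -1/a, dt/ds = 1,
  # dt/dr = (1-a)/a, dt/da = (q - r)/a^2
  q_hat <- q_row$estimate
  binom_se <- function(p, n) sqrt(pmax(p * (1 - p), 1e-12) / n)
  se_q <- binom_se(q_hat, q_row$denominator)
  se_r <- binom_se(r, r_row$denominator)
  se_s <- binom_se(s, s_row$denominator)
  se_a <- binom_se(a, sum(hm_bs$cov)) / (1 - ncr)
  se_t <- sqrt(
    se_q^2 / a^2 + se_s^2 + se_r^2 * (1 - a)^2 / a^2 +
      se_a^2 * (q_hat - r)^2 / a^4
  )
  t_row <- tibble(
    rate = "t_tab",
    estimate = t_hat,
    conf_low = max(t_hat - 1.96 * se_t, 0),
    conf_high = min(t_hat + 1.96 * se_t, 1),
    numerator = q_row$numerator, denominator = q_row$denominator
  )
  out <- new_calibration_rates(bind_rows(r_row, s_row, t_row))
  attr(out, "hmc_abundance") <- a
  attr(out, "t_se") <- se_t
  out
}

#' Correct a TAB-Seq fraction to a hydroxymethylation level
#'
#' Applies `p_hmC = g[(q - s * p_mC - r * (1 - p_mC)) / (1 - t)]` with
#' `g[x] = max(x, 0)`, where `p_mC` is the NCR-corrected mC+hmC fraction
#' from the matched BS sample at the same site. Results are additionally
#' capped at `p_mC` (hydroxymethylation cannot exceed total methylation).
#'
#' @param q_tab Raw TAB-assay unconverted fraction(s).
#' @param p_mc Matched corrected total methylation fraction(s).
#' @param rates A `calibration_rates` tibble or named list with `r_tab`,
#'   `s_tab`, `t_tab`.
#' @return Corrected hmC fraction(s) in `[0, p_mc]`.
#' @export
#' @examples
#' rates <- calibration_rates(r_tab = 0.01, s_tab = 0.05, t_tab = 0.1)
#' correct_hmc(0.3, 0.5, rates) # (0.3 - 0.025 - 0.005) / 0.9
correct_hmc <- function(q_tab, p_mc, rates) {
  r <- rate_value(rates, "r_tab")
  s <- rate_value(rates, "s_tab")
  t <- rate_value(rates, "t_tab")
  for (v in list(r = r, s = s, t = t)) assert_prob(v, "rate")
  if (t >= 1) abort("t_tab must be < 1")
  assert_prob(q_tab[!is.na(q_tab)], "q_tab")
  assert_prob(p_mc[!is.na(p_mc)], "p_mc")
  out <- (q_tab - s * p_mc - r * (1 - p_mc)) / (1 - t)
  pmin(pmax(out, 0), p_mc)
}

#' Join matched BS and TAB tables and correct both levels site-wise
#'
#' Sites are joined on (chrom, pos, strand); every BS-covered site gets an
#' NCR-corrected total methylation level `p_mc`, and CG sites with TAB
#' coverage and BS coverage of at least `min_bs_coverage` also get a
#' corrected hydroxymethylation level `p_hmc` (below that depth `p_hmc` is
#' withheld rather than imputed from a noisy `p_mc`). Counts of joined and
#' unjoined sites are reported via a message.
#'
#' @param bs,tab Allc-style tibbles for the same biological sample.
#' @param rates `calibration_rates` with ncr, r_tab, s_tab, t_tab.
#' @param min_bs_coverage Minimum BS depth required to report `p_hmc`.
#' @return Tibble: chrom, pos, strand, context, raw_frac, p_mc, p_hmc,
#'   cov_bs, cov_tab.
#' @export
correct_table <- function(bs, tab, rates, min_bs_coverage = 3) {
  assert_allc(bs, "bs")
  ncr <- rate_value(rates, "ncr")
  if (!is.null(tab) && nrow(tab) > 0) assert_allc(tab, "tab")
  tab_j <- if (is.null(tab) || nrow(tab) == 0) {
    tibble(
      chrom = character(), pos = numeric(), strand = character(),
      context_tab = character(), mc_tab = numeric(), cov_tab = numeric()
    )
  } else {
    select(tab,
      "chrom", "pos", "strand",
      context_tab = "context", mc_tab = "mc", cov_tab = "cov"
    )
  }
  joined <- left_join(
    select(bs, "chrom", "pos", "strand", "context", "mc", "cov"),
    tab_j,
    by = c("chrom", "pos", "strand")
  )
  conflict <- !is.na(joined$context_tab) & joined$context_tab != joined$context
  if (any(conflict)) {
    abort(sprintf(
      "%d joined sites have conflicting trinucleotide contexts between assays",
      sum(conflict)
    ))
  }
  n_joined <- sum(!is.na(joined$cov_tab))
  inform(sprintf(
    "correct_table: %d BS sites, %d with matched TAB coverage, %d BS-only",
    nrow(joined), n_joined, nrow(joined) - n_joined
  ))
  if (n_joined == 0L && !is.null(tab) && nrow(tab) > 0) {
    warn("no sites joined between BS and TAB tables; check coordinates")
  }
  joined |>
    mutate(
      raw_frac = ifelse(.data$cov > 0, .data$mc / .data$cov, NA_real_),
      p_mc = correct_mc(.data$mc, .data$cov, ncr),
      q_tab = ifelse(.data$cov_tab > 0, .data$mc_tab / .data$cov_tab, NA_real_),
      p_hmc = ifelse(
        context_class(.data$context) == "CG" &
          !is.na(.data$q_tab) & .data$cov >= min_bs_coverage,
        correct_hmc(.data$q_tab, .data$p_mc, rates),
        NA_real_
      )
    ) |>
    select(
      "chrom", "pos", "strand", "context", "raw_frac", "p_mc", "p_hmc",
      cov_bs = "cov", "cov_tab"
    )
}
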