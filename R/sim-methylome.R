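#' Simulate per-site true methylation states
#'
#' Assigns every catalogued cytosine a true methylation-only probability
#' `p_mc_only` and hydroxymethylation probability `p_hmc` for each group
#' (dorsal/ventral x SH/EE). CG sites draw beta noise around the mCG
#' baseline; sites inside a true DMR have the hypomethylated region's mean
#' lowered by that DMR's true difference. CH sites sit at the per-region
#' mCH means (ventral about twice dorsal under the defaults, the regional
#' asymmetry the pipeline must recover). Hydroxymethylation is placed at CG
#' sites only unless `allow_ch_hmc` is set. The housing condition does not
#' alter the true methylome: EE groups share their region's state, so any
#' EE/SH contrast is null in truth.
#'
#' @param catalog Cytosine catalogue from [simulate_genome()].
#' @param config A [sim_config()].
#' @param truth Optional tibble of true DMRs from [simulate_dmr_truth()];
#'   when `NULL` no DMRs are implanted.
#' @return A list with `state` (tibble: site columns + group, p_mc_only,
#'   p_hmc) and `true_dmrs`.
#' @export
simulate_methylome <- function(catalog, config, truth = NULL) {
  if (nrow(catalog) == 0L) abort("catalog is empty")
  validate_sim_config(config)
  n <- nrow(catalog)
  is_cg <- catalog$context_class == "CG"

  # site-level baselines are SHARED between regions: biological site effects
  # are common to dorsal and ventral, so the only true regional differences
  # are the implanted DMRs and the global CH scaling. A no-implant run is
  # therefore genuinely null at CG sites.
  shared <- with_substream(config$seed, "methylome_base", {
    list(
      base_cg = rbeta_mean(n, config$baseline_mcg, config$beta_concentration),
      ch_base = rbeta_mean(n, config$mch_dorsal, config$beta_concentration),
      hm = rbeta_mean(n, config$hmcg_level, config$beta_concentration)
    )
  })

  region_state <- function(region) {
    p_total <- ifelse(is_cg, shared$base_cg, shared$ch_base)
    if (region == "ventral") {
      ratio <- config$mch_ventral / max(config$mch_dorsal, 1e-12)
      p_total[!is_cg] <- pmin(p_total[!is_cg] * ratio, 0.99)
    }
    if (!is.null(truth) && nrow(truth) > 0) {
      hypo_dir <- paste0(region, "_hypo")
      for (i in seq_len(nrow(truth))) {
        if (truth$direction[i] != hypo_dir) next
        inside <- is_cg &
          catalog$chrom == truth$chrom[i] &
          catalog$pos > truth$start[i] &
          catalog$pos <= truth$end[i]
        p_total[inside] <- pmax(p_total[inside] - truth$true_diff[i], 0.01)
      }
    }
    hm <- ifelse(is_cg | config$allow_ch_hmc, shared$hm, 0)
    p_hmc <- pmin(hm, p_total)
    tibble(
      chrom = catalog$chrom, pos = catalog$pos, strand = catalog$strand,
      context = catalog$context, context_class = catalog$context_class,
      p_mc_only = p_total - p_hmc, p_hmc = p_hmc
    )
  }

  dorsal <- region_state("dorsal")
  ventral <- region_state("ventral")
  state <- bind_rows(
    mutate(dorsal, group = "dorsal_SH", .before = 1),
    mutate(dorsal, group = "dorsal_EE", .before = 1),
    mutate(ventral, group = "ventral_SH", .before = 1),
    mutate(ventral, group = "ventral_EE", .before = 1)
  )
  list(state = state, true_dmrs = truth)
}

#' Simulate bisulfite-assay counts from a true methylation state
#'
#' Coverage is Poisson (mean `coverage_mean`) truncated at 1; methylated
#' calls are binomial with read-level probability
#' `p_total + (1 - p_total) * ncr_true`, since both mC and hmC resist
#' bisulfite conversion and unmethylated cytosines fail to convert at the
#' non-conversion rate.
#'
#' @param state Tibble with site columns and `p_mc_only`, `p_hmc` (one
#'   group).
#' @param config A [sim_config()].
#' @param sample_id Sample label stored in the output.
#' @param coverage_mean Override of the configured mean coverage.
#' @return An allc-style tibble (chrom, pos, strand, context, mc, cov,
#'   assay = "BS", sample).
#' @export
simulate_bs_counts <- function(state, config, sample_id = "bs1",
                               coverage_mean = config$coverage_mean) {
  p_total <- state$p_mc_only + state$p_hmc
  assert_prob(p_total, "p_mc_only + p_hmc")
  with_substream(config$seed, paste0("bs_", sample_id), {
    cov <- rtpois(nrow(state), coverage_mean)
    p_read <- p_total + (1 - p_total) * config$ncr_true
    tibble(
      chrom = state$chrom, pos = state$pos, strand = state$strand,
      context = state$context, mc = rbinom(nrow(state), cov, p_read),
      cov = cov, assay = "BS", sample = sample_id
    )
  })
}

#' Simulate TAB-assay counts from a true methylation state
#'
#' The unconverted (read-as-methylated) fraction follows the forward model
#' `q = (1 - t) * p_hmc + s * p_total + r * (1 - p_total)` with
#' `p_total = p_mc_only + p_hmc`: protected hmC survives conversion except
#' for the non-protection rate `t`, total methylation leaks through at the
#' non-oxidation rate `s`, and unmethylated cytosines fail to convert at
#' rate `r`. This is the exact inverse of the hmC correction applied by
#' [correct_hmc()].
#'
#' @inheritParams simulate_bs_counts
#' @return An allc-style tibble with assay = "TAB".
#' @export
simulate_tab_counts <- function(state, config, sample_id = "tab1",
                                coverage_mean = config$coverage_mean) {
  p_total <- state$p_mc_only + state$p_hmc
  q <- (1 - config$t_true) * state$p_hmc +
    config$s_true * p_total + config$r_true * (1 - p_total)
  if (any(!is.finite(q) | q < 0 | q > 1)) {
    abort("TAB forward model produced q outside [0, 1]; check rates/states")
  }
  with_substream(config$seed, paste0("tab_", sample_id), {
    cov <- rtpois(nrow(state), coverage_mean)
    tibble(
      chrom = state$chrom, pos = state$pos, strand = state$strand,
      context = state$context, mc = rbinom(nrow(state), cov, q),
      cov = cov, assay = "TAB", sample = sample_id
    )
  })
}

#' Simulate spike-in control contigs and their assay counts
#'
#' Three control contigs drive rate estimation: `spike_unmeth` (fully
#' unmethylated, lambda-like; estimates the bisulfite non-conversion rate
#' in the BS assay and `r` in the TAB assay), `spike_meth_cg` (fully
#' CG-methylated; estimates the non-oxidation rate `s`), and `spike_hmc`
#' (hydroxymethylated at CG sites with purity `hmc_spike_purity`;
#' estimates the non-protection rate `t`). Because the hmC contig's true
#' 5hmC abundance is below 1, a matched BS-assay table for it is also
#' produced so its abundance can be measured and corrected for, exactly as
#' one would re-sequence the spike-in batch by ordinary bisulfite.
#'
#' @param config A [sim_config()].
#' @return A list: `bs` (allc tibble for `spike_unmeth` + `spike_hmc`
#'   under BS), `tab` (all three contigs under TAB), `catalog`, and
#'   `truth` (per-contig true states).
#' @export
simulate_spikeins <- function(config) {
  validate_sim_config(config)
  seqs <- with_substream(config$seed, "spike_seq", {
    vapply(1:3, function(i) {
      paste(sample(c("A", "C", "G", "T"), config$spikein_length_bp,
        replace = TRUE
      ), collapse = "")
    }, character(1))
  })
  contigs <- c("spike_unmeth", "spike_meth_cg", "spike_hmc")
  catalog <- purrr::map2_dfr(seqs, contigs, catalog_cytosines)

  state_for <- function(contig) {
    cat_i <- filter(catalog, .data$chrom == contig)
    is_cg <- cat_i$context_class == "CG"
    p_mc_only <- p_hmc <- rep(0, nrow(cat_i))
    if (contig == "spike_meth_cg") p_mc_only[is_cg] <- 1
    if (contig == "spike_hmc") p_hmc[is_cg] <- config$hmc_spike_purity
    mutate(cat_i, p_mc_only = p_mc_only, p_hmc = p_hmc)
  }
  states <- setNames(lapply(contigs, state_for), contigs)

  bs <- bind_rows(
    simulate_bs_counts(states$spike_unmeth, config, "spike_bs",
      coverage_mean = config$spikein_coverage_mean
    ),
    simulate_bs_counts(states$spike_hmc, config, "spike_hmc_bs",
      coverage_mean = config$spikein_coverage_mean
    )
  )
  tab <- purrr::imap_dfr(states, function(st, contig) {
    simulate_tab_counts(st, config, paste0(contig, "_tab"),
      coverage_mean = config$spikein_coverage_mean
    )
  })
  list(bs = bs, tab = tab, catalog = catalog, truth = states)
}
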