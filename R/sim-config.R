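#' Simulation configuration
#'
#' Builds the configuration object for the forward simulator. Defaults
#' describe the study conditions the package is designed around: a
#' mouse-like GC fraction, dentate-gyrus-scale methylation levels (mCG
#' baseline 75%, mCH a few percent with ventral twice dorsal, hmCG ~15% at
#' CG sites only), ~15x per-sample coverage, five biological replicates per
#' group, differentially methylated regions with a mean dorsal-ventral
#' difference of 26% (s.d. 4.5% across regions) and ~200 bp scale, and
#' assay error rates of the magnitude estimated from lambda/pUC19 spike-ins
#' (bisulfite non-conversion ~0.5%).
#'
#' @param genome_size Base pairs per chromosome.
#' @param n_chromosomes Number of chromosomes.
#' @param gc_fraction Fraction of G+C bases.
#' @param n_genes,gene_length_bp Gene count and (fixed) gene length used
#'   when placing gene annotations on the simulated genome.
#' @param n_de_genes Number of truly differentially expressed genes.
#' @param de_log2fc Log2 fold change applied to true DE genes.
#' @param de_target Which design cell carries the expression effect:
#'   `"ee_dorsal"` (enrichment effect in dorsal samples), `"ee_ventral"`,
#'   or `"region"` (dorsal vs ventral in both conditions).
#' @param expr_dispersion Negative-binomial dispersion of simulated counts.
#' @param expr_mean_log,expr_sd_log Log-normal parameters of baseline gene
#'   means.
#' @param n_dmrs Number of implanted DMRs.
#' @param dmr_mean_diff Mean true methylation difference inside DMRs.
#' @param dmr_diff_sd Between-DMR s.d. of the true difference.
#' @param dmr_length_bp Mean DMR length (log-normal lengths).
#' @param dmr_dorsal_fraction Fraction of DMRs hypomethylated in dorsal
#'   (the remainder are ventral-hypomethylated).
#' @param baseline_mcg Mean CG methylation outside DMRs.
#' @param mch_dorsal,mch_ventral Mean CH methylation per region.
#' @param hmcg_level Mean hydroxymethylation at CG sites.
#' @param beta_concentration Concentration of the site-level beta noise.
#' @param allow_ch_hmc Place hmC at CH sites too (negative-control use
#'   only; off by default, matching the empirical absence of CH
#'   hydroxymethylation in neurons).
#' @param coverage_mean Mean per-site read coverage (truncated Poisson).
#' @param spikein_coverage_mean Mean coverage on spike-in contigs.
#' @param spikein_length_bp Length of each spike-in contig.
#' @param ncr_true Bisulfite non-conversion rate (BS assay).
#' @param r_true,s_true,t_true TAB assay non-conversion, non-oxidation and
#'   non-protection rates.
#' @param hmc_spike_purity Per-site 5hmC abundance of the hydroxymethylated
#'   spike-in contig (deliberately < 1: real spike-ins are not fully
#'   converted to 5hmC, and the calibration must correct for that).
#' @param n_replicates Biological replicates per group.
#' @param seed Master seed; all substreams derive from it.
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(genome_size = 1e4, n_genes = 4, n_de_genes = 1, n_dmrs = 2)
#' cfg$dmr_mean_diff
sim_config <- function(genome_size = 1e6,
                       n_chromosomes = 2,
                       gc_fraction = 0.42,
                       n_genes = 400,
                       gene_length_bp = 2000,
                       n_de_genes = 40,
                       de_log2fc = 1,
                       de_target = c("ee_dorsal", "ee_ventral", "region"),
                       expr_dispersion = 0.05,
                       expr_mean_log = 4,
                       expr_sd_log = 1.5,
                       n_dmrs = 100,
                       dmr_mean_diff = 0.26,
                       dmr_diff_sd = 0.045,
                       dmr_length_bp = 200,
                       dmr_dorsal_fraction = 1,
                       baseline_mcg = 0.75,
                       mch_dorsal = 0.02,
                       mch_ventral = 0.04,
                       hmcg_level = 0.15,
                       beta_concentration = 30,
                       allow_ch_hmc = FALSE,
                       coverage_mean = 15,
                       spikein_coverage_mean = 50,
                       spikein_length_bp = 3000,
                       ncr_true = 0.005,
                       r_true = 0.003,
                       s_true = 0.02,
                       t_true = 0.08,
                       hmc_spike_purity = 0.9,
                       n_replicates = 5,
                       seed = 1) {
  cfg <- list(
    genome_size = as.numeric(genome_size),
    n_chromosomes = as.integer(n_chromosomes),
    gc_fraction = gc_fraction,
    n_genes = as.integer(n_genes),
    gene_length_bp = as.numeric(gene_length_bp),
    n_de_genes = as.integer(n_de_genes),
    de_log2fc = de_log2fc,
    de_target = match.arg(de_target),
    expr_dispersion = expr_dispersion,
    expr_mean_log = expr_mean_log,
    expr_sd_log = expr_sd_log,
    n_dmrs = as.integer(n_dmrs),
    dmr_mean_diff = dmr_mean_diff,
    dmr_diff_sd = dmr_diff_sd,
    dmr_length_bp = as.numeric(dmr_length_bp),
    dmr_dorsal_fraction = dmr_dorsal_fraction,
    baseline_mcg = baseline_mcg,
    mch_dorsal = mch_dorsal,
    mch_ventral = mch_ventral,
    hmcg_level = hmcg_level,
    beta_concentration = beta_concentration,
    allow_ch_hmc = isTRUE(allow_ch_hmc),
    coverage_mean = coverage_mean,
    spikein_coverage_mean = spikein_coverage_mean,
    spikein_length_bp = as.numeric(spikein_length_bp),
    ncr_true = ncr_true,
    r_true = r_true,
    s_true = s_true,
    t_true = t_true,
    hmc_spike_purity = hmc_spike_purity,
    n_replicates = as.integer(n_replicates),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  probs <- c(
    "gc_fraction", "dmr_mean_diff", "dmr_dorsal_fraction", "baseline_mcg",
    "mch_dorsal", "mch_ventral", "hmcg_level", "ncr_true", "r_true",
    "s_true", "t_true", "hmc_spike_purity"
  )
  for (p in probs) assert_prob(cfg[[p]], p)
  if (cfg$coverage_mean <= 0 || cfg$spikein_coverage_mean <= 0) {
    abort("coverage means must be > 0")
  }
  if (cfg$dmr_length_bp >= cfg$genome_size) {
    abort("dmr_length_bp must be smaller than genome_size")
  }
  if (cfg$n_de_genes > cfg$n_genes) abort("n_de_genes cannot exceed n_genes")
  if (cfg$n_replicates < 1) abort("n_replicates must be >= 1")
  invisible(cfg)
}

#' Read a simulation configuration from YAML
#'
#' Fields absent from the file keep their [sim_config()] defaults.
#'
#' @param path Path to a YAML file whose keys match [sim_config()]
#'   arguments.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown)) {
    abort(paste("unknown config fields:", paste(unknown, collapse = ", ")))
  }
  do.call(sim_config, vals)
}

#' @method print sim_config
#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf(
    "  genome: %d x %.0f bp (GC %.2f); %d genes, %d DMRs (mean diff %.2f)\n",
    x$n_chromosomes, x$genome_size, x$gc_fraction, x$n_genes, x$n_dmrs,
    x$dmr_mean_diff
  ))
  cat(sprintf(
    "  methylome: mCG %.2f, mCH d/v %.3f/%.3f, hmCG %.2f; coverage %.1fx\n",
    x$baseline_mcg, x$mch_dorsal, x$mch_ventral, x$hmcg_level, x$coverage_mean
  ))
  cat(sprintf(
    "  rates: ncr %.4f, r %.4f, s %.4f, t %.4f; spike purity %.2f; seed %d\n",
    x$ncr_true, x$r_true, x$s_true, x$t_true, x$hmc_spike_purity, x$seed
  ))
  invisible(x)
}
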