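test_that("cytosine catalogue reads contexts off both strands", {
  cat1 <- catalog_cytosines("ACGTAA", "toy")
  plus <- cat1[cat1$strand == "+", ]
  minus <- cat1[cat1$strand == "-", ]
  expect_equal(plus$pos, 2)
  expect_equal(plus$context_class, "CG")
  # the G at position 3 is a CG-context cytosine on the reverse strand
  expect_equal(minus$pos, 3)
  expect_equal(minus$context_class, "CG")

  cat2 <- catalog_cytosines("ACATAA", "toy")
  expect_equal(cat2$pos, 2)
  expect_equal(cat2$strand, "+")
  expect_equal(cat2$context_class, "CA")

  # every catalogued cytosine falls in exactly one context class
  cat3 <- tiny_genome()$catalog
  expect_true(all(cat3$context_class %in% c("CG", "CA", "CC", "CT")))
  expect_true(all(substr(cat3$context, 1, 1) == "C"))
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- tiny_config()
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(as.character(g1$sequences), as.character(g2$sequences))
  expect_identical(g1$catalog, g2$catalog)

  ex1 <- simulate_expression(cfg)
  ex2 <- simulate_expression(cfg)
  expect_identical(ex1$counts, ex2$counts)
  expect_identical(ex1$true_de, ex2$true_de)

  sp1 <- simulate_spikeins(cfg)
  sp2 <- simulate_spikeins(cfg)
  expect_identical(sp1$tab, sp2$tab)
})

test_that("genome sizing errors fire when requests cannot fit", {
  expect_error(
    simulate_genome(sim_config(
      genome_size = 5e3, n_chromosomes = 1, n_genes = 100, n_de_genes = 1,
      n_dmrs = 1, dmr_length_bp = 100
    )),
    "too small"
  )
  expect_error(
    simulate_genome(sim_config(
      genome_size = 5e3, n_chromosomes = 1, n_genes = 1, n_de_genes = 1,
      n_dmrs = 500, dmr_length_bp = 100
    )),
    "too small"
  )
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(baseline_mcg = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(coverage_mean = 0), "> 0")
  expect_error(sim_config(genome_size = 100, dmr_length_bp = 200), "smaller")
  expect_error(sim_config(n_genes = 5, n_de_genes = 6), "n_de_genes")
})

test_that("methylome truth implements the configured group structure", {
  me <- tiny_methylome()
  st <- me$state
  # no implants and no condition effect: SH and EE share their region state
  d_sh <- st[st$group == "dorsal_SH", ]
  d_ee <- st[st$group == "dorsal_EE", ]
  expect_identical(d_sh$p_mc_only, d_ee$p_mc_only)
  # hmC only at CG sites
  expect_true(all(st$p_hmc[st$context_class != "CG"] == 0))
  expect_true(all(st$p_mc_only + st$p_hmc <= 1))

  # zero difference => identical states between regions
  cfg0 <- tiny_config()
  me0 <- simulate_methylome(tiny_genome()$catalog, cfg0, NULL)
  d <- me0$state[me0$state$group == "dorsal_SH" & me0$state$context_class == "CG", ]
  v <- me0$state[me0$state$group == "ventral_SH" & me0$state$context_class == "CG", ]
  expect_identical(d$p_mc_only, v$p_mc_only)
})

test_that("implanted DMRs lower the hypomethylated region by the true difference", {
  cfg <- tiny_config()
  td <- simulate_dmr_truth(tiny_genome(), cfg)
  me <- tiny_methylome()
  d <- me$state[me$state$group == "dorsal_SH", ]
  v <- me$state[me$state$group == "ventral_SH", ]
  for (i in seq_len(nrow(td))) {
    inside <- d$context_class == "CG" & d$chrom == td$chrom[i] &
      d$pos > td$start[i] & d$pos <= td$end[i]
    gap <- (v$p_mc_only + v$p_hmc)[inside] - (d$p_mc_only + d$p_hmc)[inside]
    # clipping at the floor can shrink individual gaps, never grow them
    expect_true(all(gap <= td$true_diff[i] + 1e-12))
    expect_gt(mean(gap), 0.8 * td$true_diff[i])
  }
})

test_that("BS counts follow the forward model in the degenerate cases", {
  cfg <- tiny_config()
  st <- tibble::tibble(
    chrom = "chr1", pos = 1:100, strand = "+", context = "CGA",
    context_class = "CG", p_mc_only = 1, p_hmc = 0
  )
  bs <- simulate_bs_counts(st, cfg, "full")
  expect_true(all(bs$mc == bs$cov))

  cfg0 <- tiny_config(ncr_true = 0)
  st0 <- dplyr::mutate(st, p_mc_only = 0)
  bs0 <- simulate_bs_counts(st0, cfg0, "zero")
  expect_true(all(bs0$mc == 0))
  expect_true(all(bs0$cov >= 1))
})

test_that("pooled BS fraction matches the forward-model expectation", {
  # p = 0.5, ncr = 0.01 => expected read-level fraction 0.505
  cfg <- tiny_config(ncr_true = 0.01, coverage_mean = 20)
  n <- 1e5
  st <- tibble::tibble(
    chrom = "chr1", pos = seq_len(n), strand = "+", context = "CGA",
    context_class = "CG", p_mc_only = 0.5, p_hmc = 0
  )
  bs <- simulate_bs_counts(st, cfg, "half")
  frac <- sum(bs$mc) / sum(bs$cov)
  se <- sqrt(0.505 * 0.495 / sum(bs$cov))
  expect_lt(abs(frac - 0.505), 3 * se)
})

test_that("TAB counts follow the unconverted-fraction model", {
  base <- tibble::tibble(
    chrom = "chr1", pos = 1:2000, strand = "+", context = "CGA",
    context_class = "CG"
  )
  cfg_id <- tiny_config(r_true = 0, s_true = 0, t_true = 0)
  hm1 <- dplyr::mutate(base, p_mc_only = 0, p_hmc = 1)
  expect_true(all(with(simulate_tab_counts(hm1, cfg_id, "a"), mc == cov)))
  hm0 <- dplyr::mutate(base, p_mc_only = 0, p_hmc = 0)
  expect_true(all(simulate_tab_counts(hm0, cfg_id, "b")$mc == 0))

  # hand-evaluated q: 0.9*0.2 + 0.03*0.7 + 0.01*0.3 = 0.204
  cfg_q <- tiny_config(
    r_true = 0.01, s_true = 0.03, t_true = 0.1, coverage_mean = 25
  )
  mix <- dplyr::mutate(base, p_mc_only = 0.5, p_hmc = 0.2)
  tab <- simulate_tab_counts(mix, cfg_q, "c")
  frac <- sum(tab$mc) / sum(tab$cov)
  expect_lt(abs(frac - 0.204), 3 * sqrt(0.204 * 0.796 / sum(tab$cov)))
})

test_that("regional mCH asymmetry is reproduced at the configured ratio", {
  cfg <- sim_config(
    genome_size = 3.5e5, n_chromosomes = 1, n_genes = 5, n_de_genes = 1,
    n_dmrs = 1, dmr_length_bp = 100, seed = 4
  )
  g <- simulate_genome(cfg)
  me <- simulate_methylome(g$catalog, cfg, NULL)
  ch <- me$state[me$state$context_class %in% c("CA", "CC", "CT") &
    me$state$group %in% c("dorsal_SH", "ventral_SH"), ]
  expect_gt(sum(ch$group == "dorsal_SH"), 1e5)
  d_bs <- simulate_bs_counts(ch[ch$group == "dorsal_SH", ], cfg, "d")
  v_bs <- simulate_bs_counts(ch[ch$group == "ventral_SH", ], cfg, "v")
  fd <- sum(d_bs$mc) / sum(d_bs$cov)
  fv <- sum(v_bs$mc) / sum(v_bs$cov)
  ratio <- fv / fd
  se_ratio <- ratio * sqrt(
    fd * (1 - fd) / (fd^2 * sum(d_bs$cov)) +
      fv * (1 - fv) / (fv^2 * sum(v_bs$cov))
  )
  # raw read-level ratio is slightly compressed by the non-conversion floor
  expected <- (0.04 + 0.96 * cfg$ncr_true) / (0.02 + 0.98 * cfg$ncr_true)
  expect_lt(abs(ratio - expected), 3 * se_ratio)
})

test_that("spike-in contigs carry their designed methylation states", {
  cfg <- tiny_config(ncr_true = 0, r_true = 0, s_true = 0, t_true = 0)
  sp <- simulate_spikeins(cfg)
  un_bs <- sp$bs[sp$bs$chrom == "spike_unmeth", ]
  expect_true(all(un_bs$mc == 0))
  # pure hmC contig under BS with purity 1 and no errors: fully methylated
  cfg1 <- tiny_config(
    ncr_true = 0, r_true = 0, s_true = 0, t_true = 0, hmc_spike_purity = 1
  )
  sp1 <- simulate_spikeins(cfg1)
  hm_bs <- sp1$bs[sp1$bs$chrom == "spike_hmc" &
    context_class(sp1$bs$context) == "CG", ]
  expect_true(all(hm_bs$mc == hm_bs$cov))

  # methylated contig under TAB: pooled unconverted fraction ~ s
  cfg_s <- tiny_config(s_true = 0.05)
  sp_s <- simulate_spikeins(cfg_s)
  me_tab <- sp_s$tab[sp_s$tab$chrom == "spike_meth_cg" &
    context_class(sp_s$tab$context) == "CG", ]
  expect_gt(sum(me_tab$cov), 1e4)
  frac <- sum(me_tab$mc) / sum(me_tab$cov)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / sum(me_tab$cov)))
})

test_that("expression truth honours fold change, target cell and marker QC", {
  cfg <- tiny_config(n_genes = 50, n_de_genes = 5, de_log2fc = 0)
  ex0 <- simulate_expression(cfg)
  expect_true(all(ex0$true_de$log2fc == 0))

  # near-zero dispersion: group mean ratio approaches the designed fold
  cfg2 <- sim_config(
    genome_size = 2e4, n_chromosomes = 1, n_genes = 50, n_de_genes = 10,
    n_dmrs = 1, dmr_length_bp = 100, de_log2fc = 1,
    expr_dispersion = 1e-4, n_replicates = 20, seed = 2
  )
  ex <- simulate_expression(cfg2)
  aff <- ex$samples$region == "dorsal" & ex$samples$condition == "EE"
  up <- ex$true_de$gene_id[ex$true_de$sign == 1]
  ratios <- rowMeans(ex$counts[up, aff, drop = FALSE]) /
    rowMeans(ex$counts[up, !aff, drop = FALSE])
  expect_true(all(abs(ratios - 2) < 0.2))

  exc <- simulate_expression(cfg2, contaminate = TRUE)
  expect_true(exc$contaminated %in% exc$samples$sample)
  expect_true("Xist" %in% rownames(exc$counts))
})
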