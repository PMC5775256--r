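test_that("TSS distances are signed and strand-oriented", {
  dmr <- tibble::tibble(chrom = "chr1", start = 1400, end = 1600)
  plus <- tibble::tibble(
    gene_id = "g", chrom = "chr1", tss = 1000, strand = "+"
  )
  expect_equal(tss_distance(dmr, plus)$distance, 500)
  minus <- dplyr::mutate(plus, strand = "-")
  expect_equal(tss_distance(dmr, minus)$distance, -500)
  at <- tibble::tibble(chrom = "chr1", start = 900, end = 1100)
  expect_equal(tss_distance(at, plus)$distance, 0)
  # different chromosomes: no pair
  other <- dplyr::mutate(plus, chrom = "chr2")
  expect_equal(nrow(tss_distance(dmr, other)), 0)
})

test_that("enrichment score is DMR density per gene per Mb", {
  genes <- tibble::tibble(
    gene_id = paste0("g", 1:10), chrom = "chr1",
    tss = seq(10000, 100000, length.out = 10), strand = "+"
  )
  # 10 DMRs, each centred exactly on one gene's TSS
  dmrs <- tibble::tibble(
    chrom = "chr1", start = genes$tss - 50, end = genes$tss + 50
  )
  # a single 1-kb bin centred on the TSS
  curve <- enrichment_curve(dmrs, genes, window = 500, bin_width = 1000)
  expect_equal(nrow(curve), 1)
  expect_equal(curve$score, 10 / (10 * 0.001))

  # no DMRs: all-zero curve
  none <- enrichment_curve(dmrs[0, ], genes, window = 1e5, bin_width = 1e4)
  expect_true(all(none$score == 0))

  # doubling the gene set with identical placements leaves the score fixed
  genes2 <- dplyr::bind_rows(genes, dplyr::mutate(genes, gene_id = paste0(gene_id, "b")))
  dmrs2 <- dplyr::bind_rows(dmrs, dmrs)
  c1 <- enrichment_curve(dmrs2, genes, window = 500, bin_width = 1000)
  c2 <- enrichment_curve(dmrs2, genes2, window = 500, bin_width = 1000)
  expect_equal(c1$score[c1$bin_start == 0] * 2, c2$score[c2$bin_start == 0] * 2)
  expect_equal(c2$score[c2$bin_start == 0], c1$score[c1$bin_start == 0])

  expect_error(enrichment_curve(dmrs, genes[0, ]), "empty")
  expect_error(enrichment_curve(dmrs, genes, bin_width = 0), "> 0")
})

test_that("curve matches a brute-force recomputation on small instances", {
  set.seed(21)
  genes <- tibble::tibble(
    gene_id = paste0("g", 1:30),
    chrom = sample(c("chr1", "chr2"), 30, TRUE),
    tss = sample.int(900000, 30),
    strand = sample(c("+", "-"), 30, TRUE)
  )
  dmrs <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), 40, TRUE),
    start = sample.int(900000, 40)
  )
  dmrs$end <- dmrs$start + 200
  window <- 2e5; bw <- 5e4
  curve <- enrichment_curve(dmrs, genes, window = window, bin_width = bw)
  edges <- seq(-window, window, bw)
  brute <- rep(0, length(edges) - 1)
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(dmrs))) {
      if (genes$chrom[i] != dmrs$chrom[j]) next
      d <- (dmrs$start[j] + dmrs$end[j]) / 2 - genes$tss[i]
      if (genes$strand[i] == "-") d <- -d
      if (d >= -window && d < window) {
        b <- findInterval(d, edges)
        brute[b] <- brute[b] + 1
      }
    }
  }
  expect_equal(curve$n_pairs, brute)
  expect_equal(curve$score, brute / (30 * bw / 1e6), tolerance = 1e-9)
})

test_that("hypergeometric gene test matches brute-force tail summation", {
  flags <- setNames(rep(c(TRUE, FALSE), c(20, 80)), paste0("g", 1:100))
  target <- c(paste0("g", 1:5), paste0("g", 21:25)) # 5 hits of 10
  res <- dmr_gene_hypergeom(target, paste0("g", 1:100), flags)
  brute <- sum(dhyper(5:10, 20, 80, 10))
  expect_equal(res$p, brute, tolerance = 1e-9)
  expect_equal(res$hits, 5)

  # at the expected proportion the upper tail sits mid-range
  target2 <- c(paste0("g", 1:2), paste0("g", 21:28)) # 2 hits of 10, E = 2
  res2 <- dmr_gene_hypergeom(target2, paste0("g", 1:100), flags)
  expect_equal(res2$p, sum(dhyper(2:10, 20, 80, 10)), tolerance = 1e-9)
  expect_gt(res2$p, 0.3)
  expect_lt(res2$p, 0.8)

  # zero successes anywhere: p = 1
  none <- setNames(rep(FALSE, 100), paste0("g", 1:100))
  expect_equal(dmr_gene_hypergeom(target, paste0("g", 1:100), none)$p, 1)
  expect_error(dmr_gene_hypergeom(character(), paste0("g", 1:100), flags), "empty")
})

test_that("hypergeometric p-values are uniform under random DMR placement", {
  set.seed(55)
  genes <- tibble::tibble(
    gene_id = paste0("g", 1:80), chrom = "chr1",
    start = seq(0, by = 10000, length.out = 80)
  )
  genes$end <- genes$start + 2000
  ps <- vapply(1:500, function(i) {
    dmrs <- tibble::tibble(chrom = "chr1", start = runif(30, 0, 8e5))
    dmrs$end <- dmrs$start + 200
    fl <- gene_dmr_fraction(genes, dmrs, span = 1000)$flags
    target <- sample(genes$gene_id, 15)
    dmr_gene_hypergeom(target, genes$gene_id, fl)$p
  }, numeric(1))
  # the exact-test p is discrete, hence super-uniform: its CDF may sit
  # below the diagonal but must never rise meaningfully above it, and its
  # mean must sit near the uniform centre
  for (cc in seq(0.1, 0.9, by = 0.2)) {
    expect_lte(mean(ps <= cc), cc + 3 * sqrt(cc * (1 - cc) / length(ps)))
  }
  expect_gt(mean(ps), 0.45)
  expect_lt(mean(ps), 0.75)
})

test_that("gene DMR fraction counts flanked overlaps", {
  genes <- tibble::tibble(
    gene_id = paste0("g", 1:5), chrom = "chr1",
    start = c(0, 1000, 2000, 3000, 4000)
  )
  genes$end <- genes$start + 500
  expect_equal(gene_dmr_fraction(genes, genes[0, ], span = 0)$fraction, 0)
  inside <- tibble::tibble(chrom = "chr1", start = genes$start + 100, end = genes$start + 200)
  expect_equal(gene_dmr_fraction(genes, inside, span = 0)$fraction, 1)
  three <- inside[1:3, ]
  out <- gene_dmr_fraction(genes, three, span = 0)
  expect_equal(out$fraction, 0.6)
  expect_equal(out$flags$has_dmr, c(TRUE, TRUE, TRUE, FALSE, FALSE))
})

test_that("matched control band is seeded, degenerate at one resample, and exceeded by implanted signal", {
  cfg <- sim_config(
    genome_size = 2e5, n_chromosomes = 1, n_genes = 60, n_de_genes = 5,
    n_dmrs = 3, dmr_length_bp = 150, seed = 1
  )
  g <- simulate_genome(cfg)
  genes <- simulate_genes(g, cfg)
  expr <- tibble::tibble(gene_id = genes$gene_id, mean_expr = rlnorm(nrow(genes), 4, 1))
  set.seed(9)
  dmrs <- tibble::tibble(chrom = "chr1", start = runif(50, 0, 2e5 - 300))
  dmrs$end <- dmrs$start + 200
  target <- genes[sample.int(nrow(genes), 10), ]

  b1 <- matched_control_band(dmrs, target, genes, expr, window = 5e4,
    bin_width = 1e4, n_resamples = 50, seed = 3
  )
  b2 <- matched_control_band(dmrs, target, genes, expr, window = 5e4,
    bin_width = 1e4, n_resamples = 50, seed = 3
  )
  expect_identical(b1$band_lower, b2$band_lower)
  expect_identical(b1$band_upper, b2$band_upper)

  one <- matched_control_band(dmrs, target, genes, expr, window = 5e4,
    bin_width = 1e4, n_resamples = 1, seed = 3
  )
  expect_equal(one$band_lower, one$band_upper)

  implanted <- tibble::tibble(
    chrom = target$chrom, start = pmax(target$tss - 100, 0),
    end = target$tss + 100
  )
  bi <- matched_control_band(implanted, target, genes, expr, window = 5e4,
    bin_width = 1e4, n_resamples = 100, seed = 3
  )
  zero_bin <- bi[bi$bin_start == 0, ]
  expect_gt(zero_bin$score, zero_bin$band_upper)
})

test_that("peak colocalization respects closed distance conventions", {
  sizes <- tibble::tibble(chrom = "chr1", size = 1e4)
  dmrs <- tibble::tibble(chrom = "chr1", start = 5000, end = 5200)
  # peak midpoint exactly at the DMR start, max_dist = 0: a hit
  at_edge <- tibble::tibble(chrom = "chr1", start = 4990, end = 5010)
  res <- peak_dmr_colocalization(at_edge, dmrs, sizes, max_dist = 0)
  expect_equal(res$n_peaks_near_dmr, 1)
  # midpoint exactly max_dist away: still a hit (closed)
  near <- tibble::tibble(chrom = "chr1", start = 4400, end = 4600)
  expect_equal(
    peak_dmr_colocalization(near, dmrs, sizes, max_dist = 500)$n_peaks_near_dmr, 1
  )
  expect_equal(
    peak_dmr_colocalization(near, dmrs, sizes, max_dist = 499)$n_peaks_near_dmr, 0
  )
  # zero hits: p = 1
  farpk <- tibble::tibble(chrom = "chr1", start = 100, end = 200)
  expect_equal(peak_dmr_colocalization(farpk, dmrs, sizes, max_dist = 100)$p, 1)
  expect_error(peak_dmr_colocalization(farpk[0, ], dmrs, sizes), "empty")
})

test_that("colocalization p matches the brute-force hypergeometric tail", {
  set.seed(17)
  sizes <- tibble::tibble(chrom = "chr1", size = 1e6)
  dmrs <- tibble::tibble(chrom = "chr1", start = seq(0, 9.9e5, by = 5e4))
  dmrs$end <- dmrs$start + 300
  peaks <- tibble::tibble(chrom = "chr1", start = dmrs$start[1:8] + 50)
  peaks$end <- peaks$start + 100
  res <- peak_dmr_colocalization(peaks, dmrs, sizes,
    max_dist = 500, window_size = 1000
  )
  brute <- sum(dhyper(
    res$n_peaks_near_dmr:res$n_peaks, res$successes,
    res$universe - res$successes, res$n_peaks
  ))
  expect_equal(res$p, brute, tolerance = 1e-9)
  # all peaks on DMRs, successes rare: very small p on a 1e3-window genome
  expect_lt(res$p, 1e-6)
})

test_that("point-to-interval distances match a brute-force scan", {
  set.seed(3)
  starts <- sort(runif(30, 0, 1e4))
  ends <- starts + runif(30, 10, 500)
  pts <- runif(200, -100, 1.1e4)
  d <- methylaxis:::point_interval_dist(pts, starts, ends)
  brute <- vapply(pts, function(p) {
    min(pmax(starts - p, p - ends, 0))
  }, numeric(1))
  expect_equal(d, brute)
})
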