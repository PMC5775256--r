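# small shared simulation fixtures, built once per test run

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(
      genome_size = 2e4, n_chromosomes = 1, n_genes = 5, n_de_genes = 2,
      n_dmrs = 3, dmr_length_bp = 150, seed = 1
    ),
    list(...)
  )
  do.call(sim_config, args)
}

# memoised small study pieces
.fixtures <- new.env(parent = emptyenv())

tiny_genome <- function() {
  if (is.null(.fixtures$genome)) {
    .fixtures$genome <- simulate_genome(tiny_config())
  }
  .fixtures$genome
}

tiny_methylome <- function() {
  if (is.null(.fixtures$methylome)) {
    cfg <- tiny_config()
    g <- tiny_genome()
    td <- simulate_dmr_truth(g, cfg)
    .fixtures$methylome <- simulate_methylome(g$catalog, cfg, td)
  }
  .fixtures$methylome
}

# hand-rolled allc tibble builder
allc <- function(pos, mc, cov, context = "CGA", chrom = "chr1", strand = "+",
                 assay = "BS", sample = "s1") {
  tibble::tibble(
    chrom = chrom, pos = pos, strand = strand, context = context,
    mc = mc, cov = cov, assay = assay, sample = sample
  )
}
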