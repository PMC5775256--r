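#' Simulate an RNA-Seq count matrix with known differential expression
#'
#' Draws negative-binomial counts for a 2x2 design (region dorsal/ventral x
#' condition SH/EE) with `n_replicates` samples per cell. Baseline gene
#' means are log-normal; the configured number of true DE genes receive a
#' fold change of `2^de_log2fc` (random sign) in the designated target:
#' the dorsal EE cell, the ventral EE cell, or the dorsal region in both
#' conditions. A low-count female-specific marker gene ("Xist") is always
#' present; with `contaminate = TRUE` one SH sample gets a ~100-fold
#' elevated marker to exercise sample QC.
#'
#' @param config A [sim_config()].
#' @param genes Optional gene annotation tibble from [simulate_genes()];
#'   when supplied its gene_ids are used (plus the marker gene), otherwise
#'   ids are generated.
#' @param contaminate Add one marker-contaminated SH sample state.
#' @return A list: `counts` (integer matrix genes x samples), `samples`
#'   (tibble: sample, region, condition, pool), `true_de` (tibble:
#'   gene_id, sign, log2fc), `contaminated` (sample id or NA), and
#'   `marker_gene`.
#' @export
simulate_expression <- function(config, genes = NULL, contaminate = FALSE) {
  validate_sim_config(config)
  if (config$n_replicates < 2) abort("n_replicates must be >= 2 for expression")
  gene_ids <- if (is.null(genes)) {
    sprintf("gene%04d", seq_len(config$n_genes))
  } else {
    genes$gene_id
  }
  marker <- "Xist"
  samples <- tidyr::expand_grid(
    region = c("dorsal", "ventral"),
    condition = c("SH", "EE"),
    rep = seq_len(config$n_replicates)
  ) |>
    mutate(
      sample = paste(.data$region, .data$condition, .data$rep, sep = "_"),
      pool = paste0(.data$condition, "_", .data$rep)
    ) |>
    select("sample", "region", "condition", "pool")

  if (config$n_de_genes > length(gene_ids)) {
    abort("n_de_genes exceeds the number of annotated genes")
  }
  with_substream(config$seed, "expression", {
    n_genes <- length(gene_ids)
    base_mu <- rlnorm(n_genes, config$expr_mean_log, config$expr_sd_log)
    # true DE genes belong to the expressed universe: a gene that never
    # clears the count filter is not a differential-expression hypothesis
    expressed <- which(base_mu >= 10)
    if (length(expressed) < config$n_de_genes) {
      abort("too few expressed genes to host the requested DE genes")
    }
    de_idx <- expressed[sample.int(length(expressed), config$n_de_genes)]
    de_sign <- sample(c(-1, 1), config$n_de_genes, replace = TRUE)
    lfc <- rep(0, n_genes)
    lfc[de_idx] <- de_sign * config$de_log2fc

    affected <- switch(config$de_target,
      ee_dorsal = samples$region == "dorsal" & samples$condition == "EE",
      ee_ventral = samples$region == "ventral" & samples$condition == "EE",
      region = samples$region == "dorsal"
    )
    mu <- outer(base_mu, rep(1, nrow(samples)))
    mu[, affected] <- mu[, affected] * 2^lfc

    marker_mu <- rep(2, nrow(samples))
    contaminated <- NA_character_
    if (isTRUE(contaminate)) {
      sh <- which(samples$condition == "SH")
      pick <- sh[sample.int(length(sh), 1)]
      marker_mu[pick] <- 200 * mean(base_mu)
      contaminated <- samples$sample[pick]
    }
    mu <- rbind(mu, marker_mu)
    counts <- matrix(
      rnbinom(length(mu), size = 1 / config$expr_dispersion, mu = mu),
      nrow = nrow(mu),
      dimnames = list(c(gene_ids, marker), samples$sample)
    )
    list(
      counts = counts,
      samples = samples,
      true_de = tibble(
        gene_id = gene_ids[de_idx], sign = de_sign,
        log2fc = de_sign * config$de_log2fc, target = config$de_target
      ),
      contaminated = contaminated,
      marker_gene = marker
    )
  })
}

#' Simulate a complete dorsal-ventral methylome study
#'
#' Convenience orchestrator chaining [simulate_genome()],
#' [simulate_genes()], [simulate_dmr_truth()], [simulate_methylome()],
#' per-replicate [simulate_bs_counts()] (and optionally
#' [simulate_tab_counts()]), [simulate_spikeins()] and
#' [simulate_expression()], returning everything alongside the ground
#' truth. Assay tables can be restricted to a context class and to the
#' groups of interest to keep the object small.
#'
#' @param config A [sim_config()].
#' @param contexts Context classes to keep in assay tables (default CG
#'   only; use `c("CG", "CA", "CC", "CT")` for everything).
#' @param groups Group labels to generate counts for.
#' @param tab Also generate TAB-assay tables.
#' @param expression,spikeins Toggle those components.
#' @return A list of class `dg_sim`.
#' @export
simulate_study <- function(config = sim_config(),
                           contexts = "CG",
                           groups = c("dorsal_SH", "ventral_SH"),
                           tab = FALSE,
                           expression = TRUE,
                           spikeins = TRUE) {
  genome <- simulate_genome(config)
  genes <- simulate_genes(genome, config)
  true_dmrs <- simulate_dmr_truth(genome, config)
  methylome <- simulate_methylome(genome$catalog, config, true_dmrs)

  state <- filter(
    methylome$state,
    .data$context_class %in% contexts, .data$group %in% groups
  )
  bs <- purrr::map_dfr(groups, function(g) {
    st <- filter(state, .data$group == g)
    purrr::map_dfr(seq_len(config$n_replicates), function(r) {
      mutate(
        simulate_bs_counts(st, config, sprintf("%s_%d", g, r)),
        group = g
      )
    })
  })
  tab_tbl <- NULL
  if (isTRUE(tab)) {
    tab_tbl <- purrr::map_dfr(groups, function(g) {
      st <- filter(state, .data$group == g)
      purrr::map_dfr(seq_len(config$n_replicates), function(r) {
        mutate(
          simulate_tab_counts(st, config, sprintf("%s_tab_%d", g, r)),
          group = g
        )
      })
    })
  }
  structure(
    list(
      config = config,
      genome = genome,
      genes = genes,
      methylome = methylome,
      bs = bs,
      tab = tab_tbl,
      spikeins = if (isTRUE(spikeins)) simulate_spikeins(config) else NULL,
      expression = if (isTRUE(expression)) simulate_expression(config, genes) else NULL,
      truth = list(
        true_dmrs = true_dmrs,
        true_rates = list(
          ncr = config$ncr_true, r = config$r_true,
          s = config$s_true, t = config$t_true
        )
      )
    ),
    class = "dg_sim"
  )
}

#' @method print dg_sim
#' @export
print.dg_sim <- function(x, ...) {
  cat("<dg_sim> simulated dorsal-ventral methylome study\n")
  cat(sprintf(
    "  %d chrom x %.0f bp; %d genes; %d true DMRs; %s BS rows\n",
    x$config$n_chromosomes, x$config$genome_size, nrow(x$genes),
    nrow(x$truth$true_dmrs), format(nrow(x$bs), big.mark = ",")
  ))
  invisible(x)
}
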