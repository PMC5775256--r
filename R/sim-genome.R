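#' Simulate a reference genome and catalogue its cytosines
#'
#' Draws i.i.d. bases at the configured GC fraction and records every
#' cytosine on both strands with its trinucleotide context. Reverse-strand
#' cytosines (genome G's) take their context from the reverse complement,
#' so a CpG dinucleotide yields one CG-context site on each strand.
#' Cytosines within 2 bp of a chromosome end lack a full trinucleotide and
#' are dropped.
#'
#' @param config A [sim_config()].
#' @return A list with `sequences` (a [Biostrings::DNAStringSet]),
#'   `catalog` (tibble: chrom, pos (1-based), strand, context (3-mer),
#'   context_class in CG/CA/CC/CT) and `chrom_sizes`.
#' @export
#' @examples
#' g <- simulate_genome(sim_config(genome_size = 2000, n_chromosomes = 1,
#'                                 n_genes = 1, n_de_genes = 1, n_dmrs = 1,
#'                                 gene_length_bp = 500, dmr_length_bp = 100))
#' head(g$catalog)
simulate_genome <- function(config) {
  validate_sim_config(config)
  total_bp <- config$genome_size * config$n_chromosomes
  if (config$n_dmrs * (config$dmr_length_bp + 200) > 0.5 * total_bp) {
    abort("genome too small to host the requested DMRs; increase genome_size")
  }
  if (config$n_genes * (config$gene_length_bp + 200) > 0.9 * total_bp) {
    abort("genome too small to host the requested genes; increase genome_size")
  }
  seqs <- with_substream(config$seed, "genome", {
    p <- c(
      A = (1 - config$gc_fraction) / 2, C = config$gc_fraction / 2,
      G = config$gc_fraction / 2, T = (1 - config$gc_fraction) / 2
    )
    vapply(seq_len(config$n_chromosomes), function(i) {
      paste(sample(names(p), config$genome_size, replace = TRUE, prob = p),
        collapse = ""
      )
    }, character(1))
  })
  names(seqs) <- paste0("chr", seq_along(seqs))
  catalog <- purrr::map_dfr(names(seqs), function(chrom) {
    catalog_cytosines(seqs[[chrom]], chrom)
  })
  list(
    sequences = Biostrings::DNAStringSet(seqs),
    catalog = catalog,
    chrom_sizes = tibble(
      chrom = names(seqs),
      size = rep(config$genome_size, length(seqs))
    )
  )
}

#' Catalogue cytosines of a DNA sequence
#'
#' @param sequence Character scalar (A/C/G/T).
#' @param chrom Chromosome name to record.
#' @return Tibble with one row per strand-specific cytosine.
#' @export
#' @examples
#' catalog_cytosines("ACGT", "toy")
catalog_cytosines <- function(sequence, chrom = "chr1") {
  b <- strsplit(toupper(sequence), "")[[1]]
  n <- length(b)
  comp <- c(A = "T", C = "G", G = "C", T = "A")

  plus_pos <- which(b == "C")
  plus_pos <- plus_pos[plus_pos <= n - 2L]
  plus_ctx <- paste0("C", b[plus_pos + 1L], b[plus_pos + 2L])

  minus_pos <- which(b == "G")
  minus_pos <- minus_pos[minus_pos >= 3L]
  minus_ctx <- paste0("C", comp[b[minus_pos - 1L]], comp[b[minus_pos - 2L]])

  out <- tibble(
    chrom = chrom,
    pos = c(plus_pos, minus_pos),
    strand = rep(c("+", "-"), c(length(plus_pos), length(minus_pos))),
    context = c(plus_ctx, minus_ctx)
  )
  out$context_class <- context_class(out$context)
  arrange(out[!is.na(out$context_class), ], .data$pos, .data$strand)
}

#' Place non-overlapping gene annotations on a simulated genome
#'
#' Genes are laid out in randomly chosen slots (gene length plus a 200 bp
#' buffer) with random strand; the TSS is the 5' end of the gene. Intervals
#' are 0-based half-open, BED-style.
#'
#' @param genome Result of [simulate_genome()].
#' @param config A [sim_config()].
#' @return Tibble: gene_id, chrom, start, end, strand, tss.
#' @export
simulate_genes <- function(genome, config) {
  with_substream(config$seed, "genes", {
    place_intervals(
      genome$chrom_sizes, config$n_genes,
      rep(config$gene_length_bp, config$n_genes),
      substream_seed(config$seed, "gene_place"),
      what = "genes"
    ) |>
      arrange(.data$chrom, .data$start) |>
      mutate(
        gene_id = sprintf("gene%04d", row_number()),
        strand = sample(c("+", "-"), n(), replace = TRUE),
        tss = ifelse(.data$strand == "+", .data$start, .data$end - 1)
      ) |>
      select("gene_id", "chrom", "start", "end", "strand", "tss")
  })
}

# shared slot-based placement of non-overlapping intervals (0-based)
place_intervals <- function(chrom_sizes, n, lengths, seed, what = "intervals") {
  stopifnot(length(lengths) == n)
  withr::with_seed(seed, {
    slot <- max(lengths) + 200
    slots <- purrr::map_dfr(seq_len(nrow(chrom_sizes)), function(i) {
      k <- floor(chrom_sizes$size[i] / slot)
      tibble(chrom = chrom_sizes$chrom[i], slot_start = (seq_len(k) - 1) * slot)
    })
    if (nrow(slots) < n) {
      abort(sprintf("genome too small to host %d %s", n, what))
    }
    picked <- slots[sample.int(nrow(slots), n), ]
    jitter <- floor(runif(n, 0, pmax(slot - lengths, 1)))
    tibble(
      chrom = picked$chrom,
      start = picked$slot_start + jitter,
      end = picked$slot_start + jitter + lengths
    )
  })
}

#' Place true differentially methylated regions
#'
#' Draws `n_dmrs` non-overlapping intervals with log-normal lengths around
#' `dmr_length_bp` and assigns each a direction and a true methylation
#' difference ~ Normal(`dmr_mean_diff`, `dmr_diff_sd`), floored at 0.05.
#' Differences that would push the hypomethylated group below 0.02 are
#' clipped and flagged.
#'
#' @inheritParams simulate_genes
#' @return Tibble: dmr_id, chrom, start, end, direction
#'   ("dorsal_hypo"/"ventral_hypo"), true_diff, clipped.
#' @export
simulate_dmr_truth <- function(genome, config) {
  seed <- substream_seed(config$seed, "dmr_truth")
  withr::with_seed(seed, {
    sigma <- 0.3
    lens <- pmax(
      60,
      round(rlnorm(config$n_dmrs, log(config$dmr_length_bp) - sigma^2 / 2, sigma))
    )
    diffs <- pmax(0.05, rnorm(config$n_dmrs, config$dmr_mean_diff, config$dmr_diff_sd))
    dirs <- ifelse(
      runif(config$n_dmrs) < config$dmr_dorsal_fraction,
      "dorsal_hypo", "ventral_hypo"
    )
  })
  max_diff <- config$baseline_mcg - 0.02
  placed <- place_intervals(
    genome$chrom_sizes, config$n_dmrs, lens,
    substream_seed(config$seed, "dmr_place"),
    what = "DMRs"
  )
  placed$direction <- dirs
  placed$true_diff <- pmin(diffs, max_diff)
  placed$clipped <- diffs > max_diff
  placed |>
    arrange(.data$chrom, .data$start) |>
    mutate(dmr_id = sprintf("dmr%04d", row_number())) |>
    select(
      "dmr_id", "chrom", "start", "end", "direction", "true_diff", "clipped"
    )
}
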