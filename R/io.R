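#' Read / write allc-style methylation tables
#'
#' The allc layout is a TSV with columns chromosome, 1-based position,
#' strand, trinucleotide context, methylated call count and total call
#' count, plus optional assay and sample labels.
#'
#' @param path File path.
#' @return `read_allc()` returns an allc tibble.
#' @export
read_allc <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("^chrom\t", first)
  cols <- c("chrom", "pos", "strand", "context", "mc", "cov", "assay", "sample")
  x <- readr::read_tsv(
    path,
    col_names = if (has_header) TRUE else cols[seq_len(length(strsplit(first, "\t")[[1]]))],
    skip = 0,
    show_col_types = FALSE
  )
  assert_allc(x, path)
  x
}

#' @param x Allc tibble.
#' @rdname read_allc
#' @export
write_allc <- function(x, path) {
  assert_allc(x)
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read / write BED interval files
#'
#' Minimal BED3+ support: 0-based half-open intervals with optional name,
#' score and strand columns; extra columns are preserved on write.
#'
#' @param path File path.
#' @return `read_bed()` returns a tibble with chrom, start, end and any
#'   further BED columns present.
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
    comment = "#"
  )
  bed_names <- c("chrom", "start", "end", "name", "score", "strand")
  names(x)[seq_len(min(ncol(x), 6L))] <- bed_names[seq_len(min(ncol(x), 6L))]
  x
}

#' @param x Tibble with chrom, start, end first.
#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  front <- intersect(c("chrom", "start", "end", "name", "score", "strand"), names(x))
  rest <- setdiff(names(x), front)
  readr::write_tsv(x[, c(front, rest)], path, col_names = FALSE)
  invisible(path)
}

#' Write gene annotations as BED12
#'
#' Single-exon BED12 records (thickStart/End = the gene body) with the
#' TSS-bearing strand in column 6.
#'
#' @param genes Gene tibble from [simulate_genes()].
#' @param path File path.
#' @export
write_genes_bed12 <- function(genes, path) {
  out <- tibble(
    chrom = genes$chrom, start = genes$start, end = genes$end,
    name = genes$gene_id, score = 0, strand = genes$strand,
    thick_start = genes$start, thick_end = genes$end, rgb = "0,0,0",
    block_count = 1, block_sizes = genes$end - genes$start,
    block_starts = 0
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Write a simulated genome as FASTA
#'
#' @param genome Result of [simulate_genome()] (or a
#'   [Biostrings::DNAStringSet]).
#' @param path File path.
#' @export
write_fasta <- function(genome, path) {
  seqs <- if (is.list(genome) && !is.null(genome$sequences)) genome$sequences else genome
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write simulation ground truth as JSON
#'
#' @param sim A `dg_sim` object from [simulate_study()].
#' @param path File path.
#' @export
write_truth_json <- function(sim, path) {
  jsonlite::write_json(
    list(
      true_rates = sim$truth$true_rates,
      true_dmrs = sim$truth$true_dmrs,
      true_de = if (!is.null(sim$expression)) sim$expression$true_de else NULL
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read / write gene count matrices
#'
#' TSV with gene ids in the first column and one column per sample.
#'
#' @param path File path.
#' @return `read_counts()` returns an integer matrix.
#' @export
read_counts <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(x[, -1])
  rownames(m) <- x[[1]]
  m
}

#' @param counts Matrix, genes x samples.
#' @rdname read_counts
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(
    bind_cols(tibble(gene_id = rownames(counts)), as_tibble(counts)),
    path
  )
  invisible(path)
}
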