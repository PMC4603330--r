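#' Build a genome annotation with gene-order coordinates
#'
#' A `genome_annotation` holds gene coordinates for one genome together with
#' the 1-based gene *ordinal* along each chromosome. All downstream analysis
#' (block chaining, footprint overlap, superblock spans) is carried out in
#' gene ordinals, not base pairs: the method measures synteny and overlap in
#' numbers of genes.
#'
#' Ordinals are assigned per chromosome by ascending start position, with ties
#' broken by ascending end and then lexicographic `gene_id`, so they are
#' deterministic across runs. Chromosomes are listed in order of first
#' appearance in `genes`.
#'
#' @param genes data.frame with columns `gene_id`, `chromosome`, `start`,
#'   `end`, `strand` (`"+"` or `"-"`). Any `ordinal` column is recomputed.
#' @param genome_id character scalar identifying the genome.
#' @return An object of class `genome_annotation`: a list with elements
#'   `genome_id`, `genes` (the input rows, sorted by chromosome appearance and
#'   ordinal, with an `ordinal` column added) and `chromosomes` (character
#'   vector in first-appearance order).
#' @examples
#' g <- data.frame(gene_id = c("a", "b", "c"), chromosome = "chr1",
#'                 start = c(100, 50, 200), end = c(150, 90, 260),
#'                 strand = "+")
#' ann <- genome_annotation(g, "toy")
#' ann$genes$ordinal  # b, a, c -> 1, 2, 3 after sorting
#' @export
genome_annotation <- function(genes, genome_id = "genome") {
  required <- c("gene_id", "chromosome", "start", "end", "strand")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0L) {
    stop("annotation is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(genes) == 0L) {
    stop("annotation contains zero genes")
  }
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  genes$gene_id <- as.character(genes$gene_id)
  genes$chromosome <- as.character(genes$chromosome)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes$strand <- as.character(genes$strand)
  if (anyDuplicated(genes$gene_id)) {
    dup <- genes$gene_id[duplicated(genes$gene_id)][1L]
    stop("duplicate gene_id in annotation: ", dup)
  }
  if (any(genes$start > genes$end)) {
    bad <- which(genes$start > genes$end)[1L]
    stop("gene ", genes$gene_id[bad], " has start > end")
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    bad <- genes$gene_id[!(genes$strand %in% c("+", "-"))][1L]
    stop("gene ", bad, " has strand outside {+,-}")
  }
  chromosomes <- unique(genes$chromosome)
  genes$ordinal <- NA_integer_
  for (chr in chromosomes) {
    idx <- which(genes$chromosome == chr)
    o <- order(genes$start[idx], genes$end[idx], genes$gene_id[idx])
    genes$ordinal[idx[o]] <- seq_along(idx)
  }
  genes <- genes[order(match(genes$chromosome, chromosomes), genes$ordinal), , drop = FALSE]
  rownames(genes) <- NULL
  structure(
    list(genome_id = genome_id, genes = genes, chromosomes = chromosomes),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation '%s': %d genes on %d chromosome(s)\n",
              x$genome_id, nrow(x$genes), length(x$chromosomes)))
  cat("  chromosomes:", paste(utils::head(x$chromosomes, 8L), collapse = ", "),
      if (length(x$chromosomes) > 8L) "..." else "", "\n")
  invisible(x)
}

# gene_id -> (chromosome, ordinal) lookup used by the chainer and block import
gene_index <- function(annotation) {
  g <- annotation$genes
  list(chromosome = stats::setNames(g$chromosome, g$gene_id),
       ordinal = stats::setNames(g$ordinal, g$gene_id))
}
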