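#' Read gene annotations from GFF3 or BED
#'
#' Reads gene records and derives gene-order (ordinal) coordinates via
#' [genome_annotation()]. For GFF3, only records of type `"gene"` are used
#' (mRNA/CDS features are ignored: the method is gene-order based) and the
#' gene identifier is taken from the `ID` attribute (falling back to `Name`).
#' For BED, every record is a gene and the identifier is the `name` field;
#' a 6-column BED with strand is required.
#'
#' @param path path to a GFF3 or BED file.
#' @param format `"gff3"` or `"bed"`.
#' @param genome_id identifier for the genome; defaults to the file base name.
#' @return A [genome_annotation()] object.
#' @export
read_gene_annotations <- function(path, format = c("gff3", "bed"),
                                  genome_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (is.null(genome_id)) {
    genome_id <- sub("\\.[^.]*$", "", basename(path))
  }
  gr <- rtracklayer::import(path, format = format)
  if (format == "gff3") {
    meta <- S4Vectors::mcols(gr)
    if (!is.null(meta$type)) {
      gr <- gr[as.character(meta$type) == "gene"]
      meta <- S4Vectors::mcols(gr)
    }
    if (length(gr) == 0L) stop("no gene records in ", path)
    ids <- as.character(meta$ID)
    if (is.null(meta$ID) || anyNA(ids)) {
      alt <- if (!is.null(meta$Name)) as.character(meta$Name) else NULL
      if (is.null(ids) || all(is.na(ids))) ids <- alt
      else if (!is.null(alt)) ids[is.na(ids)] <- alt[is.na(ids)]
    }
    if (is.null(ids) || anyNA(ids)) {
      stop("GFF3 gene record without an ID attribute in ", path)
    }
  } else {
    if (length(gr) == 0L) stop("no gene records in ", path)
    ids <- as.character(S4Vectors::mcols(gr)$name)
    if (is.null(ids) || anyNA(ids)) stop("BED record without a name field in ", path)
  }
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*")) stop("record without strand information in ", path)
  genes <- data.frame(
    gene_id = ids,
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = strand,
    stringsAsFactors = FALSE
  )
  genome_annotation(genes, genome_id)
}

#' Write gene annotations to GFF3 or BED
#'
#' Emits the same dialect [read_gene_annotations()] consumes, so a write/read
#' round trip reproduces identical gene ordinals.
#'
#' @param annotation a [genome_annotation()] object.
#' @param path output file path.
#' @param format `"gff3"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_gene_annotations <- function(annotation, path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  g <- annotation$genes
  gr <- GenomicRanges::GRanges(
    seqnames = g$chromosome,
    ranges = IRanges::IRanges(start = g$start, end = g$end),
    strand = g$strand
  )
  if (format == "gff3") {
    S4Vectors::mcols(gr)$source <- "wgdsig"
    S4Vectors::mcols(gr)$type <- "gene"
    S4Vectors::mcols(gr)$ID <- g$gene_id
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    S4Vectors::mcols(gr)$name <- g$gene_id
    S4Vectors::mcols(gr)$score <- 0L
    rtracklayer::export(gr, path, format = "bed")
  }
  invisible(path)
}

#' Read a homolog-pair table
#'
#' Tab-separated table with at least three columns: target gene id, reference
#' gene id, percent similarity in \[0,100\]. Lines starting with `#` are
#' treated as headers and skipped. Gene ids are *not* resolved against
#' annotations here; that happens at chaining time.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `target_gene`, `reference_gene`,
#'   `similarity`.
#' @export
read_homolog_pairs <- function(path) {
  if (!file.exists(path)) stop("homolog table not found: ", path)
  lines <- readLines(path)
  keep <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (length(keep) == 0L) {
    return(data.frame(target_gene = character(), reference_gene = character(),
                      similarity = numeric(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- keep[which(nf < 3L)[1L]]
    stop("line ", bad, " of ", path, " has fewer than 3 tab-separated fields")
  }
  sim <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(sim)) {
    bad <- keep[which(is.na(sim))[1L]]
    stop("line ", bad, " of ", path, " has a non-numeric similarity")
  }
  if (any(sim < 0 | sim > 100)) {
    bad <- keep[which(sim < 0 | sim > 100)[1L]]
    stop("line ", bad, " of ", path, " has similarity outside [0,100]")
  }
  data.frame(
    target_gene = vapply(fields, `[[`, "", 1L),
    reference_gene = vapply(fields, `[[`, "", 2L),
    similarity = sim,
    stringsAsFactors = FALSE
  )
}

#' Write a homolog-pair table
#'
#' @param pairs data.frame with columns `target_gene`, `reference_gene`,
#'   `similarity`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_homolog_pairs <- function(pairs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#target_gene\treference_gene\tsimilarity", con)
  if (nrow(pairs) > 0L) {
    writeLines(sprintf("%s\t%s\t%s", pairs$target_gene, pairs$reference_gene,
                       format(pairs$similarity, trim = TRUE, scientific = FALSE)),
               con)
  }
  invisible(path)
}

#' Read syntenic blocks in DAGchainer-style text
#'
#' Consumes the CoGe-like dialect written by [write_dagchainer_blocks()]:
#' block header lines start with `#` and name the chromosome pair as
#' `<target_chr> vs <reference_chr>`; anchor lines are tab-separated with
#' fields target chromosome, target gene, reference chromosome, reference
#' gene and (optionally) percent similarity. Anchor genes are mapped to gene
#' ordinals through the two annotations; orientation and spans are recomputed
#' from the anchors.
#'
#' @param path path to the block text file.
#' @param target,reference [genome_annotation()] objects for the two genomes.
#' @return list of `syntenic_block` objects.
#' @export
read_dagchainer_blocks <- function(path, target, reference) {
  if (!file.exists(path)) stop("block file not found: ", path)
  lines <- readLines(path)
  tidx <- gene_index(target)
  ridx <- gene_index(reference)
  blocks <- list()
  counters <- new.env(parent = emptyenv())
  cur_chr <- NULL
  cur_anchors <- list()
  flush_block <- function() {
    if (is.null(cur_chr)) return(invisible(NULL))
    if (length(cur_anchors) == 0L) {
      warning("empty block group for ", cur_chr[1L], " vs ", cur_chr[2L],
              " in ", path, "; skipped")
      return(invisible(NULL))
    }
    anchors <- do.call(rbind, cur_anchors)
    key <- paste(cur_chr, collapse = "\r")
    k <- if (is.null(counters[[key]])) 1L else counters[[key]] + 1L
    counters[[key]] <- k
    blocks[[length(blocks) + 1L]] <<- new_syntenic_block(
      block_id = sprintf("%s_%s_%d", cur_chr[1L], cur_chr[2L], k),
      target_chromosome = cur_chr[1L],
      reference_chromosome = cur_chr[2L],
      anchors = anchors
    )
    invisible(NULL)
  }
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line))) next
    if (startsWith(line, "#")) {
      m <- regmatches(line, regexec("(\\S+) vs (\\S+)", line))[[1L]]
      if (length(m) == 3L) {
        flush_block()
        cur_chr <- m[2:3]
        cur_anchors <- list()
      }
      next
    }
    if (is.null(cur_chr)) {
      stop("line ", i, " of ", path, ": anchor line before any block header")
    }
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 4L) {
      stop("line ", i, " of ", path, " has fewer than 4 tab-separated fields")
    }
    tg <- f[2L]
    rg <- f[4L]
    if (is.na(tidx$ordinal[tg])) {
      stop("anchor gene ", tg, " not present in target annotation (line ", i, ")")
    }
    if (is.na(ridx$ordinal[rg])) {
      stop("anchor gene ", rg, " not present in reference annotation (line ", i, ")")
    }
    sim <- if (length(f) >= 5L) suppressWarnings(as.numeric(f[5L])) else NA_real_
    cur_anchors[[length(cur_anchors) + 1L]] <- data.frame(
      target_gene = tg, reference_gene = rg,
      target_ordinal = unname(tidx$ordinal[tg]),
      reference_ordinal = unname(ridx$ordinal[rg]),
      similarity = if (is.na(sim)) 0 else sim,
      stringsAsFactors = FALSE
    )
  }
  flush_block()
  blocks
}

#' Write syntenic blocks in DAGchainer-style text
#'
#' One `##` header per block followed by one tab-separated anchor line per
#' homolog pair; the dialect round-trips through [read_dagchainer_blocks()].
#'
#' @param blocks list of `syntenic_block` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dagchainer_blocks <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (b in blocks) {
    writeLines(sprintf("## alignment %s vs %s (%s) %s (num aligned pairs: %d)",
                       b$target_chromosome, b$reference_chromosome,
                       if (b$orientation == "parallel") "f" else "r",
                       b$block_id, nrow(b$anchors)), con)
    a <- b$anchors
    writeLines(sprintf("%s\t%s\t%s\t%s\t%s",
                       b$target_chromosome, a$target_gene,
                       b$reference_chromosome, a$reference_gene,
                       format(a$similarity, trim = TRUE, scientific = FALSE)),
               con)
  }
  invisible(path)
}

#' Histogram of homolog-pair percent similarities
#'
#' Counts pairs into half-open bins `[lo, lo + bin_width)` over \[0,100\]; the
#' final bin is closed at the top so a similarity of exactly 100 is counted
#' (e.g. bin `[90,100]` for width 10). A descriptive summary of the kind used
#' to compare divergence depth between a target and different reference
#' genomes.
#'
#' @param pairs data.frame as returned by [read_homolog_pairs()].
#' @param bin_width positive bin width in percent.
#' @return named integer vector: bin lower edge -> count (non-empty bins only),
#'   sorted by edge.
#' @export
similarity_distribution <- function(pairs, bin_width = 1) {
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0) {
    stop("bin_width must be a positive number")
  }
  s <- pairs$similarity
  if (length(s) == 0L) return(stats::setNames(integer(0), character(0)))
  if (any(s < 0 | s > 100)) stop("similarity outside [0,100]")
  nbins <- ceiling(100 / bin_width)
  idx <- pmin(floor(s / bin_width), nbins - 1L)
  tab <- table(idx * bin_width)
  counts <- stats::setNames(as.integer(tab), names(tab))
  counts[order(as.numeric(names(counts)))]
}
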