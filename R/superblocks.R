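#' Overlap of two gene-ordinal intervals, in genes
#'
#' Both intervals are 1-based inclusive `[lo, hi]`; the overlap is the number
#' of gene positions the two intervals share,
#' `max(0, min(hi_a, hi_b) - max(lo_a, lo_b) + 1)`.
#'
#' @param span_a,span_b integer vectors `c(lo, hi)` with `lo <= hi`.
#' @return non-negative integer.
#' @export
overlap_genes <- function(span_a, span_b) {
  if (span_a[1L] > span_a[2L] || span_b[1L] > span_b[2L]) {
    stop("interval has lo > hi")
  }
  max(0L, min(span_a[2L], span_b[2L]) - max(span_a[1L], span_b[1L]) + 1L)
}

#' Overlap parameters for superblock construction
#'
#' `min_overlap_genes` (T) is the number of shared reference genes required
#' for two blocks to count as overlapping. Values of 5 and 10 behave almost
#' identically in practice; requiring more than 10 impedes the identification
#' of high-multiplicity superblocks, and fewer than 5 produces superblocks of
#' artifactually high multiplicity, so values outside \[5,10\] trigger a
#' warning.
#'
#' @param min_overlap_genes integer >= 1.
#' @return list of class `overlap_params`.
#' @export
overlap_params <- function(min_overlap_genes = 5L) {
  t_genes <- as.integer(min_overlap_genes)
  if (is.na(t_genes) || t_genes < 1L) stop("min_overlap_genes must be >= 1")
  if (t_genes < 5L || t_genes > 10L) {
    warning("min_overlap_genes outside [5,10]; superblock multiplicities may be ",
            "artifactually high (below 5) or truncated (above 10)")
  }
  structure(list(min_overlap_genes = t_genes), class = "overlap_params")
}

#' Group syntenic blocks into superblocks
#'
#' Two blocks of the target genome overlap when their footprints on the same
#' reference chromosome share at least T genes. Per reference chromosome, a
#' graph with blocks as nodes and one edge per overlapping pair is built, and
#' every connected component with at least two members becomes a superblock;
#' its multiplicity B is the number of member blocks. Singleton components
#' produce nothing. Overlap is strand-agnostic: an antiparallel block
#' occupies the same reference footprint as its parallel twin.
#'
#' @param blocks list of `syntenic_block` objects.
#' @param params an [overlap_params()] object (or a bare integer T).
#' @return list of `superblock` objects, sorted by (reference chromosome,
#'   union span lower end). Each has fields `reference_chromosome`,
#'   `member_blocks` (character vector of block ids), `multiplicity_B` and
#'   `reference_union_span`.
#' @export
build_superblocks <- function(blocks, params = overlap_params()) {
  if (is.numeric(params)) params <- overlap_params(params)
  stopifnot(inherits(params, "overlap_params"))
  t_genes <- params$min_overlap_genes
  if (length(blocks) == 0L) return(list())
  rchr <- vapply(blocks, `[[`, "", "reference_chromosome")
  lo <- vapply(blocks, function(b) b$reference_span[1L], numeric(1L))
  hi <- vapply(blocks, function(b) b$reference_span[2L], numeric(1L))
  ids <- vapply(blocks, `[[`, "", "block_id")
  out <- list()
  for (chr in sort(unique(rchr))) {
    idx <- which(rchr == chr)
    n <- length(idx)
    if (n < 2L) next
    ov <- pmin(outer(hi[idx], hi[idx], pmin) - outer(lo[idx], lo[idx], pmax) + 1L, Inf)
    adj <- ov >= t_genes
    diag(adj) <- FALSE
    edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    if (nrow(edges) > 0L) {
      g <- igraph::add_edges(g, as.vector(t(edges)))
    }
    memb <- igraph::components(g)$membership
    for (comp in unique(memb)) {
      members <- idx[memb == comp]
      if (length(members) < 2L) next
      members <- members[order(lo[members], ids[members])]
      out[[length(out) + 1L]] <- structure(
        list(reference_chromosome = chr,
             member_blocks = ids[members],
             multiplicity_B = length(members),
             reference_union_span = c(min(lo[members]), max(hi[members]))),
        class = "superblock"
      )
    }
  }
  if (length(out) > 1L) {
    ord <- order(vapply(out, `[[`, "", "reference_chromosome"),
                 vapply(out, function(s) s$reference_union_span[1L], numeric(1L)))
    out <- out[ord]
  }
  out
}

#' @export
print.superblock <- function(x, ...) {
  cat(sprintf("superblock on %s[%d,%d]: B = %d (%s)\n",
              x$reference_chromosome,
              x$reference_union_span[1L], x$reference_union_span[2L],
              x$multiplicity_B, paste(x$member_blocks, collapse = ", ")))
  invisible(x)
}

#' Empirical distribution of superblock multiplicities f(B)
#'
#' Counts superblocks by multiplicity B. `f(B)` is the raw signal the tail
#' fit consumes; it stores raw counts (not proportions) — the decay rate c of
#' the exponential fit is invariant to positive rescaling.
#'
#' @param superblocks list of `superblock` objects from [build_superblocks()].
#' @param provenance optional named list recording where the distribution came
#'   from (target_id, reference_id, minL, T, ...).
#' @return object of class `multiplicity_distribution`: list with `counts`
#'   (named integer vector, names are B values >= 2, non-zero counts only) and
#'   `provenance`.
#' @export
multiplicity_distribution <- function(superblocks, provenance = list()) {
  if (length(superblocks) == 0L) {
    counts <- stats::setNames(integer(0), character(0))
  } else {
    b <- vapply(superblocks, `[[`, integer(1L), "multiplicity_B")
    tab <- table(b)
    counts <- stats::setNames(as.integer(tab), names(tab))
  }
  new_multiplicity_distribution(counts, provenance)
}

#' Construct a multiplicity distribution from raw counts
#'
#' @param counts named vector: multiplicity B (name) -> superblock count.
#' @param provenance optional named list.
#' @return `multiplicity_distribution` object.
#' @export
new_multiplicity_distribution <- function(counts, provenance = list()) {
  b <- as.integer(names(counts))
  if (length(counts) > 0L && (anyNA(b) || any(b < 2L))) {
    stop("multiplicity names must be integers >= 2")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  keep <- counts > 0
  counts <- counts[keep]
  if (length(counts) > 0L) counts <- counts[order(as.integer(names(counts)))]
  structure(list(counts = counts, provenance = provenance),
            class = "multiplicity_distribution")
}

#' @export
print.multiplicity_distribution <- function(x, ...) {
  cat("multiplicity distribution f(B):",
      if (length(x$counts) == 0L) "(empty)" else "", "\n")
  if (length(x$counts) > 0L) {
    print(x$counts)
  }
  if (length(x$provenance) > 0L) {
    cat("provenance:", paste(names(x$provenance), unlist(x$provenance),
                             sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Plot f(B) on a log scale, optionally with exponential tail fits
#'
#' Zero counts are plotted at f = 1 for visibility (open symbols) but are
#' never part of any fit.
#'
#' @param x a `multiplicity_distribution`.
#' @param fits optional list of `wgd_tailfit` objects to overlay.
#' @param ... passed to [graphics::plot()].
#' @export
plot.multiplicity_distribution <- function(x, fits = NULL, ...) {
  if (length(x$counts) == 0L) {
    stop("empty multiplicity distribution; nothing to plot")
  }
  b <- as.integer(names(x$counts))
  b_all <- seq(min(b), max(b))
  f_all <- stats::setNames(rep(0L, length(b_all)), b_all)
  f_all[names(x$counts)] <- x$counts
  shown <- pmax(f_all, 1L)
  graphics::plot(b_all, shown, log = "y", pch = ifelse(f_all > 0, 19, 1),
                 xlab = "multiplicity B", ylab = "f(B)", ...)
  if (!is.null(fits)) {
    cols <- grDevices::hcl.colors(max(3L, length(fits)), "Dark 3")
    for (i in seq_along(fits)) {
      ft <- fits[[i]]
      if (is.null(ft)) next
      xs <- seq(ft$B_min, max(b_all), length.out = 100L)
      graphics::lines(xs, ft$a * exp(-ft$c * xs), col = cols[i])
    }
    graphics::legend("topright", bty = "n",
                     legend = vapply(Filter(Negate(is.null), fits),
                                     function(ft) sprintf("B >= %d: c = %.3f", ft$B_min, ft$c), ""),
                     col = cols[seq_along(Filter(Negate(is.null), fits))], lty = 1L)
  }
  invisible(x)
}
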