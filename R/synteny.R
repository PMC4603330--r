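#' Chaining parameters for syntenic block detection
#'
#' `minL` is the minimum number of homolog anchors required to validate a
#' syntenic block (default 5; 4 and 3 are also commonly credible and are swept
#' by the panel analysis). `max_gap` is the maximum allowed gap, in gene
#' ordinals on *both* genomes, between consecutive anchors of a chain; it
#' bounds how many unmatched genes may be interspersed within a block.
#'
#' @param minL integer >= 2.
#' @param max_gap integer >= 1, in genes.
#' @return list of class `chaining_params`.
#' @export
chaining_params <- function(minL = 5L, max_gap = 20L) {
  minL <- as.integer(minL)
  max_gap <- as.integer(max_gap)
  if (is.na(minL) || minL < 2L) stop("minL must be an integer >= 2")
  if (is.na(max_gap) || max_gap < 1L) stop("max_gap must be an integer >= 1")
  structure(list(minL = minL, max_gap = max_gap), class = "chaining_params")
}

# anchors: data.frame(target_gene, reference_gene, target_ordinal,
# reference_ordinal, similarity); sorted by target ordinal on construction.
new_syntenic_block <- function(block_id, target_chromosome, reference_chromosome,
                               anchors) {
  o <- order(anchors$target_ordinal, anchors$reference_ordinal)
  anchors <- anchors[o, , drop = FALSE]
  rownames(anchors) <- NULL
  orientation <- "parallel"
  if (nrow(anchors) >= 2L) {
    dr <- anchors$reference_ordinal[nrow(anchors)] - anchors$reference_ordinal[1L]
    if (dr < 0) orientation <- "antiparallel"
  }
  structure(
    list(block_id = block_id,
         target_chromosome = target_chromosome,
         reference_chromosome = reference_chromosome,
         anchors = anchors,
         orientation = orientation,
         target_span = c(min(anchors$target_ordinal), max(anchors$target_ordinal)),
         reference_span = c(min(anchors$reference_ordinal), max(anchors$reference_ordinal))),
    class = "syntenic_block"
  )
}

#' @export
print.syntenic_block <- function(x, ...) {
  cat(sprintf("syntenic_block %s: %s[%d,%d] ~ %s[%d,%d], %d anchors, %s\n",
              x$block_id, x$target_chromosome, x$target_span[1L], x$target_span[2L],
              x$reference_chromosome, x$reference_span[1L], x$reference_span[2L],
              nrow(x$anchors), x$orientation))
  invisible(x)
}

# Best gap-bounded monotone chain in one orientation.
# Score is (anchor count, summed similarity); ties resolved toward the
# smallest predecessor index so extraction is deterministic.
chain_dp <- function(t_ord, r_ord, sim, max_gap, parallel) {
  n <- length(t_ord)
  cnt <- rep(1L, n)
  ssum <- sim
  prev <- rep(0L, n)
  for (v in seq_len(n)) {
    if (v == 1L) next
    u <- seq_len(v - 1L)
    dt <- t_ord[v] - t_ord[u]
    dr <- r_ord[v] - r_ord[u]
    ok <- dt > 0L & dt <= max_gap &
      (if (parallel) dr > 0L & dr <= max_gap else dr < 0L & dr >= -max_gap)
    if (!any(ok)) next
    cand <- u[ok]
    best_cnt <- max(cnt[cand])
    cand <- cand[cnt[cand] == best_cnt]
    best_sum <- max(ssum[cand])
    p <- cand[ssum[cand] == best_sum][1L]
    cnt[v] <- cnt[p] + 1L
    ssum[v] <- ssum[p] + sim[v]
    prev[v] <- p
  }
  end <- which(cnt == max(cnt))
  end <- end[ssum[end] == max(ssum[end])][1L]
  chain <- integer(cnt[end])
  v <- end
  for (i in rev(seq_len(cnt[end]))) {
    chain[i] <- v
    v <- prev[v]
  }
  list(idx = chain, count = max(cnt), simsum = ssum[end])
}

# Iterative best-chain extraction on one (target chr, reference chr) anchor set.
extract_chains <- function(anc, minL, max_gap) {
  chains <- list()
  repeat {
    if (nrow(anc) < minL) break
    par <- chain_dp(anc$target_ordinal, anc$reference_ordinal, anc$similarity,
                    max_gap, parallel = TRUE)
    anti <- chain_dp(anc$target_ordinal, anc$reference_ordinal, anc$similarity,
                     max_gap, parallel = FALSE)
    take <- if (anti$count > par$count ||
                (anti$count == par$count && anti$simsum > par$simsum)) anti else par
    if (take$count < minL) break
    chains[[length(chains) + 1L]] <- anc[take$idx, , drop = FALSE]
    anc <- anc[-take$idx, , drop = FALSE]
  }
  chains
}

#' Find syntenic blocks by collinear anchor chaining
#'
#' A simplified DAGchainer-style chainer: per (target chromosome, reference
#' chromosome) pair, homolog anchors are chained by dynamic programming.
#' A chain may step from anchor u to anchor v when the target ordinal strictly
#' increases by at most `max_gap` genes and the reference ordinal strictly
#' increases (parallel) or strictly decreases (antiparallel) by at most
#' `max_gap` genes. Chains are scored by anchor count with summed similarity
#' as tie-break; the highest-scoring chain is extracted, its anchors removed,
#' and the search repeated until no chain reaches `minL` anchors. Each anchor
#' therefore belongs to at most one block, and block ids
#' (`<tchr>_<rchr>_<k>`) are deterministic by extraction order.
#'
#' This is a documented stand-in for SynMap so the pipeline is testable
#' offline; precomputed SynMap/DAGchainer output can be imported with
#' [read_dagchainer_blocks()] instead — both produce the same block objects.
#'
#' @param pairs data.frame of homolog pairs ([read_homolog_pairs()]).
#' @param target,reference [genome_annotation()] objects.
#' @param params a [chaining_params()] object.
#' @return list of `syntenic_block` objects.
#' @export
find_syntenic_blocks <- function(pairs, target, reference,
                                 params = chaining_params()) {
  stopifnot(inherits(params, "chaining_params"))
  if (nrow(pairs) == 0L) return(list())
  tidx <- gene_index(target)
  ridx <- gene_index(reference)
  tchr <- unname(tidx$chromosome[pairs$target_gene])
  rchr <- unname(ridx$chromosome[pairs$reference_gene])
  if (anyNA(tchr)) {
    stop("homolog pair names gene ", pairs$target_gene[which(is.na(tchr))[1L]],
         " absent from target annotation")
  }
  if (anyNA(rchr)) {
    stop("homolog pair names gene ", pairs$reference_gene[which(is.na(rchr))[1L]],
         " absent from reference annotation")
  }
  anc <- data.frame(
    target_gene = pairs$target_gene,
    reference_gene = pairs$reference_gene,
    target_ordinal = unname(tidx$ordinal[pairs$target_gene]),
    reference_ordinal = unname(ridx$ordinal[pairs$reference_gene]),
    similarity = pairs$similarity,
    .tchr = tchr,
    .rchr = rchr,
    stringsAsFactors = FALSE
  )
  anc <- anc[!duplicated(anc[c("target_gene", "reference_gene")]), , drop = FALSE]
  groups <- split(seq_len(nrow(anc)), paste(anc$.tchr, anc$.rchr, sep = "\r"))
  anc$.tchr <- NULL
  anc$.rchr <- NULL
  blocks <- list()
  for (tc in target$chromosomes) {
    for (rc in reference$chromosomes) {
      idx <- groups[[paste(tc, rc, sep = "\r")]]
      if (is.null(idx) || length(idx) < params$minL) next
      sub <- anc[idx, , drop = FALSE]
      sub <- sub[order(sub$target_ordinal, sub$reference_ordinal), , drop = FALSE]
      chains <- extract_chains(sub, params$minL, params$max_gap)
      for (k in seq_along(chains)) {
        blocks[[length(blocks) + 1L]] <- new_syntenic_block(
          block_id = sprintf("%s_%s_%d", tc, rc, k),
          target_chromosome = tc,
          reference_chromosome = rc,
          anchors = chains[[k]]
        )
      }
    }
  }
  blocks
}

#' Re-threshold syntenic blocks by anchor count
#'
#' Keeps blocks with at least `minL` anchors, preserving order. Useful for
#' sweeping the validation threshold over imported or precomputed blocks
#' without re-running the chainer: chains with `>= minL` anchors are extracted
#' identically for any lower chaining threshold, so chaining once at the
#' smallest `minL` of a sweep and filtering is equivalent.
#'
#' @param blocks list of `syntenic_block` objects.
#' @param minL minimum anchor count.
#' @return filtered list.
#' @export
filter_blocks <- function(blocks, minL) {
  blocks[vapply(blocks, function(b) nrow(b$anchors) >= minL, logical(1L))]
}
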