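# Independent brute-force oracles and tiny fixture builders.

# annotation with n genes on one chromosome, ordinals 1..n
toy_annotation <- function(n, chr = "chr1", prefix = "g", genome_id = "toy") {
  genome_annotation(data.frame(
    gene_id = paste0(prefix, seq_len(n)),
    chromosome = chr,
    start = seq_len(n) * 1000L,
    end = seq_len(n) * 1000L + 500L,
    strand = "+",
    stringsAsFactors = FALSE
  ), genome_id = genome_id)
}

# homolog-pair table from (target ordinal, reference ordinal) anchor coords
pairs_from_anchors <- function(t_ord, r_ord, sim = NULL,
                               t_prefix = "t", r_prefix = "r") {
  if (is.null(sim)) sim <- rep(50, length(t_ord))
  data.frame(target_gene = paste0(t_prefix, t_ord),
             reference_gene = paste0(r_prefix, r_ord),
             similarity = sim,
             stringsAsFactors = FALSE)
}

# minimal syntenic-block stub carrying only what build_superblocks consumes
block_stub <- function(id, lo, hi, chr = "r1") {
  structure(list(block_id = id,
                 target_chromosome = "t1",
                 reference_chromosome = chr,
                 anchors = data.frame(),
                 orientation = "parallel",
                 target_span = c(1L, 1L),
                 reference_span = c(lo, hi)),
            class = "syntenic_block")
}

# --- superblock oracle: explicit pairwise overlap matrix + transitive closure

oracle_overlap <- function(lo_a, hi_a, lo_b, hi_b) {
  max(0L, min(hi_a, hi_b) - max(lo_a, lo_b) + 1L)
}

# returns list(partition = list of integer index sets (size >= 2), fB = table)
oracle_superblocks <- function(lo, hi, t_genes) {
  n <- length(lo)
  if (n == 0L) return(list(partition = list(), fB = integer(0)))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- oracle_overlap(lo[i], hi[i], lo[j], hi[j]) >= t_genes
    }
  }
  diag(adj) <- TRUE
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  seen <- rep(FALSE, n)
  partition <- list()
  for (i in seq_len(n)) {
    if (seen[i]) next
    members <- which(adj[i, ])
    seen[members] <- TRUE
    if (length(members) >= 2L) partition[[length(partition) + 1L]] <- members
  }
  fB <- table(vapply(partition, length, integer(1L)))
  list(partition = partition, fB = fB)
}

# --- chain oracle: exhaustive enumeration of gap-bounded monotone chains

oracle_best_chain <- function(t_ord, r_ord, sim, max_gap) {
  n <- length(t_ord)
  best <- list(count = 0L, simsum = -Inf, idx = integer(0))
  consider <- function(idx) {
    cnt <- length(idx)
    ss <- sum(sim[idx])
    if (cnt > best$count || (cnt == best$count && ss > best$simsum)) {
      best <<- list(count = cnt, simsum = ss, idx = idx)
    }
  }
  step_ok <- function(u, v, orient) {
    dt <- t_ord[v] - t_ord[u]
    dr <- r_ord[v] - r_ord[u]
    if (dt <= 0 || dt > max_gap) return(FALSE)
    if (orient > 0) dr > 0 && dr <= max_gap else dr < 0 && -dr <= max_gap
  }
  extend <- function(idx, orient) {
    consider(idx)
    last <- idx[length(idx)]
    for (v in seq_len(n)) {
      if (step_ok(last, v, orient)) extend(c(idx, v), orient)
    }
  }
  for (s in seq_len(n)) {
    extend(s, 1L)
    extend(s, -1L)
  }
  best
}

# iterative extraction with the exhaustive oracle; returns chain sizes per round
oracle_extraction_sizes <- function(t_ord, r_ord, sim, max_gap, minL) {
  sizes <- integer(0)
  alive <- seq_along(t_ord)
  repeat {
    if (length(alive) < minL) break
    best <- oracle_best_chain(t_ord[alive], r_ord[alive], sim[alive], max_gap)
    if (best$count < minL) break
    sizes <- c(sizes, best$count)
    alive <- alive[-best$idx]
  }
  sizes
}

# canonical form for f(B) count vectors so empty/name edge cases compare cleanly
norm_fB <- function(x) {
  nm <- as.character(names(x))
  o <- order(as.integer(nm))
  stats::setNames(as.integer(x)[o], nm[o])
}

# log-linear OLS oracle via stats::lm (implementation uses closed-form sums)
oracle_loglinear <- function(counts, B_min) {
  b <- as.integer(names(counts))
  keep <- b >= B_min & counts > 0
  fit <- stats::lm(log(as.numeric(counts[keep])) ~ b[keep])
  c(a = exp(unname(coef(fit)[1L])), c = -unname(coef(fit)[2L]))
}
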