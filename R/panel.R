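#' Enumerate the comparison cells of a panel design
#'
#' Crosses every ordered (target, reference) genome pair (target != reference)
#' with the block-validation thresholds `minL` and tail cutoffs `B_min`. For
#' the full design of 15 genomes, minL in \{3,4,5\} and cutoffs in \{2,3,4\}
#' this yields 15 x 14 = 210 ordered pairs and 15 x 14 x 3 x 3 = 1890 cells.
#'
#' @param genome_ids character vector of at least two distinct genome ids.
#' @param minL_values integer vector of block-validation thresholds.
#' @param cutoff_values integer vector of tail cutoffs B_min.
#' @return data.frame with columns `target`, `reference`, `minL`, `B_min`,
#'   in deterministic order (target, then reference, then minL, then B_min).
#' @export
enumerate_cells <- function(genome_ids, minL_values = c(3L, 4L, 5L),
                            cutoff_values = c(2L, 3L, 4L)) {
  if (anyDuplicated(genome_ids)) {
    stop("duplicate genome id: ", genome_ids[duplicated(genome_ids)][1L])
  }
  if (length(genome_ids) < 2L) stop("need at least two genomes")
  rows <- expand.grid(B_min = as.integer(cutoff_values),
                      minL = as.integer(minL_values),
                      reference = genome_ids,
                      target = genome_ids,
                      stringsAsFactors = FALSE)
  rows <- rows[rows$target != rows$reference, c("target", "reference", "minL", "B_min")]
  rows <- rows[order(match(rows$target, genome_ids),
                     match(rows$reference, genome_ids),
                     rows$minL, rows$B_min), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Count pairwise c wins between target genomes
#'
#' For each unordered pair of genomes \{G, H\} and every shared analysis
#' condition — reference genome (excluding G and H themselves), minL, tail
#' cutoff, and any further condition columns such as the overlap threshold T —
#' the decay rates are compared: `wins[G,H]` counts conditions with
#' `c(G) > c(H)`. Exact ties count for neither side; conditions where either
#' c is missing (the fit was undefined) are skipped. `comparable[G,H]` counts
#' conditions where both were defined. In a fully defined 15-genome design
#' each pair has 13 x 3 x 3 = 117 comparisons, 39 per fixed minL.
#'
#' @param cells data.frame with columns `target`, `reference`, `c` (numeric,
#'   `NA` = missing) plus any number of condition columns (e.g. `minL`,
#'   `B_min`, `T`).
#' @return object of class `wgd_winmatrix`: list with `genomes`, square
#'   matrices `wins` and `comparable`, and `ties`.
#' @export
pairwise_wins <- function(cells) {
  stopifnot(all(c("target", "reference", "c") %in% names(cells)))
  genomes <- unique(cells$target)
  cond_cols <- setdiff(names(cells), c("target", "c"))
  n <- length(genomes)
  wins <- matrix(0L, n, n, dimnames = list(genomes, genomes))
  comparable <- matrix(0L, n, n, dimnames = list(genomes, genomes))
  ties <- matrix(0L, n, n, dimnames = list(genomes, genomes))
  if (n < 2L) {
    return(structure(list(genomes = genomes, wins = wins,
                          comparable = comparable, ties = ties),
                     class = "wgd_winmatrix"))
  }
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      g <- genomes[i]; h <- genomes[j]
      cg <- cells[cells$target == g & !(cells$reference %in% c(g, h)), , drop = FALSE]
      ch <- cells[cells$target == h & !(cells$reference %in% c(g, h)), , drop = FALSE]
      m <- merge(cg, ch, by = cond_cols, suffixes = c(".g", ".h"))
      both <- !is.na(m$c.g) & !is.na(m$c.h)
      comparable[i, j] <- comparable[j, i] <- sum(both)
      wins[i, j] <- sum(both & m$c.g > m$c.h)
      wins[j, i] <- sum(both & m$c.h > m$c.g)
      ties[i, j] <- ties[j, i] <- sum(both & m$c.g == m$c.h)
    }
  }
  structure(list(genomes = genomes, wins = wins, comparable = comparable,
                 ties = ties),
            class = "wgd_winmatrix")
}

#' @export
print.wgd_winmatrix <- function(x, ...) {
  cat("pairwise c win matrix (row beats column):\n")
  print(x$wins)
  invisible(x)
}

#' Rank genomes by head-to-head dominance of the decay rate c
#'
#' A genome's dominance score is the number of other genomes it beats head to
#' head (more wins than losses over all shared conditions). Genomes are
#' sorted by descending dominance, with descending total wins and then
#' lexicographic id as tie-breaks. Rank 1 is the genome with the largest c
#' profile — the least persistent multiplicity tail, i.e. the least
#' whole-genome-duplication signal (a basal, unduplicated lineage in the real
#' panel); the last rank carries the heaviest tail and the most WGD signal.
#'
#' @param matrix a `wgd_winmatrix` from [pairwise_wins()].
#' @return object of class `wgd_ranking` (also a data.frame) with columns
#'   `rank`, `genome`, `dominance`, `total_wins`.
#' @export
rank_genomes <- function(matrix) {
  stopifnot(inherits(matrix, "wgd_winmatrix"))
  g <- matrix$genomes
  n <- length(g)
  w <- matrix$wins
  dominance <- integer(n)
  for (i in seq_len(n)) {
    dominance[i] <- sum(w[i, -i] > w[-i, i])
  }
  total <- as.integer(rowSums(w))
  o <- order(-dominance, -total, g)
  out <- data.frame(rank = seq_len(n), genome = g[o], dominance = dominance[o],
                    total_wins = total[o], stringsAsFactors = FALSE)
  class(out) <- c("wgd_ranking", "data.frame")
  out
}

#' @export
print.wgd_ranking <- function(x, ...) {
  cat("genome ranking by decay rate c (rank 1 = largest c, least WGD signal):\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
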