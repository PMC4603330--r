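#' Run the full target x reference x minL x T x cutoff panel analysis
#'
#' For every ordered (target, reference) genome pair, homolog anchors are
#' chained once at the smallest minL of the sweep, re-thresholded per minL
#' with [filter_blocks()] (equivalent to chaining at each minL), grouped into
#' superblocks at each overlap threshold T, and the exponential tail fitted
#' at each cutoff. The resulting cells feed [pairwise_wins()] and
#' [rank_genomes()]. Undefined fits are recorded as missing cells, never
#' fatal. Given identical inputs and seed, reruns are deterministic and the
#' written TSV outputs byte-identical.
#'
#' @param panel either a `wgd_panel` (from [simulate_panel()]), a list with
#'   named elements `genomes` (named list of [genome_annotation()]) and
#'   `homologs` (named list `"T~R"` -> homolog data.frame), or a path to a
#'   plain-text config file understood by [read_run_config()].
#' @param minL integer sweep of block-validation thresholds (default 3,4,5).
#' @param overlap integer sweep of superblock overlap thresholds T (default
#'   5 and 10; results differ little between the two).
#' @param cutoffs integer sweep of tail cutoffs B_min (default 2,3,4).
#' @param max_gap chaining gap bound in genes.
#' @param out_dir if non-NULL, writes `cells.tsv`, `wins.tsv`,
#'   `comparable.tsv`, `ranking.tsv` and `manifest.json` there.
#' @param seed recorded in the manifest (the analysis itself is
#'   deterministic; randomness lives in the simulator).
#' @param quiet suppress per-cell progress messages.
#' @return list of class `wgd_panel_result` with `cells` (data.frame with a
#'   `c` column, `NA` when the fit was undefined), `wins` (a `wgd_winmatrix`),
#'   `ranking` (a `wgd_ranking`) and `manifest`.
#' @export
run_panel <- function(panel, minL = c(3L, 4L, 5L), overlap = c(5L, 10L),
                      cutoffs = c(2L, 3L, 4L), max_gap = 20L,
                      out_dir = NULL, seed = NULL, quiet = FALSE) {
  if (is.character(panel)) {
    cfg <- read_run_config(panel)
    if (missing(minL) && !is.null(cfg$minL)) minL <- cfg$minL
    if (missing(overlap) && !is.null(cfg$overlap)) overlap <- cfg$overlap
    if (missing(cutoffs) && !is.null(cfg$cutoffs)) cutoffs <- cfg$cutoffs
    if (missing(max_gap) && !is.null(cfg$max_gap)) max_gap <- cfg$max_gap
    if (missing(out_dir) && !is.null(cfg$out_dir)) out_dir <- cfg$out_dir
    if (missing(seed) && !is.null(cfg$seed)) seed <- cfg$seed
    panel <- cfg
  }
  genomes <- panel$genomes
  homologs <- panel$homologs
  if (length(minL) == 0L || length(overlap) == 0L || length(cutoffs) == 0L) {
    stop("parameter sweeps must be non-empty")
  }
  ids <- names(genomes)
  if (length(ids) < 2L) stop("need at least two genomes")
  for (t_id in ids) {
    for (r_id in setdiff(ids, t_id)) {
      if (is.null(homologs[[paste(t_id, r_id, sep = "~")]])) {
        stop("missing homolog table for pair ", t_id, "~", r_id)
      }
    }
  }
  minL <- sort(as.integer(minL))
  overlap <- as.integer(overlap)
  cutoffs <- as.integer(cutoffs)
  rows <- list()
  for (t_id in ids) {
    for (r_id in setdiff(ids, t_id)) {
      pairs <- homologs[[paste(t_id, r_id, sep = "~")]]
      blocks <- find_syntenic_blocks(pairs, genomes[[t_id]], genomes[[r_id]],
                                     chaining_params(minL[1L], max_gap))
      for (L in minL) {
        bl <- filter_blocks(blocks, L)
        for (tt in overlap) {
          sb <- suppressWarnings(build_superblocks(bl, overlap_params(tt)))
          d <- multiplicity_distribution(sb, provenance = list(
            target_id = t_id, reference_id = r_id, minL = L, T = tt))
          fits <- fit_all_cutoffs(d, cutoffs)
          for (bm in as.character(cutoffs)) {
            ft <- fits[[bm]]
            rows[[length(rows) + 1L]] <- data.frame(
              target = t_id, reference = r_id, minL = L, T = tt,
              B_min = as.integer(bm),
              c = if (is.null(ft)) NA_real_ else ft$c,
              a = if (is.null(ft)) NA_real_ else ft$a,
              n_points = if (is.null(ft)) NA_integer_ else ft$n_points,
              stringsAsFactors = FALSE)
          }
          if (!quiet) {
            message(sprintf("cell %s vs %s minL=%d T=%d: %d blocks, %d superblocks",
                            t_id, r_id, L, tt, length(bl), length(sb)))
          }
        }
      }
    }
  }
  cells <- do.call(rbind, rows)
  wins <- pairwise_wins(cells[, c("target", "reference", "minL", "T", "B_min", "c")])
  ranking <- rank_genomes(wins)
  manifest <- list(
    genomes = ids,
    n_cells = nrow(cells),
    parameters = list(minL = minL, overlap = overlap, cutoffs = cutoffs,
                      max_gap = max_gap),
    seed = seed,
    package = "wgdsig",
    version = as.character(utils::packageVersion("wgdsig"))
  )
  result <- structure(list(cells = cells, wins = wins, ranking = ranking,
                           manifest = manifest),
                      class = "wgd_panel_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_plain(cells, file.path(out_dir, "cells.tsv"))
    write_matrix_tsv(wins$wins, file.path(out_dir, "wins.tsv"))
    write_matrix_tsv(wins$comparable, file.path(out_dir, "comparable.tsv"))
    write_tsv_plain(as.data.frame(ranking), file.path(out_dir, "ranking.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  result
}

#' @export
print.wgd_panel_result <- function(x, ...) {
  cat(sprintf("panel result: %d genomes, %d cells (%d with defined c)\n",
              length(x$manifest$genomes), nrow(x$cells), sum(!is.na(x$cells$c))))
  print(x$ranking)
  invisible(x)
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(genome = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export superblocks as TSV
#'
#' One row per superblock: reference chromosome, union span, multiplicity B
#' and comma-joined member block ids.
#'
#' @param superblocks list from [build_superblocks()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_superblocks <- function(superblocks, path) {
  df <- data.frame(
    reference_chromosome = vapply(superblocks, `[[`, "", "reference_chromosome"),
    union_lo = vapply(superblocks, function(s) s$reference_union_span[1L], numeric(1L)),
    union_hi = vapply(superblocks, function(s) s$reference_union_span[2L], numeric(1L)),
    B = vapply(superblocks, `[[`, integer(1L), "multiplicity_B"),
    member_blocks = vapply(superblocks, function(s) paste(s$member_blocks, collapse = ","), ""),
    stringsAsFactors = FALSE
  )
  write_tsv_plain(df, path)
}

#' Export a multiplicity distribution as TSV
#'
#' Columns `B` and `count`, preceded by provenance columns when present.
#'
#' @param dist a `multiplicity_distribution`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_multiplicity_distribution <- function(dist, path) {
  df <- data.frame(B = as.integer(names(dist$counts)),
                   count = as.integer(dist$counts),
                   stringsAsFactors = FALSE)
  for (nm in rev(names(dist$provenance))) {
    df <- cbind(stats::setNames(data.frame(rep(dist$provenance[[nm]],
                                               max(1L, nrow(df)))[seq_len(nrow(df))],
                                           stringsAsFactors = FALSE), nm),
                df)
  }
  write_tsv_plain(df, path)
}

#' Read a plain-text panel run configuration
#'
#' A minimal line-oriented format: `key: value` lines for scalar settings
#' (`minL`, `overlap`, `cutoffs` as comma-separated integers; `max_gap`,
#' `seed`, `out_dir`) plus repeated entries
#' \preformatted{
#' genome: <id> <annotation path> <gff3|bed>
#' pairs: <target id> <reference id> <homolog tsv path>
#' }
#' All referenced files are checked for existence before anything runs, and
#' a homolog table must be present for every ordered genome pair.
#'
#' @param path config file path.
#' @return list with `genomes`, `homologs`, and any sweep/setting entries,
#'   suitable for [run_panel()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  settings <- list()
  genome_specs <- list()
  pair_specs <- list()
  base <- dirname(path)
  for (i in seq_along(lines)) {
    m <- regmatches(lines[i], regexec("^\\s*([^:]+):\\s*(.*)$", lines[i]))[[1L]]
    if (length(m) != 3L) stop("config line not of the form 'key: value': ", lines[i])
    key <- trimws(m[2L]); val <- trimws(m[3L])
    if (key == "genome") {
      f <- strsplit(val, "\\s+")[[1L]]
      if (length(f) != 3L) stop("genome entry needs '<id> <path> <format>': ", val)
      genome_specs[[f[1L]]] <- list(path = f[2L], format = f[3L])
    } else if (key == "pairs") {
      f <- strsplit(val, "\\s+")[[1L]]
      if (length(f) != 3L) stop("pairs entry needs '<target> <reference> <path>': ", val)
      pair_specs[[paste(f[1L], f[2L], sep = "~")]] <- f[3L]
    } else {
      settings[[key]] <- val
    }
  }
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  for (id in names(genome_specs)) {
    p <- resolve(genome_specs[[id]]$path)
    if (!file.exists(p)) stop("annotation file for genome ", id, " not found: ", p)
    genome_specs[[id]]$path <- p
  }
  for (key in names(pair_specs)) {
    p <- resolve(pair_specs[[key]])
    if (!file.exists(p)) stop("homolog table for pair ", key, " not found: ", p)
    pair_specs[[key]] <- p
  }
  genomes <- lapply(names(genome_specs), function(id) {
    read_gene_annotations(genome_specs[[id]]$path,
                          format = genome_specs[[id]]$format, genome_id = id)
  })
  names(genomes) <- names(genome_specs)
  homologs <- lapply(pair_specs, read_homolog_pairs)
  int_vec <- function(key, default) {
    if (is.null(settings[[key]])) return(default)
    as.integer(strsplit(settings[[key]], ",")[[1L]])
  }
  list(genomes = genomes, homologs = homologs,
       minL = int_vec("minL", c(3L, 4L, 5L)),
       overlap = int_vec("overlap", c(5L, 10L)),
       cutoffs = int_vec("cutoffs", c(2L, 3L, 4L)),
       max_gap = int_vec("max_gap", 20L),
       seed = int_vec("seed", NULL),
       out_dir = settings[["out_dir"]])
}
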