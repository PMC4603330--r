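#' A whole-genome duplication (or triplication) event
#'
#' @param time time before present, in arbitrary time units; events within a
#'   scenario must have strictly decreasing times toward the present.
#' @param ploidy_factor 2 for a duplication, 3 for a triplication.
#' @return list of class `wgd_event`.
#' @export
wgd_event <- function(time, ploidy_factor = 2L) {
  ploidy_factor <- as.integer(ploidy_factor)
  if (!is.numeric(time) || time < 0) stop("event time must be >= 0")
  if (is.na(ploidy_factor) || ploidy_factor < 2L) stop("ploidy_factor must be >= 2")
  structure(list(time = time, ploidy_factor = ploidy_factor), class = "wgd_event")
}

#' Exponential fractionation parameters
#'
#' After polyploidization, redundant duplicate gene copies are lost over time:
#' a duplicate survives an interval of length t with probability
#' `exp(-lambda_rate * t)` (exponential loss with rate lambda). Loss of the
#' last copy of a gene is treated as lethal and never happens.
#'
#' @param lambda_rate positive per-copy loss rate per time unit.
#' @return list of class `fractionation_params`.
#' @export
fractionation_params <- function(lambda_rate = 1) {
  if (!is.numeric(lambda_rate) || lambda_rate <= 0) stop("lambda_rate must be > 0")
  structure(list(lambda_rate = lambda_rate), class = "fractionation_params")
}

#' Scripted evolutionary scenario for a target/reference genome pair
#'
#' Describes the stated world the simulator generates: an ancestor of
#' `n_ancestral_genes` genes on `n_chromosomes` chromosomes splits at
#' `speciation_time` into a reference lineage (no WGD by default) and a target
#' lineage that experiences the listed WGD events, with exponential
#' fractionation acting between events and up to the present, and inversions
#' and translocations scrambling each lineage. Percent similarity of a
#' homolog pair decays as `100 * exp(-similarity_rate * divergence_time)`
#' plus truncated Gaussian noise.
#'
#' Defaults: 2000 ancestral genes on 10 chromosomes (a mid-sized plant genome
#' at desk scale), speciation 1 time unit ago, one duplication 0.6 units ago,
#' lambda = 1 (so a duplicate created at the speciation epoch survives to the
#' present with probability about `exp(-1)`), 30 inversions and 10
#' translocations per lineage (enough rearrangement that blocks fragment, as
#' in real genomes), similarity_rate 0.21 so orthologs diverged 1 unit ago
#' have a similarity mode near 81 percent.
#'
#' @param n_ancestral_genes,n_chromosomes ancestor size.
#' @param speciation_time split time of the two lineages.
#' @param target_events list of [wgd_event()]s on the target lineage, times
#'   strictly decreasing and all `< speciation_time`.
#' @param fractionation a [fractionation_params()].
#' @param n_inversions,n_translocations rearrangement counts per lineage.
#' @param similarity_rate,noise_sd similarity decay rate and noise sd.
#' @param seed integer seed; all randomness in [simulate_pair()] flows from it.
#' @return list of class `evolution_scenario`.
#' @export
evolution_scenario <- function(n_ancestral_genes = 2000L,
                               n_chromosomes = 10L,
                               speciation_time = 1,
                               target_events = list(wgd_event(0.6, 2L)),
                               fractionation = fractionation_params(1),
                               n_inversions = 30L,
                               n_translocations = 10L,
                               similarity_rate = 0.21,
                               noise_sd = 1.5,
                               seed = 1L) {
  if (n_ancestral_genes < n_chromosomes || n_chromosomes < 1L) {
    stop("need n_ancestral_genes >= n_chromosomes >= 1")
  }
  times <- vapply(target_events, `[[`, numeric(1L), "time")
  if (length(times) > 0L) {
    if (any(diff(times) >= 0)) stop("target event times must be strictly decreasing")
    if (any(times >= speciation_time)) {
      stop("target events must postdate the speciation (time < speciation_time)")
    }
  }
  if (n_inversions < 0L || n_translocations < 0L) stop("rearrangement counts must be >= 0")
  structure(
    list(n_ancestral_genes = as.integer(n_ancestral_genes),
         n_chromosomes = as.integer(n_chromosomes),
         speciation_time = speciation_time,
         target_events = target_events,
         fractionation = fractionation,
         n_inversions = as.integer(n_inversions),
         n_translocations = as.integer(n_translocations),
         similarity_rate = similarity_rate,
         noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "evolution_scenario"
  )
}

#' Create an ancestral genome state
#'
#' Genes `1..n_genes` are laid out over chromosomes in near-equal contiguous
#' runs. The state tracks, per surviving gene copy, its ancestral gene and
#' its pre-speciation copy lineage (used to date homolog divergences).
#'
#' @param n_genes,n_chromosomes ancestor size, `n_genes >= n_chromosomes >= 1`.
#' @param seed optional; if non-NULL, `set.seed(seed)` is called (layout
#'   itself is deterministic).
#' @return a genome state (list with `copies`, `chromosomes`, `div`,
#'   `next_copy`).
#' @export
simulate_ancestor <- function(n_genes, n_chromosomes, seed = NULL) {
  n_genes <- as.integer(n_genes)
  n_chromosomes <- as.integer(n_chromosomes)
  if (is.na(n_genes) || is.na(n_chromosomes) ||
      n_genes < n_chromosomes || n_chromosomes < 1L) {
    stop("need n_genes >= n_chromosomes >= 1")
  }
  if (!is.null(seed)) set.seed(seed)
  bounds <- round(seq(0L, n_genes, length.out = n_chromosomes + 1L))
  chromosomes <- lapply(seq_len(n_chromosomes), function(i) {
    seq.int(bounds[i] + 1L, bounds[i + 1L])
  })
  copies <- data.frame(copy_id = seq_len(n_genes),
                       anc_gene = seq_len(n_genes),
                       anc_copy = 1L)
  list(copies = copies, chromosomes = chromosomes,
       div = matrix(0, 1L, 1L), next_copy = n_genes + 1L)
}

#' Apply a whole-genome duplication or triplication to a genome state
#'
#' Every chromosome is copied `ploidy_factor - 1` additional times; copies are
#' appended as new chromosomes and every gene's copy count is multiplied by
#' the ploidy factor. If `pre_speciation = TRUE` the new copies found new
#' pre-speciation copy lineages diverging at `time` (this matters only for
#' dating homolog similarities; lineage-specific events after the split leave
#' copy lineages unchanged).
#'
#' @param state a genome state.
#' @param ploidy_factor integer >= 2.
#' @param time event time (required when `pre_speciation = TRUE`).
#' @param pre_speciation whether the event predates the lineage split.
#' @return the modified state.
#' @export
apply_wgd <- function(state, ploidy_factor, time = NA_real_, pre_speciation = FALSE) {
  k <- as.integer(ploidy_factor)
  if (is.na(k) || k < 2L) stop("ploidy_factor must be >= 2")
  if (pre_speciation && is.na(time)) stop("pre-speciation events need a time")
  m <- nrow(state$div)
  copies <- state$copies
  chroms <- state$chromosomes
  new_chroms <- state$chromosomes
  new_copies <- list(copies)
  for (j in seq_len(k - 1L)) {
    dup <- copies
    dup$copy_id <- state$next_copy + (j - 1L) * nrow(copies) + seq_len(nrow(copies)) - 1L
    if (pre_speciation) dup$anc_copy <- copies$anc_copy + m * j
    new_chroms <- c(new_chroms,
                    lapply(chroms, function(v) dup$copy_id[match(v, copies$copy_id)]))
    new_copies[[j + 1L]] <- dup
  }
  state$copies <- do.call(rbind, new_copies)
  state$chromosomes <- new_chroms
  state$next_copy <- state$next_copy + (k - 1L) * nrow(copies)
  if (pre_speciation) {
    # expand the divergence-time matrix over the k replicas of each lineage
    old <- state$div
    mk <- m * k
    div <- matrix(NA_real_, mk, mk)
    for (jp in 0:(k - 1L)) {
      for (jq in 0:(k - 1L)) {
        blockv <- old
        if (jp != jq) {
          blockv <- pmax(old, 0)
          blockv[old == 0] <- time  # same parental lineage: diverged at this event
          diagv <- which(row(old) == col(old))
          blockv[diagv] <- time
        }
        div[jp * m + seq_len(m), jq * m + seq_len(m)] <- blockv
      }
    }
    diag(div) <- 0
    state$div <- div
  }
  state
}

#' Apply exponential fractionation to a genome state
#'
#' For every ancestral gene with more than one surviving copy in this genome,
#' one uniformly chosen copy is protected (losing the last copy of a gene is
#' lethal) and every other copy survives the interval independently with
#' probability `exp(-lambda_rate * duration)`. Chromosomes that lose all
#' their genes disappear.
#'
#' @param state a genome state.
#' @param lambda_rate positive loss rate.
#' @param duration elapsed time (0 leaves the state unchanged).
#' @param seed optional; if non-NULL, `set.seed(seed)` first.
#' @return the modified state.
#' @export
apply_fractionation <- function(state, lambda_rate, duration, seed = NULL) {
  if (duration < 0) stop("duration must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (duration == 0) return(state)
  copies <- state$copies
  n <- nrow(copies)
  counts <- table(copies$anc_gene)
  multi <- as.integer(names(counts)[counts > 1L])
  if (length(multi) == 0L) return(state)
  p <- exp(-lambda_rate * duration)
  at_risk <- copies$anc_gene %in% multi
  # pick one protected copy per multi-copy gene, uniformly
  perm <- sample.int(n)
  first <- !duplicated(copies$anc_gene[perm])
  protected <- logical(n)
  protected[perm[first]] <- TRUE
  survive <- protected | !at_risk | (stats::runif(n) < p)
  keep_ids <- copies$copy_id[survive]
  state$copies <- copies[survive, , drop = FALSE]
  rownames(state$copies) <- NULL
  keep_set <- rep(FALSE, max(copies$copy_id))
  keep_set[keep_ids] <- TRUE
  chroms <- lapply(state$chromosomes, function(v) v[keep_set[v]])
  state$chromosomes <- chroms[lengths(chroms) > 0L]
  state
}

#' Apply random inversions and translocations to a genome state
#'
#' Inversions reverse a uniformly chosen ordinal sub-interval of a uniformly
#' chosen chromosome; translocations excise a uniformly chosen segment and
#' re-insert it at a uniform position in a different chromosome. Gene content
#' is conserved exactly.
#'
#' @param state a genome state.
#' @param n_inversions,n_translocations non-negative counts.
#' @param seed optional; if non-NULL, `set.seed(seed)` first.
#' @return the modified state.
#' @export
apply_rearrangements <- function(state, n_inversions, n_translocations, seed = NULL) {
  if (n_inversions < 0L || n_translocations < 0L) stop("counts must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  chroms <- state$chromosomes
  for (i in seq_len(n_inversions)) {
    eligible <- which(lengths(chroms) >= 2L)
    if (length(eligible) == 0L) break
    ci <- eligible[sample.int(length(eligible), 1L)]
    v <- chroms[[ci]]
    ends <- sort(sample.int(length(v), 2L))
    v[ends[1L]:ends[2L]] <- rev(v[ends[1L]:ends[2L]])
    chroms[[ci]] <- v
  }
  for (i in seq_len(n_translocations)) {
    if (length(chroms) < 2L) break
    nonempty <- which(lengths(chroms) >= 1L)
    src <- nonempty[sample.int(length(nonempty), 1L)]
    v <- chroms[[src]]
    ends <- sort(sample.int(length(v), min(2L, length(v)), replace = (length(v) == 1L)))
    if (length(ends) == 1L) ends <- c(ends, ends)
    seg <- v[ends[1L]:ends[2L]]
    rest <- v[-(ends[1L]:ends[2L])]
    others <- setdiff(seq_along(chroms), src)
    dst <- others[sample.int(length(others), 1L)]
    w <- chroms[[dst]]
    pos <- sample.int(length(w) + 1L, 1L) - 1L
    chroms[[dst]] <- append(w, seg, after = pos)
    chroms[[src]] <- rest
  }
  state$chromosomes <- chroms[lengths(chroms) > 0L]
  state
}

# annotation with synthetic bp coordinates consistent with gene ordinals
state_to_annotation <- function(state, genome_id) {
  chroms <- state$chromosomes
  rows <- lapply(seq_along(chroms), function(i) {
    v <- chroms[[i]]
    data.frame(gene_id = sprintf("%s_g%06d", genome_id, v),
               chromosome = sprintf("%s_chr%02d", genome_id, i),
               start = (seq_along(v) - 1L) * 1000L + 1L,
               end = (seq_along(v) - 1L) * 1000L + 900L,
               strand = "+",
               stringsAsFactors = FALSE)
  })
  genome_annotation(do.call(rbind, rows), genome_id)
}

# homolog pairs between two evolved states sharing an ancestor
homologs_between <- function(state_t, state_r, id_t, id_r,
                             speciation_time, div, similarity_rate, noise_sd) {
  m <- merge(state_t$copies, state_r$copies, by = "anc_gene",
             suffixes = c(".t", ".r"))
  if (nrow(m) == 0L) {
    return(data.frame(target_gene = character(), reference_gene = character(),
                      similarity = numeric(), stringsAsFactors = FALSE))
  }
  same <- m$anc_copy.t == m$anc_copy.r
  dtime <- ifelse(same, speciation_time, div[cbind(m$anc_copy.t, m$anc_copy.r)])
  sim <- 100 * exp(-similarity_rate * dtime) +
    stats::rnorm(nrow(m), 0, noise_sd)
  sim <- pmin(100, pmax(0, sim))
  data.frame(target_gene = sprintf("%s_g%06d", id_t, m$copy_id.t),
             reference_gene = sprintf("%s_g%06d", id_r, m$copy_id.r),
             similarity = sim,
             stringsAsFactors = FALSE)
}

# evolve one lineage from the speciation point to the present
evolve_lineage <- function(state, events, speciation_time, lambda,
                           n_inversions, n_translocations) {
  prev <- speciation_time
  for (ev in events) {
    state <- apply_fractionation(state, lambda, prev - ev$time)
    state <- apply_wgd(state, ev$ploidy_factor)
    prev <- ev$time
  }
  state <- apply_fractionation(state, lambda, prev)
  apply_rearrangements(state, n_inversions, n_translocations)
}

#' Simulate a target/reference genome pair with known truth
#'
#' Runs the scenario: an ancestral genome splits at `speciation_time` into a
#' reference lineage (no WGD) and a target lineage that undergoes the
#' scenario's WGD events with exponential fractionation between events and to
#' the present; both lineages are then rearranged. Homolog pairs are emitted
#' for every (target copy, reference copy) descending from the same ancestral
#' gene, with similarity decaying in the divergence time of the pair.
#'
#' @param scenario an [evolution_scenario()]; `scenario$seed` drives all
#'   randomness.
#' @return object of class `simulated_pair`: list with `target` and
#'   `reference` ([genome_annotation()]s), `pairs` (homolog data.frame) and
#'   `truth` (the scenario plus per-copy genealogy tables).
#' @export
simulate_pair <- function(scenario) {
  stopifnot(inherits(scenario, "evolution_scenario"))
  panel <- simulate_panel(
    lineage_events = list(target = scenario$target_events, reference = list()),
    shared_events = list(),
    n_ancestral_genes = scenario$n_ancestral_genes,
    n_chromosomes = scenario$n_chromosomes,
    speciation_time = scenario$speciation_time,
    lambda_rate = scenario$fractionation$lambda_rate,
    n_inversions = scenario$n_inversions,
    n_translocations = scenario$n_translocations,
    similarity_rate = scenario$similarity_rate,
    noise_sd = scenario$noise_sd,
    seed = scenario$seed
  )
  structure(
    list(target = panel$genomes$target,
         reference = panel$genomes$reference,
         pairs = panel$homologs[["target~reference"]],
         truth = c(list(scenario = scenario), panel$truth)),
    class = "simulated_pair"
  )
}

#' Simulate a panel of genomes descending from one ancestor
#'
#' Generalises [simulate_pair()] to any number of lineages splitting from the
#' ancestor at the same time (a star phylogeny): each named lineage gets its
#' own WGD event list, plus optional `shared_events` applied to the common
#' ancestor *before* the split (times `> speciation_time`). Shared ancestral
#' polyploidy is what makes the multiplicity signal defined even for lineages
#' with no subsequent WGD, mirroring the shared ancient polyploidy of real
#' plant panels. Homolog tables are produced for every ordered genome pair.
#'
#' @param lineage_events named list: lineage id -> list of [wgd_event()]s
#'   (times `< speciation_time`, strictly decreasing).
#' @param shared_events list of [wgd_event()]s in the common ancestor, times
#'   `> speciation_time`, strictly decreasing.
#' @param n_ancestral_genes,n_chromosomes ancestor size.
#' @param speciation_time split time.
#' @param lambda_rate fractionation rate.
#' @param n_inversions,n_translocations rearrangements per lineage.
#' @param similarity_rate,noise_sd similarity decay parameters.
#' @param seed integer seed for all randomness.
#' @return object of class `wgd_panel`: list with `genomes` (named list of
#'   [genome_annotation()]), `homologs` (named list, `"T~R"` ->
#'   homolog data.frame) and `truth` (per-lineage copy tables).
#' @export
simulate_panel <- function(lineage_events,
                           shared_events = list(),
                           n_ancestral_genes = 2000L,
                           n_chromosomes = 10L,
                           speciation_time = 1,
                           lambda_rate = 1,
                           n_inversions = 30L,
                           n_translocations = 10L,
                           similarity_rate = 0.21,
                           noise_sd = 1.5,
                           seed = 1L) {
  if (is.null(names(lineage_events)) || anyNA(names(lineage_events)) ||
      any(!nzchar(names(lineage_events)))) {
    stop("lineage_events must be a named list (one entry per genome)")
  }
  set.seed(as.integer(seed))
  anc <- simulate_ancestor(n_ancestral_genes, n_chromosomes)
  prev <- NULL
  for (ev in shared_events) {
    if (ev$time <= speciation_time) {
      stop("shared events must predate the speciation (time > speciation_time)")
    }
    if (!is.null(prev)) {
      anc <- apply_fractionation(anc, lambda_rate, prev - ev$time)
    }
    anc <- apply_wgd(anc, ev$ploidy_factor, time = ev$time, pre_speciation = TRUE)
    prev <- ev$time
  }
  if (!is.null(prev)) {
    anc <- apply_fractionation(anc, lambda_rate, prev - speciation_time)
  }
  ids <- names(lineage_events)
  states <- list()
  genomes <- list()
  for (id in ids) {
    st <- evolve_lineage(anc, lineage_events[[id]], speciation_time,
                         lambda_rate, n_inversions, n_translocations)
    states[[id]] <- st
    genomes[[id]] <- state_to_annotation(st, id)
  }
  homologs <- list()
  for (t_id in ids) {
    for (r_id in ids) {
      if (t_id == r_id) next
      homologs[[paste(t_id, r_id, sep = "~")]] <- homologs_between(
        states[[t_id]], states[[r_id]], t_id, r_id,
        speciation_time, anc$div, similarity_rate, noise_sd)
    }
  }
  truth <- list(copies = lapply(states, `[[`, "copies"),
                div = anc$div,
                shared_events = shared_events,
                lineage_events = lineage_events)
  structure(list(genomes = genomes, homologs = homologs, truth = truth),
            class = "wgd_panel")
}

#' @export
print.simulated_pair <- function(x, ...) {
  cat(sprintf("simulated_pair: target %d genes, reference %d genes, %d homolog pairs\n",
              nrow(x$target$genes), nrow(x$reference$genes), nrow(x$pairs)))
  invisible(x)
}

#' @export
print.wgd_panel <- function(x, ...) {
  cat(sprintf("wgd_panel of %d genomes: %s\n", length(x$genomes),
              paste(names(x$genomes), collapse = ", ")))
  invisible(x)
}
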