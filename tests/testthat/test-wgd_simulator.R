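test_that("the ancestor splits genes over chromosomes in contiguous runs", {
  st <- simulate_ancestor(100L, 4L)
  expect_length(st$chromosomes, 4L)
  expect_equal(lengths(st$chromosomes), rep(25L, 4L))
  expect_equal(unlist(st$chromosomes), 1:100)

  one_each <- simulate_ancestor(5L, 5L)
  expect_equal(lengths(one_each$chromosomes), rep(1L, 5L))

  expect_error(simulate_ancestor(3L, 4L), "n_genes >= n_chromosomes")
})

test_that("WGD multiplies gene copies and chromosome counts", {
  st <- simulate_ancestor(100L, 4L)
  d2 <- apply_wgd(st, 2L)
  expect_equal(nrow(d2$copies), 200L)
  expect_length(d2$chromosomes, 8L)
  expect_equal(sort(table(d2$copies$anc_gene)), sort(rep(2L, 100L)),
               ignore_attr = TRUE)

  d3 <- apply_wgd(st, 3L)
  expect_equal(nrow(d3$copies), 300L)
  expect_length(d3$chromosomes, 12L)

  d4 <- apply_wgd(apply_wgd(st, 2L), 2L)
  expect_equal(nrow(d4$copies), 400L)
  expect_true(all(table(d4$copies$anc_gene) == 4L))
  # chromosome gene content is replicated, copy ids all distinct
  expect_false(anyDuplicated(d4$copies$copy_id) > 0)
  expect_equal(sort(unlist(lapply(d4$chromosomes, function(v) d4$copies$anc_gene[match(v, d4$copies$copy_id)]))),
               sort(rep(1:100, 4L)))
})

test_that("fractionation over zero time is the identity", {
  st <- apply_wgd(simulate_ancestor(50L, 2L), 2L)
  expect_identical(apply_fractionation(st, 1, 0), st)
})

test_that("extreme fractionation keeps exactly one copy per ancestral gene", {
  set.seed(4)
  st <- apply_wgd(apply_wgd(simulate_ancestor(200L, 4L), 2L), 2L)
  out <- apply_fractionation(st, lambda_rate = 1, duration = 60)
  expect_equal(nrow(out$copies), 200L)
  expect_equal(sort(out$copies$anc_gene), 1:200)
})

test_that("duplicate survival is binomial with probability exp(-lambda t)", {
  set.seed(8)
  st <- apply_wgd(simulate_ancestor(1000L, 5L), 2L)
  survivors <- replicate(30, {
    nrow(apply_fractionation(st, 1, 1)$copies) - 1000L
  })
  p <- exp(-1)
  # each replicate ~ Binomial(1000, e^-1); check pooled count in 99.9% bounds
  pooled <- sum(survivors)
  bounds <- qbinom(c(5e-4, 1 - 5e-4), 30L * 1000L, p)
  expect_gte(pooled, bounds[1L])
  expect_lte(pooled, bounds[2L])
  # and the lethality floor: never below 0 extra copies, never a lost gene
  expect_true(all(survivors >= 0))
})

test_that("rearrangements conserve gene content and respect the seed", {
  st <- apply_wgd(simulate_ancestor(120L, 3L), 2L)
  expect_identical(apply_rearrangements(st, 0L, 0L), st)

  a <- apply_rearrangements(st, 10L, 5L, seed = 42L)
  b <- apply_rearrangements(st, 10L, 5L, seed = 42L)
  expect_identical(a, b)
  expect_equal(sort(unlist(a$chromosomes)), sort(unlist(st$chromosomes)))
  expect_false(identical(a$chromosomes, st$chromosomes))

  set.seed(1)
  only_inv <- apply_rearrangements(st, 25L, 0L)
  expect_equal(lengths(only_inv$chromosomes), lengths(st$chromosomes))
  expect_equal(lapply(only_inv$chromosomes, sort), lapply(st$chromosomes, sort))
})

test_that("a single seeded inversion reverses exactly one interval", {
  st <- simulate_ancestor(30L, 1L)
  out <- apply_rearrangements(st, 1L, 0L, seed = 5L)
  v0 <- st$chromosomes[[1L]]
  v1 <- out$chromosomes[[1L]]
  changed <- which(v0 != v1)
  expect_gt(length(changed), 0L)
  span <- seq(min(changed), max(changed))
  expect_equal(v1[span], rev(v0[span]))
  expect_equal(v1[-span], v0[-span])
})

test_that("a no-WGD scenario yields one-to-one homologs and little multiplicity", {
  sc <- evolution_scenario(n_ancestral_genes = 600L, n_chromosomes = 4L,
                           target_events = list(), n_inversions = 10L,
                           n_translocations = 3L, seed = 13L)
  sp <- simulate_pair(sc)
  expect_equal(nrow(sp$target$genes), 600L)
  expect_equal(nrow(sp$reference$genes), 600L)
  expect_equal(nrow(sp$pairs), 600L)
  expect_false(anyDuplicated(sp$pairs$target_gene) > 0)
  expect_false(anyDuplicated(sp$pairs$reference_gene) > 0)
  blocks <- find_syntenic_blocks(sp$pairs, sp$target, sp$reference,
                                 chaining_params(5, 20))
  sb <- build_superblocks(blocks, overlap_params(5))
  # 1:1 orthology: block footprints tile the reference; only incidental
  # overlap at rearrangement breakpoints, so few blocks group and B stays low
  grouped <- sum(vapply(sb, `[[`, integer(1L), "multiplicity_B"))
  expect_lt(grouped, length(blocks) / 3)
  if (length(sb) > 0L) {
    expect_lte(max(vapply(sb, `[[`, integer(1L), "multiplicity_B")), 3L)
  }
})

test_that("one duplication concentrates superblock multiplicity at B = 2", {
  sc <- evolution_scenario(n_ancestral_genes = 1200L, n_chromosomes = 6L,
                           target_events = list(wgd_event(0.6, 2L)),
                           n_inversions = 6L, n_translocations = 2L,
                           seed = 23L)
  sp <- simulate_pair(sc)
  blocks <- find_syntenic_blocks(sp$pairs, sp$target, sp$reference,
                                 chaining_params(5, 20))
  d <- multiplicity_distribution(build_superblocks(blocks, overlap_params(5)))
  expect_gt(sum(d$counts), 0L)
  expect_equal(names(d$counts)[which.max(d$counts)], "2")
  expect_gte(d$counts[["2"]] / sum(d$counts), 0.5)
})

test_that("simulation truth respects the lethality floor and copy-count bound", {
  sc <- evolution_scenario(n_ancestral_genes = 500L, n_chromosomes = 5L,
                           target_events = list(wgd_event(0.7, 3L),
                                                wgd_event(0.3, 2L)),
                           seed = 31L)
  sp <- simulate_pair(sc)
  tcopies <- sp$truth$copies$target
  rcopies <- sp$truth$copies$reference
  expect_equal(sort(unique(tcopies$anc_gene)), 1:500)
  expect_equal(sort(unique(rcopies$anc_gene)), 1:500)
  expect_lte(max(table(tcopies$anc_gene)), 6L)  # 3 x 2
  expect_lte(max(table(rcopies$anc_gene)), 1L)

  # annotations are consistent with the truth tables
  expect_equal(nrow(sp$target$genes), nrow(tcopies))
  expect_equal(nrow(sp$reference$genes), nrow(rcopies))
})

test_that("homolog similarities track divergence time", {
  panel <- simulate_panel(
    lineage_events = list(g1 = list(), g2 = list()),
    shared_events = list(wgd_event(2, 2L)),
    n_ancestral_genes = 400L, n_chromosomes = 2L, speciation_time = 1,
    similarity_rate = 0.21, noise_sd = 1, seed = 3L)
  pr <- panel$homologs[["g1~g2"]]
  copies1 <- panel$truth$copies$g1
  copies2 <- panel$truth$copies$g2
  anc1 <- setNames(copies1$anc_copy, sprintf("g1_g%06d", copies1$copy_id))
  anc2 <- setNames(copies2$anc_copy, sprintf("g2_g%06d", copies2$copy_id))
  same <- anc1[pr$target_gene] == anc2[pr$reference_gene]
  # orthologs (diverged at speciation, t=1) are more similar than homeologs
  # (diverged at the shared WGD, t=2)
  expect_gt(mean(pr$similarity[same]), mean(pr$similarity[!same]))
  expect_equal(mean(pr$similarity[same]), 100 * exp(-0.21), tolerance = 0.02)
  expect_equal(mean(pr$similarity[!same]), 100 * exp(-0.42), tolerance = 0.02)
})

test_that("scenario validation catches inconsistent histories", {
  expect_error(evolution_scenario(n_ancestral_genes = 3L, n_chromosomes = 5L),
               "n_chromosomes")
  expect_error(evolution_scenario(target_events = list(wgd_event(0.3), wgd_event(0.6))),
               "strictly decreasing")
  expect_error(evolution_scenario(target_events = list(wgd_event(1.5))),
               "postdate")
  expect_error(wgd_event(0.5, 1L), "ploidy_factor")
})
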