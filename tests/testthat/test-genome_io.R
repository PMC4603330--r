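test_that("GFF3 gene records get per-chromosome ordinals by start position", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t100\t150\t.\t+\t.\tID=gA",
    "chr1\tsrc\tgene\t50\t90\t.\t-\t.\tID=gB",
    "chr1\tsrc\tmRNA\t50\t90\t.\t-\t.\tID=gB.1;Parent=gB",
    "chr1\tsrc\tgene\t200\t260\t.\t+\t.\tID=gC"
  ), path)
  ann <- read_gene_annotations(path, "gff3")
  expect_s3_class(ann, "genome_annotation")
  expect_equal(nrow(ann$genes), 3L)  # mRNA ignored
  ords <- setNames(ann$genes$ordinal, ann$genes$gene_id)
  expect_equal(ords[c("gA", "gB", "gC")], c(gA = 2L, gB = 1L, gC = 3L))
})

test_that("BED singleton gets ordinal 1 and duplicate gene ids are fatal", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr2\t10\t20\tonly\t0\t+", bed)
  ann <- read_gene_annotations(bed, "bed")
  expect_equal(ann$genes$ordinal, 1L)
  expect_equal(ann$genes$gene_id, "only")

  dup <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t10\t20\t.\t+\t.\tID=same",
    "chr1\tsrc\tgene\t30\t40\t.\t+\t.\tID=same"
  ), dup)
  expect_error(read_gene_annotations(dup, "gff3"), "duplicate gene_id")
})

test_that("ordinal ties break by end then gene_id, deterministically", {
  g <- data.frame(gene_id = c("z", "a", "m"), chromosome = "c",
                  start = c(100L, 100L, 100L), end = c(120L, 120L, 110L),
                  strand = "+")
  ann <- genome_annotation(g)
  ords <- setNames(ann$genes$ordinal, ann$genes$gene_id)
  # m has smallest end; a beats z lexicographically
  expect_equal(ords[c("m", "a", "z")], c(m = 1L, a = 2L, z = 3L))
  expect_error(genome_annotation(g[0, ]), "zero genes")
})

test_that("annotation write/read round-trips ordinals in both formats", {
  set.seed(5)
  g <- data.frame(
    gene_id = sprintf("g%02d", 1:20),
    chromosome = rep(c("chrA", "chrB"), each = 10L),
    start = as.integer(sample.int(5000, 20)),
    end = 0L, strand = sample(c("+", "-"), 20, replace = TRUE),
    stringsAsFactors = FALSE
  )
  g$end <- g$start + 300L
  ann <- genome_annotation(g, "rt")
  for (fmt in c("gff3", "bed")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_gene_annotations(ann, path, fmt)
    back <- read_gene_annotations(path, fmt, genome_id = "rt")
    expect_equal(back$genes[c("gene_id", "chromosome", "start", "end", "strand", "ordinal")],
                 ann$genes[c("gene_id", "chromosome", "start", "end", "strand", "ordinal")],
                 info = fmt)
    expect_equal(back$chromosomes, ann$chromosomes)
  }
})

test_that("homolog tables parse, skip headers and validate similarity", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#target_gene\treference_gene\tsimilarity", "g1\th7\t81.0"), path)
  pairs <- read_homolog_pairs(path)
  expect_equal(pairs$target_gene, "g1")
  expect_equal(pairs$reference_gene, "h7")
  expect_equal(pairs$similarity, 81)

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("#target_gene\treference_gene\tsimilarity", empty)
  expect_equal(nrow(read_homolog_pairs(empty)), 0L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("g1\th7\t101", bad)
  expect_error(read_homolog_pairs(bad), "outside \\[0,100\\]")

  short <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\th7\t50", "g2\th8"), short)
  expect_error(read_homolog_pairs(short), "line 2")
})

test_that("homolog write/read round-trips", {
  pairs <- data.frame(target_gene = c("a", "b"), reference_gene = c("x", "y"),
                      similarity = c(81.25, 73), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_homolog_pairs(pairs, path)
  expect_equal(read_homolog_pairs(path), pairs)
})

test_that("similarity histogram bins are half-open with a closed top bin", {
  pairs <- data.frame(similarity = c(81, 81, 73))
  h <- similarity_distribution(pairs, bin_width = 1)
  expect_equal(h, c(`73` = 1L, `81` = 2L))

  expect_length(similarity_distribution(data.frame(similarity = numeric(0))), 0L)

  # 100 falls in the final closed bin [90,100], not a phantom [100,110) bin
  h100 <- similarity_distribution(data.frame(similarity = 100), bin_width = 10)
  expect_equal(h100, c(`90` = 1L))
  # boundary values: 90 also lands in [90,100]; 89.999 in [80,90)
  hb <- similarity_distribution(data.frame(similarity = c(90, 89.999)), bin_width = 10)
  expect_equal(hb, c(`80` = 1L, `90` = 1L))
})

test_that("histogram counts always sum to the number of pairs", {
  set.seed(17)
  for (w in c(0.5, 1, 3, 10, 33)) {
    s <- runif(200, 0, 100)
    s[1:3] <- c(0, 100, 99.999)
    h <- similarity_distribution(data.frame(similarity = s), bin_width = w)
    expect_identical(sum(h), 200L)
    expect_true(all(as.numeric(names(h)) < 100))
  }
})

test_that("DAGchainer-style block text round-trips and validates gene ids", {
  tg <- toy_annotation(40, prefix = "t", genome_id = "T")
  rg <- toy_annotation(40, prefix = "r", genome_id = "R")
  pairs <- pairs_from_anchors(1:6, 1:6, sim = 60 + 1:6)
  # reference ordinals 35:31 keep every antiparallel anchor > max_gap away
  # from the diagonal so the two runs cannot merge into one chain
  pairs <- rbind(pairs, pairs_from_anchors(10:14, 35:31, sim = rep(55, 5)))
  blocks <- find_syntenic_blocks(pairs, tg, rg, chaining_params(5, 20))
  expect_length(blocks, 2L)

  path <- withr::local_tempfile(fileext = ".txt")
  write_dagchainer_blocks(blocks, path)
  back <- read_dagchainer_blocks(path, tg, rg)
  expect_length(back, 2L)
  for (i in seq_along(blocks)) {
    expect_equal(back[[i]]$anchors$target_ordinal, blocks[[i]]$anchors$target_ordinal)
    expect_equal(back[[i]]$anchors$reference_ordinal, blocks[[i]]$anchors$reference_ordinal)
    expect_equal(back[[i]]$orientation, blocks[[i]]$orientation)
    expect_equal(back[[i]]$reference_span, blocks[[i]]$reference_span)
  }

  unknown <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("## alignment chr1 vs chr1 (f) b1",
               "chr1\tt1\tchr1\tr1\t50",
               "chr1\tnope\tchr1\tr2\t50"), unknown)
  expect_error(read_dagchainer_blocks(unknown, tg, rg), "nope")

  twoheads <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("## alignment chr1 vs chr1 (f) b1",
               "## alignment chr1 vs chr1 (f) b2",
               "chr1\tt1\tchr1\tr1\t50"), twoheads)
  expect_warning(got <- read_dagchainer_blocks(twoheads, tg, rg), "empty block")
  expect_length(got, 1L)
})

test_that("grouped headers produce one block per group with the right sizes", {
  tg <- toy_annotation(30, prefix = "t")
  rg <- toy_annotation(30, prefix = "r")
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "## alignment chr1 vs chr1 (f) x",
    sprintf("chr1\tt%d\tchr1\tr%d\t50", 1:5, 1:5),
    "## alignment chr1 vs chr1 (f) y",
    sprintf("chr1\tt%d\tchr1\tr%d\t50", 11:13, 11:13)
  ), path)
  blocks <- read_dagchainer_blocks(path, tg, rg)
  expect_equal(vapply(blocks, function(b) nrow(b$anchors), integer(1L)), c(5L, 3L))
})
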