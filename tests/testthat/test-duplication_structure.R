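# two-locus fixture: a chromosome pair where locus B carries a planted
# copy of a tract from locus A
plant_windows <- function(tract_len = 10000, inverted = FALSE,
                          chrom_len = 60000, at_a = 20000, at_b = 30000,
                          seed = 1) {
  set.seed(seed)
  a <- random_dna(chrom_len)
  tract <- substr(a, at_a + 1, at_a + tract_len)
  if (inverted) {
    tract <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(tract)))
  }
  b <- paste0(random_dna(at_b), tract,
              random_dna(chrom_len - at_b - tract_len))
  genes <- data.frame(
    gene_id = c("gA", "gB"), chrom = c("chrA", "chrB"), strand = "+",
    start = c(at_a + 2000, at_b + 2000),
    end = c(at_a + 5000, at_b + 5000), located = TRUE,
    coding_start = c(at_a + 2000, at_b + 2000),
    coding_end = c(at_a + 5000, at_b + 5000), stringsAsFactors = FALSE)
  if (inverted) {
    # the copy of [at_a+2000, at_a+5000) sits mirrored within the tract
    genes$start[2] <- at_b + tract_len - 5000
    genes$end[2] <- at_b + tract_len - 2000
    genes$coding_start[2] <- genes$start[2]
    genes$coding_end[2] <- genes$end[2]
    genes$strand[2] <- "-"
  }
  make_annotation(c(chrA = a, chrB = b), genes, data.frame())
}

test_that("a planted exact duplication yields one full-identity block and
           its span", {
  ann <- plant_windows(tract_len = 10000)
  blocks <- align_genomic_neighborhoods(ann, "gA", "gB", flank = 15000)
  expect_gt(nrow(blocks), 0)
  expect_true(all(blocks$strand == "+"))
  top <- blocks[which.max(blocks$end_a - blocks$start_a), ]
  expect_equal(top$pident, 100)
  tract <- delineate_duplication_tract(blocks, c(22000, 25000),
                                       c(32000, 35000))
  expect_lte(abs(tract$span - 10000), 2 * 31)
})

test_that("an inverted copy is recovered on the reverse strand", {
  ann <- plant_windows(tract_len = 8000, inverted = TRUE, seed = 2)
  blocks <- align_genomic_neighborhoods(ann, "gA", "gB", flank = 15000)
  g <- ann$genes
  tract <- delineate_duplication_tract(
    blocks, c(g$coding_start[1], g$coding_end[1]),
    c(g$coding_start[2], g$coding_end[2]))
  expect_equal(tract$strand, "-")
  expect_lte(abs(tract$span - 8000), 2 * 31)
})

test_that("unrelated random windows produce no anchors", {
  set.seed(3)
  genes <- data.frame(
    gene_id = c("gA", "gB"), chrom = c("chrA", "chrB"), strand = "+",
    start = c(5000, 5000), end = c(8000, 8000), located = TRUE,
    coding_start = c(5000, 5000), coding_end = c(8000, 8000),
    stringsAsFactors = FALSE)
  ann <- make_annotation(c(chrA = random_dna(20000),
                           chrB = random_dna(20000)), genes, data.frame())
  blocks <- align_genomic_neighborhoods(ann, "gA", "gB", flank = 10000)
  expect_equal(nrow(blocks), 0)
  expect_null(delineate_duplication_tract(blocks, c(5000, 8000),
                                          c(5000, 8000)))
})

test_that("blocks separated by small gaps chain into one tract", {
  bl <- data.frame(start_a = c(0, 10500), end_a = c(10000, 20000),
                   start_b = c(0, 10500), end_b = c(10000, 20000),
                   strand = "+", matches = c(10000, 9500),
                   pident = 100)
  tract <- delineate_duplication_tract(bl, c(1000, 2000), c(15000, 16000),
                                       max_chain_gap = 5000)
  expect_equal(tract$span, 20000)
  expect_equal(tract$tract_a, c(0, 20000))
  # with a gap beyond the limit the chain breaks and no single chain
  # overlaps both focal genes
  tract2 <- delineate_duplication_tract(bl, c(1000, 2000), c(15000, 16000),
                                        max_chain_gap = 400)
  expect_null(tract2)
})

test_that("span takes the minimum of the two locus extents", {
  bl <- data.frame(start_a = 0, end_a = 36000, start_b = 0, end_b = 41000,
                   strand = "+", matches = 36000, pident = 100)
  tract <- delineate_duplication_tract(bl, c(100, 200), c(100, 200))
  expect_equal(tract$span, 36000)
})

test_that("structural classes count coding extents truncated by breakpoints", {
  tract <- list(tract_a = c(1000, 50000), tract_b = c(1000, 50000))
  # both ORFs inside: complete
  expect_equal(classify_structure(tract, c(2000, 30000), c(2000, 30000)),
               "complete")
  # one ORF crosses a breakpoint: partial
  expect_equal(classify_structure(tract, c(2000, 60000), c(2000, 30000)),
               "partial")
  # coding sequence beyond the tract at both loci: chimeric
  expect_equal(classify_structure(tract, c(2000, 60000), c(2000, 51000)),
               "chimeric")
  # sub-tolerance overhangs do not count as truncation
  expect_equal(classify_structure(tract, c(2000, 50100), c(900, 30000)),
               "complete")
  expect_true(is.na(classify_structure(NULL, c(0, 1), c(0, 1))))
})

test_that("mechanism classification distinguishes retrogenes from
           DNA-mediated copies", {
  cfg <- simulation_config(n_chrom = 2, genes_per_chrom = 5,
                           extent_max = 40000)
  set.seed(8)
  sim <- simulate_genome(cfg, seed = 8)
  sim <- plant_duplication_event(sim, list(class = "retro",
                                           location = "inter",
                                           orientation = "direct",
                                           ks = 0.02))
  tr <- truth_table(sim)
  ann <- suppressWarnings(select_canonical_transcripts(sim$ann))
  mech <- classify_mechanism(ann, tr$donor, tr$copy)
  expect_equal(as.character(mech), "RNA")
  expect_true(attr(mech, "poly_a"))

  # a DNA-mediated complete copy keeps its introns
  sim2 <- simulate_genome(cfg, seed = 9)
  sim2 <- plant_duplication_event(sim2, list(class = "complete",
                                             location = "inter",
                                             orientation = "direct",
                                             span = 40000, ks = 0.02))
  tr2 <- truth_table(sim2)
  ann2 <- suppressWarnings(select_canonical_transcripts(sim2$ann))
  expect_equal(as.character(classify_mechanism(ann2, tr2$donor, tr2$copy)),
               "DNA")
})

test_that("single-exon pairs carry no intron-loss signal and default to DNA", {
  genes <- data.frame(
    gene_id = c("g1", "g2"), chrom = "chr1", strand = "+",
    start = c(100, 5100), end = c(400, 5400), located = TRUE,
    coding_start = c(100, 5100), coding_end = c(400, 5400),
    canonical_tx = c("g1.t1", "g2.t1"), stringsAsFactors = FALSE)
  features <- data.frame(
    gene_id = rep(c("g1", "g2"), each = 2),
    tx_id = rep(c("g1.t1", "g2.t1"), each = 2),
    type = c("exon", "CDS", "exon", "CDS"),
    start = c(100, 100, 5100, 5100), end = c(400, 400, 5400, 5400),
    stringsAsFactors = FALSE)
  ann <- make_annotation(c(chr1 = random_dna(6000)), genes, features)
  expect_equal(as.character(classify_mechanism(ann, "g1", "g2")), "DNA")
})

test_that("pair geography reports location, orientation and distance", {
  genes <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    chrom = c("chr1", "chr1", "chr2", "scaffold_9"),
    strand = c("+", "+", "-", "+"),
    start = c(100, 7000, 100, 100), end = c(2100, 9000, 2100, 2100),
    located = c(TRUE, TRUE, TRUE, FALSE),
    coding_start = c(100, 7000, 100, 100),
    coding_end = c(2100, 9000, 2100, 2100), stringsAsFactors = FALSE)
  ann <- make_annotation(
    c(chr1 = "A", chr2 = "A", scaffold_9 = "A"), genes, data.frame())
  tract <- list(tract_a = c(1000, 2000), tract_b = c(5000, 6000))
  g <- pair_geography(ann, "g1", "g2", tract)
  expect_equal(g$location, "intrachromosomal")
  expect_equal(g$orientation, "direct")
  expect_equal(g$distance, 3000)
  g2 <- pair_geography(ann, "g1", "g3")
  expect_equal(g2$location, "interchromosomal")
  expect_true(is.na(g2$orientation))
  g3 <- pair_geography(ann, "g1", "g4")
  expect_equal(g3$location, "unassigned")
})
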