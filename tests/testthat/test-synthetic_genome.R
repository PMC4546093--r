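small_cfg <- function() {
  simulation_config(n_chrom = 2, genes_per_chrom = 5, extent_max = 40000)
}

test_that("simulation is byte-identical for a fixed seed", {
  sim1 <- simulate_genome(small_cfg(), seed = 1)
  sim2 <- simulate_genome(small_cfg(), seed = 1)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(sim1, d1)
  write_simulation(sim2, d2)
  for (f in c("genome.fa", "genome.gff3", "outgroup.fa", "centromeres.tsv")) {
    if (!file.exists(file.path(d1, f))) next
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("the requested number of gene models is emitted", {
  sim <- simulate_genome(simulation_config(n_chrom = 4, genes_per_chrom = 25,
                                           extent_max = 30000), seed = 2)
  expect_equal(nrow(sim$ann$genes), 100)
  expect_equal(length(unique(sim$ann$features$gene_id)), 100)
})

test_that("coding-extent distribution hits the target median within 20
           percent at n = 500", {
  set.seed(10)
  cfg <- simulation_config()
  x <- pmin(pmax(rlnorm(500, cfg$extent_meanlog, cfg$extent_sdlog),
                 cfg$extent_min), cfg$extent_max)
  expect_lt(abs(median(x) - 25000) / 25000, 0.2)
})

test_that("simulated genes are non-overlapping and in-frame", {
  sim <- simulate_genome(small_cfg(), seed = 4)
  g <- sim$ann$genes
  for (ch in unique(g$chrom)) {
    gg <- g[g$chrom == ch, ]
    gg <- gg[order(gg$start), ]
    if (nrow(gg) > 1) expect_true(all(gg$start[-1] >= gg$end[-nrow(gg)]))
  }
  ann <- suppressWarnings(select_canonical_transcripts(sim$ann))
  expect_true(all(!ann$genes$excluded))
  expect_true(all(ann$genes$cds_len %% 3 == 0))
})

test_that("the outgroup diverges near the configured synonymous level", {
  sim <- simulate_genome(small_cfg(), seed = 5)
  ann <- suppressWarnings(select_canonical_transcripts(sim$ann))
  og <- suppressWarnings(select_canonical_transcripts(sim$outgroup))
  ks <- vapply(ann$genes$gene_id[1:5], function(gid) {
    c1 <- as.character(cds_sequence(ann, ann$genes$canonical_tx[
      ann$genes$gene_id == gid]))
    c2 <- as.character(cds_sequence(og, og$genes$canonical_tx[
      og$genes$gene_id == gid]))
    estimate_ks_ng86(list(codons1 = dupliscan:::split_codons(c1),
                          codons2 = dupliscan:::split_codons(c2)))$ks
  }, numeric(1))
  # first-passage mutation stops at the first value >= target
  expect_true(all(ks >= 0.011))
  expect_true(all(ks < 0.02))
})

test_that("mutate_to_target_ks is exact at zero, reproducible, and close to
           target", {
  set.seed(6)
  body <- substr(random_cds(1500), 1, 1500 * 3 - 3)
  r0 <- mutate_to_target_ks(body, body, 0)
  expect_equal(r0$n_sub, 0)
  expect_equal(r0$ks, 0)

  set.seed(123)
  r1 <- mutate_to_target_ks(body, body, 0.05)
  set.seed(123)
  r2 <- mutate_to_target_ks(body, body, 0.05)
  expect_identical(r1$cds, r2$cds)
  expect_lt(abs(r1$ks - 0.05), 0.01)
  # only synonymous changes: identical proteins
  expect_equal(
    as.character(suppressWarnings(Biostrings::translate(
      Biostrings::DNAString(r1$cds)))),
    as.character(suppressWarnings(Biostrings::translate(
      Biostrings::DNAString(body)))))
})

test_that("gene-conversion tracts homogenize exactly their interval", {
  set.seed(7)
  body <- substr(random_cds(200), 1, 597)
  der <- mutate_to_target_ks(body, body, 0.05)$cds
  hom <- apply_gene_conversion_tract(body, der, c(150, 450))
  b <- strsplit(body, "")[[1]]
  d <- strsplit(der, "")[[1]]
  h <- strsplit(hom, "")[[1]]
  expect_true(all(h[151:450] == b[151:450]))
  expect_identical(h[-(151:450)], d[-(151:450)])
  # whole-CDS tract resets Ks to zero
  full <- apply_gene_conversion_tract(body, der, c(0, nchar(body)))
  expect_identical(full, body)
  # empty tract is a no-op
  expect_identical(apply_gene_conversion_tract(body, der, c(100, 100)), der)
})

test_that("planted events realize their class by construction", {
  set.seed(9)
  sim <- simulate_genome(small_cfg(), seed = 9)
  sim <- plant_duplication_event(sim, list(class = "complete",
                                           location = "intra",
                                           orientation = "direct",
                                           span = 35000, ks = 0))
  tr <- truth_table(sim)
  expect_equal(tr$class, "complete")
  expect_equal(tr$ks, 0)
  ann <- suppressWarnings(select_canonical_transcripts(sim$ann))
  cds_of <- function(gid) as.character(cds_sequence(
    ann, ann$genes$canonical_tx[ann$genes$gene_id == gid]))
  # Ks 0: the copy CDS is identical to the donor CDS
  expect_identical(cds_of(tr$donor), cds_of(tr$copy))

  sim <- plant_duplication_event(sim, list(class = "retro",
                                           location = "inter",
                                           orientation = "direct",
                                           ks = 0.03))
  tr2 <- truth_table(sim)[2, ]
  g <- sim$ann$genes
  expect_false(g$chrom[g$gene_id == tr2$copy] ==
                 g$chrom[g$gene_id == tr2$donor])
  # the retrocopy is intronless
  ex <- sim$ann$features[sim$ann$features$gene_id == tr2$copy &
                           sim$ann$features$type == "exon", ]
  expect_equal(nrow(ex), 1)

  # partial donors need a long multi-exon CDS (the cut must leave 900 nt
  # of shared coding region beyond the first intron); use a roomier genome
  simp <- simulate_genome(simulation_config(n_chrom = 2,
                                            genes_per_chrom = 8,
                                            extent_max = 40000,
                                            cds_len_range = c(1500, 2400)),
                          seed = 12)
  simp <- plant_duplication_event(simp, list(class = "partial",
                                             location = "inter",
                                             orientation = "direct",
                                             span = 25000, ks = 0.02))
  tr3 <- truth_table(simp)
  expect_equal(tr3$class, "partial")
  # the truncated copy's CDS is a prefix of the donor's coding extent
  annp <- suppressWarnings(select_canonical_transcripts(simp$ann))
  dlen <- annp$genes$cds_len[annp$genes$gene_id == tr3$donor]
  clen <- annp$genes$cds_len[annp$genes$gene_id == tr3$copy]
  expect_lt(clen, dlen)
})

test_that("realized Ks in the truth table tracks the target", {
  set.seed(10)
  sim <- simulate_genome(small_cfg(), seed = 10)
  for (ks in c(0, 0.04, 0.09)) {
    sim <- plant_duplication_event(sim, list(class = "complete",
                                             location = "inter",
                                             orientation = "direct",
                                             span = 30000, ks = ks))
  }
  tr <- truth_table(sim)
  expect_true(all(abs(tr$ks - c(0, 0.04, 0.09)) < 0.012))
})

test_that("conversion triplets have uniform mismatch structure", {
  set.seed(11)
  trip <- simulate_conversion_triplet(2000, pair_div = 0.05,
                                      outgroup_div = 0.1,
                                      tract = c(500, 800))
  rows <- lapply(unclass(trip), function(r) strsplit(r, "")[[1]])
  inside <- 501:800
  expect_true(all(rows[[1]][inside] == rows[[2]][inside]))
  out_mm <- mean(rows[[1]][-inside] != rows[[2]][-inside])
  expect_gt(out_mm, 0.02)
  expect_lt(out_mm, 0.09)
})
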