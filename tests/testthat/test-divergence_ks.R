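test_that("protein-guided codon alignment maps columns and gaps", {
  # gap-free alignment of length L -> L codon columns
  cds1 <- random_cds(12)
  aln <- codon_align_from_protein(
    c("MAAAAAAAAAA", "MAAAAAAAAAA"),
    paste0("ATG", strrep("GCT", 10), "TAA"),
    paste0("ATG", strrep("GCA", 10), "TAA"))
  expect_length(aln$codons1, 11)
  expect_equal(aln$codons1[2], "GCT")
  expect_equal(aln$codons2[2], "GCA")

  # a 2-aa gap in one protein row becomes two 3-nt gap columns
  aln2 <- codon_align_from_protein(
    c("MAAAAAAAAAA", "MAAAA--AAAA"),
    paste0("ATG", strrep("GCT", 10), "TAA"),
    paste0("ATG", strrep("GCT", 8), "TAA"))
  expect_equal(sum(aln2$codons2 == "---"), 2)
  expect_equal(sum(aln2$codons1 == "---"), 0)

  # CDS whose translation differs from the given protein is an error
  expect_error(
    codon_align_from_protein(
      c("MKKK", "MKKK"),
      paste0("ATG", strrep("AAA", 3), "TAA"),
      paste0("ATG", strrep("GGG", 3), "TAA")),
    "consistency error")
})

test_that("NG86 estimate matches the hand-counted 31-codon oracle exactly", {
  # 31 glycine codons; GGT has exactly one synonymous site (third position
  # fully degenerate, positions 1-2 nonsynonymous), so S = 31 per sequence.
  # One third-position GGT->GGC difference: Sd = 1, Nd = 0,
  # ps = 1/31, Ks = -3/4 log(1 - 4/(3*31)), Ka = 0.
  aln <- list(codons1 = rep("GGT", 31),
              codons2 = c(rep("GGT", 30), "GGC"))
  est <- estimate_ks_ng86(aln)
  expect_equal(est$S, 31)
  expect_equal(est$sd, 1)
  expect_equal(est$nd, 0)
  expect_identical(est$ks, -0.75 * log(1 - 4 / (3 * 31)))
  expect_equal(est$ka, 0)
})

test_that("identical sequences give Ks = 0 and saturation gives NA", {
  cds <- random_cds(50)
  aln <- list(codons1 = dupliscan:::split_codons(cds),
              codons2 = dupliscan:::split_codons(cds))
  est <- estimate_ks_ng86(aln)
  expect_equal(est$ks, 0)
  expect_equal(est$ka, 0)
  # saturated synonymous proportion: ps >= 3/4 is undefined under JC
  expect_true(is.na(dupliscan:::jc_correct(0.76)))
  expect_error(estimate_ks_ng86(list(codons1 = rep("GGT", 5),
                                     codons2 = rep("GGT", 5))),
               "fewer than")
})

test_that("substitutions confined to 4-fold sites give Ka = 0 and Ks near
           the JC-corrected proportion", {
  set.seed(91)
  # all-GGT sequence: every change at position 3 is synonymous
  n <- 400
  c1 <- rep("GGT", n)
  c2 <- c1
  hit <- runif(n) < 0.05
  subs <- sample(c("GGA", "GGC", "GGG"), sum(hit), replace = TRUE)
  c2[hit] <- subs
  est <- estimate_ks_ng86(list(codons1 = c1, codons2 = c2))
  p_realized <- sum(hit) / n
  expect_equal(est$ka, 0)
  expect_equal(est$ks, -0.75 * log(1 - 4 * p_realized / 3),
               tolerance = 0.01)
})

test_that("Ks is symmetric and invariant to row order", {
  set.seed(17)
  cds <- random_cds(200)
  m <- simulate_ng86_divergence(substr(cds, 1, nchar(cds) - 3), 0.05)
  a <- dupliscan:::split_codons(substr(cds, 1, nchar(cds) - 3))
  b <- dupliscan:::split_codons(m)
  expect_equal(estimate_ks_ng86(list(codons1 = a, codons2 = b))$ks,
               estimate_ks_ng86(list(codons1 = b, codons2 = a))$ks)
})

test_that("the youth filter is inclusive at Ks = 0.1", {
  pairs <- data.frame(gene1 = c("a", "b", "c"), gene2 = c("x", "y", "z"),
                      ks = c(0.1, 0.1000001, NA))
  out <- suppressMessages(filter_young_pairs(pairs))
  expect_equal(out$gene1, "a")
})

test_that("same-location pairs require exact coding-extent identity", {
  genes <- data.frame(
    gene_id = c("a", "b", "c", "d"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    strand = "+", start = 0, end = 10, located = TRUE,
    coding_start = c(100, 100, 101, 100),
    coding_end = c(500, 500, 500, 500), stringsAsFactors = FALSE)
  ann <- make_annotation(c(chr1 = "ACGT", chr2 = "ACGT"), genes,
                         data.frame())
  pairs <- data.frame(gene1 = c("a", "a", "a"), gene2 = c("b", "c", "d"),
                      ks = 0)
  out <- remove_same_location_pairs(pairs, ann)
  expect_equal(attr(out, "n_same_location"), 1)
  # 99 percent overlap is kept; different chromosomes kept
  expect_setequal(out$gene2, c("c", "d"))
})

test_that("UPGMA representative selection retains n-1 pairs with the
           documented tie-break", {
  # 3 members, Ks: AB = 0.01, AC = BC = 0.05 -> retain (A,B) and, after
  # the lexicographic tie-break, (A,C)
  m <- matrix(c(0, 0.01, 0.05,
                0.01, 0, 0.05,
                0.05, 0.05, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  rep_pairs <- select_representative_pairs(m)
  expect_equal(nrow(rep_pairs), 2)
  expect_equal(paste(rep_pairs$gene1, rep_pairs$gene2),
               c("A B", "A C"))

  # a 2-member family is a no-op
  m2 <- matrix(c(0, 0.02, 0.02, 0), 2, 2,
               dimnames = list(c("X", "Y"), c("X", "Y")))
  expect_equal(nrow(select_representative_pairs(m2)), 1)
})

test_that("shadow counts follow n-1 retained, C(n,2) - (n-1) removed", {
  set.seed(41)
  for (n in 3:5) {
    ids <- paste0("g", 1:n)
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    ks <- runif(choose(n, 2), 0.001, 0.09)
    m[lower.tri(m)] <- ks
    m <- m + t(m)
    rep_pairs <- select_representative_pairs(m)
    expect_equal(nrow(rep_pairs), n - 1)

    fams <- data.frame(family_id = "F1", gene_id = ids)
    cmb <- combn(ids, 2)
    pairs <- data.frame(gene1 = cmb[1, ], gene2 = cmb[2, ],
                        ks = m[t(cmb)])
    out <- dupliscan:::remove_shadow_pairs(pairs, fams)
    expect_equal(nrow(out), n - 1)
    expect_equal(attr(out, "n_shadow"), choose(n, 2) - (n - 1))
  }
})

test_that("UPGMA trees export as newick", {
  m <- matrix(c(0, 0.01, 0.05,
                0.01, 0, 0.05,
                0.05, 0.05, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  nwk <- upgma_newick(m)
  expect_match(nwk, "^\\(")
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, c("A", "B", "C"))
})

test_that("adjacent collinear pairs merge into a linked set with averaged Ks", {
  # two chromosomes, each carrying two adjacent genes; the pair structure
  # is collinear (A1,B1 neighbors on chr1; A2,B2 neighbors on chr2, same
  # order and strand relation)
  genes <- data.frame(
    gene_id = c("A1", "B1", "A2", "B2"),
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    strand = "+",
    start = c(100, 5000, 200, 5100), end = c(1000, 6000, 1100, 6100),
    located = TRUE,
    coding_start = c(100, 5000, 200, 5100),
    coding_end = c(1000, 6000, 1100, 6100), stringsAsFactors = FALSE)
  ann <- make_annotation(c(chr1 = "A", chr2 = "A"), genes, data.frame())
  pairs <- data.frame(gene1 = c("A1", "B1"), gene2 = c("A2", "B2"),
                      ks = c(0.02, 0.04))
  ev <- detect_linked_sets(pairs, ann)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$ks, 0.03)
  expect_equal(ev$n_members, 2)

  # partners on different chromosomes never merge
  genes2 <- genes
  genes2$chrom[4] <- "chr3"
  ann2 <- make_annotation(c(chr1 = "A", chr2 = "A", chr3 = "A"), genes2,
                          data.frame())
  expect_equal(nrow(detect_linked_sets(pairs, ann2)), 2)

  # adjacency on one side only is not collinear
  genes3 <- genes
  genes3$start[4] <- 8e6; genes3$end[4] <- 8e6 + 1000
  genes3$coding_start[4] <- 8e6; genes3$coding_end[4] <- 8e6 + 1000
  # push B2 far away in rank by adding intervening genes
  extra <- data.frame(gene_id = paste0("x", 1:3), chrom = "chr2",
                      strand = "+", start = c(2e6, 4e6, 6e6),
                      end = c(2e6, 4e6, 6e6) + 500, located = TRUE,
                      coding_start = c(2e6, 4e6, 6e6),
                      coding_end = c(2e6, 4e6, 6e6) + 500,
                      stringsAsFactors = FALSE)
  ann3 <- make_annotation(c(chr1 = "A", chr2 = "A"),
                          rbind(genes3, extra), data.frame())
  expect_equal(nrow(detect_linked_sets(pairs, ann3)), 2)
})

test_that("opposite-strand copies merge only with reversed order", {
  # inverted segmental duplication: gene order flips on the second locus
  genes <- data.frame(
    gene_id = c("A1", "B1", "A2", "B2"),
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    strand = c("+", "+", "-", "-"),
    start = c(100, 5000, 5100, 200), end = c(1000, 6000, 6100, 1100),
    located = TRUE,
    coding_start = c(100, 5000, 5100, 200),
    coding_end = c(1000, 6000, 6100, 1100), stringsAsFactors = FALSE)
  ann <- make_annotation(c(chr1 = "A", chr2 = "A"), genes, data.frame())
  pairs <- data.frame(gene1 = c("A1", "B1"), gene2 = c("A2", "B2"),
                      ks = c(0.01, 0.03))
  ev <- detect_linked_sets(pairs, ann)
  expect_equal(nrow(ev), 1)
})
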