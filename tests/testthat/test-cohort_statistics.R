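test_that("age cohorts use right-inclusive boundaries", {
  expect_equal(as.character(assign_cohort(c(0, 0.0001, 0.025, 0.03, 0.1))),
               c("K=0", "0<K<=0.025", "0<K<=0.025", "0.025<K<=0.1",
                 "0.025<K<=0.1"))
  expect_error(assign_cohort(0.11), "out of range")
  expect_error(assign_cohort(-0.01), "out of range")
})

test_that("goodness-of-fit G-test matches hand-computed Williams values", {
  # raw G = 2 * sum(O log(O/E)); q = 1 + (k+1)/(6n)
  g <- g_test_gof(c(66, 77))
  raw <- 2 * (66 * log(66 / 71.5) + 77 * log(77 / 71.5))
  expect_equal(g$G, raw / (1 + 3 / (6 * 143)))
  expect_equal(round(g$G, 3), 0.844)

  g2 <- g_test_gof(c(54, 67))
  expect_equal(round(g2$G, 2), 1.39)

  expect_equal(g_test_gof(c(10, 10))$G, 0)
  expect_error(g_test_gof(c(0, 0)), "zero total")

  # without the correction the raw statistic is returned
  expect_equal(g_test_gof(c(66, 77), williams = FALSE)$G, raw)
})

test_that("independence G-test reproduces hand-computed 2x2 and 2x3 cases", {
  tab <- rbind(intra = c(39, 65, 39), inter = c(0, 9, 20))
  g <- g_test_independence(tab)
  expect_equal(signif(g$G, 3), 25.1)
  expect_equal(g$df, 2)

  # proportional rows carry no association
  expect_equal(g_test_independence(rbind(c(10, 20), c(5, 10)))$G, 0)

  # hand-derived diagonal case: raw G = 2*20*log(2) = 27.72589,
  # q = 1 + 3*3/(6*20) = 1.075
  d <- g_test_independence(rbind(c(10, 0), c(0, 10)))
  expect_equal(d$G, 2 * 20 * log(2) / 1.075, tolerance = 1e-10)
  expect_equal(round(d$G, 2), 25.79)

  # empty column dropped with df adjustment
  expect_warning(
    g3 <- g_test_independence(rbind(c(5, 0, 5), c(3, 0, 9))),
    "empty")
  expect_equal(g3$df, 1)
})

test_that("Williams correction shrinks G and vanishes only at G = 0", {
  set.seed(31)
  for (i in 1:25) {
    o <- rpois(sample(2:5, 1), 12) + 1
    gw <- g_test_gof(o)
    gr <- g_test_gof(o, williams = FALSE)
    expect_lte(gw$G, gr$G)
    if (gr$G > 0) expect_lt(gw$G, gr$G)
    tab <- matrix(rpois(6, 10) + 1, 2, 3)
    expect_lte(g_test_independence(tab)$G,
               g_test_independence(tab, williams = FALSE)$G)
  }
  expect_equal(g_test_gof(c(7, 7), williams = TRUE)$G, 0)
})

test_that("2x2 independence agrees with collapsed goodness of fit when one
           margin is fixed by construction", {
  # a 2x2 table whose column margin equals the gof expectation reproduces
  # the same raw statistic structure
  tab <- rbind(c(30, 30), c(20, 20))
  expect_equal(g_test_independence(tab, williams = FALSE)$G, 0)
})

test_that("chromosome frequencies use half-event counting", {
  ev <- data.frame(
    location = c("intrachromosomal", "interchromosomal", "interchromosomal"),
    chrom1 = c("chr1", "chr1", "chr2"),
    chrom2 = c("chr1", "chr2", "chr3"), stringsAsFactors = FALSE)
  gpc <- c(chr1 = 100, chr2 = 100, chr3 = 100)
  cf <- chromosome_duplication_frequencies(ev, gpc)
  expect_equal(unname(cf$counts), c(1.5, 1, 0.5))
  # totals sum to the number of events
  expect_equal(sum(cf$counts), nrow(ev))
  # G equals the gof oracle on the same counts
  oracle <- g_test_gof(cf$counts, gpc / sum(gpc))
  expect_equal(cf$gof$G, oracle$G)
})

test_that("chromosome frequency test matches gof oracle for 2-chromosome case", {
  ev <- data.frame(location = rep("intrachromosomal", 4),
                   chrom1 = c("chr1", "chr1", "chr1", "chr2"),
                   chrom2 = c("chr1", "chr1", "chr1", "chr2"),
                   stringsAsFactors = FALSE)
  cf <- chromosome_duplication_frequencies(ev, c(chr1 = 50, chr2 = 50))
  expect_equal(cf$gof$G, g_test_gof(c(3, 1), c(0.5, 0.5))$G)
})

test_that("centromere bins place paralogs and split across-bin pairs", {
  ann <- make_annotation(
    c(chr1 = strrep("A", 100)),  # sequence content irrelevant here
    data.frame(gene_id = paste0("g", 1:4), chrom = "chr1", strand = "+",
               start = 0, end = 10, located = TRUE,
               coding_start = c(0e6, 12e6, 35e6, 52e6) + 50e6,
               coding_end = c(0e6, 12e6, 35e6, 52e6) + 50e6 + 10,
               stringsAsFactors = FALSE),
    data.frame(gene_id = character(), tx_id = character(),
               type = character(), start = numeric(), end = numeric()))
  cen <- data.frame(chrom = "chr1", centromere_start = 50e6 - 5,
                    centromere_end = 50e6 + 5)
  # paralog 12 Mb away falls in bin 1
  ev <- data.frame(chrom1 = "chr1", chrom2 = "chr1",
                   mid1 = 50e6 + 12e6, mid2 = 50e6 + 12e6,
                   location = "intrachromosomal")
  cb <- centromere_distance_bins(ev, cen, ann)
  expect_equal(cb$dup_counts[2], 1)
  # paralogs in bins 0 and 3 count half each
  ev2 <- data.frame(chrom1 = "chr1", chrom2 = "chr1",
                    mid1 = 50e6 + 1e6, mid2 = 50e6 + 35e6,
                    location = "intrachromosomal")
  cb2 <- centromere_distance_bins(ev2, cen, ann)
  expect_equal(cb2$dup_counts[c(1, 4)], c(0.5, 0.5))
  # G equals the gof oracle on occupied bins
  keep <- cb2$gene_counts > 0
  oracle <- g_test_gof(cb2$dup_counts[keep],
                       cb2$gene_counts[keep] / sum(cb2$gene_counts[keep]))
  expect_equal(cb2$gof$G, oracle$G)
})

test_that("trend and rank statistics match closed-form and brute-force oracles", {
  ev <- data.frame(
    span = c(100, 80, 60, 40, 20), ks = c(0.01, 0.02, 0.04, 0.06, 0.09),
    mechanism = "DNA", location = "intrachromosomal",
    distance = exp(c(0.01, 0.02, 0.04, 0.06, 0.09)))
  out <- suppressMessages(trend_and_rank_stats(ev, gene_lengths = c(10, 20, 30),
                                               coding_extents = c(5, 10, 15)))
  # strictly decreasing spans in Ks, no ties
  expect_equal(out$statistic[out$test == "kendall_span_ks_DNA"], -1)
  # distance proportional to exp(Ks): r(ks, log dist) = 1
  expect_equal(out$statistic[out$test == "pearson_ks_logdist"], 1,
               tolerance = 1e-12)

  # rank-sum W against a brute-force enumeration on two 5-element samples
  x <- c(3.2, 7.1, 1.4, 9.9, 5.5)
  y <- c(2.2, 8.8, 0.3, 4.4, 6.6)
  ev2 <- data.frame(span = x, ks = NA_real_, mechanism = "DNA",
                    location = "interchromosomal", distance = NA_real_)
  out2 <- suppressMessages(trend_and_rank_stats(ev2, y, y))
  brute <- sum(vapply(x, function(xi) sum(xi > y) + sum(xi == y) / 2,
                      numeric(1))) + 5 * 6 / 2
  expect_equal(out2$statistic[out2$test == "wilcoxon_span_gene_length"],
               brute)
  wt <- wilcox.test(x, y, exact = FALSE)
  expect_equal(out2$p[out2$test == "wilcoxon_span_gene_length"], wt$p.value)
})

test_that("zero distances are excluded from the log-distance correlation", {
  ev <- data.frame(span = 1:6, ks = c(0.01, 0.02, 0.03, 0.04, 0.05, 0.06),
                   mechanism = "DNA", location = "intrachromosomal",
                   distance = c(0, 0, 10, 100, 1000, 10000))
  expect_message(out <- trend_and_rank_stats(ev, 1:5, 1:5), "zero distance")
  expect_equal(out$n[out$test == "pearson_ks_logdist"], 4)
})
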