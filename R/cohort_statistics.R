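# ---- age cohorts --------------------------------------------------------

#' Assign a duplication event to an evolutionary age cohort
#'
#' Cohorts stratify events by synonymous divergence: `"K=0"` (identical at
#' synonymous sites), `"0<K<=0.025"`, and `"0.025<K<=0.1"`; boundaries are
#' inclusive on the right.
#'
#' @param ks Numeric vector of Ks values in `[0, 0.1]`.
#' @return Factor of cohort labels with the three levels above.
#' @export
assign_cohort <- function(ks) {
  if (any(is.na(ks)) || any(ks < 0) || any(ks > 0.1)) {
    stop("Ks out of range [0, 0.1]")
  }
  lab <- ifelse(ks == 0, "K=0",
                ifelse(ks <= 0.025, "0<K<=0.025", "0.025<K<=0.1"))
  factor(lab, levels = c("K=0", "0<K<=0.025", "0.025<K<=0.1"))
}

# ---- G-tests ------------------------------------------------------------

#' Goodness-of-fit G-test with Williams correction
#'
#' Computes the log-likelihood-ratio statistic G = 2 * sum(O * ln(O / E))
#' (with 0 * ln 0 = 0) against expected proportions, divided by the Williams
#' correction factor q = 1 + (k + 1) / (6n). Non-integer counts are allowed
#' (the half-event counting convention produces them).
#'
#' @param observed Non-negative observed counts (length k >= 2).
#' @param expected_prop Expected proportions (default equal); must sum to 1
#'   and be positive.
#' @param williams Apply the Williams correction (default TRUE).
#' @return list: `G`, `df` (k - 1), `p` (chi-square upper tail), `q`.
#' @export
g_test_gof <- function(observed,
                       expected_prop = rep(1 / length(observed),
                                           length(observed)),
                       williams = TRUE) {
  k <- length(observed)
  stopifnot(k >= 2, length(expected_prop) == k, all(expected_prop > 0),
            abs(sum(expected_prop) - 1) < 1e-8, all(observed >= 0))
  n <- sum(observed)
  if (n == 0) stop("zero total count")
  expected <- n * expected_prop
  terms <- ifelse(observed > 0, observed * log(observed / expected), 0)
  G <- 2 * sum(terms)
  q <- if (williams) 1 + (k + 1) / (6 * n) else 1
  G <- G / q
  df <- k - 1
  list(G = G, df = df, p = pchisq(G, df, lower.tail = FALSE), q = q)
}

#' G-test of independence with Williams correction
#'
#' Expected counts come from the row/column margins. Empty rows or columns
#' are dropped with a warning and the degrees of freedom adjusted. The
#' Williams correction factor for an r x c table is
#' q = 1 + (n * sum(1/R) - 1)(n * sum(1/C) - 1) / (6 n (r-1)(c-1)).
#'
#' @param tab Matrix of non-negative counts (half counts allowed), at least
#'   2 x 2 after dropping empty margins.
#' @param williams Apply the Williams correction (default TRUE).
#' @return list: `G`, `df`, `p`, `q`.
#' @export
g_test_independence <- function(tab, williams = TRUE) {
  tab <- as.matrix(tab)
  stopifnot(all(tab >= 0))
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping empty row(s)/column(s); df adjusted")
    tab <- tab[keep_r, keep_c, drop = FALSE]
  }
  r <- nrow(tab); cc <- ncol(tab)
  stopifnot(r >= 2, cc >= 2)
  n <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / n
  terms <- ifelse(tab > 0, tab * log(tab / E), 0)
  G <- 2 * sum(terms)
  q <- if (williams) {
    1 + (n * sum(1 / rowSums(tab)) - 1) * (n * sum(1 / colSums(tab)) - 1) /
      (6 * n * (r - 1) * (cc - 1))
  } else 1
  G <- G / q
  df <- (r - 1) * (cc - 1)
  list(G = G, df = df, p = pchisq(G, df, lower.tail = FALSE), q = q)
}

# ---- chromosome geography -----------------------------------------------

#' Per-chromosome duplication frequencies, normalized by gene density
#'
#' An intrachromosomal pair adds one event to its chromosome; for an
#' interchromosomal pair each paralog adds half an event to its chromosome
#' (the ancestral copy cannot be identified). Frequencies are duplicate
#' counts divided by the number of protein-coding genes per chromosome, and
#' a goodness-of-fit G-test compares duplicate counts with the gene-density
#' expectation.
#'
#' @param events Events data.frame with `location`, `chrom1`, `chrom2`.
#' @param genes_per_chrom Named vector: protein-coding genes per chromosome.
#' @param autosomes_only Drop sex chromosomes (names matching X/Y) first.
#' @return list: `counts` (duplication events per chromosome),
#'   `rel_freq` (counts / genes), `gof` (G-test result vs gene density).
#' @export
chromosome_duplication_frequencies <- function(events, genes_per_chrom,
                                               autosomes_only = FALSE) {
  ev <- events[events$location %in%
                 c("intrachromosomal", "interchromosomal"), , drop = FALSE]
  if (autosomes_only) {
    sex <- grepl("^(chr)?[XY]$", names(genes_per_chrom), ignore.case = TRUE)
    genes_per_chrom <- genes_per_chrom[!sex]
    keep <- !grepl("^(chr)?[XY]$", ev$chrom1, ignore.case = TRUE) &
      !grepl("^(chr)?[XY]$", ev$chrom2, ignore.case = TRUE)
    ev <- ev[keep, , drop = FALSE]
  }
  zero <- genes_per_chrom == 0
  if (any(zero)) {
    warning("excluding chromosome(s) with zero annotated genes: ",
            paste(names(genes_per_chrom)[zero], collapse = ", "))
    genes_per_chrom <- genes_per_chrom[!zero]
  }
  counts <- setNames(rep(0, length(genes_per_chrom)), names(genes_per_chrom))
  for (i in seq_len(nrow(ev))) {
    if (ev$location[i] == "intrachromosomal") {
      counts[ev$chrom1[i]] <- counts[ev$chrom1[i]] + 1
    } else {
      counts[ev$chrom1[i]] <- counts[ev$chrom1[i]] + 0.5
      counts[ev$chrom2[i]] <- counts[ev$chrom2[i]] + 0.5
    }
  }
  counts[is.na(counts)] <- 0
  gof <- g_test_gof(counts, genes_per_chrom / sum(genes_per_chrom))
  list(counts = counts, rel_freq = counts / genes_per_chrom, gof = gof)
}

#' Centromere-distance binning of duplicates vs genes
#'
#' Distance is measured from the centromere midpoint to the midpoint of a
#' paralog's coding extent, in bins of `bin` bp. Both paralogs of a pair
#' falling in the same bin add one event to it; paralogs in different bins
#' add half each. Bin counts are tested against the binned gene-density
#' expectation with a goodness-of-fit G-test; trailing bins beyond the last
#' occupied gene bin are dropped.
#'
#' @param events Events data.frame with `chrom1`, `chrom2`, `mid1`, `mid2`
#'   (coding-extent midpoints) and `location`.
#' @param centromeres data.frame: `chrom`, `centromere_start`,
#'   `centromere_end` (0-based half-open).
#' @param ann Annotation (gene midpoints define the expectation).
#' @param bin Bin width in bp (default 10 Mb).
#' @return list: `dup_counts`, `gene_counts` (per bin), `gof`.
#' @export
centromere_distance_bins <- function(events, centromeres, ann, bin = 1e7) {
  cen_mid <- setNames((centromeres$centromere_start +
                         centromeres$centromere_end) / 2, centromeres$chrom)
  bin_of <- function(chrom, mid) {
    cm <- cen_mid[chrom]
    ifelse(is.na(cm), NA_real_, floor(abs(mid - cm) / bin))
  }
  g <- ann$genes[ann$genes$located & !is.na(ann$genes$coding_start), ]
  no_cen <- setdiff(unique(g$chrom), names(cen_mid))
  if (length(no_cen) > 0) {
    message("chromosome(s) without centromere entry excluded: ",
            paste(no_cen, collapse = ", "))
  }
  gene_bins <- bin_of(g$chrom, (g$coding_start + g$coding_end) / 2)
  gene_bins <- gene_bins[!is.na(gene_bins)]
  n_bins <- max(gene_bins) + 1
  gene_counts <- tabulate(gene_bins + 1, nbins = n_bins)

  dup_counts <- rep(0, n_bins)
  for (i in seq_len(nrow(events))) {
    b1 <- bin_of(events$chrom1[i], events$mid1[i])
    b2 <- bin_of(events$chrom2[i], events$mid2[i])
    if (is.na(b1) || is.na(b2)) next
    b1 <- min(b1, n_bins - 1); b2 <- min(b2, n_bins - 1)
    if (b1 == b2) {
      dup_counts[b1 + 1] <- dup_counts[b1 + 1] + 1
    } else {
      dup_counts[b1 + 1] <- dup_counts[b1 + 1] + 0.5
      dup_counts[b2 + 1] <- dup_counts[b2 + 1] + 0.5
    }
  }
  keep <- gene_counts > 0
  gof <- g_test_gof(dup_counts[keep],
                    gene_counts[keep] / sum(gene_counts[keep]))
  list(dup_counts = dup_counts, gene_counts = gene_counts, gof = gof,
       bin = bin)
}

# ---- trend and rank statistics ------------------------------------------

#' Correlation, trend and rank statistics of the event cohort
#'
#' Computes (i) Kendall's tau-b between duplication span and Ks, separately
#' for DNA- and RNA-mediated events (normal approximation); (ii) the Pearson
#' correlation between Ks and log10(distance) for intrachromosomal pairs
#' with positive distance (two-sided t-based p, df = n - 2; zero distances
#' are excluded because the log is undefined, with a message); and (iii)
#' Wilcoxon rank-sum comparisons of the span distribution against gene
#' lengths and against coding-region extents. W is reported as the sum of
#' ranks of the spans in the pooled sample; its p-value comes from the
#' normal approximation with tie correction.
#'
#' @param events Events data.frame with `span`, `ks`, `mechanism`,
#'   `location`, `distance`.
#' @param gene_lengths Numeric vector of gene lengths (bp).
#' @param coding_extents Numeric vector of coding-region extents (bp).
#' @return data.frame: `test`, `statistic`, `df`, `p`, `n`.
#' @export
trend_and_rank_stats <- function(events, gene_lengths, coding_extents) {
  rows <- list()
  add <- function(test, statistic, df, p, n) {
    rows[[length(rows) + 1]] <<- data.frame(
      test = test, statistic = statistic, df = df, p = p, n = n,
      stringsAsFactors = FALSE)
  }
  for (mech in c("DNA", "RNA")) {
    d <- events[events$mechanism == mech & !is.na(events$span) &
                  !is.na(events$ks), , drop = FALSE]
    if (nrow(d) >= 3 && length(unique(d$span)) > 1 &&
        length(unique(d$ks)) > 1) {
      kt <- suppressWarnings(cor.test(d$span, d$ks, method = "kendall",
                                      exact = FALSE))
      add(paste0("kendall_span_ks_", mech), unname(kt$estimate), NA,
          kt$p.value, nrow(d))
    } else {
      add(paste0("kendall_span_ks_", mech), NA, NA, NA, nrow(d))
    }
  }
  d <- events[events$location == "intrachromosomal" &
                !is.na(events$distance), , drop = FALSE]
  n_zero <- sum(d$distance == 0)
  if (n_zero > 0) {
    message(n_zero, " intrachromosomal pair(s) with zero distance excluded",
            " from the log-distance correlation")
  }
  d <- d[d$distance > 0 & !is.na(d$ks), , drop = FALSE]
  if (nrow(d) >= 3 && length(unique(d$ks)) > 1 &&
      length(unique(d$distance)) > 1) {
    ct <- cor.test(d$ks, log10(d$distance), method = "pearson")
    add("pearson_ks_logdist", unname(ct$estimate),
        unname(ct$parameter), ct$p.value, nrow(d))
  } else {
    add("pearson_ks_logdist", NA, NA, NA, nrow(d))
  }
  spans <- events$span[!is.na(events$span)]
  ranksum <- function(x, y) {
    r <- rank(c(x, y))
    sum(r[seq_along(x)])
  }
  for (cmp in list(list("wilcoxon_span_gene_length", gene_lengths),
                   list("wilcoxon_span_coding_extent", coding_extents))) {
    y <- cmp[[2]]
    if (length(spans) >= 3 && length(y) >= 3) {
      wt <- suppressWarnings(wilcox.test(spans, y, exact = FALSE))
      add(cmp[[1]], ranksum(spans, y), NA, wt$p.value, length(spans))
    } else {
      add(cmp[[1]], NA, NA, NA, length(spans))
    }
  }
  do.call(rbind, rows)
}
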