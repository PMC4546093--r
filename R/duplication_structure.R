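# ---- neighborhood alignment ---------------------------------------------

#' Align the genomic neighborhoods of a paralog pair
#'
#' Extracts windows of `flank` bp around the coding extent of each gene
#' (clipped at chromosome ends), finds exact k-mer anchors between them on
#' both strands, and collapses anchors into same-diagonal blocks (joining
#' across short gaps, with percent identity computed from the sequences).
#' K-mers occurring more than `max_occ` times in a window (repeats) are
#' skipped. For intrachromosomal pairs with overlapping windows, the trivial
#' self-identity diagonal is removed.
#'
#' @param ann Annotation with canonical transcripts selected.
#' @param g1,g2 Gene ids of the pair.
#' @param flank Flanking window size (bp) on each side of the coding extent.
#' @param k Anchor k-mer size (<= 31).
#' @param max_occ Maximum occurrences of a k-mer in the indexed window.
#' @param join_gap Maximum same-diagonal gap (bp) joined into one block.
#' @return data.frame of alignment blocks in genomic coordinates:
#'   `start_a`, `end_a`, `start_b`, `end_b`, `strand` (`"+"` direct,
#'   `"-"` inverted), `matches`, `pident`; with the extraction windows in
#'   attributes `window_a` and `window_b`. Zero rows when no anchors exist.
#' @export
align_genomic_neighborhoods <- function(ann, g1, g2, flank = 200000, k = 31,
                                        max_occ = 10, join_gap = 50) {
  gs <- ann$genes
  r1 <- gs[gs$gene_id == g1, ]
  r2 <- gs[gs$gene_id == g2, ]
  ext <- function(r) {
    if (!is.na(r$coding_start)) c(r$coding_start, r$coding_end)
    else c(r$start, r$end)
  }
  e1 <- ext(r1); e2 <- ext(r2)
  len1 <- Biostrings::width(ann$genome)[match(r1$chrom, names(ann$genome))]
  len2 <- Biostrings::width(ann$genome)[match(r2$chrom, names(ann$genome))]
  wa <- c(max(0, e1[1] - flank), min(len1, e1[2] + flank))
  wb <- c(max(0, e2[1] - flank), min(len2, e2[2] + flank))
  sa <- as.character(Biostrings::subseq(ann$genome[[r1$chrom]],
                                        wa[1] + 1, wa[2]))
  sb_fwd <- as.character(Biostrings::subseq(ann$genome[[r2$chrom]],
                                            wb[1] + 1, wb[2]))
  sb_rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(sb_fwd)))
  wb_len <- wb[2] - wb[1]

  fwd <- .kmer_anchor_segments(sa, sb_fwd, as.integer(k),
                               as.integer(max_occ), as.integer(join_gap))
  rev <- .kmer_anchor_segments(sa, sb_rev, as.integer(k),
                               as.integer(max_occ), as.integer(join_gap))
  mk <- function(m, strand) {
    if (nrow(m) == 0) return(NULL)
    if (strand == "+") {
      sb0 <- wb[1] + m[, "start_b"]; eb0 <- wb[1] + m[, "end_b"]
    } else {
      sb0 <- wb[1] + (wb_len - m[, "end_b"])
      eb0 <- wb[1] + (wb_len - m[, "start_b"])
    }
    data.frame(start_a = wa[1] + m[, "start_a"], end_a = wa[1] + m[, "end_a"],
               start_b = sb0, end_b = eb0, strand = strand,
               matches = m[, "matches"],
               pident = 100 * m[, "matches"] / (m[, "end_a"] - m[, "start_a"]),
               stringsAsFactors = FALSE)
  }
  out <- rbind(mk(fwd, "+"), mk(rev, "-"))
  if (is.null(out)) {
    out <- data.frame(start_a = numeric(), end_a = numeric(),
                      start_b = numeric(), end_b = numeric(),
                      strand = character(), matches = numeric(),
                      pident = numeric())
  } else if (r1$chrom == r2$chrom) {
    # drop the self-identity diagonal of overlapping windows
    self <- out$strand == "+" & out$start_a == out$start_b
    out <- out[!self, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "window_a") <- wa
  attr(out, "window_b") <- wb
  attr(out, "chrom_a") <- r1$chrom
  attr(out, "chrom_b") <- r2$chrom
  out
}

# ---- tract delineation --------------------------------------------------

# best collinear chain of blocks on one strand; returns indices or NULL
best_chain <- function(bl, max_chain_gap) {
  n <- nrow(bl)
  if (n == 0) return(NULL)
  inv <- bl$strand[1] == "-"
  o <- order(bl$start_a, if (inv) -bl$start_b else bl$start_b)
  bl <- bl[o, , drop = FALSE]
  score <- bl$matches
  pred <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (bl$start_a[i] < bl$start_a[j]) next
      gap_a <- bl$start_a[i] - bl$end_a[j]
      if (gap_a > max_chain_gap) next
      if (!inv) {
        if (bl$start_b[i] < bl$start_b[j]) next
        gap_b <- bl$start_b[i] - bl$end_b[j]
      } else {
        if (bl$end_b[i] > bl$end_b[j]) next
        gap_b <- bl$start_b[j] - bl$end_b[i]
      }
      if (gap_b > max_chain_gap) next
      cand <- score[j] + bl$matches[i]
      if (cand > score[i]) {
        score[i] <- cand
        pred[i] <- j
      }
    }
  }
  list(bl = bl, score = score, pred = pred)
}

chain_members <- function(ch, i) {
  out <- integer(0)
  while (!is.na(i)) {
    out <- c(i, out)
    i <- ch$pred[i]
  }
  out
}

overlaps <- function(iv, s, e) iv[2] > s && iv[1] < e

#' Delineate the duplication tract of a paralog pair
#'
#' Chains alignment blocks collinearly (gaps at most `max_chain_gap` on both
#' loci; inverted blocks chain separately with reversed collinearity) and
#' selects the highest-scoring chain that overlaps the coding extents of
#' both focal genes. The tract on each locus runs from the outermost chained
#' coordinates (the breakpoints); the duplication span is the minimum of the
#' two tract extents.
#'
#' @param blocks Block set from [align_genomic_neighborhoods()].
#' @param extent_a,extent_b Coding extents `c(start, end)` of the two focal
#'   genes on their respective loci.
#' @param max_chain_gap Maximum unaligned gap (bp) bridged within a chain.
#' @return A list: `tract_a`, `tract_b` (per-locus intervals), `span`,
#'   `strand`, `score`, `blocks` (the chained blocks); or `NULL` when no
#'   chain overlaps both focal genes (structure undetermined).
#' @export
delineate_duplication_tract <- function(blocks, extent_a, extent_b,
                                        max_chain_gap = 5000) {
  best <- NULL
  for (st in c("+", "-")) {
    bl <- blocks[blocks$strand == st, , drop = FALSE]
    ch <- best_chain(bl, max_chain_gap)
    if (is.null(ch)) next
    for (i in order(ch$score, decreasing = TRUE)) {
      mem <- chain_members(ch, i)
      ta <- c(min(ch$bl$start_a[mem]), max(ch$bl$end_a[mem]))
      tb <- c(min(ch$bl$start_b[mem]), max(ch$bl$end_b[mem]))
      if (!overlaps(ta, extent_a[1], extent_a[2])) next
      if (!overlaps(tb, extent_b[1], extent_b[2])) next
      if (!is.null(best) && ch$score[i] <= best$score) break
      best <- list(tract_a = ta, tract_b = tb,
                   span = min(ta[2] - ta[1], tb[2] - tb[1]),
                   strand = st, score = ch$score[i],
                   blocks = ch$bl[mem, , drop = FALSE])
      break  # best eligible chain on this strand found
    }
  }
  best
}

# ---- classification -----------------------------------------------------

#' Classify the structural resemblance of a duplicate pair
#'
#' The pair is classified jointly, without inferring which copy is
#' ancestral: `complete` when both paralogs' full coding extents lie within
#' the duplication tract; `partial` when the tract breakpoint truncates the
#' coding extent of exactly one paralog (the other ORF lies wholly within
#' the tract, with no coding sequence recruited from outside); `chimeric`
#' when coding sequence extends beyond the tract at both loci -- the
#' breakpoint falls within a CDS and one paralog's annotated ORF includes
#' coding sequence originating outside the duplicated tract.
#'
#' @param tract Tract from [delineate_duplication_tract()].
#' @param extent_a,extent_b Coding extents `c(start, end)` of the paralogs.
#' @param tol Breakpoint tolerance (bp): coding sequence must extend more
#'   than this beyond the tract to count as truncated, absorbing the
#'   anchor-size edge erosion of the recovered breakpoints.
#' @return `"complete"`, `"partial"` or `"chimeric"` (or `NA` if `tract` is
#'   `NULL`).
#' @export
classify_structure <- function(tract, extent_a, extent_b, tol = 200) {
  if (is.null(tract)) return(NA_character_)
  outside <- function(ext, tr) {
    (tr[1] - ext[1]) > tol || (ext[2] - tr[2]) > tol
  }
  n_out <- outside(extent_a, tract$tract_a) + outside(extent_b, tract$tract_b)
  c("complete", "partial", "chimeric")[n_out + 1]
}

#' Classify the duplication mechanism (DNA vs RNA)
#'
#' A pair is called RNA-mediated (retrotransposed) iff one paralog's
#' canonical transcript is intronless while the partner has at least one
#' intron, and the intronless locus lacks alignable copies of the partner's
#' introns. A >= 10-nt A-run within 50 bp downstream of the intronless copy
#' is recorded as supporting (but not required) evidence. Pairs where both
#' genes are single-exon carry no intron-loss signal and are called DNA.
#'
#' @param ann Annotation with canonical transcripts selected.
#' @param g1,g2 Gene ids.
#' @param k Anchor size used to search for intron remnants.
#' @param margin Extra bp around the intronless locus searched for introns.
#' @return `"DNA"` or `"RNA"`, with attribute `poly_a` (logical) on RNA
#'   calls.
#' @export
classify_mechanism <- function(ann, g1, g2, k = 21, margin = 5000) {
  introns_of <- function(gid) {
    g <- ann$genes[ann$genes$gene_id == gid, ]
    f <- ann$features
    ex <- f[f$tx_id == g$canonical_tx & f$type == "exon", , drop = FALSE]
    ex <- ex[order(ex$start), ]
    if (nrow(ex) < 2) return(NULL)
    data.frame(start = ex$end[-nrow(ex)], end = ex$start[-1])
  }
  in1 <- introns_of(g1)
  in2 <- introns_of(g2)
  if (is.null(in1) == is.null(in2)) return("DNA")
  intronless <- if (is.null(in1)) g1 else g2
  partner_introns <- if (is.null(in1)) in2 else in1
  gi <- ann$genes[ann$genes$gene_id == intronless, ]
  gp <- ann$genes[ann$genes$gene_id == (if (is.null(in1)) g2 else g1), ]
  chrom <- ann$genome[[gi$chrom]]
  win <- c(max(0, gi$start - margin),
           min(length(chrom), gi$end + margin))
  if (gi$chrom == gp$chrom && gp$start < win[2] && gp$end > win[1]) {
    # a nearby partner's own introns must not count as remnants at the
    # intronless locus; clip the search window at the partner's boundary
    if (gp$start >= gi$end) win[2] <- min(win[2], gp$start)
    if (gp$end <= gi$start) win[1] <- max(win[1], gp$end)
    if (win[2] <= win[1]) return(structure("RNA", poly_a = FALSE))
  }
  locus_seq <- as.character(Biostrings::subseq(chrom, win[1] + 1, win[2]))
  pchrom <- ann$genome[[gp$chrom]]
  found <- FALSE
  for (r in seq_len(nrow(partner_introns))) {
    if (partner_introns$end[r] - partner_introns$start[r] < k) next
    iseq <- as.character(Biostrings::subseq(pchrom,
                                            partner_introns$start[r] + 1,
                                            partner_introns$end[r]))
    for (s in c(iseq, as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(iseq))))) {
      seg <- .kmer_anchor_segments(s, locus_seq, as.integer(k), 10L, 0L)
      if (nrow(seg) > 0) { found <- TRUE; break }
    }
    if (found) break
  }
  if (found) return("DNA")
  # supporting evidence: poly-A tract just downstream of the intronless copy
  down <- if (gi$strand == "+") {
    c(gi$end, min(length(chrom), gi$end + 50))
  } else {
    c(max(0, gi$start - 50), gi$start)
  }
  ds <- Biostrings::subseq(chrom, down[1] + 1, max(down[1] + 1, down[2]))
  if (gi$strand == "-") ds <- Biostrings::reverseComplement(ds)
  poly_a <- grepl("A{10,}", as.character(ds))
  structure("RNA", poly_a = poly_a)
}

#' Genomic geography of a pair
#'
#' @param ann Annotation.
#' @param g1,g2 Gene ids.
#' @param tract Optional tract from [delineate_duplication_tract()]; used
#'   for the inter-breakpoint distance.
#' @return list: `location` (`"intrachromosomal"`, `"interchromosomal"` or
#'   `"unassigned"`), `orientation` (`"direct"`/`"inverse"`, intra only),
#'   `distance` (bp of unique sequence between the inner tract breakpoints,
#'   0 if tracts touch or overlap; intra only).
#' @export
pair_geography <- function(ann, g1, g2, tract = NULL) {
  gs <- ann$genes
  r1 <- gs[gs$gene_id == g1, ]
  r2 <- gs[gs$gene_id == g2, ]
  if (!r1$located || !r2$located) {
    return(list(location = "unassigned", orientation = NA_character_,
                distance = NA_real_))
  }
  if (r1$chrom != r2$chrom) {
    return(list(location = "interchromosomal", orientation = NA_character_,
                distance = NA_real_))
  }
  orientation <- if (r1$strand == r2$strand) "direct" else "inverse"
  distance <- NA_real_
  if (!is.null(tract)) {
    a <- tract$tract_a; b <- tract$tract_b
    distance <- max(0, b[1] - a[2], a[1] - b[2])
  } else {
    distance <- max(0, r2$coding_start - r1$coding_end,
                    r1$coding_start - r2$coding_end)
  }
  list(location = "intrachromosomal", orientation = orientation,
       distance = distance)
}

#' Full structural characterization of one duplication event
#'
#' Runs neighborhood alignment (auto-widening the flank from `flank` to
#' `wide_flank` when the chained tract touches the window edge), tract
#' delineation, and the structure / mechanism / geography classifiers.
#'
#' @param ann Annotation with canonical transcripts selected.
#' @param g1,g2 Gene ids of the event's representative pair.
#' @param flank,wide_flank Initial and widened flanking window (bp).
#' @param k Anchor k-mer size.
#' @param max_chain_gap Maximum chained gap (bp).
#' @return One-row data.frame: `class` (`complete`/`partial`/`chimeric` for
#'   DNA-mediated events, `retro` for RNA-mediated, `NA` if undetermined),
#'   `mechanism`, `location`, `orientation`, `span`, `distance`,
#'   `tract_a_start`, `tract_a_end`, `tract_b_start`, `tract_b_end`,
#'   `aligned` (FALSE when no usable chain was found).
#' @export
characterize_event <- function(ann, g1, g2, flank = 200000,
                               wide_flank = 800000, k = 31,
                               max_chain_gap = 5000) {
  gs <- ann$genes
  r1 <- gs[gs$gene_id == g1, ]
  r2 <- gs[gs$gene_id == g2, ]
  e1 <- c(r1$coding_start, r1$coding_end)
  e2 <- c(r2$coding_start, r2$coding_end)
  run <- function(fl) {
    blocks <- align_genomic_neighborhoods(ann, g1, g2, flank = fl, k = k)
    tract <- delineate_duplication_tract(blocks, e1, e2, max_chain_gap)
    list(blocks = blocks, tract = tract)
  }
  res <- run(flank)
  if (!is.null(res$tract)) {
    wa <- attr(res$blocks, "window_a")
    wb <- attr(res$blocks, "window_b")
    touch <- res$tract$tract_a[1] <= wa[1] + k ||
      res$tract$tract_a[2] >= wa[2] - k ||
      res$tract$tract_b[1] <= wb[1] + k ||
      res$tract$tract_b[2] >= wb[2] - k
    if (touch && wide_flank > flank) res <- run(wide_flank)
  }
  tract <- res$tract
  mech <- classify_mechanism(ann, g1, g2)
  geo <- pair_geography(ann, g1, g2, tract)
  cls <- if (mech == "RNA") "retro" else classify_structure(tract, e1, e2)
  data.frame(
    class = cls, mechanism = as.character(mech),
    location = geo$location, orientation = geo$orientation,
    span = if (is.null(tract)) NA_real_ else tract$span,
    distance = if (geo$location == "intrachromosomal") geo$distance
               else NA_real_,
    tract_a_start = if (is.null(tract)) NA_real_ else tract$tract_a[1],
    tract_a_end = if (is.null(tract)) NA_real_ else tract$tract_a[2],
    tract_b_start = if (is.null(tract)) NA_real_ else tract$tract_b[1],
    tract_b_end = if (is.null(tract)) NA_real_ else tract$tract_b[2],
    aligned = !is.null(tract),
    stringsAsFactors = FALSE
  )
}
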