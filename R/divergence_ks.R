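# ---- Nei-Gojobori (1986) codon machinery --------------------------------
#
# Site and pathway tables are computed once per session and cached. The
# conventions, stated once here and relied on throughout:
#  * a possible single-nucleotide change to a stop codon counts as
#    nonsynonymous (the per-position synonymous fraction keeps denominator 3);
#  * for codon pairs differing at 2 or 3 positions, synonymous/nonsynonymous
#    differences are averaged over all minimal mutational pathways, skipping
#    pathways that pass through a stop codon (if every pathway does, all are
#    used);
#  * proportions are converted to distances with the Jukes-Cantor correction;
#    a proportion >= 3/4 is saturated and yields NA.

.ng86_env <- new.env(parent = emptyenv())

ng86_tables <- function() {
  if (!is.null(.ng86_env$tab)) return(.ng86_env$tab)
  bases <- c("A", "C", "G", "T")
  eg <- expand.grid(b3 = bases, b2 = bases, b1 = bases,
                    stringsAsFactors = FALSE)
  codons <- paste0(eg$b1, eg$b2, eg$b3)
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  is_stop <- aa == "*"

  codon_chars <- strsplit(codons, "")
  idx_of <- setNames(seq_along(codons), codons)

  syn_sites <- rep(NA_real_, 64)
  syn_changes <- vector("list", 64)  # matrix: pos, alt base, new codon index
  for (ci in seq_along(codons)) {
    if (is_stop[ci]) next
    s <- 0
    ch <- list()
    for (pos in 1:3) {
      for (alt in setdiff(bases, codon_chars[[ci]][pos])) {
        nc <- codon_chars[[ci]]
        nc[pos] <- alt
        nj <- idx_of[paste(nc, collapse = "")]
        if (!is_stop[nj] && aa[nj] == aa[ci]) {
          s <- s + 1 / 3
          ch[[length(ch) + 1]] <- c(pos, match(alt, bases), nj)
        }
      }
    }
    syn_sites[ci] <- s
    syn_changes[[ci]] <- if (length(ch)) do.call(rbind, ch) else
      matrix(integer(), 0, 3)
  }

  # pathway-averaged per-pair difference counts
  sd_mat <- matrix(NA_real_, 64, 64)
  nd_mat <- matrix(NA_real_, 64, 64)
  perms2 <- list(1:2, 2:1)
  perms3 <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (ci in seq_along(codons)) {
    if (is_stop[ci]) next
    for (cj in seq_along(codons)) {
      if (is_stop[cj]) next
      dpos <- which(codon_chars[[ci]] != codon_chars[[cj]])
      nd_ <- length(dpos)
      if (nd_ == 0) { sd_mat[ci, cj] <- 0; nd_mat[ci, cj] <- 0; next }
      perms <- switch(nd_, list(1L), perms2, perms3)
      paths <- lapply(perms, function(p) {
        cur <- codon_chars[[ci]]
        sy <- 0; ns <- 0; valid <- TRUE
        for (step in seq_len(nd_)) {
          pos <- dpos[p[step]]
          nxt <- cur
          nxt[pos] <- codon_chars[[cj]][pos]
          a1 <- aa[idx_of[paste(cur, collapse = "")]]
          a2 <- aa[idx_of[paste(nxt, collapse = "")]]
          if (a2 == "*" && step < nd_) valid <- FALSE
          if (a1 == a2 && a1 != "*") sy <- sy + 1 else ns <- ns + 1
          cur <- nxt
        }
        c(sy, ns, valid)
      })
      pm <- do.call(rbind, paths)
      use <- pm[, 3] == 1
      if (!any(use)) use <- rep(TRUE, nrow(pm))
      sd_mat[ci, cj] <- mean(pm[use, 1])
      nd_mat[ci, cj] <- mean(pm[use, 2])
    }
  }

  tab <- list(codons = codons, aa = aa, is_stop = is_stop,
              idx_of = idx_of, syn_sites = syn_sites,
              syn_changes = syn_changes, sd_mat = sd_mat, nd_mat = nd_mat)
  .ng86_env$tab <- tab
  tab
}

# split a coding sequence string into codon triplets
split_codons <- function(s) {
  s <- as.character(s)
  n <- nchar(s) %/% 3
  substring(s, 3 * seq_len(n) - 2, 3 * seq_len(n))
}

jc_correct <- function(p) {
  ifelse(is.na(p) | p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

# ---- alignment ----------------------------------------------------------

#' Global protein alignment of a paralog pair
#'
#' Needleman-Wunsch with BLOSUM62 and affine gaps (open 11, extend 1).
#'
#' @param p1,p2 Amino-acid sequences (character).
#' @return Character vector of the two aligned rows (equal width).
#' @export
align_protein_pair <- function(p1, p2) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(p1), Biostrings::AAString(p2),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1
  )
  c(as.character(Biostrings::alignedPattern(aln)),
    as.character(Biostrings::alignedSubject(aln)))
}

#' Protein-guided codon alignment
#'
#' Back-translates a protein alignment into a codon alignment: every
#' amino-acid column maps onto its source codon and every protein gap onto
#' a 3-nt gap. The coding sequences may include the terminal stop codon,
#' which is not part of the protein rows.
#'
#' @param prot_aln Character vector of two aligned protein rows.
#' @param cds1,cds2 The corresponding coding sequences (character or
#'   [Biostrings::DNAString]).
#' @return A list of class `"codon_alignment"` with elements `codons1` and
#'   `codons2`: character vectors of codon columns (`"---"` for gaps).
#' @export
codon_align_from_protein <- function(prot_aln, cds1, cds2) {
  stopifnot(length(prot_aln) == 2)
  rows <- lapply(1:2, function(i) {
    cds <- as.character(list(cds1, cds2)[[i]])
    prot <- gsub("-", "", prot_aln[i])
    trans <- as.character(suppressWarnings(Biostrings::translate(
      Biostrings::DNAString(cds), if.fuzzy.codon = "X")))
    trans <- sub("\\*$", "", trans)
    if (nchar(trans) < nchar(prot) ||
        substr(trans, 1, nchar(prot)) != prot) {
      bad <- which(strsplit(substr(trans, 1, nchar(prot)), "")[[1]] !=
                     strsplit(prot, "")[[1]])[1]
      stop("consistency error: CDS translation differs from protein row ", i,
           " at amino-acid position ", if (is.na(bad)) nchar(trans) + 1 else bad)
    }
    codons <- split_codons(cds)
    cols <- strsplit(prot_aln[i], "")[[1]]
    out <- character(length(cols))
    ci <- 0
    for (j in seq_along(cols)) {
      if (cols[j] == "-") {
        out[j] <- "---"
      } else {
        ci <- ci + 1
        out[j] <- codons[ci]
      }
    }
    out
  })
  structure(list(codons1 = rows[[1]], codons2 = rows[[2]]),
            class = "codon_alignment")
}

#' Synonymous and nonsynonymous divergence by the Nei-Gojobori method
#'
#' Counts synonymous sites per codon (averaged over the two sequences),
#' averages multiple-difference codons over all minimal mutational pathways,
#' and converts the proportions of synonymous and nonsynonymous differences
#' to distances with the Jukes-Cantor correction. Columns containing a gap,
#' a stop codon, or an ambiguous base in either row are removed first.
#'
#' @param aln A `"codon_alignment"` (see [codon_align_from_protein()]), or a
#'   list with `codons1`/`codons2` codon vectors.
#' @param min_codons Minimum analyzable codon columns (error below this).
#' @return A list: `ks`, `ka` (NA when saturated, i.e. proportion >= 3/4),
#'   `ps`, `pn`, `S`, `N` (site counts), `sd`, `nd` (difference counts) and
#'   `n_codons`.
#' @export
estimate_ks_ng86 <- function(aln, min_codons = 10) {
  tab <- ng86_tables()
  c1 <- aln$codons1
  c2 <- aln$codons2
  stopifnot(length(c1) == length(c2))
  i1 <- tab$idx_of[c1]
  i2 <- tab$idx_of[c2]
  ok <- !is.na(i1) & !is.na(i2) & !tab$is_stop[i1] & !tab$is_stop[i2]
  ok[is.na(ok)] <- FALSE
  i1 <- i1[ok]; i2 <- i2[ok]
  if (length(i1) < min_codons) {
    stop("fewer than ", min_codons,
         " analyzable codon columns after removing gap/stop columns")
  }
  ng86_from_indices(i1, i2, tab)
}

# NG86 estimate from two equal-length vectors of (non-stop) codon indices.
ng86_from_indices <- function(i1, i2, tab = ng86_tables()) {
  S <- (sum(tab$syn_sites[i1]) + sum(tab$syn_sites[i2])) / 2
  N <- 3 * length(i1) - S
  sd_ <- sum(tab$sd_mat[cbind(i1, i2)])
  nd_ <- sum(tab$nd_mat[cbind(i1, i2)])
  ps <- sd_ / S
  pn <- nd_ / N
  list(ks = jc_correct(ps), ka = jc_correct(pn), ps = ps, pn = pn,
       S = S, N = N, sd = sd_, nd = nd_, n_codons = length(i1))
}

#' Trim a protein alignment to its well-aligned core
#'
#' Structurally heterogeneous paralogs (chimeric duplicates in particular)
#' carry non-homologous segments that a global aligner still pairs up
#' column by column; estimating divergence over such columns grossly
#' inflates Ks. Scoring each alignment column +1 for an amino-acid match
#' and -1 for a mismatch or gap, the maximal-scoring contiguous run of
#' columns is the confidently homologous core: within the homologous
#' region of a young pair the match density is high (positive drift), while
#' non-homologous tails match at background frequency (negative drift), so
#' the maximal segment cuts over within a couple of columns of the true
#' junction.
#'
#' @param prot_aln Character vector of two aligned protein rows.
#' @return `c(start, end)` column range (1-based, inclusive) of the core.
#' @export
aligned_core_range <- function(prot_aln) {
  a <- strsplit(prot_aln[1], "")[[1]]
  b <- strsplit(prot_aln[2], "")[[1]]
  s <- ifelse(a == b & a != "-", 1, -1)
  best <- 0; best_range <- c(1, length(s))
  cur <- 0; cur_start <- 1
  for (i in seq_along(s)) {
    if (cur <= 0) { cur <- 0; cur_start <- i }
    cur <- cur + s[i]
    if (cur > best) { best <- cur; best_range <- c(cur_start, i) }
  }
  best_range
}

# Full divergence computation for one gene pair of an annotation with
# canonical transcripts selected: protein alignment, codon back-alignment,
# trimming to the well-aligned core, NG86 estimate. Returns a one-row
# data.frame (ks is NA on saturation or when too few codons align).
pair_divergence <- function(ann, g1, g2) {
  gs <- ann$genes
  r1 <- gs[gs$gene_id == g1, ]
  r2 <- gs[gs$gene_id == g2, ]
  pa <- align_protein_pair(r1$protein, r2$protein)
  ca <- codon_align_from_protein(
    pa,
    as.character(cds_sequence(ann, r1$canonical_tx)),
    as.character(cds_sequence(ann, r2$canonical_tx))
  )
  core <- aligned_core_range(pa)
  ca$codons1 <- ca$codons1[core[1]:core[2]]
  ca$codons2 <- ca$codons2[core[1]:core[2]]
  est <- tryCatch(estimate_ks_ng86(ca),
                  error = function(e) list(ks = NA_real_, ka = NA_real_,
                                           n_codons = 0L))
  data.frame(gene1 = min(g1, g2), gene2 = max(g1, g2),
             ks = est$ks, ka = est$ka, n_codons = est$n_codons,
             stringsAsFactors = FALSE)
}

# ---- youth filter and curation ------------------------------------------

#' Retain evolutionarily young pairs
#'
#' @param pairs Pair data.frame with a `ks` column.
#' @param ks_max Inclusive upper bound on Ks.
#' @return Pairs with `ks <= ks_max`; pairs with undefined (saturated) Ks
#'   are dropped.
#' @export
filter_young_pairs <- function(pairs, ks_max = 0.1) {
  keep <- !is.na(pairs$ks) & pairs$ks <= ks_max
  n_na <- sum(is.na(pairs$ks))
  if (n_na > 0) message(n_na, " pair(s) with undefined Ks dropped")
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove same-location pairs
#'
#' A pair is removed iff both genes lie on the same chromosome and have
#' byte-identical coding extents: duplicate annotations of one locus under
#' different gene names, not true duplications.
#'
#' @param pairs Pair data.frame (`gene1`, `gene2`).
#' @param ann Annotation with canonical transcripts selected.
#' @return The pair table without same-location pairs.
#' @export
remove_same_location_pairs <- function(pairs, ann) {
  g <- ann$genes
  i1 <- match(pairs$gene1, g$gene_id)
  i2 <- match(pairs$gene2, g$gene_id)
  same <- g$chrom[i1] == g$chrom[i2] &
    g$coding_start[i1] == g$coding_start[i2] &
    g$coding_end[i1] == g$coding_end[i2]
  same[is.na(same)] <- FALSE
  out <- pairs[!same, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_same_location") <- sum(same)
  out
}

#' UPGMA-based removal of shadow pairs
#'
#' Within a family of n genes (3 to 5 members), only n - 1 of the C(n, 2)
#' similarity pairs correspond to distinct duplication events. An UPGMA tree
#' is built from the pairwise Ks matrix; for each internal node the
#' minimum-Ks gene pair spanning the two joined clusters is retained (ties
#' broken by lexicographic gene-id order) and all remaining pairs are
#' flagged shadow.
#'
#' @param ks_mat Symmetric Ks matrix with gene ids as dimnames. `NA` entries
#'   (saturated pairs) are replaced by the largest defined distance for tree
#'   building, with a message.
#' @return data.frame (`gene1`, `gene2`, `node_height`) of retained pairs,
#'   one per internal node.
#' @export
select_representative_pairs <- function(ks_mat) {
  ids <- rownames(ks_mat)
  n <- length(ids)
  stopifnot(n >= 2, identical(rownames(ks_mat), colnames(ks_mat)))
  if (n == 2) {
    return(data.frame(gene1 = min(ids), gene2 = max(ids),
                      node_height = ks_mat[1, 2], stringsAsFactors = FALSE))
  }
  m <- ks_mat
  if (any(is.na(m[upper.tri(m)]))) {
    message("undefined Ks in family matrix; using largest defined distance")
    m[is.na(m)] <- max(m, na.rm = TRUE)
  }
  hc <- hclust(as.dist(m), method = "average")
  members <- vector("list", n - 1)
  out <- vector("list", n - 1)
  for (k in seq_len(n - 1)) {
    side <- function(v) if (v < 0) ids[-v] else members[[v]]
    left <- side(hc$merge[k, 1])
    right <- side(hc$merge[k, 2])
    members[[k]] <- c(left, right)
    cross <- expand.grid(a = left, b = right, stringsAsFactors = FALSE)
    cross$g1 <- pmin(cross$a, cross$b)
    cross$g2 <- pmax(cross$a, cross$b)
    cross$ks <- ks_mat[cbind(match(cross$g1, ids), match(cross$g2, ids))]
    ks_eff <- ifelse(is.na(cross$ks), Inf, cross$ks)
    best <- which(ks_eff == min(ks_eff))
    if (length(best) > 1) {
      lab <- paste(cross$g1[best], cross$g2[best])
      best <- best[order(lab)][1]
    }
    out[[k]] <- data.frame(gene1 = cross$g1[best], gene2 = cross$g2[best],
                           node_height = hc$height[k],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' UPGMA tree of a family's Ks matrix as a newick string
#'
#' @param ks_mat Symmetric Ks matrix with gene ids as dimnames.
#' @return A newick string (via [ape::write.tree()]).
#' @export
upgma_newick <- function(ks_mat) {
  m <- ks_mat
  m[is.na(m)] <- max(m, na.rm = TRUE)
  hc <- hclust(as.dist(m), method = "average")
  ape::write.tree(ape::as.phylo(hc))
}

# Apply shadow filtering across all families: pairs within families of
# size >= 3 are reduced to their representative set.
remove_shadow_pairs <- function(pairs, families) {
  fam_of <- setNames(families$family_id, families$gene_id)
  pairs$family_id <- fam_of[pairs$gene1]
  keep <- rep(TRUE, nrow(pairs))
  for (fid in unique(pairs$family_id)) {
    rows <- which(pairs$family_id == fid)
    genes <- sort(unique(c(pairs$gene1[rows], pairs$gene2[rows])))
    if (length(genes) < 3) next
    m <- matrix(NA_real_, length(genes), length(genes),
                dimnames = list(genes, genes))
    for (r in rows) {
      m[pairs$gene1[r], pairs$gene2[r]] <- pairs$ks[r]
      m[pairs$gene2[r], pairs$gene1[r]] <- pairs$ks[r]
    }
    diag(m) <- 0
    # single-link families can lack some pairwise hits; missing Ks entries
    # are handled inside select_representative_pairs
    rep_pairs <- select_representative_pairs(m)
    lab <- paste(pairs$gene1[rows], pairs$gene2[rows])
    keep[rows] <- lab %in% paste(rep_pairs$gene1, rep_pairs$gene2)
  }
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_shadow") <- sum(!keep)
  out
}

#' Merge co-duplicated neighbor pairs into linked sets
#'
#' Two pairs (A1, A2) and (B1, B2) arise from a single duplication event of
#' a multi-gene segment when A1 and B1 are close neighbors on one
#' chromosome, A2 and B2 are close neighbors with the same relative order
#' and strand relationship on the other locus (collinearity on both sides).
#' Merged sets carry the arithmetic mean Ks of their member pairs and are
#' treated as a single duplication event downstream.
#'
#' @param pairs Pair data.frame (`gene1`, `gene2`, `ks`).
#' @param ann Annotation with canonical transcripts selected.
#' @param max_intervening Maximum number of intervening genes between
#'   neighbors on each locus.
#' @return An events data.frame: `event_id`, `gene1`, `gene2` (the
#'   minimum-Ks member pair), `ks` (mean over members), `n_members`,
#'   `member_pairs` (";"-separated pair labels).
#' @export
detect_linked_sets <- function(pairs, ann, max_intervening = 1) {
  if (nrow(pairs) == 0) {
    return(data.frame(event_id = character(), gene1 = character(),
                      gene2 = character(), ks = numeric(),
                      n_members = integer(), member_pairs = character(),
                      stringsAsFactors = FALSE))
  }
  g <- ann$genes
  # gene order index along each chromosome
  ord <- rep(NA_real_, nrow(g))
  for (ch in unique(g$chrom)) {
    i <- which(g$chrom == ch)
    ord[i] <- rank(ifelse(is.na(g$coding_start[i]), g$start[i],
                          g$coding_start[i]))
  }
  rank_of <- setNames(ord, g$gene_id)
  chrom_of <- setNames(g$chrom, g$gene_id)
  strand_of <- setNames(g$strand, g$gene_id)

  n <- nrow(pairs)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  near <- function(x, y) {
    !is.na(chrom_of[x]) && !is.na(chrom_of[y]) &&
      chrom_of[x] == chrom_of[y] && x != y &&
      abs(rank_of[x] - rank_of[y]) <= max_intervening + 1
  }
  collinear <- function(a1, a2, b1, b2) {
    if (!(near(a1, b1) && near(a2, b2))) return(FALSE)
    rel_a <- strand_of[a1] == strand_of[a2]
    rel_b <- strand_of[b1] == strand_of[b2]
    if (rel_a != rel_b) return(FALSE)
    d1 <- rank_of[b1] - rank_of[a1]
    d2 <- rank_of[b2] - rank_of[a2]
    if (rel_a) sign(d1) == sign(d2) else sign(d1) == -sign(d2)
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        a1 <- pairs$gene1[i]; a2 <- pairs$gene2[i]
        b1 <- pairs$gene1[j]; b2 <- pairs$gene2[j]
        if (collinear(a1, a2, b1, b2) || collinear(a1, a2, b2, b1)) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  events <- lapply(sort(unique(root)), function(r) {
    rows <- which(root == r)
    ks <- pairs$ks[rows]
    rep_row <- rows[order(ifelse(is.na(ks), Inf, ks))][1]
    data.frame(gene1 = pairs$gene1[rep_row], gene2 = pairs$gene2[rep_row],
               ks = mean(ks), n_members = length(rows),
               member_pairs = paste(pairs$gene1[rows], pairs$gene2[rows],
                                    sep = "|", collapse = ";"),
               stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, events)
  ev <- ev[order(ev$gene1, ev$gene2), , drop = FALSE]
  ev$event_id <- sprintf("E%04d", seq_len(nrow(ev)))
  rownames(ev) <- NULL
  ev[, c("event_id", "gene1", "gene2", "ks", "n_members", "member_pairs")]
}

#' Write a paralog pair table
#'
#' @param pairs Pair data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
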