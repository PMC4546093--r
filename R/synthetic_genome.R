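# ---- synthetic genomes with planted, truth-labelled duplications --------
#
# The generator emulates the features the analysis relies on: multi-exon
# protein-coding genes whose coding extents follow a lognormal with median
# 25 kb and mean 65 kb, uniform-random intergenic sequence (no repeats, so
# the anchor aligner's false-positive rate is negligible), planted
# duplication events of controlled class / location / orientation / span /
# Ks with optional gene-conversion tracts, and an outgroup lineage that
# split before any duplication, at a configurable synonymous divergence
# (default Ks = 0.011). Background divergence uses a uniform
# (Jukes-Cantor-like) substitution scheme, matching the assumptions of the
# NG86/JC estimator so that recovery tests are unconfounded.

#' Simulation configuration
#'
#' @param n_chrom Number of chromosomes.
#' @param genes_per_chrom Background genes placed per chromosome.
#' @param extent_meanlog,extent_sdlog Lognormal parameters of the coding
#'   extent (start to stop codon, bp); defaults give median 25 kb and mean
#'   65 kb.
#' @param extent_min,extent_max Truncation bounds on the sampled extent (the
#'   upper bound trims the extreme lognormal tail; see the vignette).
#' @param cds_len_range Range of total CDS length (nt; rounded to codons).
#' @param exon_rate Poisson rate for the number of additional exons
#'   (n_exons = 1 + rpois(exon_rate), capped so every exon has >= 10 codons).
#' @param intergenic_mean,intergenic_min Exponential mean / minimum length
#'   of intergenic spacers (bp).
#' @param alt_tx_frac Fraction of genes given a second, shorter transcript.
#' @param minus_strand_frac Fraction of genes on the minus strand.
#' @param outgroup_ks Synonymous divergence of the outgroup lineage.
#' @param flank_divergence Substitution proportion applied to the noncoding
#'   part of each planted duplication tract.
#' @return A named list of class `"sim_config"`.
#' @export
simulation_config <- function(n_chrom = 5, genes_per_chrom = 30,
                              extent_meanlog = log(25000),
                              extent_sdlog = sqrt(2 * log(65 / 25)),
                              extent_min = 2000, extent_max = 300000,
                              cds_len_range = c(900, 2400),
                              exon_rate = 5,
                              intergenic_mean = 25000, intergenic_min = 3000,
                              alt_tx_frac = 0.1, minus_strand_frac = 0.5,
                              outgroup_ks = 0.011, flank_divergence = 0.01) {
  structure(as.list(environment()), class = "sim_config")
}

# random stop-free codon index vector of n codons (first ATG, last TAA
# appended by callers when needed)
.random_codons <- function(n) {
  tab <- ng86_tables()
  sample(which(!tab$is_stop), n, replace = TRUE)
}

.codon_string <- function(idx) {
  paste(ng86_tables()$codons[idx], collapse = "")
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Build one gene: returns region sequence plus exon/CDS intervals relative
# to the region (0-based half-open), in genomic order. Exon boundaries fall
# on codon boundaries (a simulator simplification; the pipeline does not
# rely on it). Exons and CDS coincide (no UTR is simulated).
.make_gene_region <- function(extent, cds_len, n_exons, strand) {
  n_codons <- cds_len %/% 3
  n_exons <- max(1L, min(n_exons, n_codons %/% 10))
  # codon counts per exon: random composition, each >= 10
  w <- runif(n_exons)
  part <- floor(w / sum(w) * (n_codons - 10 * n_exons)) + 10
  part[n_exons] <- n_codons - sum(part[-n_exons])
  exon_nt <- part * 3
  if (n_exons == 1) {
    intron_nt <- integer(0)
    extent <- cds_len
  } else {
    total_intron <- max(extent - cds_len, 200 * (n_exons - 1))
    wi <- runif(n_exons - 1, 0.5, 1.5)
    intron_nt <- floor(wi / sum(wi) * (total_intron - 200 * (n_exons - 1))) +
      200
    extent <- cds_len + sum(intron_nt)
  }
  # coding sequence: ATG + random codons + TAA
  tab <- ng86_tables()
  body <- .random_codons(n_codons - 2)
  coding <- paste0("ATG", .codon_string(body), "TAA")
  # assemble in coding (plus) frame
  segs <- character(0)
  feats <- list()
  off <- 0L
  cpos <- 0L
  for (e in seq_len(n_exons)) {
    exon_seq <- substr(coding, cpos + 1, cpos + exon_nt[e])
    segs <- c(segs, exon_seq)
    feats[[length(feats) + 1]] <- c(off, off + exon_nt[e])
    off <- off + exon_nt[e]
    cpos <- cpos + exon_nt[e]
    if (e < n_exons) {
      segs <- c(segs, .random_dna(intron_nt[e]))
      off <- off + intron_nt[e]
    }
  }
  region <- paste(segs, collapse = "")
  iv <- do.call(rbind, feats)
  if (strand == "-") {
    region <- .revcomp_chr(region)
    iv <- cbind(extent - iv[, 2], extent - iv[, 1])
    iv <- iv[order(iv[, 1]), , drop = FALSE]
  }
  list(region = region, extent = extent, intervals = iv, coding = coding)
}

#' Simulate a base genome with annotation and outgroup
#'
#' Generates `n_chrom` chromosomes of non-overlapping multi-exon genes
#' separated by random intergenic spacers, plus an outgroup genome: a copy
#' of the base genome whose coding sequences are mutated synonymously to
#' `outgroup_ks` and whose noncoding sequence receives the corresponding
#' substitution proportion. Deterministic for a fixed seed.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return A list of class `"duplication_sim"`: `ann` (ingroup
#'   `"annotation"`), `outgroup` (outgroup `"annotation"`), `truth` (empty
#'   truth table, filled by [plant_duplication_event()]), `tracts` (planted
#'   tract registry), `used` (gene ids consumed by events), `config`,
#'   `seed`.
#' @export
simulate_genome <- function(config = simulation_config(), seed = 1) {
  set.seed(seed)
  chroms <- paste0("chr", seq_len(config$n_chrom))
  seqs <- character(0)
  genes <- list()
  features <- list()
  gnum <- 0L
  for (ch in chroms) {
    pos <- 0L
    parts <- character(0)
    for (gi in seq_len(config$genes_per_chrom)) {
      gap <- config$intergenic_min +
        ceiling(stats::rexp(1, 1 / config$intergenic_mean))
      extent <- round(min(max(rlnorm(1, config$extent_meanlog,
                                     config$extent_sdlog),
                              config$extent_min), config$extent_max))
      cds_len <- (sample(seq(config$cds_len_range[1],
                             config$cds_len_range[2]), 1) %/% 3) * 3
      n_exons <- 1L + stats::rpois(1, config$exon_rate)
      strand <- if (runif(1) < config$minus_strand_frac) "-" else "+"
      g <- .make_gene_region(extent, cds_len, n_exons, strand)
      gnum <- gnum + 1L
      gid <- sprintf("G%04d", gnum)
      start <- pos + gap
      parts <- c(parts, .random_dna(gap), g$region)
      pos <- start + g$extent
      genes[[gnum]] <- data.frame(gene_id = gid, chrom = ch, strand = strand,
                                  start = start, end = pos,
                                  stringsAsFactors = FALSE)
      iv <- g$intervals + start
      tx1 <- paste0(gid, ".t1")
      features[[length(features) + 1]] <- data.frame(
        gene_id = gid, tx_id = tx1,
        type = rep(c("exon", "CDS"), each = nrow(iv)),
        start = rep(iv[, 1], 2), end = rep(iv[, 2], 2),
        stringsAsFactors = FALSE)
      # occasionally a second, shorter transcript (drops the last coding
      # exon) so canonical selection has work to do
      if (nrow(iv) >= 2 && runif(1) < config$alt_tx_frac) {
        drop_last <- if (strand == "+") nrow(iv) else 1L
        iv2 <- iv[-drop_last, , drop = FALSE]
        tx2 <- paste0(gid, ".t2")
        features[[length(features) + 1]] <- data.frame(
          gene_id = gid, tx_id = tx2,
          type = rep(c("exon", "CDS"), each = nrow(iv2)),
          start = rep(iv2[, 1], 2), end = rep(iv2[, 2], 2),
          stringsAsFactors = FALSE)
      }
    }
    parts <- c(parts, .random_dna(config$intergenic_min +
                                    ceiling(stats::rexp(1, 1 / config$intergenic_mean))))
    seqs[ch] <- paste(parts, collapse = "")
  }
  genome <- Biostrings::DNAStringSet(seqs)
  genes <- do.call(rbind, genes)
  genes$located <- TRUE
  features <- do.call(rbind, features)
  ann <- structure(list(genome = genome, genes = genes, features = features),
                   class = "annotation")
  outgroup <- .derive_outgroup(ann, config$outgroup_ks)
  structure(list(ann = ann, outgroup = outgroup, truth = NULL,
                 tracts = data.frame(event_id = character(),
                                     locus = character(), chrom = character(),
                                     start = numeric(), end = numeric(),
                                     stringsAsFactors = FALSE),
                 used = character(0), config = config, seed = seed),
            class = "duplication_sim")
}

# coding intervals (genomic order) of a transcript from a feature table
.cds_iv <- function(features, tx_id) {
  iv <- features[features$tx_id == tx_id & features$type == "CDS",
                 c("start", "end"), drop = FALSE]
  iv[order(iv$start), , drop = FALSE]
}

.read_coding <- function(genome, chrom, iv, strand) {
  s <- paste(vapply(seq_len(nrow(iv)), function(i) {
    as.character(Biostrings::subseq(genome[[chrom]], iv$start[i] + 1,
                                    iv$end[i]))
  }, character(1)), collapse = "")
  if (strand == "-") s <- .revcomp_chr(s)
  s
}

.write_coding <- function(genome, chrom, iv, strand, coding) {
  plus <- if (strand == "-") .revcomp_chr(coding) else coding
  off <- 0L
  x <- genome[[chrom]]
  for (i in seq_len(nrow(iv))) {
    len <- iv$end[i] - iv$start[i]
    Biostrings::subseq(x, iv$start[i] + 1, iv$end[i]) <-
      Biostrings::DNAString(substr(plus, off + 1, off + len))
    off <- off + len
  }
  genome[[chrom]] <- x
  genome
}

# outgroup = pre-duplication ancestor lineage: CDS mutated synonymously to
# target Ks, noncoding mutated at the matching substitution proportion
.derive_outgroup <- function(ann, outgroup_ks) {
  out <- ann
  p_sub <- 0.75 * (1 - exp(-4 * outgroup_ks / 3))
  tx_first <- tapply(out$features$tx_id, out$features$gene_id,
                     function(x) sort(unique(x))[1])
  cds_mask <- list()
  for (ch in names(out$genome)) cds_mask[[ch]] <- integer(0)
  for (gi in seq_len(nrow(out$genes))) {
    g <- out$genes[gi, ]
    iv <- .cds_iv(out$features, tx_first[[g$gene_id]])
    coding <- .read_coding(out$genome, g$chrom, iv, g$strand)
    body <- substr(coding, 1, nchar(coding) - 3)  # keep the stop codon
    res <- mutate_to_target_ks(body, body, outgroup_ks)
    out$genome <- .write_coding(out$genome, g$chrom, iv, g$strand,
                                paste0(res$cds,
                                       substr(coding, nchar(coding) - 2,
                                              nchar(coding))))
    # mask all transcripts' CDS from noncoding mutation
    allcds <- out$features[out$features$gene_id == g$gene_id &
                             out$features$type == "CDS", ]
    for (r in seq_len(nrow(allcds))) {
      cds_mask[[g$chrom]] <- c(cds_mask[[g$chrom]],
                               seq(allcds$start[r] + 1, allcds$end[r]))
    }
  }
  for (ch in names(out$genome)) {
    len <- length(out$genome[[ch]])
    pos <- which(runif(len) < p_sub)
    pos <- setdiff(pos, unique(cds_mask[[ch]]))
    if (length(pos) > 0) {
      old <- strsplit(as.character(out$genome[[ch]]), "")[[1]][pos]
      shift <- sample(1:3, length(pos), replace = TRUE)
      bases <- c("A", "C", "G", "T")
      new <- bases[(match(old, bases) - 1 + shift) %% 4 + 1]
      out$genome[[ch]] <- Biostrings::replaceLetterAt(
        out$genome[[ch]], pos, paste(new, collapse = ""))
    }
  }
  out
}

# ---- targeted mutation operators ----------------------------------------

#' Mutate a derived coding sequence to a target synonymous divergence
#'
#' Single-nucleotide synonymous substitutions are placed uniformly over the
#' NG86 synonymous sites of the derived copy (codons weighted by their
#' number of synonymous single-nucleotide changes) until the NG86 Ks of the
#' pair first reaches the target. Both sequences must be stop-free,
#' equal-length, in-frame coding sequences (strip the terminal stop codon
#' first).
#'
#' @param cds_ref Reference (ancestral) coding sequence.
#' @param cds_derived Derived coding sequence to mutate (often identical to
#'   `cds_ref` initially).
#' @param target_ks Target Ks in `[0, 0.3]`.
#' @return list: `cds` (mutated derived sequence), `ks` (realized NG86 Ks),
#'   `n_sub` (substitutions applied).
#' @export
mutate_to_target_ks <- function(cds_ref, cds_derived, target_ks) {
  stopifnot(target_ks >= 0, target_ks <= 0.3)
  tab <- ng86_tables()
  i_ref <- unname(tab$idx_of[split_codons(cds_ref)])
  i_der <- unname(tab$idx_of[split_codons(cds_derived)])
  stopifnot(length(i_ref) == length(i_der),
            !any(tab$is_stop[i_ref]), !any(tab$is_stop[i_der]))
  n_ch <- vapply(tab$syn_changes, function(m) {
    if (is.null(m)) 0L else nrow(m)
  }, integer(1))
  n_sub <- 0L
  repeat {
    est <- ng86_from_indices(i_ref, i_der, tab)
    if (is.na(est$ks)) stop("Ks saturated before reaching target ", target_ks)
    if (est$ks >= target_ks) break
    w <- n_ch[i_der]
    ci <- sample.int(length(i_der), 1, prob = w)
    ch <- tab$syn_changes[[i_der[ci]]]
    i_der[ci] <- ch[sample.int(nrow(ch), 1), 3]
    n_sub <- n_sub + 1L
  }
  list(cds = .codon_string(i_der), ks = est$ks, n_sub = n_sub)
}

#' Evolve a coding sequence under the NG86 substitution model
#'
#' Applies a Poisson number of synonymous substitution events -- with mean
#' `t` times the sequence's NG86 synonymous site count -- placed uniformly
#' over synonymous sites (no transition bias, uniform codon usage). `t` is
#' therefore the true synonymous divergence in substitutions per synonymous
#' site, the quantity the NG86/JC estimator aims to recover.
#'
#' @param cds Stop-free, in-frame coding sequence.
#' @param t True synonymous divergence (substitutions per synonymous site).
#' @return The mutated coding sequence (character).
#' @export
simulate_ng86_divergence <- function(cds, t) {
  tab <- ng86_tables()
  idx <- unname(tab$idx_of[split_codons(cds)])
  stopifnot(!any(tab$is_stop[idx]), t >= 0)
  n_ch <- vapply(tab$syn_changes, function(m) {
    if (is.null(m)) 0L else nrow(m)
  }, integer(1))
  n_events <- stats::rpois(1, t * sum(tab$syn_sites[idx]))
  for (e in seq_len(n_events)) {
    w <- n_ch[idx]
    ci <- sample.int(length(idx), 1, prob = w)
    ch <- tab$syn_changes[[idx[ci]]]
    idx[ci] <- ch[sample.int(nrow(ch), 1), 3]
  }
  .codon_string(idx)
}

#' Homogenize a gene-conversion tract between two coding sequences
#'
#' Overwrites the derived copy's tract with the partner's current sequence;
#' positions outside the tract are untouched.
#'
#' @param cds_ref,cds_derived Equal-length coding sequences.
#' @param tract `c(start, end)`, 0-based half-open, within the sequences.
#' @return The homogenized derived sequence (character).
#' @export
apply_gene_conversion_tract <- function(cds_ref, cds_derived, tract) {
  n <- nchar(cds_derived)
  stopifnot(nchar(cds_ref) == n, tract[1] >= 0, tract[2] <= n,
            tract[1] <= tract[2])
  if (tract[1] == tract[2]) return(cds_derived)
  paste0(substr(cds_derived, 1, tract[1]),
         substr(cds_ref, tract[1] + 1, tract[2]),
         substr(cds_derived, tract[2] + 1, n))
}

# ---- event planting -----------------------------------------------------

# occupied intervals (genes + planted tracts, with margin) on a chromosome
.occupied <- function(sim, chrom, margin = 1000) {
  g <- sim$ann$genes[sim$ann$genes$chrom == chrom, ]
  t <- sim$tracts[sim$tracts$chrom == chrom, ]
  iv <- rbind(data.frame(s = g$start, e = g$end),
              data.frame(s = t$start, e = t$end))
  if (nrow(iv) == 0) return(iv)
  iv$s <- pmax(0, iv$s - margin)
  iv$e <- iv$e + margin
  iv <- iv[order(iv$s), , drop = FALSE]
  out <- iv[1, ]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$s[i] <= out$e[nrow(out)]) {
      out$e[nrow(out)] <- max(out$e[nrow(out)], iv$e[i])
    } else out <- rbind(out, iv[i, ])
  }
  out
}

# TRUE when none of the w genes on either side of position p on chrom
# belongs to an already-planted event. Linked-set merging requires
# adjacency at BOTH loci of two pairs, so keeping every inserted copy
# outside the adjacency window of all previous event genes guarantees
# that independent events cannot masquerade as one linked set.
.isolated_position <- function(sim, chrom, p, w = 2) {
  g <- sim$ann$genes[sim$ann$genes$chrom == chrom, ]
  g <- g[order(g$start), ]
  left <- g$gene_id[g$end <= p]
  right <- g$gene_id[g$start >= p]
  near <- c(utils::tail(left, w), utils::head(right, w))
  !any(near %in% sim$used)
}

# pick an insertion point for a block on chrom; prefer desired_pos when
# free, otherwise the nearest free position, otherwise a random free
# position -- always keeping clear of other events' genes. Returns NA if
# no suitable gap exists.
.find_insertion_site <- function(sim, chrom, insert_len, desired_pos = NA) {
  occ <- .occupied(sim, chrom)
  len <- length(sim$ann$genome[[chrom]])
  gaps <- data.frame(s = c(2000, occ$e), e = c(occ$s, len - 2000))
  gaps <- gaps[gaps$e - gaps$s >= 200, , drop = FALSE]
  if (nrow(gaps) == 0) return(NA_real_)
  # isolation depends only on a gap's flanking genes, so test once per gap
  iso <- vapply(seq_len(nrow(gaps)), function(i) {
    .isolated_position(sim, chrom, round((gaps$s[i] + gaps$e[i]) / 2))
  }, logical(1))
  gaps <- gaps[iso, , drop = FALSE]
  if (nrow(gaps) == 0) return(NA_real_)
  if (!is.na(desired_pos)) {
    inside <- gaps$s <= desired_pos & desired_pos <= gaps$e
    if (any(inside)) return(desired_pos)
    cand <- c(gaps$s, gaps$e)
    return(cand[which.min(abs(cand - desired_pos))])
  }
  g <- gaps[sample.int(nrow(gaps), 1, prob = gaps$e - gaps$s), ]
  round(runif(1, g$s, g$e))
}

# shift all annotation (and tract registry) coordinates at/after pos on
# chrom by len
.shift_coords <- function(sim, chrom, pos, len) {
  a <- sim$ann
  gsel <- a$genes$chrom == chrom & a$genes$start >= pos
  a$genes$start[gsel] <- a$genes$start[gsel] + len
  a$genes$end[gsel] <- a$genes$end[gsel] + len
  fchrom <- a$genes$chrom[match(a$features$gene_id, a$genes$gene_id)]
  fsel <- fchrom == chrom & a$features$start >= pos
  a$features$start[fsel] <- a$features$start[fsel] + len
  a$features$end[fsel] <- a$features$end[fsel] + len
  sim$ann <- a
  tsel <- sim$tracts$chrom == chrom & sim$tracts$start >= pos
  sim$tracts$start[tsel] <- sim$tracts$start[tsel] + len
  sim$tracts$end[tsel] <- sim$tracts$end[tsel] + len
  sim
}

# cumulative coding length before each genomic position of a plus-strand
# CDS; returns candidate cut positions (genomic, codon-aligned) with their
# coding offsets
.codon_cut_candidates <- function(iv) {
  out <- list()
  c0 <- 0L
  for (i in seq_len(nrow(iv))) {
    len <- iv$end[i] - iv$start[i]
    # cuts strictly inside the exon, at codon boundaries
    first <- ((3 - c0) %% 3)
    if (first == 0) first <- 3
    k <- if (first <= len - 1) seq.int(first, len - 1, by = 3) else integer(0)
    k <- k[(c0 + k) %% 3 == 0]
    if (length(k) > 0) {
      out[[length(out) + 1]] <- data.frame(pos = iv$start[i] + k,
                                           coding = c0 + k, exon = i)
    }
    c0 <- c0 + len
  }
  if (length(out) == 0) {
    data.frame(pos = numeric(0), coding = numeric(0), exon = integer(0))
  } else do.call(rbind, out)
}

#' Plant one duplication event into a simulated genome
#'
#' Copies a tract around a compatible donor gene to a new location,
#' producing a derived paralog of the requested class:
#' \describe{
#'   \item{complete}{the tract covers the donor's whole coding extent plus
#'     intergenic margins;}
#'   \item{partial}{the tract breakpoint falls inside the donor CDS (at a
#'     codon boundary) and the copy's ORF is terminated by a stop codon at
#'     the truncation point, inside the tract;}
#'   \item{chimeric}{as partial, but the copy's ORF continues past the
#'     breakpoint into a novel exon recruited from outside the tract;}
#'   \item{retro}{the copy is the exon-spliced, intronless mRNA (CDS) of a
#'     multi-exon donor followed by a 12-nt poly-A tract.}
#' }
#' The copy is then mutated synonymously to the target Ks, the noncoding
#' part of the tract receives `flank_divergence` substitutions, and an
#' optional gene-conversion tract is homogenized back to the donor
#' sequence. Ground truth (including the realized NG86 Ks of the planted
#' copies) is appended to the simulation's truth table.
#'
#' @param sim A `"duplication_sim"` from [simulate_genome()].
#' @param spec list: `class` (`"complete"`, `"partial"`, `"chimeric"`,
#'   `"retro"`), `location` (`"intra"`/`"inter"`), `orientation`
#'   (`"direct"`/`"inverse"`), `span` (bp; ignored for retro), `ks` (target,
#'   in `[0, 0.1]` for the study conditions), optional `distance` (bp,
#'   intra), optional `conversion_len` (bp of homogenized coding tract).
#' @return The updated simulation object.
#' @export
plant_duplication_event <- function(sim, spec) {
  cfg <- sim$config
  g <- sim$ann$genes
  f <- sim$ann$features
  tx_first <- function(gid) sort(unique(f$tx_id[f$gene_id == gid]))[1]
  n_cds_exons <- function(gid) nrow(.cds_iv(f, tx_first(gid)))

  avail <- g$gene_id[!(g$gene_id %in% sim$used) & g$located]
  ok <- vapply(avail, function(gid) {
    r <- g[g$gene_id == gid, ]
    extent <- r$end - r$start
    switch(spec$class,
           complete = extent + 1000 <= spec$span,
           retro = n_cds_exons(gid) >= 2,
           partial = ,
           chimeric = r$strand == "+" && n_cds_exons(gid) >= 2,
           FALSE)
  }, logical(1))
  if (!any(ok)) stop("no compatible donor for event class ", spec$class,
                     " with span ", spec$span)
  # try donors in random order until one has free margins for the tract
  try_tract <- function(gid) {
    dr <- g[g$gene_id == gid, ]
    div <- .cds_iv(f, tx_first(gid))
    occ <- .occupied(sim, dr$chrom, margin = 500)
    left_lim <- max(0, occ$e[occ$e <= dr$start + 1], na.rm = TRUE)
    right_lim <- min(length(sim$ann$genome[[dr$chrom]]),
                     occ$s[occ$s >= dr$end - 1], na.rm = TRUE)
    cut_info <- NULL
    if (spec$class == "complete") {
      extent <- dr$end - dr$start
      extra <- spec$span - extent
      m1 <- round(runif(1, 500, max(500, extra - 500)))
      tract <- c(dr$start - m1, dr$start - m1 + spec$span)
      tract[1] <- max(left_lim, tract[1])
      tract[2] <- min(right_lim, tract[2])
      if (tract[1] > dr$start - 300 || tract[2] < dr$end + 300) return(NULL)
    } else if (spec$class %in% c("partial", "chimeric")) {
      cand <- .codon_cut_candidates(div)
      cds_len <- sum(div$end - div$start)
      # the cut must fall beyond the first intron so the truncated copy
      # keeps at least one intron (otherwise it would mimic a retrogene),
      # and leave >= 900 nt of shared coding region so one synonymous
      # substitution moves Ks by well under the target grid's margin
      keep <- cand$exon >= 2 &
        cand$coding >= max(900, 0.3 * cds_len) &
        cand$coding <= 0.7 * cds_len &
        (cand$pos - dr$start) <= spec$span - 500
      if (!any(keep)) return(NULL)
      ci <- sample(which(keep), 1)
      cut_info <- cand[ci, ]
      m1 <- spec$span - (cut_info$pos - dr$start)
      tract <- c(max(left_lim, dr$start - m1), cut_info$pos)
      if (tract[1] > dr$start - 200) return(NULL)
    } else {  # retro: source extent; the copy is the spliced mRNA
      tract <- c(dr$start, dr$end)
    }
    list(donor = gid, dr = dr, div = div, tract = tract, cut_info = cut_info)
  }
  sel <- NULL
  for (gid in sample(avail[ok])) {
    sel <- try_tract(gid)
    if (!is.null(sel)) break
  }
  if (is.null(sel)) stop("no donor with free margins for event class ",
                         spec$class, " with span ", spec$span)
  donor <- sel$donor
  dr <- sel$dr
  div <- sel$div
  tract <- sel$tract
  cut_info <- sel$cut_info
  dcoding <- .read_coding(sim$ann$genome, dr$chrom, div, dr$strand)

  # assemble the copy region in the donor-orientation frame
  chrom_seq <- sim$ann$genome[[dr$chrom]]
  feats_rel <- NULL  # type, start, end relative to region, donor-frame
  copy_strand_plus <- dr$strand
  if (spec$class == "retro") {
    region_plus <- paste0(dcoding, strrep("A", 12))
    L_region <- nchar(region_plus)
    L_tract <- nchar(dcoding)
    tract_rel <- c(0, L_tract)
    feats_rel <- data.frame(type = c("exon", "CDS"), start = 0,
                            end = nchar(dcoding))
    copy_strand_plus <- "+"
  } else {
    tract_seq <- as.character(Biostrings::subseq(chrom_seq, tract[1] + 1,
                                                 tract[2]))
    div_in <- div[div$start >= tract[1] & div$start < tract[2], , drop = FALSE]
    div_in$end <- pmin(div_in$end, tract[2])
    fr <- data.frame(type = "both", start = div_in$start - tract[1],
                     end = div_in$end - tract[1])
    if (spec$class == "chimeric") {
      novel_intron <- .random_dna(sample(500:1500, 1))
      n_nov <- sample(50:150, 1)
      novel_exon <- paste0(.codon_string(.random_codons(n_nov)), "TAA")
      region_plus <- paste0(tract_seq, novel_intron, novel_exon)
      fr <- rbind(fr, data.frame(type = "both",
                                 start = nchar(tract_seq) + nchar(novel_intron),
                                 end = nchar(region_plus)))
    } else {
      region_plus <- tract_seq
    }
    L_region <- nchar(region_plus)
    L_tract <- nchar(tract_seq)
    tract_rel <- c(0, L_tract)
    feats_rel <- data.frame(type = rep(c("exon", "CDS"), each = nrow(fr)),
                            start = rep(fr$start, 2), end = rep(fr$end, 2))
  }

  # register the donor tract up front so the insertion-site search (and
  # any later event) cannot land inside it
  event_id <- sprintf("T%03d", sum(sim$tracts$locus == "donor") + 1)
  sim$tracts <- rbind(sim$tracts,
                      data.frame(event_id = event_id, locus = "donor",
                                 chrom = dr$chrom, start = tract[1],
                                 end = tract[2], stringsAsFactors = FALSE))

  inverse <- identical(spec$orientation, "inverse")
  if (inverse) {
    region <- .revcomp_chr(region_plus)
    feats_rel <- data.frame(type = feats_rel$type,
                            start = L_region - feats_rel$end,
                            end = L_region - feats_rel$start)
    tract_rel <- c(L_region - tract_rel[2], L_region - tract_rel[1])
    copy_strand <- if (copy_strand_plus == "+") "-" else "+"
  } else {
    region <- region_plus
    copy_strand <- copy_strand_plus
  }

  # insertion target
  if (spec$location == "intra") {
    target_chrom <- dr$chrom
    dist <- if (!is.null(spec$distance) && !is.na(spec$distance)) {
      spec$distance
    } else round(exp(runif(1, log(5000), log(500000))))
    desired <- if (runif(1) < 0.5) tract[2] + dist else tract[1] - dist - L_region
    p <- .find_insertion_site(sim, target_chrom, L_region, desired)
  } else {
    target_chrom <- sample(setdiff(names(sim$ann$genome), dr$chrom), 1)
    p <- .find_insertion_site(sim, target_chrom, L_region)
  }
  if (is.na(p)) stop("no insertion site found on ", target_chrom)
  p <- round(p)

  # insert and shift
  sim$ann$genome[[target_chrom]] <- Biostrings::xscat(
    Biostrings::subseq(sim$ann$genome[[target_chrom]], 1, p),
    Biostrings::DNAString(region),
    Biostrings::subseq(sim$ann$genome[[target_chrom]], p + 1))
  names(sim$ann$genome) <- names(sim$ann$genome)  # xscat drops nothing here
  sim <- .shift_coords(sim, target_chrom, p, L_region)
  dtr <- sim$tracts[sim$tracts$event_id == event_id &
                      sim$tracts$locus == "donor", ]
  tract <- c(dtr$start, dtr$end)  # re-read: may have been shifted

  # register the copy gene
  copy_id <- paste0(donor, "d")
  ctx <- paste0(copy_id, ".t1")
  cf <- data.frame(gene_id = copy_id, tx_id = ctx, type = feats_rel$type,
                   start = p + feats_rel$start, end = p + feats_rel$end,
                   stringsAsFactors = FALSE)
  cf <- cf[order(cf$type, cf$start), , drop = FALSE]
  sim$ann$features <- rbind(sim$ann$features, cf)
  sim$ann$genes <- rbind(sim$ann$genes, data.frame(
    gene_id = copy_id, chrom = target_chrom, strand = copy_strand,
    start = min(cf$start), end = max(cf$end), located = TRUE,
    stringsAsFactors = FALSE))

  # partial: terminate the copy ORF with a stop codon at the truncation
  civ <- .cds_iv(sim$ann$features, ctx)
  ccoding <- .read_coding(sim$ann$genome, target_chrom, civ, copy_strand)
  if (spec$class == "partial") {
    ccoding <- paste0(substr(ccoding, 1, nchar(ccoding) - 3), "TAA")
  }

  # comparable coding region (copy vs donor), stop-free
  comp_len <- switch(spec$class,
                     complete = nchar(dcoding) - 3,
                     retro = nchar(dcoding) - 3,
                     partial = nchar(ccoding) - 3,
                     chimeric = cut_info$coding)
  donor_region <- substr(dcoding, 1, comp_len)
  copy_region <- substr(ccoding, 1, comp_len)

  res <- mutate_to_target_ks(donor_region, copy_region, spec$ks)
  copy_region <- res$cds
  conv <- NULL
  if (!is.null(spec$conversion_len) && !is.na(spec$conversion_len) &&
      spec$conversion_len > 0) {
    clen <- min(spec$conversion_len, comp_len)
    t0 <- sample.int(comp_len - clen + 1, 1) - 1
    copy_region <- apply_gene_conversion_tract(donor_region, copy_region,
                                               c(t0, t0 + clen))
    conv <- c(t0, t0 + clen)
  }
  ccoding <- paste0(copy_region, substr(ccoding, comp_len + 1,
                                        nchar(ccoding)))
  sim$ann$genome <- .write_coding(sim$ann$genome, target_chrom, civ,
                                  copy_strand, ccoding)

  # flank divergence over the noncoding part of the copy tract
  tract_copy <- c(p + tract_rel[1], p + tract_rel[2])
  if (spec$class != "retro" && cfg$flank_divergence > 0) {
    pos <- seq(tract_copy[1] + 1, tract_copy[2])
    incds <- unlist(lapply(seq_len(nrow(civ)), function(i) {
      seq(civ$start[i] + 1, civ$end[i])
    }))
    pos <- setdiff(pos, incds)
    hit <- pos[runif(length(pos)) < cfg$flank_divergence]
    if (length(hit) > 0) {
      x <- sim$ann$genome[[target_chrom]]
      old <- strsplit(as.character(Biostrings::subseq(
        x, tract_copy[1] + 1, tract_copy[2])), "")[[1]][hit - tract_copy[1]]
      bases <- c("A", "C", "G", "T")
      shift <- sample(1:3, length(hit), replace = TRUE)
      new <- bases[(match(old, bases) - 1 + shift) %% 4 + 1]
      valid <- !is.na(new)
      sim$ann$genome[[target_chrom]] <- Biostrings::replaceLetterAt(
        x, hit[valid], paste(new[valid], collapse = ""))
    }
  }

  # realized Ks on the final planted copies
  tab <- ng86_tables()
  civ2 <- .cds_iv(sim$ann$features, ctx)
  final_copy <- .read_coding(sim$ann$genome, target_chrom, civ2, copy_strand)
  est <- ng86_from_indices(
    unname(tab$idx_of[split_codons(donor_region)]),
    unname(tab$idx_of[split_codons(substr(final_copy, 1, comp_len))]), tab)

  sim$tracts <- rbind(sim$tracts,
                      data.frame(event_id = event_id, locus = "copy",
                                 chrom = target_chrom,
                                 start = tract_copy[1], end = tract_copy[2],
                                 stringsAsFactors = FALSE))
  truth_row <- data.frame(
    event_id = event_id, donor = donor, copy = copy_id,
    class = spec$class,
    mechanism = if (spec$class == "retro") "RNA" else "DNA",
    location = if (spec$location == "intra") "intrachromosomal"
               else "interchromosomal",
    orientation = if (spec$location == "intra") {
      if (dr$strand == copy_strand) "direct" else "inverse"
    } else NA_character_,
    span = min(tract[2] - tract[1], tract_copy[2] - tract_copy[1]),
    ks = est$ks,
    conversion = !is.null(conv),
    stringsAsFactors = FALSE)
  sim$truth <- rbind(sim$truth, truth_row)
  sim$used <- c(sim$used, donor, copy_id)
  sim
}

#' Final truth table of a simulation
#'
#' Adds the realized inter-tract distance (intrachromosomal events) from
#' the current, post-insertion coordinates.
#'
#' @param sim A `"duplication_sim"` with planted events.
#' @return The truth data.frame with a `distance` column.
#' @export
truth_table <- function(sim) {
  tr <- sim$truth
  if (is.null(tr)) return(NULL)
  tr$distance <- NA_real_
  for (i in seq_len(nrow(tr))) {
    tt <- sim$tracts[sim$tracts$event_id == tr$event_id[i], ]
    if (tr$location[i] == "intrachromosomal") {
      a <- tt[tt$locus == "donor", ]
      b <- tt[tt$locus == "copy", ]
      tr$distance[i] <- max(0, b$start - a$end, a$start - b$end)
    }
  }
  tr
}

#' Simulate a whole duplication study
#'
#' Builds a base genome plus outgroup and plants a grid of duplication
#' events covering class x location x orientation, with target Ks values
#' spread uniformly over `[0, ks_max]` (including exact zero).
#'
#' @param n_events Number of planted events.
#' @param seed Integer seed (drives the whole simulation).
#' @param config A [simulation_config()], or `NULL` for the default
#'   configuration with the background gene count scaled to the number of
#'   planted events.
#' @param ks_max Upper end of the planted Ks range.
#' @param class_weights Named weights for complete/partial/chimeric/retro
#'   allocation (defaults approximate an 83/13/4 structural split among
#'   DNA-mediated events plus an 11 percent retrogene fraction).
#' @param conversion_frac Fraction of events receiving a 300-bp
#'   gene-conversion tract.
#' @return A `"duplication_sim"` with `truth` filled and a `centromeres`
#'   element (synthetic mid-chromosome centromeres).
#' @export
simulate_duplication_study <- function(n_events = 60, seed = 1,
                                       config = NULL,
                                       ks_max = 0.1,
                                       class_weights = c(complete = 0.72,
                                                         partial = 0.11,
                                                         chimeric = 0.05,
                                                         retro = 0.12),
                                       conversion_frac = 0.1) {
  if (is.null(config)) {
    # enough background genes that every event can take up residence
    # outside the linked-set adjacency window of every other event
    config <- simulation_config()
    config$genes_per_chrom <- max(config$genes_per_chrom,
                                  ceiling(5 * n_events / config$n_chrom))
  }
  sim <- simulate_genome(config, seed)
  classes <- rep(names(class_weights),
                 times = round(class_weights / sum(class_weights) * n_events))
  classes <- c(classes, rep("complete", max(0, n_events - length(classes))))
  classes <- classes[seq_len(n_events)]
  locs <- rep(c("intra", "inter"), length.out = n_events)
  # retrogenes insert at random genomic locations, mostly elsewhere
  locs[classes == "retro"] <- ifelse(runif(sum(classes == "retro")) < 0.8,
                                     "inter", "intra")
  # orientation cycles at twice the location period so the (location,
  # orientation) combinations are all visited rather than confounded
  oris <- rep(rep(c("direct", "inverse"), each = 2), length.out = n_events)
  # targets stop one first-passage overshoot step short of ks_max so every
  # realized Ks stays within the youth filter (one synonymous substitution
  # moves Ks by roughly 1/S, about 0.004 on the shortest CDS)
  ks <- seq(0, ks_max - 0.006, length.out = n_events)
  ord <- sample(n_events)
  conv <- runif(n_events) < conversion_frac & ks[ord] >= 0.03
  for (i in seq_len(n_events)) {
    spec <- list(class = classes[i], location = locs[i],
                 orientation = oris[i], ks = ks[ord[i]],
                 span = round(runif(1, 30000, 100000)),
                 conversion_len = if (conv[i]) 300 else NA)
    sim <- plant_duplication_event(sim, spec)
  }
  cen <- do.call(rbind, lapply(names(sim$ann$genome), function(ch) {
    len <- length(sim$ann$genome[[ch]])
    mid <- floor(len / 2)
    data.frame(chrom = ch, centromere_start = max(0, mid - 50000),
               centromere_end = min(len, mid + 50000),
               stringsAsFactors = FALSE)
  }))
  sim$centromeres <- cen
  sim
}

#' Simulate an outgroup-anchored triplet alignment directly
#'
#' Generates the three aligned rows (paralog 1, paralog 2, outgroup) used
#' by the gene-conversion permutation test: an ancestral sequence is
#' mutated independently along each paralog lineage (total pairwise
#' divergence `pair_div`) and along the outgroup lineage (`outgroup_div`
#' from the ancestor); an optional conversion tract then homogenizes
#' paralog 2 to paralog 1. No indels are introduced, so the rows are the
#' alignment.
#'
#' @param len Sequence length (nt).
#' @param pair_div Expected proportion of sites differing between the
#'   paralogs (before conversion).
#' @param outgroup_div Expected proportion of sites at which the outgroup
#'   differs from the paralogs' ancestor.
#' @param tract `c(start, end)` (0-based half-open) conversion tract in
#'   paralog 2, or `NULL` for a negative (no-conversion) replicate.
#' @return A `"triplet_alignment"` character vector of three rows.
#' @export
simulate_conversion_triplet <- function(len, pair_div = 0.03,
                                        outgroup_div = 0.1, tract = NULL) {
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, len, replace = TRUE)
  mut <- function(x, p) {
    hit <- runif(len) < p
    shift <- sample(1:3, sum(hit), replace = TRUE)
    x[hit] <- bases[(match(x[hit], bases) - 1 + shift) %% 4 + 1]
    x
  }
  p1 <- mut(anc, pair_div / 2)
  p2 <- mut(anc, pair_div / 2)
  og <- mut(anc, outgroup_div)
  if (!is.null(tract)) {
    idx <- seq(tract[1] + 1, tract[2])
    p2[idx] <- p1[idx]
  }
  structure(c(paste(p1, collapse = ""), paste(p2, collapse = ""),
              paste(og, collapse = "")),
            class = "triplet_alignment")
}

#' Write simulation outputs to disk
#'
#' Emits the ingroup and outgroup genomes (FASTA) and annotations (GFF3),
#' the truth TSV, the synthetic centromere table, and a key-value echo of
#' the configuration.
#'
#' @param sim A `"duplication_sim"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$ann$genome, file.path(dir, "genome.fa"))
  write_gff3(sim$ann, file.path(dir, "genome.gff3"))
  Biostrings::writeXStringSet(sim$outgroup$genome,
                              file.path(dir, "outgroup.fa"))
  write_gff3(sim$outgroup, file.path(dir, "outgroup.gff3"))
  tr <- truth_table(sim)
  if (!is.null(tr)) {
    write.table(tr, file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(sim$centromeres)) {
    write.table(sim$centromeres, file.path(dir, "centromeres.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cfg <- sim$config
  writeLines(c(paste0("seed: ", sim$seed),
               paste0(names(cfg), ": ",
                      vapply(cfg, function(v) paste(v, collapse = ","),
                             character(1)))),
             file.path(dir, "config.yaml"))
  invisible(dir)
}
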