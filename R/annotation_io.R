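#' Read a genome and its gene annotation
#'
#' Loads a genome FASTA and a GFF3 annotation (gene/mRNA/exon/CDS features
#' with `Parent` links) into the package's internal representation. All
#' coordinates are converted from GFF3's 1-based inclusive convention to
#' 0-based half-open intervals at this boundary.
#'
#' @param fasta Path to a (multi-record) genome FASTA file.
#' @param gff3 Path to a GFF3 annotation file.
#' @param placed_regex Chromosome names matching this pattern are considered
#'   assigned to a chromosome; genes on any other sequence (unplaced
#'   scaffolds, supercontigs) are loaded and searched but flagged
#'   `located = FALSE` and excluded from geography statistics.
#' @return An object of class `"annotation"`: a list with
#'   \describe{
#'     \item{genome}{a [Biostrings::DNAStringSet] of chromosome sequences}
#'     \item{genes}{data.frame with one row per gene: `gene_id`, `chrom`,
#'       `strand`, `start`, `end`, `located`}
#'     \item{features}{data.frame of transcript features: `gene_id`, `tx_id`,
#'       `type` (`"exon"`/`"CDS"`), `start`, `end` (0-based half-open)}
#'   }
#' @export
load_genome_and_annotation <- function(fasta, gff3,
                                       placed_regex = "^(chr)?([0-9]+|[XYxy])$") {
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gff <- rtracklayer::readGFF(gff3)
  gff <- as.data.frame(gff, stringsAsFactors = FALSE)
  build_annotation(genome, gff, placed_regex)
}

# Assemble the internal annotation object from a readGFF-style data.frame.
build_annotation <- function(genome, gff, placed_regex = "^(chr)?([0-9]+|[XYxy])$") {
  need <- c("seqid", "type", "start", "end", "strand", "ID", "Parent")
  miss <- setdiff(need, names(gff))
  if (length(miss) > 0) {
    stop("GFF3 lacks required columns: ", paste(miss, collapse = ", "))
  }
  gff$Parent <- vapply(gff$Parent, function(p) {
    if (length(p) == 0 || all(is.na(p))) NA_character_ else as.character(p[[1]])
  }, character(1))
  gff$seqid <- as.character(gff$seqid)
  gff$type <- as.character(gff$type)
  gff$strand <- as.character(gff$strand)
  gff$ID <- as.character(gff$ID)

  gene_rows <- gff[gff$type == "gene", , drop = FALSE]
  mrna_rows <- gff[gff$type == "mRNA", , drop = FALSE]
  part_rows <- gff[gff$type %in% c("exon", "CDS"), , drop = FALSE]
  if (any(is.na(mrna_rows$Parent))) {
    stop("format error: mRNA feature without Parent gene link: ",
         paste(mrna_rows$ID[is.na(mrna_rows$Parent)], collapse = ", "))
  }
  if (any(is.na(part_rows$Parent))) {
    stop("format error: exon/CDS feature without Parent mRNA link")
  }
  tx2gene <- setNames(mrna_rows$Parent, mrna_rows$ID)
  unknown <- setdiff(unique(part_rows$Parent), names(tx2gene))
  if (length(unknown) > 0) {
    stop("format error: exon/CDS with Parent not an mRNA: ",
         paste(unknown, collapse = ", "))
  }

  genes <- data.frame(
    gene_id = gene_rows$ID,
    chrom = gene_rows$seqid,
    strand = gene_rows$strand,
    start = gene_rows$start - 1L,
    end = as.integer(gene_rows$end),
    stringsAsFactors = FALSE
  )
  genes$located <- grepl(placed_regex, genes$chrom)

  features <- data.frame(
    gene_id = unname(tx2gene[part_rows$Parent]),
    tx_id = part_rows$Parent,
    type = part_rows$type,
    start = part_rows$start - 1L,
    end = as.integer(part_rows$end),
    stringsAsFactors = FALSE
  )
  features <- features[order(features$gene_id, features$tx_id,
                             features$type, features$start), , drop = FALSE]
  rownames(features) <- NULL

  # coordinate sanity: every feature on an existing chromosome, within bounds
  chrom_len <- setNames(Biostrings::width(genome), names(genome))
  fchrom <- genes$chrom[match(features$gene_id, genes$gene_id)]
  bad <- is.na(chrom_len[fchrom]) | features$end > chrom_len[fchrom] |
    features$start < 0
  if (any(bad)) {
    i <- which(bad)[1]
    stop("coordinate error: ", features$type[i], " of transcript ",
         features$tx_id[i], " at [", features$start[i], ",", features$end[i],
         ") exceeds chromosome ", fchrom[i])
  }

  structure(list(genome = genome, genes = genes, features = features),
            class = "annotation")
}

#' @export
print.annotation <- function(x, ...) {
  cat("<annotation> ", length(x$genome), " sequence(s), ",
      nrow(x$genes), " gene(s), ",
      length(unique(x$features$tx_id)), " transcript(s)\n", sep = "")
  invisible(x)
}

# CDS intervals of one transcript, sorted by genomic start.
cds_intervals <- function(ann, tx_id) {
  f <- ann$features
  f[f$tx_id == tx_id & f$type == "CDS", c("start", "end"), drop = FALSE]
}

#' Spliced CDS sequence of a transcript
#'
#' Concatenates the CDS intervals of a transcript in genomic order and
#' reverse-complements for minus-strand genes, yielding the coding sequence
#' 5' to 3'.
#'
#' @param ann An `"annotation"` object.
#' @param tx_id Transcript identifier.
#' @return A [Biostrings::DNAString] of the coding sequence.
#' @export
cds_sequence <- function(ann, tx_id) {
  f <- ann$features
  gene_id <- f$gene_id[f$tx_id == tx_id][1]
  if (is.na(gene_id)) stop("unknown transcript: ", tx_id)
  g <- ann$genes[ann$genes$gene_id == gene_id, ]
  iv <- cds_intervals(ann, tx_id)
  iv <- iv[order(iv$start), , drop = FALSE]
  chrom <- ann$genome[[g$chrom]]
  parts <- lapply(seq_len(nrow(iv)), function(i) {
    Biostrings::subseq(chrom, iv$start[i] + 1L, iv$end[i])
  })
  s <- do.call(Biostrings::xscat, parts)
  if (g$strand == "-") s <- Biostrings::reverseComplement(s)
  s
}

#' Select one canonical transcript per gene
#'
#' For every gene, picks the transcript with the largest summed CDS length
#' (ties broken by lexicographically smallest transcript id) and attaches
#' the translated protein. Genes whose canonical CDS contains an internal
#' stop codon, is not a multiple of 3, or is empty are flagged `excluded`
#' with a warning and skipped by the downstream similarity search.
#'
#' @param ann An `"annotation"` object.
#' @return The annotation with `genes` gaining columns `canonical_tx`,
#'   `cds_len`, `coding_start`, `coding_end` (the coding extent: first CDS
#'   start to last CDS end), `protein` and `excluded`.
#' @export
select_canonical_transcripts <- function(ann) {
  cds <- ann$features[ann$features$type == "CDS", , drop = FALSE]
  len_by_tx <- tapply(cds$end - cds$start, cds$tx_id, sum)
  gene_by_tx <- cds$gene_id[match(names(len_by_tx), cds$tx_id)]

  genes <- ann$genes
  genes$canonical_tx <- NA_character_
  genes$cds_len <- NA_integer_
  genes$coding_start <- NA_integer_
  genes$coding_end <- NA_integer_
  genes$protein <- NA_character_
  genes$excluded <- FALSE

  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    txs <- names(len_by_tx)[gene_by_tx == gid]
    if (length(txs) == 0) {
      genes$excluded[i] <- TRUE
      warning("gene ", gid, " has no transcript with CDS; excluded")
      next
    }
    lens <- len_by_tx[txs]
    best <- txs[lens == max(lens)]
    tx <- sort(best)[1]
    genes$canonical_tx[i] <- tx
    genes$cds_len[i] <- as.integer(len_by_tx[tx])
    iv <- cds_intervals(ann, tx)
    genes$coding_start[i] <- min(iv$start)
    genes$coding_end[i] <- max(iv$end)
    s <- cds_sequence(ann, tx)
    if (length(s) %% 3 != 0) {
      genes$excluded[i] <- TRUE
      warning("gene ", gid, ": canonical CDS length not a multiple of 3; excluded")
      next
    }
    aa <- as.character(suppressWarnings(
      Biostrings::translate(s, if.fuzzy.codon = "X")))
    body <- sub("\\*$", "", aa)
    if (grepl("\\*", body)) {
      genes$excluded[i] <- TRUE
      warning("gene ", gid, ": internal stop codon in canonical CDS; excluded")
      next
    }
    genes$protein[i] <- body
  }
  ann$genes <- genes
  ann
}

#' Write an annotation back to GFF3
#'
#' Emits gene/mRNA/exon/CDS features with `ID`/`Parent` links, converting the
#' internal 0-based half-open intervals back to GFF3 1-based inclusive
#' coordinates. Re-reading the file reproduces identical internal intervals.
#'
#' @param ann An `"annotation"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path) {
  g <- ann$genes
  f <- ann$features
  tx <- unique(f[, c("gene_id", "tx_id")])
  tx_rng <- do.call(rbind, lapply(seq_len(nrow(tx)), function(i) {
    sub <- f[f$tx_id == tx$tx_id[i], ]
    data.frame(start = min(sub$start), end = max(sub$end))
  }))
  gi <- match(tx$gene_id, g$gene_id)
  lines <- c("##gff-version 3")
  esc <- function(x) x  # ids are plain [A-Za-z0-9_.]
  fmt <- function(chrom, type, start, end, strand, attrs) {
    paste(chrom, "dupliscan", type, start + 1L, end, ".", strand, ".", attrs,
          sep = "\t")
  }
  for (i in seq_len(nrow(g))) {
    lines <- c(lines, fmt(g$chrom[i], "gene", g$start[i], g$end[i], g$strand[i],
                          paste0("ID=", esc(g$gene_id[i]))))
    txi <- which(tx$gene_id == g$gene_id[i])
    for (j in txi) {
      lines <- c(lines, fmt(g$chrom[i], "mRNA", tx_rng$start[j], tx_rng$end[j],
                            g$strand[i],
                            paste0("ID=", tx$tx_id[j], ";Parent=", g$gene_id[i])))
      sub <- f[f$tx_id == tx$tx_id[j], ]
      for (r in seq_len(nrow(sub))) {
        lines <- c(lines, fmt(g$chrom[i], sub$type[r], sub$start[r], sub$end[r],
                              g$strand[i], paste0("Parent=", tx$tx_id[j])))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write the canonical-transcript table
#'
#' @param ann An annotation after [select_canonical_transcripts()].
#' @param path Output TSV path (`gene_id`, `transcript_id`, `cds_len`).
#' @return `path`, invisibly.
#' @export
write_canonical_table <- function(ann, path) {
  g <- ann$genes
  out <- data.frame(gene_id = g$gene_id, transcript_id = g$canonical_tx,
                    cds_len = g$cds_len)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Proteins of non-excluded genes as a named character vector.
searchable_proteins <- function(ann) {
  g <- ann$genes[!ann$genes$excluded & !is.na(ann$genes$protein), ]
  setNames(g$protein, g$gene_id)
}
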