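# Shared fixture builders. Everything is generated in code; no stored data.

# A hand-built annotation: explicit sequences and feature tables, for tests
# that need exact control over coordinates.
make_annotation <- function(seqs, genes, features) {
  structure(list(genome = Biostrings::DNAStringSet(seqs),
                 genes = genes, features = features),
            class = "annotation")
}

# random stop-free coding sequence (ATG ... TAA), length in codons
random_cds <- function(n_codons) {
  tab <- dupliscan:::ng86_tables()
  body <- sample(which(!tab$is_stop), n_codons - 2, replace = TRUE)
  paste0("ATG", paste(tab$codons[body], collapse = ""), "TAA")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein <- function(n) {
  paste(sample(setdiff(unique(Biostrings::GENETIC_CODE), "*"), n,
               replace = TRUE), collapse = "")
}

# mutate a protein to approximately the given identity, optionally with a
# small indel, for similarity-search tests
mutate_protein <- function(p, identity, indel = FALSE) {
  aas <- setdiff(unique(Biostrings::GENETIC_CODE), "*")
  x <- strsplit(p, "")[[1]]
  hit <- runif(length(x)) > identity
  x[hit] <- sample(aas, sum(hit), replace = TRUE)
  if (indel && length(x) > 60) {
    at <- sample(20:(length(x) - 40), 1)
    x <- append(x[-(at:(at + 2))], sample(aas, 2), after = at)
  }
  paste(x, collapse = "")
}

# exact permutation p-value for the max-match-run statistic by direct
# enumeration over all distinct arrangements of the condensed match vector
exact_maxrun_p <- function(matches, obs) {
  L <- length(matches)
  m <- sum(matches)
  arrangements <- combn(L, m)
  ge <- apply(arrangements, 2, function(posn) {
    v <- rep(FALSE, L)
    v[posn] <- TRUE
    dupliscan:::.max_true_run(v) >= obs
  })
  mean(ge)
}

# a small one-gene annotation whose gene structure is fully explicit:
# two exons of 30 nt each separated by a 40 nt intron, on the given strand
one_gene_annotation <- function(strand = "+", chrom_len = 400) {
  cds <- random_cds(20)  # 60 nt
  exon1 <- substr(cds, 1, 30)
  exon2 <- substr(cds, 31, 60)
  left <- random_dna(100)
  intron <- random_dna(40)
  right <- random_dna(chrom_len - 100 - 60 - 40)
  region <- paste0(exon1, intron, exon2)
  if (strand == "-") {
    region <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(region)))
  }
  seqs <- c(chr1 = paste0(left, region, right))
  iv <- if (strand == "+") {
    rbind(c(100, 130), c(170, 200))
  } else {
    rbind(c(100, 130), c(170, 200))  # mirrored layout is symmetric here
  }
  genes <- data.frame(gene_id = "gA", chrom = "chr1", strand = strand,
                      start = 100, end = 200, located = TRUE,
                      stringsAsFactors = FALSE)
  features <- data.frame(gene_id = "gA", tx_id = "gA.t1",
                         type = rep(c("exon", "CDS"), each = 2),
                         start = rep(iv[, 1], 2), end = rep(iv[, 2], 2),
                         stringsAsFactors = FALSE)
  list(ann = make_annotation(seqs, genes, features), cds = cds)
}
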