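# Karlin-Altschul parameters for gapped BLOSUM62 with gap open 11 / extend 1
# (the standard published constants for this scoring system).
.KA_LAMBDA <- 0.267
.KA_K <- 0.041

# Smith-Waterman score and alignment summary for one protein pair,
# BLOSUM62 / affine gaps (open 11, extend 1). Used both by the seeded
# search below (on candidate pairs) and directly by brute-force test
# oracles that loop over all pairs.
sw_align_proteins <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1
  )
  alen <- nchar(as.character(Biostrings::alignedPattern(aln)))
  list(score = Biostrings::score(aln),
       nmatch = Biostrings::nmatch(aln),
       length = alen)
}

# Karlin-Altschul expectation for a local alignment score given query
# length m and total database length n.
ka_expect <- function(score, m, n) {
  bits <- (.KA_LAMBDA * score - log(.KA_K)) / log(2)
  as.numeric(m) * as.numeric(n) * 2^(-bits)
}

#' All-against-all protein similarity search
#'
#' A seeded local-alignment search over a set of proteins: exact word seeds
#' (default length 4) shared by two proteins are grouped by alignment
#' diagonal, and pairs with at least two seeds on nearby diagonals (a
#' two-hit rule) are scored by full Smith-Waterman dynamic programming with
#' BLOSUM62 and affine gaps. An expectation value is computed from the raw
#' score, the query length and the total database length with the standard
#' Karlin-Altschul formula. A hit is reported for every unordered pair whose
#' best local alignment passes both the expectation and the percent-identity
#' threshold; percent identity is matches over all alignment columns,
#' including gap columns.
#'
#' @param proteins Named character vector of amino-acid sequences (names are
#'   gene ids).
#' @param min_identity Minimum percent identity (0-100) of the local
#'   alignment.
#' @param max_expect Maximum expectation value.
#' @param word_size Seed word length.
#' @param two_hit_dist Maximum distance (residues) between two same-diagonal
#'   seeds for a pair to become an alignment candidate.
#' @return A data.frame with one row per passing unordered pair:
#'   `query`, `subject` (query < subject lexicographically), `pident`,
#'   `length` (alignment columns), `evalue`, `bitscore`, `score`.
#' @export
protein_similarity_search <- function(proteins, min_identity = 40,
                                      max_expect = 1e-10, word_size = 4,
                                      two_hit_dist = 40) {
  stopifnot(length(proteins) > 0, !is.null(names(proteins)))
  short <- nchar(proteins) < word_size
  if (any(short)) {
    warning("skipping ", sum(short), " protein(s) shorter than the seed word")
    proteins <- proteins[!short]
  }
  n_prot <- length(proteins)
  db_len <- sum(nchar(proteins))
  empty <- data.frame(query = character(), subject = character(),
                      pident = numeric(), length = integer(),
                      evalue = numeric(), bitscore = numeric(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (n_prot < 2) return(empty)

  # word occurrence table: (word, protein index, position)
  occ <- data.table::rbindlist(lapply(seq_len(n_prot), function(i) {
    s <- proteins[[i]]
    np <- nchar(s) - word_size + 1L
    data.table::data.table(
      word = substring(s, seq_len(np), seq_len(np) + word_size - 1L),
      prot = i, pos = seq_len(np))
  }))
  # seed hits between different proteins sharing a word
  hits <- merge(occ, occ, by = "word", allow.cartesian = TRUE,
                suffixes = c("", ".y"))
  hits <- hits[hits$prot < hits$prot.y, ]
  if (nrow(hits) == 0) return(empty)
  hits$diag <- hits$pos - hits$pos.y
  # two-hit rule: two non-overlapping seeds on the same diagonal within
  # two_hit_dist residues of each other (small diagonal shifts from indels
  # are tolerated because any one gap-free segment suffices)
  pos <- prot <- prot.y <- NULL  # appease R CMD check
  cand <- hits[, {
    ok <- FALSE
    if (length(pos) >= 2) {
      dd <- outer(pos, pos, "-")
      ok <- any(dd >= word_size & dd <= two_hit_dist)
    }
    list(ok = ok)
  }, by = list(p1 = prot, p2 = prot.y, dg = diag)]
  cand <- unique(cand[cand$ok, c("p1", "p2")])
  if (nrow(cand) == 0) return(empty)

  rows <- lapply(seq_len(nrow(cand)), function(k) {
    ij <- c(cand$p1[k], cand$p2[k])
    a <- proteins[[ij[1]]]
    b <- proteins[[ij[2]]]
    # query = lexicographically smaller gene id, for determinism
    nm <- sort(c(names(proteins)[ij[1]], names(proteins)[ij[2]]))
    qlen <- nchar(proteins[[nm[1]]])
    # cheap score-only pass; the full alignment (for identity and length)
    # is computed only when the expectation threshold is met
    score <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
    ev <- ka_expect(score, qlen, db_len)
    if (ev > max_expect) return(NULL)
    sw <- sw_align_proteins(a, b)
    pid <- 100 * sw$nmatch / sw$length
    data.frame(query = nm[1], subject = nm[2], pident = pid,
               length = sw$length, evalue = ev,
               bitscore = (.KA_LAMBDA * sw$score - log(.KA_K)) / log(2),
               score = sw$score, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(empty)
  res <- res[res$evalue <= max_expect & res$pident >= min_identity, ,
             drop = FALSE]
  res <- res[order(res$query, res$subject), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read or write a similarity hit table
#'
#' The TSV format (`query`, `subject`, `pident`, `length`, `evalue`,
#' `bitscore`) lets an external search engine's output be substituted for
#' the internal one.
#'
#' @param path TSV path.
#' @param hits Hit data.frame as returned by [protein_similarity_search()].
#' @return `read_hit_table`: the hit data.frame. `write_hit_table`: `path`.
#' @export
read_hit_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_hit_table
#' @export
write_hit_table <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Single-link clustering of similarity hits into gene families
#'
#' Families are the connected components of the hit graph: if gene A hits
#' genes B and C, then A, B and C join one family regardless of the B-C
#' similarity. Genes without hits form singleton families.
#'
#' @param hits Threshold-filtered hit data.frame (`query`, `subject`).
#' @param all_genes Optional character vector of all searched gene ids, so
#'   that hit-less genes appear as singletons.
#' @return data.frame (`family_id`, `gene_id`); family ids are assigned in
#'   order of each family's lexicographically smallest member, making the
#'   partition invariant to input order.
#' @export
build_families <- function(hits, all_genes = NULL) {
  genes <- sort(unique(c(hits$query, hits$subject, all_genes)))
  parent <- seq_along(genes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(hits) > 0) {
    qi <- match(hits$query, genes)
    si <- match(hits$subject, genes)
    for (r in seq_len(nrow(hits))) {
      a <- find(qi[r]); b <- find(si[r])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_along(genes), find, integer(1))
  # stable family ids keyed on the smallest member gene id of each component
  comp_min <- tapply(genes, root, min)
  ord <- order(unname(comp_min))
  fam_id <- setNames(sprintf("F%04d", order(ord)), names(comp_min))
  data.frame(family_id = unname(fam_id[as.character(root)]),
             gene_id = genes, stringsAsFactors = FALSE)
}

#' Retain small gene families
#'
#' Keeps families with 2 to `max_members` members for pairing; singletons
#' (no pair to form) and larger families are dropped, with dropped family
#' sizes reported via `message()`.
#'
#' @param families Family table from [build_families()].
#' @param max_members Largest retained family size.
#' @return The filtered family table.
#' @export
filter_family_size <- function(families, max_members = 5) {
  sz <- table(families$family_id)
  drop_big <- names(sz)[sz > max_members]
  drop_single <- names(sz)[sz < 2]
  if (length(drop_big) > 0) {
    message("dropping ", length(drop_big), " famil",
            if (length(drop_big) == 1) "y" else "ies",
            " larger than ", max_members, " members (sizes: ",
            paste(sz[drop_big], collapse = ", "), ")")
  }
  if (length(drop_single) > 0) {
    message("dropping ", length(drop_single), " singleton(s)")
  }
  keep <- !(families$family_id %in% c(drop_big, drop_single))
  out <- families[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
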