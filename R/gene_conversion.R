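# ---- triplet alignment --------------------------------------------------

# Merge two pairwise alignments sharing their first sequence into a
# three-row alignment. aln_ab and aln_ac are character vectors of two
# aligned rows each, whose first rows have identical ungapped sequence.
merge_alignments_by_reference <- function(aln_ab, aln_ac) {
  ref1 <- strsplit(aln_ab[1], "")[[1]]
  ref2 <- strsplit(aln_ac[1], "")[[1]]
  b <- strsplit(aln_ab[2], "")[[1]]
  c_ <- strsplit(aln_ac[2], "")[[1]]
  if (paste(ref1[ref1 != "-"], collapse = "") !=
      paste(ref2[ref2 != "-"], collapse = "")) {
    stop("reference rows of the two alignments differ")
  }
  i <- 1L; j <- 1L
  out_a <- character(0); out_b <- character(0); out_c <- character(0)
  while (i <= length(ref1) || j <= length(ref2)) {
    g1 <- i <= length(ref1) && ref1[i] == "-"
    g2 <- j <= length(ref2) && ref2[j] == "-"
    if (g1) {
      out_a <- c(out_a, "-"); out_b <- c(out_b, b[i]); out_c <- c(out_c, "-")
      i <- i + 1L
    } else if (g2) {
      out_a <- c(out_a, "-"); out_b <- c(out_b, "-"); out_c <- c(out_c, c_[j])
      j <- j + 1L
    } else {
      out_a <- c(out_a, ref1[i]); out_b <- c(out_b, b[i])
      out_c <- c(out_c, c_[j])
      i <- i + 1L; j <- j + 1L
    }
  }
  c(paste(out_a, collapse = ""), paste(out_b, collapse = ""),
    paste(out_c, collapse = ""))
}

#' Outgroup-anchored triplet alignment of a paralog pair
#'
#' Aligns paralog 1 against paralog 2 and against the outgroup ortholog
#' (protein-guided codon alignments in both cases) and composes the two
#' through the shared paralog-1 row into a three-row nucleotide alignment.
#'
#' @param cds1,cds2,cds_out Coding sequences of paralog 1, paralog 2 and the
#'   outgroup ortholog (character or DNAString).
#' @param prot1,prot2,prot_out The corresponding proteins; derived by
#'   translation when omitted.
#' @return Character vector of three aligned rows (paralog1, paralog2,
#'   outgroup), class `"triplet_alignment"`.
#' @export
build_triplet_alignment <- function(cds1, cds2, cds_out,
                                    prot1 = NULL, prot2 = NULL,
                                    prot_out = NULL) {
  tr <- function(cds, prot) {
    if (!is.null(prot)) return(prot)
    sub("\\*$", "", as.character(suppressWarnings(Biostrings::translate(
      Biostrings::DNAString(as.character(cds)), if.fuzzy.codon = "X"))))
  }
  p1 <- tr(cds1, prot1); p2 <- tr(cds2, prot2); po <- tr(cds_out, prot_out)
  to_nt <- function(pa, ca, cb) {
    aln <- codon_align_from_protein(pa, ca, cb)
    c(paste(aln$codons1, collapse = ""), paste(aln$codons2, collapse = ""))
  }
  aln12 <- to_nt(align_protein_pair(p1, p2), cds1, cds2)
  aln1o <- to_nt(align_protein_pair(p1, po), cds1, cds_out)
  structure(merge_alignments_by_reference(aln12, aln1o),
            class = "triplet_alignment")
}

#' Read/write triplet alignments as aligned FASTA
#'
#' @param triplet A `"triplet_alignment"` (three aligned rows).
#' @param path File path.
#' @param ids Sequence names for the three rows.
#' @return `write_triplet_fasta`: `path`; `read_triplet_fasta`: the triplet.
#' @export
write_triplet_fasta <- function(triplet, path,
                                ids = c("paralog1", "paralog2", "outgroup")) {
  writeLines(as.vector(rbind(paste0(">", ids), unclass(triplet))), path)
  invisible(path)
}

#' @rdname write_triplet_fasta
#' @export
read_triplet_fasta <- function(path) {
  x <- readLines(path)
  seq_rows <- x[!startsWith(x, ">")]
  stopifnot(length(seq_rows) == 3)
  structure(seq_rows, class = "triplet_alignment")
}

# ---- permutation test ---------------------------------------------------

#' Detect ectopic gene conversion with a fragment permutation test
#'
#' The alignment is condensed to its polymorphic columns (>= 2 distinct
#' non-gap states among the three rows; columns with a gap in either
#' paralog are not informative for the pair and are skipped). Candidate
#' fragments are the maximal runs of consecutive condensed columns at which
#' the two paralogs carry the same state; a fragment's score is its length
#' in condensed columns (no interior mismatches allowed). The observed
#' maximum score is compared with the null distribution of maximum scores
#' over random permutations of condensed column order, with the add-one
#' p-value estimator p = (1 + #\{perm >= obs\}) / (1 + n_perm). Bonferroni
#' correction across the `n_tests` candidate pairs tested in the family is
#' applied to the global significance call.
#'
#' @param triplet A `"triplet_alignment"` (rows: paralog1, paralog2,
#'   outgroup) or any character vector of three equal-length aligned rows.
#' @param n_perm Number of column-order permutations.
#' @param alpha Significance level applied to the corrected p-value.
#' @param n_tests Number of candidate pairs tested in the family
#'   (Bonferroni divisor).
#' @return A list of class `"conversion_result"`: `fragments` (data.frame
#'   with alignment-column `start`/`end`, condensed `score`, `p_raw`,
#'   `p_corrected`), `p_value` (best corrected p), `significant`,
#'   `n_polymorphic`, `n_perm`.
#' @export
detect_gene_conversion <- function(triplet, n_perm = 10000, alpha = 0.05,
                                   n_tests = 1) {
  rows <- lapply(unclass(triplet), function(r) strsplit(r, "")[[1]])
  stopifnot(length(rows) == 3,
            length(unique(lengths(rows))) == 1)
  m <- do.call(rbind, rows)
  n_states <- apply(m, 2, function(col) length(unique(col[col != "-"])))
  poly <- n_states >= 2 & m[1, ] != "-" & m[2, ] != "-"
  cols <- which(poly)
  empty <- data.frame(start = integer(), end = integer(), score = integer(),
                      p_raw = numeric(), p_corrected = numeric())
  if (length(cols) < 2) {
    return(structure(list(fragments = empty, p_value = 1,
                          significant = FALSE,
                          n_polymorphic = length(cols), n_perm = n_perm),
                     class = "conversion_result"))
  }
  matches <- m[1, cols] == m[2, cols]
  r <- rle(matches)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  frag <- data.frame(ci_start = starts[r$values], ci_end = ends[r$values],
                     score = r$lengths[r$values])
  if (nrow(frag) == 0 || all(!matches)) {
    return(structure(list(fragments = empty, p_value = 1,
                          significant = FALSE,
                          n_polymorphic = length(cols), n_perm = n_perm),
                     class = "conversion_result"))
  }
  null_max <- .perm_max_runs(matches, as.integer(n_perm))
  frag$p_raw <- vapply(frag$score, function(s) {
    (1 + sum(null_max >= s)) / (1 + n_perm)
  }, numeric(1))
  frag$p_corrected <- pmin(1, frag$p_raw * n_tests)
  # report in original alignment coordinates, best first
  out <- data.frame(start = cols[frag$ci_start],
                    end = cols[frag$ci_end] + 1L,  # half-open
                    score = frag$score,
                    p_raw = frag$p_raw, p_corrected = frag$p_corrected)
  out <- out[order(-out$score, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(list(fragments = out, p_value = min(out$p_corrected),
                 significant = min(out$p_corrected) <= alpha,
                 n_polymorphic = length(cols), n_perm = n_perm),
            class = "conversion_result")
}

#' @export
print.conversion_result <- function(x, ...) {
  cat("<conversion_result> ", x$n_polymorphic, " polymorphic columns; p = ",
      format(x$p_value, digits = 3),
      if (x$significant) " (significant)" else "", "\n", sep = "")
  invisible(x)
}

#' Partition events by gene-conversion status
#'
#' @param events Events data.frame with an `event_id` column.
#' @param results Named list of `"conversion_result"` objects keyed by event
#'   id (events missing from the list are treated as untested, e.g. when no
#'   outgroup ortholog was found, and retained in both sets).
#' @return A list with `all` (every event, gaining a `conversion` column
#'   with values `"yes"`, `"no"` or `"untested"`) and `no_conversion`
#'   (events without a positive conversion signature).
#' @export
partition_by_conversion <- function(events, results) {
  status <- vapply(events$event_id, function(id) {
    r <- results[[id]]
    if (is.null(r)) "untested" else if (isTRUE(r$significant)) "yes" else "no"
  }, character(1))
  events$conversion <- unname(status)
  list(all = events,
       no_conversion = events[events$conversion != "yes", , drop = FALSE])
}

#' Write conversion results as TSV
#'
#' @param results Named list of conversion results (by event id).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_conversion_table <- function(results, path) {
  rows <- lapply(names(results), function(id) {
    r <- results[[id]]
    if (nrow(r$fragments) == 0) {
      data.frame(event_id = id, frag_start = NA_integer_,
                 frag_end = NA_integer_, score = NA_integer_,
                 p_raw = 1, p_corrected = 1, significant = FALSE)
    } else {
      data.frame(event_id = id, frag_start = r$fragments$start,
                 frag_end = r$fragments$end, score = r$fragments$score,
                 p_raw = r$fragments$p_raw,
                 p_corrected = r$fragments$p_corrected,
                 significant = r$fragments$p_corrected <= 0.05)
    }
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
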