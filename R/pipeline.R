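#' Pipeline configuration
#'
#' All stage thresholds with their defaults: similarity search identity
#' >= 40 percent and E-value <= 1e-10, families of at most 5 members,
#' youth filter Ks <= 0.1, linked-set window of 1 intervening gene, 200 kb
#' neighborhood flank (auto-widened to 800 kb), 31-mer anchors, 5 kb chain
#' gaps, and a 10,000-permutation conversion test at alpha = 0.05.
#'
#' @param min_identity,max_expect Similarity-search thresholds.
#' @param max_family Largest retained family size.
#' @param ks_max Youth filter (inclusive).
#' @param max_intervening Linked-set neighbor window (genes).
#' @param flank,wide_flank Neighborhood window sizes (bp).
#' @param anchor_k Anchor k-mer size.
#' @param max_chain_gap Maximum chained gap (bp).
#' @param n_perm,alpha Conversion permutation test parameters.
#' @param centromere_bin Bin width (bp) for the centromere-distance
#'   analysis; the 10-Mb default suits genome-scale chromosomes, smaller
#'   bins suit desk-scale simulations.
#' @param seed Root seed for all randomized stages.
#' @return A named list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(min_identity = 40, max_expect = 1e-10,
                            max_family = 5, ks_max = 0.1,
                            max_intervening = 1, flank = 200000,
                            wide_flank = 800000, anchor_k = 31,
                            max_chain_gap = 5000, n_perm = 10000,
                            alpha = 0.05, centromere_bin = 1e7, seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Best-hit outgroup orthologs
#'
#' Finds, for each query gene, the best-scoring outgroup protein by the
#' same seeded similarity search used for the paralog screen.
#'
#' @param ann Ingroup annotation with canonical transcripts selected.
#' @param outgroup_ann Outgroup annotation with canonical transcripts
#'   selected.
#' @param gene_ids Ingroup genes to look up.
#' @param config A [pipeline_config()].
#' @return Named character vector: ingroup gene id -> outgroup gene id
#'   (`NA` when no hit passes the thresholds).
#' @export
find_outgroup_orthologs <- function(ann, outgroup_ann, gene_ids,
                                    config = pipeline_config()) {
  q <- searchable_proteins(ann)
  q <- q[names(q) %in% gene_ids]
  s <- searchable_proteins(outgroup_ann)
  prot <- c(setNames(q, paste0("Q|", names(q))),
            setNames(s, paste0("O|", names(s))))
  hits <- protein_similarity_search(prot, min_identity = config$min_identity,
                                    max_expect = config$max_expect)
  out <- setNames(rep(NA_character_, length(gene_ids)), gene_ids)
  if (nrow(hits) == 0) return(out)
  qs <- ifelse(startsWith(hits$query, "Q|"), hits$query, hits$subject)
  os <- ifelse(startsWith(hits$query, "Q|"), hits$subject, hits$query)
  keep <- startsWith(qs, "Q|") & startsWith(os, "O|")
  if (!any(keep)) return(out)
  d <- data.frame(g = sub("^Q\\|", "", qs[keep]),
                  o = sub("^O\\|", "", os[keep]),
                  score = hits$score[keep], stringsAsFactors = FALSE)
  d <- d[order(d$g, -d$score, d$o), ]
  d <- d[!duplicated(d$g), ]
  out[d$g] <- d$o
  out
}

# conversion testing for a set of events (per member ORF; a linked set is
# significant when any member is)
.test_conversion <- function(events, ann, outgroup_ann, config) {
  orth <- find_outgroup_orthologs(
    ann, outgroup_ann,
    unique(c(events$gene1, events$gene2,
             unlist(strsplit(unlist(strsplit(events$member_pairs, ";")),
                             "|", fixed = TRUE)))),
    config)
  fam_sizes <- table(events$family_id)
  results <- list()
  for (i in seq_len(nrow(events))) {
    n_tests <- as.integer(fam_sizes[events$family_id[i]])
    members <- strsplit(strsplit(events$member_pairs[i], ";")[[1]], "|",
                        fixed = TRUE)
    best <- NULL
    for (mp in members) {
      og <- orth[mp[1]]
      if (is.na(og)) og <- orth[mp[2]]
      if (is.na(og)) next
      cds <- function(a, gid) {
        as.character(cds_sequence(a, a$genes$canonical_tx[
          a$genes$gene_id == gid]))
      }
      trip <- build_triplet_alignment(cds(ann, mp[1]), cds(ann, mp[2]),
                                      cds(outgroup_ann, og))
      r <- detect_gene_conversion(trip, n_perm = config$n_perm,
                                  alpha = config$alpha, n_tests = n_tests)
      if (is.null(best) || r$p_value < best$p_value) best <- r
    }
    if (!is.null(best)) results[[events$event_id[i]]] <- best
  }
  results
}

#' Run the full duplication survey pipeline
#'
#' Stages: canonical-transcript selection, all-against-all protein
#' similarity search, single-link family clustering with the small-family
#' (<= 5 members) filter, codon-level Ks estimation for every family pair,
#' curation (same-location removal, UPGMA shadow removal, linked-set
#' merging), the Ks <= 0.1 youth filter, the gene-conversion screen (when
#' an outgroup is supplied), structural characterization of every event,
#' and the cohort statistics report. Per-stage removal counts are kept and
#' checked against the accounting identity
#' pairs_in = events_out + same_location + shadow + (merged - sets) +
#' ks_filtered.
#'
#' @param ann An `"annotation"` (see [load_genome_and_annotation()]).
#' @param outgroup_ann Optional outgroup annotation for the conversion
#'   screen.
#' @param centromeres Optional centromere table (`chrom`,
#'   `centromere_start`, `centromere_end`).
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory for the events table, statistics
#'   report and stage log.
#' @param hits Optional precomputed similarity hit table (see
#'   [read_hit_table()]), substituting an external search engine's output
#'   for the internal seeded search.
#' @return list: `events` (all events), `no_conversion` (events without a
#'   conversion signature), `stats` (statistics report data.frame),
#'   `counts` (stage accounting), `ann` (annotation with canonical
#'   transcripts), `hits`, `families`.
#' @export
run_pipeline <- function(ann, outgroup_ann = NULL, centromeres = NULL,
                         config = pipeline_config(), output_dir = NULL,
                         hits = NULL) {
  set.seed(config$seed)
  log_lines <- character(0)
  say <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  ann <- suppressWarnings(select_canonical_transcripts(ann))
  if (!is.null(outgroup_ann) && is.null(outgroup_ann$genes$protein)) {
    outgroup_ann <- suppressWarnings(
      select_canonical_transcripts(outgroup_ann))
  }
  prots <- searchable_proteins(ann)
  say("stage annotation: ", nrow(ann$genes), " genes, ", length(prots),
      " searchable proteins")

  if (is.null(hits)) {
    hits <- protein_similarity_search(prots,
                                      min_identity = config$min_identity,
                                      max_expect = config$max_expect)
  } else {
    hits <- hits[hits$evalue <= config$max_expect &
                   hits$pident >= config$min_identity, , drop = FALSE]
  }
  say("stage similarity: ", nrow(hits), " hits")
  fams <- build_families(hits)
  fams <- suppressMessages(filter_family_size(fams, config$max_family))
  say("stage families: ", length(unique(fams$family_id)),
      " families of 2-", config$max_family, " members")

  # all pairwise Ks within retained families
  pair_rows <- list()
  for (fid in unique(fams$family_id)) {
    members <- sort(fams$gene_id[fams$family_id == fid])
    cmb <- combn(members, 2)
    for (j in seq_len(ncol(cmb))) {
      row <- pair_divergence(ann, cmb[1, j], cmb[2, j])
      row$family_id <- fid
      pair_rows[[length(pair_rows) + 1]] <- row
    }
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(gene1 = character(), gene2 = character(), ks = numeric(),
               ka = numeric(), n_codons = integer(),
               family_id = character())
  n_pairs_in <- nrow(pairs)
  say("stage divergence: ", n_pairs_in, " candidate pairs")

  pairs <- remove_same_location_pairs(pairs, ann)
  n_same <- attr(pairs, "n_same_location")
  say("stage curation: ", n_same, " same-location pair(s) removed")
  pairs <- suppressMessages(remove_shadow_pairs(pairs, fams))
  n_shadow <- attr(pairs, "n_shadow")
  say("stage curation: ", n_shadow, " shadow pair(s) removed")

  events <- detect_linked_sets(pairs, ann, config$max_intervening)
  fam_of <- setNames(fams$family_id, fams$gene_id)
  events$family_id <- unname(fam_of[events$gene1])
  n_merged_pairs <- sum(events$n_members[events$n_members > 1])
  n_sets <- sum(events$n_members > 1)
  say("stage curation: ", n_merged_pairs, " pair(s) merged into ", n_sets,
      " linked set(s)")

  defined <- !is.na(events$ks)
  young <- defined & events$ks <= config$ks_max
  n_ks_removed <- sum(events$n_members[!young])
  events <- events[young, , drop = FALSE]
  say("stage youth filter: ", nrow(events), " events with Ks <= ",
      config$ks_max)

  counts <- list(pairs_in = n_pairs_in, same_location = n_same,
                 shadow = n_shadow, merged_pairs = n_merged_pairs,
                 linked_sets = n_sets, ks_filtered = n_ks_removed,
                 events_out = nrow(events))
  balance <- counts$events_out + counts$same_location + counts$shadow +
    (counts$merged_pairs - counts$linked_sets) + counts$ks_filtered
  counts$accounting_ok <- balance == counts$pairs_in
  if (!counts$accounting_ok) {
    warning("filter accounting identity violated: ", balance, " != ",
            counts$pairs_in)
  }

  results <- list()
  if (!is.null(outgroup_ann) && nrow(events) > 0) {
    results <- .test_conversion(events, ann, outgroup_ann, config)
    say("stage conversion: ", sum(vapply(results, function(r) r$significant,
                                         logical(1))),
        " significant of ", length(results), " tested")
  }

  # structural characterization per event (representative pair)
  if (nrow(events) > 0) {
    chr <- lapply(seq_len(nrow(events)), function(i) {
      characterize_event(ann, events$gene1[i], events$gene2[i],
                         flank = config$flank,
                         wide_flank = config$wide_flank,
                         k = config$anchor_k,
                         max_chain_gap = config$max_chain_gap)
    })
    events <- cbind(events, do.call(rbind, chr))
    g <- ann$genes
    i1 <- match(events$gene1, g$gene_id)
    i2 <- match(events$gene2, g$gene_id)
    events$chrom1 <- g$chrom[i1]
    events$chrom2 <- g$chrom[i2]
    events$mid1 <- (g$coding_start[i1] + g$coding_end[i1]) / 2
    events$mid2 <- (g$coding_start[i2] + g$coding_end[i2]) / 2
    events$cohort <- as.character(assign_cohort(events$ks))
    say("stage structure: ", sum(events$aligned), "/", nrow(events),
        " events with delineated tracts")
  }

  parts <- partition_by_conversion(events, results)
  stats <- rbind(
    statistics_report(parts$all, ann, centromeres, variant = "all",
                      centromere_bin = config$centromere_bin),
    statistics_report(parts$no_conversion, ann, centromeres,
                      variant = "no_conversion",
                      centromere_bin = config$centromere_bin),
    statistics_report(parts$all, ann, centromeres,
                      variant = "all_autosomes", autosomes_only = TRUE,
                      centromere_bin = config$centromere_bin))

  out <- list(events = parts$all, no_conversion = parts$no_conversion,
              stats = stats, counts = counts, ann = ann, hits = hits,
              families = fams)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_events_table(parts$all, file.path(output_dir, "events.tsv"))
    write.table(stats, file.path(output_dir, "statistics.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (length(results) > 0) {
      write_conversion_table(results,
                             file.path(output_dir, "conversion.tsv"))
    }
    writeLines(log_lines, file.path(output_dir, "pipeline.log"))
    # config echo for provenance
    writeLines(paste0(names(config), ": ",
                      vapply(config, function(v) paste(v, collapse = ","),
                             character(1))),
               file.path(output_dir, "config.yaml"))
  }
  out
}

#' Write the per-event table
#'
#' One row per duplication event: member genes, Ks and cohort, chromosomal
#' location of the two paralogs, structural class, transcriptional
#' orientation, duplication span, physical distance (intrachromosomal
#' only; empty otherwise), mechanism and conversion flag.
#'
#' @param events Events data.frame from [run_pipeline()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_events_table <- function(events, path) {
  cols <- c("event_id", "gene1", "gene2", "ks", "cohort", "chrom1", "chrom2",
            "location", "class", "orientation", "span", "distance",
            "mechanism", "conversion", "n_members")
  cols <- intersect(cols, names(events))
  out <- events[, cols, drop = FALSE]
  if ("span" %in% names(out)) out$span <- round(out$span)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

# three-cohort contingency test with the collapse rule: when the two older
# cohorts do not differ for the characteristic, the two-cohort comparison
# (K=0 vs 0<K<=0.1) is additionally reported
.cohort_tests <- function(tab, test_name, variant, alpha = 0.05) {
  rows <- list()
  add <- function(test, g) {
    rows[[length(rows) + 1]] <<- data.frame(
      variant = variant, test = test, statistic = g$G, df = g$df, p = g$p,
      n = sum(tab), stringsAsFactors = FALSE)
  }
  ok3 <- sum(colSums(tab) > 0) >= 2 && sum(rowSums(tab) > 0) >= 2
  if (!ok3) return(NULL)
  g3 <- suppressWarnings(g_test_independence(tab))
  add(test_name, g3)
  if (ncol(tab) == 3) {
    old <- tab[, 2:3, drop = FALSE]
    if (sum(colSums(old) > 0) >= 2 && sum(rowSums(old) > 0) >= 2) {
      gold <- suppressWarnings(g_test_independence(old))
      if (!is.na(gold$p) && gold$p > alpha) {
        two <- cbind(tab[, 1], tab[, 2] + tab[, 3])
        if (sum(colSums(two) > 0) >= 2 && sum(rowSums(two) > 0) >= 2) {
          add(paste0(test_name, "_2cohort"),
              suppressWarnings(g_test_independence(two)))
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Cohort-level statistics report
#'
#' Computes the full statistical battery on an event set: cohort counts,
#' the intra/inter x cohort and structural-category x cohort and
#' mechanism x location G-tests of independence (with the two-cohort
#' collapse rule), the direct/inverse orientation goodness-of-fit tests,
#' normalized chromosome frequencies, centromere-distance bins, and the
#' correlation / trend / rank statistics.
#'
#' @param events Events data.frame (needs the columns added by
#'   [run_pipeline()]).
#' @param ann Annotation with canonical transcripts selected.
#' @param centromeres Optional centromere table.
#' @param variant Label recorded in the report (`"all"`,
#'   `"no_conversion"`, ...).
#' @param autosomes_only Restrict to autosomal events and genes.
#' @param centromere_bin Bin width (bp) for the centromere-distance test.
#' @return data.frame: `variant`, `test`, `statistic`, `df`, `p`, `n`.
#' @export
statistics_report <- function(events, ann, centromeres = NULL,
                              variant = "all", autosomes_only = FALSE,
                              centromere_bin = 1e7) {
  rows <- list()
  add <- function(test, statistic, df, p, n) {
    rows[[length(rows) + 1]] <<- data.frame(
      variant = variant, test = test, statistic = statistic, df = df, p = p,
      n = n, stringsAsFactors = FALSE)
  }
  if (is.null(events) || nrow(events) == 0) {
    add("n_events", 0, NA, NA, 0)
    return(do.call(rbind, rows))
  }
  ev <- events
  if (autosomes_only) {
    sex <- grepl("^(chr)?[XY]$", ev$chrom1, ignore.case = TRUE) |
      grepl("^(chr)?[XY]$", ev$chrom2, ignore.case = TRUE)
    ev <- ev[!sex, , drop = FALSE]
  }
  cohorts <- levels(assign_cohort(0))
  ev$cohort <- factor(ev$cohort, levels = cohorts)
  add("n_events", nrow(ev), NA, NA, nrow(ev))
  for (co in cohorts) {
    add(paste0("n_cohort_", co), sum(ev$cohort == co, na.rm = TRUE), NA, NA,
        nrow(ev))
  }

  located <- ev[ev$location %in%
                  c("intrachromosomal", "interchromosomal"), , drop = FALSE]
  # intra/inter by cohort
  tab <- rbind(
    intra = table(located$cohort[located$location == "intrachromosomal"]),
    inter = table(located$cohort[located$location == "interchromosomal"]))
  rows <- c(rows, list(.cohort_tests(tab, "location_by_cohort", variant)))

  # orientation goodness of fit and by cohort
  intra <- located[located$location == "intrachromosomal", , drop = FALSE]
  ori <- table(factor(intra$orientation, levels = c("direct", "inverse")))
  if (sum(ori) > 0) {
    g <- g_test_gof(as.numeric(ori))
    add("orientation_gof", g$G, g$df, g$p, sum(ori))
    otab <- rbind(direct = table(intra$cohort[intra$orientation == "direct"]),
                  inverse = table(intra$cohort[intra$orientation == "inverse"]))
    rows <- c(rows, list(.cohort_tests(otab, "orientation_by_cohort",
                                       variant)))
  }

  # structural categories (DNA-mediated) by cohort
  dna <- located[located$mechanism == "DNA" & !is.na(located$class), ,
                 drop = FALSE]
  if (nrow(dna) > 0) {
    stab <- do.call(rbind, lapply(c("complete", "partial", "chimeric"),
                                  function(cl) table(dna$cohort[dna$class == cl])))
    rownames(stab) <- c("complete", "partial", "chimeric")
    rows <- c(rows, list(.cohort_tests(stab, "structure_by_cohort", variant)))
  }

  # mechanism x location
  mtab <- rbind(
    DNA = c(intra = sum(located$mechanism == "DNA" &
                          located$location == "intrachromosomal"),
            inter = sum(located$mechanism == "DNA" &
                          located$location == "interchromosomal")),
    RNA = c(intra = sum(located$mechanism == "RNA" &
                          located$location == "intrachromosomal"),
            inter = sum(located$mechanism == "RNA" &
                          located$location == "interchromosomal")))
  if (all(rowSums(mtab) > 0) && all(colSums(mtab) > 0)) {
    g <- suppressWarnings(g_test_independence(mtab))
    add("mechanism_by_location", g$G, g$df, g$p, sum(mtab))
  }

  # chromosome frequencies normalized by gene density
  g_ann <- ann$genes[ann$genes$located, ]
  genes_per_chrom <- table(g_ann$chrom)
  if (nrow(located) > 0 && length(genes_per_chrom) >= 2) {
    cf <- suppressWarnings(chromosome_duplication_frequencies(
      located, setNames(as.numeric(genes_per_chrom),
                        names(genes_per_chrom)),
      autosomes_only = autosomes_only))
    add("chromosome_frequencies_gof", cf$gof$G, cf$gof$df, cf$gof$p,
        sum(cf$counts))
  }

  # centromere-distance bins
  if (!is.null(centromeres) && nrow(located) > 0) {
    cb <- tryCatch(suppressMessages(
      centromere_distance_bins(located, centromeres, ann,
                               bin = centromere_bin)),
      error = function(e) {
        message("centromere bin test skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(cb)) {
      add("centromere_bins_gof", cb$gof$G, cb$gof$df, cb$gof$p,
          sum(cb$dup_counts))
    }
  }

  # trends and rank statistics
  gl <- g_ann$end - g_ann$start
  ce <- g_ann$coding_end - g_ann$coding_start
  tr <- suppressMessages(trend_and_rank_stats(ev, gl, ce[!is.na(ce)]))
  tr <- cbind(variant = variant, tr)
  rows <- c(rows, list(tr))

  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
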