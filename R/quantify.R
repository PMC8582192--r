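#' Project genome alignments onto discovered transcripts
#'
#' Produces transcript-space alignment records without a second external
#' alignment pass: a read is compatible with an isoform when the isoform's
#' introns falling strictly inside the read's span match the read's introns
#' one-for-one within `jct_tol`. The aligned-base score and transcript
#' coverage are computed from the projected exonic overlap.
#'
#' @param alignments Genome alignment tibble from [read_alignments()].
#' @param isoforms Isoform tibble from [discover_isoforms()].
#' @param config A [sclr_config()].
#' @return A records tibble: `read_id`, `transcript_id`, `gene_id`, `score`
#'   (aligned transcript bases), `transcript_coverage`,
#'   `read_fraction_aligned`.
#' @export
project_to_transcripts <- function(alignments, isoforms,
                                   config = sclr_config()) {
  empty <- tibble(read_id = character(0), transcript_id = character(0),
                  gene_id = character(0), score = numeric(0),
                  transcript_coverage = numeric(0),
                  read_fraction_aligned = numeric(0))
  if (nrow(alignments) == 0L || nrow(isoforms) == 0L) return(empty)
  chains <- chains_from_alignments(alignments, config$min_intron)
  read_len <- stats::setNames(
    as.numeric(chains$end - chains$start -
                 vapply(chains$intron_key, function(k) {
                   m <- parse_intron_key(k)
                   sum(m[, "end"] - m[, "start"])
                 }, numeric(1), USE.NAMES = FALSE)),
    chains$read_id)
  iso_cs <- paste0(isoforms$chrom, ":", isoforms$strand)
  iso_introns <- lapply(isoforms$intron_key, parse_intron_key)
  iso_len <- vapply(seq_len(nrow(isoforms)), function(i) {
    as.numeric(isoform_length(isoforms$start[[i]], isoforms$end[[i]],
                              isoforms$intron_key[[i]]))
  }, numeric(1))
  idx_by_cs <- split(seq_len(nrow(isoforms)), iso_cs)
  tol <- config$jct_tol
  # reads sharing (chrom, strand, chain, window) project identically
  uwin <- chains %>%
    distinct(.data$chrom, .data$strand, .data$intron_key, .data$start,
             .data$end)
  ukeys <- unique(uwin$intron_key)
  umats <- lapply(ukeys, parse_intron_key)
  out <- vector("list", nrow(uwin))
  for (r in seq_len(nrow(uwin))) {
    cs <- paste0(uwin$chrom[[r]], ":", uwin$strand[[r]])
    cand <- idx_by_cs[[cs]]
    if (is.null(cand)) next
    rs <- uwin$start[[r]]; re <- uwin$end[[r]]
    cand <- cand[isoforms$start[cand] < re & isoforms$end[cand] > rs]
    if (length(cand) == 0L) next
    mr <- umats[[match(uwin$intron_key[[r]], ukeys)]]
    hits <- list(); h <- 0L
    for (ci in cand) {
      mt <- iso_introns[[ci]]
      inwin <- mt[mt[, "start"] > rs & mt[, "end"] < re, , drop = FALSE]
      if (nrow(inwin) != nrow(mr)) next
      if (nrow(mr) > 0L) {
        if (any(abs(inwin[, "start"] - mr[, "start"]) >= tol) ||
            any(abs(inwin[, "end"] - mr[, "end"]) >= tol)) next
      }
      # covered transcript bases: window clipped to the transcript, minus
      # the introns inside it
      ws <- max(rs, isoforms$start[[ci]]); we <- min(re, isoforms$end[[ci]])
      ii <- mt[mt[, "start"] < we & mt[, "end"] > ws, , drop = FALSE]
      intronic <- if (nrow(ii)) {
        sum(pmin(ii[, "end"], we) - pmax(ii[, "start"], ws))
      } else 0
      covered <- (we - ws) - intronic
      if (covered <= 0) next
      h <- h + 1L
      hits[[h]] <- c(ci = ci, covered = covered)
    }
    if (h == 0L) next
    hm <- do.call(rbind, hits)
    out[[r]] <- tibble(
      chrom = uwin$chrom[[r]], strand = uwin$strand[[r]],
      intron_key = uwin$intron_key[[r]], start = rs, end = re,
      transcript_id = isoforms$transcript_id[hm[, "ci"]],
      gene_id = isoforms$gene_id[hm[, "ci"]],
      score = hm[, "covered"],
      transcript_coverage = hm[, "covered"] / iso_len[hm[, "ci"]]
    )
  }
  res <- bind_rows(out)
  if (nrow(res) == 0L) return(empty)
  chains %>%
    mutate(read_len = unname(read_len[.data$read_id])) %>%
    inner_join(res, by = c("chrom", "strand", "intron_key", "start",
                           "end"), relationship = "many-to-many") %>%
    mutate(read_fraction_aligned = pmin(1, .data$score / .data$read_len)) %>%
    select("read_id", "transcript_id", "gene_id", "score",
           "transcript_coverage", "read_fraction_aligned")
}

#' Assign reads to transcripts
#'
#' The best-scoring record per read wins; score ties are broken by transcript
#' coverage, and reads still tied are ambiguous and discarded, as are reads
#' with transcript coverage below `min_assign_cov` (the "<60% discarded"
#' rule) or read fraction aligned below `min_read_frac_aligned`. Full-length
#' status requires coverage strictly above `fl_cov` (> 95% by default).
#'
#' @param records Records tibble from [project_to_transcripts()] (or built
#'   from an external transcript-space alignment).
#' @param config A [sclr_config()].
#' @return Assignment tibble: `read_id`, `barcode`, `umi`, `transcript_id`,
#'   `gene_id`, `transcript_coverage`, `read_fraction_aligned`,
#'   `full_length`.
#' @export
assign_reads <- function(records, config = sclr_config()) {
  empty <- tibble(read_id = character(0), barcode = character(0),
                  umi = character(0), transcript_id = character(0),
                  gene_id = character(0), transcript_coverage = numeric(0),
                  read_fraction_aligned = numeric(0), full_length = logical(0))
  if (nrow(records) == 0L) return(empty)
  best <- records %>%
    group_by(.data$read_id) %>%
    filter(.data$score >= max(.data$score) - 1e-9) %>%
    filter(.data$transcript_coverage >=
             max(.data$transcript_coverage) - 1e-12) %>%
    mutate(n_best = n()) %>%
    slice_head(n = 1L) %>%
    ungroup() %>%
    filter(.data$n_best == 1L,                       # unique assignment
           .data$transcript_coverage >= config$min_assign_cov,
           .data$read_fraction_aligned >= config$min_read_frac_aligned)
  if (nrow(best) == 0L) return(empty)
  hdr <- parse_read_header(best$read_id)
  best %>%
    mutate(barcode = hdr$barcode, umi = hdr$umi,
           full_length = .data$transcript_coverage > config$fl_cov) %>%
    select("read_id", "barcode", "umi", "transcript_id", "gene_id",
           "transcript_coverage", "read_fraction_aligned", "full_length") %>%
    arrange(.data$read_id)
}

#' Filter isoforms by full-length read support
#'
#' Transcripts with fewer than `min_fl_support` full-length reads are
#' discarded, and the assignments pointing at them are dropped (not
#' reassigned).
#'
#' @param assignments Assignment tibble from [assign_reads()].
#' @param config A [sclr_config()].
#' @return The filtered assignment tibble; surviving transcript ids in the
#'   `kept_transcripts` attribute, number of dropped reads in
#'   `dropped_reads`.
#' @export
filter_isoforms_by_support <- function(assignments, config = sclr_config()) {
  if (nrow(assignments) == 0L) {
    out <- assignments
    attr(out, "kept_transcripts") <- character(0)
    attr(out, "dropped_reads") <- 0L
    return(out)
  }
  fl <- assignments %>%
    group_by(.data$transcript_id) %>%
    summarise(n_fl = sum(.data$full_length), .groups = "drop")
  kept <- fl$transcript_id[fl$n_fl >= config$min_fl_support]
  out <- assignments %>% filter(.data$transcript_id %in% kept)
  attr(out, "kept_transcripts") <- sort(kept)
  attr(out, "dropped_reads") <- nrow(assignments) - nrow(out)
  out
}

# connected components of the UMI graph at edit distance <= max_ed
umi_components <- function(umis, max_ed) {
  u <- unique(umis)
  if (length(u) == 1L) return(stats::setNames(1L, u))
  d <- utils::adist(u, u)
  adj <- d <= max_ed
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  stats::setNames(as.integer(comp), u)
}

#' Collapse reads into molecules by UMI
#'
#' Within each (barcode, gene) group, UMIs are clustered as connected
#' components of the graph linking UMIs within edit distance `umi_dedup_ed`;
#' each component is one molecule. The molecule's transcript is the one with
#' most reads in the component (ties broken by the transcript's total read
#' support, then lexicographic id); the representative UMI is the most
#' frequent, then lexicographic.
#'
#' @param assignments Assignment tibble (after support filtering).
#' @param config A [sclr_config()].
#' @return Molecule tibble: `barcode`, `gene_id`, `umi`, `transcript_id`,
#'   `n_reads`.
#' @export
dedup_umis <- function(assignments, config = sclr_config()) {
  if (nrow(assignments) == 0L) {
    return(tibble(barcode = character(0), gene_id = character(0),
                  umi = character(0), transcript_id = character(0),
                  n_reads = integer(0)))
  }
  tx_support <- assignments %>% count(.data$transcript_id, name = "tx_total")
  key <- paste0(assignments$barcode, "\r", assignments$gene_id)
  comp <- integer(nrow(assignments))
  for (idx in split(seq_len(nrow(assignments)), key)) {
    cc <- umi_components(assignments$umi[idx], config$umi_dedup_ed)
    comp[idx] <- cc[assignments$umi[idx]]
  }
  reads <- assignments %>% mutate(component = comp)
  tx_pick <- reads %>%
    count(.data$barcode, .data$gene_id, .data$component,
          .data$transcript_id, name = "n_tx") %>%
    left_join(tx_support, by = "transcript_id") %>%
    arrange(.data$barcode, .data$gene_id, .data$component,
            desc(.data$n_tx), desc(.data$tx_total), .data$transcript_id) %>%
    distinct(.data$barcode, .data$gene_id, .data$component,
             .keep_all = TRUE) %>%
    select("barcode", "gene_id", "component", "transcript_id")
  umi_pick <- reads %>%
    count(.data$barcode, .data$gene_id, .data$component, .data$umi,
          name = "n_umi") %>%
    arrange(.data$barcode, .data$gene_id, .data$component,
            desc(.data$n_umi), .data$umi) %>%
    distinct(.data$barcode, .data$gene_id, .data$component,
             .keep_all = TRUE) %>%
    select("barcode", "gene_id", "component", "umi")
  sizes <- reads %>%
    count(.data$barcode, .data$gene_id, .data$component, name = "n_reads")
  tx_pick %>%
    inner_join(umi_pick, by = c("barcode", "gene_id", "component")) %>%
    inner_join(sizes, by = c("barcode", "gene_id", "component")) %>%
    select("barcode", "gene_id", "umi", "transcript_id", "n_reads") %>%
    arrange(.data$barcode, .data$gene_id, .data$umi)
}

#' Build transcript- and gene-level UMI count matrices
#'
#' @param molecules Molecule tibble from [dedup_umis()].
#' @return A list with `transcript` and `gene` long count tibbles
#'   (`transcript_id`/`gene_id`, `barcode`, `count`); gene counts are the
#'   per-gene sums of the transcript counts, so column sums agree.
#' @export
build_count_matrices <- function(molecules) {
  attr(molecules, "kept_transcripts") <- NULL
  attr(molecules, "dropped_reads") <- NULL
  transcript <- molecules %>%
    count(.data$transcript_id, .data$gene_id, .data$barcode, name = "count") %>%
    arrange(.data$transcript_id, .data$barcode)
  gene <- transcript %>%
    group_by(.data$gene_id, .data$barcode) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    arrange(.data$gene_id, .data$barcode)
  list(transcript = transcript, gene = gene)
}

#' Quantify isoforms from genome alignments
#'
#' Full quantification stage: project reads onto the discovered isoforms,
#' assign uniquely, apply the full-length support filter, collapse UMIs and
#' count. Read ids must carry the `{barcode}_{UMI}#id` demultiplexed header.
#'
#' @param alignments Genome alignment tibble (or SAM/BAM path).
#' @param isoforms Isoform tibble from [discover_isoforms()].
#' @param config A [sclr_config()].
#' @return An object of class `sclr_quant`: list with `assignments`,
#'   `molecules`, `transcript_counts`, `gene_counts`, `kept_transcripts`.
#' @export
quantify_isoforms <- function(alignments, isoforms, config = sclr_config()) {
  if (is.character(alignments)) {
    alignments <- read_alignments(alignments, keep_seq = FALSE)
  }
  records <- project_to_transcripts(alignments, isoforms, config)
  assignments <- assign_reads(records, config)
  assignments <- filter_isoforms_by_support(assignments, config)
  molecules <- dedup_umis(assignments, config)
  counts <- build_count_matrices(molecules)
  structure(list(
    assignments = assignments,
    molecules = molecules,
    transcript_counts = counts$transcript,
    gene_counts = counts$gene,
    kept_transcripts = attr(assignments, "kept_transcripts")
  ), class = "sclr_quant")
}

#' @export
print.sclr_quant <- function(x, ...) {
  cat(sprintf(paste0("<sclr_quant> %d assigned reads, %d molecules, ",
                     "%d transcripts x %d cells\n"),
              nrow(x$assignments), nrow(x$molecules),
              length(unique(x$transcript_counts$transcript_id)),
              length(unique(x$transcript_counts$barcode))))
  invisible(x)
}

#' Write a long count tibble as a wide CSV (rows x cells)
#' @param counts Long count tibble (`transcript_id` or `gene_id`, `barcode`,
#'   `count`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_count_csv <- function(counts, path) {
  id_col <- intersect(c("transcript_id", "gene_id"), names(counts))[[1L]]
  wide <- counts %>%
    select(all_of(c(id_col, "barcode", "count"))) %>%
    tidyr::pivot_wider(names_from = "barcode", values_from = "count",
                       values_fill = 0L) %>%
    arrange(.data[[id_col]])
  readr::write_csv(wide, path)
  invisible(path)
}

#' Write a long count tibble as MatrixMarket triple
#' @param counts Long count tibble.
#' @param path Output `.mtx` path; row/column name files are written next to
#'   it with `.rownames`/`.colnames` suffixes.
#' @return `path`, invisibly.
#' @export
write_count_mtx <- function(counts, path) {
  id_col <- intersect(c("transcript_id", "gene_id"), names(counts))[[1L]]
  rows <- sort(unique(counts[[id_col]]))
  cols <- sort(unique(counts$barcode))
  m <- Matrix::sparseMatrix(
    i = match(counts[[id_col]], rows),
    j = match(counts$barcode, cols),
    x = counts$count,
    dims = c(length(rows), length(cols)))
  Matrix::writeMM(m, path)
  writeLines(rows, paste0(path, ".rownames"))
  writeLines(cols, paste0(path, ".colnames"))
  invisible(path)
}
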