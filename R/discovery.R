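#' Summarize an alignment as a splice-junction chain
#'
#' Splice gaps (N operations) of at least `min_intron` bp become introns;
#' shorter gaps are absorbed into exons (they are indistinguishable from
#' deletions at nanopore error rates).
#'
#' @param alignments An alignment tibble from [read_alignments()].
#' @param min_intron Minimum gap length retained as an intron (bp).
#' @return A tibble with `read_id`, `chrom`, `strand`, `start`, `end` and the
#'   `intron_key` chain string.
#' @export
chains_from_alignments <- function(alignments, min_intron = 30L) {
  if (nrow(alignments) == 0L) {
    return(tibble(read_id = character(0), chrom = character(0),
                  strand = character(0), start = integer(0), end = integer(0),
                  intron_key = character(0)))
  }
  keys <- vapply(alignments$gaps, function(g) {
    if (is.null(g) || nrow(g) == 0L) return("")
    g <- g[g[, "end"] - g[, "start"] >= min_intron, , drop = FALSE]
    intron_key(g)
  }, character(1))
  tibble(read_id = alignments$read_id, chrom = alignments$chrom,
         strand = alignments$strand,
         start = as.integer(alignments$start),
         end = as.integer(alignments$end), intron_key = keys)
}

# greedy majority clustering of one coordinate column: most supported
# coordinate becomes the representative and absorbs coordinates strictly
# within tol; ties broken by lower coordinate. Returns named int map.
cluster_sites <- function(coords, tol) {
  if (length(coords) == 0L) return(integer(0))
  tab <- table(coords)
  vals <- as.integer(names(tab))
  cnt <- as.integer(tab)
  ord <- order(-cnt, vals)
  vals <- vals[ord]
  rep_of <- stats::setNames(rep(NA_integer_, length(vals)),
                            as.character(vals))
  for (v in vals) {
    key <- as.character(v)
    if (!is.na(rep_of[[key]])) next
    free <- vals[is.na(rep_of[as.character(vals)])]
    absorb <- free[abs(free - v) < tol]
    rep_of[as.character(absorb)] <- v
  }
  rep_of
}

#' Group read chains by similar splice junctions
#'
#' Within each chromosome/strand, junction start and end coordinates are
#' clustered greedily by descending read support (sites strictly within
#' `jct_tol` of a more supported site are moved onto it, as in the
#' "<5 bp by default" junction grouping rule), and reads whose corrected
#' chains coincide are grouped. The consensus transcript start/end is the
#' median of the member reads' outer bounds. The result is invariant to read
#' input order.
#'
#' @param chains Chain tibble from [chains_from_alignments()].
#' @param jct_tol Junction tolerance (strict, bp).
#' @return A tibble with `chrom`, `strand`, `intron_key` (corrected),
#'   `start`, `end`, `support` and a `read_ids` list column.
#' @export
group_chains <- function(chains, jct_tol = 5L) {
  if (nrow(chains) == 0L) {
    return(tibble(chrom = character(0), strand = character(0),
                  intron_key = character(0), start = integer(0),
                  end = integer(0), support = integer(0), read_ids = list()))
  }
  chains <- chains %>% arrange(.data$chrom, .data$strand, .data$read_id)
  parts <- split(chains, paste0(chains$chrom, "\r", chains$strand))
  out <- lapply(parts[sort(names(parts))], function(part) {
    ukey <- part %>% count(.data$intron_key, name = "n_reads")
    mats <- lapply(ukey$intron_key, parse_intron_key)
    # site support counts one per read carrying that coordinate
    all_starts <- unlist(lapply(seq_along(mats), function(i) {
      rep(mats[[i]][, "start"], ukey$n_reads[[i]])
    }))
    all_ends <- unlist(lapply(seq_along(mats), function(i) {
      rep(mats[[i]][, "end"], ukey$n_reads[[i]])
    }))
    smap <- cluster_sites(all_starts, jct_tol)
    emap <- cluster_sites(all_ends, jct_tol)
    corrected <- vapply(mats, function(m) {
      if (nrow(m) == 0L) return("")
      m[, "start"] <- smap[as.character(m[, "start"])]
      m[, "end"] <- emap[as.character(m[, "end"])]
      m <- m[order(m[, "start"]), , drop = FALSE]
      intron_key(m)
    }, character(1))
    key_map <- stats::setNames(corrected, ukey$intron_key)
    part$corrected_key <- unname(key_map[part$intron_key])
    part %>%
      group_by(.data$chrom, .data$strand, .data$corrected_key) %>%
      summarise(start = as.integer(round(stats::median(.data$start))),
                end = as.integer(round(stats::median(.data$end))),
                support = n(),
                read_ids = list(sort(.data$read_id)),
                .groups = "drop") %>%
      rename(intron_key = "corrected_key")
  })
  bind_rows(out) %>%
    arrange(.data$chrom, .data$start, .data$intron_key)
}

# overlap length of [s1,e1) and [s2,e2)
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

#' Correct consensus chains against the reference and merge known isoforms
#'
#' Each consensus junction strictly within `jct_tol` of a reference junction
#' of an overlapping gene is snapped onto it (remaining individual
#' donor/acceptor boundaries are snapped to the gene's site sets the same
#' way). A corrected chain identical to a reference transcript's chain whose
#' ends both lie strictly within `end_tol` of that transcript's ends is
#' merged with the reference: it takes the reference id and exact reference
#' coordinates. Everything else becomes a novel isoform assigned to the
#' overlapping gene sharing the most junctions (ties by genomic overlap;
#' none -> a `novelGene_` id).
#'
#' @param groups Consensus groups from [group_chains()].
#' @param annotation A `gene_annotation`.
#' @param config A [sclr_config()] (uses `jct_tol`, `end_tol`).
#' @return An isoform tibble: `transcript_id`, `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `intron_key`, `status` (known/novel), `support`,
#'   `read_ids`.
#' @export
correct_and_merge <- function(groups, annotation, config = sclr_config()) {
  jct_tol <- config$jct_tol
  end_tol <- config$end_tol
  n <- nrow(groups)
  if (n == 0L) return(empty_isoforms())
  genes <- annotation$genes
  tx <- annotation$transcripts
  jx <- annotation$junctions
  novel_gene_counter <- 0L
  novel_counts <- new.env(parent = emptyenv())
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    g <- groups[i, ]
    m <- parse_intron_key(g$intron_key)
    cand_genes <- genes %>%
      filter(.data$chrom == g$chrom, .data$strand == g$strand,
             .data$start < g$end, .data$end > g$start)
    # snap junctions of overlapping genes
    if (nrow(m) > 0L && nrow(cand_genes) > 0L) {
      ref_j <- jx %>%
        filter(.data$gene_id %in% cand_genes$gene_id) %>%
        distinct(.data$start, .data$end)
      for (k in seq_len(nrow(m))) {
        if (nrow(ref_j) == 0L) break
        d <- pmax(abs(ref_j$start - m[k, "start"]),
                  abs(ref_j$end - m[k, "end"]))
        best <- which(d < jct_tol)
        if (length(best)) {
          best <- best[order(d[best], ref_j$start[best])][[1L]]
          m[k, "start"] <- ref_j$start[[best]]
          m[k, "end"] <- ref_j$end[[best]]
        } else {
          # snap individual boundaries to the genes' site coordinate sets
          ss <- unique(ref_j$start); ee <- unique(ref_j$end)
          ds <- abs(ss - m[k, "start"])
          if (length(ss) && min(ds) > 0L && min(ds) < jct_tol) {
            m[k, "start"] <- ss[order(ds, ss)][[1L]]
          }
          de <- abs(ee - m[k, "end"])
          if (length(ee) && min(de) > 0L && min(de) < jct_tol) {
            m[k, "end"] <- ee[order(de, ee)][[1L]]
          }
        }
      }
      m <- m[order(m[, "start"]), , drop = FALSE]
      if (nrow(m) > 1L && any(m[-1L, "start"] < m[-nrow(m), "end"])) {
        # degenerate after snapping (two junctions on one reference
        # junction); drop duplicates
        m <- m[!duplicated(paste(m[, "start"], m[, "end"])), , drop = FALSE]
      }
    }
    ckey <- intron_key(m)
    # gene assignment: most shared junctions, then larger overlap
    gene_id <- NA_character_
    if (nrow(cand_genes) > 0L) {
      shared <- vapply(cand_genes$gene_id, function(gid) {
        rj <- jx %>% filter(.data$gene_id == gid)
        if (nrow(m) == 0L || nrow(rj) == 0L) return(0L)
        sum(paste(m[, "start"], m[, "end"]) %in% paste(rj$start, rj$end))
      }, integer(1))
      ovl <- interval_overlap(g$start, g$end, cand_genes$start,
                              cand_genes$end)
      ord <- order(-shared, -ovl, cand_genes$gene_id)
      gene_id <- cand_genes$gene_id[[ord[[1L]]]]
    }
    # merge with a reference transcript of an overlapping gene
    status <- "novel"
    out_id <- NA_character_
    out_start <- g$start; out_end <- g$end
    if (!is.na(gene_id)) {
      cand_tx <- tx %>%
        filter(.data$gene_id %in% cand_genes$gene_id,
               .data$intron_key == ckey,
               abs(.data$start - g$start) < end_tol,
               abs(.data$end - g$end) < end_tol)
      if (nrow(cand_tx) > 0L) {
        cand_tx <- cand_tx %>%
          mutate(dist = abs(.data$start - g$start) +
                   abs(.data$end - g$end)) %>%
          arrange(.data$dist, .data$transcript_id)
        hit <- cand_tx[1L, ]
        status <- "known"
        out_id <- hit$transcript_id
        gene_id <- hit$gene_id
        out_start <- hit$start
        out_end <- hit$end
      }
    }
    if (is.na(gene_id)) {
      novel_gene_counter <- novel_gene_counter + 1L
      gene_id <- sprintf("novelGene_%s_%s_%d", g$chrom, g$strand,
                         novel_gene_counter)
    }
    if (is.na(out_id)) {
      k <- (get0(gene_id, envir = novel_counts, ifnotfound = 0L)) + 1L
      assign(gene_id, k, envir = novel_counts)
      out_id <- sprintf("%s-novel-%d", gene_id, k)
    }
    rows[[i]] <- tibble(
      transcript_id = out_id, gene_id = gene_id, chrom = g$chrom,
      strand = g$strand, start = as.integer(out_start),
      end = as.integer(out_end), intron_key = ckey, status = status,
      support = g$support, read_ids = g$read_ids
    )
  }
  iso <- bind_rows(rows)
  # groups that collapsed onto the same transcript after snapping are merged
  iso %>%
    group_by(.data$transcript_id, .data$gene_id, .data$chrom, .data$strand,
             .data$intron_key, .data$status) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              support = sum(.data$support),
              read_ids = list(sort(unlist(.data$read_ids))),
              .groups = "drop") %>%
    select("transcript_id", "gene_id", "chrom", "strand", "start", "end",
           "intron_key", "status", "support", "read_ids") %>%
    arrange(.data$chrom, .data$start, .data$transcript_id)
}

empty_isoforms <- function() {
  tibble(transcript_id = character(0), gene_id = character(0),
         chrom = character(0), strand = character(0), start = integer(0),
         end = integer(0), intron_key = character(0), status = character(0),
         support = integer(0), read_ids = list())
}

isoform_length <- function(start, end, intron_key) {
  m <- parse_intron_key(intron_key)
  (end - start) - sum(m[, "end"] - m[, "start"])
}

# truncation-rate model: expected fraction of a parent's reads that appear
# truncated, linear in parent transcript length, clamped to [0, 0.95]
truncation_rate <- function(length_bp, config) {
  max(0, min(0.95, config$trunc_slope * length_bp + config$trunc_intercept))
}

#' Collapse likely truncated isoforms into their parents
#'
#' A candidate is a truncation of a longer isoform of the same gene when its
#' intron chain is a consecutive sub-chain anchored at the protocol-proximal
#' end (the 3' end for the three-prime protocol) with proximal ends within
#' `end_tol`. It is collapsed into the parent — its reads reassigned —
#' unless its support exceeds `f(L_parent) * support(parent)`, where
#' `f(L) = clamp(trunc_slope * L + trunc_intercept, 0, 0.95)`: longer
#' isoforms are expected to shed proportionally more truncated reads.
#' Longest parents are considered first.
#'
#' @param isoforms Isoform tibble from [correct_and_merge()].
#' @param config A [sclr_config()].
#' @return The collapsed isoform tibble (same shape, `collapsed_into` column
#'   recorded in the `collapsed` attribute).
#' @export
resolve_truncations <- function(isoforms, config = sclr_config()) {
  if (nrow(isoforms) == 0L) return(isoforms)
  iso <- isoforms %>%
    mutate(tx_len = purrr::pmap_int(
      list(.data$start, .data$end, .data$intron_key),
      function(s, e, k) as.integer(isoform_length(s, e, k))))
  collapsed_into <- stats::setNames(rep(NA_character_, nrow(iso)),
                                    iso$transcript_id)
  for (gid in unique(iso$gene_id)) {
    idx <- which(iso$gene_id == gid)
    if (length(idx) < 2L) next
    ord <- idx[order(-iso$tx_len[idx], iso$transcript_id[idx])]
    strand <- iso$strand[[ord[[1L]]]]
    # protocol-proximal side: 3' is the right end on "+", left end on "-"
    proximal_right <- (config$protocol_end == "three_prime") == (strand == "+")
    for (j in ord) {
      if (!is.na(collapsed_into[[iso$transcript_id[[j]]]])) next
      mj <- parse_intron_key(iso$intron_key[[j]])
      for (i in ord) {
        if (i == j) next
        if (iso$tx_len[[i]] >= iso$tx_len[[j]]) next
        if (!is.na(collapsed_into[[iso$transcript_id[[i]]]])) next
        mi <- parse_intron_key(iso$intron_key[[i]])
        if (nrow(mi) >= nrow(mj)) next
        ki <- paste(mi[, "start"], mi[, "end"], sep = "-")
        kj <- paste(mj[, "start"], mj[, "end"], sep = "-")
        anchored <- nrow(mi) == 0L ||
          if (proximal_right) {
            all(kj[(nrow(mj) - nrow(mi) + 1L):nrow(mj)] == ki)
          } else {
            all(kj[seq_len(nrow(mi))] == ki)
          }
        if (!anchored) next
        prox_ok <- if (proximal_right) {
          abs(iso$end[[i]] - iso$end[[j]]) < config$end_tol
        } else {
          abs(iso$start[[i]] - iso$start[[j]]) < config$end_tol
        }
        if (!prox_ok) next
        thr <- truncation_rate(iso$tx_len[[j]], config) * iso$support[[j]]
        if (iso$support[[i]] > thr) next
        # collapse i into j
        collapsed_into[[iso$transcript_id[[i]]]] <- iso$transcript_id[[j]]
        iso$support[[j]] <- iso$support[[j]] + iso$support[[i]]
        iso$read_ids[[j]] <- sort(c(iso$read_ids[[j]], iso$read_ids[[i]]))
      }
    }
  }
  keep <- is.na(collapsed_into[iso$transcript_id])
  out <- iso[keep, ] %>% select(-"tx_len")
  attr(out, "collapsed") <- collapsed_into[!is.na(collapsed_into)]
  out
}

# exon table (one row per exon) for an isoform tibble
isoform_exon_table <- function(isoforms) {
  if (nrow(isoforms) == 0L) {
    return(tibble(transcript_id = character(0), gene_id = character(0),
                  chrom = character(0), strand = character(0),
                  start = integer(0), end = integer(0)))
  }
  purrr::pmap_dfr(
    list(isoforms$transcript_id, isoforms$gene_id, isoforms$chrom,
         isoforms$strand, isoforms$start, isoforms$end,
         isoforms$intron_key),
    function(tid, gid, chrom, strand, s, e, key) {
      ex <- exons_from_introns(parse_intron_key(key), s, e)
      tibble(transcript_id = tid, gene_id = gid, chrom = chrom,
             strand = strand, start = as.integer(ex[, "start"]),
             end = as.integer(ex[, "end"]))
    })
}

#' Run isoform discovery
#'
#' Chains alignments, groups them by splice junctions, corrects against the
#' reference, merges known isoforms and collapses truncations. Isoforms are
#' retained here regardless of support; the full-length support filter is
#' applied during quantification where full-length status is defined.
#'
#' @param alignments Alignment tibble from [read_alignments()], or a SAM/BAM
#'   path.
#' @param annotation A `gene_annotation`.
#' @param config A [sclr_config()].
#' @return An isoform tibble (see [correct_and_merge()]).
#' @export
discover_isoforms <- function(alignments, annotation,
                              config = sclr_config()) {
  if (is.character(alignments)) {
    alignments <- read_alignments(alignments, keep_seq = FALSE)
  }
  chains <- chains_from_alignments(alignments, config$min_intron)
  groups <- group_chains(chains, config$jct_tol)
  iso <- correct_and_merge(groups, annotation, config)
  resolve_truncations(iso, config)
}

#' Write discovery results as GFF3 and transcript FASTA
#'
#' @param isoforms Isoform tibble from [discover_isoforms()].
#' @param genome A `DNAStringSet` from [read_genome()].
#' @param out_dir Output directory; writes `isoform_annotated.gff3` and
#'   `transcript_assembly.fa`.
#' @return Named character vector of the two paths, invisibly.
#' @export
finalize_isoforms <- function(isoforms, genome, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gff <- file.path(out_dir, "isoform_annotated.gff3")
  fa <- file.path(out_dir, "transcript_assembly.fa")
  exons <- isoform_exon_table(isoforms)
  write_annotation(exons, gff)
  write_fasta(extract_transcript_sequences(exons, genome), fa)
  invisible(c(gff3 = gff, fasta = fa))
}
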