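#' Classify isoforms against the reference annotation
#'
#' SQANTI-style categories: FSM (intron chain identical to a reference
#' transcript), ISM (non-empty consecutive sub-chain of a reference chain),
#' NIC (all donors and acceptors known for the gene, but a novel
#' combination), NNC (at least one novel donor or acceptor). Mono-exon
#' chains are FSM when contained within a mono-exon reference transcript of
#' the same strand, otherwise "other". Site sets are per-gene: a donor from
#' another gene does not make a junction known.
#'
#' @param isoforms Isoform tibble (needs `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `start`, `end`, `intron_key`).
#' @param annotation A `gene_annotation`.
#' @return A tibble `isoform_id`, `category`, `matched_transcript` (FSM/ISM
#'   only, NA otherwise).
#' @export
classify_isoforms <- function(isoforms, annotation) {
  n <- nrow(isoforms)
  out <- tibble(isoform_id = isoforms$transcript_id,
                category = rep("other", n),
                matched_transcript = rep(NA_character_, n))
  if (n == 0L) return(out)
  tx <- annotation$transcripts
  for (i in seq_len(n)) {
    chrom <- isoforms$chrom[[i]]; strand <- isoforms$strand[[i]]
    key <- isoforms$intron_key[[i]]
    cand <- tx[tx$chrom == chrom & tx$strand == strand, , drop = FALSE]
    if (nrow(cand) == 0L) next   # contig/strand absent -> other
    if (!nzchar(key)) {
      mono <- cand[!nzchar(cand$intron_key) &
                     cand$start <= isoforms$start[[i]] &
                     cand$end >= isoforms$end[[i]], , drop = FALSE]
      if (nrow(mono)) {
        out$category[[i]] <- "FSM"
        out$matched_transcript[[i]] <-
          sort(mono$transcript_id)[[1L]]
      }
      next
    }
    fsm <- cand[cand$intron_key == key, , drop = FALSE]
    if (nrow(fsm)) {
      out$category[[i]] <- "FSM"
      out$matched_transcript[[i]] <- sort(fsm$transcript_id)[[1L]]
      next
    }
    m <- parse_intron_key(key)
    ism_hit <- NA_character_
    for (j in order(cand$transcript_id)) {
      if (!nzchar(cand$intron_key[[j]])) next
      if (is_consecutive_subchain(m, parse_intron_key(cand$intron_key[[j]]))) {
        ism_hit <- cand$transcript_id[[j]]
        break
      }
    }
    if (!is.na(ism_hit)) {
      out$category[[i]] <- "ISM"
      out$matched_transcript[[i]] <- ism_hit
      next
    }
    sites <- gene_site_sets(annotation, isoforms$gene_id[[i]])
    dn <- donor_sites(m, strand)
    ac <- acceptor_sites(m, strand)
    if (length(sites$donors) && all(dn %in% sites$donors) &&
        all(ac %in% sites$acceptors)) {
      out$category[[i]] <- "NIC"
    } else {
      out$category[[i]] <- "NNC"
    }
  }
  out
}

#' Type the splicing difference between two isoforms of a gene
#'
#' Partitions the symmetric difference of the two intron chains into
#' splicing events: exon skipping (an intron of one chain spanning exons
#' internal to the other, with matching outer boundaries), intron retention
#' (an intron absent from the other chain whose region is exonic there),
#' and alternative 5'/3' splice sites (an intron pair sharing one boundary;
#' the changed side decides the type, strand-aware). Terminal-end
#' differences beyond `end_tol` count as alternative 5' (promoter) or 3'
#' (polyadenylation) events. Exactly one event gives that category; more
#' than one gives "complex"; identical chains give "identical_chain".
#'
#' @param iso_a,iso_b One-row isoform tibbles (same gene, chrom, strand).
#' @param config A [sclr_config()] (uses `end_tol`).
#' @return A list with `category` and `events` (character vector).
#' @export
call_splice_events <- function(iso_a, iso_b, config = sclr_config()) {
  if (iso_a$chrom != iso_b$chrom || iso_a$strand != iso_b$strand) {
    stop("isoforms on different chromosomes/strands", call. = FALSE)
  }
  strand <- iso_a$strand
  ka <- iso_a$intron_key; kb <- iso_b$intron_key
  A <- parse_intron_key(ka); B <- parse_intron_key(kb)
  akeys <- paste(A[, "start"], A[, "end"]); bkeys <- paste(B[, "start"], B[, "end"])
  da <- which(!(akeys %in% bkeys))   # introns private to A
  db <- which(!(bkeys %in% akeys))
  used_a <- logical(nrow(A)); used_b <- logical(nrow(B))
  events <- character(0)
  # exon skipping: private intron of one chain == the outer bounds of a run
  # of >=2 private introns of the other chain
  find_skip <- function(P, dp, used_p, Q, dq, used_q) {
    res <- list()
    for (ip in dp) {
      if (used_p[[ip]]) next
      spans <- dq[!used_q[dq]]
      if (length(spans) < 2L) next
      runs <- split(spans, cumsum(c(1L, diff(spans) != 1L)))
      for (run in runs) {
        for (a1 in seq_along(run)) for (a2 in seq_along(run)) {
          if (a2 <= a1) next
          r <- run[a1:a2]
          if (Q[r[[1L]], "start"] == P[ip, "start"] &&
              Q[r[[length(r)]], "end"] == P[ip, "end"]) {
            return(list(ip = ip, run = r))
          }
        }
      }
    }
    NULL
  }
  repeat {
    hit <- find_skip(A, da, used_a, B, db, used_b)
    if (!is.null(hit)) {
      used_a[[hit$ip]] <- TRUE; used_b[hit$run] <- TRUE
      events <- c(events, "exon_skipping")
      next
    }
    hit <- find_skip(B, db, used_b, A, da, used_a)
    if (!is.null(hit)) {
      used_b[[hit$ip]] <- TRUE; used_a[hit$run] <- TRUE
      events <- c(events, "exon_skipping")
      next
    }
    break
  }
  # alternative 5'/3' sites: private introns sharing exactly one boundary
  for (ia in da) {
    if (used_a[[ia]]) next
    for (ib in db) {
      if (used_b[[ib]]) next
      same_s <- A[ia, "start"] == B[ib, "start"]
      same_e <- A[ia, "end"] == B[ib, "end"]
      if (xor(same_s, same_e)) {
        changed_low <- !same_s
        # the low coordinate is the donor (5' site) on "+", acceptor on "-"
        type <- if (changed_low == (strand == "+")) "alt_five_prime" else
          "alt_three_prime"
        events <- c(events, type)
        used_a[[ia]] <- TRUE; used_b[[ib]] <- TRUE
        break
      }
    }
  }
  # intron retention: a private intron whose region is exonic (no introns)
  # in the other chain and within its span
  exonic_in <- function(intron, M, span_start, span_end) {
    if (intron[["start"]] < span_start || intron[["end"]] > span_end) {
      return(FALSE)
    }
    if (nrow(M) == 0L) return(TRUE)
    !any(M[, "start"] < intron[["end"]] & M[, "end"] > intron[["start"]])
  }
  for (ia in da) {
    if (used_a[[ia]]) next
    if (exonic_in(A[ia, ], B, iso_b$start, iso_b$end)) {
      events <- c(events, "intron_retention")
      used_a[[ia]] <- TRUE
    }
  }
  for (ib in db) {
    if (used_b[[ib]]) next
    if (exonic_in(B[ib, ], A, iso_a$start, iso_a$end)) {
      events <- c(events, "intron_retention")
      used_b[[ib]] <- TRUE
    }
  }
  # unexplained private introns each count as one event
  n_left <- sum(!used_a[da]) + sum(!used_b[db])
  events <- c(events, rep("unclassified", n_left))
  # terminal ends beyond the merge tolerance: promoter / polyadenylation
  if (abs(iso_a$start - iso_b$start) >= config$end_tol) {
    events <- c(events,
                if (strand == "+") "alt_five_prime" else "alt_three_prime")
  }
  if (abs(iso_a$end - iso_b$end) >= config$end_tol) {
    events <- c(events,
                if (strand == "+") "alt_three_prime" else "alt_five_prime")
  }
  category <- if (length(events) == 0L) "identical_chain"
  else if (length(events) > 1L || any(events == "unclassified")) "complex"
  else events[[1L]]
  list(category = category, events = events)
}

#' Splicing events between each gene's two most abundant isoforms
#'
#' Ranks transcripts by total UMI count within each multi-isoform gene and
#' types the splicing difference between the top two.
#'
#' @param transcript_counts Long transcript count tibble.
#' @param isoforms Isoform tibble.
#' @param config A [sclr_config()].
#' @return A tibble `gene_id`, `isoform_1`, `isoform_2`, `category`.
#' @export
top2_splice_events <- function(transcript_counts, isoforms,
                               config = sclr_config()) {
  totals <- transcript_counts %>%
    group_by(.data$gene_id, .data$transcript_id) %>%
    summarise(total = sum(.data$count), .groups = "drop") %>%
    filter(.data$total > 0) %>%
    arrange(.data$gene_id, desc(.data$total), .data$transcript_id)
  multi <- totals %>% count(.data$gene_id) %>% filter(.data$n >= 2L)
  out <- lapply(multi$gene_id, function(gid) {
    top <- totals %>% filter(.data$gene_id == gid) %>% slice_head(n = 2L)
    a <- isoforms %>% filter(.data$transcript_id == top$transcript_id[[1L]])
    b <- isoforms %>% filter(.data$transcript_id == top$transcript_id[[2L]])
    if (nrow(a) == 0L || nrow(b) == 0L) return(NULL)
    ev <- call_splice_events(a[1L, ], b[1L, ], config)
    tibble(gene_id = gid, isoform_1 = a$transcript_id[[1L]],
           isoform_2 = b$transcript_id[[1L]], category = ev$category)
  })
  bind_rows(out)
}

#' Per-gene isoform diversity summaries
#'
#' Counts expressed transcripts per gene (capped at ">=6") and the ranked
#' fraction of the gene's UMIs carried by each transcript.
#'
#' @param transcript_counts Long transcript count tibble (`transcript_id`,
#'   `gene_id`, `barcode`, `count`).
#' @return A list of two tibbles: `histogram` (`gene_id`, `n_isoforms`,
#'   `bin`) and `fractions` (`gene_id`, `transcript_id`, `rank`,
#'   `fraction`), both sorted by gene id.
#' @export
summarize_diversity <- function(transcript_counts) {
  totals <- transcript_counts %>%
    group_by(.data$gene_id, .data$transcript_id) %>%
    summarise(total = sum(.data$count), .groups = "drop") %>%
    filter(.data$total > 0)
  histogram <- totals %>%
    count(.data$gene_id, name = "n_isoforms") %>%
    mutate(bin = ifelse(.data$n_isoforms >= 6L, ">=6",
                        as.character(.data$n_isoforms))) %>%
    arrange(.data$gene_id)
  fractions <- totals %>%
    group_by(.data$gene_id) %>%
    arrange(desc(.data$total), .data$transcript_id, .by_group = TRUE) %>%
    mutate(rank = row_number(), fraction = .data$total / sum(.data$total)) %>%
    ungroup() %>%
    select("gene_id", "transcript_id", "rank", "fraction") %>%
    arrange(.data$gene_id, .data$rank)
  list(histogram = histogram, fractions = fractions)
}
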