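#' @importFrom dplyr %>% arrange mutate filter select group_by summarise
#'   ungroup left_join inner_join anti_join bind_rows distinct n rename
#'   first slice_head count across all_of pull row_number desc
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
NULL

# ---- intron-chain primitives -------------------------------------------------
# A chain is identified by chrom, strand and the ordered intron intervals
# (0-based half-open on the genome). Chains are compared through their string
# keys so grouping and hashing are plain vector operations.

introns_from_exons <- function(starts, ends) {
  # exon starts/ends sorted, 0-based half-open -> introns between them
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  k <- length(starts)
  if (k < 2L) return(cbind(start = integer(0), end = integer(0)))
  cbind(start = ends[-k], end = starts[-1L])
}

exons_from_introns <- function(introns, span_start, span_end) {
  if (is.null(introns) || nrow(introns) == 0L) {
    return(cbind(start = span_start, end = span_end))
  }
  cbind(start = c(span_start, introns[, "end"]),
        end = c(introns[, "start"], span_end))
}

intron_key <- function(introns) {
  if (is.null(introns) || nrow(introns) == 0L) return("")
  paste(paste0(introns[, "start"], "-", introns[, "end"]), collapse = ",")
}

parse_intron_key <- function(key) {
  if (is.na(key) || !nzchar(key)) {
    return(cbind(start = integer(0), end = integer(0)))
  }
  parts <- strsplit(strsplit(key, ",", fixed = TRUE)[[1L]], "-", fixed = TRUE)
  m <- matrix(as.integer(unlist(parts)), ncol = 2L, byrow = TRUE)
  colnames(m) <- c("start", "end")
  m
}

chain_key <- function(chrom, strand, ikey) {
  paste0(chrom, ":", strand, ":", ikey)
}

# donor is the 5' end of the intron: on "+" the lower coordinate (exon end),
# on "-" the higher coordinate
donor_sites <- function(introns, strand) {
  if (nrow(introns) == 0L) return(integer(0))
  if (strand == "-") introns[, "end"] else introns[, "start"]
}

acceptor_sites <- function(introns, strand) {
  if (nrow(introns) == 0L) return(integer(0))
  if (strand == "-") introns[, "start"] else introns[, "end"]
}

# TRUE when `sub` occurs as a consecutive run inside `full` (both intron
# matrices in coordinate order); empty `sub` matches at any position
is_consecutive_subchain <- function(sub, full) {
  ns <- nrow(sub); nf <- nrow(full)
  if (ns == 0L) return(TRUE)
  if (ns > nf) return(FALSE)
  sk <- paste(sub[, "start"], sub[, "end"], sep = "-")
  fk <- paste(full[, "start"], full[, "end"], sep = "-")
  for (off in 0:(nf - ns)) {
    if (all(fk[off + seq_len(ns)] == sk)) return(TRUE)
  }
  FALSE
}

subchain_offset <- function(sub, full) {
  # 0-based offset of the first match of sub inside full, or NA
  ns <- nrow(sub); nf <- nrow(full)
  if (ns == 0L || ns > nf) return(NA_integer_)
  sk <- paste(sub[, "start"], sub[, "end"], sep = "-")
  fk <- paste(full[, "start"], full[, "end"], sep = "-")
  for (off in 0:(nf - ns)) {
    if (all(fk[off + seq_len(ns)] == sk)) return(off)
  }
  NA_integer_
}

# ---- annotation model --------------------------------------------------------

#' Load a reference annotation
#'
#' Reads a GTF (1-based, inclusive) or GFF3 file and builds the internal
#' annotation model: genes, transcripts with their exon structures, and the
#' per-gene splice-site and intron-chain indexes used for correction and
#' classification. All internal coordinates are 0-based half-open.
#'
#' @param path Path to a `.gtf`, `.gff` or `.gff3` file.
#' @return A `gene_annotation` object: a list with tibbles `genes`
#'   (gene_id, chrom, strand, start, end), `exons` (transcript_id, gene_id,
#'   chrom, strand, start, end, ordered), `transcripts` (one row per
#'   transcript with its intron-chain key), and `junctions` (one row per
#'   distinct gene/intron).
#' @export
read_annotation <- function(path) {
  if (check_feature_lines(path) == 0L) return(empty_annotation())
  fmt <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "gff3"
  gr <- tryCatch(
    rtracklayer::import(path, format = fmt),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(gr) == 0L) return(empty_annotation())
  md <- as_tibble(as.data.frame(gr))
  if (!"type" %in% names(md)) stop("annotation has no feature types",
                                   call. = FALSE)
  ex <- md %>% filter(.data$type == "exon")
  if (nrow(ex) == 0L) return(empty_annotation())
  tx_id <- extract_parent_id(ex, c("transcript_id", "Parent", "ID"))
  if (anyNA(tx_id)) {
    stop("exon without a transcript parent in ", path, call. = FALSE)
  }
  gene_id <- if ("gene_id" %in% names(ex)) as.character(ex$gene_id) else {
    rep(NA_character_, nrow(ex))
  }
  exons <- tibble(
    transcript_id = tx_id,
    gene_id = gene_id,
    chrom = as.character(ex$seqnames),
    strand = as.character(ex$strand),
    start = as.integer(ex$start) - 1L,   # to 0-based half-open
    end = as.integer(ex$end)
  )
  # fill gene ids from transcript features when exons lack them (GFF3)
  if (anyNA(exons$gene_id)) {
    txf <- md %>% filter(.data$type %in% c("transcript", "mRNA"))
    if (nrow(txf)) {
      tid <- extract_parent_id(txf, c("transcript_id", "ID"))
      gid <- extract_parent_id(txf, c("gene_id", "Parent"))
      map <- stats::setNames(gid, tid)
      exons$gene_id <- ifelse(is.na(exons$gene_id),
                              unname(map[exons$transcript_id]),
                              exons$gene_id)
    }
    exons$gene_id <- ifelse(is.na(exons$gene_id),
                            paste0("gene_of_", exons$transcript_id),
                            exons$gene_id)
  }
  build_annotation(exons)
}

extract_parent_id <- function(df, candidates) {
  for (col in candidates) {
    if (col %in% names(df)) {
      v <- df[[col]]
      if (is(v, "List") || is.list(v)) {
        v <- vapply(v, function(x) {
          if (length(x)) as.character(x[[1L]]) else NA_character_
        }, character(1))
      }
      v <- as.character(v)
      v <- sub("^(transcript|gene):", "", v)
      if (!all(is.na(v))) return(v)
    }
  }
  rep(NA_character_, nrow(df))
}

check_feature_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^(#|\\s*$)", lines))
  for (i in body) {
    nf <- length(strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]])
    if (nf < 8L) {
      stop("malformed feature line ", i, " in ", path, call. = FALSE)
    }
  }
  invisible(length(body))
}

empty_annotation <- function() {
  structure(list(
    genes = tibble(gene_id = character(0), chrom = character(0),
                   strand = character(0), start = integer(0), end = integer(0)),
    exons = tibble(transcript_id = character(0), gene_id = character(0),
                   chrom = character(0), strand = character(0),
                   start = integer(0), end = integer(0)),
    transcripts = tibble(transcript_id = character(0), gene_id = character(0),
                         chrom = character(0), strand = character(0),
                         start = integer(0), end = integer(0),
                         n_exons = integer(0), intron_key = character(0)),
    junctions = tibble(gene_id = character(0), chrom = character(0),
                       strand = character(0), start = integer(0),
                       end = integer(0))
  ), class = "gene_annotation")
}

# assemble the model from an exon table (internal coordinates)
build_annotation <- function(exons) {
  exons <- exons %>%
    arrange(.data$chrom, .data$transcript_id, .data$start) %>%
    distinct()
  bad <- exons %>%
    group_by(.data$transcript_id) %>%
    summarise(overlap = any(.data$start[-1L] < .data$end[-n()]) && n() > 1L,
              .groups = "drop") %>%
    filter(.data$overlap)
  if (nrow(bad)) {
    stop("overlapping exons in transcript(s): ",
         paste(bad$transcript_id, collapse = ", "), call. = FALSE)
  }
  transcripts <- exons %>%
    group_by(.data$transcript_id, .data$gene_id, .data$chrom, .data$strand) %>%
    summarise(intron_key = intron_key(introns_from_exons(.data$start,
                                                         .data$end)),
              n_exons = n(),
              start = min(.data$start), end = max(.data$end),
              .groups = "drop") %>%
    select("transcript_id", "gene_id", "chrom", "strand", "start", "end",
           "n_exons", "intron_key") %>%
    arrange(.data$chrom, .data$start, .data$transcript_id)
  genes <- transcripts %>%
    group_by(.data$gene_id, .data$chrom, .data$strand) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop") %>%
    arrange(.data$chrom, .data$start, .data$gene_id)
  spliced <- transcripts %>% filter(nzchar(.data$intron_key))
  junctions <- if (nrow(spliced)) {
    purrr::pmap_dfr(
      list(spliced$gene_id, spliced$chrom, spliced$strand, spliced$intron_key),
      function(g, c, s, k) {
        m <- parse_intron_key(k)
        tibble(gene_id = g, chrom = c, strand = s,
               start = m[, "start"], end = m[, "end"])
      }) %>%
      distinct() %>%
      arrange(.data$chrom, .data$start, .data$end)
  } else {
    tibble(gene_id = character(0), chrom = character(0), strand = character(0),
           start = integer(0), end = integer(0))
  }
  structure(list(genes = genes, exons = exons, transcripts = transcripts,
                 junctions = junctions),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("<gene_annotation> %d genes, %d transcripts, %d junctions\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$junctions)))
  invisible(x)
}

# per-gene reference chain index: intron_key -> transcript ids
gene_chain_index <- function(annotation, gene_id) {
  tx <- annotation$transcripts %>% filter(.data$gene_id == !!gene_id)
  split(tx$transcript_id, tx$intron_key)
}

# donor/acceptor site sets of one gene (strand-aware)
gene_site_sets <- function(annotation, gene_id) {
  j <- annotation$junctions %>% filter(.data$gene_id == !!gene_id)
  if (nrow(j) == 0L) {
    return(list(donors = integer(0), acceptors = integer(0),
                junctions = character(0)))
  }
  strand <- j$strand[[1L]]
  ints <- cbind(start = j$start, end = j$end)
  list(donors = unique(donor_sites(ints, strand)),
       acceptors = unique(acceptor_sites(ints, strand)),
       junctions = unique(paste0(j$start, "-", j$end)))
}

#' Write an annotation model as GFF3
#'
#' Emits gene/transcript/exon features with 1-based inclusive coordinates;
#' re-reading the file with [read_annotation()] reproduces the model.
#'
#' @param annotation A `gene_annotation` or a tibble of isoform models from
#'   discovery (with columns transcript_id, gene_id, chrom, strand and a list
#'   column `exons`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  if (inherits(annotation, "gene_annotation")) {
    exons <- annotation$exons
  } else {
    exons <- annotation
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(exons) == 0L) return(invisible(path))
  tx <- exons %>%
    group_by(.data$gene_id, .data$transcript_id, .data$chrom, .data$strand) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop") %>%
    arrange(.data$chrom, .data$start, .data$gene_id, .data$transcript_id)
  genes <- tx %>%
    group_by(.data$gene_id, .data$chrom, .data$strand) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop") %>%
    arrange(.data$chrom, .data$start, .data$gene_id)
  fmt <- function(chrom, type, s0, e0, strand, attrs) {
    sprintf("%s\tsclriso\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, s0 + 1L, e0, strand, attrs)
  }
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    writeLines(fmt(g$chrom, "gene", g$start, g$end, g$strand,
                   sprintf("ID=%s", g$gene_id)), con)
    gtx <- tx %>% filter(.data$gene_id == g$gene_id)
    for (ti in seq_len(nrow(gtx))) {
      t <- gtx[ti, ]
      writeLines(fmt(t$chrom, "transcript", t$start, t$end, t$strand,
                     sprintf("ID=%s;Parent=%s;transcript_id=%s;gene_id=%s",
                             t$transcript_id, g$gene_id, t$transcript_id,
                             g$gene_id)), con)
      tex <- exons %>%
        filter(.data$transcript_id == t$transcript_id) %>%
        arrange(.data$start)
      for (ei in seq_len(nrow(tex))) {
        e <- tex[ei, ]
        writeLines(fmt(e$chrom, "exon", e$start, e$end, e$strand,
                       sprintf("Parent=%s;transcript_id=%s;gene_id=%s",
                               t$transcript_id, t$transcript_id, g$gene_id)),
                   con)
      }
    }
  }
  invisible(path)
}
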