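#' Locate the barcode-flanking adapter in a read
#'
#' Searches both strands for the best semi-global match of the adapter that
#' sits immediately 5' of the cell barcode. The reported position is the
#' first base after the flank on the matched strand, i.e. where the barcode
#' window starts.
#'
#' @param read_seq Read sequence (character).
#' @param flank Flank sequence.
#' @param flank_max_ed Maximum edit distance tolerated.
#' @return A list `(strand, pos, edit_distance)` with `pos` the 1-based
#'   position of the first base after the flank on the matched strand, or
#'   `NULL` when no match within `flank_max_ed` exists.
#' @export
locate_flank <- function(read_seq, flank, flank_max_ed) {
  hits <- locate_flank_batch(c(read_seq), flank, flank_max_ed)
  if (is.na(hits$strand[[1L]])) return(NULL)
  list(strand = hits$strand[[1L]], pos = hits$pos[[1L]],
       edit_distance = hits$ed[[1L]])
}

# vectorized flank search over a character vector of reads; returns a tibble
# with strand (+/-/NA), pos (1-based first base after flank on that strand)
# and ed. Semi-global alignment (free end-gaps on the read, flank global)
# with unit costs, so -score is the edit distance of the best placement.
locate_flank_batch <- function(reads, flank, flank_max_ed) {
  n <- length(reads)
  out <- tibble(strand = rep(NA_character_, n), pos = rep(NA_integer_, n),
                ed = rep(NA_integer_, n))
  out$multi_hit <- logical(n)
  if (n == 0L) return(out)
  fwd <- Biostrings::DNAStringSet(reads)
  rev <- Biostrings::reverseComplement(fwd)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 0, mismatch = -1,
                                                  baseOnly = FALSE)
  best_on <- function(set) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = set, subject = Biostrings::DNAString(flank),
      type = "local-global", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 1)
    ed <- as.integer(round(-Biostrings::score(pa)))
    pos <- IRanges::end(Biostrings::pattern(pa)) + 1L
    cbind(pos = pos, ed = ed)
  }
  f <- best_on(fwd)
  r <- best_on(rev)
  f_ed <- ifelse(is.na(f[, 2L]) | f[, 2L] > flank_max_ed, NA_integer_, f[, 2L])
  r_ed <- ifelse(is.na(r[, 2L]) | r[, 2L] > flank_max_ed, NA_integer_, r[, 2L])
  use_f <- !is.na(f_ed) & (is.na(r_ed) | f_ed <= r_ed)
  use_r <- !is.na(r_ed) & !use_f
  out$strand[use_f] <- "+"; out$pos[use_f] <- f[use_f, 1L]
  out$ed[use_f] <- f_ed[use_f]
  out$strand[use_r] <- "-"; out$pos[use_r] <- r[use_r, 1L]
  out$ed[use_r] <- r_ed[use_r]
  # an in-tolerance adapter on both orientations suggests a chimeric read;
  # the better hit is kept and the event is counted
  out$multi_hit <- !is.na(f_ed) & !is.na(r_ed)
  out
}

#' Match an observed barcode window against the whitelist
#'
#' Returns the unique whitelist barcode with minimal edit distance at most
#' `max_ed`; exact matches short-circuit, and ties at the minimum distance
#' are treated as ambiguous (no assignment).
#'
#' @param observed Observed barcode-length window from the read.
#' @param whitelist Character vector of same-length barcodes.
#' @param max_ed Maximum edit distance (default 2 in the protocol).
#' @return A list `(barcode, edit_distance)` or `NULL` (no match/ambiguous).
#' @export
match_barcode <- function(observed, whitelist, max_ed) {
  if (length(whitelist) == 0L) stop("whitelist is empty", call. = FALSE)
  if (length(unique(nchar(whitelist))) != 1L) {
    stop("whitelist entries have unequal lengths", call. = FALSE)
  }
  hit <- match(observed, whitelist)
  if (!is.na(hit)) {
    return(list(barcode = whitelist[[hit]], edit_distance = 0L))
  }
  d <- as.integer(utils::adist(observed, whitelist))
  dmin <- min(d)
  if (dmin > max_ed) return(NULL)
  cand <- which(d == dmin)
  if (length(cand) > 1L) return(NULL)   # ambiguous tie
  list(barcode = whitelist[[cand]], edit_distance = dmin)
}

#' Read a barcode whitelist
#' @param path Plain-text file, one barcode per line.
#' @return Character vector of barcodes.
#' @export
read_whitelist <- function(path) {
  bc <- toupper(trimws(readLines(path, warn = FALSE)))
  bc[nzchar(bc)]
}

# scan past the oligo(dT) tail: a run of >= 4 T allowing single non-T
# interruptions, starting within the first few bases. Returns the 1-based
# position of the first payload base (position after the tail), or NA when
# no tail is found.
polyt_end <- function(seq) {
  m <- regexpr("^[ACGN]{0,3}?T{4,}([^T]T{2,})*", seq, perl = TRUE)
  if (m == -1L) return(NA_integer_)
  as.integer(attr(m, "match.length")) + 1L
}

#' Demultiplex barcoded long reads
#'
#' For each read: orient by the flank adapter, take the 16 nt barcode window,
#' match it against the whitelist (edit distance <= `barcode_max_ed`), take
#' the next `umi_length` nt as the UMI, trim the poly(T) tail (3' protocol)
#' and keep the remainder as the cDNA payload, reverse-complemented to sense
#' orientation. Reads failing any step are discarded and tallied. Matched
#' reads are written with header `{barcode}_{UMI}#{original_id}`.
#'
#' @param fastq_in Input FASTQ path.
#' @param whitelist Character vector of barcodes, or a path to a whitelist
#'   file.
#' @param config A [sclr_config()].
#' @param fastq_out Output FASTQ path for the trimmed payloads.
#' @return A list with `fastq_out`, `stats` (a one-row tibble:
#'   total_reads, matched_reads, discarded_no_flank, discarded_no_barcode,
#'   discarded_ambiguous, discarded_no_polyt, multi_flank_hits) and
#'   `ed_histogram` (barcode edit-distance counts).
#' @export
demultiplex <- function(fastq_in, whitelist, config = sclr_config(),
                        fastq_out = tempfile(fileext = ".fastq")) {
  if (length(whitelist) == 1L && file.exists(whitelist)) {
    whitelist <- read_whitelist(whitelist)
  }
  if (length(whitelist) == 0L) stop("whitelist is empty", call. = FALSE)
  bc_len <- unique(nchar(whitelist))
  if (length(bc_len) != 1L) {
    stop("whitelist entries have unequal lengths", call. = FALSE)
  }
  fq <- read_fastq(fastq_in)
  n <- nrow(fq)
  stats <- c(total_reads = n, matched_reads = 0L, discarded_no_flank = 0L,
             discarded_no_barcode = 0L, discarded_ambiguous = 0L,
             discarded_no_polyt = 0L, multi_flank_hits = 0L)
  ed_hist <- integer(config$barcode_max_ed + 1L)
  names(ed_hist) <- as.character(0:config$barcode_max_ed)
  out_id <- character(n); out_seq <- character(n); out_qual <- character(n)
  n_out <- 0L
  if (n > 0L) {
    loc <- locate_flank_batch(fq$seq, config$flank_seq, config$flank_max_ed)
    stats[["multi_flank_hits"]] <- sum(loc$multi_hit)
    keep <- !is.na(loc$strand)
    minus <- keep & loc$strand == "-"
    oriented <- fq$seq
    oriented[minus] <- revcomp(fq$seq[minus])
    oriented_q <- fq$qual
    oriented_q[minus] <- reverse_strings(fq$qual[minus])
    stats[["discarded_no_flank"]] <- sum(!keep)
    bc_obs <- substring(oriented, loc$pos, loc$pos + bc_len - 1L)
    exact <- match(bc_obs, whitelist)
    for (i in which(keep)) {
      bc <- NULL
      if (!is.na(exact[[i]]) && nchar(bc_obs[[i]]) == bc_len) {
        bc <- list(barcode = whitelist[[exact[[i]]]], edit_distance = 0L)
      } else if (nchar(bc_obs[[i]]) == bc_len) {
        d <- as.integer(utils::adist(bc_obs[[i]], whitelist))
        dmin <- min(d)
        if (dmin <= config$barcode_max_ed) {
          cand <- which(d == dmin)
          if (length(cand) == 1L) {
            bc <- list(barcode = whitelist[[cand]], edit_distance = dmin)
          } else {
            stats[["discarded_ambiguous"]] <- stats[["discarded_ambiguous"]] + 1L
            next
          }
        }
      }
      if (is.null(bc)) {
        stats[["discarded_no_barcode"]] <- stats[["discarded_no_barcode"]] + 1L
        next
      }
      umi_start <- loc$pos[[i]] + bc_len
      umi <- substring(oriented[[i]], umi_start,
                       umi_start + config$umi_length - 1L)
      rest_start <- umi_start + config$umi_length
      rest <- substring(oriented[[i]], rest_start)
      rest_q <- substring(oriented_q[[i]], rest_start)
      if (config$protocol_end == "three_prime") {
        pe <- polyt_end(rest)
        if (is.na(pe) || pe > nchar(rest)) {
          stats[["discarded_no_polyt"]] <- stats[["discarded_no_polyt"]] + 1L
          next
        }
        # after the tail the cDNA is antisense; flip to sense orientation
        payload <- substring(rest, pe)
        payload_q <- reverse_strings(substring(rest_q, pe))
      } else {
        payload <- rest
        payload_q <- rest_q
      }
      if (!nzchar(payload)) {
        stats[["discarded_no_polyt"]] <- stats[["discarded_no_polyt"]] + 1L
        next
      }
      stats[["matched_reads"]] <- stats[["matched_reads"]] + 1L
      ed_hist[[as.character(bc$edit_distance)]] <-
        ed_hist[[as.character(bc$edit_distance)]] + 1L
      n_out <- n_out + 1L
      out_id[[n_out]] <- paste0(bc$barcode, "_", umi, "#", fq$id[[i]])
      out_seq[[n_out]] <- payload
      out_qual[[n_out]] <- payload_q
    }
    if (n_out > 0L && config$protocol_end == "three_prime") {
      rc_idx <- seq_len(n_out)
      out_seq[rc_idx] <- revcomp(out_seq[rc_idx])
    }
  }
  write_fastq(tibble(id = out_id[seq_len(n_out)],
                     seq = out_seq[seq_len(n_out)],
                     qual = out_qual[seq_len(n_out)]), fastq_out)
  list(fastq_out = fastq_out,
       stats = as_tibble(as.list(stats)),
       ed_histogram = ed_hist)
}

#' Parse the demultiplexed read header convention
#'
#' Headers written by [demultiplex()] (and by the simulator's perfect
#' alignments) have the form `{barcode}_{UMI}#{original_id}`.
#'
#' @param ids Character vector of read ids.
#' @return A tibble with `barcode`, `umi`, `original_id`.
#' @export
parse_read_header <- function(ids) {
  pre <- sub("#.*$", "", ids)
  tibble(
    barcode = sub("_.*$", "", pre),
    umi = sub("^[^_]*_", "", pre),
    original_id = ifelse(grepl("#", ids, fixed = TRUE),
                         sub("^[^#]*#", "", ids), NA_character_)
  )
}

# ---- minimal FASTQ I/O (4-line records) -------------------------------------

read_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L) {
    stop("truncated FASTQ record near record ",
         length(lines) %/% 4L + 1L, " in ", path, call. = FALSE)
  }
  if (length(lines) == 0L) {
    return(tibble(id = character(0), seq = character(0), qual = character(0)))
  }
  ids <- lines[seq(1L, length(lines), by = 4L)]
  if (any(!startsWith(ids, "@"))) {
    stop("malformed FASTQ record ", which(!startsWith(ids, "@"))[[1L]],
         " in ", path, call. = FALSE)
  }
  tibble(id = sub("\\s.*$", "", sub("^@", "", ids)),
         seq = toupper(lines[seq(2L, length(lines), by = 4L)]),
         qual = lines[seq(4L, length(lines), by = 4L)])
}

write_fastq <- function(reads, path) {
  if (nrow(reads) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  qual <- if ("qual" %in% names(reads) && !anyNA(reads$qual)) reads$qual else {
    vapply(nchar(reads$seq), function(n) strrep("I", n), character(1))
  }
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", qual), path)
  invisible(path)
}
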