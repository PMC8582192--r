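#' Read spliced alignments from SAM/BAM
#'
#' Parses mapped records into the block/gap representation the pipeline works
#' with: M/=/X and D CIGAR operations consume the target without opening a
#' splice gap, I consumes only the read, and N operations become splice gaps.
#' Unmapped records are skipped; secondary and supplementary records are
#' skipped by default (the recommended aligner invocation suppresses
#' secondaries). Records whose sequence length contradicts the CIGAR are
#' skipped with a counter in the `skipped_malformed` attribute.
#'
#' @param path A `.sam` or `.bam` file. SAM is converted to BAM in a
#'   temporary directory for parsing.
#' @param keep_secondary Keep secondary/supplementary records.
#' @param keep_seq Keep the read sequence (needed for pileups).
#' @return A tibble with one row per alignment: `read_id`, `chrom`, `strand`,
#'   `start`/`end` (0-based half-open outer bounds), `blocks` and `gaps`
#'   (list columns of 0-based half-open interval matrices), `score` (AS tag,
#'   or aligned target length when absent), `read_length`, and `seq`.
#' @export
read_alignments <- function(path, keep_secondary = FALSE, keep_seq = TRUE) {
  bam <- ensure_bam(path)
  what <- c("qname", "flag", "rname", "pos", "cigar", "mapq")
  if (keep_seq) what <- c(what, "seq")
  param <- Rsamtools::ScanBamParam(
    what = what, tag = "AS",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  res <- Rsamtools::scanBam(bam, param = param)[[1L]]
  n <- length(res$qname)
  if (n == 0L) return(empty_alignments())
  flag <- res$flag
  keep <- rep(TRUE, n)
  if (!keep_secondary) {
    keep <- bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L
  }
  cigar <- res$cigar
  qwidth <- GenomicAlignments::cigarWidthAlongQuerySpace(
    cigar, after.soft.clipping = FALSE)
  seqs <- if (keep_seq) as.character(res$seq) else rep(NA_character_, n)
  malformed <- keep_seq & !is.na(seqs) & seqs != "*" & nchar(seqs) != qwidth
  n_malformed <- sum(malformed & keep)
  keep <- keep & !malformed
  idx <- which(keep)
  if (length(idx) == 0L) {
    out <- empty_alignments()
    attr(out, "skipped_malformed") <- n_malformed
    return(out)
  }
  cig <- cigar[idx]
  pos <- res$pos[idx]
  blocks <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, pos = pos, ops = c("M", "=", "X", "D"), reduce.ranges = TRUE)
  gaps <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, pos = pos, ops = "N")
  bs <- as.list(IRanges::start(blocks)); be <- as.list(IRanges::end(blocks))
  gs <- as.list(IRanges::start(gaps)); ge <- as.list(IRanges::end(gaps))
  blk <- lapply(seq_along(idx), function(i) {
    cbind(start = bs[[i]] - 1L, end = be[[i]])
  })
  gp <- lapply(seq_along(idx), function(i) {
    cbind(start = gs[[i]] - 1L, end = ge[[i]])
  })
  score <- rep(NA_real_, length(idx))
  if (!is.null(res$tag$AS)) score <- as.numeric(res$tag$AS[idx])
  ref_width <- vapply(blk, function(m) sum(m[, "end"] - m[, "start"]),
                      numeric(1))
  score[is.na(score)] <- ref_width[is.na(score)]
  out <- tibble(
    read_id = res$qname[idx],
    chrom = as.character(res$rname[idx]),
    strand = ifelse(bitwAnd(res$flag[idx], 16L) != 0L, "-", "+"),
    start = vapply(blk, function(m) m[1L, "start"], integer(1)),
    end = vapply(blk, function(m) m[nrow(m), "end"], integer(1)),
    blocks = blk,
    gaps = gp,
    score = score,
    read_length = qwidth[idx],
    seq = seqs[idx]
  )
  attr(out, "skipped_malformed") <- n_malformed
  out
}

empty_alignments <- function() {
  tibble(read_id = character(0), chrom = character(0), strand = character(0),
         start = integer(0), end = integer(0), blocks = list(), gaps = list(),
         score = numeric(0), read_length = integer(0), seq = character(0))
}

ensure_bam <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    if (!file.exists(paste0(path, ".bai"))) {
      try(Rsamtools::indexBam(path), silent = TRUE)
    }
    return(path)
  }
  dest <- tempfile(fileext = "")
  Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                   indexDestination = TRUE)
  paste0(dest, ".bam")
}

# write a minimal SAM file from a tibble with read_id, chrom, pos0, strand,
# cigar, seq (used by the simulator; qual filled with constant quality)
write_sam <- function(records, contig_lengths, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (nm in names(contig_lengths)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, contig_lengths[[nm]]), con)
  }
  if (nrow(records) == 0L) return(invisible(path))
  flag <- ifelse(records$strand == "-", 16L, 0L)
  qual <- vapply(nchar(records$seq), function(n) strrep("I", n), character(1))
  writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                     records$read_id, flag, records$chrom,
                     records$pos0 + 1L, records$cigar, records$seq, qual),
             con)
  invisible(path)
}
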