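#' Load a genome FASTA
#'
#' @param path FASTA path (plain or gzipped).
#' @return A named [Biostrings::DNAStringSet]; names are truncated at the
#'   first whitespace, matching SAM/GTF contig naming.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Extract transcript sequences from the genome
#'
#' Concatenates each transcript's exon sequences 5' to 3'; minus-strand
#' transcripts are reverse-complemented. Used to build the updated transcript
#' reference after isoform discovery.
#'
#' @param annotation A `gene_annotation` (or any object with an `exons`
#'   tibble holding transcript_id, chrom, strand, start, end in 0-based
#'   half-open coordinates).
#' @param genome A named `DNAStringSet` from [read_genome()].
#' @return A `DNAStringSet` named by transcript id, ordered by transcript id.
#' @export
extract_transcript_sequences <- function(annotation, genome) {
  exons <- if (inherits(annotation, "gene_annotation")) annotation$exons else annotation
  if (nrow(exons) == 0L) return(Biostrings::DNAStringSet())
  missing <- setdiff(unique(exons$chrom), names(genome))
  if (length(missing)) {
    stop("contig(s) absent from genome: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  if (any(exons$end > lens[exons$chrom] | exons$start < 0L)) {
    stop("exon interval outside contig bounds", call. = FALSE)
  }
  ids <- sort(unique(exons$transcript_id))
  seqs <- vapply(ids, function(tx) {
    e <- exons[exons$transcript_id == tx, ]
    e <- e[order(e$start), ]
    chrom <- e$chrom[[1L]]
    pieces <- substring(as.character(genome[[chrom]]), e$start + 1L, e$end)
    s <- paste(pieces, collapse = "")
    if (e$strand[[1L]] == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    s
  }, character(1))
  Biostrings::DNAStringSet(stats::setNames(seqs, ids))
}

#' Write sequences as FASTA
#' @param seqs A named `DNAStringSet` (or named character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

reverse_strings <- function(x) {
  if (length(x) == 0L) return(character(0))
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1),
         USE.NAMES = FALSE)
}
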