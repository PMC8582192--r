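# Independent brute-force oracles used to check the package's fast paths.
# These deliberately re-derive results from first principles and share no
# code with the implementation.

# step-by-step CIGAR interpreter: returns 0-based half-open blocks (M/=/X/D
# merged) and splice gaps (N)
brute_cigar <- function(cigar, pos0) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  len <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^\\d+", "", ops)
  blocks <- list(); gaps <- list()
  t <- pos0
  cur_start <- NA_integer_
  for (i in seq_along(op)) {
    o <- op[[i]]; l <- len[[i]]
    if (o %in% c("M", "=", "X", "D")) {
      if (is.na(cur_start)) cur_start <- t
      t <- t + l
    } else if (o == "N") {
      if (!is.na(cur_start)) {
        blocks[[length(blocks) + 1L]] <- c(cur_start, t)
        cur_start <- NA_integer_
      }
      gaps[[length(gaps) + 1L]] <- c(t, t + l)
      t <- t + l
    }
    # I/S/H/P consume no reference
  }
  if (!is.na(cur_start)) blocks[[length(blocks) + 1L]] <- c(cur_start, t)
  list(blocks = do.call(rbind, blocks), gaps = if (length(gaps)) {
    do.call(rbind, gaps)
  } else matrix(integer(0), ncol = 2))
}

random_cigar <- function(max_ops = 20L) {
  n <- sample(1:max_ops, 1L)
  ops <- sample(c("M", "I", "D", "N"), n, replace = TRUE,
                prob = c(0.6, 0.1, 0.1, 0.2))
  # must start and end with M, no adjacent N
  ops[c(1L, n)] <- "M"
  for (i in seq_len(n - 1L)) {
    if (ops[[i]] == "N" && ops[[i + 1L]] == "N") ops[[i + 1L]] <- "M"
  }
  len <- ifelse(ops == "N", sample(30:200, n, replace = TRUE),
                sample(1:50, n, replace = TRUE))
  paste0(len, ops, collapse = "")
}

# read length implied by a CIGAR (query-consuming ops)
cigar_qlen <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  len <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^\\d+", "", ops)
  sum(len[op %in% c("M", "I", "S", "=", "X")])
}

# Benjamini-Hochberg step-up from the definition
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  sorted <- p[o]
  for (i in seq_len(m)) {
    q[i] <- min(pmin(1, sorted[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# closed-form 2x2 Pearson chi-square
brute_chisq_2x2 <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# O(n^2) transitive-closure clustering of UMIs at edit distance <= max_ed
brute_umi_clusters <- function(umis, max_ed) {
  u <- unique(umis)
  k <- length(u)
  comp <- seq_len(k)
  repeat {
    changed <- FALSE
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (comp[i] != comp[j] &&
          utils::adist(u[i], u[j]) <= max_ed) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  stats::setNames(match(comp, unique(comp)), u)
}

# definitional transcript classifier: chain key vs a reference transcript
# table (tibble with chrom, strand, start, end, intron_key) and per-gene
# donor/acceptor site sets
brute_classify <- function(chrom, strand, start, end, key, ref_tx,
                           donors, acceptors) {
  cand <- ref_tx[ref_tx$chrom == chrom & ref_tx$strand == strand, ]
  if (nrow(cand) == 0L) return("other")
  ints <- function(k) {
    if (!nzchar(k)) return(matrix(integer(0), ncol = 2))
    do.call(rbind, lapply(strsplit(k, ",")[[1L]], function(s) {
      as.integer(strsplit(s, "-")[[1L]])
    }))
  }
  if (!nzchar(key)) {
    mono <- cand[!nzchar(cand$intron_key) & cand$start <= start &
                   cand$end >= end, ]
    return(if (nrow(mono)) "FSM" else "other")
  }
  if (any(cand$intron_key == key)) return("FSM")
  m <- ints(key)
  for (rk in cand$intron_key[nzchar(cand$intron_key)]) {
    r <- ints(rk)
    if (nrow(m) > nrow(r)) next
    for (off in 0:(nrow(r) - nrow(m))) {
      seg <- r[off + seq_len(nrow(m)), , drop = FALSE]
      if (all(seg == m)) return("ISM")
    }
  }
  dn <- if (strand == "-") m[, 2] else m[, 1]
  ac <- if (strand == "-") m[, 1] else m[, 2]
  if (all(dn %in% donors) && all(ac %in% acceptors)) "NIC" else "NNC"
}

# small annotation fixture: two genes on opposite strands, multiple isoforms
fixture_annotation <- function() {
  gtf <- tempfile(fileext = ".gtf")
  lines <- c(
    gtf_line("chr1", "exon", 101, 200, "+", "g1", "g1.t1"),
    gtf_line("chr1", "exon", 301, 400, "+", "g1", "g1.t1"),
    gtf_line("chr1", "exon", 501, 600, "+", "g1", "g1.t1"),
    gtf_line("chr1", "exon", 701, 800, "+", "g1", "g1.t1"),
    # t2 skips the exon [301,400]
    gtf_line("chr1", "exon", 101, 200, "+", "g1", "g1.t2"),
    gtf_line("chr1", "exon", 501, 600, "+", "g1", "g1.t2"),
    gtf_line("chr1", "exon", 701, 800, "+", "g1", "g1.t2"),
    # minus-strand gene
    gtf_line("chr1", "exon", 2001, 2100, "-", "g2", "g2.t1"),
    gtf_line("chr1", "exon", 2201, 2300, "-", "g2", "g2.t1"),
    gtf_line("chr1", "exon", 2401, 2500, "-", "g2", "g2.t1"),
    # mono-exon gene
    gtf_line("chr1", "exon", 3001, 3500, "+", "g3", "g3.t1")
  )
  writeLines(lines, gtf)
  gtf
}

gtf_line <- function(chrom, type, start, end, strand, gene, tx) {
  sprintf(paste0("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\t",
                 "gene_id \"%s\"; transcript_id \"%s\";"),
          chrom, type, start, end, strand, gene, tx)
}

# write a SAM file from (read_id, chrom, pos0, strand, cigar) rows with
# sequences matching the CIGAR query length
write_test_sam <- function(rows, contig_lengths, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6", con)
  for (nm in names(contig_lengths)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, contig_lengths[[nm]]), con)
  }
  for (i in seq_len(nrow(rows))) {
    qlen <- cigar_qlen(rows$cigar[[i]])
    seq <- paste(rep("A", qlen), collapse = "")
    flag <- if (!is.null(rows$strand) && rows$strand[[i]] == "-") 16L else 0L
    writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                       rows$read_id[[i]], flag, rows$chrom[[i]],
                       rows$pos0[[i]] + 1L, rows$cigar[[i]], seq,
                       strrep("I", qlen)), con)
  }
  path
}
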