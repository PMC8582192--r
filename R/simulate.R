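# Deterministic synthetic-data generator: toy genome and multi-isoform gene
# models, cluster-specific isoform usage, barcoded error-bearing reads with
# the adapter+barcode+UMI+polyT structure, "perfect" spliced alignments (the
# pre-error coordinates, so no aligner is needed), and ground-truth tables.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random barcodes with pairwise edit distance > min_dist
separated_barcodes <- function(n, length, min_dist) {
  out <- character(0)
  while (length(out) < n) {
    cand <- random_dna(length)
    if (length(out) == 0L ||
        min(utils::adist(cand, out)) > min_dist) {
      out <- c(out, cand)
    }
  }
  out
}

#' Build a simulation design
#'
#' The design records every knob of the generator: the gene/isoform
#' structure, the cell population with cluster-specific isoform usage, the
#' read structure and error model, and planted subclonal SNVs. Defaults
#' emulate a realistic nanopore 3' 10x experiment at desk scale: 5%
#' substitutions, 2% indels, 20% truncated reads.
#'
#' @param seed Integer seed; all outputs are reproducible from
#'   (design, seed).
#' @param n_genes Number of genes.
#' @param isoforms_per_gene Range (min, max) of isoforms per gene.
#' @param n_exons Range of exons of the base isoform.
#' @param exon_len,intron_len Ranges (bp).
#' @param intergenic Spacing between gene loci (bp).
#' @param n_clusters Number of cell clusters.
#' @param cells_per_cluster Cells per cluster.
#' @param reads_per_cell Molecules (reads) per cell.
#' @param sub_rate,ins_rate,del_rate Per-base error rates for the FASTQ
#'   reads; substitutions also corrupt the perfect alignments' sequences.
#' @param truncation_prob Probability a molecule's read is 5'-truncated.
#' @param truncation_frac Range of the truncated (removed) fraction.
#' @param junction_jitter_prob Probability each junction boundary of an
#'   alignment is jittered.
#' @param junction_jitter_max Maximum jitter (bp, +/-).
#' @param dtu_genes Indices of genes given a cluster-switched isoform usage
#'   (top two isoforms at `dtu_usage` vs reversed).
#' @param dtu_usage Usage proportion of the major isoform in the first
#'   cluster for switched genes.
#' @param n_snvs Number of planted subclonal SNVs.
#' @param snv_cluster Carrier cluster (index) of planted SNVs.
#' @param snv_af Per-carrier-cell allele frequency of planted SNVs.
#' @param umi_length,barcode_length Read-structure lengths (nt).
#' @param flank_seq Adapter flanking the barcode.
#' @param polyt_len Length of the oligo(dT) stretch in reads.
#' @return An `sclr_sim_design` list.
#' @export
sim_design <- function(seed = 1L,
                       n_genes = 20L,
                       isoforms_per_gene = c(2L, 3L),
                       n_exons = c(3L, 6L),
                       exon_len = c(100L, 300L),
                       intron_len = c(80L, 400L),
                       intergenic = 1000L,
                       n_clusters = 2L,
                       cells_per_cluster = 50L,
                       reads_per_cell = 200L,
                       sub_rate = 0.05,
                       ins_rate = 0.01,
                       del_rate = 0.01,
                       truncation_prob = 0.2,
                       truncation_frac = c(0.3, 0.6),
                       junction_jitter_prob = 0,
                       junction_jitter_max = 2L,
                       dtu_genes = integer(0),
                       dtu_usage = 0.8,
                       n_snvs = 0L,
                       snv_cluster = 1L,
                       snv_af = 1.0,
                       umi_length = 10L,
                       barcode_length = 16L,
                       flank_seq = "CTACACGACGCTCTTCCGATCT",
                       polyt_len = 12L) {
  design <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 isoforms_per_gene = as.integer(isoforms_per_gene),
                 n_exons = as.integer(n_exons),
                 exon_len = as.integer(exon_len),
                 intron_len = as.integer(intron_len),
                 intergenic = as.integer(intergenic),
                 n_clusters = as.integer(n_clusters),
                 cells_per_cluster = as.integer(cells_per_cluster),
                 reads_per_cell = as.integer(reads_per_cell),
                 sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate,
                 truncation_prob = truncation_prob,
                 truncation_frac = truncation_frac,
                 junction_jitter_prob = junction_jitter_prob,
                 junction_jitter_max = as.integer(junction_jitter_max),
                 dtu_genes = as.integer(dtu_genes),
                 dtu_usage = dtu_usage,
                 n_snvs = as.integer(n_snvs),
                 snv_cluster = as.integer(snv_cluster),
                 snv_af = snv_af,
                 umi_length = as.integer(umi_length),
                 barcode_length = as.integer(barcode_length),
                 flank_seq = flank_seq,
                 polyt_len = as.integer(polyt_len))
  rates <- c(design$sub_rate, design$ins_rate, design$del_rate,
             design$truncation_prob, design$junction_jitter_prob)
  stopifnot(all(rates >= 0 & rates <= 1),
            design$isoforms_per_gene[1] >= 1L,
            design$n_exons[1] >= 2L,
            design$intron_len[1] >= 40L,
            design$dtu_usage > 0 && design$dtu_usage < 1)
  structure(design, class = "sclr_sim_design")
}

rint <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n) else
    sample(range[1]:range[2], n, replace = TRUE)
}

# sample one element of a vector (safe for length-1 vectors)
sample1 <- function(v) v[[sample.int(length(v), 1L)]]

# one gene model: base isoform + variants via exon skipping / alternative
# sites / intron retention, all chains distinct
simulate_gene <- function(design, gene_id, chrom, offset, strand) {
  ne <- rint(1L, design$n_exons)
  elen <- rint(ne, design$exon_len)
  ilen <- rint(ne - 1L, design$intron_len)
  starts <- integer(ne); ends <- integer(ne)
  pos <- offset
  for (i in seq_len(ne)) {
    starts[[i]] <- pos
    ends[[i]] <- pos + elen[[i]]
    pos <- ends[[i]] + if (i < ne) ilen[[i]] else 0L
  }
  base <- cbind(start = starts, end = ends)
  isoforms <- list(base)
  n_iso <- rint(1L, design$isoforms_per_gene)
  guard <- 0L
  while (length(isoforms) < n_iso && guard < 50L) {
    guard <- guard + 1L
    op <- sample(c("skip", "alt5", "alt3", "retain"), 1L)
    ex <- base
    ne_b <- nrow(ex)
    cand <- switch(op,
      skip = if (ne_b >= 3L) {
        k <- sample1(2:(ne_b - 1L))
        ex[-k, , drop = FALSE]
      },
      alt5 = {                         # move an internal exon's right edge
        k <- sample1(seq_len(ne_b - 1L))
        gap <- ex[k + 1L, "start"] - ex[k, "end"]
        if (gap < 45L) NULL else {
          ex[k, "end"] <- ex[k, "end"] + sample1(8:min(30L, gap - 35L))
          ex
        }
      },
      alt3 = {                         # move an internal exon's left edge
        k <- sample1(2:ne_b)
        gap <- ex[k, "start"] - ex[k - 1L, "end"]
        if (gap < 45L) NULL else {
          ex[k, "start"] <- ex[k, "start"] - sample1(8:min(30L, gap - 35L))
          ex
        }
      },
      retain = if (ne_b >= 3L) {       # keep an internal intron (not the
        k <- sample1(seq_len(ne_b - 2L))  # last, to avoid pure 3' subsets)
        merged <- ex
        merged[k, "end"] <- merged[k + 1L, "end"]
        merged[-(k + 1L), , drop = FALSE]
      })
    if (is.null(cand)) next
    key <- intron_key(introns_from_exons(cand[, "start"], cand[, "end"]))
    keys <- vapply(isoforms, function(m) {
      intron_key(introns_from_exons(m[, "start"], m[, "end"]))
    }, character(1))
    if (key %in% keys) next
    isoforms <- c(isoforms, list(cand))
  }
  purrr::imap_dfr(isoforms, function(m, i) {
    tibble(transcript_id = sprintf("%s.t%d", gene_id, i),
           gene_id = gene_id, chrom = chrom, strand = strand,
           start = as.integer(m[, "start"]), end = as.integer(m[, "end"]))
  })
}

#' Simulate a toy genome and multi-isoform annotation
#'
#' Gene loci are spaced along one contig with `intergenic` bp between them;
#' each gene gets a base isoform and variants built by exon skipping,
#' alternative 5'/3' sites and intron retention, so every classification
#' category is representable. Planted SNV positions are chosen inside each
#' carrier gene's 3'-terminal exon (covered even by truncated reads),
#' avoiding homopolymer runs.
#'
#' @param design An [sim_design()].
#' @return A list: `genome` (DNAStringSet), `annotation`
#'   (`gene_annotation`), `variants` (tibble chrom, pos, ref, alt, gene_id,
#'   cluster, af).
#' @export
simulate_transcriptome <- function(design) {
  with_seed(design$seed, {
    if (design$n_genes == 0L) {
      return(list(genome = Biostrings::DNAStringSet(),
                  annotation = empty_annotation(),
                  variants = empty_truth_variants()))
    }
    chrom <- "chr1"
    exon_rows <- list()
    offset <- design$intergenic
    strands <- sample(c("+", "-"), design$n_genes, replace = TRUE)
    for (g in seq_len(design$n_genes)) {
      gid <- sprintf("gene%02d", g)
      ex <- simulate_gene(design, gid, chrom, offset, strands[[g]])
      exon_rows[[g]] <- ex
      offset <- max(ex$end) + design$intergenic
    }
    exons <- bind_rows(exon_rows)
    genome_len <- max(exons$end) + design$intergenic
    seq <- random_dna(genome_len)
    annotation <- build_annotation(exons)
    # plant subclonal SNVs in 3'-terminal exons of distinct genes
    variants <- empty_truth_variants()
    if (design$n_snvs > 0L) {
      mask_runs <- function(s) homopolymer_mask(
        Biostrings::DNAStringSet(c(chr1 = s)), 4L)$chr1
      masked <- mask_runs(seq)
      carrier_genes <- sample(sprintf("gene%02d", seq_len(design$n_genes)),
                              design$n_snvs)
      rows <- lapply(carrier_genes, function(gid) {
        tx <- annotation$transcripts %>% filter(.data$gene_id == gid)
        ex <- annotation$exons %>%
          filter(.data$transcript_id == tx$transcript_id[[1L]]) %>%
          arrange(.data$start)
        term <- if (tx$strand[[1L]] == "+") ex[nrow(ex), ] else ex[1L, ]
        cand <- setdiff(seq(term$start + 5L, term$end - 6L), masked)
        pos <- sample1(cand)
        ref <- substring(seq, pos + 1L, pos + 1L)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
        tibble(chrom = "chr1", pos = as.integer(pos), ref = ref, alt = alt,
               gene_id = gid,
               cluster = sprintf("cluster%d", design$snv_cluster),
               af = design$snv_af)
      })
      variants <- bind_rows(rows)
    }
    list(genome = Biostrings::DNAStringSet(c(chr1 = seq)),
         annotation = annotation, variants = variants)
  })
}

empty_truth_variants <- function() {
  tibble(chrom = character(0), pos = integer(0), ref = character(0),
         alt = character(0), gene_id = character(0), cluster = character(0),
         af = numeric(0))
}

# per-gene, per-cluster isoform usage proportions
usage_matrix <- function(design, annotation) {
  genes <- split(annotation$transcripts$transcript_id,
                 annotation$transcripts$gene_id)
  rows <- purrr::imap_dfr(genes, function(txs, gid) {
    k <- length(txs)
    gnum <- as.integer(sub("gene", "", gid))
    purrr::map_dfr(seq_len(design$n_clusters), function(cl) {
      if (gnum %in% design$dtu_genes && k >= 2L) {
        p <- rep(0, k)
        major <- if (cl == 1L) 1L else 2L
        minor <- if (cl == 1L) 2L else 1L
        p[major] <- design$dtu_usage
        p[minor] <- 1 - design$dtu_usage
      } else {
        # shared across clusters: deterministic decreasing mix
        w <- rev(seq_len(k))
        p <- w / sum(w)
      }
      tibble(gene_id = gid, transcript_id = txs,
             cluster = sprintf("cluster%d", cl), prob = p)
    })
  })
  rows %>% filter(.data$prob > 0)
}

# vectorized i.i.d. per-base corruption: substitutions, insertions, deletions
corrupt_seqs <- function(seqs, sub_rate, ins_rate, del_rate) {
  if (sub_rate == 0 && ins_rate == 0 && del_rate == 0) return(seqs)
  chars <- strsplit(seqs, "", fixed = TRUE)
  lens <- lengths(chars)
  v <- unlist(chars, use.names = FALSE)
  idx <- rep.int(seq_along(seqs), lens)
  n <- length(v)
  bases <- c("A", "C", "G", "T")
  if (sub_rate > 0) {
    m <- stats::runif(n) < sub_rate
    if (any(m)) {
      shift <- sample.int(3L, sum(m), replace = TRUE)
      cur <- match(v[m], bases)
      cur[is.na(cur)] <- 1L
      v[m] <- bases[((cur - 1L + shift) %% 4L) + 1L]
    }
  }
  piece <- v
  if (del_rate > 0) {
    piece[stats::runif(n) < del_rate] <- ""
  }
  if (ins_rate > 0) {
    m <- stats::runif(n) < ins_rate
    if (any(m)) {
      piece[m] <- paste0(piece[m], sample(bases, sum(m), replace = TRUE))
    }
  }
  out <- vapply(split(piece, idx), paste, character(1), collapse = "")
  unname(out[as.character(seq_along(seqs))])
}

#' Simulate barcoded long reads with ground truth
#'
#' Draws molecules per cell according to the cluster-specific isoform usage,
#' assigns each a unique UMI (unique at the dedup edit distance within its
#' cell/gene group), optionally 5'-truncates, plants SNVs in carrier cells,
#' and emits (a) FASTQ reads with the adapter+barcode+UMI+polyT+cDNA
#' structure corrupted at the configured error rates, and (b) "perfect"
#' spliced alignment records at the pre-error coordinates (substitution
#' errors and junction jitter applied) so tests need no aligner.
#'
#' @param design An [sim_design()].
#' @param transcriptome Output of [simulate_transcriptome()].
#' @return A list: `reads` (per-read truth tibble), `fastq` (tibble id, seq,
#'   qual), `sam` (tibble of alignment fields), `truth_counts` (long
#'   transcript x cell UMI counts), `labels` (barcode, cluster), `whitelist`
#'   (character), `variants` (truth variant tibble).
#' @export
simulate_reads <- function(design, transcriptome) {
  annotation <- transcriptome$annotation
  genome_seq <- if (length(transcriptome$genome)) {
    as.character(transcriptome$genome[[1L]])
  } else ""
  with_seed(design$seed + 1L, {
    n_cells <- design$n_clusters * design$cells_per_cluster
    whitelist <- separated_barcodes(n_cells, design$barcode_length, 6L)
    labels <- tibble(
      barcode = whitelist,
      cluster = rep(sprintf("cluster%d", seq_len(design$n_clusters)),
                    each = design$cells_per_cluster))
    if (nrow(annotation$transcripts) == 0L || design$reads_per_cell == 0L) {
      return(list(reads = tibble(), fastq = tibble(id = character(0),
                                                   seq = character(0),
                                                   qual = character(0)),
                  sam = tibble(), truth_counts = tibble(), labels = labels,
                  whitelist = whitelist,
                  variants = transcriptome$variants))
    }
    usage <- usage_matrix(design, annotation)
    tx_info <- annotation$transcripts
    exon_list <- lapply(stats::setNames(tx_info$transcript_id,
                                        tx_info$transcript_id),
                        function(tid) {
      e <- annotation$exons %>% filter(.data$transcript_id == tid) %>%
        arrange(.data$start)
      cbind(start = e$start, end = e$end)
    })
    tx_strand <- stats::setNames(tx_info$strand, tx_info$transcript_id)
    tx_gene <- stats::setNames(tx_info$gene_id, tx_info$transcript_id)
    # molecules: per cell, reads_per_cell draws over gene (uniform) then
    # isoform (cluster usage)
    mols <- purrr::map_dfr(seq_len(n_cells), function(ci) {
      cl <- labels$cluster[[ci]]
      u <- usage %>% filter(.data$cluster == cl)
      genes <- unique(u$gene_id)
      g_draw <- sample(genes, design$reads_per_cell, replace = TRUE)
      tx_draw <- vapply(g_draw, function(g) {
        ug <- u[u$gene_id == g, ]
        sample(ug$transcript_id, 1L, prob = ug$prob)
      }, character(1), USE.NAMES = FALSE)
      tibble(barcode = labels$barcode[[ci]], cluster = cl,
             transcript_id = tx_draw)
    })
    # unique UMIs within each (cell, gene) group at distance > 2
    mols$gene_id <- unname(tx_gene[mols$transcript_id])
    mols$umi <- NA_character_
    grp <- paste0(mols$barcode, "\r", mols$gene_id)
    for (idx in split(seq_len(nrow(mols)), grp)) {
      got <- character(0)
      for (i in idx) {
        repeat {
          u <- random_dna(design$umi_length)
          if (length(got) == 0L || min(utils::adist(u, got)) > 2L) break
        }
        got <- c(got, u)
        mols$umi[[i]] <- u
      }
    }
    n_mol <- nrow(mols)
    mols$read_id <- sprintf("%s_%s#r%06d", mols$barcode, mols$umi,
                            seq_len(n_mol))
    # truncation: remove a fraction from the transcript 5' end
    mols$truncated <- stats::runif(n_mol) < design$truncation_prob
    trunc_frac <- stats::runif(n_mol, design$truncation_frac[1],
                               design$truncation_frac[2])
    # carrier cells for planted SNVs
    variants <- transcriptome$variants
    blocks_list <- vector("list", n_mol)
    for (i in seq_len(n_mol)) {
      ex <- exon_list[[mols$transcript_id[[i]]]]
      if (mols$truncated[[i]]) {
        txlen <- sum(ex[, "end"] - ex[, "start"])
        cut <- as.integer(round(trunc_frac[[i]] * txlen))
        strand <- tx_strand[[mols$transcript_id[[i]]]]
        # 5' end is the left side on "+", the right side on "-"
        ex <- trim_blocks(ex, cut, from_left = strand == "+")
      }
      if (design$junction_jitter_prob > 0 && nrow(ex) > 1L) {
        jmax <- design$junction_jitter_max
        deltas <- c(-jmax:-1, 1:jmax)
        for (k in seq_len(nrow(ex) - 1L)) {
          if (stats::runif(1) < design$junction_jitter_prob) {
            d <- sample1(deltas)
            if (ex[k, "end"] + d - ex[k, "start"] >= 10L) {
              ex[k, "end"] <- ex[k, "end"] + d
            }
          }
          if (stats::runif(1) < design$junction_jitter_prob) {
            d <- sample1(deltas)
            if (ex[k + 1L, "end"] - (ex[k + 1L, "start"] + d) >= 10L) {
              ex[k + 1L, "start"] <- ex[k + 1L, "start"] + d
            }
          }
        }
      }
      blocks_list[[i]] <- ex
    }
    # genome-orientation sequence of each molecule's blocks
    sam_seq <- vapply(blocks_list, function(ex) {
      paste(substring(genome_seq, ex[, "start"] + 1L, ex[, "end"]),
            collapse = "")
    }, character(1))
    # plant SNVs into carrier cells' sequences
    if (nrow(variants)) {
      carrier <- stats::setNames(labels$cluster, labels$barcode)
      for (vi in seq_len(nrow(variants))) {
        vpos <- variants$pos[[vi]]
        in_cluster <- carrier[mols$barcode] == variants$cluster[[vi]]
        for (i in which(in_cluster)) {
          ex <- blocks_list[[i]]
          hit <- which(ex[, "start"] <= vpos & ex[, "end"] > vpos)
          if (length(hit) == 0L) next
          if (stats::runif(1) > variants$af[[vi]]) next
          off <- vpos - ex[hit, "start"] +
            (if (hit > 1L) sum(ex[seq_len(hit - 1L), "end"] -
                                 ex[seq_len(hit - 1L), "start"]) else 0L) + 1L
          substring(sam_seq[[i]], off, off) <- variants$alt[[vi]]
        }
      }
    }
    # substitution errors on the aligned sequences (coordinates unchanged)
    sam_seq_err <- corrupt_seqs(sam_seq, design$sub_rate, 0, 0)
    cigar <- vapply(blocks_list, function(ex) {
      ne <- nrow(ex)
      ops <- sprintf("%dM", ex[, "end"] - ex[, "start"])
      if (ne > 1L) {
        gaps <- sprintf("%dN", ex[-1L, "start"] - ex[-ne, "end"])
        paste0(paste0(ops[-ne], gaps, collapse = ""), ops[[ne]])
      } else ops
    }, character(1))
    sam <- tibble(read_id = mols$read_id, chrom = "chr1",
                  pos0 = vapply(blocks_list, function(ex) ex[1L, "start"],
                                integer(1)),
                  strand = unname(tx_strand[mols$transcript_id]),
                  cigar = cigar, seq = sam_seq_err)
    # FASTQ: adapter + barcode + UMI + polyT + antisense cDNA, corrupted
    sense <- ifelse(sam$strand == "-", revcomp(sam_seq_err), sam_seq_err)
    raw <- paste0(design$flank_seq, mols$barcode, mols$umi,
                  strrep("T", design$polyt_len), revcomp(sense))
    fq_seq <- corrupt_seqs(raw, 0, design$ins_rate, design$del_rate)
    fastq <- tibble(id = sub("^[^#]*#", "", mols$read_id), seq = fq_seq,
                    qual = vapply(nchar(fq_seq), function(n) strrep("I", n),
                                  character(1)))
    truth_counts <- mols %>%
      count(.data$transcript_id, .data$gene_id, .data$barcode,
            name = "count") %>%
      arrange(.data$transcript_id, .data$barcode)
    list(reads = mols %>% select("read_id", "barcode", "umi", "cluster",
                                 "gene_id", "transcript_id", "truncated"),
         fastq = fastq, sam = sam, truth_counts = truth_counts,
         labels = labels, whitelist = whitelist, variants = variants)
  })
}

# remove `cut` transcript bases from one side of an exon block matrix
trim_blocks <- function(ex, cut, from_left) {
  if (cut <= 0L) return(ex)
  widths <- ex[, "end"] - ex[, "start"]
  total <- sum(widths)
  cut <- min(cut, total - 30L)          # keep at least 30 bp
  if (cut <= 0L) return(ex)
  if (from_left) {
    k <- 1L
    while (cut >= widths[[k]]) {
      cut <- cut - widths[[k]]
      k <- k + 1L
    }
    ex <- ex[k:nrow(ex), , drop = FALSE]
    ex[1L, "start"] <- ex[1L, "start"] + cut
  } else {
    k <- nrow(ex)
    while (cut >= widths[[k]]) {
      cut <- cut - widths[[k]]
      k <- k - 1L
    }
    ex <- ex[seq_len(k), , drop = FALSE]
    ex[k, "end"] <- ex[k, "end"] - cut
  }
  ex
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: [simulate_transcriptome()] then [simulate_reads()].
#'
#' @param design An [sim_design()].
#' @return A list combining both outputs (`genome`, `annotation`, `reads`,
#'   `fastq`, `sam`, `truth_counts`, `labels`, `whitelist`, `variants`).
#' @export
simulate_dataset <- function(design) {
  txome <- simulate_transcriptome(design)
  sim <- simulate_reads(design, txome)
  c(list(genome = txome$genome, annotation = txome$annotation), sim)
}

#' Write a simulated dataset to disk
#'
#' @param sim Output of [simulate_dataset()].
#' @param out_dir Output directory: writes `genome.fa`, `truth.gff3`,
#'   `reads.fastq`, `perfect.sam`, `truth_counts.csv`, `clusters.csv`,
#'   `whitelist.txt`, `truth_variants.csv`.
#' @return Named vector of paths, invisibly.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(out_dir, "genome.fa"),
    gff3 = file.path(out_dir, "truth.gff3"),
    fastq = file.path(out_dir, "reads.fastq"),
    sam = file.path(out_dir, "perfect.sam"),
    counts = file.path(out_dir, "truth_counts.csv"),
    clusters = file.path(out_dir, "clusters.csv"),
    whitelist = file.path(out_dir, "whitelist.txt"),
    variants = file.path(out_dir, "truth_variants.csv"))
  write_fasta(sim$genome, paths[["genome"]])
  write_annotation(sim$annotation, paths[["gff3"]])
  write_fastq(sim$fastq, paths[["fastq"]])
  lens <- stats::setNames(Biostrings::width(sim$genome), names(sim$genome))
  write_sam(sim$sam, lens, paths[["sam"]])
  readr::write_csv(sim$truth_counts, paths[["counts"]])
  readr::write_csv(sim$labels, paths[["clusters"]])
  writeLines(sim$whitelist, paths[["whitelist"]])
  readr::write_csv(sim$variants, paths[["variants"]])
  invisible(paths)
}

#' Simulate pseudo-bulk DTU count tables directly
#'
#' Count-level generator for studying the DTU test's operating
#' characteristics without read-level simulation: each gene gets two
#' isoforms whose usage proportions are either shared across clusters (null
#' genes) or switched (`usage` vs `1 - usage`), and per-cluster counts are
#' multinomial draws of `umis_per_cluster` molecules.
#'
#' @param n_genes Number of genes.
#' @param n_null Number of null (shared-usage) genes among them.
#' @param usage Major-isoform usage in cluster 1 for switched genes.
#' @param null_usage Shared usage for null genes.
#' @param umis_per_cluster UMIs per gene per cluster.
#' @param n_clusters Number of clusters.
#' @param seed Seed.
#' @return A long pseudo-bulk tibble (`transcript_id`, `gene_id`, `cluster`,
#'   `count`) with a `truth` attribute naming the switched genes.
#' @export
simulate_dtu_counts <- function(n_genes = 500L, n_null = n_genes,
                                usage = 0.8, null_usage = 0.5,
                                umis_per_cluster = 200L, n_clusters = 2L,
                                seed = 1L) {
  with_seed(seed, {
    rows <- purrr::map_dfr(seq_len(n_genes), function(g) {
      gid <- sprintf("g%04d", g)
      is_null <- g <= n_null
      purrr::map_dfr(seq_len(n_clusters), function(cl) {
        p1 <- if (is_null) null_usage else if (cl == 1L) usage else 1 - usage
        x <- stats::rmultinom(1L, umis_per_cluster, c(p1, 1 - p1))[, 1L]
        tibble(transcript_id = paste0(gid, c(".t1", ".t2")), gene_id = gid,
               cluster = sprintf("cluster%d", cl), count = as.integer(x))
      })
    })
    attr(rows, "switched_genes") <- if (n_null < n_genes) {
      sprintf("g%04d", (n_null + 1L):n_genes)
    } else character(0)
    rows
  })
}

#' Simulate per-cell allele counts at one site
#'
#' Count-level generator for the clonality filter's operating
#' characteristics: every cell gets `coverage` reads; under the error-only
#' model alternative reads arise i.i.d. at `error_rate` in all cells
#' (independent of barcode); a clonal site instead confines alternative
#' reads to `n_clonal` carrier cells at allele fraction `af`.
#'
#' @param n_cells Number of cells.
#' @param coverage Reads per cell at the site.
#' @param error_rate Per-read error (alt) probability for error-only sites.
#' @param n_clonal Number of carrier cells (0 = error-only site).
#' @param af Per-carrier allele fraction.
#' @param seed Seed.
#' @return A tibble (`barcode`, `ref_count`, `alt_count`).
#' @export
simulate_site_counts <- function(n_cells = 200L, coverage = 5L,
                                 error_rate = 0.03, n_clonal = 0L,
                                 af = 1.0, seed = 1L) {
  with_seed(seed, {
    bc <- sprintf("cell%04d", seq_len(n_cells))
    p <- rep(error_rate, n_cells)
    if (n_clonal > 0L) {
      p <- rep(0, n_cells)
      p[seq_len(n_clonal)] <- af
    }
    alt <- stats::rbinom(n_cells, coverage, p)
    tibble(barcode = bc, ref_count = as.integer(coverage - alt),
           alt_count = as.integer(alt))
  })
}
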