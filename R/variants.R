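#' Mask homopolymer runs in a genome
#'
#' Long-read error rates are elevated inside homopolymers, so every position
#' inside a maximal single-base run of length >= `min_run` (runs longer than
#' 3 nt by default) is excluded from variant calling.
#'
#' @param genome A named `DNAStringSet`.
#' @param min_run Minimum run length masked.
#' @return A named list of 0-based masked position vectors, one per contig.
#' @export
homopolymer_mask <- function(genome, min_run = 4L) {
  lapply(as.list(as.character(genome)), function(s) {
    if (!nzchar(s)) return(integer(0))
    r <- rle(strsplit(s, "", fixed = TRUE)[[1L]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    long <- which(r$lengths >= min_run)
    if (length(long) == 0L) return(integer(0))
    sort(unlist(lapply(long, function(i) (starts[[i]]:ends[[i]]) - 1L)))
  })
}

# per-read, per-position base calls at candidate positions.
# Returns tibble (chrom, pos, read_id, base). Positions are 0-based.
pileup_bases <- function(path, positions, min_base_qual = 7L) {
  bam <- ensure_bam(path)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "cigar", "seq", "qual"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  res <- Rsamtools::scanBam(bam, param = param)[[1L]]
  n <- length(res$qname)
  if (n == 0L) return(tibble(chrom = character(0), pos = integer(0),
                             read_id = character(0), base = character(0)))
  ref_blocks <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    res$cigar, pos = res$pos, ops = c("M", "=", "X"))
  qry_blocks <- GenomicAlignments::cigarRangesAlongQuerySpace(
    res$cigar, ops = c("M", "=", "X"), after.soft.clipping = FALSE)
  seqs <- as.character(res$seq)
  quals <- as.character(res$qual)
  chroms <- as.character(res$rname)
  rs_all <- as.list(IRanges::start(ref_blocks))
  re_all <- as.list(IRanges::end(ref_blocks))
  qs_all <- as.list(IRanges::start(qry_blocks))
  pos_by_chrom <- lapply(positions, sort)
  acc_chrom <- vector("list", n); acc_pos <- vector("list", n)
  acc_read <- vector("list", n); acc_base <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- pos_by_chrom[[chroms[[i]]]]
    if (is.null(cand) || length(cand) == 0L) next
    rs <- rs_all[[i]] - 1L; re <- re_all[[i]]   # 0-based half-open
    qs <- qs_all[[i]]
    # candidate positions inside each block, via binary search on cand
    lo <- findInterval(rs, cand, left.open = TRUE) + 1L
    hi <- findInterval(re - 1L, cand)
    inb <- integer(0); off <- integer(0)
    for (b in which(lo <= hi)) {
      p <- cand[lo[[b]]:hi[[b]]]
      inb <- c(inb, p)
      off <- c(off, qs[[b]] + (p - rs[[b]]))                # 1-based in SEQ
    }
    if (length(inb) == 0L) next
    base <- substring(seqs[[i]], off, off)
    q <- utf8ToInt(quals[[i]])[off] - 33L
    ok <- q >= min_base_qual & base %in% c("A", "C", "G", "T")
    if (!any(ok)) next
    acc_chrom[[i]] <- rep(chroms[[i]], sum(ok))
    acc_pos[[i]] <- inb[ok]
    acc_read[[i]] <- rep(res$qname[[i]], sum(ok))
    acc_base[[i]] <- base[ok]
  }
  out <- tibble(chrom = unlist(acc_chrom) %||% character(0),
                pos = as.integer(unlist(acc_pos)),
                read_id = unlist(acc_read) %||% character(0),
                base = unlist(acc_base) %||% character(0))
  out
}

#' Identify candidate SNV sites with per-cell allele counts
#'
#' Unmasked positions with pileup coverage of at least `snv_min_cov` reads
#' and reference allele frequency inside the `[snv_af_low, snv_af_high]`
#' band become candidates (positions covered by fewer than 100 reads, or
#' with RAF below 10% or above 90%, are excluded under the defaults). The
#' alternative allele is the most frequent non-reference base; indels are
#' ignored. Read ids must carry demultiplexed `{barcode}_{UMI}#id` headers
#' so counts can be attributed to cells.
#'
#' @param path SAM/BAM of barcoded genome alignments.
#' @param genome A named `DNAStringSet`.
#' @param config A [sclr_config()].
#' @param sites Optional tibble (`chrom`, `pos`, 0-based) restricting the
#'   pileup to listed positions (targeted mode).
#' @return A list with `sites` (chrom, pos, ref, alt, ref_total, alt_total,
#'   coverage, raf) and `cells` (chrom, pos, barcode, ref_count, alt_count).
#' @export
candidate_snvs <- function(path, genome, config = sclr_config(),
                           sites = NULL) {
  mask <- homopolymer_mask(genome, config$homopolymer_min_run)
  aln <- read_alignments(path, keep_seq = FALSE)
  empty <- list(
    sites = tibble(chrom = character(0), pos = integer(0), ref = character(0),
                   alt = character(0), ref_total = integer(0),
                   alt_total = integer(0), coverage = integer(0),
                   raf = numeric(0)),
    cells = tibble(chrom = character(0), pos = integer(0),
                   barcode = character(0), ref_count = integer(0),
                   alt_count = integer(0)))
  if (nrow(aln) == 0L) return(empty)
  # coverage per contig from alignment blocks (N gaps excluded)
  positions <- list()
  for (chrom in intersect(unique(aln$chrom), names(genome))) {
    rows <- which(aln$chrom == chrom)
    blk <- do.call(rbind, aln$blocks[rows])
    cov <- IRanges::coverage(IRanges::IRanges(start = blk[, "start"] + 1L,
                                              end = blk[, "end"]),
                             width = length(genome[[chrom]]))
    covv <- as.integer(cov)
    cand0 <- which(covv >= config$snv_min_cov) - 1L
    cand0 <- setdiff(cand0, mask[[chrom]])
    refb <- strsplit(as.character(genome[[chrom]]), "", fixed = TRUE)[[1L]]
    cand0 <- cand0[refb[cand0 + 1L] %in% c("A", "C", "G", "T")]
    if (!is.null(sites)) {
      cand0 <- intersect(cand0, sites$pos[sites$chrom == chrom])
    }
    if (length(cand0)) positions[[chrom]] <- cand0
  }
  if (length(positions) == 0L) return(empty)
  piles <- pileup_bases(path, positions, config$snv_min_base_qual)
  if (nrow(piles) == 0L) return(empty)
  contig_str <- lapply(as.list(as.character(genome)), identity)
  refbase <- function(chrom, pos) {
    out <- character(length(chrom))
    for (cn in unique(chrom)) {
      m <- chrom == cn
      out[m] <- substring(contig_str[[cn]], pos[m] + 1L, pos[m] + 1L)
    }
    out
  }
  site_tab <- piles %>%
    count(.data$chrom, .data$pos, .data$base, name = "n") %>%
    group_by(.data$chrom, .data$pos) %>%
    mutate(coverage = sum(.data$n)) %>%
    ungroup()
  site_tab$ref <- refbase(site_tab$chrom, site_tab$pos)
  ref_counts <- site_tab %>%
    filter(.data$base == .data$ref) %>%
    select("chrom", "pos", ref_total = "n")
  alt_counts <- site_tab %>%
    filter(.data$base != .data$ref) %>%
    arrange(.data$chrom, .data$pos, desc(.data$n), .data$base) %>%
    distinct(.data$chrom, .data$pos, .keep_all = TRUE) %>%
    select("chrom", "pos", alt = "base", alt_total = "n")
  sites_sum <- site_tab %>%
    distinct(.data$chrom, .data$pos, .data$ref, .data$coverage) %>%
    left_join(ref_counts, by = c("chrom", "pos")) %>%
    left_join(alt_counts, by = c("chrom", "pos")) %>%
    mutate(ref_total = dplyr::coalesce(.data$ref_total, 0L),
           alt_total = dplyr::coalesce(.data$alt_total, 0L),
           raf = .data$ref_total / .data$coverage) %>%
    filter(.data$coverage >= config$snv_min_cov,
           !is.na(.data$alt),
           .data$raf >= config$snv_af_low,
           .data$raf <= config$snv_af_high) %>%
    select("chrom", "pos", "ref", "alt", "ref_total", "alt_total",
           "coverage", "raf") %>%
    arrange(.data$chrom, .data$pos)
  if (nrow(sites_sum) == 0L) return(empty)
  cells <- piles %>%
    inner_join(sites_sum %>% select("chrom", "pos", "ref", "alt"),
               by = c("chrom", "pos")) %>%
    mutate(barcode = sub("_.*$", "", .data$read_id)) %>%
    group_by(.data$chrom, .data$pos, .data$barcode) %>%
    summarise(ref_count = sum(.data$base == .data$ref[1L]),
              alt_count = sum(.data$base == .data$alt[1L]),
              .groups = "drop") %>%
    filter(.data$ref_count + .data$alt_count > 0L) %>%
    arrange(.data$chrom, .data$pos, .data$barcode)
  list(sites = sites_sum, cells = cells)
}

#' Binomial clonality filter for one candidate site
#'
#' Under the null that sequencing errors strike cells at random, every cell
#' shares the site's global alternative-allele frequency. Each informative
#' cell (>= 1 read at the site) gets an exact two-sided binomial p-value for
#' its own allele counts against that global frequency; the site's p-value
#' is the smallest cell p-value Bonferroni-corrected by the number of
#' informative cells. Clonal variants concentrate alternative reads in few
#' cells and survive; uniform errors do not.
#'
#' @param cell_tab Tibble of per-cell counts for one site (`ref_count`,
#'   `alt_count`).
#' @return The site p-value (clipped at 1).
#' @export
binomial_clonality_filter <- function(cell_tab) {
  tot_alt <- sum(cell_tab$alt_count)
  tot <- sum(cell_tab$alt_count + cell_tab$ref_count)
  stopifnot(tot > 0L, tot_alt > 0L, tot_alt < tot)
  p_hat <- tot_alt / tot
  pc <- vapply(seq_len(nrow(cell_tab)), function(i) {
    n <- cell_tab$ref_count[[i]] + cell_tab$alt_count[[i]]
    stats::binom.test(cell_tab$alt_count[[i]], n, p = p_hat,
                      alternative = "two.sided")$p.value
  }, numeric(1))
  min(1, min(pc) * nrow(cell_tab))
}

#' Differential allele frequency across clusters
#'
#' Aggregates per-cell allele counts by cluster into a 2 x K (ref, alt) by
#' cluster table per site and applies the Pearson chi-square test of
#' independence (no continuity correction); p-values are BH-adjusted across
#' sites.
#'
#' @param cells Per-cell allele counts (`chrom`, `pos`, `barcode`,
#'   `ref_count`, `alt_count`).
#' @param labels Cluster labels tibble.
#' @param config A [sclr_config()].
#' @return A tibble per site: `chrom`, `pos`, `statistic`, `df`, `p_value`,
#'   `adj_p_value`, `significant`.
#' @export
differential_allele_frequency <- function(cells, labels,
                                          config = sclr_config()) {
  if (length(unique(labels$cluster)) < 2L) {
    stop("differential allele frequency needs at least two clusters",
         call. = FALSE)
  }
  x <- cells %>% inner_join(labels, by = "barcode")
  sites <- x %>% distinct(.data$chrom, .data$pos)
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    s <- x %>% filter(.data$chrom == sites$chrom[[i]],
                      .data$pos == sites$pos[[i]])
    agg <- s %>%
      group_by(.data$cluster) %>%
      summarise(ref = sum(.data$ref_count), alt = sum(.data$alt_count),
                .groups = "drop") %>%
      arrange(.data$cluster)
    tab <- rbind(ref = agg$ref, alt = agg$alt)
    colnames(tab) <- agg$cluster
    res <- chisq_independence(tab, continuity = FALSE)
    if (is.null(res)) return(NULL)
    tibble(chrom = sites$chrom[[i]], pos = sites$pos[[i]],
           statistic = res$statistic, df = res$df, p_value = res$p_value)
  })
  out <- bind_rows(rows)
  if (nrow(out)) {
    out$adj_p_value <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- out$adj_p_value < config$var_alpha
  } else {
    out <- tibble(chrom = character(0), pos = integer(0),
                  statistic = numeric(0), df = integer(0),
                  p_value = numeric(0), adj_p_value = numeric(0),
                  significant = logical(0))
  }
  arrange(out, .data$chrom, .data$pos)
}

#' Cell-barcode-aware SNV detection and clonality analysis
#'
#' Runs the full variant stage: candidate discovery from the pileup
#' (homopolymer, coverage and allele-frequency filters), the per-cell
#' binomial clonality filter with BH correction across sites, and — when
#' cluster labels are supplied — differential allele-frequency analysis of
#' the surviving sites.
#'
#' @param path SAM/BAM of barcoded genome alignments.
#' @param genome A named `DNAStringSet` (or FASTA path).
#' @param labels Optional cluster labels tibble.
#' @param config A [sclr_config()].
#' @param sites Optional targeted positions (`chrom`, `pos`).
#' @return An `sclr_variants` object; `tidy()` returns the per-site table
#'   with `binom_p`, `binom_adj_p`, `kept`, and (with labels) the
#'   differential columns; `glance()` a one-row summary.
#' @export
call_variants <- function(path, genome, labels = NULL,
                          config = sclr_config(), sites = NULL) {
  if (is.character(genome)) genome <- read_genome(genome)
  cand <- candidate_snvs(path, genome, config, sites = sites)
  tab <- cand$sites
  if (nrow(tab)) {
    tab$binom_p <- vapply(seq_len(nrow(tab)), function(i) {
      ct <- cand$cells %>% filter(.data$chrom == tab$chrom[[i]],
                                  .data$pos == tab$pos[[i]])
      binomial_clonality_filter(ct)
    }, numeric(1))
    tab$binom_adj_p <- stats::p.adjust(tab$binom_p, method = "BH")
    tab$kept <- tab$binom_adj_p < config$var_alpha
  } else {
    tab$binom_p <- numeric(0); tab$binom_adj_p <- numeric(0)
    tab$kept <- logical(0)
  }
  diff_tab <- NULL
  if (!is.null(labels) && any(tab$kept)) {
    kept_cells <- cand$cells %>%
      inner_join(tab %>% filter(.data$kept) %>% select("chrom", "pos"),
                 by = c("chrom", "pos"))
    diff_tab <- differential_allele_frequency(kept_cells, labels, config)
    tab <- tab %>% left_join(diff_tab, by = c("chrom", "pos"))
  }
  structure(list(sites = tab, cells = cand$cells, alpha = config$var_alpha),
            class = "sclr_variants")
}

#' @export
print.sclr_variants <- function(x, ...) {
  cat(sprintf("<sclr_variants> %d candidate sites, %d kept by clonality filter\n",
              nrow(x$sites), sum(x$sites$kept)))
  invisible(x)
}

#' @rdname call_variants
#' @param x An `sclr_variants` object.
#' @param ... Unused.
#' @export
tidy.sclr_variants <- function(x, ...) x$sites

#' @rdname call_variants
#' @export
glance.sclr_variants <- function(x, ...) {
  tibble(n_candidates = nrow(x$sites), n_kept = sum(x$sites$kept),
         n_significant = if ("significant" %in% names(x$sites)) {
           sum(x$sites$significant, na.rm = TRUE)
         } else NA_integer_,
         alpha = x$alpha)
}

#' Export per-cell alternative (and reference) allele count matrices
#'
#' Writes sites x cells MatrixMarket matrices of alternative and reference
#' counts for the kept sites, for external dimensionality reduction and
#' clustering.
#'
#' @param variants An `sclr_variants` object.
#' @param out_dir Output directory (`alt_matrix.mtx`, `ref_matrix.mtx` plus
#'   `.rownames`/`.colnames` sidecars).
#' @return Named vector of paths, invisibly.
#' @export
export_alt_matrix <- function(variants, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  kept <- variants$sites %>% filter(.data$kept)
  cells <- variants$cells %>%
    inner_join(kept %>% select("chrom", "pos"), by = c("chrom", "pos"))
  site_ids <- if (nrow(cells)) {
    sort(unique(paste0(cells$chrom, ":", cells$pos)))
  } else character(0)
  barcodes <- sort(unique(cells$barcode))
  write_one <- function(col, path) {
    if (length(site_ids) == 0L) {
      m <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                x = numeric(0), dims = c(0L, 0L))
    } else {
      m <- Matrix::sparseMatrix(
        i = match(paste0(cells$chrom, ":", cells$pos), site_ids),
        j = match(cells$barcode, barcodes),
        x = cells[[col]], dims = c(length(site_ids), length(barcodes)))
    }
    Matrix::writeMM(m, path)
    writeLines(site_ids, paste0(path, ".rownames"))
    writeLines(barcodes, paste0(path, ".colnames"))
    path
  }
  alt <- write_one("alt_count", file.path(out_dir, "alt_matrix.mtx"))
  ref <- write_one("ref_count", file.path(out_dir, "ref_matrix.mtx"))
  invisible(c(alt = alt, ref = ref))
}

#' Allele-frequency-by-cluster overview of kept variants
#'
#' @param object An `sclr_variants` object.
#' @param labels Cluster labels tibble.
#' @param ... Unused.
#' @return A ggplot of per-cluster alternative allele frequency per kept
#'   site.
#' @export
autoplot.sclr_variants <- function(object, labels, ...) {
  kept <- object$sites %>% filter(.data$kept)
  df <- object$cells %>%
    inner_join(kept %>% select("chrom", "pos"), by = c("chrom", "pos")) %>%
    inner_join(labels, by = "barcode") %>%
    group_by(site = paste0(.data$chrom, ":", .data$pos), .data$cluster) %>%
    summarise(af = sum(.data$alt_count) /
                sum(.data$alt_count + .data$ref_count), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cluster, y = .data$site,
                                   fill = .data$af)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1),
                                 name = "alt allele freq") +
    ggplot2::labs(x = "cluster", y = "site",
                  title = "Kept variants by cluster") +
    ggplot2::theme_minimal()
}
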