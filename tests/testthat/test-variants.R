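test_that("homopolymer masking excludes runs longer than three", {
  g <- Biostrings::DNAStringSet(c(a = "GAAAAT", b = "GAAAT", c = ""))
  m <- homopolymer_mask(g, 4L)
  expect_equal(m$a, 1:4)          # 0-based positions of the A run
  expect_equal(m$b, integer(0))   # run of 3 is kept
  expect_equal(m$c, integer(0))
})

# small pileup fixture: reads over a 60 bp contig with an alt base at
# position 30 (0-based) in some cells
pileup_fixture <- function(n_ref, n_alt, alt_cells, pos = 30L,
                           contig_seq = NULL) {
  set.seed(77)
  if (is.null(contig_seq)) {
    # avoid homopolymers by cycling bases
    contig_seq <- paste(rep(c("A", "C", "G", "T"), 15), collapse = "")
  }
  genome <- Biostrings::DNAStringSet(c(chr1 = contig_seq))
  ref <- substring(contig_seq, pos + 1L, pos + 1L)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  mk <- function(i, cell, base) {
    seq <- substring(contig_seq, 1, 60)
    substring(seq, pos + 1L, pos + 1L) <- base
    sprintf("%s_UMI%04d#r%04d\t0\tchr1\t1\t60\t60M\t*\t0\t0\t%s\t%s",
            cell, i, i, seq, strrep("I", 60))
  }
  lines <- c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:60")
  i <- 0L
  cells_ref <- sprintf("cell%03d", seq_len(n_ref))
  for (c_ in cells_ref) {
    i <- i + 1L
    lines <- c(lines, mk(i, c_, ref))
  }
  for (c_ in alt_cells) {
    i <- i + 1L
    lines <- c(lines, mk(i, c_, alt))
  }
  stopifnot(length(alt_cells) == n_alt)
  sam <- tempfile(fileext = ".sam")
  writeLines(lines, sam)
  list(sam = sam, genome = genome, ref = ref, alt = alt, pos = pos)
}

test_that("candidate sites respect coverage and allele-frequency bands", {
  cfg <- sclr_config(snv_min_cov = 100L)
  # coverage 99 -> excluded ("fewer than 100 reads")
  fx <- pileup_fixture(49, 50, sprintf("alt%03d", 1:50))
  out <- candidate_snvs(fx$sam, fx$genome, cfg)
  expect_equal(nrow(out$sites), 0L)
  # coverage 200 with RAF 0.95 -> excluded ("greater than 90%")
  fx2 <- pileup_fixture(190, 10, sprintf("alt%03d", 1:10))
  out2 <- candidate_snvs(fx2$sam, fx2$genome, cfg)
  expect_equal(nrow(out2$sites), 0L)
  # coverage 200 with RAF 0.50 -> candidate
  fx3 <- pileup_fixture(100, 100, sprintf("alt%03d", 1:100))
  out3 <- candidate_snvs(fx3$sam, fx3$genome, cfg)
  expect_equal(out3$sites$pos, fx3$pos)
  expect_equal(out3$sites$ref, fx3$ref)
  expect_equal(out3$sites$alt, fx3$alt)
  expect_equal(out3$sites$coverage, 200L)
  # conservation: per-barcode counts sum to the global counts
  expect_equal(sum(out3$cells$ref_count), out3$sites$ref_total)
  expect_equal(sum(out3$cells$alt_count), out3$sites$alt_total)
})

test_that("the exact binomial cell p-value matches the closed form", {
  # one informative cell, n = 10, all alt at p-hat = 0.5:
  # two-sided exact p = 2 * 0.5^10
  cells <- tibble::tibble(ref_count = c(10L, 0L), alt_count = c(0L, 10L))
  # p-hat = 0.5; cell 2 has all-alt: p_c = 2^-10 * 2; Bonferroni x2 cells
  p_site <- binomial_clonality_filter(cells)
  p_cell <- binom.test(10, 10, 0.5)$p.value
  expect_equal(p_cell, 2 * 0.5^10)
  expect_equal(p_site, min(1, p_cell * 2))
  # null-conforming data is not significant
  conform <- tibble::tibble(ref_count = rep(1L, 20), alt_count = rep(1L, 20))
  expect_equal(binomial_clonality_filter(conform), 1)
})

test_that("clonal concentration passes the filter and uniform errors fail", {
  # alt reads confined to 20 of 200 cells at per-cell AF 1.0
  clonal <- simulate_site_counts(n_cells = 200L, coverage = 5L,
                                 n_clonal = 20L, af = 1, seed = 5L)
  expect_lt(binomial_clonality_filter(clonal), 0.05)
  # sprayed errors at the same overall rate are retained by the null
  diffuse <- simulate_site_counts(n_cells = 200L, coverage = 5L,
                                  error_rate = 0.1, seed = 5L)
  expect_gt(binomial_clonality_filter(diffuse), 0.05)
})

test_that("differential allele frequency uses the 2x2 Pearson oracle", {
  cfg <- sclr_config()
  labels <- tibble::tibble(barcode = c("c1", "c2"),
                           cluster = c("k1", "k2"))
  cells <- tibble::tibble(
    chrom = "chr1", pos = 10L, barcode = c("c1", "c2"),
    ref_count = c(90L, 10L), alt_count = c(10L, 90L))
  out <- differential_allele_frequency(cells, labels, cfg)
  expect_equal(out$statistic, brute_chisq_2x2(90, 10, 10, 90),
               tolerance = 1e-9)
  expect_equal(out$statistic, 128, tolerance = 1e-9)
  # balanced table -> statistic 0, p = 1
  cells2 <- cells
  cells2$ref_count <- c(50L, 50L); cells2$alt_count <- c(50L, 50L)
  out2 <- differential_allele_frequency(cells2, labels, cfg)
  expect_equal(out2$statistic, 0)
  expect_equal(out2$p_value, 1)
})

test_that("a planted subclonal SNV is recovered end-to-end", {
  cfg <- sclr_config(snv_min_cov = 40L)
  d <- sim_design(seed = 83, n_genes = 6, cells_per_cluster = 15,
                  reads_per_cell = 60, sub_rate = 0.03, ins_rate = 0,
                  del_rate = 0, truncation_prob = 0, n_snvs = 1)
  sim <- simulate_dataset(d)
  paths <- write_simulation(sim, tempfile())
  v <- call_variants(paths[["sam"]], sim$genome, labels = sim$labels,
                     config = cfg)
  kept <- v$sites[v$sites$kept, ]
  expect_true(sim$variants$pos %in% kept$pos)
  hit <- kept[kept$pos == sim$variants$pos, ]
  expect_equal(hit$alt, sim$variants$alt)
  expect_true(hit$significant)
  # per-site conservation on every run
  sums <- v$cells |>
    dplyr::group_by(chrom, pos) |>
    dplyr::summarise(ref_sum = sum(ref_count), alt_sum = sum(alt_count),
                     .groups = "drop") |>
    dplyr::inner_join(v$sites, by = c("chrom", "pos"))
  expect_equal(sums$ref_sum, sums$ref_total)
  expect_equal(sums$alt_sum, sums$alt_total)
})

test_that("alt/ref matrices export kept sites with conserved column sums", {
  cfg <- sclr_config(snv_min_cov = 40L)
  fx <- pileup_fixture(100, 100, rep(sprintf("altc%02d", 1:5), each = 20))
  v <- call_variants(fx$sam, fx$genome, config = cfg)
  expect_true(all(v$sites$kept))
  out_dir <- tempfile()
  paths <- export_alt_matrix(v, out_dir)
  m <- Matrix::readMM(paths[["alt"]])
  expect_equal(sum(m), sum(v$cells$alt_count))
  rn <- readLines(paste0(paths[["alt"]], ".rownames"))
  expect_equal(rn, paste0("chr1:", v$sites$pos[v$sites$kept]))
  # no kept sites -> empty but valid files
  v0 <- v
  v0$sites$kept <- FALSE
  p0 <- export_alt_matrix(v0, tempfile())
  expect_equal(dim(Matrix::readMM(p0[["alt"]])), c(0L, 0L))
})

test_that("targeted mode restricts the pileup to listed sites", {
  cfg <- sclr_config(snv_min_cov = 40L)
  fx <- pileup_fixture(100, 100, sprintf("alt%03d", 1:100))
  keep <- candidate_snvs(fx$sam, fx$genome, cfg,
                         sites = tibble::tibble(chrom = "chr1",
                                                pos = fx$pos))
  expect_equal(nrow(keep$sites), 1L)
  none <- candidate_snvs(fx$sam, fx$genome, cfg,
                         sites = tibble::tibble(chrom = "chr1", pos = 5L))
  expect_equal(nrow(none$sites), 0L)
})
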