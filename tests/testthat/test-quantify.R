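rec <- function(read_id, tx, score, cov, rfa = 1) {
  tibble::tibble(read_id = read_id, transcript_id = tx, gene_id = "g",
                 score = score, transcript_coverage = cov,
                 read_fraction_aligned = rfa)
}

test_that("read assignment enforces uniqueness and coverage thresholds", {
  cfg <- sclr_config()
  # full coverage -> assigned and full-length
  a <- assign_reads(rec("BC_UMI#r1", "t1", 100, 1.0), cfg)
  expect_equal(a$transcript_id, "t1")
  expect_true(a$full_length)
  expect_equal(a$barcode, "BC")
  expect_equal(a$umi, "UMI")
  # coverage 0.55 < 0.60 -> discarded
  expect_equal(nrow(assign_reads(rec("b_u#r2", "t1", 100, 0.55), cfg)), 0L)
  # tie on score and coverage -> ambiguous, discarded
  tie <- dplyr::bind_rows(rec("b_u#r3", "t1", 100, 0.8),
                          rec("b_u#r3", "t2", 100, 0.8))
  expect_equal(nrow(assign_reads(tie, cfg)), 0L)
  # tie on score broken by higher transcript coverage
  near <- dplyr::bind_rows(rec("b_u#r4", "t1", 100, 1.0),
                           rec("b_u#r4", "t2", 100, 0.7))
  expect_equal(assign_reads(near, cfg)$transcript_id, "t1")
  # low read fraction aligned -> discarded
  expect_equal(nrow(assign_reads(rec("b_u#r5", "t1", 100, 0.9, rfa = 0.4),
                                 cfg)), 0L)
  # coverage exactly 0.95 is not full-length (strict >)
  a95 <- assign_reads(rec("b_u#r6", "t1", 100, 0.95), cfg)
  expect_false(a95$full_length)
})

asg <- function(read, tx, fl, bc = "B", umi = NULL, gene = "g") {
  tibble::tibble(read_id = read, barcode = bc,
                 umi = if (is.null(umi)) paste0("U", read) else umi,
                 transcript_id = tx, gene_id = gene,
                 transcript_coverage = ifelse(fl, 1, 0.8),
                 read_fraction_aligned = 1, full_length = fl)
}

test_that("isoforms need at least 5 full-length reads to survive", {
  cfg <- sclr_config()
  five_fl <- dplyr::bind_rows(lapply(1:5, function(i) {
    asg(paste0("r", i), "t_keep", TRUE)
  }))
  four_fl <- dplyr::bind_rows(
    lapply(1:4, function(i) asg(paste0("s", i), "t_drop", TRUE)),
    lapply(1:50, function(i) asg(paste0("p", i), "t_drop", FALSE)))
  out <- filter_isoforms_by_support(dplyr::bind_rows(five_fl, four_fl), cfg)
  expect_equal(attr(out, "kept_transcripts"), "t_keep")
  expect_equal(nrow(out), 5L)          # partial reads of t_drop discarded too
  expect_equal(attr(out, "dropped_reads"), 54L)
  empty <- filter_isoforms_by_support(out[0, ], cfg)
  expect_equal(attr(empty, "kept_transcripts"), character(0))
})

test_that("lowering the support threshold never removes a kept transcript", {
  set.seed(9)
  reads <- dplyr::bind_rows(lapply(1:30, function(i) {
    asg(paste0("r", i), sample(paste0("t", 1:5), 1), sample(c(TRUE, FALSE), 1))
  }))
  kept_by <- lapply(1:6, function(th) {
    attr(filter_isoforms_by_support(reads,
                                    sclr_config(min_fl_support = th)),
         "kept_transcripts")
  })
  for (i in seq_len(length(kept_by) - 1L)) {
    expect_true(all(kept_by[[i + 1L]] %in% kept_by[[i]]))
  }
})

test_that("UMI collapse merges components at edit distance <= 2", {
  cfg <- sclr_config()
  grp <- dplyr::bind_rows(
    lapply(1:3, function(i) asg(paste0("r", i), "t1", TRUE,
                                umi = "AAAAAAAAAA")),
    asg("r4", "t1", TRUE, umi = "AAAAAAAAAT"))
  mols <- dedup_umis(grp, cfg)
  expect_equal(nrow(mols), 1L)
  expect_equal(mols$umi, "AAAAAAAAAA")    # most frequent representative
  expect_equal(mols$n_reads, 4L)
  # distance 3 stays separate
  far <- dplyr::bind_rows(asg("r1", "t1", TRUE, umi = "AAAAAAAAAA"),
                          asg("r2", "t1", TRUE, umi = "AAAAAAATTT"))
  expect_equal(nrow(dedup_umis(far, cfg)), 2L)
  # single read is one molecule with its own UMI
  one <- dedup_umis(asg("r9", "t1", TRUE, umi = "ACGTACGTAC"), cfg)
  expect_equal(one$umi, "ACGTACGTAC")
  # majority transcript wins within a component
  mixed <- dplyr::bind_rows(
    lapply(1:3, function(i) asg(paste0("m", i), "t1", TRUE,
                                umi = "CCCCCCCCCC")),
    asg("m4", "t2", TRUE, umi = "CCCCCCCCCA"))
  expect_equal(dedup_umis(mixed, cfg)$transcript_id, "t1")
})

test_that("component clustering agrees with brute-force transitive closure", {
  cfg <- sclr_config()
  set.seed(31)
  for (rep in 1:5) {
    base <- replicate(8, paste(sample(c("A", "C", "G", "T"), 8,
                                      replace = TRUE), collapse = ""))
    umis <- unlist(lapply(base, function(u) {
      c(u, vapply(1:2, function(i) {
        p <- sample(8, 1)
        `substring<-`(u, p, p, sample(c("A", "C", "G", "T"), 1))
      }, character(1)))
    }))
    got <- sclriso:::umi_components(umis, cfg$umi_dedup_ed)
    want <- brute_umi_clusters(umis, cfg$umi_dedup_ed)
    # same partition (labels may differ)
    u <- names(got)
    expect_equal(outer(got[u], got[u], "=="), outer(want[u], want[u], "=="))
  }
})

test_that("count matrices aggregate molecules and conserve totals", {
  mols <- tibble::tibble(
    barcode = c("c1", "c1", "c1", "c1", "c2"),
    gene_id = c("g1", "g1", "g1", "g2", "g1"),
    umi = paste0("U", 1:5),
    transcript_id = c("t1", "t1", "t2", "t3", "t1"),
    n_reads = 1L)
  cm <- build_count_matrices(mols)
  t_c1_t1 <- cm$transcript$count[cm$transcript$transcript_id == "t1" &
                                   cm$transcript$barcode == "c1"]
  expect_equal(t_c1_t1, 2L)
  g_c1_g1 <- cm$gene$count[cm$gene$gene_id == "g1" &
                             cm$gene$barcode == "c1"]
  expect_equal(g_c1_g1, 3L)   # 2 (t1) + 1 (t2)
  # conservation per cell
  tsum <- tapply(cm$transcript$count, cm$transcript$barcode, sum)
  gsum <- tapply(cm$gene$count, cm$gene$barcode, sum)
  expect_equal(tsum, gsum)
  # empty input gives empty, well-formed tables
  cm0 <- build_count_matrices(mols[0, ])
  expect_equal(nrow(cm0$transcript), 0L)
  expect_equal(nrow(cm0$gene), 0L)
})

test_that("noiseless quantification reproduces the simulator truth matrix", {
  cfg <- sclr_config()
  d <- sim_design(seed = 41, n_genes = 5, cells_per_cluster = 5,
                  reads_per_cell = 40, sub_rate = 0, ins_rate = 0,
                  del_rate = 0, truncation_prob = 0)
  sim <- simulate_dataset(d)
  paths <- write_simulation(sim, tempfile())
  aln <- read_alignments(paths[["sam"]])
  iso <- discover_isoforms(aln, sim$annotation, cfg)
  q <- quantify_isoforms(aln, iso, cfg)
  got <- dplyr::arrange(q$transcript_counts, transcript_id, barcode)
  want <- dplyr::arrange(sim$truth_counts, transcript_id, barcode)
  expect_equal(got, want)
  # gene/transcript conservation
  tsum <- tapply(q$transcript_counts$count, q$transcript_counts$barcode, sum)
  gsum <- tapply(q$gene_counts$count, q$gene_counts$barcode, sum)
  expect_equal(tsum, gsum)
})

test_that("count writers emit readable CSV and MatrixMarket files", {
  counts <- tibble::tibble(transcript_id = c("t1", "t1", "t2"),
                           gene_id = "g1",
                           barcode = c("c1", "c2", "c1"),
                           count = c(3L, 1L, 2L))
  csv <- tempfile(fileext = ".csv")
  write_count_csv(counts, csv)
  back <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(back$c1, c(3L, 2L))
  mtx <- tempfile(fileext = ".mtx")
  write_count_mtx(counts, mtx)
  m <- Matrix::readMM(mtx)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(sum(m), 6)
})
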