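chain_row <- function(read_id, start, end, introns, chrom = "chr1",
                      strand = "+") {
  key <- if (length(introns)) {
    paste(vapply(introns, function(p) paste0(p[1], "-", p[2]), character(1)),
          collapse = ",")
  } else ""
  tibble::tibble(read_id = read_id, chrom = chrom, strand = strand,
                 start = as.integer(start), end = as.integer(end),
                 intron_key = key)
}

test_that("splice gaps shorter than min_intron are absorbed into exons", {
  sam <- tempfile(fileext = ".sam")
  rows <- tibble::tibble(
    read_id = c("mono", "spliced", "small_gap"),
    chrom = "chr1", pos0 = c(0L, 0L, 0L), strand = "+",
    cigar = c("100M", "100M100N100M", "100M20N100M"))
  write_test_sam(rows, c(chr1 = 10000L), sam)
  ch <- chains_from_alignments(read_alignments(sam), min_intron = 30L)
  ch <- ch[match(rows$read_id, ch$read_id), ]
  expect_equal(ch$intron_key, c("", "100-200", ""))
  expect_equal(ch$end, c(100L, 300L, 220L))
})

test_that("junction grouping snaps minority coordinates to the majority", {
  rows <- dplyr::bind_rows(
    lapply(1:8, function(i) chain_row(paste0("a", i), 0, 2000,
                                      list(c(1000, 1500)))),
    lapply(1:2, function(i) chain_row(paste0("b", i), 0, 2000,
                                      list(c(1003, 1500)))))
  g <- group_chains(rows, jct_tol = 5L)
  expect_equal(nrow(g), 1L)
  expect_equal(g$intron_key, "1000-1500")
  expect_equal(g$support, 10L)
  # distance 6 >= tol stays separate
  rows2 <- dplyr::bind_rows(
    lapply(1:8, function(i) chain_row(paste0("a", i), 0, 2000,
                                      list(c(1000, 1500)))),
    lapply(1:2, function(i) chain_row(paste0("b", i), 0, 2000,
                                      list(c(1006, 1500)))))
  expect_equal(nrow(group_chains(rows2, jct_tol = 5L)), 2L)
  # identical chains collapse to one group with median ends
  rows3 <- dplyr::bind_rows(lapply(1:10, function(i) {
    chain_row(paste0("c", i), i, 2000 + i, list(c(1000, 1500)))
  }))
  g3 <- group_chains(rows3, jct_tol = 5L)
  expect_equal(nrow(g3), 1L)
  expect_equal(g3$support, 10L)
  expect_equal(g3$start, as.integer(round(median(1:10))))
})

test_that("grouping is invariant to read input order", {
  set.seed(5)
  rows <- dplyr::bind_rows(
    lapply(1:6, function(i) chain_row(paste0("x", i), 0, 2000,
                                      list(c(1000, 1500)))),
    lapply(1:3, function(i) chain_row(paste0("y", i), 10, 2010,
                                      list(c(1002, 1498), c(1700, 1800)))))
  g1 <- group_chains(rows, 5L)
  g2 <- group_chains(rows[sample(nrow(rows)), ], 5L)
  expect_equal(g1, g2)
})

test_that("correction snaps junctions and merges known isoforms", {
  ann <- read_annotation(fixture_annotation())
  cfg <- sclr_config()
  # g1.t1 chain is 200-300,400-500,600-700 (0-based)
  exact <- tibble::tibble(chrom = "chr1", strand = "+",
                          intron_key = "200-300,400-500,600-700",
                          start = 110L, end = 790L, support = 10L,
                          read_ids = list(paste0("r", 1:10)))
  iso <- correct_and_merge(exact, ann, cfg)
  expect_equal(iso$status, "known")
  expect_equal(iso$transcript_id, "g1.t1")
  expect_equal(iso$start, 100L)   # takes exact reference coordinates
  expect_equal(iso$end, 800L)

  # one junction 3 bp off is snapped then merged
  off3 <- exact
  off3$intron_key <- "203-300,400-500,600-700"
  iso2 <- correct_and_merge(off3, ann, cfg)
  expect_equal(iso2$status, "known")
  expect_equal(iso2$transcript_id, "g1.t1")

  # a donor 8 bp from any reference site stays novel and keeps its donor
  off8 <- exact
  off8$intron_key <- "208-300,400-500,600-700"
  iso3 <- correct_and_merge(off8, ann, cfg)
  expect_equal(iso3$status, "novel")
  expect_equal(iso3$gene_id, "g1")
  expect_match(iso3$intron_key, "^208-300")

  # ends beyond the 100 bp tolerance prevent the merge
  far <- exact
  far$start <- 0L   # 100 bp away from the reference start of 100 -> not <100
  iso4 <- correct_and_merge(far, ann, cfg)
  expect_equal(iso4$status, "novel")
})

test_that("chains with no gene overlap found a novel gene", {
  ann <- read_annotation(fixture_annotation())
  g <- tibble::tibble(chrom = "chr1", strand = "+",
                      intron_key = "9000-9200", start = 8900L, end = 9400L,
                      support = 5L, read_ids = list("r1"))
  iso <- correct_and_merge(g, ann, sclr_config())
  expect_equal(iso$status, "novel")
  expect_match(iso$gene_id, "^novelGene_")
})

test_that("truncation collapse follows the linear length model", {
  cfg <- sclr_config()   # f(L) = 1e-4 * L, clamped
  # parent: 4 introns, transcript length ~1000 -> threshold 0.1 * support
  parent_key <- "1100-1300,1500-1700,1900-2100,2300-2500"
  child_key <- "1900-2100,2300-2500"   # last 2 introns: 3'-anchored on "+"
  mk <- function(id, key, start, end, support) {
    tibble::tibble(transcript_id = id, gene_id = "g", chrom = "chr1",
                   strand = "+", start = as.integer(start),
                   end = as.integer(end), intron_key = key,
                   status = "novel", support = as.integer(support),
                   read_ids = list(paste0(id, "_r", seq_len(support))))
  }
  parent <- mk("parent", parent_key, 1000L, 2600L, 100L)
  # parent transcript length = 1600 - 800 introns... compute: span 1600,
  # introns 4*200 = 800 -> L = 800, f = 0.08, threshold = 8 reads
  collapsed <- resolve_truncations(dplyr::bind_rows(
    parent, mk("child", child_key, 1850L, 2590L, 3L)), cfg)
  expect_equal(collapsed$transcript_id, "parent")
  expect_equal(collapsed$support, 103L)

  kept <- resolve_truncations(dplyr::bind_rows(
    parent, mk("child", child_key, 1850L, 2590L, 40L)), cfg)
  expect_setequal(kept$transcript_id, c("parent", "child"))

  # a non-sub-chain is untouched even with low support
  other <- mk("other", "1100-1300,1900-2100", 1000L, 2600L, 1L)
  out <- resolve_truncations(dplyr::bind_rows(parent, other), cfg)
  expect_setequal(out$transcript_id, c("parent", "other"))

  # 5'-anchored sub-chain is not a 3' truncation
  head_key <- "1100-1300,1500-1700"
  out2 <- resolve_truncations(dplyr::bind_rows(
    parent, mk("head", head_key, 1010L, 1750L, 3L)), cfg)
  expect_setequal(out2$transcript_id, c("parent", "head"))
})

test_that("error-free reads reproduce exactly the truth chains", {
  cfg <- sclr_config()
  d <- sim_design(seed = 21, n_genes = 6, cells_per_cluster = 5,
                  reads_per_cell = 60, sub_rate = 0, ins_rate = 0,
                  del_rate = 0, truncation_prob = 0)
  sim <- simulate_dataset(d)
  paths <- write_simulation(sim, tempfile())
  iso <- discover_isoforms(paths[["sam"]], sim$annotation, cfg)
  expect_true(all(iso$status == "known"))
  truth <- sort(unique(with(sim$annotation$transcripts,
                            sclriso:::chain_key(chrom, strand, intron_key))))
  got <- sort(unique(sclriso:::chain_key(iso$chrom, iso$strand,
                                         iso$intron_key)))
  expect_equal(got, truth)
})

test_that("discovery on its own output annotation is idempotent", {
  cfg <- sclr_config()
  d <- sim_design(seed = 22, n_genes = 4, cells_per_cluster = 5,
                  reads_per_cell = 40, sub_rate = 0, ins_rate = 0,
                  del_rate = 0, truncation_prob = 0)
  sim <- simulate_dataset(d)
  paths <- write_simulation(sim, tempfile())
  aln <- read_alignments(paths[["sam"]])
  iso <- discover_isoforms(aln, sim$annotation, cfg)
  out <- finalize_isoforms(iso, sim$genome, tempfile())
  ann2 <- read_annotation(out[["gff3"]])
  iso2 <- discover_isoforms(aln, ann2, cfg)
  expect_true(all(iso2$status == "known"))
  expect_setequal(iso2$transcript_id, iso$transcript_id)
})

test_that("the isoform set does not depend on read order", {
  cfg <- sclr_config()
  d <- sim_design(seed = 23, n_genes = 4, cells_per_cluster = 4,
                  reads_per_cell = 40, sub_rate = 0.05, ins_rate = 0,
                  del_rate = 0, truncation_prob = 0.3,
                  junction_jitter_prob = 0.2)
  sim <- simulate_dataset(d)
  paths <- write_simulation(sim, tempfile())
  aln <- read_alignments(paths[["sam"]])
  set.seed(1)
  perm <- aln[sample(nrow(aln)), ]
  iso1 <- discover_isoforms(aln, sim$annotation, cfg)
  iso2 <- discover_isoforms(perm, sim$annotation, cfg)
  expect_equal(dplyr::select(iso1, -read_ids),
               dplyr::select(iso2, -read_ids))
})

test_that("finalized GFF3 and FASTA agree with the isoform models", {
  ann <- read_annotation(fixture_annotation())
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(
    sample(c("A", "C", "G", "T"), 4000, replace = TRUE), collapse = "")))
  iso <- tibble::tibble(
    transcript_id = c("g1.t1", "novel1"), gene_id = "g1", chrom = "chr1",
    strand = "+", start = c(100L, 50L), end = c(800L, 800L),
    intron_key = c("200-300,400-500,600-700", "150-300,400-500,600-700"),
    status = c("known", "novel"), support = c(10L, 6L),
    read_ids = list("a", "b"))
  out <- finalize_isoforms(iso, genome, tempfile())
  ann2 <- read_annotation(out[["gff3"]])
  expect_setequal(ann2$transcripts$transcript_id, iso$transcript_id)
  expect_equal(
    ann2$transcripts$intron_key[match(iso$transcript_id,
                                      ann2$transcripts$transcript_id)],
    iso$intron_key)
  fa <- Biostrings::readDNAStringSet(out[["fasta"]])
  expect_setequal(names(fa), iso$transcript_id)
  # empty set still writes valid files
  out2 <- finalize_isoforms(sclriso:::empty_isoforms(), genome, tempfile())
  expect_equal(nrow(read_annotation(out2[["gff3"]])$transcripts), 0L)
  expect_equal(length(Biostrings::readDNAStringSet(out2[["fasta"]])), 0L)
})
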