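iso_row <- function(id, key, start, end, gene = "g1", chrom = "chr1",
                    strand = "+") {
  tibble::tibble(transcript_id = id, gene_id = gene, chrom = chrom,
                 strand = strand, start = as.integer(start),
                 end = as.integer(end), intron_key = key)
}

test_that("FSM/ISM/NIC/NNC definitions hold on constructed chains", {
  ann <- read_annotation(fixture_annotation())
  # g1.t1 introns: 200-300, 400-500, 600-700
  cases <- dplyr::bind_rows(
    iso_row("fsm", "200-300,400-500,600-700", 100, 800),
    iso_row("ism", "400-500", 320, 580),                    # middle intron
    # known donor 200 with known acceptor 700: never joined in a reference
    iso_row("nic", "200-700", 100, 800),
    # donor shifted 8 bp -> novel site
    iso_row("nnc", "208-700", 100, 800),
    iso_row("mono_fsm", "", 3100, 3300, gene = "g3"),
    iso_row("mono_other", "", 9000, 9100, gene = "gX"))
  got <- classify_isoforms(cases, ann)
  expect_equal(got$category,
               c("FSM", "ISM", "NIC", "NNC", "FSM", "other"))
  expect_equal(got$matched_transcript[1], "g1.t1")
  expect_false(is.na(got$matched_transcript[2]))
  expect_true(all(is.na(got$matched_transcript[3:4])))
})

test_that("classification agrees with the definitional oracle on all short chains", {
  ann <- read_annotation(fixture_annotation())
  sites <- sclriso:::gene_site_sets(ann, "g1")
  ref_tx <- ann$transcripts
  # enumerate chains with <= 3 introns over a mixed site pool: reference
  # sites plus novel ones
  pool <- sort(unique(c(200L, 300L, 400L, 500L, 600L, 700L, 208L, 650L)))
  combos <- list()
  for (n_introns in 1:3) {
    bounds <- utils::combn(pool, 2L * n_introns, simplify = FALSE)
    combos <- c(combos, bounds)
  }
  n_checked <- 0L
  for (b in combos) {
    m <- matrix(b, ncol = 2, byrow = TRUE)
    if (any(m[, 1] >= m[, 2])) next
    if (nrow(m) > 1 && any(m[-1, 1] < m[-nrow(m), 2])) next  # overlap
    key <- paste(paste0(m[, 1], "-", m[, 2]), collapse = ",")
    row <- iso_row("x", key, min(m) - 50L, max(m) + 50L)
    got <- classify_isoforms(row, ann)$category
    want <- brute_classify("chr1", "+", row$start, row$end, key, ref_tx,
                           sites$donors, sites$acceptors)
    expect_equal(got, want, info = key)
    n_checked <- n_checked + 1L
  }
  expect_gt(n_checked, 100L)
})

test_that("FSM isoforms always match a reference with the identical chain", {
  ann <- read_annotation(fixture_annotation())
  d <- sim_design(seed = 61, n_genes = 5, cells_per_cluster = 2,
                  reads_per_cell = 20, sub_rate = 0, truncation_prob = 0)
  sim <- simulate_dataset(d)
  cls <- classify_isoforms(sim$annotation$transcripts, sim$annotation)
  fsm <- cls[cls$category == "FSM", ]
  keys <- sim$annotation$transcripts
  for (i in seq_len(nrow(fsm))) {
    own <- keys$intron_key[keys$transcript_id == fsm$isoform_id[i]]
    matched <- keys$intron_key[keys$transcript_id ==
                                 fsm$matched_transcript[i]]
    expect_equal(own, matched)
  }
})

test_that("single splicing events are typed and two events are complex", {
  cfg <- sclr_config()
  # exon skipping: A joins 200-700 where B has 200-300 + 400-700... use
  # matching outer bounds
  a <- iso_row("A", "200-700", 100, 800)
  b <- iso_row("B", "200-300,400-700", 100, 800)
  ev <- call_splice_events(a, b, cfg)
  expect_equal(ev$category, "exon_skipping")
  # symmetric
  expect_equal(call_splice_events(b, a, cfg)$category, "exon_skipping")

  # intron retention: B lacks A's intron, region exonic in B
  a2 <- iso_row("A", "200-300,400-500", 100, 800)
  b2 <- iso_row("B", "200-300", 100, 800)
  expect_equal(call_splice_events(a2, b2, cfg)$category, "intron_retention")

  # alternative 3' site on "+": acceptor moved, donor shared
  a3 <- iso_row("A", "200-300", 100, 800)
  b3 <- iso_row("B", "200-330", 100, 800)
  expect_equal(call_splice_events(a3, b3, cfg)$category, "alt_three_prime")
  # same change on "-" is an alternative 5' site
  a3m <- iso_row("A", "200-300", 100, 800, strand = "-")
  b3m <- iso_row("B", "200-330", 100, 800, strand = "-")
  expect_equal(call_splice_events(a3m, b3m, cfg)$category, "alt_five_prime")

  # alternative 5' site on "+": donor moved, acceptor shared
  a4 <- iso_row("A", "200-300", 100, 800)
  b4 <- iso_row("B", "230-300", 100, 800)
  expect_equal(call_splice_events(a4, b4, cfg)$category, "alt_five_prime")

  # acceptor shift plus a skipped exon elsewhere -> complex
  a5 <- iso_row("A", "200-330,400-500,600-700", 100, 800)
  b5 <- iso_row("B", "200-300,400-700", 100, 800)
  expect_equal(call_splice_events(a5, b5, cfg)$category, "complex")

  # identical chains
  expect_equal(call_splice_events(a3, a3, cfg)$category, "identical_chain")

  # terminal difference beyond end_tol counts as promoter/polyA event
  a6 <- iso_row("A", "200-300", 100, 800)
  b6 <- iso_row("B", "200-300", 100, 950)
  expect_equal(call_splice_events(a6, b6, cfg)$category, "alt_three_prime")

  expect_error(call_splice_events(a3, iso_row("B", "200-300", 100, 800,
                                              chrom = "chr2"), cfg),
               "different")
})

test_that("event typing is symmetric across constructed pairs", {
  cfg <- sclr_config()
  pairs <- list(
    list(iso_row("A", "200-700", 100, 800),
         iso_row("B", "200-300,400-700", 100, 800)),
    list(iso_row("A", "200-300,400-500", 100, 800),
         iso_row("B", "200-300", 100, 800)),
    list(iso_row("A", "200-330", 100, 800),
         iso_row("B", "230-300", 100, 800)),
    list(iso_row("A", "200-300,450-550", 100, 800),
         iso_row("B", "210-340,600-700", 100, 900)))
  for (p in pairs) {
    expect_equal(call_splice_events(p[[1]], p[[2]], cfg)$category,
                 call_splice_events(p[[2]], p[[1]], cfg)$category)
  }
})

test_that("top-2 event typing ranks by abundance within genes", {
  cfg <- sclr_config()
  iso <- dplyr::bind_rows(
    iso_row("t1", "200-700", 100, 800),
    iso_row("t2", "200-300,400-700", 100, 800),
    iso_row("t3", "208-700", 100, 800))
  counts <- tibble::tibble(
    transcript_id = c("t1", "t2", "t3"), gene_id = "g1",
    barcode = "c1", count = c(50L, 30L, 1L))
  ev <- top2_splice_events(counts, iso, cfg)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$isoform_1, "t1")
  expect_equal(ev$isoform_2, "t2")
  expect_equal(ev$category, "exon_skipping")
})

test_that("diversity summaries count isoforms and rank usage fractions", {
  counts <- tibble::tibble(
    transcript_id = c("a1", "b1", "b2", paste0("c", 1:7)),
    gene_id = c("gA", "gB", "gB", rep("gC", 7)),
    barcode = "cell1",
    count = c(5L, 80L, 20L, rep(1L, 7)))
  s <- summarize_diversity(counts)
  expect_equal(s$histogram$n_isoforms[s$histogram$gene_id == "gA"], 1L)
  expect_equal(s$histogram$bin[s$histogram$gene_id == "gC"], ">=6")
  fb <- s$fractions[s$fractions$gene_id == "gB", ]
  expect_equal(fb$fraction, c(0.8, 0.2))
  expect_equal(fb$rank, 1:2)
  fa <- s$fractions[s$fractions$gene_id == "gA", ]
  expect_equal(fa$fraction, 1.0)
})
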