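#' Pipeline configuration
#'
#' Builds the validated record of every threshold used across the pipeline.
#' Defaults follow the published nanopore single-cell protocol: barcodes are
#' matched at edit distance <= 2, splice junctions are grouped/corrected when
#' closer than 5 bp, transcript ends are merged when closer than 100 bp,
#' isoforms need at least 5 full-length (> 95% transcript coverage) reads,
#' reads need >= 60% transcript coverage to be assigned, UMIs collapse at edit
#' distance <= 2, DTU requires isoforms with more than 15 UMIs, homopolymer
#' runs longer than 3 nt are masked, and candidate SNVs need >= 100 reads with
#' reference allele frequency between 10% and 90%.
#'
#' @param barcode_max_ed Maximum barcode edit distance (edits).
#' @param flank_seq Adapter sequence flanking the cell barcode (5' side).
#' @param flank_max_ed Maximum edit distance for the flank search.
#' @param umi_length UMI length in nt (10 for 3' v2 chemistry, 12 for v3/5').
#' @param protocol_end `"three_prime"` or `"five_prime"`.
#' @param jct_tol Junction tolerance in bp; sites strictly closer than this
#'   are grouped/corrected.
#' @param end_tol Transcript end tolerance in bp (strict).
#' @param trunc_slope,trunc_intercept Coefficients of the linear
#'   truncation-rate model `f(L) = clamp(slope * L + intercept, 0, 0.95)`.
#' @param min_fl_support Minimum full-length read support per isoform.
#' @param fl_cov Transcript coverage above which a read is full-length
#'   (strict).
#' @param min_assign_cov Minimum transcript coverage for read assignment.
#' @param min_read_frac_aligned Minimum fraction of the read aligned.
#' @param umi_dedup_ed UMI collapse edit distance.
#' @param min_intron Minimum alignment gap length treated as an intron (bp).
#' @param dtu_min_count Per-isoform UMI total a gene's isoforms must exceed
#'   (strict) to be testable for DTU.
#' @param dtu_alpha Adjusted-p significance bar for DTU.
#' @param dtu_continuity Apply Yates continuity correction to 2x2 DTU tables.
#' @param homopolymer_min_run Runs of this length or longer are masked.
#' @param snv_min_cov Minimum pileup coverage for a candidate SNV.
#' @param snv_af_low,snv_af_high Reference allele frequency band for
#'   candidates.
#' @param snv_min_base_qual Minimum base quality in pileups.
#' @param var_alpha Adjusted-p significance bar for variant tests.
#' @param strand_specific Trust the alignment strand for novel chains.
#' @param random_seed Seed recorded into outputs for provenance.
#' @return A validated `sclr_config` object (a named list).
#' @export
#' @examples
#' cfg <- sclr_config(umi_length = 10)
#' cfg$jct_tol
sclr_config <- function(barcode_max_ed = 2L,
                        flank_seq = "CTACACGACGCTCTTCCGATCT",
                        flank_max_ed = 6L,
                        umi_length = 10L,
                        protocol_end = c("three_prime", "five_prime"),
                        jct_tol = 5L,
                        end_tol = 100L,
                        trunc_slope = 1e-4,
                        trunc_intercept = 0,
                        min_fl_support = 5L,
                        fl_cov = 0.95,
                        min_assign_cov = 0.60,
                        min_read_frac_aligned = 0.5,
                        umi_dedup_ed = 2L,
                        min_intron = 30L,
                        dtu_min_count = 15L,
                        dtu_alpha = 0.01,
                        dtu_continuity = FALSE,
                        homopolymer_min_run = 4L,
                        snv_min_cov = 100L,
                        snv_af_low = 0.10,
                        snv_af_high = 0.90,
                        snv_min_base_qual = 7L,
                        var_alpha = 0.05,
                        strand_specific = TRUE,
                        random_seed = 1L) {
  protocol_end <- match.arg(protocol_end)
  cfg <- list(
    barcode_max_ed = as.integer(barcode_max_ed),
    flank_seq = toupper(as.character(flank_seq)),
    flank_max_ed = as.integer(flank_max_ed),
    umi_length = as.integer(umi_length),
    protocol_end = protocol_end,
    jct_tol = as.integer(jct_tol),
    end_tol = as.integer(end_tol),
    trunc_slope = as.numeric(trunc_slope),
    trunc_intercept = as.numeric(trunc_intercept),
    min_fl_support = as.integer(min_fl_support),
    fl_cov = as.numeric(fl_cov),
    min_assign_cov = as.numeric(min_assign_cov),
    min_read_frac_aligned = as.numeric(min_read_frac_aligned),
    umi_dedup_ed = as.integer(umi_dedup_ed),
    min_intron = as.integer(min_intron),
    dtu_min_count = as.integer(dtu_min_count),
    dtu_alpha = as.numeric(dtu_alpha),
    dtu_continuity = isTRUE(dtu_continuity),
    homopolymer_min_run = as.integer(homopolymer_min_run),
    snv_min_cov = as.integer(snv_min_cov),
    snv_af_low = as.numeric(snv_af_low),
    snv_af_high = as.numeric(snv_af_high),
    snv_min_base_qual = as.integer(snv_min_base_qual),
    var_alpha = as.numeric(var_alpha),
    strand_specific = isTRUE(strand_specific),
    random_seed = as.integer(random_seed)
  )
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (!(cfg$fl_cov > 0 && cfg$fl_cov <= 1)) {
    stop("fl_cov must satisfy 0 < fl_cov <= 1", call. = FALSE)
  }
  if (cfg$min_assign_cov > cfg$fl_cov) {
    stop("min_assign_cov must not exceed fl_cov", call. = FALSE)
  }
  if (!(cfg$snv_af_low < cfg$snv_af_high)) {
    stop("snv_af_low must be below snv_af_high", call. = FALSE)
  }
  counts <- c("barcode_max_ed", "flank_max_ed", "umi_length", "jct_tol",
              "end_tol", "min_fl_support", "umi_dedup_ed", "min_intron",
              "dtu_min_count", "homopolymer_min_run", "snv_min_cov",
              "snv_min_base_qual")
  bad <- counts[vapply(counts, function(k) cfg[[k]] < 0L, logical(1))]
  if (length(bad)) {
    stop("count thresholds must be >= 0: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!grepl("^[ACGT]+$", cfg$flank_seq)) {
    stop("flank_seq must be a DNA string (ACGT)", call. = FALSE)
  }
  structure(cfg, class = "sclr_config")
}

#' Read a pipeline configuration from JSON
#'
#' Unknown keys are rejected so that typos in a config file cannot silently
#' fall back to defaults.
#'
#' @param path Path to a JSON file of configuration overrides.
#' @return A validated `sclr_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(sclr_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(sclr_config, raw)
}

#' Write a pipeline configuration to JSON
#' @param config A `sclr_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "sclr_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.sclr_config <- function(x, ...) {
  cat("<sclr_config>\n")
  for (k in names(x)) cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
  invisible(x)
}

config_hash <- function(config) {
  # stable short fingerprint recorded in matrix metadata
  s <- paste(names(config), vapply(config, format, character(1)),
             collapse = ";")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}
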