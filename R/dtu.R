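#' Read cell-to-cluster labels
#' @param path CSV with columns `barcode` and `cluster` (header optional;
#'   two unnamed columns are accepted in that order).
#' @return A tibble `barcode`, `cluster`.
#' @export
read_cluster_labels <- function(path) {
  df <- suppressMessages(readr::read_csv(path, show_col_types = FALSE))
  if (!all(c("barcode", "cluster") %in% names(df))) {
    if (ncol(df) < 2L) stop("cluster file needs two columns", call. = FALSE)
    df <- stats::setNames(df[, 1:2], c("barcode", "cluster"))
  }
  tibble(barcode = as.character(df$barcode),
         cluster = as.character(df$cluster))
}

#' Collapse transcripts sharing an intron chain
#'
#' DTU focuses on internal splice junctions: transcripts of a gene with the
#' same intron chain are summed into one row, keyed by the most abundant
#' member's id.
#'
#' @param transcript_counts Long transcript count tibble.
#' @param isoforms Isoform tibble supplying each transcript's chain.
#' @return A collapsed long count tibble of the same shape.
#' @export
collapse_by_intron_chain <- function(transcript_counts, isoforms) {
  if (nrow(transcript_counts) == 0L) return(transcript_counts)
  chains <- isoforms %>%
    select("transcript_id", "intron_key") %>%
    distinct()
  x <- transcript_counts %>%
    inner_join(chains, by = "transcript_id")
  keys <- x %>%
    group_by(.data$gene_id, .data$intron_key, .data$transcript_id) %>%
    summarise(total = sum(.data$count), .groups = "drop") %>%
    arrange(.data$gene_id, .data$intron_key, desc(.data$total),
            .data$transcript_id) %>%
    distinct(.data$gene_id, .data$intron_key, .keep_all = TRUE) %>%
    select("gene_id", "intron_key", rep_id = "transcript_id")
  x %>%
    inner_join(keys, by = c("gene_id", "intron_key")) %>%
    group_by(transcript_id = .data$rep_id, gene_id = .data$gene_id,
             barcode = .data$barcode) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    arrange(.data$transcript_id, .data$barcode)
}

#' Aggregate single-cell counts into pseudo-bulk cluster counts
#'
#' @param counts Long count tibble (`transcript_id`, `gene_id`, `barcode`,
#'   `count`).
#' @param labels Cluster label tibble from [read_cluster_labels()].
#' @return A long tibble `transcript_id`, `gene_id`, `cluster`, `count`
#'   (clusters in lexicographic order); unlabeled cells are dropped, their
#'   number recorded in the `dropped_cells` attribute.
#' @export
pseudo_bulk <- function(counts, labels) {
  if (length(unique(labels$cluster)) < 2L) {
    stop("pseudo-bulk aggregation needs at least two clusters",
         call. = FALSE)
  }
  unlabeled <- setdiff(unique(counts$barcode), labels$barcode)
  out <- counts %>%
    inner_join(labels, by = "barcode") %>%
    group_by(.data$transcript_id, .data$gene_id, .data$cluster) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    arrange(.data$transcript_id, .data$cluster)
  attr(out, "dropped_cells") <- length(unlabeled)
  out
}

# chi-square test of independence on a counts matrix after dropping all-zero
# rows/columns; continuity correction only on request (and only 2x2 applies)
chisq_independence <- function(tab, continuity = FALSE) {
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) return(NULL)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = continuity))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), table = tab)
}

#' Test one gene for differential transcript usage
#'
#' A gene is testable when at least two of its (chain-collapsed) transcripts
#' each have total pseudo-bulk count strictly greater than `dtu_min_count`
#' (the "more than 15 UMI counts" filter). The tested rows are the union
#' over clusters of each cluster's two most expressed transcripts; the
#' statistic is the Pearson chi-square of independence on the selected rows
#' by clusters table, with all-zero rows/columns dropped.
#'
#' @param gene_tab Long pseudo-bulk tibble for one gene (`transcript_id`,
#'   `cluster`, `count`).
#' @param config A [sclr_config()].
#' @return A one-row tibble (`transcripts`, `statistic`, `df`, `p_value`)
#'   or `NULL` with attribute-free `NULL` when not testable.
#' @export
test_gene_dtu <- function(gene_tab, config = sclr_config()) {
  wide <- gene_tab %>%
    select("transcript_id", "cluster", "count") %>%
    tidyr::pivot_wider(names_from = "cluster", values_from = "count",
                       values_fill = 0L) %>%
    arrange(.data$transcript_id)
  m <- as.matrix(wide[, sort(setdiff(names(wide), "transcript_id")),
                      drop = FALSE])
  rownames(m) <- wide$transcript_id
  totals <- rowSums(m)
  if (sum(totals > config$dtu_min_count) < 2L) return(NULL)
  # union over clusters of each cluster's top-2 transcripts
  sel <- unique(unlist(lapply(seq_len(ncol(m)), function(k) {
    ord <- order(-m[, k], -totals, rownames(m))
    rownames(m)[ord[seq_len(min(2L, nrow(m)))]]
  })))
  res <- chisq_independence(m[sel, , drop = FALSE],
                            continuity = config$dtu_continuity)
  if (is.null(res)) return(NULL)
  tibble(transcripts = paste(sort(sel), collapse = ";"),
         statistic = res$statistic, df = res$df, p_value = res$p_value)
}

#' Differential transcript usage across clusters
#'
#' Collapses transcripts by intron chain, aggregates to pseudo-bulk, tests
#' each eligible gene with a chi-square test of independence, and adjusts
#' p-values with Benjamini-Hochberg across testable genes.
#'
#' @param transcript_counts Long transcript count tibble.
#' @param isoforms Isoform tibble (for intron chains).
#' @param labels Cluster labels tibble.
#' @param config A [sclr_config()].
#' @return An `sclr_dtu` object; `tidy()` returns the per-gene result table
#'   (gene_id, transcripts, statistic, df, p_value, adj_p_value, plus
#'   per-cluster usage fraction columns), `glance()` a one-row summary.
#' @export
dtu_test <- function(transcript_counts, isoforms, labels,
                     config = sclr_config()) {
  collapsed <- collapse_by_intron_chain(transcript_counts, isoforms)
  pb <- pseudo_bulk(collapsed, labels)
  genes <- sort(unique(pb$gene_id))
  rows <- lapply(genes, function(gid) {
    gt <- pb %>% filter(.data$gene_id == gid)
    res <- test_gene_dtu(gt, config)
    if (is.null(res)) return(NULL)
    sel <- strsplit(res$transcripts, ";", fixed = TRUE)[[1L]]
    usage <- gt %>%
      filter(.data$transcript_id %in% sel) %>%
      group_by(.data$cluster) %>%
      mutate(fraction = .data$count / sum(.data$count)) %>%
      ungroup()
    top_fraction <- usage %>%
      filter(.data$transcript_id == sel[[1L]]) %>%
      select("cluster", "fraction") %>%
      tidyr::pivot_wider(names_from = "cluster", values_from = "fraction",
                         names_prefix = "usage_")
    bind_rows(tibble(gene_id = gid) %>% dplyr::bind_cols(res, top_fraction))
  })
  tab <- bind_rows(rows)
  if (nrow(tab)) {
    tab$adj_p_value <- stats::p.adjust(tab$p_value, method = "BH")
    tab <- tab %>% arrange(.data$p_value, .data$gene_id)
  } else {
    tab$adj_p_value <- numeric(0)
  }
  structure(list(results = tab, n_genes = length(genes),
                 alpha = config$dtu_alpha, labels = labels),
            class = "sclr_dtu")
}

#' @export
print.sclr_dtu <- function(x, ...) {
  cat(sprintf("<sclr_dtu> %d genes tested (of %d), %d significant at adj p < %g\n",
              nrow(x$results), x$n_genes,
              sum(x$results$adj_p_value < x$alpha), x$alpha))
  invisible(x)
}

#' @rdname dtu_test
#' @param x An `sclr_dtu` object.
#' @param ... Unused.
#' @export
tidy.sclr_dtu <- function(x, ...) x$results

#' @rdname dtu_test
#' @export
glance.sclr_dtu <- function(x, ...) {
  tibble(n_genes = x$n_genes, n_tested = nrow(x$results),
         n_significant = sum(x$results$adj_p_value < x$alpha),
         alpha = x$alpha)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Volcano-style overview of DTU results
#'
#' @param object An `sclr_dtu` object.
#' @param ... Unused.
#' @return A ggplot: chi-square statistic against -log10 adjusted p, with
#'   the significance bar drawn.
#' @export
autoplot.sclr_dtu <- function(object, ...) {
  df <- object$results
  ggplot2::ggplot(df, ggplot2::aes(x = .data$statistic,
                                   y = -log10(pmax(.data$adj_p_value,
                                                   1e-300)))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$adj_p_value <
                                       object$alpha), alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(object$alpha),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick"),
                                 name = sprintf("adj p < %g", object$alpha)) +
    ggplot2::labs(x = "chi-square statistic",
                  y = "-log10 adjusted p-value",
                  title = "Differential transcript usage") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
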