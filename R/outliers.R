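join_spreads <- function(summary_cs, summary_ws) {
  m <- merge(summary_cs, summary_ws, by = "gene_id",
             suffixes = c("_cs", "_ws"), sort = TRUE)
  if (nrow(m) == 0L) stop("no shared genes between summaries", call. = FALSE)
  m
}

contrast_frame <- function(m, keep, kind, higher_ws) {
  out <- data.frame(
    gene_id = m$gene_id[keep],
    kind = rep(kind, sum(keep)),
    direction = ifelse(higher_ws[keep], "higher_in_WS", "higher_in_CS"),
    iq_r_cs = m$iq_r_cs[keep], iq_r_ws = m$iq_r_ws[keep],
    med_r_cs = m$med_r_cs[keep], med_r_ws = m$med_r_ws[keep],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("contrast_calls", "data.frame")
  out
}

#' Genes with contrasted e_T-ratio spread between compartments
#'
#' Flags genes whose inter-quartile ranges differ between the
#' cultivated and wild panels by strictly more than \code{threshold}:
#' \code{|iq_r(CS) - iq_r(WS)| > threshold}. A difference exactly at the
#' threshold is not flagged.
#'
#' @param summary_cs,summary_ws Per-gene summaries from [gene_spread()]
#'   for the cultivated and wild panels (same gene set).
#' @param threshold Minimum absolute IQR difference (default 0.2).
#' @return A \code{contrast_calls} data frame: \code{gene_id},
#'   \code{kind}, \code{direction} (which compartment has the larger
#'   quantity), and the four underlying summaries.
#' @export
iqr_contrast <- function(summary_cs, summary_ws, threshold = 0.2) {
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  m <- join_spreads(summary_cs, summary_ws)
  d <- m$iq_r_cs - m$iq_r_ws
  contrast_frame(m, abs(d) > threshold, "iqr_contrast", d < 0)
}

#' Genes with contrasted e_T-ratio location between compartments
#'
#' Flags genes whose median e_T-ratios differ between compartments by
#' more than both the fixed threshold and the average within-compartment
#' spread: \code{|med_r(CS) - med_r(WS)| > max(threshold,
#' (iq_r(CS) + iq_r(WS)) / 2)}. The compound condition keeps only
#' between-compartment differences that exceed those observed within
#' compartments. Strict inequality at the boundary.
#'
#' @inheritParams iqr_contrast
#' @param threshold Minimum absolute median difference (default 0.2).
#' @return A \code{contrast_calls} data frame; \code{direction} reports
#'   which compartment has the larger median.
#' @export
median_contrast <- function(summary_cs, summary_ws, threshold = 0.2) {
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  m <- join_spreads(summary_cs, summary_ws)
  d <- m$med_r_cs - m$med_r_ws
  cut <- pmax(threshold, (m$iq_r_cs + m$iq_r_ws) / 2)
  contrast_frame(m, abs(d) > cut, "median_contrast", d < 0)
}

#' Consensus of contrast calls across comparisons
#'
#' Genes flagged in every comparison of a list, by gene identity alone
#' (a gene counted even if its direction differs between comparisons;
#' such direction flips are reported in the \code{direction_conflicts}
#' attribute).
#'
#' @param calls_per_comparison Non-empty list of \code{contrast_calls}.
#' @return Sorted character vector of gene ids present in all call
#'   sets, with attribute \code{direction_conflicts}.
#' @export
consensus_genes <- function(calls_per_comparison) {
  stopifnot(length(calls_per_comparison) >= 1L)
  sets <- lapply(calls_per_comparison, function(x) unique(x$gene_id))
  genes <- sort(Reduce(intersect, sets))
  dirs <- lapply(calls_per_comparison, function(x)
    setNames(x$direction, x$gene_id))
  conflict <- vapply(genes, function(g) {
    length(unique(vapply(dirs, function(d) d[[g]], character(1)))) > 1L
  }, logical(1))
  structure(genes, direction_conflicts = genes[conflict])
}

#' Joint consensus over both contrast filters
#'
#' Consensus gene sets of the IQR-contrast and median-contrast filters
#' across comparisons, plus their intersection (genes contrasted in
#' both spread and location).
#'
#' @param iqr_calls,median_calls Lists of \code{contrast_calls}, one
#'   per comparison.
#' @return List: \code{iqr}, \code{median}, \code{both} (character
#'   vectors of gene ids).
#' @export
contrast_consensus <- function(iqr_calls, median_calls) {
  ci <- consensus_genes(iqr_calls)
  cm <- consensus_genes(median_calls)
  list(iqr = as.character(ci), median = as.character(cm),
       both = sort(intersect(ci, cm)))
}

#' Write contrast calls as TSV
#'
#' @param calls A \code{contrast_calls} data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_contrast_calls <- function(calls, path) {
  write_tsv(as.data.frame(calls)[order(calls$gene_id), , drop = FALSE], path)
}
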