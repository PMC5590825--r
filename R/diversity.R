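#' Per-gene spread summaries of e_T-ratios within one panel
#'
#' For each gene, over the accessions of one panel: the mean
#' (\code{avg_r}), median (\code{med_r}), sample variance with the n-1
#' denominator (\code{sigma_r} — the study's notation, despite sigma
#' conventionally denoting a standard deviation), and inter-quartile
#' range \code{iq_r} = Q3 - Q1 under the linear-interpolation quantile
#' convention (p-th quantile interpolates order statistics at rank
#' 1 + (n-1)p; \code{stats::quantile} type 7). IQR values at small n are
#' convention-sensitive, hence the explicit choice.
#'
#' @param ratios An \code{et_ratio_matrix}.
#' @param panel A \code{panel_definition}; at least 2 accessions (the
#'   variance is undefined below that) and all present in the matrix.
#' @return A data frame: \code{gene_id}, \code{avg_r}, \code{med_r},
#'   \code{sigma_r}, \code{iq_r}.
#' @export
gene_spread <- function(ratios, panel) {
  stopifnot(inherits(ratios, "et_ratio_matrix"),
            inherits(panel, "panel_definition"))
  if (length(panel$accessions) < 2L) {
    stop("panel '", panel$label,
         "' has fewer than 2 accessions; variance undefined", call. = FALSE)
  }
  absent <- setdiff(panel$accessions, ratios$accessions)
  if (length(absent) > 0L) {
    stop("panel accession(s) absent from ratio matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  m <- ratios$values[, panel$accessions, drop = FALSE]
  n <- ncol(m)
  avg <- rowMeans(m)
  # row-wise order statistics: sort each row once, interpolate quartiles
  sorted <- t(apply(m, 1L, sort))
  qat <- function(p) {
    h <- 1 + (n - 1) * p
    lo <- floor(h); hi <- ceiling(h)
    sorted[, lo] + (h - lo) * (sorted[, hi] - sorted[, lo])
  }
  med <- qat(0.5)
  iqr <- qat(0.75) - qat(0.25)
  sig <- rowSums((m - avg)^2) / (n - 1)
  data.frame(gene_id = ratios$genes, avg_r = avg, med_r = med,
             sigma_r = sig, iq_r = iqr,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare e_T-ratio spread between cultivated and wild panels
#'
#' For the chosen spread statistic (per-gene variance \code{sigma_r} or
#' inter-quartile range \code{iq_r}), computes: counts of genes whose
#' cultivated-panel spread is greater than / equal to / less than the
#' wild-panel spread (equality within tolerance 1e-12, because
#' ratio ties can be exact); the ordinary least-squares slope (with
#' intercept) of the wild spread regressed on the cultivated spread;
#' the mean per-gene difference CS - WS; and two paired tests on those
#' differences — Student's t and the Wilcoxon signed-rank (zero
#' differences dropped; exact distribution for n <= 25 without ties,
#' normal approximation with continuity correction otherwise).
#'
#' @param ratios An \code{et_ratio_matrix}.
#' @param cs,ws \code{panel_definition}s.
#' @param statistic \code{"sigma_r"} or \code{"iq_r"}.
#' @param alternative Sidedness of both tests (default two-sided).
#' @return A \code{panel_comparison}: statistic, the three direction
#'   counts, \code{slope}, \code{mean_diff}, \code{p_paired_t},
#'   \code{p_wilcoxon}, \code{n_genes}, plus the per-gene spread vectors
#'   \code{spread_cs}, \code{spread_ws} used.
#' @export
compare_panels <- function(ratios, cs, ws,
                           statistic = c("sigma_r", "iq_r"),
                           alternative = "two.sided") {
  statistic <- match.arg(statistic)
  if (length(ratios$genes) < 3L) {
    stop("fewer than 3 genes; comparison not meaningful", call. = FALSE)
  }
  scs <- gene_spread(ratios, cs)[[statistic]]
  sws <- gene_spread(ratios, ws)[[statistic]]
  names(scs) <- names(sws) <- ratios$genes

  d <- scs - sws
  tol <- 1e-12
  n_eq <- sum(abs(d) <= tol)
  n_gt <- sum(d > tol)
  n_lt <- sum(d < -tol)

  slope <- unname(stats::coef(stats::lm(sws ~ scs))[2L])
  p_t <- stats::t.test(d, alternative = alternative)$p.value
  dnz <- d[abs(d) > tol]
  if (length(dnz) == 0L) {
    warning("all spread differences are zero; Wilcoxon p reported as 1")
    p_w <- 1
  } else {
    p_w <- suppressWarnings(
      stats::wilcox.test(dnz, alternative = alternative,
                         exact = length(dnz) <= 25L, correct = TRUE)$p.value)
  }
  structure(list(statistic = statistic,
                 cs_label = cs$label, ws_label = ws$label,
                 n_genes = length(d),
                 n_cs_gt_ws = n_gt, n_cs_eq_ws = n_eq, n_cs_lt_ws = n_lt,
                 slope = slope, mean_diff = mean(d),
                 p_paired_t = p_t, p_wilcoxon = p_w,
                 spread_cs = scs, spread_ws = sws),
            class = "panel_comparison")
}

#' @export
print.panel_comparison <- function(x, ...) {
  cat("e_T-ratio spread comparison (", x$statistic, "): ",
      x$cs_label, " vs ", x$ws_label, "\n", sep = "")
  cat(sprintf("  genes: %d   CS>WS: %d   CS=WS: %d   CS<WS: %d\n",
              x$n_genes, x$n_cs_gt_ws, x$n_cs_eq_ws, x$n_cs_lt_ws))
  cat(sprintf("  slope (WS ~ CS): %.4g   mean diff (CS-WS): %.4g\n",
              x$slope, x$mean_diff))
  cat(sprintf("  paired t p: %.3g   Wilcoxon p: %.3g\n",
              x$p_paired_t, x$p_wilcoxon))
  invisible(x)
}

#' Dot plot of per-gene spread, cultivated vs wild
#'
#' One point per gene: cultivated-panel spread on the abscissa, wild on
#' the ordinate, with the fitted regression line and the y = x
#' reference.
#'
#' @param x A \code{panel_comparison}.
#' @param ... Passed to \code{plot}.
#' @export
plot.panel_comparison <- function(x, ...) {
  lab <- if (x$statistic == "sigma_r") "variance of e_T-ratios" else
    "inter-quartile range of e_T-ratios"
  plot(x$spread_cs, x$spread_ws,
       xlab = paste(lab, "-", x$cs_label),
       ylab = paste(lab, "-", x$ws_label),
       pch = 20, col = "grey40", ...)
  graphics::abline(0, 1, lty = 2)
  graphics::abline(stats::lm(x$spread_ws ~ x$spread_cs), col = "red")
  invisible(x)
}

#' Randomly subsample a panel
#'
#' Draws \code{n_draws} distinct accession subsets of size \code{k}
#' without replacement, reproducibly from \code{seed}. Labels are
#' suffixed \code{_1} .. \code{_n} (e.g. \code{popCS_6_1}).
#'
#' @param panel A \code{panel_definition}.
#' @param k Subset size, <= panel size.
#' @param n_draws Number of distinct subsets; must not exceed
#'   \code{choose(size, k)}.
#' @param seed Integer seed.
#' @return List of \code{panel_definition}s.
#' @export
subsample_panel <- function(panel, k, n_draws, seed = 1L) {
  stopifnot(inherits(panel, "panel_definition"))
  size <- length(panel$accessions)
  if (k > size) stop("k exceeds panel size", call. = FALSE)
  n_possible <- choose(size, k)
  if (n_draws > n_possible) {
    stop("requested ", n_draws, " distinct subsets but only ", n_possible,
         " of size ", k, " exist", call. = FALSE)
  }
  with_seed(seed, {
    seen <- character(0)
    out <- vector("list", n_draws)
    i <- 0L
    while (i < n_draws) {
      draw <- sort(sample(size, k))
      key <- paste(draw, collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      i <- i + 1L
      out[[i]] <- panel_definition(
        label = paste0("pop", panel$compartment, "_", k, "_", i),
        compartment = panel$compartment,
        accessions = panel$accessions[draw])
    }
    out
  })
}

#' Run the full battery of panel comparisons
#'
#' For each cultivated panel, independently re-applies the mask, the
#' gene filters and the ratio computation against the wild panel (gene
#' sets legitimately differ between comparisons), then compares spreads
#' for each requested statistic.
#'
#' @param table An unmasked \code{isoform_expression_table}.
#' @param cs_panels List of cultivated \code{panel_definition}s.
#' @param ws_panel The wild \code{panel_definition}.
#' @param min_coverage Coverage threshold for masking (default 5).
#' @param statistics Spread statistics to compare.
#' @return A list of \code{panel_comparison} objects, one per
#'   (cs panel x statistic), named \code{<cs_label>.<statistic>}; each
#'   carries its own gene count.
#' @export
run_all_comparisons <- function(table, cs_panels, ws_panel,
                                min_coverage = 5,
                                statistics = c("sigma_r", "iq_r")) {
  stopifnot(length(cs_panels) >= 1L)
  masked <- apply_coverage_mask(table, min_coverage)
  out <- list()
  for (cs in cs_panels) {
    genes <- select_genes(masked, cs, ws_panel)
    ratios <- compute_et_ratios(masked, genes, cs, ws_panel)
    for (st in statistics) {
      out[[paste(cs$label, st, sep = ".")]] <-
        compare_panels(ratios, cs, ws_panel, statistic = st)
    }
  }
  out
}

#' Write comparison results as TSV
#'
#' One row per comparison, mirroring the count/slope/test layout of the
#' study's comparison tables. Deterministic row order (input order).
#'
#' @param comparisons List of \code{panel_comparison}s.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_comparisons <- function(comparisons, path) {
  df <- do.call(rbind, lapply(comparisons, function(x) {
    data.frame(cs_panel = x$cs_label, ws_panel = x$ws_label,
               statistic = x$statistic, n_genes = x$n_genes,
               n_cs_gt_ws = x$n_cs_gt_ws, n_cs_eq_ws = x$n_cs_eq_ws,
               n_cs_lt_ws = x$n_cs_lt_ws, slope = x$slope,
               mean_diff = x$mean_diff, p_paired_t = x$p_paired_t,
               p_wilcoxon = x$p_wilcoxon, stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  write_tsv(df, path)
}

#' Write per-gene spread summaries as TSV
#'
#' @param summary A data frame from [gene_spread()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_spread_summary <- function(summary, path) {
  write_tsv(summary[order(summary$gene_id), , drop = FALSE], path)
}
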