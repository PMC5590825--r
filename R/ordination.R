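#' PCA of accessions on their e_T-ratio coordinates
#'
#' Treats each gene's e_T-ratio as one coordinate, so every accession is
#' a point in gene-dimensional space, and projects onto the first two
#' principal axes. Genes are the variables (centered; unscaled by
#' default, since ratios are already commensurate on [0,1]), accessions
#' the observations. Axis signs are canonicalised — the loading of
#' largest magnitude on each axis is made positive — so output is
#' deterministic and invariant to gene order.
#'
#' @param ratios An \code{et_ratio_matrix} (NA-free by construction).
#' @param cs,ws \code{panel_definition}s, used to label accessions.
#' @param scale. Scale genes to unit variance before the rotation
#'   (default \code{FALSE}).
#' @return An \code{accession_pca}: \code{coordinates} (data frame:
#'   accession_id, compartment, axis1, axis2),
#'   \code{variance_explained} (fractions for axes 1 and 2), and the
#'   full eigenvalue spectrum \code{eigenvalues}.
#' @export
pca_accessions <- function(ratios, cs, ws, scale. = FALSE) {
  stopifnot(inherits(ratios, "et_ratio_matrix"))
  x <- t(ratios$values)  # accessions x genes
  if (nrow(x) < 3L) stop("fewer than 3 accessions", call. = FALSE)
  gene_var <- apply(x, 2L, stats::var)
  if (all(gene_var == 0)) {
    stop("degenerate ratio matrix: all genes constant across accessions",
         call. = FALSE)
  }
  if (scale.) {
    x <- x[, gene_var > 0, drop = FALSE]
  }
  p <- stats::prcomp(x, center = TRUE, scale. = scale.)
  ev <- p$sdev^2
  if (sum(ev > 1e-12 * ev[1L]) < 2L) {
    stop("degenerate ratio matrix: fewer than 2 non-degenerate dimensions",
         call. = FALSE)
  }
  scores <- p$x[, 1:2, drop = FALSE]
  for (j in 1:2) {  # sign canonicalisation
    load <- p$rotation[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  compartment <- ifelse(rownames(scores) %in% cs$accessions, "CS",
                        ifelse(rownames(scores) %in% ws$accessions, "WS", NA))
  structure(list(
    coordinates = data.frame(accession_id = rownames(scores),
                             compartment = compartment,
                             axis1 = unname(scores[, 1L]),
                             axis2 = unname(scores[, 2L]),
                             stringsAsFactors = FALSE),
    variance_explained = ev[1:2] / sum(ev),
    eigenvalues = ev),
    class = "accession_pca")
}

#' @export
print.accession_pca <- function(x, ...) {
  cat("PCA of accessions on e_T-ratio coordinates\n")
  cat(sprintf("  variance explained: axis1 %.1f%%, axis2 %.1f%% (total %.1f%%)\n",
              100 * x$variance_explained[1L], 100 * x$variance_explained[2L],
              100 * sum(x$variance_explained)))
  print(x$coordinates, ...)
  invisible(x)
}

#' Scatter plot of accession PCA scores
#'
#' @param x An \code{accession_pca}.
#' @param ... Passed to \code{plot}.
#' @export
plot.accession_pca <- function(x, ...) {
  co <- x$coordinates
  col <- ifelse(co$compartment == "CS", "dodgerblue3", "darkorange2")
  plot(co$axis1, co$axis2, col = col, pch = 19,
       xlab = sprintf("Axis 1 (%.1f%%)", 100 * x$variance_explained[1L]),
       ylab = sprintf("Axis 2 (%.1f%%)", 100 * x$variance_explained[2L]),
       ...)
  graphics::text(co$axis1, co$axis2, co$accession_id, pos = 3, cex = 0.7)
  graphics::legend("topright", legend = c("cultivated", "wild"),
                   col = c("dodgerblue3", "darkorange2"), pch = 19, bty = "n")
  invisible(x)
}

#' Mean pairwise score distance within each compartment
#'
#' Compactness summary of the 2D projection: average Euclidean distance
#' between pairs of accessions of the same compartment.
#'
#' @param pca An \code{accession_pca}.
#' @return Named numeric vector \code{c(CS = ..., WS = ...)}.
#' @export
compartment_compactness <- function(pca) {
  co <- pca$coordinates
  mean_pairdist <- function(sub) {
    if (nrow(sub) < 2L) return(NA_real_)
    mean(stats::dist(as.matrix(sub[, c("axis1", "axis2")])))
  }
  c(CS = mean_pairdist(co[co$compartment == "CS", , drop = FALSE]),
    WS = mean_pairdist(co[co$compartment == "WS", , drop = FALSE]))
}
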