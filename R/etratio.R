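#' Mask unreliably-estimated expression cells
#'
#' When the mean mapped read depth of a gene is below \code{min_coverage}
#' for an accession, the FPKM estimates of both isoforms in that
#' (gene, accession) cell are considered unreliable and replaced by
#' \code{NA}. A coverage exactly equal to the threshold is retained
#' (the rule is strictly "smaller than").
#'
#' @param table An \code{isoform_expression_table}.
#' @param min_coverage Coverage threshold (default 5, in mean mapped
#'   reads over the gene). Must be >= 0.
#' @return The table with masked \code{fpkm} cells.
#' @export
apply_coverage_mask <- function(table, min_coverage = 5) {
  stopifnot(inherits(table, "isoform_expression_table"))
  if (!is.numeric(min_coverage) || length(min_coverage) != 1L ||
      min_coverage < 0) {
    stop("min_coverage must be a single non-negative number", call. = FALSE)
  }
  table$fpkm[table$gene_coverage < min_coverage] <- NA_real_
  table
}

#' Select genes eligible for e_T-ratio analysis
#'
#' Applies the three gene filters, on a masked table, for one
#' cultivated-vs-wild comparison:
#' \enumerate{
#'   \item the gene expresses exactly two isoforms (two distinct
#'     \code{isoform_id}s anywhere in the table);
#'   \item no masked (\code{NA}) cell for any accession of either panel
#'     — i.e. coverage at least the threshold everywhere;
#'   \item each of the two isoforms has \code{fpkm > 0} in at least one
#'     accession of the cultivated panel AND at least one accession of
#'     the wild panel.
#' }
#' "Expressed" means strictly positive FPKM.
#'
#' @param table A masked \code{isoform_expression_table} (see
#'   [apply_coverage_mask()]).
#' @param cs,ws \code{panel_definition}s for the cultivated and wild
#'   panels; every accession must be present in the table.
#' @return Character vector of retained gene ids, in table order.
#' @export
select_genes <- function(table, cs, ws) {
  stopifnot(inherits(table, "isoform_expression_table"),
            inherits(cs, "panel_definition"),
            inherits(ws, "panel_definition"))
  panel_acc <- c(cs$accessions, ws$accessions)
  absent <- setdiff(panel_acc, unique(table$accession_id))
  if (length(absent) > 0L) {
    stop("panel accession(s) absent from table: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  iso_per_gene <- tapply(table$isoform_id, table$gene_id,
                         function(x) length(unique(x)))
  two_iso <- names(iso_per_gene)[iso_per_gene == 2L]

  sub <- table[table$accession_id %in% panel_acc &
                 table$gene_id %in% two_iso, , drop = FALSE]
  # (ii) no NA cell over the union panel
  has_na <- tapply(sub$fpkm, sub$gene_id, anyNA)
  # (iii) each isoform expressed (> 0) in >= 1 accession of each panel
  in_cs <- sub$accession_id %in% cs$accessions
  expressed_ok <- vapply(split(seq_len(nrow(sub)), sub$gene_id), function(ix) {
    iso <- sub$isoform_id[ix]
    pos <- !is.na(sub$fpkm[ix]) & sub$fpkm[ix] > 0
    all(vapply(unique(iso), function(i) {
      sel <- iso == i
      any(pos[sel] & in_cs[ix][sel]) && any(pos[sel] & !in_cs[ix][sel])
    }, logical(1)))
  }, logical(1))

  keep <- names(has_na)[!has_na & expressed_ok[names(has_na)]]
  genes_in_order <- unique(table$gene_id)
  genes_in_order[genes_in_order %in% keep]
}

#' Compute the e_T-ratio matrix
#'
#' For each selected gene and each accession of the union panel, the raw
#' ratio is \eqn{r_a = FPKM(iso_1) / (FPKM(iso_1) + FPKM(iso_2))}. The
#' numerator isoform of a gene is the one whose arithmetic mean ratio
#' over all accessions of the union panel is >= 0.5 (ties broken towards
#' the lexicographically smaller \code{isoform_id}), so stored values
#' concentrate in [0.5, 1]. Using the other isoform would give exactly
#' \code{1 - value} in every cell.
#'
#' Cells with zero total expression despite adequate coverage make the
#' ratio undefined; such genes are dropped from the matrix, counted, and
#' reported via the \code{rejected_zero_total} element (and a message).
#'
#' @param table A masked \code{isoform_expression_table}.
#' @param genes Genes that passed [select_genes()].
#' @param cs,ws The panels used for selection.
#' @return An \code{et_ratio_matrix}: list with \code{values} (gene x
#'   accession matrix in [0,1]), \code{genes}, \code{accessions} (cs
#'   then ws, in panel order), \code{numerator_isoform} (named by gene),
#'   \code{cs_accessions}, \code{ws_accessions},
#'   \code{rejected_zero_total} (character vector of dropped genes).
#' @export
compute_et_ratios <- function(table, genes, cs, ws) {
  stopifnot(inherits(table, "isoform_expression_table"))
  accs <- c(cs$accessions, ws$accessions)
  sub <- table[table$gene_id %in% genes & table$accession_id %in% accs, ,
               drop = FALSE]

  n <- length(genes)
  na <- length(accs)
  gene_ix <- match(sub$gene_id, genes)
  acc_ix <- match(sub$accession_id, accs)
  # lexicographically first isoform per gene fills matrix 1, second matrix 2
  iso1 <- tapply(sub$isoform_id, factor(sub$gene_id, levels = genes), min)
  iso2 <- tapply(sub$isoform_id, factor(sub$gene_id, levels = genes), max)
  is_first <- sub$isoform_id == iso1[gene_ix]
  f1 <- f2 <- matrix(NA_real_, n, na, dimnames = list(genes, accs))
  f1[cbind(gene_ix[is_first], acc_ix[is_first])] <- sub$fpkm[is_first]
  f2[cbind(gene_ix[!is_first], acc_ix[!is_first])] <- sub$fpkm[!is_first]

  tot <- f1 + f2
  zero_total <- rowSums(tot == 0, na.rm = TRUE) > 0L
  rejected <- genes[zero_total]
  r <- f1 / tot
  # numerator convention: isoform with mean ratio >= 0.5 over the union;
  # at exactly 0.5 the lexicographically smaller isoform (iso1) wins
  flip <- rowMeans(r) < 0.5
  flip[is.na(flip)] <- FALSE
  values <- r
  values[flip, ] <- 1 - r[flip, , drop = FALSE]
  numerator <- as.character(ifelse(flip, iso2, iso1))
  names(numerator) <- genes
  if (length(rejected) > 0L) {
    message(length(rejected),
            " gene(s) rejected: zero total expression despite adequate coverage")
  }
  keep <- setdiff(genes, rejected)
  structure(list(values = values[keep, , drop = FALSE],
                 genes = keep, accessions = accs,
                 numerator_isoform = numerator[keep],
                 cs_accessions = cs$accessions,
                 ws_accessions = ws$accessions,
                 rejected_zero_total = rejected),
            class = "et_ratio_matrix")
}

#' @export
print.et_ratio_matrix <- function(x, ...) {
  cat("e_T-ratio matrix:", length(x$genes), "genes x",
      length(x$accessions), "accessions\n")
  cat("  cultivated:", paste(x$cs_accessions, collapse = ", "), "\n")
  cat("  wild:      ", paste(x$ws_accessions, collapse = ", "), "\n")
  if (length(x$rejected_zero_total) > 0L) {
    cat("  rejected (zero total expression):",
        length(x$rejected_zero_total), "\n")
  }
  cat("  mean e_T-ratio:", format(mean(x$values), digits = 4), "\n")
  invisible(x)
}

#' Run the masking, filtering and ratio pipeline in one call
#'
#' Convenience wrapper: [apply_coverage_mask()], [select_genes()],
#' [compute_et_ratios()] for one comparison.
#'
#' @inheritParams select_genes
#' @inheritParams apply_coverage_mask
#' @return An \code{et_ratio_matrix}.
#' @export
et_ratio_pipeline <- function(table, cs, ws, min_coverage = 5) {
  masked <- apply_coverage_mask(table, min_coverage)
  genes <- select_genes(masked, cs, ws)
  compute_et_ratios(masked, genes, cs, ws)
}

#' Write an e_T-ratio matrix as TSV
#'
#' Genes x accessions, plus a \code{numerator_isoform} column; rows
#' sorted by gene id. Deterministic output.
#'
#' @param ratios An \code{et_ratio_matrix}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_ratio_matrix <- function(ratios, path) {
  stopifnot(inherits(ratios, "et_ratio_matrix"))
  ord <- order(ratios$genes)
  df <- data.frame(gene_id = ratios$genes[ord],
                   numerator_isoform = unname(ratios$numerator_isoform[ord]),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(ratios$values[ord, , drop = FALSE]))
  write_tsv(df, path)
}
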