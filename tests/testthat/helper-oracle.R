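# Independent straight-line reference implementation of the masking,
# filtering and ratio pipeline: explicit per-cell loops, no vectorisation,
# no shared code with the package internals.
oracle_pipeline <- function(df, cs_acc, ws_acc, min_coverage = 5) {
  df <- as.data.frame(df)
  panel <- c(cs_acc, ws_acc)

  # coverage mask
  for (i in seq_len(nrow(df))) {
    if (df$gene_coverage[i] < min_coverage) df$fpkm[i] <- NA_real_
  }

  genes_all <- unique(df$gene_id)
  selected <- character(0)
  for (g in genes_all) {
    rows <- df[df$gene_id == g, ]
    isos <- sort(unique(rows$isoform_id))
    if (length(isos) != 2L) next
    ok <- TRUE
    for (a in panel) {
      for (iso in isos) {
        v <- rows$fpkm[rows$isoform_id == iso & rows$accession_id == a]
        if (length(v) != 1L || is.na(v)) ok <- FALSE
      }
    }
    if (!ok) next
    for (iso in isos) {
      pos_cs <- FALSE; pos_ws <- FALSE
      for (a in cs_acc) {
        v <- rows$fpkm[rows$isoform_id == iso & rows$accession_id == a]
        if (length(v) == 1L && !is.na(v) && v > 0) pos_cs <- TRUE
      }
      for (a in ws_acc) {
        v <- rows$fpkm[rows$isoform_id == iso & rows$accession_id == a]
        if (length(v) == 1L && !is.na(v) && v > 0) pos_ws <- TRUE
      }
      if (!pos_cs || !pos_ws) ok <- FALSE
    }
    if (ok) selected <- c(selected, g)
  }

  values <- matrix(NA_real_, length(selected), length(panel),
                   dimnames = list(selected, panel))
  numerator <- character(0)
  rejected <- character(0)
  for (g in selected) {
    rows <- df[df$gene_id == g, ]
    isos <- sort(unique(rows$isoform_id))
    r <- numeric(length(panel))
    bad <- FALSE
    for (j in seq_along(panel)) {
      a <- panel[j]
      f1 <- rows$fpkm[rows$isoform_id == isos[1L] & rows$accession_id == a]
      f2 <- rows$fpkm[rows$isoform_id == isos[2L] & rows$accession_id == a]
      if (f1 + f2 == 0) bad <- TRUE else r[j] <- f1 / (f1 + f2)
    }
    if (bad) { rejected <- c(rejected, g); next }
    if (mean(r) >= 0.5) {
      values[g, ] <- r
      numerator[g] <- isos[1L]
    } else {
      values[g, ] <- 1 - r
      numerator[g] <- isos[2L]
    }
  }
  keep <- setdiff(selected, rejected)
  list(selected = selected, genes = keep,
       values = values[keep, , drop = FALSE],
       numerator = numerator[keep], rejected = rejected)
}

# messy random table: mixes 1/2/3-isoform genes, low-coverage cells,
# zero-FPKM cells, a chance of all-zero totals
random_messy_table <- function(n_genes, n_cs = 3L, n_ws = 2L) {
  cs_acc <- paste0("c", seq_len(n_cs))
  ws_acc <- paste0("w", seq_len(n_ws))
  accs <- c(cs_acc, ws_acc)
  rows <- list()
  for (gi in seq_len(n_genes)) {
    g <- sprintf("g%03d", gi)
    n_iso <- sample(1:3, 1L, prob = c(0.15, 0.7, 0.15))
    isos <- paste0(g, ".", seq_len(n_iso))
    for (a in accs) {
      cov <- round(stats::runif(1, 0, 15), 2)
      fpkm <- round(stats::rexp(n_iso, 1 / 5), 3)
      fpkm[stats::runif(n_iso) < 0.15] <- 0
      for (k in seq_len(n_iso)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = g, isoform_id = isos[k], accession_id = a,
          fpkm = fpkm[k], gene_coverage = cov, stringsAsFactors = FALSE)
      }
    }
  }
  list(table = expression_table(do.call(rbind, rows)),
       cs = panel_definition("cs", "CS", cs_acc),
       ws = panel_definition("ws", "WS", ws_acc))
}

# tiny valid 2-isoform table builder for targeted cases:
# fpkm1/fpkm2/coverage are gene x accession matrices
make_table <- function(genes, accs, fpkm1, fpkm2, coverage) {
  rows <- list()
  for (i in seq_along(genes)) {
    for (j in seq_along(accs)) {
      for (k in 1:2) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = genes[i], isoform_id = paste0(genes[i], ".t", k),
          accession_id = accs[j],
          fpkm = if (k == 1L) fpkm1[i, j] else fpkm2[i, j],
          gene_coverage = coverage[i, j], stringsAsFactors = FALSE)
      }
    }
  }
  expression_table(do.call(rbind, rows))
}
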