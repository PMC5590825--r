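#' Bundle one gene's canonical/alternative isoform sequences
#'
#' @param gene_id Gene identifier.
#' @param canonical_protein Canonical protein sequence (>= 1 aa).
#' @param canonical_cds_prefix First nucleotides (typically 30) of the
#'   canonical CDS, used to anchor the start codon in the alternative
#'   mRNA.
#' @param alternative_mrna Alternative transcript sequence (optional).
#' @param alternative_protein Alternative protein, if already predicted
#'   (optional). At least one of the two alternative inputs is required.
#' @return An \code{isoform_pair}.
#' @export
isoform_pair <- function(gene_id, canonical_protein, canonical_cds_prefix,
                         alternative_mrna = NULL, alternative_protein = NULL) {
  if (is.null(alternative_mrna) && is.null(alternative_protein)) {
    stop("gene '", gene_id,
         "': need alternative_mrna and/or alternative_protein", call. = FALSE)
  }
  canonical_protein <- toupper(canonical_protein)
  if (nchar(canonical_protein) < 1L) {
    stop("gene '", gene_id, "': empty canonical protein", call. = FALSE)
  }
  structure(list(gene_id = as.character(gene_id),
                 canonical_protein = canonical_protein,
                 canonical_cds_prefix = toupper(canonical_cds_prefix),
                 alternative_mrna = if (is.null(alternative_mrna)) NULL
                                    else toupper(alternative_mrna),
                 alternative_protein = if (is.null(alternative_protein)) NULL
                                       else toupper(alternative_protein)),
            class = "isoform_pair")
}

#' Predict the alternative isoform's protein from its mRNA
#'
#' Anchors translation by locating the canonical CDS prefix in the
#' alternative mRNA — an exact substring match of the full prefix, or,
#' failing that, of the longest exact prefix of at least 12 nt. If no
#' anchor is found the canonical start context is absent from the
#' alternative transcript and \code{start_not_found} is returned (no
#' translation is attempted). Otherwise translation proceeds from the
#' anchor with the standard genetic code until the first stop codon or
#' the end of the sequence (trailing partial codons dropped).
#'
#' @param pair An \code{isoform_pair} with \code{alternative_mrna}.
#' @param min_anchor Minimum prefix length for the fallback match
#'   (default 12 nt).
#' @return List: \code{status} (\code{"ok"} or
#'   \code{"start_not_found"}) and \code{protein} (\code{NA} when not
#'   found).
#' @export
translate_alternative <- function(pair, min_anchor = 12L) {
  stopifnot(inherits(pair, "isoform_pair"))
  if (is.null(pair$alternative_mrna)) {
    stop("gene '", pair$gene_id, "': no alternative mRNA", call. = FALSE)
  }
  mrna <- chartr("U", "T", pair$alternative_mrna)
  if (grepl("[^ACGTMRWSYKVHDBN-]", mrna)) {
    stop("gene '", pair$gene_id,
         "': non-nucleotide characters in alternative mRNA", call. = FALSE)
  }
  prefix <- chartr("U", "T", pair$canonical_cds_prefix)
  pos <- -1L
  for (len in seq(nchar(prefix), min_anchor)) {
    pos <- regexpr(substr(prefix, 1L, len), mrna, fixed = TRUE)[1L]
    if (pos > 0L) break
  }
  if (pos < 0L) {
    return(list(status = "start_not_found", protein = NA_character_))
  }
  cds <- substr(mrna, pos, nchar(mrna))
  n_codons <- nchar(cds) %/% 3L
  codons <- substring(cds, 3L * seq_len(n_codons) - 2L, 3L * seq_len(n_codons))
  aas <- Biostrings::GENETIC_CODE[codons]
  aas[is.na(aas)] <- "X"  # ambiguous codons
  stop_at <- which(aas == "*")
  if (length(stop_at) > 0L) aas <- aas[seq_len(stop_at[1L] - 1L)]
  list(status = "ok", protein = paste(aas, collapse = ""))
}

# global alignment statistics under the fixed scoring scheme
# (match +1, mismatch 0, gap open 5, gap extend 1); fractions are
# relative to the canonical protein length
alignment_stats <- function(alternative, canonical) {
  alpha <- sort(unique(c(strsplit(alternative, "")[[1]],
                         strsplit(canonical, "")[[1]], "X")))
  submat <- diag(1, length(alpha))
  dimnames(submat) <- list(alpha, alpha)
  aln <- Biostrings::pairwiseAlignment(
    pattern = alternative, subject = canonical, type = "global",
    substitutionMatrix = submat, gapOpening = 5, gapExtension = 1)
  ap <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  asb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  is_match <- ap == asb & ap != "-"
  runs <- rle(is_match)
  longest_block <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  L <- nchar(canonical)
  list(identity_fraction = sum(is_match) / L,
       indel_fraction = (sum(ap == "-") + sum(asb == "-")) / L,
       aligned_length = length(ap),
       longest_identical_block = longest_block)
}

#' Classify the functional impact of an alternative isoform
#'
#' Four-category decision cascade, first match wins:
#' \enumerate{
#'   \item \strong{start lost} — the canonical start context is not
#'     found in the alternative mRNA (no protein predicted);
#'   \item \strong{early stop} — the predicted alternative protein
#'     terminates before 20\% of the canonical protein length
#'     (strictly \code{< 0.2});
#'   \item (checked after the category-4 test) \strong{slightly
#'     different} — any of: indels affecting < 10\% of canonical
#'     residues; identity > 50\% with equivalent length (length ratio
#'     within [0.9, 1.1]); or an exactly identical contiguous block of
#'     >= 500 aa;
#'   \item \strong{identical} — alternative protein exactly equals the
#'     canonical one (the event is confined to untranslated regions).
#' }
#' Categories 1-2 roll up to \emph{deleterious}, 3-4 to
#' \emph{functional}. A protein matching no rule is reported category 2
#' with reason \code{major_disruption} (the four categories are not
#' exhaustive for arbitrary sequences).
#'
#' Identity, indel fraction and the identical-block length come from
#' one fixed global alignment (match +1, mismatch 0, gap open -5, gap
#' extend -1), so calls are reproducible bit-for-bit.
#'
#' @param pair An \code{isoform_pair}.
#' @return An \code{as_impact_call}: one-row data frame with
#'   \code{gene_id}, \code{category} (1-4), \code{label},
#'   \code{rollup}, \code{reason}, and the evidence columns
#'   \code{identity_fraction}, \code{indel_fraction},
#'   \code{aligned_length}, \code{stop_position_fraction}.
#' @export
classify_as_impact <- function(pair) {
  stopifnot(inherits(pair, "isoform_pair"))
  canon <- pair$canonical_protein
  alt <- pair$alternative_protein
  if (is.null(alt)) {
    tr <- translate_alternative(pair)
    if (tr$status == "start_not_found") {
      return(impact_call(pair$gene_id, 1L, "start_lost", "start_not_found",
                         NA, NA, NA, NA))
    }
    alt <- tr$protein
  }
  L <- nchar(canon)
  stop_frac <- nchar(alt) / L
  if (stop_frac < 0.2) {
    return(impact_call(pair$gene_id, 2L, "early_stop", "early_stop",
                       NA, NA, NA, stop_frac))
  }
  if (alt == canon) {
    return(impact_call(pair$gene_id, 4L, "identical", "identical",
                       1, 0, L, stop_frac))
  }
  st <- alignment_stats(alt, canon)
  small_indel <- st$indel_fraction < 0.1
  equiv_len <- st$identity_fraction > 0.5 &&
    nchar(alt) / L >= 0.9 && nchar(alt) / L <= 1.1
  big_block <- st$longest_identical_block >= 500L
  if (small_indel || equiv_len || big_block) {
    reason <- if (small_indel) "small_indels"
              else if (equiv_len) "equivalent_length_identity"
              else "identical_block_500aa"
    return(impact_call(pair$gene_id, 3L, "slightly_different", reason,
                       st$identity_fraction, st$indel_fraction,
                       st$aligned_length, stop_frac))
  }
  impact_call(pair$gene_id, 2L, "early_stop", "major_disruption",
              st$identity_fraction, st$indel_fraction,
              st$aligned_length, stop_frac)
}

impact_call <- function(gene_id, category, label, reason,
                        identity, indel, aligned, stop_frac) {
  rollup <- if (category %in% c(1L, 2L)) "deleterious" else "functional"
  out <- data.frame(gene_id = gene_id, category = category, label = label,
                    rollup = rollup, reason = reason,
                    identity_fraction = as.numeric(identity),
                    indel_fraction = as.numeric(indel),
                    aligned_length = as.numeric(aligned),
                    stop_position_fraction = as.numeric(stop_frac),
                    stringsAsFactors = FALSE)
  class(out) <- c("as_impact_call", "data.frame")
  out
}

#' Classify a whole set of isoform pairs
#'
#' Vectorised driver over parallel named vectors (as produced by
#' [simulate_protein_pairs()] or assembled from FASTA files read with
#' [read_fasta()]).
#'
#' @param canonical_protein,canonical_cds_prefix Named character
#'   vectors, one entry per gene.
#' @param alternative_mrna,alternative_protein Named character vectors;
#'   \code{NA} where the input is not available for a gene. Every gene
#'   needs at least one of the two.
#' @return An \code{as_impact_call} data frame, one row per gene.
#' @export
classify_pairs <- function(canonical_protein, canonical_cds_prefix,
                           alternative_mrna = NULL,
                           alternative_protein = NULL) {
  genes <- names(canonical_protein)
  rows <- lapply(genes, function(g) {
    mrna <- alternative_mrna[[g]]
    prot <- alternative_protein[[g]]
    classify_as_impact(isoform_pair(
      g, canonical_protein[[g]], canonical_cds_prefix[[g]],
      alternative_mrna = if (is.null(mrna) || is.na(mrna)) NULL else mrna,
      alternative_protein = if (is.null(prot) || is.na(prot)) NULL else prot))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("as_impact_call", "data.frame")
  out
}

#' Cross-tabulate impact categories by contrast direction
#'
#' The functional-impact rollup table: for genes flagged by a contrast
#' filter, counts per direction (larger spread in CS vs in WS) of
#' identical (category 4), potentially functional (category 3),
#' non-functional protein (category 2), and no protein identified
#' (category 1), with functional/deleterious totals and row
#' percentages.
#'
#' @param calls An \code{as_impact_call} data frame.
#' @param contrast_calls A \code{contrast_calls} data frame; genes
#'   without an impact call are ignored.
#' @return An \code{impact_table}: list with \code{counts} and
#'   \code{percent} matrices (rows = directions, columns = impact
#'   classes and totals).
#' @export
impact_table <- function(calls, contrast_calls) {
  cols <- c("identical", "potentially_functional", "total_functional",
            "non_functional", "no_protein", "total_deleterious")
  dirs <- c("higher_in_CS", "higher_in_WS")
  counts <- matrix(0L, length(dirs), length(cols),
                   dimnames = list(dirs, cols))
  if (nrow(contrast_calls) > 0L) {
    m <- merge(as.data.frame(contrast_calls)[c("gene_id", "direction")],
               as.data.frame(calls)[c("gene_id", "category")],
               by = "gene_id")
    for (d in dirs) {
      cat_d <- m$category[m$direction == d]
      counts[d, "identical"] <- sum(cat_d == 4L)
      counts[d, "potentially_functional"] <- sum(cat_d == 3L)
      counts[d, "non_functional"] <- sum(cat_d == 2L)
      counts[d, "no_protein"] <- sum(cat_d == 1L)
    }
    counts[, "total_functional"] <-
      counts[, "identical"] + counts[, "potentially_functional"]
    counts[, "total_deleterious"] <-
      counts[, "non_functional"] + counts[, "no_protein"]
  }
  n_row <- counts[, "total_functional"] + counts[, "total_deleterious"]
  percent <- 100 * counts / ifelse(n_row == 0, NA, n_row)
  structure(list(counts = counts, percent = percent), class = "impact_table")
}

#' @export
print.impact_table <- function(x, ...) {
  cat("Functional impact of alternative isoforms, by contrast direction\n")
  print(x$counts)
  cat("row percentages:\n")
  print(round(x$percent, 1))
  invisible(x)
}

#' Write impact calls as TSV
#'
#' @param calls An \code{as_impact_call} data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_impact_calls <- function(calls, path) {
  write_tsv(as.data.frame(calls)[order(calls$gene_id), , drop = FALSE], path)
}
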