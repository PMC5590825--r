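#' Read a per-accession isoform expression table
#'
#' Reads the canonical tab-separated expression table: one row per
#' (gene, isoform, accession) with the FPKM estimate and the per-gene
#' mean mapped read depth (\code{gene_coverage}) for that accession.
#' The file must carry a header with columns \code{gene_id},
#' \code{isoform_id}, \code{accession_id}, \code{fpkm},
#' \code{gene_coverage} (extra columns are ignored). \code{fpkm} may be
#' \code{NA} (a masked cell); \code{gene_coverage} may not.
#'
#' Validation enforced on read: unique (gene, isoform, accession)
#' triples, non-negative \code{fpkm} and \code{gene_coverage}, and a
#' single \code{gene_coverage} value per (gene, accession) across
#' isoforms. Violations raise an error naming the offending file line.
#'
#' @param path Path to a tab-separated file with header.
#' @return An \code{isoform_expression_table}: a data frame with the five
#'   canonical columns, in file order.
#' @seealso [write_expression_table()], [expression_table()]
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = NA, stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = "NA")
  expression_table(df, .source = path)
}

#' Construct and validate an isoform expression table
#'
#' In-memory constructor for the container [read_expression_table()]
#' returns; applies the same validation.
#'
#' @param df Data frame with columns \code{gene_id}, \code{isoform_id},
#'   \code{accession_id}, \code{fpkm}, \code{gene_coverage}.
#' @param .source Optional file path, used only in error messages.
#' @return An \code{isoform_expression_table}.
#' @export
expression_table <- function(df, .source = NULL) {
  required <- c("gene_id", "isoform_id", "accession_id", "fpkm", "gene_coverage")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("expression table", src_tag(.source), ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[required]
  df$gene_id <- as.character(df$gene_id)
  df$isoform_id <- as.character(df$isoform_id)
  df$accession_id <- as.character(df$accession_id)
  df$fpkm <- as.numeric(df$fpkm)
  df$gene_coverage <- as.numeric(df$gene_coverage)

  # data row i sits on file line i + 1 (header)
  bad <- which(!is.na(df$fpkm) & df$fpkm < 0)
  if (length(bad) > 0L) {
    stop("expression table", src_tag(.source), ": negative fpkm at line ",
         bad[1L] + 1L, call. = FALSE)
  }
  bad <- which(is.na(df$gene_coverage) | df$gene_coverage < 0)
  if (length(bad) > 0L) {
    stop("expression table", src_tag(.source),
         ": missing or negative gene_coverage at line ", bad[1L] + 1L,
         call. = FALSE)
  }
  key <- paste(df$gene_id, df$isoform_id, df$accession_id, sep = "\r")
  bad <- which(duplicated(key))
  if (length(bad) > 0L) {
    stop("expression table", src_tag(.source),
         ": duplicate (gene, isoform, accession) triple at line ",
         bad[1L] + 1L, call. = FALSE)
  }
  ga <- paste(df$gene_id, df$accession_id, sep = "\r")
  cov_by_ga <- tapply(df$gene_coverage, ga, function(x) max(x) - min(x))
  if (any(cov_by_ga > 0)) {
    offender <- names(cov_by_ga)[which(cov_by_ga > 0)[1L]]
    bad <- which(ga == offender)
    stop("expression table", src_tag(.source),
         ": inconsistent gene_coverage within (gene, accession) at line ",
         bad[2L] + 1L, call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("isoform_expression_table", "data.frame")
  df
}

src_tag <- function(src) if (is.null(src)) "" else paste0(" '", src, "'")

#' Write an isoform expression table
#'
#' Deterministic writer: rows sorted by gene, isoform, accession; masked
#' FPKM cells written as the reserved string \code{NA}; UTF-8, tab
#' separated. \code{read_expression_table(write_expression_table(x))}
#' is the identity up to row order.
#'
#' @param table An \code{isoform_expression_table}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_expression_table <- function(table, path) {
  stopifnot(inherits(table, "isoform_expression_table"))
  ord <- order(table$gene_id, table$isoform_id, table$accession_id)
  write_tsv(as.data.frame(table)[ord, , drop = FALSE], path)
}

# shared deterministic TSV writer (UTF-8, "NA" for missing, no quoting)
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(paste(names(df), collapse = "\t"),
             do.call(paste, c(lapply(df, format_tsv_col), sep = "\t")))
  writeLines(lines, con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

format_tsv_col <- function(x) {
  if (is.numeric(x)) {
    out <- vapply(x, function(v) {
      if (is.na(v)) "NA" else format(v, digits = 15, scientific = FALSE, trim = TRUE)
    }, character(1))
  } else {
    out <- as.character(x)
    out[is.na(out)] <- "NA"
  }
  out
}

#' Define a population panel
#'
#' A panel names the accessions making up one population sample and the
#' compartment it belongs to: \code{CS} (cultivated) or \code{WS} (wild).
#'
#' @param label Panel label, e.g. \code{"popCS_10"}.
#' @param compartment \code{"CS"} or \code{"WS"}.
#' @param accessions Character vector of accession ids, no duplicates.
#' @return A \code{panel_definition}.
#' @export
panel_definition <- function(label, compartment, accessions) {
  compartment <- match.arg(compartment, c("CS", "WS"))
  accessions <- as.character(accessions)
  if (length(accessions) == 0L) stop("panel '", label, "': no accessions", call. = FALSE)
  if (anyDuplicated(accessions)) {
    stop("panel '", label, "': duplicate accession '",
         accessions[duplicated(accessions)][1L], "'", call. = FALSE)
  }
  structure(list(label = as.character(label), compartment = compartment,
                 accessions = accessions),
            class = "panel_definition")
}

#' @export
print.panel_definition <- function(x, ...) {
  cat("Panel", x$label, sprintf("(%s, %d accessions):", x$compartment,
                                length(x$accessions)), "\n ",
      paste(x$accessions, collapse = ", "), "\n")
  invisible(x)
}

#' Read a panel definition file
#'
#' Plain-text format: first two lines \code{#label=<label>} and
#' \code{#compartment=CS|WS}, then one accession id per line, kept in
#' file order. Blank lines are ignored.
#'
#' @param path Path to the panel file.
#' @return A \code{panel_definition}.
#' @export
read_panel <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("panel file '", path, "' is empty", call. = FALSE)
  directives <- grep("^#", lines, value = TRUE)
  get_directive <- function(key) {
    hit <- grep(paste0("^#", key, "="), directives, value = TRUE)
    if (length(hit) != 1L) {
      stop("panel file '", path, "': expected exactly one #", key, "= line",
           call. = FALSE)
    }
    sub(paste0("^#", key, "="), "", hit)
  }
  label <- get_directive("label")
  compartment <- get_directive("compartment")
  accessions <- lines[!grepl("^#", lines)]
  if (length(accessions) == 0L) {
    stop("panel file '", path, "': no accessions listed", call. = FALSE)
  }
  panel_definition(label, compartment, accessions)
}

#' Write a panel definition file
#'
#' @param panel A \code{panel_definition}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "panel_definition"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste0("#label=", panel$label),
               paste0("#compartment=", panel$compartment),
               panel$accessions),
             con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a gene-to-GO mapping
#'
#' Two-column tab-separated file: gene id, GO term id, one pair per
#' line. No header is required; a \code{gene_id<TAB>go_id} header line
#' is tolerated and skipped. Genes may be absent (unannotated); an
#' empty file yields an empty map.
#'
#' @param path Path to the mapping file.
#' @return A named list mapping \code{gene_id} to a character vector of
#'   GO term ids (class \code{go_map}).
#' @export
read_go_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) > 0L && grepl("^gene_id\t", lines[1L])) lines <- lines[-1L]
  if (length(lines) == 0L) return(go_map(list()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2L)) {
    stop("GO map '", path, "': expected two tab-separated columns at line ",
         which(nf != 2L)[1L], call. = FALSE)
  }
  genes <- vapply(parts, `[`, character(1), 1L)
  terms <- vapply(parts, `[`, character(1), 2L)
  go_map(lapply(split(terms, genes), unique))
}

#' Construct a gene-to-GO map
#'
#' @param entries Named list: gene id to character vector of GO terms.
#' @return A \code{go_map}.
#' @export
go_map <- function(entries) {
  if (length(entries) > 0L) {
    if (is.null(names(entries)) || any(!nzchar(names(entries)))) {
      stop("go_map entries must be named by gene_id", call. = FALSE)
    }
    if (any(lengths(entries) == 0L)) {
      stop("go_map: annotated genes must carry at least one term", call. = FALSE)
    }
    entries <- lapply(entries, function(x) unique(as.character(x)))
  }
  structure(entries, class = "go_map")
}

#' Write a gene-to-GO mapping
#'
#' Deterministic: rows sorted by gene id then term id, one pair per
#' line, no header.
#'
#' @param go A \code{go_map}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_go_map <- function(go, path) {
  stopifnot(inherits(go, "go_map"))
  genes <- rep(names(go), lengths(go))
  terms <- unlist(go, use.names = FALSE)
  ord <- order(genes, terms)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(genes[ord], terms[ord], sep = "\t"),
             con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

IUPAC_AA <- strsplit("ACDEFGHIKLMNPQRSTVWYBXZJUO*-", "")[[1]]
IUPAC_NT <- strsplit("ACGTUMRWSYKVHDBN-", "")[[1]]

#' Read sequences from FASTA
#'
#' Thin wrapper over \code{Biostrings::readBStringSet} returning a plain
#' named character vector, with an alphabet check: sequences must be
#' over the IUPAC amino-acid or nucleotide alphabet, per
#' \code{alphabet}.
#'
#' @param path Path to a FASTA file.
#' @param alphabet \code{"aa"} or \code{"nt"}.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path, alphabet = c("aa", "nt")) {
  alphabet <- match.arg(alphabet)
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  allowed <- if (alphabet == "aa") IUPAC_AA else IUPAC_NT
  for (i in seq_along(seqs)) {
    chars <- unique(strsplit(seqs[[i]], "")[[1]])
    bad <- setdiff(chars, allowed)
    if (length(bad) > 0L) {
      stop("FASTA '", path, "': record '", names(seqs)[i],
           "' contains non-IUPAC character(s) ", paste(bad, collapse = ""),
           call. = FALSE)
    }
  }
  seqs
}

#' Write sequences to FASTA
#'
#' Deterministic: records sorted by id. 60-column wrapping.
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  seqs <- seqs[order(names(seqs))]
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
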