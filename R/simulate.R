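#' Configure a synthetic two-isoform splicing study
#'
#' Defines the generative model for a complete synthetic study: for each
#' gene g a mean majority-isoform ratio \eqn{\mu_g} is drawn uniformly on
#' \code{ratio_mean_range}; per accession in compartment P the realised
#' ratio is \eqn{r \sim Beta(\mu_{gP}\kappa_P, (1-\mu_{gP})\kappa_P)}, so
#' the concentration \eqn{\kappa_P} sets the within-population dispersion
#' of the expression balance. A fraction \code{frac_median_shift} of
#' genes carries a planted between-compartment location shift:
#' \eqn{\mu_{g,WS} = \mu_g - } \code{shift_size}. Per-accession total
#' gene expression is log-normal; the two isoform FPKMs are \eqn{rT} and
#' \eqn{(1-r)T}. Gene coverage follows
#' \code{coverage_slope * T + N(0, coverage_noise_sd)}, floored at 0,
#' and a fraction \code{frac_low_coverage} of (gene, accession) cells is
#' forced below the coverage threshold of 5 so the masking rule fires.
#'
#' Defaults mirror the study design the analysis assumes: 2,000
#' two-isoform genes, 10 cultivated and 6 wild accessions, dispersion
#' markedly lower in the cultivated compartment
#' (\eqn{\kappa_{CS} = 200 > \kappa_{WS} = 20}), and masking/shift rates
#' such that the post-filter working set lands near 1,400 genes.
#'
#' @param n_genes Number of two-isoform genes.
#' @param n_cs,n_ws Accessions in the cultivated / wild compartment.
#' @param ratio_mean_range Range of the per-gene mean ratio \eqn{\mu_g}.
#' @param concentration_cs,concentration_ws Beta concentrations
#'   \eqn{\kappa_{CS}}, \eqn{\kappa_{WS}} (> 0; larger = tighter ratios).
#' @param total_meanlog,total_sdlog Log-normal parameters of per-gene
#'   per-accession total FPKM.
#' @param coverage_slope,coverage_noise_sd Linear coverage model
#'   coefficients (coverage in mean mapped reads).
#' @param frac_low_coverage Fraction of cells forced below coverage 5.
#' @param frac_median_shift Fraction of genes with a planted shift.
#' @param shift_size Planted shift \eqn{\delta} in mean ratio.
#' @param n_go_terms,genes_per_term GO universe size and genes annotated
#'   per background term.
#' @param p_in,p_out Annotation probability of the designated enriched
#'   term for shifted / non-shifted genes.
#' @param seed Integer seed; all randomness flows from it.
#' @return A validated \code{simulation_config} list.
#' @export
simulation_config <- function(n_genes = 2000L, n_cs = 10L, n_ws = 6L,
                              ratio_mean_range = c(0.5, 0.98),
                              concentration_cs = 200, concentration_ws = 20,
                              total_meanlog = 4, total_sdlog = 1,
                              coverage_slope = 1.5, coverage_noise_sd = 2,
                              frac_low_coverage = 0.02,
                              frac_median_shift = 0.02, shift_size = 0.3,
                              n_go_terms = 50L, genes_per_term = 40L,
                              p_in = 0.5, p_out = 0.04,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_cs = as.integer(n_cs),
              n_ws = as.integer(n_ws),
              ratio_mean_range = as.numeric(ratio_mean_range),
              concentration_cs = concentration_cs,
              concentration_ws = concentration_ws,
              total_meanlog = total_meanlog, total_sdlog = total_sdlog,
              coverage_slope = coverage_slope,
              coverage_noise_sd = coverage_noise_sd,
              frac_low_coverage = frac_low_coverage,
              frac_median_shift = frac_median_shift,
              shift_size = shift_size,
              n_go_terms = as.integer(n_go_terms),
              genes_per_term = as.integer(genes_per_term),
              p_in = p_in, p_out = p_out, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_genes >= 1L, n_cs >= 1L, n_ws >= 1L,
              concentration_cs > 0, concentration_ws > 0,
              length(ratio_mean_range) == 2L,
              ratio_mean_range[1] >= 0.5, ratio_mean_range[2] <= 1,
              ratio_mean_range[1] <= ratio_mean_range[2],
              frac_low_coverage >= 0, frac_low_coverage <= 1,
              frac_median_shift >= 0, frac_median_shift <= 1,
              shift_size >= 0, shift_size < ratio_mean_range[1],
              coverage_slope >= 0, coverage_noise_sd >= 0,
              n_go_terms >= 1L, genes_per_term >= 1L,
              p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1)
  })
  structure(cfg, class = "simulation_config")
}

# deterministic sub-stream seeds per purpose, all < 2^31
substream_seed <- function(seed, purpose) {
  offset <- c(expression = 11L, go = 23L, protein = 37L)[[purpose]]
  (as.integer(seed) %% 1000003L) * 1000L + offset
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a complete expression study
#'
#' Draws the full synthetic study defined by a [simulation_config()]:
#' the long-form expression table (every (gene, isoform, accession)
#' combination present), the two panels, and the ground truth (per-gene
#' compartment means, shifted flags, and the per-cell ratios actually
#' drawn). Byte-identical output for identical config.
#'
#' @param config A \code{simulation_config}.
#' @return A list with elements \code{table}
#'   (\code{isoform_expression_table}), \code{cs_panel}, \code{ws_panel}
#'   (\code{panel_definition}), and \code{truth} — a list with
#'   \code{genes} (data frame: gene_id, mu, mu_cs, mu_ws, shifted),
#'   \code{ratio} (gene x accession matrix of drawn ratios),
#'   \code{coverage} (matching matrix), and \code{forced_low} (logical
#'   matrix of cells forced under the coverage threshold).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(substream_seed(config$seed, "expression"), {
    ng <- config$n_genes
    genes <- sprintf("g%04d", seq_len(ng))
    cs_acc <- sprintf("CS%02d", seq_len(config$n_cs))
    ws_acc <- sprintf("WS%02d", seq_len(config$n_ws))
    accs <- c(cs_acc, ws_acc)
    na <- length(accs)

    mu <- stats::runif(ng, config$ratio_mean_range[1], config$ratio_mean_range[2])
    shifted <- stats::runif(ng) < config$frac_median_shift
    mu_cs <- mu
    mu_ws <- ifelse(shifted, mu - config$shift_size, mu)

    kappa <- c(rep(config$concentration_cs, config$n_cs),
               rep(config$concentration_ws, config$n_ws))
    mu_cell <- cbind(matrix(mu_cs, ng, config$n_cs),
                     matrix(mu_ws, ng, config$n_ws))
    kap_cell <- matrix(kappa, ng, na, byrow = TRUE)
    ratio <- matrix(stats::rbeta(ng * na, mu_cell * kap_cell,
                                 (1 - mu_cell) * kap_cell), ng, na)
    total <- matrix(stats::rlnorm(ng * na, config$total_meanlog,
                                  config$total_sdlog), ng, na)
    coverage <- config$coverage_slope * total +
      matrix(stats::rnorm(ng * na, 0, config$coverage_noise_sd), ng, na)
    coverage[coverage < 0] <- 0
    forced <- matrix(stats::runif(ng * na) < config$frac_low_coverage, ng, na)
    coverage[forced] <- stats::runif(sum(forced), 0, 4.9)
    dimnames(ratio) <- dimnames(coverage) <- dimnames(forced) <-
      list(genes, accs)

    fpkm1 <- ratio * total
    fpkm2 <- (1 - ratio) * total
    gene_col <- rep(rep(genes, each = na), times = 2L)
    df <- data.frame(
      gene_id = gene_col,
      isoform_id = paste0(gene_col, rep(c(".1", ".2"), each = ng * na)),
      accession_id = rep(rep(accs, times = ng), times = 2L),
      fpkm = c(as.vector(t(fpkm1)), as.vector(t(fpkm2))),
      gene_coverage = rep(as.vector(t(coverage)), times = 2L),
      stringsAsFactors = FALSE
    )
    tab <- expression_table(df)

    truth <- list(
      genes = data.frame(gene_id = genes, mu = mu, mu_cs = mu_cs,
                         mu_ws = mu_ws, shifted = shifted,
                         stringsAsFactors = FALSE),
      ratio = ratio, coverage = coverage, forced_low = forced
    )
    list(table = tab,
         cs_panel = panel_definition(paste0("popCS_", config$n_cs), "CS", cs_acc),
         ws_panel = panel_definition(paste0("popWS_", config$n_ws), "WS", ws_acc),
         truth = truth)
  })
}

#' Simulate GO annotation with one planted enriched term
#'
#' Assigns \code{n_go_terms} GO terms over the simulated genes. The
#' first term (\code{GO:0000001}) is the designated enriched term: it
#' annotates shifted genes with probability \code{p_in} and all other
#' genes with probability \code{p_out}. Each background term annotates
#' \code{genes_per_term} genes drawn uniformly. Genes receiving no term
#' are left unannotated.
#'
#' @param config A \code{simulation_config}.
#' @param truth The \code{truth} element of [simulate_expression()].
#' @return A list: \code{go} (a \code{go_map}) and \code{enriched_term}
#'   (the planted term id).
#' @export
simulate_go <- function(config, truth) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(substream_seed(config$seed, "go"), {
    genes <- truth$genes$gene_id
    shifted <- truth$genes$shifted
    terms <- sprintf("GO:%07d", seq_len(config$n_go_terms))
    enriched <- terms[1L]

    ann_gene <- character(0)
    ann_term <- character(0)
    p_enr <- ifelse(shifted, config$p_in, config$p_out)
    hit <- stats::runif(length(genes)) < p_enr
    ann_gene <- c(ann_gene, genes[hit])
    ann_term <- c(ann_term, rep(enriched, sum(hit)))
    for (t in terms[-1L]) {
      picked <- sample(genes, min(config$genes_per_term, length(genes)))
      ann_gene <- c(ann_gene, picked)
      ann_term <- c(ann_term, rep(t, length(picked)))
    }
    list(go = go_map(lapply(split(ann_term, ann_gene), unique)),
         enriched_term = enriched)
  })
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# one codon per amino acid, used for reverse translation of synthetic CDS
CODON1 <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
            H = "CAT", I = "ATT", K = "AAA", L = "CTT", M = "ATG", N = "AAT",
            P = "CCT", Q = "CAA", R = "CGT", S = "TCT", T = "ACT", V = "GTT",
            W = "TGG", Y = "TAT")

random_protein <- function(len) {
  paste0("M", paste(sample(AA20, len - 1L, replace = TRUE), collapse = ""))
}

random_nt <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

reverse_translate <- function(protein) {
  paste(CODON1[strsplit(protein, "")[[1]]], collapse = "")
}

#' Simulate canonical/alternative isoform protein pairs
#'
#' Generates \code{n_per_category} gene pairs for each of the four
#' functional-impact categories, with known ground truth:
#' \describe{
#'   \item{1 (start lost)}{alternative mRNA lacking the canonical start
#'     context entirely — no anchored translation is possible.}
#'   \item{2 (early stop)}{alternative mRNA whose translation terminates
#'     before 20\% of the canonical protein length (stop codon
#'     substituted early in the CDS).}
#'   \item{3 (slightly different)}{alternative protein differing from
#'     the canonical by a small internal deletion (< 10\% of residues),
#'     or an equal-length variant with > 50\% identity, or a >= 500-aa
#'     identical core with a divergent flank — cycled in that order.}
#'   \item{4 (identical)}{alternative mRNA whose CDS is the canonical
#'     one; only the untranslated regions differ.}
#' }
#'
#' @param n_per_category Pairs per category (>= 1).
#' @param seed Integer seed.
#' @return A list with named character vectors
#'   \code{canonical_protein}, \code{canonical_cds_prefix} (first 30 nt
#'   of the canonical CDS), \code{alternative_mrna} (categories 1, 2, 4),
#'   \code{alternative_protein} (category 3), and \code{truth}
#'   (data frame: gene_id, category).
#' @export
simulate_protein_pairs <- function(n_per_category, seed = 1L) {
  stopifnot(n_per_category >= 1L)
  with_seed(substream_seed(seed, "protein"), {
    out_can <- out_prefix <- out_mrna <- out_prot <- character(0)
    ids <- character(0); cats <- integer(0)
    idx <- 0L
    for (cat in 1:4) {
      for (i in seq_len(n_per_category)) {
        idx <- idx + 1L
        gid <- sprintf("pg%03d", idx)
        L <- if (cat == 3L && (i - 1L) %% 3L == 2L) {
          sample(600:800, 1L)  # needs a >= 500-aa identical core
        } else sample(200:600, 1L)
        canon <- random_protein(L)
        cds <- paste0(reverse_translate(canon), "TAA")
        prefix <- substr(cds, 1L, 30L)
        alt_mrna <- NA_character_
        alt_prot <- NA_character_
        if (cat == 1L) {
          # random mRNA; reject draws containing the 12-nt anchor
          repeat {
            alt_mrna <- random_nt(600L)
            if (!grepl(substr(cds, 1L, 12L), alt_mrna, fixed = TRUE)) break
          }
        } else if (cat == 2L) {
          # substitute a stop codon before 20% of canonical length
          stop_at <- sample(seq(12L, max(12L, floor(0.15 * L))), 1L)
          codons <- substring(cds, seq(1L, nchar(cds) - 2L, 3L),
                              seq(3L, nchar(cds), 3L))
          codons[stop_at + 1L] <- "TAA"
          alt_mrna <- paste0(random_nt(40L), paste(codons, collapse = ""),
                             random_nt(30L))
        } else if (cat == 3L) {
          variant <- (i - 1L) %% 3L
          if (variant == 0L) {
            # internal deletion of < 10% of residues
            d <- max(1L, floor(0.05 * L))
            at <- sample(seq(31L, L - d - 10L), 1L)
            alt_prot <- paste0(substr(canon, 1L, at - 1L),
                               substr(canon, at + d, L))
          } else if (variant == 1L) {
            # equal length, ~30% of residues substituted
            aa <- strsplit(canon, "")[[1]]
            pos <- sample(2:L, floor(0.3 * L))
            aa[pos] <- vapply(aa[pos], function(a)
              sample(setdiff(AA20, a), 1L), character(1))
            alt_prot <- paste(aa, collapse = "")
          } else {
            # identical >= 520-aa core, long divergent tail
            core <- 520L
            alt_prot <- paste0(substr(canon, 1L, core),
                               paste(sample(AA20, 200L, replace = TRUE),
                                     collapse = ""))
          }
        } else {
          alt_mrna <- paste0(random_nt(50L), cds, random_nt(80L))
        }
        out_can[gid] <- canon
        out_prefix[gid] <- prefix
        out_mrna[gid] <- alt_mrna
        out_prot[gid] <- alt_prot
        ids <- c(ids, gid); cats <- c(cats, cat)
      }
    }
    list(canonical_protein = out_can,
         canonical_cds_prefix = out_prefix,
         alternative_mrna = out_mrna,
         alternative_protein = out_prot,
         truth = data.frame(gene_id = ids, category = cats,
                            stringsAsFactors = FALSE))
  })
}
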