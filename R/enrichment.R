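#' Hypergeometric upper-tail probability, log-space
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(N, K, n): the
#' probability of observing at least \code{k} annotated genes in a draw
#' of \code{n} from a universe of \code{N} genes of which \code{K} are
#' annotated. Computed by summing the point masses
#' \eqn{C(K,j) C(N-K,n-j) / C(N,n)} for \eqn{j = k..min(n,K)} in
#' log-space (\code{lchoose} + log-sum-exp), so the tail is stable even
#' when the binomials overflow double precision.
#'
#' @param k Observed overlap (included in the tail).
#' @param K Annotated genes in the universe.
#' @param n Draw (foreground) size.
#' @param N Universe (background) size.
#' @return \eqn{P(X \ge k)}; exactly 1 when \code{k <= max(0, n+K-N)}.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  stopifnot(length(k) == 1L, length(K) == 1L, length(n) == 1L, length(N) == 1L)
  k <- as.numeric(k); K <- as.numeric(K); n <- as.numeric(n); N <- as.numeric(N)
  if (K > N || n > N || k > min(n, K) || k < 0 || any(c(k, K, n, N) %% 1 != 0)) {
    stop("invalid hypergeometric configuration: need 0 <= k <= min(n, K), ",
         "K <= N, n <= N, all integers", call. = FALSE)
  }
  j_min <- max(0, n + K - N)  # support lower bound
  if (k <= j_min) return(1)
  j <- seq(k, min(n, K))
  logs <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
  m <- max(logs)
  min(1, exp(m + log(sum(exp(logs - m)))))
}

#' Singular Enrichment Analysis of GO terms
#'
#' Hypergeometric over-representation test of every GO term annotating
#' at least one foreground gene, against a background universe, with
#' Bonferroni control. Following standard SEA practice the background
#' is restricted to annotated genes, and unannotated foreground genes
#' are dropped from the draw size (their count is messaged). The
#' Bonferroni multiplier is, by default, the number of terms actually
#' tested (terms with >= 1 foreground gene); set
#' \code{universe = "background_terms"} to use all terms with >= 1
#' background gene instead.
#'
#' @param foreground Character vector of gene ids; must be a subset of
#'   \code{background}.
#' @param background Character vector of gene ids (the comparison's
#'   working gene set).
#' @param go A \code{go_map}.
#' @param alpha Significance level after correction (default 0.05).
#' @param universe Bonferroni multiplier convention, see above.
#' @return An \code{enrichment_result} data frame, one row per tested
#'   term: \code{term}, \code{k} (foreground genes with the term),
#'   \code{n} (annotated foreground size), \code{K} (background genes
#'   with the term), \code{N} (annotated background size),
#'   \code{p_raw}, \code{p_adjusted}, \code{significant}; sorted by
#'   \code{p_adjusted} then term id. Attributes:
#'   \code{n_unannotated_foreground}, \code{bonferroni_m}.
#' @export
sea <- function(foreground, background, go, alpha = 0.05,
                universe = c("foreground_terms", "background_terms")) {
  universe <- match.arg(universe)
  stopifnot(inherits(go, "go_map"))
  foreground <- unique(as.character(foreground))
  background <- unique(as.character(background))
  if (length(foreground) == 0L) stop("empty foreground", call. = FALSE)
  outside <- setdiff(foreground, background)
  if (length(outside) > 0L) {
    stop("foreground gene(s) outside background: ",
         paste(utils::head(outside, 5L), collapse = ", "), call. = FALSE)
  }
  annotated <- intersect(background, names(go))
  fg <- intersect(foreground, annotated)
  n_dropped <- length(foreground) - length(fg)
  if (n_dropped > 0L) {
    message(n_dropped, " unannotated foreground gene(s) dropped from the test")
  }
  if (length(fg) == 0L) stop("no annotated foreground genes", call. = FALSE)

  N <- length(annotated)
  n <- length(fg)
  bg_terms <- table(unlist(go[annotated], use.names = FALSE))
  fg_terms <- table(unlist(go[fg], use.names = FALSE))
  terms <- sort(names(fg_terms))
  m <- if (universe == "foreground_terms") length(terms) else length(bg_terms)

  p_raw <- vapply(terms, function(t)
    hypergeom_upper_tail(k = fg_terms[[t]], K = bg_terms[[t]], n = n, N = N),
    numeric(1))
  p_adj <- pmin(1, p_raw * m)
  out <- data.frame(term = terms,
                    k = as.integer(fg_terms[terms]),
                    n = n,
                    K = as.integer(bg_terms[terms]),
                    N = N,
                    p_raw = unname(p_raw),
                    p_adjusted = unname(p_adj),
                    significant = unname(p_adj < alpha),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_adjusted, out$term), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unannotated_foreground") <- n_dropped
  attr(out, "bonferroni_m") <- m
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Write an enrichment result as TSV
#'
#' @param result An \code{enrichment_result}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_enrichment <- function(result, path) {
  write_tsv(as.data.frame(result), path)
}
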