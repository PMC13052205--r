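#' Upper tail of the hypergeometric distribution
#'
#' p = P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of
#' drawing at least \code{k} annotated genes when \code{n} candidates are
#' drawn from a universe of \code{N} genes of which \code{K} carry the
#' term. Identical to the one-sided Fisher exact tail on the 2x2 table.
#'
#' @param k observed overlap (candidates carrying the term).
#' @param K genes in the universe carrying the term.
#' @param n candidate genes (drawn from the universe).
#' @param N universe size.
#' @return the upper-tail p-value, in (0, 1]. Vectorized.
#' @export
hypergeom_tail <- function(k, K, n, N) {
  bad <- k < 0 | K < 0 | n < 0 | K > N | n > N | k > pmin(K, n)
  if (any(bad)) stop("hypergeometric bounds violated: need 0 <= k <= ",
                     "min(K, n), K <= N, n <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' One-sided over-representation of functional terms
#'
#' Tests each term's genes for over-representation among the candidate
#' genes with the hypergeometric upper tail. Candidates outside the
#' universe are dropped (count reported in the \code{n_dropped}
#' attribute); terms with fewer than \code{min_term_size} genes in the
#' universe are excluded before testing. No multiple-testing correction is
#' applied to the ranking; a Benjamini-Hochberg column is emitted for
#' reference only and never filters the output. The display threshold
#' marks rows for reporting but does not affect the computation.
#'
#' @param candidates character vector of candidate gene IDs.
#' @param term_map data.frame with columns \code{gene_id} and
#'   \code{term_id} (optionally \code{term_name}, \code{namespace}).
#' @param universe character vector of gene IDs forming the annotation
#'   universe; defaults to all genes in \code{term_map}.
#' @param min_term_size exclude terms with fewer universe genes than this
#'   (default 5).
#' @param display_p rows with p below this get \code{display = TRUE}
#'   (default 0.10).
#' @return data.frame ranked by p: \code{term_id}, \code{k}, \code{K},
#'   \code{n}, \code{N}, \code{p}, \code{p_bh}, \code{display} (+
#'   \code{term_name}/\code{namespace} when present in \code{term_map}).
#' @export
enrich_terms <- function(candidates, term_map, universe = NULL,
                         min_term_size = 5L, display_p = 0.10) {
  stopifnot(all(c("gene_id", "term_id") %in% names(term_map)))
  if (is.null(universe)) universe <- unique(term_map$gene_id)
  universe <- unique(universe)
  term_map <- term_map[term_map$gene_id %in% universe, , drop = FALSE]
  n_dropped <- sum(!unique(candidates) %in% universe)
  cand <- unique(candidates[candidates %in% universe])
  if (length(cand) == 0L) {
    warning("no candidate genes remain after universe intersection")
    out <- data.frame(term_id = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      p_bh = numeric(), display = logical())
    attr(out, "n_dropped") <- n_dropped
    return(out)
  }
  pairs <- unique(term_map[, c("gene_id", "term_id")])
  sets <- split(pairs$gene_id, pairs$term_id)
  K <- lengths(sets)
  sets <- sets[K >= min_term_size]
  K <- K[K >= min_term_size]
  if (length(sets) == 0L) {
    out <- data.frame(term_id = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      p_bh = numeric(), display = logical())
    attr(out, "n_dropped") <- n_dropped
    return(out)
  }
  k <- vapply(sets, function(g) sum(cand %in% g), 0L)
  N <- length(universe)
  n <- length(cand)
  p <- hypergeom_tail(k, K, n, N)
  out <- data.frame(term_id = names(sets), k = as.integer(k),
                    K = as.integer(K), n = n, N = N, p = p,
                    p_bh = stats::p.adjust(p, method = "BH"),
                    display = p < display_p, row.names = NULL)
  meta_cols <- intersect(c("term_name", "namespace"), names(term_map))
  if (length(meta_cols) > 0L) {
    meta <- unique(term_map[, c("term_id", meta_cols), drop = FALSE])
    out <- merge(out, meta, by = "term_id", all.x = TRUE, sort = FALSE)
  }
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}
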