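# Hypergeometric over-representation of a gene set (typically the most
# differentially spliced genes) against a user-supplied gene-to-GO map,
# with Benjamini-Hochberg correction.

#' Hypergeometric upper-tail probability
#'
#' Probability of drawing at least `k` annotated genes when sampling `n`
#' genes without replacement from a background of `N` genes of which `K`
#' are annotated:
#' `p = sum_{i=k}^{min(K,n)} C(K,i) C(N-K, n-i) / C(N,n)`.
#' Evaluated via the stable distribution-function implementation in
#' `stats::phyper`.
#'
#' @param k Query genes carrying the annotation.
#' @param K Background genes carrying the annotation.
#' @param n Query size.
#' @param N Background size.
#' @return p in `[0, 1]`; `k = 0` gives exactly 1.
#' @examples
#' hypergeom_upper(5, 5, 5, 10)  # 1/252
#' @export
hypergeom_upper <- function(k, K, n, N) {
  if (any(k < 0 | n < 0 | K < 0 | N < 0) || any(k > n) || any(n > N) ||
      any(k > K) || any(K > N))
    stop("need 0 <= k <= n <= N and k <= K <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' GO term over-representation of a gene set
#'
#' Tests every annotation term for enrichment of the query genes by the
#' one-sided hypergeometric test, then applies Benjamini-Hochberg correction
#' across tested terms. Query genes absent from the background are dropped
#' (count reported via a message); terms annotating fewer than
#' `min_term_size` background genes are not tested. The background defaults
#' to all annotated genes; supplying the set of expressed genes instead is
#' recommended when available, since it is the proper sampling universe.
#'
#' @param query Character vector of gene ids (duplicates ignored).
#' @param annot An `annotation_map` from [read_annotation()].
#' @param min_term_size Minimum background genes per tested term (default 3).
#' @param background Optional custom background gene set; terms are
#'   restricted to it.
#' @return Data frame of class `enrichment_result`, one row per tested term,
#'   sorted by (p_adj, p, term_id): term_id, term_name, k, K, n, N, p,
#'   p_adj.
#' @export
go_enrich <- function(query, annot, min_term_size = 3L, background = NULL) {
  stopifnot(inherits(annot, "annotation_map"))
  bg <- if (is.null(background)) annot$background
        else sort(unique(as.character(background)))
  query <- unique(as.character(query))
  eff <- intersect(query, bg)
  if (length(eff) < length(query))
    message("go_enrich: dropped ", length(query) - length(eff),
            " query gene(s) outside the background")
  if (length(eff) == 0L) stop("no query gene is in the background")
  n <- length(eff); N <- length(bg)
  rows <- lapply(names(annot$terms), function(tm) {
    genes <- intersect(annot$terms[[tm]], bg)
    K <- length(genes)
    if (K < min_term_size) return(NULL)
    k <- length(intersect(eff, genes))
    data.frame(term_id = tm,
               term_name = unname(annot$term_names[tm]),
               k = k, K = K, n = n, N = N,
               p = hypergeom_upper(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("no term passes min_term_size against this background")
  df <- do.call(rbind, rows)
  df$p_adj <- stats::p.adjust(df$p, method = "BH")
  df <- df[order(df$p_adj, df$p, df$term_id), ]
  rownames(df) <- NULL
  class(df) <- c("enrichment_result", "data.frame")
  df
}
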