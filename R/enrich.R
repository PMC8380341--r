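#' Build a validated term collection
#'
#' @param terms Named list as returned by [read_gmt()] (each element:
#'   `name`, `category`, `genes`).
#' @param universe Character vector of all measurable gene ids; every term
#'   member must belong to it (members outside are dropped, and a term left
#'   empty is an error).
#' @return A `term_collection` object.
#' @export
term_collection <- function(terms, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop_domain("universe must be non-empty")
  if (!length(terms)) stop_domain("no terms supplied")
  terms <- lapply(terms, function(t) {
    t$genes <- intersect(t$genes, universe)
    t
  })
  sizes <- vapply(terms, function(t) length(t$genes), integer(1))
  if (any(sizes == 0L)) {
    stop_domain("terms with no members in the universe: ",
                paste(head(names(terms)[sizes == 0L], 5), collapse = ", "))
  }
  structure(list(terms = terms, universe = universe), class = "term_collection")
}

#' Hypergeometric upper-tail probability (over-representation)
#'
#' Probability of observing `k` or more term members in a draw of `n` genes
#' from a universe of `N` containing `K` term members:
#' `sum_{i=k}^{min(K,n)} C(K,i) C(N-K,n-i) / C(N,n)`.
#'
#' @param k Observed overlap.
#' @param K Term size.
#' @param n Drawn set size.
#' @param N Universe size.
#' @return Upper-tail p in (0, 1]. Vectorised.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(k < 0) || any(k > pmin(K, n)) || any(K > N) || any(n > N) ||
      any(c(k, K, n, N) != floor(c(k, K, n, N)))) {
    stop_domain("hypergeom_upper_tail: need integer 0 <= k <= min(K, n), K <= N, n <= N")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of a DE set against a term collection
#'
#' The DE set is the paper-style gene filter |log2fc| > `lfc` and
#' p < `alpha` applied to `de_records`, intersected with the collection's
#' universe. Each term with at least one DE member is tested with
#' [hypergeom_upper_tail()]; BH q-values are computed over the tested terms
#' and `significant` flags raw p < `alpha`.
#'
#' @param de_records DE table from [call_differential()].
#' @param collection A [term_collection()].
#' @param lfc,alpha Gene-filter thresholds (defaults 1 and 0.05).
#' @param ease Use the conservative EASE-style statistic (test `k - 1`
#'   successes instead of `k`). Default `FALSE`.
#' @return `data.frame` sorted by p ascending: `term_id`, `name`,
#'   `category`, `k`, `K`, `n`, `N`, `p`, `q`, `fold_enrichment`,
#'   `significant`.
#' @export
enrich_terms <- function(de_records, collection, lfc = 1, alpha = 0.05,
                         ease = FALSE) {
  stopifnot(inherits(collection, "term_collection"))
  empty <- data.frame(term_id = character(0), name = character(0),
                      category = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0), fold_enrichment = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
  de_set <- de_records$feature_id[abs(de_records$log2fc) > lfc &
                                    de_records$p < alpha]
  de_set <- intersect(unique(de_set), collection$universe)
  if (!length(de_set)) {
    warning("empty DE set; no enrichment computed")
    return(empty)
  }
  N <- length(collection$universe)
  n <- length(de_set)
  rows <- lapply(names(collection$terms), function(id) {
    t <- collection$terms[[id]]
    K <- length(t$genes)
    k <- length(intersect(t$genes, de_set))
    if (k == 0L) return(NULL)
    k_test <- if (ease) max(0L, k - 1L) else k
    p <- hypergeom_upper_tail(k_test, K, n, N)
    data.frame(term_id = id, name = t$name, category = t$category,
               k = k, K = K, n = n, N = N, p = p,
               fold_enrichment = (k / n) / (K / N), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$p < alpha
  out <- out[order(out$p, out$term_id),
             c("term_id", "name", "category", "k", "K", "n", "N", "p", "q",
               "fold_enrichment", "significant")]
  rownames(out) <- NULL
  out
}
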