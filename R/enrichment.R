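# Hypergeometric over-representation analysis with Benjamini-Hochberg FDR.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of seeing
#' at least `k` annotated proteins in a query of size `n` drawn from a
#' background of `N` proteins of which `K` carry the annotation. Computed
#' stably (log-space) via [stats::phyper()].
#'
#' @param k Query hits (vectorised).
#' @param K Background hits.
#' @param n Query size.
#' @param N Background size.
#' @return Upper-tail p-value(s) in (0, 1].
#' @examples
#' hypergeometric_tail(5, 5, 5, 20)  # 1 / choose(20, 5)
#' @export
hypergeometric_tail <- function(k, K, n, N) {
  if (any(K > N) || any(n > N)) stop("K and n must not exceed N", call. = FALSE)
  if (any(k < 0) || any(k > pmin(K, n))) {
    stop("k must satisfy 0 <= k <= min(K, n)", call. = FALSE)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' output order matches input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Term over-representation in a protein set
#'
#' Hypergeometric test of every annotation term against a query set, with
#' BH-FDR correction across the tested terms. Only terms with at least one
#' query hit are tested and reported.
#'
#' @param query Character vector of query accessions (must be a subset of
#'   the background).
#' @param background Character vector of background accessions (e.g. all
#'   proteins identified in the experiment).
#' @param annotations Named list: term id -> character vector of annotated
#'   accessions.
#' @param alpha Significance level on the q-value (default 0.05).
#' @return Data frame sorted by p-value: `term`, `k` (query hits), `K`
#'   (background hits), `n`, `N`, `p_value`, `q_value`, `significant`.
#' @export
enrich_terms <- function(query, background, annotations, alpha = 0.05) {
  query <- unique(query); background <- unique(background)
  stray <- setdiff(query, background)
  if (length(stray)) {
    stop("query accessions missing from the background: ",
         paste(utils::head(stray, 10), collapse = ", "), call. = FALSE)
  }
  if (length(annotations) == 0L) stop("no annotation terms given", call. = FALSE)
  N <- length(background); n <- length(query)
  rows <- lapply(names(annotations), function(term) {
    ann <- intersect(unique(annotations[[term]]), background)
    k <- length(intersect(ann, query))
    if (k == 0L) return(NULL)
    data.frame(term = term, k = k, K = length(ann), n = n, N = N,
               p_value = hypergeometric_tail(k, length(ann), n, N),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p_value = numeric(),
                      q_value = numeric(), significant = logical()))
  }
  rows$q_value <- bh_fdr(rows$p_value)
  rows$significant <- rows$q_value < alpha
  rows <- rows[order(rows$p_value, rows$term), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}
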