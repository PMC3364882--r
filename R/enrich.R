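# Category enrichment of gene lists via the EASE score (a conservative
# variant of the one-sided Fisher/hypergeometric test that removes one
# gene from the observed overlap) with Bonferroni correction.

#' EASE score for a list/category overlap
#'
#' One-sided hypergeometric upper-tail probability with the observed
#' overlap reduced by one: `P(X >= k - 1)` for X hypergeometric with
#' category size `K`, background `N`, list size `n`. By construction the
#' score is 1 for k of 0 or 1 and always at least the exact Fisher
#' one-sided p of the same table.
#'
#' @param k genes in both the list and the category
#' @param n list size
#' @param K category size in the background
#' @param N background size
#' @return probability in (0, 1]
#' @export
ease_score <- function(k, n, K, N) {
  if (k < 0 || n < 0 || K < 0 || N < 1 || k > n || k > K || n > N || K > N)
    stop("inconsistent counts: require k <= min(n, K) and n, K <= N")
  if (k <= 1) return(1.0)
  stats::phyper(k - 2, K, N - K, n, lower.tail = FALSE)
}

#' Enrichment of a gene list over plain category annotations
#'
#' Every category overlapping the list (k >= 1) is tested with
#' [ease_score()]; Bonferroni correction multiplies by the number of
#' tested categories. The background is the set of genes in the supplied
#' annotation map (the convention of annotation-tool backgrounds), unless
#' given explicitly.
#'
#' @param gene_list character vector of gene ids (must be in the background)
#' @param categories data.frame (gene, category)
#' @param background character vector of gene ids; default: all genes in
#'   `categories`
#' @param alpha significance level applied to the Bonferroni p
#' @return data.frame sorted by EASE p: category, k, n, K, N, ease_p,
#'   bonferroni_p, significant
#' @export
enrich_gene_list <- function(gene_list, categories, background = NULL,
                             alpha = 0.05) {
  background <- unique(background %||% categories$gene)
  missing <- setdiff(gene_list, background)
  if (length(missing))
    stop("genes absent from background: ", paste(head(missing, 5), collapse = ", "))
  gene_list <- unique(gene_list)
  categories <- categories[categories$gene %in% background, , drop = FALSE]
  n <- length(gene_list); N <- length(background)
  res <- lapply(split(categories$gene, categories$category), function(memb) {
    memb <- unique(memb)
    k <- length(intersect(gene_list, memb))
    if (k < 1) return(NULL)
    data.frame(k = k, K = length(memb), ease_p = ease_score(k, n, length(memb), N))
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res))
    return(data.frame(category = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), ease_p = numeric(0),
                      bonferroni_p = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE))
  m <- length(res)
  out <- data.frame(category = names(res),
                    k = vapply(res, function(r) r$k, numeric(1)),
                    n = n,
                    K = vapply(res, function(r) r$K, numeric(1)),
                    N = N,
                    ease_p = vapply(res, function(r) r$ease_p, numeric(1)),
                    stringsAsFactors = FALSE)
  out$bonferroni_p <- pmin(out$ease_p * m, 1)
  out$significant <- out$bonferroni_p < alpha
  out <- out[order(out$ease_p, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}
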