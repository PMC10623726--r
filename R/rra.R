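#' Robust Rank Aggregation score for one gene
#'
#' Given a gene's normalized ranks across `n_lists` ranked gene lists (rank
#' divided by list length, in (0, 1]; lists missing the gene contribute the
#' worst possible rank 1), the score is the minimum over k of the beta
#' order-statistic CDF: rho = min_k P(Beta(k, n - k + 1) <= r_(k)) over the
#' ascending sorted ranks r_(1) <= ... <= r_(n). Small rho means the gene
#' sits unusually high in at least some of the lists. The per-gene p-value
#' applies the reference method's Bonferroni-style correction,
#' p = min(1, rho * n_lists).
#'
#' @param normalized_ranks numeric vector of values in (0, 1], one per list.
#' @return List with `rho` and `p`.
#' @examples
#' rra_rho(c(0.1, 1.0))$rho  # min(1 - (1 - 0.1)^2, 1) = 0.19
#' @export
rra_rho <- function(normalized_ranks) {
  r <- as.numeric(normalized_ranks)
  if (length(r) == 0) stop("empty rank vector", call. = FALSE)
  if (any(!is.finite(r)) || any(r <= 0) || any(r > 1)) {
    stop("normalized ranks must lie in (0, 1]", call. = FALSE)
  }
  n <- length(r)
  s <- sort(r)
  rho <- min(stats::pbeta(s, seq_len(n), n - seq_len(n) + 1))
  list(rho = rho, p = min(1, rho * n))
}

#' Aggregate ranked DEG lists by Robust Rank Aggregation
#'
#' Builds one consensus ranked gene list per (tissue, cell type) from the
#' per-study ordered DEG lists. Each gene's normalized rank in a list is its
#' position divided by the list length, and 1.0 for lists that do not contain
#' it. Per-gene p-values from [rra_rho()] are Benjamini-Hochberg adjusted
#' across the union of genes; output is ordered by adjusted p ascending with
#' ties broken by the best (smallest) single-list normalized rank and then
#' lexicographic gene symbol, and truncated to at most `cap` genes.
#'
#' @param deg_lists list of character vectors, each ordered most to least
#'   significant; at least one must be non-empty.
#' @param cap maximum output length (default 3000).
#' @return data.frame with columns `gene`, `p`, `adj_p`, ordered as above.
#' @export
rra_aggregate <- function(deg_lists, cap = 3000) {
  deg_lists <- lapply(deg_lists, function(l) {
    l <- gene_key(as.character(l))
    l[!duplicated(l)]
  })
  deg_lists <- Filter(function(l) length(l) > 0, deg_lists)
  if (length(deg_lists) == 0) stop("all DEG lists are empty", call. = FALSE)
  genes <- unique(unlist(deg_lists, use.names = FALSE))
  n_lists <- length(deg_lists)
  # normalized rank matrix, worst rank 1.0 where a list misses the gene
  rmat <- matrix(1.0, nrow = length(genes), ncol = n_lists,
                 dimnames = list(genes, NULL))
  for (j in seq_len(n_lists)) {
    l <- deg_lists[[j]]
    rmat[l, j] <- seq_along(l) / length(l)
  }
  pv <- apply(rmat, 1, function(r) rra_rho(r)$p)
  adj <- stats::p.adjust(pv, method = "BH")
  best <- apply(rmat, 1, min)
  ord <- order(adj, best, genes)
  out <- data.frame(gene = genes[ord], p = unname(pv[ord]),
                    adj_p = unname(adj[ord]), stringsAsFactors = FALSE)
  utils::head(out, cap)
}
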