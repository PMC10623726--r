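# Pre-ranked GSEA of a query gene set against an aggregated DEG list.
# The aggregated lists carry ranks, not expression statistics, so the
# running sum is unweighted (KS-style): +1/|hits| at each hit,
# -1/(|L| - |hits|) at each miss; ES is the signed extremum.

# null ES distributions are memoised per (list length, hit count,
# n_perm, seed) so annotating many clusters against many cell types reuses
# them; results are independent of evaluation order.
.gsea_cache <- new.env(parent = emptyenv())

# ES from sorted hit positions in a list of length l
es_from_positions <- function(pos, l) {
  h <- length(pos)
  if (h == 0) return(0)
  miss_dec <- if (l > h) 1 / (l - h) else 0
  i <- seq_len(h)
  at_hit <- i / h - (pos - i) * miss_dec          # running sum just after hit i
  before_hit <- (i - 1) / h - (pos - i) * miss_dec # just before hit i
  hi <- max(at_hit)
  lo <- min(before_hit, 0)
  if (hi >= -lo) hi else lo
}

null_es_distribution <- function(l, h, n_perm, seed) {
  key <- paste(l, h, n_perm, seed, sep = "_")
  hit <- .gsea_cache[[key]]
  if (!is.null(hit)) return(hit)
  null <- with_preserved_rng(seed, {
    vapply(seq_len(n_perm),
           function(i) es_from_positions(sort(sample.int(l, h)), l),
           numeric(1))
  })
  .gsea_cache[[key]] <- null
  null
}

#' Pre-ranked GSEA p-value of a query against an aggregated DEG list
#'
#' Restricts the query to genes present in the ranked list, computes the
#' unweighted Kolmogorov-Smirnov-style enrichment score (ES, the signed
#' extremum of the running sum), and estimates significance against a null
#' of `n_perm` same-size gene sets drawn uniformly from the list. The
#' normalized score is NES = ES / mean(positive null ES) and the p-value
#' uses the add-one estimator (1 + #\{null ES >= ES\}) / (1 + n_perm). Only
#' positive enrichment is informative for cell-type annotation: when the
#' query does not intersect the list or ES <= 0 the component is reported
#' absent (`NULL`) and the caller falls back to the hypergeometric p alone.
#'
#' @param query character vector of query gene symbols.
#' @param degs aggregated DEG list: a data.frame with a `gene` column
#'   ordered most to least significant, or a character vector.
#' @param n_perm number of permutations, at least 100 (default 1000).
#' @param seed RNG seed for the permutation null (default 0); identical
#'   inputs and seed give identical results.
#' @return `NULL` when the component is absent, else a list with `es`,
#'   `nes`, `p`.
#' @export
gsea_pvalue <- function(query, degs, n_perm = 1000, seed = 0) {
  if (!is.numeric(n_perm) || n_perm < 100) {
    stop("n_perm must be at least 100", call. = FALSE)
  }
  ranked <- if (is.data.frame(degs)) degs$gene else degs
  ranked <- gene_key(as.character(ranked))
  if (length(ranked) == 0) return(NULL)
  x <- unique(gene_key(query))
  pos <- which(ranked %in% x)
  if (length(pos) == 0) return(NULL)
  es <- es_from_positions(pos, length(ranked))
  if (es <= 0) return(NULL)
  null <- null_es_distribution(length(ranked), length(pos), n_perm, seed)
  pos_null <- null[null > 0]
  nes <- if (length(pos_null) > 0) es / mean(pos_null) else NA_real_
  p <- (1 + sum(null >= es)) / (1 + n_perm)
  list(es = es, nes = nes, p = p)
}
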