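#' Frequency-weighted gene universe for one cell type
#'
#' Assigns each gene of the universe G a raw weight: its usage frequency
#' when it is a canonical marker of the cell type, baseline 1 otherwise, then
#' rescales all weights to have mean exactly 1 over G. With every frequency
#' equal to 1 all weights are exactly 1 and the weighted test degenerates to
#' the conventional hypergeometric test. Markers absent from the universe
#' are dropped with a warning.
#'
#' @param universe character vector of gene symbols (G, typically all
#'   protein-coding genes or all genes of the marker map).
#' @param freq named integer vector of marker usage frequencies (gene -> count).
#' @return List with `genes` (upper-cased keys) and `w` (normalized weights,
#'   mean 1).
#' @export
normalize_weights <- function(universe, freq = NULL) {
  genes <- unique(gene_key(universe))
  if (length(genes) == 0) stop("empty gene universe", call. = FALSE)
  w <- rep(1, length(genes))
  names(w) <- genes
  if (!is.null(freq) && length(freq) > 0) {
    keys <- gene_key(names(freq))
    inside <- keys %in% genes
    if (any(!inside)) {
      warning(sum(!inside), " marker(s) outside the gene universe dropped: ",
              paste(utils::head(keys[!inside], 5), collapse = ", "))
    }
    w[keys[inside]] <- as.numeric(freq[inside])
  }
  w <- w / mean(w)
  list(genes = genes, w = w)
}

# log generalized binomial coefficient via the gamma function,
# lchoose(x, y) for real x >= y >= 0
lchoose_gamma <- function(x, y) lgamma(x + 1) - lgamma(y + 1) - lgamma(x - y + 1)

#' Weighted hypergeometric over-representation p-value
#'
#' Tests whether a query gene set X (a cluster's top differentially
#' upregulated genes) is over-represented in a cell type's canonical marker
#' set Mc, with each gene contributing its normalized usage-frequency weight
#' raised to the power Q rather than a unit count. Writing
#' N = sum_{G} w^Q, n = sum_{X} w^Q, m = sum_{Mc} w^Q and k = sum_{X
#' intersect Mc} w^Q, the p-value is the upper tail
#' \deqn{P = \sum_{a = k+1}^{\min(m, n)} \frac{C(m, a)\, C(N-m, n-a)}{C(N, n)}}
#' evaluated on the unit grid a = k+1, k+2, ... while a <= min(m, n), with
#' each generalized binomial coefficient computed through the gamma
#' function. Q > 1 amplifies weight differences so frequently used markers
#' dominate; at Q with uniform weights the sum is exactly the classical
#' hypergeometric tail P(overlap > k). An empty sum (k already at its
#' maximum) is clamped to the smallest positive double rather than zero so a
#' downstream Fisher combination stays finite.
#'
#' @param query character vector of query gene symbols (set-based; order is
#'   ignored here).
#' @param markers named integer vector of marker usage frequencies for the
#'   cell type.
#' @param universe character vector of universe gene symbols, or a weighted
#'   universe from [normalize_weights()] (then `markers` must be the same
#'   frequency table used to weight it).
#' @param Q power scaling factor, default 3.
#' @return p-value in (0, 1].
#' @export
whg_pvalue <- function(query, markers, universe, Q = 3) {
  if (!is.numeric(Q) || Q <= 0) stop("Q must be positive", call. = FALSE)
  wu <- if (is.list(universe) && !is.null(universe$w)) universe
        else normalize_weights(universe, markers)
  genes <- wu$genes
  wq <- wu$w^Q
  x <- intersect(unique(gene_key(query)), genes)
  if (length(x) == 0) stop("query shares no genes with the universe", call. = FALSE)
  mset <- intersect(gene_key(names(markers)), genes)
  N <- sum(wq)
  n <- sum(wq[x])
  m <- sum(wq[mset])
  k <- sum(wq[intersect(x, mset)])
  whg_tail(N, n, m, k)
}

#' @keywords internal
#' @noRd
whg_tail <- function(N, n, m, k) {
  top <- min(m, n)
  if (k + 1 > top) {
    return(.Machine$double.xmin)  # empty sum: floor, keeps log finite
  }
  a <- seq(k + 1, top, by = 1)
  lp <- lchoose_gamma(m, a) + lchoose_gamma(N - m, n - a) - lchoose_gamma(N, n)
  p <- sum(exp(lp))
  min(1, max(p, .Machine$double.xmin))
}

#' Fisher combination of the two enrichment components
#'
#' Combines the weighted hypergeometric p-value with the GSEA p-value by
#' Fisher's method: T = -2 (ln p_whg + ln p_gsea) referred to a chi-square
#' distribution with 4 degrees of freedom. When the GSEA component is absent
#' (no DEG list, no overlap, or non-positive enrichment) the combined value
#' is the hypergeometric p-value passed through unchanged.
#'
#' @param p_whg p-value in (0, 1].
#' @param p_gsea p-value in (0, 1], or `NULL`/`NA` when absent.
#' @return Combined p-value in (0, 1].
#' @export
fisher_combine <- function(p_whg, p_gsea = NULL) {
  check <- function(p) {
    if (!is.numeric(p) || !is.finite(p) || p <= 0 || p > 1) {
      stop("p-values must lie in (0, 1]", call. = FALSE)
    }
  }
  check(p_whg)
  if (is.null(p_gsea) || (length(p_gsea) == 1 && is.na(p_gsea))) {
    return(p_whg)
  }
  check(p_gsea)
  stat <- -2 * (log(p_whg) + log(p_gsea))
  stats::pchisq(stat, df = 4, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control with monotonicity enforcement;
#' adjusted values dominate the raw ones elementwise and preserve their
#' order.
#' @param pvals numeric vector of p-values in [0, 1].
#' @return Vector of q-values.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric())
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}
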