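#' Hierarchy-aware correctness of a single prediction
#'
#' A predicted cell-type label counts as correct when it equals the true
#' label or is a strict descendant of it in the cell-type hierarchy (a
#' subtype of the truth). Predictions that are ancestors of the truth,
#' unresolvable labels (warned) and `"unassigned"` are incorrect.
#'
#' @param pred predicted cell-type id or `"unassigned"`.
#' @param truth true cell-type id; must be a hierarchy node.
#' @param hierarchy a `cell_hierarchy`.
#' @return Logical.
#' @export
is_correct <- function(pred, truth, hierarchy) {
  if (!truth %in% hierarchy$nodes) {
    stop("truth label '", truth, "' not in hierarchy", call. = FALSE)
  }
  if (identical(pred, "unassigned")) return(FALSE)
  if (!pred %in% hierarchy$nodes) {
    warning("predicted label '", pred, "' not in hierarchy; counted as wrong")
    return(FALSE)
  }
  pred %in% descendants(hierarchy, truth)
}

#' Subtype-aware annotation accuracy
#'
#' Proportion of predictions counted correct by [is_correct()] relative to
#' all labels; unassigned predictions stay in the denominator.
#'
#' @param preds data.frame with columns `cluster`, `predicted`, `truth` (or
#'   vectors via `truth`).
#' @param hierarchy a `cell_hierarchy`.
#' @param truth optional character vector of true labels when `preds` is a
#'   character vector of predictions.
#' @return Accuracy in [0, 1].
#' @export
accuracy <- function(preds, hierarchy, truth = NULL) {
  if (is.data.frame(preds)) {
    stopifnot(all(c("predicted", "truth") %in% names(preds)))
    predicted <- preds$predicted
    truth <- preds$truth
  } else {
    predicted <- preds
  }
  if (length(predicted) == 0) stop("no predictions to score", call. = FALSE)
  stopifnot(length(predicted) == length(truth))
  ok <- mapply(function(p, t) is_correct(p, t, hierarchy), predicted, truth)
  mean(ok)
}

#' Map a predicted label onto a major-cell-type catalog
#'
#' Returns the nearest ancestor-or-self of the prediction that is present in
#' the catalog, searching upward breadth-first; among catalog hits at the
#' same (shortest) distance the lexicographically smallest wins. Returns
#' `"unmapped"` when no node on any root path is catalogued.
#'
#' @param pred predicted cell-type id.
#' @param catalog character vector of catalog cell-type ids (user-supplied).
#' @param hierarchy a `cell_hierarchy`.
#' @return Catalog id or `"unmapped"`.
#' @export
catalog_map <- function(pred, catalog, hierarchy) {
  if (!pred %in% hierarchy$nodes) return("unmapped")
  frontier <- pred
  seen <- character()
  while (length(frontier) > 0) {
    hit <- sort(intersect(frontier, catalog))
    if (length(hit) > 0) return(hit[1])
    seen <- c(seen, frontier)
    frontier <- setdiff(unique(unlist(hierarchy$parents[frontier],
                                      use.names = FALSE)), seen)
  }
  "unmapped"
}

#' Clustering diagnostics across resolutions
#'
#' For each candidate clustering (e.g. one Seurat resolution) summarises the
#' top-1 annotations: the number of clusters, the number of distinct
#' annotated cell types (unassigned clusters are excluded from the distinct
#' count) and their ratio. A ratio of 1 means every cluster received its own
#' cell type (no redundancy); lower ratios flag over-clustering. All rows
#' are reported in input order; choosing among them is left to the user.
#'
#' @param annotations named list: one character vector of top-1 cell-type
#'   labels per clustering (one element per cluster; may contain
#'   `"unassigned"`).
#' @return data.frame with `clustering_id`, `n_clusters`, `n_unique`,
#'   `ratio`.
#' @export
clustering_diagnostics <- function(annotations) {
  stopifnot(length(annotations) >= 1)
  ids <- names(annotations) %||% as.character(seq_along(annotations))
  rows <- lapply(seq_along(annotations), function(i) {
    labels <- annotations[[i]]
    stopifnot(length(labels) >= 1)
    uniq <- length(unique(setdiff(labels, "unassigned")))
    data.frame(clustering_id = ids[i], n_clusters = length(labels),
               n_unique = uniq, ratio = uniq / length(labels),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
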