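#' Build a marker map from curated entries
#'
#' A marker map is the central reference structure for annotation: per
#' (tissue, cell type) it stores the canonical-marker usage-frequency table
#' (from [aggregate_canonical()]) and, where the entries carry DEG lists, a
#' consensus ranked DEG list (from [rra_aggregate()]). Each tissue also gets
#' the cell-type hierarchy pruned to its recorded cell types, with children
#' of unrecorded nodes re-attached to the nearest recorded ancestor.
#'
#' @param entries list of `marker_entry` (see [load_marker_entries()]).
#' @param cell_hier `cell_hierarchy` of cell types; every entry's cell type
#'   must resolve to one of its nodes.
#' @param tissue_hier optional `cell_hierarchy` of tissues used to validate
#'   entry tissue ids.
#' @param species species label; defaults to the entries' species.
#' @return An object of class `marker_map`.
#' @export
build_marker_map <- function(entries, cell_hier, tissue_hier = NULL,
                             species = NULL) {
  if (length(entries) == 0) {
    return(structure(list(species = species %||% "human",
                          cell_hierarchy = cell_hier, tissues = list()),
                     class = "marker_map"))
  }
  cts <- vapply(entries, `[[`, "", "cell_type")
  tis <- vapply(entries, `[[`, "", "tissue")
  bad_ct <- setdiff(unique(cts), cell_hier$nodes)
  if (length(bad_ct) > 0) {
    stop("cell type(s) not in hierarchy: ", paste(bad_ct, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(tissue_hier)) {
    bad_t <- setdiff(unique(tis), tissue_hier$nodes)
    if (length(bad_t) > 0) {
      stop("tissue(s) not in hierarchy: ", paste(bad_t, collapse = ", "),
           call. = FALSE)
    }
  }
  species <- species %||% entries[[1]]$species
  tissues <- list()
  for (t in sort(unique(tis))) {
    t_entries <- entries[tis == t]
    t_cts <- sort(unique(vapply(t_entries, `[[`, "", "cell_type")))
    cell_types <- list()
    for (ct in t_cts) {
      e <- Filter(function(x) identical(x$cell_type, ct), t_entries)
      freq <- suppressWarnings(aggregate_canonical(e))
      deg_sources <- Filter(function(l) length(l) > 0,
                            lapply(e, `[[`, "deg_list"))
      degs <- if (length(deg_sources) > 0) rra_aggregate(deg_sources) else NULL
      cell_types[[ct]] <- list(freq = freq, degs = degs,
                               n_entries = length(e),
                               deg_sources = deg_sources)
    }
    tissues[[t]] <- list(hierarchy = prune_hierarchy(cell_hier, t_cts),
                         cell_types = cell_types)
  }
  structure(list(species = species, cell_hierarchy = cell_hier,
                 tissues = tissues),
            class = "marker_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.marker_map <- function(x, ...) {
  n_ct <- sum(vapply(x$tissues, function(t) length(t$cell_types), 0L))
  cat("<marker_map> species:", x$species, "|", length(x$tissues),
      "tissue(s),", n_ct, "(tissue, cell type) key(s)\n")
  invisible(x)
}

#' All gene symbols recorded in a marker map
#'
#' Union of canonical markers and aggregated DEG genes over every
#' (tissue, cell type); the default gene universe for annotation when no
#' protein-coding list is supplied.
#' @param map a `marker_map`.
#' @return Character vector of gene keys.
#' @export
map_genes <- function(map) {
  g <- unlist(lapply(map$tissues, function(t) {
    lapply(t$cell_types, function(ct) {
      c(names(ct$freq), if (!is.null(ct$degs)) ct$degs$gene)
    })
  }), use.names = FALSE)
  sort(unique(g))
}

#' Default specific-to-general cell-type mapping
#'
#' Maps every cell type in the map to its top-level lineage: the ancestor
#' that is a direct child of a root on its lineage path (itself when it
#' already is one, or a root).
#' @param map a `marker_map`.
#' @return Named character vector specific -> general.
#' @export
default_generalization <- function(map) {
  h <- map$cell_hierarchy
  cts <- unique(unlist(lapply(map$tissues, function(t) names(t$cell_types)),
                       use.names = FALSE))
  stats::setNames(vapply(cts, function(ct) {
    path <- lineage_path(h, ct)
    if (length(path) >= 2) path[2] else ct
  }, ""), cts)
}

#' Merge a marker map across tissues into a pan-tissue map
#'
#' For tissues with few curated studies, evidence can be pooled across
#' tissues. Specific cell types are first remapped to general ones (by
#' default their top-level lineage, so e.g. a lung-specific epithelial
#' subtype is counted under "epithelial cell"); a general cell type is then
#' retained only when it occurs in strictly more than `min_tissues` distinct
#' tissues and has strictly more than `min_entries` total entries. Retained
#' types get usage frequencies summed across tissues and DEG lists
#' re-aggregated over all contributing per-study lists.
#'
#' @param map a `marker_map` built by [build_marker_map()].
#' @param generalization named character vector specific -> general cell
#'   type; defaults to [default_generalization()].
#' @param min_tissues,min_entries strict lower bounds (defaults 2 and 5).
#' @return A `marker_map` with the single pseudo-tissue `"pan-tissue"`;
#'   possibly empty.
#' @export
build_pan_tissue_map <- function(map, generalization = NULL,
                                 min_tissues = 2, min_entries = 5) {
  gen <- generalization %||% default_generalization(map)
  acc <- list()  # general ct -> list(tissues, n_entries, freqs, deg_sources)
  for (t in names(map$tissues)) {
    for (ct in names(map$tissues[[t]]$cell_types)) {
      rec <- map$tissues[[t]]$cell_types[[ct]]
      g <- if (ct %in% names(gen)) unname(gen[ct]) else ct
      a <- acc[[g]] %||% list(tissues = character(), n_entries = 0L,
                              freqs = list(), deg_sources = list())
      a$tissues <- union(a$tissues, t)
      a$n_entries <- a$n_entries + rec$n_entries
      a$freqs <- c(a$freqs, list(rec$freq))
      a$deg_sources <- c(a$deg_sources, rec$deg_sources)
      acc[[g]] <- a
    }
  }
  keep <- names(acc)[vapply(acc, function(a) {
    length(a$tissues) > min_tissues && a$n_entries > min_entries
  }, NA)]
  if (length(keep) == 0) {
    return(structure(list(species = map$species,
                          cell_hierarchy = map$cell_hierarchy, tissues = list()),
                     class = "marker_map"))
  }
  cell_types <- list()
  for (g in sort(keep)) {
    a <- acc[[g]]
    all_genes <- unlist(a$freqs)
    tab <- tapply(as.integer(all_genes), names(all_genes), sum)
    freq <- stats::setNames(as.integer(tab), names(tab))
    freq <- freq[order(-freq, names(freq))]
    degs <- if (length(a$deg_sources) > 0) rra_aggregate(a$deg_sources) else NULL
    cell_types[[g]] <- list(freq = freq, degs = degs, n_entries = a$n_entries,
                            deg_sources = a$deg_sources)
  }
  structure(list(
    species = map$species, cell_hierarchy = map$cell_hierarchy,
    tissues = list("pan-tissue" = list(
      hierarchy = prune_hierarchy(map$cell_hierarchy, names(cell_types)),
      cell_types = cell_types))),
    class = "marker_map")
}

#' Write a marker map to TSV files
#'
#' Emits three tab-separated files under `prefix`: `<prefix>_markers.tsv`
#' (species, tissue, cell_type, gene, frequency), `<prefix>_degs.tsv`
#' (species, tissue, cell_type, gene, rank, adj_p) and
#' `<prefix>_hierarchy.tsv` (child_id, parent_id, child_name for the full
#' cell-type hierarchy).
#'
#' @param map a `marker_map`.
#' @param prefix output path prefix.
#' @return Invisibly, the three paths written.
#' @export
write_marker_map <- function(map, prefix) {
  mk <- list(); dg <- list()
  for (t in names(map$tissues)) {
    for (ct in names(map$tissues[[t]]$cell_types)) {
      rec <- map$tissues[[t]]$cell_types[[ct]]
      if (length(rec$freq) > 0) {
        mk[[length(mk) + 1]] <- data.frame(
          species = map$species, tissue = t, cell_type = ct,
          gene = gene_display(names(rec$freq), map$species),
          frequency = as.integer(rec$freq))
      }
      if (!is.null(rec$degs) && nrow(rec$degs) > 0) {
        dg[[length(dg) + 1]] <- data.frame(
          species = map$species, tissue = t, cell_type = ct,
          gene = gene_display(rec$degs$gene, map$species),
          rank = seq_len(nrow(rec$degs)),
          adj_p = signif(rec$degs$adj_p, 10))
      }
    }
  }
  empty_mk <- data.frame(species = character(), tissue = character(),
                         cell_type = character(), gene = character(),
                         frequency = integer())
  empty_dg <- data.frame(species = character(), tissue = character(),
                         cell_type = character(), gene = character(),
                         rank = integer(), adj_p = numeric())
  paths <- c(markers = paste0(prefix, "_markers.tsv"),
             degs = paste0(prefix, "_degs.tsv"),
             hierarchy = paste0(prefix, "_hierarchy.tsv"))
  write_tsv_atomic(if (length(mk)) do.call(rbind, mk) else empty_mk,
                   paths[["markers"]])
  write_tsv_atomic(if (length(dg)) do.call(rbind, dg) else empty_dg,
                   paths[["degs"]])
  write_hierarchy(map$cell_hierarchy, paths[["hierarchy"]])
  invisible(paths)
}

#' Read a marker map from TSV files
#'
#' Inverse of [write_marker_map()]. A map read from disk carries the
#' aggregated DEG lists only, so pan-tissue re-aggregation treats each
#' stored list as a single contributing list; entry counts are recovered as
#' the maximum usage frequency per cell type (a lower bound).
#'
#' @param markers_path canonical-marker map TSV.
#' @param hierarchy_path hierarchy edge-list TSV.
#' @param degs_path optional DEG map TSV.
#' @param species species label override; default taken from the file.
#' @return A `marker_map`.
#' @export
read_marker_map <- function(markers_path, hierarchy_path, degs_path = NULL,
                            species = NULL) {
  mk <- read_tsv_checked(markers_path,
                         required = c("species", "tissue", "cell_type",
                                      "gene", "frequency"))
  hier <- read_hierarchy(hierarchy_path)
  dg <- NULL
  if (!is.null(degs_path) && file.exists(degs_path)) {
    dg <- read_tsv_checked(degs_path,
                           required = c("species", "tissue", "cell_type",
                                        "gene", "rank", "adj_p"))
  }
  species <- species %||% (if (nrow(mk) > 0) mk$species[1] else "human")
  tissues <- list()
  keys <- unique(rbind(mk[c("tissue", "cell_type")],
                       if (!is.null(dg)) dg[c("tissue", "cell_type")]))
  for (t in sort(unique(keys$tissue))) {
    cts <- sort(unique(keys$cell_type[keys$tissue == t]))
    cell_types <- list()
    for (ct in cts) {
      sel <- mk$tissue == t & mk$cell_type == ct
      freq <- stats::setNames(as.integer(mk$frequency[sel]),
                              gene_key(mk$gene[sel]))
      freq <- freq[order(-freq, names(freq))]
      degs <- NULL
      deg_sources <- list()
      if (!is.null(dg)) {
        dsel <- dg$tissue == t & dg$cell_type == ct
        if (any(dsel)) {
          ord <- order(as.integer(dg$rank[dsel]))
          degs <- data.frame(gene = gene_key(dg$gene[dsel])[ord],
                             p = NA_real_,
                             adj_p = as.numeric(dg$adj_p[dsel])[ord],
                             stringsAsFactors = FALSE)
          deg_sources <- list(degs$gene)
        }
      }
      cell_types[[ct]] <- list(
        freq = freq, degs = degs,
        n_entries = if (length(freq) > 0) max(freq) else 1L,
        deg_sources = deg_sources)
    }
    tissues[[t]] <- list(hierarchy = prune_hierarchy(hier, cts),
                         cell_types = cell_types)
  }
  structure(list(species = species, cell_hierarchy = hier, tissues = tissues),
            class = "marker_map")
}
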