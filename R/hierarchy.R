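#' Cell-type / tissue hierarchies
#'
#' A hierarchy is a rooted directed acyclic graph of ontology-style terms
#' (cell types or tissues) with child-to-parent edges, as extracted from the
#' Cell Ontology or Uberon. Roots are nodes without parents. Ancestor and
#' descendant queries are reflexive-transitive: every node is its own
#' ancestor and descendant.
#'
#' @param edges data.frame with columns `child` and `parent` (term ids);
#'   rows with an empty/NA `parent` declare explicit roots.
#' @param labels optional named character vector of display names keyed by id.
#' @return An object of class `cell_hierarchy` with elements `nodes`,
#'   `parents` (named list), `children` (named list), `roots` and `labels`.
#' @examples
#' h <- cell_hierarchy(data.frame(
#'   child = c("B cell", "memory B cell"),
#'   parent = c("lymphocyte", "B cell")))
#' ancestors(h, "memory B cell")
#' @export
cell_hierarchy <- function(edges, labels = NULL) {
  stopifnot(is.data.frame(edges), all(c("child", "parent") %in% names(edges)))
  child <- as.character(edges$child)
  parent <- as.character(edges$parent)
  keep <- nzchar(child) & !is.na(child)
  child <- child[keep]
  parent <- parent[keep]
  real <- !is.na(parent) & nzchar(parent)
  nodes <- unique(c(child, parent[real]))

  parents <- split(parent[real], child[real])
  parents <- lapply(parents, unique)
  children <- split(child[real], parent[real])
  children <- lapply(children, unique)
  roots <- setdiff(nodes, names(parents))
  if (length(nodes) > 0 && length(roots) == 0) {
    stop("hierarchy has no roots (cycle over all nodes?)", call. = FALSE)
  }
  if (any(real)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = child[real], to = parent[real]),
      directed = TRUE, vertices = nodes)
    if (!igraph::is_dag(g)) stop("hierarchy contains a cycle", call. = FALSE)
  }
  lab <- stats::setNames(nodes, nodes)
  if (!is.null(labels)) lab[names(labels)] <- labels
  structure(list(nodes = nodes, parents = parents, children = children,
                 roots = roots, labels = lab),
            class = "cell_hierarchy")
}

#' @export
print.cell_hierarchy <- function(x, ...) {
  cat("<cell_hierarchy> ", length(x$nodes), " nodes, ",
      length(x$roots), " root(s): ",
      paste(utils::head(x$roots, 5), collapse = ", "), "\n", sep = "")
  invisible(x)
}

walk_closure <- function(h, id, link) {
  if (!id %in% h$nodes) return(character())
  seen <- id
  frontier <- id
  while (length(frontier) > 0) {
    nxt <- unique(unlist(h[[link]][frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Ancestors of a node (reflexive)
#'
#' @param h a `cell_hierarchy`.
#' @param id node id.
#' @return Character vector of ids: the node itself plus everything reachable
#'   through child-to-parent edges.
#' @export
ancestors <- function(h, id) walk_closure(h, id, "parents")

#' Descendants of a node (reflexive)
#' @inheritParams ancestors
#' @export
descendants <- function(h, id) walk_closure(h, id, "children")

#' @keywords internal
#' @noRd
reaches_root <- function(h, id) any(ancestors(h, id) %in% h$roots)

#' Root-to-node lineage path
#'
#' Follows the first recorded parent at each step; returns ids ordered from a
#' root down to `id`.
#' @inheritParams ancestors
#' @export
lineage_path <- function(h, id) {
  if (!id %in% h$nodes) return(character())
  path <- id
  cur <- id
  while (!cur %in% h$roots) {
    ps <- h$parents[[cur]]
    if (is.null(ps) || length(ps) == 0) break
    cur <- sort(ps)[1]
    if (cur %in% path) break
    path <- c(cur, path)
  }
  path
}

#' Prune a hierarchy to a recorded node set
#'
#' Retains only the nodes in `keep` plus the roots they reach; every retained
#' node is re-attached to its nearest retained proper ancestor, so children
#' whose parents carry no recorded entries are connected to the closest
#' recorded (or root) ancestor. The result stays acyclic and every retained
#' node still reaches a root.
#'
#' @param h a `cell_hierarchy`.
#' @param keep character vector of node ids to retain.
#' @return A pruned `cell_hierarchy`.
#' @export
prune_hierarchy <- function(h, keep) {
  keep <- intersect(unique(keep), h$nodes)
  roots_kept <- unique(unlist(lapply(keep, function(id) {
    intersect(ancestors(h, id), h$roots)
  }), use.names = FALSE))
  retained <- unique(c(keep, roots_kept))
  edges <- data.frame(child = character(), parent = character())
  for (id in setdiff(retained, h$roots)) {
    # BFS upward, stopping each branch at the first retained ancestor
    new_parents <- character()
    frontier <- h$parents[[id]]
    seen <- id
    while (length(frontier) > 0) {
      frontier <- setdiff(unique(frontier), seen)
      seen <- c(seen, frontier)
      hit <- intersect(frontier, retained)
      new_parents <- c(new_parents, hit)
      frontier <- unlist(h$parents[setdiff(frontier, hit)], use.names = FALSE)
    }
    if (length(new_parents) > 0) {
      edges <- rbind(edges, data.frame(child = id, parent = unique(new_parents)))
    }
  }
  # explicit root rows keep isolated retained roots in the node set
  if (length(retained) > 0) {
    root_rows <- data.frame(child = intersect(retained, h$roots), parent = NA_character_)
    edges <- rbind(edges, root_rows)
  }
  cell_hierarchy(edges, labels = h$labels[intersect(names(h$labels), retained)])
}

#' Read a hierarchy from an edge-list TSV
#'
#' Expects tab-separated columns `child_id`, `parent_id` and optionally
#' `child_name`; an empty `parent_id` marks a root.
#' @param path file path.
#' @return A `cell_hierarchy`.
#' @export
read_hierarchy <- function(path) {
  df <- read_tsv_checked(path, required = c("child_id", "parent_id"))
  labels <- NULL
  if ("child_name" %in% names(df)) {
    has <- nzchar(df$child_name)
    labels <- stats::setNames(df$child_name[has], df$child_id[has])
  }
  cell_hierarchy(data.frame(child = df$child_id, parent = df$parent_id),
                 labels = labels)
}

#' Write a hierarchy as an edge-list TSV
#' @param h a `cell_hierarchy`.
#' @param path output file path.
#' @export
write_hierarchy <- function(h, path) {
  rows <- lapply(sort(h$nodes), function(id) {
    ps <- h$parents[[id]]
    if (is.null(ps) || length(ps) == 0) ps <- ""
    data.frame(child_id = id, parent_id = sort(ps),
               child_name = unname(h$labels[id]))
  })
  write_tsv_atomic(do.call(rbind, rows), path)
}

#' Read a minimal OBO file into a hierarchy
#'
#' Convenience reader for Cell Ontology / Uberon style OBO stanzas, limited
#' to the `id`, `name` and `is_a` tags; everything else is ignored. Obsolete
#' terms are skipped.
#' @param path OBO file path.
#' @return A `cell_hierarchy`.
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  term_starts <- which(lines == "[Term]")
  edges <- list()
  labels <- character()
  for (i in seq_along(term_starts)) {
    from <- term_starts[i] + 1L
    to <- if (i < length(term_starts)) term_starts[i + 1] - 1L else length(lines)
    block <- lines[from:to]
    block <- block[!grepl("^\\[", block)]
    get_tag <- function(tag) {
      v <- sub(paste0("^", tag, ":\\s*"), "", grep(paste0("^", tag, ":"), block, value = TRUE))
      sub("\\s*(!.*)?$", "", v)
    }
    if (length(get_tag("is_obsolete")) > 0) next
    id <- get_tag("id")[1]
    if (is.na(id) || !nzchar(id)) next
    nm <- get_tag("name")
    if (length(nm) > 0) labels[id] <- nm[1]
    isa <- get_tag("is_a")
    if (length(isa) > 0) {
      edges[[length(edges) + 1]] <- data.frame(child = id, parent = isa)
    } else {
      edges[[length(edges) + 1]] <- data.frame(child = id, parent = NA_character_)
    }
  }
  if (length(edges) == 0) stop("no [Term] stanzas in ", path, call. = FALSE)
  cell_hierarchy(do.call(rbind, edges), labels = labels)
}
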