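#' Annotate one cluster's gene list against a marker map
#'
#' The core annotation routine. The query is a cluster's ordered
#' differentially upregulated genes (DUGs), truncated to `max_genes` (top 30
#' by default, which is sufficient in practice). For every cell type
#' recorded under the tissue, the weighted hypergeometric p-value against
#' its canonical markers and the positive-side pre-ranked GSEA p-value
#' against its aggregated DEG list are combined by Fisher's method; combined
#' p-values are Benjamini-Hochberg adjusted across the cell types tested for
#' this cluster and ranked ascending, ties broken by raw combined p, then
#' larger total overlap, then cell-type id. Each returned row carries the
#' overlap genes partitioned by provenance: canonical markers only, DEG list
#' only, or both. A cluster is flagged unassigned only when no cell type
#' shares any gene with the query.
#'
#' @param query ordered character vector of gene symbols (most upregulated
#'   first).
#' @param map a `marker_map`.
#' @param tissue tissue id present in the map (use `"pan-tissue"` with a
#'   pan-tissue map).
#' @param universe optional gene universe (protein-coding symbols); default
#'   is every gene recorded in the map.
#' @param top_k number of top-ranked cell types to return, 1 or 10.
#' @param max_genes query truncation limit (default 30).
#' @param Q weight power scaling factor (default 3).
#' @param n_perm GSEA permutations (default 1000).
#' @param seed GSEA permutation seed (default 0).
#' @param cluster cluster id used in the output.
#' @return data.frame with one row per reported cell type: `cluster`,
#'   `rank`, `cell_type`, `lineage_path`, `p_whg`, `es`, `nes`, `p_gsea`,
#'   `p_combined`, `p_adj`, `overlap_canonical`, `overlap_deg`,
#'   `overlap_both`, `unassigned`. Zero ranked rows (a single unassigned
#'   row) when nothing overlaps.
#' @export
annotate_cluster <- function(query, map, tissue, universe = NULL,
                             top_k = 1, max_genes = 30, Q = 3,
                             n_perm = 1000, seed = 0, cluster = "cluster1") {
  if (!top_k %in% c(1, 10)) stop("top_k must be 1 or 10", call. = FALSE)
  if (!tissue %in% names(map$tissues)) {
    stop("unknown tissue '", tissue, "'; available: ",
         paste(names(map$tissues), collapse = ", "), call. = FALSE)
  }
  x <- gene_key(as.character(query))
  x <- x[!duplicated(x)]
  if (length(x) == 0) stop("empty query gene list", call. = FALSE)
  x <- utils::head(x, max_genes)

  universe <- gene_key(universe %||% map_genes(map))
  universe <- union(universe, x)  # queries are genes; keep them testable

  trec <- map$tissues[[tissue]]
  hier <- trec$hierarchy
  rows <- list()
  for (ct in names(trec$cell_types)) {
    rec <- trec$cell_types[[ct]]
    canon <- intersect(x, names(rec$freq))
    deg_genes <- if (!is.null(rec$degs)) rec$degs$gene else character()
    indeg <- intersect(x, deg_genes)
    p_whg <- NA_real_
    if (length(rec$freq) > 0) {
      wu <- suppressWarnings(normalize_weights(universe, rec$freq))
      p_whg <- whg_pvalue(x, rec$freq, wu, Q = Q)
    }
    gs <- if (!is.null(rec$degs)) {
      gsea_pvalue(x, rec$degs, n_perm = n_perm, seed = seed)
    } else NULL
    p_comb <- if (is.na(p_whg)) {
      if (is.null(gs)) NA_real_ else gs$p
    } else {
      fisher_combine(p_whg, if (is.null(gs)) NULL else gs$p)
    }
    both <- intersect(canon, indeg)
    rows[[ct]] <- data.frame(
      cluster = cluster, cell_type = ct,
      lineage_path = paste(lineage_path(hier, ct), collapse = " > "),
      p_whg = p_whg,
      es = if (is.null(gs)) NA_real_ else gs$es,
      nes = if (is.null(gs)) NA_real_ else gs$nes,
      p_gsea = if (is.null(gs)) NA_real_ else gs$p,
      p_combined = p_comb,
      overlap_canonical = paste(gene_display(sort(setdiff(canon, both)), map$species),
                                collapse = ";"),
      overlap_deg = paste(gene_display(sort(setdiff(indeg, both)), map$species),
                          collapse = ";"),
      overlap_both = paste(gene_display(sort(both), map$species), collapse = ";"),
      n_overlap = length(union(canon, indeg)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  if (is.null(res) || all(res$n_overlap == 0) || all(is.na(res$p_combined))) {
    out <- empty_report_row(cluster)
    return(out)
  }
  res <- res[!is.na(res$p_combined), , drop = FALSE]
  res$p_adj <- bh_adjust(res$p_combined)
  ord <- order(res$p_adj, res$p_combined, -res$n_overlap, res$cell_type)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  res$unassigned <- FALSE
  res <- utils::head(res, top_k)
  rownames(res) <- NULL
  res[report_columns()]
}

report_columns <- function() {
  c("cluster", "rank", "cell_type", "lineage_path", "p_whg", "es", "nes",
    "p_gsea", "p_combined", "p_adj", "overlap_canonical", "overlap_deg",
    "overlap_both", "unassigned")
}

empty_report_row <- function(cluster) {
  data.frame(cluster = cluster, rank = NA_integer_,
             cell_type = "unassigned", lineage_path = "",
             p_whg = NA_real_, es = NA_real_, nes = NA_real_,
             p_gsea = NA_real_, p_combined = NA_real_, p_adj = NA_real_,
             overlap_canonical = "", overlap_deg = "", overlap_both = "",
             unassigned = TRUE, stringsAsFactors = FALSE)
}

#' Annotate many clusters
#'
#' Applies [annotate_cluster()] to a named list of query gene lists and
#' binds the per-cluster report blocks.
#' @param queries named list of ordered gene-symbol vectors.
#' @inheritParams annotate_cluster
#' @return data.frame of report rows for all clusters.
#' @export
annotate_clusters <- function(queries, map, tissue, universe = NULL,
                              top_k = 1, max_genes = 30, Q = 3,
                              n_perm = 1000, seed = 0) {
  stopifnot(length(queries) > 0)
  ids <- names(queries) %||% paste0("cluster", seq_along(queries))
  if (is.null(names(queries))) names(queries) <- ids
  out <- lapply(ids, function(id) {
    annotate_cluster(queries[[id]], map, tissue, universe = universe,
                     top_k = top_k, max_genes = max_genes, Q = Q,
                     n_perm = n_perm, seed = seed, cluster = id)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write an annotation report as TSV plus a JSON mirror
#'
#' @param report data.frame from [annotate_clusters()].
#' @param path TSV output path; the JSON mirror is written next to it with
#'   extension `.json`.
#' @return Invisibly, the two paths.
#' @export
write_report <- function(report, path) {
  fmt <- report
  for (col in c("p_whg", "es", "nes", "p_gsea", "p_combined", "p_adj")) {
    fmt[[col]] <- ifelse(is.na(report[[col]]), "",
                         formatC(report[[col]], digits = 6, format = "g"))
  }
  write_tsv_atomic(fmt, path)
  json_path <- sub("\\.[^.]*$", "", path)
  json_path <- paste0(json_path, ".json")
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  jsonlite::write_json(report, tmp, dataframe = "rows", na = "null",
                       digits = NA, pretty = TRUE)
  file.rename(tmp, json_path)
  invisible(c(tsv = path, json = json_path))
}

#' Read cluster query gene lists
#'
#' Two input layouts are accepted. Plain text: one gene symbol per line in
#' ranked order, with optional `>cluster` section headers separating
#' clusters (a headerless file is a single cluster). Table: a tab-separated
#' file whose header contains `cluster` and `gene` columns (FindAllMarkers
#' style); genes are taken per cluster in file order, which is assumed
#' ranked, optionally re-ordered by a numeric `avg_log2FC` column
#' decreasing when present.
#'
#' @param path input file.
#' @return Named list of ordered gene-symbol vectors.
#' @export
read_queries <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1, warn = FALSE)
  if (grepl("\t", first) && grepl("cluster", tolower(first)) &&
      grepl("gene", tolower(first))) {
    df <- read_tsv_checked(path, required = character())
    names(df) <- tolower(names(df))
    if (!all(c("cluster", "gene") %in% names(df))) {
      stop("query table needs 'cluster' and 'gene' columns", call. = FALSE)
    }
    if ("avg_log2fc" %in% names(df)) {
      df <- df[order(df$cluster, -as.numeric(df$avg_log2fc)), ]
    }
    return(split(df$gene, df$cluster))
  }
  lines <- trimws(readLines(path, warn = FALSE))
  queries <- list()
  current <- "cluster1"
  for (i in seq_along(lines)) {
    l <- lines[i]
    if (!nzchar(l) || startsWith(l, "#")) next
    if (startsWith(l, ">")) {
      current <- trimws(sub("^>", "", l))
      if (!nzchar(current)) {
        stop("line ", i, ": empty cluster header", call. = FALSE)
      }
      next
    }
    if (grepl("\\s", l)) {
      stop("line ", i, ": expected one gene symbol per line, got '", l, "'",
           call. = FALSE)
    }
    queries[[current]] <- c(queries[[current]], l)
  }
  if (length(queries) == 0) stop("no genes found in ", path, call. = FALSE)
  queries
}
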