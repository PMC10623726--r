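#' Load raw cell-marker entries from TSV
#'
#' One row per curated study entry. Required tab-separated columns:
#' `species`, `tissue`, `cell_type`, `markers` (semicolon-separated canonical
#' marker symbols), `degs` (semicolon-separated DEG symbols ordered from most
#' to least significant) and `source_id`. Duplicate genes within a field are
#' collapsed keeping the first occurrence. Rows where both `markers` and
#' `degs` are empty violate the entry invariant and are rejected; their row
#' numbers are reported in the error.
#'
#' @param path TSV file path.
#' @param synonyms optional named character vector mapping raw gene symbols to
#'   standard symbols (applied after case-normalisation).
#' @return A list of `marker_entry` objects, each a list with fields
#'   `species`, `tissue`, `cell_type`, `canonical_markers`, `deg_list`,
#'   `source_id`.
#' @export
load_marker_entries <- function(path, synonyms = NULL) {
  df <- read_tsv_checked(path, required = c("species", "tissue", "cell_type",
                                            "markers", "degs", "source_id"))
  if (nrow(df) == 0) {
    warning("no marker entries in ", path)
    return(list())
  }
  std <- function(genes) {
    k <- gene_key(genes)
    if (!is.null(synonyms)) {
      syn <- stats::setNames(gene_key(synonyms), gene_key(names(synonyms)))
      hit <- k %in% names(syn)
      k[hit] <- unname(syn[k[hit]])
    }
    k[!duplicated(k)]
  }
  entries <- vector("list", nrow(df))
  bad <- integer()
  for (i in seq_len(nrow(df))) {
    markers <- std(split_genes(df$markers[i]))
    degs <- std(split_genes(df$degs[i]))
    if (length(markers) == 0 && length(degs) == 0) {
      bad <- c(bad, i)
      next
    }
    entries[[i]] <- marker_entry(species = df$species[i], tissue = df$tissue[i],
                                 cell_type = df$cell_type[i],
                                 canonical_markers = markers, deg_list = degs,
                                 source_id = df$source_id[i])
  }
  if (length(bad) > 0) {
    warning("rejected ", length(bad), " row(s) with neither markers nor DEGs: row ",
            paste(bad, collapse = ", "))
  }
  Filter(Negate(is.null), entries)
}

#' Construct a single marker entry
#'
#' @param species `"human"` or `"mouse"`.
#' @param tissue,cell_type standardized term ids.
#' @param canonical_markers character vector of marker symbols (no duplicates).
#' @param deg_list ordered character vector of DEG symbols, may be empty.
#' @param source_id free-text study identifier.
#' @export
marker_entry <- function(species, tissue, cell_type,
                         canonical_markers = character(),
                         deg_list = character(), source_id = "") {
  canonical_markers <- canonical_markers[!duplicated(gene_key(canonical_markers))]
  deg_list <- deg_list[!duplicated(gene_key(deg_list))]
  if (length(canonical_markers) == 0 && length(deg_list) == 0) {
    stop("marker entry needs at least one canonical marker or DEG", call. = FALSE)
  }
  structure(list(species = species, tissue = tissue, cell_type = cell_type,
                 canonical_markers = gene_key(canonical_markers),
                 deg_list = gene_key(deg_list), source_id = source_id),
            class = "marker_entry")
}

#' Aggregate canonical markers into a usage-frequency table
#'
#' Takes the union of canonical markers across all entries for one
#' (tissue, cell type) pair; the frequency of a gene is the number of entries
#' whose canonical marker list contains it (each entry counts a gene at most
#' once). High frequency means the marker is widely used to identify this
#' cell type and earns it a larger weight in the enrichment test.
#'
#' @param entries list of `marker_entry`.
#' @param tissue,cell_type the pair to aggregate; `NULL` keeps all entries.
#' @return Named integer vector gene -> frequency (a frequency table).
#' @export
aggregate_canonical <- function(entries, tissue = NULL, cell_type = NULL) {
  sel <- Filter(function(e) {
    (is.null(tissue) || identical(e$tissue, tissue)) &&
      (is.null(cell_type) || identical(e$cell_type, cell_type))
  }, entries)
  markers <- unlist(lapply(sel, function(e) unique(e$canonical_markers)),
                    use.names = FALSE)
  if (length(markers) == 0) {
    warning("no canonical markers for (", tissue, ", ", cell_type, ")")
    return(stats::setNames(integer(), character()))
  }
  tab <- table(markers)
  freq <- stats::setNames(as.integer(tab), names(tab))
  freq[order(-freq, names(freq))]
}
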