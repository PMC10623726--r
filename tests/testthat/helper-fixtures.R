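# Small hand-built objects shared across tests.

# lymphocyte tree: cell -> {B cell, T cell}; B cell -> memory B cell
toy_hierarchy <- function() {
  cell_hierarchy(data.frame(
    child = c("B cell", "T cell", "memory B cell"),
    parent = c("cell", "cell", "B cell")))
}

# two blood cell types with distinct markers and short DEG lists
toy_entries <- function() {
  list(
    marker_entry("human", "blood", "B cell",
                 canonical_markers = c("CD79A", "MS4A1"),
                 deg_list = c("MS4A1", "CD79B", "CD19"), source_id = "s1"),
    marker_entry("human", "blood", "B cell",
                 canonical_markers = c("MS4A1", "CD19"),
                 deg_list = c("CD79A", "MS4A1", "CD19"), source_id = "s2"),
    marker_entry("human", "blood", "T cell",
                 canonical_markers = c("CD3D", "CD3E"),
                 deg_list = c("CD3D", "CD3E", "IL7R"), source_id = "s3"))
}

toy_map <- function() build_marker_map(toy_entries(), toy_hierarchy())

write_entries_tsv <- function(rows, path) {
  header <- "species\ttissue\tcell_type\tmarkers\tdegs\tsource_id"
  writeLines(c(header, rows), path)
  path
}

# exhaustive classical hypergeometric tail P(overlap > k): enumerate every
# draw of size n from a universe of size N containing m marked genes
enum_hyper_tail <- function(N, n, m, k) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= m) > k)
}

# independent ES route used as an oracle: explicit step-by-step running sum
es_brute <- function(hit_logical) {
  l <- length(hit_logical)
  h <- sum(hit_logical)
  step <- ifelse(hit_logical, 1 / h, -1 / (l - h))
  run <- cumsum(step)
  run[which.max(abs(run))]
}
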