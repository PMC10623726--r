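test_that("marker entry TSV parsing collapses duplicates and rejects empty rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_entries_tsv(c(
    "human\tblood\tB cell\tCD79A;MS4A1\tMS4A1;CD79B\ts1",
    "human\tblood\tB cell\t\t\ts2",
    "human\tblood\tT cell\tCD3D;CD3D\t\ts3"), path)
  expect_warning(entries <- load_marker_entries(path), "rejected 1 row")
  expect_length(entries, 2)
  expect_equal(entries[[1]]$canonical_markers, c("CD79A", "MS4A1"))
  expect_equal(entries[[1]]$deg_list, c("MS4A1", "CD79B"))
  expect_equal(entries[[2]]$canonical_markers, "CD3D")  # duplicate collapsed

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("species\ttissue\tmarkers\tdegs\tsource_id", bad)
  expect_error(load_marker_entries(bad), "cell_type")
})

test_that("synonym table standardises symbols after case normalisation", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_entries_tsv("human\tblood\tB cell\tcd79a;B220\t\ts1", path)
  entries <- load_marker_entries(path, synonyms = c(B220 = "PTPRC"))
  expect_setequal(entries[[1]]$canonical_markers, c("CD79A", "PTPRC"))
})

test_that("canonical aggregation counts usage across entries", {
  entries <- toy_entries()
  freq <- aggregate_canonical(entries, "blood", "B cell")
  expect_equal(freq[["MS4A1"]], 2L)
  expect_equal(freq[["CD79A"]], 1L)
  expect_equal(freq[["CD19"]], 1L)
  # frequency conservation: total equals entry-gene mentions
  mentions <- sum(lengths(lapply(
    Filter(function(e) e$cell_type == "B cell", entries),
    `[[`, "canonical_markers")))
  expect_equal(sum(freq), mentions)
  expect_warning(empty <- aggregate_canonical(entries, "blood", "NK cell"),
                 "no canonical markers")
  expect_length(empty, 0)
})

test_that("map construction aggregates per key and prunes per-tissue hierarchies", {
  map <- toy_map()
  expect_named(map$tissues, "blood")
  cts <- map$tissues$blood$cell_types
  expect_setequal(names(cts), c("B cell", "T cell"))
  expect_equal(cts[["B cell"]]$n_entries, 2L)
  expect_true(all(c("B cell", "T cell", "cell") %in%
                    map$tissues$blood$hierarchy$nodes))
  expect_false("memory B cell" %in% map$tissues$blood$hierarchy$nodes)
  # single-list DEG aggregation is present and ordered
  expect_true(!is.null(cts[["T cell"]]$degs))
  expect_error(
    build_marker_map(list(marker_entry("human", "blood", "NK cell",
                                       canonical_markers = "NKG7")),
                     toy_hierarchy()),
    "NK cell")
  empty <- build_marker_map(list(), toy_hierarchy())
  expect_length(empty$tissues, 0)
})

test_that("marker map TSV round-trip preserves frequencies and DEG order", {
  map <- toy_map()
  prefix <- file.path(withr::local_tempdir(), "map")
  paths <- write_marker_map(map, prefix)
  map2 <- read_marker_map(paths[["markers"]], paths[["hierarchy"]],
                          paths[["degs"]])
  f1 <- map$tissues$blood$cell_types[["B cell"]]$freq
  f2 <- map2$tissues$blood$cell_types[["B cell"]]$freq
  expect_equal(f2[names(f1)], f1)
  expect_equal(map2$tissues$blood$cell_types[["T cell"]]$degs$gene,
               map$tissues$blood$cell_types[["T cell"]]$degs$gene)
})

make_pan_entries <- function(tissues, n_per_tissue, ct = "epithelial cell") {
  unlist(lapply(tissues, function(t) {
    lapply(seq_len(n_per_tissue), function(i) {
      marker_entry("human", t, ct, canonical_markers = c("EPCAM", "KRT18"),
                   source_id = paste0(t, i))
    })
  }), recursive = FALSE)
}

pan_hier <- cell_hierarchy(data.frame(
  child = c("epithelial cell", "epithelial cell of lung"),
  parent = c("cell", "epithelial cell")))

test_that("pan-tissue filters are strict: > 2 tissues and > 5 entries", {
  # 2 tissues, 10 entries: excluded (needs strictly more than two tissues)
  m2 <- build_marker_map(make_pan_entries(c("lung", "liver"), 5), pan_hier)
  expect_length(build_pan_tissue_map(m2)$tissues, 0)
  # 3 tissues, 6 entries: included
  m3 <- build_marker_map(make_pan_entries(c("lung", "liver", "gut"), 2), pan_hier)
  pan <- build_pan_tissue_map(m3)
  expect_named(pan$tissues, "pan-tissue")
  rec <- pan$tissues[["pan-tissue"]]$cell_types[["epithelial cell"]]
  expect_equal(rec$n_entries, 6L)
  expect_equal(rec$freq[["EPCAM"]], 6L)  # summed across tissues
  # 3 tissues, 5 entries: excluded (needs strictly more than 5 entries)
  m5 <- build_marker_map(c(make_pan_entries(c("lung", "liver"), 2),
                           make_pan_entries("gut", 1)), pan_hier)
  expect_length(build_pan_tissue_map(m5)$tissues, 0)
})

test_that("specific cell types fold into their general type before filtering", {
  entries <- c(make_pan_entries(c("liver", "gut"), 2, ct = "epithelial cell"),
               make_pan_entries("lung", 3, ct = "epithelial cell of lung"))
  map <- build_marker_map(entries, pan_hier)
  pan <- build_pan_tissue_map(map)
  cts <- names(pan$tissues[["pan-tissue"]]$cell_types)
  expect_equal(cts, "epithelial cell")
  expect_equal(pan$tissues[["pan-tissue"]]$cell_types[[1]]$n_entries, 7L)
})

test_that("pan-tissue inclusion is monotone in the entry set", {
  full <- make_pan_entries(c("lung", "liver", "gut"), 3)
  pan_full <- build_pan_tissue_map(build_marker_map(full, pan_hier))
  for (drop in seq(1, 6, by = 2)) {
    sub <- full[-seq_len(drop)]
    pan_sub <- build_pan_tissue_map(build_marker_map(sub, pan_hier))
    kept_sub <- names(pan_sub$tissues[["pan-tissue"]]$cell_types)
    kept_full <- names(pan_full$tissues[["pan-tissue"]]$cell_types)
    expect_true(all(kept_sub %in% kept_full))
  }
})
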