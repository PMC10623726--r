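test_that("a query matching one cell type's markers ranks that type first", {
  map <- toy_map()
  rep <- annotate_cluster(c("CD79A", "MS4A1", "CD19"), map, "blood",
                          n_perm = 100, seed = 0)
  expect_equal(rep$cell_type, "B cell")
  expect_equal(rep$rank, 1L)
  expect_false(rep$unassigned)
  expect_equal(rep$lineage_path, "cell > B cell")
  # enumeration on the fixture map: B cell overlap 3/3, T cell 0 => the
  # hypergeometric tail for B cell is strictly the smallest
  rep10 <- annotate_cluster(c("CD79A", "MS4A1", "CD19"), map, "blood",
                            top_k = 10, n_perm = 100, seed = 0)
  expect_lt(rep10$p_combined[rep10$cell_type == "B cell"],
            rep10$p_combined[rep10$cell_type == "T cell"])
  expect_true(all(rep10$p_adj >= rep10$p_combined - 1e-15))
  expect_true(all(rep10$p_combined > 0 & rep10$p_combined <= 1))
})

test_that("zero overlap everywhere flags the cluster unassigned", {
  map <- toy_map()
  rep <- annotate_cluster(c("FOXA2", "ALB", "TTR"), map, "blood",
                          n_perm = 100, seed = 0)
  expect_true(rep$unassigned)
  expect_equal(rep$cell_type, "unassigned")
  expect_true(is.na(rep$rank))
})

test_that("overlap provenance partitions canonical-only, DEG-only and both", {
  map <- toy_map()
  # MS4A1 is canonical and in the DEG list; CD79B is DEG-only; CD79A has
  # canonical plus DEG membership via entry s2
  rep <- annotate_cluster(c("MS4A1", "CD79B"), map, "blood",
                          n_perm = 100, seed = 0)
  expect_equal(rep$overlap_both, "MS4A1")
  expect_equal(rep$overlap_deg, "CD79B")
  expect_equal(rep$overlap_canonical, "")
  parts <- unlist(strsplit(c(rep$overlap_canonical, rep$overlap_deg,
                             rep$overlap_both), ";"))
  expect_false(any(duplicated(parts[nzchar(parts)])))
})

test_that("argument validation covers tissue, query and top_k", {
  map <- toy_map()
  expect_error(annotate_cluster("CD79A", map, "brain"), "blood")
  expect_error(annotate_cluster(character(), map, "blood"), "empty query")
  expect_error(annotate_cluster("CD79A", map, "blood", top_k = 3), "1 or 10")
})

test_that("queries are truncated to the top max_genes before testing", {
  map <- toy_map()
  long_query <- c(paste0("FAKE", 1:30), "CD79A", "MS4A1")  # markers past the cap
  rep <- annotate_cluster(long_query, map, "blood", max_genes = 30,
                          n_perm = 100, seed = 0)
  expect_true(rep$unassigned)
})

test_that("multi-cluster annotation emits one block per cluster and writes reports", {
  map <- toy_map()
  queries <- list(c1 = c("CD79A", "MS4A1"), c2 = c("CD3D", "CD3E"),
                  c3 = c("ALB", "TTR"))
  rep <- annotate_clusters(queries, map, "blood", n_perm = 100, seed = 0)
  expect_equal(nrow(rep), 3)
  expect_equal(rep$cluster, c("c1", "c2", "c3"))
  expect_equal(rep$cell_type[1:2], c("B cell", "T cell"))
  expect_true(rep$unassigned[3])

  out <- file.path(withr::local_tempdir(), "report.tsv")
  paths <- write_report(rep, out)
  expect_true(file.exists(paths[["tsv"]]))
  expect_true(file.exists(paths[["json"]]))
  back <- utils::read.delim(paths[["tsv"]])
  expect_equal(nrow(back), 3)
  js <- jsonlite::read_json(paths[["json"]])
  expect_length(js, 3)
})

test_that("query readers accept sectioned plain text and marker tables", {
  dir <- withr::local_tempdir()
  plain <- file.path(dir, "q.txt")
  writeLines(c(">c1", "CD79A", "MS4A1", ">c2", "CD3D"), plain)
  q <- read_queries(plain)
  expect_named(q, c("c1", "c2"))
  expect_equal(q$c1, c("CD79A", "MS4A1"))

  single <- file.path(dir, "s.txt")
  writeLines(c("CD79A", "MS4A1"), single)
  expect_named(read_queries(single), "cluster1")

  tab <- file.path(dir, "t.tsv")
  writeLines(c("cluster\tgene\tavg_log2FC",
               "c1\tMS4A1\t1.0", "c1\tCD79A\t2.5", "c2\tCD3D\t1.1"), tab)
  qt <- read_queries(tab)
  expect_equal(qt$c1, c("CD79A", "MS4A1"))  # reordered by fold change

  bad <- file.path(dir, "bad.txt")
  writeLines(c("CD79A", "two tokens"), bad)
  expect_error(read_queries(bad), "line 2")
})
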