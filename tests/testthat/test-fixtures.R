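test_that("the generator is deterministic and writes byte-identical files", {
  spec <- fixture_spec(seed = 4, n_genes = 300, n_cell_types = 8,
                       deg_len = c(20, 40))
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  write_fixture(d1, spec, n_queries = 6)
  write_fixture(d2, spec, n_queries = 6)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  e1 <- generate_entries(spec)
  e2 <- generate_entries(spec)
  expect_identical(e1, e2)
})

test_that("zero sibling overlap yields pairwise-disjoint core marker sets", {
  spec <- fixture_spec(seed = 2, n_genes = 500, n_cell_types = 10,
                       sibling_overlap = 0, depth = 2)
  gen <- generate_map(spec)
  cts <- gen$map$tissues$tissue1$cell_types
  cores <- lapply(cts, function(x) names(x$freq))
  for (i in seq_along(cores)) {
    for (j in seq_len(i - 1)) {
      expect_length(intersect(cores[[i]], cores[[j]]), 0)
    }
  }
})

test_that("tree depth controls the number of proper ancestors of leaves", {
  spec <- fixture_spec(seed = 6, n_genes = 600, n_cell_types = 12, depth = 3)
  gen <- generate_map(spec)
  h <- gen$hierarchy
  leaves <- setdiff(h$nodes, unlist(h$children[h$nodes], use.names = FALSE))
  leaves <- h$nodes[!h$nodes %in% names(h$children)]
  for (leaf in leaves) {
    expect_length(setdiff(ancestors(h, leaf), leaf), 2)
  }
  expect_true(all(vapply(h$nodes, function(n) {
    any(ancestors(h, n) %in% h$roots)
  }, NA)))
})

test_that("generated maps satisfy the container invariants and round-trip", {
  spec <- fixture_spec(seed = 8, n_genes = 400, n_cell_types = 6,
                       deg_len = c(15, 25))
  gen <- generate_map(spec)
  trec <- gen$map$tissues$tissue1
  expect_true(all(names(trec$cell_types) %in% trec$hierarchy$nodes))
  for (ct in names(trec$cell_types)) {
    rec <- trec$cell_types[[ct]]
    expect_true(all(rec$freq >= 1))
    expect_false(any(duplicated(names(rec$freq))))
    expect_false(any(duplicated(rec$degs$gene)))
    expect_true(!is.unsorted(rec$degs$adj_p))
  }
  prefix <- file.path(withr::local_tempdir(), "map")
  paths <- write_marker_map(gen$map, prefix)
  back <- read_marker_map(paths[["markers"]], paths[["hierarchy"]],
                          paths[["degs"]])
  ct1 <- names(trec$cell_types)[1]
  expect_equal(sort(names(back$tissues$tissue1$cell_types[[ct1]]$freq)),
               sort(names(trec$cell_types[[ct1]]$freq)))
  expect_equal(back$tissues$tissue1$cell_types[[ct1]]$degs$gene,
               trec$cell_types[[ct1]]$degs$gene)
})

test_that("queries carry the requested noise mix and planted ordering", {
  spec <- fixture_spec(seed = 12, n_genes = 500, n_cell_types = 8,
                       noise_fraction = 0.2, query_len = 30)
  gen <- generate_map(spec)
  cts <- names(gen$map$tissues$tissue1$cell_types)
  qs <- generate_queries(gen$map, cts[1:4], spec, universe = gen$universe)
  for (qid in names(qs$queries)) {
    q <- qs$queries[[qid]]
    expect_length(q, 30)
    rec <- gen$map$tissues$tissue1$cell_types[[qs$truth[qid]]]
    pool <- union(names(rec$freq), rec$degs$gene)
    expect_equal(sum(!q %in% pool), 6)       # exactly 20% noise
    expect_true(all(q[1:24] %in% pool))      # planted genes lead the list
  }
  # zero noise: every gene comes from the planted type
  spec0 <- fixture_spec(seed = 12, n_genes = 500, n_cell_types = 8,
                        noise_fraction = 0)
  gen0 <- generate_map(spec0)
  qs0 <- generate_queries(gen0$map, cts[1], spec0, universe = gen0$universe)
  rec0 <- gen0$map$tissues$tissue1$cell_types[[cts[1]]]
  expect_true(all(qs0$queries[[1]] %in% union(names(rec0$freq), rec0$degs$gene)))
  expect_error(generate_queries(gen$map, "no-such-type", spec), "not in map")
})

test_that("per-study entries reconstruct frequencies and RRA recovers the order", {
  spec <- fixture_spec(seed = 3, n_genes = 400, n_cell_types = 5,
                       marker_keep_prob = 1, entries_per_type = c(3, 3),
                       deg_len = c(30, 40), deg_jitter = 0.05)
  entries <- generate_entries(spec)
  ct <- entries[[1]]$cell_type
  freq <- aggregate_canonical(entries, "tissue1", ct)
  expect_true(all(freq == 3))  # keep_prob 1, exactly 3 entries per type

  # aggregation over the jittered per-study permutations of one underlying
  # order concentrates that order's head at the top
  lists <- lapply(Filter(function(e) e$cell_type == ct, entries), `[[`, "deg_list")
  agg <- rra_aggregate(lists)
  consensus_top <- lists[[1]][order(rowMeans(
    sapply(lists, function(l) match(lists[[1]], l))))][1:5]
  expect_gte(length(intersect(agg$gene[1:10], consensus_top)), 4)
})

test_that("infeasible marker demand is rejected", {
  spec <- fixture_spec(seed = 1, n_genes = 20, n_cell_types = 10,
                       markers_per_type = c(8, 15))
  expect_error(generate_map(spec), "infeasible")
})
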