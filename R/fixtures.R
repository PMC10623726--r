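#' Specification for the synthetic fixture generator
#'
#' Describes a synthetic marker map and query workload: a gene universe, a
#' rooted cell-type tree per tissue, per-type core marker sets with
#' controlled sibling overlap, long-tailed usage frequencies, ranked DEG
#' lists with the core markers near the top, and query gene lists with a
#' planted true cell type plus uniform background noise. Defaults emulate a
#' modestly curated tissue: a 1000-gene universe, 20 cell types in a
#' 3-level tree, 8-15 canonical markers per type with geometric usage
#' frequencies of mean 3, DEG lists of 60-120 genes, 30-gene queries with
#' 20% noise.
#'
#' @param seed RNG seed; everything downstream is deterministic given it.
#' @param n_genes universe size.
#' @param n_tissues number of tissues (cell types are shared across them).
#' @param n_cell_types recorded cell types per tissue.
#' @param depth tree depth counting the root level (3 = root, internal,
#'   leaves).
#' @param markers_per_type integer range of core marker set sizes.
#' @param freq_mean mean of the geometric usage-frequency distribution
#'   (floored at 1).
#' @param deg_len integer range of DEG list lengths.
#' @param sibling_overlap fraction of a sibling's core shared with the
#'   previous sibling, in [0, 1).
#' @param query_len query gene-list length.
#' @param noise_fraction share of query genes drawn uniformly from
#'   non-marker genes, in [0, 1).
#' @param entries_per_type integer range of per-study entries per cell type.
#' @param marker_keep_prob probability an entry keeps each core marker.
#' @param deg_jitter rank jitter (fraction of list length) applied to
#'   per-study DEG permutations.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 0, n_genes = 1000, n_tissues = 1,
                         n_cell_types = 20, depth = 3,
                         markers_per_type = c(8, 15), freq_mean = 3,
                         deg_len = c(60, 120), sibling_overlap = 0.1,
                         query_len = 30, noise_fraction = 0.2,
                         entries_per_type = c(3, 6),
                         marker_keep_prob = 0.7, deg_jitter = 0.15) {
  spec <- list(seed = seed, n_genes = n_genes, n_tissues = n_tissues,
               n_cell_types = n_cell_types, depth = depth,
               markers_per_type = markers_per_type, freq_mean = freq_mean,
               deg_len = deg_len, sibling_overlap = sibling_overlap,
               query_len = query_len, noise_fraction = noise_fraction,
               entries_per_type = entries_per_type,
               marker_keep_prob = marker_keep_prob, deg_jitter = deg_jitter)
  counts <- c(n_genes, n_tissues, n_cell_types, depth, query_len)
  if (any(counts <= 0)) stop("all counts must be positive", call. = FALSE)
  if (noise_fraction < 0 || noise_fraction >= 1) {
    stop("noise_fraction must lie in [0, 1)", call. = FALSE)
  }
  if (sibling_overlap < 0 || sibling_overlap >= 1) {
    stop("sibling_overlap must lie in [0, 1)", call. = FALSE)
  }
  structure(spec, class = "fixture_spec")
}

# range sampler safe against R's sample(scalar) expansion
sample_range <- function(range, n = 1) {
  vals <- seq(range[1], range[2])
  if (length(vals) == 1) rep(vals, n) else sample(vals, n, replace = TRUE)
}

# tree shape: root "cell", internal levels, leaves; all non-root nodes are
# recorded cell types
fixture_tree <- function(n_ct, depth) {
  ids <- sprintf("ct%02d", seq_len(n_ct))
  edges <- data.frame(child = character(), parent = character())
  if (depth <= 2) {
    edges <- data.frame(child = ids, parent = "cell")
    return(list(edges = edges, levels = list(ids)))
  }
  levels <- list()
  remaining <- n_ct
  taken <- 0
  for (l in seq_len(depth - 2)) {
    size <- max(2, ceiling(remaining^(1 / (depth - l))))
    size <- min(size, remaining - (depth - 2 - l))
    levels[[l]] <- ids[taken + seq_len(size)]
    taken <- taken + size
    remaining <- remaining - size
  }
  levels[[depth - 1]] <- ids[taken + seq_len(remaining)]
  parents_of <- function(children, parents) {
    data.frame(child = children,
               parent = parents[((seq_along(children) - 1) %% length(parents)) + 1])
  }
  edges <- rbind(parents_of(levels[[1]], "cell"))
  for (l in 2:(depth - 1)) {
    edges <- rbind(edges, parents_of(levels[[l]], levels[[l - 1]]))
  }
  list(edges = edges, levels = levels)
}

# shared structural skeleton used by both generate_map and generate_entries:
# hierarchy, core marker sets (with sibling overlap and parent sampling of
# child cores), and the underlying DEG order per cell type
fixture_structure <- function(spec) {
  tree <- fixture_tree(spec$n_cell_types, spec$depth)
  hier <- cell_hierarchy(tree$edges)
  cts <- sprintf("ct%02d", seq_len(spec$n_cell_types))
  genes <- sprintf("GENE%05d", seq_len(spec$n_genes))

  sizes <- sample_range(spec$markers_per_type, length(cts))
  if (sum(sizes) > spec$n_genes) {
    stop("infeasible spec: more core markers than genes", call. = FALSE)
  }
  shuffled <- sample(genes)
  cores <- list()
  at <- 0
  for (i in seq_along(cts)) {
    cores[[cts[i]]] <- shuffled[at + seq_len(sizes[i])]
    at <- at + sizes[i]
  }
  # sibling overlap: each non-first sibling swaps part of its core for genes
  # from the previous sibling's core
  if (spec$sibling_overlap > 0) {
    for (p in unique(tree$edges$parent)) {
      sibs <- intersect(cts, tree$edges$child[tree$edges$parent == p])
      if (length(sibs) < 2) next
      for (i in 2:length(sibs)) {
        core <- cores[[sibs[i]]]
        n_share <- min(floor(spec$sibling_overlap * length(core)),
                       length(cores[[sibs[i - 1]]]))
        if (n_share > 0) {
          shared <- sample(cores[[sibs[i - 1]]], n_share)
          core[length(core) - seq_len(n_share) + 1] <- shared
          cores[[sibs[i]]] <- unique(core)
        }
      }
    }
  }
  # parent types carry a sample of each child's core
  for (p in intersect(cts, unique(tree$edges$parent))) {
    kids <- intersect(cts, tree$edges$child[tree$edges$parent == p])
    extra <- unlist(lapply(kids, function(k) {
      sample(cores[[k]], min(2, length(cores[[k]])))
    }), use.names = FALSE)
    cores[[p]] <- unique(c(cores[[p]], extra))
  }
  # underlying DEG order: shuffled core first, then background filler
  deg_orders <- list()
  for (ct in cts) {
    len <- sample_range(spec$deg_len)
    core <- cores[[ct]]
    len <- max(len, length(core))
    filler <- sample(setdiff(genes, core), len - length(core))
    deg_orders[[ct]] <- c(sample(core), filler)
  }
  list(hierarchy = hier, cell_types = cts, genes = genes, cores = cores,
       deg_orders = deg_orders)
}

#' Generate a synthetic marker map
#'
#' Deterministic given `spec$seed`. Each cell type receives a distinctive
#' core marker set (with the configured overlap between adjacent siblings
#' and parents sampling their children's cores), geometric usage
#' frequencies floored at 1, and an aggregated DEG list with the core
#' markers at the top.
#'
#' @param spec a [fixture_spec()].
#' @return List with `map` (a `marker_map`), `hierarchy` (the full
#'   `cell_hierarchy`) and `universe` (all gene symbols).
#' @export
generate_map <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_preserved_rng(spec$seed, {
    st <- fixture_structure(spec)
    tissues <- list()
    t_ids <- sprintf("tissue%d", seq_len(spec$n_tissues))
    for (t in t_ids) {
      cell_types <- list()
      for (ct in st$cell_types) {
        core <- st$cores[[ct]]
        freq <- stats::setNames(stats::rgeom(length(core),
                                             prob = 1 / spec$freq_mean) + 1L,
                                core)
        freq <- freq[order(-freq, names(freq))]
        ord <- st$deg_orders[[ct]]
        adj_p <- sort(stats::runif(length(ord), 0, 0.2))
        degs <- data.frame(gene = ord, p = adj_p, adj_p = adj_p,
                           stringsAsFactors = FALSE)
        n_entries <- sample_range(spec$entries_per_type)
        cell_types[[ct]] <- list(freq = freq, degs = degs,
                                 n_entries = n_entries,
                                 deg_sources = list(ord))
      }
      tissues[[t]] <- list(hierarchy = prune_hierarchy(st$hierarchy, st$cell_types),
                           cell_types = cell_types)
    }
    map <- structure(list(species = "human", cell_hierarchy = st$hierarchy,
                          tissues = tissues),
                     class = "marker_map")
    list(map = map, hierarchy = st$hierarchy, universe = st$genes)
  })
}

#' Generate per-study marker entries
#'
#' Produces raw entries whose aggregation reconstructs the fixture: per
#' (tissue, cell type) a seeded number of entries whose canonical markers
#' subsample the core set and whose DEG lists are rank-jittered permutations
#' of a shared underlying order, so [aggregate_canonical()] recovers usage
#' counts and [rra_aggregate()] recovers the order.
#'
#' @param spec a [fixture_spec()].
#' @return List of `marker_entry`.
#' @export
generate_entries <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_preserved_rng(spec$seed, {
    st <- fixture_structure(spec)
    entries <- list()
    t_ids <- sprintf("tissue%d", seq_len(spec$n_tissues))
    for (t in t_ids) {
      for (ct in st$cell_types) {
        core <- st$cores[[ct]]
        base <- st$deg_orders[[ct]]
        n_entries <- sample_range(spec$entries_per_type)
        for (e in seq_len(n_entries)) {
          keep <- core[stats::runif(length(core)) < spec$marker_keep_prob]
          if (length(keep) == 0) keep <- sample(core, 1)
          jitter <- stats::rnorm(length(base), sd = spec$deg_jitter * length(base))
          deg <- base[order(seq_along(base) + jitter)]
          entries[[length(entries) + 1]] <- marker_entry(
            species = "human", tissue = t, cell_type = ct,
            canonical_markers = keep, deg_list = deg,
            source_id = sprintf("%s_%s_s%d", t, ct, e))
        }
      }
    }
    entries
  })
}

#' Generate query gene lists with planted truth
#'
#' Each query emulates one cluster's ordered DUG list for a planted cell
#' type: `(1 - noise_fraction) * query_len` signal genes sampled without
#' replacement from the type's canonical markers (weighted by usage
#' frequency) and the top of its DEG list, followed by noise genes drawn
#' uniformly from universe genes outside the type's marker/DEG pool. Signal
#' genes precede noise genes, emulating fold-change-ordered DUGs.
#'
#' @param map a `marker_map` (typically from [generate_map()]).
#' @param truth_types character vector of planted cell-type ids, one per
#'   query (recycled ids allowed).
#' @param spec a [fixture_spec()]; `spec$seed` drives sampling.
#' @param tissue tissue id; defaults to the map's first tissue.
#' @param universe optional gene pool for noise; defaults to [map_genes()].
#' @return List with `queries` (named list of gene vectors) and `truth`
#'   (named character vector query id -> planted cell type).
#' @export
generate_queries <- function(map, truth_types, spec,
                             tissue = names(map$tissues)[1],
                             universe = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  cts <- names(map$tissues[[tissue]]$cell_types)
  bad <- setdiff(unique(truth_types), cts)
  if (length(bad) > 0) {
    stop("planted type(s) not in map: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  universe <- universe %||% map_genes(map)
  with_preserved_rng(spec$seed + 1L, {
    queries <- list()
    truth <- character()
    n_noise <- round(spec$noise_fraction * spec$query_len)
    n_signal <- spec$query_len - n_noise
    for (i in seq_along(truth_types)) {
      ct <- truth_types[i]
      rec <- map$tissues[[tissue]]$cell_types[[ct]]
      deg_top <- if (!is.null(rec$degs)) utils::head(rec$degs$gene, 30) else character()
      pool <- union(names(rec$freq), deg_top)
      w <- stats::setNames(rep(1, length(pool)), pool)
      w[intersect(pool, names(rec$freq))] <-
        as.numeric(rec$freq[intersect(pool, names(rec$freq))])
      take <- min(n_signal, length(pool))
      signal <- sample(pool, take, prob = w[pool])
      if (take < n_signal && !is.null(rec$degs)) {
        extra <- setdiff(rec$degs$gene, c(pool, signal))
        signal <- c(signal, utils::head(extra, n_signal - take))
      }
      full_pool <- union(pool, if (!is.null(rec$degs)) rec$degs$gene else character())
      noise <- sample(setdiff(universe, full_pool), n_noise)
      qid <- sprintf("q%03d", i)
      queries[[qid]] <- c(signal, noise)
      truth[qid] <- ct
    }
    list(queries = queries, truth = truth)
  })
}

#' Write fixture files to a directory
#'
#' Emits the marker-map TSVs, the hierarchy edge list, the query gene lists
#' (plain text with `>cluster` section headers) and the planted-truth TSV.
#' Byte-identical across runs with the same spec.
#'
#' @param dir output directory (created if needed).
#' @param spec a [fixture_spec()].
#' @param n_queries number of queries; planted types cycle through the
#'   map's cell types.
#' @return Invisibly, the generated objects (`map`, `hierarchy`, `universe`,
#'   `queries`, `truth`).
#' @export
write_fixture <- function(dir, spec, n_queries = 20) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_map(spec)
  tissue <- names(gen$map$tissues)[1]
  cts <- names(gen$map$tissues[[tissue]]$cell_types)
  planted <- cts[((seq_len(n_queries) - 1) %% length(cts)) + 1]
  qs <- generate_queries(gen$map, planted, spec, universe = gen$universe)
  write_marker_map(gen$map, file.path(dir, "map"))
  lines <- unlist(lapply(names(qs$queries), function(id) {
    c(paste0(">", id), qs$queries[[id]])
  }), use.names = FALSE)
  writeLines(lines, file.path(dir, "queries.txt"))
  write_tsv_atomic(data.frame(query = names(qs$truth),
                              cell_type = unname(qs$truth)),
                   file.path(dir, "truth.tsv"))
  writeLines(gen$universe, file.path(dir, "universe.txt"))
  invisible(c(gen, qs))
}
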