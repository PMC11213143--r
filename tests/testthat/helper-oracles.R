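# Independent brute-force oracles and random-instance generators used
# to validate the vectorized implementations.

# BFS neighborhood by repeated edge scans (no igraph, no adjacency
# precomputation) — deliberately naive
oracle_neighborhood <- function(graph, v, r) {
  reached <- v
  frontier <- v
  depth <- 0L
  while (depth < r && length(frontier) > 0L) {
    nxt <- integer(0)
    for (u in frontier) {
      e <- graph$edges
      nb <- c(e[e[, 1L] == u, 2L], e[e[, 2L] == u, 1L])
      nxt <- c(nxt, setdiff(nb, reached))
    }
    nxt <- unique(nxt)
    reached <- c(reached, nxt)
    frontier <- nxt
    depth <- depth + 1L
  }
  sort(reached)
}

# every unordered pair of distinct member positions in a neighborhood,
# as a 2-row matrix of concepts (explicit enumeration via combn)
neighborhood_pair_concepts <- function(s, nb) {
  if (length(nb) < 2L) return(NULL)
  idx <- utils::combn(length(nb), 2L)
  rbind(s$concepts[nb[idx[1L, ]]], s$concepts[nb[idx[2L, ]]])
}

# naive rollup: iterate neighborhoods, tally members and distinct pairs
oracle_rollup <- function(s, r) {
  counts <- stats::setNames(numeric(length(feature_keys(s$K))),
                            feature_keys(s$K))
  for (v in seq_len(s$topology$n_vertices)) {
    nb <- oracle_neighborhood(s$topology, v, r)
    mono_tab <- table(mono_key(s$concepts[nb]))
    counts[names(mono_tab)] <- counts[names(mono_tab)] + mono_tab
    pc <- neighborhood_pair_concepts(s, nb)
    if (!is.null(pc)) {
      bi_tab <- table(bigram_key(pc[1L, ], pc[2L, ]))
      counts[names(bi_tab)] <- counts[names(bi_tab)] + bi_tab
    }
  }
  counts
}

# naive convolution: per-vertex neighborhood enumeration with direct
# dictionary lookups of every monogram and pair
oracle_k2conv <- function(s, kernel) {
  w <- kernel$weights
  vapply(seq_len(s$topology$n_vertices), function(v) {
    nb <- oracle_neighborhood(s$topology, v, kernel$r)
    keys <- mono_key(s$concepts[nb])
    pc <- neighborhood_pair_concepts(s, nb)
    if (!is.null(pc)) keys <- c(keys, bigram_key(pc[1L, ], pc[2L, ]))
    present <- keys %in% names(w)
    sum(w[keys[present]])
  }, 0)
}

# random map graph of any of the three kinds
random_map_graph <- function(seed) {
  withr::with_seed(seed, {
    kind <- sample(c("sequence", "grid", "pointcloud"), 1L)
    switch(kind,
      sequence = build_sequence_graph(sample(1:50, 1L), sample(1:3, 1L)),
      grid = build_grid_graph(sample(1:7, 1L), sample(1:7, 1L),
                              connectivity = sample(c(4L, 8L), 1L)),
      pointcloud = build_pointcloud_graph(
        matrix(stats::runif(3 * sample(2:50, 1L), 0, 10), ncol = 3L),
        cutoff = stats::runif(1L, 2, 5)))
  })
}

random_sprite <- function(seed, K = NULL) {
  g <- random_map_graph(seed)
  withr::with_seed(seed + 1L, {
    if (is.null(K)) K <- sample(1:5, 1L)
    sprite(g, sample.int(K, g$n_vertices, replace = TRUE), K)
  })
}

random_kernel <- function(K, r, seed) {
  keys <- feature_keys(K)
  w <- withr::with_seed(seed, stats::rnorm(length(keys)))
  names(w) <- keys
  structure(list(weights = w, K = as.integer(K), r = as.integer(r),
                 variant = "fold_change", hyperparams = list(),
                 p_values = NULL),
            class = "prospect_kernel")
}

# best concept-label agreement over all permutations (K <= 6)
all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(all_permutations(v[-i]), function(rest) c(v[i], rest))))
}

best_concept_agreement <- function(true, pred, K) {
  stopifnot(K <= 6L)
  max(vapply(all_permutations(seq_len(K)),
             function(p) mean(p[pred] == true), 0))
}

# shared small end-to-end fit used by several tests
fit_synth_prospector <- function(train, K = 5L, r = 1L,
                                 variant = "fold_change",
                                 pool_size = 10000L, seed = 7L) {
  graphs <- lapply(train, `[[`, "graph")
  q <- fit_quantizer(sample_pool(graphs, pool_size, seed = seed),
                     K = K, seed = seed)
  embs <- rescale_embeddings(
    lapply(lapply(graphs, quantize, q = q), rollup, r = r), "l1")
  kern <- if (variant == "fold_change") {
    fit_kernel_foldchange(compute_class_profiles(embs), embs)
  } else {
    fit_kernel_linear(embs)
  }
  list(quantizer = q, kernel = kern, embeddings = embs)
}

mean_test_auprc <- function(test, q, kernel, shuffle_seed = NULL) {
  maps <- batch_prospect(lapply(test, `[[`, "graph"), q, kernel)
  scores <- lapply(maps, `[[`, "scores")
  if (!is.null(shuffle_seed)) {
    scores <- withr::with_seed(shuffle_seed, lapply(scores, sample))
  }
  mean(vapply(seq_along(test), function(i)
    auprc(scores[[i]], test[[i]]$graph$mask), 0))
}
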