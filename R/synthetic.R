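# Synthetic multiple-instance datasets: map graphs with
# Gaussian-mixture token embeddings and planted class-1 regions of
# controllable prevalence and dispersion.

#' Configuration for the synthetic generator
#'
#' Encodes the multiple instance assumption: class-1 data resemble
#' class-0 data except for a planted set of class-1-specific tokens.
#' Every token draws a latent concept (background tokens from
#' `background_concept_probs`, planted tokens from
#' `signal_concept_probs`) and an embedding equal to that concept's
#' centroid plus isotropic Gaussian noise. Centroids are placed on a
#' scaled orthogonal frame (`separation * e_k`, pairwise distance
#' `separation * sqrt(2)`), guaranteeing the stated minimum separation
#' in any `embed_dim >= K_true`.
#'
#' Regions are grown on a 1-hop contiguity graph (immediate sequence
#' neighbors; rook adjacency for grids), so planted regions are solid
#' runs or blobs without interior holes even when the data graph adds
#' longer-range smoothing edges; component separation is enforced on
#' the data graph itself.
#'
#' Defaults describe the reference study conditions: 50 data per class
#' on a 100-token sequence with 2-hop connectivity, 5 latent concepts
#' in 8 dimensions, centroid separation 6 vs noise sd 1, background
#' uniform over concepts 1..4, signal concentrated on concept 5 which
#' never occurs in background (masked tokens are class-specific, per
#' the multiple instance assumption), prevalence 0.1 planted as 2
#' compact regions.
#'
#' @param n_class0,n_class1 number of data per class.
#' @param graph_kind "sequence", "grid" or "pointcloud".
#' @param graph_params list of arguments for the matching builder
#'   (`n_tokens`/`hops`; `rows`/`cols`/`connectivity`; `coords`/`cutoff`).
#' @param K_true number of latent concepts.
#' @param embed_dim embedding dimension, >= K_true.
#' @param concept_centroid_separation minimum pairwise centroid
#'   distance.
#' @param noise_sd isotropic Gaussian noise sd (> 0).
#' @param background_concept_probs,signal_concept_probs probability
#'   vectors over the K_true concepts (each sums to 1).
#' @param prevalence fraction of tokens planted in each class-1 datum,
#'   in (0, 1).
#' @param n_regions number of connected components to plant.
#' @param region_mode "compact" (breadth-first growth) or "scatter"
#'   (random-walk growth, straggly high-dispersion regions).
#' @param seed integer master seed; all randomness flows from it.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_class0 = 50L, n_class1 = 50L,
                         graph_kind = c("sequence", "grid", "pointcloud"),
                         graph_params = list(n_tokens = 100L, hops = 2L),
                         K_true = 5L, embed_dim = 8L,
                         concept_centroid_separation = 6,
                         noise_sd = 1,
                         background_concept_probs = c(rep(0.25, 4), 0),
                         signal_concept_probs = c(0, 0, 0, 0, 1),
                         prevalence = 0.1, n_regions = 2L,
                         region_mode = c("compact", "scatter"),
                         seed = 1L) {
  graph_kind <- match.arg(graph_kind)
  region_mode <- match.arg(region_mode)
  K_true <- as.integer(K_true)
  if (K_true < 1L) stop("K_true must be >= 1")
  if (embed_dim < K_true) stop("embed_dim must be >= K_true")
  check_simplex <- function(p, what) {
    if (length(p) != K_true || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop(what, " must be a probability vector over K_true concepts")
  }
  check_simplex(background_concept_probs, "background_concept_probs")
  check_simplex(signal_concept_probs, "signal_concept_probs")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie in (0, 1)")
  cfg <- list(n_class0 = as.integer(n_class0),
              n_class1 = as.integer(n_class1),
              graph_kind = graph_kind, graph_params = graph_params,
              K_true = K_true, embed_dim = as.integer(embed_dim),
              concept_centroid_separation = concept_centroid_separation,
              noise_sd = noise_sd,
              background_concept_probs = background_concept_probs,
              signal_concept_probs = signal_concept_probs,
              prevalence = prevalence, n_regions = as.integer(n_regions),
              region_mode = region_mode, seed = as.integer(seed))
  class(cfg) <- "synth_config"
  cfg
}

# 1-hop contiguity graph used for region growth: immediate sequence
# neighbors / rook adjacency; point clouds keep their distance graph
contiguity_graph <- function(cfg) {
  p <- cfg$graph_params
  switch(cfg$graph_kind,
    sequence = build_sequence_graph(p$n_tokens, hops = 1L),
    grid = build_grid_graph(p$rows, p$cols, connectivity = 4L,
                            keep = p$keep),
    pointcloud = build_pointcloud_graph(p$coords, p$cutoff))
}

build_config_graph <- function(cfg, datum_id, label) {
  p <- cfg$graph_params
  switch(cfg$graph_kind,
    sequence = build_sequence_graph(p$n_tokens,
                                    hops = p$hops %||% 2L,
                                    datum_id = datum_id, label = label),
    grid = build_grid_graph(p$rows, p$cols,
                            connectivity = p$connectivity %||% 8L,
                            keep = p$keep, datum_id = datum_id,
                            label = label),
    pointcloud = build_pointcloud_graph(p$coords, p$cutoff,
                                        datum_id = datum_id,
                                        label = label))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adjacency_list <- function(graph) {
  adj <- vector("list", graph$n_vertices)
  for (i in seq_len(graph$n_vertices)) adj[[i]] <- integer(0)
  e <- graph$edges
  if (nrow(e)) {
    for (k in seq_len(nrow(e))) {
      adj[[e[k, 1L]]] <- c(adj[[e[k, 1L]]], e[k, 2L])
      adj[[e[k, 2L]]] <- c(adj[[e[k, 2L]]], e[k, 1L])
    }
  }
  adj
}

# grow one connected region of the requested size from `root`, using
# only `available` vertices; compact = randomized BFS frontier,
# scatter = random-walk frontier. Returns NULL if it gets stuck.
grow_region <- function(adj, root, size, available, mode) {
  region <- root
  frontier <- setdiff(adj[[root]], which(!available))
  frontier <- frontier[available[frontier]]
  while (length(region) < size) {
    if (length(frontier) == 0L) return(NULL)
    nxt <- if (mode == "compact") {
      frontier[sample.int(length(frontier), 1L)]
    } else {
      # random walk: step from a random current member
      cand <- integer(0)
      anchors <- sample(region)
      for (a in anchors) {
        nb <- adj[[a]]
        nb <- nb[available[nb] & !(nb %in% region)]
        if (length(nb)) { cand <- nb; break }
      }
      if (length(cand) == 0L) frontier[sample.int(length(frontier), 1L)]
      else cand[sample.int(length(cand), 1L)]
    }
    region <- c(region, nxt)
    frontier <- setdiff(unique(c(frontier, adj[[nxt]])), region)
    frontier <- frontier[available[frontier]]
  }
  region
}

#' Plant class-specific regions in a graph
#'
#' Produces a mask with exactly `n_positive` true vertices forming
#' exactly `n_regions` connected components, grown from random
#' distinct roots by seeded breadth-first (compact) or random-walk
#' (scatter) expansion. Vertices adjacent to a finished region are
#' blocked for later regions so components stay disjoint. Deterministic
#' per seed; errors after bounded retries when the graph cannot host
#' the requested layout.
#'
#' @param graph a `map_graph`.
#' @param n_positive total masked vertices (<= n_vertices).
#' @param n_regions number of components (<= n_positive).
#' @param seed integer seed.
#' @param mode "compact" or "scatter".
#' @param max_tries retry budget.
#' @param growth_graph optional `map_graph` on the same vertex set
#'   whose edges drive region growth (e.g. the 1-hop contiguity graph
#'   of a multi-hop sequence graph, so grown regions have no interior
#'   holes); its edge set should be a subset of `graph`'s so regions
#'   stay connected in `graph`. Component separation is always
#'   enforced on `graph` itself. Defaults to `graph`.
#' @return logical mask of length `n_vertices`.
#' @export
plant_regions <- function(graph, n_positive, n_regions, seed = 1L,
                          mode = c("compact", "scatter"),
                          max_tries = 100L, growth_graph = NULL) {
  stopifnot(inherits(graph, "map_graph"))
  mode <- match.arg(mode)
  n_positive <- as.integer(n_positive)
  n_regions <- as.integer(n_regions)
  if (n_positive < 1L || n_positive > graph$n_vertices)
    stop("n_positive must lie in 1..n_vertices")
  if (n_regions < 1L || n_regions > n_positive)
    stop("n_regions must lie in 1..n_positive")
  if (is.null(growth_graph)) growth_graph <- graph
  stopifnot(inherits(growth_graph, "map_graph"),
            growth_graph$n_vertices == graph$n_vertices)
  adj <- adjacency_list(growth_graph)
  halo_adj <- adjacency_list(graph)
  # near-equal split of n_positive into n_regions sizes
  base <- n_positive %/% n_regions
  sizes <- rep(base, n_regions)
  extra <- n_positive - base * n_regions
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  withr::with_seed(seed, {
    for (try in seq_len(max_tries)) {
      available <- rep(TRUE, graph$n_vertices)
      mask <- rep(FALSE, graph$n_vertices)
      ok <- TRUE
      for (s in sizes) {
        roots <- which(available)
        if (length(roots) == 0L) { ok <- FALSE; break }
        root <- roots[sample.int(length(roots), 1L)]
        region <- grow_region(adj, root, s, available, mode)
        if (is.null(region)) { ok <- FALSE; break }
        mask[region] <- TRUE
        # block the region and its data-graph halo so components stay
        # disjoint in the data graph, not just the growth graph
        halo <- unique(unlist(halo_adj[region]))
        available[c(region, halo)] <- FALSE
      }
      if (ok) return(mask)
    }
  })
  stop("could not place ", n_regions, " disjoint regions totalling ",
       n_positive, " vertices after ", max_tries, " attempts")
}

#' Generate a synthetic multiple-instance dataset
#'
#' Draws `n_class0 + n_class1` data under a [synth_config()]. Class-0
#' data have all-background tokens and an all-false mask; class-1 data
#' carry a planted mask of `round(prevalence * T)` vertices in
#' `n_regions` components whose tokens draw concepts from the signal
#' distribution. Embeddings are concept centroids plus Gaussian noise.
#'
#' All randomness flows from `config$seed`: the master seed draws one
#' sub-seed per datum (recorded in the output), so any datum is
#' reproducible in isolation.
#'
#' @param config a `synth_config`.
#' @return list of `synth_datum` objects, each with fields `graph`
#'   (a `map_graph` with embeddings, mask, label), `true_concepts`,
#'   `seed`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n_total <- config$n_class0 + config$n_class1
  centroids <- config$concept_centroid_separation *
    diag(config$K_true)[, seq_len(config$K_true), drop = FALSE]
  centroids <- cbind(centroids,
                     matrix(0, config$K_true,
                            config$embed_dim - config$K_true))
  datum_seeds <- withr::with_seed(config$seed,
    sample.int(.Machine$integer.max - 1L, n_total))
  labels <- c(rep(0L, config$n_class0), rep(1L, config$n_class1))
  growth <- contiguity_graph(config)
  lapply(seq_len(n_total), function(i) {
    id <- sprintf("synth_%03d_c%d", i, labels[i])
    g <- build_config_graph(config, id, labels[i])
    Tn <- g$n_vertices
    mask <- rep(FALSE, Tn)
    if (labels[i] == 1L) {
      n_pos <- max(config$n_regions, round(config$prevalence * Tn))
      mask <- plant_regions(g, n_pos, config$n_regions,
                            seed = datum_seeds[i],
                            mode = config$region_mode,
                            growth_graph = growth)
    }
    withr::with_seed(datum_seeds[i] %% 2000000000L + 1L, {
      concepts <- sample.int(config$K_true, Tn, replace = TRUE,
                             prob = config$background_concept_probs)
      if (any(mask)) {
        concepts[mask] <- sample.int(config$K_true, sum(mask),
                                     replace = TRUE,
                                     prob = config$signal_concept_probs)
      }
      emb <- centroids[concepts, , drop = FALSE] +
        matrix(stats::rnorm(Tn * config$embed_dim, sd = config$noise_sd),
               Tn, config$embed_dim)
    })
    g$embeddings <- emb
    g$mask <- mask
    structure(list(graph = g, true_concepts = concepts,
                   seed = datum_seeds[i]),
              class = "synth_datum")
  })
}

#' Write a synthetic dataset to disk
#'
#' One set of map-graph files per datum (see [write_map_graph()]) plus
#' a `manifest.tsv` listing datum_id, label, realized prevalence and
#' realized dispersion.
#'
#' @param data list of `synth_datum` from [generate_dataset()].
#' @param dir output directory.
#' @return invisibly, the manifest path.
#' @export
write_dataset <- function(data, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- vapply(data, function(d) {
    write_map_graph(d$graph, dir)
    rs <- region_stats(d$graph, d$graph$mask)
    sprintf("%s\t%d\t%s\t%s", d$graph$datum_id, d$graph$label,
            num_fmt(rs$prevalence), num_fmt(rs$dispersion))
  }, "")
  manifest <- file.path(dir, "manifest.tsv")
  writeLines(c("datum_id\tlabel\tprevalence\tdispersion", rows), manifest)
  invisible(manifest)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir dataset directory containing `manifest.tsv`.
#' @return list of `map_graph` objects in manifest order.
#' @export
read_dataset <- function(dir) {
  manifest <- file.path(dir, "manifest.tsv")
  if (!file.exists(manifest)) stop("no manifest.tsv in ", dir)
  tab <- utils::read.delim(manifest, header = TRUE,
                           colClasses = c("character", "integer",
                                          "numeric", "numeric"))
  lapply(tab$datum_id, function(id) read_map_graph(dir, id))
}
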