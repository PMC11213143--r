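# Layer I: vector quantization of token embeddings into K concepts.

#' Pool token embeddings from a dataset
#'
#' Draws up to `target_size` token embeddings uniformly at random
#' without replacement across all graphs (capped at the total token
#' count), forming the representative sample on which the quantizer is
#' fit. Deterministic for a fixed seed.
#'
#' @param dataset list of `map_graph` objects carrying embeddings.
#' @param target_size desired pool size (default 10000).
#' @param seed integer RNG seed.
#' @return numeric matrix, one pooled embedding per row.
#' @export
sample_pool <- function(dataset, target_size = 10000L, seed = 1L) {
  if (length(dataset) == 0L) stop("dataset is empty")
  embs <- lapply(dataset, function(g) {
    stopifnot(inherits(g, "map_graph"))
    if (is.null(g$embeddings)) stop("datum '", g$datum_id, "' has no embeddings")
    g$embeddings
  })
  pool <- do.call(rbind, embs)
  n <- nrow(pool)
  if (n < 1L) stop("dataset contains no tokens")
  take <- min(as.integer(target_size), n)
  idx <- withr::with_seed(seed, sample.int(n, take, replace = FALSE))
  pool[idx, , drop = FALSE]
}

#' Fit a K-way quantizer by k-means
#'
#' Partitions the pooled embedding space into K concepts with k-means
#' (10 restarts, seeded). The fitted centroids define the concept
#' vocabulary `1..K`; any embedding is later assigned to its nearest
#' centroid by Euclidean distance.
#'
#' @param embedding_pool numeric matrix n x d, n >= K, finite.
#' @param K number of concepts, >= 1.
#' @param seed integer RNG seed.
#' @param nstart number of k-means restarts.
#' @return an object of class `quantizer` with fields `centroids`
#'   (K x d), `K`, `seed`, `sample_size`.
#' @export
fit_quantizer <- function(embedding_pool, K, seed = 1L, nstart = 10L) {
  embedding_pool <- as.matrix(embedding_pool)
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("K must be >= 1")
  if (nrow(embedding_pool) < K) stop("pool size must be >= K")
  if (any(!is.finite(embedding_pool))) stop("embeddings must be finite")
  if (K == 1L) {
    centroids <- matrix(colMeans(embedding_pool), nrow = 1L)
  } else {
    km <- withr::with_seed(seed,
      stats::kmeans(embedding_pool, centers = K, nstart = nstart,
                    iter.max = 100L))
    centroids <- km$centers
  }
  dimnames(centroids) <- NULL
  structure(list(centroids = centroids, K = K, seed = as.integer(seed),
                 sample_size = nrow(embedding_pool)),
            class = "quantizer")
}

#' @export
print.quantizer <- function(x, ...) {
  cat(sprintf("quantizer: K = %d concepts, d = %d, fit on %d embeddings\n",
              x$K, ncol(x$centroids), x$sample_size))
  invisible(x)
}

# nearest centroid per row; ties broken toward the lowest concept index
assign_concepts <- function(embeddings, centroids) {
  # squared distances via ||x||^2 - 2 x.c + ||c||^2 (||x||^2 constant per row)
  cross <- embeddings %*% t(centroids)
  cnorm <- rowSums(centroids^2)
  d2 <- sweep(-2 * cross, 2L, cnorm, "+")
  max.col(-d2, ties.method = "first")
}

#' Quantize a map graph into a data sprite
#'
#' Replaces each vertex's embedding by the index of its nearest
#' centroid, producing a sprite: the same topology with one categorical
#' concept in `1..K` per vertex (a d-fold compression of the features).
#'
#' @param graph a `map_graph` with embeddings whose dimension matches
#'   the quantizer's centroids.
#' @param q a `quantizer`.
#' @return an object of class `sprite` with fields `topology`
#'   (the input `map_graph`), `concepts`, `K`.
#' @export
quantize <- function(graph, q) {
  stopifnot(inherits(graph, "map_graph"), inherits(q, "quantizer"))
  if (is.null(graph$embeddings))
    stop("datum '", graph$datum_id, "' has no embeddings")
  if (ncol(graph$embeddings) != ncol(q$centroids))
    stop("embedding dimension (", ncol(graph$embeddings),
         ") does not match quantizer dimension (", ncol(q$centroids), ")")
  sprite(graph, assign_concepts(graph$embeddings, q$centroids), q$K)
}

#' Construct a data sprite directly
#'
#' @param topology a `map_graph`.
#' @param concepts integer vector of per-vertex concepts in `1..K`.
#' @param K vocabulary size.
#' @return an object of class `sprite`.
#' @export
sprite <- function(topology, concepts, K) {
  stopifnot(inherits(topology, "map_graph"))
  concepts <- as.integer(concepts); K <- as.integer(K)
  if (length(concepts) != topology$n_vertices)
    stop("concepts must have one entry per vertex")
  if (any(is.na(concepts)) || any(concepts < 1L) || any(concepts > K))
    stop("concepts must lie in 1..K")
  structure(list(topology = topology, concepts = concepts, K = K),
            class = "sprite")
}

#' @export
print.sprite <- function(x, ...) {
  cat(sprintf("sprite '%s': %d vertices, K = %d concepts\n",
              x$topology$datum_id, x$topology$n_vertices, x$K))
  invisible(x)
}

#' Write / read a fitted quantizer as a text bundle
#'
#' @param q a `quantizer`.
#' @param path file path.
#' @return `write_quantizer` invisibly returns `path`; `read_quantizer`
#'   returns the `quantizer`.
#' @export
write_quantizer <- function(q, path) {
  stopifnot(inherits(q, "quantizer"))
  lines <- c("# quantizer v1",
             sprintf("# K: %d", q$K),
             sprintf("# d: %d", ncol(q$centroids)),
             sprintf("# seed: %d", q$seed),
             sprintf("# sample_size: %d", q$sample_size),
             apply(q$centroids, 1L,
                   function(row) paste(num_fmt(row), collapse = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_quantizer
#' @export
read_quantizer <- function(path) {
  lines <- readLines(path)
  K <- as.integer(header_field(lines, "K"))
  body <- lines[!startsWith(lines, "#") & lines != ""]
  centroids <- matrix(as.numeric(unlist(strsplit(body, "\t", fixed = TRUE))),
                      nrow = K, byrow = TRUE)
  structure(list(centroids = centroids, K = K,
                 seed = as.integer(header_field(lines, "seed")),
                 sample_size = as.integer(header_field(lines, "sample_size"))),
            class = "quantizer")
}

#' Export a sprite as TSV
#'
#' @param s a `sprite`.
#' @param path file path; columns `vertex`, `concept`.
#' @export
write_sprite <- function(s, path) {
  stopifnot(inherits(s, "sprite"))
  writeLines(c(sprintf("# sprite v1 (K: %d, datum_id: %s)", s$K,
                       s$topology$datum_id),
               "vertex\tconcept",
               sprintf("%d\t%d", seq_len(s$topology$n_vertices), s$concepts)),
             path)
  invisible(path)
}
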