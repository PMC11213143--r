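#' Construct a map graph
#'
#' A map graph represents one unstructured datum as a graph of tokens:
#' each vertex is a token (a sentence, an image patch, a residue) and
#' edges encode sequential or spatial adjacency. Vertices are indexed
#' `1..n_vertices`. Optionally carries a dense matrix of per-token
#' embeddings, a logical ground-truth mask of class-specific tokens
#' (used only for model selection and evaluation, never for fitting),
#' a datum identifier and a binary datum-level label.
#'
#' @param n_vertices positive integer, number of tokens T.
#' @param edges two-column integer matrix of undirected edges (one row
#'   per edge, vertex indices in `1..n_vertices`), or NULL for no edges.
#'   Self-loops are rejected; duplicate edges are collapsed.
#' @param embeddings optional numeric matrix with `n_vertices` rows.
#' @param mask optional logical vector of length `n_vertices`.
#' @param datum_id character identifier.
#' @param label optional datum-level binary label (0 or 1).
#' @return an object of class `map_graph`.
#' @export
map_graph <- function(n_vertices, edges = NULL, embeddings = NULL,
                      mask = NULL, datum_id = "datum", label = NULL) {
  n_vertices <- as.integer(n_vertices)
  if (length(n_vertices) != 1L || is.na(n_vertices) || n_vertices < 1L)
    stop("n_vertices must be a positive integer")
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  } else {
    edges <- matrix(as.integer(edges), ncol = 2L)
    if (any(is.na(edges)) || any(edges < 1L) || any(edges > n_vertices))
      stop("edge endpoints must be vertex indices in 1..n_vertices")
    if (any(edges[, 1L] == edges[, 2L]))
      stop("self-loop edges are not allowed")
    # canonical form: low endpoint first, unique, sorted
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L]))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  if (!is.null(embeddings)) {
    embeddings <- as.matrix(embeddings)
    storage.mode(embeddings) <- "double"
    if (nrow(embeddings) != n_vertices)
      stop("embeddings must have one row per vertex")
  }
  if (!is.null(mask)) {
    mask <- as.logical(mask)
    if (length(mask) != n_vertices || any(is.na(mask)))
      stop("mask must be a logical vector of length n_vertices")
  }
  if (!is.null(label)) {
    label <- as.integer(label)
    if (!label %in% c(0L, 1L)) stop("label must be 0 or 1")
  }
  structure(list(n_vertices = n_vertices, edges = edges,
                 embeddings = embeddings, mask = mask,
                 datum_id = as.character(datum_id), label = label),
            class = "map_graph")
}

#' @export
print.map_graph <- function(x, ...) {
  cat(sprintf("map_graph '%s': %d vertices, %d edges%s%s%s\n",
              x$datum_id, x$n_vertices, nrow(x$edges),
              if (!is.null(x$embeddings))
                sprintf(", %d-dim embeddings", ncol(x$embeddings)) else "",
              if (!is.null(x$mask))
                sprintf(", mask (%d positive)", sum(x$mask)) else "",
              if (!is.null(x$label)) sprintf(", label %d", x$label) else ""))
  invisible(x)
}

#' Convert a map graph to an igraph object
#'
#' @param graph a `map_graph`.
#' @return an undirected `igraph` graph with the same vertices and edges.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "map_graph"))
  mg_igraph(graph)
}

# igraph construction that is robust to isolated trailing vertices
mg_igraph <- function(graph) {
  igraph::make_graph(t(graph$edges), n = graph$n_vertices, directed = FALSE)
}

#' Sequence map graph with k-hop connectivity
#'
#' Tokens of a 1D sequence (e.g. sentences of a document) connected to
#' all tokens within `hops` positions, the convention used for text.
#'
#' @param n_tokens positive integer.
#' @param hops positive integer; edge \{i, j\} exists iff 0 < |i - j| <= hops.
#' @param datum_id,label passed to [map_graph()].
#' @return a `map_graph`.
#' @export
build_sequence_graph <- function(n_tokens, hops = 2L, datum_id = "seq",
                                 label = NULL) {
  n_tokens <- as.integer(n_tokens); hops <- as.integer(hops)
  if (is.na(n_tokens) || n_tokens < 1L) stop("n_tokens must be >= 1")
  if (is.na(hops) || hops < 1L) stop("hops must be >= 1")
  src <- rep(seq_len(n_tokens), each = hops)
  dst <- src + rep(seq_len(hops), times = n_tokens)
  keep <- dst <= n_tokens
  map_graph(n_tokens, cbind(src[keep], dst[keep]),
            datum_id = datum_id, label = label)
}

#' Grid map graph with rook or rook+diagonal connectivity
#'
#' Tokens on a `rows` x `cols` raster (e.g. image patches), connected
#' 4-way (rook) or 8-way (rook + diagonal). An optional `keep` vector
#' restricts vertices to foreground cells (e.g. a tissue mask); kept
#' cells are re-indexed compactly in row-major order and only edges
#' between two kept cells survive.
#'
#' @param rows,cols positive integers.
#' @param connectivity 4 or 8.
#' @param keep optional logical vector of length `rows * cols` in
#'   row-major order.
#' @param datum_id,label passed to [map_graph()].
#' @return a `map_graph`; its `grid_dims` and `grid_cells` attributes
#'   record the raster shape and each vertex's original cell index.
#' @export
build_grid_graph <- function(rows, cols, connectivity = 8L, keep = NULL,
                             datum_id = "grid", label = NULL) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (is.na(rows) || rows < 1L || is.na(cols) || cols < 1L)
    stop("rows and cols must be >= 1")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  n_cells <- rows * cols
  if (is.null(keep)) keep <- rep(TRUE, n_cells)
  keep <- as.logical(keep)
  if (length(keep) != n_cells || any(is.na(keep)))
    stop("keep must be logical of length rows*cols")
  if (!any(keep)) stop("keep must retain at least one cell")
  # cell (r, c) -> row-major index (r-1)*cols + c
  cell_r <- rep(seq_len(rows), each = cols)
  cell_c <- rep(seq_len(cols), times = rows)
  offsets <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8L) offsets <- c(offsets, list(c(1L, 1L), c(1L, -1L)))
  src <- integer(0); dst <- integer(0)
  for (off in offsets) {
    r2 <- cell_r + off[1L]; c2 <- cell_c + off[2L]
    ok <- r2 >= 1L & r2 <= rows & c2 >= 1L & c2 <= cols
    src <- c(src, which(ok))
    dst <- c(dst, ((r2 - 1L) * cols + c2)[ok])
  }
  new_index <- cumsum(keep); new_index[!keep] <- NA_integer_
  ok <- keep[src] & keep[dst]
  g <- map_graph(sum(keep), cbind(new_index[src[ok]], new_index[dst[ok]]),
                 datum_id = datum_id, label = label)
  attr(g, "grid_dims") <- c(rows, cols)
  attr(g, "grid_cells") <- which(keep)
  g
}

#' Point-cloud map graph from 3D coordinates
#'
#' Tokens with one 3D coordinate each (e.g. a representative atom per
#' residue), connected when their Euclidean distance is at most
#' `cutoff` (in the same units as the coordinates, typically Angstrom).
#'
#' @param coords numeric matrix T x 3 of finite coordinates.
#' @param cutoff positive distance threshold.
#' @param datum_id,label passed to [map_graph()].
#' @return a `map_graph`.
#' @export
build_pointcloud_graph <- function(coords, cutoff, datum_id = "points",
                                   label = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must have 3 columns")
  if (any(!is.finite(coords))) stop("coords must be finite")
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("cutoff must be a positive number")
  n <- nrow(coords)
  edges <- NULL
  if (n >= 2L) {
    d <- as.matrix(stats::dist(coords))
    pair <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
    edges <- pair[, c("row", "col"), drop = FALSE]
  }
  map_graph(n, edges, datum_id = datum_id, label = label)
}

#' r-neighborhood of a vertex
#'
#' All vertices within unweighted shortest-path (hop) distance `r` of
#' `vertex`, always including `vertex` itself (`r = 0` gives the
#' singleton set).
#'
#' @param graph a `map_graph`.
#' @param vertex vertex index in `1..n_vertices`.
#' @param r non-negative integer radius.
#' @return sorted integer vector of vertex indices.
#' @export
neighborhood <- function(graph, vertex, r) {
  stopifnot(inherits(graph, "map_graph"))
  vertex <- as.integer(vertex); r <- as.integer(r)
  if (is.na(vertex) || vertex < 1L || vertex > graph$n_vertices)
    stop("vertex index out of range")
  if (is.na(r) || r < 0L) stop("r must be a non-negative integer")
  sort(as.integer(
    igraph::ego(mg_igraph(graph), order = r, nodes = vertex)[[1L]]))
}

# r-neighborhoods of every vertex at once (list of integer vectors)
all_neighborhoods <- function(graph, r) {
  lapply(igraph::ego(mg_igraph(graph), order = r), as.integer)
}

# ---- serialization -------------------------------------------------------
# Text formats, one datum per set of files in a directory:
#   <id>.graph.tsv  edge list src<TAB>dst with '#' header lines
#                   (n_vertices, datum_id, label, indexing: 1-based)
#   <id>.mask.tsv   one positive vertex index per line (written only
#                   when a mask is attached)
#   <id>.embed.tsv  whitespace-delimited dense matrix, rows = vertices

num_fmt <- function(x) sprintf("%.17g", x)

#' Write a map graph to plain-text files
#'
#' @param graph a `map_graph`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_map_graph <- function(graph, dir) {
  stopifnot(inherits(graph, "map_graph"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- graph$datum_id
  gpath <- file.path(dir, paste0(id, ".graph.tsv"))
  hdr <- c("# map_graph v1",
           "# indexing: 1-based",
           sprintf("# n_vertices: %d", graph$n_vertices),
           sprintf("# datum_id: %s", id),
           sprintf("# label: %s",
                   if (is.null(graph$label)) "NA" else graph$label),
           "src\tdst")
  body <- sprintf("%d\t%d", graph$edges[, 1L], graph$edges[, 2L])
  writeLines(c(hdr, body), gpath)
  paths <- gpath
  if (!is.null(graph$mask)) {
    mpath <- file.path(dir, paste0(id, ".mask.tsv"))
    writeLines(c("# mask v1 (positive vertex indices, 1-based)",
                 sprintf("# n_vertices: %d", graph$n_vertices),
                 as.character(which(graph$mask))), mpath)
    paths <- c(paths, mpath)
  }
  if (!is.null(graph$embeddings)) {
    epath <- file.path(dir, paste0(id, ".embed.tsv"))
    writeLines(apply(graph$embeddings, 1L,
                     function(row) paste(num_fmt(row), collapse = "\t")),
               epath)
    paths <- c(paths, epath)
  }
  invisible(paths)
}

header_field <- function(lines, key) {
  pat <- paste0("^# ", key, ": ")
  hit <- grep(pat, lines, value = TRUE)
  if (length(hit) == 0L) stop("missing header field: ", key)
  sub(pat, "", hit[1L])
}

#' Read a map graph written by [write_map_graph()]
#'
#' @param dir directory containing the files.
#' @param id datum identifier (file stem).
#' @return a `map_graph` with mask and embeddings re-attached when their
#'   files are present.
#' @export
read_map_graph <- function(dir, id) {
  gpath <- file.path(dir, paste0(id, ".graph.tsv"))
  if (!file.exists(gpath)) stop("no graph file for datum '", id, "'")
  lines <- readLines(gpath)
  n <- as.integer(header_field(lines, "n_vertices"))
  lab <- header_field(lines, "label")
  label <- if (identical(lab, "NA")) NULL else as.integer(lab)
  body <- lines[!startsWith(lines, "#")]
  body <- body[body != "" & body != "src\tdst"]
  edges <- if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    matrix(as.integer(unlist(parts)), ncol = 2L, byrow = TRUE)
  } else NULL
  mask <- NULL
  mpath <- file.path(dir, paste0(id, ".mask.tsv"))
  if (file.exists(mpath)) {
    mlines <- readLines(mpath)
    idx <- as.integer(mlines[!startsWith(mlines, "#") & mlines != ""])
    mask <- rep(FALSE, n); mask[idx] <- TRUE
  }
  emb <- NULL
  epath <- file.path(dir, paste0(id, ".embed.tsv"))
  if (file.exists(epath)) {
    emb <- as.matrix(utils::read.table(epath, header = FALSE, sep = "\t"))
    dimnames(emb) <- NULL
  }
  map_graph(n, edges, embeddings = emb, mask = mask,
            datum_id = id, label = label)
}
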