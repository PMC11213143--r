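# Layer II inference: convolve the fitted kernel over every vertex of
# a sprite to produce a prospect map of attribution scores.

#' Convolve a kernel over a sprite
#'
#' For every vertex v, with N_r(v) the set of vertices within hop
#' distance r of v (including v itself), the attribution score is
#'
#'   a(v) = sum over u in N_r(v) of w<mono(c_u)>
#'        + sum over unordered pairs \{u, w\} of distinct vertices in
#'          N_r(v) of w<bigram(c_u, c_w)>
#'
#' i.e. the total kernel weight of all concept monograms and
#' skip-bigrams present in the neighborhood. r controls the degree of
#' smoothing over the map. Implemented via per-neighborhood concept
#' histograms, costing O(sum_v |N_r(v)| + T K^2) rather than the naive
#' O(sum_v |N_r(v)|^2).
#'
#' @param s a `sprite`.
#' @param kernel a `prospect_kernel` with matching K; its `r` field
#'   sets the neighborhood radius.
#' @param normalize divide each score by |N_r(v)| (default FALSE;
#'   scores are raw neighborhood totals).
#' @return an object of class `prospect_map`: `topology`, `scores`
#'   (per-vertex numeric), `r`, `datum_id`.
#' @export
k2conv <- function(s, kernel, normalize = FALSE) {
  stopifnot(inherits(s, "sprite"), inherits(kernel, "prospect_kernel"))
  if (s$K != kernel$K)
    stop("sprite K (", s$K, ") does not match kernel K (", kernel$K, ")")
  H <- neighborhood_histograms(s, kernel$r)
  m <- kernel_matrices(kernel)
  mono_term <- as.numeric(H %*% m$mono)
  # unordered distinct pairs: (h' W h - sum_a h_a W_aa) / 2 per vertex
  HW <- H %*% m$bigram
  diagW <- diag(m$bigram)
  bigram_term <- (rowSums(HW * H) - as.numeric(H %*% diagW)) / 2
  scores <- mono_term + bigram_term
  if (normalize) scores <- scores / rowSums(H)
  structure(list(topology = s$topology, scores = scores,
                 r = kernel$r, datum_id = s$topology$datum_id),
            class = "prospect_map")
}

#' @export
print.prospect_map <- function(x, ...) {
  cat(sprintf("prospect_map '%s': %d vertices, r = %d, scores in [%.4g, %.4g]\n",
              x$datum_id, x$topology$n_vertices, x$r,
              min(x$scores), max(x$scores)))
  invisible(x)
}

#' Quantize and convolve a whole dataset
#'
#' Composition of [quantize()] and [k2conv()] per datum, preserving
#' order; errors are re-signalled with the offending datum's id.
#'
#' @param dataset list of `map_graph` objects with embeddings.
#' @param q a `quantizer`.
#' @param kernel a `prospect_kernel`.
#' @param normalize passed to [k2conv()].
#' @return list of `prospect_map`, one per datum.
#' @export
batch_prospect <- function(dataset, q, kernel, normalize = FALSE) {
  lapply(dataset, function(g) {
    tryCatch(k2conv(quantize(g, q), kernel, normalize = normalize),
             error = function(e)
               stop("datum '", g$datum_id, "': ", conditionMessage(e),
                    call. = FALSE))
  })
}

#' Export a prospect map as TSV
#'
#' Columns `vertex`, `score`; for graphs built by [build_grid_graph()]
#' set `grid = TRUE` to write `row`, `col`, `score` instead (using the
#' recorded raster shape).
#'
#' @param p a `prospect_map`.
#' @param path file path.
#' @param grid write grid coordinates instead of vertex indices.
#' @export
write_prospect_map <- function(p, path, grid = FALSE) {
  stopifnot(inherits(p, "prospect_map"))
  hdr <- sprintf("# prospect_map v1 (datum_id: %s, r: %d)", p$datum_id, p$r)
  if (grid) {
    dims <- attr(p$topology, "grid_dims")
    cells <- attr(p$topology, "grid_cells")
    if (is.null(dims)) stop("topology carries no grid metadata")
    rows <- (cells - 1L) %/% dims[2L] + 1L
    cols <- (cells - 1L) %% dims[2L] + 1L
    writeLines(c(hdr, "row\tcol\tscore",
                 sprintf("%d\t%d\t%s", rows, cols, num_fmt(p$scores))),
               path)
  } else {
    writeLines(c(hdr, "vertex\tscore",
                 sprintf("%d\t%s", seq_along(p$scores), num_fmt(p$scores))),
               path)
  }
  invisible(path)
}

#' Read a prospect map TSV written by [write_prospect_map()]
#'
#' @param path file path (vertex format).
#' @param graph optional `map_graph` to attach as topology.
#' @return a `prospect_map` (topology NULL unless supplied).
#' @export
read_prospect_map <- function(path, graph = NULL) {
  lines <- readLines(path)
  meta <- sub("^# prospect_map v1 \\(datum_id: (.*), r: (\\d+)\\)$", "\\1|\\2",
              lines[1L])
  parts <- strsplit(meta, "|", fixed = TRUE)[[1L]]
  body <- lines[!startsWith(lines, "#") & !startsWith(lines, "vertex") &
                lines != ""]
  sc <- vapply(strsplit(body, "\t", fixed = TRUE),
               function(p) as.numeric(p[2L]), 0)
  structure(list(topology = graph, scores = sc,
                 r = as.integer(parts[2L]), datum_id = parts[1L]),
            class = "prospect_map")
}
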