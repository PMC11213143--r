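# Rollup: datum-level monogram and skip-bigram frequencies over all
# r-neighborhoods of a sprite.
#
# Feature keys live in a fixed universe for a vocabulary of size K:
# monograms m1..mK followed by canonical unordered bigrams b<a>.<b>
# with a <= b, in lexicographic order. The unordered keying carries
# K + K(K+1)/2 entries; an ordered Cartesian-product keying (the 2K+K^2
# upper bound) distinguishes (a,b) from (b,a), but the convolution sums
# over unordered vertex pairs of an undirected neighborhood, so the two
# keyings are equivalent and the canonical one is used throughout.

#' Feature key helpers
#'
#' `feature_keys(K)` returns the full ordered key universe for a
#' vocabulary of `K` concepts; `mono_key(c)` and `bigram_key(a, b)`
#' build individual keys (bigrams are canonicalized so that
#' `bigram_key(a, b) == bigram_key(b, a)`).
#'
#' @param K vocabulary size.
#' @return character vector of keys.
#' @export
feature_keys <- function(K) {
  K <- as.integer(K)
  stopifnot(K >= 1L)
  pairs <- which(upper.tri(diag(K), diag = TRUE), arr.ind = TRUE)
  ord <- order(pairs[, "row"], pairs[, "col"])
  c(sprintf("m%d", seq_len(K)),
    sprintf("b%d.%d", pairs[ord, "row"], pairs[ord, "col"]))
}

#' @rdname feature_keys
#' @param c,a,b concept indices.
#' @export
mono_key <- function(c) sprintf("m%d", as.integer(c))

#' @rdname feature_keys
#' @export
bigram_key <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  sprintf("b%d.%d", pmin(a, b), pmax(a, b))
}

# per-vertex concept histograms over r-neighborhoods: T x K integer matrix
neighborhood_histograms <- function(s, r) {
  stopifnot(inherits(s, "sprite"))
  r <- as.integer(r)
  if (is.na(r) || r < 0L) stop("r must be a non-negative integer")
  Tn <- s$topology$n_vertices
  nb <- all_neighborhoods(s$topology, r)
  members <- unlist(nb, use.names = FALSE)
  owner <- rep.int(seq_len(Tn), lengths(nb))
  counts <- tabulate((owner - 1L) * s$K + s$concepts[members], Tn * s$K)
  matrix(counts, nrow = Tn, ncol = s$K, byrow = TRUE)
}

#' Roll a sprite up into a datum-level embedding
#'
#' Traverses every vertex's r-neighborhood (hop distance <= r,
#' including the vertex itself) and counts, summed over all T
#' neighborhoods: each member vertex's concept (monograms) and each
#' unordered pair of distinct member vertices' concepts (skip-bigrams —
#' "skip" because the paired vertices need not be adjacent). The result
#' is a bag-of-concepts vector over the full key universe.
#'
#' @param s a `sprite`.
#' @param r non-negative neighborhood radius.
#' @return an object of class `sprite_embedding`: `counts` (named
#'   numeric over [feature_keys()]), `rescaled` (NULL until
#'   [rescale_embeddings()]), `datum_id`, `label`, `r`, `K`.
#' @export
rollup <- function(s, r) {
  H <- neighborhood_histograms(s, r)
  K <- s$K
  mono <- colSums(H)
  M <- crossprod(H)                      # sum_v H[v,a] * H[v,b]
  counts <- numeric(K + K * (K + 1L) / 2L)
  names(counts) <- feature_keys(K)
  counts[seq_len(K)] <- mono
  pos <- K
  for (a in seq_len(K)) for (b in a:K) {
    pos <- pos + 1L
    counts[pos] <- if (a == b) (M[a, a] - mono[a]) / 2 else M[a, b]
  }
  structure(list(counts = counts, rescaled = NULL,
                 datum_id = s$topology$datum_id,
                 label = s$topology$label, r = as.integer(r), K = K),
            class = "sprite_embedding")
}

#' @export
print.sprite_embedding <- function(x, ...) {
  cat(sprintf("sprite_embedding '%s': K = %d, r = %d, %d keys (%d nonzero)%s\n",
              x$datum_id, x$K, x$r, length(x$counts), sum(x$counts > 0),
              if (is.null(x$rescaled)) "" else ", rescaled"))
  invisible(x)
}

#' Rescale sprite embeddings across a dataset
#'
#' Converts raw rollup counts into per-datum probabilities so that
#' class profiles are comparable across data of different sizes.
#' `l1` divides each datum's counts by their total (the default; the
#' result is a probability vector over the key universe). `tfidf`
#' multiplies the l1 term frequencies by smoothed inverse document
#' frequencies `ln(N / (1 + df_key)) + 1` (df = number of data with a
#' nonzero count for the key) and re-normalizes each datum to sum 1.
#'
#' @param embeddings list of `sprite_embedding` objects sharing K and r.
#' @param method "l1" or "tfidf".
#' @return the input list with the `rescaled` field filled in.
#' @export
rescale_embeddings <- function(embeddings, method = c("l1", "tfidf")) {
  method <- match.arg(method)
  if (length(embeddings) == 0L) stop("need at least one embedding")
  Ks <- vapply(embeddings, function(e) {
    stopifnot(inherits(e, "sprite_embedding"))
    e$K
  }, 0L)
  rs <- vapply(embeddings, `[[`, 0L, "r")
  if (length(unique(Ks)) > 1L || length(unique(rs)) > 1L)
    stop("all embeddings must share the same K and r")
  Z <- do.call(rbind, lapply(embeddings, `[[`, "counts"))
  tot <- rowSums(Z)
  if (any(tot == 0)) {
    bad <- vapply(embeddings[tot == 0], `[[`, "", "datum_id")
    stop("zero total count for datum(s): ", paste(bad, collapse = ", "))
  }
  tf <- Z / tot
  if (method == "tfidf") {
    df <- colSums(Z > 0)
    idf <- log(nrow(Z) / (1 + df)) + 1
    tf <- tf * rep(idf, each = nrow(Z))
    tf <- tf / rowSums(tf)
  }
  for (i in seq_along(embeddings)) {
    v <- tf[i, ]
    names(v) <- colnames(Z)
    embeddings[[i]]$rescaled <- v
  }
  embeddings
}

#' Export a sprite embedding as TSV
#'
#' Columns: `key_type` (mono/bigram), `c1`, `c2` (empty for
#' monograms), `count`, `rescaled` (empty if not rescaled).
#'
#' @param e a `sprite_embedding`.
#' @param path file path.
#' @export
write_sprite_embedding <- function(e, path) {
  stopifnot(inherits(e, "sprite_embedding"))
  keys <- names(e$counts)
  is_mono <- startsWith(keys, "m")
  c1 <- ifelse(is_mono, sub("^m", "", keys), sub("^b(\\d+)\\.\\d+$", "\\1", keys))
  c2 <- ifelse(is_mono, "", sub("^b\\d+\\.(\\d+)$", "\\1", keys))
  resc <- if (is.null(e$rescaled)) rep("", length(keys)) else num_fmt(e$rescaled)
  writeLines(c(sprintf("# sprite_embedding v1 (datum_id: %s, K: %d, r: %d)",
                       e$datum_id, e$K, e$r),
               "key_type\tc1\tc2\tcount\trescaled",
               sprintf("%s\t%s\t%s\t%s\t%s",
                       ifelse(is_mono, "mono", "bigram"),
                       c1, c2, num_fmt(e$counts), resc)),
             path)
  invisible(path)
}
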