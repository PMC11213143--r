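# Layer II fitting: learn the global kernel mapping every monogram and
# skip-bigram key to a class-association weight.

embedding_matrix <- function(embeddings, slot = "rescaled") {
  rows <- lapply(embeddings, function(e) {
    stopifnot(inherits(e, "sprite_embedding"))
    v <- e[[slot]]
    if (is.null(v))
      stop("embeddings must be rescaled first (see rescale_embeddings)")
    v
  })
  if (length(unique(lengths(rows))) > 1L)
    stop("all embeddings must share the same key universe")
  do.call(rbind, rows)
}

embedding_labels <- function(embeddings) {
  labs <- vapply(embeddings, function(e) {
    if (is.null(e$label)) stop("datum '", e$datum_id, "' has no label")
    e$label
  }, integer(1))
  labs
}

#' Mean sprite embeddings per class
#'
#' The class profiles are the arithmetic means of the rescaled sprite
#' embeddings within each class, with keys absent from a datum counting
#' as zero. The class-0 mean plays the role of a baseline vector that
#' class-1 data are compared against.
#'
#' @param embeddings list of rescaled `sprite_embedding`s with labels;
#'   both classes must be present.
#' @return an object of class `class_profiles` with fields
#'   `mean_class0`, `mean_class1` (named numeric over the key
#'   universe), `n0`, `n1`, `K`, `r`.
#' @export
compute_class_profiles <- function(embeddings) {
  Z <- embedding_matrix(embeddings)
  y <- embedding_labels(embeddings)
  if (!all(c(0L, 1L) %in% y))
    stop("both classes must be present in the training data")
  structure(list(
    mean_class0 = colMeans(Z[y == 0L, , drop = FALSE]),
    mean_class1 = colMeans(Z[y == 1L, , drop = FALSE]),
    n0 = sum(y == 0L), n1 = sum(y == 1L),
    K = embeddings[[1L]]$K, r = embeddings[[1L]]$r),
    class = "class_profiles")
}

# Welch two-sample t-test p-values, vectorized over columns.
# Zero pooled standard error: p = 1 when the means agree, 0 otherwise.
welch_p_values <- function(X1, X0) {
  n1 <- nrow(X1); n0 <- nrow(X0)
  if (n1 < 2L || n0 < 2L)
    stop("the significance filter needs at least two data per class")
  m1 <- colMeans(X1); m0 <- colMeans(X0)
  v1 <- colSums(sweep(X1, 2L, m1)^2) / (n1 - 1L)
  v0 <- colSums(sweep(X0, 2L, m0)^2) / (n0 - 1L)
  se2 <- v1 / n1 + v0 / n0
  tstat <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v0 / n0)^2 / (n0 - 1L))
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(m1[degenerate] == m0[degenerate], 1, 0)
  p
}

new_kernel <- function(weights, K, r, variant, hyperparams,
                       p_values = NULL) {
  structure(list(weights = weights, K = as.integer(K), r = as.integer(r),
                 variant = variant, hyperparams = hyperparams,
                 p_values = p_values),
            class = "prospect_kernel")
}

#' @export
print.prospect_kernel <- function(x, ...) {
  cat(sprintf("prospect_kernel (%s): K = %d, r = %d, %d keys (%d nonzero)\n",
              x$variant, x$K, x$r, length(x$weights),
              sum(x$weights != 0)))
  invisible(x)
}

#' Fit a kernel by class-wise log2 fold changes
#'
#' The parameter-free variant: each key's raw weight is
#' `log2(mean_class1 + epsilon) - log2(mean_class0 + epsilon)`, the
#' log fold change of its class-mean probabilities (the pseudocount
#' guards the log at zero). Keys whose per-datum rescaled values do not
#' differ between classes by a Welch two-sample t-test at level `alpha`
#' are zeroed out, which regularizes the kernel toward the class-0
#' baseline.
#'
#' @param profiles `class_profiles` from [compute_class_profiles()].
#' @param embeddings the rescaled, labeled embeddings the profiles were
#'   computed from (used for the per-key test).
#' @param alpha significance level in (0, 1), default 0.05.
#' @param epsilon positive pseudocount, default 1e-6.
#' @param bh_correct apply Benjamini-Hochberg correction to the per-key
#'   p-values before thresholding (default FALSE).
#' @return a `prospect_kernel` (variant "fold_change") whose
#'   `p_values` field stores the per-key test results.
#' @export
fit_kernel_foldchange <- function(profiles, embeddings, alpha = 0.05,
                                  epsilon = 1e-6, bh_correct = FALSE) {
  stopifnot(inherits(profiles, "class_profiles"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (!is.numeric(epsilon) || epsilon <= 0) stop("epsilon must be positive")
  raw <- log2(profiles$mean_class1 + epsilon) -
         log2(profiles$mean_class0 + epsilon)
  Z <- embedding_matrix(embeddings)
  y <- embedding_labels(embeddings)
  p <- welch_p_values(Z[y == 1L, , drop = FALSE],
                      Z[y == 0L, , drop = FALSE])
  names(p) <- colnames(Z)
  p_adj <- if (bh_correct) stats::p.adjust(p, method = "BH") else p
  weights <- ifelse(p_adj < alpha, raw, 0)
  names(weights) <- names(raw)
  new_kernel(weights, profiles$K, profiles$r, "fold_change",
             list(alpha = alpha, epsilon = epsilon,
                  bh_correct = bh_correct),
             p_values = p)
}

#' Fit a kernel by elastic-net logistic regression
#'
#' The trainable variant: a binary logistic regression of the datum
#' label on the rescaled sprite embedding, with an elastic-net penalty
#' mixing lasso and ridge via `lambda_mix` (1 = lasso, 0 = ridge) at
#' fixed regularization `strength`. The fitted coefficients become the
#' kernel weights; the intercept is fitted but excluded. Embeddings are
#' already on a common probability scale, so no re-standardization is
#' applied.
#'
#' @param embeddings list of rescaled, labeled `sprite_embedding`s.
#' @param lambda_mix elastic-net mixing in [0, 1], default 0.5.
#' @param strength positive regularization strength, default 0.01.
#' @return a `prospect_kernel` (variant "linear").
#' @export
fit_kernel_linear <- function(embeddings, lambda_mix = 0.5,
                              strength = 0.01) {
  if (!is.numeric(lambda_mix) || lambda_mix < 0 || lambda_mix > 1)
    stop("lambda_mix must lie in [0, 1]")
  if (!is.numeric(strength) || strength <= 0)
    stop("strength must be positive")
  Z <- embedding_matrix(embeddings)
  y <- embedding_labels(embeddings)
  if (!all(c(0L, 1L) %in% y))
    stop("both classes must be present in the training data")
  fit <- tryCatch(
    glmnet::glmnet(Z, y, family = "binomial", alpha = lambda_mix,
                   lambda = strength, standardize = FALSE,
                   thresh = 1e-8, maxit = 1e4),
    error = function(e)
      stop("linear kernel fit failed (degenerate design?): ",
           conditionMessage(e)))
  weights <- as.numeric(fit$beta[, 1L])
  names(weights) <- colnames(Z)
  new_kernel(weights, embeddings[[1L]]$K, embeddings[[1L]]$r, "linear",
             list(lambda_mix = lambda_mix, strength = strength))
}

#' Look up a kernel weight
#'
#' Dictionary semantics: unseen keys return 0; bigram queries are
#' canonicalized so `(a, b)` and `(b, a)` return the same weight.
#'
#' @param kernel a `prospect_kernel`.
#' @param key a feature key from [mono_key()] or [bigram_key()].
#' @return the stored weight, or 0 when absent.
#' @export
kernel_lookup <- function(kernel, key) {
  stopifnot(inherits(kernel, "prospect_kernel"))
  concepts <- as.integer(strsplit(sub("^[mb]", "", key), ".", fixed = TRUE)[[1L]])
  if (any(concepts < 1L) || any(concepts > kernel$K))
    stop("key concept outside 1..K")
  if (startsWith(key, "b"))
    key <- bigram_key(concepts[1L], concepts[2L])
  w <- kernel$weights[key]
  if (is.na(w)) 0 else unname(w)
}

# kernel as a monogram vector and symmetric K x K bigram matrix
kernel_matrices <- function(kernel) {
  K <- kernel$K
  wmono <- numeric(K)
  W <- matrix(0, K, K)
  for (key in names(kernel$weights)) {
    w <- kernel$weights[[key]]
    if (startsWith(key, "m")) {
      wmono[as.integer(sub("^m", "", key))] <- w
    } else {
      ab <- as.integer(strsplit(sub("^b", "", key), ".", fixed = TRUE)[[1L]])
      W[ab[1L], ab[2L]] <- w
      W[ab[2L], ab[1L]] <- w
    }
  }
  list(mono = wmono, bigram = W)
}

#' Serialize a kernel to a structured text file
#'
#' Metadata block followed by one line per key in stable universe
#' order: `key_type c1 c2 weight p_value` (p_value empty for the
#' linear variant).
#'
#' @param kernel a `prospect_kernel`.
#' @param path file path.
#' @export
write_kernel <- function(kernel, path) {
  stopifnot(inherits(kernel, "prospect_kernel"))
  hp <- kernel$hyperparams
  keys <- names(kernel$weights)
  is_mono <- startsWith(keys, "m")
  c1 <- ifelse(is_mono, sub("^m", "", keys),
               sub("^b(\\d+)\\.\\d+$", "\\1", keys))
  c2 <- ifelse(is_mono, "", sub("^b\\d+\\.(\\d+)$", "\\1", keys))
  pv <- if (is.null(kernel$p_values)) rep("", length(keys))
        else num_fmt(kernel$p_values[keys])
  writeLines(c("# prospect_kernel v1",
               sprintf("# variant: %s", kernel$variant),
               sprintf("# K: %d", kernel$K),
               sprintf("# r: %d", kernel$r),
               sprintf("# hyperparams: %s",
                       paste(names(hp), unlist(hp), sep = "=",
                             collapse = ",")),
               "key_type\tc1\tc2\tweight\tp_value",
               sprintf("%s\t%s\t%s\t%s\t%s",
                       ifelse(is_mono, "mono", "bigram"), c1, c2,
                       num_fmt(kernel$weights), pv)),
             path)
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  lines <- readLines(path)
  K <- as.integer(header_field(lines, "K"))
  r <- as.integer(header_field(lines, "r"))
  variant <- header_field(lines, "variant")
  hp_str <- header_field(lines, "hyperparams")
  hp <- list()
  for (kv in strsplit(hp_str, ",", fixed = TRUE)[[1L]]) {
    parts <- strsplit(kv, "=", fixed = TRUE)[[1L]]
    val <- suppressWarnings(as.numeric(parts[2L]))
    hp[[parts[1L]]] <- if (is.na(val)) as.logical(parts[2L]) else val
  }
  body <- lines[!startsWith(lines, "#") & lines != "" &
                !startsWith(lines, "key_type")]
  parts <- strsplit(body, "\t", fixed = TRUE)
  keys <- vapply(parts, function(p) {
    if (p[1L] == "mono") mono_key(p[2L]) else bigram_key(p[2L], p[3L])
  }, "")
  weights <- vapply(parts, function(p) as.numeric(p[4L]), 0)
  names(weights) <- keys
  p_values <- vapply(parts, function(p)
    if (length(p) >= 5L && nzchar(p[5L])) as.numeric(p[5L]) else NA_real_, 0)
  names(p_values) <- keys
  if (all(is.na(p_values))) p_values <- NULL
  new_kernel(weights, K, r, variant, hp, p_values = p_values)
}

#' Export kernel internals for interpretability
#'
#' Writes the monogram weight vector and the concept-by-concept bigram
#' weight matrix as TSVs, the tabular form behind semantic-network and
#' heatmap renderings of a fitted kernel.
#'
#' @param kernel a `prospect_kernel`.
#' @param mono_path,bigram_path output TSV paths.
#' @export
export_kernel_tables <- function(kernel, mono_path, bigram_path) {
  m <- kernel_matrices(kernel)
  writeLines(c("concept\tweight",
               sprintf("%d\t%s", seq_len(kernel$K), num_fmt(m$mono))),
             mono_path)
  writeLines(c(paste(c("concept", sprintf("c%d", seq_len(kernel$K))),
                     collapse = "\t"),
               vapply(seq_len(kernel$K), function(a)
                 paste(c(sprintf("%d", a), num_fmt(m$bigram[a, ])),
                       collapse = "\t"), "")),
             bigram_path)
  invisible(c(mono_path, bigram_path))
}
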