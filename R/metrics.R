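# Token-level localization metrics, region-characteristic statistics,
# and sequential model selection over hyperparameter grids.

check_mask <- function(scores, mask) {
  mask <- as.logical(mask)
  if (length(mask) != length(scores))
    stop("scores and mask must have equal length")
  if (any(is.na(mask)) || any(!is.finite(scores)))
    stop("scores must be finite and mask free of NA")
  if (!any(mask) || all(mask))
    stop("mask must contain at least one positive and one negative")
  mask
}

#' Area under the precision-recall curve
#'
#' Ranks vertices by score (descending) and accumulates the step-wise
#' sum \eqn{\sum_n (R_n - R_{n-1}) P_n} over the distinct score
#' thresholds, i.e. the non-interpolated area under the
#' precision-recall curve. Tied scores enter as a single threshold.
#' A random or constant ranking scores about the mask prevalence; a
#' perfect ranking scores 1.
#'
#' @param scores per-vertex numeric scores.
#' @param mask per-vertex logical ground truth with at least one
#'   positive and one negative.
#' @return AUPRC in [0, 1].
#' @export
auprc <- function(scores, mask) {
  mask <- check_mask(scores, mask)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; m <- mask[ord]
  tp <- cumsum(m); fp <- cumsum(!m)
  last_of_block <- c(s[-1L] != s[-length(s)], TRUE)
  tp <- tp[last_of_block]; fp <- fp[last_of_block]
  prec <- tp / (tp + fp)
  rec <- tp / sum(mask)
  sum(diff(c(0, rec)) * prec)
}

#' Precision, dice and Matthews correlation at a threshold
#'
#' Binarizes `score >= threshold` as positive and computes
#' precision = TP/(TP+FP), dice = 2TP/(2TP+FP+FN) and the Matthews
#' correlation coefficient from the contingency table. Conventions:
#' 0/0 precision and dice are 0; MCC with a zero denominator is 0.
#'
#' @param scores,mask as in [auprc()].
#' @param threshold binarization threshold; the default 0 suits signed
#'   fold-change kernels, where positive scores mark class-1
#'   association.
#' @return named numeric `c(precision, dice, mcc)`.
#' @export
threshold_metrics <- function(scores, mask, threshold = 0) {
  mask <- check_mask(scores, mask)
  pred <- scores >= threshold
  tp <- sum(pred & mask); fp <- sum(pred & !mask)
  fn <- sum(!pred & mask); tn <- sum(!pred & !mask)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  dice <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  c(precision = precision, dice = dice, mcc = mcc)
}

#' Average precision over a threshold set
#'
#' The mean of the precision values obtained by binarizing at each
#' supplied threshold (0/0 precision counts as 0). Distinct from the
#' PR-curve area of [auprc()]; by default the thresholds are the
#' deciles of the score distribution (see [evaluate_map()]).
#'
#' @param scores,mask as in [auprc()].
#' @param thresholds non-empty numeric vector.
#' @return mean precision in [0, 1].
#' @export
average_precision_thresholds <- function(scores, mask, thresholds) {
  mask <- check_mask(scores, mask)
  if (length(thresholds) == 0L) stop("thresholds must be non-empty")
  mean(vapply(thresholds, function(t) {
    pred <- scores >= t
    tp <- sum(pred & mask); fp <- sum(pred & !mask)
    if (tp + fp == 0) 0 else tp / (tp + fp)
  }, 0))
}

decile_thresholds <- function(scores) {
  unname(stats::quantile(scores, probs = seq(0.1, 1, by = 0.1), type = 7))
}

#' Prevalence and dispersion of a masked region
#'
#' Characterizes the ground-truth class-1 region of a datum:
#' prevalence is the fraction of masked tokens; dispersion is the
#' number of connected components of the mask-induced subgraph divided
#' by their mean size (an empty mask gives prevalence 0, dispersion 0).
#' Low dispersion means one large compact region; singletons scattered
#' over the graph give dispersion equal to their count.
#'
#' @param graph a `map_graph`.
#' @param mask per-vertex logical of length `n_vertices`.
#' @return an object of class `region_stats`: `prevalence`,
#'   `dispersion`, `n_components`, `mean_component_size`.
#' @export
region_stats <- function(graph, mask) {
  stopifnot(inherits(graph, "map_graph"))
  mask <- as.logical(mask)
  if (length(mask) != graph$n_vertices || any(is.na(mask)))
    stop("mask must be logical of length n_vertices")
  if (!any(mask)) {
    return(structure(list(prevalence = 0, dispersion = 0,
                          n_components = 0L, mean_component_size = 0),
                     class = "region_stats"))
  }
  sub <- igraph::induced_subgraph(mg_igraph(graph), which(mask))
  comp <- igraph::components(sub)
  mean_size <- mean(comp$csize)
  structure(list(prevalence = sum(mask) / graph$n_vertices,
                 dispersion = comp$no / mean_size,
                 n_components = comp$no,
                 mean_component_size = mean_size),
            class = "region_stats")
}

#' @export
print.region_stats <- function(x, ...) {
  cat(sprintf(
    "region_stats: prevalence %.3f, dispersion %.3f (%d components, mean size %.2f)\n",
    x$prevalence, x$dispersion, x$n_components, x$mean_component_size))
  invisible(x)
}

#' Evaluate one prospect map against a ground-truth mask
#'
#' @param p a `prospect_map`.
#' @param mask per-vertex logical ground truth (defaults to the mask
#'   attached to the map's topology).
#' @param threshold binarization threshold for precision/dice/MCC.
#' @param ap_thresholds thresholds for [average_precision_thresholds()];
#'   default the deciles of this datum's scores.
#' @return an object of class `eval_result`: `auprc`, `ap`,
#'   `precision`, `dice`, `mcc`, `threshold`, `datum_id`.
#' @export
evaluate_map <- function(p, mask = NULL, threshold = 0,
                         ap_thresholds = NULL) {
  stopifnot(inherits(p, "prospect_map"))
  if (is.null(mask)) {
    if (is.null(p$topology) || is.null(p$topology$mask))
      stop("no mask supplied and none attached to datum '", p$datum_id, "'")
    mask <- p$topology$mask
  }
  mask <- check_mask(p$scores, mask)
  if (is.null(ap_thresholds)) ap_thresholds <- decile_thresholds(p$scores)
  tm <- threshold_metrics(p$scores, mask, threshold)
  structure(list(auprc = auprc(p$scores, mask),
                 ap = average_precision_thresholds(p$scores, mask,
                                                  ap_thresholds),
                 precision = unname(tm["precision"]),
                 dice = unname(tm["dice"]), mcc = unname(tm["mcc"]),
                 threshold = threshold, datum_id = p$datum_id),
            class = "eval_result")
}

#' Macro-average evaluation results
#'
#' @param results list of `eval_result`.
#' @return named numeric of per-metric means over data.
#' @export
macro_average <- function(results) {
  stopifnot(length(results) >= 1L)
  mets <- c("auprc", "ap", "precision", "dice", "mcc")
  vapply(mets, function(m)
    mean(vapply(results, function(r) r[[m]], 0)), 0)
}

#' Sequential model selection over a hyperparameter grid
#'
#' Ranks candidates lexicographically by mean precision, then dice,
#' then MCC, then AUPRC (all descending) — the sequential ranking used
#' to pick a configuration from a grid by its ability to localize
#' ground-truth regions on the training set. Remaining ties go to the
#' smallest K, then smallest r, then input order.
#'
#' @param candidates non-empty list; each element has `hyperparams`
#'   (a list, ideally with `K` and `r`) and `metrics` (named numeric
#'   with `precision`, `dice`, `mcc`, `auprc`, macro-averaged over the
#'   training data).
#' @return the winning candidate, with its input position in field
#'   `index`.
#' @export
select_model <- function(candidates) {
  if (length(candidates) == 0L) stop("candidate list is empty")
  get_m <- function(cand, m) {
    v <- cand$metrics[[m]]
    if (is.null(v) || is.na(v)) -Inf else v
  }
  get_h <- function(cand, h) {
    v <- cand$hyperparams[[h]]
    if (is.null(v)) Inf else v
  }
  ord <- order(-vapply(candidates, get_m, 0, "precision"),
               -vapply(candidates, get_m, 0, "dice"),
               -vapply(candidates, get_m, 0, "mcc"),
               -vapply(candidates, get_m, 0, "auprc"),
               vapply(candidates, get_h, 0, "K"),
               vapply(candidates, get_h, 0, "r"),
               seq_along(candidates))
  best <- candidates[[ord[1L]]]
  best$index <- ord[1L]
  best
}
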