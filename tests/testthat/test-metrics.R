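test_that("auprc matches hand-computed PR areas", {
  expect_equal(auprc(c(0.9, 0.8, 0.1), c(TRUE, TRUE, FALSE)), 1)
  # one step at recall 1, precision 0.5
  expect_equal(auprc(c(0.1, 0.9), c(TRUE, FALSE)), 0.5)
  # constant scores: single threshold, precision = prevalence
  expect_equal(auprc(rep(1, 8), c(rep(TRUE, 2), rep(FALSE, 6))), 0.25)
  # worst ranking: positives last among 1 pos / 3 neg
  expect_equal(auprc(c(4, 3, 2, 1), c(FALSE, FALSE, FALSE, TRUE)), 0.25)
  expect_error(auprc(c(1, 2), c(TRUE, TRUE)), "positive and one negative")
})

test_that("auprc of random scores approaches prevalence", {
  set.seed(314)
  scores <- runif(1e4)
  mask <- seq_len(1e4) <= 2500
  expect_equal(auprc(scores, mask), 0.25, tolerance = 0.03)
})

test_that("auprc is invariant under strictly monotone transforms", {
  set.seed(7)
  scores <- rnorm(200)
  mask <- sample(c(TRUE, FALSE), 200, replace = TRUE, prob = c(0.3, 0.7))
  base <- auprc(scores, mask)
  expect_equal(auprc(3 * scores + 10, mask), base)
  expect_equal(auprc(exp(scores), mask), base)
  expect_equal(auprc(rank(scores), mask), base)
})

test_that("auprc agrees with an external PR-curve implementation", {
  has_sklearn <- nzchar(Sys.which("python")) &&
    system2(Sys.which("python"), c("-c", "'import sklearn'"),
            stdout = FALSE, stderr = FALSE) == 0
  if (!has_sklearn) {
    # fall back to a second independent hand case rather than skipping
    expect_equal(auprc(c(5, 4, 3, 2, 1),
                       c(TRUE, FALSE, TRUE, FALSE, FALSE)),
                 1 * 0.5 + (2 / 3 - 1 / 2) * 0 + 0.5 * 2 / 3)
    succeed()
    return()
  }
  set.seed(99)
  scores <- round(rnorm(60), 2)   # rounded -> ties exercised
  mask <- sample(c(TRUE, FALSE), 60, replace = TRUE)
  script <- paste(
    "import sys, json",
    "from sklearn.metrics import average_precision_score",
    "d = json.loads(sys.stdin.read())",
    "print(repr(average_precision_score(d['y'], d['s'])))",
    sep = "; ")
  out <- system2(Sys.which("python"), c("-c", shQuote(script)),
                 input = sprintf('{"y": [%s], "s": [%s]}',
                                 paste(as.integer(mask), collapse = ","),
                                 paste(scores, collapse = ",")),
                 stdout = TRUE)
  expect_equal(auprc(scores, mask), as.numeric(out), tolerance = 1e-12)
})

test_that("threshold metrics reproduce contingency-table formulas", {
  perfect <- threshold_metrics(c(1, 1, 0, 0), c(TRUE, TRUE, FALSE, FALSE),
                               threshold = 0.5)
  expect_equal(unname(perfect), c(1, 1, 1))

  # TP=3 FP=1 FN=1 TN=5
  scores <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  mask <- c(TRUE, TRUE, TRUE, FALSE, TRUE, rep(FALSE, 5))
  m <- threshold_metrics(scores, mask, 0.5)
  expect_equal(unname(m["precision"]), 0.75)
  expect_equal(unname(m["dice"]), 0.75)
  expect_equal(unname(m["mcc"]), 14 / 24, tolerance = 1e-12)
  # dice equals precision when FP = FN
  expect_equal(unname(m["dice"]), unname(m["precision"]))

  # all predicted negative: the 0/0 conventions give zeros
  none <- threshold_metrics(c(-1, -1, -1), c(TRUE, FALSE, FALSE), 0)
  expect_equal(unname(none), c(0, 0, 0))
})

test_that("average precision over thresholds is a mean of precisions", {
  scores <- c(0.9, 0.8, 0.2, 0.1)
  mask <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(average_precision_thresholds(scores, mask, 0.5), 1)
  expect_equal(average_precision_thresholds(scores, mask, c(0.5, 0.85)), 1)
  # single threshold equals that threshold's precision
  expect_equal(average_precision_thresholds(scores, mask, 0.15),
               unname(threshold_metrics(scores, mask, 0.15)["precision"]))
  # hand-built 10-token case over its deciles
  s10 <- seq(0.1, 1, by = 0.1)
  m10 <- c(rep(FALSE, 6), rep(TRUE, 4))
  dec <- unname(quantile(s10, seq(0.1, 1, 0.1)))
  by_hand <- mean(vapply(dec, function(t) {
    tp <- sum(s10 >= t & m10); fp <- sum(s10 >= t & !m10)
    if (tp + fp == 0) 0 else tp / (tp + fp)
  }, 0))
  expect_equal(average_precision_thresholds(s10, m10, dec), by_hand)
  expect_error(average_precision_thresholds(s10, m10, numeric(0)),
               "non-empty")
})

test_that("region stats follow the component-count / mean-size ratio", {
  g <- build_sequence_graph(20, 1)
  mask <- rep(FALSE, 20); mask[c(1:2, 10:13)] <- TRUE
  rs <- region_stats(g, mask)
  expect_equal(rs$prevalence, 6 / 20)
  expect_equal(rs$n_components, 2L)
  expect_equal(rs$mean_component_size, 3)
  expect_equal(rs$dispersion, 2 / 3)

  # empty mask convention
  rs0 <- region_stats(g, rep(FALSE, 20))
  expect_equal(c(rs0$prevalence, rs0$dispersion), c(0, 0))

  # one solid region of size s: dispersion 1/s
  mask1 <- rep(FALSE, 20); mask1[5:9] <- TRUE
  expect_equal(region_stats(g, mask1)$dispersion, 1 / 5)

  # n singletons: dispersion n
  maskn <- rep(FALSE, 20); maskn[c(1, 5, 9, 13)] <- TRUE
  expect_equal(region_stats(g, maskn)$dispersion, 4)

  # relabeling vertices while preserving the induced subgraph
  perm <- c(11:20, 1:10)
  g2 <- map_graph(20, cbind(perm[g$edges[, 1]], perm[g$edges[, 2]]))
  mask2 <- rep(FALSE, 20); mask2[perm[which(mask)]] <- TRUE
  expect_equal(region_stats(g2, mask2)$dispersion, rs$dispersion)
})

test_that("model selection ranks lexicographically with stable ties", {
  cand <- function(K, r, precision, dice = 0.5, mcc = 0.5, auprc = 0.5)
    list(hyperparams = list(K = K, r = r),
         metrics = c(precision = precision, dice = dice, mcc = mcc,
                     auprc = auprc))
  expect_equal(select_model(list(cand(3, 1, 0.7)))$hyperparams$K, 3)
  # precision dominates everything else
  best <- select_model(list(cand(3, 1, 0.9, dice = 0.1, auprc = 0.1),
                            cand(5, 2, 0.8, dice = 1, auprc = 1)))
  expect_equal(best$hyperparams$K, 3)
  # equal precision: dice decides
  best2 <- select_model(list(cand(3, 1, 0.8, dice = 0.6),
                             cand(5, 2, 0.8, dice = 0.7)))
  expect_equal(best2$hyperparams$K, 5)
  # full metric tie: smallest K then r then input order
  best3 <- select_model(list(cand(5, 2, 0.8), cand(3, 2, 0.8),
                             cand(3, 1, 0.8)))
  expect_equal(unlist(best3$hyperparams), c(K = 3, r = 1))
  best4 <- select_model(list(cand(3, 1, 0.8), cand(3, 1, 0.8)))
  expect_equal(best4$index, 1L)
  expect_error(select_model(list()), "empty")
})

test_that("evaluate_map bundles the per-datum metrics", {
  g <- build_sequence_graph(10, 1)
  g$mask <- c(rep(TRUE, 3), rep(FALSE, 7))
  s <- sprite(g, c(rep(2L, 3), rep(1L, 7)), 2L)
  kern <- random_kernel(2, 0, 5)
  kern$weights[] <- 0
  kern$weights["m2"] <- 1
  res <- evaluate_map(k2conv(s, kern), threshold = 0.5)
  expect_equal(res$auprc, 1)
  expect_equal(res$precision, 1)
  expect_equal(res$dice, 1)
  expect_equal(res$mcc, 1)
  expect_equal(macro_average(list(res, res))[["auprc"]], 1)
})
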