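# build a sprite_embedding by hand from a named count vector
manual_embedding <- function(counts, K, label, id = "m", r = 1L) {
  full <- stats::setNames(numeric(length(feature_keys(K))),
                          feature_keys(K))
  full[names(counts)] <- counts
  structure(list(counts = full, rescaled = NULL, datum_id = id,
                 label = as.integer(label), r = r, K = as.integer(K)),
            class = "sprite_embedding")
}

test_that("class profiles average rescaled embeddings with implicit zeros", {
  K <- 2L
  e1 <- manual_embedding(c(m1 = 4), K, 0, "a")        # l1 -> m1 = 1
  e2 <- manual_embedding(c(m2 = 2), K, 0, "b")        # l1 -> m2 = 1
  e3 <- manual_embedding(c(m1 = 1, m2 = 1), K, 1, "c")
  es <- rescale_embeddings(list(e1, e2, e3), "l1")
  prof <- compute_class_profiles(es)
  expect_equal(unname(prof$mean_class0[c("m1", "m2")]), c(0.5, 0.5))
  expect_equal(unname(prof$mean_class1[c("m1", "m2")]), c(0.5, 0.5))
  expect_equal(c(prof$n0, prof$n1), c(2L, 1L))

  # two identical class-0 data: profile equals either datum
  es2 <- rescale_embeddings(list(e1, e1, e3), "l1")
  expect_equal(compute_class_profiles(es2)$mean_class0,
               es2[[1]]$rescaled)

  # permuting data leaves profiles unchanged
  expect_equal(compute_class_profiles(es[c(3, 1, 2)]),
               compute_class_profiles(es))

  expect_error(compute_class_profiles(es[1:2]), "both classes")
})

test_that("fold-change weights are hand-computable log2 ratios", {
  K <- 2L
  # class means: m1 0.5 vs 0.25, m2 0.5 vs 0.75 — two data per class,
  # within-class values differ so the Welch test is defined
  mk <- function(p1, label, id) manual_embedding(
    c(m1 = p1 * 100, m2 = (1 - p1) * 100), K, label, id)
  es <- rescale_embeddings(list(
    mk(0.20, 0, "a"), mk(0.30, 0, "b"),
    mk(0.45, 1, "c"), mk(0.55, 1, "d")), "l1")
  prof <- compute_class_profiles(es)
  eps <- 1e-9
  kern <- fit_kernel_foldchange(prof, es, alpha = 0.2, epsilon = eps)
  expect_equal(kernel_lookup(kern, "m1"),
               log2(0.5 + eps) - log2(0.25 + eps), tolerance = 1e-6)
  expect_equal(kernel_lookup(kern, "m1"), 1.0, tolerance = 1e-4)
  expect_equal(kernel_lookup(kern, "m2"),
               log2(0.5 / 0.75), tolerance = 1e-4)

  # equal class means: raw fold change is zero everywhere
  es_eq <- rescale_embeddings(list(
    mk(0.4, 0, "a"), mk(0.6, 0, "b"), mk(0.4, 1, "c"), mk(0.6, 1, "d")),
    "l1")
  prof_eq <- compute_class_profiles(es_eq)
  raw <- log2(prof_eq$mean_class1 + 1e-6) - log2(prof_eq$mean_class0 + 1e-6)
  expect_true(all(raw == 0))

  expect_error(fit_kernel_foldchange(prof, es, alpha = 1.2), "alpha")
  expect_error(fit_kernel_foldchange(prof, es, epsilon = 0), "epsilon")
})

test_that("significance filter zeroes non-separated keys and controls nesting", {
  # key m2 (and its complement) drawn at very different rates by class;
  # planted key must survive and get the largest positive weight
  K <- 3L
  es <- withr::with_seed(42, {
    mk_rand <- function(label, id) {
      rate <- if (label == 1) 0.5 else 0.05
      n2 <- rbinom(1, 40, rate)
      n3 <- rbinom(1, 40, 0.2)
      manual_embedding(c(m1 = 40 - n2 / 2 - n3 / 2, m2 = n2, m3 = n3),
                       K, label, id)
    }
    c(lapply(1:40, function(i) mk_rand(0, paste0("c0_", i))),
      lapply(1:40, function(i) mk_rand(1, paste0("c1_", i))))
  })
  es <- rescale_embeddings(es, "l1")
  kern <- fit_kernel_foldchange(compute_class_profiles(es), es)
  w <- kern$weights
  expect_gt(w[["m2"]], 0)
  expect_equal(names(which.max(w)), "m2")
  # independent check of the test itself: per-key Welch via stats::t.test
  Z <- do.call(rbind, lapply(es, `[[`, "rescaled"))
  y <- vapply(es, `[[`, 0L, "label")
  for (key in c("m1", "m2", "m3")) {
    ref <- stats::t.test(Z[y == 1, key], Z[y == 0, key])$p.value
    expect_equal(unname(kern$p_values[key]), ref, tolerance = 1e-10)
  }
  # raising alpha never shrinks the surviving set
  surv <- function(a) names(which(
    fit_kernel_foldchange(compute_class_profiles(es), es,
                          alpha = a)$weights != 0))
  expect_true(all(surv(0.01) %in% surv(0.05)))
  expect_true(all(surv(0.05) %in% surv(0.5)))
})

test_that("fold-change kernels are antisymmetric under label swap", {
  es <- withr::with_seed(77, lapply(1:20, function(i) {
    s <- random_sprite(500 + i, K = 3)
    s$topology$label <- as.integer(i <= 10)
    rollup(s, 1)
  }))
  es <- rescale_embeddings(es, "l1")
  flip <- lapply(es, function(e) { e$label <- 1L - e$label; e })
  k1 <- fit_kernel_foldchange(compute_class_profiles(es), es,
                              epsilon = 1e-9)
  k2 <- fit_kernel_foldchange(compute_class_profiles(flip), flip,
                              epsilon = 1e-9)
  expect_equal(k1$p_values, k2$p_values)
  expect_equal(k1$weights, -k2$weights)
  # invariant to within-class ordering of the data
  k3 <- fit_kernel_foldchange(compute_class_profiles(rev(es)), rev(es),
                              epsilon = 1e-9)
  expect_equal(k3$weights, k1$weights)
})

test_that("linear variant recovers a separating key and sparsifies", {
  K <- 2L
  es <- withr::with_seed(9, c(
    lapply(1:40, function(i) manual_embedding(
      c(m1 = 50 + rnorm(1), m2 = abs(rnorm(1, 0, 0.5))), K, 0,
      paste0("a", i))),
    lapply(1:40, function(i) manual_embedding(
      c(m1 = 50 + rnorm(1), m2 = 20 + rnorm(1)), K, 1,
      paste0("b", i)))))
  es <- rescale_embeddings(es, "l1")
  kern <- fit_kernel_linear(es, lambda_mix = 0.5, strength = 0.01)
  expect_equal(kern$variant, "linear")
  expect_gt(kern$weights[["m2"]], 0)
  # m2 is the largest-magnitude positive weight (its complement m1 is
  # coupled negatively through the probability rescaling)
  pos <- kern$weights[kern$weights > 0]
  expect_equal(names(which.max(pos)), "m2")

  # label flip negates the dominant coefficient's sign
  flip <- lapply(es, function(e) { e$label <- 1L - e$label; e })
  kern_f <- fit_kernel_linear(flip, lambda_mix = 0.5, strength = 0.01)
  expect_lt(kern_f$weights[["m2"]], 0)

  # lasso limit with heavy strength: most weights exactly zero
  sparse <- fit_kernel_linear(es, lambda_mix = 1, strength = 0.5)
  expect_gt(sum(sparse$weights == 0), length(sparse$weights) / 2)

  expect_error(fit_kernel_linear(es, lambda_mix = 2), "lambda_mix")
  expect_error(fit_kernel_linear(es, strength = -1), "strength")
})

test_that("kernel lookup has dictionary semantics", {
  kern <- random_kernel(6, 1, 3)
  kern$weights <- kern$weights[setdiff(names(kern$weights), "b2.5")]
  expect_equal(kernel_lookup(kern, "b2.5"), 0)   # absent -> 0
  expect_equal(kernel_lookup(kern, bigram_key(5, 3)),
               kernel_lookup(kern, bigram_key(3, 5)))
  expect_equal(kernel_lookup(kern, "b5.3"), kern$weights[["b3.5"]])
  expect_error(kernel_lookup(kern, mono_key(7)), "1..K")
})

test_that("kernel serialization round-trips weights and metadata", {
  es <- withr::with_seed(13, lapply(1:12, function(i) {
    s <- random_sprite(700 + i, K = 4)
    s$topology$label <- as.integer(i %% 2)
    rollup(s, 1)
  }))
  es <- rescale_embeddings(es, "l1")
  kern <- fit_kernel_foldchange(compute_class_profiles(es), es)
  path <- withr::local_tempfile(fileext = ".txt")
  write_kernel(kern, path)
  k2 <- read_kernel(path)
  expect_equal(k2$weights, kern$weights)
  expect_equal(k2$p_values, kern$p_values)
  expect_equal(k2$K, kern$K)
  expect_equal(k2$r, kern$r)
  expect_equal(k2$variant, kern$variant)
  expect_equal(k2$hyperparams$alpha, kern$hyperparams$alpha)
})
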