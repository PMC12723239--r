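test_that("stratified folds balance classes to within one sample", {
  labels <- rep(c("x", "y"), each = 10)
  fp <- make_stratified_folds(labels, 10, seed = 1)
  expect_s3_class(fp, "fold_plan")
  tab <- table(fp$fold_of, labels)
  expect_true(all(tab == 1))
  # same seed, same plan
  expect_identical(fp, make_stratified_folds(labels, 10, seed = 1))
  # random labelings: per-fold class counts within 1 of proportionality
  set.seed(9)
  for (rep in 1:5) {
    lab <- sample(c("a", "b", "c"), 47, replace = TRUE)
    fp2 <- suppressWarnings(make_stratified_folds(lab, 5, seed = rep))
    tab2 <- table(fp2$fold_of, lab)
    for (cl in colnames(tab2)) {
      expect_lte(diff(range(tab2[, cl])), 1)
    }
  }
  expect_error(make_stratified_folds(c("a", "b"), 10), "exceeds")
})

test_that("genus-grouped folds never split a genus", {
  set.seed(4)
  for (rep in 1:8) {
    n_genera <- sample(6:15, 1)
    sizes <- sample(1:6, n_genera, replace = TRUE)
    genera <- rep(paste0("g", seq_len(n_genera)), sizes)
    labels <- sample(c("hot", "cold"), length(genera), replace = TRUE)
    fp <- make_genus_grouped_folds(labels, genera, n_folds = 4, seed = rep)
    expect_identical(fp$scenario, "bias_mitigation")
    split_counts <- tapply(fp$fold_of, genera, function(f) length(unique(f)))
    expect_true(all(split_counts == 1))
  }
  expect_error(make_genus_grouped_folds(c("a", "b"), c("g1", "g2"), 10),
               "n_folds")
})

test_that("genus-grouped folds keep both labels represented (toy case)", {
  genera <- rep(c("g1", "g2", "g3", "g4"), c(3, 3, 2, 2))
  labels <- c("A", "A", "B", "B", "B", "A", "A", "B", "B", "A")
  fp <- make_genus_grouped_folds(labels, genera, n_folds = 2, seed = 1)
  tab <- table(fp$fold_of, labels)
  expect_true(all(tab > 0))
})

test_that("cross-validated accuracy equals correct/total on plugin oracles", {
  set.seed(10)
  x <- matrix(rnorm(60 * 4), 60)
  y <- rep(c("p", "q"), c(42, 18))  # 70/30
  fp <- make_stratified_folds(y, 6, seed = 2)
  majority <- classifier_spec("plugin", list(
    fit_predict = function(tr_x, tr_y, te_x) {
      rep(names(which.max(table(tr_y))), nrow(te_x))
    }))
  acc_major <- cross_validate(x, y, fp, majority)
  expect_equal(as.numeric(acc_major), 0.70)
  # true-label oracle: identify each held-out row by nearest match against
  # the full (globally scaled) matrix and answer its real label
  lookup <- classifier_spec("plugin", list(
    fit_predict = function(tr_x, tr_y, te_x) {
      vapply(seq_len(nrow(te_x)), function(i) {
        d <- colSums((t(scale(x)) - te_x[i, ])^2)
        y[which.min(d)]
      }, character(1))
    }))
  acc_true <- cross_validate(x, y, fp, lookup)
  expect_equal(as.numeric(acc_true), 1.0)
  fp_tiny <- suppressWarnings(make_stratified_folds(c("a", "b"), 2))
  expect_error(cross_validate(matrix(c(1, NaN), 2, 1), c("a", "b"),
                              fp_tiny, majority),
               "NaN|NA")
})

test_that("label-permuted data classifies at chance (negative control)", {
  set.seed(12)
  x <- matrix(rnorm(60 * 10), 60)
  y <- sample(rep(c("u", "v"), each = 30))   # labels independent of x
  fp <- make_stratified_folds(y, 5, seed = 3)
  acc <- cross_validate(x, y, fp, classifier_spec("svm_rbf"))
  expect_lt(abs(as.numeric(acc) - 0.5), 2.5 * sqrt(0.25 / 60) + 0.05)
})

test_that("svm separates planted taxonomic signal at k=6 on synthetic data", {
  ds <- tiny_dataset(seed = 31, n_genera = 3, samples = 3,
                     genome_length = 15000, beta_twin = 1)
  proxies <- lapply(seq_along(ds$records), function(i) {
    select_proxy(ds$records[[i]], proxy_config(5, 10000), seed = 31 + i)
  })
  sig <- signature_matrix(proxies, k = 6)
  fp <- make_stratified_folds(ds$metadata$domain, 3, seed = 1)
  acc <- cross_validate(sig, ds$metadata$domain, fp,
                        classifier_spec("svm_rbf"))
  expect_gte(as.numeric(acc), 0.95)
})

test_that("the small MLP classifier learns a separable toy problem", {
  set.seed(55)
  x <- rbind(matrix(rnorm(40 * 5, -1), 40), matrix(rnorm(40 * 5, 1), 40))
  y <- rep(c("lo", "hi"), each = 40)
  fp <- make_stratified_folds(y, 4, seed = 1)
  acc <- cross_validate(x, y, fp, classifier_spec("ann_256_64",
                                                  list(epochs = 40L)))
  expect_gte(as.numeric(acc), 0.9)
})

test_that("proxy robustness reports zero variance for degenerate fixed proxies", {
  # genomes shorter than the proxy length: every repeat uses the identical
  # whole-genome fallback, so accuracy variance across repeats is exactly 0
  ds <- tiny_dataset(seed = 61, n_genera = 3, samples = 2,
                     genome_length = 5000)
  res <- suppressWarnings(proxy_robustness_experiment(
    ds$records, ds$metadata$domain, k_values = c(2, 3),
    proxy_lengths = 50000, repeats = 3,
    spec = classifier_spec("plugin", list(
      fit_predict = function(tr_x, tr_y, te_x)
        rep(names(which.max(table(tr_y))), nrow(te_x)))),
    n_folds = 3, seed = 1))
  expect_identical(nrow(res), 2L)
  expect_true(all(res$variance_pct == 0))
})

test_that("proxy robustness has low variance across random proxies", {
  ds <- tiny_dataset(seed = 62, n_genera = 3, samples = 2,
                     genome_length = 30000, beta_twin = 1)
  res <- proxy_robustness_experiment(
    ds$records, ds$metadata$domain, k_values = 6,
    proxy_lengths = 10000, n = 5, repeats = 4,
    spec = classifier_spec("svm_rbf"), n_folds = 3, seed = 5)
  expect_identical(nrow(res), 1L)
  # the signature is pervasive: redrawing proxies moves accuracy by little
  # (variance in percentage-squared units, i.e. sd below ~10 points)
  expect_lt(res$variance_pct, 100)
  expect_gte(res$mean_accuracy_pct, 80)
})

test_that("grid search reports per-combination accuracies and the argmax", {
  ds <- tiny_dataset(seed = 63, n_genera = 4, samples = 2,
                     genome_length = 20000)
  res <- grid_search_k_length(
    ds$records, ds$metadata$domain, genera = ds$metadata$genus,
    k_values = c(1, 6), proxy_lengths = 10000, n = 5,
    scenario = "bias_mitigation", n_folds = 4, seed = 2)
  expect_identical(nrow(res), 2L)
  best <- attr(res, "best")
  expect_true(best$accuracy_pct == max(res$accuracy_pct))
  # longer k-mers capture the planted signal at least as well as k = 1
  expect_gte(res$accuracy_pct[res$k == 6], res$accuracy_pct[res$k == 1])
})
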