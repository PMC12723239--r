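#' Standard stratified fold assignment
#'
#' Conventional stratified k-fold cross-validation: within each class,
#' shuffled samples are dealt round-robin (with a rotating per-class start
#' fold), so every fold's per-class count is within one sample of exact
#' proportionality.
#'
#' @param labels Character/factor vector of class labels; names, if present,
#'   become the sample ids of the plan.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed.
#' @return An object of class `fold_plan`: list with `fold_of` (integer
#'   1..n_folds per sample), `scenario = "standard"`, `n_folds`.
#' @export
make_stratified_folds <- function(labels, n_folds = 10L, seed = 1L) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n_folds > n) stop("n_folds (", n_folds, ") exceeds sample count (", n, ")")
  tab <- table(labels)
  if (any(tab < n_folds)) {
    warning("class(es) with fewer than n_folds samples: ",
            paste(names(tab)[tab < n_folds], collapse = ", "))
  }
  set.seed(as.integer(seed))
  fold_of <- integer(n)
  offset <- 0L
  for (cl in names(sort(tab, decreasing = TRUE))) {
    idx <- sample(which(labels == cl))
    fold_of[idx] <- ((offset + seq_along(idx) - 1L) %% n_folds) + 1L
    offset <- offset + length(idx)
  }
  names(fold_of) <- names(labels)
  structure(list(fold_of = fold_of, scenario = "standard",
                 n_folds = as.integer(n_folds)),
            class = "fold_plan")
}

#' Genus-grouped (bias mitigation) fold assignment
#'
#' Folds in which all samples of a genus share one fold, while per-fold
#' label proportions stay as close as possible to the whole-dataset
#' proportions. This isolates environment signal from genus signal: a
#' held-out genus can only be predicted from environment-specific patterns,
#' never from same-genus training samples.
#'
#' Assignment is greedy: genera in decreasing size order, each placed in the
#' fold minimizing the sum over labels of the squared deviation of fold
#' label counts from the global proportions scaled to the fold's projected
#' size; ties go to the currently smallest fold, then the lowest fold index.
#'
#' @param labels Class labels per sample.
#' @param genera Genus per sample (same length as `labels`).
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed (shuffles order among equally sized genera).
#' @return A `fold_plan` with `scenario = "bias_mitigation"`.
#' @export
make_genus_grouped_folds <- function(labels, genera, n_folds = 10L, seed = 1L) {
  labels <- as.character(labels); genera <- as.character(genera)
  stopifnot(length(labels) == length(genera))
  if (anyNA(genera) || any(!nzchar(genera))) {
    stop("genus must be known for every sample")
  }
  gtab <- table(genera)
  if (length(gtab) < n_folds) {
    stop("only ", length(gtab), " distinct genera; use n_folds <= ",
         length(gtab))
  }
  set.seed(as.integer(seed))
  gnames <- names(gtab)[sample(length(gtab))]   # random tie order
  gnames <- gnames[order(-gtab[gnames])]        # stable: decreasing size
  classes <- sort(unique(labels))
  p_global <- as.numeric(table(factor(labels, classes))) / length(labels)
  fold_counts <- matrix(0, n_folds, length(classes),
                        dimnames = list(NULL, classes))
  fold_size <- numeric(n_folds)
  genus_fold <- stats::setNames(integer(length(gnames)), gnames)
  for (g in gnames) {
    gl <- as.numeric(table(factor(labels[genera == g], classes)))
    cost <- vapply(seq_len(n_folds), function(f) {
      proj <- fold_size[f] + sum(gl)
      sum((fold_counts[f, ] + gl - p_global * proj)^2)
    }, numeric(1))
    best <- which(cost == min(cost))
    if (length(best) > 1L) {
      best <- best[fold_size[best] == min(fold_size[best])]
      best <- best[1L]
    }
    genus_fold[g] <- best
    fold_counts[best, ] <- fold_counts[best, ] + gl
    fold_size[best] <- fold_size[best] + sum(gl)
  }
  fold_of <- genus_fold[genera]
  names(fold_of) <- names(labels)
  structure(list(fold_of = unname(fold_of) + 0L, scenario = "bias_mitigation",
                 n_folds = as.integer(n_folds), genus_fold = genus_fold),
            class = "fold_plan")
}

#' Cross-validated classification accuracy
#'
#' Per fold: features are standardized with the training fold's mean and
#' standard deviation (constant features scale by 1), the classifier is fit
#' on the training folds and predicts the held-out fold. Accuracy is the
#' ratio of correctly predicted labels to all labels, over the concatenated
#' held-out predictions.
#'
#' @param features Numeric matrix, rows aligned with `labels`.
#' @param labels Class labels.
#' @param foldplan A [make_stratified_folds()] /
#'   [make_genus_grouped_folds()] plan.
#' @param spec A [classifier_spec()].
#' @param seed Integer seed fanned out to per-fold classifier randomness.
#' @return Accuracy in `[0, 1]`, with attribute `predictions` (character
#'   vector aligned with `labels`).
#' @export
cross_validate <- function(features, labels, foldplan,
                           spec = classifier_spec("svm_rbf"), seed = 1L) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels),
            inherits(foldplan, "fold_plan"))
  if (anyNA(features) || any(!is.finite(features))) {
    stop("features contain NA/NaN/Inf values")
  }
  pred <- character(length(labels))
  for (f in sort(unique(foldplan$fold_of))) {
    test <- foldplan$fold_of == f
    mu <- colMeans(features[!test, , drop = FALSE])
    sdv <- apply(features[!test, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0 | is.na(sdv)] <- 1
    scale_ <- function(m) sweep(sweep(m, 2, mu), 2, sdv, "/")
    set.seed(as.integer(seed) * 1000L + f)
    pred[test] <- .fit_predict(spec,
                               scale_(features[!test, , drop = FALSE]),
                               labels[!test],
                               scale_(features[test, , drop = FALSE]))
  }
  acc <- mean(pred == labels)
  attr(acc, "predictions") <- pred
  acc
}

#' Proxy-choice robustness experiment
#'
#' Repeats classification with freshly drawn random genome proxies to test
#' whether accuracy depends on the particular proxy — i.e. whether the
#' genomic signature is pervasive across the genome. Each repeat redraws all
#' proxies with a derived seed, then runs cross-validation for every
#' (k, proxy length) combination.
#'
#' @param records List of [genome_record()]s.
#' @param labels Class labels aligned with `records`.
#' @param k_values Integer vector of k-mer sizes.
#' @param proxy_lengths Numeric vector of total proxy lengths in bp.
#' @param n Sub-fragments per proxy (default 10).
#' @param repeats Number of proxy redraws (default 10).
#' @param spec A [classifier_spec()].
#' @param foldplan Optional fixed `fold_plan`; default standard stratified.
#' @param n_folds Folds when `foldplan` is NULL.
#' @param seed Integer seed.
#' @return A data.frame with columns `k`, `proxy_length`,
#'   `mean_accuracy_pct`, `variance_pct` (variance of the per-repeat
#'   accuracies expressed in percent, i.e. percentage-squared units).
#' @export
proxy_robustness_experiment <- function(records, labels, k_values = 6L,
                                        proxy_lengths = 100000L, n = 10L,
                                        repeats = 10L,
                                        spec = classifier_spec("svm_rbf"),
                                        foldplan = NULL, n_folds = 10L,
                                        seed = 1L) {
  stopifnot(repeats >= 1L)
  if (is.null(foldplan)) {
    foldplan <- make_stratified_folds(labels, n_folds, seed)
  }
  grid <- expand.grid(k = k_values, proxy_length = proxy_lengths)
  acc <- array(NA_real_, c(nrow(grid), repeats))
  for (r in seq_len(repeats)) {
    for (li in seq_along(proxy_lengths)) {
      len <- proxy_lengths[li]
      cfg <- proxy_config(n, len)
      proxies <- lapply(seq_along(records), function(i) {
        suppressWarnings(
          select_proxy(records[[i]], cfg, seed = seed * 10000L + r * 100L + i))
      })
      for (ki in seq_along(k_values)) {
        row <- which(grid$k == k_values[ki] & grid$proxy_length == len)
        sig <- signature_matrix(proxies, k = k_values[ki])
        acc[row, r] <- cross_validate(sig, labels, foldplan, spec,
                                      seed = seed + r)
      }
    }
  }
  data.frame(grid,
             mean_accuracy_pct = round(100 * rowMeans(acc), 2),
             variance_pct = round(apply(100 * acc, 1, stats::var), 4))
}

#' Grid search over k-mer size and proxy length
#'
#' Runs cross-validated classification for every (k, proxy length)
#' combination with a fixed randomly selected proxy per length, and reports
#' the accuracy table plus the best configuration.
#'
#' @inheritParams proxy_robustness_experiment
#' @param genera Optional genus per record; required when
#'   `scenario = "bias_mitigation"`.
#' @param scenario `"standard"` or `"bias_mitigation"`.
#' @param include_whole Also evaluate the whole genome as proxy.
#' @return A data.frame with per-combination `accuracy_pct`; attribute
#'   `best` holds the argmax row.
#' @export
grid_search_k_length <- function(records, labels, genera = NULL,
                                 k_values = 1:9,
                                 proxy_lengths = c(10000L, 50000L, 100000L),
                                 n = 10L,
                                 spec = classifier_spec("svm_rbf"),
                                 scenario = c("standard", "bias_mitigation"),
                                 include_whole = FALSE, n_folds = 10L,
                                 seed = 1L) {
  scenario <- match.arg(scenario)
  foldplan <- if (scenario == "standard") {
    make_stratified_folds(labels, n_folds, seed)
  } else {
    if (is.null(genera)) stop("bias_mitigation scenario requires genera")
    make_genus_grouped_folds(labels, genera, n_folds, seed)
  }
  lengths_all <- c(as.list(proxy_lengths), if (include_whole) list(Inf))
  out <- list()
  for (len in lengths_all) {
    proxies <- lapply(seq_along(records), function(i) {
      if (is.infinite(len)) return(select_whole_genome(records[[i]]))
      suppressWarnings(select_proxy(records[[i]], proxy_config(n, len),
                                    seed = seed * 1000L + i))
    })
    for (k in k_values) {
      sig <- signature_matrix(proxies, k = k)
      a <- cross_validate(sig, labels, foldplan, spec, seed = seed)
      out[[length(out) + 1L]] <- data.frame(
        k = k, proxy_length = if (is.infinite(len)) NA else len,
        whole_genome = is.infinite(len), scenario = scenario,
        accuracy_pct = round(100 * as.numeric(a), 2))
    }
  }
  res <- do.call(rbind, out)
  attr(res, "best") <- res[which.max(res$accuracy_pct), ]
  res
}
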