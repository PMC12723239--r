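#' Classifier specification
#'
#' The harness's classifier set: an RBF-kernel support vector machine
#' (library defaults: `cost = 1`, `gamma = 1/ncol(x)`, recorded in the spec
#' object), a random forest with 100 trees, a feed-forward neural network
#' with two hidden layers of sizes 256 and 64 trained with Adam at learning
#' rate 0.001, or a user plugin.
#'
#' A plugin supplies `params$fit_predict`, a
#' `function(train_x, train_y, test_x)` returning predicted labels — used
#' both for external classifiers and for oracle/majority baselines in tests.
#'
#' @param name One of `"svm_rbf"`, `"random_forest_100"`, `"ann_256_64"`,
#'   `"plugin"`.
#' @param params Named list of hyperparameter overrides.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(name = c("svm_rbf", "random_forest_100",
                                     "ann_256_64", "plugin"),
                            params = list()) {
  name <- match.arg(name)
  defaults <- switch(name,
    svm_rbf = list(cost = 1, gamma = NULL),  # NULL: e1071 default 1/ncol
    random_forest_100 = list(ntree = 100L),
    ann_256_64 = list(hidden = c(256L, 64L), lr = 0.001, epochs = 80L),
    plugin = list(fit_predict = NULL))
  params <- utils::modifyList(defaults, params)
  if (name == "plugin" && !is.function(params$fit_predict)) {
    stop("plugin classifier requires params$fit_predict function")
  }
  structure(list(name = name, params = params), class = "classifier_spec")
}

# returns predicted labels (character) for test_x
.fit_predict <- function(spec, train_x, train_y, test_x) {
  y <- factor(train_y)
  p <- spec$params
  pred <- switch(spec$name,
    svm_rbf = {
      args <- list(x = train_x, y = y, kernel = "radial", cost = p$cost,
                   scale = FALSE)
      if (!is.null(p$gamma)) args$gamma <- p$gamma
      fit <- do.call(e1071::svm, args)
      stats::predict(fit, test_x)
    },
    random_forest_100 = {
      fit <- randomForest::randomForest(x = train_x, y = y, ntree = p$ntree)
      stats::predict(fit, test_x)
    },
    ann_256_64 = .mlp_fit_predict(train_x, y, test_x, hidden = p$hidden,
                                  lr = p$lr, epochs = p$epochs),
    plugin = p$fit_predict(train_x, train_y, test_x))
  as.character(pred)
}

# Minimal two-hidden-layer MLP (ReLU, softmax, cross-entropy, Adam,
# full-batch). Small by design: the harness's sample counts are in the
# hundreds, so full-batch Adam is stable and dependency-free.
.mlp_fit_predict <- function(train_x, train_y, test_x, hidden = c(256L, 64L),
                             lr = 0.001, epochs = 80L) {
  x <- as.matrix(train_x)
  classes <- levels(train_y)
  yi <- as.integer(train_y)
  n <- nrow(x); d <- ncol(x); kcl <- length(classes)
  sizes <- c(d, hidden, kcl)
  nl <- length(sizes) - 1L
  W <- vector("list", nl); b <- vector("list", nl)
  for (l in seq_len(nl)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  onehot <- matrix(0, n, kcl); onehot[cbind(seq_len(n), yi)] <- 1
  forward <- function(x) {
    a <- list(x)
    for (l in seq_len(nl)) {
      z <- sweep(a[[l]] %*% W[[l]], 2, b[[l]], "+")
      a[[l + 1L]] <- if (l < nl) pmax(z, 0) else {
        z <- z - apply(z, 1, max)
        ez <- exp(z); ez / rowSums(ez)
      }
    }
    a
  }
  for (t in seq_len(epochs)) {
    a <- forward(x)
    delta <- (a[[nl + 1L]] - onehot) / n
    for (l in rev(seq_len(nl))) {
      gW <- crossprod(a[[l]], delta)
      gb <- colSums(delta)
      if (l > 1L) delta <- (delta %*% t(W[[l]])) * (a[[l]] > 0)
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
      cor1 <- 1 - beta1^t; cor2 <- 1 - beta2^t
      W[[l]] <- W[[l]] - lr * (mW[[l]] / cor1) / (sqrt(vW[[l]] / cor2) + eps)
      b[[l]] <- b[[l]] - lr * (mb[[l]] / cor1) / (sqrt(vb[[l]] / cor2) + eps)
    }
  }
  probs <- forward(as.matrix(test_x))[[nl + 1L]]
  classes[max.col(probs, ties.method = "first")]
}
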