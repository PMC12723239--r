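# Native non-parametric clusterers and reducers for the pair pipeline.
# All operate on a numeric feature matrix (rows = samples) and return an
# integer cluster label per row; -1 marks noise. None takes a preset
# cluster count.

#' Affinity propagation clustering
#'
#' Message-passing exemplar selection (responsibility/availability updates,
#' damped) on negative squared Euclidean similarities; the number of
#' clusters emerges from the data.
#'
#' The preference (self-similarity) defaults to the 0.9 quantile of the
#' off-diagonal similarities: the pipeline ranks clusterings by genus
#' accuracy, for which fine granularity (clusters at the scale of a few
#' nearest neighbours) errs on the right side — under-clustering merges
#' genera and scores zero. Pass the median for the classic
#' moderate-granularity behaviour.
#'
#' @param x Numeric matrix (rows = samples).
#' @param preference Self-similarity; default 0.9 quantile off-diagonal.
#' @param damping Update damping in (0.5, 1).
#' @param max_iter,conv_iter Iteration cap and required stable iterations.
#' @return Integer cluster labels (1-based).
#' @export
affinity_propagation <- function(x, preference = NULL, damping = 0.9,
                                 max_iter = 200L, conv_iter = 25L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n == 1L) return(1L)
  S <- -as.matrix(stats::dist(x))^2
  if (is.null(preference)) {
    preference <- stats::quantile(S[row(S) != col(S)], 0.9, names = FALSE)
  }
  diag(S) <- preference
  # tiny deterministic jitter breaks exact ties without an RNG draw per run
  S <- S + S * 1e-12 * (outer(seq_len(n), seq_len(n)) %% 7)
  R <- matrix(0, n, n); A <- matrix(0, n, n)
  exemplars_prev <- integer(0); stable <- 0L
  for (it in seq_len(max_iter)) {
    AS <- A + S
    max1 <- apply(AS, 1, max)
    which1 <- max.col(AS, ties.method = "first")
    AS2 <- AS; AS2[cbind(seq_len(n), which1)] <- -Inf
    max2 <- apply(AS2, 1, max)
    Rnew <- S - max1
    Rnew[cbind(seq_len(n), which1)] <- S[cbind(seq_len(n), which1)] - max2
    R <- damping * R + (1 - damping) * Rnew
    Rp <- pmax(R, 0); diag(Rp) <- diag(R)
    Anew <- matrix(rep(colSums(Rp), each = n), n, n) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0); diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    exemplars <- which(diag(A) + diag(R) > 0)
    if (identical(exemplars, exemplars_prev)) {
      stable <- stable + 1L
      if (stable >= conv_iter && length(exemplars) > 0L) break
    } else {
      stable <- 0L; exemplars_prev <- exemplars
    }
  }
  if (length(exemplars) == 0L) return(rep(1L, n))
  assign <- apply(S[, exemplars, drop = FALSE], 1, which.max)
  assign[exemplars] <- seq_along(exemplars)
  as.integer(assign)
}

#' Mean shift clustering
#'
#' Flat-kernel mean shift: every point iterates to the mean of its
#' bandwidth neighbourhood until convergence; converged modes closer than
#' the bandwidth are merged and points labelled by their mode.
#'
#' The default bandwidth is the nearest-neighbour estimate: the average,
#' over all points, of the distance to the `ceiling(quantile * n)`-th
#' nearest neighbour (quantile 0.1). This adapts the kernel to the local
#' scale of the tightest structures rather than the global pairwise
#' distance distribution.
#'
#' @param x Numeric matrix.
#' @param bandwidth Kernel radius; default nearest-neighbour estimate (see
#'   Details).
#' @param quantile Neighbour fraction for the bandwidth estimate.
#' @param max_iter Iteration cap per point.
#' @return Integer cluster labels (1-based).
#' @export
mean_shift <- function(x, bandwidth = NULL, quantile = 0.1,
                       max_iter = 300L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n == 1L) return(1L)
  if (is.null(bandwidth)) {
    D <- as.matrix(stats::dist(x))
    k <- max(1L, ceiling(quantile * n))
    knn <- apply(D, 1, function(d) sort(d[-which.min(d)])[k])
    bandwidth <- mean(knn)
    if (bandwidth <= 0) bandwidth <- 1e-8
  }
  modes <- x
  for (i in seq_len(n)) {
    cur <- x[i, ]
    for (it in seq_len(max_iter)) {
      d2 <- colSums((t(x) - cur)^2)
      nb <- d2 <= bandwidth^2
      nxt <- colMeans(x[nb, , drop = FALSE])
      if (sqrt(sum((nxt - cur)^2)) < 1e-7 * bandwidth) { cur <- nxt; break }
      cur <- nxt
    }
    modes[i, ] <- cur
  }
  labels <- integer(n)
  centers <- NULL
  for (i in seq_len(n)) {
    if (!is.null(centers)) {
      d <- sqrt(colSums((t(centers) - modes[i, ])^2))
      j <- which(d < bandwidth / 2)
      if (length(j) > 0L) { labels[i] <- j[1L]; next }
    }
    centers <- rbind(centers, modes[i, ])
    labels[i] <- nrow(centers)
  }
  labels
}

#' Iterative medoid splitting
#'
#' Starts from a single medoid (the point minimizing total distance) and
#' repeatedly splits the loosest cluster — the one with the largest mean
#' member-to-medoid distance — by promoting its farthest member to a new
#' medoid and reassigning, until every cluster's mean distance is at most
#' `ratio` times the global mean pairwise distance.
#'
#' @param x Numeric matrix.
#' @param ratio Stopping fraction of the global mean distance (default
#'   0.3, favouring genus-scale granularity).
#' @param max_clusters Safety cap (default `nrow(x)`).
#' @return Integer cluster labels (1-based).
#' @export
iterative_medoids <- function(x, ratio = 0.3, max_clusters = nrow(x)) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n == 1L) return(1L)
  D <- as.matrix(stats::dist(x))
  global_mean <- mean(D[upper.tri(D)])
  medoids <- which.min(rowSums(D))
  repeat {
    assign <- apply(D[, medoids, drop = FALSE], 1, which.min)
    mean_d <- vapply(seq_along(medoids), function(ci) {
      mean(D[assign == ci, medoids[ci]])
    }, numeric(1))
    worst <- which.max(mean_d)
    if (mean_d[worst] <= ratio * global_mean ||
        length(medoids) >= max_clusters) break
    members <- which(assign == worst)
    far <- members[which.max(D[members, medoids[worst]])]
    if (far %in% medoids) break
    medoids <- c(medoids, far)
  }
  as.integer(apply(D[, medoids, drop = FALSE], 1, which.min))
}

# dimensionality reducers -----------------------------------------------

.reduce_features <- function(x, reducer, params = list()) {
  switch(reducer,
    identity = as.matrix(x),
    pca = {
      ncomp <- params$ncomp %||% min(10L, nrow(x) - 1L, ncol(x))
      pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
      pr$x[, seq_len(min(ncomp, ncol(pr$x))), drop = FALSE]
    },
    plugin = {
      if (!is.function(params$reduce_fun)) {
        stop("plugin reducer unavailable (no params$reduce_fun)")
      }
      params$reduce_fun(x)
    },
    stop("unknown reducer: ", reducer))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
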