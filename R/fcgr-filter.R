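# Layer 2 of the pair pipeline: FCGR image distances, intra-genus derived
# thresholds, and candidate-pair filtering.

# windowed sums over all w x w windows fully inside m (valid mode), via an
# integral image
.window_sums <- function(m, w) {
  I <- t(apply(apply(m, 2, cumsum), 1, cumsum))  # I[i,j] = sum m[1:i,1:j]
  I <- rbind(0, cbind(0, I))
  nr <- nrow(m); nc <- ncol(m)
  rows <- seq_len(nr - w + 1L); cols <- seq_len(nc - w + 1L)
  I[rows + w, cols + w, drop = FALSE] - I[rows, cols + w, drop = FALSE] -
    I[rows + w, cols, drop = FALSE] + I[rows, cols, drop = FALSE]
}

#' Structural dissimilarity (DSSIM) between two FCGR grids
#'
#' `DSSIM = (1 - mean SSIM) / 2`, with SSIM computed over all 7x7 windows
#' (uniform weights, population moments) at unit dynamic range with
#' stabilizers `C1 = 0.01^2`, `C2 = 0.03^2`. Grids are max-normalized to
#' `[0, 1]` before comparison.
#'
#' @param gridA,gridB Equal-dimension non-negative matrices.
#' @param window SSIM window side (default 7).
#' @return DSSIM in `[0, 1]`.
#' @export
dssim <- function(gridA, gridB, window = 7L) {
  gridA <- unclass(as.matrix(gridA)); gridB <- unclass(as.matrix(gridB))
  if (!all(dim(gridA) == dim(gridB))) {
    stop("dssim: grid dimensions differ (", paste(dim(gridA), collapse = "x"),
         " vs ", paste(dim(gridB), collapse = "x"), ")")
  }
  if (min(dim(gridA)) < window) {
    stop("dssim: grid smaller than the ", window, "x", window, " SSIM window")
  }
  if (max(gridA) > 0) gridA <- gridA / max(gridA)
  if (max(gridB) > 0) gridB <- gridB / max(gridB)
  N <- window^2
  C1 <- 0.01^2; C2 <- 0.03^2
  mx <- .window_sums(gridA, window) / N
  my <- .window_sums(gridB, window) / N
  vx <- .window_sums(gridA^2, window) / N - mx^2
  vy <- .window_sums(gridB^2, window) / N - my^2
  cxy <- .window_sums(gridA * gridB, window) / N - mx * my
  ssim <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
  (1 - mean(ssim)) / 2
}

# block-sum pooling by integer factor
.pool <- function(m, factor) {
  if (factor == 1L) return(m)
  side <- nrow(m) %/% factor
  idx <- rep(seq_len(side), each = factor)
  rowsum(t(rowsum(m, idx)), idx)
}

#' Multi-scale descriptor distance between FCGR grids
#'
#' Euclidean distance between unit-normalized multi-scale descriptors: the
#' grid is block-sum pooled at its native resolution and at half and
#' quarter resolution, the three flattened grids are concatenated and the
#' concatenation L2-normalized. Satisfies the metric axioms (it is a
#' Euclidean distance in descriptor space) and is invariant to overall
#' count scale. Swappable: any `function(gridA, gridB)` can stand in for it
#' in [filter_pairs()].
#'
#' @param gridA,gridB Equal-dimension non-negative matrices with side a
#'   power of 2.
#' @return Distance `>= 0`.
#' @export
descriptor_distance <- function(gridA, gridB) {
  gridA <- unclass(as.matrix(gridA)); gridB <- unclass(as.matrix(gridB))
  if (!all(dim(gridA) == dim(gridB))) {
    stop("descriptor_distance: grid dimensions differ")
  }
  desc <- function(m) {
    factors <- c(1L, 2L, 4L)
    factors <- factors[factors < nrow(m)]
    v <- unlist(lapply(factors, function(f) as.numeric(.pool(m, f))))
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v / nrm else v
  }
  sqrt(sum((desc(gridA) - desc(gridB))^2))
}

#' Built-in FCGR distance metrics
#'
#' @return Named list of `function(gridA, gridB)` metrics: `descriptor` and
#'   `dssim`. Perceptual-network metrics (e.g. LPIPS) need pretrained
#'   weights and are supplied as plugins instead.
#' @export
fcgr_metrics <- function() {
  list(descriptor = descriptor_distance, dssim = dssim)
}

#' Reference distance thresholds
#'
#' The fixed threshold set determined on the full curated 693-genome
#' extremophile collection (92 multi-sample genera), bundled for running
#' the reference operating point; [derive_threshold()] recomputes
#' data-derived thresholds for any other dataset.
#'
#' @return Named numeric vector (`descriptor`, `dssim`, `lpips`).
#' @export
reference_thresholds <- function() {
  c(descriptor = 0.190211, dssim = 0.501385, lpips = 0.177668)
}

#' Derive an intra-genus FCGR distance threshold
#'
#' A bacterium-archaeon pair counts as similar when its FCGR distance is
#' below the typical distance among species of one genus. Per genus with at
#' least two samples, the mean of all pairwise FCGR distances is computed;
#' the genus means are sorted, `floor(0.05 * m)` values are dropped from
#' each tail as outliers, and the threshold is the 90th percentile (linear
#' interpolation between closest ranks) of the remainder.
#'
#' @param fcgrs Named list of FCGR grids (names = genome ids).
#' @param genera Named character vector of genus per genome id.
#' @param metric A `function(gridA, gridB)` distance.
#' @return Threshold (numeric) with attributes `n_genera` (qualifying genus
#'   count), `genus_means`, `derivation = "data_derived"`.
#' @export
derive_threshold <- function(fcgrs, genera, metric = descriptor_distance) {
  ids <- names(fcgrs)
  stopifnot(!is.null(ids), all(ids %in% names(genera)))
  genera <- genera[ids]
  sizes <- table(genera)
  qual <- names(sizes)[sizes >= 2L]
  if (length(qual) == 0L) {
    stop("no genus with at least two samples; cannot derive a threshold")
  }
  genus_means <- vapply(sort(qual), function(g) {
    members <- ids[genera == g]
    pairs <- utils::combn(members, 2L)
    mean(vapply(seq_len(ncol(pairs)), function(j) {
      metric(fcgrs[[pairs[1L, j]]], fcgrs[[pairs[2L, j]]])
    }, numeric(1)))
  }, numeric(1))
  sorted <- sort(genus_means)
  trim <- floor(0.05 * length(sorted))
  kept <- if (trim > 0L) {
    sorted[(trim + 1L):(length(sorted) - trim)]
  } else sorted
  thr <- stats::quantile(kept, 0.9, type = 7, names = FALSE)
  attr(thr, "n_genera") <- length(genus_means)
  attr(thr, "genus_means") <- genus_means
  attr(thr, "derivation") <- "data_derived"
  thr
}

#' Filter candidate pairs by FCGR distance
#'
#' Computes every active metric's distance for each candidate pair and
#' keeps the pair when the distance is strictly below that metric's
#' threshold for every active metric (`rule = "all"`, the default) or for a
#' strict majority of them (`rule = "majority"`).
#'
#' @param pairs A data.frame with `bacterium` and `archaeon` id columns
#'   (e.g. retained rows of [consensus_pairs()]).
#' @param fcgrs Named list of FCGR grids covering every pair member.
#' @param thresholds Named numeric vector, metric name -> threshold. Names
#'   must match `metrics`.
#' @param metrics Named list of metric functions (default
#'   [fcgr_metrics()]).
#' @param rule `"all"` or `"majority"`.
#' @return The pairs data.frame with one `dist_<metric>` column per metric
#'   and a logical `confirmed` column; rows are all input pairs.
#' @export
filter_pairs <- function(pairs, fcgrs, thresholds,
                         metrics = fcgr_metrics(),
                         rule = c("all", "majority")) {
  rule <- match.arg(rule)
  stopifnot(is.data.frame(pairs),
            all(c("bacterium", "archaeon") %in% names(pairs)))
  active <- intersect(names(metrics), names(thresholds))
  if (length(active) == 0L) stop("no metric has a threshold")
  if (nrow(pairs) == 0L) {
    for (m in active) pairs[[paste0("dist_", m)]] <- numeric(0)
    pairs$confirmed <- logical(0)
    return(pairs)
  }
  members <- unique(c(pairs$bacterium, pairs$archaeon))
  missing <- setdiff(members, names(fcgrs))
  if (length(missing) > 0L) {
    stop("missing FCGR for sample(s): ", paste(missing, collapse = ", "))
  }
  below <- matrix(NA, nrow(pairs), length(active),
                  dimnames = list(NULL, active))
  for (m in active) {
    d <- vapply(seq_len(nrow(pairs)), function(i) {
      metrics[[m]](fcgrs[[pairs$bacterium[i]]], fcgrs[[pairs$archaeon[i]]])
    }, numeric(1))
    pairs[[paste0("dist_", m)]] <- d
    below[, m] <- d < thresholds[[m]]
  }
  pairs$confirmed <- if (rule == "all") {
    rowSums(below) == length(active)
  } else {
    rowSums(below) > length(active) / 2
  }
  pairs
}
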