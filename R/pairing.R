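#' Reducer x clusterer combination
#'
#' Layer 1 of the pair pipeline clusters genomic signatures with
#' combinations of a dimensionality reducer and a non-parametric clusterer
#' (no preset cluster count). Native reducers: `identity`, `pca`; native
#' clusterers: `affinity_propagation`, `mean_shift`, `iterative_medoids`.
#' `plugin` slots accept external tools (e.g. UMAP, HDBSCAN, VAE-based or
#' contrastive clusterings) via `params$reduce_fun` / `params$cluster_fun`
#' functions, or `params$labels_file` — a two-column TSV (sample id, cluster
#' label, -1 = noise) in the label interchange format.
#'
#' @param reducer `"identity"`, `"pca"` or `"plugin"`.
#' @param clusterer `"affinity_propagation"`, `"mean_shift"`,
#'   `"iterative_medoids"` or `"plugin"`.
#' @param params Named list of options for either side.
#' @param name Display name; default `"<reducer>+<clusterer>"`.
#' @return An object of class `combo_spec`.
#' @export
combo_spec <- function(reducer = c("identity", "pca", "plugin"),
                       clusterer = c("affinity_propagation", "mean_shift",
                                     "iterative_medoids", "plugin"),
                       params = list(), name = NULL) {
  reducer <- match.arg(reducer)
  clusterer <- match.arg(clusterer)
  structure(list(reducer = reducer, clusterer = clusterer, params = params,
                 name = name %||% paste(reducer, clusterer, sep = "+")),
            class = "combo_spec")
}

#' The default native combination set
#'
#' @return List of six [combo_spec()]s: {identity, pca} x
#'   {affinity_propagation, mean_shift, iterative_medoids}.
#' @export
default_combos <- function() {
  out <- list()
  for (r in c("identity", "pca")) {
    for (cl in c("affinity_propagation", "mean_shift", "iterative_medoids")) {
      out[[length(out) + 1L]] <- combo_spec(r, cl)
    }
  }
  out
}

#' Run one reducer+clusterer combination
#'
#' @param signatures Numeric signature matrix with genome ids as rownames.
#' @param combo A [combo_spec()].
#' @param seed Integer seed (applied before reduction/clustering; native
#'   methods are deterministic given the data, plugins may not be).
#' @return Named integer vector of cluster labels (-1 = noise), aligned
#'   with `rownames(signatures)`.
#' @export
run_combo <- function(signatures, combo, seed = 1L) {
  stopifnot(inherits(combo, "combo_spec"))
  signatures <- as.matrix(signatures)
  if (anyNA(signatures) || any(!is.finite(signatures))) {
    stop("signature matrix contains non-finite values")
  }
  set.seed(as.integer(seed))
  if (!is.null(combo$params$labels_file)) {
    lab <- utils::read.table(combo$params$labels_file, header = FALSE,
                             sep = "\t", stringsAsFactors = FALSE)
    labels <- stats::setNames(as.integer(lab[[2L]]), lab[[1L]])
    missing <- setdiff(rownames(signatures), names(labels))
    if (length(missing) > 0L) {
      stop("labels file lacks sample(s): ", paste(missing, collapse = ", "))
    }
    return(labels[rownames(signatures)])
  }
  red <- .reduce_features(signatures, combo$reducer, combo$params)
  labels <- switch(combo$clusterer,
    affinity_propagation = affinity_propagation(
      red, preference = combo$params$preference %||% NULL,
      damping = combo$params$damping %||% 0.9),
    mean_shift = mean_shift(red, bandwidth = combo$params$bandwidth %||% NULL),
    iterative_medoids = iterative_medoids(
      red, ratio = combo$params$ratio %||% 0.3),
    plugin = {
      if (!is.function(combo$params$cluster_fun)) {
        stop("plugin clusterer unavailable (no params$cluster_fun)")
      }
      combo$params$cluster_fun(red)
    })
  stats::setNames(as.integer(labels), rownames(signatures))
}

#' Genus-accuracy score of a clustering
#'
#' Per cluster, completeness is the proportion of members belonging to the
#' cluster's majority genus (contamination is its complement); a cluster is
#' genus-accurate when completeness > 0.5. The score is the ratio of
#' genus-accurate clusters to all clusters (noise, label -1, is not a
#' cluster).
#'
#' @param labels Integer cluster labels (-1 = noise).
#' @param genera Genus per sample, aligned with `labels`.
#' @return Score in `[0, 1]` with attributes `n_clusters` and `clusters` (a
#'   data.frame of per-cluster completeness/contamination).
#' @export
score_combo <- function(labels, genera) {
  stopifnot(length(labels) == length(genera))
  keep <- labels != -1L
  if (!any(keep)) {
    warning("all points labelled noise; genus-accuracy ratio reported as 0")
    out <- 0
    attr(out, "n_clusters") <- 0L
    return(out)
  }
  ids <- sort(unique(labels[keep]))
  rows <- lapply(ids, function(cl) {
    g <- genera[labels == cl]
    comp <- max(table(g)) / length(g)
    data.frame(cluster = cl, size = length(g), completeness = comp,
               contamination = 1 - comp,
               genus_accurate = comp > 0.5 && (1 - comp) < 0.5)
  })
  tab <- do.call(rbind, rows)
  out <- mean(tab$genus_accurate)
  attr(out, "n_clusters") <- nrow(tab)
  attr(out, "clusters") <- tab
  out
}

#' Score a list of combinations by genus accuracy
#'
#' Runs each combination once and attaches its genus-accuracy ratio and
#' cluster count. A combination whose plugin is unavailable is skipped with
#' a warning (score `NA`) and the pipeline proceeds with the rest.
#'
#' @param signatures Signature matrix.
#' @param genera Genus per row of `signatures`.
#' @param combos List of [combo_spec()]s.
#' @param seed Integer seed.
#' @return The combos list, each with `$score` and `$n_clusters` set.
#' @export
score_combos <- function(signatures, genera, combos = default_combos(),
                         seed = 1L) {
  lapply(seq_along(combos), function(i) {
    cb <- combos[[i]]
    res <- tryCatch(run_combo(signatures, cb, seed = seed + i),
                    error = function(e) {
                      warning("combo '", cb$name, "' skipped: ",
                              conditionMessage(e))
                      NULL
                    })
    if (is.null(res)) {
      cb$score <- NA_real_; cb$n_clusters <- NA_integer_
    } else {
      s <- score_combo(res, genera)
      cb$score <- as.numeric(s)
      cb$n_clusters <- attr(s, "n_clusters")
    }
    cb
  })
}

#' Select the top combinations by genus accuracy
#'
#' Descending score; ties broken by fewer clusters, then lexical name.
#' Skipped (NA-scored) combinations are never selected.
#'
#' @param scored Output of [score_combos()].
#' @param top_n Number to keep (default 5).
#' @return List of the selected `combo_spec`s.
#' @export
select_top_combos <- function(scored, top_n = 5L) {
  ok <- Filter(function(cb) !is.na(cb$score), scored)
  if (length(ok) < top_n) {
    warning("only ", length(ok), " scored combination(s) available; ",
            "selecting all")
    top_n <- length(ok)
  }
  scores <- vapply(ok, `[[`, numeric(1), "score")
  ncl <- vapply(ok, `[[`, numeric(1), "n_clusters")
  nm <- vapply(ok, `[[`, character(1), "name")
  ord <- order(-scores, ncl, nm)
  ok[ord[seq_len(top_n)]]
}

#' Consensus cross-domain candidate pairs
#'
#' For each selected combination the clustering is run `runs` times with
#' different seeds; every (bacterium, archaeon) pair sharing a non-noise
#' cluster in a run gains one support count for that combination. A pair is
#' retained when its support exceeds `min_runs` runs within a combination
#' for a strict majority of the combinations. (Support is counted per
#' combination, not pooled.)
#'
#' @param combos List of [combo_spec()]s (typically [select_top_combos()]).
#' @param signatures Signature matrix (rownames = genome ids).
#' @param domains Named character vector (`"bacteria"`/`"archaea"`) per
#'   genome id.
#' @param runs Clustering repetitions per combination (default 10).
#' @param min_runs Retention needs support strictly greater than this
#'   (default 5).
#' @param seed Integer seed fanned out per combination and run.
#' @return A data.frame of class `candidate_pairs`: `bacterium`,
#'   `archaeon`, one support column per combination, `retained`.
#' @export
consensus_pairs <- function(combos, signatures, domains, runs = 10L,
                            min_runs = 5L, seed = 1L) {
  signatures <- as.matrix(signatures)
  ids <- rownames(signatures)
  stopifnot(!is.null(ids), all(ids %in% names(domains)))
  domains <- domains[ids]
  if (!all(c("bacteria", "archaea") %in% domains)) {
    stop("both domains must be present for pair extraction")
  }
  support <- list()
  for (ci in seq_along(combos)) {
    counts <- new.env(parent = emptyenv())
    for (r in seq_len(runs)) {
      labels <- run_combo(signatures, combos[[ci]],
                          seed = seed + ci * 1000L + r)
      for (cl in setdiff(unique(labels), -1L)) {
        members <- ids[labels == cl]
        bact <- members[domains[members] == "bacteria"]
        arch <- members[domains[members] == "archaea"]
        for (b in bact) for (a in arch) {
          key <- paste(b, a, sep = "\r")
          counts[[key]] <- (counts[[key]] %||% 0L) + 1L
        }
      }
    }
    support[[ci]] <- counts
  }
  keys <- unique(unlist(lapply(support, ls)))
  if (length(keys) == 0L) {
    out <- data.frame(bacterium = character(0), archaeon = character(0),
                      retained = logical(0))
    class(out) <- c("candidate_pairs", "data.frame")
    return(out)
  }
  combo_names <- make.unique(vapply(combos, `[[`, character(1), "name"))
  supp_mat <- vapply(seq_along(combos), function(ci) {
    vapply(keys, function(k) support[[ci]][[k]] %||% 0L, integer(1))
  }, integer(length(keys)))
  supp_mat <- matrix(supp_mat, nrow = length(keys),
                     dimnames = list(NULL, combo_names))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  retained <- rowSums(supp_mat > min_runs) > length(combos) / 2
  out <- data.frame(bacterium = vapply(parts, `[[`, character(1), 1L),
                    archaeon = vapply(parts, `[[`, character(1), 2L),
                    supp_mat, retained = retained, check.names = FALSE)
  out <- out[order(-rowSums(supp_mat), out$bacterium, out$archaeon), ]
  rownames(out) <- NULL
  class(out) <- c("candidate_pairs", "data.frame")
  out
}
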