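#' Forward-strand 3-mer frequency profile
#'
#' @param seq DNA string (typically a genome proxy sequence).
#' @return Named numeric 64-vector of forward-strand 3-mer frequencies
#'   (canonical averaging is deliberately not applied: 3-mers are read as
#'   quasi-codons, which are strand-specific).
#' @export
threemer_profile <- function(seq) {
  counts <- count_kmers(seq, 3L)
  total <- attr(counts, "total_counted")
  v <- as.numeric(counts)
  if (total > 0) v <- v / total
  stats::setNames(v, names(counts))
}

#' Run the multilayered bacterium-archaeon pair pipeline
#'
#' End-to-end orchestration: genome proxies, canonical k-mer signatures and
#' FCGRs; layer 1 consensus clustering over the top genus-accurate
#' reducer-clusterer combinations (candidate pairs); layer 2 FCGR distance
#' filtering against intra-genus derived thresholds (confirmed pairs);
#' environment-label hypothesis testing (environment-related pairs);
#' 3-mer profile scoring per pair; optional geographic co-occurrence
#' cross-referencing. Layer outputs are monotone filters: confirmed pairs
#' are a subset of candidates, environment-related pairs of confirmed
#' ones.
#'
#' @param records Named list of [genome_record()]s with domain, genus and
#'   environment labels.
#' @param k k-mer size for signatures and FCGRs (default 6).
#' @param proxy_n,proxy_length Proxy sampling parameters (default 10
#'   fragments, 100 kbp).
#' @param combos Candidate reducer-clusterer combinations
#'   (default [default_combos()]).
#' @param top_n Combinations kept after genus-accuracy ranking (default 5).
#' @param runs,min_runs Consensus runs per combination and the strict
#'   support threshold (defaults 10 and 5: a pair needs >5 of 10 runs in a
#'   majority of combinations).
#' @param metrics FCGR distance metrics (default [fcgr_metrics()]).
#' @param rule Threshold rule for [filter_pairs()] (default `"all"`).
#' @param env_rule An [env_match_rule()].
#' @param exclude Genome ids excluded at the hypothesis-testing layer.
#' @param occurrences Optional occurrence data.frame
#'   ([read_occurrences()]); keyed by species name.
#' @param shap_n_perm Permutations for Shapley attribution (default 64).
#' @param out_dir Optional directory; when given, per-layer TSV/JSON
#'   artifacts and a manifest are written.
#' @param seed Integer master seed; every random decision derives from it.
#' @return List of class `pair_pipeline_result` with elements `signatures`,
#'   `combo_ranking`, `candidates` (all scored pairs), `confirmed`,
#'   `env_related`, `groups`, `pair_scores` (per-pair 3-mer similarity
#'   report), `thresholds`, `cooccurrence` (or NULL), `manifest`.
#' @export
run_pipeline <- function(records, k = 6L, proxy_n = 10L,
                         proxy_length = 100000L,
                         combos = default_combos(), top_n = 5L,
                         runs = 10L, min_runs = 5L,
                         metrics = fcgr_metrics(),
                         rule = c("all", "majority"),
                         env_rule = env_match_rule(),
                         exclude = character(0),
                         occurrences = NULL,
                         shap_n_perm = 64L,
                         out_dir = NULL, seed = 1L) {
  rule <- match.arg(rule)
  stopifnot(length(records) >= 2L)
  if (is.null(names(records))) {
    names(records) <- vapply(records, `[[`, character(1), "id")
  }
  ids <- names(records)
  genera <- stats::setNames(vapply(records, `[[`, character(1), "genus"), ids)
  domains <- stats::setNames(vapply(records, `[[`, character(1), "domain"),
                             ids)
  # proxies and signatures -------------------------------------------------
  cfg <- proxy_config(proxy_n, proxy_length)
  proxies <- lapply(seq_along(records), function(i) {
    suppressWarnings(select_proxy(records[[i]], cfg, seed = seed * 100L + i))
  })
  names(proxies) <- ids
  sig <- signature_matrix(proxies, k = k)
  fcgrs <- lapply(proxies, function(p) fcgr(p$sequence$sequence, k = k))
  # layer 1: consensus clustering ------------------------------------------
  scored <- score_combos(sig, genera, combos, seed = seed)
  top <- select_top_combos(scored, top_n)
  candidates <- consensus_pairs(top, sig, domains, runs = runs,
                                min_runs = min_runs, seed = seed)
  retained <- candidates[candidates$retained, , drop = FALSE]
  # layer 2: FCGR distance filter ------------------------------------------
  thresholds <- vapply(metrics, function(m) {
    as.numeric(derive_threshold(fcgrs, genera, m))
  }, numeric(1))
  confirmed_all <- filter_pairs(retained, fcgrs, thresholds, metrics, rule)
  confirmed <- confirmed_all[confirmed_all$confirmed, , drop = FALSE]
  # hypothesis testing ------------------------------------------------------
  env_related <- environment_related_pairs(confirmed, records, env_rule,
                                           exclude)
  groups <- group_by_bacterium(env_related)
  # 3-mer profile analysis ---------------------------------------------------
  profiles <- t(vapply(proxies, function(p) {
    threemer_profile(p$sequence$sequence)
  }, numeric(64L)))
  mean_profile <- colMeans(profiles)
  env_labels <- stats::setNames(
    vapply(records, `[[`, character(1), "temp_label"), ids)
  pair_scores <- .score_pairs(env_related, profiles, mean_profile,
                              env_labels, shap_n_perm, seed)
  # co-occurrence -----------------------------------------------------------
  cooc <- NULL
  if (!is.null(occurrences) && length(groups) > 0L) {
    species_of <- stats::setNames(
      vapply(records, `[[`, character(1), "species"), ids)
    sp_groups <- lapply(groups, function(g) {
      list(group_id = g$group_id, bacterium = species_of[[g$bacterium]],
           archaea = unname(species_of[g$archaea]))
    })
    cooc <- cooccurrence_report(sp_groups, occurrences)
  }
  manifest <- list(
    n_genomes = length(records), k = k, proxy_n = proxy_n,
    proxy_length = proxy_length, runs = runs, min_runs = min_runs,
    support_counting = "per-combination, majority across combinations",
    top_combos = vapply(top, `[[`, character(1), "name"),
    metrics = names(metrics), rule = rule,
    thresholds = as.list(thresholds),
    threshold_derivation = "trimmed 90th percentile of intra-genus means",
    percentile_method = "linear interpolation (type 7)",
    shap = list(backend = "random_forest_100 + permutation Shapley",
                n_perm = shap_n_perm),
    rounding = "half_down", seed = seed,
    n_candidates = nrow(retained), n_confirmed = nrow(confirmed),
    n_env_related = nrow(env_related))
  result <- structure(
    list(signatures = sig, combo_ranking = scored, candidates = candidates,
         confirmed = confirmed_all, env_related = env_related,
         groups = groups, pair_scores = pair_scores,
         thresholds = thresholds, cooccurrence = cooc, manifest = manifest),
    class = "pair_pipeline_result")
  if (!is.null(out_dir)) .write_pipeline_outputs(result, out_dir)
  result
}

# per-pair 3-mer profile scores (Spearman, Shapley top sets, shared ratio,
# combined score)
.score_pairs <- function(pairs, profiles, mean_profile, env_labels,
                         shap_n_perm, seed) {
  empty <- data.frame(bacterium = character(0), archaeon = character(0),
                      shared_ratio = numeric(0), rho = numeric(0),
                      p_value = numeric(0), combined = numeric(0),
                      label = character(0), shared_kmers = character(0),
                      shared_aa = character(0))
  if (nrow(pairs) == 0L) return(empty)
  members <- unique(c(pairs$bacterium, pairs$archaeon))
  labeled <- names(env_labels)[!is.na(env_labels)]
  if (!all(members %in% labeled)) return(empty)
  feat <- profiles[labeled, , drop = FALSE]
  labs <- env_labels[labeled]
  rel <- list(); dev <- list()
  for (m in members) {
    rel[[m]] <- environment_relevant_kmers(feat, labs, m,
                                           n_perm = shap_n_perm, seed = seed)
    dev[[m]] <- deviation_profile(profiles[m, ], mean_profile)
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    b <- pairs$bacterium[i]; a <- pairs$archaeon[i]
    sp <- profile_spearman(profiles[b, ], profiles[a, ])
    sr <- shared_ratio(rel[[b]], rel[[a]], dev[[b]], dev[[a]])
    cs <- combined_score(as.numeric(sr), sp$rho)
    kmers <- attr(sr, "shared_kmers")
    aa <- vapply(kmers, function(k) translate_codon(k)[["three"]],
                 character(1))
    data.frame(bacterium = b, archaeon = a,
               shared_ratio = round(as.numeric(sr), 2),
               rho = round(sp$rho, 2), p_value = sp$p_value,
               combined = cs$score, label = cs$label,
               shared_kmers = paste(kmers, collapse = ","),
               shared_aa = paste(aa, collapse = ","))
  })
  do.call(rbind, rows)
}

.write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  write_signature_tsv(result$signatures,
                      file.path(out_dir, "signatures.tsv"))
  rank_df <- data.frame(
    name = vapply(result$combo_ranking, `[[`, character(1), "name"),
    score = vapply(result$combo_ranking, `[[`, numeric(1), "score"),
    n_clusters = vapply(result$combo_ranking, function(cb)
      as.numeric(cb$n_clusters %||% NA), numeric(1)))
  wt(rank_df, "combo_ranking.tsv")
  wt(result$candidates, "candidate_pairs.tsv")
  wt(result$confirmed, "confirmed_pairs.tsv")
  wt(result$env_related, "environment_related_pairs.tsv")
  wt(result$pair_scores, "pair_scores.tsv")
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pair_pipeline_result <- function(x, ...) {
  cat("<pair_pipeline_result>\n")
  cat("  genomes:          ", x$manifest$n_genomes, "\n")
  cat("  top combinations: ", paste(x$manifest$top_combos, collapse = ", "),
      "\n")
  cat("  candidate pairs:  ", x$manifest$n_candidates, "\n")
  cat("  confirmed pairs:  ", x$manifest$n_confirmed, "\n")
  cat("  env-related pairs:", x$manifest$n_env_related, "\n")
  invisible(x)
}
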