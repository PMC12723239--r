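# 3-mer frequency profile analysis of environment-related pairs.
#
# Profiles use the full 64 forward-strand 3-mers of the genome proxy (not
# the canonical 32): the analysis treats 3-mers as quasi-codons, and codons
# are strand- and orientation-specific.

#' 3-mer deviation profile
#'
#' Per-3-mer deviation of a sample's frequencies from the dataset mean
#' frequencies, with an over/under-representation sign.
#'
#' @param freqs Named numeric 64-vector of a sample's 3-mer frequencies.
#' @param mean_freqs Named numeric 64-vector of dataset mean frequencies.
#' @return An object of class `deviation_profile`: list with `deviation`
#'   (named numeric) and `sign` (`"over"`, `"under"` or `"zero"` per
#'   3-mer).
#' @export
deviation_profile <- function(freqs, mean_freqs) {
  if (length(freqs) != 64L || length(mean_freqs) != 64L) {
    stop("deviation_profile expects 64-element 3-mer frequency vectors")
  }
  if (!is.null(names(freqs)) && !is.null(names(mean_freqs))) {
    mean_freqs <- mean_freqs[names(freqs)]
  }
  d <- as.numeric(freqs) - as.numeric(mean_freqs)
  names(d) <- names(freqs)
  structure(list(deviation = d,
                 sign = ifelse(d > 0, "over", ifelse(d < 0, "under", "zero"))),
            class = "deviation_profile")
}

#' Spearman rank correlation of two 3-mer profiles
#'
#' Rank correlation with average ranks for ties and a two-sided p-value
#' (large-sample approximation, appropriate for 64 tied-prone counts).
#'
#' @param a,b Numeric vectors of equal length >= 3 (counts or frequencies;
#'   ranks are scale-invariant when totals are equal — frequencies are used
#'   throughout this package).
#' @return List with `rho` and `p_value`.
#' @export
profile_spearman <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3L)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("undefined correlation: constant vector")
  }
  ct <- suppressWarnings(
    stats::cor.test(a, b, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Shapley feature attributions for one prediction
#'
#' Model-agnostic Shapley values of a single instance's features for a
#' scalar prediction function, relative to a background instance. With
#' `exact = TRUE` all `2^d` feature coalitions are enumerated (tractable for
#' small d); otherwise a seeded Monte-Carlo permutation estimate is used:
#' for each sampled permutation, features switch one by one from background
#' to instance values and the marginal prediction changes are averaged.
#'
#' @param predict_fun `function(matrix) -> numeric` scalar prediction per
#'   row.
#' @param x Numeric instance vector.
#' @param background Numeric vector of the same length (e.g. feature means
#'   of the training data).
#' @param exact Enumerate all coalitions (requires `length(x) <= 20`).
#' @param n_perm Permutations for the Monte-Carlo estimate.
#' @param seed Integer seed.
#' @return Named numeric attribution vector; sums (exactly for
#'   `exact = TRUE`, in expectation otherwise) to
#'   `predict_fun(x) - predict_fun(background)`.
#' @export
shapley_attribution <- function(predict_fun, x, background, exact = FALSE,
                                n_perm = 128L, seed = 1L) {
  d <- length(x)
  stopifnot(length(background) == d)
  feat_names <- names(x)
  x <- as.numeric(x); background <- as.numeric(background)
  if (exact) {
    if (d > 20L) stop("exact Shapley enumeration limited to 20 features")
    subsets <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), d)))
    inst <- t(apply(subsets, 1, function(s) ifelse(s, x, background)))
    vals <- predict_fun(inst)
    sizes <- rowSums(subsets)
    phi <- numeric(d)
    for (i in seq_len(d)) {
      without <- which(!subsets[, i])
      # match S to S + {i}: flipping bit i adds 2^(i-1) to the row index - 1
      with_i <- without + 2L^(i - 1L)
      s <- sizes[without]
      w <- factorial(s) * factorial(d - s - 1L) / factorial(d)
      phi[i] <- sum(w * (vals[with_i] - vals[without]))
    }
  } else {
    set.seed(as.integer(seed))
    phi <- numeric(d)
    for (p in seq_len(n_perm)) {
      ord <- sample.int(d)
      inst <- matrix(background, d + 1L, d, byrow = TRUE)
      for (j in seq_len(d)) {
        inst[(j + 1L):(d + 1L), ord[j]] <- x[ord[j]]
      }
      vals <- predict_fun(inst)
      phi[ord] <- phi[ord] + diff(vals)
    }
    phi <- phi / n_perm
  }
  names(phi) <- feat_names
  phi
}

#' Environment-relevant 3-mers of a sample
#'
#' Ranks a sample's 3-mers by the absolute Shapley attribution of their
#' frequencies to the classifier's probability for the sample's true
#' environment class, and keeps the top `top_n`. The default attribution
#' model is a 100-tree random forest fit on the supplied training matrix;
#' any fitted model can be passed instead as a
#' `function(matrix) -> probability` for the relevant class.
#'
#' @param features Numeric matrix of 3-mer frequencies (rows = samples,
#'   named), 64 columns.
#' @param labels Environment labels aligned with rows.
#' @param sample Row name (or index) of the sample to explain.
#' @param predict_prob Optional `function(matrix) -> numeric` probability
#'   of the sample's true class; when `NULL` a random forest is fit.
#' @param top_n Number of 3-mers to keep (default 15).
#' @param n_perm,seed Passed to [shapley_attribution()].
#' @return An object of class `relevant_set`: list with `sample`, `kmers`
#'   (character, ordered by descending |attribution|), `attribution` (named
#'   numeric for the kept 3-mers), `degenerate` (TRUE when all attributions
#'   were ~0 and the order fell back to lexicographic).
#' @export
environment_relevant_kmers <- function(features, labels, sample,
                                       predict_prob = NULL, top_n = 15L,
                                       n_perm = 128L, seed = 1L) {
  features <- as.matrix(features)
  if (is.character(sample)) {
    if (!sample %in% rownames(features)) {
      stop("sample '", sample, "' not found in feature matrix")
    }
    idx <- match(sample, rownames(features))
  } else {
    idx <- as.integer(sample)
    sample <- rownames(features)[idx] %||% as.character(idx)
  }
  true_class <- as.character(labels[idx])
  if (is.null(predict_prob)) {
    set.seed(as.integer(seed))
    fit <- randomForest::randomForest(x = features, y = factor(labels),
                                      ntree = 100L)
    predict_prob <- function(m) {
      colnames(m) <- colnames(features)
      stats::predict(fit, m, type = "prob")[, true_class]
    }
  }
  phi <- shapley_attribution(predict_prob, features[idx, ],
                             colMeans(features), n_perm = n_perm,
                             seed = seed)
  degenerate <- all(abs(phi) < 1e-12)
  ord <- if (degenerate) {
    warning("all attributions ~0; falling back to lexicographic order")
    order(names(phi))
  } else {
    order(-abs(phi), names(phi))
  }
  keep <- ord[seq_len(min(top_n, length(phi)))]
  structure(list(sample = sample, kmers = names(phi)[keep],
                 attribution = phi[keep], degenerate = degenerate),
            class = "relevant_set")
}

#' Shared environment-relevant 3-mer ratio of a pair
#'
#' The number of 3-mers present in both members' top sets AND showing the
#' same over/under-representation sign in both deviation profiles, divided
#' by the standard set size (15).
#'
#' @param relA,relB [environment_relevant_kmers()] results.
#' @param devA,devB [deviation_profile()]s of the same two samples.
#' @param set_size Expected top-set size (default 15).
#' @return Ratio in `[0, 1]` with attribute `shared_kmers` (the same-sign
#'   shared 3-mers).
#' @export
shared_ratio <- function(relA, relB, devA, devB, set_size = 15L) {
  stopifnot(inherits(relA, "relevant_set"), inherits(relB, "relevant_set"),
            inherits(devA, "deviation_profile"),
            inherits(devB, "deviation_profile"))
  for (r in list(relA, relB)) {
    if (length(r$kmers) != set_size && !isTRUE(r$degenerate)) {
      stop("relevant set of '", r$sample, "' has ", length(r$kmers),
           " 3-mers; expected ", set_size)
    }
  }
  shared <- intersect(relA$kmers, relB$kmers)
  same_sign <- shared[vapply(shared, function(m) {
    devA$sign[[m]] == devB$sign[[m]] && devA$sign[[m]] != "zero"
  }, logical(1))]
  out <- length(same_sign) / set_size
  attr(out, "shared_kmers") <- same_sign
  out
}

# nearest-rounding to `digits` decimals; "half_down" resolves exact halves
# downward, "half_up" upward (halves detected to 1e-9 so printed 2-decimal
# inputs behave as exact decimals)
.round_decimal <- function(x, digits = 2L, mode = c("half_down", "half_up")) {
  mode <- match.arg(mode)
  s <- x * 10^digits
  f <- floor(s + 1e-9)
  frac <- s - f
  up <- if (mode == "half_up") frac >= 0.5 - 1e-9 else frac > 0.5 + 1e-9
  (f + as.numeric(up)) / 10^digits
}

#' Combined 3-mer similarity score and descriptive label
#'
#' The average of the shared environment-relevant 3-mer ratio and the
#' Spearman rho, rounded to two decimals, with a descriptive label:
#' `Compelling` for scores >= 0.85, `Very strong` for 0.80-0.85, `Strong`
#' for 0.75-0.80, `Moderate` for 0.70-0.75, `Low` below 0.70 (intervals
#' half-open, upper class wins at its boundary).
#'
#' Exact halves in the third decimal are rounded down by default
#' (`rounding = "half_down"`), the convention that best matches the
#' bundled worked-example table; `"half_up"` is available.
#'
#' @param shared_ratio Ratio in `[0, 1]`.
#' @param rho Spearman rho in `[-1, 1]`.
#' @param rounding `"half_down"` or `"half_up"`.
#' @return List with `score` (2-decimal numeric) and `label`.
#' @examples
#' combined_score(0.90, 0.76) # 0.83, "Very strong"
#' @export
combined_score <- function(shared_ratio, rho,
                           rounding = c("half_down", "half_up")) {
  rounding <- match.arg(rounding)
  stopifnot(shared_ratio >= 0, shared_ratio <= 1, rho >= -1, rho <= 1)
  score <- .round_decimal((shared_ratio + rho) / 2, 2L, rounding)
  label <- if (score >= 0.85) "Compelling"
  else if (score >= 0.80) "Very strong"
  else if (score >= 0.75) "Strong"
  else if (score >= 0.70) "Moderate"
  else "Low"
  list(score = score, label = label)
}

.aa_three <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
               Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
               L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
               S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
               "*" = "Stop")

#' Translate a 3-mer as a quasi-codon
#'
#' Standard genetic code; stop codons are labelled `"Stop"`.
#'
#' @param threemer A 3-character DNA string over ACGT.
#' @return Named character vector with elements `one` (one-letter code,
#'   `*` for stops) and `three` (three-letter code).
#' @examples
#' translate_codon("CAA") # Gln
#' @export
translate_codon <- function(threemer) {
  stopifnot(is.character(threemer), length(threemer) == 1L)
  if (nchar(threemer) != 3L || grepl("[^ACGT]", threemer)) {
    stop("translate_codon expects a 3-mer over {A,C,G,T}: '", threemer, "'")
  }
  one <- unname(Biostrings::GENETIC_CODE[threemer])
  c(one = one, three = unname(.aa_three[one]))
}
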