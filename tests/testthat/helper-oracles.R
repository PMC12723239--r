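# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths.

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste0(sample(alphabet, n, replace = TRUE), collapse = "")
}

# naive dictionary-scan k-mer counter (string loop, no Biostrings)
all_kmers_sorted <- function(k) {
  out <- c("A", "C", "G", "T")
  if (k > 1) for (i in 2:k) {
    out <- as.vector(outer(out, c("A", "C", "G", "T"), paste0))
  }
  sort(out)
}

naive_count_kmers <- function(seq, k) {
  counts <- stats::setNames(integer(4^k), all_kmers_sorted(k))
  if (nchar(seq) >= k) {
    for (i in 1:(nchar(seq) - k + 1)) {
      w <- substr(seq, i, i + k - 1)
      if (!grepl("[^ACGT]", w)) counts[w] <- counts[w] + 1L
    }
  }
  counts
}

# string-reversal + complement lookup (no Biostrings)
naive_rc <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# rank-then-Pearson Spearman oracle
naive_spearman <- function(a, b) stats::cor(rank(a), rank(b))

# direct double-loop SSIM (population moments, uniform 7x7 window)
naive_mean_ssim <- function(A, B, w = 7) {
  A <- A / max(A); B <- B / max(B)
  C1 <- 0.01^2; C2 <- 0.03^2
  vals <- c()
  for (i in 1:(nrow(A) - w + 1)) {
    for (j in 1:(ncol(A) - w + 1)) {
      a <- A[i:(i + w - 1), j:(j + w - 1)]
      b <- B[i:(i + w - 1), j:(j + w - 1)]
      ma <- mean(a); mb <- mean(b)
      va <- mean(a^2) - ma^2; vb <- mean(b^2) - mb^2
      cab <- mean(a * b) - ma * mb
      vals <- c(vals, ((2 * ma * mb + C1) * (2 * cab + C2)) /
                  ((ma^2 + mb^2 + C1) * (va + vb + C2)))
    }
  }
  mean(vals)
}

# sort-and-interpolate percentile oracle (type-7 linear interpolation)
naive_trimmed_p90 <- function(means) {
  s <- sort(means)
  trim <- floor(0.05 * length(s))
  if (trim > 0) s <- s[(trim + 1):(length(s) - trim)]
  h <- (length(s) - 1) * 0.9 + 1
  lo <- floor(h); hi <- ceiling(h)
  unname(s[lo] + (h - lo) * (s[hi] - s[lo]))
}

# exact Shapley values by direct coalition enumeration (independent of the
# package's subset indexing)
naive_shapley <- function(predict_fun, x, background) {
  d <- length(x)
  phi <- numeric(d)
  subsets <- lapply(0:(2^d - 1), function(m) which(bitwAnd(m, 2^(0:(d - 1))) > 0))
  v <- vapply(subsets, function(S) {
    z <- background; z[S] <- x[S]
    predict_fun(matrix(z, 1))
  }, numeric(1))
  names(v) <- vapply(subsets, function(S) paste(S, collapse = ","), "")
  for (i in 1:d) {
    for (si in seq_along(subsets)) {
      S <- subsets[[si]]
      if (i %in% S) next
      key_with <- paste(sort(c(S, i)), collapse = ",")
      w <- factorial(length(S)) * factorial(d - length(S) - 1) / factorial(d)
      phi[i] <- phi[i] + w * (v[[key_with]] - v[[si]])
    }
  }
  phi
}

# small genome set for fast supervised / pipeline tests
tiny_dataset <- function(seed = 1, n_genera = 4, samples = 3,
                         genome_length = 20000, ...) {
  generate_dataset(synthetic_config(
    n_genera_per_domain = n_genera, samples_per_genus = samples,
    genome_length = genome_length, seed = seed, ...))
}
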