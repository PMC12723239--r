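test_that("deviation profiles subtract the dataset mean elementwise", {
  base <- stats::setNames(rep(1 / 64, 64), kmer_names(3))
  dp0 <- deviation_profile(base, base)
  expect_true(all(dp0$deviation == 0))
  expect_true(all(dp0$sign == "zero"))
  samp <- base
  samp[["AAA"]] <- samp[["AAA"]] + 0.02
  dp <- deviation_profile(samp, base)
  expect_equal(dp$deviation[["AAA"]], 0.02)
  expect_identical(dp$sign[["AAA"]], "over")
  expect_error(deviation_profile(base[1:10], base), "64")
  # naive loop oracle
  set.seed(41)
  a <- stats::setNames(runif(64), kmer_names(3))
  b <- stats::setNames(runif(64), kmer_names(3))
  dp2 <- deviation_profile(a, b)
  for (i in sample(64, 10)) {
    expect_equal(dp2$deviation[[i]], a[[i]] - b[[i]])
    expect_identical(dp2$sign[[i]], if (a[[i]] > b[[i]]) "over" else "under")
  }
})

test_that("Spearman correlation matches the rank-then-Pearson oracle", {
  x <- 1:64
  expect_equal(profile_spearman(x, x)$rho, 1)
  expect_equal(profile_spearman(x, rev(x))$rho, -1)
  set.seed(42)
  for (rep in 1:5) {
    a <- rpois(64, 30); b <- rpois(64, 30)
    if (sd(a) == 0 || sd(b) == 0) next
    got <- profile_spearman(a, b)
    expect_equal(got$rho, naive_spearman(a, b), tolerance = 1e-12)
    expect_true(got$p_value >= 0 && got$p_value <= 1)
  }
  expect_error(profile_spearman(rep(1, 10), 1:10), "constant")
})

test_that("exact Shapley attributions match brute-force enumeration", {
  # 2-feature linear model: phi has a closed form and tiny enumeration
  predf <- function(m) 2 * m[, 1] - 3 * m[, 2] + 1
  x <- c(a = 1, b = 2); bg <- c(0, 0)
  got <- shapley_attribution(predf, x, bg, exact = TRUE)
  expect_equal(unname(got), c(2 * 1, -3 * 2))
  expect_equal(unname(got), naive_shapley(predf, x, bg))
  # non-additive model: still equals the direct enumeration
  predf2 <- function(m) m[, 1] * m[, 2] + m[, 3]
  x3 <- c(1, 2, 3); bg3 <- c(0.5, -1, 0)
  expect_equal(unname(shapley_attribution(predf2, x3, bg3, exact = TRUE)),
               naive_shapley(predf2, x3, bg3))
  # efficiency: attributions sum to f(x) - f(background)
  expect_equal(sum(shapley_attribution(predf2, x3, bg3, exact = TRUE)),
               predf2(matrix(x3, 1)) - predf2(matrix(bg3, 1)))
})

test_that("Monte-Carlo Shapley is seeded and close to exact on small models", {
  predf <- function(m) m[, 1] * m[, 2] + 0.5 * m[, 3]
  x <- c(1, 2, 3); bg <- c(0, 0, 0)
  mc1 <- shapley_attribution(predf, x, bg, n_perm = 200, seed = 7)
  mc2 <- shapley_attribution(predf, x, bg, n_perm = 200, seed = 7)
  expect_identical(mc1, mc2)
  exact <- shapley_attribution(predf, x, bg, exact = TRUE)
  expect_equal(unname(mc1), unname(exact), tolerance = 0.2)
})

test_that("a single-feature model ranks that feature first", {
  feats <- matrix(runif(20 * 64), 20, dimnames = list(
    paste0("s", 1:20), kmer_names(3)))
  labs <- rep(c("hot", "cold"), 10)
  only_aaa <- function(m) m[, 1]  # uses only feature AAA
  rel <- environment_relevant_kmers(feats, labs, "s1",
                                    predict_prob = only_aaa, n_perm = 50)
  expect_identical(rel$kmers[1], "AAA")
  expect_length(rel$kmers, 15)
  expect_false(rel$degenerate)
  # constant model: all attributions ~0, lexicographic fallback with warning
  expect_warning(
    rel0 <- environment_relevant_kmers(feats, labs, "s1",
                                       predict_prob = function(m) rep(1, nrow(m)),
                                       n_perm = 20),
    "lexicographic")
  expect_true(rel0$degenerate)
  expect_identical(rel0$kmers, sort(kmer_names(3))[1:15])
  expect_error(environment_relevant_kmers(feats, labs, "nope"), "not found")
})

test_that("shared ratio counts same-sign members of both top sets out of 15", {
  mk_rel <- function(kmers) {
    structure(list(sample = "x", kmers = kmers,
                   attribution = stats::setNames(seq_along(kmers), kmers),
                   degenerate = FALSE), class = "relevant_set")
  }
  all3 <- kmer_names(3)
  base <- stats::setNames(rep(1 / 64, 64), all3)
  up <- base; up[1:32] <- up[1:32] + 0.01; up[33:64] <- up[33:64] - 0.01
  devA <- deviation_profile(up, base)
  # identical sets, identical signs
  relA <- mk_rel(all3[1:15])
  expect_equal(as.numeric(shared_ratio(relA, relA, devA, devA)), 1)
  # disjoint sets
  relB <- mk_rel(all3[16:30])
  expect_equal(as.numeric(shared_ratio(relA, relB, devA, devA)), 0)
  # 12 shared 3-mers of which 10 same-sign
  relC <- mk_rel(all3[c(1:12, 40:42)])
  down <- base; down[1:10] <- down[1:10] + 0.01
  down[11:12] <- down[11:12] - 0.01; down[43:64] <- down[43:64] - 0.01
  devC <- deviation_profile(down, base)
  got <- shared_ratio(relA, relC, devA, devC)
  expect_equal(as.numeric(got), 10 / 15, tolerance = 1e-12)
  # symmetry
  expect_equal(as.numeric(shared_ratio(relC, relA, devC, devA)),
               as.numeric(got))
  expect_error(shared_ratio(mk_rel(all3[1:10]), relA, devA, devA), "expected")
})

test_that("combined scores reproduce the worked-example rows and labels", {
  expect_identical(combined_score(0.90, 0.76),
                   list(score = 0.83, label = "Very strong"))
  expect_identical(combined_score(1.00, 0.94),
                   list(score = 0.97, label = "Compelling"))
  expect_identical(combined_score(0, 0), list(score = 0, label = "Low"))
  # label boundaries are closed at the upper class
  expect_identical(combined_score(0.85, 0.85)$label, "Compelling")
  expect_identical(combined_score(0.80, 0.80)$label, "Very strong")
  expect_identical(combined_score(0.70, 0.70)$label, "Moderate")
  # rounding modes differ exactly on third-decimal halves
  expect_equal(combined_score(0.83, 0.96, "half_down")$score, 0.89)
  expect_equal(combined_score(0.83, 0.96, "half_up")$score, 0.90)
})

test_that("combined score is monotone in both arguments", {
  set.seed(44)
  for (rep in 1:20) {
    r1 <- runif(1); rho1 <- runif(1, -1, 1)
    r2 <- min(1, r1 + runif(1, 0, 0.3))
    rho2 <- min(1, rho1 + runif(1, 0, 0.3))
    expect_gte(combined_score(r2, rho1)$score, combined_score(r1, rho1)$score)
    expect_gte(combined_score(r1, rho2)$score, combined_score(r1, rho1)$score)
  }
})

test_that("quasi-codon translation follows the standard genetic code", {
  expect_identical(translate_codon("CAA")[["three"]], "Gln")
  expect_identical(translate_codon("ACG")[["three"]], "Thr")
  expect_identical(translate_codon("ATG")[["three"]], "Met")
  expect_identical(translate_codon("TAA")[["three"]], "Stop")
  expect_identical(translate_codon("TGG")[["one"]], "W")
  expect_error(translate_codon("AC"), "3-mer")
  expect_error(translate_codon("ANN"), "3-mer")
})
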