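test_that("DSSIM satisfies identity and matches the direct-formula oracle", {
  set.seed(23)
  a <- matrix(runif(32 * 32), 32)
  b <- matrix(runif(32 * 32), 32)
  expect_equal(dssim(a, a), 0)
  expect_gt(dssim(matrix(1, 16, 16), matrix(c(1, 0), 16, 16)), 0)
  expect_equal(dssim(a, b), (1 - naive_mean_ssim(a, b)) / 2,
               tolerance = 1e-9)
  expect_equal(dssim(a, b), dssim(b, a), tolerance = 1e-12)
  expect_error(dssim(a, matrix(0, 8, 8)), "differ")
})

test_that("descriptor distance satisfies the metric axioms on fuzzed grids", {
  set.seed(24)
  grids <- lapply(1:8, function(i) matrix(rexp(16 * 16), 16))
  for (g in grids) expect_equal(descriptor_distance(g, g), 0)
  for (i in 1:5) {
    a <- grids[[sample(8, 1)]]; b <- grids[[sample(8, 1)]]
    expect_equal(descriptor_distance(a, b), descriptor_distance(b, a))
    expect_gte(descriptor_distance(a, b), 0)
  }
  # triangle inequality on 100 fuzzed triples
  for (i in 1:100) {
    t3 <- sample(8, 3)
    dab <- descriptor_distance(grids[[t3[1]]], grids[[t3[2]]])
    dbc <- descriptor_distance(grids[[t3[2]]], grids[[t3[3]]])
    dac <- descriptor_distance(grids[[t3[1]]], grids[[t3[3]]])
    expect_lte(dac, dab + dbc + 1e-12)
  }
  # scale invariance: counts vs frequencies give the same distance
  expect_equal(descriptor_distance(grids[[1]], grids[[2]]),
               descriptor_distance(grids[[1]] * 37, grids[[2]] / 5))
})

test_that("threshold derivation matches the sort-and-interpolate oracle", {
  # construct genomes whose genus means are known: two genomes per genus,
  # the i-th genus at mutual descriptor distance d_i
  set.seed(25)
  base <- matrix(runif(64), 8)
  mk_genus <- function(shift) {
    a <- matrix(runif(64), 8)
    b <- a + shift * matrix(1, 8, 8) * runif(64)
    list(a, b)
  }
  fcgrs <- list(); genera <- c()
  for (i in 1:20) {
    pair <- mk_genus(i / 10)
    fcgrs[[paste0("g", i, "_1")]] <- pair[[1]]
    fcgrs[[paste0("g", i, "_2")]] <- pair[[2]]
    genera[paste0("g", i, "_1")] <- paste0("g", i)
    genera[paste0("g", i, "_2")] <- paste0("g", i)
  }
  thr <- derive_threshold(fcgrs, genera, descriptor_distance)
  means <- vapply(paste0("g", 1:20), function(g) {
    descriptor_distance(fcgrs[[paste0(g, "_1")]], fcgrs[[paste0(g, "_2")]])
  }, numeric(1))
  expect_equal(as.numeric(thr), naive_trimmed_p90(means), tolerance = 1e-12)
  expect_identical(attr(thr, "n_genera"), 20L)
  # order invariance
  perm <- sample(length(fcgrs))
  thr2 <- derive_threshold(fcgrs[perm], genera, descriptor_distance)
  expect_equal(as.numeric(thr2), as.numeric(thr), tolerance = 1e-12)
})

test_that("threshold derivation handles degenerate genus structures", {
  g <- list(a1 = matrix(1:16, 4), a2 = matrix(16:1, 4))
  genera <- c(a1 = "g", a2 = "g")
  thr <- derive_threshold(g, genera, descriptor_distance)
  # single qualifying genus: threshold is its mean (no trimming at floor)
  expect_equal(as.numeric(thr),
               descriptor_distance(g$a1, g$a2), tolerance = 1e-12)
  expect_error(derive_threshold(g["a1"], c(a1 = "g"), descriptor_distance),
               "at least two")
  # identical genus means collapse to that constant
  same <- list(x1 = matrix(1, 4, 4), x2 = matrix(2, 4, 4),
               y1 = matrix(1, 4, 4), y2 = matrix(2, 4, 4))
  gsame <- c(x1 = "x", x2 = "x", y1 = "y", y2 = "y")
  c0 <- descriptor_distance(same$x1, same$x2)
  expect_equal(as.numeric(derive_threshold(same, gsame, descriptor_distance)),
               c0, tolerance = 1e-12)
})

test_that("pair filtering applies strict thresholds per metric", {
  pairs <- data.frame(bacterium = c("b1", "b2"), archaeon = c("a1", "a2"))
  # metrics stubbed to return fixed distances per pair
  fcgrs <- list(b1 = matrix(1, 8, 8), a1 = matrix(1, 8, 8),
                b2 = matrix(2, 8, 8), a2 = matrix(3, 8, 8))
  m1 <- function(x, y) if (identical(x, y)) 0.1 else 0.19
  metrics <- list(descriptor = m1,
                  dssim = function(x, y) 0.2)
  thr <- c(descriptor = 0.190211, dssim = 0.501385)
  out <- filter_pairs(pairs, fcgrs, thr, metrics, rule = "all")
  expect_true(out$confirmed[1])   # 0.1 < 0.190211 and 0.2 < 0.501385
  expect_true(out$confirmed[2])   # 0.19 < 0.190211 (strictly)
  # a distance exactly equal to its threshold is rejected
  thr_eq <- c(descriptor = 0.19, dssim = 0.501385)
  out2 <- filter_pairs(pairs, fcgrs, thr_eq, metrics, rule = "all")
  expect_false(out2$confirmed[2])
  expect_true(out2$confirmed[1])
  # majority rule tolerates one failing metric
  out3 <- filter_pairs(pairs, fcgrs, c(descriptor = 0.15, dssim = 0.5,
                                       extra = 1),
                       c(metrics, list(extra = function(x, y) 0.5)),
                       rule = "majority")
  expect_true(out3$confirmed[1])  # 2 of 3 below
  # empty candidate list passes through
  empty <- filter_pairs(pairs[0, ], fcgrs, thr, metrics)
  expect_identical(nrow(empty), 0L)
  expect_true("confirmed" %in% names(empty))
  expect_error(filter_pairs(data.frame(bacterium = "zz", archaeon = "a1"),
                            fcgrs, thr, metrics), "zz")
})

test_that("the reference threshold set is exposed for the reference operating point", {
  thr <- reference_thresholds()
  expect_identical(names(thr), c("descriptor", "dssim", "lpips"))
  expect_true(all(thr > 0))
})
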