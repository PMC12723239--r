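test_that("native clusterers separate two well-separated blobs", {
  set.seed(17)
  x <- rbind(matrix(rnorm(30 * 3, 0, 0.2), 30),
             matrix(rnorm(30 * 3, 5, 0.2), 30))
  split_lab <- rep(1:2, each = 30)
  for (fun in list(affinity_propagation, mean_shift, iterative_medoids)) {
    lab <- fun(x)
    # every blob is covered by clusters that never mix the two blobs
    expect_true(all(tapply(split_lab, lab, function(v) length(unique(v))) == 1))
  }
})

test_that("combos run deterministically and plugins pass labels through", {
  set.seed(18)
  x <- matrix(rnorm(20 * 5), 20, dimnames = list(paste0("s", 1:20), NULL))
  cb <- combo_spec("pca", "iterative_medoids")
  expect_identical(run_combo(x, cb, seed = 4), run_combo(x, cb, seed = 4))
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(id = rownames(x), lab = rep(c(1L, -1L), 10)), f,
              sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  ext <- combo_spec("identity", "plugin", params = list(labels_file = f))
  got <- run_combo(x, ext)
  expect_identical(unname(got), rep(c(1L, -1L), 10))
  # unavailable plugin is skipped by score_combos with a warning
  bad <- combo_spec("identity", "plugin")
  expect_warning(scored <- score_combos(x, rep(c("a", "b"), 10), list(bad)),
                 "skipped")
  expect_true(is.na(scored[[1]]$score))
})

test_that("genus-accuracy scoring matches its definition and boundaries", {
  lab <- c(1, 1, 1, 1, 2, 2)
  gen <- c("g1", "g1", "g1", "g2", "g1", "g2")
  s <- score_combo(lab, gen)
  tab <- attr(s, "clusters")
  expect_equal(tab$completeness[tab$cluster == 1], 0.75)
  expect_true(tab$genus_accurate[tab$cluster == 1])
  expect_equal(tab$completeness[tab$cluster == 2], 0.5)
  expect_false(tab$genus_accurate[tab$cluster == 2])  # >50% is strict
  expect_equal(as.numeric(s), 0.5)
  # perfect genus clustering scores 1
  expect_equal(as.numeric(score_combo(match(gen, unique(gen)), gen)), 1)
  expect_warning(s0 <- score_combo(rep(-1L, 4), rep("g", 4)), "noise")
  expect_equal(as.numeric(s0), 0)
})

test_that("genus-accuracy score equals a brute-force confusion recompute", {
  set.seed(19)
  for (rep in 1:10) {
    lab <- sample(c(-1L, 1L, 2L, 3L, 4L), 40, replace = TRUE)
    gen <- sample(paste0("g", 1:5), 40, replace = TRUE)
    if (all(lab == -1L)) next
    s <- score_combo(lab, gen)
    cls <- setdiff(sort(unique(lab)), -1L)
    acc <- vapply(cls, function(cl) {
      conf <- table(gen[lab == cl])
      max(conf) / sum(conf) > 0.5
    }, logical(1))
    expect_equal(as.numeric(s), mean(acc))
  }
})

test_that("top-combo selection orders by score with deterministic tie-breaks", {
  mk <- function(name, score, ncl) {
    cb <- combo_spec("identity", "mean_shift", name = name)
    cb$score <- score; cb$n_clusters <- ncl
    cb
  }
  scored <- list(mk("e", 0.5, 4), mk("a", 0.9, 10), mk("b", 0.9, 3),
                 mk("c", 0.7, 2), mk("d", 0.9, 3), mk("f", 0.2, 1),
                 mk("skip", NA, NA))
  top <- select_top_combos(scored, 5)
  expect_identical(vapply(top, `[[`, "", "name"), c("b", "d", "a", "c", "e"))
  expect_warning(select_top_combos(scored[1:3], 5), "available")
})

test_that("consensus retention needs >5 runs in a majority of combos", {
  ids <- c("b1", "b2", "a1", "a2")
  doms <- stats::setNames(c("bacteria", "bacteria", "archaea", "archaea"), ids)
  sig <- matrix(0, 4, 2, dimnames = list(ids, NULL))
  # a plugin whose labels depend on the run (it counts its invocations):
  # pair (b1, a1) co-clusters in the first `hits` runs of each combo
  make_combo <- function(hits, name) {
    counter <- new.env(); counter$i <- 0
    combo_spec("identity", "plugin", name = name, params = list(
      cluster_fun = function(red) {
        counter$i <- counter$i + 1
        if (counter$i <= hits) c(1L, 2L, 1L, 3L) else c(1L, 2L, 4L, 3L)
      }))
  }
  # 10/10 runs in all 5 combos: retained
  res <- consensus_pairs(lapply(1:5, function(i) make_combo(10, paste0("c", i))),
                         sig, doms, runs = 10, seed = 1)
  expect_identical(res$bacterium[res$retained], "b1")
  expect_identical(res$archaeon[res$retained], "a1")
  # 6/10 runs but only 2 of 5 combos: not retained (majority fails)
  combos2 <- c(lapply(1:2, function(i) make_combo(6, paste0("y", i))),
               lapply(3:5, function(i) make_combo(0, paste0("y", i))))
  res2 <- consensus_pairs(combos2, sig, doms, runs = 10, seed = 1)
  expect_false(any(res2$retained))
  # exactly 5/10 runs in all 5 combos: not retained (">5" is strict)
  res3 <- consensus_pairs(lapply(1:5, function(i) make_combo(5, paste0("z", i))),
                          sig, doms, runs = 10, seed = 1)
  expect_false(any(res3$retained))
})

test_that("consensus pairs are always cross-domain and can be empty", {
  ids <- c("b1", "b2", "a1")
  doms <- stats::setNames(c("bacteria", "bacteria", "archaea"), ids)
  sig <- matrix(0, 3, 2, dimnames = list(ids, NULL))
  same_cluster <- combo_spec("identity", "plugin", params = list(
    cluster_fun = function(red) c(1L, 1L, 2L)))  # archaea never joins
  res <- consensus_pairs(list(same_cluster), sig, doms, runs = 3, seed = 1)
  expect_identical(nrow(res), 0L)
  all_together <- combo_spec("identity", "plugin", params = list(
    cluster_fun = function(red) c(1L, 1L, 1L)))
  res2 <- consensus_pairs(list(all_together), sig, doms, runs = 10, seed = 1)
  expect_true(all(doms[res2$bacterium] == "bacteria"))
  expect_true(all(doms[res2$archaeon] == "archaea"))
  expect_identical(nrow(res2), 2L)  # (b1,a1), (b2,a1); never (b1,b2)
})
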