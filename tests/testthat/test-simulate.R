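test_that("scenario I emits the declared mixed-type composition, reproducibly", {
  cd <- simulate_phenomic("I", seed = 42, scale = 1)
  expect_equal(dim(cd$data), c(600, 300))
  expect_equal(sum(cd$types %in% c("categorical", "binary")), 100)
  expect_equal(sum(cd$types == "ordinal"), 60)
  expect_false(any(is.na(cd$data)))
  for (j in which(cd$types == "ordinal")) {
    q <- length(cd$levels[[j]])
    expect_true(q >= 2 && q <= 6)
    expect_true(all(cd$data[, j] %in% seq_len(q)))
  }
  cd2 <- simulate_phenomic("I", seed = 42, scale = 1)
  expect_identical(cd$data, cd2$data)
})

test_that("scaling reduces dimensions and discretization counts proportionally", {
  cd <- simulate_phenomic("I", seed = 1, scale = 1 / 3)
  expect_equal(dim(cd$data), c(200, 100))
  expect_equal(sum(cd$types %in% c("categorical", "binary")), 33)
  expect_equal(sum(cd$types == "ordinal"), 20)
  expect_error(simulate_phenomic("I", seed = 1, scale = 0.005), "scale too small")
})

test_that("scenario I/II cluster structure shows up in both distance matrices", {
  cd <- simulate_phenomic("I", seed = 3, scale = 0.2, discretize = FALSE)
  a <- association_matrix(cd)
  vcl <- cd$var_clusters
  same_v <- outer(vcl, vcl, "==") & vcl > 0
  diff_v <- outer(vcl > 0, vcl > 0, "&") & !outer(vcl, vcl, "==")
  ut <- upper.tri(a$r)
  expect_gt(mean(abs(a$r[same_v & ut])), mean(abs(a$r[diff_v & ut])))
  gd <- gower_distance_matrix(cd)
  scl <- cd$subj_clusters
  same_s <- outer(scl, scl, "==") & scl > 0
  diff_s <- outer(scl > 0, scl > 0, "&") & !outer(scl, scl, "==")
  uts <- upper.tri(gd$d)
  expect_lt(mean(gd$d[same_s & uts]), mean(gd$d[diff_s & uts]))
})

test_that("scenario III has strong subject but sparse variable correlation", {
  cd <- simulate_phenomic("III", seed = 4, scale = 0.2, discretize = FALSE)
  a <- association_matrix(cd)
  # variable correlations are sparse: with ~40 effective subject clusters the
  # null |r| scale is ~1/sqrt(40), so 0.2 bounds "no structure" at desk scale
  expect_lt(mean(abs(a$r[upper.tri(a$r)])), 0.2)
  gd <- gower_distance_matrix(cd)
  scl <- cd$subj_clusters
  same_s <- outer(scl, scl, "==") & scl > 0
  diff_s <- outer(scl > 0, scl > 0, "&") & !outer(scl, scl, "==")
  uts <- upper.tri(gd$d)
  expect_lt(mean(gd$d[same_s & uts]), 0.25 * mean(gd$d[diff_s & uts]))
})

test_that("Poisson cluster sizes keep their mean under the >= 1 and truncation rules", {
  set.seed(5)
  draws <- replicate(200, mean(phenoimpute:::cluster_sizes(6, 40, 1e6)))
  expect_lt(abs(mean(draws) - 40) / 40, 0.1)
  # truncation: sizes never exceed the total
  set.seed(6)
  for (i in 1:50) {
    s <- phenoimpute:::cluster_sizes(6, 40, 100)
    expect_lte(sum(s), 100)
    expect_true(all(s >= 1))
  }
})

test_that("discretization is closed over its level sets and optional", {
  cd <- simulate_phenomic("I", seed = 7, scale = 0.1, discretize = FALSE)
  expect_true(all(cd$types == "continuous"))
  d0 <- discretize_variables(cd, 0, 0)
  expect_identical(d0$data, cd$data)
  d1 <- discretize_variables(cd, 4, 3, seed = 8)
  expect_equal(sum(d1$types %in% c("categorical", "binary")), 4)
  expect_equal(sum(d1$types == "ordinal"), 3)
  for (j in which(d1$types != "continuous")) {
    expect_true(all(d1$data[, j] %in% c(0, seq_along(d1$levels[[j]]))))
  }
  expect_error(discretize_variables(cd, 100, 100), "more columns")
})

test_that("ordinalized columns stay strongly rank-correlated with their source", {
  cd <- simulate_phenomic("I", seed = 9, scale = 0.2, discretize = FALSE)
  j <- which(cd$var_clusters == 0)[1]
  src <- cd$data[, j]
  d1 <- discretize_variables(cd, 0, 1, seed = 10)
  jd <- which(d1$types == "ordinal")
  expect_gte(as.numeric(corr_spearman(src_of <- cd$data[, jd], d1$data[, jd])), 0.8)
})

test_that("scenario III nominals are sparse with up to 30 levels", {
  cd <- simulate_phenomic("III", seed = 11, scale = 1 / 3)
  noms <- which(cd$types %in% c("categorical", "binary"))
  expect_equal(length(noms), 33)
  qs <- vapply(noms, function(j) length(cd$levels[[j]]), integer(1))
  expect_true(all(qs <= 30))
  expect_gt(max(qs), 6)  # the sparse cutting creates many-level variables
})
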