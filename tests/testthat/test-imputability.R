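test_that("IM is exp(-E) with the per-cell max rule", {
  # arithmetic of the definition, through the filter interface
  scores <- structure(list(
    im_subject = c(0.2, 0.9), im_variable = c(0.9, 0.1),
    im_cell = data.frame(i = c(1L, 2L), j = c(1L, 2L), variable = c("V1", "V2"),
                         im = c(max(0.2, 0.9), max(0.9, 0.1))),
    t = 1, rate = 0.05, method = "knn-vs"), class = "imputability_scores")
  expect_equal(scores$im_cell$im, c(0.9, 0.9))
  expect_equal(exp(-1), 0.3678794, tolerance = 1e-6)
})

test_that("perfectly imputable structure yields IM near 1", {
  tab <- duplicated_fixture(n = 40, p = 8, seed = 4)
  md <- generate_missing(tab, 0.05, seed = 5)
  im <- compute_im(md, t = 4, rate = 0.05, seed = 6, K = 2, min_pairs = 5)
  # near-perfect on average; occasional cells collide with a masked duplicate
  expect_gt(mean(im$im_variable), 0.85)
  expect_gt(mean(im$im_subject), 0.8)
  expect_gt(stats::median(im$im_cell$im), 0.9)
  expect_true(all(im$im_cell$im > 0 & im$im_cell$im <= 1))
})

test_that("independent noise variables score lower IMv than clustered ones", {
  set.seed(7)
  n <- 60
  base <- rnorm(n)
  clustered <- sapply(1:6, function(k) 0.2 * k + (0.5 + 0.1 * k) * base)
  noise <- matrix(rnorm(n * 6, sd = 2), n, 6)
  z <- cbind(clustered, noise)
  colnames(z) <- paste0("V", 1:12)
  tab <- phenoimpute:::new_phenomic_table(z, rep("continuous", 12),
                                          rep(list(character(0)), 12))
  md <- generate_missing(tab, 0.05, seed = 8)
  im <- compute_im(md, t = 5, rate = 0.05, seed = 9, K = 3, min_pairs = 5)
  expect_gt(mean(im$im_variable[1:6]), mean(im$im_variable[7:12]))
})

test_that("subjects or variables missed by every second layer are flagged unsampled", {
  tab <- mixed_fixture(n = 40, seed = 10)
  md <- generate_missing(tab, 0.05, seed = 11)
  # one repetition hiding very few cells cannot touch every subject
  im <- compute_im(md, t = 1, rate = 0.02, seed = 12, min_pairs = 5)
  expect_true(any(im$unsampled_subject))
  # unsampled entities still get a (pooled) finite score in (0, 1]
  expect_true(all(im$im_subject > 0 & im$im_subject <= 1))
})

test_that("the IM filter partitions deterministically", {
  n_cells <- 100
  scores <- structure(list(
    im_subject = rep(0.5, 10), im_variable = rep(0.5, 10),
    im_cell = data.frame(i = rep(1:10, each = 10), j = rep(1:10, times = 10),
                         variable = "V", im = rep(0.5, n_cells)),
    t = 1, rate = 0.05, method = "knn-vs"), class = "imputability_scores")
  part <- filter_by_im(scores, mode = "quantile", cutoff = 0.25)
  expect_equal(nrow(part$flagged), 25)
  # all-equal IMs: ties break by (i, j) lexicographic order
  expect_equal(part$flagged$i, rep(1:3, c(10, 10, 5)))
  part0 <- filter_by_im(scores, mode = "threshold", cutoff = 0)
  expect_equal(nrow(part0$flagged), 0)  # IM > 0 always
  expect_error(filter_by_im(scores, cutoff = 1.5), "cutoff")
})

test_that("dropping the lowest-IM quartile of cells reduces evaluated RMSE", {
  set.seed(20)
  n <- 60
  base <- rnorm(n)
  clustered <- sapply(1:8, function(k) 0.2 * k + (0.5 + 0.1 * k) * base + rnorm(n, sd = 0.2))
  noise <- matrix(rnorm(n * 6, sd = 2), n, 6)
  z <- cbind(clustered, noise)
  colnames(z) <- paste0("V", 1:14)
  cd <- phenoimpute:::new_phenomic_table(z, rep("continuous", 14),
                                         rep(list(character(0)), 14))
  md <- generate_missing(cd, 0.08, seed = 21)
  layer <- missing_layer(md, cd)
  res <- impute_phenomic(md, "knn-v", min_pairs = 5)
  im <- compute_im(md, t = 5, rate = 0.05, seed = 22, min_pairs = 5)
  part <- filter_by_im(im, mode = "quantile", cutoff = 0.25)
  all_ev <- evaluate_imputation(res, cd, layer)
  keep <- layer
  keep[cbind(part$flagged$i, part$flagged$j)] <- FALSE
  kept_ev <- evaluate_imputation(res, cd, keep)
  expect_lt(kept_ev$rmse_continuous, all_ev$rmse_continuous)
})
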