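test_that("neighbour weights follow the squared-odds formula", {
  expect_equal(neighbor_weights(0), 0)
  expect_equal(neighbor_weights(0.8), (0.64 / 0.360001)^2)
  expect_equal(neighbor_weights(-0.8), neighbor_weights(0.8))
  expect_true(all(diff(neighbor_weights(seq(0, 0.99, by = 0.01))) > 0))
})

test_that("aggregation follows the per-type rules", {
  agg <- phenoimpute:::aggregate_predictions
  expect_equal(agg("continuous", c(2, 4), c(1, 3), NA), 3.5)
  expect_equal(agg("ordinal", c(5, 4.6), c(1, 1), 4), 4)    # 4.8 -> round -> clip at q=4
  expect_equal(agg("ordinal", c(0.4, 0.2), c(1, 1), 4), 1)  # clip from below
  expect_equal(agg("categorical", c(1, 1, 2), c(1, 1, 1), 3), 1)  # majority
  expect_equal(agg("categorical", c(1, 2), c(1, 1), 3), 1)        # tie -> lowest
  expect_equal(agg("binary", c(0, 1, 1), c(5, 1, 1), 2), 0)       # weighted
})

test_that("KNN-V recovers held-out cells exactly through a duplicate variable", {
  tab <- duplicated_fixture(n = 30, p = 6, seed = 2)
  truth <- tab$data
  set.seed(5)
  # mask only the first half of the columns so each cell's duplicate column
  # (j + 3) stays observed at that subject
  cells <- cbind(sample(nrow(truth), 20), sample(1:3, 20, replace = TRUE))
  cells <- unique(cells)
  md <- phenoimpute:::mask_cells(tab, cells)
  res <- impute_phenomic(md, "knn-v", K = 2, min_pairs = 5)
  expect_equal(res$table$data[cells], truth[cells], tolerance = 1e-8)
  expect_false(any(is.na(res$table$data)))
})

test_that("KNN-S: a duplicated subject dominates and reproduces its values", {
  tab <- duplicated_fixture(n = 30, p = 6, seed = 3)
  truth <- tab$data
  # hide one cell of subject 1; its duplicate is subject 31
  md <- phenoimpute:::mask_cells(tab, cbind(1, 2))
  res <- impute_phenomic(md, "knn-s", K = 3)
  expect_equal(res$table$data[1, 2], truth[31, 2], tolerance = 1e-8)
})

test_that("KNN-S averages equidistant neighbours and takes majority votes", {
  # three subjects: target shares distance with both neighbours
  z <- rbind(c(NA, 0, 0), c(1, 0.5, 0), c(3, -0.5, 0))
  colnames(z) <- c("t", "a", "b")
  tab <- phenoimpute:::new_phenomic_table(z, rep("continuous", 3), rep(list(character(0)), 3))
  gd <- gower_distance_matrix(tab)
  expect_equal(gd$d[1, 2], gd$d[1, 3])
  res <- phenoimpute:::knn_s_engine(tab, gd, cbind(1L, 1L), K = 2)
  expect_equal(res$values, 2)  # equal weights -> plain mean of 1 and 3
  # nominal vote {A, A, B} with equal weights
  expect_equal(phenoimpute:::weighted_vote(c(1, 1, 2), c(1, 1, 1)), 1)
})

test_that("cells with no eligible neighbours fall back to the column marginal", {
  # subject 1 observes only variable 1 -> no variable neighbour is usable
  z <- matrix(rnorm(40), 10, 4)
  z[1, ] <- NA
  z[1, 1] <- NA  # target cell
  z[2:10, ] <- matrix(rnorm(36), 9, 4)
  colnames(z) <- paste0("V", 1:4)
  tab <- phenoimpute:::new_phenomic_table(z, rep("continuous", 4), rep(list(character(0)), 4))
  res <- impute_phenomic(tab, "knn-v", K = 3, min_pairs = 5)
  pr <- res$provenance
  row1 <- pr[pr$i == 1 & pr$j == 1, ]
  expect_match(row1$fallback, "marginal_fallback")
  expect_equal(unname(res$table$data[1, 1]), mean(z[2:10, 1]))
})

test_that("mean imputation uses mean / rounded mean / lowest-tie mode by type", {
  df <- data.frame(c1 = c(1, 2, 3, NA),
                   o1 = c("a", "a", "c", NA),
                   b1 = c("no", "no", "yes", NA),
                   stringsAsFactors = FALSE)
  spec <- list(c1 = list(type = "continuous"),
               o1 = list(type = "ordinal", levels = list("a", "b", "c")),
               b1 = list(type = "binary", levels = list("no", "yes")))
  tab <- phenomic_table(df, spec)
  res <- impute_phenomic(tab, "mean")
  expect_equal(res$table$data[4, "c1"], 2)
  expect_equal(res$table$data[4, "o1"], 2)  # mean 5/3 rounds to 2
  expect_equal(res$table$data[4, "b1"], 0)  # mode
  # a fully-missing column cannot be mean-imputed
  df$c1 <- NA_real_
  tab2 <- phenomic_table(df, spec)
  expect_error(impute_phenomic(tab2, "mean"), "no observed values")
})

test_that("every imputer clears the mask and respects type ranges", {
  tab <- mixed_fixture(n = 50, seed = 6, miss = 0.15)
  for (m in c("mean", "knn-v", "knn-s")) {
    res <- impute_phenomic(tab, m, min_pairs = 5)
    expect_false(any(is.na(res$table$data)), info = m)
    for (j in which(tab$types == "ordinal")) {
      expect_true(all(res$table$data[, j] %in% seq_along(tab$levels[[j]])), info = m)
    }
    for (j in which(tab$types == "binary")) {
      expect_true(all(res$table$data[, j] %in% 0:1), info = m)
    }
  }
})

test_that("imputation with a fixed seed is bit-reproducible", {
  tab <- mixed_fixture(n = 40, seed = 10, miss = 0.15)
  r1 <- impute_phenomic(tab, "knn-h", n_reps = 3, seed = 77, min_pairs = 5)
  r2 <- impute_phenomic(tab, "knn-h", n_reps = 3, seed = 77, min_pairs = 5)
  expect_identical(r1$table$data, r2$table$data)
  expect_identical(r1$weight$p_global, r2$weight$p_global)
})
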