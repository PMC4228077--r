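test_that("the closed-form hybrid weight hits its boundary and symmetric cases", {
  # perfect subject-based imputer -> all weight on KNN-S
  expect_equal(as.numeric(p_closed_form(c(0, 0, 0), c(1, 0.5, 2))), 1)
  # perfect variable-based imputer -> all weight on KNN-V
  expect_equal(as.numeric(p_closed_form(c(1, 0.5, 2), c(0, 0, 0))), 0)
  # symmetric errors -> 0.5
  expect_equal(as.numeric(p_closed_form(c(2, 0), c(0, 2))), 0.5)
  # degenerate denominator -> 0.5 with a flag
  pd <- p_closed_form(c(0, 0), c(0, 0))
  expect_equal(as.numeric(pd), 0.5)
  expect_equal(attr(pd, "flag"), "degenerate")
  # minimization property: the returned p beats nearby mixtures
  set.seed(1)
  es <- rnorm(50, sd = 0.5); ev <- rnorm(50)
  p <- as.numeric(p_closed_form(es, ev))
  obj <- function(p) sum((p * es + (1 - p) * ev)^2)
  expect_lte(obj(p), obj(min(p + 0.01, 1)))
  expect_lte(obj(p), obj(max(p - 0.01, 0)))
})

test_that("per-cell mixing follows p * KNN-S + (1 - p) * KNN-V", {
  cmb <- phenoimpute:::combine_hybrid
  expect_equal(cmb("continuous", 2, 4, 0.25, NA), 3.5)
  expect_equal(cmb("ordinal", 2, 4, 0.25, 4), 4)      # 3.5 rounds up
  expect_equal(cmb("ordinal", 1, 5, 0.9, 4), 1)       # 1.4 -> 1
  expect_equal(cmb("categorical", 3, 1, 0.8, 3), 3)   # p > 0.5 -> subject side
  expect_equal(cmb("categorical", 3, 1, 0.2, 3), 1)
  expect_equal(cmb("categorical", 3, 1, 0.5, 3), 1)   # tie -> lowest code
})

test_that("KNN-H reduces to KNN-V at p = 0 and KNN-S at p = 1", {
  tab <- mixed_fixture(n = 50, seed = 21, miss = 0.12)
  rv <- impute_phenomic(tab, "knn-v", min_pairs = 5)
  rs <- impute_phenomic(tab, "knn-s", min_pairs = 5)
  h0 <- impute_phenomic(tab, "knn-h", p = 0, min_pairs = 5)
  h1 <- impute_phenomic(tab, "knn-h", p = 1, min_pairs = 5)
  # identical except where one side fell back marginally (both fall back
  # identically there)
  expect_identical(h0$table$data, rv$table$data)
  expect_identical(h1$table$data, rs$table$data)
})

test_that("KNN-A with constant windows is bit-identical to KNN-H", {
  tab <- mixed_fixture(n = 50, seed = 22, miss = 0.12)
  hw <- estimate_p(tab, K = 5, n_reps = 3, rate = 0.05, seed = 9,
                   adaptive = TRUE, min_pairs = 5)
  hw_const <- hw
  hw_const$p_window[] <- hw$p_global
  hw_const$window_flags[] <- ""
  ha <- impute_phenomic(tab, "knn-a", p = hw_const, min_pairs = 5)
  hh <- impute_phenomic(tab, "knn-h", p = hw$p_global, min_pairs = 5)
  expect_identical(ha$table$data, hh$table$data)
})

test_that("sparse r_max windows inherit the global weight", {
  hw <- structure(list(p_global = 0.7, adaptive = TRUE,
                       grid = c(0.5, 0.6), p_window = c(0.2, 0.7),
                       window_flags = c("", "too_few_observations"),
                       r_max = c(0.5, 0.6, NA)),
                  class = "hybrid_weight")
  expect_equal(phenoimpute:::p_for_variable(hw, 1)$p, 0.2)
  w2 <- phenoimpute:::p_for_variable(hw, 2)
  expect_equal(w2$p, 0.7)
  expect_equal(w2$flag, "window_fallback")
  w3 <- phenoimpute:::p_for_variable(hw, 3)
  expect_equal(w3$p, 0.7)
  expect_equal(w3$flag, "no_r_max")
})

test_that("adaptive weights track which side is reliable in each r_max regime", {
  # construct data where high-r_max variables are exactly predictable from a
  # duplicate variable (KNN-V exact) and subjects come in near-duplicate
  # pairs (KNN-S informative everywhere)
  set.seed(31)
  n <- 60
  base <- matrix(rnorm(n / 2 * 8), n / 2, 8)
  z <- rbind(base, base + matrix(rnorm(n / 2 * 8, sd = 0.02), n / 2, 8))
  dup <- z[, 1:4]                      # duplicates: r = 1 with columns 1..4
  noise <- matrix(rnorm(n * 4, sd = 1), n, 4)  # independent: r_max ~ 0
  zz <- cbind(z[, 1:4], dup, noise)
  colnames(zz) <- paste0("V", seq_len(ncol(zz)))
  tab <- phenoimpute:::new_phenomic_table(zz, rep("continuous", ncol(zz)),
                                          rep(list(character(0)), ncol(zz)))
  md <- generate_missing(tab, 0.08, seed = 32)
  hw <- estimate_p(md, K = 3, n_reps = 10, rate = 0.08, seed = 33,
                   adaptive = TRUE, min_pairs = 5)
  rmax_dup <- hw$r_max[1]      # ~ 1: duplicate variable present
  rmax_noise <- hw$r_max[12]   # small
  p_high <- phenoimpute:::p_for_variable(hw, 1)$p
  expect_gt(rmax_dup, 0.9)
  # where a perfect variable neighbour exists, weight leans to KNN-V
  expect_lte(p_high, 0.2)
})
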