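test_that("Spearman equals Pearson on midranks, including ties", {
  expect_equal(as.numeric(corr_spearman(1:4, c(2, 4, 6, 8))), 1)
  expect_equal(as.numeric(corr_spearman(1:4, c(8, 6, 4, 2))), -1)
  # sum d^2 = 4 in the classical formula: 1 - 6*4/(5*24) = 0.8
  expect_equal(as.numeric(corr_spearman(1:5, c(2, 1, 4, 3, 5))), 0.8)
  set.seed(42)
  for (rep in 1:10) {
    x <- sample(1:5, 9, replace = TRUE)  # plenty of ties
    y <- sample(1:4, 9, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(as.numeric(corr_spearman(x, y)), cor(rank(x), rank(y)))
  }
  expect_equal(as.numeric(corr_spearman(rep(1, 5), 1:5)), 0)
  expect_equal(attr(corr_spearman(rep(1, 5), 1:5), "flag"), "degenerate")
})

test_that("point biserial equals Pearson on the 0/1 coding", {
  expect_equal(as.numeric(corr_point_biserial(c(0, 0, 1, 1), c(0, 0, 1, 1))), 1)
  expect_equal(as.numeric(corr_point_biserial(c(1, 2, 1, 2), c(0, 0, 1, 1))), 0)
  expect_equal(as.numeric(corr_point_biserial(1:4, c(0, 0, 1, 1))), 2 / sqrt(5))
  set.seed(7)
  x <- rnorm(25); y <- rbinom(25, 1, 0.4)
  expect_equal(as.numeric(corr_point_biserial(x, y)), cor(x, y))
  # multi-class extension is the unsigned correlation ratio
  g <- rep(1:3, each = 5)
  xx <- rnorm(15) + g
  r <- corr_point_biserial(xx, g)
  fit <- anova(lm(xx ~ factor(g)))
  expect_equal(as.numeric(r), sqrt(fit$`Sum Sq`[1] / sum(fit$`Sum Sq`)))
  expect_gte(as.numeric(r), 0)
})

test_that("rank biserial is the point biserial on midranks", {
  expect_equal(as.numeric(corr_rank_biserial(c(1, 1, 3, 3), c(0, 0, 1, 1))), 1)
  expect_equal(as.numeric(corr_rank_biserial(c(1, 3, 1, 3), c(0, 0, 1, 1))), 0)
  expect_equal(as.numeric(corr_rank_biserial(1:4, c(0, 0, 1, 1))), 2 / sqrt(5))
  set.seed(8)
  x <- sample(1:4, 30, replace = TRUE)
  y <- rbinom(30, 1, 0.5)
  expect_equal(as.numeric(corr_rank_biserial(x, y)),
               as.numeric(corr_point_biserial(rank(x), y)))
})

test_that("phi is the signed sqrt(X^2/N) and equals Pearson on 0/1 codes", {
  tab_to_vec <- function(tab) {
    x <- rep(c(0, 0, 1, 1), times = as.vector(t(tab)))
    y <- rep(c(0, 1, 0, 1), times = as.vector(t(tab)))
    list(x = x, y = y)
  }
  v <- tab_to_vec(matrix(c(8, 2, 2, 8), 2, byrow = TRUE))
  r <- corr_phi(v$x, v$y)
  expect_equal(as.numeric(r), 0.6)
  x2 <- suppressWarnings(chisq.test(table(v$x, v$y), correct = FALSE)$statistic)
  expect_equal(abs(as.numeric(r)), sqrt(as.numeric(x2) / length(v$x)))
  v2 <- tab_to_vec(matrix(c(10, 0, 0, 10), 2, byrow = TRUE))
  expect_equal(abs(as.numeric(corr_phi(v2$x, v2$y))), 1)
  v3 <- tab_to_vec(matrix(c(5, 5, 5, 5), 2, byrow = TRUE))
  expect_equal(as.numeric(corr_phi(v3$x, v3$y)), 0)
  # anti-diagonal table gives a negative phi
  v4 <- tab_to_vec(matrix(c(2, 8, 8, 2), 2, byrow = TRUE))
  expect_equal(as.numeric(corr_phi(v4$x, v4$y)), -0.6)
})

test_that("Cramer's V reduces to |phi| for 2x2 and hits its extremes", {
  x <- rep(rep(1:3, each = 10), 1)
  expect_equal(as.numeric(corr_cramers_v(x, x)), 1)
  set.seed(1)
  xi <- rep(1:3, each = 9)
  yi <- rep(rep(1:3, times = 3), 3)  # exactly uniform joint
  expect_equal(as.numeric(corr_cramers_v(xi, yi)), 0)
  x2 <- rep(c(0, 0, 1, 1), times = c(8, 2, 2, 8))
  y2 <- rep(c(0, 1, 0, 1), times = c(8, 2, 2, 8))
  expect_equal(as.numeric(corr_cramers_v(x2, y2)), 0.6)
})

test_that("polyserial recovers the generating latent correlation", {
  set.seed(11)
  n <- 2000
  # independence
  r0 <- corr_polyserial(rnorm(n), sample(1:4, n, replace = TRUE))
  expect_lt(abs(as.numeric(r0)), 0.05)
  # rho = 0.7, 4 equal-probability levels
  z1 <- rnorm(n); z2 <- 0.7 * z1 + sqrt(1 - 0.49) * rnorm(n)
  y <- findInterval(z2, qnorm(c(0.25, 0.5, 0.75))) + 1L
  expect_lt(abs(as.numeric(corr_polyserial(z1, y)) - 0.7), 0.05)
  # degenerate: constant ordinal
  rc <- corr_polyserial(rnorm(20), rep(2, 20))
  expect_equal(as.numeric(rc), 0)
  expect_equal(attr(rc, "flag"), "degenerate")
})

test_that("polychoric recovers the generating latent correlation", {
  set.seed(12)
  n <- 2000
  cutv <- function(z, k) findInterval(z, qnorm(seq_len(k - 1) / k)) + 1L
  # identical discretization of one latent -> essentially 1
  z <- rnorm(500)
  y <- cutv(z, 3)
  expect_gte(as.numeric(corr_polychoric(y, y)), 0.99)
  # rho = 0.5, both margins 3 levels: mean estimate over 5 replicates
  est5 <- replicate(5, {
    z1 <- rnorm(n); z2 <- 0.5 * z1 + sqrt(0.75) * rnorm(n)
    as.numeric(corr_polychoric(cutv(z1, 3), cutv(z2, 3)))
  })
  expect_lt(abs(mean(est5) - 0.5), 0.07)
  # independence
  est0 <- replicate(5, {
    as.numeric(corr_polychoric(sample(1:3, n, TRUE), sample(1:4, n, TRUE)))
  })
  expect_lt(abs(mean(est0)), 0.05)
})

test_that("mixed_correlation dispatches by declared type pair", {
  set.seed(3)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  expect_equal(as.numeric(mixed_correlation(x, y, "continuous", "continuous")),
               as.numeric(corr_spearman(x, y)))
  o <- sample(1:4, 40, TRUE); b <- rbinom(40, 1, 0.5)
  expect_equal(as.numeric(mixed_correlation(o, b, "ordinal", "binary")),
               as.numeric(corr_rank_biserial(o, b)))
  k <- sample(1:3, 40, TRUE)
  expect_equal(as.numeric(mixed_correlation(b, k, "binary", "categorical")),
               as.numeric(corr_cramers_v(b, k)))
  # argument order does not matter
  expect_equal(as.numeric(mixed_correlation(k, b, "categorical", "binary")),
               as.numeric(mixed_correlation(b, k, "binary", "categorical")))
  # too few complete pairs
  x[3:40] <- NA
  r <- mixed_correlation(x, y, "continuous", "continuous", min_pairs = 10)
  expect_equal(as.numeric(r), 0)
  expect_equal(attr(r, "flag"), "insufficient_pairs")
})

test_that("the association matrix is symmetric, unit-diagonal and permutation-equivariant", {
  tab <- mixed_fixture(n = 50, seed = 5, miss = 0.1)
  a <- association_matrix(tab, min_pairs = 5)
  expect_equal(a$r, t(a$r))
  expect_equal(unname(diag(a$r)), rep(1, ncol(tab$data)))
  expect_true(all(abs(a$r) <= 1 + 1e-12))
  perm <- sample(nrow(tab$data))
  tab2 <- phenoimpute:::new_phenomic_table(tab$data[perm, ], tab$types, tab$levels)
  a2 <- association_matrix(tab2, min_pairs = 5)
  expect_equal(a2$r, a$r)
})
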