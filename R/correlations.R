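#' @title Mixed-type pairwise correlation measures
#'
#' @description
#' Association between two variables of possibly different types is measured
#' on a common, Pearson-comparable scale so that neighbours can be ranked
#' across types:
#'
#' | pair                  | measure                               |
#' |-----------------------|---------------------------------------|
#' | continuous/continuous | Spearman rank correlation             |
#' | continuous/ordinal    | polyserial (two-step ML)              |
#' | continuous/binary     | point biserial (= Pearson on 0/1)     |
#' | continuous/categorical| point-biserial extension (unsigned)   |
#' | ordinal/ordinal       | polychoric (two-step ML)              |
#' | ordinal/binary        | rank biserial (midranks, then 0/1)    |
#' | ordinal/categorical   | rank-biserial extension (unsigned)    |
#' | binary/binary         | phi (signed sqrt(X^2/N))              |
#' | binary or categorical/categorical | Cramer's V (unsigned)     |
#'
#' Degenerate inputs (constant vectors, single observed level, too few
#' complete pairs) return 0 with a `flag` attribute instead of failing, so a
#' full association matrix can always be assembled under general missingness.
#'
#' @name mixed-correlations
NULL

# scalar correlation with an optional degeneracy flag carried as an attribute
corr_result <- function(r, flag = NULL) {
  r <- as.numeric(r)
  if (!is.null(flag)) attr(r, "flag") <- flag
  r
}

corr_flag <- function(r) {
  f <- attr(r, "flag")
  if (is.null(f)) "" else f
}

complete_pairs <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  list(x = x[ok], y = y[ok], n = sum(ok))
}

#' Spearman rank correlation (continuous vs continuous)
#'
#' Pearson correlation of midranks; ties get midranks.
#'
#' @param x,y numeric vectors (pairwise-complete cases are used).
#' @return correlation in `[-1, 1]`; 0 with `flag = "degenerate"` when either
#'   vector is constant on the complete pairs.
#' @export
corr_spearman <- function(x, y) {
  cp <- complete_pairs(x, y)
  if (cp$n < 2 || length(unique(cp$x)) < 2 || length(unique(cp$y)) < 2) {
    return(corr_result(0, "degenerate"))
  }
  corr_result(stats::cor(rank(cp$x), rank(cp$y)))
}

# correlation ratio eta = sqrt(SS_between / SS_total): the unsigned
# multi-class generalization of the point-biserial correlation (for two
# groups eta equals |Pearson on 0/1|).
eta_assoc <- function(x, g) {
  xs <- split(x, g)
  xs <- xs[lengths(xs) > 0]
  if (length(xs) < 2) return(corr_result(0, "degenerate"))
  grand <- mean(x)
  sst <- sum((x - grand)^2)
  if (sst <= 0) return(corr_result(0, "degenerate"))
  ssb <- sum(vapply(xs, function(v) length(v) * (mean(v) - grand)^2, numeric(1)))
  corr_result(sqrt(max(ssb, 0) / sst))
}

#' Point biserial correlation and its multi-class extension
#'
#' For a binary grouping this is exactly the Pearson correlation of `x` with
#' the 0/1 coding (signed). For a multi-class grouping it is the unsigned
#' correlation ratio under the normal-conditional model.
#'
#' @param x numeric vector.
#' @param y group codes (0/1 for binary, `1..L` for multi-class).
#' @return correlation; flagged 0 on degeneracies.
#' @export
corr_point_biserial <- function(x, y) {
  cp <- complete_pairs(x, y)
  lv_all <- unique(y[!is.na(y)])
  lv <- unique(cp$y)
  dropped <- length(setdiff(lv_all, lv)) > 0
  if (cp$n < 2 || length(lv) < 2 || length(unique(cp$x)) < 2) {
    return(corr_result(0, "degenerate"))
  }
  if (length(lv) == 2) {
    y01 <- as.numeric(cp$y == max(lv))
    r <- stats::cor(cp$x, y01)
    # orient by the declared coding, not the observed max, for 0/1 input
    if (all(lv %in% c(0, 1))) r <- stats::cor(cp$x, cp$y)
    return(corr_result(r, if (dropped) "level_dropped" else NULL))
  }
  r <- eta_assoc(cp$x, cp$y)
  if (dropped) attr(r, "flag") <- paste(c(corr_flag(r), "level_dropped")[c(corr_flag(r) != "", TRUE)], collapse = "+")
  r
}

#' Rank biserial correlation and its multi-class extension
#'
#' The point biserial (or its extension) applied to the midranks of the
#' ordinal variable.
#'
#' @param x ordinal codes (`1..q`).
#' @param y group codes as in [corr_point_biserial()].
#' @return correlation; flagged 0 on degeneracies.
#' @export
corr_rank_biserial <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x2 <- x
  x2[ok] <- rank(x[ok])
  corr_point_biserial(x2, y)
}

#' Phi coefficient (binary vs binary)
#'
#' Equals the signed square root of `X^2/N` for the uncorrected chi-square of
#' the 2x2 table; the sign is that of the Pearson correlation of the 0/1
#' codings, so phi coincides with Pearson on 0/1 codes.
#'
#' @param x,y binary 0/1 codes.
#' @return correlation in `[-1, 1]`; flagged 0 when a margin is degenerate.
#' @export
corr_phi <- function(x, y) {
  cp <- complete_pairs(x, y)
  if (cp$n < 2 || length(unique(cp$x)) < 2 || length(unique(cp$y)) < 2) {
    return(corr_result(0, "degenerate"))
  }
  corr_result(stats::cor(cp$x, cp$y))
}

# uncorrected Pearson chi-square of a contingency table
chisq_stat <- function(tab) {
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (any(dim(tab) < 2)) return(NA_real_)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

#' Cramer's V (nominal vs nominal)
#'
#' `sqrt(X^2 / (N * (H - 1)))` with `H` the smaller table dimension and `X^2`
#' the uncorrected chi-square; unsigned, in `[0, 1]`.
#'
#' @param x,y nominal codes.
#' @return association in `[0, 1]`; flagged 0 when a margin is degenerate.
#' @export
corr_cramers_v <- function(x, y) {
  cp <- complete_pairs(x, y)
  if (cp$n < 2) return(corr_result(0, "degenerate"))
  tab <- table(cp$x, cp$y)
  x2 <- chisq_stat(tab)
  if (is.na(x2)) return(corr_result(0, "degenerate"))
  h <- min(sum(rowSums(tab) > 0), sum(colSums(tab) > 0))
  v <- sqrt(x2 / (cp$n * (h - 1)))
  corr_result(min(v, 1))
}

# 32-node Gauss-Legendre rule on [-1, 1], cached
.gl_cache <- new.env(parent = emptyenv())
gl_rule <- function(n = 32L) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]])) .gl_cache[[key]] <- pracma::gaussLegendre(n, -1, 1)
  .gl_cache[[key]]
}

# thresholds from marginal proportions (two-step approach)
marginal_thresholds <- function(counts) {
  p <- counts / sum(counts)
  stats::qnorm(cumsum(p)[-length(p)])
}

#' Polyserial correlation (continuous vs ordinal), two-step ML
#'
#' The ordinal variable is modelled as a thresholded latent standard normal
#' jointly bivariate-normal with the (standardized) continuous variable.
#' Thresholds are fixed from the marginal level frequencies via the inverse
#' normal CDF; the latent correlation is then estimated by 1-D maximum
#' likelihood (tolerance 1e-6, rho restricted to (-0.999, 0.999)).
#'
#' @param x numeric vector.
#' @param y ordinal codes `1..q`.
#' @return the ML estimate of the latent correlation; flagged 0 on
#'   degeneracies; Spearman on the integer codes (flag
#'   `"polyserial_fallback"`) if the likelihood is not finite.
#' @export
corr_polyserial <- function(x, y) {
  cp <- complete_pairs(x, y)
  lv <- sort(unique(cp$y))
  if (cp$n < 3 || length(lv) < 2 || stats::sd(cp$x) == 0) {
    return(corr_result(0, "degenerate"))
  }
  yy <- match(cp$y, lv)                      # consecutive 1..q on observed levels
  counts <- tabulate(yy, nbins = length(lv))
  tau <- marginal_thresholds(counts)
  z <- (cp$x - mean(cp$x)) / stats::sd(cp$x)
  hi <- c(tau, Inf)[yy]
  lo <- c(-Inf, tau)[yy]
  nll <- function(rho) {
    s <- sqrt(1 - rho^2)
    pr <- stats::pnorm((hi - rho * z) / s) - stats::pnorm((lo - rho * z) / s)
    -sum(log(pmax(pr, 1e-300)))
  }
  opt <- tryCatch(stats::optimize(nll, c(-0.999, 0.999), tol = 1e-6),
                  error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$objective)) {
    r <- corr_spearman(cp$x, cp$y)
    return(corr_result(as.numeric(r), "polyserial_fallback"))
  }
  corr_result(opt$minimum)
}

#' Polychoric correlation (ordinal vs ordinal), two-step ML
#'
#' Both ordinal margins are modelled as thresholded latent standard normals
#' with a bivariate-normal joint; thresholds come from the marginal level
#' frequencies, then the latent correlation maximizes the multinomial
#' likelihood of the contingency table. Bivariate-normal cell probabilities
#' are computed by Gauss-Legendre quadrature of the conditional normal CDF.
#'
#' @param x,y ordinal codes.
#' @return the ML estimate of the latent correlation; flagged 0 on
#'   degeneracies; Spearman fallback (flag `"polychoric_fallback"`) if the
#'   likelihood is not finite.
#' @export
corr_polychoric <- function(x, y) {
  cp <- complete_pairs(x, y)
  lx <- sort(unique(cp$x)); ly <- sort(unique(cp$y))
  if (cp$n < 3 || length(lx) < 2 || length(ly) < 2) {
    return(corr_result(0, "degenerate"))
  }
  xx <- match(cp$x, lx); yy <- match(cp$y, ly)
  qx <- length(lx); qy <- length(ly)
  tab <- table(factor(xx, levels = seq_len(qx)), factor(yy, levels = seq_len(qy)))
  taux <- marginal_thresholds(rowSums(tab))
  tauy <- marginal_thresholds(colSums(tab))
  # quadrature nodes over the x-side latent intervals (clipped to +/- 8 sd)
  gl <- gl_rule(32L)
  lox <- pmax(c(-Inf, taux), -8); hix <- pmin(c(taux, Inf), 8)
  mid <- (lox + hix) / 2; half <- (hix - lox) / 2
  z <- as.vector(vapply(seq_len(qx), function(j) mid[j] + half[j] * gl$x, numeric(length(gl$x))))
  w <- as.vector(vapply(seq_len(qx), function(j) half[j] * gl$w * stats::dnorm(mid[j] + half[j] * gl$x), numeric(length(gl$x))))
  grp <- rep(seq_len(qx), each = length(gl$x))
  tabm <- as.matrix(tab)
  nll <- function(rho) {
    s <- sqrt(1 - rho^2)
    cuts <- (matrix(tauy, nrow = length(z), ncol = qy - 1, byrow = TRUE) - rho * z) / s
    cum <- cbind(0, stats::pnorm(cuts), 1)
    cell <- cum[, -1, drop = FALSE] - cum[, -ncol(cum), drop = FALSE]  # nodes x qy
    prob <- rowsum(cell * w, grp)                                      # qx x qy
    -sum(tabm * log(pmax(prob, 1e-12)))
  }
  opt <- tryCatch(stats::optimize(nll, c(-0.999, 0.999), tol = 1e-6),
                  error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$objective)) {
    r <- corr_spearman(cp$x, cp$y)
    return(corr_result(as.numeric(r), "polychoric_fallback"))
  }
  corr_result(opt$minimum)
}

#' Type-dispatched mixed correlation
#'
#' Routes a pair of columns to the measure appropriate for their declared
#' types (see [mixed-correlations]) and enforces the minimum
#' pairwise-complete sample size.
#'
#' @param x,y coded columns (internal coding; see [phenomic_table()]).
#' @param type_x,type_y their variable types.
#' @param min_pairs minimum number of pairwise-complete observations; below
#'   it the pair is flagged `"insufficient_pairs"` and gets r = 0.
#' @return correlation with optional `flag` attribute.
#' @export
mixed_correlation <- function(x, y, type_x, type_y, min_pairs = 10) {
  n_ok <- sum(!is.na(x) & !is.na(y))
  if (n_ok < min_pairs) return(corr_result(0, "insufficient_pairs"))
  ty <- c(type_x, type_y)
  key <- paste(sort(ty), collapse = "/")
  # order the pair so that the first argument matches the measure's signature
  if (ty[1] != sort(ty)[1]) { tmp <- x; x <- y; y <- tmp }
  switch(key,
    "continuous/continuous" = corr_spearman(x, y),
    "continuous/ordinal"    = corr_polyserial(x, y),
    "binary/continuous"     = corr_point_biserial(y, x),
    "categorical/continuous" = corr_point_biserial(y, x),
    "ordinal/ordinal"       = corr_polychoric(x, y),
    "binary/ordinal"        = corr_rank_biserial(y, x),
    "categorical/ordinal"   = corr_rank_biserial(y, x),
    "binary/binary"         = corr_phi(x, y),
    "binary/categorical"    = corr_cramers_v(x, y),
    "categorical/categorical" = corr_cramers_v(x, y),
    stop("unknown type pair: ", key)
  )
}

#' Mixed-type association matrix of a phenomic table
#'
#' Computes all pairwise correlations of a table's variables with the
#' type-dispatched measures, on pairwise-complete observations.
#'
#' @param x a [phenomic_table].
#' @param min_pairs minimum pairwise-complete observations per pair (pairs
#'   below it get r = 0 and are ineligible as imputation neighbours).
#' @return an object of class `association_matrix`: list with `r` (P x P,
#'   diagonal 1), `n_pairs` (P x P counts) and `flags` (P x P character).
#' @export
association_matrix <- function(x, min_pairs = 10) {
  stopifnot(inherits(x, "phenomic_table"))
  z <- x$data
  p <- ncol(z)
  obs <- !is.na(z)
  npairs <- crossprod(obs)
  r <- diag(1, p)
  flags <- matrix("", p, p)
  for (j in seq_len(p - 1)) {
    for (k in (j + 1):p) {
      rr <- mixed_correlation(z[, j], z[, k], x$types[j], x$types[k], min_pairs)
      r[j, k] <- r[k, j] <- as.numeric(rr)
      flags[j, k] <- flags[k, j] <- corr_flag(rr)
    }
  }
  dimnames(r) <- dimnames(flags) <- list(colnames(z), colnames(z))
  dimnames(npairs) <- dimnames(r)
  structure(list(r = r, n_pairs = npairs, flags = flags, min_pairs = min_pairs),
            class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, ...) {
  p <- ncol(x$r)
  off <- x$r[upper.tri(x$r)]
  cat(sprintf("association_matrix: %d x %d; |r| median %.3f, max %.3f; %d flagged pairs\n",
              p, p, stats::median(abs(off)), max(abs(off)),
              sum(x$flags[upper.tri(x$flags)] != "")))
  invisible(x)
}
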