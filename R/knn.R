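#' Neighbour weights from correlations
#'
#' The weight given to the k-th nearest neighbour with correlation (or
#' similarity) `r_k` is `w_k = (r_k^2 / (1 - r_k^2 + eps))^2` with
#' `eps = 1e-6`, so near-perfect neighbours dominate the weighted average.
#'
#' @param r numeric vector of correlations/similarities, `|r| <= 1`.
#' @param eps stabilizer for `|r| = 1`.
#' @return nonnegative weights, same length as `r`.
#' @export
neighbor_weights <- function(r, eps = 1e-6) {
  stopifnot(all(abs(r) <= 1 + 1e-12))
  (r^2 / (1 - r^2 + eps))^2
}

# ---- small helpers ---------------------------------------------------------

# mode over positive-integer codes, ties broken by the lowest code
mode_lowest <- function(v, nbins) {
  counts <- tabulate(v, nbins = nbins)
  which.max(counts)
}

clip_round <- function(v, q) pmin(pmax(1, floor(v + 0.5)), q)

# marginal (column-wise) fallback value for variable j on the current table
marginal_value <- function(z, types, levels, j) {
  col <- z[, j][!is.na(z[, j])]
  if (!length(col)) stop("column '", colnames(z)[j], "' has no observed values")
  switch(types[j],
    continuous = mean(col),
    ordinal = clip_round(mean(col), length(levels[[j]])),
    binary = mode_lowest(col + 1, 2) - 1,
    categorical = mode_lowest(col, length(levels[[j]]))
  )
}

# weighted majority vote over discrete predictions; ties -> lowest code
weighted_vote <- function(preds, w) {
  cl <- sort(unique(preds))
  if (length(cl) == 1) return(cl)
  sc <- vapply(cl, function(cc) sum(w[preds == cc]), numeric(1))
  cl[which.max(sc)]
}

# aggregate per-neighbour predictions per the type rules: weighted average
# (continuous), rounded clipped weighted average (ordinal), weighted majority
# vote (binary/categorical)
aggregate_predictions <- function(type, preds, w, q) {
  if (type %in% c("binary", "categorical")) return(weighted_vote(preds, w))
  sw <- sum(w)
  v <- if (sw > 0) sum(w * preds) / sw else mean(preds)
  if (type == "ordinal") v <- clip_round(v, q)
  v
}

# ---- per-pair single-predictor GLM fits (KNN-V) ----------------------------

# bin a continuous predictor into at most 5 quantile bins for the
# contingency-table fallback
quantile_binner <- function(xx) {
  br <- unique(stats::quantile(xx, probs = seq(0, 1, by = 0.2), names = FALSE))
  if (length(br) < 2) br <- c(-Inf, Inf)
  function(v) findInterval(v, br, all.inside = TRUE)
}

# conditional mean (continuous target) or mode (ordinal/nominal target) of
# the target given the neighbour's value -- the Discussion's fallback when a
# GLM fit fails on sparse levels
contingency_fit <- function(yy, xx, target_type, discrete_x, q) {
  if (!discrete_x) {
    binner <- quantile_binner(xx)
    xb <- binner(xx)
  } else {
    binner <- identity
    xb <- xx
  }
  grp <- split(yy, xb)
  vals <- vapply(grp, function(g) {
    if (target_type == "continuous") mean(g)
    else if (target_type == "binary") mode_lowest(g + 1, 2) - 1
    else mode_lowest(g, q)
  }, numeric(1))
  keys <- names(grp)
  function(v) {
    out <- vals[match(as.character(binner(v)), keys)]
    unname(out)   # NA for unseen level -> caller falls back marginally
  }
}

# Fit the single-predictor model for target j / neighbour k on available
# cases and return list(pred = function(v) scalar-or-NA, flag = chr).
# Target-type link per the aggregation table: linear / ordinal logistic /
# logistic / multinomial logistic; fit failures fall back to the contingency
# table. Ordinal predictions are the expected level (the scalar feeding the
# rounded weighted average); binary/categorical predictions are classes.
fit_pair <- function(z, types, levels, j, k) {
  ok <- !is.na(z[, j]) & !is.na(z[, k])
  yy <- z[ok, j]
  xx <- z[ok, k]
  ttype <- types[j]
  discrete_x <- types[k] == "categorical"
  q <- if (ttype == "continuous") NA_integer_ else length(levels[[j]])

  if (length(yy) < 2 || length(unique(yy)) < 2) {
    val <- if (!length(yy)) NA_real_ else if (ttype == "continuous") mean(yy) else yy[1]
    return(list(pred = function(v) val, flag = "constant_fit"))
  }

  if (ttype == "continuous") {
    if (discrete_x) {
      return(list(pred = contingency_fit(yy, xx, ttype, TRUE, q), flag = ""))
    }
    vx <- stats::var(xx)
    if (vx <= 0) {
      m <- mean(yy)
      return(list(pred = function(v) m, flag = "constant_fit"))
    }
    b <- stats::cov(xx, yy) / vx
    a <- mean(yy) - b * mean(xx)
    return(list(pred = function(v) a + b * v, flag = ""))
  }

  if (ttype == "binary") {
    if (discrete_x) {
      p1 <- vapply(split(yy, xx), mean, numeric(1))
      keys <- names(p1)
      return(list(pred = function(v) {
        p <- p1[match(as.character(v), keys)]
        if (is.na(p)) NA_real_ else as.numeric(p > 0.5)
      }, flag = ""))
    }
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(cbind(1, xx), yy, family = stats::binomial())),
      error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) {
      return(list(pred = contingency_fit(yy, xx, ttype, FALSE, q),
                  flag = "contingency_fallback"))
    }
    cf <- fit$coefficients
    return(list(pred = function(v) as.numeric(stats::plogis(cf[1] + cf[2] * v) > 0.5),
                flag = ""))
  }

  if (ttype == "ordinal") {
    lvs <- sort(unique(yy))
    dd <- data.frame(yv = factor(yy, levels = lvs, ordered = TRUE),
                     xv = if (discrete_x) factor(xx, levels = sort(unique(xx))) else xx)
    fit <- tryCatch(
      suppressWarnings(MASS::polr(yv ~ xv, data = dd, method = "logistic", Hess = FALSE)),
      error = function(e) NULL)
    if (!is.null(fit) && !discrete_x &&
        (!("xv" %in% names(fit$coefficients)) || anyNA(fit$coefficients))) {
      fit <- NULL  # degenerate predictor dropped from the fit
    }
    if (!is.null(fit)) {
      if (discrete_x) {
        xl <- levels(dd$xv)
        nd <- data.frame(xv = factor(xl, levels = xl))
        pr <- stats::predict(fit, newdata = nd, type = "probs")
        if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1)
        ev <- as.numeric(pr %*% lvs)
        return(list(pred = function(v) ev[match(as.character(v), xl)], flag = ""))
      }
      b <- fit$coefficients[["xv"]]
      zeta <- fit$zeta
      return(list(pred = function(v) {
        cum <- stats::plogis(zeta - b * v)
        sum(lvs * diff(c(0, cum, 1)))
      }, flag = ""))
    }
    # multinomial fallback, then contingency
    mfit <- tryCatch(
      suppressWarnings(nnet::multinom(yv ~ xv, data = dd, trace = FALSE)),
      error = function(e) NULL)
    if (!is.null(mfit)) {
      if (discrete_x) {
        xl <- levels(dd$xv)
        nd <- data.frame(xv = factor(xl, levels = xl))
        pr <- stats::predict(mfit, newdata = nd, type = "probs")
        if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)
        ev <- as.numeric(pr %*% lvs)
        return(list(pred = function(v) ev[match(as.character(v), xl)],
                    flag = "multinom_fallback"))
      }
      B <- stats::coef(mfit)
      if (is.null(dim(B))) B <- matrix(B, nrow = 1)
      return(list(pred = function(v) {
        eta <- c(0, B %*% c(1, v))
        p <- exp(eta - max(eta)); p <- p / sum(p)
        sum(lvs * p)
      }, flag = "multinom_fallback"))
    }
    return(list(pred = contingency_fit(yy, xx, ttype, discrete_x, q),
                flag = "contingency_fallback"))
  }

  # categorical target
  lvs <- sort(unique(yy))
  sparse <- q > 10 || min(tabulate(match(yy, lvs))) < 2
  if (discrete_x || sparse) {
    # with a discrete predictor the saturated multinomial logistic reduces to
    # the conditional mode of the contingency table; sparse targets go there
    # directly for stability
    return(list(pred = contingency_fit(yy, xx, ttype, discrete_x, q),
                flag = if (sparse && !discrete_x) "contingency_fallback" else ""))
  }
  dd <- data.frame(yv = factor(yy, levels = lvs), xv = xx)
  mfit <- tryCatch(
    suppressWarnings(nnet::multinom(yv ~ xv, data = dd, trace = FALSE)),
    error = function(e) NULL)
  if (is.null(mfit)) {
    return(list(pred = contingency_fit(yy, xx, ttype, FALSE, q),
                flag = "contingency_fallback"))
  }
  B <- stats::coef(mfit)
  if (is.null(dim(B))) B <- matrix(B, nrow = 1)
  list(pred = function(v) {
    eta <- c(0, B %*% c(1, v))
    lvs[which.max(eta)]   # argmax of softmax = argmax of eta; first tie = lowest
  }, flag = "")
}

# ---- KNN-V -----------------------------------------------------------------

# Impute the given missing cells by the K nearest variables. Neighbour
# variables must be observed at the cell's subject, share >= min_pairs
# complete observations with the target and not be flagged degenerate;
# ranking is by d = |1 - r|. Returns list(values, prov).
knn_v_engine <- function(x, assoc, cells, K = 5) {
  z <- x$data
  types <- x$types
  p <- ncol(z)
  d <- abs(1 - assoc$r)
  diag(d) <- Inf
  bad_flag <- matrix(grepl("degenerate|insufficient", assoc$flags), p, p)
  eligible <- assoc$n_pairs >= assoc$min_pairs & !bad_flag
  diag(eligible) <- FALSE
  cand_order <- lapply(seq_len(p), function(j) {
    ks <- which(eligible[j, ])
    ks[order(d[j, ks])]
  })
  fits <- new.env(parent = emptyenv())
  nc <- nrow(cells)
  values <- numeric(nc)
  n_used <- integer(nc)
  fallback <- character(nc)
  for (ci in seq_len(nc)) {
    i <- cells[ci, 1]; j <- cells[ci, 2]
    cand <- cand_order[[j]]
    cand <- cand[!is.na(z[i, cand])]
    sel <- cand[seq_len(min(K, length(cand)))]
    if (!length(sel)) {
      values[ci] <- marginal_value(z, types, x$levels, j)
      n_used[ci] <- 0L
      fallback[ci] <- "marginal_fallback"
      next
    }
    preds <- numeric(0); wts <- numeric(0); flags <- character(0)
    for (k in sel) {
      key <- paste0(j, ":", k)
      f <- fits[[key]]
      if (is.null(f)) {
        f <- fit_pair(z, types, x$levels, j, k)
        fits[[key]] <- f
      }
      val <- f$pred(z[i, k])
      if (is.na(val)) {
        flags <- c(flags, "unseen_level")
        next
      }
      preds <- c(preds, val)
      wts <- c(wts, neighbor_weights(assoc$r[j, k]))
      if (nzchar(f$flag)) flags <- c(flags, f$flag)
    }
    if (!length(preds)) {
      values[ci] <- marginal_value(z, types, x$levels, j)
      n_used[ci] <- 0L
      fallback[ci] <- "marginal_fallback"
      next
    }
    values[ci] <- aggregate_predictions(types[j], preds, wts, n_levels(x, j))
    n_used[ci] <- length(preds)
    fallback[ci] <- paste(unique(flags), collapse = "+")
  }
  list(values = values, n_neighbors = n_used, fallback = fallback)
}

# ---- KNN-S -----------------------------------------------------------------

# Impute the given missing cells by the K nearest subjects under Gower
# distance; similarity r = 1 - d feeds the same weight formula, and the
# neighbours' raw values of the target variable are aggregated by the type
# rules.
knn_s_engine <- function(x, gd, cells, K = 5) {
  z <- x$data
  types <- x$types
  nc <- nrow(cells)
  values <- numeric(nc)
  n_used <- integer(nc)
  fallback <- character(nc)
  obs <- !is.na(z)
  for (ci in seq_len(nc)) {
    i <- cells[ci, 1]; j <- cells[ci, 2]
    cand <- which(obs[, j])
    cand <- cand[cand != i]
    if (!length(cand)) {
      values[ci] <- marginal_value(z, types, x$levels, j)
      n_used[ci] <- 0L
      fallback[ci] <- "marginal_fallback"
      next
    }
    dv <- gd$d[i, cand]
    sel <- cand[order(dv)][seq_len(min(K, length(cand)))]
    r <- 1 - gd$d[i, sel]
    w <- neighbor_weights(r)
    flags <- character(0)
    if (any(gd$incomparable[i, sel])) flags <- "incomparable_neighbor"
    values[ci] <- aggregate_predictions(types[j], z[sel, j], w, n_levels(x, j))
    n_used[ci] <- length(sel)
    fallback[ci] <- paste(flags, collapse = "+")
  }
  list(values = values, n_neighbors = n_used, fallback = fallback)
}
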