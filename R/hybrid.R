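#' Closed-form hybrid weight from paired second-layer errors
#'
#' Given per-cell normalized errors of the subject-based (`e_s`) and
#' variable-based (`e_v`) imputers on the same hidden cells, the weight of
#' the convex combination `p * KNN-S + (1 - p) * KNN-V` that minimizes the
#' total squared error `sum(p*e_s + (1-p)*e_v)^2` is
#' `p = (sum e_v^2 - sum e_s e_v) / (sum e_s^2 - 2 sum e_s e_v + sum e_v^2)`,
#' clipped to `[0, 1]` -- so a perfect subject-based imputer (`e_s = 0`)
#' gets full weight.
#'
#' @param e_s,e_v numeric vectors of paired errors.
#' @return `p` in `[0, 1]`; 0.5 with `flag = "degenerate"` when the
#'   denominator vanishes.
#' @export
p_closed_form <- function(e_s, e_v) {
  stopifnot(length(e_s) == length(e_v))
  den <- sum(e_s^2) - 2 * sum(e_s * e_v) + sum(e_v^2)
  if (!is.finite(den) || abs(den) < 1e-12) {
    return(structure(0.5, flag = "degenerate"))
  }
  min(max((sum(e_v^2) - sum(e_s * e_v)) / den, 0), 1)
}

# signed normalized per-cell error: continuous scaled by the column sd,
# ordinal by (q - 1); nominal cells contribute a 0/1 misclassification
# indicator
normalized_errors <- function(pred, truth, jidx, types, sds, qs) {
  ty <- types[jidx]
  e <- numeric(length(pred))
  con <- ty == "continuous"
  e[con] <- ifelse(sds[jidx[con]] > 0, (pred[con] - truth[con]) / sds[jidx[con]], 0)
  ord <- ty == "ordinal"
  e[ord] <- (pred[ord] - truth[ord]) / (qs[jidx[ord]] - 1)
  nom <- ty %in% c("binary", "categorical")
  e[nom] <- as.numeric(pred[nom] != truth[nom])
  e
}

#' Estimate the hybrid weight p by second-layer simulation
#'
#' Repeatedly hides a small extra fraction of the observed cells (a "second
#' layer" of missingness), imputes the hidden cells with both KNN-S and
#' KNN-V, and derives the weight of the convex combination from the paired
#' normalized errors via [p_closed_form()]. The global estimate is the mean
#' of the per-repetition weights. With `adaptive = TRUE` the paired errors
#' are additionally pooled across repetitions and a weight is estimated in
#' each sliding window `(r_max - 0.1, r_max + 0.1)` over a 0.01-step grid of
#' `r_max` (the correlation between a cell's variable and its closest
#' neighbour variable); windows with fewer than 10 error pairs inherit the
#' global weight.
#'
#' @param x a [phenomic_table] with missing values.
#' @param K number of neighbours.
#' @param n_reps number of second-layer repetitions (default 20).
#' @param rate fraction of observed cells hidden per repetition (default 5%).
#' @param seed RNG seed for the second layers.
#' @param adaptive also estimate the per-window weights used by KNN-A.
#' @param min_pairs minimum pairwise-complete observations for a neighbour
#'   pair.
#' @param assoc,gd optional precomputed [association_matrix()] and
#'   [gower_distance_matrix()] of `x` (computed once here otherwise; the
#'   second-layer runs reuse them, with Gower distances updated
#'   incrementally for the hidden cells).
#' @return an object of class `hybrid_weight`: `p_global`, per-repetition
#'   `p_reps`, and for adaptive estimates `grid`, `p_window`, `n_window`,
#'   plus the per-variable `r_max`.
#' @export
estimate_p <- function(x, K = 5, n_reps = 20, rate = 0.05, seed = NULL,
                       adaptive = FALSE, min_pairs = 10,
                       assoc = NULL, gd = NULL) {
  stopifnot(inherits(x, "phenomic_table"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(assoc)) assoc <- association_matrix(x, min_pairs)
  if (is.null(gd)) gd <- gower_distance_matrix(x)
  z <- x$data
  obs_idx <- which(!is.na(z))
  n_hide <- round(rate * length(obs_idx))
  if (n_hide < 1) stop("rate too small: no observed cell would be hidden")
  if (n_hide >= length(obs_idx)) stop("rate too large: no observed cells would remain")
  sds <- apply(z, 2, stats::sd, na.rm = TRUE)
  qs <- vapply(seq_len(ncol(z)), function(j) {
    if (x$types[j] == "continuous") NA_integer_ else length(x$levels[[j]])
  }, integer(1))
  r_max <- variable_r_max(assoc)

  p_reps <- numeric(n_reps)
  rep_flags <- character(n_reps)
  pool_s <- pool_v <- pool_j <- vector("list", n_reps)
  for (rep in seq_len(n_reps)) {
    hid <- sample(obs_idx, n_hide)
    cells <- arrayInd(hid, dim(z))
    x2 <- mask_cells(x, cells)
    gd2 <- gower_remove_cells(gd, x, cells)
    rv <- knn_v_engine(x2, assoc, cells, K)
    rs <- knn_s_engine(x2, gd2, cells, K)
    truth <- z[hid]
    e_v <- normalized_errors(rv$values, truth, cells[, 2], x$types, sds, qs)
    e_s <- normalized_errors(rs$values, truth, cells[, 2], x$types, sds, qs)
    ph <- p_closed_form(e_s, e_v)
    p_reps[rep] <- as.numeric(ph)
    rep_flags[rep] <- if (is.null(attr(ph, "flag"))) "" else attr(ph, "flag")
    pool_s[[rep]] <- e_s; pool_v[[rep]] <- e_v; pool_j[[rep]] <- cells[, 2]
  }
  p_global <- mean(p_reps)

  grid <- p_window <- n_window <- NULL
  window_flags <- NULL
  if (adaptive) {
    e_s <- unlist(pool_s); e_v <- unlist(pool_v)
    rmax_cell <- r_max[unlist(pool_j)]
    keep <- !is.na(rmax_cell)
    e_s <- e_s[keep]; e_v <- e_v[keep]; rmax_cell <- rmax_cell[keep]
    if (length(rmax_cell)) {
      grid <- seq(round(min(rmax_cell), 2), round(max(rmax_cell), 2), by = 0.01)
      p_window <- n_window <- numeric(length(grid))
      window_flags <- character(length(grid))
      for (g in seq_along(grid)) {
        idx <- rmax_cell > grid[g] - 0.1 & rmax_cell < grid[g] + 0.1
        n_window[g] <- sum(idx)
        if (n_window[g] >= 10) {
          pw <- p_closed_form(e_s[idx], e_v[idx])
          p_window[g] <- as.numeric(pw)
          window_flags[g] <- if (is.null(attr(pw, "flag"))) "" else attr(pw, "flag")
        } else {
          p_window[g] <- p_global
          window_flags[g] <- "too_few_observations"
        }
      }
    }
  }
  structure(list(p_global = p_global, p_reps = p_reps, rep_flags = rep_flags,
                 grid = grid, p_window = p_window, n_window = n_window,
                 window_flags = window_flags, r_max = r_max,
                 n_reps = n_reps, rate = rate, adaptive = adaptive, K = K),
            class = "hybrid_weight")
}

# r_max per variable: the correlation with its closest eligible neighbour
# (closest under d = |1 - r|, i.e. the maximal r)
variable_r_max <- function(assoc) {
  p <- ncol(assoc$r)
  bad <- matrix(grepl("degenerate|insufficient", assoc$flags), p, p)
  eligible <- assoc$n_pairs >= assoc$min_pairs & !bad
  diag(eligible) <- FALSE
  vapply(seq_len(p), function(j) {
    ks <- which(eligible[j, ])
    if (!length(ks)) NA_real_ else max(assoc$r[j, ks])
  }, numeric(1))
}

# the weight applied to a cell of variable j
p_for_variable <- function(hw, j) {
  if (!inherits(hw, "hybrid_weight")) return(list(p = as.numeric(hw), flag = ""))
  if (!hw$adaptive || is.null(hw$grid)) return(list(p = hw$p_global, flag = ""))
  rm <- hw$r_max[j]
  if (is.na(rm)) return(list(p = hw$p_global, flag = "no_r_max"))
  g <- which.min(abs(hw$grid - rm))
  flag <- if (hw$window_flags[g] == "too_few_observations") "window_fallback" else ""
  list(p = hw$p_window[g], flag = flag)
}

# convex combination of the two methods' imputed values for one cell
combine_hybrid <- function(type, v_s, v_v, p, q) {
  if (type %in% c("binary", "categorical")) {
    if (p > 0.5) return(v_s)
    if (p < 0.5) return(v_v)
    return(min(v_s, v_v))
  }
  v <- p * v_s + (1 - p) * v_v
  if (type == "ordinal") v <- clip_round(v, q)
  v
}

#' @export
print.hybrid_weight <- function(x, ...) {
  cat(sprintf("hybrid_weight: p_global = %.3f (from %d second-layer repetitions at %.0f%% rate)\n",
              x$p_global, x$n_reps, 100 * x$rate))
  if (x$adaptive && !is.null(x$grid)) {
    est <- x$window_flags != "too_few_observations"
    cat(sprintf("  adaptive: %d r_max windows on [%.2f, %.2f], %d estimated (rest inherit p_global)\n",
                length(x$grid), min(x$grid), max(x$grid), sum(est)))
  }
  invisible(x)
}
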