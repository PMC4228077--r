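#' Variable distance matrix
#'
#' Distance between variables is `d = |1 - r|` for the mixed-type correlation
#' `r`, so perfectly correlated variables are at distance 0 and (note)
#' strongly anti-correlated variables rank as *far* neighbours. Set
#' `rank_by_abs = TRUE` to rank neighbours by `1 - |r|` instead (non-default).
#'
#' @param x a [phenomic_table] or an [association_matrix()].
#' @param min_pairs passed to [association_matrix()] when `x` is a table.
#' @param rank_by_abs use `1 - |r|` instead of `|1 - r|`.
#' @return P x P numeric distance matrix, diagonal 0.
#' @export
variable_distance_matrix <- function(x, min_pairs = 10, rank_by_abs = FALSE) {
  assoc <- if (inherits(x, "association_matrix")) x else association_matrix(x, min_pairs)
  d <- if (rank_by_abs) 1 - abs(assoc$r) else abs(1 - assoc$r)
  diag(d) <- 0
  d
}

#' Gower distance matrix between subjects
#'
#' The distance between two subjects is the average per-variable
#' dissimilarity over variables observed in both: 0/1 match/mismatch for
#' binary and categorical variables, and the absolute difference divided by
#' the variable's total observed range for continuous and ordinal variables
#' (ordinal on its integer codes). Pairs sharing no observed variable get
#' distance 1 and are flagged incomparable.
#'
#' @param x a [phenomic_table].
#' @param ranges optional per-variable ranges to scale numeric
#'   dissimilarities by (defaults to the observed ranges; used to keep the
#'   scaling of second-layer updates consistent with the first-layer table).
#' @return an object of class `subject_distance`: list with `d` (N x N in
#'   `[0,1]`, diagonal 0), `incomparable` (logical N x N) and internal sums
#'   used for incremental masking updates.
#' @export
gower_distance_matrix <- function(x, ranges = NULL) {
  stopifnot(inherits(x, "phenomic_table"))
  z <- x$data
  n <- nrow(z)
  s <- matrix(0, n, n)
  cnt <- matrix(0, n, n)
  numericish <- x$types %in% c("continuous", "ordinal")
  if (is.null(ranges)) ranges <- rep(NA_real_, ncol(z))
  for (v in seq_len(ncol(z))) {
    col <- z[, v]
    if (all(is.na(col))) next
    if (numericish[v]) {
      rng <- if (is.na(ranges[v])) diff(range(col, na.rm = TRUE)) else ranges[v]
      ranges[v] <- rng
      contrib <- if (rng > 0) abs(outer(col, col, "-")) / rng else outer(col, col, function(a, b) (a - b) * 0)
    } else {
      contrib <- 1 * outer(col, col, "!=")
    }
    ok <- !is.na(contrib)
    contrib[!ok] <- 0
    s <- s + contrib
    cnt <- cnt + ok
  }
  d <- ifelse(cnt > 0, s / cnt, 1)
  incomparable <- cnt == 0
  diag(d) <- 0
  diag(incomparable) <- FALSE
  dimnames(d) <- list(rownames(z), rownames(z))
  structure(list(d = d, sums = s, counts = cnt, ranges = ranges,
                 incomparable = incomparable),
            class = "subject_distance")
}

# Remove the contribution of newly-hidden cells from a Gower object without
# recomputing the full N x N x P sweep. `cells` is a 2-column (i, j) index
# matrix of cells that are observed in `x` and become missing.
gower_remove_cells <- function(gd, x, cells) {
  z <- x$data
  obs <- !is.na(z)
  s <- gd$sums; cnt <- gd$counts
  numericish <- x$types %in% c("continuous", "ordinal")
  for (row in seq_len(nrow(cells))) {
    i <- cells[row, 1]; j <- cells[row, 2]
    if (!obs[i, j]) next
    others <- which(obs[, j])
    others <- others[others != i]
    if (length(others)) {
      if (numericish[j]) {
        rng <- gd$ranges[j]
        contrib <- if (rng > 0) abs(z[i, j] - z[others, j]) / rng else rep(0, length(others))
      } else {
        contrib <- 1 * (z[others, j] != z[i, j])
      }
      s[i, others] <- s[i, others] - contrib
      s[others, i] <- s[others, i] - contrib
      cnt[i, others] <- cnt[i, others] - 1
      cnt[others, i] <- cnt[others, i] - 1
    }
    cnt[i, i] <- cnt[i, i] - 1
    obs[i, j] <- FALSE
  }
  s[s < 0] <- 0  # guard against floating-point drift
  d <- ifelse(cnt > 0, s / cnt, 1)
  incomparable <- cnt == 0
  diag(d) <- 0
  diag(incomparable) <- FALSE
  structure(list(d = d, sums = s, counts = cnt, ranges = gd$ranges,
                 incomparable = incomparable),
            class = "subject_distance")
}

#' @export
print.subject_distance <- function(x, ...) {
  off <- x$d[upper.tri(x$d)]
  cat(sprintf("subject_distance (Gower): %d subjects; median %.3f, range [%.3f, %.3f]; %d incomparable pairs\n",
              nrow(x$d), stats::median(off), min(off), max(off),
              sum(x$incomparable[upper.tri(x$incomparable)])))
  invisible(x)
}
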