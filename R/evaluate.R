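#' Generate MCAR missing values
#'
#' Hides exactly `round(m * #observed)` observed cells, drawn uniformly at
#' random (missing completely at random). Applied to an already-incomplete
#' table it produces a second layer of missingness: original missing cells
#' are never re-drawn, so the two layers are disjoint.
#'
#' @param x a [phenomic_table] (complete or not).
#' @param m fraction of observed cells to hide, in (0, 1).
#' @param seed RNG seed.
#' @return a [phenomic_table] with the extra cells missing.
#' @export
generate_missing <- function(x, m, seed = NULL) {
  stopifnot(inherits(x, "phenomic_table"))
  if (!is.numeric(m) || length(m) != 1 || m <= 0 || m >= 1) {
    stop("m must be a fraction in (0, 1)")
  }
  if (!is.null(seed)) set.seed(seed)
  obs <- which(!is.na(x$data))
  n_hide <- round(m * length(obs))
  if (n_hide < 1) stop("m too small: no cell would be hidden")
  hid <- sample(obs, n_hide)
  mask_cells(x, arrayInd(hid, dim(x$data)))
}

#' Cells missing in one table but observed in another
#'
#' @param md the table with (more) missing values.
#' @param reference the table the missingness was generated from.
#' @return logical N x P mask of the newly-missing layer.
#' @export
missing_layer <- function(md, reference) {
  is.na(md$data) & !is.na(reference$data)
}

#' Evaluate an imputation against known truth
#'
#' Per-cell normalized squared errors: `(yhat - y)^2 / var(y_j)` for
#' continuous cells (`var` from the truth's observed values, denominator
#' n - 1), `((yhat - y) / (q - 1))^2` for ordinal cells with `q` levels, and
#' a 0/1 misclassification indicator for nominal (binary or categorical)
#' cells. Aggregates are `RMSE = sqrt(mean(e^2))` for continuous and ordinal
#' and `PFC = mean(e)` for nominal.
#'
#' @param imputed a `phenomic_imputation` or completed [phenomic_table].
#' @param truth the complete reference table.
#' @param eval_mask logical N x P mask (or 2-column index matrix) of the
#'   cells to score; defaults to all cells observed in `truth`.
#' @return an object of class `imputation_eval` with fields
#'   `rmse_continuous`, `rmse_ordinal`, `pfc_nominal`, per-cell errors
#'   (`cells`), counts `n_cells` and `flags`.
#' @export
evaluate_imputation <- function(imputed, truth, eval_mask = NULL) {
  tab <- if (inherits(imputed, "phenomic_imputation")) imputed$table else imputed
  stopifnot(inherits(tab, "phenomic_table"), inherits(truth, "phenomic_table"))
  zi <- tab$data; zt <- truth$data
  stopifnot(all(dim(zi) == dim(zt)))
  if (is.null(eval_mask)) {
    cells <- which(!is.na(zt), arr.ind = TRUE)
  } else if (is.logical(eval_mask)) {
    cells <- which(eval_mask, arr.ind = TRUE)
  } else {
    cells <- eval_mask
  }
  dimnames(cells) <- NULL
  lin <- cells[, 1] + (cells[, 2] - 1) * nrow(zt)
  if (anyNA(zt[lin])) stop("truth is missing on some evaluated cells")
  if (anyNA(zi[lin])) stop("imputation left some evaluated cells missing")
  types <- truth$types
  vars <- apply(zt, 2, stats::var, na.rm = TRUE)
  qs <- vapply(seq_along(types), function(j) {
    if (types[j] == "continuous") NA_integer_ else length(truth$levels[[j]])
  }, integer(1))
  jidx <- cells[, 2]
  ty <- types[jidx]
  pred <- zi[lin]; yy <- zt[lin]
  e2 <- numeric(length(lin))
  flags <- character(0)
  keep <- rep(TRUE, length(lin))
  con <- ty == "continuous"
  zero_var <- con & (is.na(vars[jidx]) | vars[jidx] <= 0)
  if (any(zero_var)) {
    keep[zero_var] <- FALSE
    flags <- "zero_variance_excluded"
  }
  cc <- con & keep
  e2[cc] <- (pred[cc] - yy[cc])^2 / vars[jidx[cc]]
  ord <- ty == "ordinal"
  e2[ord] <- ((pred[ord] - yy[ord]) / (qs[jidx[ord]] - 1))^2
  nom <- ty %in% c("binary", "categorical")
  e2[nom] <- as.numeric(pred[nom] != yy[nom])
  cells_df <- data.frame(i = cells[, 1], j = jidx, type = ty, e2 = e2,
                         excluded = !keep, stringsAsFactors = FALSE)
  rmse_con <- if (any(cc)) sqrt(mean(e2[cc])) else NA_real_
  rmse_ord <- if (any(ord)) sqrt(mean(e2[ord])) else NA_real_
  pfc_nom <- if (any(nom)) mean(e2[nom]) else NA_real_
  structure(list(rmse_continuous = rmse_con, rmse_ordinal = rmse_ord,
                 pfc_nominal = pfc_nom,
                 n_cells = c(continuous = sum(cc), ordinal = sum(ord), nominal = sum(nom)),
                 cells = cells_df, flags = flags),
            class = "imputation_eval")
}

#' @export
print.imputation_eval <- function(x, ...) {
  cat("imputation_eval:\n")
  cat(sprintf("  continuous RMSE: %s  (n = %d)\n",
              fmt_or_na(x$rmse_continuous), x$n_cells[["continuous"]]))
  cat(sprintf("  ordinal    RMSE: %s  (n = %d)\n",
              fmt_or_na(x$rmse_ordinal), x$n_cells[["ordinal"]]))
  cat(sprintf("  nominal    PFC : %s  (n = %d)\n",
              fmt_or_na(x$pfc_nominal), x$n_cells[["nominal"]]))
  invisible(x)
}

fmt_or_na <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)

#' Compare imputation methods over repeated MCAR draws
#'
#' For each repetition one missing-data realization is generated from the
#' complete table and *every* method is run on that same realization (a
#' paired design: within a repetition, differences are attributable to the
#' method alone). Errors are scored on the hidden cells.
#'
#' @param cd the complete [phenomic_table].
#' @param methods character vector of method names (built-ins or registered)
#'   or a named list of imputer functions `(x, seed) -> imputation`.
#' @param m missing rate per repetition.
#' @param reps number of repetitions (default 20).
#' @param seed master seed; per-repetition seeds are drawn from it.
#' @param K,n_reps,rate,min_pairs settings forwarded to built-in methods.
#' @return an object of class `method_comparison`: long data frame `results`
#'   (method x repetition x metric) plus a mean summary.
#' @export
compare_methods <- function(cd, methods, m, reps = 20, seed = NULL,
                            K = 5, n_reps = 20, rate = 0.05, min_pairs = 10) {
  stopifnot(inherits(cd, "phenomic_table"))
  fns <- resolve_imputers(methods, K = K, n_reps = n_reps, rate = rate,
                          min_pairs = min_pairs)
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1, reps)
  rows <- list()
  for (r in seq_len(reps)) {
    md <- generate_missing(cd, m, seed = rep_seeds[r])
    layer <- missing_layer(md, cd)
    for (nm in names(fns)) {
      ev <- tryCatch({
        res <- fns[[nm]](md, seed = rep_seeds[r])
        evaluate_imputation(res, cd, layer)
      }, error = function(e) NULL)
      rows[[length(rows) + 1]] <- if (is.null(ev)) {
        data.frame(method = nm, rep = r, rmse_continuous = NA_real_,
                   rmse_ordinal = NA_real_, pfc_nominal = NA_real_,
                   failed = TRUE, stringsAsFactors = FALSE)
      } else {
        data.frame(method = nm, rep = r, rmse_continuous = ev$rmse_continuous,
                   rmse_ordinal = ev$rmse_ordinal, pfc_nominal = ev$pfc_nominal,
                   failed = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)
  means <- stats::aggregate(results[c("rmse_continuous", "rmse_ordinal", "pfc_nominal")],
                            by = list(method = results$method), FUN = mean, na.rm = TRUE)
  structure(list(results = results, means = means, m = m, reps = reps),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("method_comparison: %d repetitions at %.0f%% missingness\n",
              x$reps, 100 * x$m))
  print(x$means, row.names = FALSE)
  invisible(x)
}
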