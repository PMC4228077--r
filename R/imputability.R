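#' Imputability measure (IM)
#'
#' Quantifies how reliably each subject's and each variable's missing cells
#' can be imputed, without ground truth: a second layer of missing values is
#' hidden among the observed cells, imputed, and scored; the procedure is
#' repeated `t` times. `E_i` is the average over repetitions of the RMSE of
#' subject i's hidden cells under the subject-based imputer (KNN-S) and
#' `E_j` the analogue for variable j under the variable-based imputer
#' (KNN-V); then `IMs_i = exp(-E_i)`, `IMv_j = exp(-E_j)`, both in (0, 1],
#' and the IM of a missing cell (i, j) is `max(IMs_i, IMv_j)`. Low IM flags
#' cells that cannot be imputed reliably from either direction.
#'
#' Subjects or variables never hit by a second layer get their `E` from the
#' pooled errors of all repetitions and are flagged `"unsampled"`.
#'
#' @param md a [phenomic_table] with missing values.
#' @param t number of second-layer repetitions (10 is usually sufficient).
#' @param rate fraction of observed cells hidden per repetition.
#' @param seed RNG seed.
#' @param K neighbours per imputation.
#' @param min_pairs eligibility threshold for variable neighbours.
#' @param method `"knn-vs"` (default): subject side scored by KNN-S,
#'   variable side by KNN-V, per the measure's definition. `"selected"`:
#'   score both sides with the single imputer in `imputer` (e.g. the method
#'   picked by [sts_select()]).
#' @param imputer imputer function `(x, seed) -> imputation` used when
#'   `method = "selected"`.
#' @return an object of class `imputability_scores`: `im_subject` (length
#'   N), `im_variable` (length P), `im_cell` (data frame over the originally
#'   missing cells), `E_subject`, `E_variable` and unsampled flags.
#' @export
compute_im <- function(md, t = 10, rate = 0.05, seed = NULL, K = 5,
                       min_pairs = 10, method = c("knn-vs", "selected"),
                       imputer = NULL) {
  stopifnot(inherits(md, "phenomic_table"))
  method <- match.arg(method)
  if (method == "selected" && !is.function(imputer)) {
    stop("method = 'selected' requires an imputer function")
  }
  if (!is.null(seed)) set.seed(seed)
  z <- md$data
  n <- nrow(z); p <- ncol(z)
  obs_idx <- which(!is.na(z))
  n_hide <- round(rate * length(obs_idx))
  if (n_hide < 1) stop("rate too small: no observed cell would be hidden")
  if (n_hide >= length(obs_idx)) stop("rate too large: no observed cells would remain")

  use_knn <- method == "knn-vs"
  if (use_knn) {
    assoc <- association_matrix(md, min_pairs)
    gd <- gower_distance_matrix(md)
  }
  vars <- apply(z, 2, stats::var, na.rm = TRUE)
  qs <- vapply(seq_len(p), function(j) {
    if (md$types[j] == "continuous") NA_integer_ else length(md$levels[[j]])
  }, integer(1))

  subj_sum <- subj_cnt <- numeric(n)
  var_sum <- var_cnt <- numeric(p)
  pool_s <- pool_v <- numeric(0)
  for (rep in seq_len(t)) {
    hid <- sample(obs_idx, n_hide)
    cells <- arrayInd(hid, dim(z))
    x2 <- mask_cells(md, cells)
    if (use_knn) {
      gd2 <- gower_remove_cells(gd, md, cells)
      pred_v <- knn_v_engine(x2, assoc, cells, K)$values
      pred_s <- knn_s_engine(x2, gd2, cells, K)$values
    } else {
      res <- imputed_table(imputer(x2, seed = sample.int(.Machine$integer.max - 1, 1)))
      lin <- cells[, 1] + (cells[, 2] - 1) * n
      pred_v <- pred_s <- res$data[lin]
    }
    truth <- z[hid]
    e2_v <- cell_e2(pred_v, truth, cells[, 2], md$types, vars, qs)
    e2_s <- cell_e2(pred_s, truth, cells[, 2], md$types, vars, qs)
    # per-subject RMSE of this repetition under the subject-based imputer
    for (i in unique(cells[, 1])) {
      sel <- cells[, 1] == i
      subj_sum[i] <- subj_sum[i] + sqrt(mean(e2_s[sel]))
      subj_cnt[i] <- subj_cnt[i] + 1
    }
    for (j in unique(cells[, 2])) {
      sel <- cells[, 2] == j
      var_sum[j] <- var_sum[j] + sqrt(mean(e2_v[sel]))
      var_cnt[j] <- var_cnt[j] + 1
    }
    pool_s <- c(pool_s, e2_s)
    pool_v <- c(pool_v, e2_v)
  }
  e_subj <- ifelse(subj_cnt > 0, subj_sum / subj_cnt, sqrt(mean(pool_s)))
  e_var <- ifelse(var_cnt > 0, var_sum / var_cnt, sqrt(mean(pool_v)))
  unsampled_subj <- subj_cnt == 0
  unsampled_var <- var_cnt == 0
  im_s <- exp(-e_subj)
  im_v <- exp(-e_var)
  miss <- which(is.na(z), arr.ind = TRUE)
  dimnames(miss) <- NULL
  im_cell <- data.frame(i = miss[, 1], j = miss[, 2],
                        variable = colnames(z)[miss[, 2]],
                        im = pmax(im_s[miss[, 1]], im_v[miss[, 2]]),
                        stringsAsFactors = FALSE)
  structure(list(im_subject = im_s, im_variable = im_v, im_cell = im_cell,
                 E_subject = e_subj, E_variable = e_var,
                 unsampled_subject = unsampled_subj, unsampled_variable = unsampled_var,
                 t = t, rate = rate, method = method),
            class = "imputability_scores")
}

# normalized squared error per cell (the e^2 of the evaluation metrics)
cell_e2 <- function(pred, truth, jidx, types, vars, qs) {
  ty <- types[jidx]
  e2 <- numeric(length(pred))
  con <- ty == "continuous"
  e2[con] <- ifelse(vars[jidx[con]] > 0, (pred[con] - truth[con])^2 / vars[jidx[con]], 0)
  ord <- ty == "ordinal"
  e2[ord] <- ((pred[ord] - truth[ord]) / (qs[jidx[ord]] - 1))^2
  nom <- ty %in% c("binary", "categorical")
  e2[nom] <- as.numeric(pred[nom] != truth[nom])
  e2
}

#' @export
print.imputability_scores <- function(x, ...) {
  cat(sprintf("imputability_scores (t = %d, rate = %.0f%%, %s):\n",
              x$t, 100 * x$rate, x$method))
  cat(sprintf("  IMs (subjects):  median %.3f, range [%.3f, %.3f]%s\n",
              stats::median(x$im_subject), min(x$im_subject), max(x$im_subject),
              if (any(x$unsampled_subject)) sprintf(" (%d unsampled)", sum(x$unsampled_subject)) else ""))
  cat(sprintf("  IMv (variables): median %.3f, range [%.3f, %.3f]%s\n",
              stats::median(x$im_variable), min(x$im_variable), max(x$im_variable),
              if (any(x$unsampled_variable)) sprintf(" (%d unsampled)", sum(x$unsampled_variable)) else ""))
  cat(sprintf("  %d missing cells scored\n", nrow(x$im_cell)))
  invisible(x)
}

#' Partition missing cells by imputability
#'
#' In `"quantile"` mode the `floor(cutoff * #cells)` lowest-IM cells are
#' flagged (ties broken deterministically by (i, j) order); in `"threshold"`
#' mode cells with `IM < cutoff` are flagged. Flagged cells are the ones the
#' application guideline recommends not to impute (Option B) or to impute
#' with caution.
#'
#' @param scores an [compute_im()] result.
#' @param cells optional data frame with columns `i`, `j` restricting the
#'   cell set (default: all originally missing cells).
#' @param mode `"quantile"` or `"threshold"`.
#' @param cutoff fraction in `[0, 1]` (quantile mode) or IM threshold.
#' @return list with data frames `imputable` and `flagged`.
#' @export
filter_by_im <- function(scores, cells = NULL, mode = c("quantile", "threshold"),
                         cutoff = 0.25) {
  stopifnot(inherits(scores, "imputability_scores"))
  mode <- match.arg(mode)
  if (!is.numeric(cutoff) || cutoff < 0 || cutoff > 1) {
    stop("cutoff must be in [0, 1]")
  }
  df <- if (is.null(cells)) scores$im_cell else {
    data.frame(i = cells$i, j = cells$j,
               im = pmax(scores$im_subject[cells$i], scores$im_variable[cells$j]))
  }
  df <- df[order(df$i, df$j), , drop = FALSE]
  if (mode == "quantile") {
    k <- floor(cutoff * nrow(df))
    ord <- order(df$im, df$i, df$j)
    flagged_idx <- ord[seq_len(k)]
  } else {
    flagged_idx <- which(df$im < cutoff)
  }
  flagged <- df[sort(flagged_idx), , drop = FALSE]
  imputable <- df[setdiff(seq_len(nrow(df)), flagged_idx), , drop = FALSE]
  rownames(flagged) <- rownames(imputable) <- NULL
  list(imputable = imputable, flagged = flagged)
}
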