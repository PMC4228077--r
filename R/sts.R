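#' Self-training selection (STS) of the best imputer per data type
#'
#' Without ground truth, methods are compared on *second-layer* missing
#' values: a small extra fraction of the observed cells is hidden, every
#' registered method imputes the same two-layer table, and the hidden cells
#' are scored (RMSE for continuous and ordinal cells, PFC for nominal
#' cells). Over `n_reps` repetitions -- with all methods seeing identical
#' second layers (a paired design) -- the method with the smallest average
#' error per data type is selected. Methods whose average error is within 5%
#' of the minimum are reported as comparable.
#'
#' @param md a [phenomic_table] with missing values.
#' @param methods character vector of method names or named list of imputer
#'   functions (see [register_imputer()]).
#' @param n_reps second-layer repetitions (default 20).
#' @param rate second-layer rate (default 5%).
#' @param seed RNG seed.
#' @param K,hybrid_reps,min_pairs settings forwarded to built-in methods
#'   (`hybrid_reps` is the internal repetition count the hybrids use to
#'   estimate their own weight).
#' @param comparable_margin methods within this relative margin of the
#'   minimum average error count as comparable (default 0.05).
#' @return an object of class `sts_report`: `mean_error` (method x type),
#'   `selected` (type -> method), `comparable` (type -> methods within the
#'   margin), failure counts and settings.
#' @export
sts_select <- function(md, methods, n_reps = 20, rate = 0.05, seed = NULL,
                       K = 5, hybrid_reps = 20, min_pairs = 10,
                       comparable_margin = 0.05) {
  stopifnot(inherits(md, "phenomic_table"))
  fns <- resolve_imputers(methods, K = K, n_reps = hybrid_reps, rate = rate,
                          min_pairs = min_pairs)
  if (length(fns) < 1) stop("at least one imputer is required")
  if (!is.null(seed)) set.seed(seed)
  z <- md$data
  obs_idx <- which(!is.na(z))
  n_hide <- round(rate * length(obs_idx))
  if (n_hide < 1) stop("rate too small: no observed cell would be hidden")
  types_present <- c(
    continuous = any(md$types == "continuous"),
    ordinal = any(md$types == "ordinal"),
    nominal = any(md$types %in% c("binary", "categorical"))
  )
  metric_names <- c(continuous = "rmse_continuous", ordinal = "rmse_ordinal",
                    nominal = "pfc_nominal")
  err <- array(NA_real_, dim = c(length(fns), 3, n_reps),
               dimnames = list(names(fns), names(metric_names), NULL))
  failures <- integer(length(fns))
  names(failures) <- names(fns)
  rep_seeds <- sample.int(.Machine$integer.max - 1, n_reps)
  for (rep in seq_len(n_reps)) {
    set.seed(rep_seeds[rep])
    hid <- sample(obs_idx, n_hide)
    cells <- arrayInd(hid, dim(z))
    x2 <- mask_cells(md, cells)
    layer <- matrix(FALSE, nrow(z), ncol(z))
    layer[cells] <- TRUE
    for (mi in seq_along(fns)) {
      ev <- tryCatch({
        res <- fns[[mi]](x2, seed = rep_seeds[rep])
        evaluate_imputation(res, md, layer)
      }, error = function(e) NULL)
      if (is.null(ev)) {
        failures[mi] <- failures[mi] + 1L
      } else {
        err[mi, , rep] <- c(ev$rmse_continuous, ev$rmse_ordinal, ev$pfc_nominal)
      }
    }
  }
  excluded <- failures > n_reps / 2
  mean_error <- apply(err, c(1, 2), mean, na.rm = TRUE)
  mean_error[excluded, ] <- NA_real_
  mean_error[!is.finite(mean_error)] <- NA_real_
  selected <- comparable <- stats::setNames(vector("list", 3), names(metric_names))
  for (ty in names(metric_names)) {
    if (!types_present[[ty]] || all(is.na(mean_error[, ty]))) {
      selected[[ty]] <- NA_character_
      comparable[[ty]] <- character(0)
      next
    }
    me <- stats::setNames(mean_error[, ty], rownames(mean_error))
    best <- min(me, na.rm = TRUE)
    selected[[ty]] <- names(which.min(me))
    comparable[[ty]] <- names(me)[!is.na(me) & me <= (1 + comparable_margin) * best]
  }
  structure(list(mean_error = mean_error, per_rep = err,
                 selected = unlist(selected), comparable = comparable,
                 failures = failures, excluded = excluded,
                 n_reps = n_reps, rate = rate,
                 comparable_margin = comparable_margin),
            class = "sts_report")
}

#' @export
print.sts_report <- function(x, ...) {
  cat(sprintf("sts_report (%d second-layer repetitions at %.0f%% rate):\n",
              x$n_reps, 100 * x$rate))
  print(round(x$mean_error, 4))
  for (ty in names(x$comparable)) {
    if (is.na(x$selected[[ty]])) next
    cat(sprintf("  %s: selected '%s' (comparable: %s)\n", ty, x$selected[[ty]],
                paste(x$comparable[[ty]], collapse = ", ")))
  }
  if (any(x$failures > 0)) {
    cat("  failures:", paste(sprintf("%s=%d", names(x$failures), x$failures)[x$failures > 0],
                             collapse = ", "), "\n")
  }
  invisible(x)
}

#' Accuracy of the STS scheme on a complete dataset
#'
#' Evaluates how often STS picks the truly best method. For each of
#' `n_outer` missing-data realizations of the complete table, the "true"
#' best method per data type is determined by scoring every method on the
#' first-layer cells against the known truth (methods within the 5% margin
#' of the minimum all count as correct); [sts_select()] is then run on the
#' realization alone, and the accuracy is the fraction of realizations in
#' which the STS choice lies in the comparable-best set.
#'
#' @param cd the complete [phenomic_table].
#' @param methods as in [sts_select()].
#' @param m first-layer missing rate.
#' @param n_outer number of missing-data realizations (default 20).
#' @param n_inner second-layer repetitions inside each [sts_select()] call.
#' @param rate second-layer rate.
#' @param seed master seed.
#' @param K,hybrid_reps,min_pairs,comparable_margin as in [sts_select()].
#' @return an object of class `sts_accuracy`: per-type accuracy (in %), and
#'   the per-realization choices.
#' @export
sts_accuracy <- function(cd, methods, m, n_outer = 20, n_inner = 20,
                         rate = 0.05, seed = NULL, K = 5, hybrid_reps = 20,
                         min_pairs = 10, comparable_margin = 0.05) {
  stopifnot(inherits(cd, "phenomic_table"))
  if (any(is.na(cd$data))) stop("cd must be complete")
  fns <- resolve_imputers(methods, K = K, n_reps = hybrid_reps, rate = rate,
                          min_pairs = min_pairs)
  if (length(fns) < 2) stop("at least two imputers are required")
  if (!is.null(seed)) set.seed(seed)
  outer_seeds <- sample.int(.Machine$integer.max - 2, n_outer)
  metric_names <- c(continuous = "rmse_continuous", ordinal = "rmse_ordinal",
                    nominal = "pfc_nominal")
  hits <- matrix(NA, n_outer, 3, dimnames = list(NULL, names(metric_names)))
  picks <- matrix(NA_character_, n_outer, 3, dimnames = list(NULL, names(metric_names)))
  truth_best <- vector("list", n_outer)
  for (b in seq_len(n_outer)) {
    md <- generate_missing(cd, m, seed = outer_seeds[b])
    layer <- missing_layer(md, cd)
    true_err <- matrix(NA_real_, length(fns), 3,
                       dimnames = list(names(fns), names(metric_names)))
    for (mi in seq_along(fns)) {
      ev <- tryCatch({
        res <- fns[[mi]](md, seed = outer_seeds[b])
        evaluate_imputation(res, cd, layer)
      }, error = function(e) NULL)
      if (!is.null(ev)) {
        true_err[mi, ] <- c(ev$rmse_continuous, ev$rmse_ordinal, ev$pfc_nominal)
      }
    }
    sts <- sts_select(md, fns, n_reps = n_inner, rate = rate,
                      seed = outer_seeds[b] + 1, K = K, hybrid_reps = hybrid_reps,
                      min_pairs = min_pairs, comparable_margin = comparable_margin)
    best_sets <- list()
    for (ty in names(metric_names)) {
      te <- stats::setNames(true_err[, ty], rownames(true_err))
      if (all(is.na(te))) next
      best <- min(te, na.rm = TRUE)
      best_sets[[ty]] <- names(te)[!is.na(te) & te <= (1 + comparable_margin) * best]
      picks[b, ty] <- sts$selected[[ty]]
      hits[b, ty] <- !is.na(sts$selected[[ty]]) && sts$selected[[ty]] %in% best_sets[[ty]]
    }
    truth_best[[b]] <- best_sets
  }
  accuracy <- 100 * colMeans(hits, na.rm = TRUE)
  structure(list(accuracy = accuracy, hits = hits, picks = picks,
                 truth_best = truth_best, n_outer = n_outer, n_inner = n_inner,
                 m = m),
            class = "sts_accuracy")
}

#' @export
print.sts_accuracy <- function(x, ...) {
  cat(sprintf("sts_accuracy over %d realizations at %.0f%% missingness:\n",
              x$n_outer, 100 * x$m))
  for (ty in names(x$accuracy)) {
    if (is.nan(x$accuracy[[ty]])) next
    cat(sprintf("  %s: %.0f%%\n", ty, x$accuracy[[ty]]))
  }
  invisible(x)
}
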