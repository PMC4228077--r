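#' Impute a mixed-type phenomic table
#'
#' The front end to the five built-in imputers:
#'
#' * `"knn-v"` -- impute from the K nearest *variables*, ranked by the
#'   mixed-type correlation distance `|1 - r|`; each neighbour contributes a
#'   single-predictor GLM prediction (linear / ordinal logistic / logistic /
#'   multinomial logistic by target type) and predictions are pooled by a
#'   correlation-weighted average (continuous), its rounded clipped version
#'   (ordinal) or a weighted majority vote (nominal).
#' * `"knn-s"` -- impute from the K nearest *subjects* under Gower distance,
#'   pooling the neighbours' observed values of the target variable with the
#'   same weighting (similarity `1 - d`) and aggregation rules.
#' * `"knn-h"` -- the convex combination `p * KNN-S + (1 - p) * KNN-V` with a
#'   global `p` estimated by second-layer simulation (see [estimate_p()]).
#' * `"knn-a"` -- as `"knn-h"` but with `p` varying by the cell's `r_max`
#'   sliding window (adaptive weight).
#' * `"mean"` -- column mean (continuous), rounded clipped mean (ordinal) or
#'   mode with lowest-level ties (nominal): the baseline.
#'
#' Every missing cell is imputed (cells with no usable neighbours fall back
#' to the column marginal and are flagged in the provenance).
#'
#' @param x a [phenomic_table] with missing values.
#' @param method one of `"knn-v"`, `"knn-s"`, `"knn-h"`, `"knn-a"`, `"mean"`.
#' @param K number of nearest neighbours (default 5).
#' @param p hybrid weight for `"knn-h"`/`"knn-a"`: a number in `[0, 1]`, a
#'   precomputed [estimate_p()] object, or `NULL` to estimate it here.
#' @param n_reps,rate second-layer repetitions and rate for estimating `p`.
#' @param min_pairs minimum pairwise-complete observations for a variable
#'   pair to be an eligible neighbour.
#' @param seed RNG seed (only the hybrid weight estimation draws random
#'   numbers; KNN-V/KNN-S/mean are deterministic).
#' @param assoc,gd optional precomputed [association_matrix()] and
#'   [gower_distance_matrix()] of `x`, to avoid recomputation across several
#'   calls on the same table.
#' @return an object of class `phenomic_imputation`: the completed `table`,
#'   a per-cell `provenance` data frame (method, neighbour count, hybrid
#'   weight, fallback flags), and the estimation settings.
#' @export
impute_phenomic <- function(x, method = c("knn-v", "knn-s", "knn-h", "knn-a", "mean"),
                            K = 5, p = NULL, n_reps = 20, rate = 0.05,
                            min_pairs = 10, seed = NULL, assoc = NULL, gd = NULL) {
  stopifnot(inherits(x, "phenomic_table"))
  method <- match.arg(method)
  cells <- which(is.na(x$data), arr.ind = TRUE)
  dimnames(cells) <- NULL
  if (!nrow(cells)) {
    return(new_imputation(x, empty_provenance(), method, K, NULL, seed))
  }

  if (method == "mean") {
    vals <- vapply(cells[, 2], function(j) marginal_value(x$data, x$types, x$levels, j),
                   numeric(1))
    prov <- cell_provenance(x, cells, "mean", 0L, NA_real_, "")
    return(new_imputation(fill_cells(x, cells, vals), prov, method, K, NULL, seed))
  }

  if (method == "knn-v") {
    if (is.null(assoc)) assoc <- association_matrix(x, min_pairs)
    eng <- knn_v_engine(x, assoc, cells, K)
    prov <- cell_provenance(x, cells, "knn-v", eng$n_neighbors, NA_real_, eng$fallback)
    return(new_imputation(fill_cells(x, cells, eng$values), prov, method, K, NULL, seed))
  }

  if (method == "knn-s") {
    if (is.null(gd)) gd <- gower_distance_matrix(x)
    eng <- knn_s_engine(x, gd, cells, K)
    prov <- cell_provenance(x, cells, "knn-s", eng$n_neighbors, NA_real_, eng$fallback)
    return(new_imputation(fill_cells(x, cells, eng$values), prov, method, K, NULL, seed))
  }

  # hybrids
  adaptive <- method == "knn-a"
  if (is.null(assoc)) assoc <- association_matrix(x, min_pairs)
  if (is.null(gd)) gd <- gower_distance_matrix(x)
  hw <- p
  if (is.null(hw)) {
    hw <- estimate_p(x, K = K, n_reps = n_reps, rate = rate, seed = seed,
                     adaptive = adaptive, min_pairs = min_pairs,
                     assoc = assoc, gd = gd)
  } else if (is.numeric(hw)) {
    stopifnot(hw >= 0, hw <= 1)
  } else {
    stopifnot(inherits(hw, "hybrid_weight"))
    if (adaptive && !hw$adaptive) {
      stop("method 'knn-a' needs an adaptive hybrid_weight (estimate_p(..., adaptive = TRUE))")
    }
  }
  eng_v <- knn_v_engine(x, assoc, cells, K)
  eng_s <- knn_s_engine(x, gd, cells, K)
  vals <- numeric(nrow(cells))
  p_used <- numeric(nrow(cells))
  fallback <- character(nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    j <- cells[ci, 2]
    pj <- if (adaptive) p_for_variable(hw, j) else
      list(p = if (is.numeric(hw)) as.numeric(hw) else hw$p_global, flag = "")
    p_used[ci] <- pj$p
    flags <- pj$flag
    v_marg <- grepl("marginal_fallback", eng_v$fallback[ci])
    s_marg <- grepl("marginal_fallback", eng_s$fallback[ci])
    if (v_marg && !s_marg) {
      vals[ci] <- eng_s$values[ci]
      flags <- c(flags, "knn_v_marginal_used_s")
    } else if (s_marg && !v_marg) {
      vals[ci] <- eng_v$values[ci]
      flags <- c(flags, "knn_s_marginal_used_v")
    } else {
      vals[ci] <- combine_hybrid(x$types[j], eng_s$values[ci], eng_v$values[ci],
                                 pj$p, n_levels(x, j))
      if (v_marg && s_marg) flags <- c(flags, "marginal_fallback")
    }
    fallback[ci] <- paste(flags[nzchar(flags)], collapse = "+")
  }
  prov <- cell_provenance(x, cells, method, pmax(eng_v$n_neighbors, eng_s$n_neighbors),
                          p_used, fallback)
  new_imputation(fill_cells(x, cells, vals), prov, method, K,
                 if (is.numeric(hw)) NULL else hw, seed)
}

fill_cells <- function(x, cells, values) {
  z <- x$data
  z[cells] <- values
  new_phenomic_table(z, x$types, x$levels)
}

cell_provenance <- function(x, cells, method, n_neighbors, p, fallback) {
  data.frame(i = cells[, 1], j = cells[, 2],
             variable = colnames(x$data)[cells[, 2]],
             type = x$types[cells[, 2]],
             method = method, n_neighbors = n_neighbors, p = p,
             fallback = fallback, stringsAsFactors = FALSE)
}

empty_provenance <- function() {
  data.frame(i = integer(0), j = integer(0), variable = character(0),
             type = character(0), method = character(0),
             n_neighbors = integer(0), p = numeric(0), fallback = character(0),
             stringsAsFactors = FALSE)
}

new_imputation <- function(table, provenance, method, K, weight, seed) {
  structure(list(table = table, provenance = provenance, method = method,
                 K = K, weight = weight, seed = seed),
            class = "phenomic_imputation")
}

#' @export
print.phenomic_imputation <- function(x, ...) {
  n <- nrow(x$provenance)
  cat(sprintf("phenomic_imputation: method '%s' (K = %d), %d cells imputed\n",
              x$method, x$K, n))
  if (!is.null(x$weight)) {
    cat(sprintf("  hybrid weight p_global = %.3f%s\n", x$weight$p_global,
                if (x$weight$adaptive) " (adaptive)" else ""))
  }
  nf <- sum(nzchar(x$provenance$fallback))
  if (n > 0) cat(sprintf("  cells with fallback flags: %d (%.1f%%)\n", nf, 100 * nf / n))
  invisible(x)
}

#' @export
summary.phenomic_imputation <- function(object, ...) {
  pr <- object$provenance
  out <- list(
    method = object$method,
    n_imputed = nrow(pr),
    by_type = table(pr$type),
    fallbacks = table(pr$fallback[nzchar(pr$fallback)]),
    remaining_missing = sum(is.na(object$table$data))
  )
  class(out) <- "summary.phenomic_imputation"
  out
}

#' @export
print.summary.phenomic_imputation <- function(x, ...) {
  cat(sprintf("Imputation by '%s': %d cells imputed, %d still missing\n",
              x$method, x$n_imputed, x$remaining_missing))
  if (length(x$by_type)) {
    cat("  by type:", paste(sprintf("%s=%d", names(x$by_type), x$by_type), collapse = ", "), "\n")
  }
  if (length(x$fallbacks)) {
    cat("  fallbacks:\n")
    for (nm in names(x$fallbacks)) cat(sprintf("    %s: %d\n", nm, x$fallbacks[[nm]]))
  }
  invisible(x)
}

# ---- pluggable-imputer registry -------------------------------------------

.imputer_registry <- new.env(parent = emptyenv())

builtin_imputers <- c("mean", "knn-v", "knn-s", "knn-h", "knn-a")

#' Register a pluggable imputer
#'
#' Any function taking `(x, seed)` -- a [phenomic_table] and an integer seed
#' -- and returning a `phenomic_imputation` or a completed [phenomic_table]
#' can be registered under a name and then participate in [sts_select()],
#' [compare_methods()] and [run_guideline()] alongside the built-ins.
#' Adapters for external imputers (random-forest or chained-equation
#' packages) attach here.
#'
#' @param name method name.
#' @param fn the imputer function.
#' @return `name`, invisibly.
#' @export
register_imputer <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1, is.function(fn))
  assign(name, fn, envir = .imputer_registry)
  invisible(name)
}

#' @rdname register_imputer
#' @param K,n_reps,rate,min_pairs settings passed to [impute_phenomic()] when
#'   resolving a built-in method name.
#' @export
get_imputer <- function(name, K = 5, n_reps = 20, rate = 0.05, min_pairs = 10) {
  if (exists(name, envir = .imputer_registry, inherits = FALSE)) {
    return(get(name, envir = .imputer_registry))
  }
  if (name %in% builtin_imputers) {
    force(name); force(K); force(n_reps); force(rate); force(min_pairs)
    return(function(x, seed = NULL) {
      impute_phenomic(x, method = name, K = K, n_reps = n_reps, rate = rate,
                      min_pairs = min_pairs, seed = seed)
    })
  }
  stop("unknown imputer: '", name, "'")
}

# turn a character vector / named list of functions into a named list of fns
resolve_imputers <- function(methods, K = 5, n_reps = 20, rate = 0.05, min_pairs = 10) {
  if (is.character(methods)) {
    fns <- lapply(methods, get_imputer, K = K, n_reps = n_reps, rate = rate,
                  min_pairs = min_pairs)
    names(fns) <- methods
    return(fns)
  }
  stopifnot(is.list(methods), !is.null(names(methods)), all(nzchar(names(methods))))
  methods
}

# normalize the return value of a pluggable imputer to a phenomic_table
imputed_table <- function(res) {
  if (inherits(res, "phenomic_imputation")) return(res$table)
  if (inherits(res, "phenomic_table")) return(res)
  stop("an imputer must return a phenomic_imputation or phenomic_table")
}
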