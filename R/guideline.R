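#' End-to-end application guideline
#'
#' Runs the recommended pipeline on a table with missing values:
#'
#' 1. **STS** per data type -- [sts_select()] picks the best imputer for
#'    continuous, ordinal and nominal cells separately;
#' 2. **IM** -- [compute_im()] scores every missing cell's imputability;
#' 3. **imputation** -- each data type is imputed with its winning method;
#' 4. **Option A**: all missing cells are imputed and reported together with
#'    their IMs; **Option B**: only cells passing the IM filter are imputed,
#'    the rest stay missing and are flagged.
#'
#' Stage seeds are derived from the master seed by fixed offsets (+1 STS,
#' +2 IM, +3 imputation), so stages are decoupled but the whole run is
#' reproducible.
#'
#' @param md a [phenomic_table] with missing values.
#' @param methods roster of imputer names/functions for STS.
#' @param option `"A"` (impute everything) or `"B"` (IM-thresholded).
#' @param K neighbours.
#' @param sts_reps,sts_rate second-layer settings for [sts_select()].
#' @param im_t,im_rate settings for [compute_im()].
#' @param im_method `"knn-vs"` (IM from KNN-S/KNN-V, the measure's
#'   definition; default) or `"selected"` (IM from the STS winner).
#' @param im_mode,im_cutoff the [filter_by_im()] rule (required for Option
#'   B).
#' @param min_pairs,hybrid_reps forwarded to the built-in methods.
#' @param seed master seed.
#' @return an object of class `phenomic_guideline`: `imputation` (a
#'   `phenomic_imputation` whose table is complete under Option A, partial
#'   under Option B), `im`, `sts`, `skipped` (Option B cells left missing)
#'   and the configuration.
#' @export
run_guideline <- function(md, methods = c("mean", "knn-v", "knn-s", "knn-h", "knn-a"),
                          option = c("A", "B"), K = 5,
                          sts_reps = 20, sts_rate = 0.05,
                          im_t = 10, im_rate = 0.05,
                          im_method = c("knn-vs", "selected"),
                          im_mode = c("quantile", "threshold"), im_cutoff = NULL,
                          min_pairs = 10, hybrid_reps = 20, seed = NULL) {
  stopifnot(inherits(md, "phenomic_table"))
  option <- match.arg(option)
  im_method <- match.arg(im_method)
  im_mode <- match.arg(im_mode)
  if (option == "B" && is.null(im_cutoff)) {
    stop("Option B requires an im_cutoff")
  }
  base_seed <- if (is.null(seed)) NULL else seed %% (.Machine$integer.max - 10L)
  stage_seed <- function(offset) if (is.null(base_seed)) NULL else base_seed + offset
  fns <- resolve_imputers(methods, K = K, n_reps = hybrid_reps, rate = sts_rate,
                          min_pairs = min_pairs)

  sts <- tryCatch(
    sts_select(md, fns, n_reps = sts_reps, rate = sts_rate,
               seed = stage_seed(1L), K = K, hybrid_reps = hybrid_reps,
               min_pairs = min_pairs),
    error = function(e) stop("guideline stage 'sts': ", conditionMessage(e)))

  winner_fn <- NULL
  if (im_method == "selected") {
    first_win <- stats::na.omit(sts$selected)[1]
    winner_fn <- fns[[first_win]]
  }
  im <- tryCatch(
    compute_im(md, t = im_t, rate = im_rate, seed = stage_seed(2L), K = K,
               min_pairs = min_pairs, method = im_method, imputer = winner_fn),
    error = function(e) stop("guideline stage 'im': ", conditionMessage(e)))

  # impute each data type with its winner; one run per distinct winning method
  type_of <- function(ty) if (ty %in% c("binary", "categorical")) "nominal" else ty
  cell_types <- vapply(md$types, type_of, character(1))
  miss <- which(is.na(md$data), arr.ind = TRUE)
  dimnames(miss) <- NULL
  winners <- sts$selected
  fallback_method <- names(fns)[1]
  z <- md$data
  prov_list <- list()
  distinct <- unique(stats::na.omit(winners[unique(cell_types[miss[, 2]])]))
  if (!length(distinct)) distinct <- fallback_method
  runs <- list()
  for (mname in distinct) {
    runs[[mname]] <- tryCatch(
      fns[[mname]](md, seed = stage_seed(3L)),
      error = function(e) stop("guideline stage 'impute[", mname, "]': ",
                               conditionMessage(e)))
  }
  for (ci in seq_len(nrow(miss))) {
    i <- miss[ci, 1]; j <- miss[ci, 2]
    w <- winners[[cell_types[j]]]
    if (is.na(w)) w <- distinct[1]
    tabw <- imputed_table(runs[[w]])
    z[i, j] <- tabw$data[i, j]
    prov_list[[ci]] <- data.frame(i = i, j = j, variable = colnames(z)[j],
                                  type = md$types[j], method = w,
                                  stringsAsFactors = FALSE)
  }
  prov <- if (length(prov_list)) do.call(rbind, prov_list) else
    cbind(empty_provenance()[c("i", "j", "variable", "type", "method")])
  prov$im <- im$im_cell$im[match(paste(prov$i, prov$j),
                                 paste(im$im_cell$i, im$im_cell$j))]
  prov$imputed <- TRUE

  skipped <- NULL
  if (option == "B") {
    part <- filter_by_im(im, mode = im_mode, cutoff = im_cutoff)
    skipped <- part$flagged
    if (nrow(skipped)) {
      z[cbind(skipped$i, skipped$j)] <- NA_real_
      sk <- paste(prov$i, prov$j) %in% paste(skipped$i, skipped$j)
      prov$imputed[sk] <- FALSE
    }
  }
  result <- new_imputation(new_phenomic_table(z, md$types, md$levels), prov,
                           paste0("guideline-", option), K, NULL, seed)
  structure(list(imputation = result, im = im, sts = sts, skipped = skipped,
                 option = option, methods = names(fns), seed = seed),
            class = "phenomic_guideline")
}

#' @export
print.phenomic_guideline <- function(x, ...) {
  cat(sprintf("phenomic_guideline (Option %s):\n", x$option))
  sel <- x$sts$selected[!is.na(x$sts$selected)]
  cat("  STS winners:", paste(sprintf("%s='%s'", names(sel), sel), collapse = ", "), "\n")
  n_imp <- sum(x$imputation$provenance$imputed)
  n_skip <- if (is.null(x$skipped)) 0 else nrow(x$skipped)
  cat(sprintf("  %d cells imputed, %d left missing by the IM filter\n", n_imp, n_skip))
  invisible(x)
}
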