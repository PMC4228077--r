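#' Mixed-type phenomic tables
#'
#' A `phenomic_table` holds a subjects x variables table in which every
#' variable is declared as one of four types: `continuous`, `ordinal`,
#' `binary` or `categorical` (multi-class nominal). Values are stored
#' internally as a numeric matrix of codes:
#'
#' * continuous -- the raw value;
#' * ordinal -- consecutive positive integers `1..q` following the declared
#'   level order;
#' * binary -- `0/1` (first declared level is 0);
#' * categorical -- integer codes `1..L` enumerating the declared labels.
#'
#' Missing cells are `NA`; the missingness mask is always `is.na()` of the
#' code matrix, so the two can never disagree.
#'
#' @param data a data.frame (or matrix) of raw values on the label scale;
#'   columns must be named.
#' @param spec a named list, one entry per column, each a list with elements
#'   `type` (one of `"continuous"`, `"ordinal"`, `"binary"`, `"categorical"`)
#'   and, for non-continuous types, `levels` (character vector; for ordinal
#'   the order is the rank order). A categorical variable declared with
#'   exactly two levels is normalized to `binary`. Levels may be omitted for
#'   binary/categorical variables, in which case the sorted observed values
#'   are used.
#'
#' @return an object of class `phenomic_table` with fields `data` (numeric
#'   code matrix), `types` (character vector) and `levels` (named list).
#' @export
phenomic_table <- function(data, spec) {
  data <- as.data.frame(data, check.names = FALSE, stringsAsFactors = FALSE)
  nms <- names(data)
  if (anyDuplicated(nms)) {
    stop("duplicate variable names: ", paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  missing_spec <- setdiff(nms, names(spec))
  if (length(missing_spec)) {
    stop("unknown column(s) not covered by the type spec: ",
         paste(missing_spec, collapse = ", "))
  }
  types <- character(length(nms))
  levels <- vector("list", length(nms))
  names(levels) <- nms
  codes <- matrix(NA_real_, nrow = nrow(data), ncol = length(nms),
                  dimnames = list(rownames(data), nms))
  for (j in seq_along(nms)) {
    sp <- spec[[nms[j]]]
    ty <- match.arg(sp$type, c("continuous", "ordinal", "binary", "categorical"))
    lv <- as.character(unlist(sp$levels))
    raw <- data[[j]]
    if (ty == "continuous") {
      v <- suppressWarnings(as.numeric(as.character(raw)))
      bad <- !is.na(raw) & trimws(as.character(raw)) != "" & is.na(v)
      if (any(bad)) {
        stop("variable '", nms[j], "': non-numeric value in continuous column: '",
             as.character(raw)[which(bad)[1]], "'")
      }
      codes[, j] <- v
      types[j] <- ty
      levels[[j]] <- character(0)
      next
    }
    chr <- as.character(raw)
    chr[!is.na(chr) & trimws(chr) == ""] <- NA
    if (!length(lv)) {
      if (ty == "ordinal") stop("variable '", nms[j], "': ordinal variables require an ordered 'levels' list")
      lv <- sort(unique(chr[!is.na(chr)]))
    }
    if (anyDuplicated(lv)) stop("variable '", nms[j], "': duplicated levels")
    if (ty == "binary" && length(lv) != 2) {
      stop("variable '", nms[j], "': binary variables require exactly 2 levels")
    }
    if (ty == "categorical" && length(lv) == 2) ty <- "binary"
    if (length(lv) < 2) stop("variable '", nms[j], "': needs at least 2 levels")
    m <- match(chr, lv)
    bad <- !is.na(chr) & is.na(m)
    if (any(bad)) {
      stop("variable '", nms[j], "': value outside declared levels: '",
           chr[which(bad)[1]], "'")
    }
    codes[, j] <- if (ty == "binary") m - 1 else m
    types[j] <- ty
    levels[[j]] <- lv
  }
  new_phenomic_table(codes, types, levels)
}

# low-level constructor on already-coded values (used by the simulators)
new_phenomic_table <- function(data, types, levels) {
  stopifnot(is.matrix(data), ncol(data) == length(types), length(types) == length(levels))
  if (is.null(colnames(data))) colnames(data) <- paste0("V", seq_len(ncol(data)))
  names(levels) <- colnames(data)
  structure(list(data = data, types = types, levels = levels),
            class = "phenomic_table")
}

#' @export
dim.phenomic_table <- function(x) dim(x$data)

#' Missingness mask of a phenomic table
#'
#' @param x a [phenomic_table].
#' @return logical N x P matrix, `TRUE` where the cell is missing.
#' @export
missing_mask <- function(x) {
  stopifnot(inherits(x, "phenomic_table"))
  is.na(x$data)
}

# number of levels of variable j (q for ordinal, L for categorical, 2 for binary)
n_levels <- function(x, j) {
  if (x$types[j] == "continuous") return(NA_integer_)
  length(x$levels[[j]])
}

#' @export
print.phenomic_table <- function(x, ...) {
  d <- dim(x$data)
  nmiss <- sum(is.na(x$data))
  cat(sprintf("phenomic_table: %d subjects x %d variables (%d missing cells, %.1f%%)\n",
              d[1], d[2], nmiss, 100 * nmiss / prod(d)))
  tt <- table(factor(x$types, levels = c("continuous", "ordinal", "binary", "categorical")))
  cat("  types:", paste(sprintf("%s=%d", names(tt), tt), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.phenomic_table <- function(object, ...) {
  miss_by_var <- colMeans(is.na(object$data))
  out <- data.frame(
    variable = colnames(object$data),
    type = object$types,
    n_levels = vapply(seq_along(object$types), function(j) {
      if (object$types[j] == "continuous") NA_integer_ else length(object$levels[[j]])
    }, integer(1)),
    pct_missing = 100 * miss_by_var,
    row.names = NULL
  )
  class(out) <- c("summary.phenomic_table", class(out))
  out
}

# decode internal codes back to the label scale (data.frame of characters/numerics)
decode_phenomic <- function(x) {
  stopifnot(inherits(x, "phenomic_table"))
  out <- as.data.frame(x$data[, , drop = FALSE])
  names(out) <- colnames(x$data)
  for (j in seq_along(x$types)) {
    ty <- x$types[j]
    if (ty == "continuous") next
    lv <- x$levels[[j]]
    code <- x$data[, j]
    idx <- if (ty == "binary") code + 1 else code
    out[[j]] <- lv[idx]
  }
  out
}

# the spec of a table, in the JSON-ready shape
table_spec <- function(x) {
  sp <- lapply(seq_along(x$types), function(j) {
    list(type = x$types[j], levels = as.list(x$levels[[j]]))
  })
  names(sp) <- colnames(x$data)
  sp
}

#' Read a phenomic table from CSV plus a JSON type spec
#'
#' The CSV must have a header row; the JSON spec maps every column name to
#' `{"type": ..., "levels": [...]}`. Cells equal to any of `na_strings`
#' (default `"NA"` and the empty string) are treated as missing.
#'
#' @param table_path path to the CSV file.
#' @param spec_path path to the JSON type spec.
#' @param na_strings character vector of tokens encoding a missing cell.
#' @return a [phenomic_table].
#' @export
read_phenomic_csv <- function(table_path, spec_path, na_strings = c("NA", "")) {
  df <- utils::read.csv(table_path, check.names = FALSE, colClasses = "character",
                        na.strings = na_strings, stringsAsFactors = FALSE)
  spec <- jsonlite::fromJSON(spec_path, simplifyVector = FALSE)
  phenomic_table(df, spec)
}

#' Write an imputed table to CSV (with an optional provenance sidecar)
#'
#' Values are written back on the original label scale. Cells still missing
#' (e.g. those left unimputed under Option B of the application guideline)
#' are written as `"NA"`. When `result` is a [impute_phenomic()] result and
#' `provenance_path` is given, a JSON sidecar records, per imputed cell, the
#' method used, the neighbour count, the hybrid weight and any fallback.
#'
#' @param result a `phenomic_imputation` (from [impute_phenomic()]) or a
#'   [phenomic_table].
#' @param path output CSV path.
#' @param provenance_path optional path for the JSON provenance sidecar.
#' @return `path`, invisibly.
#' @export
write_imputed_csv <- function(result, path, provenance_path = NULL) {
  tab <- if (inherits(result, "phenomic_imputation")) result$table else result
  stopifnot(inherits(tab, "phenomic_table"))
  utils::write.csv(decode_phenomic(tab), path, row.names = FALSE, na = "NA")
  if (!is.null(provenance_path)) {
    prov <- if (inherits(result, "phenomic_imputation")) result$provenance else NULL
    jsonlite::write_json(prov, provenance_path, dataframe = "rows", auto_unbox = TRUE,
                         na = "null", digits = NA)
  }
  invisible(path)
}

#' Write the JSON type spec of a table
#'
#' @param x a [phenomic_table].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_phenomic_spec <- function(x, path) {
  jsonlite::write_json(table_spec(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# set cells (matrix of i,j or logical mask) to missing; returns a new table
mask_cells <- function(x, cells) {
  z <- x$data
  if (is.logical(cells)) {
    z[cells] <- NA_real_
  } else {
    z[cells] <- NA_real_
  }
  new_phenomic_table(z, x$types, x$levels)
}
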