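# fixtures are built in code -- no data files

# small correlated mixed-type table: two continuous (correlated), one
# ordinal cut from the first continuous, one binary, one categorical
mixed_fixture <- function(n = 60, seed = 1, miss = 0) {
  set.seed(seed)
  z1 <- rnorm(n)
  z2 <- 0.8 * z1 + rnorm(n, sd = 0.6)
  ord <- findInterval(z1, quantile(z1, c(0.25, 0.5, 0.75))) + 1L
  bin <- as.integer(z2 > 0)
  cat3 <- sample(1:3, n, replace = TRUE)
  df <- data.frame(
    c1 = z1, c2 = z2,
    o1 = c("a", "b", "c", "d")[ord],
    b1 = c("no", "yes")[bin + 1],
    k1 = c("x", "y", "z")[cat3],
    stringsAsFactors = FALSE
  )
  spec <- list(
    c1 = list(type = "continuous"),
    c2 = list(type = "continuous"),
    o1 = list(type = "ordinal", levels = list("a", "b", "c", "d")),
    b1 = list(type = "binary", levels = list("no", "yes")),
    k1 = list(type = "categorical", levels = list("x", "y", "z"))
  )
  tab <- phenomic_table(df, spec)
  if (miss > 0) tab <- generate_missing(tab, miss, seed = seed + 1)
  tab
}

# table where every variable and every subject has an exact duplicate:
# perfect neighbours in both directions
duplicated_fixture <- function(n = 30, p = 6, seed = 1) {
  set.seed(seed)
  half <- matrix(rnorm(n * p / 2), n, p / 2)
  z <- cbind(half, half)
  z <- rbind(z, z)  # duplicate subjects too
  colnames(z) <- paste0("V", seq_len(p))
  phenoimpute:::new_phenomic_table(z, rep("continuous", p), rep(list(character(0)), p))
}

# fully randomized mixed table for fuzzing (types, levels and missingness
# all random)
random_mixed_table <- function(seed, n = 12, p = 6, miss = 0.15) {
  set.seed(seed)
  types <- sample(c("continuous", "ordinal", "binary", "categorical"), p, replace = TRUE)
  z <- matrix(NA_real_, n, p)
  levels <- vector("list", p)
  for (j in seq_len(p)) {
    if (types[j] == "continuous") {
      z[, j] <- rnorm(n)
      levels[[j]] <- character(0)
    } else if (types[j] == "binary") {
      z[, j] <- sample(0:1, n, replace = TRUE)
      levels[[j]] <- c("n", "y")
    } else {
      q <- sample(3:5, 1)
      z[, j] <- sample(seq_len(q), n, replace = TRUE)
      levels[[j]] <- paste0("l", seq_len(q))
    }
  }
  colnames(z) <- paste0("V", seq_len(p))
  tab <- phenoimpute:::new_phenomic_table(z, types, levels)
  if (miss > 0) {
    hide <- sample(length(z), max(1, round(miss * length(z))))
    tab <- phenoimpute:::mask_cells(tab, arrayInd(hide, dim(z)))
  }
  tab
}

# an imputer that cheats by looking up the truth -- used to test STS soundness
make_oracle_imputer <- function(truth) {
  force(truth)
  function(x, seed = NULL) {
    z <- x$data
    z[is.na(z)] <- truth$data[is.na(z)]
    phenoimpute:::new_phenomic_table(z, x$types, x$levels)
  }
}

# write a table + spec to temp CSV/JSON; returns the two paths
write_fixture_csv <- function(df, spec, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  tp <- file.path(dir, "table.csv")
  sp <- file.path(dir, "spec.json")
  utils::write.csv(df, tp, row.names = FALSE, na = "NA")
  jsonlite::write_json(spec, sp, auto_unbox = TRUE)
  list(table = tp, spec = sp)
}
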