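#' Simulate block-correlated mixed-type phenomic data
#'
#' Three complete-data scenarios used to benchmark the imputers, emulating
#' the correlation structures of real phenomic tables (600 subjects x 300
#' variables at full scale):
#'
#' * **Scenario I** -- six variable clusters and six subject clusters.
#'   Cluster sizes are Poisson (mean 40 variables, mean 80 subjects). Each
#'   variable cluster shares a common basis `N(mu, 4)` with
#'   `mu ~ UNIF(-2, 2)`; its variables are linear transforms
#'   `alpha + beta * basis` (`alpha ~ UNIF(-1, 1)`, `beta ~ UNIF(0.5, 2)`,
#'   positive slopes preserving the within-cluster correlation). Remaining
#'   variables are independent `N(0, 4)`. Each subject cluster shares an
#'   additive basis `N(1, 2)` of length P; unclustered subjects get
#'   independent additive `N(0, 4)` vectors. Finally 100 variables are cut
#'   into nominal and 60 into ordinal variables with 3--6 levels at random
#'   quantile points.
#' * **Scenario II** -- as I but with twenty clusters of each kind (Poisson
#'   means 15 variables / 25 subjects).
#' * **Scenario III** -- no variable clusters, forty subject clusters
#'   (Poisson mean 14). Within a cluster all subjects share one base vector
#'   (entries `N(0, 4)`) plus `N(0, 0.01)` noise, giving strong
#'   between-subject but sparse between-variable correlation. 100 variables
#'   are cut into sparse nominals: cut points always include the extreme
#'   5% / 95% quantiles plus up to 27 more drawn from `UNIF(0.01, 0.99)`
#'   (up to 30 levels).
#'
#' `scale` multiplies N, P, the Poisson cluster-size means and the
#' discretization counts proportionally, for reduced desk-scale runs.
#'
#' @param scenario `"I"`, `"II"` or `"III"`.
#' @param n_subjects,n_variables full-scale dimensions.
#' @param seed RNG seed.
#' @param scale multiplier in (0, 1].
#' @param discretize set `FALSE` to keep all variables continuous.
#' @return a complete [phenomic_table] with extra fields `var_clusters` and
#'   `subj_clusters` (integer memberships, 0 = unclustered).
#' @export
simulate_phenomic <- function(scenario = c("I", "II", "III"),
                              n_subjects = 600, n_variables = 300,
                              seed = NULL, scale = 1, discretize = TRUE) {
  scenario <- match.arg(scenario)
  stopifnot(scale > 0, scale <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- round(n_subjects * scale)
  p <- round(n_variables * scale)
  if (n < 4 || p < 4) stop("scale too small: table would be degenerate")
  par <- switch(scenario,
    I   = list(kv = 6, vmean = 40, ks = 6, smean = 80, n_nom = 100, n_ord = 60),
    II  = list(kv = 20, vmean = 15, ks = 20, smean = 25, n_nom = 100, n_ord = 60),
    III = list(kv = 0, vmean = 0, ks = 40, smean = 14, n_nom = 100, n_ord = 0)
  )
  n_nom <- round(par$n_nom * scale)
  n_ord <- round(par$n_ord * scale)

  if (scenario %in% c("I", "II")) {
    x <- matrix(stats::rnorm(n * p, 0, 2), n, p)
    var_cl <- integer(p)
    vs <- cluster_sizes(par$kv, max(1, par$vmean * scale), p)
    pos <- 0
    for (ci in seq_along(vs)) {
      mu <- stats::runif(1, -2, 2)
      delta <- stats::rnorm(n, mu, 2)
      for (v in seq_len(vs[ci])) {
        alpha <- stats::runif(1, -1, 1)
        beta <- stats::runif(1, 0.5, 2)
        x[, pos + v] <- alpha + beta * delta
      }
      var_cl[pos + seq_len(vs[ci])] <- ci
      pos <- pos + vs[ci]
    }
    subj_cl <- integer(n)
    ss <- cluster_sizes(par$ks, max(1, par$smean * scale), n)
    pos <- 0
    for (ci in seq_along(ss)) {
      gamma <- stats::rnorm(p, 1, sqrt(2))
      rows <- pos + seq_len(ss[ci])
      x[rows, ] <- x[rows, , drop = FALSE] + rep(gamma, each = length(rows))
      subj_cl[rows] <- ci
      pos <- pos + ss[ci]
    }
    if (pos < n) {
      for (i in (pos + 1):n) x[i, ] <- x[i, ] + stats::rnorm(p, 0, 2)
    }
  } else {
    x <- matrix(0, n, p)
    subj_cl <- integer(n)
    var_cl <- integer(p)
    ss <- cluster_sizes(par$ks, max(1, par$smean * scale), n)
    pos <- 0
    for (ci in seq_along(ss)) {
      gamma <- stats::rnorm(p, 0, 2)
      rows <- pos + seq_len(ss[ci])
      for (i in rows) x[i, ] <- gamma + stats::rnorm(p, 0, 0.1)
      subj_cl[rows] <- ci
      pos <- pos + ss[ci]
    }
    if (pos < n) {
      for (i in (pos + 1):n) x[i, ] <- stats::rnorm(p, 0, 2)
    }
  }
  colnames(x) <- sprintf("V%03d", seq_len(p))
  rownames(x) <- sprintf("S%03d", seq_len(n))
  tab <- new_phenomic_table(x, rep("continuous", p), rep(list(character(0)), p))
  if (discretize && (n_nom + n_ord) > 0) {
    tab <- discretize_variables(tab, n_nominal = n_nom, n_ordinal = n_ord,
                                sparse = scenario == "III")
  }
  tab$var_clusters <- var_cl
  tab$subj_clusters <- subj_cl
  tab$scenario <- scenario
  tab
}

# Poisson cluster sizes (each forced >= 1), truncated in order if they
# overshoot the total; the remainder stays unclustered
cluster_sizes <- function(k, mean, total) {
  if (k < 1) return(integer(0))
  sizes <- stats::rpois(k, mean)
  sizes[sizes < 1] <- 1L
  cum <- cumsum(sizes)
  if (cum[k] > total) {
    keep <- which(cum <= total)
    sizes <- sizes[keep]
    used <- if (length(keep)) cum[length(keep)] else 0
    if (length(sizes) < k && total - used > 0) sizes <- c(sizes, total - used)
  }
  sizes[sizes > 0]
}

#' Discretize continuous variables into ordinal/nominal ones
#'
#' Randomly chosen continuous columns are cut at random quantile points into
#' 3--6 levels; ordinal columns keep the cut order, nominal columns get
#' their level labels randomly shuffled so the codes carry no order. With
#' `sparse = TRUE` the cuts mimic heavily skewed categoricals: the extreme
#' 5%/95% quantiles are always cut points and up to 27 further cut points
#' are drawn from `UNIF(0.01, 0.99)` (up to 30 levels).
#'
#' @param x a [phenomic_table].
#' @param n_nominal,n_ordinal how many columns to convert.
#' @param seed RNG seed.
#' @param sparse use the extreme-quantile sparse cutting instead of 3--6
#'   balanced levels (nominal only).
#' @return the table with converted columns (types and levels updated).
#' @export
discretize_variables <- function(x, n_nominal, n_ordinal, seed = NULL,
                                 sparse = FALSE) {
  stopifnot(inherits(x, "phenomic_table"))
  if (!is.null(seed)) set.seed(seed)
  con <- which(x$types == "continuous")
  if (n_nominal + n_ordinal > length(con)) {
    stop("more columns to discretize than continuous columns available")
  }
  if (n_nominal + n_ordinal == 0) return(x)
  chosen <- sample(con, n_nominal + n_ordinal)
  nom_cols <- chosen[seq_len(n_nominal)]
  ord_cols <- chosen[n_nominal + seq_len(n_ordinal)]
  z <- x$data
  types <- x$types
  levels <- x$levels
  cut_column <- function(col, probs) {
    cuts <- unique(stats::quantile(col, probs = probs, na.rm = TRUE, names = FALSE))
    codes <- findInterval(col, cuts) + 1L
    # relabel to consecutive codes in case cuts collapsed
    lv <- sort(unique(codes[!is.na(codes)]))
    match(codes, lv)
  }
  for (j in nom_cols) {
    probs <- if (sparse) {
      m <- sample(2:29, 1)
      sort(c(0.05, 0.95, stats::runif(m - 2, 0.01, 0.99)))
    } else {
      nl <- sample(3:6, 1)
      sort(stats::runif(nl - 1, 0.15, 0.85))
    }
    codes <- cut_column(z[, j], probs)
    nl <- max(codes, na.rm = TRUE)
    if (nl < 2) next
    perm <- sample(nl)           # shuffled labels: codes carry no order
    z[, j] <- perm[codes]
    if (nl == 2) {
      types[j] <- "binary"
      z[, j] <- z[, j] - 1
    } else {
      types[j] <- "categorical"
    }
    levels[[j]] <- paste0("l", seq_len(nl))
  }
  for (j in ord_cols) {
    nl <- sample(3:6, 1)
    probs <- sort(stats::runif(nl - 1, 0.15, 0.85))
    codes <- cut_column(z[, j], probs)
    nl <- max(codes, na.rm = TRUE)
    if (nl < 2) next
    z[, j] <- codes
    types[j] <- "ordinal"
    levels[[j]] <- paste0("l", seq_len(nl))
  }
  out <- new_phenomic_table(z, types, levels)
  out$var_clusters <- x$var_clusters
  out$subj_clusters <- x$subj_clusters
  out
}
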