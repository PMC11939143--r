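# Correlation structure of body metrics and body weight: Pearson matrices,
# age-quartile stratification, and Mantel permutation tests between the
# per-group correlation matrices.

#' Pearson correlation matrix over selected columns
#'
#' Pairwise Pearson correlations over complete rows. Zero-variance columns
#' get NA correlations (flagged with a warning), never a silent 0.
#'
#' @param table observation data.frame.
#' @param columns character vector of numeric column names (default: the
#'   five body metrics plus bw_lb, those present).
#' @return object of class `correlation_matrix`: list(labels, values, n).
#' @export
pearson_matrix <- function(table, columns = NULL) {
  if (is.null(columns))
    columns <- intersect(c("width_px", "length_px", "contour_area_px2",
                           "avg_height_mm", "volume_mm_px2", "bw_lb"),
                         names(table))
  missing <- setdiff(columns, names(table))
  if (length(missing))
    stop_validation("columns not in table: %s", paste(missing, collapse = ", "))
  x <- table[, columns, drop = FALSE]
  x <- x[complete.cases(x), , drop = FALSE]
  if (nrow(x) < 3) stop_validation("need >= 3 complete rows")
  zerovar <- vapply(x, function(v) stats::var(v) == 0, logical(1))
  if (any(zerovar))
    warning("zero-variance column(s), correlations undefined: ",
            paste(columns[zerovar], collapse = ", "))
  vals <- suppressWarnings(cor(as.matrix(x), method = "pearson"))
  structure(list(labels = columns, values = vals, n = nrow(x)),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("correlation_matrix over %d rows:\n", x$n))
  print(round(x$values, 3))
  invisible(x)
}

#' Split an observation table into quartile groups
#'
#' Nearest-rank quartiles of the `by` column: cut points are the values at
#' ranks ceiling(n/4), ceiling(n/2), ceiling(3n/4); ties go to the lower
#' group. Groups are labelled with their value ranges.
#'
#' @param table observation data.frame.
#' @param by numeric column to stratify on (default `"age_days"`).
#' @return named list of four data.frames; names give the value ranges.
#' @export
quartile_groups <- function(table, by = "age_days") {
  v <- table[[by]]
  if (is.null(v) || !is.numeric(v)) stop_validation("column '%s' must be numeric", by)
  n <- length(v)
  if (n < 8) stop_validation("need >= 8 rows to form quartiles")
  s <- sort(v)
  cuts <- s[ceiling(n * c(1, 2, 3) / 4)]
  if (length(unique(c(cuts, max(v)))) < 4)
    stop_validation("degenerate quartiles: '%s' has too few distinct values", by)
  grp <- findInterval(v, c(-Inf, cuts), left.open = TRUE)  # v <= cut -> lower
  out <- lapply(1:4, function(g) table[grp == g, , drop = FALSE])
  lo <- c(min(v), cuts[1:3])
  hi <- c(cuts[1:3], max(v))
  names(out) <- sprintf("%g-%g", vapply(1:4, function(g)
    if (nrow(out[[g]])) min(out[[g]][[by]]) else lo[g], numeric(1)),
    vapply(1:4, function(g)
      if (nrow(out[[g]])) max(out[[g]][[by]]) else hi[g], numeric(1)))
  out
}

#' Mantel test between two correlation matrices
#'
#' Statistic: Pearson correlation of the upper-triangle (off-diagonal)
#' entries. Significance: one-sided permutation test, simultaneously
#' permuting rows and columns of the second matrix;
#' `p = (1 + #\{r_perm >= r_obs\}) / (1 + n_perm)`. With the default 999
#' permutations the smallest attainable p is 0.001.
#'
#' @param m1,m2 `correlation_matrix` objects (or plain symmetric matrices
#'   with identical dimnames) over the same labels in the same order.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @return list(r, p, n_perm).
#' @export
mantel_test <- function(m1, m2, n_perm = 999, seed = 1) {
  get_vals <- function(m) if (inherits(m, "correlation_matrix")) m$values else m
  get_labs <- function(m) if (inherits(m, "correlation_matrix")) m$labels
                          else rownames(m)
  v1 <- get_vals(m1); v2 <- get_vals(m2)
  l1 <- get_labs(m1); l2 <- get_labs(m2)
  if (!identical(dim(v1), dim(v2)) ||
      (!is.null(l1) && !is.null(l2) && !identical(l1, l2)))
    stop_validation("matrices must share labels and order")
  if (n_perm < 99) stop_validation("n_perm must be >= 99")
  ut <- upper.tri(v1)
  r_obs <- cor(v1[ut], v2[ut])
  k <- nrow(v1)
  with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      pp <- sample(k)
      r_perm <- cor(v1[ut], v2[pp, pp][ut])
      if (r_perm >= r_obs) hits <- hits + 1L
    }
    list(r = r_obs, p = (1 + hits) / (1 + n_perm), n_perm = n_perm)
  })
}

#' Correlation matrices per age quartile plus pairwise Mantel tests
#'
#' The standard age-stratified analysis: split on age quartiles, compute
#' the Pearson matrix of metrics and BW within each group, and test every
#' pair of groups for similarity of correlation structure with a Mantel
#' test.
#'
#' @param table observation table (per-calf-date medians).
#' @param columns columns for [pearson_matrix()].
#' @param n_perm,seed Mantel settings.
#' @return list(groups, matrices, mantel) where `mantel` is a data.frame of
#'   pairwise (r, p).
#' @export
age_quartile_correlations <- function(table, columns = NULL, n_perm = 999,
                                      seed = 1) {
  groups <- quartile_groups(table, "age_days")
  mats <- lapply(groups, pearson_matrix, columns = columns)
  pairs <- utils::combn(names(groups), 2)
  mt <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    res <- mantel_test(mats[[a]], mats[[b]], n_perm = n_perm,
                       seed = child_seed(seed, i))
    data.frame(group1 = a, group2 = b, r = res$r, p = res$p,
               stringsAsFactors = FALSE)
  }))
  list(groups = groups, matrices = mats, mantel = mt)
}
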