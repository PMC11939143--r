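test_that("Pearson matrices match hand formulas and flag degenerate columns", {
  tab <- data.frame(x = c(1, 2, 3), y = c(2, 4, 6), z = c(1, 3, 2))
  m <- pearson_matrix(tab, c("x", "y", "z"))
  expect_equal(m$values["x", "y"], 1)
  expect_equal(m$values["x", "z"], 0.5)
  expect_equal(m$n, 3)
  expect_true(isSymmetric(m$values))
  expect_equal(unname(diag(m$values)), rep(1, 3))

  tab$neg <- -tab$x
  expect_equal(pearson_matrix(tab, c("x", "neg"))$values["x", "neg"], -1)

  tab$flat <- 5
  expect_warning(mz <- pearson_matrix(tab, c("x", "flat")), "zero-variance")
  expect_true(is.na(mz$values["x", "flat"]))

  expect_error(pearson_matrix(tab[1:2, ], c("x", "y")), ">= 3")
  expect_error(pearson_matrix(tab, c("x", "nope")), "nope")
})

test_that("Pearson matrices are invariant to positive affine rescaling", {
  set.seed(3)
  tab <- data.frame(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  m1 <- pearson_matrix(tab, c("a", "b", "c"))
  tab$a <- 100 + 7 * tab$a
  tab$c <- 3 * tab$c - 2
  m2 <- pearson_matrix(tab, c("a", "b", "c"))
  expect_equal(m1$values, m2$values, tolerance = 1e-12)
})

test_that("quartile groups follow the nearest-rank convention", {
  tab <- data.frame(age_days = 1:8)
  g <- quartile_groups(tab)
  expect_equal(lapply(unname(g), function(x) x$age_days),
               list(c(1, 2), c(3, 4), c(5, 6), c(7, 8)))

  expect_error(quartile_groups(data.frame(age_days = rep(5, 20))),
               "degenerate")
  expect_error(quartile_groups(data.frame(age_days = 1:7)), ">= 8")

  herd <- simulate_growth(seed = 21)
  med <- aggregate_median(transform(herd, frame_id = seq_len(nrow(herd))))
  med$age_days <- herd$age_days[match(paste(med$calf_id, med$date),
                                      paste(herd$calf_id, herd$date))]
  gr <- quartile_groups(med)
  expect_equal(length(gr), 4)
  expect_true(all(vapply(gr, nrow, integer(1)) > 0))
  # groups tile the age range in order
  maxs <- vapply(gr, function(x) max(x$age_days), numeric(1))
  mins <- vapply(gr, function(x) min(x$age_days), numeric(1))
  expect_true(all(maxs[-4] < mins[-1]))
})

test_that("Mantel test: identity, p bounds, label checks, oracle agreement", {
  set.seed(10)
  x <- matrix(rnorm(60), 10, 6)
  colnames(x) <- letters[1:6]
  m1 <- pearson_matrix(as.data.frame(x), letters[1:6])
  res <- mantel_test(m1, m1, n_perm = 199, seed = 1)
  expect_equal(res$r, 1)
  expect_gte(res$p, 1 / 200)
  expect_lte(res$p, 1)

  y <- matrix(rnorm(60), 10, 6); colnames(y) <- letters[1:6]
  m2 <- pearson_matrix(as.data.frame(y), letters[1:6])
  res2 <- mantel_test(m1, m2, n_perm = 999, seed = 2)
  expect_gte(res2$p, 0.001)

  m3 <- pearson_matrix(as.data.frame(y[, 1:5]), letters[1:5])
  expect_error(mantel_test(m1, m3), "labels")
  expect_error(mantel_test(m1, m2, n_perm = 10), "99")

  skip_if_not_installed("vegan")
  vg <- vegan::mantel(as.dist(1 - m1$values), as.dist(1 - m2$values),
                      permutations = 99)
  # statistic agreement: ours correlates correlation entries, vegan the
  # corresponding distances (1 - r), so the r values match exactly
  expect_equal(res2$r, unname(vg$statistic), tolerance = 1e-12)
})

test_that("Mantel r is invariant to simultaneous relabeling", {
  set.seed(11)
  x <- matrix(rnorm(80), 16, 5); colnames(x) <- letters[1:5]
  y <- matrix(rnorm(80), 16, 5); colnames(y) <- letters[1:5]
  m1 <- pearson_matrix(as.data.frame(x), letters[1:5])
  m2 <- pearson_matrix(as.data.frame(y), letters[1:5])
  r0 <- mantel_test(m1, m2, n_perm = 99, seed = 1)$r
  perm <- c(3, 1, 5, 2, 4)
  relabel <- function(m, p) {
    list(labels = m$labels[p],
         values = m$values[p, p], n = m$n) |>
      structure(class = "correlation_matrix")
  }
  r1 <- mantel_test(relabel(m1, perm), relabel(m2, perm),
                    n_perm = 99, seed = 1)$r
  expect_equal(r1, r0, tolerance = 1e-12)
})

test_that("Mantel p is approximately uniform under the null", {
  set.seed(12)
  ps <- replicate(60, {
    x <- matrix(rnorm(72), 12, 6); colnames(x) <- letters[1:6]
    y <- matrix(rnorm(72), 12, 6); colnames(y) <- letters[1:6]
    mantel_test(pearson_matrix(as.data.frame(x), letters[1:6]),
                pearson_matrix(as.data.frame(y), letters[1:6]),
                n_perm = 99, seed = sample.int(1e6, 1))$p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("age-quartile analysis yields four matrices and pairwise Mantel rows", {
  herd <- simulate_growth(n_calves = 30, seed = 14)
  out <- age_quartile_correlations(herd, n_perm = 99, seed = 4)
  expect_equal(length(out$matrices), 4)
  expect_equal(nrow(out$mantel), 6)
  expect_true(all(out$mantel$p >= 0.01 & out$mantel$p <= 1))
  # strong shared metric-BW structure -> high Mantel r between age groups
  expect_true(all(out$mantel$r > 0.5))
})
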