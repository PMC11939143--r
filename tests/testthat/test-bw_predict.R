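test_that("grouped folds partition calves evenly with no leakage", {
  ids <- rep(sprintf("c%02d", 1:20), each = 8)
  folds <- grouped_kfold(ids, k = 5, seed = 3)
  expect_equal(length(folds), 5)
  for (fd in folds) {
    expect_equal(length(fd$test_calves), 4)
    expect_equal(length(fd$train_calves), 16)
    expect_equal(length(intersect(fd$train_calves, fd$test_calves)), 0)
  }
  all_test <- unlist(lapply(folds, `[[`, "test_calves"))
  expect_setequal(all_test, unique(ids))
  expect_equal(anyDuplicated(all_test), 0)

  expect_error(grouped_kfold(ids, k = 1), "k must")
  expect_error(grouped_kfold(ids, k = 21), "k must")
})

test_that("regression metrics match hand computation", {
  m <- regression_metrics(c(100, 150), c(110, 140))
  expect_equal(unname(m["mse"]), 100)
  expect_equal(unname(m["rmse"]), 10)
  expect_equal(unname(m["mae"]), 10)
  expect_equal(unname(m["mape"]), (10 / 100 + 10 / 150) / 2 * 100)

  y <- c(90, 110, 130, 150)
  perfect <- regression_metrics(y, y)
  expect_equal(unname(perfect), c(1, 0, 0, 0, 0))
  expect_equal(unname(regression_metrics(y, rep(mean(y), 4))["r2"]), 0)
  expect_error(regression_metrics(c(0, 1), c(1, 1)), "MAPE")
  expect_error(regression_metrics(1, 1), "length")
})

test_that("rmse^2 equals mse for arbitrary inputs", {
  set.seed(4)
  for (i in 1:20) {
    y <- runif(15, 80, 220); yh <- y + rnorm(15, 0, 10)
    m <- regression_metrics(y, yh)
    expect_equal(unname(m["rmse"]^2), unname(m["mse"]), tolerance = 1e-12)
  }
})

make_linear_table <- function(n = 40, noise = 0, seed = 9) {
  set.seed(seed)
  tab <- data.frame(calf_id = rep_len(sprintf("c%02d", 1:10), n),
                    date = as.character(seq_len(n)),
                    age_days = sample(21:69, n, TRUE),
                    length_px = runif(n, 600, 900),
                    width_px = runif(n, 350, 550),
                    avg_height_mm = runif(n, 250, 450),
                    volume_mm_px2 = runif(n, 3e7, 6e7),
                    contour_area_px2 = runif(n, 9e4, 1.9e5))
  tab$bw_lb <- 30 + 1.2 * tab$age_days + 0.05 * tab$width_px +
    0.02 * tab$length_px + 0.1 * tab$avg_height_mm +
    4e-7 * tab$volume_mm_px2 + 1e-4 * tab$contour_area_px2 +
    rnorm(n, 0, noise)
  tab
}

test_that("OLS fit matches the normal-equation oracle and its invariances", {
  tab <- make_linear_table(n = 10, noise = 2)
  pred <- fit_linear(tab)
  X <- cbind(1, as.matrix(tab[, feature_spec()]))
  # normal equations, column-scaled for conditioning: beta = (X'X)^-1 X'y
  s <- sqrt(colSums(X^2))
  Xs <- sweep(X, 2, s, "/")
  beta <- solve(t(Xs) %*% Xs, t(Xs) %*% tab$bw_lb) / s
  expect_equal(unname(coef(attr(pred, "fit"))), c(beta), tolerance = 1e-6)

  # noiseless data: zero training residuals
  tab0 <- make_linear_table(noise = 0)
  p0 <- fit_linear(tab0)
  expect_lt(max(abs(p0(tab0) - tab0$bw_lb)), 1e-8)

  # adding a constant shifts the intercept only
  tab_c <- tab0; tab_c$bw_lb <- tab_c$bw_lb + 50
  f0 <- coef(attr(fit_linear(tab0), "fit"))
  f1 <- coef(attr(fit_linear(tab_c), "fit"))
  expect_equal(unname(f1[1] - f0[1]), 50, tolerance = 1e-8)
  expect_equal(f1[-1], f0[-1], tolerance = 1e-8)

  # rank deficiency is an error
  tab_r <- tab0; tab_r$volume_mm_px2 <- 2 * tab_r$contour_area_px2
  expect_error(fit_linear(tab_r), "rank")
})

test_that("randomized-search boosting is seeded and beats the mean baseline", {
  tab <- make_linear_table(n = 60, noise = 5)
  sp <- search_space(n_estimators = c(50, 150), n_iterations = 4)
  p1 <- fit_gbt(tab, space = sp, seed = 11)
  p2 <- fit_gbt(tab, space = sp, seed = 11)
  expect_equal(attr(p1, "pars"), attr(p2, "pars"))
  expect_equal(p1(tab), p2(tab))

  rmse_fit <- sqrt(mean((tab$bw_lb - p1(tab))^2))
  rmse_mean <- sqrt(mean((tab$bw_lb - mean(tab$bw_lb))^2))
  expect_lt(rmse_fit, rmse_mean)

  const <- tab; const$bw_lb <- 100
  expect_error(fit_gbt(const, space = sp), "constant")
  expect_error(fit_gbt(tab[1:5, ], space = sp), ">= 10")
})

test_that("boosting outperforms the linear model on a nonlinear response", {
  set.seed(15)
  tab <- make_linear_table(n = 160, noise = 0)
  tab$bw_lb <- 100 + 0.004 * (tab$age_days - 45)^3 +
    30 * sin(tab$width_px / 40)
  tr <- tab[1:120, ]; te <- tab[121:160, ]
  lin <- fit_linear(tr)
  gbt <- fit_gbt(tr, space = search_space(n_estimators = c(100, 300),
                                          n_iterations = 6), seed = 2)
  rmse <- function(p) sqrt(mean((te$bw_lb - p(te))^2))
  expect_lt(rmse(gbt), rmse(lin))
})

test_that("repeated grouped CV pools folds and reports per-repetition metrics", {
  herd <- simulate_growth(seed = 18)
  cv <- repeat_cv(herd, models = list(linear = function(tr) fit_linear(tr)),
                  k = 5, n_rep = 3, seed = 6)
  expect_equal(nrow(cv$per_rep), 3)
  expect_true(all(cv$per_rep$rmse^2 - cv$per_rep$mse < 1e-10))
  # strong linear signal in the default herd
  expect_gt(cv$summary$r2_mean, 0.7)

  # identical model under two names: no between-model variance
  same <- list(a = function(tr) fit_linear(tr),
               b = function(tr) fit_linear(tr))
  cv2 <- repeat_cv(herd, models = same, k = 5, n_rep = 2, seed = 6)
  expect_equal(cv2$anova$eta_sq, rep(0, 5), tolerance = 1e-20)
})

test_that("near-noiseless herds push linear-model test R2 toward 1", {
  links <- growth_model_params()$metric_links
  for (nm in names(links)) links[[nm]][3] <- 0.999
  p <- growth_model_params(sd_intercept_lb = 0.01, sd_slope = 0.001,
                           sd_resid_lb = 0.01, metric_links = links)
  herd <- simulate_growth(p, seed = 19)
  cv <- repeat_cv(herd, models = list(linear = function(tr) fit_linear(tr)),
                  k = 5, n_rep = 2, seed = 2)
  expect_gt(cv$summary$r2_mean, 0.999)
})
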