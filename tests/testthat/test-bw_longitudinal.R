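make_series <- function(n_calves = 4, visits = 10) {
  simulate_growth(n_calves = n_calves, visits_per_calf = visits, seed = 44)
}

test_that("time-forward splits follow the floor rule and keep time order", {
  one_calf <- function(n) {
    data.frame(calf_id = "c1", date = as.character(1:n), age_days = seq_len(n),
               bw_lb = 100 + seq_len(n))
  }
  sp <- time_forward_split(one_calf(10), split_spec(0.9))
  expect_equal(nrow(sp$train), 9)
  expect_equal(nrow(sp$test), 1)

  sp2 <- time_forward_split(one_calf(9), split_spec(0.5))
  expect_equal(nrow(sp2$train), 4)   # floor(0.5 * 9)
  expect_equal(nrow(sp2$test), 5)

  # a calf below the longitudinal minimum is excluded with a warning
  tab <- rbind(one_calf(10),
               transform(one_calf(4), calf_id = "c2"))
  expect_warning(sp3 <- time_forward_split(tab, split_spec(0.5)), "c2")
  expect_false("c2" %in% c(sp3$train$calf_id, sp3$test$calf_id))

  # train fraction high enough to take all: clamped to n-1
  sp4 <- time_forward_split(one_calf(5), split_spec(0.99))
  expect_equal(nrow(sp4$train), 4)
  expect_equal(nrow(sp4$test), 1)
})

test_that("temporal integrity holds across splits and seeds", {
  herd <- make_series(n_calves = 8)
  for (tf in c(0.9, 0.8, 0.7, 0.6, 0.5)) {
    sp <- time_forward_split(herd, split_spec(tf))
    for (id in unique(sp$test$calf_id)) {
      expect_lt(max(sp$train$age_days[sp$train$calf_id == id]),
                min(sp$test$age_days[sp$test$calf_id == id]))
    }
  }
})

test_that("random timepoint removal is uniform, seeded, and validated", {
  herd <- make_series()
  n <- nrow(herd)
  d1 <- drop_random_timepoint(herd, seed = 9)
  d2 <- drop_random_timepoint(herd, seed = 9)
  expect_equal(nrow(d1), n - 1)
  expect_identical(d1, d2)

  # approximate uniformity over eligible rows
  counts <- table(vapply(1:400, function(s) {
    d <- drop_random_timepoint(herd, seed = s)
    setdiff(paste(herd$calf_id, herd$date), paste(d$calf_id, d$date))
  }, character(1)))
  eligible <- sum(table(herd$calf_id) > 5)
  expect_gt(length(counts), 0.5 * nrow(herd))
  chi <- suppressWarnings(stats::chisq.test(counts))
  expect_gt(chi$p.value, 0.001)

  few <- herd[herd$age_days < 30, ]
  expect_error(drop_random_timepoint(few, min_obs = 10), "more than")
})

test_that("mixed model recovers known parameters on simulated herds", {
  tab <- simulate_lmm_table(n_calves = 50, visits_per_calf = 10,
                            sd_intercept_lb = 10, sd_resid_lb = 3, seed = 5)
  fit <- fit_lmm(tab)
  beta <- attr(tab, "beta")
  expect_lt(abs(fit$fixed[["age_days"]] - beta[["age_days"]]) /
              beta[["age_days"]], 0.1)
  expect_lt(abs(sqrt(fit$var_intercept) - 10) / 10, 0.3)
  expect_lt(abs(sqrt(fit$var_resid) - 3) / 3, 0.3)
})

test_that("mixed-model predictions use calf intercepts for known calves", {
  tab <- simulate_lmm_table(n_calves = 20, sd_intercept_lb = 15,
                            sd_resid_lb = 2, seed = 6)
  fit <- fit_lmm(tab)
  with_re <- predict(fit, tab, use_ranef = TRUE)
  without <- predict(fit, tab, use_ranef = FALSE)
  expect_gt(max(abs(with_re - without)), 1)
  # the gap per calf equals its predicted random intercept
  gaps <- tapply(with_re - without, tab$calf_id, mean)
  expect_equal(as.numeric(gaps[names(fit$ranef)]), as.numeric(fit$ranef),
               tolerance = 1e-6)

  # unseen calves fall back to fixed effects
  new <- tab[1:3, ]; new$calf_id <- "stranger"
  expect_equal(predict(fit, new),
               predict(fit, new, use_ranef = FALSE))
})

test_that("zero between-calf variance collapses the LMM toward OLS", {
  tab <- simulate_lmm_table(n_calves = 30, sd_intercept_lb = 0,
                            sd_resid_lb = 3, seed = 7)
  expect_warning(fit <- fit_lmm(tab), "singular")
  expect_lt(fit$var_intercept, 0.5)
  ols <- coef(attr(fit_linear(tab), "fit"))
  expect_equal(unname(fit$fixed), unname(ols), tolerance = 0.02)
})

test_that("forecasting experiment preserves time order and ranks LMM first", {
  herd <- simulate_growth(growth_model_params(sd_intercept_lb = 20,
                                              sd_resid_lb = 2),
                          n_calves = 12, seed = 77)
  fc <- run_forecast(herd,
                     models = list(
                       linear = function(tr) fit_linear(tr),
                       lmm = function(tr) {
                         f <- suppressWarnings(fit_lmm(tr))
                         function(nd) predict(f, nd)
                       }),
                     train_fractions = c(0.9, 0.5), n_iter = 4, seed = 5)
  expect_named(fc, c("90:10", "50:50"))
  s <- fc[["50:50"]]$summary
  expect_gt(s$r2_mean[s$model == "lmm"], s$r2_mean[s$model == "linear"])
  # shrinking the train fraction shrinks every calf's training series
  expect_lte(mean(fc[["50:50"]]$per_rep$r2), 1)

  # identical predictors across model slots -> effect size 0
  same <- run_forecast(herd,
                       models = list(a = function(tr) fit_linear(tr),
                                     b = function(tr) fit_linear(tr)),
                       train_fractions = 0.5, n_iter = 2, seed = 5)
  expect_equal(same[["50:50"]]$anova$eta_sq, rep(0, 5), tolerance = 1e-20)
})
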