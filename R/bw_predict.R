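# Single-time-point body-weight prediction: calf-grouped k-fold
# cross-validation repeated with reshuffled folds; linear model and
# gradient-boosted trees with randomized hyperparameter search; R2, MSE,
# RMSE, MAE, MAPE; ANOVA comparison between models.

#' The fixed feature set for body-weight models
#'
#' Six predictors (age plus the five body metrics) and the response bw_lb.
#'
#' @return character vector of predictor names with attribute `response`.
#' @export
feature_spec <- function() {
  structure(c("age_days", "length_px", "width_px", "avg_height_mm",
              "volume_mm_px2", "contour_area_px2"),
            response = "bw_lb")
}

check_features <- function(table, spec = feature_spec()) {
  cols <- c(spec, attr(spec, "response"))
  missing <- setdiff(cols, names(table))
  if (length(missing))
    stop_validation("table lacks modeling column(s): %s",
                    paste(missing, collapse = ", "))
  if (anyNA(table[, cols]))
    stop_validation("modeling rows must have no missing values")
  invisible(table)
}

#' Randomized-search space for the gradient-boosted-tree model
#'
#' Hyperparameters are sampled uniformly: learning rate in \[0.01, 0.9\],
#' number of trees in \[50, 10000\], L1/L2 regularization each in \[0, 1\].
#' The full protocol draws 1000 candidate configurations; the desk profile
#' ([desk_search_space()]) shrinks the search so the repeated experiments
#' run on a single workstation core.
#'
#' @param learning_rate,n_estimators,reg_alpha,reg_lambda (lo, hi) bounds.
#' @param n_iterations number of sampled configurations (>= 1).
#' @return object of class `search_space`.
#' @export
search_space <- function(learning_rate = c(0.01, 0.9),
                         n_estimators = c(50, 10000),
                         reg_alpha = c(0, 1), reg_lambda = c(0, 1),
                         n_iterations = 1000) {
  if (n_iterations < 1) stop_validation("n_iterations must be >= 1")
  structure(list(learning_rate = learning_rate, n_estimators = n_estimators,
                 reg_alpha = reg_alpha, reg_lambda = reg_lambda,
                 n_iterations = n_iterations),
            class = "search_space")
}

#' Desk-profile search space
#'
#' A reduced randomized search (10 candidates, at most 300 trees) for
#' repeated experiments on one core; see the methods vignette for the
#' rationale.
#'
#' @export
desk_search_space <- function() {
  search_space(n_estimators = c(50, 300), n_iterations = 10)
}

#' Partition calves into k disjoint folds
#'
#' Fold assignment is at the calf level, so no animal can contribute
#' frames to both train and test. Folds are as even as possible.
#'
#' @param calf_ids vector of calf identifiers (duplicates allowed; folds
#'   are over unique calves).
#' @param k number of folds (2 <= k <= number of distinct calves).
#' @param seed integer seed.
#' @return list of k elements, each `list(train_calves, test_calves)`.
#' @export
grouped_kfold <- function(calf_ids, k = 5, seed = 1) {
  calves <- unique(as.character(calf_ids))
  if (!is_count(k) || k < 2 || k > length(calves))
    stop_validation("k must satisfy 2 <= k <= number of distinct calves (%d)",
                    length(calves))
  with_seed(seed, {
    shuffled <- sample(calves)
    fold <- rep(seq_len(k), length.out = length(calves))
    lapply(seq_len(k), function(i)
      list(train_calves = shuffled[fold != i],
           test_calves = shuffled[fold == i]))
  })
}

#' Regression performance metrics
#'
#' R2 uses the test-set mean as baseline: `1 - SS_res / SS_tot`. MAPE is in
#' percent. Requires strictly positive observed values (for MAPE).
#'
#' @param y observed response (lb).
#' @param yhat predictions (lb).
#' @return named numeric: r2, mse, rmse, mae, mape.
#' @export
regression_metrics <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 2)
    stop_validation("y and yhat must have equal length >= 2")
  if (any(y == 0)) stop_validation("zero response value: MAPE undefined")
  res <- y - yhat
  c(r2 = 1 - sum(res^2) / sum((y - mean(y))^2),
    mse = mean(res^2),
    rmse = sqrt(mean(res^2)),
    mae = mean(abs(res)),
    mape = 100 * mean(abs(res) / abs(y)))
}

#' Fit the ordinary least-squares body-weight model
#'
#' BW on the six predictors plus intercept. Returns a predictor closure.
#'
#' @param train training observation table.
#' @param spec [feature_spec()].
#' @return function(table) -> numeric predictions, with the `lm` fit as
#'   attribute `fit`.
#' @export
fit_linear <- function(train, spec = feature_spec()) {
  check_features(train, spec)
  if (nrow(train) < length(spec) + 2)
    stop_validation("too few rows to fit the linear model")
  f <- as.formula(paste(attr(spec, "response"), "~",
                        paste(spec, collapse = " + ")))
  fit <- lm(f, data = train)
  if (anyNA(coef(fit))) stop_validation("rank-deficient design matrix")
  structure(function(table) unname(predict(fit, newdata = table)), fit = fit)
}

xgb_matrix <- function(table, spec) {
  xgboost::xgb.DMatrix(data = as.matrix(table[, spec, drop = FALSE]),
                       label = table[[attr(spec, "response")]])
}

fit_xgb_one <- function(train, spec, pars) {
  dtrain <- xgb_matrix(train, spec)
  xgboost::xgb.train(
    params = list(objective = "reg:squarederror", eta = pars$learning_rate,
                  alpha = pars$reg_alpha, lambda = pars$reg_lambda,
                  nthread = 1),
    data = dtrain, nrounds = pars$n_estimators, verbose = 0)
}

#' Fit gradient-boosted trees with randomized hyperparameter search
#'
#' Samples `n_iterations` configurations uniformly from the search space,
#' scores each by 3-fold cross-validated RMSE *within the training data*
#' (so model selection never sees the test set), refits the best
#' configuration on the full training table. Deterministic given the seed.
#'
#' @param train training observation table (>= 10 rows, non-constant
#'   response).
#' @param spec [feature_spec()].
#' @param space [search_space()].
#' @param seed integer seed.
#' @param inner_folds folds for the inner selection CV.
#' @return function(table) -> predictions, with attributes `fit` (the
#'   xgboost booster) and `pars` (the selected configuration).
#' @export
fit_gbt <- function(train, spec = feature_spec(), space = desk_search_space(),
                    seed = 1, inner_folds = 3) {
  check_features(train, spec)
  if (nrow(train) < 10) stop_validation("fit_gbt needs >= 10 training rows")
  y <- train[[attr(spec, "response")]]
  if (stats::var(y) == 0) stop_validation("constant training response")
  with_seed(seed, {
    cand <- data.frame(
      learning_rate = runif(space$n_iterations, space$learning_rate[1],
                            space$learning_rate[2]),
      n_estimators = sample(space$n_estimators[1]:space$n_estimators[2],
                            space$n_iterations, replace = TRUE),
      reg_alpha = runif(space$n_iterations, space$reg_alpha[1], space$reg_alpha[2]),
      reg_lambda = runif(space$n_iterations, space$reg_lambda[1],
                         space$reg_lambda[2]))
    fold <- sample(rep(seq_len(inner_folds), length.out = nrow(train)))
    rmse <- vapply(seq_len(space$n_iterations), function(i) {
      pars <- cand[i, ]
      errs <- vapply(seq_len(inner_folds), function(f) {
        tr <- train[fold != f, , drop = FALSE]
        te <- train[fold == f, , drop = FALSE]
        if (nrow(te) == 0 || nrow(tr) < 2) return(NA_real_)
        booster <- fit_xgb_one(tr, spec, pars)
        pred <- predict(booster, as.matrix(te[, spec, drop = FALSE]))
        sqrt(mean((te[[attr(spec, "response")]] - pred)^2))
      }, numeric(1))
      mean(errs, na.rm = TRUE)
    }, numeric(1))
    best <- cand[which.min(rmse), ]
    booster <- fit_xgb_one(train, spec, best)
    structure(function(table)
      predict(booster, as.matrix(table[, spec, drop = FALSE])),
      fit = booster, pars = best)
  })
}

#' Repeated calf-grouped cross-validation
#'
#' Each repetition reshuffles calves into k folds, fits every model on each
#' training split and predicts its test split; test predictions are pooled
#' over the k folds before computing metrics (one value per metric per
#' model per repetition). Reports mean and SD over repetitions plus a
#' one-way ANOVA between models per metric.
#'
#' @param table observation table with the modeling columns.
#' @param models named list of fitting functions `function(train) ->
#'   predictor`; default linear + gbt (desk profile).
#' @param k folds (5 in the reference protocol).
#' @param n_rep repetitions (100 in the reference protocol).
#' @param seed master seed; repetition seeds are derived by counter.
#' @return object of class `cv_report`: `per_rep` (long data.frame),
#'   `summary` (mean/sd per model x metric), `anova` (p and eta squared per
#'   metric).
#' @export
repeat_cv <- function(table, models = NULL, k = 5, n_rep = 100, seed = 1) {
  check_features(table)
  if (is.null(models))
    models <- list(
      linear = function(train) fit_linear(train),
      gbt = function(train) fit_gbt(train, space = desk_search_space(),
                                    seed = child_seed(seed, 777)))
  per_rep <- list()
  for (rep_i in seq_len(n_rep)) {
    folds <- grouped_kfold(table$calf_id, k = k,
                           seed = child_seed(seed, rep_i))
    for (mn in names(models)) {
      y_all <- numeric(0); yhat_all <- numeric(0)
      for (fd in folds) {
        tr <- table[table$calf_id %in% fd$train_calves, , drop = FALSE]
        te <- table[table$calf_id %in% fd$test_calves, , drop = FALSE]
        stopifnot(length(intersect(tr$calf_id, te$calf_id)) == 0)
        pred <- models[[mn]](tr)
        y_all <- c(y_all, te$bw_lb)
        yhat_all <- c(yhat_all, pred(te))
      }
      m <- regression_metrics(y_all, yhat_all)
      per_rep[[length(per_rep) + 1]] <-
        data.frame(rep = rep_i, model = mn, t(m), stringsAsFactors = FALSE)
    }
  }
  per_rep <- do.call(rbind, per_rep)
  summarize_model_metrics(per_rep)
}

# shared summary/ANOVA over a long per-iteration metric table
summarize_model_metrics <- function(per_rep, family_size = NULL) {
  metrics <- c("r2", "mse", "rmse", "mae", "mape")
  summary <- do.call(rbind, lapply(split(per_rep, per_rep$model), function(g) {
    row <- data.frame(model = g$model[1], n_rep = nrow(g),
                      stringsAsFactors = FALSE)
    for (m in metrics) {
      row[[paste0(m, "_mean")]] <- mean(g[[m]])
      row[[paste0(m, "_sd")]] <- sd(g[[m]])
    }
    row
  }))
  rownames(summary) <- NULL
  if (is.null(family_size)) family_size <- length(unique(per_rep$model))
  anova_tab <- do.call(rbind, lapply(metrics, function(m) {
    if (length(unique(per_rep$model)) < 2 || stats::var(per_rep[[m]]) == 0)
      return(data.frame(metric = m, f = NA_real_, p = NA_real_,
                        p_adjusted = NA_real_, eta_sq = 0,
                        stringsAsFactors = FALSE))
    fit <- aov(per_rep[[m]] ~ factor(model), data = per_rep)
    at <- anova(fit)
    data.frame(metric = m, f = at[["F value"]][1], p = at[["Pr(>F)"]][1],
               p_adjusted = min(1, at[["Pr(>F)"]][1] * family_size),
               eta_sq = eta_squared(fit), stringsAsFactors = FALSE)
  }))
  structure(list(per_rep = per_rep, summary = summary, anova = anova_tab,
                 family_size = family_size),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Repeated grouped CV report\n")
  print(x$summary, row.names = FALSE, digits = 4)
  print(x$anova, row.names = FALSE, digits = 4)
  invisible(x)
}
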