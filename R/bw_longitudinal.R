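# Multiple-time-point forecasting: per-calf time-forward splits, simulated
# missing timepoints, three models (linear, gradient-boosted trees,
# random-intercept linear mixed model), repeated evaluation with
# ANOVA/Tukey/eta-squared comparisons per train fraction.

#' Time-forward split specification
#'
#' @param train_fraction fraction of each calf's chronologically ordered
#'   observations used for training; reference protocol uses 0.9, 0.8,
#'   0.7, 0.6, 0.5.
#' @param min_obs_per_calf calves with fewer observations are dropped (with
#'   a warning) before splitting.
#' @return object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.5, min_obs_per_calf = 5) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_validation("train_fraction must be in (0, 1)")
  structure(list(train_fraction = train_fraction,
                 min_obs_per_calf = min_obs_per_calf),
            class = "split_spec")
}

#' Chronological per-calf train/test split
#'
#' Per calf, observations are sorted by age and the first
#' `floor(train_fraction * n)` (clamped to \[1, n-1\]) go to training, the
#' remainder to testing, so every calf's training ages strictly precede
#' its test ages. Calves with fewer than `min_obs_per_calf` observations
#' are excluded with a warning.
#'
#' @param table observation table.
#' @param spec [split_spec()].
#' @return list(train, test) of data.frames.
#' @export
time_forward_split <- function(table, spec = split_spec()) {
  counts <- table(table$calf_id)
  drop <- names(counts)[counts < spec$min_obs_per_calf]
  if (length(drop)) {
    warning("calf/calves dropped (fewer than ", spec$min_obs_per_calf,
            " observations): ", paste(drop, collapse = ", "))
    table <- table[!(table$calf_id %in% drop), , drop = FALSE]
  }
  if (nrow(table) == 0) stop_validation("no calves left after filtering")
  tr_list <- list(); te_list <- list()
  for (g in split(table, table$calf_id)) {
    g <- g[order(g$age_days), , drop = FALSE]
    n <- nrow(g)
    n_tr <- min(max(floor(spec$train_fraction * n), 1), n - 1)
    tr_list[[length(tr_list) + 1]] <- g[seq_len(n_tr), , drop = FALSE]
    te_list[[length(te_list) + 1]] <- g[(n_tr + 1):n, , drop = FALSE]
  }
  list(train = do.call(rbind, tr_list), test = do.call(rbind, te_list))
}

#' Remove one random calf-timepoint
#'
#' Emulates a missing visit: exactly one row of a uniformly chosen eligible
#' calf (one with more than `min_obs` observations) is removed.
#' Deterministic per seed.
#'
#' @param table observation table.
#' @param seed integer seed.
#' @param min_obs only calves with more than this many rows are eligible,
#'   so removal never pushes a calf below the longitudinal minimum.
#' @return the table minus one row.
#' @export
drop_random_timepoint <- function(table, seed = 1, min_obs = 5) {
  counts <- table(table$calf_id)
  eligible <- which(table$calf_id %in% names(counts)[counts > min_obs])
  if (length(eligible) == 0)
    stop_validation("no calf has more than %d observations", min_obs)
  with_seed(seed, {
    table[-sample(eligible, 1), , drop = FALSE]
  })
}

#' Fit the random-intercept linear mixed model
#'
#' REML fit of BW on the six fixed effects with a per-calf random
#' intercept: `bw_lb ~ age_days + ... + (1 | calf_id)` via lme4. A singular
#' fit (random-intercept variance estimated at the boundary) is flagged
#' with a warning, not an error.
#'
#' @param train training observation table (>= 2 calves).
#' @param spec [feature_spec()].
#' @return object of class `lmm_fit`: fixed coefficients, variance
#'   components, per-calf predicted random intercepts, and the underlying
#'   `lmerMod`.
#' @export
fit_lmm <- function(train, spec = feature_spec()) {
  check_features(train, spec)
  if (length(unique(train$calf_id)) < 2)
    stop_validation("fit_lmm needs >= 2 calves")
  f <- as.formula(paste(attr(spec, "response"), "~",
                        paste(spec, collapse = " + "), "+ (1 | calf_id)"))
  # metrics stay in native units (volume ~ 1e7 mm*px^2); lme4's rescaling
  # advice is expected and harmless here
  fit <- withCallingHandlers(
    suppressMessages(lme4::lmer(f, data = train, REML = TRUE)),
    warning = function(w) {
      if (grepl("different scales", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (lme4::isSingular(fit, tol = 1e-5))
    warning("singular mixed-model fit: random-intercept variance near 0")
  vc <- as.data.frame(lme4::VarCorr(fit))
  re <- lme4::ranef(fit)$calf_id
  structure(list(fixed = lme4::fixef(fit),
                 var_intercept = vc$vcov[vc$grp == "calf_id"][1],
                 var_resid = vc$vcov[vc$grp == "Residual"][1],
                 ranef = stats::setNames(re[["(Intercept)"]], rownames(re)),
                 model = fit),
            class = "lmm_fit")
}

#' Predict body weight from a fitted mixed model
#'
#' Test rows of calves seen in training use the calf's predicted random
#' intercept; unseen calves (or `use_ranef = FALSE`) get fixed-effects-only
#' predictions.
#'
#' @param object an `lmm_fit`.
#' @param newdata observation table.
#' @param use_ranef include predicted random intercepts where available.
#' @param ... unused.
#' @return numeric predictions (lb).
#' @export
predict.lmm_fit <- function(object, newdata, use_ranef = TRUE, ...) {
  p <- predict(object$model, newdata = newdata,
               re.form = if (use_ranef) NULL else NA,
               allow.new.levels = TRUE)
  unname(p)
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Random-intercept mixed model (REML)\n")
  print(round(x$fixed, 5))
  cat(sprintf("var(intercept) = %.3f, var(resid) = %.3f\n",
              x$var_intercept, x$var_resid))
  invisible(x)
}

#' Repeated time-forward forecasting experiment
#'
#' Per iteration: remove one random calf-timepoint, split each calf's
#' series chronologically, fit every model on the training portion, score
#' pooled test predictions. Per train fraction: mean and SD per model and
#' metric, one-way ANOVA between models with Bonferroni-adjusted p
#' (family = number of models), eta squared, and Tukey HSD letters on R2.
#'
#' @param table observation table.
#' @param models named list of fitting functions; defaults to linear, gbt
#'   (desk profile) and lmm.
#' @param train_fractions numeric vector of split fractions.
#' @param n_iter iterations per split (100 in the reference protocol).
#' @param seed master seed; iteration seeds are derived by counter.
#' @param min_obs_per_calf longitudinal minimum per calf.
#' @return named list (one `cv_report` per train fraction, with Tukey
#'   letters on r2 attached as `$letters_r2`).
#' @export
run_forecast <- function(table, models = NULL,
                         train_fractions = c(0.9, 0.8, 0.7, 0.6, 0.5),
                         n_iter = 100, seed = 1, min_obs_per_calf = 5) {
  check_features(table)
  if (is.null(models))
    models <- list(
      linear = function(train) fit_linear(train),
      gbt = function(train) fit_gbt(train, space = desk_search_space(),
                                    seed = child_seed(seed, 778)),
      lmm = function(train) {
        fit <- suppressWarnings(fit_lmm(train))
        function(newdata) predict(fit, newdata)
      })
  out <- list()
  for (tf in train_fractions) {
    spec <- split_spec(tf, min_obs_per_calf)
    rows <- list()
    for (it in seq_len(n_iter)) {
      tab_i <- drop_random_timepoint(table, seed = child_seed(seed, it),
                                     min_obs = min_obs_per_calf)
      sp <- suppressWarnings(time_forward_split(tab_i, spec))
      stopifnot(all(vapply(unique(sp$test$calf_id), function(id) {
        max(sp$train$age_days[sp$train$calf_id == id]) <
          min(sp$test$age_days[sp$test$calf_id == id])
      }, logical(1))))
      for (mn in names(models)) {
        pred <- models[[mn]](sp$train)
        m <- regression_metrics(sp$test$bw_lb, pred(sp$test))
        rows[[length(rows) + 1]] <-
          data.frame(rep = it, model = mn, t(m), stringsAsFactors = FALSE)
      }
    }
    rep_tab <- do.call(rbind, rows)
    report <- summarize_model_metrics(rep_tab,
                                      family_size = length(models))
    if (length(models) >= 2 && stats::var(rep_tab$r2) > 0) {
      d <- rep_tab; d$model <- factor(d$model)
      report$letters_r2 <- tryCatch(
        tukey_letters(aov(r2 ~ model, data = d), "model"),
        error = function(e) NULL)
    }
    out[[sprintf("%d:%d", round(100 * tf), round(100 * (1 - tf)))]] <- report
  }
  out
}
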