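# Synthetic longitudinal herds.
#
# Body weight follows a linear random-coefficients growth model,
#   BW_ij = (b0 + u0_i) + (b1 + u1_i) * age_ij + e_ij,
# with independent zero-mean Gaussian calf effects u0, u1 and residual e.
# The five body metrics are affine functions of the true BW with
# multiplicative noise; the per-metric noise level is derived from a target
# Pearson correlation with BW, so the default herd reproduces the strong
# metric-BW correlation regime (about 0.9) the analysis assumes.
#
# Default calibration (the emulated trial conditions): 20 Holstein calves,
# ages 21-69 d, visits 2-3x/week over 4 weeks, population BW mean
# approximately 147 lb with an overall SD around 26 lb. Intercept 85 lb and
# slope 1.4 lb/d put the mid-age (45 d) mean at 148 lb; the variance
# components below combine with the age spread to give an overall SD near
# 26 lb.

#' Growth-model parameters for herd simulation
#'
#' @param beta0_lb population intercept, lb (BW at age 0 extrapolated).
#' @param beta1_lb_per_day population growth rate, lb/day.
#' @param sd_intercept_lb SD of calf-specific intercept deviations, lb.
#' @param sd_slope SD of calf-specific slope deviations, lb/day.
#' @param sd_resid_lb residual (visit-to-visit) SD, lb.
#' @param metric_links named list of affine links metric = a0 + a1 * BW;
#'   each element is `c(a0, a1, target_r)` where `target_r` is the intended
#'   Pearson correlation between the noisy metric and BW (the multiplicative
#'   noise SD is derived from it).
#' @return an object of class `growth_model_params`.
#' @export
growth_model_params <- function(beta0_lb = 85, beta1_lb_per_day = 1.4,
                                sd_intercept_lb = 12, sd_slope = 0.25,
                                sd_resid_lb = 5,
                                metric_links = list(
                                  contour_area_px2 = c(40000, 600, 0.93),
                                  volume_mm_px2    = c(1e7, 240000, 0.91),
                                  avg_height_mm    = c(200, 1.0, 0.88),
                                  width_px         = c(250, 1.5, 0.85),
                                  length_px        = c(450, 2.0, 0.85))) {
  if (any(c(sd_intercept_lb, sd_slope, sd_resid_lb) < 0))
    stop_validation("SDs must be >= 0")
  for (nm in names(metric_links)) {
    l <- metric_links[[nm]]
    if (length(l) != 3 || l[2] <= 0 || l[3] <= 0 || l[3] > 1)
      stop_validation("metric link '%s' must be c(a0, a1 > 0, 0 < target_r <= 1)", nm)
  }
  structure(list(beta0_lb = beta0_lb, beta1_lb_per_day = beta1_lb_per_day,
                 sd_intercept_lb = sd_intercept_lb, sd_slope = sd_slope,
                 sd_resid_lb = sd_resid_lb, metric_links = metric_links),
            class = "growth_model_params")
}

# marginal BW SD implied by params over a uniform age spread, used to turn a
# target metric-BW correlation into a noise SD
implied_bw_sd <- function(params, age_range) {
  ages <- seq(age_range[1], age_range[2], length.out = 200)
  va <- stats::var(ages) * (199 / 200)
  ma2 <- mean(ages^2)
  sqrt(params$sd_intercept_lb^2 + ma2 * params$sd_slope^2 +
         params$sd_resid_lb^2 + params$beta1_lb_per_day^2 * va)
}

#' Simulate a longitudinal calf herd
#'
#' Draws per-calf random intercepts and slopes, visit ages on a 3-4 day
#' cadence starting from a calf-specific entry age, BW from the growth
#' model, and body metrics from the affine links with multiplicative
#' Gaussian noise calibrated to each link's target correlation. The result
#' passes [validate_observations()].
#'
#' @param params [growth_model_params()].
#' @param n_calves number of calves (>= 2).
#' @param visits_per_calf visits per calf (>= 2).
#' @param age_range (lo, hi) days; visit ages stay inside this window.
#' @param seed integer seed; the herd is reproducible given (params, seed).
#' @return a data.frame with columns calf_id, date, age_days, bw_lb and the
#'   five metric columns, sorted by (calf_id, age_days).
#' @export
simulate_growth <- function(params = growth_model_params(), n_calves = 20,
                            visits_per_calf = 10, age_range = c(21, 69),
                            seed = 1) {
  if (!is_count(n_calves) || n_calves < 2)
    stop_validation("n_calves must be an integer >= 2")
  if (!is_count(visits_per_calf) || visits_per_calf < 2)
    stop_validation("visits_per_calf must be an integer >= 2")
  with_seed(seed, {
    span <- age_range[2] - age_range[1]
    effects <- data.frame(calf_id = sprintf("calf%02d", seq_len(n_calves)),
                          u0 = rnorm(n_calves, 0, params$sd_intercept_lb),
                          u1 = rnorm(n_calves, 0, params$sd_slope))
    rows <- lapply(seq_len(n_calves), function(i) {
      u0 <- effects$u0[i]
      u1 <- effects$u1[i]
      # centre the visit ages on the mid-age so the population mean BW sits
      # at beta0 + beta1 * mid-age (gaps average 3.5 d)
      max_start <- age_range[2] - 3.5 * (visits_per_calf - 1)
      start <- if (max_start <= age_range[1]) age_range[1] else
        round(runif(1, age_range[1], max_start))
      gaps <- sample(3:4, visits_per_calf - 1, replace = TRUE)
      ages <- pmin(start + c(0, cumsum(gaps)), age_range[2])
      ages <- ages[!duplicated(ages)]
      bw <- (params$beta0_lb + u0) +
        (params$beta1_lb_per_day + u1) * ages +
        rnorm(length(ages), 0, params$sd_resid_lb)
      data.frame(calf_id = sprintf("calf%02d", i),
                 date = format(as.Date("2023-01-01") + ages, "%Y-%m-%d"),
                 age_days = ages, bw_lb = pmax(bw, 1),
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    bw_sd <- implied_bw_sd(params, age_range)
    bw_mean <- params$beta0_lb + params$beta1_lb_per_day * mean(age_range)
    for (nm in names(params$metric_links)) {
      l <- params$metric_links[[nm]]
      mu <- l[1] + l[2] * tab$bw_lb
      mu_pop <- l[1] + l[2] * bw_mean
      noise_sd <- l[2] * bw_sd * sqrt(1 / l[3]^2 - 1)   # additive scale
      cv <- noise_sd / mu_pop
      tab[[nm]] <- pmax(mu * (1 + rnorm(nrow(tab), 0, cv)), 0)
    }
    tab <- validate_observations(tab)
    attr(tab, "calf_effects") <- effects   # true random effects, for checks
    tab
  })
}

#' Simulate a herd from an explicit random-intercept mixed model
#'
#' Unlike [simulate_growth()], the six predictors (age plus five body
#' metrics) are generated exogenously and BW is built directly from the
#' linear mixed model
#' \deqn{BW_{ij} = \beta_0 + x_{ij}'\beta + u_i + e_{ij},}
#' with a per-calf random intercept `u_i ~ N(0, sd_intercept^2)` and
#' residual `e ~ N(0, sd_resid^2)`. This is the ground-truth generator for
#' mixed-model parameter-recovery checks.
#'
#' @param beta named numeric vector of fixed effects; must contain
#'   `(Intercept)` and `age_days`, other names among the metric columns.
#' @param n_calves,visits_per_calf herd dimensions.
#' @param sd_intercept_lb,sd_resid_lb variance components (SD scale).
#' @param age_range (lo, hi) days.
#' @param seed integer seed.
#' @return observation table with known generating parameters as attributes
#'   `beta`, `sd_intercept_lb`, `sd_resid_lb`.
#' @export
simulate_lmm_table <- function(beta = c(`(Intercept)` = 60, age_days = 1.5,
                                        length_px = 0.02, width_px = 0.03,
                                        avg_height_mm = 0.05,
                                        volume_mm_px2 = 5e-7,
                                        contour_area_px2 = 1e-4),
                               n_calves = 50, visits_per_calf = 10,
                               sd_intercept_lb = 10, sd_resid_lb = 3,
                               age_range = c(21, 69), seed = 1) {
  stopifnot(all(c("(Intercept)", "age_days") %in% names(beta)))
  with_seed(seed, {
    metric_mu <- c(length_px = 740, width_px = 470, avg_height_mm = 350,
                   volume_mm_px2 = 4.5e7, contour_area_px2 = 130000)
    metric_sd <- metric_mu * 0.15
    rows <- lapply(seq_len(n_calves), function(i) {
      u <- rnorm(1, 0, sd_intercept_lb)
      ages <- sort(sample(seq(age_range[1], age_range[2]), visits_per_calf))
      d <- data.frame(calf_id = sprintf("calf%03d", i),
                      date = format(as.Date("2023-01-01") + ages, "%Y-%m-%d"),
                      age_days = ages, stringsAsFactors = FALSE)
      for (nm in names(metric_mu))
        d[[nm]] <- pmax(rnorm(nrow(d), metric_mu[nm], metric_sd[nm]), 1)
      eta <- beta[["(Intercept)"]] + u
      for (nm in setdiff(names(beta), "(Intercept)"))
        eta <- eta + beta[[nm]] * d[[nm]]
      d$bw_lb <- pmax(eta + rnorm(nrow(d), 0, sd_resid_lb), 1)
      d
    })
    tab <- validate_observations(do.call(rbind, rows))
    attr(tab, "beta") <- beta
    attr(tab, "sd_intercept_lb") <- sd_intercept_lb
    attr(tab, "sd_resid_lb") <- sd_resid_lb
    tab
  })
}
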