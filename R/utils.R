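# internal helpers shared across modules

#' @importFrom stats rnorm runif median sd aov anova TukeyHSD cor lm predict
#'   coef p.adjust quantile complete.cases as.formula setNames
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a master seed and a counter, kept below 2^31.
child_seed <- function(seed, counter) {
  (as.double(seed) * 1009 + as.double(counter) * 9176) %% 2147483647
}

stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x == floor(x)

#' Convert pounds to kilograms
#'
#' Body weights are recorded in pounds on-farm; downstream reporting often
#' needs kilograms. 1 lb = 0.45359237 kg exactly.
#'
#' @param lb numeric vector of weights in pounds.
#' @return numeric vector of weights in kilograms.
#' @export
#' @examples
#' lb_to_kg(146.73)
lb_to_kg <- function(lb) lb * 0.45359237

#' Convert kilograms to pounds
#' @param kg numeric vector of weights in kilograms.
#' @return numeric vector of weights in pounds.
#' @export
kg_to_lb <- function(kg) kg / 0.45359237

#' Segmentation success rate as a percentage
#'
#' @param n_success number of frames successfully segmented.
#' @param n_total number of frames attempted.
#' @return percentage in \[0, 100\].
#' @export
success_rate <- function(n_success, n_total) {
  if (!is_count(n_success) || !is_count(n_total) || n_total <= 0 ||
      n_success < 0 || n_success > n_total)
    stop_validation("success_rate() needs 0 <= n_success <= n_total, n_total > 0")
  100 * n_success / n_total
}
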