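# Mask-level segmentation scoring (IoU, Dice, pixel accuracy) and
# statistical comparison of segmentation methods (one-way ANOVA per metric,
# Tukey HSD letters, Bonferroni-adjusted p, eta squared).

check_same_shape <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth)))
    stop_validation("mask shapes differ: %s vs %s",
                    paste(dim(pred), collapse = "x"),
                    paste(dim(truth), collapse = "x"))
}

#' Intersection over union of two binary masks
#'
#' Defined as 1 when both masks are empty (perfect agreement).
#'
#' @param pred,truth {0,1} matrices of identical shape.
#' @return value in \[0, 1\].
#' @export
mask_iou <- function(pred, truth) {
  check_same_shape(pred, truth)
  p <- pred != 0; t <- truth != 0
  u <- sum(p | t)
  if (u == 0) return(1)
  sum(p & t) / u
}

#' Dice coefficient of two binary masks
#'
#' Twice the intersection over the summed areas; 1 when both masks are
#' empty. Algebraically `2 * iou / (1 + iou)`.
#'
#' @inheritParams mask_iou
#' @return value in \[0, 1\].
#' @export
mask_dice <- function(pred, truth) {
  check_same_shape(pred, truth)
  p <- pred != 0; t <- truth != 0
  s <- sum(p) + sum(t)
  if (s == 0) return(1)
  2 * sum(p & t) / s
}

#' Pixel accuracy of a predicted mask
#'
#' Fraction of all pixels (foreground and background) classified correctly.
#'
#' @inheritParams mask_iou
#' @return value in \[0, 1\].
#' @export
pixel_accuracy <- function(pred, truth) {
  check_same_shape(pred, truth)
  mean((pred != 0) == (truth != 0))
}

#' Score a batch of predicted masks against ground truth
#'
#' Failed frames (NULL predictions) are recorded with `success = FALSE` and
#' NA metrics; they are excluded from metric summaries but counted in the
#' success rate.
#'
#' @param preds list of predicted {0,1} masks or NULL for failures.
#' @param truths list of ground-truth masks, same length.
#' @param method method label attached to every row.
#' @param frame_ids optional frame identifiers.
#' @return data.frame with frame_id, method, success, iou, dice,
#'   pixel_accuracy.
#' @export
evaluate_masks <- function(preds, truths, method = "method",
                           frame_ids = NULL) {
  stopifnot(length(preds) == length(truths))
  if (is.null(frame_ids)) frame_ids <- sprintf("frame%04d", seq_along(preds))
  rows <- lapply(seq_along(preds), function(i) {
    ok <- !is.null(preds[[i]])
    data.frame(frame_id = frame_ids[i], method = method, success = ok,
               iou = if (ok) mask_iou(preds[[i]], truths[[i]]) else NA_real_,
               dice = if (ok) mask_dice(preds[[i]], truths[[i]]) else NA_real_,
               pixel_accuracy = if (ok) pixel_accuracy(preds[[i]], truths[[i]])
                                else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# eta squared from a fitted one-way aov: SS_between / SS_total
eta_squared <- function(fit) {
  ss <- anova(fit)[["Sum Sq"]]
  ss[1] / sum(ss)
}

# compact letter display from Tukey HSD over a one-way aov
tukey_letters <- function(fit, factor_name = "method") {
  glht <- multcomp::glht(fit, linfct = do.call(
    multcomp::mcp, stats::setNames(list("Tukey"), factor_name)))
  lt <- multcomp::cld(glht)$mcletters$Letters
  lt[order(names(lt))]
}

#' Compare segmentation methods statistically
#'
#' For each metric (iou, dice, pixel_accuracy): per-method mean and SD over
#' successful frames, one-way ANOVA across methods, Bonferroni-adjusted p
#' (`min(1, p * family_size)`), eta squared (SS_between / SS_total), and
#' Tukey HSD grouping letters. Methods with fewer than two successful rows
#' are dropped with a warning. Success rates are reported per method.
#'
#' @param rows data.frame from [evaluate_masks()] (possibly several methods
#'   bound together).
#' @param family_size Bonferroni multiplier; the number of tests in the
#'   declared family. Required, never inferred.
#' @return list of class `comparison_report` with elements `summary`
#'   (per method x metric), `tests` (per metric: F, p, adjusted p, eta
#'   squared), `letters`, and `success` (per-method success rates).
#' @export
compare_methods <- function(rows, family_size) {
  if (missing(family_size) || !is_count(family_size) || family_size < 1)
    stop_validation("family_size (Bonferroni multiplier) is required")
  counts <- table(rows$method[rows$success])
  keep <- names(counts)[counts >= 2]
  dropped <- setdiff(unique(rows$method), keep)
  if (length(dropped)) {
    warning("method(s) dropped (fewer than 2 successful rows): ",
            paste(dropped, collapse = ", "))
    rows <- rows[rows$method %in% keep, , drop = FALSE]
  }
  if (length(keep) < 2)
    stop_validation("compare_methods needs >= 2 methods with >= 2 successes")
  ok <- rows[rows$success, , drop = FALSE]
  ok$method <- factor(ok$method)
  metrics <- intersect(c("iou", "dice", "pixel_accuracy"), names(ok))
  summary <- do.call(rbind, lapply(split(ok, ok$method), function(g) {
    row <- data.frame(method = as.character(g$method[1]), n = nrow(g),
                      stringsAsFactors = FALSE)
    for (m in metrics) {
      row[[paste0(m, "_mean")]] <- mean(g[[m]])
      row[[paste0(m, "_sd")]] <- sd(g[[m]])
    }
    row
  }))
  rownames(summary) <- NULL
  tests <- do.call(rbind, lapply(metrics, function(m) {
    if (stats::var(ok[[m]]) == 0) {
      return(data.frame(metric = m, f = 0, p = 1, p_adjusted = 1,
                        eta_sq = 0, stringsAsFactors = FALSE))
    }
    fit <- aov(ok[[m]] ~ method, data = ok)
    at <- anova(fit)
    data.frame(metric = m, f = at[["F value"]][1], p = at[["Pr(>F)"]][1],
               p_adjusted = min(1, at[["Pr(>F)"]][1] * family_size),
               eta_sq = eta_squared(fit), stringsAsFactors = FALSE)
  }))
  letters <- lapply(stats::setNames(metrics, metrics), function(m) {
    if (stats::var(ok[[m]]) == 0)
      return(stats::setNames(rep("a", nlevels(ok$method)), levels(ok$method)))
    tukey_letters(aov(ok[[m]] ~ method, data = ok))
  })
  succ <- vapply(split(rows, rows$method),
                 function(g) mean(g$success), numeric(1))
  structure(list(summary = summary, tests = tests, letters = letters,
                 success = succ, family_size = family_size),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Method comparison (Bonferroni family size ", x$family_size, ")\n", sep = "")
  print(x$summary, row.names = FALSE)
  print(x$tests, row.names = FALSE)
  invisible(x)
}
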