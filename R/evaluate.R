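# Performance metrics and agreement analyses for CRM estimates.

#' RMSE and coefficient of determination
#'
#' `rmse = sqrt(mean((est - ref)^2))` and `r2 = 1 - SS_res / SS_tot`. With a
#' constant reference, R2 is undefined and returned as `NA`.
#'
#' @param est,ref Equal-length numeric vectors (CRM percent).
#' @return A list with `rmse` and `r2`.
#' @export
regression_metrics <- function(est, ref) {
  if (length(est) != length(ref) || length(est) < 2L)
    stop_invalid("`est` and `ref` must be equal-length vectors of length >= 2")
  resid <- est - ref
  rmse <- sqrt(mean(resid^2))
  ss_tot <- sum((ref - mean(ref))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - sum(resid^2) / ss_tot
  list(rmse = rmse, r2 = r2)
}

#' ROC AUC for classification at a CRM threshold
#'
#' Labels reference values at or above `threshold` as the positive class and
#' scores with the CRM estimate; the AUC is the Mann-Whitney rank statistic
#' (probability that a random positive outscores a random negative, ties
#' counting one half). Undefined (`NA`) when only one class is present.
#'
#' @param est CRM estimates (scores).
#' @param ref Reference CRM values.
#' @param threshold Classification threshold, percent (clinically 70, 40
#'   or 5).
#' @return AUC in \[0, 1\], or `NA`.
#' @export
roc_auc_at_threshold <- function(est, ref, threshold) {
  pos <- ref >= threshold
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(est)            # average ranks handle ties as 1/2
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bland-Altman agreement between estimated and reference CRM
#'
#' Differences are `est - ref`; the bias is their mean and the limits of
#' agreement are `bias +/- 1.96 sd(differences)`. Because the reference is a
#' gold standard, the natural x-coordinate for plotting is the reference CRM
#' rather than the pair mean, and it is returned alongside the differences.
#'
#' @param est,ref Equal-length numeric vectors.
#' @return A list of class `bland_altman`: `bias`, `loa_low`, `loa_high`,
#'   `differences`, `x` (= `ref`).
#' @export
bland_altman <- function(est, ref) {
  if (length(est) != length(ref) || length(est) < 2L)
    stop_invalid("`est` and `ref` must be equal-length vectors of length >= 2")
  d <- est - ref
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, differences = d, x = ref),
            class = "bland_altman")
}

#' Bland-Altman plot
#'
#' @param x A `bland_altman` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$x, x$differences, xlab = "Reference CRM (%)",
                 ylab = "Estimated - reference CRM (%)", ...)
  graphics::abline(h = c(x$loa_low, x$bias, x$loa_high),
                   lty = c(2, 1, 2), col = "red3")
  invisible(x)
}

#' Accuracy summarized per ramp speed
#'
#' Computes session-level RMSE and R2 separately for the depressurization and
#' repressurization windows of each session (attributed to the signed ramp
#' rate: negative while depressurizing, positive while repressurizing), then
#' summarizes the session-level RMSE distribution per rate (n, median,
#' quartiles, mean, sd).
#'
#' @param predictions Pooled prediction rows from [subjectwise_cv()] (columns
#'   `session_id`, `phase`, `ramp_rate`, `reference_crm`, `estimate`).
#' @return A list with `sessions` (one row per session x rate with its RMSE
#'   and R2) and `by_rate` (the distribution summary per rate).
#' @export
per_speed_metrics <- function(predictions) {
  p <- predictions[predictions$phase %in% c("depressurization",
                                            "repressurization"), , drop = FALSE]
  if (nrow(p) == 0L)
    return(list(sessions = data.frame(), by_rate = data.frame()))
  key <- interaction(p$session_id, p$ramp_rate, drop = TRUE)
  parts <- split(p, key)
  sessions <- do.call(rbind, lapply(parts, function(q) {
    m <- if (nrow(q) >= 2L) regression_metrics(q$estimate, q$reference_crm)
         else list(rmse = NA_real_, r2 = NA_real_)
    data.frame(session_id = q$session_id[1L], ramp_rate = q$ramp_rate[1L],
               n_windows = nrow(q), rmse = m$rmse, r2 = m$r2,
               stringsAsFactors = FALSE)
  }))
  rownames(sessions) <- NULL
  by_rate <- do.call(rbind, lapply(split(sessions, sessions$ramp_rate),
                                   function(q) {
    data.frame(ramp_rate = q$ramp_rate[1L], n_sessions = nrow(q),
               rmse_median = stats::median(q$rmse, na.rm = TRUE),
               rmse_q1 = stats::quantile(q$rmse, 0.25, na.rm = TRUE, names = FALSE),
               rmse_q3 = stats::quantile(q$rmse, 0.75, na.rm = TRUE, names = FALSE),
               rmse_mean = mean(q$rmse, na.rm = TRUE),
               rmse_sd = stats::sd(q$rmse, na.rm = TRUE),
               r2_mean = mean(q$r2, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  by_rate <- by_rate[order(by_rate$ramp_rate), , drop = FALSE]
  rownames(by_rate) <- NULL
  list(sessions = sessions, by_rate = by_rate)
}

#' Build the full evaluation report from a cross-validation result
#'
#' Collects the fold-aggregated accuracy metrics, the Bland-Altman analysis
#' of the pooled held-out predictions, the per-ramp-speed breakdown and the
#' fold-mean feature importances into one report object.
#'
#' @param cv A `crm_cv` from [subjectwise_cv()].
#' @return A list of class `eval_report`.
#' @export
eval_report <- function(cv) {
  pr <- cv$predictions
  ba <- bland_altman(pr$estimate, pr$reference_crm)
  structure(list(
    metrics = cv$metrics,
    bland_altman = list(bias = ba$bias, loa_low = ba$loa_low,
                        loa_high = ba$loa_high),
    per_speed = per_speed_metrics(pr)$by_rate,
    importance = cv$importance,
    n_windows = nrow(pr),
    n_subjects = length(unique(pr$subject_id))
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<eval_report> %d windows, %d subjects\n", x$n_windows,
              x$n_subjects))
  cat(sprintf("  RMSE %.1f +/- %.1f %%CRM, R2 %.2f +/- %.2f\n",
              m$rmse["mean"], m$rmse["sd"], m$r2["mean"], m$r2["sd"]))
  for (nm in grep("^auc_", names(m), value = TRUE))
    cat(sprintf("  %s: %.3f +/- %.3f\n", nm, m[[nm]]["mean"], m[[nm]]["sd"]))
  cat(sprintf("  Bland-Altman bias %.2f, LoA [%.1f, %.1f]\n",
              x$bland_altman$bias, x$bland_altman$loa_low,
              x$bland_altman$loa_high))
  if (!is.null(x$importance)) {
    top <- sort(x$importance, decreasing = TRUE)
    cat("  importance:", paste(sprintf("%s %.2f", names(top), top),
                               collapse = ", "), "\n")
  }
  invisible(x)
}
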