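#' Behavioural summary by memory load
#'
#' Accuracy (percent correct) and median reaction time per load and over the
#' session. Reaction time is defined relative to probe stimulus onset,
#' `RT = ts_response - ts_probe`. Loads with no trials get `NA` entries.
#' Trials with negative RT are counted in `n_negative_rt` and excluded from
#' the medians (they indicate corrupt timestamps, not behaviour).
#'
#' @param trials a Sternberg trials table.
#' @param correct_only restrict the RT medians to correct trials (accuracy
#'   medians always use all trials).
#' @return object of class `behavior_summary`: list with `per_load`
#'   (data.frame `load`, `n_trials`, `accuracy_pct`, `median_rt_s`),
#'   `overall_accuracy_pct`, `n_trials`, `n_negative_rt`.
#' @export
#' @examples
#' s <- generate_sternberg_session(generator_config(n_trials = 20, seed = 3))
#' behavior_by_load(s$trials)
behavior_by_load <- function(trials, correct_only = FALSE) {
  if (!nrow(trials)) stopf("no trials")
  if (any(trials$ts_response == 0)) stopf("all trials must have response timestamps")
  rt <- trials$ts_response - trials$ts_probe
  n_neg <- sum(rt < 0)
  per <- lapply(1:3, function(L) {
    sel <- trials$load == L
    n <- sum(sel)
    if (n == 0)
      return(data.frame(load = L, n_trials = 0L, accuracy_pct = NA_real_,
                        median_rt_s = NA_real_))
    rt_sel <- sel & rt >= 0
    if (correct_only) rt_sel <- rt_sel & trials$response_accuracy == 1
    data.frame(load = L, n_trials = n,
               accuracy_pct = 100 * mean(trials$response_accuracy[sel]),
               median_rt_s = if (any(rt_sel)) stats::median(rt[rt_sel]) else NA_real_)
  })
  structure(list(per_load = do.call(rbind, per),
                 overall_accuracy_pct = 100 * mean(trials$response_accuracy),
                 n_trials = nrow(trials), n_negative_rt = n_neg),
            class = "behavior_summary")
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat(sprintf("Behaviour over %d trials: %.2f%% correct\n",
              x$n_trials, x$overall_accuracy_pct))
  print(x$per_load, row.names = FALSE)
  if (x$n_negative_rt) cat(sprintf("  [%d trial(s) with negative RT flagged]\n", x$n_negative_rt))
  invisible(x)
}

#' One-way repeated-measures ANOVA of per-subject medians
#'
#' Tests a within-subject factor (memory load) on a complete subjects-by-
#' conditions table of median reaction times, using the subject-by-condition
#' interaction as the error term: `F = MS_condition / MS_residual` with
#' `df1 = k - 1` and `df2 = (k - 1)(n - 1)`.
#'
#' @param per_subject_medians numeric matrix or data.frame, one row per
#'   subject, one column per condition; no missing cells (no imputation is
#'   attempted).
#' @return object of class `rm_anova`: list with `F`, `df1`, `df2`, `p`.
#' @export
#' @examples
#' m <- matrix(rnorm(15, mean = rep(c(0.7, 0.8, 0.9), each = 5), sd = 0.05), 5)
#' rm_anova_rt(m)
rm_anova_rt <- function(per_subject_medians) {
  m <- as.matrix(per_subject_medians)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stopf("need at least 2 subjects and 2 conditions")
  if (any(!is.finite(m))) stopf("missing or non-finite cells are not allowed")
  gm <- mean(m)
  ss_cond <- n * sum((colMeans(m) - gm)^2)
  ss_subj <- k * sum((rowMeans(m) - gm)^2)
  ss_tot <- sum((m - gm)^2)
  ss_res <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1L; df2 <- (k - 1L) * (n - 1L)
  Fv <- (ss_cond / df1) / (ss_res / df2)
  if (is.nan(Fv)) Fv <- 0   # 0/0: no condition effect and no residual
  structure(list(F = Fv, df1 = df1, df2 = df2,
                 p = stats::pf(Fv, df1, df2, lower.tail = FALSE)),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("repeated-measures ANOVA: F(%d,%d) = %.3f, p = %.4g\n",
              x$df1, x$df2, x$F, x$p))
  invisible(x)
}
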