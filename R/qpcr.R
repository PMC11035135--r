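# relative expression by 2^(-ddCt), primer efficiency, and tests on delta-Ct

# per-sample delta Ct (mean target Ct - mean housekeeping Ct) for one target
# gene; technical replicates are averaged within a sample first
sample_delta_ct <- function(table, target, group) {
  tab <- table[table$group == group, , drop = FALSE]
  stop_if(nrow(tab) == 0L, sprintf("group '%s' not present", group))
  samples <- unique(tab$sample)
  vapply(samples, function(s) {
    st <- tab[tab$sample == s, , drop = FALSE]
    tgt <- st$ct[st$gene == target & st$role == "target"]
    hk <- st$ct[st$role == "housekeeping"]
    stop_if(length(hk) == 0L,
            sprintf("sample '%s' has no housekeeping measurement", s))
    stop_if(length(tgt) == 0L,
            sprintf("sample '%s' has no Ct for target '%s'", s, target))
    mean(tgt) - mean(hk)
  }, numeric(1))
}

# t-test on delta-Ct values that tolerates degenerate (zero-variance) data:
# with no within-group spread the t statistic is 0 (p = 1) for equal means
# and +/- infinity (p = 0 or 1 by direction) otherwise
delta_ct_p <- function(a, b, alternative, var_equal) {
  tryCatch(
    stats::t.test(a, b, alternative = alternative,
                  var.equal = var_equal)$p.value,
    error = function(e) {
      d <- mean(a) - mean(b)
      tol <- 1e-10 * max(1, abs(mean(a)), abs(mean(b)))
      switch(alternative,
             two.sided = if (abs(d) <= tol) 1 else 0,
             less = if (d < -tol) 0 else 1,
             greater = if (d > tol) 0 else 1)
    })
}

#' Relative expression by the 2^(-ddCt) method
#'
#' Per sample, delta-Ct = mean Ct(target) - mean Ct(housekeeping) (technical
#' replicates averaged first); delta-delta-Ct = mean delta-Ct(case) - mean
#' delta-Ct(control); fold change = 2^(-ddCt). The standard error of ddCt
#' combines the two group s.e.m.s in quadrature, and a Student's t-test on
#' the per-sample delta-Ct values gives the p-value. Two error conventions
#' for the fold are reported, labeled: `fold_se_delta` propagates the ddCt
#' s.e.m. through the exponential (fold * ln 2 * se), and `fold_se_samples`
#' is the s.e.m. of per-sample case folds relative to the control mean.
#'
#' @param table a `ct_table` (long format: sample, group, gene, role,
#'   replicate, ct), e.g. from [make_ct_table()] or [read_ct_table()].
#' @param target target gene name.
#' @param case,control group labels.
#' @param alternative test sidedness for the t-test on delta-Ct, passed to
#'   [ddct_test()].
#' @param var_equal use the pooled-variance Student's t-test (default);
#'   FALSE gives Welch.
#' @return a `fold_change_result`: list with `gene`, `ddct`, `fold`,
#'   `se_ddct`, `fold_se_delta`, `fold_se_samples`, `p_value`, `alternative`,
#'   `delta_ct_case`, `delta_ct_control`.
#' @examples
#' tab <- make_ct_table(ct_design_spec(data.frame(gene = "Aqp1", fold = 16),
#'                                     noise_sd = 0, sample_shift_sd = 0))
#' relative_expression(tab$table, "Aqp1", "Aqp1", "GFP")$fold  # 16
#' @export
relative_expression <- function(table, target, case, control,
                                alternative = "two.sided", var_equal = TRUE) {
  dct_case <- sample_delta_ct(table, target, case)
  dct_ctrl <- sample_delta_ct(table, target, control)
  ddct <- mean(dct_case) - mean(dct_ctrl)
  fold <- 2^(-ddct)
  se <- if (length(dct_case) > 1 && length(dct_ctrl) > 1)
    sqrt(sem(dct_case)^2 + sem(dct_ctrl)^2) else NA_real_
  p <- if (length(dct_case) > 1 && length(dct_ctrl) > 1)
    delta_ct_p(dct_case, dct_ctrl, alternative, var_equal) else NA_real_
  per_sample_fold <- 2^(-(dct_case - mean(dct_ctrl)))
  structure(list(gene = target, ddct = ddct, fold = fold, se_ddct = se,
                 fold_se_delta = if (is.na(se)) NA_real_ else
                   fold * log(2) * se,
                 fold_se_samples = if (length(per_sample_fold) > 1)
                   sem(per_sample_fold) else NA_real_,
                 p_value = p, alternative = alternative,
                 delta_ct_case = dct_case, delta_ct_control = dct_ctrl),
            class = "fold_change_result")
}

#' @export
print.fold_change_result <- function(x, ...) {
  cat(sprintf("<fold_change_result> %s: fold = %.4g (ddCt = %.4g +/- %.3g), p = %.3g (%s)\n",
              x$gene, x$fold, x$ddct, x$se_ddct, x$p_value, x$alternative))
  invisible(x)
}

#' Primer amplification efficiency from a serial-dilution series
#'
#' Fits Ct against log10(dilution factor) by ordinary least squares and
#' converts the slope to efficiency = (10^(-1/slope) - 1) * 100. A slope of
#' -1/log10(2) = -3.3219 cycles per decade corresponds to perfect doubling
#' (100%). A non-negative slope cannot arise from dilution of a working
#' assay; the result is then flagged invalid rather than silently reported.
#'
#' @param dilution dilution factors (1 = undiluted, 0.1 = tenfold diluted);
#'   at least 3 distinct values.
#' @param ct corresponding Ct values.
#' @return list with `efficiency_pct`, `slope`, `intercept`, `r_squared`,
#'   `valid` (FALSE when slope >= 0, with a `reason`).
#' @examples
#' d <- 10^-(0:4); primer_efficiency(d, 20 - log10(d) / log10(2))
#' @export
primer_efficiency <- function(dilution, ct) {
  stop_if(length(dilution) != length(ct), "dilution and ct lengths differ")
  stop_if(length(unique(dilution)) < 3L, "need >= 3 distinct dilutions")
  stop_if(any(dilution <= 0), "dilution factors must be positive")
  x <- log10(dilution)
  fit <- stats::lm(ct ~ x)
  cf <- unname(stats::coef(fit))
  slope <- cf[2]
  sst <- sum((ct - mean(ct))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  if (slope >= 0) {
    return(list(efficiency_pct = NA_real_, slope = slope,
                intercept = cf[1], r_squared = r2, valid = FALSE,
                reason = "non-negative slope: Ct must increase with dilution"))
  }
  list(efficiency_pct = (10^(-1 / slope) - 1) * 100, slope = slope,
       intercept = cf[1], r_squared = r2, valid = TRUE)
}

#' Student's t-test on per-sample delta-Ct values
#'
#' The significance test behind qRT-PCR fold changes: a two-sample t-test on
#' the per-sample delta-Ct values of case vs control. Two-sided by default;
#' the one-sided variant exists for comparisons whose direction is known a
#' priori (e.g. an ER-stress induction expected to increase expression, i.e.
#' lower the case delta-Ct: `alternative = "less"`).
#'
#' @inheritParams relative_expression
#' @param alternative `"two.sided"`, `"less"` (case delta-Ct lower, i.e.
#'   up-regulation) or `"greater"`.
#' @return the p-value.
#' @export
ddct_test <- function(table, target, case, control,
                      alternative = c("two.sided", "less", "greater"),
                      var_equal = TRUE) {
  alternative <- match.arg(alternative)
  dct_case <- sample_delta_ct(table, target, case)
  dct_ctrl <- sample_delta_ct(table, target, control)
  stop_if(length(dct_case) < 2L || length(dct_ctrl) < 2L,
          "need at least two samples per group")
  delta_ct_p(dct_case, dct_ctrl, alternative, var_equal)
}
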