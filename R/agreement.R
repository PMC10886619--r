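# Method-comparison statistics for validating one titration method against
# another: absolute log10 differences, Bland-Altman ratio analysis on
# log10-transformed titers, Lin's concordance correlation coefficient, and
# a normality-gated comparison of replicate variability.

#' Absolute log10 difference between two titers
#'
#' @param mean_a,mean_b Positive titers (PFU/mL); vectorised.
#' @return `|log10(mean_a) - log10(mean_b)|`, in log10 units (decades).
#' @examples
#' abs_log10_difference(1.08e9, 1.03e9)
#' @export
abs_log10_difference <- function(mean_a, mean_b) {
  if (any(!is.finite(mean_a)) || any(mean_a <= 0) ||
      any(!is.finite(mean_b)) || any(mean_b <= 0))
    stop("titers must be positive", call. = FALSE)
  abs(log10(mean_a) - log10(mean_b))
}

#' Bland-Altman agreement analysis on the ratio scale
#'
#' Agreement between two measurement methods whose errors are
#' multiplicative: per pair the ratio evaluated/reference is formed and all
#' statistics are computed on log10 ratios.  The bias is the geometric mean
#' ratio `10^mean(l)`; the 95% limits of agreement are
#' `10^(mean(l) +/- 1.96 sd(l))`; the confidence interval of the bias uses
#' the t distribution with n - 1 degrees of freedom on the log scale.
#'
#' @param reference Positive titers by the reference method.
#' @param evaluated Positive titers by the evaluated method, same length.
#' @param conf_level Confidence level for the bias CI (default 0.95).
#'
#' @return An object of class `bland_altman`: list with `n`, `bias_ratio`,
#'   `bias_ci`, `limits_of_agreement`, and per-pair `ratios` and `averages`
#'   (mean of the two log10 titers, for plotting ratio vs average).
#' @examples
#' ba <- bland_altman_ratio(c(1e8, 2e8, 5e7), c(1.1e8, 1.8e8, 5.5e7))
#' ba$bias_ratio
#' @export
bland_altman_ratio <- function(reference, evaluated, conf_level = 0.95) {
  if (length(reference) != length(evaluated))
    stop("reference and evaluated must have the same length", call. = FALSE)
  n <- length(reference)
  if (n < 2)
    stop("at least two pairs are required", call. = FALSE)
  if (any(reference <= 0) || any(evaluated <= 0))
    stop("titers must be positive", call. = FALSE)

  l <- log10(evaluated / reference)
  m <- mean(l)
  s <- stats::sd(l)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
  structure(list(
    n = n,
    bias_ratio = 10^m,
    bias_ci = 10^(m + c(-1, 1) * tq * s / sqrt(n)),
    limits_of_agreement = 10^(m + c(-1, 1) * 1.96 * s),
    ratios = evaluated / reference,
    log_ratios = l,
    averages = (log10(reference) + log10(evaluated)) / 2,
    conf_level = conf_level), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman ratio analysis (n = %d pairs)\n", x$n))
  cat(sprintf("  bias (geometric mean ratio): %.3f (%.0f%% CI %.3f-%.3f)\n",
              x$bias_ratio, 100 * x$conf_level, x$bias_ci[1], x$bias_ci[2]))
  cat(sprintf("  95%% limits of agreement:     %.3f-%.3f\n",
              x$limits_of_agreement[1], x$limits_of_agreement[2]))
  invisible(x)
}

#' Bland-Altman plot (ratio vs average)
#'
#' Ratio of the two methods against the average log10 titer, with a solid
#' bias line and dashed 95% limits of agreement.
#'
#' @param x A [bland_altman_ratio()] result.
#' @param ... Passed to [plot()].
#' @return Invisibly, `x`.
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$averages, x$ratios, log = "y",
                 xlab = "average titer (log10 PFU/mL)",
                 ylab = "ratio evaluated / reference", ...)
  graphics::abline(h = x$bias_ratio, lty = 1)
  graphics::abline(h = x$limits_of_agreement, lty = 2)
  invisible(x)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement index penalising both deviation from the 45-degree line and
#' loss of correlation: `ccc = 2 s_xy / (s_x^2 + s_y^2 + (mean x - mean
#' y)^2)` with population (n denominator) moments.  The confidence interval
#' applies the Fisher z transform with Lin's (1989) variance formula and
#' back-transforms.
#'
#' @param x,y Numeric vectors of equal length n >= 3.
#' @param conf_level Confidence level (default 0.95).
#'
#' @return List with `ccc`, `ci` (lower, upper), `n`, and the Pearson
#'   correlation `r`.
#' @examples
#' lins_ccc(c(1, 2, 3), c(2, 3, 4))$ccc  # 4/7
#' @export
lins_ccc <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y))
    stop("x and y must have the same length", call. = FALSE)
  n <- length(x)
  if (n < 3)
    stop("at least three pairs are required", call. = FALSE)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  if (vx == 0 && vy == 0)
    stop("both inputs are constant; concordance is undefined", call. = FALSE)
  ccc <- 2 * sxy / (vx + vy + (mx - my)^2)

  if (vx == 0 || vy == 0) {
    # no correlation structure; CI undefined, return point estimate only
    return(list(ccc = ccc, ci = c(NA_real_, NA_real_), n = n, r = NA_real_))
  }
  r <- sxy / sqrt(vx * vy)
  u <- (mx - my) / (vx * vy)^(1 / 4)
  if (abs(ccc) >= 1 - 1e-12 || abs(r) >= 1 - 1e-12) {
    ci <- c(ccc, ccc)  # perfect agreement: degenerate interval
  } else {
    z <- atanh(ccc)
    se2 <- ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
              2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
              ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2)
    q <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- tanh(z + c(-1, 1) * q * sqrt(se2))
  }
  list(ccc = ccc, ci = ci, n = n, r = r)
}

#' Compare replicate variability between two methods
#'
#' Compares two groups of per-titration coefficients of variation with a
#' normality gate: each group is screened with a one-sample
#' Kolmogorov-Smirnov test against a normal distribution with
#' sample-estimated moments; if both groups pass, an equal-variance
#' two-sample Student's t test is used, otherwise the Mann-Whitney
#' (Wilcoxon rank-sum) test.  The gate is anti-conservative at small n
#' (moments are estimated from the data); the branch actually taken is
#' always reported.
#'
#' @param cvs_a,cvs_b Numeric vectors of CVs (percent), each non-empty;
#'   normality screening needs n >= 3 per group (smaller groups fall back
#'   to the nonparametric branch).
#' @param normality_alpha Significance level of the gate (default 0.05).
#' @param welch Use the Welch (unequal-variance) form when the parametric
#'   branch is taken (default `FALSE`, the classical Student's test).
#'
#' @return List with `test_name`, `statistic`, `p_value`, `normality_p`
#'   (per-group KS p values), and `group_summary` (mean and SD per group).
#' @export
compare_variability <- function(cvs_a, cvs_b, normality_alpha = 0.05,
                                welch = FALSE) {
  if (length(cvs_a) == 0 || length(cvs_b) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  if (length(cvs_a) < 2 || length(cvs_b) < 2)
    stop("each group needs at least two values for a location test",
         call. = FALSE)

  ks_p <- function(v) {
    if (length(v) < 3 || stats::sd(v) == 0) return(NA_real_)
    suppressWarnings(
      stats::ks.test(v, "pnorm", mean(v), stats::sd(v))$p.value)
  }
  pa <- ks_p(cvs_a); pb <- ks_p(cvs_b)
  normal <- !is.na(pa) && !is.na(pb) &&
    pa > normality_alpha && pb > normality_alpha

  if (normal) {
    tt <- stats::t.test(cvs_a, cvs_b, var.equal = !welch)
    name <- if (welch) "Welch t-test" else "Student t-test"
    stat <- unname(tt$statistic); p <- tt$p.value
  } else {
    tt <- suppressWarnings(stats::wilcox.test(cvs_a, cvs_b))
    name <- "Mann-Whitney"
    stat <- unname(tt$statistic); p <- tt$p.value
  }
  list(test_name = name, statistic = stat, p_value = p,
       normality_p = c(a = pa, b = pb),
       group_summary = list(
         a = c(mean = mean(cvs_a), sd = stats::sd(cvs_a)),
         b = c(mean = mean(cvs_b), sd = stats::sd(cvs_b))))
}

#' Full method-comparison report for paired titrations
#'
#' Given paired titers measured by a reference and an evaluated method and
#' grouped into replicate sets (e.g. one dilution tube titrated several
#' times by both methods), computes per-group mean/SD/CV for each method,
#' the absolute log10 difference of the per-group means and their grand
#' mean, the Bland-Altman ratio analysis over all pairs, Lin's concordance
#' correlation coefficient, and the normality-gated comparison of
#' per-group CVs.
#'
#' @param pairs Data frame with columns `group`, `label`,
#'   `reference_titer`, `evaluated_titer` (see [read_paired_titers()]).
#' @param ccc_scale Scale on which the CCC is computed: `"log10"` (default;
#'   titers typically span decades) or `"raw"`.
#' @param welch Passed to [compare_variability()].
#'
#' @return An object of class `agreement_report`.
#' @examples
#' rep <- method_comparison_report(table1_titers())
#' rep$bland_altman$bias_ratio
#' @export
method_comparison_report <- function(pairs, ccc_scale = c("log10", "raw"),
                                     welch = FALSE) {
  ccc_scale <- match.arg(ccc_scale)
  need <- c("group", "label", "reference_titer", "evaluated_titer")
  if (!all(need %in% names(pairs)))
    stop("pairs must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(pairs) < 2)
    stop("at least two pairs are required", call. = FALSE)
  if (any(pairs$reference_titer <= 0) || any(pairs$evaluated_titer <= 0))
    stop("titers must be positive", call. = FALSE)

  groups <- unique(as.character(pairs$group))
  per_group <- do.call(rbind, lapply(groups, function(g) {
    sub <- pairs[pairs$group == g, , drop = FALSE]
    ra <- aggregate_replicates(sub$reference_titer)
    ea <- aggregate_replicates(sub$evaluated_titer)
    data.frame(group = g, n = nrow(sub),
               reference_mean = ra$mean, reference_sd = ra$sd,
               reference_cv = ra$cv_percent,
               evaluated_mean = ea$mean, evaluated_sd = ea$sd,
               evaluated_cv = ea$cv_percent,
               abs_log10_diff = abs_log10_difference(ra$mean, ea$mean),
               stringsAsFactors = FALSE)
  }))

  ba <- bland_altman_ratio(pairs$reference_titer, pairs$evaluated_titer)
  ccc <- if (ccc_scale == "log10")
    lins_ccc(log10(pairs$reference_titer), log10(pairs$evaluated_titer))
  else
    lins_ccc(pairs$reference_titer, pairs$evaluated_titer)
  vt <- compare_variability(per_group$reference_cv, per_group$evaluated_cv,
                            welch = welch)

  structure(list(
    n_pairs = nrow(pairs),
    per_group = per_group,
    mean_abs_log10_diff = mean(per_group$abs_log10_diff),
    bland_altman = ba,
    ccc = ccc,
    ccc_scale = ccc_scale,
    variability_test = vt), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Method-comparison report (%d pairs, %d groups)\n",
              x$n_pairs, nrow(x$per_group)))
  cat(sprintf("  mean |delta log10| of group means: %.3f\n",
              x$mean_abs_log10_diff))
  cat(sprintf("  Bland-Altman bias: %.3f (CI %.3f-%.3f), LoA %.3f-%.3f\n",
              x$bland_altman$bias_ratio,
              x$bland_altman$bias_ci[1], x$bland_altman$bias_ci[2],
              x$bland_altman$limits_of_agreement[1],
              x$bland_altman$limits_of_agreement[2]))
  cat(sprintf("  Lin's CCC (%s scale): %.3f (CI %.3f-%.3f)\n",
              x$ccc_scale, x$ccc$ccc, x$ccc$ci[1], x$ccc$ci[2]))
  vs <- x$variability_test
  cat(sprintf("  CV comparison (%s): reference %.2f%% vs evaluated %.2f%%, p = %.4f\n",
              vs$test_name, vs$group_summary$a[["mean"]],
              vs$group_summary$b[["mean"]], vs$p_value))
  invisible(x)
}
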