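#' Grouped samples for comparison statistics
#'
#' A named list of numeric vectors with a unit label documenting the
#' statistical unit (per-telomere Rg, per-nucleus percentage,
#' per-replicate ratio). Keeping the unit on the object prevents mixing
#' units across tests.
#'
#' @param samples named list of numeric vectors.
#' @param unit unit label.
#' @return object of class `"group_samples"`.
#' @export
group_samples <- function(samples, unit = "value") {
  if (!is.list(samples) || is.null(names(samples)) ||
      any(names(samples) == ""))
    stopf("`samples` must be a named list of numeric vectors")
  samples <- lapply(samples, function(x) as.numeric(x[is.finite(x)]))
  structure(list(samples = samples, unit = unit), class = "group_samples")
}

gs_data <- function(gs) {
  data.frame(
    group = factor(rep(names(gs$samples), lengths(gs$samples)),
                   levels = names(gs$samples)),
    value = unlist(gs$samples, use.names = FALSE))
}

gs_stats <- function(gs) {
  data.frame(group = names(gs$samples),
             n = unname(lengths(gs$samples)),
             mean = vapply(gs$samples, mean, 0),
             sem = vapply(gs$samples, sem, 0),
             row.names = NULL)
}

comparison_result <- function(test, statistic, df, p_value, comparisons,
                              groups, conf_level = 0.95) {
  structure(list(test = test, statistic = statistic, df = df,
                 p_value = p_value, comparisons = comparisons,
                 groups = groups, conf_level = conf_level),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, digits = 4, ...) {
  cat(sprintf("%s (confidence level %.0f%%)\n", x$test,
              100 * x$conf_level))
  if (!is.null(x$statistic))
    cat(sprintf("  statistic = %.4g, p = %.4g\n", x$statistic, x$p_value))
  if (!is.null(x$comparisons)) {
    cat("  comparisons:\n")
    print(format(x$comparisons, digits = digits), row.names = FALSE)
  }
  cat("  group means +/- s.e.m.:\n")
  print(format(x$groups, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Two-tailed unpaired t test
#'
#' Equal-variance by default (set `var_equal = FALSE` for Welch). When
#' both samples are constant and equal the test is degenerate and the
#' convention t = 0, p = 1 applies; constant samples with different
#' means are an error.
#'
#' @param a,b numeric vectors with at least 2 values each.
#' @param var_equal pool the variances (default `TRUE`).
#' @param conf_level confidence level.
#' @return a `comparison_result` with the t statistic, degrees of
#'   freedom and two-tailed p.
#' @export
ttest_two_tailed <- function(a, b, var_equal = TRUE, conf_level = 0.95) {
  if (length(a) < 2 || length(b) < 2)
    stopf("each sample needs at least 2 values")
  gs <- group_samples(list(a = a, b = b))
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(comparison_result("Two-tailed unpaired t test", 0,
                               length(a) + length(b) - 2, 1,
                               NULL, gs_stats(gs), conf_level))
    }
    stopf("zero variance in both samples with unequal means")
  }
  tt <- stats::t.test(a, b, var.equal = var_equal,
                      conf.level = conf_level)
  comparison_result("Two-tailed unpaired t test",
                    unname(tt$statistic), unname(tt$parameter),
                    tt$p.value, NULL, gs_stats(gs), conf_level)
}

#' One-way ANOVA with Dunnett's multiple comparison test
#'
#' Fits a one-way ANOVA across all groups and reports
#' Dunnett-adjusted p-values for each treatment-versus-control
#' comparison (single-step adjustment over the multivariate t
#' distribution, via \pkg{multcomp}).
#'
#' @param groups a [group_samples()] with >= 2 groups including the
#'   control; every group needs >= 2 values.
#' @param control control group label.
#' @param conf_level confidence level.
#' @return a `comparison_result`; `comparisons` holds one row per
#'   treatment-vs-control contrast with `estimate`, `se`, `statistic`,
#'   `p_adj`.
#' @export
anova_dunnett <- function(groups, control, conf_level = 0.95) {
  if (!inherits(groups, "group_samples"))
    groups <- group_samples(groups)
  if (!control %in% names(groups$samples))
    stopf("control group '%s' not present", control)
  if (length(groups$samples) < 2) stopf("need at least 2 groups")
  if (any(lengths(groups$samples) < 2))
    stopf("every group needs at least 2 values")
  df <- gs_data(groups)
  df$group <- stats::relevel(df$group, ref = control)
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
  sm <- summary(gl)
  comps <- data.frame(comparison = names(sm$test$coefficients),
                      estimate = unname(sm$test$coefficients),
                      se = unname(sm$test$sigma),
                      statistic = unname(sm$test$tstat),
                      p_adj = unname(as.numeric(sm$test$pvalues)))
  comparison_result("One-way ANOVA with Dunnett's multiple comparison test",
                    an[["F value"]][1], unname(an[["Df"]]),
                    an[["Pr(>F)"]][1], comps, gs_stats(groups), conf_level)
}

#' One-way ANOVA with Tukey's multiple comparisons
#'
#' Fits a one-way ANOVA and reports Tukey honest-significant-difference
#' adjusted p-values for all pairwise group comparisons -- the procedure
#' used to compare group mean Rg distributions.
#'
#' @inheritParams anova_dunnett
#' @return a `comparison_result`; `comparisons` holds all pairwise
#'   contrasts with `estimate`, `ci_lo`, `ci_hi`, `p_adj`.
#' @export
anova_tukey <- function(groups, conf_level = 0.95) {
  if (!inherits(groups, "group_samples"))
    groups <- group_samples(groups)
  if (length(groups$samples) < 2) stopf("need at least 2 groups")
  if (any(lengths(groups$samples) < 2))
    stopf("every group needs at least 2 values")
  df <- gs_data(groups)
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = conf_level)$group
  comps <- data.frame(comparison = rownames(tk),
                      estimate = unname(tk[, "diff"]),
                      ci_lo = unname(tk[, "lwr"]),
                      ci_hi = unname(tk[, "upr"]),
                      p_adj = unname(tk[, "p adj"]))
  comparison_result("One-way ANOVA with Tukey's multiple comparisons",
                    an[["F value"]][1], unname(an[["Df"]]),
                    an[["Pr(>F)"]][1], comps, gs_stats(groups), conf_level)
}

#' Write a comparisons CSV
#'
#' Emits the tidy `test,comparison,estimate,p_adj` records of one or
#' more comparison results.
#'
#' @param results a `comparison_result` or list of them.
#' @param path output file.
#' @export
write_comparisons <- function(results, path) {
  if (inherits(results, "comparison_result")) results <- list(results)
  rows <- do.call(rbind, lapply(results, function(r) {
    if (is.null(r$comparisons))
      return(data.frame(test = r$test, comparison = "a-b",
                        estimate = diff(rev(r$groups$mean))[1],
                        p_adj = r$p_value))
    data.frame(test = r$test, comparison = r$comparisons$comparison,
               estimate = r$comparisons$estimate,
               p_adj = r$comparisons$p_adj)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
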