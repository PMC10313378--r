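#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator of overall survival, optionally stratified by a
#' grouping column. Censored observations reduce the risk set without
#' producing steps.
#'
#' @param clinical tibble with `os_time` (months) and `event` (1 = death,
#'   0 = censored).
#' @param group_col optional name of a grouping column (e.g. `"tfe"`).
#' @return a `km_fit` wrapping the [survival::survfit] object; `tidy()`
#'   gives the step function (`time`, `n_risk`, `n_event`, `estimate`,
#'   `group`), `glance()` the per-group medians.
#' @export
km_estimate <- function(clinical, group_col = NULL) {
  check_columns(clinical, c("os_time", "event"), "clinical table")
  if (!nrow(clinical)) stop_degenerate("empty clinical table")
  validate_clinical_values(clinical)
  df <- as.data.frame(clinical)
  fit <- if (is.null(group_col)) {
    survival::survfit(survival::Surv(os_time, event) ~ 1, data = df)
  } else {
    check_columns(df, group_col, "clinical table")
    df$.group <- factor(df[[group_col]])
    survival::survfit(survival::Surv(os_time, event) ~ .group, data = df)
  }
  structure(list(fit = fit, group_col = group_col), class = "km_fit")
}

validate_clinical_values <- function(df) {
  if (any(df$os_time < 0) || any(!is.finite(df$os_time)))
    stop_validation("os_time must be finite and >= 0")
  if (!all(df$event %in% c(0, 1))) stop_validation("event must be 0 or 1")
  invisible(df)
}

#' @rdname km_estimate
#' @param x a `km_fit`.
#' @param ... unused.
#' @method tidy km_fit
#' @export
tidy.km_fit <- function(x, ...) {
  s <- x$fit
  grp <- if (is.null(s$strata)) rep("all", length(s$time)) else
    rep(sub("^\\.group=", "", names(s$strata)), s$strata)
  tibble(group = grp, time = s$time, n_risk = s$n.risk, n_event = s$n.event,
         n_censor = s$n.censor, estimate = s$surv)
}

#' @rdname km_estimate
#' @method glance km_fit
#' @export
glance.km_fit <- function(x, ...) {
  tab <- summary(x$fit)$table
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = 1,
                                       dimnames = list("all", names(tab)))
  tibble(group = sub("^\\.group=", "", rownames(tab)),
         n = tab[, "records"], events = tab[, "events"],
         median_survival = tab[, "median"])
}

#' @export
print.km_fit <- function(x, ...) {
  print(x$fit)
  invisible(x)
}

#' Log-rank (Mantel-Cox) test across groups
#'
#' k-group Mantel-Cox test of equality of survival curves; df = k - 1 with a
#' chi-square p value.
#'
#' @param clinical tibble with `os_time`, `event` and the grouping column.
#' @param group_col grouping column name.
#' @return a `logrank_test` list: `statistic`, `df`, `p_value`, `n`;
#'   `glance()` returns the same as a one-row tibble.
#' @export
logrank_test <- function(clinical, group_col = "tfe") {
  check_columns(clinical, c("os_time", "event", group_col), "clinical table")
  validate_clinical_values(clinical)
  g <- factor(clinical[[group_col]])
  if (nlevels(droplevels(g)) < 2)
    stop_validation("log-rank test needs at least 2 non-empty groups")
  if (any(table(droplevels(g)) == 0))
    stop_validation("every group must contain at least one subject")
  df <- data.frame(os_time = clinical$os_time, event = clinical$event,
                   .group = droplevels(g))
  sd_ <- survival::survdiff(survival::Surv(os_time, event) ~ .group, data = df)
  k <- length(sd_$n)
  structure(list(statistic = unname(sd_$chisq), df = k - 1L,
                 p_value = stats::pchisq(sd_$chisq, k - 1L, lower.tail = FALSE),
                 n = sum(sd_$n)),
            class = "logrank_test")
}

#' @rdname logrank_test
#' @param x a `logrank_test`.
#' @param ... unused.
#' @method glance logrank_test
#' @export
glance.logrank_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value, n = x$n)
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank (Mantel-Cox): chisq = %.3f, df = %d, p = %.3g (n = %d)\n",
              x$statistic, x$df, x$p_value, x$n))
  invisible(x)
}

#' Mann-Whitney U test (two groups)
#'
#' Unpaired two-sided Mann-Whitney U. The exact null distribution is used
#' for small samples (both groups <= 8, no ties); otherwise the normal
#' approximation with midrank tie correction.
#'
#' @param a,b numeric samples.
#' @return tibble with `U`, `p_value`, `n_a`, `n_b`, `method`.
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) stop_validation("both samples must be non-empty")
  exact <- length(a) <= 8 && length(b) <= 8 && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = !exact))
  tibble(U = unname(wt$statistic), p_value = wt$p.value,
         n_a = length(a), n_b = length(b),
         method = if (exact) "exact" else "normal approximation")
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' @param values numeric response.
#' @param groups group labels (>= 3 groups, each with >= 2 observations).
#' @return list with `anova` (tibble: `F`, `p_value`, `df_between`,
#'   `df_within`) and `tukey` (tibble of pairwise adjusted p values).
#' @export
anova_tukey <- function(values, groups) {
  g <- factor(groups)
  if (any(table(g) < 2))
    stop_validation("every group needs at least 2 observations")
  if (nlevels(g) < 3)
    stop_validation("one-way ANOVA with Tukey is for 3 or more groups")
  fit <- stats::aov(values ~ g)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  list(anova = tibble(F = an$`F value`[1], p_value = an$`Pr(>F)`[1],
                      df_between = an$Df[1], df_within = an$Df[2]),
       tukey = tibble(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"]))
}
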