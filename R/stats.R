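#' One-way ANOVA with Tukey's HSD pairwise comparisons
#'
#' Group comparisons across conditions or sub-regions use a one-way F test
#' followed by Tukey's honest significant difference test, with the null
#' hypothesis rejected at `p < alpha` (default 0.05).
#'
#' @param values Numeric response.
#' @param group Grouping factor (>= 2 groups with >= 2 values each).
#' @param alpha Significance level.
#' @return A `test_result`: `statistic` (F), `p_value`, `reject`,
#'   `pairwise` (tibble of Tukey-adjusted contrasts), `alpha`, `method`.
#' @export
anova_tukey <- function(values, group, alpha = 0.05) {
  group <- factor(group)
  stopifnot(length(values) == length(group), nlevels(group) >= 2,
            all(table(group) >= 2))
  if (stats::var(values) < 1e-24) {
    lev <- levels(group)
    cmb <- utils::combn(lev, 2)
    pairwise <- tibble::tibble(
      contrast = paste(cmb[2, ], cmb[1, ], sep = "-"),
      estimate = 0, p_adj = 1)
    return(new_test_result(0, 1, pairwise, alpha, "one-way ANOVA + Tukey HSD"))
  }
  fit <- stats::aov(values ~ group)
  tab <- summary(fit)[[1]]
  f <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$group
  pairwise <- tibble::tibble(contrast = rownames(tk),
                             estimate = unname(tk[, "diff"]),
                             p_adj = unname(tk[, "p adj"]))
  new_test_result(f, p, pairwise, alpha, "one-way ANOVA + Tukey HSD")
}

#' Compare regression slopes across groups (ANCOVA + Tukey HSD)
#'
#' Distribution slopes are compared on their binned log-log CCD points: a
#' homogeneity-of-slopes F test (the group-by-covariate interaction) plus
#' Tukey-adjusted pairwise contrasts of the per-group slope estimates.
#'
#' @param data Data frame with columns `x`, `y` (e.g. `log10(t)`,
#'   `log10(P)`) and `group` (>= 2 groups with >= 3 points each).
#' @param alpha Significance level.
#' @return A `test_result` (statistic = interaction F; `pairwise` holds
#'   Tukey-adjusted slope differences).
#' @export
ancova_slopes <- function(data, alpha = 0.05) {
  data <- as.data.frame(data)
  stopifnot(all(c("x", "y", "group") %in% names(data)))
  data$group <- factor(data$group)
  stopifnot(nlevels(data$group) >= 2, all(table(data$group) >= 3))
  spread <- tapply(data$x, data$group, function(v) stats::var(v))
  if (any(spread < 1e-24)) {
    stop("a group has constant x; its slope is undefined", call. = FALSE)
  }
  full <- stats::lm(y ~ x * group, data = data)
  add <- stats::lm(y ~ x + group, data = data)
  cmp <- stats::anova(add, full)
  f <- cmp$F[2]
  p <- cmp$`Pr(>F)`[2]
  emt <- emmeans::emtrends(full, ~group, var = "x")
  prs <- as.data.frame(emmeans::contrast(emt, "pairwise", adjust = "tukey"))
  pairwise <- tibble::tibble(contrast = as.character(prs$contrast),
                             estimate = prs$estimate,
                             p_adj = prs$p.value)
  new_test_result(f, p, pairwise, alpha,
                  "ANCOVA homogeneity of slopes + Tukey HSD")
}

#' Cohen's d with 95% confidence interval and qualitative band
#'
#' `d = (mean(a) - mean(b)) / pooled SD` (sign convention: group `a` minus
#' group `b`). The 95% CI uses the normal approximation to the standard
#' error of d by default, or noncentral-t inversion. Bands follow the
#' 0.2 / 0.5 / 0.8 convention, with 0.5-0.8 read as medium-strong; an
#' effect is `significant` when the CI excludes zero.
#'
#' @param a,b Numeric samples (each n >= 2).
#' @param ci_method `"normal"` (default) or `"nct"` (noncentral t).
#' @param hedges Apply the small-sample (Hedges) correction to d.
#' @return An `effect_size`: `d`, `ci` (`c(lo, hi)`), `band`,
#'   `significant`, `n` (`c(n_a, n_b)`).
#' @export
cohens_d <- function(a, b, ci_method = c("normal", "nct"), hedges = FALSE) {
  ci_method <- match.arg(ci_method)
  na <- length(a); nb <- length(b)
  stopifnot(na >= 2, nb >= 2)
  df <- na + nb - 2
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df)
  if (sp < 1e-12) {
    if (abs(mean(a) - mean(b)) < 1e-12) {
      return(structure(list(d = 0, ci = c(0, 0), band = "negligible",
                            significant = FALSE, n = c(na, nb)),
                       class = "effect_size"))
    }
    stop("zero pooled SD with unequal means: Cohen's d undefined",
         call. = FALSE)
  }
  d <- (mean(a) - mean(b)) / sp
  if (hedges) d <- d * (1 - 3 / (4 * df - 1))
  if (ci_method == "normal") {
    se <- sqrt((na + nb) / (na * nb) + d^2 / (2 * (na + nb)))
    ci <- d + c(-1, 1) * stats::qnorm(0.975) * se
  } else {
    tval <- d * sqrt(na * nb / (na + nb))
    scale <- sqrt((na + nb) / (na * nb))
    lo <- tryCatch(stats::uniroot(
      \(ncp) suppressWarnings(stats::pt(tval, df, ncp)) - 0.975,
      interval = tval + c(-10, 10) * (1 + abs(tval)))$root,
      error = function(e) NA_real_)
    hi <- tryCatch(stats::uniroot(
      \(ncp) suppressWarnings(stats::pt(tval, df, ncp)) - 0.025,
      interval = tval + c(-10, 10) * (1 + abs(tval)))$root,
      error = function(e) NA_real_)
    ci <- c(lo, hi) * scale
  }
  structure(list(d = d, ci = ci, band = d_band(d),
                 significant = isTRUE(ci[1] > 0) || isTRUE(ci[2] < 0),
                 n = c(na, nb)),
            class = "effect_size")
}

d_band <- function(d) {
  ad <- abs(d)
  if (ad < 0.2) "negligible"
  else if (ad < 0.5) "small"
  else if (ad < 0.8) "medium_strong"
  else "large"
}

#' One-tailed one-sample t-test against zero
#'
#' Used for testing whether per-connection changes (e.g. percent
#' reliability changes after stimulation) are significantly above (or
#' below) no change.
#'
#' @param deltas Numeric changes (n >= 2).
#' @param direction `"greater"` (mean > 0) or `"less"`.
#' @param alpha Significance level.
#' @return A `test_result` (statistic = t).
#' @export
one_tailed_t <- function(deltas, direction = c("greater", "less"),
                         alpha = 0.05) {
  direction <- match.arg(direction)
  stopifnot(length(deltas) >= 2)
  if (stats::sd(deltas) < 1e-24) {
    m <- mean(deltas)
    p <- if (m == 0) 0.5
    else if ((m > 0) == (direction == "greater")) 0 else 1
    return(new_test_result(ifelse(m == 0, 0, sign(m) * Inf), p, NULL,
                           alpha, "one-tailed t (degenerate)"))
  }
  tt <- stats::t.test(deltas, mu = 0, alternative = direction)
  new_test_result(unname(tt$statistic), tt$p.value, NULL, alpha,
                  "one-tailed one-sample t")
}

new_test_result <- function(statistic, p_value, pairwise, alpha, method) {
  structure(list(statistic = statistic, p_value = p_value,
                 pairwise = pairwise, alpha = alpha,
                 reject = is.finite(p_value) && p_value < alpha,
                 method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat("<test_result> ", x$method, ": statistic = ",
      format(x$statistic, digits = 4), ", p = ",
      format(x$p_value, digits = 4),
      if (x$reject) " (reject at " else " (retain at ", x$alpha, ")\n",
      sep = "")
  if (!is.null(x$pairwise)) print(x$pairwise)
  invisible(x)
}

#' @export
print.effect_size <- function(x, ...) {
  cat("<effect_size> d = ", format(x$d, digits = 3), " [",
      format(x$ci[1], digits = 3), ", ", format(x$ci[2], digits = 3),
      "] (", x$band, if (x$significant) ", CI excludes 0" else "", ")\n",
      sep = "")
  invisible(x)
}
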