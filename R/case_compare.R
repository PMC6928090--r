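#' Summarize a per-frame metric series for one case
#'
#' @param df A data frame of per-frame values.
#' @param value Column holding the metric (tidy-eval).
#' @param label Case label (e.g. `"3_0.003"`: number of core proteins and
#'   external driving force per the case-naming convention).
#' @return A one-row tibble: `case`, `n`, `mean`, `se`.
#' @export
summarize_case <- function(df, value, label = "case") {
  v <- dplyr::pull(df, {{ value }})
  if (length(v) < 2) abort("need at least 2 values for an SE")
  tibble::tibble(case = label, n = length(v), mean = mean(v),
                 se = se_mean(v))
}

#' Summarize a metric across cases
#'
#' @param df A data frame with one row per frame per case.
#' @param value Metric column (tidy-eval).
#' @param case Case-label column (tidy-eval).
#' @return A tibble with one row per case: `case`, `n`, `mean`, `se`.
#' @export
summarize_cases <- function(df, value, case) {
  out <- dplyr::summarise(
    dplyr::group_by(df, case = {{ case }}),
    n = dplyr::n(), mean = mean({{ value }}),
    se = stats::sd({{ value }}) / sqrt(dplyr::n()), .groups = "drop"
  )
  if (any(out$n < 2)) abort("every case needs at least 2 values")
  out
}

#' Significance stars for a p-value
#'
#' Thresholds follow the reporting convention `*** p < 0.001`,
#' `** p < 0.01`, `* p < 0.05`.
#'
#' @param p Numeric p-values.
#' @return Character vector of stars (`"ns"` when not significant).
#' @export
p_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**",
                   p < 0.05 ~ "*", TRUE ~ "ns")
}

#' One-way ANOVA of a per-frame metric across cases
#'
#' Fixed-effects one-way analysis of variance treating frames as
#' independent observations (matching the reference analysis; see
#' [block_se()] for an autocorrelation-aware alternative on single-case
#' summaries). Emits both the omnibus test across all cases and all
#' pairwise two-group ANOVAs.
#'
#' @param df A data frame with metric and case columns.
#' @param value Metric column (tidy-eval).
#' @param case Case-label column (tidy-eval).
#' @return A `case_anova` object. [glance()] gives the omnibus F and
#'   p-value; [tidy()] the pairwise table with significance stars.
#' @export
anova_across_cases <- function(df, value, case) {
  dat <- tibble::tibble(value = dplyr::pull(df, {{ value }}),
                        case = as.character(dplyr::pull(df, {{ case }})))
  counts <- table(dat$case)
  if (length(counts) < 2) abort("need at least 2 cases")
  if (any(counts < 2)) {
    abort(paste0("case ", names(counts)[which(counts < 2)[1]],
                 " has fewer than 2 values"))
  }
  fit <- aov(value ~ case, data = dat)
  an <- anova(fit)
  omnibus <- tibble::tibble(
    f_statistic = an[["F value"]][1], p_value = an[["Pr(>F)"]][1],
    df_between = an[["Df"]][1], df_within = an[["Df"]][2],
    stars = p_stars(an[["Pr(>F)"]][1])
  )
  labs <- sort(unique(dat$case))
  pairs <- utils::combn(labs, 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(p) {
    sub <- dat[dat$case %in% p, ]
    a <- anova(aov(value ~ case, data = sub))
    tibble::tibble(case_a = p[1], case_b = p[2],
                   f_statistic = a[["F value"]][1],
                   p_value = a[["Pr(>F)"]][1],
                   stars = p_stars(a[["Pr(>F)"]][1]))
  })
  structure(list(omnibus = omnibus, pairwise = pairwise, fit = fit),
            class = "case_anova")
}

#' @export
print.case_anova <- function(x, ...) {
  cat(sprintf("<case_anova> omnibus F = %.4g, p = %.3g %s\n",
              x$omnibus$f_statistic, x$omnibus$p_value, x$omnibus$stars))
  print(x$pairwise)
  invisible(x)
}

#' @describeIn anova_across_cases Pairwise two-group ANOVA table.
#' @param x A `case_anova`.
#' @param ... Unused.
#' @method tidy case_anova
#' @export
tidy.case_anova <- function(x, ...) x$pairwise

#' @describeIn anova_across_cases One-row omnibus summary.
#' @method glance case_anova
#' @export
glance.case_anova <- function(x, ...) x$omnibus
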