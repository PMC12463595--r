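# -- scale-level group comparisons -------------------------------------------

#' Welch two-sample t test from summary statistics
#'
#' Unequal-variance t test with Satterthwaite degrees of freedom, computable
#' directly from published (n, mean, SD) summaries — useful when raw data are
#' unavailable.
#'
#' @param n1,mean1,sd1 First group's size, mean, SD.
#' @param n2,mean2,sd2 Second group's size, mean, SD.
#' @return A one-row tibble: `statistic`, `df`, `p_value` (two-sided).
#' @export
#' @examples
#' welch_t_summary(675, 31.46, 5.28, 2673, 31.74, 5.36)
welch_t_summary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 > 0, sd2 > 0)
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  tibble::tibble(statistic = t, df = df,
                 p_value = 2 * pt(-abs(t), df))
}

#' One-way ANOVA from summary statistics
#'
#' Between/within sums of squares reconstructed from per-group (n, mean, SD),
#' yielding the same F as raw-data ANOVA on any data with those moments.
#'
#' @param groups A data frame with columns `n`, `mean`, `sd` (and optionally
#'   `group` labels), one row per group.
#' @return A one-row tibble: `F`, `df_between`, `df_within`, `p_value`, plus
#'   `ss_between`, `ss_within`.
#' @export
#' @examples
#' oneway_anova_summary(data.frame(
#'   group = c("infant", "kindergarten", "primary", "junior_high"),
#'   n = c(1416, 1506, 406, 20),
#'   mean = c(32.13, 31.85, 29.55, 30.8),
#'   sd = c(4.92, 5.11, 6.89, 5.69)
#' ))
oneway_anova_summary <- function(groups) {
  stopifnot(nrow(groups) >= 2, all(groups$n >= 2), all(groups$sd > 0))
  N <- sum(groups$n)
  k <- nrow(groups)
  grand <- sum(groups$n * groups$mean) / N
  ssb <- sum(groups$n * (groups$mean - grand)^2)
  ssw <- sum((groups$n - 1) * groups$sd^2)
  df1 <- k - 1; df2 <- N - k
  F <- (ssb / df1) / (ssw / df2)
  tibble::tibble(F = F, df_between = df1, df_within = df2,
                 p_value = pf(F, df1, df2, lower.tail = FALSE),
                 ss_between = ssb, ss_within = ssw)
}

#' Bonferroni-adjusted pairwise comparisons from summary statistics
#'
#' All pairwise pooled-variance t tests (the textbook Bonferroni t test:
#' pooled within-group variance from the ANOVA, N - k degrees of freedom),
#' each p-value multiplied by the number of pairs and capped at 1. For each
#' significant pair the ordered relation (which group scores higher) is
#' reported.
#'
#' @inheritParams oneway_anova_summary
#' @param alpha Significance level for the reported relations (default 0.05).
#' @return A tibble with one row per pair: group labels, mean difference,
#'   `statistic`, `df`, `p_value` (unadjusted), `p_adjusted`, `significant`,
#'   `relation` (e.g. `"infant > primary"`, `NA` when not significant). The
#'   attribute `"summary"` collapses the significant relations (e.g.
#'   `"1,2 > 3"` style by group position).
#' @export
bonferroni_pairwise <- function(groups, alpha = 0.05) {
  stopifnot(nrow(groups) >= 2)
  if (!"group" %in% names(groups)) {
    groups$group <- as.character(seq_len(nrow(groups)))
  }
  an <- oneway_anova_summary(groups)
  mse <- an$ss_within / an$df_within
  pairs <- utils::combn(nrow(groups), 2)
  npair <- ncol(pairs)
  rows <- lapply(seq_len(npair), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt(mse * (1 / groups$n[a] + 1 / groups$n[b]))
    t <- (groups$mean[a] - groups$mean[b]) / se
    p <- 2 * pt(-abs(t), an$df_within)
    padj <- min(1, p * npair)
    sig <- padj < alpha
    tibble::tibble(
      group1 = groups$group[a], group2 = groups$group[b],
      diff = groups$mean[a] - groups$mean[b],
      statistic = t, df = an$df_within, p_value = p, p_adjusted = padj,
      significant = sig,
      relation = ifelse(sig,
                        ifelse(t > 0,
                               paste(groups$group[a], ">", groups$group[b]),
                               paste(groups$group[b], ">", groups$group[a])),
                        NA_character_)
    )
  })
  out <- dplyr::bind_rows(rows)
  # collapse relations that share a lower group: "1,2 > 3"
  sig <- out[out$significant, ]
  summary_str <- if (nrow(sig) > 0) {
    higher <- vapply(strsplit(sig$relation, " > "), `[`, "", 1)
    lower <- vapply(strsplit(sig$relation, " > "), `[`, "", 2)
    paste(vapply(split(higher, lower), function(h)
      paste(paste(sort(unique(h)), collapse = ","), ">", ""), ""),
      names(split(higher, lower)), sep = "", collapse = "; ")
  } else {
    "no significant pairs"
  }
  attr(out, "summary") <- summary_str
  out
}

#' Scale-level group comparison of total scores
#'
#' The standard companion analysis to item-level DIF: a Welch t test of
#' total scores by gender and a one-way ANOVA across age groups with
#' Bonferroni-adjusted pairwise tests, from raw responses and covariates.
#'
#' @param responses Response tibble on the raw scale.
#' @param covariates Covariate tibble.
#' @param config A [run_config()].
#' @return An object of class `group_comparison`: `group_summaries` (n, mean,
#'   SD of totals per gender and age group), `gender_test`, `age_anova`,
#'   `age_pairwise`.
#' @export
group_comparison <- function(responses, covariates, config = run_config()) {
  covariates <- as_covariates(covariates)
  tot <- total_scores_and_severity(responses, config)
  d <- dplyr::inner_join(tot, covariates, by = "person_id")
  d <- d[!is.na(d$total), ]
  summarize_by <- function(var) {
    d |>
      dplyr::group_by(group = .data[[var]]) |>
      dplyr::summarise(n = dplyr::n(), mean = mean(.data$total),
                       sd = sd(.data$total), .groups = "drop") |>
      dplyr::mutate(variable = var, .before = 1) |>
      dplyr::mutate(group = as.character(.data$group))
  }
  gsum <- dplyr::bind_rows(summarize_by("gender"), summarize_by("age_group"))
  gg <- gsum[gsum$variable == "gender", ]
  gender_test <- welch_t_summary(gg$n[1], gg$mean[1], gg$sd[1],
                                 gg$n[2], gg$mean[2], gg$sd[2])
  ga <- gsum[gsum$variable == "age_group", c("group", "n", "mean", "sd")]
  structure(
    list(group_summaries = gsum,
         gender_test = gender_test,
         age_anova = oneway_anova_summary(ga),
         age_pairwise = bonferroni_pairwise(ga)),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\n")
  print(x$group_summaries, n = Inf)
  cat(sprintf("  gender (Welch): t = %.2f, df = %.1f, p = %.3g\n",
              x$gender_test$statistic, x$gender_test$df,
              x$gender_test$p_value))
  cat(sprintf("  age (ANOVA): F = %.2f (%d, %d), p = %.3g; %s\n",
              x$age_anova$F, x$age_anova$df_between, x$age_anova$df_within,
              x$age_anova$p_value, attr(x$age_pairwise, "summary")))
  invisible(x)
}
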