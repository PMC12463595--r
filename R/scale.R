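#' The 15 CARS items
#'
#' Item labels for the first-edition Childhood Autism Rating Scale, a
#' clinician-rated instrument with 15 items scored on an ordinal 1--4 scale
#' (1 = age-appropriate behaviour, 4 = severely abnormal behaviour). The
#' total score ranges 15--60, higher meaning more severe autistic symptoms.
#'
#' @return A tibble with columns `item` (1--15) and `label` (snake-case item
#'   name used as the column name of response tables).
#' @export
#' @examples
#' cars_items()
cars_items <- function() {
  tibble::tibble(
    item = 1:15,
    label = c(
      "relating_to_people", "imitation", "emotional_response", "body_use",
      "object_use", "adaptation_to_change", "visual_response",
      "listening_response", "taste_smell_touch_response", "fear_nervousness",
      "verbal_communication", "nonverbal_communication", "activity_level",
      "intellectual_response", "general_impression"
    )
  )
}

# canonical covariate levels; first level of each factor is the reference
# (the predominant group in the target population)
cars_covariate_levels <- function() {
  list(
    gender = c("male", "female"),
    age_group = c("infant", "kindergarten", "primary", "junior_high"),
    symptom_level = c("mild_moderate", "non_autism", "severe")
  )
}

#' Analysis configuration
#'
#' Bundles every tunable threshold and numerical control used across the
#' pipeline so that one object travels through calibration, diagnostics,
#' residual PCA and DIF detection.
#'
#' @param score_range Integer length-2: the declared raw category range of the
#'   instrument (default 1--4).
#' @param conv_tol Joint-maximum-likelihood convergence tolerance: iteration
#'   stops when the largest absolute parameter change falls below this many
#'   logits.
#' @param max_iter Maximum JML iterations.
#' @param min_count Minimum responses a rating category should attract before
#'   it is flagged as sparse (default 10).
#' @param interval_bounds Length-2 numeric: acceptable range, in logits, for
#'   the gap between adjacent Andrich thresholds (default 1.4--5).
#' @param mnsq_bounds Length-2 numeric: acceptable infit/outfit mean-square
#'   range (default 0.75--1.33).
#' @param zstd_bounds Length-2 numeric: acceptable standardized fit range
#'   (default -2 to 2).
#' @param zstd_cap Reported standardized fit values are capped at +/- this
#'   value (default 9.9, the conventional display cap).
#' @param loading_cutoff Absolute residual-PCA loading above which an item is
#'   listed as contributing to a contrast (default 0.4).
#' @param second_contrast_min Report the second residual contrast whenever its
#'   eigenvalue reaches this value (default 1.8).
#' @param severity_cutoffs Length-2 numeric total-score cutoffs: totals below
#'   the first are classified non-autism, totals at or above the second severe,
#'   the rest mild-to-moderate (default 30 and 37).
#' @param extreme_adjust Score-point adjustment applied to zero/perfect raw
#'   scores before maximum-likelihood scoring (default 0.3).
#' @param bias_correction Apply the standard joint-maximum-likelihood
#'   statistical-bias correction: step difficulties are shrunk by
#'   (I-1)/I after convergence (JML inflates the logit spread of item
#'   parameters by about I/(I-1) for an I-item test, a bias that persists at
#'   any sample size) and person measures re-solved against the corrected
#'   items. Default TRUE.
#' @param n_lambda Number of points on the DIF penalty path (default 50).
#' @param n_quad Gauss-Hermite quadrature nodes for the marginal GPCM
#'   likelihood (default 21).
#' @param prox_tol Relative objective-change convergence tolerance of the
#'   proximal-gradient DIF optimizer (default 1e-7).
#' @param prox_max_iter Maximum proximal-gradient iterations per penalty value.
#' @param seed Optional integer seed recorded with the configuration.
#'
#' @return A list of class `run_config`.
#' @export
#' @examples
#' cfg <- run_config(min_count = 20)
#' cfg$interval_bounds
run_config <- function(score_range = c(1L, 4L),
                       conv_tol = 0.005,
                       max_iter = 200L,
                       min_count = 10L,
                       interval_bounds = c(1.4, 5.0),
                       mnsq_bounds = c(0.75, 1.33),
                       zstd_bounds = c(-2, 2),
                       zstd_cap = 9.9,
                       loading_cutoff = 0.4,
                       second_contrast_min = 1.8,
                       severity_cutoffs = c(30, 37),
                       extreme_adjust = 0.3,
                       bias_correction = TRUE,
                       n_lambda = 50L,
                       n_quad = 21L,
                       prox_tol = 1e-7,
                       prox_max_iter = 3000L,
                       seed = NULL) {
  stopifnot(
    length(score_range) == 2, score_range[1] < score_range[2],
    conv_tol > 0, max_iter >= 1, min_count >= 0,
    length(interval_bounds) == 2, interval_bounds[1] < interval_bounds[2],
    interval_bounds[1] > 0,
    length(mnsq_bounds) == 2, mnsq_bounds[1] < mnsq_bounds[2],
    mnsq_bounds[1] > 0,
    length(zstd_bounds) == 2, zstd_bounds[1] < zstd_bounds[2],
    zstd_cap > 0, loading_cutoff >= 0,
    length(severity_cutoffs) == 2, severity_cutoffs[1] < severity_cutoffs[2],
    extreme_adjust > 0, extreme_adjust < 1,
    n_lambda >= 2, n_quad >= 3, prox_tol > 0
  )
  structure(
    list(
      score_range = as.integer(score_range),
      conv_tol = conv_tol, max_iter = as.integer(max_iter),
      min_count = as.integer(min_count),
      interval_bounds = interval_bounds,
      mnsq_bounds = mnsq_bounds, zstd_bounds = zstd_bounds,
      zstd_cap = zstd_cap,
      loading_cutoff = loading_cutoff,
      second_contrast_min = second_contrast_min,
      severity_cutoffs = severity_cutoffs,
      extreme_adjust = extreme_adjust,
      bias_correction = isTRUE(bias_correction),
      n_lambda = as.integer(n_lambda), n_quad = as.integer(n_quad),
      prox_tol = prox_tol, prox_max_iter = as.integer(prox_max_iter),
      seed = seed
    ),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in setdiff(names(x), "seed")) {
    cat(sprintf("  %-20s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  if (!is.null(x$seed)) cat(sprintf("  %-20s %s\n", "seed", x$seed))
  invisible(x)
}
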