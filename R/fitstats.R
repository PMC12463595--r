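# -- mean-square fit statistics ----------------------------------------------

# Wilson-Hilferty standardization of a mean-square with model variance q2
wh_zstd <- function(mnsq, q2) {
  q <- sqrt(pmax(q2, 1e-12))
  (mnsq^(1 / 3) - 1) * (3 / q) + q / 3
}

mnsq_block <- function(d, by, cap, mnsq_bounds, zstd_bounds) {
  d |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      outfit = mean(.data$std_residual^2),
      infit = sum(.data$residual^2) / sum(.data$variance),
      q2_out = pmax(sum(.data$kurtosis / .data$variance^2) / dplyr::n()^2 -
                      1 / dplyr::n(), 0),
      q2_in = pmax(sum(.data$kurtosis - .data$variance^2) /
                     sum(.data$variance)^2, 0),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      outfit_zstd = pmin(pmax(wh_zstd(.data$outfit, .data$q2_out), -cap), cap),
      infit_zstd = pmin(pmax(wh_zstd(.data$infit, .data$q2_in), -cap), cap),
      misfit = .data$infit < mnsq_bounds[1] | .data$infit > mnsq_bounds[2] |
        .data$outfit < mnsq_bounds[1] | .data$outfit > mnsq_bounds[2] |
        .data$infit_zstd < zstd_bounds[1] | .data$infit_zstd > zstd_bounds[2] |
        .data$outfit_zstd < zstd_bounds[1] | .data$outfit_zstd > zstd_bounds[2]
    ) |>
    dplyr::select(-"q2_out", -"q2_in")
}

#' Infit/outfit mean-square and standardized fit statistics
#'
#' Per item and per person: outfit MNSQ (unweighted mean of squared
#' standardized residuals), infit MNSQ (information-weighted,
#' \eqn{\sum y^2 / \sum W}), and their standardized forms via the
#' Wilson-Hilferty cube-root transform with model-based variance
#' (outfit: \eqn{q^2 = [\sum C/W^2 - N]/N^2}; infit:
#' \eqn{q^2 = \sum(C - W^2)/(\sum W)^2}). Reported standardized values are
#' capped at +/- `zstd_cap` (default 9.9). Values outside the configured
#' acceptance bands (default MNSQ 0.75--1.33, Zstd -2..2) are flagged.
#' Also computes scale-level separation and reliability for persons and items
#' via [separation_reliability()].
#'
#' @param resid A residual table from [residual_table()] (or a `pcm_fit`, in
#'   which case `responses` must be supplied).
#' @param responses Response tibble, only needed when `resid` is a fit.
#' @param fit Optional [fit_pcm()] result; enables the scale-level block
#'   (item difficulties and person measures with their standard errors).
#' @param config A [run_config()].
#' @return An object of class `rasch_fitstats` with tibbles `items`,
#'   `persons` and `scale` (separation/reliability per level).
#' @export
fit_statistics <- function(resid, responses = NULL, fit = NULL,
                           config = run_config()) {
  if (inherits(resid, "pcm_fit")) {
    fit <- resid
    resid <- residual_table(fit, responses)
  }
  if (nrow(resid) == 0) stop("empty residual table", call. = FALSE)
  zero_var <- resid$variance <= 1e-12
  if (any(zero_var)) resid <- resid[!zero_var, ]
  items <- mnsq_block(resid, c("item", "label"), config$zstd_cap,
                      config$mnsq_bounds, config$zstd_bounds)
  persons <- mnsq_block(resid, "person_id", config$zstd_cap,
                        config$mnsq_bounds, config$zstd_bounds)
  scale <- NULL
  if (!is.null(fit)) {
    pers <- fit$persons[!fit$persons$extreme, ]
    sr_p <- separation_reliability(pers$theta, pers$se)
    isum <- fit$item_summary
    ise <- fit$items |>
      dplyr::group_by(.data$item) |>
      dplyr::summarise(se = sqrt(mean(.data$se^2)), .groups = "drop")
    sr_i <- separation_reliability(isum$difficulty, ise$se)
    scale <- dplyr::bind_rows(
      dplyr::mutate(sr_p, level = "person", .before = 1),
      dplyr::mutate(sr_i, level = "item", .before = 1)
    )
  }
  structure(list(items = items, persons = persons, scale = scale),
            class = "rasch_fitstats")
}

#' @export
print.rasch_fitstats <- function(x, ...) {
  cat("<rasch_fitstats>\n")
  print(x$items, n = Inf)
  if (!is.null(x$scale)) print(x$scale)
  invisible(x)
}

# -- separation and reliability ----------------------------------------------

#' Separation index and reliability from measures and standard errors
#'
#' The root-mean-square error is \eqn{RMSE = \sqrt{mean(SE^2)}}, the
#' error-corrected ("true") SD is
#' \eqn{\sqrt{\max(0, SD_{obs}^2 - RMSE^2)}}, separation is
#' G = trueSD / RMSE, and reliability R = G^2 / (1 + G^2). A separation above
#' 2 and reliability above 0.8 support that the scale distinguishes the
#' measured entities beyond measurement error.
#'
#' @param measures Numeric vector of at least 2 finite measures (logits).
#' @param ses Positive standard errors of the same length.
#' @return A one-row tibble: `n`, `sd_observed`, `rmse`, `sd_true`,
#'   `separation`, `reliability`, `degenerate` (TRUE when observed variance
#'   does not exceed error variance, in which case G = R = 0).
#' @export
#' @examples
#' separation_reliability(c(-1, 0, 1, 2), c(0.3, 0.3, 0.3, 0.3))
separation_reliability <- function(measures, ses) {
  ok <- is.finite(measures) & is.finite(ses)
  measures <- measures[ok]; ses <- ses[ok]
  if (length(measures) < 2) stop("need >= 2 finite measures", call. = FALSE)
  sd_obs <- sd(measures)
  rmse <- sqrt(mean(ses^2))
  v_true <- sd_obs^2 - rmse^2
  degenerate <- v_true <= 0
  sd_true <- sqrt(max(0, v_true))
  G <- if (degenerate) 0 else sd_true / rmse
  tibble::tibble(
    n = length(measures), sd_observed = sd_obs, rmse = rmse,
    sd_true = sd_true, separation = G,
    reliability = reliability_from_separation(G),
    degenerate = degenerate
  )
}

#' Reliability implied by a separation index
#'
#' The identity R = G^2 / (1 + G^2). Its complement 1 - R is the share of
#' observed measure variance attributable to measurement error.
#'
#' @param G Separation index (non-negative).
#' @return Reliability in `[0, 1)`.
#' @export
#' @examples
#' reliability_from_separation(2.57)  # 0.87 at 2 decimals
#' reliability_from_separation(1)     # 0.5
reliability_from_separation <- function(G) {
  stopifnot(all(G >= 0))
  G^2 / (1 + G^2)
}

#' Error share of measure variance
#'
#' @param reliability Reliability in `[0, 1]`.
#' @return 1 - reliability: the fraction of observed variance due to random
#'   measurement error.
#' @export
#' @examples
#' error_share(0.87)  # 0.13: 13% of the variance is error
error_share <- function(reliability) {
  stopifnot(all(reliability >= 0 & reliability <= 1))
  1 - reliability
}
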