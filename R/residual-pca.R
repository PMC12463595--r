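# -- PCA of standardized residuals -------------------------------------------

#' Item-by-item correlation of standardized residuals
#'
#' Pairwise-complete Pearson correlations between the standardized residuals
#' of all item pairs. Under a unidimensional model the residuals are
#' approximately uncorrelated noise; shared structure signals a secondary
#' dimension. Items with zero residual variance are excluded with a warning.
#'
#' @param resid Residual table from [residual_table()].
#' @return A symmetric correlation matrix with unit diagonal, item labels as
#'   dimnames.
#' @export
residual_correlation <- function(resid) {
  wide <- tidyr::pivot_wider(resid[c("person_id", "label", "std_residual")],
                             names_from = "label",
                             values_from = "std_residual")
  Z <- as.matrix(wide[-1])
  v <- apply(Z, 2, var, na.rm = TRUE)
  drop_items <- names(v)[!is.finite(v) | v <= 1e-12]
  if (length(drop_items) > 0) {
    warning("excluding zero-residual-variance item(s): ",
            paste(drop_items, collapse = ", "), call. = FALSE)
    Z <- Z[, setdiff(colnames(Z), drop_items), drop = FALSE]
  }
  cor(Z, use = "pairwise.complete.obs")
}

#' Contrast eigenvalues and loadings of the residual correlation matrix
#'
#' Eigen-decomposition of the standardized-residual correlation matrix.
#' Eigenvalues are in item (strength-of-one-item) units and sum to the number
#' of items L; a first contrast below 2 is the conventional "no more
#' structure than two items' worth" support for unidimensionality. Loadings
#' of each contrast are signed so that the largest-magnitude loading is
#' positive.
#'
#' @param cormat Correlation matrix from [residual_correlation()].
#' @param n_contrasts Number of contrasts to return loadings for (default 2).
#' @return A list with `eigenvalues` (all, decreasing) and `loadings` (tibble
#'   `label`, `contrast`, `loading`).
#' @export
contrast_eigen <- function(cormat, n_contrasts = 2) {
  if (any(!is.finite(cormat))) {
    stop("correlation matrix has non-finite entries", call. = FALSE)
  }
  eg <- eigen(cormat, symmetric = TRUE)
  n_contrasts <- min(n_contrasts, ncol(cormat))
  loads <- lapply(seq_len(n_contrasts), function(k) {
    v <- eg$vectors[, k] * sqrt(eg$values[k])   # component loadings
    if (v[which.max(abs(v))] < 0) v <- -v
    tibble::tibble(label = colnames(cormat), contrast = k, loading = v)
  })
  list(eigenvalues = eg$values, loadings = dplyr::bind_rows(loads))
}

#' Variance decomposition in eigenvalue units
#'
#' Expresses the variance explained by the Rasch measures in the same
#' "eigenvalue units" as the residual contrasts: with L items, the measure
#' variance is \eqn{V_m = L \cdot SS_{explained} / SS_{residual}}, where
#' \eqn{SS_{explained} = \sum_{pi} (E_{pi} - \bar x_i)^2} (modelled scores
#' about the item means) and \eqn{SS_{residual} = \sum_{pi} (x_{pi} -
#' E_{pi})^2}. Percentages follow: measures% = \eqn{V_m/(V_m+L)}, and
#' contrast k explains \eqn{eig_k/(V_m+L)} — so measures% plus all contrast
#' percentages is 100%.
#'
#' @param fit A [fit_pcm()] result.
#' @param resid Residual table from [residual_table()].
#' @param eigenvalues Contrast eigenvalues from [contrast_eigen()].
#' @return A tibble with one row per component (`measures`, `contrast_1`,
#'   ...): `eigenvalue_units`, `pct_variance`.
#' @export
variance_decomposition <- function(fit, resid, eigenvalues) {
  L <- length(unique(resid$item))
  xbar <- tapply(resid$observed, resid$item, mean)
  ss_expl <- sum((resid$expected - xbar[as.character(resid$item)])^2)
  ss_resid <- sum(resid$residual^2)
  if (ss_resid <= 0) stop("zero residual sum of squares", call. = FALSE)
  v_m <- L * ss_expl / ss_resid
  variance_percents(v_m, eigenvalues, L)
}

#' Percent-variance arithmetic of the residual PCA
#'
#' Pure arithmetic step shared by [variance_decomposition()]: given the
#' measure variance in eigenvalue units, the contrast eigenvalues and the item
#' count, returns each component's share of the total \eqn{V_m + L}.
#'
#' @param v_m Measure variance in eigenvalue units.
#' @param eigenvalues Contrast eigenvalues (item units).
#' @param L Number of items.
#' @return A tibble: `component`, `eigenvalue_units`, `pct_variance`.
#' @export
#' @examples
#' variance_percents(18.08, c(2.27), 15)  # measures 54.7%, contrast 6.9%
variance_percents <- function(v_m, eigenvalues, L) {
  stopifnot(v_m >= 0, L > 0)
  total <- v_m + L
  tibble::tibble(
    component = c("measures", paste0("contrast_", seq_along(eigenvalues))),
    eigenvalue_units = c(v_m, eigenvalues),
    pct_variance = 100 * c(v_m, eigenvalues) / total
  )
}

#' Items contributing to a residual contrast
#'
#' Lists the items whose absolute loading on a contrast reaches the cutoff
#' (default 0.4, a conventional, admittedly arbitrary screen for a
#' meaningful loading).
#'
#' @param loadings Loadings tibble from [contrast_eigen()].
#' @param cutoff Absolute-loading cutoff.
#' @return The qualifying rows of `loadings`, ordered by contrast then
#'   decreasing absolute loading.
#' @export
screen_loadings <- function(loadings, cutoff = 0.4) {
  loadings |>
    dplyr::filter(abs(.data$loading) >= cutoff) |>
    dplyr::arrange(.data$contrast, dplyr::desc(abs(.data$loading)))
}

#' Unidimensionality assessment by PCA of standardized residuals
#'
#' Runs the full residual-PCA chain: residual correlations, contrast
#' eigenvalues and loadings, variance decomposition, and loading screening.
#' The second contrast is screened whenever its eigenvalue reaches
#' `second_contrast_min` (default 1.8).
#'
#' @param fit A [fit_pcm()] result.
#' @param responses The response tibble the model was fitted to.
#' @param config A [run_config()] (`loading_cutoff`, `second_contrast_min`).
#' @return An object of class `residual_pca`: `eigenvalues`, `variance`
#'   (decomposition tibble), `loadings`, `screened` (items over the cutoff,
#'   first contrast always, second when its eigenvalue qualifies),
#'   `unidimensional` (measures% > 40 and first contrast eigenvalue < 2).
#' @export
residual_pca <- function(fit, responses, config = run_config()) {
  resid <- residual_table(fit, responses)
  cm <- residual_correlation(resid)
  ce <- contrast_eigen(cm, n_contrasts = 2)
  decomp <- variance_decomposition(fit, resid, ce$eigenvalues)
  keep <- c(1, if (length(ce$eigenvalues) > 1 &&
                     ce$eigenvalues[2] >= config$second_contrast_min) 2)
  screened <- screen_loadings(
    ce$loadings[ce$loadings$contrast %in% keep, ], config$loading_cutoff)
  structure(
    list(
      eigenvalues = ce$eigenvalues,
      variance = decomp,
      loadings = ce$loadings,
      screened = screened,
      measures_pct = decomp$pct_variance[decomp$component == "measures"],
      unidimensional =
        decomp$pct_variance[decomp$component == "measures"] > 40 &&
        ce$eigenvalues[1] < 2
    ),
    class = "residual_pca"
  )
}

#' @export
print.residual_pca <- function(x, ...) {
  cat("<residual_pca>\n")
  cat(sprintf("  measures explain %.1f%% of the variance\n", x$measures_pct))
  cat(sprintf("  first contrast eigenvalue %.2f (%.1f%%)\n",
              x$eigenvalues[1],
              x$variance$pct_variance[x$variance$component == "contrast_1"]))
  cat(sprintf("  unidimensionality supported: %s\n", x$unidimensional))
  invisible(x)
}
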