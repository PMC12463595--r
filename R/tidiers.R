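# -- broom-style tidiers ------------------------------------------------------

#' Tidy a Partial Credit Model fit
#'
#' @param x A [fit_pcm()] result.
#' @param what `"items"` (one row per step, default), `"persons"`, or
#'   `"difficulty"` (one row per item).
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.pcm_fit <- function(x, what = c("items", "persons", "difficulty"), ...) {
  what <- match.arg(what)
  switch(what,
         items = x$items,
         persons = x$persons,
         difficulty = x$item_summary)
}

#' One-row summary of a Partial Credit Model fit
#'
#' @param x A [fit_pcm()] result.
#' @param ... Unused.
#' @return A one-row tibble: item/person counts, log-likelihood, convergence.
#' @exportS3Method generics::glance
glance.pcm_fit <- function(x, ...) {
  tibble::tibble(
    n_items = max(x$items$item),
    n_persons = nrow(x$persons),
    n_extreme = sum(x$persons$extreme),
    loglik = x$loglik,
    n_iterations = nrow(x$iterations),
    converged = x$converged,
    mean_item_difficulty = mean(x$item_summary$difficulty)
  )
}

#' @rdname tidy.pcm_fit
#' @exportS3Method generics::tidy
tidy.rasch_fitstats <- function(x, what = c("items", "persons", "scale"),
                                ...) {
  what <- match.arg(what)
  x[[what]]
}

#' @rdname tidy.pcm_fit
#' @exportS3Method generics::tidy
tidy.residual_pca <- function(x, what = c("variance", "loadings", "screened"),
                              ...) {
  what <- match.arg(what)
  x[[what]]
}

#' One-row summary of a residual PCA
#'
#' @param x A [residual_pca()] result.
#' @param ... Unused.
#' @return A one-row tibble: measures%, first/second contrast eigenvalues and
#'   the unidimensionality verdict.
#' @exportS3Method generics::glance
glance.residual_pca <- function(x, ...) {
  tibble::tibble(
    measures_pct = x$measures_pct,
    eigenvalue_1 = x$eigenvalues[1],
    eigenvalue_2 = if (length(x$eigenvalues) > 1) x$eigenvalues[2] else NA,
    unidimensional = x$unidimensional
  )
}

#' @rdname tidy.pcm_fit
#' @exportS3Method generics::tidy
tidy.dif_fit <- function(x, what = c("gamma", "path", "flags"), ...) {
  what <- match.arg(what)
  x[[what]]
}

#' One-row summary of a DIF penalty-path fit
#'
#' @param x A [dif_lasso()] result.
#' @param ... Unused.
#' @return A one-row tibble: selected lambda, BIC, nonzero coefficients,
#'   flagged items.
#' @exportS3Method generics::glance
glance.dif_fit <- function(x, ...) {
  sel <- x$path[x$selected, ]
  tibble::tibble(
    lambda = sel$lambda, loglik = sel$loglik, df = sel$df, bic = sel$bic,
    n_nonzero = sel$n_nonzero, n_flagged = sum(x$flags$dif),
    lambda_max = x$lambda_max, n = x$n
  )
}

# -- plots --------------------------------------------------------------------

#' Person-item map of a PCM fit
#'
#' Dot-histogram of person measures mirrored against item difficulties on the
#' shared logit scale (the graphical sibling of [wright_map()]).
#'
#' @param object A [fit_pcm()] result.
#' @param bin Bin width in logits.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.pcm_fit <- function(object, bin = 0.5, ...) {
  pers <- object$persons[!object$persons$extreme, ]
  ggplot2::ggplot() +
    ggplot2::geom_histogram(
      data = pers, ggplot2::aes(x = .data$theta, y = ggplot2::after_stat(count)),
      binwidth = bin, fill = "grey70", colour = "grey40") +
    ggplot2::geom_point(
      data = object$item_summary,
      ggplot2::aes(x = .data$difficulty, y = 0), shape = 17, size = 2) +
    ggplot2::geom_text(
      data = object$item_summary,
      ggplot2::aes(x = .data$difficulty, y = 0, label = .data$item),
      vjust = 2, size = 3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "logit", y = "persons",
                  title = "Person-item map") +
    ggplot2::theme_minimal()
}

#' Scree-style plot of residual-contrast eigenvalues
#'
#' @param object A [residual_pca()] result.
#' @param ... Unused.
#' @return A ggplot with the conventional eigenvalue-2 reference line.
#' @exportS3Method ggplot2::autoplot
autoplot.residual_pca <- function(object, ...) {
  d <- tibble::tibble(contrast = seq_along(object$eigenvalues),
                      eigenvalue = object$eigenvalues)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$contrast, y = .data$eigenvalue)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 2, linetype = 2) +
    ggplot2::labs(x = "residual contrast", y = "eigenvalue (item units)",
                  title = "Standardized-residual PCA") +
    ggplot2::theme_minimal()
}

#' Coefficient-path plot of a DIF fit
#'
#' BIC along the penalty path with the selected model marked.
#'
#' @param object A [dif_lasso()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.dif_fit <- function(object, ...) {
  ggplot2::ggplot(object$path,
                  ggplot2::aes(x = log(.data$lambda), y = .data$bic)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = log(object$path$lambda[object$selected]),
                        linetype = 2) +
    ggplot2::labs(x = expression(log(lambda)), y = "BIC",
                  title = "Penalty path (BIC selection)") +
    ggplot2::theme_minimal()
}
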