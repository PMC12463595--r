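# -- quadrature ---------------------------------------------------------------

#' Gauss-Hermite quadrature for a standard-normal ability
#'
#' Nodes and weights for integrating smooth functions against N(0,1), by
#' Golub-Welsch eigen-decomposition of the Hermite Jacobi matrix.
#'
#' @param n Number of nodes.
#' @return A list with numeric `nodes` and `weights` (weights sum to 1).
#' @export
#' @examples
#' q <- gauss_hermite_normal(21)
#' sum(q$weights * q$nodes^2)  # ~1: the N(0,1) variance
gauss_hermite_normal <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(list(nodes = 0, weights = 1))
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1) / 2)
  J[cbind(1:(n - 1), 2:n)] <- off
  J[cbind(2:n, 1:(n - 1))] <- off
  eg <- eigen(J, symmetric = TRUE)
  ord <- order(eg$values)
  list(nodes = eg$values[ord] * sqrt(2),
       weights = (eg$vectors[1, ord])^2)
}

# -- data preparation ---------------------------------------------------------

# align responses and covariates, recode categories, collapse covariate rows
# to unique patterns
dif_prep <- function(responses, covariates, config) {
  covariates <- as_covariates(covariates)
  idx <- match(as.character(responses$person_id),
               as.character(covariates$person_id))
  if (anyNA(idx)) {
    stop("persons in the response table lack covariate rows", call. = FALSE)
  }
  covariates <- covariates[idx, ]
  X <- resp_matrix(responses)
  rc <- recode_categories(X, config$score_range)
  D <- covariate_dummies(covariates)
  key <- apply(D, 1, paste, collapse = "/")
  ukey <- unique(key)
  Xu <- D[match(ukey, key), , drop = FALSE]
  pat <- match(key, ukey) - 1L
  maxm <- max(rc$m)
  delta0 <- matrix(0, ncol(X), maxm)
  for (i in seq_len(ncol(X))) if (rc$m[i] < maxm) {
    delta0[i, seq(rc$m[i] + 1, maxm)] <- NA
  }
  gh <- gauss_hermite_normal(config$n_quad)
  list(codes = rc$codes, m = rc$m, map = rc$map, labels = colnames(X),
       pat = pat, Xu = Xu, delta_template = delta0,
       nodes = gh$nodes, weights = gh$weights, n = nrow(X))
}

# pad a list of step vectors into the I x maxm template
steps_to_matrix <- function(steps_list, template) {
  out <- template
  for (i in seq_along(steps_list)) {
    out[i, seq_along(steps_list[[i]])] <- steps_list[[i]]
  }
  out[is.na(out)] <- 0   # unused cells, never touched by the likelihood
  out
}

# -- marginal likelihood ------------------------------------------------------

#' Marginal log-likelihood of the uniform-DIF GPCM
#'
#' Adjacent-categories model with item discriminations and group-specific
#' difficulty shifts,
#' \deqn{\log\frac{P(Y_{pi}=r)}{P(Y_{pi}=r-1)} =
#'   \beta_i(\theta_p - \delta_{ir} - x_p^\top\gamma_i),}
#' with the ability integrated out against N(0, sigma^2) by fixed-node
#' Gauss-Hermite quadrature.
#'
#' @param params A list with `beta` (length-I positive vector), `steps`
#'   (list of I step-difficulty vectors), `gamma` (I x 6 matrix of DIF
#'   coefficients over the dummy columns of [covariate_dummies()]) and
#'   `sigma` (positive ability SD).
#' @param responses Response tibble.
#' @param covariates Covariate tibble aligned by `person_id`.
#' @param config A [run_config()] (`n_quad`, `score_range`).
#' @return The marginal log-likelihood (scalar).
#' @export
gpcm_marginal_loglik <- function(params, responses, covariates,
                                 config = run_config()) {
  if (any(!is.finite(unlist(params[c("beta", "steps", "gamma", "sigma")])))) {
    stop("non-finite parameters", call. = FALSE)
  }
  stopifnot(all(params$beta > 0), params$sigma > 0)
  # category structure is declared by the parameters: item i has
  # length(steps[[i]]) + 1 categories, coded from the range minimum
  covariates <- as_covariates(covariates)
  idx <- match(as.character(responses$person_id),
               as.character(covariates$person_id))
  if (anyNA(idx)) {
    stop("persons in the response table lack covariate rows", call. = FALSE)
  }
  X <- resp_matrix(responses)
  codes <- X - config$score_range[1]
  m <- vapply(params$steps, length, 1L)
  if (any(codes > rep(m, each = nrow(codes)), na.rm = TRUE)) {
    stop("responses exceed the category range declared by `params$steps`",
         call. = FALSE)
  }
  D <- covariate_dummies(covariates[idx, ])
  key <- apply(D, 1, paste, collapse = "/")
  ukey <- unique(key)
  delta <- matrix(0, length(m), max(m))
  for (i in seq_along(m)) delta[i, seq_len(m[i])] <- params$steps[[i]]
  gh <- gauss_hermite_normal(config$n_quad)
  res <- gpcm_loglik_cpp(codes, match(key, ukey) - 1L,
                         D[match(ukey, key), , drop = FALSE],
                         params$beta, delta, m, as.matrix(params$gamma),
                         params$sigma, gh$nodes, gh$weights, FALSE)
  res$loglik
}

# internal: loglik (and gradient) on prepared data
eval_gpcm <- function(prep, beta, delta, gamma, sigma, grad = FALSE) {
  gpcm_loglik_cpp(prep$codes, prep$pat, prep$Xu, beta, delta, prep$m,
                  gamma, sigma, prep$nodes, prep$weights, grad)
}

# -- penalized fitting --------------------------------------------------------

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# proximal-gradient fit at one penalty value on prepared data.
# Smooth block: log beta (optional), step difficulties, log sigma (optional);
# gamma block gets the soft-threshold proximal step, so zeros are exact.
fit_penalized_prep <- function(prep, lambda, start = NULL, est_beta = TRUE,
                               est_sigma = FALSE, tol = 1e-7,
                               max_iter = 3000L) {
  I <- length(prep$m); K <- ncol(prep$Xu); maxm <- ncol(prep$delta_template)
  dmask <- !is.na(prep$delta_template)
  if (is.null(start)) {
    start <- list(beta = rep(1, I), delta = matrix(0, I, maxm),
                  gamma = matrix(0, I, K), sigma = 1)
  }
  beta <- start$beta; delta <- start$delta
  gamma <- start$gamma; sigma <- start$sigma

  ev <- eval_gpcm(prep, beta, delta, gamma, sigma, grad = TRUE)
  f <- -ev$loglik
  pen <- if (is.finite(lambda)) lambda * sum(abs(gamma)) else 0
  obj <- f + pen
  step <- 2 / prep$n
  converged <- FALSE
  grad_norm <- NA_real_
  for (it in seq_len(max_iter)) {
    g_lb <- if (est_beta) -beta * ev$grad_beta else rep(0, I)
    g_d <- -ev$grad_delta; g_d[!dmask] <- 0
    g_g <- -ev$grad_gamma
    g_ls <- if (est_sigma) -sigma * ev$grad_sigma else 0
    repeat {
      lb_new <- log(beta) - step * g_lb
      d_new <- delta - step * g_d
      ls_new <- log(sigma) - step * g_ls
      g_new <- if (is.finite(lambda)) {
        soft_threshold(gamma - step * g_g, step * lambda)
      } else {
        matrix(0, I, K)
      }
      beta_new <- exp(pmin(pmax(lb_new, -4), 4))
      sigma_new <- exp(pmin(pmax(ls_new, -4), 4))
      ev_new <- eval_gpcm(prep, beta_new, d_new, g_new, sigma_new,
                          grad = FALSE)
      f_new <- -ev_new$loglik
      dx <- c(lb_new - log(beta), d_new[dmask] - delta[dmask],
              g_new - gamma, ls_new - log(sigma))
      gvec <- c(g_lb, g_d[dmask], g_g, g_ls)
      if (f_new <= f + sum(gvec * dx) + sum(dx^2) / (2 * step) + 1e-10 ||
          step < 1e-12) break
      step <- step / 2
    }
    beta <- beta_new; delta <- d_new; gamma <- g_new; sigma <- sigma_new
    pen_new <- if (is.finite(lambda)) lambda * sum(abs(gamma)) else 0
    obj_new <- f_new + pen_new
    rel <- (obj - obj_new) / (abs(obj) + 1)
    obj <- obj_new
    ev <- eval_gpcm(prep, beta, delta, gamma, sigma, grad = TRUE)
    f <- -ev$loglik
    step <- min(step * 2, 100 / prep$n)
    if (it > 1 && abs(rel) < tol) { converged <- TRUE; break }
  }
  g_g <- -ev$grad_gamma
  grad_norm <- sqrt(sum(ev$grad_delta[dmask]^2) +
                      if (est_beta) sum((beta * ev$grad_beta)^2) else 0)
  list(beta = beta, delta = delta, gamma = gamma, sigma = sigma,
       loglik = ev$loglik, grad_gamma = -g_g, converged = converged,
       grad_norm = grad_norm, iterations = it)
}

#' Fit the lasso-penalized GPCM at one penalty value
#'
#' Maximizes the marginal log-likelihood minus \eqn{\lambda \sum |\gamma|}
#' by proximal-gradient iterations with backtracking: smooth updates on the
#' discriminations (log scale), step difficulties and (optionally) the
#' ability SD, and a soft-threshold proximal step on the DIF coefficients —
#' so reported zero coefficients are exactly zero.
#'
#' By default the ability SD is fixed at 1 and discriminations are free
#' (estimating both jointly is unidentified in this model; see the vignette).
#'
#' @param responses Response tibble (rescored data recommended, matching the
#'   reference analysis workflow).
#' @param covariates Covariate tibble.
#' @param lambda Penalty value (>= 0; `Inf` freezes all gamma at 0).
#' @param config A [run_config()].
#' @param est_beta Estimate discriminations (default TRUE).
#' @param est_sigma Estimate the ability SD (default FALSE; only identified
#'   with `est_beta = FALSE`).
#' @param start Optional warm-start parameter list.
#' @return A list with `beta`, `steps` (list), `gamma` (items x dummies, with
#'   dimnames), `sigma`, `loglik` (unpenalized, at the solution), `df`
#'   (nonzero free parameters), `bic`, `converged`, `grad_norm`.
#' @export
fit_penalized <- function(responses, covariates, lambda,
                          config = run_config(), est_beta = TRUE,
                          est_sigma = FALSE, start = NULL) {
  stopifnot(lambda >= 0)
  prep <- dif_prep(responses, covariates, config)
  res <- fit_penalized_prep(prep, lambda, start = start, est_beta = est_beta,
                            est_sigma = est_sigma, tol = config$prox_tol,
                            max_iter = config$prox_max_iter)
  finish_penalized(res, prep, est_beta, est_sigma)
}

finish_penalized <- function(res, prep, est_beta, est_sigma) {
  I <- length(prep$m)
  steps <- lapply(seq_len(I), function(i) res$delta[i, seq_len(prep$m[i])])
  names(steps) <- prep$labels
  gamma <- res$gamma
  dimnames(gamma) <- list(prep$labels, colnames(prep$Xu))
  df <- sum(prep$m) + (if (est_beta) I else 0L) +
    (if (est_sigma) 1L else 0L) + sum(gamma != 0)
  list(beta = res$beta, steps = steps, gamma = gamma, sigma = res$sigma,
       loglik = res$loglik, df = df,
       bic = -2 * res$loglik + df * log(prep$n),
       converged = res$converged, grad_norm = res$grad_norm,
       grad_gamma = res$grad_gamma, iterations = res$iterations)
}

# -- penalty path with BIC selection -----------------------------------------

#' Uniform DIF detection along a lasso penalty path with BIC selection
#'
#' Fits the penalized GPCM over a log-spaced grid of penalty values from
#' \eqn{\lambda_{max}} (the smallest penalty at which every DIF coefficient
#' is zero, from the Karush-Kuhn-Tucker condition at the no-DIF fit) down to
#' \eqn{\lambda_{max}/1000}, with warm starts along the path. Each model's
#' BIC is \eqn{-2\,\mathrm{logLik} + df\,\log(n)} with df the number of
#' nonzero free parameters; the selected model minimizes BIC among converged
#' fits. An item is flagged for uniform DIF when any of its coefficients is
#' nonzero in the selected model.
#'
#' @inheritParams fit_penalized
#' @param n_lambda Number of grid points (default from `config`).
#' @return An object of class `dif_fit`: `path` (per-lambda tibble with
#'   `lambda`, `loglik`, `df`, `bic`, `n_nonzero`, `converged`), `selected`
#'   (index into the path), `model` (parameter list of the selected model),
#'   `gamma` (selected DIF coefficients, tibble item x dummy columns),
#'   `flags` (per-item logical), `lambda_max`, `n`.
#' @export
dif_lasso <- function(responses, covariates, config = run_config(),
                      n_lambda = config$n_lambda, est_beta = TRUE,
                      est_sigma = FALSE) {
  prep <- dif_prep(responses, covariates, config)
  null_fit <- fit_penalized_prep(prep, Inf, est_beta = est_beta,
                                 est_sigma = est_sigma,
                                 tol = config$prox_tol,
                                 max_iter = config$prox_max_iter)
  lambda_max <- max(abs(null_fit$grad_gamma))
  if (!is.finite(lambda_max) || lambda_max <= 0) lambda_max <- 1
  grid <- exp(seq(log(lambda_max), log(lambda_max * 1e-3),
                  length.out = n_lambda))
  fits <- vector("list", n_lambda)
  start <- null_fit[c("beta", "delta", "gamma", "sigma")]
  rows <- vector("list", n_lambda)
  for (j in seq_len(n_lambda)) {
    res <- fit_penalized_prep(prep, grid[j], start = start,
                              est_beta = est_beta, est_sigma = est_sigma,
                              tol = config$prox_tol,
                              max_iter = config$prox_max_iter)
    start <- res[c("beta", "delta", "gamma", "sigma")]
    fin <- finish_penalized(res, prep, est_beta, est_sigma)
    fits[[j]] <- fin
    rows[[j]] <- tibble::tibble(
      lambda = grid[j], loglik = fin$loglik,
      penalized_loglik = fin$loglik - grid[j] * sum(abs(res$gamma)),
      df = fin$df, bic = fin$bic, n_nonzero = sum(res$gamma != 0),
      converged = fin$converged
    )
  }
  path <- dplyr::bind_rows(rows)
  eligible <- which(path$converged)
  if (length(eligible) == 0) {
    stop("no penalty value converged", call. = FALSE)
  }
  selected <- eligible[which.min(path$bic[eligible])]
  model <- fits[[selected]]
  gamma_tbl <- dplyr::bind_cols(
    tibble::tibble(item = seq_along(prep$labels), label = prep$labels),
    tibble::as_tibble(model$gamma)
  )
  flags <- rowSums(model$gamma != 0) > 0
  structure(
    list(path = path, selected = selected, model = model, gamma = gamma_tbl,
         flags = tibble::tibble(item = seq_along(prep$labels),
                                label = prep$labels, dif = unname(flags)),
         lambda_max = lambda_max, n = prep$n,
         est_beta = est_beta, est_sigma = est_sigma),
    class = "dif_fit"
  )
}

#' @export
print.dif_fit <- function(x, ...) {
  cat(sprintf(
    "<dif_fit> %d-point penalty path, BIC-selected lambda = %.4g (index %d)\n",
    nrow(x$path), x$path$lambda[x$selected], x$selected))
  cat(sprintf("  %d of %d items flagged for uniform DIF\n",
              sum(x$flags$dif), nrow(x$flags)))
  invisible(x)
}

#' Per-item DIF coefficient table
#'
#' One row per item, one column per covariate dummy (`female`;
#' `kindergarten`, `primary`, `junior_high`; `non_autism`, `severe`), from
#' the BIC-selected model. A zero coefficient means the coded group functions
#' equally to the reference group on that item; a nonzero \eqn{\gamma}
#' shifts the item's effective difficulty by \eqn{\gamma} logits for that
#' group (group difficulty = baseline difficulty + \eqn{\gamma}).
#'
#' @param dif A [dif_lasso()] result.
#' @return A tibble: `item`, `label`, six coefficient columns, `dif` flag.
#' @export
dif_report <- function(dif) {
  stopifnot(inherits(dif, "dif_fit"))
  dplyr::left_join(dif$gamma, dif$flags[c("item", "dif")], by = "item")
}

# -- classical comparator -----------------------------------------------------

#' Classical two-group Welch test on one item
#'
#' The per-item classical DIF comparator: a Welch unequal-variance t test of
#' the item's scores (or of its standardized PCM residuals, which condition
#' on overall severity, when a fit is supplied) between two covariate groups.
#'
#' @param responses Response tibble.
#' @param covariates Covariate tibble.
#' @param item Item index or label.
#' @param group Covariate to split on (default `"gender"`); must be binary in
#'   the data, otherwise supply `levels`.
#' @param levels Optional length-2 character: the two levels to compare.
#' @param fit Optional [fit_pcm()] result; when given, the test is on
#'   standardized residuals instead of raw scores.
#' @return A one-row tibble: group ns, means, `statistic`, `df`, `p_value`.
#' @export
welch_dif_baseline <- function(responses, covariates, item,
                               group = "gender", levels = NULL, fit = NULL) {
  covariates <- as_covariates(covariates)
  labels <- item_cols(responses)
  if (is.character(item)) item <- match(item, labels)
  stopifnot(!is.na(item), item >= 1, item <= length(labels))
  if (is.null(fit)) {
    values <- responses[[labels[item]]]
    ids <- responses$person_id
  } else {
    resid <- residual_table(fit, responses)
    resid <- resid[resid$item == item, ]
    values <- resid$std_residual
    ids <- resid$person_id
  }
  g <- covariates[[group]][match(as.character(ids),
                                 as.character(covariates$person_id))]
  if (is.null(levels)) {
    levels <- base::levels(droplevels(g))
    if (length(levels) != 2) {
      stop("'", group, "' is not binary here; supply `levels`",
           call. = FALSE)
    }
  }
  x1 <- values[g == levels[1] & !is.na(values)]
  x2 <- values[g == levels[2] & !is.na(values)]
  if (length(x1) < 2 || length(x2) < 2) {
    stop("each group needs at least 2 members", call. = FALSE)
  }
  out <- welch_t_summary(length(x1), mean(x1), sd(x1),
                         length(x2), mean(x2), sd(x2))
  dplyr::bind_cols(
    tibble::tibble(item = item, label = labels[item],
                   group1 = levels[1], group2 = levels[2],
                   n1 = length(x1), n2 = length(x2),
                   mean1 = mean(x1), mean2 = mean(x2)),
    out
  )
}
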