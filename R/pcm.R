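# -- partial credit model primitives ----------------------------------------

#' Partial Credit Model category probabilities
#'
#' Probability of each response category 0..m under the PCM with
#' \eqn{P(X=h) \propto \exp\{\sum_{k \le h} (\theta - \delta_k)\}} (the empty
#' sum for h = 0 being 0). Computed with a row-wise max shift for numerical
#' stability; exact to enumeration.
#'
#' @param theta Numeric vector of person locations (logits).
#' @param steps Numeric vector of step difficulties \eqn{\delta_1..\delta_m}
#'   (Andrich thresholds, logits).
#' @return For scalar `theta` a probability vector of length m+1; otherwise a
#'   matrix with one row per theta. Rows sum to 1.
#' @export
#' @examples
#' category_probabilities(0, c(0, 0, 0))   # uniform 1/4
#' category_probabilities(0, 0)            # dichotomous at threshold: 0.5/0.5
category_probabilities <- function(theta, steps) {
  p <- pcm_probs(theta, steps)
  if (length(theta) == 1) drop(p) else p
}

# internal matrix version: length(theta) x (m+1); collapses to unique theta
# values first (raw score is sufficient, so JML fits have few distinct ones)
pcm_probs <- function(theta, steps) {
  u <- unique(theta)
  if (length(u) < 0.7 * length(theta)) {
    p <- pcm_probs_raw(u, steps)
    return(p[match(theta, u), , drop = FALSE])
  }
  pcm_probs_raw(theta, steps)
}

pcm_probs_raw <- function(theta, steps) {
  m <- length(steps)
  cs <- c(0, cumsum(steps))
  z <- outer(theta, 0:m) - matrix(cs, length(theta), m + 1, byrow = TRUE)
  z <- z - apply(z, 1, max)
  p <- exp(z)
  p / rowSums(p)
}

#' Conditional moments of an item score under the PCM
#'
#' Expected score E, model variance W and fourth central moment C of a single
#' item response at given person locations — the ingredients of residual-based
#' fit statistics.
#'
#' @inheritParams category_probabilities
#' @return A tibble with columns `theta`, `E`, `W`, `C`.
#' @export
#' @examples
#' expected_score_moments(0, c(0, 0, 0))  # E = 1.5 by symmetry
expected_score_moments <- function(theta, steps) {
  mom <- pcm_moments(theta, steps)
  tibble::tibble(theta = theta, E = mom$E, W = mom$W, C = mom$C)
}

# internal: list(E, W, C) vectors over theta (computed on unique values)
pcm_moments <- function(theta, steps) {
  u <- unique(theta)
  idx <- match(theta, u)
  p <- pcm_probs_raw(u, steps)
  h <- 0:length(steps)
  E <- drop(p %*% h)
  W <- drop(p %*% h^2) - E^2
  dev <- outer(rep(1, length(u)), h) - E
  C <- rowSums(p * dev^4)
  list(E = E[idx], W = pmax(W, 0)[idx], C = pmax(C, 0)[idx])
}

# -- internal calibration helpers -------------------------------------------

# recode raw categories to 0..m_i per item, structurally dropping unobserved
# categories; returns list(codes matrix, steps_per_item, map tibble)
recode_categories <- function(X, score_range) {
  n_items <- ncol(X)
  labels <- colnames(X)
  codes <- matrix(NA_integer_, nrow(X), n_items, dimnames = dimnames(X))
  maps <- vector("list", n_items)
  m_i <- integer(n_items)
  for (i in seq_len(n_items)) {
    obs <- sort(unique(X[, i][!is.na(X[, i])]))
    if (length(obs) < 2) {
      stop(sprintf("item '%s' has fewer than 2 observed categories",
                   labels[i]), call. = FALSE)
    }
    code <- match(X[, i], obs) - 1L
    codes[, i] <- code
    all_raw <- seq(min(obs), max(obs))
    maps[[i]] <- tibble::tibble(
      item = i, label = labels[i], raw = as.integer(all_raw),
      code = match(all_raw, obs) - 1L   # NA = structurally dropped
    )
    m_i[i] <- length(obs) - 1L
  }
  list(codes = codes, m = m_i, map = dplyr::bind_rows(maps))
}

# sum of log category probabilities over observed cells
pcm_loglik <- function(codes, theta, steps_list) {
  ll <- 0
  for (i in seq_along(steps_list)) {
    obs <- which(!is.na(codes[, i]))
    if (length(obs) == 0) next
    p <- pcm_probs(theta[obs], steps_list[[i]])
    ll <- ll + sum(log(pmax(p[cbind(seq_along(obs), codes[obs, i] + 1L)],
                            1e-300)))
  }
  ll
}

# per-person sum of E and W over observed items
pcm_score_fun <- function(codes, theta, steps_list) {
  n <- length(theta)
  Esum <- numeric(n); Wsum <- numeric(n)
  for (i in seq_along(steps_list)) {
    obs <- which(!is.na(codes[, i]))
    if (length(obs) == 0) next
    mom <- pcm_moments(theta[obs], steps_list[[i]])
    Esum[obs] <- Esum[obs] + mom$E
    Wsum[obs] <- Wsum[obs] + mom$W
  }
  list(E = Esum, W = Wsum)
}

# Newton ingredients for item i's steps: gradient and expected information
item_step_newton <- function(code_i, theta, steps) {
  obs <- which(!is.na(code_i))
  m <- length(steps)
  p <- pcm_probs(theta[obs], steps)
  # S[, r] = P(h >= r), r = 1..m
  S <- vapply(seq_len(m), function(r)
    rowSums(p[, seq(r + 1, m + 1), drop = FALSE]), numeric(nrow(p)))
  Tr <- vapply(seq_len(m), function(r) sum(code_i[obs] >= r), 0)
  g <- colSums(S) - Tr                     # d loglik / d delta_r
  cS <- colSums(S)
  M <- matrix(cS[pmax(rep(seq_len(m), m), rep(seq_len(m), each = m))], m, m)
  info <- M - crossprod(S)                 # sum_p Cov(u_r, u_s), = -Hessian
  list(g = g, info = info, n_obs = length(obs))
}

# ML theta for fractional target scores given anchored steps (Newton)
solve_theta <- function(target, codes_row_obs, steps_list, init = 0,
                        tol = 1e-8, max_iter = 100) {
  theta <- init
  for (k in seq_len(max_iter)) {
    E <- 0; W <- 0
    for (i in codes_row_obs) {
      mom <- pcm_moments(theta, steps_list[[i]])
      E <- E + mom$E; W <- W + mom$W
    }
    step <- (target - E) / pmax(W, 1e-10)
    step <- pmin(pmax(step, -1), 1)
    theta <- theta + step
    if (abs(step) < tol) break
  }
  theta
}

# -- JML calibration ---------------------------------------------------------

#' Calibrate a Partial Credit Model by joint maximum likelihood
#'
#' Alternating Newton updates of person measures and item step difficulties
#' (Andrich thresholds) under the PCM, with the identification convention that
#' the mean item difficulty (mean of each item's steps, averaged over items)
#' is 0 logits. Persons with extreme (all-minimum or all-maximum) raw scores
#' are excluded from item estimation and receive measures from a fractional
#' score adjustment (see `extreme_adjust` in [run_config()]). Standard errors
#' come from the inverse observed information at the solution. Raw categories
#' that attract no responses are structurally dropped and the remaining
#' categories renumbered; the mapping is recorded in the fit.
#'
#' No incidental-parameter bias correction is applied: estimates differ from
#' conditional/marginal estimators, which matters mainly for extreme step
#' difficulties (see the package vignette).
#'
#' @param responses Response tibble (`person_id` + one integer column per
#'   item).
#' @param config A [run_config()] (convergence tolerance, max iterations,
#'   extreme-score adjustment).
#' @return An object of class `pcm_fit` with tibble fields:
#'   * `items`: one row per item step (`item`, `label`, `step`, `delta`,
#'     `se`);
#'   * `item_summary`: per-item difficulty (mean of its steps) and step count;
#'   * `persons`: `person_id`, `total` (raw-scale total over observed items),
#'     `theta`, `se`, `extreme`;
#'   * `iterations`: per-iteration largest parameter change and
#'     log-likelihood;
#'   * `category_map`: raw-to-internal category codes, `NA` code = dropped;
#'   plus `converged` and the key settings.
#' @export
#' @examples
#' sim <- simulate_cars(design_table1(n_persons = 300), seed = 7)
#' fit <- fit_pcm(sim$responses)
#' fit
fit_pcm <- function(responses, config = run_config()) {
  validate_responses(responses, config$score_range)
  X <- resp_matrix(responses)
  if (ncol(X) < 2) stop("need at least 2 items", call. = FALSE)
  rc <- recode_categories(X, config$score_range)
  codes <- rc$codes
  n <- nrow(codes); n_items <- ncol(codes)
  labels <- colnames(codes)
  max_obs <- matrix(rep(rc$m, each = n), n, n_items) * !is.na(codes)
  total <- rowSums(codes, na.rm = TRUE)
  maxposs <- rowSums(max_obs)
  n_obs_items <- rowSums(!is.na(codes))
  extreme <- total == 0 | total == maxposs | n_obs_items == 0
  if (sum(!extreme) < 2) {
    stop("fewer than 2 persons with non-extreme scores", call. = FALSE)
  }

  ne <- which(!extreme)
  codes_ne <- codes[ne, , drop = FALSE]
  tot_ne <- total[ne]; max_ne <- maxposs[ne]
  theta <- log((tot_ne + 0.5) / (max_ne - tot_ne + 0.5))
  steps_list <- lapply(rc$m, function(m) rep(0, m))

  iters <- list()
  converged <- FALSE
  ll_old <- pcm_loglik(codes_ne, theta, steps_list)
  for (it in seq_len(config$max_iter)) {
    # proposed person step (Newton on the score equation)
    sf <- pcm_score_fun(codes_ne, theta, steps_list)
    dtheta <- pmin(pmax((tot_ne - sf$E) / pmax(sf$W, 1e-10), -1), 1)
    # proposed item steps given updated persons
    theta_try <- theta + dtheta
    ddelta <- vector("list", n_items)
    for (i in seq_len(n_items)) {
      nw <- item_step_newton(codes_ne[, i], theta_try, steps_list[[i]])
      d <- tryCatch(solve(nw$info, nw$g), error = function(e) {
        nw$g / pmax(diag(nw$info), 1e-8)
      })
      ddelta[[i]] <- pmin(pmax(d, -1), 1)
    }
    # accept with step halving so the joint log-likelihood never decreases
    scale <- 1
    repeat {
      th_new <- theta + scale * dtheta
      st_new <- lapply(seq_len(n_items),
                       function(i) steps_list[[i]] + scale * ddelta[[i]])
      ll_new <- pcm_loglik(codes_ne, th_new, st_new)
      if (ll_new >= ll_old - 1e-9 || scale < 1e-4) break
      scale <- scale / 2
    }
    max_change <- scale * max(abs(dtheta),
                              max(vapply(ddelta, function(d) max(abs(d)), 0)))
    theta <- th_new; steps_list <- st_new; ll_old <- ll_new
    # identification: mean item difficulty -> 0 (shift leaves loglik intact)
    centre <- mean(vapply(steps_list, mean, 0))
    steps_list <- lapply(steps_list, function(s) s - centre)
    theta <- theta - centre
    iters[[it]] <- tibble::tibble(iter = it, max_change = max_change,
                                  loglik = ll_new)
    if (max_change < config$conv_tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("PCM calibration did not converge in ", config$max_iter,
            " iterations", call. = FALSE)
  }

  # JML statistical-bias correction: shrink the (centred) step difficulties
  # by (I-1)/I — JML inflates the item logit spread by ~I/(I-1) however large
  # n gets — then re-solve person measures against the corrected items
  if (config$bias_correction && n_items > 1) {
    shrink <- (n_items - 1) / n_items
    steps_list <- lapply(steps_list, function(s) s * shrink)
    for (k in seq_len(100)) {
      sf <- pcm_score_fun(codes_ne, theta, steps_list)
      dth <- pmin(pmax((tot_ne - sf$E) / pmax(sf$W, 1e-10), -1), 1)
      theta <- theta + dth
      if (max(abs(dth)) < 1e-7) break
    }
  }

  # standard errors
  sf <- pcm_score_fun(codes_ne, theta, steps_list)
  se_theta <- 1 / sqrt(pmax(sf$W, 1e-10))
  item_rows <- list()
  for (i in seq_len(n_items)) {
    nw <- item_step_newton(codes_ne[, i], theta, steps_list[[i]])
    se_d <- sqrt(pmax(diag(tryCatch(solve(nw$info),
                                    error = function(e)
                                      diag(1 / pmax(diag(nw$info), 1e-8)))),
                      0))
    item_rows[[i]] <- tibble::tibble(
      item = i, label = labels[i], step = seq_along(steps_list[[i]]),
      delta = steps_list[[i]], se = se_d
    )
  }
  items <- dplyr::bind_rows(item_rows)

  # measures for all persons (extremes via fractional-score adjustment)
  theta_all <- numeric(n); se_all <- numeric(n)
  theta_all[ne] <- theta; se_all[ne] <- se_theta
  for (p in which(extreme)) {
    obs <- which(!is.na(codes[p, ]))
    if (length(obs) == 0) { theta_all[p] <- NA; se_all[p] <- NA; next }
    targ <- if (total[p] == 0) config$extreme_adjust
            else maxposs[p] - config$extreme_adjust
    th <- solve_theta(targ, obs, steps_list)
    theta_all[p] <- th
    W <- sum(pcm_score_fun(codes[p, , drop = FALSE], th, steps_list)$W)
    se_all[p] <- 1 / sqrt(pmax(W, 1e-10))
  }

  raw_total <- rowSums(X, na.rm = TRUE)
  persons <- tibble::tibble(
    person_id = rownames(codes), total = as.numeric(raw_total),
    theta = theta_all, se = se_all, extreme = extreme
  )

  structure(
    list(
      items = items,
      item_summary = items |>
        dplyr::group_by(.data$item, .data$label) |>
        dplyr::summarise(difficulty = mean(.data$delta),
                         n_steps = dplyr::n(), .groups = "drop"),
      persons = persons,
      iterations = dplyr::bind_rows(iters),
      category_map = rc$map,
      converged = converged,
      loglik = pcm_loglik(codes_ne, theta, steps_list),
      conv_tol = config$conv_tol,
      extreme_adjust = config$extreme_adjust,
      bias_correction = config$bias_correction
    ),
    class = "pcm_fit"
  )
}

#' @export
print.pcm_fit <- function(x, ...) {
  cat(sprintf(
    "<pcm_fit> %d items, %d persons (%d extreme), %s after %d iterations\n",
    max(x$items$item), nrow(x$persons), sum(x$persons$extreme),
    if (x$converged) "converged" else "NOT converged", nrow(x$iterations)
  ))
  cat(sprintf("  log-likelihood %.2f; mean item difficulty %.4f\n",
              x$loglik, mean(x$item_summary$difficulty)))
  invisible(x)
}

# internal: steps per item as a list, from a pcm_fit
fit_steps <- function(fit) {
  split(fit$items$delta, fit$items$item)
}

#' Score persons against anchored item parameters
#'
#' Maximum-likelihood person measures for new response rows (or bare total
#' scores) under the step difficulties of an existing fit. Extreme raw scores
#' receive the fractional-score adjustment and are flagged.
#'
#' @param responses A response tibble with the same item columns as the fit,
#'   or a numeric vector of total *internal* scores (sum of 0-based category
#'   codes over all items).
#' @param fit A [fit_pcm()] result supplying the anchored steps.
#' @param config A [run_config()] (extreme-score adjustment).
#' @return A tibble with `theta`, `se` and `extreme`.
#' @export
score_person <- function(responses, fit, config = run_config()) {
  steps_list <- fit_steps(fit)
  m_tot <- sum(vapply(steps_list, length, 1L))
  if (is.numeric(responses) && is.null(dim(responses))) {
    totals <- responses
    obs_list <- rep(list(seq_along(steps_list)), length(totals))
    maxposs <- rep(m_tot, length(totals))
  } else {
    X <- resp_matrix(responses)
    rc <- recode_categories_anchored(X, fit)
    totals <- rowSums(rc, na.rm = TRUE)
    obs_list <- apply(!is.na(rc), 1, which, simplify = FALSE)
    maxposs <- vapply(obs_list, function(o)
      sum(vapply(steps_list[o], length, 1L)), 0)
  }
  out <- lapply(seq_along(totals), function(p) {
    extreme <- totals[p] <= 0 || totals[p] >= maxposs[p]
    targ <- if (totals[p] <= 0) config$extreme_adjust
            else if (totals[p] >= maxposs[p]) maxposs[p] - config$extreme_adjust
            else totals[p]
    th <- solve_theta(targ, obs_list[[p]], steps_list)
    W <- sum(vapply(obs_list[[p]], function(i)
      pcm_moments(th, steps_list[[i]])$W, 0))
    tibble::tibble(theta = th, se = 1 / sqrt(pmax(W, 1e-10)),
                   extreme = extreme)
  })
  dplyr::bind_rows(out)
}

# map raw responses through the fit's category map to internal codes
recode_categories_anchored <- function(X, fit) {
  out <- matrix(NA_integer_, nrow(X), ncol(X), dimnames = dimnames(X))
  for (i in seq_len(ncol(X))) {
    map <- fit$category_map[fit$category_map$item == i, ]
    out[, i] <- map$code[match(X[, i], map$raw)]
  }
  out
}
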