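# R-side quadrature-free oracle: marginal likelihood by adaptive integration
oracle_marginal_loglik <- function(params, responses, covariates) {
  X <- covariate_dummies(covariates)
  Y <- pcmdif:::resp_matrix(responses) - 1L
  pcat <- function(theta, beta, steps, off) {
    z <- cumsum(c(0, beta * (theta - steps - off)))
    p <- exp(z - max(z))
    p / sum(p)
  }
  ll <- 0
  for (p in seq_len(nrow(Y))) {
    f <- function(th) vapply(th, function(t) {
      v <- stats::dnorm(t, 0, params$sigma)
      for (i in seq_along(params$steps)) {
        if (is.na(Y[p, i])) next
        off <- sum(X[p, ] * params$gamma[i, ])
        v <- v * pcat(t, params$beta[i], params$steps[[i]], off)[Y[p, i] + 1]
      }
      v
    }, 0)
    ll <- ll + log(stats::integrate(f, -Inf, Inf, rel.tol = 1e-10)$value)
  }
  ll
}

toy_gpcm <- function() {
  resp <- tibble::tibble(person_id = 1:3, a = c(1L, 3L, 4L),
                         b = c(2L, 2L, 1L), c = c(4L, 1L, 3L))
  cov <- toy_covariates(3)
  set.seed(8)
  params <- list(
    beta = c(1.2, 0.8, 1.0),
    steps = list(c(-1, 0, 1), c(-0.5, 0.5, 1.5), c(-2, 0, 2)),
    gamma = matrix(rnorm(18, 0, 0.3), 3, 6),
    sigma = 1.1
  )
  list(resp = resp, cov = cov, params = params)
}

test_that("quadrature matches adaptive integration on a toy set", {
  t <- toy_gpcm()
  ll <- gpcm_marginal_loglik(t$params, t$resp, t$cov,
                             run_config(n_quad = 41))
  ll0 <- oracle_marginal_loglik(t$params, t$resp, t$cov)
  expect_equal(ll, ll0, tolerance = 1e-4)
  # default node count is already close
  ll21 <- gpcm_marginal_loglik(t$params, t$resp, t$cov, run_config())
  expect_equal(ll21, ll0, tolerance = 1e-3)
})

test_that("the marginal likelihood is additive and reduces to the PCM", {
  t <- toy_gpcm()
  ll <- gpcm_marginal_loglik(t$params, t$resp, t$cov, run_config())
  stacked <- dplyr::bind_rows(t$resp,
                              dplyr::mutate(t$resp, person_id = 4:6))
  cov2 <- dplyr::bind_rows(t$cov, dplyr::mutate(t$cov, person_id = 4:6))
  ll2 <- gpcm_marginal_loglik(t$params, stacked, cov2, run_config())
  expect_equal(ll2, 2 * ll, tolerance = 1e-10)

  # beta = 1, gamma = 0, sigma -> 0: one person at theta = 0 follows the PCM
  params <- list(beta = rep(1, 3), steps = t$params$steps,
                 gamma = matrix(0, 3, 6), sigma = 1e-4)
  one <- t$resp[1, ]
  llp <- gpcm_marginal_loglik(params, one, t$cov[1, ], run_config())
  direct <- sum(vapply(1:3, function(i) {
    log(category_probabilities(0, params$steps[[i]])[one[[i + 1]]])
  }, 0))
  expect_equal(llp, direct, tolerance = 1e-4)

  expect_error(
    gpcm_marginal_loglik(list(beta = c(1, 1, NaN), steps = t$params$steps,
                              gamma = t$params$gamma, sigma = 1),
                         t$resp, t$cov),
    "non-finite"
  )
})

test_that("heavy penalties zero every DIF coefficient exactly", {
  sim <- simulate_cars(design_table1(n_persons = 300), seed = 61)
  cfg <- run_config(n_quad = 11, prox_tol = 1e-6, prox_max_iter = 500)
  f <- fit_penalized(sim$responses, sim$covariates, lambda = 1e5,
                     config = cfg)
  expect_true(all(f$gamma == 0))       # exact zeros, not small floats
  expect_true(all(f$beta > 0))
})

test_that("the l1 norm of DIF coefficients shrinks along the penalty", {
  dif <- matrix(0, 15, 6); dif[2, 1] <- 1
  sim <- simulate_cars(design_table1(n_persons = 600, dif = dif), seed = 62)
  cfg <- run_config(n_quad = 11, prox_tol = 1e-6, prox_max_iter = 1500)
  lams <- c(0.5, 5, 50)
  norms <- vapply(lams, function(l) {
    sum(abs(fit_penalized(sim$responses, sim$covariates, l,
                          config = cfg)$gamma))
  }, 0)
  expect_true(all(diff(norms) <= 1e-4))
})

test_that("a planted coefficient is recovered when barely penalized", {
  dif <- matrix(0, 15, 6); dif[1, 1] <- 1.0
  sim <- simulate_cars(design_table1(n_persons = 2000, dif = dif), seed = 31)
  cfg <- run_config(n_quad = 15, prox_tol = 1e-7, prox_max_iter = 8000)
  f <- fit_penalized(sim$responses, sim$covariates, lambda = 0.01,
                     config = cfg, est_beta = FALSE, est_sigma = TRUE)
  expect_lt(abs(f$gamma[1, 1] - 1.0), 0.3)
  # unplanted gender coefficients stay small (the tiny junior-high stratum,
  # ~12 persons here, cannot pin its own coefficients down and is ignored)
  expect_lt(max(abs(f$gamma[-1, 1])), 0.5)
})

test_that("with the penalty saturated the GPCM agrees with the JML engine", {
  d <- recovery_design(2000)
  sim <- simulate_cars(d, seed = 63)
  cfg <- run_config(n_quad = 15, prox_tol = 1e-7, prox_max_iter = 5000)
  f <- fit_penalized(sim$responses, sim$covariates, lambda = 1e5,
                     config = cfg, est_beta = FALSE, est_sigma = TRUE)
  jml <- fit_pcm(sim$responses)
  # compare centred step difficulties (the two identifications differ by a
  # location shift); different estimation families, 0.15-logit tolerance
  mml_steps <- unlist(f$steps)
  mml_steps <- mml_steps - mean(mml_steps)
  jml_steps <- jml$items$delta - mean(jml$items$delta)
  expect_lt(max(abs(mml_steps - jml_steps)), 0.15)
})

test_that("BIC bookkeeping is exact along the path", {
  sim <- simulate_cars(design_table1(n_persons = 400), seed = 64)
  cfg <- run_config(n_quad = 11, n_lambda = 4, prox_tol = 1e-5,
                    prox_max_iter = 800)
  fit <- dif_lasso(sim$responses, sim$covariates, cfg)
  expect_equal(fit$path$bic,
               -2 * fit$path$loglik + fit$path$df * log(fit$n),
               tolerance = 1e-10)
  # closed-form spot check of the BIC formula
  expect_equal(2000 + 10 * log(3348), 2081.158, tolerance = 1e-3)
  # the largest penalty keeps every coefficient at zero
  expect_identical(fit$path$n_nonzero[1], 0L)
  # df never increases as lambda grows
  expect_true(all(diff(fit$path$df) >= 0))
  # path continuity: selected-model parameters are finite and named
  expect_true(all(is.finite(fit$model$beta)))
  expect_identical(dim(fit$model$gamma), c(15L, 6L))
})

test_that("the DIF report has the published table shape and round-trips", {
  sim <- simulate_cars(design_table1(n_persons = 400), seed = 65)
  cfg <- run_config(n_quad = 11, n_lambda = 3, prox_tol = 1e-5,
                    prox_max_iter = 600)
  fit <- dif_lasso(sim$responses, sim$covariates, cfg)
  rep <- dif_report(fit)
  expect_identical(nrow(rep), 15L)
  expect_true(all(c("female", "kindergarten", "primary", "junior_high",
                    "non_autism", "severe") %in% names(rep)))
  # an all-zero row means the groups function equally to the reference
  zero_rows <- rowSums(as.matrix(rep[pcmdif:::dummy_names()]) != 0) == 0
  expect_identical(unname(zero_rows), !rep$dif)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_report(rep, tmp)
  back <- read_report(tmp)
  expect_equal(as.data.frame(back), as.data.frame(rep), tolerance = 1e-12)
})

test_that("the Welch comparator matches hand computation and detects DIF", {
  # identical groups: t = 0
  resp <- tibble::tibble(person_id = 1:4, a = c(2L, 3L, 2L, 3L),
                         b = c(1L, 4L, 1L, 4L))
  cov <- as_covariates(tibble::tibble(
    person_id = 1:4, gender = c("male", "male", "female", "female"),
    age_group = "infant", symptom_level = "severe"
  ))
  w <- welch_dif_baseline(resp, cov, "a")
  expect_equal(w$statistic, 0)
  # 6-value toy against the textbook formula
  resp2 <- tibble::tibble(person_id = 1:6, a = c(1L, 2L, 3L, 2L, 3L, 4L))
  cov2 <- as_covariates(tibble::tibble(
    person_id = 1:6, gender = rep(c("male", "female"), each = 3),
    age_group = "infant", symptom_level = "severe"
  ))
  w2 <- welch_dif_baseline(resp2, cov2, "a")
  x1 <- c(1, 2, 3); x2 <- c(2, 3, 4)
  se <- sqrt(var(x1) / 3 + var(x2) / 3)
  t_hand <- (mean(x1) - mean(x2)) / se
  df_hand <- se^4 / ((var(x1) / 3)^2 / 2 + (var(x2) / 3)^2 / 2)
  expect_equal(w2$statistic, t_hand, tolerance = 1e-12)
  expect_equal(w2$df, df_hand, tolerance = 1e-12)
  # planted uniform DIF inflates |t| relative to the null
  dif <- matrix(0, 15, 6); dif[3, 1] <- 1.5
  s1 <- simulate_cars(design_table1(n_persons = 1500, dif = dif), seed = 66)
  s0 <- simulate_cars(design_table1(n_persons = 1500), seed = 66)
  t1 <- abs(welch_dif_baseline(s1$responses, s1$covariates, 3)$statistic)
  t0 <- abs(welch_dif_baseline(s0$responses, s0$covariates, 3)$statistic)
  expect_gt(t1, t0)
})
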