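# independent enumeration oracle for the PCM closed form
oracle_probs <- function(theta, steps) {
  num <- vapply(0:length(steps), function(h) {
    exp(sum(theta - steps[seq_len(h)]))
  }, 0)
  num / sum(num)
}

test_that("category probabilities match the closed form", {
  expect_equal(category_probabilities(0, c(0, 0, 0)), rep(0.25, 4))
  # dichotomous item at its threshold: 50/50
  expect_equal(category_probabilities(0.7, 0.7), c(0.5, 0.5))
  # direct evaluation: theta = 1, steps (-1, 0, 1) -> (1, e2, e3, e3)/sum
  w <- exp(c(0, 2, 3, 3))
  expect_equal(category_probabilities(1, c(-1, 0, 1)), w / sum(w),
               tolerance = 1e-12)
})

test_that("probabilities and moments agree with enumeration to 1e-12", {
  set.seed(42)
  for (rep in 1:25) {
    m <- sample(1:5, 1)
    steps <- rnorm(m, 0, 2)
    theta <- rnorm(1, 0, 2)
    p <- category_probabilities(theta, steps)
    p0 <- oracle_probs(theta, steps)
    expect_equal(p, p0, tolerance = 1e-12)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    h <- 0:m
    mom <- expected_score_moments(theta, steps)
    expect_equal(mom$E, sum(h * p0), tolerance = 1e-12)
    expect_equal(mom$W, sum((h - sum(h * p0))^2 * p0), tolerance = 1e-12)
    expect_equal(mom$C, sum((h - sum(h * p0))^4 * p0), tolerance = 1e-12)
  }
})

test_that("moments respect symmetry and boundary behaviour", {
  expect_equal(expected_score_moments(0, c(0, 0, 0))$E, 1.5)
  far <- expected_score_moments(40, c(0, 0, 0))
  expect_equal(far$E, 3, tolerance = 1e-10)
  expect_lt(far$W, 1e-10)
})

test_that("JML calibration is exchangeable, centred and score-sufficient", {
  sim <- simulate_cars(scaled_margins_design(500), seed = 14)
  fit <- fit_pcm(sim$responses)
  # identification: mean item difficulty 0
  expect_lt(abs(mean(fit$item_summary$difficulty)), 1e-10)
  # row permutation leaves item estimates untouched
  perm <- sample(nrow(sim$responses))
  fit2 <- fit_pcm(sim$responses[perm, ])
  expect_equal(fit2$items$delta, fit$items$delta, tolerance = 1e-8)
  # equal raw totals on complete data get equal measures
  pers <- fit$persons[!fit$persons$extreme, ]
  by_total <- split(pers$theta, pers$total)
  spread <- vapply(by_total, function(v) diff(range(v)), 0)
  expect_lt(max(spread), 1e-6)
  # every finite measure has a positive SE
  expect_true(all(fit$persons$se[is.finite(fit$persons$theta)] > 0))
})

test_that("the iteration log shows monotone convergence", {
  sim <- simulate_cars(scaled_margins_design(400), seed = 8)
  fit <- fit_pcm(sim$responses)
  expect_true(fit$converged)
  # log-likelihood never decreases across accepted iterations
  expect_true(all(diff(fit$iterations$loglik) > -1e-6))
  # max parameter change non-increasing over the final 3 iterations
  tail_chg <- tail(fit$iterations$max_change, 3)
  expect_true(all(diff(tail_chg) <= 1e-12))
})

test_that("step-difficulty recovery improves with sample size", {
  rmse_at <- function(n, seed) {
    d <- recovery_design(n)
    sim <- simulate_cars(d, seed = seed)
    fit <- fit_pcm(sim$responses)
    est <- fit$items$delta
    truth <- unlist(d$item_steps)
    sqrt(mean((est - truth)^2))
  }
  seeds <- 1:20
  small <- vapply(seeds, function(s) rmse_at(250, s), 0)
  large <- vapply(seeds, function(s) rmse_at(4000, 1000 + s), 0)
  expect_lt(mean(large), mean(small))
})

test_that("anchored scoring is monotone, self-consistent and flags extremes",
{
  sim <- simulate_cars(scaled_margins_design(600), seed = 23)
  fit <- fit_pcm(sim$responses)
  steps_list <- pcmdif:::fit_steps(fit)
  # responses at the model expectation for theta = 0 score back near 0
  target <- sum(vapply(steps_list, function(s) pcmdif:::pcm_moments(0, s)$E, 0))
  sc <- score_person(target, fit)
  expect_lt(abs(sc$theta), 0.05)
  expect_false(sc$extreme)
  # higher totals give higher measures
  m_tot <- sum(vapply(steps_list, length, 1L))
  sc_all <- score_person(seq(0, m_tot), fit)
  expect_true(all(diff(sc_all$theta) > 0))
  # the all-minimum row is flagged and sits below every non-extreme measure
  expect_true(sc_all$extreme[1])
  expect_lt(sc_all$theta[1], min(sc_all$theta[-c(1, m_tot + 1)]))
})

test_that("unobserved categories are structurally dropped and renumbered", {
  set.seed(6)
  df <- tibble::tibble(
    person_id = 1:80,
    a = sample(c(1L, 2L, 4L), 80, replace = TRUE),   # category 3 never used
    b = sample(1:4, 80, replace = TRUE),
    c = sample(1:3, 80, replace = TRUE)
  )
  fit <- fit_pcm(df)
  map_a <- fit$category_map[fit$category_map$label == "a", ]
  expect_true(is.na(map_a$code[map_a$raw == 3]))
  expect_identical(sum(fit$items$label == "a"), 2L)  # 3 categories -> 2 steps
})
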