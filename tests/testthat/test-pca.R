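test_that("residual correlations match brute-force pairwise correlation", {
  # 5 persons x 3 items toy residual table
  z <- matrix(c(0.3, -1.2, 0.8, 1.5, -0.4,
                -0.7, 0.9, 0.2, -1.1, 0.6,
                1.0, 0.4, -0.9, 0.3, -0.8), 5, 3)
  rt <- tibble::tibble(
    person_id = rep(1:5, 3), item = rep(1:3, each = 5),
    label = rep(c("x", "y", "z"), each = 5),
    std_residual = as.vector(z)
  )
  cm <- residual_correlation(rt)
  brute <- diag(3)
  for (i in 1:3) for (j in 1:3) brute[i, j] <- cor(z[, i], z[, j])
  dimnames(brute) <- dimnames(cm)
  expect_equal(cm, brute, tolerance = 1e-12)
  # duplicated items correlate exactly 1
  rt2 <- dplyr::bind_rows(rt, dplyr::mutate(rt[rt$label == "x", ],
                                            item = 4L, label = "x2"))
  cm2 <- residual_correlation(rt2)
  expect_equal(cm2["x", "x2"], 1)
})

test_that("independent items leave residuals uncorrelated", {
  sim <- simulate_cars(recovery_design(5000), seed = 70)
  fit <- fit_pcm(sim$responses)
  cm <- residual_correlation(residual_table(fit, sim$responses))
  off <- cm[upper.tri(cm)]
  # per-person residual sums vanish at the ML measure, which forces an
  # ipsative correlation of about -1/(I-1) between independent items; the
  # spread around that value is pure sampling noise
  expect_lt(max(abs(off + 1 / 14)), 0.05)
  expect_lt(abs(mean(off) + 1 / 14), 0.02)
})

test_that("contrast eigenvalues conserve trace and orient loadings", {
  expect_equal(contrast_eigen(diag(15))$eigenvalues, rep(1, 15))
  sim <- simulate_cars(scaled_margins_design(600), seed = 25)
  fit <- fit_pcm(sim$responses)
  ce <- contrast_eigen(residual_correlation(residual_table(fit,
                                                           sim$responses)))
  expect_equal(sum(ce$eigenvalues), 15, tolerance = 1e-8)
  expect_true(all(ce$eigenvalues >= -1e-10))
  expect_true(all(diff(ce$eigenvalues) <= 1e-12))
  # sign convention: the largest-magnitude loading on each contrast positive
  for (k in 1:2) {
    lk <- ce$loadings$loading[ce$loadings$contrast == k]
    expect_gt(lk[which.max(abs(lk))], 0)
  }
})

test_that("two planted residual clusters share loading signs", {
  # block correlation structure: items 1-4 and 5-8 form opposite clusters
  R <- diag(8)
  R[1:4, 1:4] <- 0.4; R[5:8, 5:8] <- 0.4
  R[1:4, 5:8] <- -0.2; R[5:8, 1:4] <- -0.2
  diag(R) <- 1
  dimnames(R) <- list(paste0("i", 1:8), paste0("i", 1:8))
  ce <- contrast_eigen(R)
  l1 <- ce$loadings$loading[ce$loadings$contrast == 1]
  expect_identical(length(unique(sign(l1[1:4]))), 1L)
  expect_identical(length(unique(sign(l1[5:8]))), 1L)
  expect_true(sign(l1[1]) != sign(l1[5]))
})

test_that("variance decomposition follows the eigenvalue-unit convention", {
  # degenerate: no measure variance -> 0%
  vp0 <- variance_percents(0, c(1, 1), 2)
  expect_equal(vp0$pct_variance[vp0$component == "measures"], 0)
  # percentages always total 100 with all contrasts included
  vp <- variance_percents(18.08, rep(15 / 6, 6), 15)
  expect_equal(sum(vp$pct_variance), 100, tolerance = 1e-12)
  # full pipeline: decomposition is internally consistent
  sim <- simulate_cars(scaled_margins_design(700), seed = 33)
  fit <- fit_pcm(sim$responses)
  rt <- residual_table(fit, sim$responses)
  ce <- contrast_eigen(residual_correlation(rt))
  vd <- variance_decomposition(fit, rt, ce$eigenvalues)
  expect_equal(sum(vd$pct_variance), 100, tolerance = 1e-8)
  expect_true(all(vd$pct_variance >= 0))
})

test_that("loading screening respects the cutoff", {
  loadings <- tibble::tibble(
    label = c("a", "b", "c"), contrast = 1,
    loading = c(0.45, 0.39, -0.62)
  )
  hit <- screen_loadings(loadings, 0.4)
  expect_setequal(hit$label, c("a", "c"))      # 0.45 in, 0.39 out, |-0.62| in
  expect_identical(nrow(screen_loadings(loadings, 0)), 3L)
})

test_that("well-targeted unidimensional data shows strong measure variance", {
  # a population whose severity range matches the item range: the measures
  # explain well over the conventional 40% and no spurious contrast appears
  d <- recovery_design(3348)
  d$ability_sd <- 2
  hits <- vapply(1:5, function(s) {
    sim <- simulate_cars(d, seed = 500 + s)
    fit <- fit_pcm(sim$responses)
    pca <- residual_pca(fit, sim$responses)
    c(pca$measures_pct > 40, pca$eigenvalues[1] < 2)
  }, logical(2))
  expect_gte(mean(hits[1, ]), 0.8)
  expect_gte(mean(hits[2, ]), 0.8)
})
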