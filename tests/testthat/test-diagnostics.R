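test_that("category counts conserve responses and flag sparse categories", {
  set.seed(3)
  n <- 3348
  df <- tibble::tibble(
    person_id = seq_len(n),
    a = c(rep(1L, 1000), rep(2L, 1200), rep(3L, 1143), rep(4L, 5)),
    b = sample(1:4, n, replace = TRUE)
  )
  df$b[1:10] <- NA
  cc <- category_counts(df)
  # a rarely-endorsed top category (5 of 3,348) is flagged
  expect_true(cc$sparse[cc$label == "a" & cc$category == 4])
  expect_false(any(cc$sparse[cc$label == "a" & cc$category < 4]))
  # a well-filled item has no flags
  expect_false(any(cc$sparse[cc$label == "b"]))
  # counts per item sum to the non-missing responses
  sums <- tapply(cc$count, cc$label, sum)
  expect_identical(as.integer(sums[c("a", "b")]),
                   c(sum(!is.na(df$a)), sum(!is.na(df$b))))
})

test_that("threshold intervals are differences with range and order flags", {
  iv <- threshold_intervals(c(-1, 0, 1))
  expect_equal(iv$interval, c(1, 1))
  expect_true(all(iv$out_of_range))       # below the 1.4 working minimum
  expect_false(any(iv$disordered))
  # a reversed pair is disordered
  iv2 <- threshold_intervals(c(0.5, -0.5, 3))
  expect_true(iv2$disordered[1])
  expect_error(threshold_intervals(1.2), "at least 2")
})

test_that("collapsing merges sparse categories per the direction rule", {
  n <- 3005
  df <- tibble::tibble(
    person_id = seq_len(n),
    a = c(rep(1L, 1000), rep(2L, 1000), rep(3L, 1000), rep(4L, 5)),
    b = rep(1:4, length.out = n)
  )
  rs <- rescore_collapse(df)
  map_a <- rs$map[rs$map$label == "a", ]
  expect_identical(map_a$to, c(1L, 2L, 3L, 3L))   # sparse top merges down
  expect_identical(rs$map$to[rs$map$label == "b"], 1:4)  # untouched
  expect_true(rs$refit_recommended)
  # refitting the rescored data leaves one fewer threshold on the item
  fit <- fit_pcm(rs$responses)
  expect_identical(sum(fit$items$label == "a"), 2L)
  expect_identical(sum(fit$items$label == "b"), 3L)
})

test_that("collapse maps are total and order-preserving", {
  set.seed(9)
  for (rep in 1:15) {
    counts <- sample(c(0, 3, 8, 40, 500), 4, replace = TRUE)
    if (sum(counts >= 10) < 2) counts[c(1, 3)] <- c(400, 400)
    df <- tibble::tibble(
      person_id = seq_len(sum(counts)),
      x = rep(1:4, counts),
      y = rep(1:4, length.out = sum(counts))
    )
    rs <- rescore_collapse(df)
    m <- rs$map[rs$map$label == "x", ]
    expect_identical(nrow(m), 4L)                       # total
    expect_true(all(diff(m$to) >= 0))                   # order-preserving
    expect_lte(length(unique(m$to)), 4L)                # never adds thresholds
    # no remaining sparse categories among observed ones
    cc <- category_counts(rs$responses)
    ccx <- cc[cc$label == "x" & cc$count > 0, ]
    expect_true(all(!ccx$sparse))
  }
  # collapsing below 2 categories errors
  df <- tibble::tibble(person_id = 1:12, x = rep(c(1L, 2L), 6),
                       y = rep(1:4, 3))
  expect_error(rescore_collapse(df, config = run_config(min_count = 10)),
               "fewer than 2")
})

test_that("residuals satisfy the score equation and the enumeration identity",
{
  sim <- simulate_cars(scaled_margins_design(400), seed = 18)
  fit <- fit_pcm(sim$responses)
  rt <- residual_table(fit, sim$responses)
  # per-person residual sums vanish at the ML measure (complete data)
  psums <- tapply(rt$residual, rt$person_id, sum)
  expect_lt(max(abs(psums)), 1e-3)
  # standardized residuals recompute from the moments
  expect_equal(rt$std_residual,
               (rt$observed - rt$expected) / sqrt(rt$variance),
               tolerance = 1e-10)
  # the |y| = 0.5 case: x = 1 or 2 under theta = 0, steps (0,0,0) has E = 1.5
  expect_equal(abs(1 - pcmdif:::pcm_moments(0, c(0, 0, 0))$E), 0.5)
})

test_that("fit statistics flag misfit and standardize correctly", {
  # closed form: MNSQ = 1 with variance q^2 gives Zstd = q/3
  expect_equal(pcmdif:::wh_zstd(1, 0.09), 0.1)
  expect_equal(pcmdif:::wh_zstd(1, 4), 2 / 3)
  # an item replaced by pure noise misfits; well-behaved items do not
  sim <- simulate_cars(scaled_margins_design(800), seed = 4)
  resp <- sim$responses
  resp$object_use <- sample(1:4, nrow(resp), replace = TRUE)
  fit <- fit_pcm(resp)
  fs <- fit_statistics(fit, resp)
  noisy <- fs$items[fs$items$label == "object_use", ]
  expect_gt(noisy$outfit, 1.33)
  expect_true(noisy$misfit)
  # a sub-0.75 mean square is flagged regardless of direction
  expect_true(fs$items$misfit[which.min(fs$items$infit)] ||
                min(fs$items$infit) >= 0.75)
  # reported standardized values respect the display cap
  expect_true(all(abs(fs$items$infit_zstd) <= 9.9 + 1e-12))
})

test_that("null simulations keep flagged-item fraction low", {
  # data generated from the model it is scored against: over 20 seeds the
  # average fraction of items with |Zstd| > 2 stays at or below 10%
  frac <- vapply(1:20, function(s) {
    sim <- simulate_cars(design_table1(n_persons = 400), seed = 300 + s)
    fit <- fit_pcm(sim$responses)
    fs <- fit_statistics(fit, sim$responses)
    mean(abs(fs$items$infit_zstd) > 2 | abs(fs$items$outfit_zstd) > 2)
  }, 0)
  expect_lte(mean(frac), 0.10)
})

test_that("separation and reliability obey their identity", {
  expect_equal(reliability_from_separation(1), 0.5)
  set.seed(2)
  for (rep in 1:10) {
    sr <- separation_reliability(rnorm(30, 0, 2), runif(30, 0.2, 0.6))
    expect_equal(sr$reliability,
                 sr$separation^2 / (1 + sr$separation^2), tolerance = 1e-12)
  }
  # degenerate: error variance swamps observed variance
  sr0 <- separation_reliability(c(0.01, -0.01, 0.02), c(1, 1, 1))
  expect_true(sr0$degenerate)
  expect_identical(sr0$separation, 0)
  expect_identical(sr0$reliability, 0)
})

test_that("the Wright map is deterministic with items at the extremes", {
  sim <- simulate_cars(scaled_margins_design(300), seed = 44)
  fit <- fit_pcm(sim$responses)
  m1 <- wright_map(fit, print = FALSE)
  m2 <- wright_map(fit, print = FALSE)
  expect_identical(m1, m2)
  hardest <- fit$item_summary$label[which.max(fit$item_summary$difficulty)]
  easiest <- fit$item_summary$label[which.min(fit$item_summary$difficulty)]
  first_item_line <- min(grep(hardest, m1, fixed = TRUE))
  last_item_line <- max(grep(easiest, m1, fixed = TRUE))
  expect_lt(first_item_line, last_item_line)
})

test_that("totals and severity classes follow the conventional cutoffs", {
  df <- tibble::tibble(person_id = 1:2)
  for (lab in cars_items()$label) df[[lab]] <- c(1L, 4L)
  tot <- total_scores_and_severity(df)
  expect_equal(tot$total, c(15, 60))
  # printed-style cutoffs: 29 non-autism, 32 mild-to-moderate, 38 severe
  mk_row <- function(total) {
    v <- rep(1L, 15)
    idx <- 1
    while (sum(v) < total) { v[idx] <- min(4L, v[idx] + 1L); idx <- idx %% 15 + 1 }
    v
  }
  rows <- t(vapply(c(29, 32, 38), mk_row, integer(15)))
  colnames(rows) <- cars_items()$label
  df3 <- dplyr::bind_cols(tibble::tibble(person_id = 1:3),
                          tibble::as_tibble(rows))
  tot3 <- total_scores_and_severity(df3)
  expect_equal(tot3$total, c(29, 32, 38))
  expect_identical(as.character(tot3$severity),
                   c("non_autism", "mild_moderate", "severe"))
  # any missing item leaves the person unclassified
  df3$imitation[2] <- NA
  tot4 <- total_scores_and_severity(df3)
  expect_true(is.na(tot4$total[2]) && is.na(tot4$severity[2]))
})
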