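# shared fixtures: all generated in code, nothing stored on disk

# scaled-down Table-1-style margins for an arbitrary n
scaled_margins_design <- function(n, ...) design_table1(n_persons = n, ...)

# recovery design: moderate, well-populated step difficulties so that every
# category attracts responses and all steps are estimable
recovery_design <- function(n = 3348) {
  locs <- seq(-1.5, 1.5, length.out = 15)
  simulation_design(
    n_persons = n,
    gender_freq = pcmdif:::scale_freq(c(male = 2673L, female = 675L), n),
    age_freq = pcmdif:::scale_freq(
      c(infant = 1416L, kindergarten = 1506L, primary = 406L,
        junior_high = 20L), n),
    severity_freq = pcmdif:::scale_freq(
      c(mild_moderate = 1635L, non_autism = 1114L, severe = 599L), n),
    item_steps = lapply(locs, function(l) l + c(-1.3, 0, 1.3))
  )
}

# tiny deterministic response table for I/O and arithmetic tests
toy_responses <- function() {
  tibble::tibble(
    person_id = 1:6,
    item_a = c(1L, 2L, 3L, 4L, 2L, 3L),
    item_b = c(2L, 2L, 3L, 4L, 1L, 3L),
    item_c = c(1L, 1L, 2L, 3L, 2L, 4L)
  )
}

toy_covariates <- function(n = 6) {
  as_covariates(tibble::tibble(
    person_id = seq_len(n),
    gender = rep(c("male", "female"), length.out = n),
    age_group = rep(c("infant", "kindergarten", "primary"), length.out = n),
    symptom_level = rep(c("mild_moderate", "non_autism", "severe"),
                        length.out = n)
  ))
}
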