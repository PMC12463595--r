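# -- simulation designs ------------------------------------------------------

#' Specify a response-simulation design
#'
#' A simulation design fixes everything needed to generate ordinal responses
#' from an adjacent-categories (generalized partial credit) model: covariate
#' margins, item step difficulties, discriminations, optional uniform-DIF
#' coefficients and the latent ability distribution. Covariate cells are
#' assigned *exactly* to their target frequencies (a seeded permutation of a
#' fixed level vector), never multinomially, so margins are reproduced without
#' sampling noise.
#'
#' @param n_persons Number of persons.
#' @param gender_freq,age_freq,severity_freq Named integer vectors of level
#'   frequencies (names must match the canonical covariate levels, see
#'   [as_covariates()]); each must sum to `n_persons`.
#' @param item_steps List of numeric vectors: step difficulties (Andrich
#'   thresholds) per item, in logits; length m_i per item, one fewer than the
#'   item's category count.
#' @param discrimination Positive numeric vector of item discriminations
#'   (1 for a pure partial credit model).
#' @param dif Numeric matrix, items x 6 dummy columns (`female`,
#'   `kindergarten`, `primary`, `junior_high`, `non_autism`, `severe`):
#'   uniform-DIF shifts, in logits, added to every step difficulty of an item
#'   for members of the coded group. Default all zero.
#' @param ability_mean,ability_sd Mean and SD of the Normal latent ability.
#' @param ability_shift Optional length-6 numeric: ability mean shift per
#'   dummy column (group-level severity differences); default all zero.
#' @return A list of class `simulation_design`.
#' @seealso [design_table1()] for the preset emulating the reference clinical
#'   sample.
#' @export
simulation_design <- function(n_persons,
                              gender_freq,
                              age_freq,
                              severity_freq,
                              item_steps,
                              discrimination = rep(1, length(item_steps)),
                              dif = NULL,
                              ability_mean = 0,
                              ability_sd = 1,
                              ability_shift = rep(0, 6)) {
  levs <- cars_covariate_levels()
  chk_freq <- function(f, nm) {
    if (!identical(names(f), levs[[nm]])) {
      stop(nm, " frequencies must be named ",
           paste(levs[[nm]], collapse = ", "), call. = FALSE)
    }
    if (sum(f) != n_persons) {
      stop(nm, " frequencies sum to ", sum(f), ", not n_persons = ",
           n_persons, call. = FALSE)
    }
    as.integer(f)
  }
  gender_freq <- setNames(chk_freq(gender_freq, "gender"), levs$gender)
  age_freq <- setNames(chk_freq(age_freq, "age_group"), levs$age_group)
  severity_freq <- setNames(chk_freq(severity_freq, "symptom_level"),
                            levs$symptom_level)
  n_items <- length(item_steps)
  stopifnot(n_items >= 1)
  item_steps <- lapply(item_steps, as.numeric)
  if (any(vapply(item_steps, length, 1L) < 1)) {
    stop("each item needs at least one step difficulty", call. = FALSE)
  }
  stopifnot(length(discrimination) == n_items, all(discrimination > 0))
  if (is.null(dif)) dif <- matrix(0, n_items, 6)
  dif <- as.matrix(dif)
  stopifnot(nrow(dif) == n_items, ncol(dif) == 6)
  colnames(dif) <- dummy_names()
  stopifnot(ability_sd > 0, length(ability_shift) == 6)
  structure(
    list(
      n_persons = as.integer(n_persons),
      gender_freq = gender_freq, age_freq = age_freq,
      severity_freq = severity_freq,
      item_steps = item_steps, discrimination = as.numeric(discrimination),
      dif = dif, ability_mean = ability_mean, ability_sd = ability_sd,
      ability_shift = as.numeric(ability_shift)
    ),
    class = "simulation_design"
  )
}

dummy_names <- function() {
  c("female", "kindergarten", "primary", "junior_high", "non_autism", "severe")
}

# largest-remainder scaling of integer frequencies to a new total
scale_freq <- function(freq, n) {
  raw <- freq / sum(freq) * n
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  setNames(as.integer(base), names(freq))
}

#' Preset design emulating the reference clinical sample
#'
#' Returns the default [simulation_design()]: 3,348 persons with exact
#' covariate margins of a large autism referral sample (gender 2,673/675; age
#' groups 1,416/1,506/406/20; severity classes 1,114/1,635/599), 15 items on
#' a 4-category scale, discrimination 1 (a pure partial credit model) and no
#' DIF. Item locations follow the instrument's difficulty hierarchy (hardest:
#' adaptation to environmental change; easiest: consistency of intellectual
#' response), with common relative steps of -3.4/0/+3.4 logits around each
#' location so that the extreme categories of the most extreme items attract
#' few responses, as observed with this instrument in referred samples. The
#' ability distribution is Normal(-1.33, 1): persons sit 1.33 logits below
#' the item centre, the offset reported for this population, which also
#' reproduces the instrument's typical mean total score of about 31.7.
#'
#' @param n_persons Total sample size; frequencies are scaled to it by largest
#'   remainder (default 3,348 reproduces the margins exactly).
#' @param dif Optional items x 6 uniform-DIF matrix (see
#'   [simulation_design()]).
#' @return A `simulation_design`.
#' @export
#' @examples
#' d <- design_table1()
#' d$severity_freq
design_table1 <- function(n_persons = 3348L, dif = NULL) {
  locations <- c(
    -0.81, -0.91, 0.77, 1.08, 0.56, 1.53, 1.02, 0.81, 0.87, 1.26,
    -3.00, 0.94, -1.46, -3.89, 1.25
  )
  rel <- c(-3.4, 0, 3.4)
  steps <- lapply(locations, function(l) l + rel)
  names(steps) <- cars_items()$label
  simulation_design(
    n_persons = n_persons,
    gender_freq = scale_freq(c(male = 2673L, female = 675L), n_persons),
    age_freq = scale_freq(
      c(infant = 1416L, kindergarten = 1506L, primary = 406L,
        junior_high = 20L), n_persons),
    severity_freq = scale_freq(
      c(mild_moderate = 1635L, non_autism = 1114L, severe = 599L), n_persons),
    item_steps = steps,
    dif = dif,
    ability_mean = -1.33
  )
}

# -- generation --------------------------------------------------------------

#' Generate a covariate population with latent abilities
#'
#' Assigns covariate levels to exact design frequencies (independent seeded
#' permutations per covariate, so joint cells vary but margins are exact) and
#' draws latent abilities from the design's Normal distribution, optionally
#' mean-shifted per covariate group.
#'
#' @param design A [simulation_design()].
#' @param seed Integer seed; the same seed reproduces the population exactly.
#' @return A covariate tibble (`person_id`, `gender`, `age_group`,
#'   `symptom_level`) with an extra numeric `ability` column holding the
#'   generating latent trait.
#' @export
generate_population <- function(design, seed = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  if (!is.null(seed)) set.seed(seed)
  n <- design$n_persons
  draw <- function(freq) sample(rep(names(freq), freq), n, replace = FALSE)
  cov <- tibble::tibble(
    person_id = seq_len(n),
    gender = draw(design$gender_freq),
    age_group = draw(design$age_freq),
    symptom_level = draw(design$severity_freq)
  )
  cov <- as_covariates(cov)
  X <- covariate_dummies(cov)
  mu <- design$ability_mean + drop(X %*% design$ability_shift)
  cov$ability <- rnorm(n, mean = mu, sd = design$ability_sd)
  cov
}

#' Generate ordinal item responses from the design's GPCM
#'
#' Draws each response from the adjacent-categories model
#' \deqn{\log\frac{P(Y_{pi}=r)}{P(Y_{pi}=r-1)} =
#'   \beta_i(\theta_p - \delta_{ir} - x_p^\top\gamma_i),}
#' i.e. the group-specific effective step difficulty is
#' \eqn{\delta_{ir} + x_p^\top\gamma_i} (uniform DIF). With all
#' \eqn{\gamma = 0} and \eqn{\beta = 1} this is a pure partial credit model.
#'
#' @param population Tibble from [generate_population()] (must carry
#'   `ability`).
#' @param design The [simulation_design()] used to build the population.
#' @param seed Optional integer seed for the response draws.
#' @return A response tibble: `person_id` plus one integer column per item,
#'   raw categories starting at 1.
#' @export
generate_responses <- function(population, design, seed = NULL) {
  stopifnot(inherits(design, "simulation_design"),
            "ability" %in% names(population))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(population)
  theta <- population$ability
  X <- covariate_dummies(population)
  n_items <- length(design$item_steps)
  labels <- if (!is.null(names(design$item_steps))) {
    names(design$item_steps)
  } else if (n_items == 15) {
    cars_items()$label
  } else {
    paste0("item", seq_len(n_items))
  }
  out <- matrix(NA_integer_, n, n_items, dimnames = list(NULL, labels))
  for (i in seq_len(n_items)) {
    steps <- design$item_steps[[i]]
    beta <- design$discrimination[i]
    offset <- drop(X %*% design$dif[i, ])       # per-person DIF shift
    # cumulative logits z_h = beta * (h*theta - sum_{r<=h} steps - h*offset)
    m <- length(steps)
    z <- matrix(0, n, m + 1)
    for (h in seq_len(m)) {
      z[, h + 1] <- beta * (h * theta - sum(steps[seq_len(h)]) - h * offset)
    }
    z <- z - apply(z, 1, max)
    p <- exp(z)
    p <- p / rowSums(p)
    u <- runif(n)
    out[, i] <- max.col(u < t(apply(p, 1, cumsum)), ties.method = "first")
  }
  dplyr::bind_cols(
    tibble::tibble(person_id = population$person_id),
    tibble::as_tibble(out)
  )
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper: [generate_population()] then [generate_responses()]
#' under a single seed.
#'
#' @param design A [simulation_design()]; defaults to [design_table1()].
#' @param seed Integer seed.
#' @return A list with elements `responses` and `covariates`.
#' @export
#' @examples
#' sim <- simulate_cars(design_table1(n_persons = 100), seed = 1)
#' dim(sim$responses)
simulate_cars <- function(design = design_table1(), seed = NULL) {
  pop <- generate_population(design, seed = seed)
  resp <- generate_responses(pop, design)  # continues the seeded stream
  list(responses = resp, covariates = pop)
}
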