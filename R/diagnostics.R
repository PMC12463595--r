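# -- category function -------------------------------------------------------

#' Category response counts with sparse-category flags
#'
#' Counts, per item, how many responses each raw category attracted. A
#' functioning rating category should attract a minimum number of responses
#' (default 10); categories below that are flagged sparse.
#'
#' @param responses Response tibble.
#' @param config A [run_config()] (`min_count`, `score_range`).
#' @return A tibble with one row per item x declared category: `item`,
#'   `label`, `category`, `count`, `sparse`.
#' @export
category_counts <- function(responses, config = run_config()) {
  X <- resp_matrix(responses)
  cats <- seq(config$score_range[1], config$score_range[2])
  out <- lapply(seq_len(ncol(X)), function(i) {
    cnt <- vapply(cats, function(k) sum(X[, i] == k, na.rm = TRUE), 0L)
    tibble::tibble(item = i, label = colnames(X)[i], category = cats,
                   count = cnt, sparse = cnt < config$min_count)
  })
  dplyr::bind_rows(out)
}

#' Gaps between adjacent Andrich thresholds
#'
#' Computes the interval between each pair of adjacent thresholds of one item
#' and flags intervals falling outside the recommended working range
#' (default 1.4--5 logits): too-narrow intervals mean a category never becomes
#' modal over a useful stretch of the latent continuum; too-wide intervals
#' lump people of very different severity into one category. A non-positive
#' interval marks disordered thresholds.
#'
#' @param steps Numeric vector of at least two threshold estimates (logits),
#'   in category order.
#' @param config A [run_config()] (`interval_bounds`).
#' @return A tibble with one row per adjacent pair: `from`, `to`, `interval`,
#'   `out_of_range`, `disordered`.
#' @export
#' @examples
#' threshold_intervals(c(-3.87, 0.70, 3.17))   # 4.57 and 2.47, both in range
threshold_intervals <- function(steps, config = run_config()) {
  if (length(steps) < 2) {
    stop("need at least 2 thresholds to form an interval", call. = FALSE)
  }
  iv <- diff(steps)
  tibble::tibble(
    from = seq_along(iv), to = seq_along(iv) + 1L, interval = iv,
    out_of_range = iv < config$interval_bounds[1] |
      iv > config$interval_bounds[2],
    disordered = iv <= 0
  )
}

# -- rescoring ----------------------------------------------------------------

#' Collapse malfunctioning rating categories
#'
#' Rescoring rule: every category flagged sparse (below the minimum count) is
#' merged into an adjacent category — a sparse top category merges downward, a
#' sparse bottom category upward, and an interior sparse category into the
#' smaller neighbour (ties toward the lower category). The resulting map is
#' total and order-preserving; collapsing never increases the number of
#' thresholds. A re-fit of the calibration on the rescored data is
#' recommended whenever any item changed.
#'
#' @param responses Response tibble on the raw scale.
#' @param counts Optional result of [category_counts()]; computed when
#'   missing.
#' @param config A [run_config()] (`min_count`, `score_range`).
#' @return A list with `responses` (rescored tibble, categories renumbered
#'   contiguously from the raw minimum), `map` (tibble `item`, `label`,
#'   `from`, `to`), and `refit_recommended` (logical).
#' @export
rescore_collapse <- function(responses, counts = NULL,
                             config = run_config()) {
  if (is.null(counts)) counts <- category_counts(responses, config)
  X <- resp_matrix(responses)
  cats <- seq(config$score_range[1], config$score_range[2])
  maps <- list()
  changed <- FALSE
  for (i in seq_len(ncol(X))) {
    ci <- counts[counts$item == i, ]
    cnt <- ci$count[match(cats, ci$category)]
    groups <- seq_along(cats)       # merge groups, contiguous by construction
    repeat {
      gcnt <- tapply(cnt, groups, sum)
      glev <- as.integer(names(gcnt))
      sparse <- which(gcnt < config$min_count)
      if (length(sparse) == 0) break
      if (length(glev) <= 2) {
        stop(sprintf(
          "item '%s': collapsing would leave fewer than 2 categories",
          colnames(X)[i]), call. = FALSE)
      }
      pos <- sparse[which.min(gcnt[sparse])][1]   # sparsest group first
      sg <- glev[pos]
      if (pos == length(glev)) {
        tgt <- glev[pos - 1]                       # top: merge downward
      } else if (pos == 1) {
        tgt <- glev[pos + 1]                       # bottom: merge upward
      } else {
        nb <- c(glev[pos - 1], glev[pos + 1])
        tgt <- nb[order(gcnt[match(nb, glev)], nb)][1]  # smaller, ties lower
      }
      groups[groups == sg] <- tgt
      changed <- TRUE
    }
    # renumber groups contiguously, preserving order
    new_lab <- match(groups, sort(unique(groups))) + config$score_range[1] - 1L
    maps[[i]] <- tibble::tibble(item = i, label = colnames(X)[i],
                                from = cats, to = as.integer(new_lab))
    X[, i] <- new_lab[match(X[, i], cats)]
  }
  map <- dplyr::bind_rows(maps)
  out <- dplyr::bind_cols(
    tibble::tibble(person_id = responses$person_id),
    tibble::as_tibble(X)
  )
  list(responses = out, map = map, refit_recommended = changed)
}

# -- residuals ---------------------------------------------------------------

#' Score residuals against the fitted Partial Credit Model
#'
#' For every observed person-item cell: the expected score E, model variance
#' W, fourth central moment C, raw residual y = x - E and standardized
#' residual z = y / sqrt(W), all evaluated at the estimated person measure and
#' item steps. Missing cells are excluded.
#'
#' @param fit A [fit_pcm()] result.
#' @param responses The response tibble the model was fitted to (or rescored
#'   data matching the fit's category map).
#' @param include_extreme Keep rows for extreme persons (default FALSE; their
#'   residuals are not model-constrained and are excluded from fit
#'   statistics).
#' @return A long tibble: `person_id`, `item`, `label`, `observed` (internal
#'   0-based code), `expected`, `variance`, `kurtosis`, `residual`,
#'   `std_residual`.
#' @export
residual_table <- function(fit, responses, include_extreme = FALSE) {
  X <- resp_matrix(responses)
  codes <- recode_categories_anchored(X, fit)
  steps_list <- fit_steps(fit)
  persons <- fit$persons
  keep <- if (include_extreme) rep(TRUE, nrow(persons)) else !persons$extreme
  rows <- list()
  for (i in seq_along(steps_list)) {
    obs <- which(!is.na(codes[, i]) & keep)
    if (length(obs) == 0) next
    mom <- pcm_moments(persons$theta[obs], steps_list[[i]])
    x <- unname(codes[obs, i])
    rows[[i]] <- tibble::tibble(
      person_id = persons$person_id[obs], item = i,
      label = fit$items$label[match(i, fit$items$item)],
      observed = as.numeric(x), expected = mom$E, variance = mom$W,
      kurtosis = mom$C, residual = x - mom$E,
      std_residual = (x - mom$E) / sqrt(pmax(mom$W, 1e-12))
    )
  }
  dplyr::bind_rows(rows)
}

# -- totals and severity classification --------------------------------------

#' Total scores and severity classification
#'
#' Sums the raw item scores (for the 15-item scale on 1--4 categories the
#' total ranges 15--60) and classifies each person by the instrument's
#' conventional total-score cutoffs: below the first cutoff non-autism, at or
#' above the second severe, in between mild-to-moderate. Persons with any
#' missing item are excluded from classification (totals are not rescaled)
#' and returned with `NA`.
#'
#' @param responses Response tibble on the raw 1--4 scale.
#' @param config A [run_config()] (`severity_cutoffs`).
#' @return A tibble: `person_id`, `total`, `severity` (factor
#'   non_autism/mild_moderate/severe).
#' @export
#' @examples
#' df <- tibble::tibble(person_id = 1:3,
#'                      a = c(1, 2, 4), b = c(1, 2, 4), c = c(1, 2, 4))
#' # not the full scale, but the rule is the same
#' total_scores_and_severity(df, run_config(severity_cutoffs = c(5, 9)))
total_scores_and_severity <- function(responses, config = run_config()) {
  X <- resp_matrix(responses)
  complete <- rowSums(is.na(X)) == 0
  total <- unname(ifelse(complete, rowSums(X), NA_real_))
  cut <- config$severity_cutoffs
  sev <- dplyr::case_when(
    is.na(total) ~ NA_character_,
    total < cut[1] ~ "non_autism",
    total >= cut[2] ~ "severe",
    TRUE ~ "mild_moderate"
  )
  tibble::tibble(
    person_id = responses$person_id, total = total,
    severity = factor(sev,
                      levels = c("non_autism", "mild_moderate", "severe"))
  )
}

# -- combined diagnostics -----------------------------------------------------

#' Full category-function diagnostics for a fitted scale
#'
#' Combines category counts, threshold estimates and threshold-interval checks
#' into the per-item diagnostic table: sparse categories, disordered
#' thresholds, and intervals outside the recommended range.
#'
#' @param fit A [fit_pcm()] result.
#' @param responses The response tibble the model was fitted to.
#' @param config A [run_config()].
#' @return An object of class `cars_diagnostics` with fields `counts`
#'   (from [category_counts()]), `thresholds` (tibble `item`, `label`,
#'   `step`, `delta`), `intervals` (per-item interval table with flags) and
#'   `flags` (one row per item: any_sparse, any_disordered,
#'   any_interval_out).
#' @export
diagnose_categories <- function(fit, responses, config = run_config()) {
  counts <- category_counts(responses, config)
  thresholds <- fit$items[c("item", "label", "step", "delta")]
  ivs <- lapply(split(thresholds, thresholds$item), function(d) {
    if (nrow(d) < 2) return(NULL)
    dplyr::bind_cols(tibble::tibble(item = d$item[1], label = d$label[1]),
                     threshold_intervals(d$delta, config))
  })
  intervals <- dplyr::bind_rows(ivs)
  flags <- dplyr::left_join(
    counts |> dplyr::group_by(.data$item, .data$label) |>
      dplyr::summarise(any_sparse = any(.data$sparse & .data$count > 0) |
                         any(.data$count == 0), .groups = "drop"),
    intervals |> dplyr::group_by(.data$item) |>
      dplyr::summarise(any_disordered = any(.data$disordered),
                       any_interval_out = any(.data$out_of_range),
                       .groups = "drop"),
    by = "item"
  )
  structure(list(counts = counts, thresholds = thresholds,
                 intervals = intervals, flags = flags),
            class = "cars_diagnostics")
}

#' @export
print.cars_diagnostics <- function(x, ...) {
  cat("<cars_diagnostics>\n")
  flagged <- x$flags[x$flags$any_sparse | x$flags$any_disordered %in% TRUE |
                       x$flags$any_interval_out %in% TRUE, ]
  cat(sprintf("  %d of %d items flagged (sparse / disordered / interval)\n",
              nrow(flagged), nrow(x$flags)))
  print(x$flags, n = Inf)
  invisible(x)
}

# -- Wright map ---------------------------------------------------------------

#' Text person-item (Wright) map
#'
#' Fixed-width text display of the joint logit scale: person measures binned
#' on the left (each `#` a fixed number of persons, `.` the remainder), item
#' difficulties (mean of each item's steps) labelled on the right. Output is
#' deterministic for a given fit.
#'
#' @param fit A [fit_pcm()] result.
#' @param bin Bin width in logits (default 0.5).
#' @param hash Persons per `#` (default: about 1% of the sample, at least 1).
#' @return The map as a character vector of lines, invisibly; printed when
#'   `print = TRUE`.
#' @param print Print the map to the console (default TRUE).
#' @export
wright_map <- function(fit, bin = 0.5, hash = NULL, print = TRUE) {
  th <- fit$persons$theta[!fit$persons$extreme]
  diffs <- fit$item_summary
  if (is.null(hash)) hash <- max(1L, floor(length(th) / 100))
  lo <- floor(min(c(th, diffs$difficulty)) / bin) * bin
  hi <- ceiling(max(c(th, diffs$difficulty)) / bin) * bin
  edges <- seq(hi, lo, by = -bin)
  lines <- character(0)
  for (e in edges) {
    np <- sum(th >= e & th < e + bin)
    pers <- paste0(strrep("#", np %/% hash), if (np %% hash > 0) "." else "")
    its <- diffs$label[diffs$difficulty >= e & diffs$difficulty < e + bin]
    lines <- c(lines, sprintf("%6.1f |%-20s| %s", e,
                              substr(pers, 1, 20), paste(its, collapse = " ")))
  }
  header <- c(sprintf("Each '#' = %d persons, '.' = fewer", hash),
              " logit |persons             | items")
  out <- c(header, lines)
  if (print) cat(out, sep = "\n")
  invisible(out)
}
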