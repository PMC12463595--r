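# -- response tables ---------------------------------------------------------

# internal: item columns of a response tibble (everything except person_id)
item_cols <- function(responses) setdiff(names(responses), "person_id")

# internal: persons x items integer matrix, rownames = person ids
resp_matrix <- function(responses) {
  items <- item_cols(responses)
  m <- as.matrix(responses[items])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(responses$person_id)
  m
}

# internal: validate a raw-score tibble against a declared category range
validate_responses <- function(responses, score_range) {
  items <- item_cols(responses)
  if (length(items) < 1) stop("response table has no item columns", call. = FALSE)
  for (it in items) {
    v <- responses[[it]]
    if (!is.numeric(v)) {
      stop(sprintf("item column '%s' is not numeric", it), call. = FALSE)
    }
    bad <- which(!is.na(v) & (v < score_range[1] | v > score_range[2] | v != round(v)))
    if (length(bad) > 0) {
      stop(sprintf(
        "score %s outside declared range %d..%d at row %d, item '%s'",
        format(v[bad[1]]), score_range[1], score_range[2], bad[1], it
      ), call. = FALSE)
    }
  }
  invisible(responses)
}

#' Read an item-response table from CSV
#'
#' Reads a persons-by-items table of ordinal item scores. The CSV must have a
#' header row with one column per item; a `person_id` column is optional and
#' created (row numbers) when absent. Blank cells become missing responses;
#' any non-missing score outside the declared category range is a validation
#' error naming the offending cell.
#'
#' @param path Path to a comma-separated, UTF-8, headered CSV file.
#' @param config A [run_config()]; its `score_range` declares the valid raw
#'   categories.
#' @return A tibble with a `person_id` column followed by one integer column
#'   per item.
#' @export
read_responses <- function(path, config = run_config()) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    stop(sprintf("malformed CSV '%s': parse problem at line %d (%s)",
                 path, probs$row[1] + 1L, probs$expected[1]), call. = FALSE)
  }
  if (!"person_id" %in% names(df)) {
    df <- dplyr::mutate(df, person_id = dplyr::row_number(), .before = 1)
  }
  validate_responses(df, config$score_range)
  df <- dplyr::mutate(df, dplyr::across(!"person_id", as.integer))
  tibble::as_tibble(df)
}

#' Write an item-response table to CSV
#'
#' @param responses Response tibble as returned by [read_responses()] or
#'   [generate_responses()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(responses, path) {
  readr::write_csv(responses, path, progress = FALSE)
  invisible(path)
}

# -- covariates --------------------------------------------------------------

#' Read a person covariate table from CSV
#'
#' Reads per-person demographic covariates: `gender` (male/female),
#' `age_group` (infant/kindergarten/primary/junior_high) and `symptom_level`
#' (mild_moderate/non_autism/severe). Each covariate is reference-coded with
#' the predominant category of the target population as the reference level
#' (male, infant, mild-to-moderate); dummy expansion of a k-level factor
#' yields k-1 columns. Level frequencies are reported via `message()`.
#'
#' @param path Path to a CSV with columns `gender`, `age_group`,
#'   `symptom_level` and optionally `person_id`.
#' @param quiet Suppress the frequency message.
#' @return A tibble with `person_id` and the three covariates as factors whose
#'   first level is the reference.
#' @export
read_covariates <- function(path, quiet = FALSE) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_covariates(df, quiet = quiet)
}

#' Coerce a data frame to a validated covariate table
#'
#' @param df Data frame with columns `gender`, `age_group`, `symptom_level`.
#' @param quiet Suppress the frequency message.
#' @return A covariate tibble with reference-coded factors.
#' @export
as_covariates <- function(df, quiet = TRUE) {
  levs <- cars_covariate_levels()
  need <- names(levs)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("covariate table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"person_id" %in% names(df)) {
    df <- dplyr::mutate(df, person_id = dplyr::row_number(), .before = 1)
  }
  for (v in need) {
    vals <- as.character(df[[v]])
    unknown <- setdiff(unique(vals[!is.na(vals)]), levs[[v]])
    if (length(unknown) > 0) {
      stop(sprintf("unknown %s label(s): %s (expected %s)", v,
                   paste(unknown, collapse = ", "),
                   paste(levs[[v]], collapse = ", ")), call. = FALSE)
    }
    df[[v]] <- factor(vals, levels = levs[[v]])
  }
  if (!quiet) {
    for (v in need) {
      tb <- table(df[[v]])
      message(v, ": ", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "))
    }
  }
  tibble::as_tibble(df)
}

#' Write a covariate table to CSV
#'
#' @param covariates Covariate tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(covariates, path) {
  readr::write_csv(covariates, path, progress = FALSE)
  invisible(path)
}

#' Reference-coded dummy matrix of the covariates
#'
#' Expands the three covariates into the six dummy columns used by the DIF
#' model: `female`, `kindergarten`, `primary`, `junior_high`, `non_autism`,
#' `severe`. The predominant groups (male, infant, mild-to-moderate) are the
#' reference and map to all-zero rows.
#'
#' @param covariates Covariate tibble from [read_covariates()] or
#'   [generate_population()].
#' @return Numeric matrix with one row per person and k-1 columns per k-level
#'   covariate.
#' @export
#' @examples
#' cov <- as_covariates(data.frame(
#'   gender = "female", age_group = "primary", symptom_level = "severe"
#' ))
#' covariate_dummies(cov)
covariate_dummies <- function(covariates) {
  covariates <- as_covariates(covariates)
  levs <- cars_covariate_levels()
  cols <- list()
  for (v in names(levs)) {
    for (lv in levs[[v]][-1]) {
      cols[[lv]] <- as.numeric(covariates[[v]] == lv)
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- as.character(covariates$person_id)
  X
}

# -- structured reports ------------------------------------------------------

# internal: convert a pipeline object to a plain serializable list
as_report <- function(x) {
  cls <- class(x)[1]
  fields <- if (inherits(x, "data.frame")) list(data = x) else unclass(x)
  list(schema = paste0("pcmdif/", cls, "/1"), fields = fields)
}

#' Write a pipeline result to a structured report file
#'
#' Serializes any finished stage output (a `pcm_fit`, diagnostics, residual
#' PCA, DIF fit, or a plain tibble) to deterministic, schema-versioned JSON
#' that [read_report()] loads back.
#'
#' @param result A pipeline result object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  rep <- as_report(result)
  ok <- tryCatch({
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         na = "null", null = "null", pretty = TRUE,
                         force = TRUE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write report to '", path, "': ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read a structured report file
#'
#' @param path Path written by [write_report()].
#' @return The reconstructed object. Tabular fields come back as tibbles; the
#'   original S3 class is restored from the schema tag.
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(rep$schema) || !grepl("^pcmdif/", rep$schema)) {
    stop("'", path, "' is not a pcmdif report", call. = FALSE)
  }
  cls <- strsplit(rep$schema, "/")[[1]][2]
  fields <- lapply(rep$fields, function(f) {
    if (is.data.frame(f)) tibble::as_tibble(f) else f
  })
  if (identical(names(fields), "data") && is.data.frame(fields$data)) {
    return(fields$data)
  }
  structure(fields, class = cls)
}
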