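#' Read and validate a monitoring CSV
#'
#' Expects the exact header `date,WT,EC,TN,TP,Q,CHLA`, ISO-8601 dates and
#' `.` as decimal separator. Malformed cells (including comma decimal
#' separators) raise a parse error naming the offending line; rows with any
#' missing field are dropped with a message giving the count; physical-range
#' violations (WT <= -5 deg C, negative EC/TN/TP/Q/CHLA, non-increasing
#' dates) raise an error naming the first offending row.
#'
#' @param path Path to a CSV file.
#' @return A validated monitoring tibble.
#' @export
read_monitoring <- function(path) {
  if (!file.exists(path)) {
    stopf("File `%s` does not exist.", path, class = "bloomregime_input_error")
  }
  hdr <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                               show_col_types = FALSE))
  if (!identical(hdr, c("date", chla_vars))) {
    stopf("Malformed header: expected `date,WT,EC,TN,TP,Q,CHLA`, got `%s`.",
          paste(hdr, collapse = ","), class = "bloomregime_parse_error")
  }
  tbl <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      date = readr::col_date(),
      WT = readr::col_double(), EC = readr::col_double(),
      TN = readr::col_double(), TP = readr::col_double(),
      Q = readr::col_double(), CHLA = readr::col_double()
    ),
    show_col_types = FALSE
  ))
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    stopf("Parse error at line %d of `%s`: expected %s, got `%s`.",
          probs$row[1], path, probs$expected[1], probs$actual[1],
          class = "bloomregime_parse_error")
  }
  if (nrow(tbl) == 0) {
    stopf("`%s` contains no data rows.", path,
          class = "bloomregime_input_error")
  }
  incomplete <- !stats::complete.cases(tbl)
  if (any(incomplete)) {
    inform(sprintf("Dropped %d row(s) with missing fields.", sum(incomplete)))
    tbl <- tbl[!incomplete, ]
    if (nrow(tbl) == 0) {
      stopf("All rows of `%s` had missing fields.", path,
            class = "bloomregime_input_error")
    }
  }
  validate_monitoring(tbl)
}

#' Validate an in-memory monitoring table
#'
#' @param data Data frame with columns `date`, `WT`, `EC`, `TN`, `TP`, `Q`,
#'   `CHLA`.
#' @return The data as a tibble, unchanged, if valid.
#' @export
validate_monitoring <- function(data) {
  missing <- setdiff(c("date", chla_vars), names(data))
  if (length(missing) > 0) {
    stopf("Missing column(s): %s.", paste(missing, collapse = ", "),
          class = "bloomregime_input_error")
  }
  tbl <- tibble::as_tibble(data)
  if (anyNA(tbl[c("date", chla_vars)])) {
    stopf("Monitoring table contains missing values; drop or fill them first.",
          class = "bloomregime_input_error")
  }
  bad_wt <- which(tbl$WT <= -5)
  if (length(bad_wt) > 0) {
    stopf("WT <= -5 deg C at row %d.", bad_wt[1],
          class = "bloomregime_input_error")
  }
  for (v in c("EC", "TN", "TP", "Q", "CHLA")) {
    bad <- which(tbl[[v]] < 0)
    if (length(bad) > 0) {
      stopf("Negative %s at row %d.", v, bad[1],
            class = "bloomregime_input_error")
    }
  }
  if (nrow(tbl) > 1 && any(diff(as.numeric(tbl$date)) <= 0)) {
    bad <- which(diff(as.numeric(tbl$date)) <= 0)[1] + 1L
    stopf("Dates are not strictly increasing at row %d.", bad,
          class = "bloomregime_input_error")
  }
  tbl
}

#' Fit a per-variable min-max normalizer
#'
#' Stores the extrema of each requested variable on the supplied (fitting)
#' table; [apply_normalizer()] then maps values x to
#' (x - min) / (max - min). Fit the spec on the training portion only and
#' apply it to test or scenario data to avoid information leakage.
#'
#' @param data Monitoring table (or any data frame holding the variables).
#' @param variables Character vector of columns to normalize. Defaults to
#'   the five drivers plus `CHLA`.
#' @return A `normalization_spec`: tibble with columns `variable`, `min`,
#'   `max`.
#' @export
fit_normalizer <- function(data, variables = chla_vars) {
  if (nrow(data) == 0) {
    stopf("Cannot fit a normalizer on an empty table.",
          class = "bloomregime_input_error")
  }
  missing <- setdiff(variables, names(data))
  if (length(missing) > 0) {
    stopf("Variable(s) %s absent from the data.",
          paste(missing, collapse = ", "),
          class = "bloomregime_contract_error")
  }
  spec <- tibble::tibble(
    variable = variables,
    min = unname(vapply(variables, function(v) min(data[[v]]), numeric(1))),
    max = unname(vapply(variables, function(v) max(data[[v]]), numeric(1)))
  )
  degenerate <- spec$variable[spec$max <= spec$min]
  if (length(degenerate) > 0) {
    stopf("Constant column(s) %s: min-max scale is degenerate.",
          paste(degenerate, collapse = ", "),
          class = "bloomregime_degenerate_scale_error")
  }
  structure(spec, class = c("normalization_spec", class(spec)))
}

#' Apply (or invert) a fitted min-max normalizer
#'
#' Values outside the fitted range map outside \[0, 1\] and are deliberately
#' not clipped: test-set or scenario values beyond the training extrema stay
#' informative.
#'
#' @param spec A `normalization_spec` from [fit_normalizer()].
#' @param data Data frame containing the spec's variables.
#' @param variables Subset of variables to transform; defaults to all in the
#'   spec.
#' @return Tibble of normalized columns in the requested order.
#' @export
apply_normalizer <- function(spec, data, variables = spec$variable) {
  missing_spec <- setdiff(variables, spec$variable)
  if (length(missing_spec) > 0) {
    stopf("Variable(s) %s not in the normalization spec.",
          paste(missing_spec, collapse = ", "),
          class = "bloomregime_contract_error")
  }
  missing_data <- setdiff(variables, names(data))
  if (length(missing_data) > 0) {
    stopf("Variable(s) %s absent from the data.",
          paste(missing_data, collapse = ", "),
          class = "bloomregime_contract_error")
  }
  out <- lapply(variables, function(v) {
    i <- match(v, spec$variable)
    (data[[v]] - spec$min[i]) / (spec$max[i] - spec$min[i])
  })
  tibble::as_tibble(setNames(out, variables))
}

#' @rdname apply_normalizer
#' @param x Numeric vector on the normalized scale.
#' @param variable Single variable name to denormalize.
#' @export
denormalize <- function(spec, x, variable) {
  i <- match(variable, spec$variable)
  if (is.na(i)) {
    stopf("Variable `%s` not in the normalization spec.", variable,
          class = "bloomregime_contract_error")
  }
  x * (spec$max[i] - spec$min[i]) + spec$min[i]
}

#' Seeded 70/30 train/test split
#'
#' Rows are permuted uniformly at random under the seed; the first
#' `floor(frac * n)` permuted rows form the training set. The split is
#' random, not chronological, and fully determined by the seed.
#'
#' @param data Monitoring table with at least 10 rows.
#' @param seed Integer seed (recorded in the result).
#' @param frac Training fraction, default 0.7.
#' @return A `split_index`: list with integer vectors `train` and `test`
#'   and the `seed`.
#' @export
split_train_test <- function(data, seed, frac = 0.7) {
  n <- nrow(data)
  if (n < 10) {
    stopf("Need at least 10 rows to split, got %d.", n,
          class = "bloomregime_input_error")
  }
  perm <- with_seed(seed, sample.int(n))
  n_train <- floor(frac * n)
  structure(
    list(train = sort(perm[seq_len(n_train)]),
         test = sort(perm[-seq_len(n_train)]),
         seed = as.integer(seed)),
    class = "split_index"
  )
}
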