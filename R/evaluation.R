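#' Model-performance statistics on the concentration scale
#'
#' Computes the three statistics used to judge chlorophyll-a models, always
#' on the original mg/m3 scale:
#' R2 = 1 - sum((C - Chat)^2) / sum((C - mean(C))^2);
#' RSR = RMSE / SD of the observations (so R2 = 1 - RSR^2 identically);
#' APBIAS = 100 * sum(|C - Chat|) / sum(C), the absolute bias as a percent
#' of the observed total. Perfect prediction gives (1, 0, 0); predicting the
#' observed mean gives R2 = 0, RSR = 1.
#'
#' @param observed Observed chlorophyll-a (mg/m3), not all identical.
#' @param predicted Predictions on the same scale and length.
#' @param model,set Optional labels recorded in the report.
#' @return A `metrics_report`: one-row tibble with `model`, `set`, `n`,
#'   `r_squared`, `rsr`, `apbias_percent`.
#' @export
compute_metrics <- function(observed, predicted, model = NA_character_,
                            set = NA_character_) {
  if (length(observed) != length(predicted) || length(observed) < 2) {
    stopf("`observed` and `predicted` must be equal-length with >= 2 values.",
          class = "bloomregime_contract_error")
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    stopf("Observations are constant: R2 is undefined.",
          class = "bloomregime_undefined_metric_error")
  }
  if (sum(observed) <= 0) {
    stopf("Sum of observations is not positive: APBIAS is undefined.",
          class = "bloomregime_undefined_metric_error")
  }
  ss_res <- sum((observed - predicted)^2)
  out <- tibble::tibble(
    model = model, set = set, n = length(observed),
    r_squared = 1 - ss_res / ss_tot,
    rsr = sqrt(ss_res) / sqrt(ss_tot),
    apbias_percent = 100 * sum(abs(observed - predicted)) / sum(observed)
  )
  class(out) <- c("metrics_report", class(out))
  out
}

#' Compare clustered and non-clustered models on a shared split
#'
#' Produces the one-row-per-model accuracy table: for every fitted
#' `regime_ann` (any K), training and test predictions are pooled across
#' clusters -- each record is predicted by its assigned cluster's network --
#' and a single metrics row per set is computed. Pooling uses every test
#' record exactly once. A cluster with no test records triggers a warning
#' but the remaining records are still pooled.
#'
#' @param fits Named list of `regime_ann` objects sharing the same data and
#'   split (names become the `model` column; defaults to `K=<k>`).
#' @return Tibble of `metrics_report` rows, two per fit (training, testing).
#' @export
comparison_report <- function(fits) {
  if (inherits(fits, "regime_ann")) fits <- list(fits)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- vapply(fits, function(f) sprintf("K=%d", f$k), character(1))
  }
  purrr::imap_dfr(fits, function(fit, label) {
    dplyr::bind_rows(
      regime_metrics(fit, "training", label),
      regime_metrics(fit, "testing", label)
    )
  })
}

# Pooled metrics of one regime_ann on one side of its split.
regime_metrics <- function(fit, set, label = sprintf("K=%d", fit$k)) {
  idx <- if (set == "training") fit$split$train else fit$split$test
  rows <- fit$data[idx, ]
  cl <- assign_cluster(fit$partition, rows$WT)
  empty <- setdiff(seq_len(fit$k), unique(cl))
  if (length(empty) > 0 && set == "testing") {
    warn(sprintf("Cluster(s) %s have no %s records; pooling the rest.",
                 paste(empty, collapse = ", "), set))
  }
  pred <- numeric(nrow(rows))
  for (k in unique(cl)) {
    pred[cl == k] <- predict(fit$models[[k]], rows[cl == k, ])
  }
  compute_metrics(rows$CHLA, pred, model = label, set = set)
}

#' Write a model-comparison table to CSV
#'
#' @param report Tibble from [comparison_report()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(report, path) {
  wide <- report |>
    tidyr::pivot_wider(
      id_cols = "model",
      names_from = "set",
      values_from = c("r_squared", "rsr", "apbias_percent", "n")
    )
  readr::write_csv(wide, path)
  invisible(path)
}

#' @exportS3Method ggplot2::autoplot
autoplot.metrics_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object,
                              c("r_squared", "rsr", "apbias_percent"),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$model, y = .data$value,
                                     fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
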