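#' Connection-weight relative importance (Garson partitioning)
#'
#' For every hidden node j the absolute products c_ij = |W1_ij * W2_j| are
#' shared out across inputs, r_ij = c_ij / sum_i' c_i'j; the importance of
#' input i is the normalised aggregate over hidden nodes,
#' RI_i = 100 * sum_j r_ij / sum_i' sum_j r_i'j. Hidden nodes whose
#' connections are all zero contribute nothing; biases are excluded. The
#' result is invariant to rescaling the output layer and to sign flips of
#' any weights, and always sums to 100.
#'
#' @param model A trained `chla_ann` or raw `network_params`.
#' @param labels Input names; taken from the model when available.
#' @return An `importance_profile`: tibble with columns `variable` and
#'   `ri_percent` (descending), plus a `model` attribute.
#' @export
relative_importance <- function(model, labels = NULL) {
  if (inherits(model, "chla_ann")) {
    labels <- labels %||% model$inputs
    params <- model$params
  } else if (inherits(model, "network_params")) {
    params <- model
  } else {
    stopf("`model` must be a `chla_ann` or `network_params`.",
          class = "bloomregime_contract_error")
  }
  labels <- labels %||% paste0("x", seq_len(params$n_inputs))

  C <- abs(params$W1 * rep(params$W2, each = params$n_inputs))  # N x M
  col_tot <- colSums(C)
  active <- col_tot > 0
  if (!any(active)) {
    stopf("All connection weights are zero: importance is undefined.",
          class = "bloomregime_undefined_importance_error")
  }
  R <- sweep(C[, active, drop = FALSE], 2, col_tot[active], "/")
  ri <- rowSums(R)
  ri <- 100 * ri / sum(ri)

  out <- tibble::tibble(variable = labels, ri_percent = ri)
  out <- dplyr::arrange(out, dplyr::desc(.data$ri_percent))
  attr(out, "model") <- if (inherits(model, "chla_ann")) {
    sprintf("chla_ann_M%d_seed%d", params$n_hidden, model$seed)
  } else {
    sprintf("network_%dx%d", params$n_inputs, params$n_hidden)
  }
  class(out) <- c("importance_profile", class(out))
  out
}

#' Importance profiles per cluster with a reach-averaged summary
#'
#' Given per-station fitted regime models (or a flat list of single-cluster
#' models), returns one Garson profile per station and cluster plus the
#' reach mean: the arithmetic mean of the station profiles within each
#' cluster.
#'
#' @param models Named list. Elements are either `regime_ann` fits (one per
#'   station) or `chla_ann` models (then all are treated as stations of one
#'   cluster).
#' @return Tibble with columns `station`, `cluster`, `variable`,
#'   `ri_percent`; reach means appear with `station = "reach_mean"`.
#' @export
importance_by_cluster <- function(models) {
  if (length(models) == 0) {
    stopf("Need at least one trained model.",
          class = "bloomregime_contract_error")
  }
  if (is.null(names(models))) {
    names(models) <- paste0("station", seq_along(models))
  }
  per_station <- purrr::imap_dfr(models, function(m, station) {
    if (inherits(m, "regime_ann")) {
      purrr::imap_dfr(m$models, function(sub, cl) {
        prof <- relative_importance(sub)
        tibble::tibble(station = station, cluster = as.integer(cl),
                       variable = prof$variable, ri_percent = prof$ri_percent)
      })
    } else {
      prof <- relative_importance(m)
      tibble::tibble(station = station, cluster = 1L,
                     variable = prof$variable, ri_percent = prof$ri_percent)
    }
  })
  reach <- per_station |>
    dplyr::group_by(.data$cluster, .data$variable) |>
    dplyr::summarise(ri_percent = mean(.data$ri_percent), .groups = "drop") |>
    dplyr::mutate(station = "reach_mean", .before = 1)
  dplyr::bind_rows(per_station, reach)
}

#' Write importance profiles to CSV
#'
#' @param profiles Tibble from [importance_by_cluster()], or a single
#'   `importance_profile`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_importance <- function(profiles, path) {
  if (inherits(profiles, "importance_profile")) {
    profiles <- tibble::tibble(
      cluster = 1L, station = attr(profiles, "model") %||% "model",
      variable = profiles$variable, ri_percent = profiles$ri_percent
    )
  }
  readr::write_csv(profiles[c("cluster", "station", "variable", "ri_percent")],
                   path)
  invisible(path)
}

#' @exportS3Method ggplot2::autoplot
autoplot.importance_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$variable,
                                                  .data$ri_percent),
                               y = .data$ri_percent)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Relative importance (%)",
                  title = "Connection-weight variable importance") +
    ggplot2::theme_minimal()
}
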