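#' Define a scenario grid
#'
#' A discharge sweep (optionally crossed with conductivity) around fixed
#' values of the remaining drivers. The default Q grid, 20 to 600 m3/s in
#' steps of 20, spans the management range of a gated weir; the default
#' two-way grid crosses Q = 250-600 (step 50) with EC = 140-500 uS/cm
#' (step 20).
#'
#' @param q_values Ascending discharge grid (m3/s).
#' @param ec_values Optional ascending conductivity grid (uS/cm).
#' @param fixed_inputs Named vector of values for the non-swept drivers
#'   (e.g. from [cluster_means()]).
#' @param cluster Cluster id the scenario is meant for (used to pick the
#'   network out of a `regime_ann`).
#' @return A `scenario_grid` list.
#' @export
scenario_grid <- function(q_values = seq(20, 600, by = 20),
                          ec_values = NULL,
                          fixed_inputs,
                          cluster = NULL) {
  if (length(q_values) < 2 || is.unsorted(q_values, strictly = TRUE)) {
    stopf("`q_values` must be >= 2 strictly increasing values.",
          class = "bloomregime_config_error")
  }
  if (!is.null(ec_values) && is.unsorted(ec_values, strictly = TRUE)) {
    stopf("`ec_values` must be strictly increasing.",
          class = "bloomregime_config_error")
  }
  if (!all(is.finite(fixed_inputs))) {
    stopf("`fixed_inputs` must be finite.", class = "bloomregime_config_error")
  }
  structure(
    list(q_values = as.numeric(q_values),
         ec_values = if (is.null(ec_values)) NULL else as.numeric(ec_values),
         fixed_inputs = fixed_inputs,
         cluster = cluster),
    class = "scenario_grid"
  )
}

#' Generic chlorophyll-a prediction used by the scenario engine
#'
#' Dispatches on the model type: a `chla_ann` normalizes the drivers with
#' its own spec, runs the network and denormalizes; a `regime_ann` routes
#' each record to its assigned cluster's network; a function wrapped by
#' [chla_model_function()] is called directly (useful for closed-form
#' responses in tests and what-if analyses).
#'
#' @param model The model object.
#' @param newdata Data frame with the driver columns.
#' @return Numeric vector of chlorophyll-a predictions (mg/m3).
#' @export
predict_chla <- function(model, newdata) UseMethod("predict_chla")

#' @export
predict_chla.chla_ann <- function(model, newdata) predict(model, newdata)

#' @export
predict_chla.regime_ann <- function(model, newdata) predict(model, newdata)

#' @export
predict_chla.chla_model_function <- function(model, newdata) {
  as.numeric(model$fn(newdata))
}

#' @rdname predict_chla
#' @param fn Function taking a driver data frame and returning mg/m3.
#' @export
chla_model_function <- function(fn) {
  structure(list(fn = fn), class = "chla_model_function")
}

# Resolve the network a grid should be run through.
scenario_model <- function(model, grid) {
  if (inherits(model, "regime_ann")) {
    cl <- grid$cluster %||% model$k
    model$models[[cl]]
  } else {
    model
  }
}

# Grid points outside a fitted normalizer's range are predicted anyway, but
# flagged: a discharge sweep deliberately exceeds observed flows.
warn_extrapolation <- function(model, values, variable) {
  if (!inherits(model, "chla_ann")) return(invisible())
  spec <- model$normalizer
  i <- match(variable, spec$variable)
  outside <- values < spec$min[i] | values > spec$max[i]
  if (any(outside)) {
    warn(sprintf(
      "%d %s grid point(s) outside the fitted range [%.3g, %.3g]: %s",
      sum(outside), variable, spec$min[i], spec$max[i],
      paste(format(values[outside]), collapse = ", ")))
  }
  invisible()
}

# Smallest grid value whose prediction is at or below the threshold.
find_mitigation <- function(q_values, predictions, threshold) {
  hit <- which(predictions <= threshold)
  if (length(hit) == 0) NA_real_ else q_values[min(hit)]
}

#' Discharge sweep: find the bloom-mitigation discharge
#'
#' Predicts chlorophyll-a along the discharge grid with all other drivers
#' held at `grid$fixed_inputs`, and locates the mitigation discharge: the
#' smallest grid Q whose prediction falls to `reduction_fraction` (default
#' 50%) of the sweep maximum, or -- when `target_chla` is given -- to that
#' absolute concentration.
#'
#' @param model A `chla_ann`, `regime_ann` (the grid's cluster network is
#'   used, defaulting to the warmest), or [chla_model_function()].
#' @param grid A [scenario_grid()] without `ec_values`.
#' @param reduction_fraction Fraction of the sweep maximum defining
#'   suppression, default 0.5.
#' @param target_chla Optional absolute target (mg/m3) overriding the
#'   fractional criterion.
#' @return A `scenario_result`: list with `predictions` (tibble `Q`,
#'   `chla`), `max_chla`, `threshold`, and `mitigation_q` (NA when never
#'   reached).
#' @export
run_q_sweep <- function(model, grid, reduction_fraction = 0.5,
                        target_chla = NULL) {
  stopifnot(inherits(grid, "scenario_grid"))
  net <- scenario_model(model, grid)
  newdata <- scenario_frame(grid, q = grid$q_values)
  warn_extrapolation(net, grid$q_values, "Q")
  chla <- predict_chla(net, newdata)
  max_chla <- max(chla)
  threshold <- if (is.null(target_chla)) reduction_fraction * max_chla
               else target_chla
  structure(
    list(predictions = tibble::tibble(Q = grid$q_values, chla = chla),
         max_chla = max_chla, threshold = threshold,
         mitigation_q = find_mitigation(grid$q_values, chla, threshold),
         criterion = if (is.null(target_chla)) {
           sprintf("%.0f%% of sweep maximum", 100 * reduction_fraction)
         } else {
           sprintf("%.3g mg/m3 absolute", target_chla)
         }),
    class = "scenario_result"
  )
}

#' Discharge-by-conductivity scenario surface
#'
#' Predicts chlorophyll-a over the full Q x EC grid and, for each EC value,
#' locates the mitigation discharge -- by default the 50%-of-maximum
#' criterion evaluated within that EC column, or an absolute `target_chla`.
#'
#' @inheritParams run_q_sweep
#' @param grid A [scenario_grid()] with both `q_values` and `ec_values`.
#' @return A `scenario_surface`: list with `surface` (tibble `Q`, `EC`,
#'   `chla`) and `mitigation` (tibble `EC`, `mitigation_q`).
#' @export
run_q_ec_grid <- function(model, grid, reduction_fraction = 0.5,
                          target_chla = NULL) {
  stopifnot(inherits(grid, "scenario_grid"))
  if (is.null(grid$ec_values)) {
    stopf("`grid` has no `ec_values`; use `run_q_sweep()`.",
          class = "bloomregime_config_error")
  }
  net <- scenario_model(model, grid)
  pts <- tidyr::expand_grid(EC = grid$ec_values, Q = grid$q_values)
  newdata <- scenario_frame(grid, q = pts$Q, ec = pts$EC)
  warn_extrapolation(net, grid$q_values, "Q")
  warn_extrapolation(net, grid$ec_values, "EC")
  pts$chla <- predict_chla(net, newdata)
  mitigation <- pts |>
    dplyr::group_by(.data$EC) |>
    dplyr::summarise(
      max_chla = max(.data$chla),
      mitigation_q = find_mitigation(
        .data$Q, .data$chla,
        if (is.null(target_chla)) reduction_fraction * max(.data$chla)
        else target_chla),
      .groups = "drop"
    )
  structure(
    list(surface = pts[c("Q", "EC", "chla")], mitigation = mitigation),
    class = "scenario_surface"
  )
}

# Build the driver frame for a set of grid points.
scenario_frame <- function(grid, q, ec = NULL) {
  fixed <- grid$fixed_inputs
  out <- tibble::tibble(.rows = length(q))
  for (v in chla_inputs) {
    out[[v]] <- if (v == "Q") {
      q
    } else if (v == "EC" && !is.null(ec)) {
      ec
    } else {
      if (!v %in% names(fixed)) {
        stopf("`fixed_inputs` must provide `%s`.", v,
              class = "bloomregime_config_error")
      }
      rep(unname(fixed[v]), length(q))
    }
  }
  out
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Discharge sweep over %d points (%g-%g m3/s)\n",
              nrow(x$predictions), min(x$predictions$Q), max(x$predictions$Q)))
  cat(sprintf("max Chl-a %.2f mg/m3; criterion %s (threshold %.2f)\n",
              x$max_chla, x$criterion, x$threshold))
  if (is.na(x$mitigation_q)) {
    cat("mitigation discharge: not reached on this grid\n")
  } else {
    cat(sprintf("mitigation discharge: %g m3/s\n", x$mitigation_q))
  }
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.scenario_result <- function(object, ...) {
  p <- ggplot2::ggplot(object$predictions,
                       ggplot2::aes(x = .data$Q, y = .data$chla)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "Weir discharge (m3/s)",
                  y = "Predicted Chl-a (mg/m3)",
                  title = "Chlorophyll-a response to weir discharge") +
    ggplot2::theme_minimal()
  if (!is.na(object$mitigation_q)) {
    p <- p + ggplot2::geom_vline(xintercept = object$mitigation_q,
                                 linetype = "dotted")
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.scenario_surface <- function(object, ...) {
  ggplot2::ggplot(object$surface,
                  ggplot2::aes(x = .data$EC, y = .data$Q,
                               fill = .data$chla)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "Chl-a (mg/m3)") +
    ggplot2::labs(x = "EC (uS/cm)", y = "Weir discharge (m3/s)",
                  title = "Chlorophyll-a over the discharge-conductivity grid") +
    ggplot2::theme_minimal()
}
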