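#' Fit clustered chlorophyll-a models
#'
#' The full modelling chain for one station and one K: split the table
#' 70/30, partition the training rows into K thermal regimes by
#' [kmeans_wt()], then fit one network per cluster on that cluster's
#' training rows (each with its own min-max normalizer fitted on those rows
#' only). K = 1 reproduces the conventional single-model analysis.
#'
#' @param data Validated monitoring table.
#' @param k Number of WT clusters (>= 1).
#' @param hidden_size Hidden nodes per network (default 15); ignored when
#'   `select_hidden = TRUE`.
#' @param config A [train_config()]; its seed drives initialization.
#' @param seed Master seed for the split and clustering; per-stage seeds are
#'   derived as seed + 101 (split), seed + 211 (clustering), and
#'   `config$seed + 307 + cluster` for each network's initialization.
#' @param split Optional pre-computed `split_index` (use the same one across
#'   K values when building a comparison).
#' @param select_hidden Select M per cluster by cross-validation.
#' @param restarts K-means restarts.
#' @return A `regime_ann`: list with `k`, `partition`, `split`, `models`
#'   (one `chla_ann` per cluster), and the `data`.
#' @examples
#' sim <- simulate_monitoring(goryung_config(n_days = 150, seed = 2))
#' fit <- fit_regime_models(sim$data, k = 2, hidden_size = 4,
#'                          config = train_config(max_epochs = 150), seed = 1)
#' glance(fit)
#' @export
fit_regime_models <- function(data, k, hidden_size = 15,
                              config = train_config(), seed = 1,
                              split = NULL, select_hidden = FALSE,
                              restarts = 10) {
  data <- validate_monitoring(data)
  split <- split %||% split_train_test(data, seed = seed + 101L)
  train_rows <- data[split$train, ]
  partition <- kmeans_wt(train_rows, k = k, seed = seed + 211L,
                         restarts = restarts)
  models <- lapply(seq_len(k), function(cl) {
    rows <- train_rows[partition$labels == cl, ]
    cfg <- config
    cfg$seed <- config$seed + 307L + cl
    fit_chla_ann(rows, hidden_size = hidden_size, config = cfg,
                 select_hidden = select_hidden)
  })
  names(models) <- as.character(seq_len(k))
  structure(
    list(k = as.integer(k), partition = partition, split = split,
         models = models, data = data, seed = as.integer(seed)),
    class = "regime_ann"
  )
}

#' @export
predict.regime_ann <- function(object, newdata, ...) {
  cl <- assign_cluster(object$partition, newdata$WT)
  pred <- numeric(nrow(newdata))
  for (k in unique(cl)) {
    pred[cl == k] <- predict(object$models[[k]], newdata[cl == k, ])
  }
  pred
}

#' @export
print.regime_ann <- function(x, ...) {
  cat(sprintf("regime_ann: K = %d thermal regime(s), %d train / %d test rows\n",
              x$k, length(x$split$train), length(x$split$test)))
  print(tidy(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.regime_ann <- function(x, ...) {
  tibble::tibble(
    cluster = seq_len(x$k),
    centroid_wt = x$partition$centroids,
    n_train = x$partition$sizes,
    hidden_size = vapply(x$models, function(m) m$hidden_size, integer(1)),
    epochs = vapply(x$models, function(m) m$report$epochs, integer(1)),
    final_sse = vapply(x$models, function(m) tail(m$report$sse_path, 1),
                       numeric(1))
  )
}

#' @exportS3Method generics::glance
glance.regime_ann <- function(x, ...) {
  test <- regime_metrics(x, "testing")
  tibble::tibble(
    k = x$k,
    test_r_squared = test$r_squared,
    test_rsr = test$rsr,
    test_apbias_percent = test$apbias_percent,
    n_train = length(x$split$train),
    n_test = length(x$split$test)
  )
}

#' Per-cluster training means of the drivers
#'
#' The fixed (non-swept) inputs of a scenario default to these values.
#'
#' @param fit A `regime_ann`.
#' @param cluster Cluster id; defaults to the warmest cluster.
#' @return Named numeric vector of mean WT, EC, TN, TP, Q over the
#'   cluster's training rows.
#' @export
cluster_means <- function(fit, cluster = fit$k) {
  rows <- fit$data[fit$split$train, ]
  rows <- rows[fit$partition$labels == cluster, ]
  vapply(chla_inputs, function(v) mean(rows[[v]]), numeric(1))
}
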