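#' Training configuration for the neural regressor
#'
#' "Adaptive gradient descent" is implemented as AdaGrad: each parameter is
#' updated as w <- w - lr * g / sqrt(G + eps), with G the running sum of
#' squared gradients for that parameter and g the full-batch gradient of the
#' half-SSE cost. Training stops at `max_epochs` or when the relative change
#' in cost over `early_stop_window` epochs drops below `early_stop_tol`.
#'
#' @param learning_rate AdaGrad step size, default 0.1.
#' @param adagrad_epsilon Denominator stabiliser, default 1e-8.
#' @param max_epochs Epoch budget, default 5000.
#' @param early_stop_window,early_stop_tol Early-stopping lookback (epochs)
#'   and relative tolerance.
#' @param cv_folds Folds for hidden-size selection, default 5.
#' @param hidden_size_grid Candidate hidden-layer sizes, default
#'   c(5, 10, 15, 20, 25).
#' @param seed Integer seed for weight initialization and fold assignment.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.1,
                         adagrad_epsilon = 1e-8,
                         max_epochs = 5000,
                         early_stop_window = 50,
                         early_stop_tol = 1e-6,
                         cv_folds = 5,
                         hidden_size_grid = c(5, 10, 15, 20, 25),
                         seed = 1) {
  check_number(learning_rate, "learning_rate", 0)
  check_number(adagrad_epsilon, "adagrad_epsilon", 0, strict = TRUE)
  if (max_epochs < 1) stopf("`max_epochs` must be >= 1.",
                            class = "bloomregime_config_error")
  if (cv_folds < 2) stopf("`cv_folds` must be >= 2.",
                          class = "bloomregime_config_error")
  structure(
    list(learning_rate = learning_rate, adagrad_epsilon = adagrad_epsilon,
         max_epochs = as.integer(max_epochs),
         early_stop_window = as.integer(early_stop_window),
         early_stop_tol = early_stop_tol, cv_folds = as.integer(cv_folds),
         hidden_size_grid = as.integer(hidden_size_grid),
         seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Xavier initialization of a single-hidden-layer network
#'
#' Input-to-hidden weights are drawn uniformly on \[-1/sqrt(N), +1/sqrt(N)\]
#' (N inputs); hidden-to-output weights on \[-1/sqrt(M), +1/sqrt(M)\]
#' (M hidden nodes, the layer's own fan-in); all biases start at zero.
#'
#' @param n_inputs Number of input nodes N.
#' @param n_hidden Number of hidden nodes M.
#' @param seed Integer seed; the same seed reproduces the parameters.
#' @return A `network_params` list: `W1` (N x M), `b1` (M), `W2` (M), `b2`
#'   (scalar), plus `n_inputs`, `n_hidden`.
#' @export
xavier_init <- function(n_inputs, n_hidden, seed = 1) {
  stopifnot(n_inputs >= 1, n_hidden >= 1)
  n_inputs <- as.integer(n_inputs)
  n_hidden <- as.integer(n_hidden)
  with_seed(seed, {
    lim1 <- 1 / sqrt(n_inputs)
    lim2 <- 1 / sqrt(n_hidden)
    structure(
      list(
        W1 = matrix(runif(n_inputs * n_hidden, -lim1, lim1), n_inputs, n_hidden),
        b1 = rep(0, n_hidden),
        W2 = runif(n_hidden, -lim2, lim2),
        b2 = 0,
        n_inputs = n_inputs,
        n_hidden = n_hidden
      ),
      class = "network_params"
    )
  })
}

#' Forward pass of the network
#'
#' Computes b2 + sum_j tanh(x %*% W1 + b1)_j * W2_j for each row of `x`:
#' a tanh hidden layer and a linear output node, so predictions are bounded
#' by |b2| + sum(|W2|).
#'
#' @param params A `network_params`.
#' @param x Numeric vector of length N or matrix with N columns, on the
#'   normalized scale.
#' @return Numeric vector of predictions (normalized scale).
#' @export
ann_forward <- function(params, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != params$n_inputs) {
    stopf("Input has %d columns but the network expects %d.",
          ncol(x), params$n_inputs, class = "bloomregime_contract_error")
  }
  H <- sweep(x %*% params$W1, 2, params$b1, "+")
  as.vector(tanh(H) %*% params$W2 + params$b2)
}

#' Half sum-of-squared-errors cost
#'
#' @param predicted,observed Equal-length numeric vectors.
#' @return 0.5 * sum((predicted - observed)^2).
#' @export
sse <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) < 1) {
    stopf("`predicted` and `observed` must be equal-length, non-empty.",
          class = "bloomregime_contract_error")
  }
  0.5 * sum((predicted - observed)^2)
}

# Full-batch analytic gradients of the half-SSE cost through the network.
# Returned in the same shapes as the parameters.
ann_gradients <- function(params, X, y) {
  H <- sweep(X %*% params$W1, 2, params$b1, "+")
  A <- tanh(H)
  pred <- as.vector(A %*% params$W2 + params$b2)
  d <- pred - y                                   # d(cost)/d(pred)
  dH <- (d %*% t(params$W2)) * (1 - A^2)          # back through tanh
  list(
    W1 = unname(t(X) %*% dH),
    b1 = unname(colSums(dH)),
    W2 = as.vector(t(A) %*% d),
    b2 = sum(d),
    cost = 0.5 * sum(d^2),
    pred = pred
  )
}

#' Train the network by full-batch AdaGrad
#'
#' Gradients of the half-SSE cost are computed analytically over the whole
#' training batch each epoch (training is therefore deterministic given the
#' initial parameters), and every trainable parameter is updated with its
#' own AdaGrad-scaled step.
#'
#' @param params Initial `network_params`, e.g. from [xavier_init()].
#' @param X Normalized input matrix (rows = records).
#' @param y Normalized target vector.
#' @param config A [train_config()].
#' @return A `train_report`: list with `params` (trained), `sse_path`
#'   (per-epoch cost), `epochs`, and `converged` (TRUE if early stopping
#'   fired before `max_epochs`).
#' @export
ann_train <- function(params, X, y, config = train_config()) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stopf("Need at least 2 training rows.",
                         class = "bloomregime_contract_error")
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stopf("Training data must be finite.", class = "bloomregime_contract_error")
  }
  lr <- config$learning_rate
  eps <- config$adagrad_epsilon
  G <- list(W1 = params$W1 * 0, b1 = params$b1 * 0,
            W2 = params$W2 * 0, b2 = 0)
  sse_path <- numeric(config$max_epochs)
  converged <- FALSE
  epochs <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    g <- ann_gradients(params, X, y)
    if (!is.finite(g$cost)) {
      stopf("Training diverged (non-finite cost) at epoch %d.", epoch,
            class = "bloomregime_training_error")
    }
    for (nm in c("W1", "b1", "W2", "b2")) {
      G[[nm]] <- G[[nm]] + g[[nm]]^2
      params[[nm]] <- params[[nm]] - lr * g[[nm]] / sqrt(G[[nm]] + eps)
    }
    sse_path[epoch] <- g$cost
    epochs <- epoch
    w <- config$early_stop_window
    if (epoch > w) {
      ref <- sse_path[epoch - w]
      if (abs(ref - sse_path[epoch]) <= config$early_stop_tol * max(abs(ref), 1e-12)) {
        converged <- TRUE
        break
      }
    }
  }

  structure(
    list(params = params, sse_path = sse_path[seq_len(epochs)],
         epochs = epochs, converged = converged),
    class = "train_report"
  )
}

#' Choose the hidden-layer size by k-fold cross-validation
#'
#' For each candidate size, trains on k-1 folds and scores the half-SSE on
#' the held-out fold; the size with the lowest mean validation cost wins,
#' ties going to the smaller network.
#'
#' @param X Normalized input matrix.
#' @param y Normalized target vector.
#' @param config A [train_config()]; supplies the grid, fold count and seed.
#' @return List with `hidden_size` (the winner) and `scores` (tibble of
#'   per-size mean validation SSE).
#' @export
select_hidden_size <- function(X, y, config = train_config()) {
  X <- as.matrix(X)
  grid <- config$hidden_size_grid
  if (length(grid) == 0) stopf("Empty hidden-size grid.",
                               class = "bloomregime_contract_error")
  n <- nrow(X)
  if (n < 2 * config$cv_folds) {
    stopf("Too few rows (%d) for %d-fold cross-validation.", n,
          config$cv_folds, class = "bloomregime_contract_error")
  }
  folds <- with_seed(config$seed + 7919L,
                     sample(rep_len(seq_len(config$cv_folds), n)))
  mean_scores <- vapply(grid, function(m) {
    fold_scores <- vapply(seq_len(config$cv_folds), function(f) {
      tr <- folds != f
      init <- xavier_init(ncol(X), m, seed = config$seed + 31L * m + f)
      fit <- ann_train(init, X[tr, , drop = FALSE], y[tr], config)
      sse(ann_forward(fit$params, X[!tr, , drop = FALSE]), y[!tr])
    }, numeric(1))
    mean(fold_scores)
  }, numeric(1))
  list(
    hidden_size = choose_best_size(grid, mean_scores),
    scores = tibble::tibble(hidden_size = grid, mean_val_sse = mean_scores)
  )
}

# Lowest score wins; exact ties go to the smaller size.
choose_best_size <- function(sizes, scores) {
  best <- min(scores)
  min(sizes[scores == best])
}

#' Fit a chlorophyll-a network on a monitoring table
#'
#' Convenience wrapper tying the pieces together for one (sub)set of
#' records: fits the min-max normalizer on `data` (pass the training rows
#' only), normalizes drivers and target, initializes with Xavier weights and
#' trains with AdaGrad. Predictions from the fitted object are denormalized
#' back to mg/m3.
#'
#' @param data Monitoring table used for fitting (training rows).
#' @param hidden_size Hidden-layer size M; ignored when
#'   `select_hidden = TRUE`.
#' @param config A [train_config()].
#' @param select_hidden If TRUE, pick M by cross-validation from
#'   `config$hidden_size_grid` before the final fit.
#' @param inputs Driver columns, default `c("WT","EC","TN","TP","Q")`.
#' @return A `chla_ann` model: trained `params`, the `normalizer`, the
#'   training `report`, `inputs`, `hidden_size`, `seed`.
#' @examples
#' sim <- simulate_monitoring(goryung_config(n_days = 120, seed = 5))
#' fit <- fit_chla_ann(sim$data, hidden_size = 5,
#'                     config = train_config(max_epochs = 200))
#' head(predict(fit, sim$data))
#' @export
fit_chla_ann <- function(data, hidden_size = 15, config = train_config(),
                         select_hidden = FALSE, inputs = chla_inputs) {
  spec <- fit_normalizer(data, c(inputs, "CHLA"))
  norm <- apply_normalizer(spec, data)
  X <- as.matrix(norm[inputs])
  y <- norm$CHLA
  if (select_hidden) {
    sel <- select_hidden_size(X, y, config)
    hidden_size <- sel$hidden_size
  } else {
    sel <- NULL
  }
  init <- xavier_init(length(inputs), hidden_size, seed = config$seed)
  report <- ann_train(init, X, y, config)
  structure(
    list(params = report$params, normalizer = spec, report = report,
         inputs = inputs, hidden_size = as.integer(hidden_size),
         seed = config$seed, selection = sel$scores, config = config),
    class = "chla_ann"
  )
}

#' @export
predict.chla_ann <- function(object, newdata, ...) {
  norm <- apply_normalizer(object$normalizer, newdata, object$inputs)
  denormalize(object$normalizer,
              ann_forward(object$params, as.matrix(norm)), "CHLA")
}

#' @export
print.chla_ann <- function(x, ...) {
  cat(sprintf("chla_ann: %d inputs -> %d tanh hidden nodes -> linear output\n",
              x$params$n_inputs, x$params$n_hidden))
  cat(sprintf("trained %d epochs (converged: %s), final half-SSE %.4g\n",
              x$report$epochs, x$report$converged,
              tail(x$report$sse_path, 1)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.chla_ann <- function(x, ...) {
  p <- x$params
  input_rows <- tibble::tibble(
    layer = "input_hidden",
    from = rep(x$inputs, times = p$n_hidden),
    to = rep(paste0("h", seq_len(p$n_hidden)), each = p$n_inputs),
    weight = as.vector(p$W1)
  )
  out_rows <- tibble::tibble(
    layer = "hidden_output",
    from = paste0("h", seq_len(p$n_hidden)),
    to = "CHLA",
    weight = p$W2
  )
  bias_rows <- tibble::tibble(
    layer = "bias",
    from = c(paste0("h", seq_len(p$n_hidden)), "output"),
    to = c(paste0("h", seq_len(p$n_hidden)), "CHLA"),
    weight = c(p$b1, p$b2)
  )
  dplyr::bind_rows(input_rows, out_rows, bias_rows)
}

#' @exportS3Method generics::glance
glance.chla_ann <- function(x, ...) {
  tibble::tibble(
    n_inputs = x$params$n_inputs,
    hidden_size = x$params$n_hidden,
    epochs = x$report$epochs,
    converged = x$report$converged,
    final_sse = tail(x$report$sse_path, 1),
    seed = x$seed
  )
}

#' Round-trip a fitted model to a JSON file
#'
#' Persists shapes, weights, the normalization spec, the training
#' configuration and seed, so scenario predictions are reproducible
#' bit-for-bit from the file.
#'
#' @param model A `chla_ann`.
#' @param path Output JSON path.
#' @return `path` invisibly; `read_chla_model()` returns the restored model.
#' @export
write_chla_model <- function(model, path) {
  obj <- list(
    inputs = model$inputs,
    hidden_size = model$hidden_size,
    seed = model$seed,
    params = list(W1 = model$params$W1, b1 = model$params$b1,
                  W2 = model$params$W2, b2 = model$params$b2),
    normalizer = as.data.frame(model$normalizer),
    config = unclass(model$config)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_chla_model
#' @export
read_chla_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  n_in <- length(obj$inputs)
  params <- structure(
    list(W1 = matrix(unlist(obj$params$W1), nrow = n_in),
         b1 = as.numeric(obj$params$b1),
         W2 = as.numeric(obj$params$W2),
         b2 = as.numeric(obj$params$b2),
         n_inputs = n_in, n_hidden = length(obj$params$b1)),
    class = "network_params"
  )
  spec <- tibble::as_tibble(obj$normalizer)
  class(spec) <- c("normalization_spec", class(spec))
  cfg <- do.call(train_config, obj$config[setdiff(names(obj$config), NULL)])
  structure(
    list(params = params, normalizer = spec, report = NULL,
         inputs = obj$inputs, hidden_size = as.integer(obj$hidden_size),
         seed = as.integer(obj$seed), selection = NULL, config = cfg),
    class = "chla_ann"
  )
}
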