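test_that("Xavier initialization respects the fan-in intervals with zero biases", {
  p <- xavier_init(5, 15, seed = 3)
  expect_true(all(abs(p$W1) <= 1 / sqrt(5)))
  expect_true(all(abs(p$W2) <= 1 / sqrt(15)))
  expect_equal(p$b1, rep(0, 15))
  expect_equal(p$b2, 0)
  expect_identical(xavier_init(5, 15, seed = 3), p)
  expect_false(identical(xavier_init(5, 15, seed = 4)$W1, p$W1))
})

test_that("the forward pass matches hand evaluation", {
  p <- xavier_init(3, 4, seed = 1)
  p$W1[] <- 0; p$W2[] <- 0; p$b2 <- 0.3
  expect_equal(ann_forward(p, matrix(stats::runif(15), 5, 3)), rep(0.3, 5))

  p1 <- structure(list(W1 = matrix(1), b1 = 0, W2 = 1, b2 = 0,
                       n_inputs = 1L, n_hidden = 1L),
                  class = "network_params")
  expect_equal(ann_forward(p1, 0), 0)

  p2 <- structure(list(W1 = matrix(c(1, 1), 2, 1), b1 = 0, W2 = 2, b2 = 1,
                       n_inputs = 2L, n_hidden = 1L),
                  class = "network_params")
  expect_equal(ann_forward(p2, c(0.5, 0.5)), 1 + 2 * tanh(1))
  expect_equal(ann_forward(p2, c(0.5, 0.5)), 2.5232, tolerance = 1e-4)

  expect_error(ann_forward(p2, c(1, 2, 3)),
               class = "bloomregime_contract_error")
})

test_that("the half-SSE cost behaves as its closed form", {
  expect_equal(sse(c(2, 4), c(1, 2)), 2.5)
  expect_equal(sse(1:5, 1:5), 0)
  r <- stats::rnorm(20)
  expect_equal(sse(2 * r, rep(0, 20)), 4 * sse(r, rep(0, 20)))
  expect_error(sse(1:3, 1:2), class = "bloomregime_contract_error")
})

test_that("analytic gradients match central finite differences", {
  set.seed(99)
  for (rep in 1:10) {
    n_in <- sample(2:4, 1)
    m <- sample(2:5, 1)
    p <- xavier_init(n_in, m, seed = rep)
    p$b1 <- stats::rnorm(m, 0, 0.3)
    p$b2 <- stats::rnorm(1, 0, 0.3)
    X <- matrix(stats::runif(6 * n_in), 6, n_in)
    y <- stats::runif(6)
    got <- bloomregime:::ann_gradients(p, X, y)
    want <- numeric_gradients(p, X, y)
    for (nm in c("W1", "b1", "W2", "b2")) {
      denom <- pmax(abs(want[[nm]]), 1e-4)
      expect_lt(max(abs(got[[nm]] - want[[nm]]) / denom), 1e-6)
    }
  }
})

test_that("training fits a linear map to high accuracy", {
  with_seed <- function(s, code) withr::with_seed(s, code)
  X <- with_seed(7, matrix(stats::runif(1000), 500, 2))
  y <- 0.3 * X[, 1] + 0.7 * X[, 2]
  fit <- ann_train(xavier_init(2, 5, seed = 1), X, y, train_config())
  pred <- ann_forward(fit$params, X)
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  expect_gte(r2, 0.99)
  expect_lte(tail(fit$sse_path, 1), fit$sse_path[1])
})

test_that("degenerate training settings behave as contracts state", {
  X <- matrix(stats::runif(40), 20, 2)
  y <- stats::runif(20)
  p0 <- xavier_init(2, 3, seed = 5)

  frozen <- ann_train(p0, X, y, train_config(learning_rate = 0, max_epochs = 10))
  expect_equal(frozen$params$W1, p0$W1)
  expect_equal(frozen$params$W2, p0$W2)
  expect_equal(frozen$sse_path, rep(frozen$sse_path[1], 10))

  one <- ann_train(p0, X, y, train_config(max_epochs = 1))
  expect_length(one$sse_path, 1)
  expect_equal(one$epochs, 1L)

  expect_error(ann_train(p0, X[1, , drop = FALSE], y[1]),
               class = "bloomregime_contract_error")
  expect_error(ann_train(p0, X * NA, y), class = "bloomregime_contract_error")
})

test_that("predictions are bounded by the output-layer weights", {
  p <- xavier_init(4, 6, seed = 8)
  bound <- abs(p$b2) + sum(abs(p$W2))
  X <- matrix(stats::rnorm(400, sd = 50), 100, 4)
  expect_true(all(abs(ann_forward(p, X)) <= bound + 1e-12))
})

test_that("hidden-size selection returns the grid minimiser with ties to the smaller size", {
  X <- withr::with_seed(3, matrix(stats::runif(160), 80, 2))
  y <- 0.4 * X[, 1] + 0.6 * X[, 2]
  cfg <- train_config(max_epochs = 60, hidden_size_grid = c(3L),
                      cv_folds = 4)
  sel <- select_hidden_size(X, y, cfg)
  expect_equal(sel$hidden_size, 3L)
  expect_equal(nrow(sel$scores), 1)

  cfg2 <- train_config(max_epochs = 40, hidden_size_grid = c(2L, 4L),
                       cv_folds = 4)
  sel2 <- select_hidden_size(X, y, cfg2)
  expect_equal(sel2$hidden_size,
               bloomregime:::choose_best_size(sel2$scores$hidden_size,
                                             sel2$scores$mean_val_sse))
  expect_equal(bloomregime:::choose_best_size(c(10L, 15L), c(0.5, 0.5)), 10L)
  expect_error(select_hidden_size(X[1:6, ], y[1:6],
                                  train_config(cv_folds = 5)),
               class = "bloomregime_contract_error")
})

test_that("the default grid carries the conventional sizes", {
  cfg <- train_config()
  expect_equal(cfg$hidden_size_grid, c(5L, 10L, 15L, 20L, 25L))
  expect_true(15L %in% cfg$hidden_size_grid)
})

test_that("fitted models predict on the concentration scale and round-trip to JSON", {
  sim <- simulate_monitoring(goryung_config(n_days = 150, seed = 6))
  fit <- fit_chla_ann(sim$data, hidden_size = 4,
                      config = train_config(max_epochs = 300, seed = 2))
  pred <- predict(fit, sim$data)
  expect_length(pred, 150)
  expect_true(all(is.finite(pred)))

  path <- withr::local_tempfile(fileext = ".json")
  write_chla_model(fit, path)
  got <- read_chla_model(path)
  expect_equal(predict(got, sim$data), pred, tolerance = 1e-12)
  expect_equal(got$params$W1, fit$params$W1, tolerance = 1e-15)

  g <- glance(fit)
  expect_equal(g$hidden_size, 4L)
  td <- tidy(fit)
  expect_equal(sum(td$layer == "input_hidden"), 5 * 4)
})
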