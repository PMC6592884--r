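fixed_cluster33 <- c(WT = 26.5, EC = 360, TN = 3.26, TP = 0.048, Q = 181)

test_that("a flat response yields no mitigation discharge", {
  flat <- chla_model_function(function(df) rep(30, nrow(df)))
  grid <- scenario_grid(fixed_inputs = fixed_cluster33)
  res <- run_q_sweep(flat, grid)
  expect_true(is.na(res$mitigation_q))
  expect_equal(res$max_chla, 30)
})

test_that("the closed-form decay response locates the known mitigation discharge", {
  decay <- chla_model_function(function(df) 60 * exp(-df$Q / 200))
  grid <- scenario_grid(q_values = seq(20, 600, by = 20),
                        fixed_inputs = fixed_cluster33)
  res <- run_q_sweep(decay, grid)
  expect_equal(res$max_chla, 60 * exp(-20 / 200), tolerance = 1e-12)
  expect_equal(res$max_chla, 54.29, tolerance = 1e-3)
  expect_equal(res$mitigation_q, 160)
  expect_equal(res$threshold, res$max_chla / 2)
  expect_equal(nrow(res$predictions), 30)

  # oracle identity: the finder equals a brute-force scan
  brute <- min(res$predictions$Q[res$predictions$chla <= res$threshold])
  expect_equal(res$mitigation_q, brute)

  # absolute-concentration criterion
  res40 <- run_q_sweep(decay, grid, target_chla = 40)
  brute40 <- min(res$predictions$Q[res$predictions$chla <= 40])
  expect_equal(res40$mitigation_q, brute40)
})

test_that("the finder matches a brute-force scan on random monotone-free responses", {
  set.seed(17)
  for (rep in 1:20) {
    q <- seq(20, 600, by = 20)
    chla <- stats::runif(length(q), 5, 60)
    model <- chla_model_function(function(df) chla[match(df$Q, q)])
    res <- run_q_sweep(model, scenario_grid(q_values = q,
                                            fixed_inputs = fixed_cluster33))
    hits <- which(chla <= 0.5 * max(chla))
    want <- if (length(hits) == 0) NA_real_ else q[min(hits)]
    expect_equal(res$mitigation_q, want)
  }
})

test_that("the default two-way grid has the stated shape", {
  grid <- scenario_grid(q_values = seq(250, 600, by = 50),
                        ec_values = seq(140, 500, by = 20),
                        fixed_inputs = fixed_cluster33)
  expect_length(grid$q_values, 8)
  expect_length(grid$ec_values, 19)
  model <- chla_model_function(function(df) 60 * exp(-df$Q / 200))
  surf <- run_q_ec_grid(model, grid)
  expect_equal(nrow(surf$surface), 152)
})

test_that("an EC-blind model yields identical columns; EC-driven blooms need more water", {
  grid <- scenario_grid(q_values = seq(250, 600, by = 50),
                        ec_values = seq(140, 500, by = 20),
                        fixed_inputs = fixed_cluster33)
  blind <- chla_model_function(function(df) 50 * exp(-df$Q / 150))
  surf <- run_q_ec_grid(blind, grid)
  by_ec <- split(surf$surface$chla, surf$surface$EC)
  for (col in by_ec) expect_equal(col, by_ec[[1]])
  expect_equal(length(unique(surf$mitigation$mitigation_q)), 1)

  # chlorophyll increasing in EC, decreasing in Q, with an absolute target:
  # the required discharge must be non-decreasing in EC
  ec_driven <- chla_model_function(function(df) {
    80 * exp(-df$Q / 250) * (0.4 + 0.002 * df$EC)
  })
  surf2 <- run_q_ec_grid(ec_driven, grid, target_chla = 25)
  mq <- surf2$mitigation$mitigation_q[order(surf2$mitigation$EC)]
  mq <- mq[!is.na(mq)]
  expect_true(all(diff(mq) >= 0))
})

test_that("scenario predictions from a trained model are reproducible from its file", {
  sim <- simulate_monitoring(goryung_config(n_days = 300, seed = 19))
  fit <- fit_regime_models(sim$data, k = 2, hidden_size = 4,
                           config = train_config(max_epochs = 200), seed = 7)
  fixed <- cluster_means(fit, 2)
  grid <- scenario_grid(fixed_inputs = fixed, cluster = 2)
  res <- suppressWarnings(run_q_sweep(fit, grid))

  path <- withr::local_tempfile(fileext = ".json")
  write_chla_model(fit$models[[2]], path)
  restored <- read_chla_model(path)
  res2 <- suppressWarnings(run_q_sweep(restored, grid))
  expect_identical(res$predictions$chla, res2$predictions$chla)
  expect_identical(res$mitigation_q, res2$mitigation_q)
})

test_that("sweeps beyond the fitted discharge range warn but still predict", {
  sim <- simulate_monitoring(goryung_config(n_days = 200, seed = 20))
  fit <- fit_chla_ann(sim$data, hidden_size = 3,
                      config = train_config(max_epochs = 100))
  grid <- scenario_grid(q_values = c(10, 50, 100, 1e5),
                        fixed_inputs = fixed_cluster33)
  expect_warning(res <- run_q_sweep(fit, grid), "outside the fitted range")
  expect_true(all(is.finite(res$predictions$chla)))
})

test_that("grid validation rejects malformed scenarios", {
  expect_error(scenario_grid(q_values = c(100, 50),
                             fixed_inputs = fixed_cluster33),
               class = "bloomregime_config_error")
  expect_error(scenario_grid(q_values = 100, fixed_inputs = fixed_cluster33),
               class = "bloomregime_config_error")
  expect_error(scenario_grid(fixed_inputs = c(WT = NA_real_)),
               class = "bloomregime_config_error")
  grid <- scenario_grid(fixed_inputs = fixed_cluster33[-1])
  flat <- chla_model_function(function(df) rep(1, nrow(df)))
  expect_error(run_q_sweep(flat, grid), class = "bloomregime_config_error")
})
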