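#' Configure an end-to-end pipeline run
#'
#' @param input Path to a monitoring CSV, or a [generator_config()] to
#'   simulate the input table.
#' @param k_values Cluster counts to fit and compare, default `c(1, 2, 3)`.
#' @param hidden_size Hidden nodes per network, default 15.
#' @param train A [train_config()].
#' @param q_values,ec_values Scenario grids (see [scenario_grid()]).
#' @param reduction_fraction Bloom-suppression criterion for scenarios.
#' @param out_dir Output directory (created; must not contain a previous
#'   manifest unless `overwrite = TRUE`).
#' @param seed Master seed; stage seeds are derived from it (generator:
#'   seed, split: seed + 101, clustering: seed + 211, network k:
#'   seed + 307 + k).
#' @param select_hidden Select hidden sizes by cross-validation.
#' @param overwrite Allow writing into a non-empty `out_dir`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input,
                            k_values = c(1, 2, 3),
                            hidden_size = 15,
                            train = train_config(),
                            q_values = seq(20, 600, by = 20),
                            ec_values = NULL,
                            reduction_fraction = 0.5,
                            out_dir,
                            seed = 1,
                            select_hidden = FALSE,
                            overwrite = FALSE) {
  if (any(k_values < 1)) {
    stopf("All `k_values` must be >= 1.", class = "bloomregime_config_error")
  }
  if (is.character(input) && !file.exists(input)) {
    stopf("Input file `%s` not found.", input,
          class = "bloomregime_config_error")
  }
  structure(
    list(input = input, k_values = sort(unique(as.integer(k_values))),
         hidden_size = as.integer(hidden_size), train = train,
         q_values = q_values, ec_values = ec_values,
         reduction_fraction = reduction_fraction,
         out_dir = out_dir, seed = as.integer(seed),
         select_hidden = isTRUE(select_hidden),
         overwrite = isTRUE(overwrite)),
    class = "pipeline_config"
  )
}

#' Run the full clustered-network analysis
#'
#' Orchestrates the whole chain: load or simulate the monitoring table,
#' split it once, then for every K cluster the training rows, train one
#' network per cluster, write the models, the one-row-per-model comparison
#' table, the per-cluster importance profiles, and -- for the warmest
#' cluster of the largest K -- the discharge scenario outputs. A JSON
#' manifest records seeds, the package version, and an MD5 hash of every
#' file written; rerunning with the same config reproduces the hashes.
#' Any stage failure aborts with the stage name and removes partial outputs.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  created <- !dir.exists(out)
  if (!created && length(dir(out)) > 0 && !config$overwrite) {
    stopf("Output directory `%s` is not empty; set `overwrite = TRUE`.",
          out, class = "bloomregime_config_error")
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  log_lines <- character(0)
  t0 <- Sys.time()

  add_file <- function(path) files <<- c(files, path)
  log_stage <- function(stage, seed, t_start) {
    line <- sprintf("stage=%s seed=%s elapsed=%.2fs", stage,
                    paste(seed, collapse = ","),
                    as.numeric(difftime(Sys.time(), t_start, units = "secs")))
    inform(line)
    log_lines <<- c(log_lines, line)
  }
  run_stage <- function(stage, seed, code) {
    t_start <- Sys.time()
    result <- tryCatch(code, error = function(e) {
      unlink(file.path(out, dir(out)), recursive = TRUE)
      stopf("Pipeline stage `%s` failed: %s", stage, conditionMessage(e),
            class = "bloomregime_pipeline_error")
    })
    log_stage(stage, seed, t_start)
    result
  }

  # -- input ----------------------------------------------------------------
  data <- run_stage("input", config$seed, {
    if (is.character(config$input)) {
      read_monitoring(config$input)
    } else {
      sim <- simulate_monitoring(config$input)
      path <- file.path(out, "monitoring.csv")
      write_monitoring(sim, path)
      add_file(path)
      add_file(file.path(out, "monitoring_truth.json"))
      sim$data
    }
  })

  split <- split_train_test(data, seed = config$seed + 101L)
  fits <- list()
  for (k in config$k_values) {
    label <- sprintf("K=%d", k)
    fits[[label]] <- run_stage(
      paste0("train_", label), config$seed + 307L + k, {
        cfg <- config$train
        cfg$seed <- config$seed + 307L + k
        fit <- fit_regime_models(data, k = k,
                                 hidden_size = config$hidden_size,
                                 config = cfg, seed = config$seed,
                                 split = split,
                                 select_hidden = config$select_hidden)
        ppath <- file.path(out, sprintf("partition_k%d.json", k))
        write_partition(fit$partition, ppath)
        add_file(ppath)
        for (cl in seq_len(k)) {
          mpath <- file.path(out, sprintf("model_k%d_cluster%d.json", k, cl))
          write_chla_model(fit$models[[cl]], mpath)
          add_file(mpath)
        }
        fit
      })
  }

  run_stage("evaluate", config$seed, {
    report <- comparison_report(fits)
    path <- file.path(out, "comparison.csv")
    write_comparison(report, path)
    add_file(path)
  })

  run_stage("importance", config$seed, {
    profiles <- purrr::imap_dfr(fits, function(fit, label) {
      purrr::imap_dfr(fit$models, function(m, cl) {
        prof <- relative_importance(m)
        tibble::tibble(cluster = as.integer(cl), station = label,
                       variable = prof$variable,
                       ri_percent = prof$ri_percent)
      })
    })
    path <- file.path(out, "importance.csv")
    readr::write_csv(profiles, path)
    add_file(path)
  })

  run_stage("scenario", config$seed, {
    fit <- fits[[length(fits)]]
    fixed <- cluster_means(fit, fit$k)
    grid <- scenario_grid(q_values = config$q_values,
                          fixed_inputs = fixed, cluster = fit$k)
    sweep_res <- suppressWarnings(
      run_q_sweep(fit, grid, reduction_fraction = config$reduction_fraction))
    path <- file.path(out, "scenario_q_sweep.csv")
    readr::write_csv(
      dplyr::mutate(sweep_res$predictions,
                    mitigation_q = sweep_res$mitigation_q,
                    threshold = sweep_res$threshold),
      path)
    add_file(path)
    if (!is.null(config$ec_values)) {
      grid2 <- scenario_grid(q_values = config$q_values,
                             ec_values = config$ec_values,
                             fixed_inputs = fixed, cluster = fit$k)
      surf <- suppressWarnings(
        run_q_ec_grid(fit, grid2,
                      reduction_fraction = config$reduction_fraction))
      spath <- file.path(out, "scenario_q_ec_surface.csv")
      readr::write_csv(surf$surface, spath)
      add_file(spath)
      mpath <- file.path(out, "scenario_q_ec_mitigation.csv")
      readr::write_csv(surf$mitigation, mpath)
      add_file(mpath)
    }
  })

  manifest <- list(
    package = "bloomregime",
    version = as.character(utils::packageVersion("bloomregime")),
    master_seed = config$seed,
    stage_seeds = list(generator = config$seed, split = config$seed + 101L,
                       clustering = config$seed + 211L,
                       networks = config$seed + 307L + config$k_values),
    k_values = config$k_values,
    log = log_lines,
    files = lapply(setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f))),
    elapsed_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
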