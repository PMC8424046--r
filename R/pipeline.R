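#' Default end-to-end pipeline configuration
#'
#' Nested configuration for [run_pipeline()]. Each element feeds one
#' stage; the global `seed` is propagated (via deterministic child seeds)
#' to every stochastic stage.
#'
#' @param seed global seed.
#' @param n_plants,days,solvents,replicates,missing_rate,n_grid simulate
#'   stage (`n_grid` is the chromatogram grid size).
#' @param indicators,k_grid,d_grid,field_kind,layout,imputed encode stage.
#' @param model a [cnn_config()] (its `layout`/`seed` are overridden to
#'   match).
#' @param train_fraction,group_by_plant split settings.
#' @param n_range,tau,prominence,literal_rule evaluation settings.
#' @export
pipeline_config <- function(seed = 1L, n_plants = 6L, days = 10L,
                            solvents = c("E1", "E2", "E3"), replicates = 2L,
                            missing_rate = 0.05, n_grid = 1501L,
                            indicators = c("williams_r", "stochastic_D"),
                            k_grid = c(60, 720, 1440, 4320),
                            d_grid = c(720, 1440),
                            field_kind = "GASF",
                            layout = "stacked_5d", imputed = TRUE,
                            model = cnn_config(layout = layout),
                            train_fraction = 0.85, group_by_plant = TRUE,
                            n_range = 1:10, tau = 1e-3, prominence = 0.05,
                            literal_rule = FALSE) {
  model$layout <- layout
  model$seed <- as.integer(seed)
  model$n_out <- as.integer(n_grid)
  list(seed = as.integer(seed),
       simulate = list(n_plants = n_plants, days = days, solvents = solvents,
                       replicates = replicates, missing_rate = missing_rate,
                       n_grid = as.integer(n_grid)),
       encode = list(indicators = indicators, k_grid = k_grid, d_grid = d_grid,
                     field_kind = field_kind, layout = layout, imputed = imputed),
       model = model,
       split = list(train_fraction = train_fraction,
                    group_by_plant = group_by_plant),
       evaluate = list(n_range = n_range, tau = tau, prominence = prominence,
                       literal_rule = literal_rule))
}

#' Load a pipeline configuration from JSON or YAML
#'
#' File values override the defaults of [pipeline_config()].
#'
#' @param path a `.json` or `.yaml`/`.yml` file.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_chromcast("the yaml package is needed to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg <- pipeline_config(seed = raw$seed %||% 1L)
  for (sect in intersect(names(raw), names(cfg))) {
    if (is.list(cfg[[sect]])) {
      for (k in intersect(names(raw[[sect]]), names(cfg[[sect]]))) {
        cfg[[sect]][[k]] <- raw[[sect]][[k]]
      }
    } else cfg[[sect]] <- raw[[sect]]
  }
  cfg
}

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f)
  # serialization of plain lists of atomic vectors is stable within a session
  substr(unname(tools::md5sum(f)), 1L, 12L)
}

stage_dir <- function(run_dir, stage, cfg) {
  d <- file.path(run_dir, paste0(stage, "-", config_hash(cfg)))
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

#' Run the simulate - encode - train - evaluate pipeline
#'
#' Stage outputs are written under `run_dir` in directories addressed by a
#' hash of the stage's (cumulative) configuration, so re-running with a
#' changed evaluation setting reuses the cached simulation, encoding, and
#' model. The evaluation metrics are also written as JSON.
#'
#' @param config a [pipeline_config()].
#' @param run_dir output directory.
#' @param stages which stages to run (later stages pull cached ancestors).
#' @param verbose print progress.
#' @return list with the stage artifact paths and (when evaluated) the
#'   `metrics` list.
#' @export
run_pipeline <- function(config = pipeline_config(), run_dir = tempfile("chromcast-run-"),
                         stages = c("simulate", "encode", "train", "evaluate"),
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  out <- list(run_dir = run_dir)

  sim_cfg <- c(config$simulate, seed = config$seed)
  sim_dir <- stage_dir(run_dir, "simulate", sim_cfg)
  sim_path <- file.path(sim_dir, "dataset.rds")
  ds <- NULL
  if ("simulate" %in% stages || !file.exists(sim_path)) {
    if (file.exists(sim_path)) {
      ds <- readRDS(sim_path)
    } else {
      say("simulate: %d plants x %d days", sim_cfg$n_plants, sim_cfg$days)
      ds <- gen_dataset(sim_cfg$n_plants,
                        truth = synthetic_truth(n_grid = sim_cfg$n_grid %||% 1501L),
                        seed = config$seed, days = sim_cfg$days,
                        solvents = sim_cfg$solvents,
                        replicates = sim_cfg$replicates,
                        missing_rate = sim_cfg$missing_rate)
      saveRDS(ds, sim_path)
      write.csv(ds$truth$peaks, file.path(sim_dir, "truth_peaks.csv"),
                row.names = FALSE)
    }
  }
  out$simulate <- sim_path
  if (!length(setdiff(stages, "simulate"))) return(out)

  enc_cfg <- c(config$encode, list(parent = sim_cfg))
  enc_dir <- stage_dir(run_dir, "encode", enc_cfg)
  enc_path <- file.path(enc_dir, "pairs.rds")
  if (file.exists(enc_path)) {
    pairs <- readRDS(enc_path)
  } else {
    if (is.null(ds)) ds <- readRDS(sim_path)
    say("encode: layout %s, imputed = %s", config$encode$layout, config$encode$imputed)
    pairs <- suppressWarnings(
      build_training_pairs(ds, indicators = config$encode$indicators,
                           k_grid = config$encode$k_grid,
                           d_grid = config$encode$d_grid,
                           field_kind = config$encode$field_kind,
                           layout = config$encode$layout,
                           imputed = config$encode$imputed,
                           seed = child_seed(config$seed, "impute")))
    saveRDS(pairs, enc_path)
  }
  out$encode <- enc_path
  if (!length(setdiff(stages, c("simulate", "encode")))) return(out)

  model_cfg <- config$model
  model_cfg$n_out <- nrow(pairs$targets)
  trn_cfg <- list(model = unclass(model_cfg), split = config$split, parent = enc_cfg)
  trn_dir <- stage_dir(run_dir, "train", trn_cfg)
  model_path <- file.path(trn_dir, "model.rds")
  if (file.exists(model_path)) {
    fit <- readRDS(model_path)
  } else {
    split <- split_data(pairs, config$split$train_fraction,
                        seed = child_seed(config$seed, "split"),
                        group_by_plant = config$split$group_by_plant)
    say("train: %d train / %d test pairs, %d epochs",
        length(split$train), length(split$test), model_cfg$epochs)
    model <- train_cnn(model_cfg, pairs, pair_idx = split$train)
    fit <- list(model = model, split = split)
    saveRDS(fit, model_path)
    write.csv(model$history, file.path(trn_dir, "history.csv"), row.names = FALSE)
  }
  out$train <- model_path
  if (!length(setdiff(stages, c("simulate", "encode", "train")))) return(out)

  ev_cfg <- c(config$evaluate, list(parent = trn_cfg))
  ev_dir <- stage_dir(run_dir, "evaluate", ev_cfg)
  metrics_path <- file.path(ev_dir, "metrics.json")
  if (file.exists(metrics_path)) {
    metrics <- jsonlite::read_json(metrics_path, simplifyVector = TRUE)
  } else {
    say("evaluate: %d held-out pairs", length(fit$split$test))
    metrics <- evaluate_model(fit$model, pairs, fit$split$test,
                              n_range = config$evaluate$n_range,
                              tau = config$evaluate$tau,
                              prominence = config$evaluate$prominence,
                              literal_rule = config$evaluate$literal_rule)
    jsonlite::write_json(metrics, metrics_path, auto_unbox = TRUE, digits = NA)
  }
  out$evaluate <- metrics_path
  out$metrics <- metrics
  out
}

#' Score a trained model on held-out pairs
#'
#' Computes per-pair cross-correlation, R-squared and MCC, scans the
#' matching tolerance for `n*`, and returns summary statistics.
#'
#' @param model a `trained_model`.
#' @param pairs the [pair_dataset()].
#' @param test_idx held-out pair indices.
#' @param n_range,tau,prominence,literal_rule evaluation settings.
#' @export
evaluate_model <- function(model, pairs, test_idx, n_range = 1:10, tau = 1e-3,
                           prominence = 0.05, literal_rule = FALSE) {
  preds <- predict(model, pairs, test_idx)
  tgrid <- pairs$time %||% (seq_len(nrow(pairs$targets)) - 1)
  as_conc <- function(y) inverse_log(structure(
    list(time = tgrid, values = y, scale = 10, floor = 1e-12, meta = list()),
    class = "log_profile"))
  samples <- lapply(seq_along(test_idx), function(q) {
    chat <- as_conc(preds[, q])
    ctrue <- as_conc(pairs$targets[, test_idx[q]])
    list(pred = detect_peaks(chat, prominence, source = "predicted"),
         test = detect_peaks(ctrue, prominence, source = "test"),
         chat = chat, ctrue = ctrue,
         xcorr = cross_correlation(chat, ctrue),
         r2 = r_squared(preds[, q], pairs$targets[, test_idx[q]]))
  })
  scan <- scan_tolerance(lapply(samples, function(s) s[c("pred", "test")]),
                         n_range = n_range, tau = tau,
                         literal_rule = literal_rule)
  xc <- vapply(samples, `[[`, numeric(1), "xcorr")
  r2 <- vapply(samples, `[[`, numeric(1), "r2")
  list(n_test = length(test_idx),
       xcorr = list(mean = mean(xc), sd = sd(xc)),
       r2 = list(mean = mean(r2), sd = sd(r2)),
       mcc = list(mu = scan$mu, sigma = scan$sigma, n_values = scan$n_values),
       n_star = scan$n_star,
       mcc_at_1 = scan$mu[match(1, scan$n_values)],
       mcc_at_n_star = scan$mu[match(scan$n_star, scan$n_values)])
}
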