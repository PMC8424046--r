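#' Construct a pair dataset
#'
#' The container consumed by [train_cnn()]: a 4-d tensor array, a map from
#' pairs to tensors (several pairs may share one tensor: the augmented
#' images of a plant pair with each of its chromatograms), the target
#' log-profile matrix, and per-pair grouping labels.
#'
#' @param tensors numeric array `(H, W, C, T)`.
#' @param targets matrix `n_out x P` of log-profile targets.
#' @param pair_tensor integer vector of length `P`, tensor index per pair.
#' @param plant,solvent,combo optional per-pair labels.
#' @param time target time grid, minutes.
#' @export
pair_dataset <- function(tensors, targets, pair_tensor = seq_len(ncol(targets)),
                         plant = NULL, solvent = NULL, combo = NULL,
                         time = NULL) {
  stopifnot(length(dim(tensors)) == 4L, is.matrix(targets))
  if (length(pair_tensor) != ncol(targets)) {
    stop_chromcast("pair_tensor must have one entry per target column")
  }
  if (any(pair_tensor < 1L) || any(pair_tensor > dim(tensors)[4L])) {
    stop_chromcast("pair_tensor indexes outside the tensor array")
  }
  structure(list(tensors = tensors, targets = targets,
                 pair_tensor = as.integer(pair_tensor),
                 plant = plant, solvent = solvent, combo = combo,
                 time = time),
            class = "pair_dataset")
}

#' @export
print.pair_dataset <- function(x, ...) {
  d <- dim(x$tensors)
  cat(sprintf("<pair_dataset> %d pairs over %d tensors (%dx%dx%d), targets %d points\n",
              ncol(x$targets), d[4L], d[1L], d[2L], d[3L], nrow(x$targets)))
  invisible(x)
}

# replicate-averaged, baseline-corrected log target for one (plant, solvent)
prep_target <- function(chroms, beads = TRUE, ...) {
  ab <- rowMeans(vapply(chroms, function(ch) ch$absorbance,
                        numeric(length(chroms[[1L]]$time))))
  avg <- chromatogram(chroms[[1L]]$time, ab, chroms[[1L]]$meta)
  corrected <- if (beads) beads_correct(avg, ...)$corrected else avg
  log_transform(to_concentration(corrected))
}

#' Build CNN training pairs from a synthetic dataset
#'
#' Runs the full preprocessing chain: per-channel imputation (or not),
#' indicator normalization over the augmentation grids, PAA resampling,
#' Gramian encoding, tensor assembly, and chromatogram preparation
#' (replicate averaging, baseline correction, unit-area normalization, log
#' transform). Every augmented tensor of a plant pairs with each of that
#' plant's per-solvent target profiles.
#'
#' @param ds a [gen_dataset()] result.
#' @param indicators,k_grid,d_grid,field_kind,m passed to [augment()].
#' @param layout tensor layout, `"stacked_5d"` or `"concat_1d"`.
#' @param imputed impute gaps first (`TRUE`) or carry them into the images
#'   as zeroed pixels (`FALSE`).
#' @param beads apply baseline correction to the targets.
#' @param seed seed for the imputation draws.
#' @return a [pair_dataset()].
#' @export
build_training_pairs <- function(ds, indicators = c("williams_r", "stochastic_D"),
                                 k_grid = c(5, 20, 30, 60, 720, 1440, 4320, 7200),
                                 d_grid = c(720, 1440, 4320),
                                 field_kind = "GASF", m = 128L,
                                 layout = c("stacked_5d", "concat_1d"),
                                 imputed = TRUE, beads = TRUE, seed = 1L) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  layout <- match.arg(layout)
  n_plants <- length(ds$plants)

  tensor_list <- list()
  tensor_plant <- character(0)
  tensor_combo <- character(0)
  for (p in seq_len(n_plants)) {
    env <- ds$plants[[p]]$observed
    if (imputed) {
      env <- lapply(env, function(s) {
        if (!any(s$missing)) return(s)
        mfit <- fit_stochastic_model(s)
        impute(s, mfit, seed = child_seed(seed, paste0(s$parameter, "_", p)))
      })
    }
    per_channel <- lapply(env, augment, indicators = indicators,
                          k_grid = k_grid, d_grid = d_grid,
                          field_kind = field_kind, m = m)
    n_combos <- length(per_channel[[1L]])
    for (cmb in seq_len(n_combos)) {
      imgs <- lapply(per_channel, `[[`, cmb)
      tensor_list[[length(tensor_list) + 1L]] <- assemble_input(imgs, layout)
      cfg <- imgs[[1L]]$config
      tensor_plant <- c(tensor_plant, ds$plants[[p]]$id)
      tensor_combo <- c(tensor_combo,
                        paste(cfg$indicator, cfg$k, cfg$d, sep = "_"))
    }
  }
  td <- dim(tensor_list[[1L]])
  tensors <- array(0, dim = c(td, length(tensor_list)))
  for (i in seq_along(tensor_list)) tensors[, , , i] <- tensor_list[[i]]
  rm(tensor_list)

  # one target per (plant, solvent), replicates averaged
  keys <- vapply(ds$chromatograms, function(ch)
    paste(ch$meta$plant, ch$meta$solvent, sep = "|"), character(1))
  uk <- unique(keys)
  tmat <- NULL
  tgt_plant <- character(0); tgt_solvent <- character(0)
  for (k in uk) {
    lp <- prep_target(ds$chromatograms[keys == k], beads = beads)
    tmat <- cbind(tmat, lp$values)
    tgt_plant <- c(tgt_plant, strsplit(k, "|", fixed = TRUE)[[1L]][1L])
    tgt_solvent <- c(tgt_solvent, strsplit(k, "|", fixed = TRUE)[[1L]][2L])
  }
  tgrid <- ds$chromatograms[[1L]]$time

  pair_tensor <- integer(0)
  pair_target <- integer(0)
  for (ti in seq_along(tensor_plant)) {
    cols <- which(tgt_plant == tensor_plant[ti])
    pair_tensor <- c(pair_tensor, rep(ti, length(cols)))
    pair_target <- c(pair_target, cols)
  }
  pair_dataset(tensors, tmat[, pair_target, drop = FALSE], pair_tensor,
               plant = tgt_plant[pair_target],
               solvent = tgt_solvent[pair_target],
               combo = tensor_combo[pair_tensor],
               time = tgrid)
}

#' Randomized k-fold cross-validation with solvent stratification
#'
#' Assigns pairs (grouped by plant unless disabled) to seeded folds, trains
#' a model per fold on the remainder, and scores the held-out pairs with
#' cross-correlation (concentration scale), R-squared (log scale), and
#' MCC(n). Reports per-solvent metric summaries and one-tailed two-sample
#' t-tests between solvent strata.
#'
#' @param pairs a [pair_dataset()] with solvent labels.
#' @param config a [cnn_config()].
#' @param folds number of folds (each fold must keep >= 2 pairs).
#' @param seed fold-assignment seed.
#' @param group_by_plant keep a plant's pairs in one fold.
#' @param n_mcc tolerance multiplier for the MCC metric.
#' @param prominence relative prominence for peak detection.
#' @return list with per-pair `metrics`, per-stratum `summary`, and
#'   pairwise `tests`.
#' @export
cross_validate <- function(pairs, config, folds = 60L, seed = 1L,
                           group_by_plant = TRUE, n_mcc = 1L,
                           prominence = 0.05) {
  stopifnot(inherits(pairs, "pair_dataset"))
  n <- ncol(pairs$targets)
  groups <- if (group_by_plant && !is.null(pairs$plant)) pairs$plant else as.character(seq_len(n))
  ids <- unique(groups)
  if (folds > length(ids)) stop_chromcast("more folds (%d) than groups (%d)", folds, length(ids))
  fold_of_id <- with_seed(seed, {
    ord <- sample(length(ids))
    f <- rep(seq_len(folds), length.out = length(ids))
    stats::setNames(f[order(ord)], ids)
  })
  fold <- unname(fold_of_id[groups])
  if (min(table(fold)) < 2L) stop_chromcast("a fold has fewer than 2 pairs")

  rows <- list()
  for (k in seq_len(folds)) {
    test_idx <- which(fold == k)
    train_idx <- which(fold != k)
    cfg <- config
    cfg$seed <- child_seed(seed, paste0("fold", k))
    model <- train_cnn(cfg, pairs, pair_idx = train_idx)
    rows[[k]] <- score_predictions(model, pairs, test_idx, n_mcc = n_mcc,
                                   prominence = prominence)
    rows[[k]]$fold <- k
  }
  metrics <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(metrics, metrics$solvent), function(df) {
    data.frame(solvent = df$solvent[1L], n = nrow(df),
               xcorr_mean = mean(df$xcorr), xcorr_sd = sd(df$xcorr),
               r2_mean = mean(df$r2), r2_sd = sd(df$r2),
               mcc_mean = mean(df$mcc), mcc_sd = sd(df$mcc))
  }))
  svs <- sort(unique(metrics$solvent))
  tests <- NULL
  if (length(svs) > 1L) {
    cmb <- utils::combn(svs, 2L)
    tests <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
      a <- metrics$xcorr[metrics$solvent == cmb[1L, i]]
      b <- metrics$xcorr[metrics$solvent == cmb[2L, i]]
      tt <- t.test(a, b, alternative = "greater")
      data.frame(better = cmb[1L, i], worse = cmb[2L, i],
                 statistic = unname(tt$statistic), p_value = tt$p.value)
    }))
  }
  list(metrics = metrics, summary = summary, tests = tests)
}

# per-pair metric rows for the predictions of `model` on `idx`
score_predictions <- function(model, pairs, idx, n_mcc = 1L, n_range = NULL,
                              prominence = 0.05) {
  preds <- predict(model, pairs, idx)
  tgrid <- pairs$time %||% (seq_len(nrow(pairs$targets)) - 1)
  out <- lapply(seq_along(idx), function(q) {
    i <- idx[q]
    yhat <- preds[, q]
    ytrue <- pairs$targets[, i]
    chat <- inverse_log(structure(list(time = tgrid, values = yhat, scale = 10,
                                       floor = 1e-12, meta = list()),
                                  class = "log_profile"))
    ctrue <- inverse_log(structure(list(time = tgrid, values = ytrue, scale = 10,
                                        floor = 1e-12, meta = list()),
                                   class = "log_profile"))
    pk_pred <- detect_peaks(chat, prominence = prominence, source = "predicted")
    pk_test <- detect_peaks(ctrue, prominence = prominence, source = "test")
    m <- match_peaks(pk_pred, pk_test, n = n_mcc)
    data.frame(pair = i,
               solvent = pairs$solvent[i] %||% NA_character_,
               plant = pairs$plant[i] %||% NA_character_,
               xcorr = cross_correlation(chat, ctrue),
               r2 = r_squared(yhat, ytrue),
               mcc = m$mcc)
  })
  do.call(rbind, out)
}
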