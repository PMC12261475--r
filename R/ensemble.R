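#' Train a cross-validation ensemble ("combined model")
#'
#' Implements the full training protocol: short positives are prepadded with
#' random background residues to the window length, sequences are encoded,
#' split into stratified k folds, and one classifier is trained per fold.
#' The resulting ensemble scores a window with the arithmetic mean of the k
#' fold probabilities.
#'
#' @param positives,negatives Tibbles with `id` and `residues` columns
#'   (e.g. from [read_fasta()]). Training sequences must be at most
#'   `window_len` long; negatives are typically already window-length.
#' @param model_config An [model_config()].
#' @param train_config A [train_config()]; its `seed` governs padding,
#'   splitting, initialization and dropout.
#' @param k Number of folds (default 6).
#' @param freqs Background table for prepadding.
#' @return An object of class `asm_ensemble` with one `asm_fold_model` per
#'   fold.
#' @export
asm_train <- function(positives, negatives,
                      model_config = amyloscan::model_config(),
                      train_config = amyloscan::train_config(),
                      k = 6, freqs = background_freqs()) {
  cfg <- model_config; tc <- train_config
  for (tbl in list(positives, negatives))
    stopifnot(is.data.frame(tbl), all(c("id", "residues") %in% names(tbl)))
  if (any(nchar(c(positives$residues, negatives$residues)) > cfg$window_len))
    abort(paste0("training sequences longer than ", cfg$window_len,
                 " tokens: window them before training"))

  encode_padded <- function(records, stream) {
    set.seed(sub_seed(tc$seed, stream))
    vapply(records$residues, function(r) {
      tok <- encode_tokens(r)
      if (length(tok) < cfg$window_len) prepad_random(tok, cfg$window_len, freqs)
      else as.integer(tok)
    }, integer(cfg$window_len), USE.NAMES = FALSE)
  }
  xp <- encode_padded(positives, "pads_pos")
  xn <- encode_padded(negatives, "pads_neg")
  x <- cbind(xp, xn)
  colnames(x) <- c(positives$id, negatives$id)
  y <- c(rep(1, ncol(xp)), rep(0, ncol(xn)))
  names(y) <- colnames(x)

  split <- cv_split(positives$id, negatives$id, k = k, seed = sub_seed(tc$seed, "cv"))
  folds <- lapply(seq_len(k), function(i) {
    tr <- split$train_ids[[i]]
    va <- split$val_ids[[i]]
    if (is.numeric(tc$neg_per_pos)) {
      trp <- tr[y[tr] == 1]; trn <- tr[y[tr] == 0]
      keep <- min(length(trn), ceiling(tc$neg_per_pos * length(trp)))
      set.seed(sub_seed(tc$seed, paste0("negsub", i)))
      tr <- c(trp, sample(trn, keep))
    }
    repad_fn <- NULL
    if (tc$resample_pads_each_epoch) {
      all_records <- dplyr::bind_rows(positives["residues"] |> dplyr::mutate(id = positives$id),
                                      negatives["residues"] |> dplyr::mutate(id = negatives$id))
      repad_fn <- function(epoch) {
        set.seed(sub_seed(tc$seed, paste0("pads_epoch", epoch)))
        xx <- vapply(all_records$residues, function(r) {
          tok <- encode_tokens(r)
          if (length(tok) < cfg$window_len) prepad_random(tok, cfg$window_len, freqs)
          else as.integer(tok)
        }, integer(cfg$window_len), USE.NAMES = FALSE)
        colnames(xx) <- all_records$id
        xx[, tr, drop = FALSE]
      }
    }
    train_fold(x[, tr, drop = FALSE], y[tr], x[, va, drop = FALSE], y[va],
               model_config = cfg, train_config = tc, fold_index = i - 1L,
               repad_fn = repad_fn)
  })
  new_ensemble(folds, cfg, tc)
}

new_ensemble <- function(folds, model_config, train_config = NULL) {
  if (length(folds) < 2) abort("an ensemble needs at least 2 fold models")
  structure(list(folds = folds, model_config = model_config,
                 train_config = train_config, k = length(folds)),
            class = "asm_ensemble")
}

#' @export
print.asm_ensemble <- function(x, ...) {
  cat("<asm_ensemble>", x$k, "fold models |", n_params(x$folds[[1]]$model),
      "trainable parameters each\n")
  invisible(x)
}

#' Average fold probabilities
#'
#' The ensemble's combination rule: the arithmetic mean of the per-fold
#' sigmoid probabilities for one window.
#'
#' @param fold_probs Numeric vector of probabilities, one per fold.
#' @return The mean, guaranteed inside `[min, max]` of the inputs.
#' @examples
#' combine_probs(c(0.2, 0.4, 0.6, 0.8, 1.0, 0.0))
#' @export
combine_probs <- function(fold_probs) {
  if (length(fold_probs) < 1) abort("`fold_probs` is empty")
  if (any(!is.finite(fold_probs)) || any(fold_probs < 0 | fold_probs > 1))
    abort("probabilities must lie in [0, 1]")
  mean(fold_probs)
}

# Fold-probability matrix for a batch of windows: n_windows x k.
ensemble_window_probs <- function(ensemble, windows) {
  vapply(ensemble$folds, function(f) predict_window_prob(f, windows),
         numeric(ncol(windows)))
}

#' @describeIn tidy_amyloscan Per-epoch training and validation loss for
#'   every fold of an ensemble.
#' @export
tidy.asm_ensemble <- function(x, ...) {
  purrr::map_dfr(x$folds, function(f)
    dplyr::mutate(f$history, fold = f$fold_index, .before = 1)) |>
    tidyr::pivot_longer(c("train_loss", "val_loss"),
                        names_to = "metric", values_to = "loss")
}

#' Broom-style accessors for fitted ensembles
#'
#' @param x An `asm_ensemble`.
#' @param ... Unused.
#' @name tidy_amyloscan
NULL

#' @describeIn tidy_amyloscan One-row summary of an ensemble fit.
#' @export
glance.asm_ensemble <- function(x, ...) {
  vl <- vapply(x$folds, function(f) f$val_metrics$val_loss, numeric(1))
  tibble(
    k = x$k,
    n_params = n_params(x$folds[[1]]$model),
    epochs = nrow(x$folds[[1]]$history),
    mean_val_loss = mean(vl),
    sd_val_loss = stats::sd(vl)
  )
}

#' Save / load an ensemble as plain-text checkpoints
#'
#' One directory per ensemble: `fold_<i>_weights.txt` holds the flat
#' parameter vector of each fold at full precision, `config.json` records
#' the architecture, training configuration and per-file checksums.
#'
#' @param ensemble An `asm_ensemble`.
#' @param dir Checkpoint directory (created if missing).
#' @return `dir` (save) or the restored `asm_ensemble` (load).
#' @export
save_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "asm_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(ensemble$k)
  for (i in seq_len(ensemble$k)) {
    files[i] <- file.path(dir, sprintf("fold_%d_weights.txt", i - 1))
    writeLines(formatC(ensemble$folds[[i]]$model$params, format = "g", digits = 17),
               files[i])
  }
  meta <- list(
    model_config = unclass(ensemble$model_config),
    train_config = if (!is.null(ensemble$train_config)) unclass(ensemble$train_config),
    k = ensemble$k,
    checksums = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(meta, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  cfg <- do.call(model_config, meta$model_config[
    c("vocab_size", "embed_dim", "bi_units", "uni_units", "dropout", "window_len",
      "readout")])
  folds <- lapply(seq_len(meta$k), function(i) {
    f <- file.path(dir, sprintf("fold_%d_weights.txt", i - 1))
    params <- as.numeric(readLines(f))
    if (length(params) != count_trainable_params(cfg))
      abort(paste0("checkpoint ", f, " has ", length(params),
                   " weights; expected ", count_trainable_params(cfg)))
    structure(list(fold_index = i - 1L,
                   model = structure(list(config = cfg, params = params),
                                     class = "asm_bilstm"),
                   history = tibble(), n_train = NA_integer_, n_val = NA_integer_,
                   val_metrics = list(val_loss = NA_real_)),
              class = "asm_fold_model")
  })
  new_ensemble(folds, cfg)
}
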