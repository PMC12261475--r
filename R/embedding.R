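#' Penultimate-layer representation of windows
#'
#' Returns the unidirectional LSTM's final-state output for each window --
#' the representation feeding the sigmoid unit, taken at the position of the
#' final dropout layer (inactive at inference, so identical to the layer
#' output). Entries lie in (-1, 1) (tanh-gated state).
#'
#' @param fold An `asm_fold_model` or `asm_bilstm`.
#' @param windows Integer window matrix (`window_len` x n) or token vector.
#' @return Numeric matrix, n rows by `uni_units` columns.
#' @export
penultimate_embedding <- function(fold, windows) {
  model <- if (inherits(fold, "asm_fold_model")) fold$model else fold
  stopifnot(inherits(model, "asm_bilstm"))
  cfg <- model$config
  windows <- as_window_matrix(windows, cfg$window_len)
  n <- ncol(windows)
  chunks <- split(seq_len(n), ceiling(seq_len(n) / 1024))
  do.call(rbind, lapply(chunks, function(idx) {
    res <- cpp_bilstm_predict(windows[, idx, drop = FALSE], model$params,
                              cfg$vocab_size, cfg$embed_dim, cfg$bi_units,
                              cfg$uni_units, cfg$readout == "sequence", TRUE)
    matrix(res$embedding, ncol = cfg$uni_units)
  }))
}

#' Embed the best-scoring window of each sequence
#'
#' For every record, the best window found by [scan_sequences()] is embedded
#' by every fold model; per-fold vectors are concatenated, giving
#' `k * uni_units` dimensions (24 for the defaults). Set
#' `combine = "mean"` to average fold vectors instead.
#'
#' @param ensemble An `asm_ensemble`.
#' @param records Tibble with `id`, `residues` and optionally `source`
#'   (group label) columns.
#' @param threshold Detection threshold stored per sequence (default 0.5).
#' @param combine `"concat"` (default) or `"mean"` across folds.
#' @return An object of class `asm_embedding`: list with `ids`, `vectors`
#'   (n x D matrix), `detected`, `max_prob`, `group`.
#' @export
best_window_embeddings <- function(ensemble, records, threshold = 0.5,
                                   combine = c("concat", "mean")) {
  combine <- match.arg(combine)
  stopifnot(inherits(ensemble, "asm_ensemble"))
  cfg <- ensemble$model_config
  hits <- scan_sequences(ensemble, records, threshold = threshold)
  best_windows <- vapply(seq_len(nrow(records)), function(i) {
    tok <- encode_tokens(records$residues[i])
    if (length(tok) < cfg$window_len) {
      postpad_zero(tok, cfg$window_len)
    } else {
      s <- hits$best_start[i]
      tok[(s + 1):(s + cfg$window_len)]
    }
  }, integer(cfg$window_len))
  per_fold <- lapply(ensemble$folds, penultimate_embedding,
                     windows = best_windows)
  vectors <- if (combine == "concat") do.call(cbind, per_fold)
             else Reduce(`+`, per_fold) / length(per_fold)
  expect_d <- if (combine == "concat") ensemble$k * cfg$uni_units else cfg$uni_units
  stopifnot(ncol(vectors) == expect_d, all(is.finite(vectors)))
  group <- if ("source" %in% names(records)) records$source else NULL
  group <- group %||% rep("all", nrow(records))
  group[is.na(group)] <- "all"
  structure(list(ids = records$id, vectors = vectors,
                 detected = hits$detected, max_prob = hits$max_prob,
                 group = group),
            class = "asm_embedding")
}

#' @export
print.asm_embedding <- function(x, ...) {
  cat("<asm_embedding>", length(x$ids), "sequences x", ncol(x$vectors),
      "dimensions |", sum(x$detected), "detected\n")
  invisible(x)
}

#' @export
as_tibble.asm_embedding <- function(x, ...) {
  dplyr::bind_cols(
    tibble(id = x$ids, group = x$group, detected = x$detected,
           max_prob = x$max_prob),
    as_tibble(as.data.frame(x$vectors), .name_repair = ~ paste0("V", seq_along(.x)))
  )
}

#' Project embeddings to two dimensions
#'
#' Linear 2-D projection of the penultimate-layer vectors for visual
#' inspection: principal components (default) or classical
#' multidimensional scaling on Euclidean distances. Both preserve row order
#' and map identical inputs to identical points.
#'
#' @param x An `asm_embedding`.
#' @param method `"pca"` (default) or `"mds"`.
#' @param seed Kept for interface stability; both methods are deterministic.
#' @return A tibble: `id`, `group`, `detected`, `max_prob`, `dim1`, `dim2`.
#' @export
project_2d <- function(x, method = c("pca", "mds"), seed = 1) {
  stopifnot(inherits(x, "asm_embedding"))
  method <- match.arg(method)
  n <- nrow(x$vectors)
  if (n < 3) abort("need at least 3 sequences to project")
  coords <- if (method == "pca") {
    p <- prcomp(x$vectors, center = TRUE, scale. = FALSE)
    k <- ncol(p$x)
    cbind(p$x[, 1], if (k >= 2) p$x[, 2] else 0)
  } else {
    cmdscale(dist(x$vectors), k = 2)
  }
  if (any(!is.finite(coords))) abort("projection produced non-finite coordinates")
  tibble(id = x$ids, group = x$group, detected = x$detected,
         max_prob = x$max_prob, dim1 = coords[, 1], dim2 = coords[, 2])
}

#' Retention rate per group
#'
#' Fraction of each set/family detected at the scan threshold, the summary
#' shown in retention plots.
#'
#' @param x An `asm_embedding` (or tibble with `group` and `detected`).
#' @return Tibble: `group`, `n`, `retention`.
#' @export
retention_by_group <- function(x) {
  tbl <- if (inherits(x, "asm_embedding"))
    tibble(group = x$group, detected = x$detected) else as_tibble(x)
  stopifnot(all(c("group", "detected") %in% names(tbl)))
  if (nrow(tbl) == 0) abort("no sequences / empty group set")
  tbl |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), retention = mean(.data$detected),
                     .groups = "drop")
}

#' @describeIn project_2d Scatter plot of the 2-D projection; dots mark
#'   detected sequences and crosses mark undetected ones, colored by group.
#' @param object An `asm_embedding`.
#' @param ... Passed to [project_2d()].
#' @export
autoplot.asm_embedding <- function(object, ...) {
  pts <- project_2d(object, ...)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                    colour = .data$group,
                                    shape = .data$detected)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 4),
                                labels = c(`TRUE` = "detected", `FALSE` = "not detected")) +
    ggplot2::labs(x = "dimension 1", y = "dimension 2",
                  colour = "set", shape = NULL) +
    ggplot2::theme_minimal()
}

#' Retention bar plot
#'
#' @param x An `asm_embedding` or a retention tibble from
#'   [retention_by_group()].
#' @return A ggplot object.
#' @export
plot_retention <- function(x) {
  tbl <- if (inherits(x, "asm_embedding")) retention_by_group(x) else as_tibble(x)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$group, y = .data$retention,
                                    fill = .data$group)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_y_continuous(limits = c(0, 1), labels = function(v) paste0(100 * v, "%")) +
    ggplot2::labs(x = NULL, y = "retention (detected fraction)") +
    ggplot2::theme_minimal()
}

#' Histogram of best-window begin/end shifts
#'
#' Localization diagnostic: distribution of the best-scoring window's begin
#' and end positions relative to the annotated motif boundaries.
#'
#' @param shifts An `asm_shifts` tibble from [motif_shifts()].
#' @return A ggplot object with one facet per boundary.
#' @export
plot_motif_shifts <- function(shifts) {
  long <- tidyr::pivot_longer(as_tibble(shifts), c("begin_shift", "end_shift"),
                              names_to = "boundary", values_to = "shift")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$shift)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey30") +
    ggplot2::facet_wrap(~boundary, scales = "free_x") +
    ggplot2::labs(x = "shift of best window relative to motif (residues)",
                  y = "sequences") +
    ggplot2::theme_minimal()
}
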