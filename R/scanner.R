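#' Scan one sequence with a combined model
#'
#' Slides the fixed 40-token window (step 1) over the sequence, scores each
#' window with every fold model in inference mode, averages the fold
#' probabilities per window, and max-pools the window means into one
#' per-sequence score. Ties at the maximum are broken toward the smallest
#' start. Sequences shorter than the window are zero-postpadded into a
#' single window.
#'
#' @param ensemble An `asm_ensemble`.
#' @param residues A cleaned residue string.
#' @param id Sequence id for the output rows.
#' @param threshold Detection threshold on the max-pooled mean probability
#'   (default 0.5).
#' @return A list with `window_scores` (tibble: `parent_id`, `start`, `end`,
#'   per-fold probabilities in a `fold_probs` list-column, `mean_prob`) and
#'   `hit` (one-row tibble: `parent_id`, `length`, `best_start`, `best_end`,
#'   `max_prob`, `detected`, `n_windows`, `fold_probs` of the best window).
#'   Coordinates are 0-based, half-open; [write_hits()] converts to 1-based
#'   inclusive on output.
#' @export
scan_sequence <- function(ensemble, residues, id = "seq", threshold = 0.5) {
  stopifnot(inherits(ensemble, "asm_ensemble"))
  if (!is.character(residues) || length(residues) != 1 || !nzchar(residues))
    abort("`residues` must be a single nonempty string")
  cfg <- ensemble$model_config
  tok <- encode_tokens(residues)
  wm <- window_matrix(tok, size = cfg$window_len, step = 1)
  probs <- ensemble_window_probs(ensemble, wm$mat)         # n_win x k
  probs <- matrix(probs, ncol = ensemble$k)
  means <- rowMeans(probs)
  best <- which.max(means)                                  # first index on ties
  windows <- tibble(
    parent_id = id, start = wm$starts, end = wm$ends,
    fold_probs = lapply(seq_len(nrow(probs)), function(i) probs[i, ]),
    mean_prob = means
  )
  hit <- tibble(
    parent_id = id, length = length(tok),
    best_start = wm$starts[best], best_end = wm$ends[best],
    max_prob = means[best], detected = means[best] >= threshold,
    n_windows = length(means),
    fold_probs = list(probs[best, ])
  )
  list(window_scores = windows, hit = hit)
}

#' Scan a table of sequences
#'
#' Vectorized scan: all windows of all records are scored in one inference
#' pass per fold, then max-pooled per sequence.
#'
#' @param ensemble An `asm_ensemble`.
#' @param records Tibble with `id` and `residues` columns.
#' @param threshold Detection threshold (default 0.5).
#' @return A hit tibble, one row per input sequence in input order, with the
#'   columns documented in [scan_sequence()].
#' @export
scan_sequences <- function(ensemble, records, threshold = 0.5) {
  stopifnot(inherits(ensemble, "asm_ensemble"), is.data.frame(records),
            all(c("id", "residues") %in% names(records)))
  if (nrow(records) == 0) abort("`records` is empty")
  cfg <- ensemble$model_config
  wms <- lapply(records$residues, function(r)
    window_matrix(encode_tokens(r), size = cfg$window_len, step = 1))
  n_win <- vapply(wms, function(w) length(w$starts), integer(1))
  big <- do.call(cbind, lapply(wms, `[[`, "mat"))
  probs <- matrix(ensemble_window_probs(ensemble, big), ncol = ensemble$k)
  means <- rowMeans(probs)
  offsets <- cumsum(c(0L, n_win[-length(n_win)]))
  purrr::map_dfr(seq_len(nrow(records)), function(i) {
    sel <- offsets[i] + seq_len(n_win[i])
    mi <- means[sel]
    best <- which.max(mi)
    tibble(
      parent_id = records$id[i],
      length = nchar(records$residues[i]),
      best_start = wms[[i]]$starts[best],
      best_end = wms[[i]]$ends[best],
      max_prob = mi[best],
      detected = mi[best] >= threshold,
      n_windows = n_win[i],
      fold_probs = list(probs[sel[best], ])
    )
  })
}

#' Scan a FASTA file and report hits
#'
#' @param ensemble An `asm_ensemble`.
#' @param path FASTA file of protein sequences (any length).
#' @param threshold Detection threshold (default 0.5).
#' @param out Optional TSV path; when given the hit table is also written
#'   via [write_hits()].
#' @return The hit tibble (0-based coordinates; the TSV uses 1-based
#'   inclusive). A summary message reports sequence and detection counts.
#' @export
scan_fasta <- function(ensemble, path, threshold = 0.5, out = NULL) {
  records <- read_fasta(path)
  hits <- scan_sequences(ensemble, records, threshold = threshold)
  inform(paste0("scanned ", nrow(hits), " sequence(s); ",
                sum(hits$detected), " detected at threshold ", threshold))
  if (!is.null(out)) write_hits(hits, out)
  hits
}

#' Write a hit table as TSV
#'
#' Converts internal 0-based half-open best-window coordinates to 1-based
#' inclusive, and serializes the per-fold probabilities as a comma-joined
#' column for auditability.
#'
#' @param hits A hit tibble from [scan_sequences()]/[scan_fasta()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  out <- dplyr::transmute(
    hits,
    seq_id = .data$parent_id,
    length = .data$length,
    best_start = .data$best_start + 1L,
    best_end = .data$best_end,
    max_prob = .data$max_prob,
    detected = .data$detected,
    fold_probs = vapply(.data$fold_probs,
                        function(p) paste(formatC(p, format = "g", digits = 8),
                                          collapse = ","), character(1))
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Best-window shift relative to an annotated motif
#'
#' Quantifies motif localization: how far the best-scoring window's begin
#' and end lie from the true (rigorously cut) motif boundaries, and what
#' fraction of the motif the window covers. Negative `begin_shift` means the
#' window begins before the motif; positive `end_shift` means it extends
#' past the motif end.
#'
#' @param hit A one-row hit tibble (from [scan_sequence()] or one row of
#'   [scan_sequences()] output), 0-based half-open coordinates.
#' @param motif_start,motif_end Motif interval, 0-based half-open.
#' @return A one-row tibble: `parent_id`, `begin_shift`, `end_shift`,
#'   `coverage`.
#' @examples
#' h <- tibble::tibble(parent_id = "s", best_start = 10, best_end = 50)
#' locate_motif_shift(h, 15, 40)  # begin -5, end +10, coverage 1
#' @export
locate_motif_shift <- function(hit, motif_start, motif_end) {
  stopifnot(is.data.frame(hit), nrow(hit) == 1)
  if (motif_start < 0 || motif_end <= motif_start)
    abort("motif interval must satisfy 0 <= start < end")
  ov <- max(0, min(hit$best_end, motif_end) - max(hit$best_start, motif_start))
  tibble(
    parent_id = hit$parent_id,
    begin_shift = hit$best_start - motif_start,
    end_shift = hit$best_end - motif_end,
    coverage = ov / (motif_end - motif_start)
  )
}

#' Motif shifts for a whole hit table
#'
#' @param hits Hit tibble (0-based coordinates).
#' @param annotations Tibble with `seq_id`, `motif_start`, `motif_end`
#'   (0-based half-open; use [read_annotations()] for 1-based TSV input).
#' @return Tibble of shifts for every hit with an annotation, class
#'   `asm_shifts` for plotting.
#' @export
motif_shifts <- function(hits, annotations) {
  stopifnot(all(c("seq_id", "motif_start", "motif_end") %in% names(annotations)))
  joined <- dplyr::inner_join(hits, annotations,
                              by = c(parent_id = "seq_id"))
  out <- purrr::map_dfr(seq_len(nrow(joined)), function(i)
    locate_motif_shift(joined[i, c("parent_id", "best_start", "best_end")],
                       joined$motif_start[i], joined$motif_end[i]))
  out$detected <- joined$detected
  class(out) <- c("asm_shifts", class(out))
  out
}

#' Read a motif-coordinate annotation TSV
#'
#' Expects columns `seq_id`, `motif_start`, `motif_end` in 1-based inclusive
#' coordinates (the output-table convention) and converts them to the
#' internal 0-based half-open convention.
#'
#' @param path TSV path.
#' @return Tibble with 0-based half-open `motif_start`, `motif_end` plus any
#'   extra columns (e.g. `family`).
#' @export
read_annotations <- function(path) {
  tab <- as_tibble(read.delim(path, stringsAsFactors = FALSE))
  if (!all(c("seq_id", "motif_start", "motif_end") %in% names(tab)))
    abort("annotation TSV must have columns seq_id, motif_start, motif_end")
  tab$motif_start <- tab$motif_start - 1L
  tab
}
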