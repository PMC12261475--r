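#' Prepad a short token sequence with random background residues
#'
#' Training motifs shorter than the model window are prepended with residues
#' sampled i.i.d. from a background frequency table, mimicking sequence
#' noise upstream of the motif. The original tokens always occupy the
#' suffix; padding tokens are real residues, never PAD.
#'
#' @param tokens Integer token vector (values 1..25), length 1..`target_len`.
#' @param target_len Window length (default 40).
#' @param freqs An `asm_freqs` table, default [background_freqs()].
#' @param alphabet An [asm_alphabet()].
#' @return Integer vector of length `target_len`. Uses the session RNG;
#'   wrap in `withr::with_seed()` or `set.seed()` for reproducibility.
#' @export
prepad_random <- function(tokens, target_len = 40, freqs = background_freqs(),
                          alphabet = asm_alphabet()) {
  check_tokens(tokens, target_len)
  n_pad <- target_len - length(tokens)
  if (n_pad == 0) return(as.integer(tokens))
  pad_res <- sample(names(freqs), n_pad, replace = TRUE, prob = unclass(freqs))
  c(match(pad_res, alphabet$residues), as.integer(tokens))
}

#' Postpad a short token sequence with PAD tokens
#'
#' Short scan inputs (sequences below the window size) are extended to the
#' window length with PAD tokens (index 0) appended after the residues.
#'
#' @inheritParams prepad_random
#' @return Integer vector of length `target_len`.
#' @examples
#' postpad_zero(c(5L, 6L, 7L), target_len = 5)
#' @export
postpad_zero <- function(tokens, target_len = 40) {
  check_tokens(tokens, target_len)
  c(as.integer(tokens), integer(target_len - length(tokens)))
}

check_tokens <- function(tokens, target_len) {
  if (length(tokens) < 1) abort("empty token sequence")
  if (length(tokens) > target_len)
    abort(paste0("sequence of length ", length(tokens), " exceeds target length ",
                 target_len, "; use make_windows() instead"))
  if (any(tokens < 1)) abort("tokens must be residue indices >= 1")
  invisible(TRUE)
}

#' Slide a fixed-size window over an encoded sequence
#'
#' Produces every window of `size` tokens at stride `step`. A sequence
#' shorter than `size` yields exactly one zero-postpadded window whose
#' `end` is the true sequence length. Coordinates are 0-based, half-open.
#'
#' @param residues A cleaned residue string.
#' @param id Parent sequence id recorded in each window.
#' @param size Window size (default 40).
#' @param step Stride (default 1).
#' @param alphabet An [asm_alphabet()].
#' @return A tibble with columns `parent_id`, `start`, `end` and a `tokens`
#'   list-column of integer vectors of length `size`.
#' @examples
#' nrow(make_windows(strrep("A", 100)))  # 61 windows
#' @export
make_windows <- function(residues, id = "seq", size = 40, step = 1,
                         alphabet = asm_alphabet()) {
  if (size <= 0 || step <= 0) abort("`size` and `step` must be positive")
  tokens <- encode_tokens(residues, alphabet)
  wm <- window_matrix(tokens, size = size, step = step)
  tibble(
    parent_id = id,
    start = wm$starts,
    end = wm$ends,
    tokens = lapply(seq_len(ncol(wm$mat)), function(j) wm$mat[, j])
  )
}

# Internal: windows as a size x n integer matrix (columns = windows).
window_matrix <- function(tokens, size = 40, step = 1) {
  L <- length(tokens)
  size <- as.integer(size)
  if (L < size) {
    mat <- matrix(postpad_zero(tokens, size), ncol = 1)
    return(list(mat = mat, starts = 0L, ends = L))
  }
  starts <- as.integer(seq.int(0L, L - size, by = step))
  mat <- vapply(starts, function(s) tokens[(s + 1):(s + size)], integer(size))
  list(mat = matrix(mat, nrow = size), starts = starts, ends = starts + size)
}
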