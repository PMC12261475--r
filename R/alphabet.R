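#' The fixed 26-token residue alphabet
#'
#' The model tokenizer uses 26 symbols: index 0 is the padding token (used
#' only for zero postpadding of short scan inputs) and indices 1--25 are the
#' residue letters: the 20 canonical amino acids plus the extended IUPAC
#' letters B, Z, X, U and O. The 26-row embedding is an architectural
#' contract: together with the default layer sizes it fixes the trainable
#' parameter count of the per-window classifier at 1,637 (see
#' [count_trainable_params()]).
#'
#' @return An object of class `asm_alphabet`: a list with `symbols`
#'   (length-26 character vector, `"<pad>"` first) and `pad_index` (0).
#' @examples
#' ab <- asm_alphabet()
#' length(ab$symbols)
#' @export
asm_alphabet <- function() {
  residues <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "B", "Z", "X", "U", "O")
  structure(
    list(symbols = c("<pad>", residues), residues = residues, pad_index = 0L),
    class = "asm_alphabet"
  )
}

#' @export
print.asm_alphabet <- function(x, ...) {
  cat("<asm_alphabet> 26 tokens: <pad> +", paste(x$residues, collapse = ""), "\n")
  invisible(x)
}

#' Normalize a raw amino-acid string
#'
#' Uppercases, strips whitespace, and maps any character outside the 25
#' residue letters (e.g. `*`, `-`, `.`, `J`) to `X`. Real proteome FASTA
#' files routinely contain such characters, so they are substituted rather
#' than rejected; the number of substitutions is attached as attribute
#' `n_substituted`.
#'
#' @param raw A character vector of raw sequences.
#' @return Character vector of cleaned sequences with attribute
#'   `n_substituted` (total substitutions across inputs).
#' @examples
#' clean_sequence("mk-v*")
#' @export
clean_sequence <- function(raw) {
  if (!is.character(raw) || length(raw) < 1) abort("`raw` must be a character vector")
  x <- toupper(gsub("\\s+", "", raw))
  if (any(!nzchar(x))) abort("sequence empty after cleaning")
  pattern <- "[^ACDEFGHIKLMNPQRSTVWYBZXUO]"
  n_sub <- sum(nchar(x) - nchar(gsub(pattern, "", x)))
  out <- gsub(pattern, "X", x)
  attr(out, "n_substituted") <- n_sub
  out
}

#' Encode residues to token indices
#'
#' @param residues A single cleaned residue string.
#' @param alphabet An [asm_alphabet()].
#' @return Integer vector of token indices in 1..25 (0 is reserved for PAD
#'   and never produced for a cleaned sequence).
#' @examples
#' encode_tokens("MKV")
#' @export
encode_tokens <- function(residues, alphabet = asm_alphabet()) {
  if (!is.character(residues) || length(residues) != 1 || !nzchar(residues))
    abort("`residues` must be a single nonempty string")
  chars <- strsplit(residues, "")[[1]]
  idx <- match(chars, alphabet$residues)
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    abort(paste0("symbols not in alphabet: ", paste(bad, collapse = ", "),
                 " (run clean_sequence() first)"))
  }
  idx
}

#' Decode token indices back to residues
#'
#' PAD tokens (index 0) are dropped, so decoding a zero-postpadded window
#' recovers the original residues.
#'
#' @param tokens Integer vector of indices in 0..25.
#' @inheritParams encode_tokens
#' @return A residue string.
#' @export
decode_tokens <- function(tokens, alphabet = asm_alphabet()) {
  if (length(tokens) == 0) abort("`tokens` is empty")
  if (any(tokens < 0 | tokens > length(alphabet$residues)))
    abort("token index out of range 0..25")
  paste(alphabet$residues[tokens[tokens > 0]], collapse = "")
}
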