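#' Background amino-acid frequency table
#'
#' Returns the residue frequency table used for random-fragment prepadding
#' and for sampling synthetic background sequences. The packaged default is
#' the UniProtKB/Swiss-Prot amino-acid composition (20 canonical residues),
#' shipped as a 2-column TSV; any table in the same format can be supplied.
#'
#' @param path Optional path to a TSV with columns `residue` and
#'   `probability`. `NULL` (default) loads the packaged Swiss-Prot table.
#' @return A named numeric vector of class `asm_freqs`, normalized to sum
#'   exactly to 1.
#' @examples
#' f <- background_freqs()
#' sum(f)
#' @export
background_freqs <- function(path = NULL) {
  path <- path %||% system.file("extdata", "swissprot_freqs.tsv",
                                package = "amyloscan", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("residue", "probability") %in% names(tab)))
    abort("frequency table must have columns `residue` and `probability`")
  as_freqs(setNames(tab$probability, tab$residue))
}

# Validate + normalize a named probability vector over residue letters.
as_freqs <- function(p) {
  ab <- asm_alphabet()
  if (is.null(names(p)) || !all(names(p) %in% ab$residues))
    abort("frequency names must be residue letters from the alphabet")
  if (anyDuplicated(names(p))) abort("duplicate residues in frequency table")
  if (any(p < 0) || sum(p) <= 0) abort("probabilities must be nonnegative with positive sum")
  structure(p / sum(p), class = "asm_freqs")
}

#' @export
print.asm_freqs <- function(x, ...) {
  cat("<asm_freqs>", length(x), "residues, top:",
      paste0(head(names(sort(unclass(x), decreasing = TRUE)), 3), collapse = ","), "\n")
  invisible(x)
}
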