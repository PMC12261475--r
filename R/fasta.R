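#' Read protein sequences from FASTA
#'
#' Reads a (plain or gzipped) FASTA file into a tibble of sequence records.
#' Sequences are normalized with [clean_sequence()]; the id is the first
#' whitespace-delimited token of the header, with the full header retained.
#'
#' @param path Path to a FASTA file.
#' @param source Optional set/family tag recorded in the `source` column.
#' @return A tibble with columns `id`, `residues`, `desc` (full header) and
#'   `source`, one row per entry in file order.
#' @details Duplicate ids and empty sequences are rejected with an error
#'   naming the offender. Nonstandard residue characters are mapped to `X`;
#'   a message reports how many were substituted.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a descr", "MKV", ">b", "GG"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path, source = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) abort(paste0("malformed FASTA in '", path, "': ",
                                     conditionMessage(e)))
  )
  if (length(set) == 0) abort(paste0("no FASTA entries in '", path, "'"))
  headers <- names(set) %||% rep("", length(set))
  ids <- sub("\\s.*$", "", headers)
  if (any(!nzchar(ids)))
    abort(paste0("entry ", which(!nzchar(ids))[1], " in '", path, "' has an empty header"))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    abort(paste0("duplicate sequence id(s) in '", path, "': ",
                 paste(unique(dup), collapse = ", ")))
  raw <- as.character(set)
  empty <- !nzchar(raw)
  if (any(empty))
    abort(paste0("empty sequence for id '", ids[which(empty)[1]], "' in '", path, "'"))
  cleaned <- clean_sequence(raw)
  n_sub <- attr(cleaned, "n_substituted")
  if (n_sub > 0)
    inform(paste0("read_fasta: substituted ", n_sub,
                  " nonstandard residue character(s) with 'X'"))
  tibble(
    id = ids,
    residues = as.character(cleaned),
    desc = headers,
    source = source %||% NA_character_
  )
}

#' Write sequence records to FASTA
#'
#' @param records A tibble with `id` and `residues` columns (as returned by
#'   [read_fasta()] or the synthetic generator).
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param width Line width for wrapping sequences (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  stopifnot(is.data.frame(records), all(c("id", "residues") %in% names(records)))
  if (anyDuplicated(records$id)) abort("duplicate ids in `records`")
  set <- Biostrings::AAStringSet(setNames(records$residues, records$id))
  Biostrings::writeXStringSet(set, path, width = width,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
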