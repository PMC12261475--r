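#' Define a synthetic motif family
#'
#' A family is a length range plus a set of anchors: conserved positions at
#' fixed *relative* locations along the motif, each with one dominant
#' residue carrying most of the probability mass. Anchors at relative (not
#' absolute) positions let family identity survive length variation, the
#' way conserved patterns do in real amyloid signaling motifs. Dominant
#' residues are drawn from an amyloid-prone pool (Q, N, G, S, Y, F by
#' default); sharing this compositional bias across families is what makes
#' held-out families detectable by a model trained on other families.
#'
#' @param family_id Family label.
#' @param length_range Integer `c(min, max)` motif length, max at most 40.
#' @param n_anchors Number of conserved positions (default 8).
#' @param anchor_mass Probability mass on each anchor's dominant residue
#'   (default 0.9); the remainder is spread over the background.
#' @param anchor_pool Residues eligible as dominant anchor residues.
#' @param background `asm_freqs` table for non-anchor positions.
#' @return A list of class `asm_family_spec` with an `anchors` tibble
#'   (`rel_pos`, `residue`, `mass`). Anchor placement uses the session RNG.
#' @export
motif_family_spec <- function(family_id, length_range = c(21, 40), n_anchors = 8,
                              anchor_mass = 0.9,
                              anchor_pool = c("Q", "N", "G", "S", "Y", "F"),
                              background = background_freqs()) {
  if (length_range[1] > length_range[2] || length_range[2] > 40)
    abort("`length_range` must satisfy min <= max <= 40")
  if (n_anchors > length_range[1])
    abort("more anchors than the minimum motif length")
  if (anchor_mass <= 0 || anchor_mass > 1) abort("`anchor_mass` must be in (0, 1]")
  anchors <- tibble(
    rel_pos = sort(runif(n_anchors)),
    residue = sample(anchor_pool, n_anchors, replace = TRUE),
    mass = anchor_mass
  )
  structure(list(family_id = family_id, length_range = as.integer(length_range),
                 anchors = anchors, background = background),
            class = "asm_family_spec")
}

#' @export
print.asm_family_spec <- function(x, ...) {
  cat("<asm_family_spec>", x$family_id, "| lengths", x$length_range[1], "-",
      x$length_range[2], "|", nrow(x$anchors), "anchors:",
      paste(x$anchors$residue, collapse = ""), "\n")
  invisible(x)
}

# Uniform integer draw on [lo, hi], safe for degenerate ranges (unlike
# sample(seq(lo, hi), ...), which falls into sample()'s scalar behavior).
sample_int_range <- function(lo, hi, n = 1) {
  lo + sample.int(hi - lo + 1, n, replace = TRUE) - 1L
}

# Scale relative anchor positions to a drawn length, resolving collisions
# upward to the nearest free index (deterministic).
anchor_positions <- function(rel_pos, L) {
  if (length(rel_pos) > L) abort("more anchors than motif positions")
  pos <- pmin(floor(rel_pos * L), L - 1)
  used <- logical(L)
  out <- integer(length(pos))
  for (i in seq_along(pos)) {
    p <- pos[i]
    while (used[p + 1]) p <- (p + 1) %% L
    used[p + 1] <- TRUE
    out[i] <- p
  }
  sort(out)
}

#' Sample motifs from a family
#'
#' Lengths are uniform over the family's range; anchor positions are scaled
#' to the drawn length (collisions resolved to distinct indices); anchor
#' positions emit the dominant residue with probability `mass` and a
#' background draw otherwise; all other positions are background draws.
#'
#' @param spec An [motif_family_spec()].
#' @param n Number of motifs.
#' @param prefix Id prefix (default the family id).
#' @return Tibble of records: `id`, `residues`, `source` = family id.
#' @export
sample_motif <- function(spec, n = 1, prefix = NULL) {
  stopifnot(inherits(spec, "asm_family_spec"))
  prefix <- prefix %||% spec$family_id
  bg <- spec$background
  bg_res <- names(bg)
  residues <- vapply(seq_len(n), function(i) {
    L <- sample_int_range(spec$length_range[1], spec$length_range[2])
    seq_chars <- sample(bg_res, L, replace = TRUE, prob = unclass(bg))
    pos <- anchor_positions(spec$anchors$rel_pos, L)
    keep <- runif(nrow(spec$anchors)) < spec$anchors$mass
    seq_chars[pos[keep] + 1] <- spec$anchors$residue[keep]
    paste(seq_chars, collapse = "")
  }, character(1))
  tibble(id = sprintf("%s_m%04d", prefix, seq_len(n)), residues = residues,
         source = spec$family_id)
}

#' Sample background sequences
#'
#' Residues i.i.d. from a background frequency table; emulates the role of
#' a general negative set approximating the whole protein space.
#'
#' @param n Number of sequences.
#' @param length A single length or `c(min, max)` range (uniform).
#' @param freqs `asm_freqs` table.
#' @param prefix Id prefix.
#' @return Tibble of records with `source = "background"`.
#' @export
sample_background <- function(n, length = 40, freqs = background_freqs(),
                              prefix = "bg") {
  if (n < 1) abort("`n` must be >= 1")
  if (!length(length) %in% 1:2 || any(length < 1))
    abort("`length` must be a positive scalar or c(min, max)")
  lens <- if (base::length(length) == 1) rep(length, n)
          else sample_int_range(length[1], length[2], n)
  res <- vapply(lens, function(L)
    paste(sample(names(freqs), L, replace = TRUE, prob = unclass(freqs)),
          collapse = ""), character(1))
  tibble(id = sprintf("%s_%05d", prefix, seq_len(n)), residues = res,
         source = "background")
}

#' Implant a motif into a background domain
#'
#' Builds a background-filled domain of exactly `domain_length` residues
#' with the motif inserted at a uniform-random feasible offset restricted to
#' the half nearer the chosen terminus (C-terminal half by default,
#' emulating effector-side motifs; N for receptor-side).
#'
#' @param motif_residues Motif string (length at most `domain_length`).
#' @param domain_length Domain length (default 100).
#' @param side `"C"` or `"N"` terminus bias.
#' @param freqs Background table for the non-motif positions.
#' @return List with `residues`, `start`, `end` (0-based half-open motif
#'   coordinates within the domain).
#' @export
implant_motif <- function(motif_residues, domain_length = 100, side = c("C", "N"),
                          freqs = background_freqs()) {
  side <- match.arg(side)
  L <- nchar(motif_residues)
  if (L > domain_length) abort("motif longer than the domain")
  max_off <- domain_length - L
  lo <- if (side == "C") floor(max_off / 2) else 0L
  hi <- if (side == "C") max_off else ceiling(max_off / 2)
  off <- if (hi > lo) sample_int_range(lo, hi) else as.integer(lo)
  ctx <- sample(names(freqs), domain_length, replace = TRUE, prob = unclass(freqs))
  chars <- strsplit(motif_residues, "")[[1]]
  ctx[(off + 1):(off + L)] <- chars
  list(residues = paste(ctx, collapse = ""), start = as.integer(off),
       end = as.integer(off + L))
}

#' Cut a motif with a fixed envelope from its context
#'
#' Returns the substring `[max(0, start - e), min(L, end + e))` of the
#' context sequence; `e = 0` recovers the rigorously cut motif exactly.
#'
#' @param context Context (domain) residue string.
#' @param start,end Motif interval within the context, 0-based half-open.
#' @param e Envelope width per side (nonnegative).
#' @return Residue string.
#' @export
make_envelope <- function(context, start, end, e = 0) {
  L <- nchar(context)
  if (e < 0) abort("`e` must be nonnegative")
  if (start < 0 || end <= start || end > L) abort("invalid motif interval")
  substr(context, max(0, start - e) + 1, min(L, end + e))
}

#' Configuration of the synthetic benchmark
#'
#' Defaults define the packaged benchmark conditions: 8 training families
#' (motif lengths 21--40, effector-side style) plus 2 held-out novel
#' families (lengths 11--30, receptor-side style), 120 training motifs per
#' family, 20,000 background 40-mer training negatives, test motifs with
#' 0/5/10-residue envelopes and 100-residue domain contexts, 2,000 fresh
#' evaluation negatives and 200 motif-free background domains.
#'
#' @param n_train_families,n_heldout_families Family counts.
#' @param motifs_per_family Training motifs per training family.
#' @param n_test_per_family Same-family test motifs per training family.
#' @param n_heldout_per_family Test motifs per held-out family.
#' @param n_negative_windows Background 40-mers for training.
#' @param n_eval_negatives Fresh background 40-mers for evaluation.
#' @param n_domain_negatives Motif-free background domains.
#' @param domain_length Domain context length (default 100).
#' @param envelope_sizes Envelope widths for test variants.
#' @param terminus_side `"C"` or `"N"` implantation bias.
#' @param train_length_range,heldout_length_range Motif length ranges.
#' @param n_anchors,anchor_mass Family conservation parameters.
#' @param seed Root seed; every component draws from a named substream.
#' @return A validated list of class `asm_benchmark_config`.
#' @export
synthetic_benchmark_config <- function(n_train_families = 8, n_heldout_families = 2,
                                       motifs_per_family = 120,
                                       n_test_per_family = 40,
                                       n_heldout_per_family = 40,
                                       n_negative_windows = 20000,
                                       n_eval_negatives = 2000,
                                       n_domain_negatives = 200,
                                       domain_length = 100,
                                       envelope_sizes = c(0, 5, 10),
                                       terminus_side = c("C", "N"),
                                       train_length_range = c(21, 40),
                                       heldout_length_range = c(11, 30),
                                       n_anchors = 8, anchor_mass = 0.9,
                                       seed = 1) {
  terminus_side <- match.arg(terminus_side)
  if (any(c(n_train_families, n_heldout_families, motifs_per_family,
            n_test_per_family, n_heldout_per_family, n_negative_windows,
            n_eval_negatives, n_domain_negatives) < 1))
    abort("all benchmark counts must be >= 1")
  if (domain_length < 40) abort("`domain_length` must be >= 40")
  structure(list(
    n_train_families = n_train_families, n_heldout_families = n_heldout_families,
    motifs_per_family = motifs_per_family, n_test_per_family = n_test_per_family,
    n_heldout_per_family = n_heldout_per_family,
    n_negative_windows = n_negative_windows, n_eval_negatives = n_eval_negatives,
    n_domain_negatives = n_domain_negatives, domain_length = domain_length,
    envelope_sizes = envelope_sizes, terminus_side = terminus_side,
    train_length_range = train_length_range,
    heldout_length_range = heldout_length_range,
    n_anchors = n_anchors, anchor_mass = anchor_mass, seed = seed
  ), class = "asm_benchmark_config")
}

#' Generate the synthetic benchmark in memory
#'
#' Fully reproducible from `config$seed`: families, motifs, implants and
#' negatives each draw from a named substream of the root seed, so
#' components can be regenerated independently.
#'
#' @param config A [synthetic_benchmark_config()].
#' @return A list of tibbles: `train_pos`, `train_neg`, per-envelope test
#'   sets `test_same_env<e>` / `test_novel_env<e>`, domain sets
#'   `test_same_dom` / `test_novel_dom`, `annotations` (0-based half-open
#'   `motif_start`/`motif_end` plus `family`), `eval_neg`, `domain_neg`,
#'   `family_specs`, and the `config`.
#' @export
generate_benchmark <- function(config = synthetic_benchmark_config()) {
  stopifnot(inherits(config, "asm_benchmark_config"))
  cf <- config
  freqs <- background_freqs()

  set.seed(sub_seed(cf$seed, "families"))
  n_fam <- cf$n_train_families + cf$n_heldout_families
  fam_ids <- sprintf("fam%02d", seq_len(n_fam))
  is_train <- seq_len(n_fam) <= cf$n_train_families
  specs <- lapply(seq_len(n_fam), function(i)
    motif_family_spec(fam_ids[i],
                      length_range = if (is_train[i]) cf$train_length_range
                                     else cf$heldout_length_range,
                      n_anchors = cf$n_anchors, anchor_mass = cf$anchor_mass,
                      background = freqs))
  names(specs) <- fam_ids

  sample_set <- function(which_fams, n_per, stream) {
    purrr::map_dfr(which_fams, function(fid) {
      set.seed(sub_seed(cf$seed, paste0(stream, "_", fid)))
      sample_motif(specs[[fid]], n_per, prefix = paste0(fid, "_", stream))
    })
  }
  train_pos <- sample_set(fam_ids[is_train], cf$motifs_per_family, "train")
  test_same <- sample_set(fam_ids[is_train], cf$n_test_per_family, "test")
  test_novel <- sample_set(fam_ids[!is_train], cf$n_heldout_per_family, "novel")

  implant_set <- function(motifs, stream) {
    set.seed(sub_seed(cf$seed, stream))
    imp <- lapply(motifs$residues, implant_motif, domain_length = cf$domain_length,
                  side = cf$terminus_side, freqs = freqs)
    tibble(
      id = motifs$id, source = motifs$source,
      residues = vapply(imp, `[[`, character(1), "residues"),
      motif_start = vapply(imp, `[[`, integer(1), "start"),
      motif_end = vapply(imp, `[[`, integer(1), "end")
    )
  }
  dom_same <- implant_set(test_same, "implant_same")
  dom_novel <- implant_set(test_novel, "implant_novel")

  env_set <- function(doms) {
    setNames(lapply(cf$envelope_sizes, function(e) {
      tibble(id = doms$id,
             residues = vapply(seq_len(nrow(doms)), function(i)
               make_envelope(doms$residues[i], doms$motif_start[i],
                             doms$motif_end[i], e), character(1)),
             source = doms$source)
    }), paste0("env", cf$envelope_sizes))
  }
  same_envs <- env_set(dom_same)
  novel_envs <- env_set(dom_novel)

  set.seed(sub_seed(cf$seed, "train_neg"))
  train_neg <- sample_background(cf$n_negative_windows, 40, freqs, prefix = "pbneg")
  set.seed(sub_seed(cf$seed, "eval_neg"))
  eval_neg <- sample_background(cf$n_eval_negatives, 40, freqs, prefix = "evneg")
  set.seed(sub_seed(cf$seed, "domain_neg"))
  domain_neg <- sample_background(cf$n_domain_negatives, cf$domain_length,
                                  freqs, prefix = "domneg")

  annotations <- dplyr::bind_rows(
    dplyr::transmute(dom_same, seq_id = .data$id, motif_start = .data$motif_start,
                     motif_end = .data$motif_end, family = .data$source,
                     split = "same"),
    dplyr::transmute(dom_novel, seq_id = .data$id, motif_start = .data$motif_start,
                     motif_end = .data$motif_end, family = .data$source,
                     split = "novel")
  )

  out <- c(
    list(train_pos = train_pos, train_neg = train_neg),
    setNames(same_envs, paste0("test_same_", names(same_envs))),
    list(test_same_dom = dom_same[c("id", "residues", "source")]),
    setNames(novel_envs, paste0("test_novel_", names(novel_envs))),
    list(test_novel_dom = dom_novel[c("id", "residues", "source")],
         annotations = annotations, eval_neg = eval_neg,
         domain_neg = domain_neg, family_specs = specs, config = cf)
  )
  out
}

#' Generate the benchmark and write it to disk
#'
#' Writes one FASTA per split, the motif-coordinate annotation TSV (1-based
#' inclusive, output convention), and a `manifest.json` recording every
#' generation parameter and per-file MD5 checksum. Regeneration with the
#' same seed is byte-identical.
#'
#' @param config A [synthetic_benchmark_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest list, invisibly; the in-memory bundle is attached as
#'   attribute `bundle`.
#' @export
build_benchmark <- function(config = synthetic_benchmark_config(), out_dir) {
  bundle <- generate_benchmark(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  splits <- setdiff(names(bundle), c("annotations", "family_specs", "config"))
  files <- character(0)
  for (nm in splits) {
    f <- file.path(out_dir, paste0(nm, ".fasta"))
    write_fasta(bundle[[nm]], f)
    files[nm] <- f
  }
  ann_path <- file.path(out_dir, "annotations.tsv")
  ann_out <- dplyr::mutate(bundle$annotations, motif_start = .data$motif_start + 1L)
  utils::write.table(ann_out, ann_path, sep = "\t", quote = FALSE, row.names = FALSE)
  files["annotations"] <- ann_path
  manifest <- list(
    config = lapply(unclass(config), unname),
    counts = lapply(bundle[splits], nrow),
    checksums = as.list(tools::md5sum(unname(files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(manifest, "bundle") <- bundle
  invisible(manifest)
}
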