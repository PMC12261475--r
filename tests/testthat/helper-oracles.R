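# Independent oracles and small fixture builders used across the suite.

# Brute-force trainable-parameter count: enumerate every weight tensor of
# the architecture and sum element counts. Kept deliberately independent of
# the package's closed-form formula.
enumerate_params <- function(V, d, u1, u2) {
  tensors <- list(
    embedding = c(V, d),
    fwd_kernel = c(d, 4 * u1), fwd_recurrent = c(u1, 4 * u1), fwd_bias = c(4 * u1, 1),
    bwd_kernel = c(d, 4 * u1), bwd_recurrent = c(u1, 4 * u1), bwd_bias = c(4 * u1, 1),
    uni_kernel = c(2 * u1, 4 * u2), uni_recurrent = c(u2, 4 * u2), uni_bias = c(4 * u2, 1),
    out_weights = c(u2, 1), out_bias = c(1, 1)
  )
  sum(vapply(tensors, prod, numeric(1)))
}

# O(n^2) brute-force ROC: sweep every distinct score as a >= threshold,
# recount TP/FP from scratch each time.
brute_roc <- function(scores, labels) {
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  pts <- data.frame(fpr = 0, tpr = 0)
  for (th in sort(unique(scores), decreasing = TRUE)) {
    sel <- scores >= th
    pts <- rbind(pts, data.frame(fpr = sum(sel & labels == 0) / n_neg,
                                 tpr = sum(sel & labels == 1) / n_pos))
  }
  if (pts$fpr[nrow(pts)] != 1 || pts$tpr[nrow(pts)] != 1)
    pts <- rbind(pts, data.frame(fpr = 1, tpr = 1))
  unique(pts)
}

# Random cleaned residue string.
random_residues <- function(n, alphabet = asm_alphabet()) {
  paste(sample(alphabet$residues[1:20], n, replace = TRUE), collapse = "")
}

# A linearly separable toy training set: positives carry a fixed conserved
# 10-residue anchor inside background; negatives are pure background.
toy_training <- function(n_pos = 20, n_neg = 20, seed = 1) {
  set.seed(seed)
  freqs <- background_freqs()
  anchor <- "QNGQYGNSGF"
  pos <- vapply(seq_len(n_pos), function(i) {
    bg <- paste(sample(names(freqs), 30, TRUE, prob = freqs), collapse = "")
    paste0(substr(bg, 1, 15), anchor, substr(bg, 16, 30))
  }, character(1))
  neg <- vapply(seq_len(n_neg), function(i)
    paste(sample(names(freqs), 40, TRUE, prob = freqs), collapse = ""), character(1))
  x <- vapply(c(pos, neg), encode_tokens, integer(40), USE.NAMES = FALSE)
  storage.mode(x) <- "integer"
  list(x = x, y = rep(1:0, c(n_pos, n_neg)), pos = pos, neg = neg)
}

# A tiny untrained ensemble (cheap fixture for shape/determinism tests).
tiny_ensemble <- function(k = 3, seed = 5, config = model_config()) {
  folds <- lapply(seq_len(k), function(i) {
    structure(list(fold_index = i - 1L,
                   model = build_model(config, seed = seed + i),
                   history = tibble::tibble(),
                   n_train = NA_integer_, n_val = NA_integer_,
                   val_metrics = list(val_loss = NA_real_)),
              class = "asm_fold_model")
  })
  amyloscan:::new_ensemble(folds, config)
}

write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}
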