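test_that("combine_probs is the arithmetic mean, bounded by its inputs", {
  expect_identical(combine_probs(c(0.2, 0.4, 0.6, 0.8, 1.0, 0.0)), 0.5)
  expect_identical(combine_probs(rep(0.37, 6)), 0.37)
  expect_error(combine_probs(numeric(0)), "empty")
  expect_error(combine_probs(c(0.5, 1.2)), "0, 1")
  set.seed(14)
  for (i in 1:1000) {
    p <- runif(sample(1:8, 1))
    m <- combine_probs(p)
    expect_gte(m, min(p)); expect_lte(m, max(p))
  }
})

test_that("scan_sequence enumerates windows, max-pools, and breaks ties leftmost", {
  ens <- tiny_ensemble()
  # length 40: a single window whose mean is the sequence score
  r40 <- withr::with_seed(1, random_residues(40))
  sc <- scan_sequence(ens, r40, id = "one")
  expect_identical(nrow(sc$window_scores), 1L)
  expect_identical(sc$hit$max_prob, sc$window_scores$mean_prob[1])
  expect_identical(sc$hit$n_windows, 1L)
  expect_identical(sc$window_scores$mean_prob[1],
                   combine_probs(sc$window_scores$fold_probs[[1]]))

  # length 42: three windows
  r42 <- withr::with_seed(2, random_residues(42))
  sc42 <- scan_sequence(ens, r42)
  expect_identical(nrow(sc42$window_scores), 3L)
  expect_identical(sc42$hit$max_prob, max(sc42$window_scores$mean_prob))

  # homopolymer: every window identical, so all means tie -> leftmost start
  tie <- scan_sequence(ens, strrep("A", 45))
  expect_identical(length(unique(tie$window_scores$mean_prob)), 1L)
  expect_identical(tie$hit$best_start, 0L)

  expect_error(scan_sequence(ens, ""), "nonempty")
})

test_that("per-sequence max is an upper bound on every window mean", {
  ens <- tiny_ensemble()
  set.seed(5)
  for (L in c(7L, 40L, 73L, 160L)) {
    sc <- scan_sequence(ens, random_residues(L))
    expect_identical(sc$hit$n_windows, max(1L, L - 39L))
    expect_true(all(sc$hit$max_prob >= sc$window_scores$mean_prob))
  }
})

test_that("scan_sequences/scan_fasta respect thresholds and are deterministic", {
  ens <- tiny_ensemble()
  set.seed(6)
  rec <- tibble::tibble(id = paste0("s", 1:3),
                        residues = vapply(c(25, 40, 90), random_residues, character(1)))
  h_hi <- scan_sequences(ens, rec, threshold = 1.1)
  expect_false(any(h_hi$detected))   # probability cannot exceed 1
  h_lo <- scan_sequences(ens, rec, threshold = 0)
  expect_true(all(h_lo$detected))
  expect_identical(h_lo$parent_id, rec$id)

  f <- tempfile(fileext = ".fasta")
  write_fasta(rec, f)
  t1 <- suppressMessages(scan_fasta(ens, f))
  t2 <- suppressMessages(scan_fasta(ens, f))
  expect_identical(t1, t2)
  # agreement between the batch scan and the single-sequence scan
  one <- scan_sequence(ens, rec$residues[3], id = "s3")
  expect_identical(t1$max_prob[3], one$hit$max_prob)

  out <- tempfile(fileext = ".tsv")
  write_hits(t1, out)
  tab <- read.delim(out)
  expect_identical(tab$best_start, t1$best_start + 1L)  # 1-based on disk
  expect_identical(tab$best_end, t1$best_end)
})

test_that("locate_motif_shift computes shifts and coverage by interval arithmetic", {
  hit <- tibble::tibble(parent_id = "s", best_start = 10, best_end = 50)
  sh <- locate_motif_shift(hit, 15, 40)
  expect_identical(sh$begin_shift, -5)
  expect_identical(sh$end_shift, 10)
  expect_identical(sh$coverage, 1)

  hit0 <- tibble::tibble(parent_id = "s", best_start = 0, best_end = 40)
  expect_identical(locate_motif_shift(hit0, 50, 70)$coverage, 0)

  # brute-force residue counting oracle for a partial overlap
  hit5 <- tibble::tibble(parent_id = "s", best_start = 5, best_end = 45)
  inside <- sum(vapply(0:19, function(p) p >= 5 && p < 45, logical(1)))
  sh5 <- locate_motif_shift(hit5, 0, 20)
  expect_identical(sh5$coverage, inside / 20)
  expect_identical(sh5$begin_shift, 5)
  expect_identical(sh5$end_shift, 25)

  expect_error(locate_motif_shift(hit, 40, 15), "interval")

  # coverage == 1 exactly when the window encloses the motif
  set.seed(8)
  for (i in 1:200) {
    bs <- sample(0:60, 1); ms <- sample(0:75, 1); me <- ms + sample(5:25, 1)
    h <- tibble::tibble(parent_id = "x", best_start = bs, best_end = bs + 40)
    cv <- locate_motif_shift(h, ms, me)$coverage
    expect_identical(cv == 1, bs <= ms && bs + 40 >= me)
  }
})
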