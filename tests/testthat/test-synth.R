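test_that("family specs validate their geometry", {
  set.seed(1)
  sp <- motif_family_spec("famA")
  expect_s3_class(sp, "asm_family_spec")
  expect_identical(nrow(sp$anchors), 8L)
  expect_true(all(sp$anchors$rel_pos >= 0 & sp$anchors$rel_pos < 1))
  expect_error(motif_family_spec("f", length_range = c(5, 50)), "max <= 40")
  expect_error(motif_family_spec("f", length_range = c(5, 10), n_anchors = 11),
               "more anchors")
})

test_that("fully conserved anchors always emit their dominant residue", {
  set.seed(2)
  sp <- motif_family_spec("famG", length_range = c(20, 30), n_anchors = 3,
                          anchor_mass = 1, anchor_pool = "G")
  for (i in 1:50) {
    m <- sample_motif(sp, 1)
    L <- nchar(m$residues)
    pos <- amyloscan:::anchor_positions(sp$anchors$rel_pos, L)
    chars <- strsplit(m$residues, "")[[1]]
    expect_identical(chars[pos + 1], rep("G", 3))
  }
})

test_that("motif lengths cover the range approximately uniformly", {
  set.seed(3)
  sp <- motif_family_spec("famL", length_range = c(21, 40))
  lens <- nchar(sample_motif(sp, 1000)$residues)
  expect_setequal(sort(unique(lens)), 21:40)
  cs <- suppressWarnings(stats::chisq.test(table(factor(lens, levels = 21:40))))
  expect_gt(cs$p.value, 0.01)
})

test_that("families with disjoint anchor residues are more self-similar", {
  set.seed(4)
  spA <- motif_family_spec("A", length_range = c(30, 30), n_anchors = 10,
                           anchor_pool = c("Q", "N"))
  spB <- motif_family_spec("B", length_range = c(30, 30), n_anchors = 10,
                           anchor_pool = c("G", "S"))
  ma <- sample_motif(spA, 30)$residues
  mb <- sample_motif(spB, 30)$residues
  ident <- function(a, b) mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  pairs <- function(x, y) mean(vapply(1:20, function(i)
    ident(sample(x, 1), sample(y, 1)), numeric(1)))
  expect_gt(pairs(ma, ma), pairs(ma, mb))
})

test_that("background samples have the right shape and composition", {
  set.seed(5)
  bg <- sample_background(10, 40)
  expect_identical(nrow(bg), 10L)
  expect_true(all(nchar(bg$residues) == 40))
  # law of large numbers vs a uniform table
  unif <- amyloscan:::as_freqs(setNames(rep(1 / 20, 20), names(background_freqs())))
  big <- sample_background(2500, 40, unif)
  tab <- table(strsplit(paste(big$residues, collapse = ""), "")[[1]])
  expect_lt(max(abs(tab / sum(tab) - 1 / 20)), 0.01)
  # determinism under an explicit seed
  a <- withr::with_seed(11, sample_background(5, c(10, 20)))
  b <- withr::with_seed(11, sample_background(5, c(10, 20)))
  expect_identical(a, b)
  expect_error(sample_background(0, 40), ">= 1")
  expect_error(sample_background(2, c(0, 5)), "positive")
})

test_that("implant_motif places the motif inside the domain with true coordinates", {
  set.seed(6)
  for (i in 1:200) {
    L <- sample(11:40, 1)
    motif <- random_residues(L)
    side <- sample(c("C", "N"), 1)
    imp <- implant_motif(motif, 100, side = side)
    expect_identical(nchar(imp$residues), 100L)
    expect_gte(imp$start, 0); expect_lte(imp$end, 100)
    expect_identical(substr(imp$residues, imp$start + 1, imp$end), motif)
    mid <- (imp$start + imp$end) / 2
    if (side == "C") expect_gte(imp$end, 50) else expect_lte(imp$start, 50)
  }
  # boundary: domain exactly the motif length
  m <- random_residues(25)
  imp <- implant_motif(m, 25)
  expect_identical(c(imp$start, imp$end), c(0L, 25L))
  expect_identical(imp$residues, m)
  expect_error(implant_motif(random_residues(50), 40), "longer")
})

test_that("make_envelope cuts the documented substring with clipping", {
  ctx <- random_residues(100)
  expect_identical(make_envelope(ctx, 20, 45, 0), substr(ctx, 21, 45))
  env5 <- make_envelope(ctx, 20, 45, 5)
  expect_identical(nchar(env5), 35L)
  expect_identical(env5, substr(ctx, 16, 50))
  # clipped at the left edge
  expect_identical(make_envelope(ctx, 0, 20, 10), substr(ctx, 1, 30))
  expect_error(make_envelope(ctx, 30, 20, 5), "interval")
  expect_error(make_envelope(ctx, 0, 20, -1), "nonnegative")
})

small_bench_config <- function(seed = 7) {
  synthetic_benchmark_config(
    n_train_families = 3, n_heldout_families = 2, motifs_per_family = 10,
    n_test_per_family = 4, n_heldout_per_family = 4,
    n_negative_windows = 30, n_eval_negatives = 20, n_domain_negatives = 5,
    seed = seed
  )
}

test_that("benchmark bundles are internally consistent", {
  bench <- generate_benchmark(small_bench_config())
  expect_identical(nrow(bench$train_pos), 30L)
  expect_identical(nrow(bench$train_neg), 30L)
  expect_identical(nrow(bench$test_same_env0), 12L)
  expect_identical(nrow(bench$test_novel_env0), 8L)
  # train and held-out family ids are disjoint
  expect_length(intersect(unique(bench$train_pos$source),
                          unique(bench$test_novel_env0$source)), 0)
  # every domain record's annotated interval recovers its envelope-0 motif
  doms <- rbind(bench$test_same_dom, bench$test_novel_dom)
  env0 <- rbind(bench$test_same_env0, bench$test_novel_env0)
  ann <- bench$annotations
  for (i in seq_len(nrow(ann))) {
    d <- doms[doms$id == ann$seq_id[i], ]
    m <- env0[env0$id == ann$seq_id[i], ]
    expect_identical(substr(d$residues, ann$motif_start[i] + 1, ann$motif_end[i]),
                     m$residues)
  }
  # envelope-5 variants are wider unless clipped
  expect_true(all(nchar(bench$test_same_env5$residues) >=
                  nchar(bench$test_same_env0$residues)))
})

test_that("benchmark files are byte-identical across regenerations", {
  d1 <- file.path(tempdir(), "bench_a")
  d2 <- file.path(tempdir(), "bench_b")
  m1 <- build_benchmark(small_bench_config(seed = 13), d1)
  m2 <- build_benchmark(small_bench_config(seed = 13), d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in setdiff(f1, "manifest.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  # manifest checksums describe the actual files
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_identical(length(man$checksums), length(f1) - 1L)
  # a different seed changes content
  d3 <- file.path(tempdir(), "bench_c")
  build_benchmark(small_bench_config(seed = 14), d3)
  expect_false(identical(readLines(file.path(d1, "train_pos.fasta")),
                         readLines(file.path(d3, "train_pos.fasta"))))
  # counts in the manifest match the files on disk
  tp <- read_fasta(file.path(d1, "train_pos.fasta"))
  expect_identical(nrow(tp), man$counts$train_pos)
})

test_that("written annotations are 1-based and round-trip through read_annotations", {
  d <- file.path(tempdir(), "bench_ann")
  build_benchmark(small_bench_config(seed = 21), d)
  raw <- read.delim(file.path(d, "annotations.tsv"))
  back <- read_annotations(file.path(d, "annotations.tsv"))
  expect_identical(back$motif_start, raw$motif_start - 1L)
  expect_identical(back$motif_end, raw$motif_end)
  doms <- read_fasta(file.path(d, "test_same_dom.fasta"))
  i <- match(doms$id[1], back$seq_id)
  env0 <- read_fasta(file.path(d, "test_same_env0.fasta"))
  expect_identical(substr(doms$residues[1], back$motif_start[i] + 1, back$motif_end[i]),
                   env0$residues[env0$id == doms$id[1]])
})
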