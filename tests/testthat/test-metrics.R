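test_that("roc_curve matches the worked threshold sweep and handles ties", {
  rc <- roc_curve(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))
  expect_true(all(c("fpr", "tpr") %in% names(rc)))
  pts <- paste(rc$fpr, rc$tpr)
  for (p in c("0 0.5", "0.5 0.5", "0.5 1")) expect_true(p %in% pts)
  expect_identical(rc$fpr[1], 0); expect_identical(rc$tpr[1], 0)
  expect_identical(rc$fpr[nrow(rc)], 1); expect_identical(rc$tpr[nrow(rc)], 1)

  # perfectly separated: passes through (0, 1)
  rc2 <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_true(any(rc2$fpr == 0 & rc2$tpr == 1))

  # all scores identical: (0,0) and (1,1) only
  rc3 <- roc_curve(rep(0.5, 10), rep(c(1, 0), 5))
  expect_identical(nrow(rc3), 2L)

  expect_error(roc_curve(1:3, c(1, 1, 1)), "both classes")
  expect_error(roc_curve(1:3, c(1, 0)), "lengths")
})

test_that("roc_curve agrees with O(n^2) brute-force enumeration", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(4:50, 1)
    labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), sample(1:3, 1))  # induce ties
    rc <- roc_curve(scores, labels)
    bf <- brute_roc(scores, labels)
    expect_equal(as.data.frame(rc[c("fpr", "tpr")]), bf,
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("recall_at_fpr interpolates the staircase as specified", {
  # separable classifier: recall 1 even at tiny FPR
  perfect <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_identical(recall_at_fpr(perfect, 1e-5), 1)
  # constant scores give the diagonal
  flat <- roc_curve(rep(0.5, 20), rep(c(1, 0), 10))
  expect_equal(recall_at_fpr(flat, 0.3), 0.3)
  # worked interpolation between (0,0.5) and (0.5,0.5)
  rc <- roc_curve(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))
  expect_identical(recall_at_fpr(rc, 0.25), 0.5)
  # at the vertical segment the maximum TPR is taken
  expect_identical(recall_at_fpr(rc, 0.5), 1)
  expect_error(recall_at_fpr(rc, -0.1), "0, 1")
})

test_that("recall_at_fpr is nondecreasing in the target and 1 at FPR 1", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    labels <- c(1, 0, sample(0:1, n - 2, TRUE))
    scores <- round(runif(n), 2)
    rc <- roc_curve(scores, labels)
    targets <- sort(runif(15))
    vals <- recall_at_fpr(rc, targets)
    expect_true(all(diff(vals) >= -1e-12))
    expect_identical(recall_at_fpr(rc, 1), 1)
  }
})

test_that("average_precision matches hand computations", {
  expect_identical(average_precision(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # single positive ranked second: precision 1/2 at its recall step
  expect_identical(average_precision(c(0.4, 0.6), c(1, 0)), 0.5)
})

test_that("AP and AUROC are invariant under strictly increasing transforms", {
  set.seed(23)
  for (i in 1:100) {
    n <- sample(10:80, 1)
    labels <- c(1, 0, sample(0:1, n - 2, TRUE))
    scores <- runif(n)
    expect_equal(average_precision(scores^2, labels),
                 average_precision(scores, labels), tolerance = 1e-12)
    expect_equal(average_precision(exp(3 * scores), labels),
                 average_precision(scores, labels), tolerance = 1e-12)
    expect_equal(auroc(scores^2, labels), auroc(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUROC agrees with an established implementation and is ~0.5 on noise", {
  skip_if_not_installed("pROC")
  set.seed(41)
  for (i in 1:10) {
    n <- sample(20:100, 1)
    labels <- c(1, 0, sample(0:1, n - 2, TRUE))
    scores <- round(runif(n), 2)
    ours <- auroc(scores, labels)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-10)
  }
  # balanced random scores: AUROC within 0.03 of chance
  set.seed(2024)
  scores <- runif(2000)
  labels <- rep(c(1, 0), 1000)
  expect_lt(abs(auroc(scores, labels) - 0.5), 0.03)
})

test_that("prf_vs_evidenced reproduces the proteome-scan accounting", {
  row <- prf_vs_evidenced(16, 124, 25)
  expect_identical(row$recall_2dp, 0.64)
  expect_identical(row$precision_2dp, 0.13)
  expect_identical(row$f1_2dp, 0.21)
  expect_identical(prf_vs_evidenced(9, 21, 25)$recall_2dp, 0.36)
  zero <- prf_vs_evidenced(0, 10, 25)
  expect_identical(zero$precision, 0)
  expect_identical(zero$recall, 0)
  expect_identical(zero$f1, 0)
  # no hits at all: precision defined as 0, nothing crashes
  expect_identical(prf_vs_evidenced(0, 0, 25)$precision, 0)
  expect_error(prf_vs_evidenced(5, 4, 25), "exceed")
  expect_error(prf_vs_evidenced(26, 30, 25), "exceed")
  expect_error(prf_vs_evidenced(1, 2, 0), ">= 1")
})

test_that("retention_rate counts the detected fraction", {
  expect_identical(retention_rate(c(0.6, 0.4)), 0.5)
  expect_identical(retention_rate(c(0.1, 0.2), 0.5), 0)
  expect_identical(retention_rate(c(0.1, 0.2), 0), 1)
  expect_identical(retention_rate(c(0.5, 0.4)), 0.5)  # >= is inclusive
  expect_error(retention_rate(numeric(0)), "empty")
})

test_that("evaluate_scores bundles AP, AUROC and recall columns", {
  set.seed(55)
  pos <- runif(50, 0.4, 1); neg <- runif(200, 0, 0.6)
  tab <- evaluate_scores(pos, neg, fpr_targets = c(0.1, 0.01))
  expect_identical(nrow(tab), 1L)
  expect_true(all(c("ap", "auroc") %in% names(tab)))
  expect_identical(sum(grepl("^recall_at_", names(tab))), 2L)
  expect_true(all(tab$ap >= 0 & tab$ap <= 1))
})
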