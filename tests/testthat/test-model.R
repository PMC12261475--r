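test_that("closed-form parameter count matches brute-force tensor enumeration", {
  # default architecture: the 1,637-parameter contract
  expect_identical(count_trainable_params(model_config()), 1637L)
  expect_identical(enumerate_params(26, 8, 8, 4), 1637)
  # small configs, expected values frozen from the enumeration oracle
  expect_identical(enumerate_params(4, 2, 2, 2), 147)
  expect_identical(count_trainable_params(model_config(4, 2, 2, 2)), 147L)
  expect_identical(enumerate_params(1, 1, 1, 1), 43)
  expect_identical(count_trainable_params(model_config(1, 1, 1, 1)), 43L)
})

test_that("closed form equals the allocated weight count for 50 random configs", {
  set.seed(20)
  for (i in 1:50) {
    cfg <- model_config(vocab_size = sample(2:30, 1), embed_dim = sample(1:12, 1),
                        bi_units = sample(1:10, 1), uni_units = sample(1:8, 1),
                        window_len = 40L)
    m <- build_model(cfg)
    expect_identical(n_params(m), count_trainable_params(cfg))
    expect_identical(n_params(m),
                     as.integer(enumerate_params(cfg$vocab_size, cfg$embed_dim,
                                                 cfg$bi_units, cfg$uni_units)))
  }
})

test_that("built models output probabilities in (0,1) and are seed-deterministic", {
  cfg <- model_config()
  m1 <- build_model(cfg, seed = 11)
  m2 <- build_model(cfg, seed = 11)
  expect_identical(m1$params, m2$params)
  set.seed(1)
  x <- vapply(1:8, function(i) encode_tokens(random_residues(40)), integer(40))
  p1 <- predict_window_prob(m1, x)
  expect_true(all(p1 > 0 & p1 < 1))
  expect_identical(p1, predict_window_prob(m2, x))
  # inference is a pure function: repeated calls agree bitwise
  expect_identical(p1, predict_window_prob(m1, x))
  expect_error(model_config(dropout = 1), "dropout")
  expect_error(model_config(embed_dim = 0), ">= 1")
})

test_that("cv_split partitions each class into near-equal disjoint blocks", {
  pos <- paste0("p", 1:12); neg <- paste0("n", 1:12)
  sp <- cv_split(pos, neg, k = 6, seed = 4)
  expect_identical(nrow(sp), 6L)
  for (i in 1:6) {
    expect_length(intersect(sp$val_ids[[i]], sp$train_ids[[i]]), 0)
    expect_identical(sum(sp$val_ids[[i]] %in% pos), 2L)
    expect_identical(sum(sp$val_ids[[i]] %in% neg), 2L)
  }
  all_val <- unlist(sp$val_ids)
  expect_setequal(all_val, c(pos, neg))
  expect_identical(anyDuplicated(all_val), 0L)
  # uneven sizes differ by at most one per class
  sp2 <- cv_split(paste0("p", 1:14), paste0("n", 1:9), k = 3, seed = 1)
  np <- vapply(sp2$val_ids, function(v) sum(grepl("^p", v)), integer(1))
  expect_lte(diff(range(np)), 1)
  # determinism
  expect_identical(cv_split(pos, neg, 6, seed = 99), cv_split(pos, neg, 6, seed = 99))
  expect_error(cv_split(pos[1:3], neg, k = 6), "at least")
})

test_that("training solves a separable toy problem and records finite losses", {
  toy <- toy_training(seed = 1)
  fm <- train_fold(toy$x, toy$y, toy$x, toy$y,
                   train_config = train_config(batch_size = 4, epochs = 30, seed = 3))
  expect_identical(nrow(fm$history), 30L)
  expect_true(all(is.finite(fm$history$train_loss)))
  expect_true(all(is.finite(fm$history$val_loss)))
  p <- predict_window_prob(fm, toy$x)
  expect_identical(mean((p >= 0.5) == (toy$y == 1)), 1)  # training accuracy 1.0
})

test_that("loss decreases over the first epochs of the toy problem", {
  toy <- toy_training(seed = 2)
  fm <- train_fold(toy$x, toy$y,
                   train_config = train_config(batch_size = 4, epochs = 5, seed = 8))
  expect_lt(fm$history$train_loss[5], fm$history$train_loss[1])
})

test_that("training is deterministic given the seed", {
  toy <- toy_training(n_pos = 8, n_neg = 8, seed = 3)
  tc <- train_config(batch_size = 4, epochs = 3, seed = 21)
  f1 <- train_fold(toy$x, toy$y, toy$x, toy$y, train_config = tc)
  f2 <- train_fold(toy$x, toy$y, toy$x, toy$y, train_config = tc)
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$history$val_loss, f2$history$val_loss)
})

test_that("training rejects single-class data and wrong window lengths", {
  toy <- toy_training(n_pos = 6, n_neg = 6, seed = 4)
  expect_error(train_fold(toy$x, rep(1, 12)), "both classes")
  expect_error(train_fold(toy$x[1:30, ], toy$y), "40 rows")
  expect_error(train_fold(toy$x, toy$y[1:3]), "labels")
})
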