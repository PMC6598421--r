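test_that("binary cross-entropy matches its closed form and clips", {
  expect_equal(binary_cross_entropy(1, 0.5), log(2), tolerance = 1e-12)
  expect_lt(binary_cross_entropy(1, 1), 1e-6)       # ~0 up to clipping
  expect_equal(binary_cross_entropy(0, 1), -log(1e-7), tolerance = 1e-9)
  expect_equal(binary_cross_entropy(0, 0.25), -log(0.75), tolerance = 1e-12)
  # batch loss is the mean of per-example losses (scalar-loop oracle)
  set.seed(1)
  y <- rbinom(50, 1, 0.5)
  p <- runif(50)
  scalar <- vapply(seq_along(y), function(i) {
    binary_cross_entropy(y[i], p[i])
  }, numeric(1))
  expect_equal(binary_cross_entropy(y, p), mean(scalar), tolerance = 1e-12)
  expect_true(all(binary_cross_entropy(y, p, mean = FALSE) >= 0))
})

test_that("model construction is seed-deterministic with exact param counts", {
  cfg <- model_config(l_text = 6, l_hash = 3, embedding_dim = 5,
                      lstm_units = 4, dense_units = 3, seed = 11)
  m1 <- build_deep_model(cfg, vocab_size = 100)
  m2 <- build_deep_model(cfg, vocab_size = 100)
  expect_identical(m1$params, m2$params)
  # embedding parameters: vocab_size x embedding_dim per branch
  expect_equal(length(m1$params$emb_t) + length(m1$params$emb_h),
               100 * 5 * 2)
  # full closed-form count: embeddings + LSTM (De*4H + H*4H + 4H) x2 +
  # dense1/2 (H*D + D) x2 + dense3 (2D*D + D) + dense4 (D + 1)
  De <- 5; H <- 4; D <- 3
  expected <- 2 * (100 * De) + 2 * (De * 4 * H + H * 4 * H + 4 * H) +
    2 * (H * D + D) + (2 * D * D + D) + (D + 1)
  expect_equal(n_parameters(m1), expected)
  # interface contract: probabilities in [0, 1]
  Xt <- matrix(sample(0:100, 12), 2, 6)
  Xh <- matrix(sample(0:100, 6), 2, 3)
  p <- dealerscan:::cpp_deep_forward(m1$params, Xt, Xh)
  expect_length(p, 2)
  expect_true(all(p >= 0 & p <= 1))
  expect_error(model_config(lstm_dropout = 1.2))
})

test_that("analytic gradients agree with finite differences", {
  cfg <- model_config(l_text = 4, l_hash = 3, embedding_dim = 3,
                      lstm_units = 4, dense_units = 2, seed = 3,
                      lstm_dropout = 0, lstm_recurrent_dropout = 0)
  m <- build_deep_model(cfg, vocab_size = 7)
  set.seed(42)
  B <- 5
  Xt <- matrix(sample(0:7, B * 4, replace = TRUE), B, 4)
  Xh <- matrix(sample(0:7, B * 3, replace = TRUE), B, 3)
  Xt[1, ] <- 0L  # include an all-padding row
  y <- c(1, 0, 1, 1, 0)
  g <- dealerscan:::cpp_deep_grad(m$params, Xt, Xh, y, 0, 0, 1L)
  eps <- 1e-5
  for (nm in names(m$params)) {
    G <- g$grads[[nm]]
    idx <- sample(length(m$params[[nm]]), min(6, length(m$params[[nm]])))
    for (j in idx) {
      p1 <- m$params; p1[[nm]][j] <- p1[[nm]][j] + eps
      p2 <- m$params; p2[[nm]][j] <- p2[[nm]][j] - eps
      num <- (dealerscan:::cpp_deep_grad(p1, Xt, Xh, y, 0, 0, 1L)$loss -
              dealerscan:::cpp_deep_grad(p2, Xt, Xh, y, 0, 0, 1L)$loss) /
        (2 * eps)
      expect_lt(abs(num - G[j]), 1e-7)
    }
  }
})

test_that("the early-stopping rule fires exactly per its definition", {
  hist <- c(0.9, 0.5, 0.4, 0.45, 0.43, 0.95)
  # never fires before the final epoch, fires at epoch 6
  for (e in 1:5) expect_false(early_stop_check(hist[1:e], window = 4))
  expect_true(early_stop_check(hist, window = 4))
  # monotone decreasing never fires
  dec <- seq(1, 0.1, length.out = 30)
  for (e in seq_along(dec)) {
    expect_false(early_stop_check(dec[1:e], window = 4))
  }
  # a spike must exceed ALL of the previous `window` losses, not just some
  expect_false(early_stop_check(c(0.9, 0.5, 0.4, 0.45, 0.43, 0.48),
                                window = 4))  # 0.48 < 0.5
})

test_that("training reduces loss on a separable corpus, reproducibly", {
  corpus <- separable_clean_corpus(200, seed = 6)
  vocab <- build_vocabulary(corpus)
  cfg <- model_config(l_text = 8, l_hash = 2, desk_scale = TRUE, seed = 5,
                      max_epochs = 6)
  enc <- encode_clean(corpus, vocab, cfg)
  set.seed(2)
  val_idx <- sample(200, 50)
  tr <- dealerscan:::subset_encoded(enc, setdiff(1:200, val_idx))
  va <- dealerscan:::subset_encoded(enc, val_idx)
  net <- build_deep_model(cfg, vocab$size + 1L)
  fit1 <- train_deep(net, tr, va)
  expect_true(fit1$trained)
  expect_equal(fit1$state$epochs, length(fit1$state$val_loss))
  expect_lt(tail(fit1$state$train_loss, 1), fit1$state$train_loss[1])
  # same seed, same everything
  fit2 <- train_deep(build_deep_model(cfg, vocab$size + 1L), tr, va)
  expect_identical(fit1$params, fit2$params)
  expect_identical(predict(fit1, va), predict(fit2, va))
  # guards
  empty <- dealerscan:::subset_encoded(enc, integer())
  expect_error(train_deep(net, empty, va), "non-empty")
  expect_error(train_deep(net, tr, tr), "disjoint")
})

test_that("prediction thresholds strictly above the decision threshold", {
  corpus <- separable_clean_corpus(60, seed = 8)
  vocab <- build_vocabulary(corpus)
  cfg <- model_config(l_text = 8, l_hash = 2, desk_scale = TRUE, seed = 5,
                      max_epochs = 2)
  enc <- encode_clean(corpus, vocab, cfg)
  tr <- dealerscan:::subset_encoded(enc, 1:40)
  va <- dealerscan:::subset_encoded(enc, 41:60)
  net <- train_deep(build_deep_model(cfg, vocab$size + 1L), tr, va)
  out <- predict(net, va)
  # vectorized labels equal the scalar thresholding rule
  expect_equal(out$label,
               vapply(out$prob, function(p) as.integer(p > 0.5), integer(1)))
  # p exactly at the threshold is class 0 by the strict rule
  expect_equal(as.integer(0.5 > 0.5), 0L)
  bad <- va
  bad$text <- bad$text[, 1:3, drop = FALSE]
  expect_error(predict(net, bad), "do not match")
})

test_that("checkpoints restore predictions exactly", {
  corpus <- separable_clean_corpus(50, seed = 9)
  vocab <- build_vocabulary(corpus)
  cfg <- model_config(l_text = 8, l_hash = 2, desk_scale = TRUE, seed = 4,
                      max_epochs = 2)
  enc <- encode_clean(corpus, vocab, cfg)
  tr <- dealerscan:::subset_encoded(enc, 1:35)
  va <- dealerscan:::subset_encoded(enc, 36:50)
  net <- train_deep(build_deep_model(cfg, vocab$size + 1L), tr, va)
  dir <- withr::local_tempdir()
  save_model(net, dir)
  back <- load_model(dir)
  expect_equal(predict(back, va), predict(net, va), tolerance = 1e-12)
})

test_that("baselines separate a trivially separable feature space", {
  # feature A perfectly separates the classes
  x <- cbind(A = rep(c(1, 0), each = 20), B = runif(40))
  y <- rep(c(1, 0), each = 20)
  dt <- train_baseline("decision_tree", x, y, seed = 1)
  expect_equal(predict(dt, x)$label, y)
  svm <- train_baseline("svm", rbind(c(0, 0), c(1, 1)), c(0, 1), seed = 1)
  expect_equal(predict(svm, rbind(c(0, 0), c(1, 1)))$label, c(0L, 1L))
  expect_error(train_baseline("boost", x, y), "arg")

  # a single-tree forest grown on the full sample without bootstrap
  # agrees with the CART tree on separable data
  rf1 <- train_baseline("random_forest", x, y, seed = 1, ntree = 1,
                        mtry = ncol(x), replace = FALSE,
                        sampsize = nrow(x))
  expect_equal(predict(rf1, x)$label, predict(dt, x)$label)

  # probabilities are exposed for every model (AUC computable)
  for (m in list(dt, svm, rf1)) {
    pr <- predict(m, x)$prob
    expect_true(all(pr >= 0 & pr <= 1))
  }
})
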