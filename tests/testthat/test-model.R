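test_that("step-1 training separates separable labels and refuses single-class data", {
  set.seed(21)
  n <- 400
  X <- cbind(sig = c(runif(n / 2, 0, 0.4), runif(n / 2, 0.6, 1)),
             noise = runif(n))
  y <- rep(c(0, 1), each = n / 2)
  tr <- list(X = X, y = y)
  m <- train_step1(tr, default_model_params(nrounds = 40, max_depth = 3), seed = 1)
  acc <- mean((predict_step(m, X) > 0.5) == y)
  expect_gte(acc, 0.99)
  expect_error(train_step1(list(X = X, y = rep(1, n)),
                           default_model_params(nrounds = 5)), "single class")
})

test_that("pure-noise labels give chance-level held-out discrimination", {
  set.seed(33)
  n <- 2000
  X <- matrix(runif(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- rbinom(n, 1, 0.5)
  half <- seq_len(n / 2)
  m <- train_step1(list(X = X[half, ], y = y[half]),
                   default_model_params(nrounds = 40, max_depth = 3), seed = 2)
  auc <- roc_auc(predict_step(m, X[-half, ]), y[-half])
  expect_lt(abs(auc - 0.5), 0.08)
})

test_that("training is reproducible and independent of complex input order", {
  enc <- shared_encoded()[1:3]
  p <- toy_params(nrounds = 10L, nfold = 2L)
  m1 <- train_two_step(enc, params = p, seed = 4)
  m2 <- train_two_step(enc, params = p, seed = 4)
  m3 <- train_two_step(rev(enc), params = p, seed = 4)
  probe <- shared_encoded()[[4]]
  p1 <- predict_complex(m1, probe)$step2
  expect_equal(predict_complex(m2, probe)$step2, p1, tolerance = 1e-9)
  expect_equal(predict_complex(m3, probe)$step2, p1, tolerance = 1e-9)
})

test_that("step-2 augmentation appends the step-1 score plus 12 environment values in structural mode", {
  enc <- shared_encoded()[1:2]
  tr <- build_training_set(enc, seed = 1)
  fake <- lapply(enc, function(e) {
    na <- nrow(e$blocks_a); nb <- nrow(e$blocks_b)
    matrix(runif(na * nb), na, nb)
  })
  names(fake) <- vapply(enc, `[[`, character(1), "complex_id")
  tr2 <- augment_step2(tr, fake, enc)
  expect_equal(ncol(tr2$X), ncol(tr$X) + 13L)
  expect_error(augment_step2(tr, fake[1], enc), "missing step-1 scores")
  # constant score matrix: appended score column is constant
  const <- lapply(fake, function(m) matrix(0.5, nrow(m), ncol(m)))
  tr3 <- augment_step2(tr, const, enc)
  expect_true(all(tr3$X[, "step1.score"] == 0.5))
})

test_that("sequence-mode augmentation appends the step-1 score only", {
  enc_seq <- load_benchmark(shared_benchmark_dir(), mode = "sequence")[1:2]
  expect_equal(enc_seq[[1]]$mode, "sequence")
  expect_null(enc_seq[[1]]$graph_a)
  tr <- build_training_set(enc_seq, seed = 1)
  fake <- lapply(enc_seq, function(e)
    matrix(runif(nrow(e$blocks_a) * nrow(e$blocks_b)),
           nrow(e$blocks_a), nrow(e$blocks_b)))
  names(fake) <- vapply(enc_seq, `[[`, character(1), "complex_id")
  tr2 <- augment_step2(tr, fake, enc_seq)
  expect_equal(ncol(tr2$X), ncol(tr$X) + 1L)
  # the sequence block carries no structural columns
  expect_false(any(grepl("^ss\\.|^acc\\.|^hse\\.|^venv\\.", colnames(enc_seq[[1]]$blocks_a))))
})

test_that("end-to-end prediction is exactly symmetric under chain-order swap", {
  model <- shared_small_model()
  for (enc in shared_encoded()[5:6]) {
    pred <- predict_complex(model, enc)
    expect_true(all(pred$step2 >= 0 & pred$step2 <= 1))
    expect_equal(dim(pred$step2), c(nrow(enc$blocks_a), nrow(enc$blocks_b)))
    swapped <- enc
    swapped$blocks_a <- enc$blocks_b; swapped$blocks_b <- enc$blocks_a
    swapped$graph_a <- enc$graph_b; swapped$graph_b <- enc$graph_a
    swapped$contacts$labels <- t(enc$contacts$labels)
    swapped$pair <- pairsite:::swap_pair(enc$pair)
    pred_sw <- predict_complex(model, swapped)
    expect_identical(pred_sw$step2, t(pred$step2))
    expect_identical(pred_sw$step1, t(pred$step1))
  }
})

test_that("feature importance shares sum to one and find the informative family", {
  set.seed(8)
  n <- 600
  X <- cbind(matrix(runif(n * 3), n, 3), runif(n))
  colnames(X) <- c("good.a", "good.b", "junk.a", "junk.b")
  y <- as.numeric(X[, "good.a"] > 0.5)
  m <- train_step1(list(X = X, y = y),
                   default_model_params(nrounds = 20, max_depth = 3), seed = 3)
  imp <- feature_importance(m)
  expect_equal(sum(imp), 1, tolerance = 1e-9)
  expect_equal(names(imp)[1], "good")
  expect_setequal(names(imp), c("good", "junk"))
})
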