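test_that("rank ROC-AUC matches an independent reference implementation to 1e-12", {
  set.seed(19)
  for (k in 1:10) {
    n <- 150
    s <- runif(n)
    if (k %% 2 == 0) s <- round(s, 1)  # introduce ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<", levels = c(0, 1))))
    expect_equal(roc_auc(s, y), ref, tolerance = 1e-12)
  }
  expect_equal(roc_auc(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1.0)
  expect_error(roc_auc(runif(5), rep(1, 5)), "single-class")
})

test_that("random scores give chance-level AUC and prevalence-level PR-AUC", {
  set.seed(29)
  n <- 2000
  s <- runif(n); y <- rbinom(n, 1, 0.15)
  expect_lt(abs(roc_auc(s, y) - 0.5), 0.04)
  expect_lt(abs(pr_auc(s, y) - mean(y)), 0.04)
})

test_that("threshold metric suite recovers closed-form confusion values", {
  m <- compute_metrics(c(0.9, 0.8, 0.1), c(1, 1, 0))
  expect_equal(m$roc_auc, 1.0)
  expect_equal(m$mcc, 1.0)
  expect_equal(m$precision, 1.0)
  expect_equal(m$recall, 1.0)
  expect_equal(m$specificity, 1.0)
  # MCC of confusion (TP=2, FP=0, TN=1, FN=0) is exactly 1
  expect_equal(pairsite:::.mcc(2, 0, 1, 0), 1.0)
  # max-MCC ties resolve to the lowest threshold
  m2 <- compute_metrics(c(0.2, 0.4, 0.6, 0.8), c(0, 0, 1, 1))
  expect_equal(m2$threshold, 0.6)
  expect_error(compute_metrics(runif(4), rep(0, 4)), "single-class")
})

test_that("Mann-Whitney U has the exact small-sample behavior and the U identity", {
  # identical samples: U = nm/2 and the test is maximally non-significant
  r <- mann_whitney_u(1:5, 1:5)
  expect_equal(r$U, 12.5)
  expect_equal(r$p_value, 1)
  # complete separation at n = m = 3: exact two-sided p = 2/20
  r2 <- mann_whitney_u(c(10, 11, 12), c(1, 2, 3))
  expect_equal(r2$U, 9)
  expect_equal(r2$p_value, 0.1)
  # U(x, y) + U(y, x) = nm
  set.seed(13)
  x <- runif(6); y <- runif(8)
  expect_equal(mann_whitney_u(x, y)$U + mann_whitney_u(y, x)$U, 48)
  expect_error(mann_whitney_u(numeric(0), 1:3), "empty group")
})

test_that("the large-sample normal approximation agrees with the reference test", {
  set.seed(37)
  x <- rnorm(30); y <- rnorm(35, 0.5)
  got <- mann_whitney_u(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(got$U + length(x) * length(y) - got$U, 30 * 35)
  # pooled ROC-AUC equals the Mann-Whitney rank formulation
  s <- c(x, y); lab <- rep(c(1, 0), c(30, 35))
  expect_equal(roc_auc(s, lab), mann_whitney_u(x, y)$U / (30 * 35),
               tolerance = 1e-12)
})

test_that("leave-one-out trains without the held-out complex and flags degenerate inputs", {
  enc <- shared_encoded()[1:4]
  loo <- loo_cv(enc, params = toy_params(nrounds = 8L, nfold = 2L), seed = 2)
  expect_s3_class(loo, "ps_loo")
  expect_equal(length(loo), 4L)
  for (k in seq_along(enc)) {
    r <- loo[[k]]
    expect_equal(dim(r$step2), dim(enc[[k]]$contacts$labels))  # full, unsampled
    expect_equal(r$complex_id, enc[[k]]$complex_id)
  }
  expect_error(loo_cv(enc[1], params = toy_params()), ">= 2 complexes")
  # duplicated complexes leak by construction: held-out AUC near-perfect
  dup <- enc[c(1, 1, 2)]
  dup[[2]]$complex_id <- "dup-copy"
  dup[[2]]$pair$complex_id <- "dup-copy"
  dup[[2]]$contacts$complex_id <- "dup-copy"
  loo2 <- loo_cv(dup, params = toy_params(nrounds = 20L, nfold = 2L), seed = 3)
  auc <- roc_auc(as.vector(loo2[[1]]$step2), as.vector(loo2[[1]]$pair_labels))
  expect_gt(auc, 0.95)
})

test_that("evaluation reports pool and average AUCs over complexes", {
  enc <- shared_encoded()[1:4]
  loo <- loo_cv(enc, params = toy_params(nrounds = 8L, nfold = 2L), seed = 2)
  rep <- evaluation_report(loo)
  all_aucs <- c(rep$pairs$step1$roc_auc, rep$pairs$step2$roc_auc,
                rep$site$step2_smoothed$roc_auc, rep$site$max_baseline$roc_auc)
  expect_true(all(all_aucs >= 0 & all_aucs <= 1))
  expect_true(rep$site_threshold_metrics$mcc >= -1 &&
              rep$site_threshold_metrics$mcc <= 1)
  expect_equal(length(rep$pairs$per_complex_step2), 4L)
  # pooled pair AUC recomputable from the per-complex matrices
  pool_s <- unlist(lapply(loo, function(r) as.vector(r$step2)))
  pool_l <- unlist(lapply(loo, function(r) as.vector(r$pair_labels)))
  expect_equal(rep$pairs$step2$roc_auc, roc_auc(pool_s, pool_l))
})
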