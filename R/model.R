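# Two-step stacked gradient-boosted tree classifier over encoded residue
# pairs.  Step 1 scores pairs from the encoded features; step 2 re-scores
# them from the same features plus the step-1 scores and their structural
# pairwise environments.  Step-1 scores fed to step-2 during training come
# from K-fold out-of-fold prediction over complexes to avoid leakage.

#' Default boosted-tree hyperparameters
#'
#' @param ... Overrides (e.g. `nrounds = 60`).
#' @return Named list with `max_depth`, `eta`, `nrounds`, `subsample`,
#'   `nthread`, `nfold` (out-of-fold splits for stacking).
#' @export
default_model_params <- function(...) {
  p <- list(max_depth = 6L, eta = 0.1, nrounds = 500L, subsample = 1,
            nthread = 1L, nfold = 5L)
  over <- list(...)
  p[names(over)] <- over
  p
}

#' Build a sampled, symmetric training set from encoded complexes
#'
#' Enumerates cross-chain pairs per complex, applies per-complex negative
#' sampling, and emits both the AB and BA ordering of every sampled pair.
#' Rows are sorted canonically (complex, ordering, i, j) so the training
#' matrix is independent of input order.
#'
#' @param encoded_list List of `ps_encoded` complexes (see
#'   [encode_complex()]).
#' @param ratio Negatives per positive (default 3).
#' @param seed Sampling seed.
#' @return List with feature matrix `X`, numeric labels `y`, and `meta`
#'   data frame (`complex_id`, `i`, `j`, `ordering`).
#' @export
build_training_set <- function(encoded_list, ratio = 3, seed = 1L) {
  all_pairs <- do.call(rbind, lapply(encoded_list, function(enc) {
    if (is.null(enc$contacts)) stop("training requires structural contact labels")
    enumerate_pairs(enc$pair, enc$contacts)
  }))
  sampled <- sample_negatives(all_pairs, ratio = ratio, seed = seed)
  sampled <- sampled[order(sampled$complex_id, sampled$i, sampled$j), , drop = FALSE]
  by_cx <- split(sampled, sampled$complex_id)
  enc_by_id <- setNames(encoded_list,
                        vapply(encoded_list, `[[`, character(1), "complex_id"))
  rows <- lapply(by_cx, function(df) {
    enc <- enc_by_id[[df$complex_id[1]]]
    idx <- as.matrix(df[, c("i", "j")])
    list(ab = pair_feature_matrix(enc, idx, "A"),
         ba = pair_feature_matrix(enc, idx, "B"),
         df = df)
  })
  X <- do.call(rbind, unlist(lapply(rows, function(r) list(r$ab, r$ba)),
                             recursive = FALSE))
  meta <- do.call(rbind, lapply(rows, function(r)
    rbind(cbind(r$df, ordering = "AB"), cbind(r$df, ordering = "BA"))))
  rownames(meta) <- NULL
  list(X = X, y = as.numeric(meta$label), meta = meta)
}

# fit one boosted-tree step
.fit_xgb <- function(X, y, params, seed, step) {
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  .with_seed(seed, {
    booster <- xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = params$max_depth, eta = params$eta,
                    subsample = params$subsample, nthread = params$nthread,
                    seed = seed),
      data = xgboost::xgb.DMatrix(X, label = y),
      nrounds = params$nrounds, verbose = 0)
  })
  structure(list(step = step, booster = booster,
                 feature_names = colnames(X), params = params, seed = seed),
            class = "ps_trained_step")
}

#' Train the step-1 pair classifier
#'
#' @param training Output of [build_training_set()].
#' @param params Hyperparameters from [default_model_params()].
#' @param seed Integer seed (also fixes xgboost's RNG).
#' @return A `ps_trained_step` (opaque booster handle plus feature layout).
#' @export
train_step1 <- function(training, params = default_model_params(), seed = 1L) {
  .fit_xgb(training$X, training$y, params, seed, step = 1L)
}

#' Score a feature matrix with a trained step
#'
#' Columns are matched to the step's training layout by name.
#'
#' @param step A `ps_trained_step`.
#' @param X Feature matrix.
#' @return Numeric scores in `[0, 1]`.
#' @export
predict_step <- function(step, X) {
  if (!identical(colnames(X), step$feature_names)) {
    if (!all(step$feature_names %in% colnames(X)))
      stop("feature matrix does not match the model's feature layout")
    X <- X[, step$feature_names, drop = FALSE]
  }
  predict(step$booster, xgboost::xgb.DMatrix(X))
}

# symmetry-averaged all-pairs score matrix for one encoded complex
.predict_matrix <- function(step, encoded, augment_with = NULL) {
  na <- nrow(encoded$blocks_a); nb <- nrow(encoded$blocks_b)
  idx <- cbind(i = rep(seq_len(na), times = nb), j = rep(seq_len(nb), each = na))
  Xab <- pair_feature_matrix(encoded, idx, "A")
  Xba <- pair_feature_matrix(encoded, idx, "B")
  if (!is.null(augment_with)) {
    Xab <- cbind(Xab, augment_with$ab)
    Xba <- cbind(Xba, augment_with$ba)
  }
  ab <- matrix(predict_step(step, Xab), na, nb)
  ba <- t(matrix(predict_step(step, Xba), na, nb))  # BA rows in (i,j) order
  symmetrize(ab, ba)
}

#' Step-1 score matrix for a complex
#'
#' Scores all cross-chain pairs in both orderings and symmetry-averages.
#'
#' @param step1 Trained step-1 model.
#' @param encoded A `ps_encoded` complex.
#' @return Numeric matrix `len(A) x len(B)`.
#' @export
predict_step1_matrix <- function(step1, encoded) .predict_matrix(step1, encoded)

# step-2 augmentation columns for given pair indices from a step-1 score
# matrix: the (symmetrized) score plus its 12 pairwise environment values in
# structural mode, score only in sequence mode.  Returns ab/ba blocks (the
# BA block swaps the i-side and j-side environment aggregates).
.augment_columns <- function(encoded, idx, score_matrix) {
  s <- score_matrix[idx]
  if (encoded$mode != "structural") {
    ab <- cbind(step1.score = s)
    return(list(ab = ab, ba = ab))
  }
  penv <- pairwise_env_matrix(score_matrix, idx, encoded$graph_a, encoded$graph_b)
  colnames(penv) <- paste0("step1.", PAIRWISE_ENV_NAMES)
  ab <- cbind(step1.score = s, penv)
  ba <- ab[, c(1, 6:9, 2:5, 10:13), drop = FALSE]  # swap dot_j and i_dot blocks
  colnames(ba) <- colnames(ab)
  list(ab = ab, ba = ba)
}

#' Augment a training set with step-1 scores and their environments
#'
#' Appends to every pair row its out-of-fold step-1 score and, in structural
#' mode, the 12 structural pairwise environment values of that score.
#'
#' @param training Output of [build_training_set()].
#' @param score_matrices Named list (by complex id) of step-1 score matrices.
#' @param encoded_list The encoded complexes (for graphs and mode).
#' @return Training list with the augmented `X`.
#' @export
augment_step2 <- function(training, score_matrices, encoded_list) {
  enc_by_id <- setNames(encoded_list,
                        vapply(encoded_list, `[[`, character(1), "complex_id"))
  miss <- setdiff(unique(training$meta$complex_id), names(score_matrices))
  if (length(miss))
    stop(sprintf("missing step-1 scores for complex %s", miss[1]))
  n <- nrow(training$X)
  aug <- NULL
  for (cx in unique(training$meta$complex_id)) {
    enc <- enc_by_id[[cx]]
    S <- score_matrices[[cx]]
    for (ord in c("AB", "BA")) {
      sel <- which(training$meta$complex_id == cx & training$meta$ordering == ord)
      if (!length(sel)) next
      idx <- as.matrix(training$meta[sel, c("i", "j")])
      cols <- .augment_columns(enc, idx, S)
      block <- if (ord == "AB") cols$ab else cols$ba
      if (is.null(aug)) aug <- matrix(0, n, ncol(block),
                                      dimnames = list(NULL, colnames(block)))
      aug[sel, ] <- block
    }
  }
  training$X <- cbind(training$X, aug)
  training
}

# deterministic fold assignment over sorted complex ids
.complex_folds <- function(ids, nfold) {
  ids <- sort(unique(ids))
  setNames((seq_along(ids) - 1L) %% nfold + 1L, ids)
}

# K-fold out-of-fold step-1 score matrices for every training complex
.oof_step1_matrices <- function(encoded_list, training, params, seed) {
  ids <- vapply(encoded_list, `[[`, character(1), "complex_id")
  nfold <- min(params$nfold, length(ids))
  folds <- .complex_folds(ids, nfold)
  out <- list()
  for (f in seq_len(nfold)) {
    hold <- names(folds)[folds == f]
    keep <- !(training$meta$complex_id %in% hold)
    sub <- list(X = training$X[keep, , drop = FALSE], y = training$y[keep])
    m <- .fit_xgb(sub$X, sub$y, params, seed + f, step = 1L)
    for (cx in hold)
      out[[cx]] <- predict_step1_matrix(m, encoded_list[[which(ids == cx)]])
  }
  out
}

#' Train the full two-step model over a set of complexes
#'
#' Builds the sampled symmetric training set, fits step 1, produces K-fold
#' out-of-fold step-1 score matrices for every training complex, augments the
#' rows with those scores and their pairwise environments, and fits step 2.
#' Optionally fits the isotonic expected-precision calibration on
#' out-of-fold binding-site scores.
#'
#' @param encoded_list List of `ps_encoded` complexes.
#' @param params Hyperparameters ([default_model_params()]).
#' @param seed Integer seed controlling sampling, folds and boosters.
#' @param ratio Negatives per positive.
#' @param calibrate Fit the isotonic calibration map (default `FALSE`; used
#'   by [cmd_train()]).
#' @return An object of class `ps_model` with `step1`, `step2`, `mode`, and
#'   optionally `calibration`.
#' @export
train_two_step <- function(encoded_list, params = default_model_params(),
                           seed = 1L, ratio = 3, calibrate = FALSE) {
  training <- build_training_set(encoded_list, ratio = ratio, seed = seed)
  step1 <- train_step1(training, params, seed)
  oof <- .oof_step1_matrices(encoded_list, training, params, seed)
  training2 <- augment_step2(training, oof, encoded_list)
  step2 <- .fit_xgb(training2$X, training2$y, params, seed, step = 2L)
  model <- structure(list(step1 = step1, step2 = step2,
                          mode = encoded_list[[1]]$mode,
                          params = params, seed = seed, ratio = ratio),
                     class = "ps_model")
  if (calibrate)
    model$calibration <- .fit_oof_calibration(model, encoded_list, training,
                                              training2, oof, params, seed)
  model
}

# isotonic calibration fit on out-of-fold step-2 binding-site scores
.fit_oof_calibration <- function(model, encoded_list, training, training2,
                                 oof, params, seed) {
  ids <- vapply(encoded_list, `[[`, character(1), "complex_id")
  nfold <- min(params$nfold, length(ids))
  folds <- .complex_folds(ids, nfold)
  scores <- numeric(0); labels <- integer(0)
  for (f in seq_len(nfold)) {
    hold <- names(folds)[folds == f]
    keep <- !(training2$meta$complex_id %in% hold)
    m2 <- .fit_xgb(training2$X[keep, , drop = FALSE], training2$y[keep],
                   params, seed + 100 + f, step = 2L)
    for (cx in hold) {
      enc <- encoded_list[[which(ids == cx)]]
      S2 <- .predict_step2_matrix(model$step1, m2, enc)
      prof <- binding_site_scores(S2)
      sm <- c(smooth_profile(prof$a), smooth_profile(prof$b))
      lab <- c(as.integer(rowSums(enc$contacts$labels) > 0),
               as.integer(colSums(enc$contacts$labels) > 0))
      scores <- c(scores, sm); labels <- c(labels, lab)
    }
  }
  fit_calibration(scores, labels)
}

# full pipeline score matrix given both steps
.predict_step2_matrix <- function(step1, step2, encoded) {
  S1 <- predict_step1_matrix(step1, encoded)
  na <- nrow(S1); nb <- ncol(S1)
  idx <- cbind(i = rep(seq_len(na), times = nb), j = rep(seq_len(nb), each = na))
  aug <- .augment_columns(encoded, idx, S1)
  .predict_matrix(step2, encoded, augment_with = aug)
}

#' End-to-end pair score prediction for one complex
#'
#' Runs encode, step 1, symmetrization, pairwise environments, step 2 and a
#' final symmetrization; every cross-chain pair is scored (no sampling).
#'
#' @param model A `ps_model` from [train_two_step()].
#' @param encoded A `ps_encoded` complex (must match the model's mode).
#' @return List with `step1` and `step2` score matrices (`len(A) x len(B)`).
#' @export
predict_complex <- function(model, encoded) {
  if (!identical(model$mode, encoded$mode))
    stop(sprintf("model mode '%s' does not match input mode '%s'",
                 model$mode, encoded$mode))
  S1 <- predict_step1_matrix(model$step1, encoded)
  na <- nrow(S1); nb <- ncol(S1)
  idx <- cbind(i = rep(seq_len(na), times = nb), j = rep(seq_len(nb), each = na))
  aug <- .augment_columns(encoded, idx, S1)
  S2 <- .predict_matrix(model$step2, encoded, augment_with = aug)
  list(step1 = S1, step2 = S2)
}

# default feature-family extraction from a column name
.feature_family <- function(name) {
  nm <- sub("^r[12]\\.", "", name)
  nm <- sub("^venv\\.", "", nm)
  sub("\\..*$", "", nm)
}

#' Per-family split-count importance shares
#'
#' Importance of a feature is its share of the total number of tree splits in
#' the ensemble; features are grouped into families (identity, profile,
#' conservation, secondary structure, accessibility, exposure, geometry,
#' step-1 scores) and shares are summed per family.  Unused features
#' contribute zero.  Shares sum to 1.
#'
#' @param step A `ps_trained_step`.
#' @param family_map Optional named character vector mapping feature names to
#'   family labels; defaults to the prefix before the first dot (ignoring the
#'   residue-slot and environment prefixes).
#' @return Named numeric vector of family shares, decreasing.
#' @export
feature_importance <- function(step, family_map = NULL) {
  imp <- xgboost::xgb.importance(model = step$booster)
  share <- setNames(rep(0, length(step$feature_names)), step$feature_names)
  share[imp$Feature] <- imp$Frequency
  fam <- if (is.null(family_map)) {
    vapply(names(share), .feature_family, character(1))
  } else family_map[names(share)]
  out <- tapply(share, fam, sum)
  sort(out / sum(out), decreasing = TRUE)
}
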