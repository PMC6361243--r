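# Leave-one-out evaluation over complexes: pair- and residue-level metric
# suite and the partner-specificity Mann-Whitney test.

#' Rank-based ROC-AUC
#'
#' Computed via the Mann-Whitney rank statistic with midranks for ties.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (logical or 0/1).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("ROC-AUC undefined: single-class labels")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Precision-recall AUC
#'
#' Step-wise interpolation over the full recall range: thresholds sweep the
#' distinct score values from high to low, and each recall increment
#' contributes `delta_recall x precision` at that threshold (tied scores are
#' processed as one block).
#'
#' @inheritParams roc_auc
#' @return PR-AUC in `[0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  if (n1 == 0L || all(labels)) stop("PR-AUC undefined: single-class labels")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  block_end <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie block
  tp <- cumsum(y)[block_end]
  fp <- cumsum(!y)[block_end]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

# Matthews correlation coefficient from confusion counts
.mcc <- function(tp, fp, tn, fn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' Threshold metric suite at the MCC-maximizing threshold
#'
#' Scans every distinct score value as a threshold (predict positive when
#' `score >= t`), picks the threshold maximizing the Matthews correlation
#' coefficient (ties resolved to the lowest threshold), and reports MCC,
#' precision, recall, specificity and negative predictive value there,
#' together with ROC-AUC and PR-AUC.
#'
#' @inheritParams roc_auc
#' @return List with `roc_auc`, `pr_auc`, `mcc`, `precision`, `recall`,
#'   `specificity`, `npv`, `threshold`.
#' @export
compute_metrics <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L) stop("metrics undefined: single-class labels")
  ths <- sort(unique(scores))
  best <- NULL
  for (t in ths) {
    pred <- scores >= t
    tp <- sum(pred & labels); fp <- sum(pred & !labels)
    tn <- sum(!pred & !labels); fn <- sum(!pred & labels)
    m <- .mcc(tp, fp, tn, fn)
    if (is.null(best) || m > best$mcc + 1e-15) {
      best <- list(mcc = m, threshold = t,
                   precision = if (tp + fp > 0) tp / (tp + fp) else 0,
                   recall = tp / (tp + fn),
                   specificity = tn / (tn + fp),
                   npv = if (tn + fn > 0) tn / (tn + fn) else 0)
    }
  }
  c(list(roc_auc = roc_auc(scores, labels), pr_auc = pr_auc(scores, labels)),
    best)
}

#' Mann-Whitney U test
#'
#' Two-sided test of the null that both samples come from the same
#' distribution.  When both samples have at most 8 observations the p-value
#' is computed by exact enumeration of all group assignments of the pooled
#' values (valid under ties); otherwise by the normal approximation with tie
#' correction.
#'
#' @param x,y Numeric samples.
#' @return List with `U` (statistic of `x`), `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("empty group in Mann-Whitney test")
  n <- length(x); m <- length(y)
  ustat <- function(xv, yv) {
    sum(outer(xv, yv, ">")) + 0.5 * sum(outer(xv, yv, "=="))
  }
  U <- ustat(x, y)
  mu <- n * m / 2
  if (n <= 8L && m <= 8L) {
    pool <- c(x, y)
    picks <- combn(n + m, n)
    us <- apply(picks, 2, function(ix) ustat(pool[ix], pool[-ix]))
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    r <- rank(c(x, y))
    ties <- table(r)
    N <- n + m
    sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (U - mu) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation with tie correction"
  }
  list(U = U, p_value = min(p, 1), method = method)
}

#' Leave-one-out cross-validation over complexes
#'
#' For each complex, the two-step model is trained on the sampled pairs of
#' all other complexes and the left-out complex is scored in full (no
#' sampling).  Binding-site profiles (rank-based raw and smoothed, plus the
#' maximum-score baseline) are derived from both the step-1 and step-2
#' score matrices.
#'
#' @param encoded_list List of `ps_encoded` complexes (>= 2).
#' @param params Model hyperparameters ([default_model_params()]).
#' @param seed Integer seed.
#' @param ratio Negatives per positive.
#' @return An object of class `ps_loo`: per-complex list with score matrices,
#'   site profiles and residue interface labels.
#' @export
loo_cv <- function(encoded_list, params = default_model_params(), seed = 1L,
                   ratio = 3) {
  if (length(encoded_list) < 2L) stop("leave-one-out requires >= 2 complexes")
  ids <- vapply(encoded_list, `[[`, character(1), "complex_id")
  results <- vector("list", length(encoded_list))
  names(results) <- ids
  for (k in seq_along(encoded_list)) {
    model <- train_two_step(encoded_list[-k], params = params, seed = seed,
                            ratio = ratio)
    enc <- encoded_list[[k]]
    pred <- predict_complex(model, enc)
    site <- function(S) {
      bs <- binding_site_scores(S)
      mx <- max_score_baseline(S)
      list(raw = bs, smoothed = list(a = smooth_profile(bs$a),
                                     b = smooth_profile(bs$b)),
           max_baseline = mx)
    }
    lab <- enc$contacts$labels
    results[[k]] <- list(
      complex_id = enc$complex_id,
      pair_labels = lab,
      site_labels = list(a = rowSums(lab) > 0, b = colSums(lab) > 0),
      step1 = pred$step1, step2 = pred$step2,
      site_step1 = site(pred$step1), site_step2 = site(pred$step2),
      sequences = list(a = chain_sequence(enc$pair$chain_a),
                       b = chain_sequence(enc$pair$chain_b)))
  }
  structure(results, class = "ps_loo")
}

# pooled and per-complex-averaged AUCs over a list of (scores, labels) units;
# single-class units are skipped from the average but kept in the pool
.pooled_metrics <- function(units) {
  pool_s <- unlist(lapply(units, `[[`, "scores"))
  pool_l <- unlist(lapply(units, `[[`, "labels"))
  per <- vapply(units, function(u) {
    if (length(unique(as.logical(u$labels))) < 2L) return(NA_real_)
    roc_auc(u$scores, u$labels)
  }, numeric(1))
  list(avg_roc_auc = mean(per, na.rm = TRUE),
       roc_auc = roc_auc(pool_s, pool_l),
       pr_auc = pr_auc(pool_s, pool_l),
       per_complex = per,
       pooled = list(scores = pool_s, labels = pool_l))
}

#' Metric report of a leave-one-out run
#'
#' Mirrors the evaluation suite used for pair predictors: averaged and
#' pooled ROC-AUC plus pooled PR-AUC for residue-residue contact prediction,
#' the same AUCs for binding-site prediction (rank-based smoothed scores,
#' for both steps, and the maximum-score baseline), and MCC, precision,
#' recall, specificity and NPV at the MCC-maximizing threshold of the pooled
#' binding-site scores.
#'
#' @param loo A `ps_loo` object.
#' @return Nested list of metrics.
#' @export
evaluation_report <- function(loo) {
  pair_units <- function(which) lapply(loo, function(r)
    list(scores = as.vector(r[[which]]), labels = as.vector(r$pair_labels)))
  site_units <- function(extract) lapply(loo, function(r)
    list(scores = c(extract(r)$a, extract(r)$b),
         labels = c(r$site_labels$a, r$site_labels$b)))
  pairs1 <- .pooled_metrics(pair_units("step1"))
  pairs2 <- .pooled_metrics(pair_units("step2"))
  site1 <- .pooled_metrics(site_units(function(r) r$site_step1$smoothed))
  site2 <- .pooled_metrics(site_units(function(r) r$site_step2$smoothed))
  site2_raw <- .pooled_metrics(site_units(function(r) r$site_step2$raw))
  site_max <- .pooled_metrics(site_units(function(r) r$site_step2$max_baseline))
  thr <- compute_metrics(site2$pooled$scores, site2$pooled$labels)
  strip <- function(x) x[setdiff(names(x), c("pooled", "per_complex"))]
  list(pairs = list(step1 = strip(pairs1), step2 = strip(pairs2),
                    per_complex_step2 = pairs2$per_complex),
       site = list(step1_smoothed = strip(site1),
                   step2_smoothed = strip(site2),
                   step2_raw = strip(site2_raw),
                   max_baseline = strip(site_max)),
       site_threshold_metrics = thr)
}

#' Partner-specificity analysis of a leave-one-out run
#'
#' Identifies proteins that occur (sequence identity > `identity`) in at
#' least two complexes, collects for each interaction the smoothed
#' binding-site scores of its own interface residues (specific distribution)
#' and the scores, under the same prediction, of residues that are interface
#' residues only in the protein's other interactions (non-specific
#' distribution), pools both across proteins and compares them with the
#' Mann-Whitney U test.
#'
#' @param loo A `ps_loo` object.
#' @param identity Sequence-identity threshold for treating two chains as
#'   the same protein (default 0.9, computed by global alignment).
#' @return List with the pooled score groups and the test result.
#' @export
partner_specificity_analysis <- function(loo, identity = 0.9) {
  chains <- do.call(rbind, lapply(loo, function(r) data.frame(
    complex_id = r$complex_id, side = c("a", "b"),
    seq = c(r$sequences$a, r$sequences$b))))
  n <- nrow(chains)
  # group chains by >identity global-alignment sequence identity (union-find)
  grp <- seq_len(n)
  find <- function(i) { while (grp[i] != i) i <- grp[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pid <- Biostrings::pid(Biostrings::pairwiseAlignment(
      chains$seq[i], chains$seq[j], substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 4), type = "PID1") / 100
    if (pid > identity) grp[find(j)] <- find(i)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  specific <- numeric(0); nonspecific <- numeric(0)
  for (g in unique(roots)) {
    members <- which(roots == g)
    if (length(members) < 2L) next
    ifaces <- lapply(members, function(k) {
      r <- loo[[chains$complex_id[k]]]
      which(r$site_labels[[chains$side[k]]])
    })
    for (mi in seq_along(members)) {
      k <- members[mi]
      r <- loo[[chains$complex_id[k]]]
      sc <- r$site_step2$smoothed[[chains$side[k]]]
      own <- ifaces[[mi]]
      others <- setdiff(unique(unlist(ifaces[-mi])), own)
      specific <- c(specific, sc[own])
      nonspecific <- c(nonspecific, sc[others])
    }
  }
  if (length(specific) == 0L || length(nonspecific) == 0L)
    stop("no shared proteins with distinct interfaces found")
  test <- mann_whitney_u(specific, nonspecific)
  list(specific = specific, nonspecific = nonspecific, test = test)
}

#' Write an evaluation report as JSON plus a readable table
#'
#' @param report Output of [evaluation_report()].
#' @param path_json,path_table Output file paths.
#' @export
write_report <- function(report, path_json, path_table) {
  jsonlite::write_json(report, path_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  fmt <- function(x) sprintf("%.4f", x)
  t2 <- report$site_threshold_metrics
  lines <- c(
    sprintf("%-28s %9s %9s %9s", "unit", "avgAUCroc", "AUCroc", "AUCpr"),
    sprintf("%-28s %9s %9s %9s", "pair step1",
            fmt(report$pairs$step1$avg_roc_auc), fmt(report$pairs$step1$roc_auc),
            fmt(report$pairs$step1$pr_auc)),
    sprintf("%-28s %9s %9s %9s", "pair step2",
            fmt(report$pairs$step2$avg_roc_auc), fmt(report$pairs$step2$roc_auc),
            fmt(report$pairs$step2$pr_auc)),
    sprintf("%-28s %9s %9s %9s", "site step1 (rank+smooth)",
            fmt(report$site$step1_smoothed$avg_roc_auc),
            fmt(report$site$step1_smoothed$roc_auc),
            fmt(report$site$step1_smoothed$pr_auc)),
    sprintf("%-28s %9s %9s %9s", "site step2 (rank+smooth)",
            fmt(report$site$step2_smoothed$avg_roc_auc),
            fmt(report$site$step2_smoothed$roc_auc),
            fmt(report$site$step2_smoothed$pr_auc)),
    sprintf("%-28s %9s %9s %9s", "site step2 (max baseline)",
            fmt(report$site$max_baseline$avg_roc_auc),
            fmt(report$site$max_baseline$roc_auc),
            fmt(report$site$max_baseline$pr_auc)),
    sprintf("MCC %.4f PR %.4f RC %.4f SPC %.4f NPV %.4f at threshold %.4f",
            t2$mcc, t2$precision, t2$recall, t2$specificity, t2$npv,
            t2$threshold))
  writeLines(lines, path_table)
  invisible(report)
}
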