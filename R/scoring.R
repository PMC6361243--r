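# Conversion of pair score matrices into per-residue binding-site scores:
# rank-based scoring over exponentially growing top-score buckets, sequence
# window smoothing, and isotonic expected-precision calibration.

#' Rank-based binding-site scores from a pair score matrix
#'
#' All cross-chain pairs are sorted from highest to lowest score (ties broken
#' by ascending `(i, j)` index, a fixed documented convention).  For bucket
#' sizes `2^0, 2^1, ..., 2^floor(log2(n))` (capped at `n`, the number of
#' pairs), a residue earns `Xc / 2^k` where `Xc` counts the pairs among the
#' `2^k` highest-scored ones that contain it.  The score depends only on the
#' ranking, so any strictly increasing transform of the matrix leaves it
#' unchanged.
#'
#' @param scores Numeric matrix `len(A) x len(B)` of pair scores.
#' @return List with per-residue raw score vectors `a` and `b`.
#' @export
binding_site_scores <- function(scores) {
  scores <- as.matrix(scores)
  na <- nrow(scores); nb <- ncol(scores)
  n <- na * nb
  if (n < 1L) stop("empty score matrix")
  ii <- rep(seq_len(na), times = nb)
  jj <- rep(seq_len(nb), each = na)
  ord <- order(-as.vector(scores), ii, jj)
  ri <- ii[ord]; rj <- jj[ord]
  out_a <- numeric(na); out_b <- numeric(nb)
  for (k in 0:floor(log2(n))) {
    b <- min(2^k, n)
    ta <- tabulate(ri[seq_len(b)], nbins = na)
    tb <- tabulate(rj[seq_len(b)], nbins = nb)
    out_a <- out_a + ta / 2^k
    out_b <- out_b + tb / 2^k
  }
  list(a = out_a, b = out_b)
}

#' Smooth per-residue scores along the sequence
#'
#' Weighted three-residue window with weights `(1/4, 1/2, 1/4)`; at the
#' termini the missing neighbor is dropped and the weights renormalized
#' (e.g. `(2 raw[1] + raw[2]) / 3`).
#'
#' @param raw Numeric vector of per-residue scores.
#' @return Smoothed vector of the same length.
#' @export
smooth_profile <- function(raw) {
  n <- length(raw)
  if (n <= 1L) return(raw)
  prev <- c(NA, raw[-n]); nxt <- c(raw[-1], NA)
  num <- ifelse(is.na(prev), 0, prev) + 2 * raw + ifelse(is.na(nxt), 0, nxt)
  den <- 2 + (!is.na(prev)) + (!is.na(nxt))
  num / den
}

#' Fit an isotonic score-to-expected-precision calibration
#'
#' Pool-adjacent-violators regression of binary interface labels on scores
#' from held-out complexes; the fitted non-decreasing step function maps a
#' score to an expected precision in `[0, 1]`.
#'
#' @param scores Calibration scores.
#' @param labels Binary interface labels (0/1) of the same residues.
#' @return An object of class `ps_calibration`.
#' @export
fit_calibration <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2L)
    stop("calibration requires both label classes")
  ord <- order(scores)
  iso <- isoreg(scores[ord], labels[ord])
  x <- iso$x; yf <- pmin(pmax(iso$yf, 0), 1)
  last <- !duplicated(x, fromLast = TRUE)  # for tied scores keep the upper fit
  structure(list(x = x[last], y = yf[last]), class = "ps_calibration")
}

#' Apply a calibration map
#'
#' @param calibration A `ps_calibration` from [fit_calibration()].
#' @param scores Scores to map.
#' @return Expected precisions in `[0, 1]` (non-decreasing in the score).
#' @export
apply_calibration <- function(calibration, scores) {
  f <- approxfun(calibration$x, calibration$y, method = "constant",
                 rule = 2, f = 0, ties = "ordered")
  pmin(pmax(f(scores), 0), 1)
}

#' Maximum-score baseline for binding-site scores
#'
#' The per-residue score is the maximum pair score the residue takes part in
#' (the baseline scoring strategy used by earlier pair predictors).
#'
#' @param scores Numeric matrix `len(A) x len(B)`.
#' @return List with per-residue vectors `a` and `b`.
#' @export
max_score_baseline <- function(scores) {
  scores <- as.matrix(scores)
  if (length(scores) < 1L) stop("empty score matrix")
  list(a = apply(scores, 1, max), b = apply(scores, 2, max))
}

#' Full binding-site profile of one complex
#'
#' Raw rank-based scores, their smoothed version, and optionally calibrated
#' expected precisions, for both chains.
#'
#' @param scores Pair score matrix.
#' @param calibration Optional `ps_calibration`.
#' @return List of two data frames (`a`, `b`) with columns `raw`, `smoothed`
#'   and (if calibrated) `expected_precision`.
#' @export
binding_site_profile <- function(scores, calibration = NULL) {
  raw <- binding_site_scores(scores)
  mk <- function(v) {
    df <- data.frame(raw = v, smoothed = smooth_profile(v))
    if (!is.null(calibration))
      df$expected_precision <- apply_calibration(calibration, df$smoothed)
    df
  }
  list(a = mk(raw$a), b = mk(raw$b))
}

#' Write per-residue binding-site tables
#'
#' Tab-separated columns: chain, res_number, aa, raw, smoothed and (when
#' calibrated) expected_precision.
#'
#' @param profile Output of [binding_site_profile()].
#' @param pair The complex's [protein_pair()].
#' @param path Output path.
#' @export
write_site_table <- function(profile, pair, path) {
  mk <- function(chain, df)
    cbind(data.frame(chain = chain$chain_id, res_number = chain$res_number,
                     aa = chain$aa), df)
  out <- rbind(mk(pair$chain_a, profile$a), mk(pair$chain_b, profile$b))
  write.table(format(out, digits = 6), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write the pair score table
#'
#' Tab-separated columns: chainA, resA, chainB, resB, score.
#'
#' @param scores Pair score matrix.
#' @param pair The complex's [protein_pair()].
#' @param path Output path.
#' @export
write_pair_table <- function(scores, pair, path) {
  na <- nrow(scores); nb <- ncol(scores)
  df <- data.frame(chainA = pair$chain_a$chain_id,
                   resA = rep(pair$chain_a$res_number, times = nb),
                   chainB = pair$chain_b$chain_id,
                   resB = rep(pair$chain_b$res_number, each = na),
                   score = as.vector(scores))
  write.table(format(df, digits = 6), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
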