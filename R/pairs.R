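# Cross-chain pair enumeration, class-imbalance sampling and symmetry
# handling.

#' Enumerate all cross-chain residue pairs with contact labels
#'
#' @param pair A [protein_pair()].
#' @param contacts The matching `ps_contact_map`.
#' @return Data frame with columns `complex_id`, `i`, `j` (1-based residue
#'   indices in chains A and B) and logical `label`.
#' @export
enumerate_pairs <- function(pair, contacts) {
  na <- chain_length(pair$chain_a); nb <- chain_length(pair$chain_b)
  if (!identical(dim(contacts$labels), c(na, nb)))
    stop("contact map dimensions do not match chain lengths")
  data.frame(complex_id = pair$complex_id,
             i = rep(seq_len(na), times = nb),
             j = rep(seq_len(nb), each = na),
             label = as.vector(contacts$labels))
}

# Deterministic per-complex RNG substream: hashing the complex id keeps each
# complex's draws stable when other complexes are added or removed.
.complex_seed <- function(seed, complex_id) {
  h <- 0
  for (cc in utf8ToInt(complex_id)) h <- (h * 31 + cc) %% 2147480009
  as.integer((seed + h) %% 2147483647)
}

# run expr with a temporary seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  expr
}

#' Per-complex negative sampling of labeled pairs
#'
#' Keeps every contact pair and draws, within each complex, up to
#' `ratio x positives` non-contact pairs uniformly without replacement
#' (all negatives when fewer are available).  Residues without coordinates
#' stay eligible as negatives.  Complexes with no positive pair contribute
#' nothing and are dropped with a message.  Deterministic given `seed`; each
#' complex uses an id-hashed RNG substream.
#'
#' @param pairs Labeled pair data frame from [enumerate_pairs()] (possibly
#'   several complexes row-bound).
#' @param ratio Negatives per positive (default 3).
#' @param seed Integer seed.
#' @return Subset of `pairs` rows (positives first within each complex).
#' @export
sample_negatives <- function(pairs, ratio = 3, seed = 1L) {
  out <- lapply(split(pairs, pairs$complex_id), function(df) {
    pos <- df[df$label, , drop = FALSE]
    if (nrow(pos) == 0L) {
      message(sprintf("complex %s has no contact pairs; skipped", df$complex_id[1]))
      return(df[0, , drop = FALSE])
    }
    neg <- df[!df$label, , drop = FALSE]
    k <- min(ratio * nrow(pos), nrow(neg))
    sel <- .with_seed(.complex_seed(seed, df$complex_id[1]),
                      sample.int(nrow(neg), k))
    rbind(pos, neg[sort(sel), , drop = FALSE])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Symmetry-average the two ordering predictions
#'
#' A pair `(i, j)` is scored once in AB ordering and once in BA ordering;
#' both get the mean of the two model outputs.
#'
#' @param scores_ab Matrix `len(A) x len(B)` of AB-ordering scores.
#' @param scores_ba Matrix `len(B) x len(A)` of BA-ordering scores.
#' @return Matrix `len(A) x len(B)`: `(ab[i,j] + ba[j,i]) / 2`.
#' @export
symmetrize <- function(scores_ab, scores_ba) {
  if (!identical(dim(scores_ab), rev(dim(scores_ba))))
    stop("score matrix shapes do not match under transposition")
  (scores_ab + t(scores_ba)) / 2
}
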