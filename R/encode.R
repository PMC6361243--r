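# Assembly of per-residue feature blocks: sequence features through a
# sliding window, structural features, and their Voronoi environments.

# one-hot matrix (n x 22) for a chain's residues
.aa_onehot_matrix <- function(aa) {
  m <- matrix(0, length(aa), 22, dimnames = list(NULL, paste0("aa.", AA_ALPHABET22)))
  m[cbind(seq_along(aa), match(aa, AA_ALPHABET22))] <- 1
  m
}

.ss_onehot_matrix <- function(ss) {
  m <- matrix(0, length(ss), 8, dimnames = list(NULL, paste0("ss.", SS_CLASSES)))
  m[cbind(seq_along(ss), match(ss, SS_CLASSES))] <- 1
  m
}

# per-residue sequence feature block (n x 64): identity one-hot, PSSM, PSFM,
# information content, conservation
.sequence_block <- function(chain, profile) {
  n <- chain_length(chain)
  stopifnot(profile_length(profile) == n)
  cons <- vapply(seq_len(n), function(i) conservation(profile$frequencies[i, ]),
                 numeric(1))
  cbind(.aa_onehot_matrix(chain$aa),
        `colnames<-`(profile$log_odds, paste0("pssm.", AA20)),
        `colnames<-`(profile$frequencies, paste0("psfm.", AA20)),
        prof.info = profile$info,
        cons.score = cons)
}

# padding vector for window slots beyond the termini: zero features with the
# gap one-hot slot set
.gap_pad <- function(block_colnames) {
  pad <- numeric(length(block_colnames))
  names(pad) <- block_colnames
  pad["aa.-"] <- 1
  pad
}

# structural per-residue block (n x 15)
.structural_block <- function(pair, which) {
  chain <- if (which == "A") pair$chain_a else pair$chain_b
  n <- chain_length(chain)
  ss <- secondary_structure(chain)
  acc <- accessibility(pair, which)
  hse <- half_sphere_exposure(chain)
  resolved <- chain_resolved(chain)
  kd <- unname(KD_HYDROPATHY[chain$aa]); kd[is.na(kd)] <- 0
  # protrusion proxy: neighbor-count deficit relative to the chain mean
  cn <- hse$contact_number
  cn_bar <- if (any(resolved)) mean(cn[resolved]) else 0
  protr <- (cn_bar - cn) / max(cn_bar, 1)
  protr[!resolved] <- 0
  # depth proxy: radial position of the C-alpha from the chain centroid
  radial <- numeric(n)
  has_ca <- !is.null(chain$ca) && any(!is.na(chain$ca[, 1]))
  if (has_ca) {
    ok <- !is.na(chain$ca[, 1])
    ctr <- colMeans(chain$ca[ok, , drop = FALSE])
    d <- sqrt(rowSums(sweep(chain$ca, 2, ctr)^2))
    dmax <- max(d[ok], 1e-9)
    radial[ok] <- d[ok] / dmax
  }
  cbind(.ss_onehot_matrix(ss),
        acc.rel = acc$rel_accessibility,
        hse.up = hse$hse_up, hse.down = hse$hse_down,
        hse.cn = hse$contact_number,
        geom.kd = kd, geom.protrusion = protr, geom.radial = radial)
}

# Voronoi environment features of a per-residue feature matrix: real columns
# get (sum, mean, max, min), one-hot groups get class counts.
.voronoi_env_block <- function(real_feats, onehot_feats, graph) {
  n <- nrow(real_feats)
  p <- ncol(real_feats)
  env <- matrix(0, n, 4 * p)
  colnames(env) <- as.vector(vapply(colnames(real_feats), .env_names,
                                    character(4)))
  counts <- matrix(0, n, ncol(onehot_feats),
                   dimnames = list(NULL, paste0("venv.", colnames(onehot_feats), ".count")))
  for (i in seq_len(n)) {
    nb <- graph$neighbors[[i]]
    if (length(nb) == 0L) next
    sub <- real_feats[nb, , drop = FALSE]
    s <- colSums(sub)
    env[i, ] <- as.vector(rbind(s, s / length(nb),
                                apply(sub, 2, max), apply(sub, 2, min)))
    counts[i, ] <- colSums(onehot_feats[nb, , drop = FALSE])
  }
  colnames(env) <- as.vector(t(vapply(colnames(real_feats), function(nm)
    paste0("venv.", nm, ".", c("sum", "mean", "max", "min")), character(4))))
  cbind(env, counts)
}

#' Encode one complex into per-residue feature blocks
#'
#' Builds, for each chain: the sequence block (identity one-hot, profile
#' columns, information content, conservation) expanded through an 11-residue
#' sliding window; in structural mode additionally the structural block
#' (secondary structure, relative accessibility, half-sphere exposure,
#' contact number, hydrophobicity, protrusion and radial-depth proxies) and
#' the Voronoi-neighborhood environments of all features.  Also computes the
#' contact map (structural mode) and the neighbor graphs needed later for
#' pairwise environment scores.
#'
#' @param pair A [protein_pair()].
#' @param profile_a,profile_b Optional profile objects (see [read_pssm()]);
#'   defaults to [pseudo_profile()] of each chain.
#' @param window Sliding-window length (odd; default 11).
#' @param contact_threshold Contact distance in Angstrom (default 6).
#' @return An object of class `ps_encoded` with residue block matrices
#'   `blocks_a`, `blocks_b`, neighbor graphs, and (structural mode) the
#'   `ps_contact_map`.
#' @export
encode_complex <- function(pair, profile_a = NULL, profile_b = NULL,
                           window = 11L, contact_threshold = 6.0) {
  if (is.null(profile_a)) profile_a <- pseudo_profile(pair$chain_a$aa)
  if (is.null(profile_b)) profile_b <- pseudo_profile(pair$chain_b$aa)
  enc_chain <- function(chain, profile, which) {
    seq_block <- .sequence_block(chain, profile)
    win <- sliding_window(seq_block, window, pad = .gap_pad(colnames(seq_block)))
    if (pair$mode != "structural") return(list(block = win, graph = NULL))
    struct_block <- .structural_block(pair, which)
    graph <- voronoi_neighbors(chain)
    onehot_cols <- c(colnames(seq_block)[1:22], colnames(struct_block)[1:8])
    all_feats <- cbind(seq_block, struct_block)
    real_cols <- setdiff(colnames(all_feats), onehot_cols)
    env <- .voronoi_env_block(all_feats[, real_cols, drop = FALSE],
                              all_feats[, onehot_cols, drop = FALSE], graph)
    list(block = cbind(win, struct_block, env), graph = graph)
  }
  ea <- enc_chain(pair$chain_a, profile_a, "A")
  eb <- enc_chain(pair$chain_b, profile_b, "B")
  contacts <- if (pair$mode == "structural")
    compute_contacts(pair, contact_threshold) else NULL
  structure(list(complex_id = pair$complex_id, pair = pair,
                 blocks_a = ea$block, blocks_b = eb$block,
                 graph_a = ea$graph, graph_b = eb$graph,
                 contacts = contacts, mode = pair$mode),
            class = "ps_encoded")
}

#' Concatenate two residue blocks into one pair feature vector
#'
#' The AB ordering is `[block of the first residue, block of the second]`;
#' the BA ordering is its block-swapped image, so both orderings of the same
#' residue pair are mirror encodings.
#'
#' @param i_desc,j_desc Equal-layout numeric feature vectors of the two
#'   residues.
#' @param ordering `"AB"` or `"BA"` (recorded for provenance; the first
#'   argument is always placed first).
#' @return Numeric vector of length `2 * length(i_desc)` with `r1.`/`r2.`
#'   name prefixes.
#' @export
encode_pair <- function(i_desc, j_desc, ordering = c("AB", "BA")) {
  ordering <- match.arg(ordering)
  if (length(i_desc) != length(j_desc) ||
      !identical(names(i_desc), names(j_desc)))
    stop("residue blocks have mismatched layouts (mode mismatch?)")
  out <- c(i_desc, j_desc)
  names(out) <- c(paste0("r1.", names(i_desc)), paste0("r2.", names(j_desc)))
  out
}

# Pair feature matrix for given (i, j) index rows, one ordering.
# first = "A": rows are [block_a[i], block_b[j]]; first = "B": swapped.
pair_feature_matrix <- function(encoded, idx, first = c("A", "B")) {
  first <- match.arg(first)
  ba <- encoded$blocks_a; bb <- encoded$blocks_b
  if (first == "A") {
    m <- cbind(ba[idx[, 1], , drop = FALSE], bb[idx[, 2], , drop = FALSE])
  } else {
    m <- cbind(bb[idx[, 2], , drop = FALSE], ba[idx[, 1], , drop = FALSE])
  }
  colnames(m) <- c(paste0("r1.", colnames(ba)), paste0("r2.", colnames(bb)))
  m
}
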