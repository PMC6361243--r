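# Environment encodings: sequential sliding window, Voronoi structural
# neighborhoods over the C-alpha Delaunay tessellation, and structural
# pairwise environments of predicted pair scores.

#' Sliding-window concatenation of per-residue features
#'
#' For residue `k`, concatenates the feature rows of residues
#' `k - (width-1)/2 ... k + (width-1)/2` in order.  Positions beyond the
#' chain termini are filled with the padding vector, so every output row has
#' the same length `width * ncol(features)`.
#'
#' @param features Numeric matrix, one row per residue.
#' @param width Odd window length (default 11).
#' @param pad Padding vector of length `ncol(features)`; by default all
#'   zeros.  Callers encoding residue blocks pass a vector with the gap
#'   one-hot slot set.
#' @return Matrix `nrow(features) x (width * ncol(features))`.
#' @export
sliding_window <- function(features, width = 11L, pad = NULL) {
  features <- as.matrix(features)
  stopifnot(width %% 2L == 1L)
  n <- nrow(features); p <- ncol(features)
  if (is.null(pad)) pad <- numeric(p)
  stopifnot(length(pad) == p)
  half <- (width - 1L) %/% 2L
  blocks <- lapply(-half:half, function(off) {
    out <- matrix(rep(pad, each = n), n, p)
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    out[ok, ] <- features[src[ok], , drop = FALSE]
    out
  })
  out <- do.call(cbind, blocks)
  if (!is.null(colnames(features)))
    colnames(out) <- paste0(rep(colnames(features), times = width), ".w",
                            rep(-half:half, each = p))
  out
}

#' Delaunay adjacency of a 3-D point cloud
#'
#' Two points are neighbors iff their Voronoi cells share a facet, i.e. they
#' are joined by a Delaunay edge.  Computed by empty-circumsphere tetrahedron
#' enumeration; for 4 or fewer points the (possibly degenerate) tessellation
#' is a single simplex and all pairs are adjacent.  Fully degenerate clouds
#' (all points coplanar or collinear) are perturbed by a deterministic,
#' seeded jitter of magnitude `1e-4` Angstrom and retried.
#'
#' @param points Numeric matrix `n x 3`.
#' @param jitter_seed Seed for the degeneracy-breaking jitter.
#' @return Symmetric logical adjacency matrix without self-loops.
#' @export
voronoi_adjacency <- function(points, jitter_seed = 1L) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L)
  n <- nrow(points)
  degenerate <- n >= 3L && {
    ctr <- sweep(points, 2, colMeans(points))
    qr(ctr)$rank < 3L
  }
  if (degenerate) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(jitter_seed)
    points <- points + matrix(runif(3 * n, -1e-4, 1e-4), n, 3)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  adj <- delaunay_adjacency(points)
  if (n >= 5L && !any(adj)) {  # numerically degenerate despite full rank
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(jitter_seed)
    points <- points + matrix(runif(3 * n, -1e-4, 1e-4), n, 3)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    adj <- delaunay_adjacency(points)
  }
  adj
}

#' Voronoi neighbor graph of a chain
#'
#' Builds the residue neighbor graph from the Delaunay tessellation of the
#' chain's C-alpha atoms.  Residues without a C-alpha are excluded from the
#' tessellation and recorded as neighborless (flagged).
#'
#' @param chain A `ps_chain` with coordinates.
#' @param jitter_seed Passed to [voronoi_adjacency()].
#' @return An object of class `ps_neighbor_graph` with fields `chain_id`,
#'   `n`, `neighbors` (list of integer vectors, 1-based residue indices) and
#'   `flagged` (residues without C-alpha).
#' @export
voronoi_neighbors <- function(chain, jitter_seed = 1L) {
  n <- chain_length(chain)
  if (is.null(chain$ca)) stop("voronoi_neighbors requires coordinates")
  has_ca <- !is.na(chain$ca[, 1])
  idx <- which(has_ca)
  neighbors <- rep(list(integer(0)), n)
  if (length(idx) >= 2L) {
    adj <- voronoi_adjacency(chain$ca[idx, , drop = FALSE], jitter_seed)
    for (k in seq_along(idx))
      neighbors[[idx[k]]] <- idx[which(adj[k, ])]
  }
  structure(list(chain_id = chain$chain_id, n = n,
                 neighbors = neighbors, flagged = !has_ca),
            class = "ps_neighbor_graph")
}

#' Four-statistic environment aggregation of a real-valued feature
#'
#' Summarizes a neighborhood's feature values as (sum, mean, max, min).  An
#' empty neighborhood yields `(0, 0, 0, 0)` with the `missing` attribute set,
#' since max and min are undefined there.
#'
#' @param values Feature values of the neighboring residues.
#' @return Named numeric vector `(sum, mean, max, min)`.
#' @export
env_real <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L)
    return(structure(c(sum = 0, mean = 0, max = 0, min = 0), missing = TRUE))
  c(sum = sum(values), mean = mean(values), max = max(values), min = min(values))
}

#' Environment aggregation of a one-hot feature
#'
#' Element-wise sum of the neighbors' one-hot vectors (a class count vector).
#'
#' @param onehots List of equal-length binary vectors.
#' @return Numeric vector of class counts; zero vector for an empty
#'   neighborhood.
#' @export
env_onehot <- function(onehots) {
  if (length(onehots) == 0L) return(numeric(0))
  k <- length(onehots[[1]])
  if (any(vapply(onehots, length, integer(1)) != k))
    stop("one-hot vectors differ in length")
  Reduce(`+`, lapply(onehots, as.numeric))
}

.env_names <- function(prefix) paste0(prefix, ".", c("sum", "mean", "max", "min"))

PAIRWISE_ENV_NAMES <- c(.env_names("env_dot_j"), .env_names("env_i_dot"),
                        .env_names("env_dot_dot"))

#' Structural pairwise environment of a pair score
#'
#' For a residue pair `(i, j)` and a cross-chain score matrix `F`, aggregates
#' (sum, mean, max, min): scores `F(r, j)` over the Voronoi neighbors `r` of
#' `i`; scores `F(i, s)` over the neighbors `s` of `j`; and scores `F(r, s)`
#' over both neighborhoods jointly (mean divided by `|Ni| |Nj|`).  Empty
#' neighborhoods contribute zeros.
#'
#' @param scores Numeric matrix `len(A) x len(B)` of pair scores.
#' @param i,j Residue indices (1-based) in chains A and B.
#' @param graph_a,graph_b `ps_neighbor_graph`s of the two chains.
#' @return Named numeric vector of 12 values.
#' @export
pairwise_env <- function(scores, i, j, graph_a, graph_b) {
  ni <- graph_a$neighbors[[i]]
  nj <- graph_b$neighbors[[j]]
  out <- c(env_real(scores[ni, j]),
           env_real(scores[i, nj]),
           env_real(scores[ni, nj]))
  names(out) <- PAIRWISE_ENV_NAMES
  out
}

# Batch version over an index matrix (columns i, j); rows ~ pairs.
pairwise_env_matrix <- function(scores, pairs_idx, graph_a, graph_b) {
  out <- matrix(0, nrow(pairs_idx), 12,
                dimnames = list(NULL, PAIRWISE_ENV_NAMES))
  for (r in seq_len(nrow(pairs_idx)))
    out[r, ] <- pairwise_env(scores, pairs_idx[r, 1], pairs_idx[r, 2],
                             graph_a, graph_b)
  out
}
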