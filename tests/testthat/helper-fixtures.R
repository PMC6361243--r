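# Shared fixtures: tiny hand-written PDB text, point-cloud generators,
# brute-force oracles, and lazily built benchmark/LOO objects reused by the
# model and acceptance tests.

# minimal PDB: chain A = ALA, MSE, GLY (CA-only), chain B = LEU, VAL
tiny_pdb <- function(path = tempfile(fileext = ".pdb")) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
    "HETATM    4  N   MSE A   2       3.300   1.500   0.000  1.00  0.00           N",
    "HETATM    5  CA  MSE A   2       4.700   1.800   0.100  1.00  0.00           C",
    "HETATM    6  C   MSE A   2       5.600   3.000   0.000  1.00  0.00           C",
    "HETATM    7 SE   MSE A   2       5.200   0.300   0.900  1.00  0.00          SE",
    "ATOM      8  CA  GLY A   3       7.000   3.400   0.200  1.00  0.00           C",
    "TER",
    "ATOM      9  N   LEU B   1       1.000   5.000   0.000  1.00  0.00           N",
    "ATOM     10  CA  LEU B   1       2.400   5.200   0.100  1.00  0.00           C",
    "ATOM     11  CA  VAL B   2       9.000   9.000   9.000  1.00  0.00           C",
    "HETATM   12  O   HOH B  90      50.000  50.000  50.000  1.00  0.00           O",
    "TER", "END")
  writeLines(lines, path)
  path
}

# random point cloud with a reproducible seed
make_cloud <- function(n, seed, scale = 10) {
  set.seed(seed)
  matrix(runif(3 * n, 0, scale), n, 3)
}

# brute-force Delaunay adjacency oracle: enumerate all tetrahedra, solve the
# circumsphere with explicit cofactor formulas, and accept tetrahedra whose
# sphere holds no other point strictly inside
delaunay_oracle <- function(pts, tol = 1e-9) {
  n <- nrow(pts)
  adj <- matrix(FALSE, n, n)
  if (n <= 4) { adj[] <- TRUE; diag(adj) <- FALSE; return(adj) }
  nr <- rowSums(pts^2)
  combs <- combn(n, 4)
  for (c in seq_len(ncol(combs))) {
    q <- combs[, c]
    A <- 2 * (pts[q[2:4], , drop = FALSE] -
                matrix(pts[q[1], ], 3, 3, byrow = TRUE))
    b <- nr[q[2:4]] - nr[q[1]]
    det <- det(A)
    if (abs(det) < 1e-10) next
    ctr <- solve(A, b)
    r2 <- sum((pts[q[1], ] - ctr)^2)
    others <- setdiff(seq_len(n), q)
    d2 <- rowSums(sweep(pts[others, , drop = FALSE], 2, ctr)^2)
    if (any(d2 < r2 - tol * (1 + r2))) next
    for (u in 1:3) for (v in (u + 1):4) {
      adj[q[u], q[v]] <- TRUE
      adj[q[v], q[u]] <- TRUE
    }
  }
  adj
}

# brute-force contact oracle: double loop over residues and atom pairs
contact_oracle <- function(pair, threshold = 6.0) {
  na <- length(pair$chain_a$aa); nb <- length(pair$chain_b$aa)
  out <- matrix(FALSE, na, nb)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    A <- pair$chain_a$atoms[[i]]; B <- pair$chain_b$atoms[[j]]
    if (nrow(A) == 0 || nrow(B) == 0) next
    mind <- Inf
    for (p in seq_len(nrow(A))) for (q in seq_len(nrow(B)))
      mind <- min(mind, sqrt(sum((A[p, ] - B[q, ])^2)))
    out[i, j] <- mind < threshold
  }
  out
}

# independent rank-bucket oracle for the binding-site scoring function
site_score_oracle <- function(scores) {
  na <- nrow(scores); nb <- ncol(scores); n <- na * nb
  df <- expand.grid(i = seq_len(na), j = seq_len(nb))
  df$s <- scores[cbind(df$i, df$j)]
  df <- df[order(-df$s, df$i, df$j), ]
  a <- numeric(na); b <- numeric(nb)
  k <- 0
  while (2^k <= n) {
    top <- df[seq_len(min(2^k, n)), ]
    for (r in seq_len(na)) a[r] <- a[r] + sum(top$i == r) / 2^k
    for (r in seq_len(nb)) b[r] <- b[r] + sum(top$j == r) / 2^k
    k <- k + 1
  }
  list(a = a, b = b)
}

# lazily built shared objects (expensive: built once per test run)
.shared <- new.env()

shared_benchmark_dir <- function() {
  if (is.null(.shared$bench_dir)) {
    d <- file.path(tempdir(), "pairsite-bench")
    if (!dir.exists(d))
      make_benchmark_set(10, d, seed = 1, informativeness = 0.9, n_shared = 2)
    .shared$bench_dir <- d
  }
  .shared$bench_dir
}

shared_encoded <- function() {
  if (is.null(.shared$encoded))
    .shared$encoded <- load_benchmark(shared_benchmark_dir())
  .shared$encoded
}

# scaled-down boosting configuration used for all toy-data runs
toy_params <- function(...) default_model_params(nrounds = 60L, max_depth = 4L,
                                                 eta = 0.2, ...)

# the leave-one-out run shared by the learning-sanity and scoring tests
shared_loo <- function() {
  if (is.null(.shared$loo))
    .shared$loo <- loo_cv(shared_encoded(), params = toy_params(), seed = 1)
  .shared$loo
}

# a small trained model over the first four shared complexes (quick config)
shared_small_model <- function() {
  if (is.null(.shared$model))
    .shared$model <- train_two_step(shared_encoded()[1:4],
                                    params = toy_params(nrounds = 15L, nfold = 2L),
                                    seed = 1)
  .shared$model
}
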