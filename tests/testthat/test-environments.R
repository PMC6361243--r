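test_that("sliding windows concatenate neighbors and pad beyond the termini", {
  X <- matrix(seq_len(22), 11, 2)  # chain of 11 residues, 2 features
  colnames(X) <- c("f1", "f2")
  W <- sliding_window(X, 11)
  expect_equal(ncol(W), 11L * 2L)
  # center residue of a length-11 chain sees the whole chain in order
  expect_equal(unname(W[6, ]), as.vector(t(X)))
  # first residue: 5 padding blocks then residues 1..6
  pad <- c(9, 9)
  Wp <- sliding_window(X, 11, pad = pad)
  expect_equal(unname(Wp[1, 1:10]), rep(pad, 5))
  expect_equal(unname(Wp[1, 11:12]), unname(X[1, ]))
  expect_error(sliding_window(X, 4))
})

test_that("real-valued environment aggregation returns (sum, mean, max, min)", {
  expect_equal(unname(env_real(c(2, 4))), c(6, 3, 4, 2))
  expect_equal(unname(env_real(5)), c(5, 5, 5, 5))
  empty <- env_real(numeric(0))
  expect_equal(as.numeric(empty), c(0, 0, 0, 0))
  expect_true(attr(empty, "missing"))
})

test_that("one-hot environment aggregation sums class vectors", {
  expect_equal(env_onehot(list(c(1, 0, 0), c(0, 1, 0), c(1, 0, 0))), c(2, 1, 0))
  expect_equal(env_onehot(list()), numeric(0))
  expect_error(env_onehot(list(c(1, 0), c(1, 0, 0))), "length")
  # conservation: total counts equal neighborhood size
  set.seed(3)
  oh <- lapply(1:7, function(i) { v <- numeric(5); v[sample(5, 1)] <- 1; v })
  expect_equal(sum(env_onehot(oh)), 7)
})

test_that("Voronoi adjacency is complete on a tetrahedron and matches the brute-force oracle", {
  tetra <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  adj <- voronoi_adjacency(tetra)
  expect_equal(sum(adj) / 2, 6)
  for (seed in 1:6) {
    pts <- make_cloud(sample(8:14, 1), seed = 100 + seed)
    expect_equal(voronoi_adjacency(pts), delaunay_oracle(pts),
                 info = sprintf("cloud seed %d", seed))
  }
})

test_that("Voronoi adjacency is invariant under rigid-body transforms", {
  pts <- make_cloud(15, seed = 9)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- pts %*% R + matrix(c(5, -3, 2), 15, 3, byrow = TRUE)
  expect_equal(voronoi_adjacency(moved), voronoi_adjacency(pts))
})

test_that("degenerate point clouds are jittered instead of failing, and missing C-alphas are neighborless", {
  flat <- cbind(make_cloud(8, 2)[, 1:2], 0)  # coplanar
  adj <- voronoi_adjacency(flat)
  expect_true(any(adj))
  # residue without CA: degree 0, flagged
  atoms <- lapply(1:6, function(i) matrix(runif(3), 1, 3))
  names6 <- rep(list("CA"), 6)
  names6[[3]] <- "CB"  # residue 3 has no CA
  ch <- new_chain("A", rep("A", 6), 1:6, atoms, names6)
  g <- voronoi_neighbors(ch)
  expect_equal(g$neighbors[[3]], integer(0))
  expect_true(g$flagged[3])
})

test_that("pairwise environment scores match their stated examples and a nested-loop oracle", {
  graph <- function(neigh, n) structure(list(chain_id = "A", n = n,
                                             neighbors = neigh,
                                             flagged = rep(FALSE, n)),
                                        class = "ps_neighbor_graph")
  S <- matrix(0, 3, 3)
  S[2, 1] <- 0.2; S[3, 1] <- 0.6
  ga <- graph(list(integer(0), integer(0), integer(0)), 3)
  ga$neighbors[[1]] <- c(2L, 3L)
  gb <- graph(rep(list(integer(0)), 3), 3)
  pe <- pairwise_env(S, 1, 1, ga, gb)
  expect_equal(unname(pe[1:4]), c(0.8, 0.4, 0.6, 0.2))
  # joint-neighborhood statistics
  S2 <- matrix(0, 2, 3); S2[2, 2] <- 0.1; S2[2, 3] <- 0.3
  ga2 <- graph(list(2L, integer(0)), 2)
  gb2 <- graph(list(c(2L, 3L), integer(0), integer(0)), 3)
  pe2 <- pairwise_env(S2, 1, 1, ga2, gb2)
  expect_equal(unname(pe2[9:12]), c(0.4, 0.2, 0.3, 0.1))
  # oracle equivalence on random graphs and matrices
  set.seed(11)
  for (rep_k in 1:25) {
    na <- sample(4:7, 1); nb <- sample(4:7, 1)
    S <- matrix(runif(na * nb), na, nb)
    ga <- graph(lapply(seq_len(na), function(i)
      sample(setdiff(seq_len(na), i), sample(0:(na - 1), 1))), na)
    gb <- graph(lapply(seq_len(nb), function(j)
      sample(setdiff(seq_len(nb), j), sample(0:(nb - 1), 1))), nb)
    i <- sample(na, 1); j <- sample(nb, 1)
    got <- pairwise_env(S, i, j, ga, gb)
    ni <- ga$neighbors[[i]]; nj <- gb$neighbors[[j]]
    stat4 <- function(v) if (length(v) == 0) c(0, 0, 0, 0) else
      c(sum(v), mean(v), max(v), min(v))
    dotj <- stat4(vapply(ni, function(r) S[r, j], numeric(1)))
    idot <- stat4(vapply(nj, function(s) S[i, s], numeric(1)))
    joint <- numeric(0)
    for (r in ni) for (s in nj) joint <- c(joint, S[r, s])
    expect_equal(unname(got), c(dotj, idot, stat4(joint)))
    # transposing the problem swaps the one-sided aggregates
    got_t <- pairwise_env(t(S), j, i, gb, ga)
    expect_equal(unname(got_t), unname(got[c(5:8, 1:4, 9:12)]))
  }
  # constant matrix: the one-sided environment is (c |Ni|, c, c, c)
  Sc <- matrix(0.3, 4, 4)
  gac <- graph(list(c(2L, 3L, 4L), 1L, 1L, 1L), 4)
  gbc <- graph(rep(list(integer(0)), 4), 4)
  expect_equal(unname(pairwise_env(Sc, 1, 2, gac, gbc)[1:4]),
               c(0.3 * 3, 0.3, 0.3, 0.3))
})
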