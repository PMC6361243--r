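test_that("toy complexes force an interface of the requested width with geometry-derived labels", {
  spec <- toy_complex_spec(seed = 12, n_res_a = 20, n_res_b = 18,
                           interface_width = 4)
  toy <- make_toy_complex(spec)
  # interface designation is exactly the realized contact residues
  expect_equal(which(rowSums(toy$contacts$labels) > 0), toy$interface_a,
               ignore_attr = TRUE)
  expect_equal(which(colSums(toy$contacts$labels) > 0), toy$interface_b,
               ignore_attr = TRUE)
  expect_equal(length(toy$interface_a), 4L)
  expect_equal(length(toy$interface_b), 4L)
  # ground truth recomputable from the coordinates, never stored stale
  expect_equal(toy$contacts$labels, compute_contacts(toy$pair)$labels)
})

test_that("toy generation is deterministic per seed down to the written PDB bytes", {
  spec <- toy_complex_spec(seed = 31, n_res_a = 14, n_res_b = 14,
                           interface_width = 3)
  f1 <- tempfile(fileext = ".pdb"); f2 <- tempfile(fileext = ".pdb")
  write_toy_pdb(make_toy_complex(spec), f1)
  write_toy_pdb(make_toy_complex(spec), f2)
  expect_identical(readLines(f1), readLines(f2))
  spec2 <- toy_complex_spec(seed = 32, n_res_a = 14, n_res_b = 14,
                            interface_width = 3)
  f3 <- tempfile(fileext = ".pdb")
  write_toy_pdb(make_toy_complex(spec2), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("contact maps are invariant under rigid-body transforms of the whole complex", {
  toy <- make_toy_complex(toy_complex_spec(seed = 8, n_res_a = 12, n_res_b = 12,
                                           interface_width = 3))
  th <- 1.1
  R <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  shift <- c(20, -7, 3)
  move <- function(chain) {
    chain$atoms <- lapply(chain$atoms, function(m)
      sweep(m %*% R, 2, -shift))
    new_chain(chain$chain_id, chain$aa, chain$res_number, chain$atoms,
              chain$atom_names)
  }
  moved <- protein_pair("m", move(toy$pair$chain_a), move(toy$pair$chain_b),
                        "structural")
  expect_equal(compute_contacts(moved)$labels, toy$contacts$labels)
})

test_that("profile informativeness controls the interface-conservation association", {
  chain <- new_chain("A", rep(AA_ALPHABET22[1:20], length.out = 500))
  pairq <- protein_pair("q", chain, new_chain("B", rep("A", 10)), "sequence")
  iface <- sort(sample(500, 250))
  set.seed(1)
  prof0 <- make_synthetic_profiles(pairq, iface, 1:5, informativeness = 0,
                                   seed = 5)
  cons0 <- conservation(prof0$a)
  ks <- suppressWarnings(stats::ks.test(cons0[iface], cons0[-iface]))  # ties expected
  expect_gt(ks$p.value, 0.01)  # identical distributions at informativeness 0
  prof1 <- make_synthetic_profiles(pairq, iface, 1:5, informativeness = 1,
                                   seed = 5)
  cons1 <- conservation(prof1$a)
  expect_gt(mean(cons1[iface]), mean(cons1[-iface]))
})

test_that("synthetic profiles round-trip losslessly through the PSSM reader", {
  toy <- make_toy_complex(toy_complex_spec(seed = 3, n_res_a = 10, n_res_b = 10,
                                           interface_width = 3))
  prof <- make_synthetic_profiles(toy$pair, toy$interface_a, toy$interface_b,
                                  0.9, seed = 9)
  f <- tempfile(fileext = ".pssm")
  write_pssm(prof$a, toy$pair$chain_a$aa, f)
  back <- read_pssm(f, 10)
  expect_equal(back$log_odds, prof$a$log_odds)
  expect_equal(back$frequencies, prof$a$frequencies)
  expect_equal(back$info, prof$a$info)
})

test_that("benchmark directories carry a complete manifest with per-complex seeds", {
  d <- tempfile()
  make_benchmark_set(4, d, seed = 3)
  man <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_equal(length(man), 4L)
  for (e in man) {
    expect_true(file.exists(file.path(d, e$pdb)))
    expect_true(file.exists(file.path(d, e$pssm_a)))
    expect_true(file.exists(file.path(d, e$fasta)))
  }
  # different complexes get different deterministic sub-seeds: distinct files
  expect_false(identical(readLines(file.path(d, man[[1]]$pdb)),
                         readLines(file.path(d, man[[2]]$pdb))))
  enc <- load_benchmark(d)
  expect_equal(length(enc), 4L)
  expect_s3_class(enc[[1]], "ps_encoded")
})
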