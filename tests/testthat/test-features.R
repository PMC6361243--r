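test_that("residue one-hot encoding covers the 22-symbol alphabet exactly once each", {
  for (k in seq_along(AA_ALPHABET22)) {
    v <- one_hot_aa(AA_ALPHABET22[k])
    expect_equal(sum(v), 1)
    expect_equal(which(v == 1), k, ignore_attr = TRUE)
  }
  expect_equal(which(one_hot_aa("X") == 1), 21L, ignore_attr = TRUE)
  expect_error(one_hot_aa("B"), "unknown residue symbol")
})

test_that("PSSM files parse into profile columns with normalized frequencies", {
  path <- tempfile(fileext = ".pssm")
  # 3 rows; log-odds put 1 in the A column of row 1; percentages sum to 100
  hdr <- paste(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"), collapse = "  ")
  row_lo <- function(i, first) paste(c(first, rep(0, 19)), collapse = " ")
  row_fq <- paste(c(60, 40, rep(0, 18)), collapse = " ")
  writeLines(c("", "Last position-specific scoring matrix computed",
               paste("   ", hdr, hdr),
               sprintf("%5d A %s %s 0.50", 1, row_lo(1, 1), row_fq),
               sprintf("%5d C %s %s 0.25", 2, row_lo(2, 0), row_fq),
               sprintf("%5d D %s %s 0.00", 3, row_lo(3, 0), row_fq)), path)
  prof <- read_pssm(path)
  expect_equal(nrow(prof$log_odds), 3L)
  expect_equal(unname(prof$log_odds[1, "A"]), 1)
  expect_equal(rowSums(prof$frequencies), rep(1, 3))
  expect_equal(prof$info[1], 0.5)
  expect_error(read_pssm(path, expected_length = 4), "3 rows")
})

test_that("pseudo-profiles are deterministic substitution-matrix columns", {
  p <- pseudo_profile("AA")
  expect_equal(p$log_odds[1, ], p$log_odds[2, ])
  expect_equal(p$frequencies[1, ], p$frequencies[2, ])
  expect_equal(unname(rowSums(p$frequencies)), rep(1, 2))
  # the W column's log-odds equal the shipped BLOSUM62 row for W
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  aa20 <- AA_ALPHABET22[1:20]
  pw <- pseudo_profile("W")
  expect_equal(unname(pw$log_odds[1, ]), unname(e$BLOSUM62["W", aa20]))
})

test_that("entropy conservation has the right fixed points and closed-form values", {
  one <- c(1, rep(0, 19))
  expect_equal(conservation(one), 1.0)
  expect_equal(conservation(rep(1 / 20, 20)), 0.0)
  half <- c(0.5, 0.5, rep(0, 18))
  expect_equal(conservation(half), 1 - log(2) / log(20), tolerance = 1e-12)
  expect_error(conservation(rep(0, 20)), "all-zero")
})

test_that("half-sphere exposure counts neighbors within radius and splits hemispheres", {
  # isolated pair 11 A apart: each sees the other, contact number 1
  mk_res <- function(x) list(matrix(c(x, 0, 0), 1, 3))
  ch <- new_chain("A", c("G", "G"), 1:2,
                  c(mk_res(0), mk_res(11)), list("CA", "CA"))
  h <- half_sphere_exposure(ch)
  expect_equal(h$contact_number, c(1L, 1L))
  # beyond the radius nothing is counted
  ch2 <- new_chain("A", c("G", "G"), 1:2, c(mk_res(0), mk_res(13)),
                   list("CA", "CA"))
  expect_equal(half_sphere_exposure(ch2)$contact_number, c(0L, 0L))
  # chain of one residue sees nothing
  ch1 <- new_chain("A", "G", 1, mk_res(0), list("CA"))
  expect_equal(unlist(half_sphere_exposure(ch1)[1, 1:3]), c(hse_up = 0L,
               hse_down = 0L, contact_number = 0L))
})

test_that("contact number equals a brute-force neighbor count on random coordinates", {
  set.seed(71)
  n <- 25
  ca <- matrix(runif(3 * n, 0, 30), n, 3)
  atoms <- lapply(seq_len(n), function(i) ca[i, , drop = FALSE])
  ch <- new_chain("A", sample(AA_ALPHABET22[1:20], n, TRUE), 1:n, atoms,
                  rep(list("CA"), n))
  h <- half_sphere_exposure(ch, radius = 12)
  d <- as.matrix(dist(ca))
  brute <- vapply(seq_len(n), function(i) sum(d[i, -i] <= 12), integer(1))
  expect_equal(h$contact_number, brute)
  expect_true(all(h$hse_up >= 0 & h$hse_down >= 0))
})

test_that("dihedral secondary structure labels ideal helices and extended chains", {
  bb <- pairsite:::.build_backbone(rep("A", 12), rep(-57, 12), rep(-47, 12))
  helix <- new_chain("A", rep("A", 12), 1:12, bb$atoms, bb$atom_names)
  ss <- secondary_structure(helix)
  expect_true(all(ss[2:11] == "H"))
  bb2 <- pairsite:::.build_backbone(rep("A", 12), rep(-139, 12), rep(135, 12))
  ext <- new_chain("A", rep("A", 12), 1:12, bb2$atoms, bb2$atom_names)
  expect_false(any(secondary_structure(ext) == "H"))
  expect_true(all(secondary_structure(ext)[2:11] == "E"))
  # single residue has no dihedrals
  one <- new_chain("A", "A", 1, bb$atoms[1], bb$atom_names[1])
  expect_equal(secondary_structure(one), "-")
})

test_that("rolling-probe accessibility matches the closed form for a lone atom and detects burial", {
  # lone carbon atom: total SASA is exactly 4 pi (r + probe)^2
  ch <- new_chain("A", "G", 1, list(matrix(0, 1, 3)), list("CA"))
  sasa <- pairsite:::chain_sasa(ch)
  expect_equal(sasa, 4 * pi * (1.70 + 1.4)^2, tolerance = 1e-9)
  # a single isolated residue is (clipped) fully exposed
  toy <- make_toy_complex(toy_complex_spec(seed = 4, n_res_a = 10, n_res_b = 10,
                                           interface_width = 3))
  iso <- protein_pair("iso",
                      new_chain("A", "A", 1, toy$pair$chain_a$atoms[1],
                                toy$pair$chain_a$atom_names[1]),
                      toy$pair$chain_b, "structural")
  acc <- accessibility(iso, "A")
  expect_equal(acc$rel_accessibility[1], 1)
  # residue enclosed in a tight synthetic atom cage is buried
  sph <- function(n, r) {
    z <- 1 - 2 * (seq_len(n) - 0.5) / n
    th <- pi * (3 - sqrt(5)) * seq_len(n)
    cbind(r * sqrt(1 - z^2) * cos(th), r * sqrt(1 - z^2) * sin(th), r * z)
  }
  cage <- sph(150, 3.4)
  caged <- new_chain("A", c("G", "X"), 1:2,
                     list(matrix(0, 1, 3), cage),
                     list("CA", rep("C", nrow(cage))))
  pairc <- protein_pair("c", caged, toy$pair$chain_b, "structural")
  expect_lt(accessibility(pairc, "A")$rel_accessibility[1], 0.05)
})
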