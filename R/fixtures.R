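# Deterministic synthetic-complex generator: toy two-chain complexes with
# geometrically forced interfaces, synthetic sequence profiles, and whole
# benchmark directories, so the full pipeline runs offline.
#
# Backbones are built from ideal internal coordinates (NeRF chain
# extension); side chains are represented by C-beta only, which suffices for
# heavy-atom contacts, exposure and accessibility features.

# ideal backbone geometry (bond lengths in Angstrom, angles in degrees)
.BB <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
            b_ca_cb = 1.521,
            a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
            a_ca_c_o = 120.5, a_n_ca_cb = 110.4,
            t_c_n_ca_cb = -122.6, omega = 180)

# phi/psi templates per geometry; coil cycles through a fixed list
.TEMPLATES <- list(
  helix = list(phi = -57, psi = -47),
  strand = list(phi = -139, psi = 135),
  coil = list(phi = c(-80, -150, -70, -120), psi = c(100, 60, 140, -10)))

# place atom d given a-b-c, bond |cd|, angle b-c-d, torsion a-b-c-d (degrees)
.nerf <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- -torsion * pi / 180  # right-handed dihedral
  bc <- .unit(c - b); ab <- b - a
  n <- .unit(c(ab[2] * bc[3] - ab[3] * bc[2],
               ab[3] * bc[1] - ab[1] * bc[3],
               ab[1] * bc[2] - ab[2] * bc[1]))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * cos(tor) * sin(ang), bond * sin(tor) * sin(ang))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# build one chain's backbone (+O, +CB except Gly) from phi/psi series;
# returns list(atoms, atom_names) per residue
.build_backbone <- function(aa, phi, psi) {
  n <- length(aa)
  g <- .BB
  N <- matrix(0, n, 3); CA <- matrix(0, n, 3); C <- matrix(0, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  ang <- g$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (i in 2:n) {
    N[i, ] <- .nerf(N[i - 1, ], CA[i - 1, ], C[i - 1, ], g$b_c_n, g$a_ca_c_n,
                    psi[i - 1])
    CA[i, ] <- .nerf(CA[i - 1, ], C[i - 1, ], N[i, ], g$b_n_ca, g$a_c_n_ca,
                     g$omega)
    C[i, ] <- .nerf(C[i - 1, ], N[i, ], CA[i, ], g$b_ca_c, g$a_n_ca_c, phi[i])
  }
  atoms <- vector("list", n); nm <- vector("list", n)
  for (i in seq_len(n)) {
    psi_i <- if (i < n) psi[i] else psi[length(psi)]
    O <- .nerf(N[i, ], CA[i, ], C[i, ], g$b_c_o, g$a_ca_c_o, psi_i + 180)
    at <- rbind(N[i, ], CA[i, ], C[i, ], O)
    an <- c("N", "CA", "C", "O")
    if (aa[i] != "G") {
      CB <- .nerf(C[i, ], N[i, ], CA[i, ], g$b_ca_cb, g$a_n_ca_cb,
                  g$t_c_n_ca_cb)
      at <- rbind(at, CB)
      an <- c(an, "CB")
    }
    dimnames(at) <- list(NULL, c("x", "y", "z"))
    atoms[[i]] <- at
    nm[[i]] <- an
  }
  list(atoms = atoms, atom_names = nm)
}

.apply_transform <- function(res, R, t) {
  res$atoms <- lapply(res$atoms, function(m) sweep(m %*% t(R), 2, -t))
  res
}

# rotation taking unit vector u onto unit vector v
.rot_between <- function(u, v) {
  u <- .unit(u); v <- .unit(v)
  w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(w^2)); cth <- sum(u * v)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w <- .unit(p - sum(p * u) * u)
    return(2 * outer(w, w) - diag(3))
  }
  K <- matrix(c(0, w[3], -w[2], -w[3], 0, w[1], w[2], -w[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - cth) / s^2)
}

# rotation by angle (radians) about a unit axis
.rot_axis <- function(u, angle) {
  u <- .unit(u)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# principal axis (unit) and centroid of a point set
.axis <- function(pts) {
  ctr <- colMeans(pts)
  v <- svd(sweep(pts, 2, ctr))$v[, 1]
  list(center = ctr, axis = .unit(v))
}

#' Specification of a synthetic toy complex
#'
#' @param seed Integer seed; fixes sequences, jitter and placement.
#' @param n_res_a,n_res_b Chain lengths (>= 6).
#' @param interface_width Number of residues per chain meant to fall within
#'   contact range of the partner.
#' @param geometry Backbone template: `"strand"` (default), `"helix"` or
#'   `"coil"`.
#' @param feature_informativeness In `[0, 1]`: how strongly synthetic profile
#'   columns correlate with interface membership (0 = none).
#' @param sequence_a,sequence_b Optional fixed sequences (otherwise random).
#' @param interface_center_a,interface_center_b Optional interface center
#'   indices (default: chain midpoints).
#' @return A `ps_toy_spec` list.
#' @export
toy_complex_spec <- function(seed = 1L, n_res_a = 24L, n_res_b = 24L,
                             interface_width = 6L,
                             geometry = c("strand", "helix", "coil"),
                             feature_informativeness = 0.9,
                             sequence_a = NULL, sequence_b = NULL,
                             interface_center_a = NULL,
                             interface_center_b = NULL) {
  geometry <- match.arg(geometry)
  stopifnot(n_res_a >= 6L, n_res_b >= 6L, interface_width >= 1L,
            feature_informativeness >= 0, feature_informativeness <= 1)
  structure(list(seed = as.integer(seed), n_res_a = as.integer(n_res_a),
                 n_res_b = as.integer(n_res_b),
                 interface_width = as.integer(interface_width),
                 geometry = geometry,
                 feature_informativeness = feature_informativeness,
                 sequence_a = sequence_a, sequence_b = sequence_b,
                 interface_center_a = interface_center_a,
                 interface_center_b = interface_center_b),
            class = "ps_toy_spec")
}

# designated interface indices around a center
.iface_idx <- function(center, width, n) {
  lo <- center - (width - 1L) %/% 2L
  idx <- lo:(lo + width - 1L)
  if (any(idx < 1L) || any(idx > n)) stop("interface does not fit in chain")
  idx
}

#' Generate a toy two-chain complex with a forced interface
#'
#' Both chains are built from ideal internal coordinates and placed on a
#' skew-line arrangement: the inter-chain separation is smallest at the
#' designated interface centers and grows monotonically away from them.  The
#' placement gap, tilt and partner roll are searched over a small
#' deterministic grid until exactly `interface_width` residues per chain lie
#' in contact (6.0 Angstrom heavy-atom rule) around the requested centers;
#' the realized contact residues are returned as the interface designation.
#' If no grid point achieves the requested width the geometry request is
#' infeasible and an error is raised.  Ground-truth labels are always
#' recomputed from the coordinates, never hard-coded.
#'
#' @param spec A [toy_complex_spec()].
#' @param complex_id Identifier (default derived from the seed).
#' @return List with the [protein_pair()], its `ps_contact_map`, the
#'   designated `interface_a`/`interface_b` indices and the spec.
#' @export
make_toy_complex <- function(spec, complex_id = sprintf("toy%04d", spec$seed)) {
  .with_seed(spec$seed, {
    seq_a <- spec$sequence_a %||% sample(AA20, spec$n_res_a, replace = TRUE)
    seq_b <- spec$sequence_b %||% sample(AA20, spec$n_res_b, replace = TRUE)
    if (is.character(seq_a) && length(seq_a) == 1L && nchar(seq_a) > 1L)
      seq_a <- strsplit(seq_a, "")[[1]]
    if (is.character(seq_b) && length(seq_b) == 1L && nchar(seq_b) > 1L)
      seq_b <- strsplit(seq_b, "")[[1]]
    tpl <- .TEMPLATES[[spec$geometry]]
    mk_angles <- function(n) list(phi = rep(tpl$phi, length.out = n),
                                  psi = rep(tpl$psi, length.out = n))
    ang_a <- mk_angles(spec$n_res_a); ang_b <- mk_angles(spec$n_res_b)
    res_a <- .build_backbone(seq_a, ang_a$phi, ang_a$psi)
    res_b <- .build_backbone(seq_b, ang_b$phi, ang_b$psi)
    # small jitter breaks exact repeats (helps tessellation non-degeneracy)
    jit <- function(res) {
      res$atoms <- lapply(res$atoms, function(m)
        m + matrix(runif(length(m), -0.05, 0.05), nrow(m), 3))
      res
    }
    res_a <- jit(res_a); res_b <- jit(res_b)
    ca_of <- function(res) t(vapply(seq_along(res$atoms), function(i)
      res$atoms[[i]][match("CA", res$atom_names[[i]]), ], numeric(3)))
    ic_a <- spec$interface_center_a %||% ((spec$n_res_a + 1L) %/% 2L)
    ic_b <- spec$interface_center_b %||% ((spec$n_res_b + 1L) %/% 2L)
    if_a <- .iface_idx(ic_a, spec$interface_width, spec$n_res_a)
    if_b <- .iface_idx(ic_b, spec$interface_width, spec$n_res_b)
    # canonicalize chain A: principal axis -> x, interface centroid -> origin
    ca_a <- ca_of(res_a)
    ax_a <- .axis(ca_a)
    Ra <- .rot_between(ax_a$axis, c(1, 0, 0))
    ctr_a <- colMeans(ca_a[if_a, , drop = FALSE])
    res_a <- .apply_transform(res_a, Ra, -as.vector(Ra %*% ctr_a))
    ca_b0 <- ca_of(res_b)
    ax_b <- .axis(ca_b0)
    ctr_b <- colMeans(ca_b0[if_b, , drop = FALSE])
    hw <- (spec$interface_width + 1) / 2
    rise <- mean(sqrt(rowSums(diff(ca_of(res_a))^2)))
    chain_a <- new_chain("A", seq_a, seq_len(spec$n_res_a), res_a$atoms,
                         res_a$atom_names)
    mk_pair <- function(gap, sin_tilt, roll) {
      Rroll <- .rot_axis(ax_b$axis, roll)
      dir <- c(sqrt(1 - sin_tilt^2), 0, sin_tilt)
      Rb <- .rot_between(ax_b$axis, dir) %*% Rroll
      t_b <- c(0, gap, 0) - as.vector(Rb %*% ctr_b)
      res_b2 <- .apply_transform(res_b, Rb, t_b)
      chain_b <- new_chain("B", seq_b, seq_len(spec$n_res_b), res_b2$atoms,
                           res_b2$atom_names)
      protein_pair(complex_id, chain_a, chain_b, "structural")
    }
    # adaptive search: roll the partner around its axis, tilt the skew
    # angle, and sweep the gap until exactly `interface_width` residues per
    # chain are in contact, centered at the requested interface positions
    target_sin <- pmin(0.92, 3.5 / (hw * rise))
    w <- spec$interface_width
    best <- NULL
    for (roll in c(0, pi / 2, pi, 3 * pi / 2, pi / 4, 5 * pi / 4)) {
      for (st in unique(pmin(0.95, target_sin * c(1, 1.3, 0.75, 1.6, 0.55, 2)))) {
        for (gap in seq(6.2, 9.8, by = 0.2)) {
          pair <- mk_pair(gap, st, roll)
          cm <- compute_contacts(pair)
          got_a <- which(rowSums(cm$labels) > 0)
          got_b <- which(colSums(cm$labels) > 0)
          if (length(got_a) == w && length(got_b) == w &&
              abs(mean(got_a) - mean(if_a)) <= 2.5 &&
              abs(mean(got_b) - mean(if_b)) <= 2.5) {
            best <- list(pair = pair, contacts = cm,
                         iface_a = got_a, iface_b = got_b)
            break
          }
        }
        if (!is.null(best)) break
      }
      if (!is.null(best)) break
    }
    if (is.null(best))
      stop("infeasible geometry request: no placement yields an interface of the designated width")
    list(pair = best$pair, contacts = best$contacts,
         interface_a = as.integer(best$iface_a),
         interface_b = as.integer(best$iface_b),
         spec = spec)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a toy complex as a PDB file
#'
#' Minimal but valid ATOM records (chains A/B, element column set), suitable
#' for [load_structure()].
#'
#' @param toy Output of [make_toy_complex()].
#' @param path Output path.
#' @export
write_toy_pdb <- function(toy, path) {
  lines <- character(0)
  serial <- 0L
  one_to_three <- setNames(names(AA_THREE_TO_ONE)[1:20], AA_THREE_TO_ONE[1:20])
  for (chain in list(toy$pair$chain_a, toy$pair$chain_b)) {
    for (i in seq_len(chain_length(chain))) {
      at <- chain$atoms[[i]]; an <- chain$atom_names[[i]]
      res3 <- one_to_three[[chain$aa[i]]]
      for (k in seq_len(nrow(at))) {
        serial <- serial + 1L
        lines <- c(lines, sprintf(
          "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, an[k], res3, chain$chain_id, chain$res_number[i],
          at[k, 1], at[k, 2], at[k, 3], substr(an[k], 1, 1)))
      }
    }
    lines <- c(lines, "TER")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Synthetic sequence profiles correlated with interface membership
#'
#' Emulates the noisy relationship between conservation and interface
#' membership seen in real profiles: every residue draws a baseline
#' concentration (mass piled on its own amino acid), a minority of residues
#' anywhere in the chain are spuriously conserved, and interface residues
#' add an extra concentration boost of random per-residue strength scaled by
#' `informativeness` (0 makes both classes identically distributed; 1 gives
#' a strong but still overlapping separation).  Columns are quantized to
#' integer percentages (largest-remainder rounding) and integer half-bit
#' log-odds so files written with [write_pssm()] round-trip exactly through
#' [read_pssm()].
#'
#' @param pair A [protein_pair()].
#' @param interface_a,interface_b Interface residue indices per chain.
#' @param informativeness In `[0, 1]`.
#' @param seed Integer seed.
#' @return List with profile objects `a` and `b`.
#' @export
make_synthetic_profiles <- function(pair, interface_a, interface_b,
                                    informativeness = 0.9, seed = 1L) {
  stopifnot(informativeness >= 0, informativeness <= 1)
  mk <- function(chain, iface, sub_seed) .with_seed(sub_seed, {
    n <- chain_length(chain)
    lo <- matrix(0, n, 20); fq <- matrix(0, n, 20); info <- numeric(n)
    # baseline concentration with occasional spurious conservation (both
    # classes), plus an interface boost of random strength
    spur <- (runif(n) < 0.2) * runif(n, 1, 5)
    boost <- informativeness * 8 * runif(n, 0.25, 1)
    for (i in seq_len(n)) {
      w <- 0.6 + spur[i] + boost[i] * (i %in% iface)
      raw <- runif(20, 0.5, 1.5)
      k <- match(chain$aa[i], AA20)
      if (!is.na(k)) raw[k] <- raw[k] + w
      p <- raw / sum(raw)
      # largest-remainder quantization to integer percentages
      f100 <- floor(p * 100)
      rem <- p * 100 - f100
      short <- 100L - sum(f100)
      if (short > 0) {
        add <- order(rem, decreasing = TRUE)[seq_len(short)]
        f100[add] <- f100[add] + 1
      }
      p <- f100 / 100
      fq[i, ] <- p
      lo[i, ] <- round(pmax(pmin(2 * log2(pmax(p, 1e-3) / AA_BACKGROUND), 12), -10))
      info[i] <- round(sum(p[p > 0] * log2(p[p > 0] / AA_BACKGROUND[p > 0])), 2)
    }
    new_profile(lo, fq, info)
  })
  list(a = mk(pair$chain_a, interface_a, .complex_seed(seed, "profA")),
       b = mk(pair$chain_b, interface_b, .complex_seed(seed, "profB")))
}

#' Generate a benchmark directory of toy complexes
#'
#' Writes `n_complexes` toy complexes (varied lengths, interface widths and
#' placements; deterministic per-complex seeds derived from `seed`) with PDB,
#' FASTA and PSSM files plus a JSON manifest, ready for [load_benchmark()]
#' and leave-one-out evaluation.  With `n_shared > 0`, the first `n_shared`
#' complexes are paired with an extra complex re-using the same chain-A
#' sequence but a different partner and interface location; the shared
#' chain's profile marks the union of its interfaces, as conservation on a
#' real multi-partner protein would.
#'
#' @param n_complexes Number of base complexes (>= 2).
#' @param dir Output directory (created).
#' @param seed Integer master seed.
#' @param informativeness Profile informativeness in `[0, 1]`.
#' @param n_shared Number of shared-protein complex pairs to append.
#' @return The manifest as a data frame (invisibly writes files).
#' @export
make_benchmark_set <- function(n_complexes, dir, seed = 1L,
                               informativeness = 0.9, n_shared = 0L) {
  stopifnot(n_complexes >= 2L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lengths_a <- rep(c(22L, 26L, 30L, 24L, 28L, 32L), length.out = n_complexes)
  lengths_b <- rep(c(24L, 28L, 22L, 30L, 26L, 20L), length.out = n_complexes)
  widths <- rep(c(6L, 5L, 7L), length.out = n_complexes)
  entries <- list()
  build_one <- function(id, spec, prof_iface_a = NULL) {
    # rare placement failures retry under a deterministically bumped seed
    toy <- NULL
    for (attempt in 0:9) {
      sp <- spec
      sp$seed <- as.integer((spec$seed + attempt * 7919L) %% 2147483647L)
      toy <- tryCatch(make_toy_complex(sp, complex_id = id),
                      error = function(e) NULL)
      if (!is.null(toy)) break
    }
    if (is.null(toy)) stop(sprintf("could not place complex %s", id))
    prof <- make_synthetic_profiles(
      toy$pair, prof_iface_a %||% toy$interface_a, toy$interface_b,
      informativeness, seed = .complex_seed(seed, id))
    pdb <- file.path(dir, paste0(id, ".pdb"))
    write_toy_pdb(toy, pdb)
    fasta <- file.path(dir, paste0(id, ".fasta"))
    writeLines(c(paste0(">", id, "_A"), chain_sequence(toy$pair$chain_a),
                 paste0(">", id, "_B"), chain_sequence(toy$pair$chain_b)), fasta)
    pa <- file.path(dir, paste0(id, "_A.pssm"))
    pb <- file.path(dir, paste0(id, "_B.pssm"))
    write_pssm(prof$a, toy$pair$chain_a$aa, pa)
    write_pssm(prof$b, toy$pair$chain_b$aa, pb)
    list(complex_id = id, pdb = basename(pdb), fasta = basename(fasta),
         pssm_a = basename(pa), pssm_b = basename(pb),
         chain_a = "A", chain_b = "B",
         interface_a = toy$interface_a, interface_b = toy$interface_b,
         toy = toy)
  }
  for (k in seq_len(n_complexes)) {
    id <- sprintf("cx%03d", k)
    spec <- toy_complex_spec(seed = .complex_seed(seed, id),
                             n_res_a = lengths_a[k], n_res_b = lengths_b[k],
                             interface_width = widths[k],
                             feature_informativeness = informativeness)
    entries[[id]] <- build_one(id, spec)
  }
  if (n_shared > 0L) {
    for (k in seq_len(min(n_shared, n_complexes))) {
      base <- entries[[sprintf("cx%03d", k)]]
      id <- sprintf("cx%03dS", k)
      seq_a <- strsplit(chain_sequence(base$toy$pair$chain_a), "")[[1]]
      na <- length(seq_a)
      alt_center <- if (base$interface_a[1] > na / 2) 5L + (base$toy$spec$interface_width %/% 2L)
                    else na - 4L - (base$toy$spec$interface_width %/% 2L)
      spec <- toy_complex_spec(seed = .complex_seed(seed, id),
                               n_res_a = na,
                               n_res_b = lengths_b[(k %% length(lengths_b)) + 1L],
                               interface_width = base$toy$spec$interface_width,
                               feature_informativeness = informativeness,
                               sequence_a = seq_a,
                               interface_center_a = alt_center)
      entries[[id]] <- build_one(id, spec)
      # union-marked profile for the shared chain in both complexes
      for (pair_k in c(sprintf("cx%03d", k), id)) {
        e <- entries[[pair_k]]
        union_iface <- sort(unique(c(base$interface_a, entries[[id]]$interface_a)))
        prof <- make_synthetic_profiles(
          e$toy$pair, union_iface, e$toy$interface_b, informativeness,
          seed = .complex_seed(seed, pair_k))
        write_pssm(prof$a, e$toy$pair$chain_a$aa, file.path(dir, e$pssm_a))
      }
    }
  }
  manifest <- lapply(entries, function(e) e[setdiff(names(e), "toy")])
  jsonlite::write_json(unname(manifest), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(entries)
}

#' Load a benchmark directory
#'
#' Reads the manifest and returns encoded complexes ready for training or
#' evaluation.
#'
#' @param dir Directory written by [make_benchmark_set()].
#' @param mode `"structural"` (PDB + profiles) or `"sequence"` (FASTA +
#'   profiles).
#' @return List of `ps_encoded` complexes.
#' @export
load_benchmark <- function(dir, mode = c("structural", "sequence")) {
  mode <- match.arg(mode)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  lapply(manifest, function(e) {
    pair <- if (mode == "structural")
      load_structure(file.path(dir, e$pdb), e$chain_a, e$chain_b,
                     complex_id = e$complex_id)
    else load_fasta_pair(file.path(dir, e$fasta), complex_id = e$complex_id)
    pa <- read_pssm(file.path(dir, e$pssm_a), chain_length(pair$chain_a))
    pb <- read_pssm(file.path(dir, e$pssm_b), chain_length(pair$chain_b))
    enc <- encode_complex(pair, pa, pb)
    if (mode == "sequence") {
      # contact labels still come from the solved structure
      spair <- load_structure(file.path(dir, e$pdb), e$chain_a, e$chain_b,
                              complex_id = e$complex_id)
      enc$contacts <- compute_contacts(spair)
    }
    enc
  })
}
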