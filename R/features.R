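# Single-residue features: identity one-hot, sequence profiles, conservation,
# half-sphere exposure, secondary structure, solvent accessibility.
#
# External feature generators (PSI-BLAST, AL2CO, DSSP, PSAIA) are replaced by
# internal providers behind the same interface; profile files in the
# PSI-BLAST ASCII dialect can still be ingested directly.

# PSI-BLAST column order of PSSM files (differs from the alphabetical order
# used internally).
PSIBLAST_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' One-hot encode a residue identity
#'
#' @param aa Single one-letter code from the 22-symbol alphabet
#'   ([AA_ALPHABET22]): 20 standard residues, `X`, gap.
#' @return Binary vector of length 22 with exactly one element set.
#' @export
one_hot_aa <- function(aa) {
  k <- match(aa, AA_ALPHABET22)
  if (length(aa) != 1L || is.na(k))
    stop(sprintf("unknown residue symbol '%s'", paste(aa, collapse = "")))
  v <- numeric(22)
  v[k] <- 1
  names(v) <- AA_ALPHABET22
  v
}

# container for per-chain profiles: log-odds and frequency matrices (n x 20,
# columns in alphabetical AA order) plus per-position information content
new_profile <- function(log_odds, frequencies, info) {
  stopifnot(ncol(log_odds) == 20L, ncol(frequencies) == 20L,
            nrow(log_odds) == nrow(frequencies),
            length(info) == nrow(log_odds))
  colnames(log_odds) <- AA20
  colnames(frequencies) <- AA20
  structure(list(log_odds = log_odds, frequencies = frequencies,
                 info = as.numeric(info)),
            class = "ps_profile")
}

profile_length <- function(profile) nrow(profile$log_odds)

#' Read a PSI-BLAST ASCII PSSM file
#'
#' Expects the standard dialect: a header line naming 20 log-odds columns and
#' 20 percentage columns, one row per sequence position, and trailing
#' per-position statistics (the first of which is kept as information
#' content).  Percentages are converted to frequencies in `[0, 1]`; columns
#' are reordered to the package's alphabetical amino-acid order.
#'
#' @param path Path to the PSSM file.
#' @param expected_length Optional chain length; a row-count mismatch raises
#'   an error.
#' @return A profile object with `log_odds`, `frequencies` (`n x 20`) and
#'   `info` (length `n`).
#' @export
read_pssm <- function(path, expected_length = NULL) {
  lines <- readLines(path)
  rows <- grep("^\\s*[0-9]+\\s+[A-ZX-]\\s", lines, value = TRUE)
  if (length(rows) == 0L) stop("no PSSM rows found in file")
  parsed <- lapply(strsplit(trimws(rows), "\\s+"), identity)
  nf <- vapply(parsed, length, integer(1))
  if (any(nf < 42L)) stop("malformed PSSM row: expected 20 log-odds and 20 percentage columns")
  n <- length(parsed)
  lo <- matrix(0, n, 20); fq <- matrix(0, n, 20); info <- numeric(n)
  for (i in seq_len(n)) {
    v <- parsed[[i]]
    lo[i, ] <- as.numeric(v[3:22])
    fq[i, ] <- as.numeric(v[23:42]) / 100
    info[i] <- if (length(v) >= 43L) as.numeric(v[43]) else 0
  }
  ord <- match(AA20, PSIBLAST_ORDER)
  lo <- lo[, ord, drop = FALSE]
  fq <- fq[, ord, drop = FALSE]
  if (!is.null(expected_length) && n != expected_length)
    stop(sprintf("PSSM has %d rows but chain has %d residues", n, expected_length))
  new_profile(lo, fq, info)
}

#' Write a profile in the PSI-BLAST ASCII dialect
#'
#' Inverse of [read_pssm()]; used by the synthetic-data generator.
#'
#' @param profile A profile object.
#' @param sequence One-letter residue codes (length must match the profile).
#' @param path Output path.
#' @export
write_pssm <- function(profile, sequence, path) {
  stopifnot(length(sequence) == profile_length(profile))
  ord <- match(PSIBLAST_ORDER, AA20)
  hdr <- paste(c(sprintf("%4s", PSIBLAST_ORDER), sprintf("%4s", PSIBLAST_ORDER)),
               collapse = "")
  out <- c("", "Last position-specific scoring matrix computed", paste0("      ", hdr))
  for (i in seq_len(profile_length(profile))) {
    out <- c(out, paste0(
      sprintf("%5d %s ", i, sequence[i]),
      paste(sprintf("%4d", round(profile$log_odds[i, ord])), collapse = ""),
      paste(sprintf("%4d", round(100 * profile$frequencies[i, ord])), collapse = ""),
      sprintf(" %5.2f", profile$info[i])))
  }
  writeLines(out, path)
  invisible(path)
}

#' Deterministic substitution-matrix pseudo-profile
#'
#' Fallback provider when no profile file is supplied: the log-odds row of a
#' residue is its BLOSUM62 row (zeros for `X`), and frequencies are the
#' background-weighted softmax of that row in half-bit units, so a chain with
#' no homolog information still yields a well-formed profile.
#'
#' @param sequence Character vector of one-letter codes (or a single string).
#' @return A profile object (see [read_pssm()]).
#' @export
pseudo_profile <- function(sequence) {
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1]]
  if (length(sequence) == 0L) stop("empty sequence")
  if (!all(sequence %in% AA_ALPHABET22[1:21]))
    stop("unknown residue symbol in sequence")
  B <- blosum62()
  n <- length(sequence)
  lo <- matrix(0, n, 20); fq <- matrix(0, n, 20); info <- numeric(n)
  for (i in seq_len(n)) {
    s <- if (sequence[i] == "X") rep(0, 20) else as.numeric(B[sequence[i], ])
    lo[i, ] <- s
    w <- AA_BACKGROUND * 2^(s / 2)   # BLOSUM scores are half-bits
    p <- w / sum(w)
    fq[i, ] <- p
    info[i] <- sum(p * log2(p / AA_BACKGROUND))
  }
  new_profile(lo, fq, info)
}

#' Profile conservation score
#'
#' Normalized Shannon-entropy conservation of a frequency column:
#' `1 - H(p) / log(20)`, in `[0, 1]`, 1 = fully conserved.  Accepts a single
#' frequency vector or a profile object (vectorized over positions).
#'
#' @param x Frequency vector of length 20, or a profile object.
#' @return Conservation score(s) in `[0, 1]`.
#' @export
conservation <- function(x) {
  if (inherits(x, "ps_profile"))
    return(apply(x$frequencies, 1, conservation))
  p <- as.numeric(x)
  if (all(p == 0)) stop("all-zero frequency column")
  p <- p / sum(p)
  p <- p[p > 0]
  h <- -sum(p * log(p))
  1 - h / log(20)
}

# ---------------------------------------------------------------------------
# Structural single-residue features

# unit vector or zero vector if degenerate
.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (!is.finite(n) || n < 1e-9) c(0, 0, 0) else v / n
}

#' Half-sphere exposure and contact number
#'
#' Counts neighboring C-alpha atoms within `radius` of each residue's
#' C-alpha, split into the hemisphere toward the side chain (`hse_up`) and
#' the opposite one (`hse_down`).  The side-chain direction is the
#' C-alpha-to-C-beta vector when a C-beta atom exists, otherwise a pseudo
#' C-beta direction built from the flanking C-alpha positions (covers
#' glycine).  `contact_number = hse_up + hse_down`.
#'
#' @param chain A `ps_chain` with coordinates.
#' @param radius Sphere radius in Angstrom (default 12).
#' @return Data frame with columns `hse_up`, `hse_down`, `contact_number`
#'   and a logical `flagged` column for residues without a C-alpha.
#' @export
half_sphere_exposure <- function(chain, radius = 12) {
  n <- chain_length(chain)
  ca <- chain$ca
  if (is.null(ca)) stop("half_sphere_exposure requires coordinates")
  up <- integer(n); down <- integer(n); flagged <- logical(n)
  has_ca <- !is.na(ca[, 1])
  for (i in seq_len(n)) {
    if (!has_ca[i]) { flagged[i] <- TRUE; next }
    # side-chain direction
    k <- match("CB", chain$atom_names[[i]])
    if (!is.na(k)) {
      dir <- .unit(chain$atoms[[i]][k, ] - ca[i, ])
    } else {
      v <- c(0, 0, 0)
      if (i > 1L && has_ca[i - 1L]) v <- v + (ca[i, ] - ca[i - 1L, ])
      if (i < n && has_ca[i + 1L]) v <- v + (ca[i, ] - ca[i + 1L, ])
      dir <- .unit(v)
    }
    for (j in seq_len(n)) {
      if (j == i || !has_ca[j]) next
      d <- ca[j, ] - ca[i, ]
      if (sum(d^2) <= radius^2) {
        if (sum(d * dir) > 0) up[i] <- up[i] + 1L else down[i] <- down[i] + 1L
      }
    }
  }
  data.frame(hse_up = up, hse_down = down, contact_number = up + down,
             flagged = flagged)
}

# dihedral angle (degrees) of four points
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# backbone atom of residue i, or NULL
.bb_atom <- function(chain, i, name) {
  k <- match(name, chain$atom_names[[i]])
  if (is.na(k)) NULL else chain$atoms[[i]][k, ]
}

SS_CLASSES <- c("H", "G", "I", "E", "B", "T", "S", "-")

#' Backbone-dihedral secondary-structure assignment
#'
#' Internal assigner over the 8-class alphabet (`H G I E B T S -`) using
#' phi/psi dihedral rules: residues in the canonical alpha region form `H`
#' runs (length >= 4), shorter alpha runs of 3 become `G` (single/double
#' alpha residues `T`), residues in the beta region form `E` runs (length
#' >= 2), and everything else, including residues with missing backbone
#' atoms and chain termini, is `-`.  The `I`, `B` and `S` classes are never
#' emitted by these rules but remain part of the one-hot alphabet so that
#' externally ingested assignments fit the same encoding.
#'
#' @param chain A `ps_chain` with backbone coordinates.
#' @return Character vector of per-residue classes.
#' @export
secondary_structure <- function(chain) {
  n <- chain_length(chain)
  if (is.null(chain$atoms)) stop("secondary_structure requires coordinates")
  phi <- rep(NA_real_, n); psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    Ni <- .bb_atom(chain, i, "N"); CAi <- .bb_atom(chain, i, "CA")
    Ci <- .bb_atom(chain, i, "C")
    if (is.null(Ni) || is.null(CAi) || is.null(Ci)) next
    if (i > 1L) {
      Cp <- .bb_atom(chain, i - 1L, "C")
      if (!is.null(Cp)) phi[i] <- .dihedral(Cp, Ni, CAi, Ci)
    }
    if (i < n) {
      Nn <- .bb_atom(chain, i + 1L, "N")
      if (!is.null(Nn)) psi[i] <- .dihedral(Ni, CAi, Ci, Nn)
    }
  }
  alpha <- !is.na(phi) & !is.na(psi) &
    phi >= -100 & phi <= -30 & psi >= -80 & psi <= -5
  beta <- !is.na(phi) & !is.na(psi) &
    phi >= -180 & phi <= -45 & (psi >= 90 | psi <= -170)
  ss <- rep("-", n)
  r <- rle(alpha)
  pos <- cumsum(c(1L, r$lengths))
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    idx <- pos[k]:(pos[k] + r$lengths[k] - 1L)
    ss[idx] <- if (r$lengths[k] >= 4L) "H" else if (r$lengths[k] == 3L) "G" else "T"
  }
  r <- rle(beta & ss == "-")
  pos <- cumsum(c(1L, r$lengths))
  for (k in seq_along(r$values)) {
    if (!r$values[k] || r$lengths[k] < 2L) next
    ss[pos[k]:(pos[k] + r$lengths[k] - 1L)] <- "E"
  }
  ss
}

# per-atom radii for a residue's heavy atoms
.atom_radii <- function(atom_names) {
  el <- .atom_element(atom_names)
  r <- VDW_RADII[el]
  r[is.na(r)] <- VDW_DEFAULT
  unname(r)
}

# raw per-residue SASA of an isolated chain (A^2)
chain_sasa <- function(chain, probe = 1.4, n_sphere = 100) {
  resolved <- chain_resolved(chain)
  idx <- which(resolved)
  sasa <- numeric(chain_length(chain))
  if (length(idx)) {
    xyz <- do.call(rbind, chain$atoms[idx])
    radii <- unlist(lapply(chain$atom_names[idx], .atom_radii))
    per_atom <- sasa_atoms(xyz, radii, probe, n_sphere)
    grp <- rep(seq_along(idx), vapply(chain$atoms[idx], nrow, integer(1)))
    sasa[idx] <- as.numeric(tapply(per_atom, grp, sum))
  }
  sasa
}

#' Relative solvent accessibility of the unbound chains
#'
#' Rolling-probe (Shrake-Rupley) SASA of the isolated chain, summed per
#' residue and normalized by the residue type's theoretical maximum, clipped
#' to `[0, 1]`.  Residues with no atoms get 0 and are flagged.
#'
#' @param pair A structural [protein_pair()].
#' @param which `"A"` or `"B"`: which partner to compute.
#' @param probe Probe radius in Angstrom (default 1.4).
#' @return Data frame with columns `rel_accessibility` and `flagged`.
#' @export
accessibility <- function(pair, which = c("A", "B"), probe = 1.4) {
  which <- match.arg(which)
  chain <- if (which == "A") pair$chain_a else pair$chain_b
  resolved <- chain_resolved(chain)
  sasa <- chain_sasa(chain, probe = probe)
  mx <- MAX_ASA[chain$aa]
  mx[is.na(mx)] <- MAX_ASA[["X"]]
  rel <- pmin(pmax(sasa / mx, 0), 1)
  rel[!resolved] <- 0
  data.frame(rel_accessibility = rel, flagged = !resolved)
}
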