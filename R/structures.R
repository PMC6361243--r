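# Data model for two-chain complexes and residue-residue contact labeling.

#' Construct a protein chain
#'
#' A chain is an ordered list of residues with one-letter codes, author
#' residue numbers and (optionally) heavy-atom coordinates.  `seq_index` is
#' purely positional (1-based, gap-free): insertion codes and numbering gaps
#' in the source file do not perturb it, so sliding windows stay well defined.
#'
#' @param chain_id Single chain identifier.
#' @param aa Character vector of one-letter residue codes (20 standard plus
#'   `X`); the gap symbol is reserved for window padding and not allowed here.
#' @param res_number Author residue numbers (integer; `NA` for residues that
#'   have no coordinates, e.g. present in SEQRES only).
#' @param atoms List (one element per residue) of numeric matrices with
#'   columns x, y, z holding heavy-atom coordinates in Angstrom; a 0-row
#'   matrix marks an unresolved residue.  `NULL` for sequence-only chains.
#' @param atom_names List of character vectors naming each heavy atom
#'   (e.g. `"CA"`), parallel to `atoms`.
#' @return An object of class `ps_chain`.
#' @export
new_chain <- function(chain_id, aa, res_number = seq_along(aa),
                      atoms = NULL, atom_names = NULL) {
  aa <- as.character(aa)
  stopifnot(length(aa) >= 1L, all(aa %in% AA_ALPHABET22[1:21]))
  n <- length(aa)
  if (is.null(atoms)) {
    atoms <- NULL
    ca <- NULL
  } else {
    stopifnot(length(atoms) == n, length(atom_names) == n)
    atoms <- lapply(atoms, function(m) {
      m <- as.matrix(m)
      if (nrow(m) > 0L) {
        storage.mode(m) <- "double"
        if (any(!is.finite(m))) stop("non-finite atom coordinate")
      }
      dimnames(m) <- list(NULL, c("x", "y", "z"))
      m
    })
    ca <- t(vapply(seq_len(n), function(i) {
      k <- match("CA", atom_names[[i]])
      if (is.na(k)) rep(NA_real_, 3) else atoms[[i]][k, ]
    }, numeric(3)))
    colnames(ca) <- c("x", "y", "z")
  }
  structure(list(
    chain_id = as.character(chain_id),
    aa = aa,
    res_number = as.integer(res_number),
    seq_index = seq_len(n),
    atoms = atoms,
    atom_names = atom_names,
    ca = ca
  ), class = "ps_chain")
}

chain_length <- function(chain) length(chain$aa)

chain_sequence <- function(chain) paste(chain$aa, collapse = "")

# TRUE per residue when at least one heavy atom is present
chain_resolved <- function(chain) {
  if (is.null(chain$atoms)) rep(FALSE, chain_length(chain))
  else vapply(chain$atoms, nrow, integer(1)) > 0L
}

#' Construct a two-chain complex
#'
#' @param complex_id Identifier for the complex instance.
#' @param chain_a,chain_b `ps_chain` objects (see [new_chain()]).
#' @param mode `"structural"` (heavy atoms available) or `"sequence"`.
#' @return An object of class `ps_pair`.
#' @export
protein_pair <- function(complex_id, chain_a, chain_b,
                         mode = c("structural", "sequence")) {
  mode <- match.arg(mode)
  stopifnot(inherits(chain_a, "ps_chain"), inherits(chain_b, "ps_chain"))
  if (chain_length(chain_a) == 0L || chain_length(chain_b) == 0L)
    stop("both chains must be non-empty")
  if (mode == "structural" && (is.null(chain_a$atoms) || is.null(chain_b$atoms)))
    stop("structural mode requires atom coordinates on both chains")
  structure(list(complex_id = as.character(complex_id),
                 chain_a = chain_a, chain_b = chain_b, mode = mode),
            class = "ps_pair")
}

#' @export
print.ps_pair <- function(x, ...) {
  cat(sprintf("<ps_pair> %s: chain %s (%d aa) x chain %s (%d aa), %s mode\n",
              x$complex_id, x$chain_a$chain_id, chain_length(x$chain_a),
              x$chain_b$chain_id, chain_length(x$chain_b), x$mode))
  invisible(x)
}

# Swap the two chain roles (used by symmetry code and tests).
swap_pair <- function(pair) {
  protein_pair(pair$complex_id, pair$chain_b, pair$chain_a, pair$mode)
}

# ---------------------------------------------------------------------------
# PDB loading

# element of an atom from its PDB atom name (digits stripped, first letter;
# two-letter selenium recognised)
.atom_element <- function(elety) {
  nm <- gsub("[0-9']", "", toupper(elety))
  ifelse(substr(nm, 1, 2) == "SE", "SE", substr(nm, 1, 1))
}

.parse_chain_atoms <- function(at, chain_id) {
  at <- at[at$chain == chain_id, , drop = FALSE]
  if (nrow(at) == 0L) stop(sprintf("chain '%s' not found in structure", chain_id))
  # drop waters
  at <- at[!(toupper(at$resid) %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  # keep heavy atoms, altloc blank or A
  elem <- .atom_element(at$elety)
  at <- at[!(elem %in% c("H", "D")) & (is.na(at$alt) | at$alt %in% c("", "A")), ,
           drop = FALSE]
  if (nrow(at) == 0L) stop(sprintf("chain '%s' has no protein residues", chain_id))
  key <- paste(at$resno, at$insert, sep = "|")
  ukey <- unique(key)
  res <- lapply(ukey, function(k) at[key == k, , drop = FALSE])
  # amino-acid residues: standard names, or HETATM entries with a peptide
  # backbone (N, CA, C) -- covers MSE and other modified residues; anything
  # else (ligands, ions) is excluded
  is_aa <- vapply(res, function(r) {
    toupper(r$resid[1]) %in% names(AA_THREE_TO_ONE) ||
      all(c("N", "CA", "C") %in% r$elety)
  }, logical(1))
  res <- res[is_aa]
  if (length(res) == 0L) stop(sprintf("chain '%s' has no protein residues", chain_id))
  list(
    aa = vapply(res, function(r) three_to_one(r$resid[1]), character(1)),
    res_number = vapply(res, function(r) as.integer(r$resno[1]), integer(1)),
    atoms = lapply(res, function(r) as.matrix(r[, c("x", "y", "z")])),
    atom_names = lapply(res, function(r) r$elety)
  )
}

# Merge SEQRES-only residues into an ATOM-derived chain by global alignment.
# SEQRES positions not matched to an ATOM residue become unresolved residues
# (empty atom matrix, res_number NA) so they stay available for sequence
# features while contributing nothing to geometry.
.merge_seqres <- function(parsed, seqres3) {
  seq_full <- three_to_one(seqres3)
  seq_atom <- parsed$aa
  if (length(seq_full) <= length(seq_atom)) return(parsed)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(paste(seq_atom, collapse = "")),
    Biostrings::AAString(paste(seq_full, collapse = "")),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 4,
    type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  su <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ia <- 0L
  out_aa <- character(0); out_num <- integer(0)
  out_atoms <- list(); out_names <- list()
  empty <- matrix(numeric(0), 0, 3, dimnames = list(NULL, c("x", "y", "z")))
  for (k in seq_along(pa)) {
    if (su[k] == "-") { if (pa[k] != "-") ia <- ia + 1L; next }
    if (pa[k] != "-") {
      ia <- ia + 1L
      out_aa <- c(out_aa, seq_atom[ia])
      out_num <- c(out_num, parsed$res_number[ia])
      out_atoms <- c(out_atoms, parsed$atoms[ia])
      out_names <- c(out_names, parsed$atom_names[ia])
    } else {
      out_aa <- c(out_aa, su[k])
      out_num <- c(out_num, NA_integer_)
      out_atoms <- c(out_atoms, list(empty))
      out_names <- c(out_names, list(character(0)))
    }
  }
  out_aa[!out_aa %in% AA_ALPHABET22[1:21]] <- "X"
  list(aa = out_aa, res_number = out_num, atoms = out_atoms,
       atom_names = out_names)
}

#' Load a two-chain complex from a PDB file
#'
#' Reads the first model, keeps heavy atoms (hydrogens and alternate
#' locations beyond `A` discarded), excludes waters and non-peptide ligands,
#' maps nonstandard residue names (MSE to M, others to X) and retains
#' SEQRES-only residues as unresolved (coordinate-less) entries.
#'
#' @param path Path to a PDB file.
#' @param chain_a_id,chain_b_id Chain identifiers of the two partners.
#' @param complex_id Optional complex label; defaults to the file base name.
#' @return A [protein_pair()] in structural mode.
#' @export
load_structure <- function(path, chain_a_id, chain_b_id,
                           complex_id = sub("\\.pdb$", "", basename(path))) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  mk <- function(cid) {
    parsed <- .parse_chain_atoms(pdb$atom, cid)
    if (!is.null(pdb$seqres) && any(names(pdb$seqres) == cid))
      parsed <- .merge_seqres(parsed, unname(pdb$seqres[names(pdb$seqres) == cid]))
    new_chain(cid, parsed$aa, parsed$res_number, parsed$atoms, parsed$atom_names)
  }
  protein_pair(complex_id, mk(chain_a_id), mk(chain_b_id), "structural")
}

#' Load a two-chain complex from a FASTA file (sequence-only mode)
#'
#' The first two records become chains A and B.
#'
#' @inheritParams load_structure
#' @return A [protein_pair()] in sequence mode.
#' @export
load_fasta_pair <- function(path, complex_id = sub("\\.(fa|fasta)$", "", basename(path))) {
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) < 2L) stop("FASTA must contain at least two records")
  mk <- function(k, cid) {
    aa <- strsplit(as.character(ss[[k]]), "")[[1]]
    aa[!aa %in% AA_ALPHABET22[1:21]] <- "X"
    new_chain(cid, aa)
  }
  protein_pair(complex_id, mk(1L, "A"), mk(2L, "B"), "sequence")
}

# ---------------------------------------------------------------------------
# Contact maps

#' Label interacting residue pairs of a complex
#'
#' A cross-chain residue pair is a contact when the minimum distance over all
#' heavy-atom pairs is strictly below `threshold` (default 6.0 Angstrom).
#' Pairs where either residue has no resolved heavy atom are labeled
#' non-contact and flagged in the `flagged` matrix.
#'
#' @param pair A structural-mode [protein_pair()].
#' @param threshold Contact distance threshold in Angstrom (strict `<`).
#' @return An object of class `ps_contact_map`: `labels` is a logical
#'   `len(A) x len(B)` matrix, `flagged` marks pairs with missing geometry.
#' @export
compute_contacts <- function(pair, threshold = 6.0) {
  if (pair$mode != "structural")
    stop("compute_contacts requires a structural-mode pair")
  na <- chain_length(pair$chain_a); nb <- chain_length(pair$chain_b)
  lab <- matrix(FALSE, na, nb)
  flg <- matrix(FALSE, na, nb)
  res_a <- chain_resolved(pair$chain_a); res_b <- chain_resolved(pair$chain_b)
  flg[!res_a, ] <- TRUE
  flg[, !res_b] <- TRUE
  ia <- which(res_a); ib <- which(res_b)
  if (length(ia) && length(ib)) {
    A <- do.call(rbind, pair$chain_a$atoms[ia])
    B <- do.call(rbind, pair$chain_b$atoms[ib])
    ra <- rep(seq_along(ia), vapply(pair$chain_a$atoms[ia], nrow, integer(1)))
    rb <- rep(seq_along(ib), vapply(pair$chain_b$atoms[ib], nrow, integer(1)))
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    mind <- min_by_group(d2, ra, rb, length(ia), length(ib))
    lab[ia, ib] <- sqrt(pmax(mind, 0)) < threshold
  }
  structure(list(complex_id = pair$complex_id, labels = lab,
                 flagged = flg, threshold = threshold),
            class = "ps_contact_map")
}

#' Write contact labels as tab-separated text
#'
#' Columns: complex_id, chainA, resA, chainB, resB, label (0/1).
#'
#' @param contacts A `ps_contact_map`.
#' @param pair The [protein_pair()] the map was computed from.
#' @param path Output file path.
#' @export
write_contacts <- function(contacts, pair, path) {
  na <- nrow(contacts$labels); nb <- ncol(contacts$labels)
  df <- data.frame(
    complex_id = contacts$complex_id,
    chainA = pair$chain_a$chain_id,
    resA = rep(pair$chain_a$res_number, times = nb),
    chainB = pair$chain_b$chain_id,
    resB = rep(pair$chain_b$res_number, each = na),
    label = as.integer(as.vector(contacts$labels)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
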