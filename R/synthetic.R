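# Synthetic fixtures: every stage of the protocol can be exercised from
# generated inputs alone (no downloads). All generators are deterministic
# functions of their seeds.

#' Build an ideal alpha-helix
#'
#' Backbone N/CA/C/O built by natural-extension from textbook helix torsions
#' (phi -57, psi -47, omega 180 degrees; 3.6 residues per turn, ~1.5 A rise);
#' C-beta is placed with ideal tetrahedral geometry for non-glycine residues.
#'
#' @param n_res number of residues (>= 4)
#' @param sequence 1-letter sequence of length `n_res` (default poly-alanine)
#' @return ProteinStructure, chain "A", residues numbered 1..n_res
#' @export
make_ideal_helix <- function(n_res, sequence = NULL) {
  if (n_res < 4) stop("invalid argument: a helix needs at least 4 residues")
  if (is.null(sequence)) sequence <- strrep("A", n_res)
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (length(aa) != n_res)
    stop("invalid argument: sequence length must equal n_res")
  if (!all(aa %in% AA_ALPHABET))
    stop("invalid argument: sequence letters must be standard amino acids")
  phi <- -57; psi <- -47; omega <- 180
  N <- list(c(0, 0, 0))
  CA <- list(c(1.458, 0, 0))
  C <- list(c(1.458 + 1.525 * cos(pi * (180 - 111.2) / 180),
              1.525 * sin(pi * (180 - 111.2) / 180), 0))
  for (i in seq_len(n_res - 1)) {
    N[[i + 1]] <- place_atom(N[[i]], CA[[i]], C[[i]], 1.329, 116.2, psi)
    CA[[i + 1]] <- place_atom(CA[[i]], C[[i]], N[[i + 1]], 1.458, 121.7, omega)
    C[[i + 1]] <- place_atom(C[[i]], N[[i + 1]], CA[[i + 1]], 1.525, 111.2, phi)
  }
  rows <- list()
  add <- function(resno, resname, name, element, xyz)
    rows[[length(rows) + 1]] <<- data.frame(
      record = "ATOM", chain = "A", resno = resno, icode = "",
      resname = resname, name = name, element = element,
      x = xyz[1], y = xyz[2], z = xyz[3], occ = 1, stringsAsFactors = FALSE)
  for (i in seq_len(n_res)) {
    resname <- aa1to3(aa[i])
    add(i, resname, "N", "N", N[[i]])
    add(i, resname, "CA", "C", CA[[i]])
    add(i, resname, "C", "C", C[[i]])
    add(i, resname, "O", "O",
        place_atom(N[[i]], CA[[i]], C[[i]], 1.231, 120.8, psi + 180))
    if (aa[i] != "G")
      add(i, resname, "CB", "C", ideal_cb(N[[i]], CA[[i]], C[[i]]))
  }
  new_structure(do.call(rbind, rows), title = "ideal alpha-helix fixture")
}

#' Generate a toy alignment with planted conserved substitutions
#'
#' Background columns are uniform over the 20 amino acids. At a planted
#' column, non-reference rows draw the planted amino acid with the stated
#' frequency (uniform over the other 19 otherwise); the reference (row 1,
#' id "ref") draws from the background excluding the planted amino acid, so
#' the planted substitution is guaranteed to differ from the wild type.
#' A planted frequency of 1 makes the column monomorphic (reference
#' included). Deterministic for a fixed seed.
#'
#' @param length number of alignment columns
#' @param n_seqs number of sequences (>= 2)
#' @param planted data.frame with columns position, aa, freq (freq in (0, 1])
#' @param seed RNG seed
#' @return an [new_alignment()] object; row 1 is the reference
#' @export
make_toy_msa <- function(length, n_seqs, planted = NULL, seed = 1) {
  if (n_seqs < 2) stop("invalid argument: n_seqs must be >= 2")
  if (!is.null(planted) && nrow(planted)) {
    if (any(planted$position < 1 | planted$position > length))
      stop("invalid argument: planted position out of range")
    if (any(planted$freq <= 0 | planted$freq > 1))
      stop("invalid argument: planted frequencies must be in (0, 1]")
    if (!all(planted$aa %in% AA_ALPHABET))
      stop("invalid argument: planted amino acids must be standard")
  }
  with_seed(seed, {
    mat <- matrix(sample(AA_ALPHABET, n_seqs * length, replace = TRUE),
                  nrow = n_seqs)
    if (!is.null(planted) && nrow(planted)) {
      for (k in seq_len(nrow(planted))) {
        p <- planted$position[k]; a <- planted$aa[k]; f <- planted$freq[k]
        others <- setdiff(AA_ALPHABET, a)
        if (f >= 1) {
          mat[, p] <- a
        } else {
          mat[1, p] <- sample(others, 1)
          for (r in 2:n_seqs)
            mat[r, p] <- if (runif(1) < f) a else sample(others, 1)
        }
      }
    }
    ids <- c("ref", sprintf("seq%03d", seq_len(n_seqs - 1) + 1))
    new_alignment(ids, apply(mat, 1, paste, collapse = ""))
  })
}

#' Closed-cage SASA fixture
#'
#' One central single-atom residue surrounded by a tetrahedral shell placed
#' so that every probe-expanded sample point of the center is occluded
#' (center SASA exactly 0 at any sampling density), while removing any one
#' shell atom opens a hole. Shell atoms keep their outward exposure.
#' @return ProteinStructure of five single-atom glycine residues; residue 1
#'   is the caged center
#' @export
make_cage_fixture <- function() {
  # shell radius chosen so the occlusion cap (~80 deg) exceeds the
  # tetrahedral covering radius (70.5 deg) but not the vertex gap (109.5 deg)
  dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  shell <- dirs * 1.08
  rows <- data.frame(
    record = "ATOM", chain = "A", resno = 1:5, icode = "", resname = "GLY",
    name = "CA", element = "C",
    x = c(0, shell[, 1]), y = c(0, shell[, 2]), z = c(0, shell[, 3]),
    occ = 1, stringsAsFactors = FALSE)
  new_structure(rows, title = "SASA cage fixture")
}

#' Random enumerable packing instance with its exhaustive optimum
#'
#' Small discrete optimization instances (at most 3 positions x 5 states)
#' with random one-body and pairwise energies; the optimum is found by
#' exhaustive enumeration over all state combinations (lexicographically
#' smallest assignment on ties) and stored with the instance, serving as the
#' oracle for the packing engine.
#'
#' @param n_positions number of positions (<= 3)
#' @param n_states states per position (<= 5)
#' @param seed RNG seed
#' @return object of class `PackingInstance`: `one_body`, `two_body`,
#'   `optimum` (list: assignment, energy)
#' @export
make_packing_instance <- function(n_positions, n_states, seed = 1) {
  if (n_positions > 3 || n_positions < 1)
    stop("invalid argument: n_positions must be between 1 and 3")
  if (n_states > 5 || n_states < 1)
    stop("invalid argument: n_states must be between 1 and 5")
  with_seed(seed, {
    one_body <- lapply(seq_len(n_positions), function(i)
      runif(n_states, -5, 5))
    two_body <- list()
    if (n_positions > 1) {
      for (i in seq_len(n_positions - 1)) for (j in (i + 1):n_positions)
        two_body[[paste(i, j, sep = ":")]] <-
          matrix(runif(n_states^2, -3, 3), n_states, n_states)
    }
    grid <- as.matrix(expand.grid(rep(list(seq_len(n_states)), n_positions)))
    energies <- apply(grid, 1, function(a)
      eval_assignment(one_body, two_body, as.integer(a)))
    best_idx <- which(energies <= min(energies) + 1e-12)
    best <- grid[best_idx, , drop = FALSE]
    ord <- do.call(order, as.data.frame(best))
    structure(list(one_body = one_body, two_body = two_body,
                   n_positions = n_positions, n_states = n_states,
                   optimum = list(assignment = as.integer(best[ord[1], ]),
                                  energy = min(energies))),
              class = "PackingInstance")
  })
}
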