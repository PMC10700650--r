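# Surrogate energy function shared by the ddG scan and the design loop.
#
# E = clash_weight * sum(overlap^2) over non-bonded heavy-atom pairs
#   - contact_weight * (# hydrophobic interaction-center pairs within
#     contact_radius)
#   - hbond_energy * (# detected hydrogen bonds)
#   + sum(reference_energies[aa]) over polymer residues
#   - pssm_bias_weight * sum(PSSM score of the residue's amino acid), when a
#     PSSM is supplied.
# Each term is independently testable; the protocol needs a ranking-competent
# energy, not a physical force field, and the units are kcal/mol-like
# surrogate units.

#' Surrogate energy model parameters
#'
#' @param clash_weight weight of the squared-overlap steric term (default 10)
#' @param contact_weight reward per hydrophobic interaction-center pair
#'   within `contact_radius` (default 0.5)
#' @param contact_radius hydrophobic contact distance (Angstrom, default 8)
#' @param hbond_energy reward per detected hydrogen bond (default 1)
#' @param pssm_bias_weight weight coupling sequence choices to PSSM scores
#'   (default 1; set 0 to decouple)
#' @param vdw_radii named per-element van der Waals radii (Angstrom)
#' @param reference_energies named per-amino-acid reference energies
#'   (default: all zero)
#' @return object of class `EnergyModel`
#' @export
energy_model <- function(clash_weight = 10, contact_weight = 0.5,
                         contact_radius = 8, hbond_energy = 1,
                         pssm_bias_weight = 1,
                         vdw_radii = VDW_RADII,
                         reference_energies = setNames(rep(0, 20), AA_ALPHABET)) {
  stopifnot(is.finite(clash_weight), is.finite(contact_weight),
            is.finite(contact_radius), is.finite(hbond_energy),
            is.finite(pssm_bias_weight), all(vdw_radii > 0))
  structure(list(clash_weight = clash_weight, contact_weight = contact_weight,
                 contact_radius = contact_radius, hbond_energy = hbond_energy,
                 pssm_bias_weight = pssm_bias_weight, vdw_radii = vdw_radii,
                 reference_energies = reference_energies),
            class = "EnergyModel")
}

# Clash-pair inclusion rule: skip intra-residue pairs and, for
# sequence-adjacent residues of the same chain, pairs where both atoms are
# backbone (or CB) -- covalent and near-covalent geometry must not be
# penalized. Designed interaction centers ("CEN") count as side-chain atoms.
clash_pair_included <- function(chain_i, resno_i, key_i, name_i,
                                chain_j, resno_j, key_j, name_j) {
  if (key_i == key_j) return(FALSE)
  if (chain_i == chain_j && abs(resno_i - resno_j) == 1 &&
      name_i %in% ADJACENT_EXCLUDED_ATOMS &&
      name_j %in% ADJACENT_EXCLUDED_ATOMS) return(FALSE)
  TRUE
}

clash_energy_atoms <- function(atoms, em) {
  n <- nrow(atoms)
  if (n < 2) return(0)
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  radii <- vdw_radius(atoms$element, em$vdw_radii)
  keys <- residue_key(atoms$chain, atoms$resno, atoms$icode)
  d2 <- outer(rowSums(coords^2), rowSums(coords^2), "+") -
    2 * coords %*% t(coords)
  d2[d2 < 0] <- 0
  rsum <- outer(radii, radii, "+")
  overlap <- rsum - sqrt(d2)
  cand <- which(upper.tri(overlap) & overlap > 0, arr.ind = TRUE)
  if (!nrow(cand)) return(0)
  total <- 0
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (clash_pair_included(atoms$chain[i], atoms$resno[i], keys[i],
                            atoms$name[i],
                            atoms$chain[j], atoms$resno[j], keys[j],
                            atoms$name[j]))
      total <- total + overlap[i, j]^2
  }
  em$clash_weight * total
}

#' Per-residue side-chain interaction centers
#'
#' For a designed (reduced) residue the center is its "CEN" pseudo-atom; for
#' a full-atom residue it is the centroid of the side-chain heavy atoms (CA
#' for glycine). Hetero residues carry no center.
#' @param structure ProteinStructure
#' @return data.frame: key, chain, resno, aa, x, y, z, hydrophobic
#' @export
interaction_centers <- function(structure) {
  rt <- residue_table(structure)
  rt <- rt[!rt$hetero, , drop = FALSE]
  at <- structure$atoms
  keys <- atom_residue_keys(structure)
  rows <- lapply(seq_len(nrow(rt)), function(i) {
    sel <- which(keys == rt$key[i])
    res <- at[sel, , drop = FALSE]
    cen <- which(res$name == "CEN")
    if (length(cen)) {
      xyz <- c(res$x[cen[1]], res$y[cen[1]], res$z[cen[1]])
    } else {
      sc <- which(!(res$name %in% BACKBONE_ATOMS))
      if (!length(sc)) sc <- which(res$name == "CA")
      if (!length(sc)) sc <- seq_len(nrow(res))
      xyz <- c(mean(res$x[sc]), mean(res$y[sc]), mean(res$z[sc]))
    }
    data.frame(key = rt$key[i], chain = rt$chain[i], resno = rt$resno[i],
               aa = rt$aa[i], x = xyz[1], y = xyz[2], z = xyz[3],
               hydrophobic = rt$aa[i] %in% HYDROPHOBIC_AA,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

contact_count <- function(centers, radius) {
  hyd <- centers[centers$hydrophobic, , drop = FALSE]
  if (nrow(hyd) < 2) return(0)
  coords <- as.matrix(hyd[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(coords))
  sum(d[upper.tri(d)] <= radius)
}

sequence_bias_energy <- function(structure, em, pssm) {
  rt <- residue_table(structure)
  rt <- rt[!rt$hetero & rt$aa %in% AA_ALPHABET, , drop = FALSE]
  e <- sum(em$reference_energies[rt$aa])
  if (!is.null(pssm)) {
    sel <- rt$chain == pssm$chain
    idx <- match(rt$resno[sel], pssm$positions)
    ok <- !is.na(idx)
    if (any(ok))
      e <- e - em$pssm_bias_weight *
        sum(pssm$scores[cbind(idx[ok], match(rt$aa[sel][ok], AA_ALPHABET))])
  }
  e
}

#' Total surrogate energy of a model
#'
#' Deterministic sum of the steric, hydrophobic-contact, hydrogen-bond,
#' reference and (optional) PSSM-bias terms. Ligand (HETATM) atoms
#' participate in the steric term only.
#'
#' @param model a ProteinStructure or VariantModel
#' @param em an [energy_model()]
#' @param pssm optional PSSM supplying the sequence-design bias
#' @param details if TRUE, return the per-term breakdown as an attribute
#' @return numeric energy (surrogate units)
#' @export
total_energy <- function(model, em = energy_model(), pssm = NULL,
                         details = FALSE) {
  s <- if (inherits(model, "VariantModel")) model$structure else model
  if (!inherits(s, "ProteinStructure") || !nrow(s$atoms))
    stop("invalid model: no coordinates to score")
  terms <- c(
    clash = clash_energy_atoms(s$atoms, em),
    contact = -em$contact_weight *
      contact_count(interaction_centers(s), em$contact_radius),
    hbond = -em$hbond_energy * nrow(detect_hbonds(s)),
    sequence = sequence_bias_energy(s, em, pssm)
  )
  out <- sum(terms)
  if (details) attr(out, "terms") <- terms
  out
}
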