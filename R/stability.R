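# Predicted folding free-energy changes (ddG): built-in surrogate scorer and
# the external-table adapter, plus the stabilizing-cutoff filter.

new_ddg_records <- function(chain = character(), position = integer(),
                            wt = character(), mut = character(),
                            ddg = numeric(), method = character()) {
  data.frame(chain = chain, position = as.integer(position), wt = wt,
             mut = mut, ddg = ddg, method = method, stringsAsFactors = FALSE)
}

#' Surrogate ddG of a point mutation
#'
#' The mutated position and every residue with a heavy atom within the
#' contact radius are locally repacked (reduced side-chain representation,
#' wild-type amino acids fixed at the neighbours); the ddG is the energy of
#' the best repacked mutant minus that of the identically repacked wild
#' type. Negative values are stabilizing; units are kcal/mol-like surrogate
#' units. A self-substitution is 0 by construction. Deterministic for a
#' fixed seed.
#'
#' @param structure wild-type ProteinStructure
#' @param mutation list or one-row data.frame with chain, position, wt, mut
#' @param em an [energy_model()]
#' @param rotlib rotamer library
#' @param seed RNG seed
#' @param pssm optional PSSM (adds the sequence-bias term)
#' @param mc_steps Metropolis steps per local repack (default 300)
#' @return one-row ddG record (chain, position, wt, mut, ddg, method)
#' @export
surrogate_ddg <- function(structure, mutation, em = energy_model(),
                          rotlib = default_rotamer_library(), seed = 1,
                          pssm = NULL, mc_steps = 300) {
  mut <- as.list(mutation)
  key <- resolve_residue(structure, list(chain = mut$chain,
                                         resno = mut$position))
  res <- residue_table(structure)
  wt_here <- res$aa[res$key == key]
  if (is.na(wt_here) || wt_here != toupper(mut$wt))
    stop("wild-type mismatch at ", key, ": structure has ", wt_here,
         ", mutation claims ", mut$wt)
  if (toupper(mut$wt) == toupper(mut$mut))
    return(new_ddg_records(mut$chain, mut$position, mut$wt, mut$mut, 0,
                           "surrogate"))
  poly <- polymer_residues(structure, mut$chain)
  at <- structure$atoms
  akeys <- atom_residue_keys(structure)
  mutc <- as.matrix(at[akeys == key, c("x", "y", "z"), drop = FALSE])
  coords <- as.matrix(at[, c("x", "y", "z")])
  d2 <- outer(rowSums(coords^2), rowSums(mutc^2), "+") -
    2 * coords %*% t(mutc)
  dmin_atom <- sqrt(pmax(0, apply(d2, 1, min)))
  dmin_res <- tapply(dmin_atom, akeys, min)
  neighbors <- poly$resno[poly$key != key & poly$aa %in% AA_ALPHABET &
                            dmin_res[poly$key] <= em$contact_radius]
  designable <- c(mut$position, neighbors)
  schedule <- list(mc_steps = mc_steps, kT_start = 5, kT_end = 0.3)
  # neighbours keep their wild type; the substitution itself is forced
  wt_of_neighbors <- as.list(poly$aa[match(neighbors, poly$resno)])
  allowed_mut <- c(list(toupper(mut$mut)), wt_of_neighbors)
  allowed_wt <- c(list(toupper(mut$wt)), wt_of_neighbors)
  e_mut <- pack_rotamers(structure, designable, allowed_mut, em, rotlib,
                         schedule, seed = seed, pssm = pssm,
                         chain = mut$chain, include_wt = FALSE)$total_energy
  e_wt <- pack_rotamers(structure, designable, allowed_wt, em, rotlib,
                        schedule, seed = seed, pssm = pssm,
                        chain = mut$chain)$total_energy
  new_ddg_records(mut$chain, mut$position, toupper(mut$wt),
                  toupper(mut$mut), e_mut - e_wt, "surrogate")
}

#' Read an external per-mutation ddG table
#'
#' TSV with columns chain, position, wt, mut, ddg (e.g. exported from an
#' external all-atom scorer). Duplicate (chain, position, mut) rows keep the
#' lowest ddG; the collision is reported.
#'
#' @param path TSV file
#' @return ddG records data.frame, method "external"
#' @export
read_ddg_table <- function(path) {
  if (!file.exists(path)) stop("cannot read ddG table: ", path)
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      colClasses = "character", stringsAsFactors = FALSE),
    error = function(e) stop("format error in '", path, "': ",
                             conditionMessage(e)))
  need <- c("chain", "position", "wt", "mut", "ddg")
  if (!all(need %in% names(tab)))
    stop("format error in '", path, "': expected columns ",
         paste(need, collapse = ", "))
  ddg <- suppressWarnings(as.numeric(tab$ddg))
  if (any(is.na(ddg)))
    stop("format error in '", path, "' at line ",
         which(is.na(ddg))[1] + 1, ": non-numeric ddg value '",
         tab$ddg[which(is.na(ddg))[1]], "'")
  pos <- suppressWarnings(as.integer(tab$position))
  if (any(is.na(pos)))
    stop("format error in '", path, "' at line ",
         which(is.na(pos))[1] + 1, ": non-integer position")
  rec <- new_ddg_records(tab$chain, pos, toupper(tab$wt), toupper(tab$mut),
                         ddg, "external")
  k <- paste(rec$chain, rec$position, rec$mut, sep = ":")
  if (anyDuplicated(k)) {
    message("read_ddg_table: ", sum(duplicated(k)),
            " duplicate row(s); keeping the lowest ddg per mutation")
    rec <- rec[order(match(k, unique(k)), rec$ddg), , drop = FALSE]
    rec <- rec[!duplicated(paste(rec$chain, rec$position, rec$mut,
                                 sep = ":")), , drop = FALSE]
    rownames(rec) <- NULL
  }
  rec
}

#' Keep records predicted to stabilize beyond a cutoff
#'
#' Strict inequality ("less than"): a record at exactly the cutoff is
#' excluded. Input order is preserved. Mixing surrogate and external records
#' in one call is allowed but warned about, since their units are not
#' calibrated against each other.
#'
#' @param records ddG records data.frame
#' @param cutoff ddG cutoff (default -0.5, kcal/mol-like)
#' @return the subset with `ddg < cutoff`
#' @export
filter_by_ddg <- function(records, cutoff = -0.5) {
  if (!is.finite(cutoff)) stop("invalid argument: cutoff must be finite")
  if (!nrow(records)) return(records)
  if (length(unique(records$method)) > 1)
    warning("mixing surrogate and external ddG records in one filter run")
  out <- records[records$ddg < cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}
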