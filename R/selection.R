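# Variant screening: optimal rigid superposition, C-alpha RMSD against the
# wild type, and the final ranked selection with its mutation-overlap table.

#' Optimal least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation R and translation t minimizing the RMSD of
#' `R a_i + t` against `b_i`. Reflections are prevented by sign-correcting
#' the smallest singular direction.
#'
#' @param coords_a,coords_b N x 3 matrices of paired points (N >= 3,
#'   non-collinear)
#' @return list: `rotation` (3 x 3, det +1), `translation` (3-vector),
#'   `rmsd` (Angstrom)
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  A <- as.matrix(coords_a); B <- as.matrix(coords_b)
  if (ncol(A) != 3 || ncol(B) != 3 || nrow(A) != nrow(B))
    stop("invalid argument: paired N x 3 coordinate matrices required")
  if (nrow(A) < 3)
    stop("invalid argument: at least 3 point pairs required")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  if (svd(Ac)$d[2] < 1e-8 * max(1, svd(Ac)$d[1]) ||
      svd(Bc)$d[2] < 1e-8 * max(1, svd(Bc)$d[1]))
    stop("invalid argument: degenerate (collinear) point set")
  H <- t(Ac) %*% Bc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rot_a <- Ac %*% t(R)
  rmsd <- sqrt(mean(rowSums((rot_a - Bc)^2)))
  list(rotation = R, translation = as.numeric(cb - R %*% ca), rmsd = rmsd)
}

#' C-alpha RMSD of a variant model against the wild-type structure
#'
#' Residues are matched by (chain, author number, insertion code); the RMSD
#' is that of the optimal rigid superposition over all matched C-alpha atoms.
#'
#' @param variant VariantModel or ProteinStructure
#' @param wt wild-type ProteinStructure
#' @return RMSD in Angstrom
#' @export
ca_rmsd <- function(variant, wt) {
  vs <- if (inherits(variant, "VariantModel")) variant$structure else variant
  get_ca <- function(s) {
    at <- s$atoms
    sel <- at$name == "CA" & !at$hetero
    keys <- residue_key(at$chain, at$resno, at$icode)[sel]
    m <- as.matrix(at[sel, c("x", "y", "z")])
    rownames(m) <- keys
    m[!duplicated(keys), , drop = FALSE]
  }
  a <- get_ca(vs); b <- get_ca(wt)
  common <- intersect(rownames(a), rownames(b))
  if (length(common) < 3)
    stop("invalid argument: fewer than 3 matched C-alpha atoms")
  kabsch_superpose(a[common, , drop = FALSE], b[common, , drop = FALSE])$rmsd
}

#' Rank variants by energy and screen by C-alpha RMSD
#'
#' Variants failing either gate (RMSD above the cutoff, or energy not below
#' the wild-type reference) are dropped; the survivors are sorted by
#' ascending energy gap (equal-energy variants keep input order), truncated
#' to the requested count, and summarized with a mutation-overlap table. When
#' variants carry a matched-representation wild-type reference energy (as
#' produced by [generate_variants()]) it is used; otherwise the scalar
#' `wt_energy` is.
#'
#' @param variants list of VariantModel with `total_energy` and `ca_rmsd` set
#' @param wt_energy scalar wild-type energy (fallback reference)
#' @param config a [design_config()] supplying `rmsd_cutoff` and
#'   `n_variants_requested`
#' @return object of class `SelectionReport`: `table` (ranked data.frame),
#'   `overlap` (mutation -> number of selected variants containing it,
#'   flagged when shared by more than 5), `selected` (list of VariantModel)
#' @export
rank_and_select <- function(variants, wt_energy = NULL,
                            config = design_config()) {
  if (!length(variants)) {
    warning("no variants to select from")
    return(structure(list(table = data.frame(), overlap = data.frame(),
                          selected = list()), class = "SelectionReport"))
  }
  gap <- vapply(variants, function(v) {
    if (!is.null(v$wt_energy_ref)) v$total_energy - v$wt_energy_ref
    else if (!is.null(wt_energy)) v$total_energy - wt_energy
    else stop("no wild-type reference energy available")
  }, numeric(1))
  rmsd <- vapply(variants, function(v) {
    if (is.na(v$ca_rmsd)) stop("variant lacks ca_rmsd; run ca_rmsd() first")
    v$ca_rmsd
  }, numeric(1))
  keep <- which(rmsd <= config$rmsd_cutoff & gap < 0)
  if (!length(keep)) {
    warning("no variants pass the RMSD and energy gates")
    return(structure(list(table = data.frame(), overlap = data.frame(),
                          selected = list()), class = "SelectionReport"))
  }
  ord <- keep[order(gap[keep])]  # stable: ties keep input order
  ord <- ord[seq_len(min(length(ord), config$n_variants_requested))]
  selected <- variants[ord]
  tab <- data.frame(
    id = vapply(selected, function(v)
      if (is.na(v$id)) "" else v$id, character(1)),
    energy = vapply(selected, function(v) v$total_energy, numeric(1)),
    energy_gap = gap[ord],
    ca_rmsd = rmsd[ord],
    n_mutations = vapply(selected, function(v) nrow(v$mutations), integer(1)),
    stringsAsFactors = FALSE
  )
  muts <- unlist(lapply(selected, function(v)
    if (nrow(v$mutations))
      sprintf("%s%d%s", v$mutations$wt, v$mutations$position,
              v$mutations$mut)
    else character(0)))
  overlap <- if (length(muts)) {
    cnt <- sort(table(muts), decreasing = TRUE)
    data.frame(mutation = names(cnt), count = as.integer(cnt),
               flagged = as.integer(cnt) > 5, stringsAsFactors = FALSE)
  } else data.frame(mutation = character(), count = integer(),
                    flagged = logical(), stringsAsFactors = FALSE)
  structure(list(table = tab, overlap = overlap, selected = selected),
            class = "SelectionReport")
}

#' @export
print.SelectionReport <- function(x, ...) {
  cat("SelectionReport:", nrow(x$table), "variant(s) selected\n")
  if (nrow(x$table)) print(x$table, row.names = FALSE)
  invisible(x)
}
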