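# Structural exclusion rules: solvent accessibility, hydrogen bonding,
# secondary structure, and the per-mutation filter battery.

#' Shrake-Rupley solvent-accessible surface area
#'
#' For every heavy atom, `n_points` quasi-uniform sphere points are placed at
#' radius r + probe; the accessible fraction (points not inside any other
#' atom's expanded sphere) times the expanded-sphere area gives the atomic
#' SASA. All heavy atoms, including hetero groups, occlude.
#'
#' @param structure non-empty ProteinStructure
#' @param probe probe radius in Angstrom (default 1.4, water)
#' @param n_points sphere sample count (>= 92; default 960)
#' @return object of class `SasaResult`: `per_atom` (A^2, one value per atom
#'   row), `per_residue` (named by residue key), `probe_radius`, `n_points`
#' @export
compute_sasa <- function(structure, probe = 1.4, n_points = 960) {
  if (!inherits(structure, "ProteinStructure") || !nrow(structure$atoms))
    stop("invalid argument: empty structure")
  if (n_points < 92) stop("invalid argument: n_points must be >= 92")
  at <- structure$atoms
  coords <- as.matrix(at[, c("x", "y", "z")])
  radii <- vdw_radius(at$element)
  expanded <- radii + probe
  n <- nrow(coords)
  sphere <- fibonacci_sphere(n_points)
  d2 <- outer(rowSums(coords^2), rowSums(coords^2), "+") -
    2 * coords %*% t(coords)
  d2[d2 < 0] <- 0
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    cutoff <- (expanded[i] + expanded)^2
    nb <- which(d2[i, ] < cutoff & seq_len(n) != i)
    if (!length(nb)) {
      per_atom[i] <- 4 * pi * expanded[i]^2
      next
    }
    pts <- sweep(sphere * expanded[i], 2, coords[i, ], "+")
    buried <- rep(FALSE, n_points)
    for (j in nb) {
      dj2 <- (pts[, 1] - coords[j, 1])^2 + (pts[, 2] - coords[j, 2])^2 +
        (pts[, 3] - coords[j, 3])^2
      buried <- buried | (dj2 < expanded[j]^2)
      if (all(buried)) break
    }
    per_atom[i] <- mean(!buried) * 4 * pi * expanded[i]^2
  }
  keys <- atom_residue_keys(structure)
  per_residue <- vapply(split(per_atom, factor(keys, levels = unique(keys))),
                        sum, numeric(1))
  structure(list(per_atom = per_atom, per_residue = per_residue,
                 probe_radius = probe, n_points = n_points),
            class = "SasaResult")
}

#' Relative per-residue solvent accessibility
#'
#' Per-residue SASA divided by the residue type's theoretical Gly-X-Gly
#' maximum ([max_sasa_reference()]), clipped to [0, 1.2]. Only polymer
#' residues are reported; a polymer residue type absent from the reference
#' table is a configuration error.
#'
#' @param structure the structure `sasa` was computed on
#' @param sasa a [compute_sasa()] result
#' @return named numeric vector (residue key -> fraction)
#' @export
relative_sasa <- function(structure, sasa) {
  rt <- residue_table(structure)
  rt <- rt[!rt$hetero, , drop = FALSE]
  ref <- max_sasa_reference()
  unknown <- unique(rt$resname[!(rt$aa %in% names(ref))])
  if (length(unknown))
    stop("configuration error: no reference maximum SASA for residue type(s) ",
         paste(unknown, collapse = ", "))
  frac <- sasa$per_residue[rt$key] / ref[rt$aa]
  setNames(pmin(1.2, pmax(0, frac)), rt$key)
}

hbond_participants <- function(structure) {
  at <- structure$atoms
  keys <- atom_residue_keys(structure)
  poly <- !at$hetero
  donors <- list(); acceptors <- list()
  for (key in unique(keys[poly])) {
    sel <- which(keys == key & poly)
    res <- at[sel, , drop = FALSE]
    resname <- res$resname[1]
    find <- function(nm) {
      k <- match(nm, res$name)
      if (is.na(k)) NULL else sel[k]
    }
    # backbone amide donor (absent in proline) and carbonyl acceptor
    if (resname != "PRO") {
      ni <- find("N"); cai <- find("CA")
      if (!is.null(ni) && !is.null(cai))
        donors[[length(donors) + 1]] <- data.frame(
          idx = ni, ante = cai, key = key, sidechain = FALSE)
    }
    oi <- find("O")
    if (!is.null(oi))
      acceptors[[length(acceptors) + 1]] <- data.frame(
        idx = oi, key = key, sidechain = FALSE)
    dd <- SC_DONORS[SC_DONORS$resname == resname, , drop = FALSE]
    for (r in seq_len(nrow(dd))) {
      di <- find(dd$atom[r]); ai <- find(dd$antecedent[r])
      if (!is.null(di) && !is.null(ai))
        donors[[length(donors) + 1]] <- data.frame(
          idx = di, ante = ai, key = key, sidechain = TRUE)
    }
    aa_ <- SC_ACCEPTORS[SC_ACCEPTORS$resname == resname, , drop = FALSE]
    for (r in seq_len(nrow(aa_))) {
      ci <- find(aa_$atom[r])
      if (!is.null(ci))
        acceptors[[length(acceptors) + 1]] <- data.frame(
          idx = ci, key = key, sidechain = TRUE)
    }
  }
  list(donors = if (length(donors)) do.call(rbind, donors) else NULL,
       acceptors = if (length(acceptors)) do.call(rbind, acceptors) else NULL)
}

#' Geometric hydrogen-bond detection
#'
#' Donor-acceptor pairs are drawn from a per-residue chemistry table
#' (backbone amide N donates, carbonyl O accepts; side-chain donors and
#' acceptors per amino acid) and kept when the heavy-atom distance is at most
#' `d_max` and the antecedent-donor-acceptor angle is at least `angle_min`.
#' Intra-residue pairs, and backbone-backbone pairs of sequence-adjacent
#' residues (covalent neighbours), are excluded. Hydrogens are never placed:
#' donor capability is inferred from heavy-atom chemistry.
#'
#' @param structure ProteinStructure
#' @param d_max maximum donor-acceptor heavy-atom distance (Angstrom)
#' @param angle_min minimum antecedent-donor-acceptor angle (degrees)
#' @return data.frame, one row per hydrogen bond, with donor/acceptor residue
#'   keys, atom names, side-chain flags, distance and angle
#' @export
detect_hbonds <- function(structure, d_max = 3.5, angle_min = 120) {
  empty <- data.frame(donor_key = character(), donor_atom = character(),
                      donor_sidechain = logical(), acceptor_key = character(),
                      acceptor_atom = character(),
                      acceptor_sidechain = logical(),
                      distance = numeric(), angle = numeric(),
                      stringsAsFactors = FALSE)
  parts <- hbond_participants(structure)
  if (is.null(parts$donors) || is.null(parts$acceptors)) return(empty)
  at <- structure$atoms
  coords <- as.matrix(at[, c("x", "y", "z")])
  D <- parts$donors; A <- parts$acceptors
  out <- list()
  for (i in seq_len(nrow(D))) {
    dpos <- coords[D$idx[i], ]
    dres <- D$key[i]
    dist <- sqrt(colSums((t(coords[A$idx, , drop = FALSE]) - dpos)^2))
    for (j in which(dist <= d_max)) {
      ares <- A$key[j]
      if (ares == dres) next
      if (!D$sidechain[i] && !A$sidechain[j]) {
        # skip covalently adjacent backbone pairs
        dp <- strsplit(dres, ":")[[1]]; ap <- strsplit(ares, ":")[[1]]
        if (dp[1] == ap[1] &&
            abs(as.integer(dp[2]) - as.integer(ap[2])) == 1) next
      }
      ang <- point_angle(coords[D$ante[i], ], dpos, coords[A$idx[j], ])
      if (ang >= angle_min) {
        out[[length(out) + 1]] <- data.frame(
          donor_key = dres, donor_atom = at$name[D$idx[i]],
          donor_sidechain = D$sidechain[i],
          acceptor_key = ares, acceptor_atom = at$name[A$idx[j]],
          acceptor_sidechain = A$sidechain[j],
          distance = dist[j], angle = ang, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

backbone_dihedrals <- function(structure, chain_id = NULL) {
  res <- polymer_residues(structure, chain_id)
  at <- structure$atoms
  keys <- atom_residue_keys(structure)
  getxyz <- function(key, name) {
    k <- which(keys == key & at$name == name)
    if (!length(k)) return(NULL)
    c(at$x[k[1]], at$y[k[1]], at$z[k[1]])
  }
  n <- nrow(res)
  phi <- rep(NA_real_, n); psi <- rep(NA_real_, n)
  bb <- lapply(res$key, function(k)
    list(N = getxyz(k, "N"), CA = getxyz(k, "CA"),
         C = getxyz(k, "C")))
  linked <- function(i, j) {  # peptide-bond continuity between residues i < j
    if (is.null(bb[[i]]$C) || is.null(bb[[j]]$N)) return(FALSE)
    vnorm(bb[[j]]$N - bb[[i]]$C) < 2.5
  }
  for (i in seq_len(n)) {
    b <- bb[[i]]
    if (is.null(b$N) || is.null(b$CA) || is.null(b$C)) next
    if (i > 1 && linked(i - 1, i))
      phi[i] <- dihedral_angle(bb[[i - 1]]$C, b$N, b$CA, b$C)
    if (i < n && linked(i, i + 1))
      psi[i] <- dihedral_angle(b$N, b$CA, b$C, bb[[i + 1]]$N)
  }
  data.frame(key = res$key, resno = res$resno, phi = phi, psi = psi,
             incomplete = vapply(bb, function(b)
       is.null(b$N) || is.null(b$CA) || is.null(b$C), logical(1)),
             stringsAsFactors = FALSE)
}

label_runs <- function(compat, min_run, label, current) {
  r <- rle(compat & current == "L")
  pos <- 1
  for (k in seq_along(r$lengths)) {
    if (r$values[k] && r$lengths[k] >= min_run)
      current[pos:(pos + r$lengths[k] - 1)] <- label
    pos <- pos + r$lengths[k]
  }
  current
}

#' Dihedral-rule secondary-structure assignment
#'
#' A residue is helix-compatible when phi is in [-100, -30] and psi in
#' [-80, -5] degrees; runs of at least 4 compatible residues are labelled
#' "H". Strand compatibility (phi in [-170, -70], psi in [90, 180]) in runs
#' of at least 3 yields "E". Everything else, including chain termini and
#' residues with missing backbone, is "L".
#'
#' @param structure ProteinStructure with >= 3 consecutive full-backbone
#'   residues
#' @param chain_id chain to label (default: first polymer chain)
#' @return named character vector (residue key -> "H"/"E"/"L")
#' @export
assign_secondary_structure <- function(structure, chain_id = NULL) {
  di <- backbone_dihedrals(structure, chain_id)
  if (any(di$incomplete))
    warning("residues with missing backbone labelled 'L': ",
            paste(di$key[di$incomplete], collapse = ", "))
  compat_h <- !is.na(di$phi) & !is.na(di$psi) &
    di$phi >= -100 & di$phi <= -30 & di$psi >= -80 & di$psi <= -5
  compat_e <- !is.na(di$phi) & !is.na(di$psi) &
    di$phi >= -170 & di$phi <= -70 & di$psi >= 90 & di$psi <= 180
  labels <- rep("L", nrow(di))
  labels <- label_runs(compat_h, 4, "H", labels)
  labels <- label_runs(compat_e, 3, "E", labels)
  setNames(labels, di$key)
}

#' Filter configuration
#'
#' Thresholds for the structural exclusion battery. The active-site radius is
#' the only threshold printed by the source protocol; the others
#' operationalize what was originally done by visual inspection and are all
#' configuration-exposed.
#'
#' @param catalytic_residues required non-empty vector of author residue
#'   numbers (or "chain:resno" keys) of catalytic residues
#' @param chain chain the battery operates on
#' @param active_site_radius exclusion radius around catalytic residues
#'   (Angstrom, default 5)
#' @param exposure_threshold relative-SASA above which a position counts as
#'   exposed (default 0.25)
#' @param burial_threshold relative-SASA below which a position counts as
#'   buried (default 0.10)
#' @param volume_threshold side-chain volume decrease (A^3) treated as cavity
#'   creation at buried positions (default 40)
#' @export
filter_config <- function(catalytic_residues, chain = "A",
                          active_site_radius = 5.0,
                          exposure_threshold = 0.25,
                          burial_threshold = 0.10,
                          volume_threshold = 40) {
  if (missing(catalytic_residues) || !length(catalytic_residues))
    stop("configuration error: catalytic_residues must be a non-empty list")
  structure(list(catalytic_residues = catalytic_residues, chain = chain,
                 active_site_radius = active_site_radius,
                 exposure_threshold = exposure_threshold,
                 burial_threshold = burial_threshold,
                 volume_threshold = volume_threshold),
            class = "FilterConfig")
}

#' Evaluate the six structural exclusion rules for one mutation
#'
#' Rules: active_site (any heavy atom within the exclusion radius of a
#' catalytic residue), unsat_hbond (wild-type side chain hydrogen-bonds in a
#' role the mutant chemistry cannot fill), exposed_hydrophobic (hydrophobic
#' mutant at an exposed position), loop_flexibility (glycine introduced, or
#' proline removed, in a loop), proline_in_helix, cavity_creation (large
#' volume loss at a buried position). The verdict records a pass/fail and
#' reason per rule; a mutation is accepted iff all rules pass.
#'
#' @param structure ProteinStructure (the wild-type model)
#' @param mutation list or one-row data.frame with chain, position, wt, mut
#' @param config a [filter_config()]
#' @param sasa [compute_sasa()] result for `structure`
#' @param ss [assign_secondary_structure()] labels for `structure`
#' @param hbonds [detect_hbonds()] result for `structure`
#' @param rel precomputed [relative_sasa()] (optional; computed if NULL)
#' @return object of class `FilterVerdict`: `mutation`, `rules` (data.frame
#'   rule/pass/reason), `accepted`
#' @export
evaluate_mutation_filters <- function(structure, mutation, config,
                                      sasa, ss, hbonds, rel = NULL) {
  if (!inherits(config, "FilterConfig")) config <- do.call(filter_config, config)
  mut <- as.list(mutation)
  key <- resolve_residue(structure, list(chain = mut$chain,
                                         resno = mut$position))
  if (is.null(rel)) rel <- relative_sasa(structure, sasa)
  rules <- data.frame(rule = character(), pass = logical(),
                      reason = character(), stringsAsFactors = FALSE)
  add <- function(rule, pass, reason)
    rbind(rules, data.frame(rule = rule, pass = pass, reason = reason,
                            stringsAsFactors = FALSE))

  dmin <- min(vapply(config$catalytic_residues, function(cr)
    min_heavy_atom_distance(structure, key, cr), numeric(1)))
  rules <- add("active_site", dmin > config$active_site_radius,
               sprintf("min distance to catalytic residues %.2f A", dmin))

  sc_hb <- hbonds[(hbonds$donor_key == key & hbonds$donor_sidechain) |
                  (hbonds$acceptor_key == key & hbonds$acceptor_sidechain), ,
                  drop = FALSE]
  roles <- unique(c(if (any(sc_hb$donor_key == key & sc_hb$donor_sidechain))
    "donor",
    if (any(sc_hb$acceptor_key == key & sc_hb$acceptor_sidechain))
      "acceptor"))
  lacking <- c(
    if ("donor" %in% roles && !(mut$mut %in% SC_DONOR_AA)) "donor",
    if ("acceptor" %in% roles && !(mut$mut %in% SC_ACCEPTOR_AA)) "acceptor")
  rules <- add("unsat_hbond", length(lacking) == 0,
               if (length(lacking))
                 paste("mutant cannot act as side-chain",
                       paste(lacking, collapse = "/"))
               else "wild-type side-chain hydrogen bonds preserved or absent")

  r <- unname(rel[key])
  rules <- add("exposed_hydrophobic",
               !(mut$mut %in% HYDROPHOBIC_AA && r > config$exposure_threshold),
               sprintf("relative SASA %.2f", r))

  label <- unname(ss[key])
  rules <- add("loop_flexibility",
               !(label == "L" && (mut$mut == "G" || mut$wt == "P")),
               sprintf("secondary structure '%s'", label))

  rules <- add("proline_in_helix", !(mut$mut == "P" && label == "H"),
               sprintf("secondary structure '%s'", label))

  vol <- residue_volumes()
  dv <- unname(vol[mut$wt] - vol[mut$mut])
  rules <- add("cavity_creation",
               !(r < config$burial_threshold && isTRUE(dv > config$volume_threshold)),
               sprintf("relative SASA %.2f, volume change %.1f A^3", r, -dv))

  structure(list(mutation = mut[c("chain", "position", "wt", "mut")],
                 rules = rules, accepted = all(rules$pass)),
            class = "FilterVerdict")
}

#' @export
print.FilterVerdict <- function(x, ...) {
  m <- x$mutation
  cat(sprintf("%s%s%s%s: %s\n", m$wt, m$position, m$mut,
              if (m$chain != "A") paste0(" (", m$chain, ")") else "",
              if (x$accepted) "accepted" else "rejected"))
  failed <- x$rules[!x$rules$pass, ]
  if (nrow(failed))
    cat(paste0("  fail ", failed$rule, ": ", failed$reason, "\n"), sep = "")
  invisible(x)
}

#' Apply the structural filter battery to a candidate pool
#'
#' SASA, secondary structure and hydrogen bonds are computed once on the
#' wild-type structure; every candidate receives a [evaluate_mutation_filters()]
#' verdict. Survivors preserve input order.
#'
#' @param pool non-empty candidate data.frame (chain, position, wt, mut, ...)
#' @param structure the wild-type ProteinStructure
#' @param config a [filter_config()]
#' @param sasa,ss,hbonds optional precomputed artifacts (computed if NULL)
#' @return list with `pool` (surviving rows), `verdicts` (list of
#'   FilterVerdict), `summary` (failure count per rule)
#' @export
apply_filter_battery <- function(pool, structure, config,
                                 sasa = NULL, ss = NULL, hbonds = NULL) {
  if (is.null(pool) || !nrow(pool))
    stop("invalid argument: candidate pool is empty")
  if (!inherits(config, "FilterConfig")) config <- do.call(filter_config, config)
  if (is.null(sasa)) sasa <- compute_sasa(structure)
  if (is.null(ss)) ss <- assign_secondary_structure(structure, config$chain)
  if (is.null(hbonds)) hbonds <- detect_hbonds(structure)
  rel <- relative_sasa(structure, sasa)
  verdicts <- lapply(seq_len(nrow(pool)), function(i)
    evaluate_mutation_filters(structure, pool[i, ], config, sasa, ss, hbonds,
                              rel = rel))
  accepted <- vapply(verdicts, function(v) v$accepted, logical(1))
  rule_names <- verdicts[[1]]$rules$rule
  failures <- setNames(vapply(rule_names, function(rn)
    sum(vapply(verdicts, function(v)
      !v$rules$pass[v$rules$rule == rn], logical(1))), numeric(1)), rule_names)
  survivors <- pool[accepted, , drop = FALSE]
  rownames(survivors) <- NULL
  list(pool = survivors, verdicts = verdicts, summary = failures)
}

#' Tabulate filter verdicts for export
#' @param verdicts list of FilterVerdict from [apply_filter_battery()]
#' @return data.frame: mutation columns, one pass/fail column per rule,
#'   accepted flag, reasons for failed rules
#' @export
verdict_table <- function(verdicts) {
  rows <- lapply(verdicts, function(v) {
    passes <- setNames(as.list(v$rules$pass), v$rules$rule)
    failed <- v$rules[!v$rules$pass, ]
    data.frame(chain = v$mutation$chain, position = v$mutation$position,
               wt = v$mutation$wt, mut = v$mutation$mut,
               as.data.frame(passes),
               accepted = v$accepted,
               reasons = paste(sprintf("%s: %s", failed$rule, failed$reason),
                               collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
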