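# Fixtures and independent oracles, all built in code at test time.

# ---- tiny PDB texts -------------------------------------------------------

pdb_line <- function(record, serial, name, resname, chain, resno, x, y, z,
                     occ = 1, element = NULL, altloc = " ") {
  if (is.null(element)) element <- substr(gsub("[0-9]", "", name), 1, 1)
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, altloc, resname, chain, resno, x, y, z,
          occ, 0, element)
}

write_single_ala_pdb <- function(path) {
  lines <- c(
    pdb_line("ATOM", 1, "N", "ALA", "A", 1, 0.000, 0.000, 0.000),
    pdb_line("ATOM", 2, "CA", "ALA", "A", 1, 1.458, 0.000, 0.000),
    pdb_line("ATOM", 3, "C", "ALA", "A", 1, 2.009, 1.420, 0.000),
    pdb_line("ATOM", 4, "O", "ALA", "A", 1, 1.251, 2.390, 0.000),
    pdb_line("ATOM", 5, "CB", "ALA", "A", 1, 1.988, -0.773, -1.199),
    "END")
  writeLines(lines, path)
  path
}

# one-residue structure built directly (no file)
single_atom_structure <- function(xyz = c(0, 0, 0), element = "C",
                                  resname = "GLY", name = "CA") {
  new_structure(data.frame(
    record = "ATOM", chain = "A", resno = 1L, icode = "", resname = resname,
    name = name, element = element, x = xyz[1], y = xyz[2], z = xyz[3],
    occ = 1, stringsAsFactors = FALSE))
}

# n single-atom residues at the given coordinate matrix
atoms_structure <- function(coords, element = "C", record = "ATOM",
                            resno = NULL, resname = "GLY", name = "CA",
                            chain = "A") {
  coords <- matrix(coords, ncol = 3)
  n <- nrow(coords)
  if (is.null(resno)) resno <- seq_len(n)
  new_structure(data.frame(
    record = record, chain = chain, resno = as.integer(resno), icode = "",
    resname = resname, name = name, element = element,
    x = coords[, 1], y = coords[, 2], z = coords[, 3], occ = 1,
    stringsAsFactors = FALSE))
}

random_cluster_structure <- function(n_atoms = 5, spread = 3, seed = 1) {
  set.seed(seed)
  atoms_structure(matrix(runif(n_atoms * 3, -spread, spread), ncol = 3),
                  element = sample(c("C", "N", "O", "S"), n_atoms, TRUE))
}

# backbone chain with prescribed torsions (independent of make_ideal_helix's
# fixed parameters); used to test the dihedral classification rule
build_torsion_chain <- function(phis, psis, sequence = NULL) {
  n <- length(phis)
  stopifnot(length(psis) == n)
  if (is.null(sequence)) sequence <- strrep("A", n)
  aa <- strsplit(sequence, "")[[1]]
  pa <- stabdesign:::place_atom
  N <- list(c(0, 0, 0)); CA <- list(c(1.458, 0, 0))
  C <- list(c(1.458 + 1.525 * cos(pi * (180 - 111.2) / 180),
              1.525 * sin(pi * (180 - 111.2) / 180), 0))
  for (i in seq_len(n - 1)) {
    N[[i + 1]] <- pa(N[[i]], CA[[i]], C[[i]], 1.329, 116.2, psis[i])
    CA[[i + 1]] <- pa(CA[[i]], C[[i]], N[[i + 1]], 1.458, 121.7, 180)
    C[[i + 1]] <- pa(C[[i]], N[[i + 1]], CA[[i + 1]], 1.525, 111.2,
                     phis[i + 1])
  }
  rows <- list()
  for (i in seq_len(n)) {
    for (spec in list(list("N", "N", N[[i]]), list("CA", "C", CA[[i]]),
                      list("C", "C", C[[i]]),
                      list("O", "O", pa(N[[i]], CA[[i]], C[[i]], 1.231,
                                        120.8, psis[i] + 180)))) {
      rows[[length(rows) + 1]] <- data.frame(
        record = "ATOM", chain = "A", resno = i, icode = "",
        resname = aa1to3(aa[i]), name = spec[[1]], element = spec[[2]],
        x = spec[[3]][1], y = spec[[3]][2], z = spec[[3]][3], occ = 1,
        stringsAsFactors = FALSE)
    }
  }
  new_structure(do.call(rbind, rows))
}

# ---- independent numerical oracles ---------------------------------------

# RMSD after optimal rotation, found by direct numerical minimization over
# Euler angles (independent of the closed-form Kabsch path)
rmsd_numeric_oracle <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  rot <- function(p) {
    cx <- cos(p[1]); sx <- sin(p[1]); cy <- cos(p[2]); sy <- sin(p[2])
    cz <- cos(p[3]); sz <- sin(p[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(p) sqrt(mean(rowSums((Ac %*% t(rot(p)) - Bc)^2)))
  starts <- rbind(c(0, 0, 0), c(pi, 0, 0), c(0, pi, 0), c(0, 0, pi),
                  c(pi / 2, pi / 2, 0), c(-pi / 2, 0, pi / 2),
                  c(pi / 3, -pi / 3, pi / 3), c(2, 1, -1))
  best <- Inf
  for (k in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[k, ], obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 5000))
    best <- min(best, fit$value)
  }
  best
}

# brute-force minimum heavy-atom distance
min_dist_bruteforce <- function(s, key_a, key_b) {
  keys <- stabdesign:::atom_residue_keys(s)
  A <- as.matrix(s$atoms[keys == key_a, c("x", "y", "z"), drop = FALSE])
  B <- as.matrix(s$atoms[keys == key_b, c("x", "y", "z"), drop = FALSE])
  best <- Inf
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
  best
}

# exhaustive enumeration over a packing problem's state tables
enumerate_optimum <- function(one_body, two_body) {
  grid <- as.matrix(expand.grid(lapply(lengths(one_body), seq_len)))
  energies <- apply(grid, 1, function(a)
    stabdesign:::eval_assignment(one_body, two_body, as.integer(a)))
  list(energy = min(energies),
       assignment = as.integer(grid[which.min(energies), ]))
}

# ---- mixed structural-filter battery fixture -----------------------------
#
# An 18-residue helix carrying: a serine whose OG hydrogen-bonds a backbone
# carbonyl (rule: unsatisfied H-bond), a leucine buried under per-atom
# hetero cages (rule: cavity creation), a catalytic residue (rule: active
# site), plus exposed interior positions (rules: exposed hydrophobic,
# proline-in-helix) and loop termini (rule: loop flexibility).
make_battery_fixture <- function() {
  seq18 <- "SKDLESNQTRHGSLKENA"
  h <- make_ideal_helix(18, seq18)
  at <- h$atoms
  keys <- stabdesign:::atom_residue_keys(h)
  getxyz <- function(resno, name) {
    k <- which(at$resno == resno & at$name == name)
    c(at$x[k], at$y[k], at$z[k])
  }
  # serine 13: place OG 1.4 A from CB toward the carbonyl O of residue 9
  cb <- getxyz(13, "CB"); o9 <- getxyz(9, "O")
  og <- cb + 1.4 * (o9 - cb) / sqrt(sum((o9 - cb)^2))
  at <- rbind(at, data.frame(
    record = "ATOM", chain = "A", resno = 13L, icode = "", resname = "SER",
    name = "OG", element = "O", x = og[1], y = og[2], z = og[3], occ = 1,
    hetero = FALSE, stringsAsFactors = FALSE))
  # bury leucine 14: tetrahedral hetero cage around each heavy atom
  dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  cage_rows <- list()
  serial <- 0
  for (k in which(at$resno == 14 & !at$hetero)) {
    for (d in seq_len(4)) {
      serial <- serial + 1
      cage_rows[[serial]] <- data.frame(
        record = "HETATM", chain = "A", resno = 900L + serial, icode = "",
        resname = "CAG", name = "C1", element = "C",
        x = at$x[k] + 1.08 * dirs[d, 1], y = at$y[k] + 1.08 * dirs[d, 2],
        z = at$z[k] + 1.08 * dirs[d, 3], occ = 1, hetero = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  at <- rbind(at, do.call(rbind, cage_rows))
  s <- new_structure(at[, setdiff(names(at), "hetero")])
  # intended failures: 4 active-site, 11 proline-in-helix, 10 exposed
  # hydrophobic, 18 loop flexibility, 13 unsatisfied H-bond, 14 cavity;
  # 9/15/16/12 survive
  list(structure = s, catalytic = 3L,
       pool = data.frame(
         chain = "A",
         position = c(4L, 11L, 10L, 18L, 13L, 14L, 9L, 15L, 16L, 12L),
         wt = c("L", "H", "R", "A", "S", "L", "T", "K", "E", "G"),
         mut = c("I", "P", "F", "G", "D", "A", "S", "R", "Q", "S"),
         source = "pssm", pssm_score = 1,
         stringsAsFactors = FALSE))
}

# independent rule-by-rule oracle over a battery fixture
battery_oracle <- function(fx, active_site_radius = 5.0,
                           exposure_threshold = 0.25,
                           burial_threshold = 0.10, volume_threshold = 40) {
  s <- fx$structure
  sasa <- compute_sasa(s)
  rel <- relative_sasa(s, sasa)
  ss <- assign_secondary_structure(s)
  hb <- detect_hbonds(s)
  vol <- residue_volumes()
  vapply(seq_len(nrow(fx$pool)), function(i) {
    p <- fx$pool[i, ]
    key <- paste0("A:", p$position, ":")
    d <- min_heavy_atom_distance(s, p$position, fx$catalytic)
    if (d <= active_site_radius) return(FALSE)
    sc_donor <- any(hb$donor_key == key & hb$donor_sidechain)
    sc_accept <- any(hb$acceptor_key == key & hb$acceptor_sidechain)
    if (sc_donor && !(p$mut %in% stabdesign:::SC_DONOR_AA)) return(FALSE)
    if (sc_accept && !(p$mut %in% stabdesign:::SC_ACCEPTOR_AA)) return(FALSE)
    if (p$mut %in% HYDROPHOBIC_AA && rel[key] > exposure_threshold)
      return(FALSE)
    if (ss[key] == "L" && (p$mut == "G" || p$wt == "P")) return(FALSE)
    if (p$mut == "P" && ss[key] == "H") return(FALSE)
    if (rel[key] < burial_threshold &&
        (vol[p$wt] - vol[p$mut]) > volume_threshold) return(FALSE)
    TRUE
  }, logical(1))
}
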