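test_that("isolated-atom SASA matches the analytic sphere", {
  s <- single_atom_structure(element = "C")
  sasa <- compute_sasa(s)
  analytic <- 4 * pi * (1.70 + 1.4)^2
  expect_equal(sasa$per_atom, analytic, tolerance = 0.01)
  expect_equal(unname(sasa$per_residue["A:1:"]), sasa$per_atom)
  # two carbons beyond mutual occlusion range stay fully exposed
  s2 <- atoms_structure(rbind(c(0, 0, 0), c(6.5, 0, 0)))
  sasa2 <- compute_sasa(s2)
  expect_equal(sasa2$per_atom, rep(analytic, 2), tolerance = 0.01)
  expect_error(compute_sasa(s, n_points = 50), "n_points")
})

test_that("the cage fixture's center has exactly zero SASA", {
  cage <- make_cage_fixture()
  for (np in c(960, 10000)) {
    sasa <- compute_sasa(cage, n_points = np)
    expect_equal(unname(sasa$per_residue["A:1:"]), 0)
    expect_true(all(sasa$per_residue[-1] > 0))  # shell stays open outward
  }
  # removing one shell atom opens the cage
  holed <- new_structure(cage$atoms[cage$atoms$resno != 3,
                                    !(names(cage$atoms) %in% "hetero")])
  expect_gt(compute_sasa(holed)$per_residue["A:1:"], 0)
})

test_that("default sampling agrees with the dense oracle on random clusters", {
  # the lattice estimates each atom's exposed fraction; compare fractions
  worst <- 0
  for (seed in 1:10) {
    s <- random_cluster_structure(n_atoms = 5, spread = 2.5, seed = seed)
    area <- 4 * pi * (stabdesign:::vdw_radius(s$atoms$element) + 1.4)^2
    f960 <- compute_sasa(s, n_points = 960)$per_atom / area
    f10k <- compute_sasa(s, n_points = 10000)$per_atom / area
    worst <- max(worst, max(abs(f960 - f10k)))
  }
  expect_lt(worst, 0.03)
})

test_that("SASA is exactly translation-invariant, rotation-stable in sampling", {
  s <- make_ideal_helix(8, "ADKLWSTH")
  base <- compute_sasa(s)$per_residue
  s_t <- s
  s_t$atoms[, c("x", "y", "z")] <- s$atoms[, c("x", "y", "z")] +
    rep(c(5, 6, -7), each = nrow(s$atoms))
  expect_equal(compute_sasa(s_t)$per_residue, base, tolerance = 1e-9)
  # the sample lattice is fixed in space, so rotations agree only to the
  # sampling resolution
  rot <- stabdesign:::rotation_matrix(c(0.3, 1, -2), 0.8)
  s_r <- s
  s_r$atoms[, c("x", "y", "z")] <-
    stabdesign:::rigid_transform(as.matrix(s$atoms[, c("x", "y", "z")]),
                                 rot, c(0, 0, 0))
  expect_equal(compute_sasa(s_r)$per_residue, base, tolerance = 0.03)
})

test_that("relative SASA normalizes, clips and rejects unknown residues", {
  # an isolated residue exceeds its Gly-X-Gly context maximum, so it clips
  path <- withr::local_tempfile(fileext = ".pdb")
  s <- read_pdb(write_single_ala_pdb(path))
  rel <- relative_sasa(s, compute_sasa(s))
  expect_gte(unname(rel["A:1:"]), 1)
  expect_lte(unname(rel["A:1:"]), 1.2)
  # a fully caged residue scores zero
  cage <- make_cage_fixture()
  expect_equal(unname(relative_sasa(cage, compute_sasa(cage))["A:1:"]), 0)
  # unknown polymer residue type
  bad <- single_atom_structure(resname = "XYZ")
  expect_error(relative_sasa(bad, compute_sasa(bad)), "configuration error")
})

test_that("hydrogen bonds require both distance and angle", {
  # constructed N(donor, antecedent CA) ... O(acceptor): 2.9 A, angle 160 deg
  build <- function(d_no) {
    new_structure(data.frame(
      record = "ATOM", chain = "A", resno = c(1L, 1L, 5L), icode = "",
      resname = c("GLY", "GLY", "GLY"), name = c("CA", "N", "O"),
      element = c("C", "N", "O"),
      x = c(-1.46 * cos(pi * 20 / 180), 0, d_no),
      y = c(1.46 * sin(pi * 20 / 180), 0, 0),
      z = 0, occ = 1, stringsAsFactors = FALSE))
  }
  hb <- detect_hbonds(build(2.9))
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, 2.9, tolerance = 1e-9)
  expect_equal(hb$angle, 160, tolerance = 1e-6)
  expect_equal(nrow(detect_hbonds(build(4.0))), 0)  # too far
  # angle below the cutoff: bend the antecedent to 100 degrees
  expect_equal(nrow(detect_hbonds(build(2.9), angle_min = 165)), 0)
})

test_that("an ideal helix shows its backbone i -> i-4 hydrogen bonds", {
  h <- make_ideal_helix(12)
  hb <- detect_hbonds(h)
  expect_gte(nrow(hb), 1)
  sep <- vapply(seq_len(nrow(hb)), function(i) {
    as.integer(strsplit(hb$donor_key[i], ":")[[1]][2]) -
      as.integer(strsplit(hb$acceptor_key[i], ":")[[1]][2])
  }, numeric(1))
  expect_true(all(sep == 4))
  expect_equal(nrow(hb), 12 - 4)
  # oracle distances from the helix geometry itself
  at <- h$atoms
  for (i in seq_len(nrow(hb))) {
    dres <- as.integer(strsplit(hb$donor_key[i], ":")[[1]][2])
    n <- unlist(at[at$resno == dres & at$name == "N", c("x", "y", "z")])
    o <- unlist(at[at$resno == dres - 4 & at$name == "O", c("x", "y", "z")])
    expect_equal(hb$distance[i], sqrt(sum((n - o)^2)), tolerance = 1e-9)
  }
})

test_that("secondary structure follows the dihedral run rules", {
  h <- make_ideal_helix(10)
  ss <- assign_secondary_structure(h)
  expect_equal(unname(ss), c("L", rep("H", 8), "L"))
  # a 2-residue fragment can never satisfy the run lengths
  frag <- build_torsion_chain(c(-57, -57), c(-47, -47))
  expect_equal(unname(assign_secondary_structure(frag)), c("L", "L"))
  # alternating-noise torsions defeat both rules
  noisy <- build_torsion_chain(rep(c(-57, 60), 5), rep(c(120, -47), 5))
  expect_true(all(assign_secondary_structure(noisy) == "L"))
  # extended strand torsions in runs >= 3 yield 'E'
  sheet <- build_torsion_chain(rep(-120, 6), rep(130, 6))
  expect_true(all(assign_secondary_structure(sheet)[2:5] == "E"))
  # missing backbone labels 'L' with a warning
  h2 <- make_ideal_helix(10)
  h2$atoms <- h2$atoms[!(h2$atoms$resno == 5 & h2$atoms$name == "CA"), ]
  expect_warning(ss2 <- assign_secondary_structure(h2), "missing backbone")
  expect_equal(unname(ss2["A:5:"]), "L")
})

test_that("each exclusion rule fires on its designed case", {
  fx <- make_battery_fixture()
  cfg <- filter_config(fx$catalytic, chain = "A")
  s <- fx$structure
  sasa <- compute_sasa(s)
  ss <- assign_secondary_structure(s)
  hb <- detect_hbonds(s)
  verdict_for <- function(pos) {
    i <- which(fx$pool$position == pos)
    evaluate_mutation_filters(s, fx$pool[i, ], cfg, sasa, ss, hb)
  }
  failed_rules <- function(v) v$rules$rule[!v$rules$pass]
  expect_true("active_site" %in% failed_rules(verdict_for(4)))
  expect_true("proline_in_helix" %in% failed_rules(verdict_for(11)))
  expect_true("loop_flexibility" %in% failed_rules(verdict_for(18)))
  expect_true("unsat_hbond" %in% failed_rules(verdict_for(13)))
  expect_true("cavity_creation" %in% failed_rules(verdict_for(14)))
  expect_true(verdict_for(9)$accepted)
  # cavity rule threshold arithmetic: L -> A loses 166.7 - 88.6 = 78.1 A^3
  vols <- residue_volumes()
  expect_equal(unname(vols["L"] - vols["A"]), 78.1, tolerance = 1e-9)
  expect_error(filter_config(character(0)), "configuration error")
})

test_that("the battery matches a rule-by-rule hand oracle", {
  fx <- make_battery_fixture()
  res <- apply_filter_battery(fx$pool, fx$structure,
                              filter_config(fx$catalytic, chain = "A"))
  oracle <- battery_oracle(fx)
  expect_equal(fx$pool$position %in% res$pool$position, unname(oracle))
  expect_equal(res$pool$position, fx$pool$position[oracle])  # order preserved
  expect_true(all(res$summary >= 1))  # every rule exercised at least once
  expect_equal(sum(vapply(res$verdicts, function(v) v$accepted, logical(1))),
               nrow(res$pool))
})

test_that("the battery is order-independent and threshold-monotone", {
  fx <- make_battery_fixture()
  cfg <- filter_config(fx$catalytic, chain = "A")
  res <- apply_filter_battery(fx$pool, fx$structure, cfg)
  perm <- c(7, 2, 9, 4, 1, 10, 3, 6, 5, 8)
  res_p <- apply_filter_battery(fx$pool[perm, ], fx$structure, cfg)
  expect_setequal(paste(res_p$pool$position, res_p$pool$mut),
                  paste(res$pool$position, res$pool$mut))
  # tightening thresholds never increases survivors
  res_r6 <- apply_filter_battery(fx$pool, fx$structure,
                                 filter_config(fx$catalytic, chain = "A",
                                               active_site_radius = 6))
  expect_lte(nrow(res_r6$pool), nrow(res$pool))
  res_e15 <- apply_filter_battery(fx$pool, fx$structure,
                                  filter_config(fx$catalytic, chain = "A",
                                                exposure_threshold = 0.15))
  expect_lte(nrow(res_e15$pool), nrow(res$pool))
  expect_error(apply_filter_battery(fx$pool[0, ], fx$structure, cfg),
               "empty")
})
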