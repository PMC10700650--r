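test_that("total energy terms evaluate exactly on constructed toys", {
  em <- energy_model()
  # two distant non-bonded glycines: every term vanishes
  far <- atoms_structure(rbind(c(0, 0, 0), c(20, 0, 0)), resno = c(1, 5))
  expect_equal(total_energy(far, em), 0)
  # two carbons at 2.0 A (radii sum 3.4): clash = 10 * 1.4^2
  clash <- atoms_structure(rbind(c(0, 0, 0), c(2, 0, 0)), resno = c(1, 5))
  expect_equal(total_energy(clash, em), 10 * 1.4^2, tolerance = 1e-12)
  # same pair on sequence-adjacent backbone is excluded from the clash sum
  adj <- atoms_structure(rbind(c(0, 0, 0), c(2, 0, 0)), resno = c(1, 2),
                         name = "CA")
  expect_equal(total_energy(adj, em), 0)
  # one hydrophobic interaction-center pair inside the radius: -contact_weight
  pair <- new_structure(data.frame(
    record = "ATOM", chain = "A", resno = c(1L, 5L), icode = "",
    resname = "LEU", name = "CB", element = "C",
    x = c(0, 6), y = 0, z = 0, occ = 1, stringsAsFactors = FALSE))
  expect_equal(total_energy(pair, em), -em$contact_weight)
  # per-residue reference energies add up
  em2 <- energy_model(reference_energies = setNames(rep(2, 20), AA_ALPHABET))
  expect_equal(total_energy(far, em2), 4)
})

test_that("the pssm bias term couples sequence choice to conservation", {
  s <- atoms_structure(rbind(c(0, 0, 0), c(20, 0, 0)), resname = "SER",
                       resno = c(1, 2), name = "CB")
  pssm <- compute_pssm(new_alignment(c("r", "h"), c("SS", "SS")), "r")
  em <- energy_model(pssm_bias_weight = 2)
  expected <- -2 * (pssm$scores[1, "S"] + pssm$scores[2, "S"])
  expect_equal(total_energy(s, em, pssm), unname(expected),
               tolerance = 1e-12)
})

test_that("annealing attains the exhaustive optimum on enumerable instances", {
  for (seed in 1:30) {
    set.seed(seed)
    inst <- make_packing_instance(sample(1:3, 1), sample(2:5, 1), seed = seed)
    fit <- anneal_states(inst$one_body, inst$two_body, mc_steps = 2000,
                         seed = seed + 1000)
    oracle <- enumerate_optimum(inst$one_body, inst$two_body)
    expect_equal(fit$energy, oracle$energy, tolerance = 1e-9)
    expect_equal(fit$energy, inst$optimum$energy, tolerance = 1e-9)
  }
})

test_that("more annealing steps never worsen the best-visited energy", {
  for (seed in 1:5) {
    inst <- make_packing_instance(3, 5, seed = seed)
    e_short <- anneal_states(inst$one_body, inst$two_body, mc_steps = 30,
                             seed = 9)$energy
    e_long <- anneal_states(inst$one_body, inst$two_body, mc_steps = 2000,
                            seed = 9)$energy
    expect_lte(e_long, e_short + 1e-9)
  }
})

test_that("packing picks the forced optimum and handles the identity case", {
  one <- list(c(5, -3))
  expect_equal(anneal_states(one, list(), mc_steps = 100, seed = 1)$assignment,
               2L)
  h <- make_ideal_helix(8)
  expect_warning(v <- pack_rotamers(h, integer(0), list(), seed = 1),
                 "empty designable")
  expect_equal(v$sequence, extract_sequence(h))
  expect_equal(nrow(v$mutations), 0)
  expect_equal(v$total_energy, total_energy(h))
})

test_that("structure-level packing equals brute-force enumeration", {
  h <- make_ideal_helix(9, "ASKDLENQT")
  em <- energy_model()
  rotlib <- default_rotamer_library()
  allowed <- list(c("F", "S"), c("W"))
  v <- pack_rotamers(h, c(4, 6), allowed, em, rotlib,
                     schedule = list(mc_steps = 1500, kT_start = 5,
                                     kT_end = 0.3), seed = 7)
  # oracle: enumerate every state pair and rescore assembled models with the
  # independent full-energy path
  problem <- stabdesign:::build_pack_problem(h, c(4, 6), allowed, em, rotlib)
  grid <- as.matrix(expand.grid(lapply(lengths(problem$one_body), seq_len)))
  energies <- apply(grid, 1, function(a) total_energy(
    stabdesign:::assemble_variant(problem, as.integer(a)), em))
  expect_equal(v$total_energy, min(energies), tolerance = 1e-9)
  expect_true(all(v$mutations$mut %in% c("F", "S", "W")))
})

test_that("packing is deterministic for a fixed seed", {
  h <- make_ideal_helix(10)
  args <- list(h, c(3, 5, 7), list("F", c("W", "Y"), "K"), seed = 42)
  v1 <- do.call(pack_rotamers, args)
  v2 <- do.call(pack_rotamers, args)
  expect_identical(v1$sequence, v2$sequence)
  expect_identical(v1$structure$atoms, v2$structure$atoms)
  expect_identical(v1$total_energy, v2$total_energy)
})

test_that("relaxation is identity at zero steps and never raises the energy", {
  h <- make_ideal_helix(8)
  v <- pack_rotamers(h, c(4, 5), list("F", "W"), seed = 2)
  expect_identical(relax_model(v, steps = 0), v)
  r <- relax_model(v, steps = 30, seed = 3)
  expect_lte(r$total_energy, v$total_energy)
  expect_equal(r$sequence, v$sequence)  # relaxation moves atoms, not sequence
  expect_equal(r$total_energy, total_energy(r))  # reported = recomputed
})

test_that("relaxation relieves a constructed interaction-center clash", {
  # two reduced side-chain centers overlapping by 1.4 A
  s <- new_structure(data.frame(
    record = "ATOM", chain = "A", resno = c(1L, 5L), icode = "",
    resname = "SER", name = "CEN", element = "C",
    x = c(0, 2), y = 0, z = 0, occ = 1, stringsAsFactors = FALSE))
  em <- energy_model(contact_weight = 0)
  e0 <- total_energy(s, em)
  expect_equal(e0, 10 * 1.4^2, tolerance = 1e-12)
  r <- relax_model(s, em, steps = 400, step_size = 0.4, seed = 8)
  expect_lt(r$total_energy, e0)
  # the clash term at the output coordinates explains the drop
  expect_equal(r$total_energy, total_energy(r$structure, em),
               tolerance = 1e-12)
})

test_that("generated variants respect every contract", {
  h <- make_ideal_helix(30, strrep("ASKDLENQTG", 3))
  pool <- data.frame(
    chain = "A",
    position = c(2, 5, 8, 12, 15, 18, 22, 25, 28),
    wt = strsplit(strrep("ASKDLENQTG", 3), "")[[1]][c(2, 5, 8, 12, 15, 18,
                                                      22, 25, 28)],
    mut = c("T", "F", "R", "E", "W", "D", "Y", "W", "K"),
    source = "pssm", pssm_score = 1, stringsAsFactors = FALSE)
  cfg <- design_config(n_variants_requested = 5, mc_steps = 600,
                       relax_steps = 10, seed = 11)
  # reference energies rewarding the pool amino acids stand in for the
  # conservation bias of a full run
  refs <- setNames(rep(0, 20), AA_ALPHABET)
  refs[unique(pool$mut)] <- -2
  em <- energy_model(reference_energies = refs)
  vars <- generate_variants(h, pool, cfg, em = em)
  expect_length(vars, 5)
  L <- 30
  lo <- ceiling(cfg$mutation_fraction_min * L)
  hi <- floor(cfg$mutation_fraction_max * L)
  for (v in vars) {
    expect_gte(nrow(v$mutations), lo)
    expect_lte(nrow(v$mutations), hi)
    expect_true(all(paste(v$mutations$position, v$mutations$mut) %in%
                      paste(pool$position, pool$mut)))
    expect_lt(v$total_energy, v$wt_energy_ref)
    expect_lt(v$energy_gap, 0)
  }
  # determinism contract: identical master seed and config, identical output
  vars2 <- generate_variants(h, pool, cfg, em = em)
  expect_identical(lapply(vars, function(v) v$sequence),
                   lapply(vars2, function(v) v$sequence))
  expect_identical(vars[[1]]$structure$atoms, vars2[[1]]$structure$atoms)
})

test_that("an undersized pool is an invalid-configuration error", {
  h <- make_ideal_helix(30)
  pool <- data.frame(chain = "A", position = 5L, wt = "A", mut = "F",
                     source = "pssm", pssm_score = 1, stringsAsFactors = FALSE)
  cfg <- design_config(mutation_fraction_min = 0.1, seed = 1)
  expect_error(generate_variants(h, pool, cfg), "invalid configuration")
})

test_that("subset sizes derive from the stated fraction bounds", {
  expect_equal(ceiling(0.02 * 100), 2)
  expect_equal(floor(0.20 * 100), 20)
  h <- make_ideal_helix(12)
  pool <- data.frame(chain = "A", position = c(3L, 5L, 7L, 9L),
                     wt = "A", mut = c("S", "T", "K", "E"),
                     source = "pssm", pssm_score = 1, stringsAsFactors = FALSE)
  cfg <- design_config(mutation_fraction_min = 0.2,
                       mutation_fraction_max = 0.34,
                       n_variants_requested = 3, mc_steps = 300,
                       relax_steps = 5, seed = 3)
  refs <- setNames(rep(0, 20), AA_ALPHABET)
  refs[unique(pool$mut)] <- -2
  em <- energy_model(contact_weight = 0, reference_energies = refs)
  vars <- generate_variants(h, pool, cfg, em = em)
  expect_length(vars, 3)
  for (v in vars) {
    expect_gte(nrow(v$mutations), ceiling(0.2 * 12))  # 3
    expect_lte(nrow(v$mutations), floor(0.34 * 12))   # 4
  }
})
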