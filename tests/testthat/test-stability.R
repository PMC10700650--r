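test_that("read_ddg_table parses, deduplicates to the lowest ddg, and errors", {
  tab <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chain\tposition\twt\tmut\tddg",
               "A\t101\tL\tF\t-0.6", "A\t192\tS\tK\t-1.2",
               "A\t30\tT\tA\t0.4"), tab)
  rec <- read_ddg_table(tab)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$method, rep("external", 3))
  expect_equal(rec$ddg, c(-0.6, -1.2, 0.4))

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chain\tposition\twt\tmut\tddg",
               "A\t101\tL\tF\t-0.2", "A\t101\tL\tF\t-0.6"), dup)
  expect_message(rec2 <- read_ddg_table(dup), "duplicate")
  expect_equal(nrow(rec2), 1)
  expect_equal(rec2$ddg, -0.6)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chain\tposition\twt\tmut\tddg", "A\t101\tL\tF\tabc"), bad)
  expect_error(read_ddg_table(bad), "line 2")
})

test_that("the ddg filter is strict at the cutoff and order-preserving", {
  rec <- data.frame(chain = "A", position = 1:4, wt = "L", mut = "F",
                    ddg = c(-0.6, -0.51, -0.4, 0.2), method = "external",
                    stringsAsFactors = FALSE)
  kept <- filter_by_ddg(rec, -0.5)
  expect_equal(kept$ddg, c(-0.6, -0.51))
  # exactly the cutoff is excluded ("less than")
  at_cut <- rbind(rec, data.frame(chain = "A", position = 5L, wt = "L",
                                  mut = "I", ddg = -0.5,
                                  method = "external"))
  expect_false(-0.5 %in% filter_by_ddg(at_cut, -0.5)$ddg)
  expect_equal(nrow(filter_by_ddg(rec[0, ], -0.5)), 0)
  expect_warning(filter_by_ddg(transform(rec, method = c("external",
                                                         "surrogate",
                                                         "external",
                                                         "external")), -0.5),
                 "mixing")
})

test_that("lowering the cutoff never adds records", {
  set.seed(42)
  rec <- data.frame(chain = "A", position = 1:50, wt = "L", mut = "F",
                    ddg = runif(50, -3, 1), method = "external",
                    stringsAsFactors = FALSE)
  cuts <- c(0, -0.5, -1, -1.5, -2.5)
  sizes <- vapply(cuts, function(ct) nrow(filter_by_ddg(rec, ct)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
  for (k in 2:length(cuts)) {
    inner <- filter_by_ddg(rec, cuts[k])$position
    outer <- filter_by_ddg(rec, cuts[k - 1])$position
    expect_true(all(inner %in% outer))
  }
})

test_that("a self-substitution has ddg zero by construction", {
  h <- make_ideal_helix(10)
  d <- surrogate_ddg(h, list(chain = "A", position = 5, wt = "A", mut = "A"))
  expect_equal(d$ddg, 0)
  expect_equal(d$method, "surrogate")
})

test_that("surrogate ddg errors on missing or mismatched residues", {
  h <- make_ideal_helix(10)
  expect_error(surrogate_ddg(h, list(chain = "A", position = 99, wt = "A",
                                     mut = "W")), "not found")
  expect_error(surrogate_ddg(h, list(chain = "A", position = 5, wt = "L",
                                     mut = "W")), "mismatch")
})

test_that("gaining hydrophobic contacts is stabilizing, forced clashes are not", {
  h <- make_ideal_helix(14)
  # burying a large hydrophobic into a clash-free helix face gains contacts
  d_w <- surrogate_ddg(h, list(chain = "A", position = 7, wt = "A",
                               mut = "W"), seed = 3)
  expect_lt(d_w$ddg, 0)
  # an obstruction right outside CB makes every bulky rotamer clash
  at <- h$atoms
  cb <- at[at$resno == 7 & at$name == "CB", c("x", "y", "z")]
  ca <- at[at$resno == 7 & at$name == "CA", c("x", "y", "z")]
  dir <- as.numeric(cb - ca) / sqrt(sum((cb - ca)^2))
  block <- as.numeric(cb) + 1.6 * dir
  blocked <- new_structure(rbind(
    h$atoms[, !(names(h$atoms) %in% "hetero")],
    data.frame(record = "HETATM", chain = "A", resno = 900L, icode = "",
               resname = "BLK", name = "C1", element = "C",
               x = block[1], y = block[2], z = block[3], occ = 1,
               stringsAsFactors = FALSE)))
  d_blocked <- surrogate_ddg(blocked, list(chain = "A", position = 7,
                                           wt = "A", mut = "W"), seed = 3,
                             em = energy_model(contact_weight = 0))
  expect_gt(d_blocked$ddg, 0)
})

test_that("surrogate ddg matches an exhaustive state-enumeration oracle", {
  h <- make_ideal_helix(8)
  em <- energy_model()
  rotlib <- default_rotamer_library()
  mut <- list(chain = "A", position = 4, wt = "A", mut = "F")
  d <- surrogate_ddg(h, mut, em, rotlib, seed = 5)
  # oracle: enumerate every (aa fixed, rotamer) state of the local repack and
  # score the assembled structures with the full energy recomputation
  energy_of_best <- function(target_aa) {
    at <- h$atoms
    neighbors <- residue_table(h)$resno[residue_table(h)$resno != 4]
    near <- neighbors[vapply(neighbors, function(r)
      min_heavy_atom_distance(h, r, 4) <= em$contact_radius, logical(1))]
    problem <- stabdesign:::build_pack_problem(
      h, c(4, near), c(list(target_aa), rep(list(character(0)), length(near))),
      em, rotlib)
    grid <- as.matrix(expand.grid(lapply(lengths(problem$one_body), seq_len)))
    min(apply(grid, 1, function(a) total_energy(
      stabdesign:::assemble_variant(problem, as.integer(a)), em)))
  }
  expect_equal(d$ddg, energy_of_best("F") - energy_of_best("A"),
               tolerance = 1e-9)
})

test_that("surrogate ddg is invariant under rigid-body transforms", {
  h <- make_ideal_helix(10)
  mut <- list(chain = "A", position = 5, wt = "A", mut = "F")
  d1 <- surrogate_ddg(h, mut, seed = 2)
  rot <- stabdesign:::rotation_matrix(c(1, -2, 0.5), 1.1)
  h2 <- h
  h2$atoms[, c("x", "y", "z")] <-
    stabdesign:::rigid_transform(as.matrix(h$atoms[, c("x", "y", "z")]),
                                 rot, c(10, -4, 2))
  d2 <- surrogate_ddg(h2, mut, seed = 2)
  expect_equal(d1$ddg, d2$ddg, tolerance = 1e-6)
})

test_that("ddg is antisymmetric on enumerable two-state toys", {
  # A<->V at a helix position: both local repacks reach their exhaustive
  # optima, so ddg(A->V | helix_A) = -ddg(V->A | helix_V)
  hA <- make_ideal_helix(8, "AAAAAAAA")
  hV <- make_ideal_helix(8, "AAAVAAAA")
  fwd <- surrogate_ddg(hA, list(chain = "A", position = 4, wt = "A",
                                mut = "V"), seed = 1, mc_steps = 500)
  rev <- surrogate_ddg(hV, list(chain = "A", position = 4, wt = "V",
                                mut = "A"), seed = 1, mc_steps = 500)
  expect_equal(fwd$ddg, -rev$ddg, tolerance = 1e-6)
})
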