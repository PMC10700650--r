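# Combinatorial variant design: rotamer library, Monte-Carlo packing over a
# precomputed interaction decomposition, perturb-minimize relaxation, and the
# variant generation loop.
#
# Designed positions use a reduced side-chain representation: the side chain
# is a single interaction center placed at a rotamer-specific offset in the
# C-beta frame of the residue. This avoids a full side-chain builder while
# preserving packing decisions; the fidelity trade-off is documented in the
# methods vignette.

#' Read a rotamer library from TSV
#'
#' Columns: aa (1-letter), rotamer (index), dx/dy/dz (offset of the
#' interaction center from C-beta, in the local C-beta frame, Angstrom),
#' prior. Priors are renormalized per amino acid.
#' @param path TSV file
#' @return named list (per amino acid): `offsets` (k x 3 matrix), `priors`
#' @export
read_rotamer_library <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("aa", "rotamer", "dx", "dy", "dz", "prior")
  if (!all(need %in% names(tab)))
    stop("rotamer library must have columns ", paste(need, collapse = ", "))
  lib <- lapply(split(tab, tab$aa), function(d) {
    d <- d[order(d$rotamer), , drop = FALSE]
    list(offsets = as.matrix(d[, c("dx", "dy", "dz")]),
         priors = d$prior / sum(d$prior))
  })
  missing_aa <- setdiff(AA_ALPHABET, names(lib))
  if (length(missing_aa))
    stop("rotamer library lacks amino acid(s): ",
         paste(missing_aa, collapse = ", "))
  structure(lib, class = "RotamerLibrary")
}

#' The shipped minimal rotamer library
#'
#' One to three interaction-center rotamers per amino acid with uniform
#' priors; sufficient for relative packing decisions and replaceable via
#' [read_rotamer_library()].
#' @export
default_rotamer_library <- function() {
  read_rotamer_library(system.file("extdata", "rotamers.tsv",
                                   package = "stabdesign", mustWork = TRUE))
}

#' Design-loop configuration
#'
#' @param mutation_fraction_min,mutation_fraction_max designable-subset size
#'   as a fraction of the design-region length (defaults 0.02 and 0.20)
#' @param ddg_cutoff stabilizing ddG cutoff, kcal/mol-like (default -0.5)
#' @param active_site_radius exclusion radius (Angstrom, default 5)
#' @param mc_steps Metropolis steps per packing run (default 2000)
#' @param kT_start,kT_end geometric cooling schedule endpoints (defaults 5
#'   and 0.3)
#' @param relax_steps perturb-minimize iterations (default 50)
#' @param relax_step_size maximum per-atom displacement per move (Angstrom,
#'   default 0.3)
#' @param rmsd_cutoff C-alpha RMSD screening cutoff (Angstrom, default 1.0)
#' @param n_variants_requested number of variants to emit (default 10)
#' @param seed master seed; per-variant seeds are derived from it
#' @param max_attempts_factor design attempts allowed per requested variant
#' @export
design_config <- function(mutation_fraction_min = 0.02,
                          mutation_fraction_max = 0.20,
                          ddg_cutoff = -0.5,
                          active_site_radius = 5.0,
                          mc_steps = 2000, kT_start = 5, kT_end = 0.3,
                          relax_steps = 50, relax_step_size = 0.3,
                          rmsd_cutoff = 1.0, n_variants_requested = 10,
                          seed = 1, max_attempts_factor = 5) {
  if (!(mutation_fraction_min > 0 &&
        mutation_fraction_min <= mutation_fraction_max &&
        mutation_fraction_max < 1))
    stop("invalid configuration: need 0 < fraction_min <= fraction_max < 1")
  if (mc_steps < 0 || relax_steps < 0)
    stop("invalid configuration: step counts must be >= 0")
  structure(as.list(environment()), class = "DesignConfig")
}

cb_frame <- function(n, ca, c, cb = NULL) {
  if (is.null(cb)) cb <- ideal_cb(n, ca, c)
  e1 <- unitv(cb - ca)
  v <- n - ca
  e2 <- v - sum(v * e1) * e1
  e2 <- if (vnorm(e2) < 1e-8) unitv(vcross(e1, c(0, 0, 1))) else unitv(e2)
  e3 <- vcross(e1, e2)
  list(origin = cb, basis = cbind(e1, e2, e3))
}

strip_sidechains <- function(structure, keys) {
  at <- structure$atoms
  akeys <- atom_residue_keys(structure)
  keep <- !(akeys %in% keys) | (at$name %in% BACKBONE_ATOMS)
  new_structure(at[keep, , drop = FALSE], title = structure$title)
}

# Precompute the exact decomposition of the surrogate energy over designable
# positions: E(total) = fixed + sum_i one_body[i][s_i] + sum_{i<j}
# two_body[[i:j]][s_i, s_j]. States at a position are ordered by (amino acid,
# rotamer index), which also fixes lexicographic tie-breaking.
build_pack_problem <- function(structure, designable, allowed, em, rotlib,
                               pssm = NULL, chain = NULL, include_wt = TRUE) {
  if (is.null(chain)) chain <- first_polymer_chain(structure)
  res <- polymer_residues(structure, chain)
  designable <- as.integer(designable)
  idx <- match(designable, res$resno)
  if (any(is.na(idx)))
    stop("position not in structure: ",
         paste(designable[is.na(idx)], collapse = ", "))
  if (any(!(res$aa[idx] %in% AA_ALPHABET)))
    stop("non-standard residues are not designable: ",
         paste(designable[!(res$aa[idx] %in% AA_ALPHABET)], collapse = ", "))
  keys <- res$key[idx]
  wt_aa <- res$aa[idx]
  np <- length(designable)

  at <- structure$atoms
  akeys <- atom_residue_keys(structure)
  getxyz <- function(key, name) {
    k <- which(akeys == key & at$name == name)
    if (!length(k)) return(NULL)
    c(at$x[k[1]], at$y[k[1]], at$z[k[1]])
  }
  frames <- lapply(keys, function(k) {
    n <- getxyz(k, "N"); ca <- getxyz(k, "CA"); c_ <- getxyz(k, "C")
    if (is.null(n) || is.null(ca) || is.null(c_))
      stop("designable residue ", k, " lacks a full backbone")
    cb <- getxyz(k, "CB")
    cb_frame(n, ca, c_, cb)
  })

  states <- vector("list", np)
  for (i in seq_len(np)) {
    aas <- sort(unique(c(if (include_wt) wt_aa[i], allowed[[i]])))
    if (!length(aas))
      stop("no allowed amino acid at position ", designable[i])
    bad <- setdiff(aas, AA_ALPHABET)
    if (length(bad)) stop("unknown amino acid(s) in allowed set: ",
                          paste(bad, collapse = ", "))
    st <- list()
    for (aa in aas) {
      rot <- rotlib[[aa]]
      for (r in seq_len(nrow(rot$offsets))) {
        cen <- frames[[i]]$origin + frames[[i]]$basis %*% rot$offsets[r, ]
        st[[length(st) + 1]] <- list(aa = aa, rotamer = r,
                                     center = as.numeric(cen))
      }
    }
    states[[i]] <- st
  }

  base <- strip_sidechains(structure, keys)
  bat <- base$atoms
  bkeys <- atom_residue_keys(base)
  bcoords <- as.matrix(bat[, c("x", "y", "z")])
  bradii <- vdw_radius(bat$element, em$vdw_radii)
  cen_radius <- vdw_radius("C", em$vdw_radii)

  # fixed-part energy: clash among fixed atoms, contacts among non-designable
  # centers, hydrogen bonds of the reduced model, sequence terms of the
  # non-designable residues
  centers_fixed <- interaction_centers(base)
  centers_fixed <- centers_fixed[!(centers_fixed$key %in% keys), , drop = FALSE]
  seq_fixed <- {
    rt <- residue_table(base)
    rt <- rt[!rt$hetero & rt$aa %in% AA_ALPHABET &
               !(rt$key %in% keys), , drop = FALSE]
    e <- sum(em$reference_energies[rt$aa])
    if (!is.null(pssm)) {
      sel <- rt$chain == pssm$chain
      pidx <- match(rt$resno[sel], pssm$positions)
      ok <- !is.na(pidx)
      if (any(ok))
        e <- e - em$pssm_bias_weight *
          sum(pssm$scores[cbind(pidx[ok], match(rt$aa[sel][ok], AA_ALPHABET))])
    }
    e
  }
  fixed_energy <- clash_energy_atoms(bat, em) -
    em$contact_weight * contact_count(centers_fixed, em$contact_radius) -
    em$hbond_energy * nrow(detect_hbonds(base)) +
    seq_fixed

  hyd_fixed <- centers_fixed[centers_fixed$hydrophobic, , drop = FALSE]
  hyd_coords <- as.matrix(hyd_fixed[, c("x", "y", "z")])

  one_body <- vector("list", np)
  for (i in seq_len(np)) {
    own <- bkeys == keys[i]
    vals <- vapply(states[[i]], function(st) {
      cen <- st$center
      d <- sqrt(colSums((t(bcoords) - cen)^2))
      overlap <- pmax(0, bradii + cen_radius - d)
      overlap[own] <- 0  # same-residue pairs excluded
      e <- em$clash_weight * sum(overlap^2)
      if (st$aa %in% HYDROPHOBIC_AA && nrow(hyd_coords)) {
        dc <- sqrt(colSums((t(hyd_coords) - cen)^2))
        e <- e - em$contact_weight * sum(dc <= em$contact_radius)
      }
      e <- e + unname(em$reference_energies[st$aa])
      if (!is.null(pssm)) {
        sc <- pssm_score_at(pssm, designable[i], st$aa)
        if (!is.na(sc)) e <- e - em$pssm_bias_weight * sc
      }
      e
    }, numeric(1))
    one_body[[i]] <- vals
  }

  two_body <- list()
  if (np > 1) {
    for (i in seq_len(np - 1)) for (j in (i + 1):np) {
      m <- matrix(0, length(states[[i]]), length(states[[j]]))
      for (a in seq_along(states[[i]])) for (b in seq_along(states[[j]])) {
        sa <- states[[i]][[a]]; sb <- states[[j]][[b]]
        d <- vnorm(sa$center - sb$center)
        overlap <- max(0, 2 * cen_radius - d)
        e <- em$clash_weight * overlap^2
        if (sa$aa %in% HYDROPHOBIC_AA && sb$aa %in% HYDROPHOBIC_AA &&
            d <= em$contact_radius)
          e <- e - em$contact_weight
        m[a, b] <- e
      }
      two_body[[paste(i, j, sep = ":")]] <- m
    }
  }

  list(structure = structure, base = base, chain = chain,
       positions = designable, keys = keys, wt_aa = wt_aa,
       states = states, one_body = one_body, two_body = two_body,
       fixed_energy = fixed_energy, em = em, pssm = pssm)
}

problem_tables <- function(problem) {
  list(one_body = problem$one_body, two_body = problem$two_body)
}

lex_less <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  FALSE
}

eval_assignment <- function(one_body, two_body, assign) {
  e <- sum(vapply(seq_along(assign), function(i) one_body[[i]][assign[i]],
                  numeric(1)))
  for (nm in names(two_body)) {
    ij <- as.integer(strsplit(nm, ":", fixed = TRUE)[[1]])
    e <- e + two_body[[nm]][assign[ij[1]], assign[ij[2]]]
  }
  e
}

#' Simulated-annealing Metropolis optimization over discrete states
#'
#' The packing engine: positions carry discrete states with precomputed
#' one-body energies and pairwise two-body energies; a Metropolis walk under
#' a geometric cooling schedule returns the best state visited. Ties are
#' broken toward the lexicographically smallest assignment. Deterministic for
#' a fixed seed.
#'
#' @param one_body list of numeric vectors (one per position)
#' @param two_body named list "i:j" -> matrix of pair energies (i < j)
#' @param mc_steps number of Metropolis proposals
#' @param kT_start,kT_end geometric cooling endpoints
#' @param seed RNG seed
#' @return list: `assignment` (state index per position), `energy`
#' @export
anneal_states <- function(one_body, two_body = list(), mc_steps = 2000,
                          kT_start = 5, kT_end = 0.3, seed = 1) {
  np <- length(one_body)
  nstates <- lengths(one_body)
  # greedy one-body start; first index wins ties (lexicographic)
  assign <- vapply(one_body, which.min, integer(1))
  cur_e <- eval_assignment(one_body, two_body, assign)
  best <- assign; best_e <- cur_e
  if (mc_steps > 0 && any(nstates > 1)) {
    pair_idx <- lapply(names(two_body), function(nm)
      as.integer(strsplit(nm, ":", fixed = TRUE)[[1]]))
    kts <- kT_start * (kT_end / kT_start)^(seq_len(mc_steps) / mc_steps)
    with_seed(seed, {
      for (step in seq_len(mc_steps)) {
        i <- sample.int(np, 1)
        if (nstates[i] == 1) next
        s_new <- sample.int(nstates[i], 1)
        s_old <- assign[i]
        if (s_new == s_old) next
        de <- one_body[[i]][s_new] - one_body[[i]][s_old]
        for (k in seq_along(pair_idx)) {
          pi_ <- pair_idx[[k]]
          if (pi_[1] == i)
            de <- de + two_body[[k]][s_new, assign[pi_[2]]] -
              two_body[[k]][s_old, assign[pi_[2]]]
          else if (pi_[2] == i)
            de <- de + two_body[[k]][assign[pi_[1]], s_new] -
              two_body[[k]][assign[pi_[1]], s_old]
        }
        if (de <= 0 || runif(1) < exp(-de / kts[step])) {
          assign[i] <- s_new
          cur_e <- cur_e + de
          if (cur_e < best_e - 1e-9) {
            best <- assign
            best_e <- eval_assignment(one_body, two_body, assign)
            cur_e <- best_e
          } else if (cur_e <= best_e + 1e-9 && lex_less(assign, best)) {
            best <- assign
            best_e <- eval_assignment(one_body, two_body, assign)
            cur_e <- best_e
          }
        }
      }
    })
  }
  list(assignment = best, energy = best_e)
}

assemble_variant <- function(problem, assignment) {
  base <- problem$base
  at <- base$atoms
  akeys <- atom_residue_keys(base)
  pieces <- list()
  done <- rep(FALSE, nrow(at))
  ord_keys <- unique(akeys)
  for (key in ord_keys) {
    sel <- which(akeys == key)
    block <- at[sel, , drop = FALSE]
    di <- match(key, problem$keys)
    if (!is.na(di)) {
      st <- problem$states[[di]][[assignment[di]]]
      block$resname <- aa1to3(st$aa)
      cen_row <- block[1, , drop = FALSE]
      cen_row$name <- "CEN"; cen_row$element <- "C"
      cen_row$x <- st$center[1]; cen_row$y <- st$center[2]
      cen_row$z <- st$center[3]; cen_row$occ <- 1
      block <- rbind(block, cen_row)
    }
    pieces[[length(pieces) + 1]] <- block
    done[sel] <- TRUE
  }
  new_structure(do.call(rbind, pieces), title = base$title)
}

new_variant_model <- function(structure, chain, mutations, total_energy,
                              ca_rmsd = NA_real_, wt_energy_ref = NULL,
                              id = NA_character_) {
  structure(list(
    id = id,
    sequence = extract_sequence(structure, chain),
    structure = structure,
    chain = chain,
    mutations = mutations,
    total_energy = total_energy,
    ca_rmsd = ca_rmsd,
    wt_energy_ref = wt_energy_ref,
    energy_gap = if (is.null(wt_energy_ref)) NA_real_
                 else total_energy - wt_energy_ref
  ), class = "VariantModel")
}

#' @export
print.VariantModel <- function(x, ...) {
  cat("VariantModel", if (!is.na(x$id)) paste0("'", x$id, "'") else "",
      ":", nrow(x$mutations), "mutation(s), energy",
      sprintf("%.3f", x$total_energy),
      if (!is.na(x$ca_rmsd)) sprintf(", Ca RMSD %.3f A", x$ca_rmsd) else "",
      "\n")
  if (nrow(x$mutations))
    cat(" ", paste(sprintf("%s%d%s", x$mutations$wt, x$mutations$position,
                           x$mutations$mut), collapse = " "), "\n")
  invisible(x)
}

mutation_df <- function(chain, position, wt, mut) {
  data.frame(chain = chain, position = as.integer(position), wt = wt,
             mut = mut, stringsAsFactors = FALSE)
}

#' Monte-Carlo rotamer packing over designable positions
#'
#' Builds the exact one-/two-body decomposition of the surrogate energy over
#' the designable positions (side chains reduced to interaction centers) and
#' optimizes amino-acid and rotamer choices with [anneal_states()]. The wild
#' type is always allowed at every position. Deterministic for a fixed seed.
#'
#' @param structure wild-type ProteinStructure
#' @param designable_positions author residue numbers to design
#' @param allowed_aas_per_position list (parallel to positions) of allowed
#'   amino-acid vectors; the position's wild type is added automatically
#'   unless `include_wt` is FALSE (used to force a substitution, as the ddG
#'   scan does)
#' @param em an [energy_model()]
#' @param rotlib a rotamer library ([default_rotamer_library()])
#' @param schedule list with mc_steps, kT_start, kT_end
#' @param seed RNG seed
#' @param pssm optional PSSM supplying the sequence bias
#' @param chain chain to design (default: first polymer chain)
#' @param include_wt keep the wild type in every position's allowed set
#'   (default TRUE)
#' @return a `VariantModel` (best-energy state visited). An empty designable
#'   set returns the input as an identity variant with a warning.
#' @export
pack_rotamers <- function(structure, designable_positions,
                          allowed_aas_per_position,
                          em = energy_model(),
                          rotlib = default_rotamer_library(),
                          schedule = list(mc_steps = 2000, kT_start = 5,
                                          kT_end = 0.3),
                          seed = 1, pssm = NULL, chain = NULL,
                          include_wt = TRUE) {
  if (is.null(chain)) chain <- first_polymer_chain(structure)
  if (!length(designable_positions)) {
    warning("empty designable set: returning the wild type unchanged")
    return(new_variant_model(structure, chain,
                             mutation_df(character(), integer(), character(),
                                         character()),
                             total_energy(structure, em, pssm)))
  }
  problem <- build_pack_problem(structure, designable_positions,
                                allowed_aas_per_position, em, rotlib,
                                pssm, chain, include_wt = include_wt)
  fit <- anneal_states(problem$one_body, problem$two_body,
                       mc_steps = schedule$mc_steps,
                       kT_start = schedule$kT_start,
                       kT_end = schedule$kT_end, seed = seed)
  model <- assemble_variant(problem, fit$assignment)
  chosen <- vapply(seq_along(fit$assignment), function(i)
    problem$states[[i]][[fit$assignment[i]]]$aa, character(1))
  changed <- chosen != problem$wt_aa
  new_variant_model(model, chain,
                    mutation_df(rep(chain, sum(changed)),
                                problem$positions[changed],
                                problem$wt_aa[changed], chosen[changed]),
                    problem$fixed_energy + fit$energy)
}

#' Perturb-minimize relaxation of a variant model
#'
#' Iterated random perturbations of the side-chain interaction centers
#' (displacement at most `step_size` per atom per move) plus a smaller
#' backbone jitter, accepted by Metropolis on the surrogate energy under a
#' geometric cooling schedule. The best-visited model is returned, so the
#' output energy never exceeds the input energy. Deterministic for a fixed
#' seed.
#'
#' @param model a VariantModel (or ProteinStructure)
#' @param em an [energy_model()]
#' @param steps number of perturbation cycles (0 returns the input)
#' @param step_size maximum center displacement per move (Angstrom)
#' @param seed RNG seed
#' @param pssm optional PSSM for the sequence-bias term
#' @param backbone_jitter maximum backbone displacement per move (default
#'   step_size / 5)
#' @param kT_start,kT_end cooling endpoints
#' @return relaxed VariantModel
#' @export
relax_model <- function(model, em = energy_model(), steps = 50,
                        step_size = 0.3, seed = 1, pssm = NULL,
                        backbone_jitter = NULL, kT_start = 1, kT_end = 0.05) {
  if (steps < 0) stop("invalid argument: steps must be >= 0")
  if (inherits(model, "ProteinStructure")) {
    chain <- first_polymer_chain(model)
    model <- new_variant_model(model, chain,
                               mutation_df(character(), integer(),
                                           character(), character()),
                               total_energy(model, em, pssm))
  }
  if (steps == 0) return(model)
  if (is.null(backbone_jitter)) backbone_jitter <- step_size / 5
  s <- model$structure
  cen_idx <- which(s$atoms$name == "CEN")
  bb_idx <- which(s$atoms$name %in% BACKBONE_ATOMS & !s$atoms$hetero)
  cur <- s
  cur_e <- total_energy(cur, em, pssm)
  best <- cur; best_e <- cur_e
  kts <- kT_start * (kT_end / kT_start)^(seq_len(steps) / steps)
  clip_rows <- function(m, maxlen) {
    len <- sqrt(rowSums(m^2))
    scale <- ifelse(len > maxlen, maxlen / len, 1)
    m * scale
  }
  with_seed(seed, {
    for (step in seq_len(steps)) {
      prop <- cur
      if (length(cen_idx)) {
        d <- clip_rows(matrix(runif(3 * length(cen_idx), -step_size,
                                    step_size), ncol = 3), step_size)
        prop$atoms[cen_idx, c("x", "y", "z")] <-
          prop$atoms[cen_idx, c("x", "y", "z")] + d
      }
      if (length(bb_idx) && backbone_jitter > 0) {
        d <- clip_rows(matrix(runif(3 * length(bb_idx), -backbone_jitter,
                                    backbone_jitter), ncol = 3),
                       backbone_jitter)
        prop$atoms[bb_idx, c("x", "y", "z")] <-
          prop$atoms[bb_idx, c("x", "y", "z")] + d
      }
      e <- total_energy(prop, em, pssm)
      if (e <= cur_e || runif(1) < exp(-(e - cur_e) / kts[step])) {
        cur <- prop; cur_e <- e
        if (cur_e < best_e) { best <- cur; best_e <- cur_e }
      }
    }
  })
  out <- model
  out$structure <- best
  out$total_energy <- best_e
  if (!is.null(out$wt_energy_ref))
    out$energy_gap <- best_e - out$wt_energy_ref
  out
}

derive_seed <- function(master, k) {
  as.integer((as.numeric(master) + 7919 * as.numeric(k)) %% 2147483647)
}

#' Generate candidate multi-mutant variants from the surviving pool
#'
#' For each requested variant a designable subset of size m (uniform between
#' ceil(fraction_min * L) and floor(fraction_max * L), L the design-region
#' length) is drawn from the pool positions; allowed amino acids are the wild
#' type plus the pool substitutions at those positions; the subset is packed
#' ([pack_rotamers()]) and relaxed ([relax_model()]). The wild-type reference
#' energy is computed on the same reduced representation (identity repack and
#' relax over the same subset with the same seeds), and a variant is kept
#' only if its energy is strictly below that reference and its mutation count
#' lies within the configured bounds. Per-variant seeds derive from the
#' master seed.
#'
#' @param structure wild-type ProteinStructure (design region)
#' @param surviving_pool filtered candidate data.frame (chain, position, wt,
#'   mut, ...)
#' @param config a [design_config()]
#' @param em an [energy_model()]
#' @param rotlib rotamer library
#' @param pssm optional PSSM
#' @param chain design chain (default: first polymer chain)
#' @return list of VariantModel
#' @export
generate_variants <- function(structure, surviving_pool,
                              config = design_config(),
                              em = energy_model(),
                              rotlib = default_rotamer_library(),
                              pssm = NULL, chain = NULL) {
  if (is.null(surviving_pool) || !nrow(surviving_pool))
    stop("invalid configuration: surviving pool is empty")
  if (is.null(chain)) chain <- first_polymer_chain(structure)
  res <- polymer_residues(structure, chain)
  pool <- surviving_pool[surviving_pool$chain == chain &
                           surviving_pool$position %in% res$resno, ,
                         drop = FALSE]
  L <- nrow(res)
  m_lo <- ceiling(config$mutation_fraction_min * L)
  m_hi <- floor(config$mutation_fraction_max * L)
  pool_positions <- sort(unique(pool$position))
  if (m_hi < m_lo)
    stop("invalid configuration: fraction window admits no subset size for L = ", L)
  if (length(pool_positions) < m_lo)
    stop("invalid configuration: pool spans ", length(pool_positions),
         " position(s) but at least ", m_lo,
         " are required; achievable maximum is ", length(pool_positions))
  m_hi_eff <- min(m_hi, length(pool_positions))
  schedule <- list(mc_steps = config$mc_steps, kT_start = config$kT_start,
                   kT_end = config$kT_end)
  variants <- list()
  n_req <- config$n_variants_requested
  max_attempts <- max(1, ceiling(config$max_attempts_factor * n_req))
  attempt <- 0
  while (length(variants) < n_req && attempt < max_attempts) {
    attempt <- attempt + 1
    seed_i <- derive_seed(config$seed, attempt)
    m <- with_seed(seed_i, {
      choices <- m_lo:m_hi_eff
      mm <- choices[sample.int(length(choices), 1)]
      list(m = mm, positions = sort(sample(pool_positions, mm)))
    })
    positions <- m$positions
    allowed <- lapply(positions, function(p)
      unique(pool$mut[pool$position == p]))
    packed <- pack_rotamers(structure, positions, allowed, em, rotlib,
                            schedule, seed = seed_i, pssm = pssm,
                            chain = chain)
    relaxed <- relax_model(packed, em, steps = config$relax_steps,
                           step_size = config$relax_step_size,
                           seed = derive_seed(seed_i, 1), pssm = pssm)
    wt_packed <- pack_rotamers(structure, positions,
                               lapply(positions, function(p) character(0)),
                               em, rotlib, schedule, seed = seed_i,
                               pssm = pssm, chain = chain)
    wt_relaxed <- relax_model(wt_packed, em, steps = config$relax_steps,
                              step_size = config$relax_step_size,
                              seed = derive_seed(seed_i, 1), pssm = pssm)
    n_mut <- nrow(relaxed$mutations)
    gap <- relaxed$total_energy - wt_relaxed$total_energy
    if (n_mut >= m_lo && n_mut <= m_hi && gap < 0) {
      v <- relaxed
      v$wt_energy_ref <- wt_relaxed$total_energy
      v$energy_gap <- gap
      v$id <- sprintf("variant_%02d", length(variants) + 1)
      variants[[length(variants) + 1]] <- v
    }
  }
  if (length(variants) < n_req)
    warning("generated ", length(variants), " of ", n_req,
            " requested variants within the attempt budget")
  variants
}
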