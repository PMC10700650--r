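# Orchestration of the full stabilization protocol: truncate -> PSSM scan ->
# curated merge -> ddG -> ddG filter -> structural filter battery -> variant
# generation -> RMSD/energy selection -> reports.

#' Assemble and validate a run configuration
#'
#' All defaults mirror the protocol's printed parameters: ddG cutoff -0.5,
#' active-site exclusion radius 5 A, designable subsets of 2-20 percent of
#' the design region, and an 11-residue N-terminal truncation.
#'
#' @param structure path to a PDB file, or a ProteinStructure
#' @param alignment path to an aligned-FASTA homolog alignment, or an
#'   Alignment
#' @param catalytic_residues required non-empty vector of author residue
#'   numbers of the catalytic residues (active-site exclusion rule)
#' @param outdir output directory for stage artifacts and the manifest
#' @param chain design chain (default first polymer chain at run time)
#' @param reference_id alignment row corresponding to the structure (default:
#'   first sequence)
#' @param curated_table optional curated-mutation TSV path
#' @param ddg_table optional external ddG TSV; when given it replaces the
#'   surrogate scorer
#' @param n_terminal_truncation flexible N-terminal residues to remove before
#'   design (default 11)
#' @param pseudocount,background PSSM smoothing parameters
#' @param ddg_cutoff stabilizing cutoff, strict (default -0.5)
#' @param ddg_mc_steps Metropolis steps per surrogate-ddG local repack
#' @param active_site_radius,exposure_threshold,burial_threshold,volume_threshold
#'   structural-filter thresholds (see [filter_config()])
#' @param mutation_fraction_min,mutation_fraction_max,mc_steps,kT_start,kT_end,relax_steps,relax_step_size,rmsd_cutoff,n_variants_requested
#'   design and selection parameters (see [design_config()])
#' @param seed master seed for every stochastic stage
#' @return object of class `RunConfig`
#' @export
run_config <- function(structure, alignment, catalytic_residues, outdir,
                       chain = NULL, reference_id = NULL,
                       curated_table = NULL, ddg_table = NULL,
                       n_terminal_truncation = 11,
                       pseudocount = 1, background = NULL,
                       ddg_cutoff = -0.5, ddg_mc_steps = 300,
                       active_site_radius = 5.0,
                       exposure_threshold = 0.25, burial_threshold = 0.10,
                       volume_threshold = 40,
                       mutation_fraction_min = 0.02,
                       mutation_fraction_max = 0.20,
                       mc_steps = 2000, kT_start = 5, kT_end = 0.3,
                       relax_steps = 50, relax_step_size = 0.3,
                       rmsd_cutoff = 1.0, n_variants_requested = 10,
                       seed = 1) {
  if (missing(catalytic_residues) || !length(catalytic_residues))
    stop("configuration error: catalytic_residues must be non-empty")
  cfg <- as.list(environment())
  paths <- c(if (is.character(structure)) structure,
             if (is.character(alignment)) alignment,
             curated_table, ddg_table)
  for (pth in paths)
    if (!file.exists(pth)) stop("configuration error: file not found: ", pth)
  structure(cfg, class = "RunConfig")
}

#' Read a run configuration from a YAML file
#'
#' Recognized keys are the arguments of [run_config()]; relative paths are
#' resolved against the YAML file's directory.
#' @param path YAML file
#' @return a validated `RunConfig`
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("configuration error: unknown key(s) in '", path, "': ",
         paste(unknown, collapse = ", "))
  base <- dirname(normalizePath(path))
  for (k in c("structure", "alignment", "curated_table", "ddg_table",
              "outdir"))
    if (!is.null(y[[k]]) && is.character(y[[k]]) &&
        !grepl("^(/|[A-Za-z]:)", y[[k]]))
      y[[k]] <- file.path(base, y[[k]])
  do.call(run_config, y)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_fasta <- function(seqs, ids, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", ids[i]), con)
    writeLines(gsub("(.{60})", "\\1\n", seqs[i]), con)
  }
  invisible(path)
}

config_fingerprint <- function(cfg) {
  keep <- cfg[!vapply(cfg, function(x)
    inherits(x, "ProteinStructure") || inherits(x, "Alignment"), logical(1))]
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(keep, auto_unbox = TRUE, null = "null",
                              digits = NA), tf)
  unname(tools::md5sum(tf))
}

#' Run the stabilization design protocol end to end
#'
#' Stages run in order: N-terminal truncation, PSSM scan (positive-score
#' candidate pool), curated-table merge, ddG (surrogate or external table),
#' ddG cutoff filter, structural filter battery, variant generation, and
#' RMSD/energy selection. Stage artifacts are written to `config$outdir`; the
#' returned manifest records the seed, a configuration fingerprint,
#' per-stage candidate counts (as both mutation and distinct-position
#' counts) and output paths. Re-running with the same configuration and seed
#' reproduces identical outputs.
#'
#' @param config a [run_config()]
#' @param quiet suppress per-stage progress messages
#' @return the run manifest (list), invisibly also written as JSON
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  say <- function(...) if (!quiet) message("[stabdesign] ", ...)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  manifest <- list(seed = config$seed,
                   config_fingerprint = config_fingerprint(config),
                   parameters = list(
                     ddg_cutoff = config$ddg_cutoff,
                     active_site_radius = config$active_site_radius,
                     n_terminal_truncation = config$n_terminal_truncation,
                     mutation_fraction_min = config$mutation_fraction_min,
                     mutation_fraction_max = config$mutation_fraction_max,
                     rmsd_cutoff = config$rmsd_cutoff,
                     n_variants_requested = config$n_variants_requested),
                   counts = list(), outputs = list(), stages = character())
  abort_stage <- function(stage, e) {
    manifest$error <<- paste0("stage '", stage, "': ", conditionMessage(e))
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
    stop("pipeline aborted at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  run_stage <- function(stage, expr) {
    manifest$stages <<- c(manifest$stages, stage)
    say("stage ", stage)
    tryCatch(expr, error = function(e) abort_stage(stage, e))
  }

  # -- load & truncate ------------------------------------------------------
  wt_full <- run_stage("load", {
    if (is.character(config$structure)) read_pdb(config$structure)
    else config$structure
  })
  chain <- if (is.null(config$chain)) first_polymer_chain(wt_full)
           else config$chain
  wt <- run_stage("truncate",
                  truncate_n_terminus(wt_full, config$n_terminal_truncation,
                                      chain))
  design_region <- polymer_residues(wt, chain)
  say("design region: ", nrow(design_region), " residues")

  # -- PSSM scan ------------------------------------------------------------
  scan <- run_stage("scan", {
    aln <- if (is.character(config$alignment)) read_alignment(config$alignment)
           else config$alignment
    ref_id <- if (is.null(config$reference_id)) aln$ids[1]
              else config$reference_id
    background <- if (is.null(config$background)) rep(1 / 20, 20)
                  else config$background
    pssm <- compute_pssm(aln, ref_id, pseudocount = config$pseudocount,
                         background = background)
    full_res <- polymer_residues(wt_full, chain)
    if (nchar(pssm$reference_seq) != nrow(full_res))
      stop("reference sequence length (", nchar(pssm$reference_seq),
           ") does not match the structure chain (", nrow(full_res),
           " residues)")
    if (pssm$reference_seq != paste(full_res$aa, collapse = ""))
      warning("reference sequence differs from the structure sequence; ",
              "author-position mapping may be unreliable")
    pssm <- map_pssm_positions(pssm, full_res$resno, chain)
    pool <- positive_mutations(pssm, pssm$reference_seq)
    pool <- pool[pool$position %in% design_region$resno, , drop = FALSE]
    write_pssm(pssm, out("pssm.tsv"))
    list(pssm = pssm, pool = pool, full_res = full_res)
  })
  pssm <- scan$pssm

  pool <- run_stage("merge", {
    p <- scan$pool
    if (!is.null(config$curated_table)) {
      p <- merge_candidate_pool(p, config$curated_table,
                                reference_seq = pssm$reference_seq,
                                positions = pssm$positions, chain = chain)
      p <- p[p$position %in% design_region$resno, , drop = FALSE]
    }
    write_tsv(p, out("pool.tsv"))
    p
  })
  manifest$counts$initial_pool <- nrow(pool)
  manifest$counts$initial_positions <- length(unique(pool$position))
  say("initial pool: ", nrow(pool), " mutations at ",
      length(unique(pool$position)), " positions")

  # -- ddG ------------------------------------------------------------------
  em <- energy_model()
  rotlib <- default_rotamer_library()
  ddg_records <- run_stage("ddg", {
    if (!nrow(pool)) stop("candidate pool is empty")
    if (!is.null(config$ddg_table)) {
      ext <- read_ddg_table(config$ddg_table)
      k_pool <- paste(pool$chain, pool$position, pool$mut, sep = ":")
      k_ext <- paste(ext$chain, ext$position, ext$mut, sep = ":")
      rec <- ext[k_ext %in% k_pool, , drop = FALSE]
      say(nrow(pool) - nrow(rec), " candidates lack an external ddG record")
      rec
    } else {
      do.call(rbind, lapply(seq_len(nrow(pool)), function(i)
        surrogate_ddg(wt, pool[i, ], em, rotlib,
                      seed = derive_seed(config$seed, i), pssm = pssm,
                      mc_steps = config$ddg_mc_steps)))
    }
  })
  write_tsv(ddg_records, out("ddg.tsv"))

  ddg_kept <- run_stage("ddg_filter",
                        filter_by_ddg(ddg_records, config$ddg_cutoff))
  pool_ddg <- {
    k_pool <- paste(pool$chain, pool$position, pool$mut, sep = ":")
    k_kept <- paste(ddg_kept$chain, ddg_kept$position, ddg_kept$mut, sep = ":")
    merge_keep <- pool[k_pool %in% k_kept, , drop = FALSE]
    merge_keep$ddg <- ddg_kept$ddg[match(k_pool[k_pool %in% k_kept], k_kept)]
    merge_keep
  }
  write_tsv(pool_ddg, out("pool_after_ddg.tsv"))
  manifest$counts$after_ddg <- nrow(pool_ddg)
  say("after ddG filter (< ", config$ddg_cutoff, "): ", nrow(pool_ddg),
      " mutations")

  # -- structural filter battery -------------------------------------------
  battery <- run_stage("filters", {
    if (!nrow(pool_ddg)) stop("no candidates survive the ddG filter")
    fcfg <- filter_config(config$catalytic_residues, chain = chain,
                          active_site_radius = config$active_site_radius,
                          exposure_threshold = config$exposure_threshold,
                          burial_threshold = config$burial_threshold,
                          volume_threshold = config$volume_threshold)
    apply_filter_battery(pool_ddg, wt, fcfg)
  })
  write_tsv(verdict_table(battery$verdicts), out("verdicts.tsv"))
  write_tsv(battery$pool, out("pool_filtered.tsv"))
  manifest$counts$after_filters <- nrow(battery$pool)
  manifest$counts$after_filters_positions <-
    length(unique(battery$pool$position))
  manifest$counts$filter_failures <- as.list(battery$summary)
  say("after structural filters: ", nrow(battery$pool), " mutations at ",
      length(unique(battery$pool$position)), " positions")

  # -- design ---------------------------------------------------------------
  dcfg <- design_config(
    mutation_fraction_min = config$mutation_fraction_min,
    mutation_fraction_max = config$mutation_fraction_max,
    ddg_cutoff = config$ddg_cutoff,
    active_site_radius = config$active_site_radius,
    mc_steps = config$mc_steps, kT_start = config$kT_start,
    kT_end = config$kT_end, relax_steps = config$relax_steps,
    relax_step_size = config$relax_step_size,
    rmsd_cutoff = config$rmsd_cutoff,
    n_variants_requested = config$n_variants_requested, seed = config$seed)
  variants <- run_stage("design", {
    if (!nrow(battery$pool)) stop("no candidates survive the filter battery")
    generate_variants(wt, battery$pool, dcfg, em, rotlib, pssm = pssm,
                      chain = chain)
  })
  manifest$counts$generated <- length(variants)
  say("generated ", length(variants), " variants")

  # -- selection ------------------------------------------------------------
  report <- run_stage("select", {
    variants <- lapply(variants, function(v) {
      v$ca_rmsd <- ca_rmsd(v, wt)
      v
    })
    rank_and_select(variants, wt_energy = total_energy(wt, em, pssm),
                    config = dcfg)
  })
  manifest$counts$selected <- nrow(report$table)
  say("selected ", nrow(report$table), " variants")

  if (nrow(report$table)) {
    write_fasta(vapply(report$selected, function(v) v$sequence, character(1)),
                report$table$id, out("selected_variants.fasta"))
    for (v in report$selected)
      write_model(v$structure, out(paste0(v$id, ".pdb")))
    write_tsv(report$table, out("selection.tsv"))
    write_tsv(report$overlap, out("overlap.tsv"))
    mutation_rows <- do.call(rbind, lapply(report$selected, function(v)
      cbind(id = v$id, v$mutations)))
    write_tsv(mutation_rows, out("selected_mutations.tsv"))
  }
  manifest$outputs <- as.list(list.files(config$outdir, full.names = FALSE))
  manifest$counts <- manifest$counts
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(manifest)
}

#' Write a ready-to-run synthetic demonstration input set
#'
#' Generates a helical toy protein, a planted-signal homolog alignment whose
#' reference row matches the toy sequence, an empty curated table, and a YAML
#' run configuration wired to those files — everything needed to exercise the
#' full protocol without downloads.
#'
#' @param dir output directory (created if needed)
#' @param n_res toy protein length (default 60)
#' @param n_seqs homolog count (default 50)
#' @param n_planted planted conserved substitutions (default 12)
#' @param seed RNG seed
#' @return path to the written YAML configuration
#' @export
write_demo_inputs <- function(dir, n_res = 60, n_seqs = 50, n_planted = 12,
                              seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  helix <- with_seed(seed, {
    # hydrophilic-leaning toy sequence: keeps exposed-hydrophobic failures
    # from dominating the battery
    aa_bg <- c("S", "T", "N", "Q", "D", "E", "K", "R", "H", "G", "A", "L")
    make_ideal_helix(n_res, paste(sample(aa_bg, n_res, TRUE), collapse = ""))
  })
  seq_wt <- extract_sequence(helix)
  planted <- with_seed(seed + 1, {
    # plant conserved polar/charged substitutions away from the termini
    pos <- sort(sample(seq(13, n_res - 2), n_planted))
    data.frame(position = pos,
               aa = vapply(pos, function(p)
                 sample(setdiff(c("S", "T", "N", "Q", "D", "E", "K", "R"),
                                substr(seq_wt, p, p)), 1), character(1)),
               freq = 0.9)
  })
  msa <- make_toy_msa(n_res, n_seqs, planted, seed = seed + 2)
  # the reference row must be the toy protein's own sequence
  msa$sequences[1] <- seq_wt
  aln <- new_alignment(msa$ids, unname(msa$sequences))
  # planted columns of non-reference rows stay as generated; re-impose the
  # wild type only at reference row positions
  write_fasta(unname(aln$sequences), aln$ids, file.path(dir, "homologs.fasta"))
  write_model(helix, file.path(dir, "toy_protein.pdb"))
  writeLines("chain\tposition\twt\tmut", file.path(dir, "curated.tsv"))
  cfg <- list(structure = "toy_protein.pdb", alignment = "homologs.fasta",
              curated_table = "curated.tsv",
              catalytic_residues = as.integer(
                11 + ceiling((n_res - 11) * c(0.3, 0.6))),
              n_terminal_truncation = 11L,
              n_variants_requested = 10L,
              outdir = "results", seed = as.integer(seed))
  yaml::write_yaml(cfg, file.path(dir, "run.yaml"))
  file.path(dir, "run.yaml")
}
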