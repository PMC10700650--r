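# Homolog conservation: alignments, PSSM construction, and the candidate
# substitution pool.

#' Construct an Alignment object
#'
#' @param ids character vector of sequence identifiers
#' @param seqs character vector of aligned sequences (equal lengths). Input is
#'   upper-cased; "." is treated as the gap character "-"; letters outside the
#'   20 amino acids are rendered as "X".
#' @return object of class `Alignment` with fields `ids`, `sequences` (named
#'   character vector) and `length` (number of columns)
#' @export
new_alignment <- function(ids, seqs) {
  if (!length(seqs)) stop("format error: alignment has no sequences")
  if (length(ids) != length(seqs)) stop("ids and sequences differ in length")
  seqs <- toupper(seqs)
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1)
    stop("format error: aligned sequences have unequal lengths (",
         paste(sort(unique(lens)), collapse = ", "), ")")
  allowed <- c(AA_ALPHABET, "-", "X")
  seqs <- vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    ch[!(ch %in% allowed)] <- "X"
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  structure(list(ids = ids, sequences = setNames(seqs, ids),
                 length = unname(lens[1])),
            class = "Alignment")
}

#' @export
print.Alignment <- function(x, ...) {
  cat("Alignment:", length(x$ids), "sequences x", x$length, "columns\n")
  invisible(x)
}

#' Read an aligned-FASTA multiple sequence alignment
#'
#' @param path path to an aligned FASTA file with at least one sequence
#' @return an [new_alignment()] object
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("cannot read alignment file: ", path)
  fa <- tryCatch(
    seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                       forceDNAtolower = FALSE),
    error = function(e) stop("format error reading '", path, "': ",
                             conditionMessage(e)))
  if (!length(fa)) stop("format error: no sequences in '", path, "'")
  new_alignment(names(fa), vapply(fa, function(s) as.character(s)[1],
                                  character(1)))
}

alignment_matrix <- function(alignment) {
  do.call(rbind, strsplit(unname(alignment$sequences), ""))
}

#' Build a position-specific scoring matrix from a homolog alignment
#'
#' One score row is produced for every alignment column at which the
#' reference sequence is ungapped. The score of amino acid `a` at column `c`
#' is the log2 odds of its smoothed column frequency over the background:
#' `log2(((n_ca + k) / (N_c + 20 k)) / bg_a)`, with `N_c` the number of
#' ungapped (non-X) symbols in the column and `k` the additive pseudocount.
#' Gaps and "X" are excluded from the counts. An optional per-sequence weight
#' vector is accepted as a hook; the default applies no sequence weighting.
#'
#' @param alignment an [new_alignment()] object
#' @param reference_id id of the reference sequence (row whose ungapped
#'   positions define the PSSM rows)
#' @param pseudocount additive (Laplace) pseudocount, default 1
#' @param background length-20 vector of background amino-acid frequencies in
#'   [AA_ALPHABET] order (or named); must be positive and sum to 1. Default
#'   uniform 1/20.
#' @param weights optional per-sequence weights (default: all 1)
#' @return object of class `PSSM`: `scores` (L x 20, bits), `column_to_position`
#'   (alignment column -> reference position, NA where the reference is
#'   gapped), `reference_id`, `reference_seq`, `positions` (author numbering
#'   of each row, defaults to 1..L; see [map_pssm_positions()]), `chain`.
#' @export
compute_pssm <- function(alignment, reference_id,
                         pseudocount = 1,
                         background = rep(1 / 20, 20),
                         weights = NULL) {
  if (!reference_id %in% alignment$ids)
    stop("reference sequence not found: '", reference_id, "'")
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("invalid argument: pseudocount must be positive")
  if (length(background) != 20)
    stop("invalid argument: background must have 20 entries")
  if (!is.null(names(background))) background <- background[AA_ALPHABET]
  background <- as.numeric(background)
  if (any(!is.finite(background)) || any(background <= 0))
    stop("invalid argument: background frequencies must be positive")
  if (abs(sum(background) - 1) > 1e-6)
    stop("invalid argument: background frequencies must sum to 1")
  mat <- alignment_matrix(alignment)
  if (is.null(weights)) weights <- rep(1, nrow(mat))
  if (length(weights) != nrow(mat))
    stop("invalid argument: one weight per sequence required")
  ref_row <- mat[match(reference_id, alignment$ids), ]
  keep <- ref_row != "-"
  cols <- which(keep)
  L <- length(cols)
  if (!L) stop("reference sequence is entirely gapped")
  scores <- matrix(NA_real_, nrow = L, ncol = 20,
                   dimnames = list(NULL, AA_ALPHABET))
  for (i in seq_len(L)) {
    col <- mat[, cols[i]]
    use <- col %in% AA_ALPHABET
    n <- vapply(AA_ALPHABET, function(a) sum(weights[use][col[use] == a]),
                numeric(1))
    N <- sum(n)
    freq <- (n + pseudocount) / (N + 20 * pseudocount)
    scores[i, ] <- log2(freq / background)
  }
  col2pos <- rep(NA_integer_, alignment$length)
  col2pos[cols] <- seq_len(L)
  structure(list(
    scores = scores,
    column_to_position = col2pos,
    reference_id = reference_id,
    reference_seq = paste(ref_row[keep], collapse = ""),
    positions = seq_len(L),
    chain = "A"
  ), class = "PSSM")
}

#' Attach author numbering (and chain) to PSSM rows
#'
#' By default PSSM rows are addressed 1..L in reference-sequence order; when
#' the reference corresponds to a structure whose author numbering differs,
#' supply the author residue numbers here so that downstream candidates carry
#' structure-addressable positions.
#' @param pssm a PSSM
#' @param positions integer vector, one author position per PSSM row
#' @param chain chain id the positions refer to
#' @export
map_pssm_positions <- function(pssm, positions, chain = "A") {
  if (length(positions) != nrow(pssm$scores))
    stop("invalid argument: one position per PSSM row required")
  pssm$positions <- as.integer(positions)
  pssm$chain <- chain
  pssm
}

#' @export
print.PSSM <- function(x, ...) {
  cat("PSSM:", nrow(x$scores), "positions (reference '", x$reference_id,
      "'), chain ", x$chain, "\n", sep = "")
  invisible(x)
}

pssm_score_at <- function(pssm, position, aa) {
  i <- match(position, pssm$positions)
  if (is.na(i) || !(aa %in% AA_ALPHABET)) return(NA_real_)
  pssm$scores[i, aa]
}

empty_pool <- function() {
  data.frame(chain = character(), position = integer(), wt = character(),
             mut = character(), source = character(), pssm_score = numeric(),
             stringsAsFactors = FALSE)
}

#' Candidate substitutions favoured by the PSSM
#'
#' Emits one candidate per (position, amino acid) pair whose PSSM score
#' exceeds the positivity threshold and whose amino acid differs from the
#' wild type; positions whose wild type is non-standard ("X") are never
#' designable and are skipped.
#'
#' @param pssm a [compute_pssm()] result
#' @param wt_sequence wild-type sequence; one letter per PSSM row
#' @param chain chain id stamped on the candidates (default: the PSSM's)
#' @param threshold positivity threshold in bits (default 0: strictly
#'   positive scores qualify)
#' @return data.frame pool with columns chain, position, wt, mut, source
#'   ("pssm"), pssm_score
#' @export
positive_mutations <- function(pssm, wt_sequence, chain = NULL, threshold = 0) {
  wt <- strsplit(toupper(wt_sequence), "")[[1]]
  if (length(wt) != nrow(pssm$scores))
    stop("invalid argument: wild-type sequence length (", length(wt),
         ") does not match PSSM rows (", nrow(pssm$scores), ")")
  if (is.null(chain)) chain <- pssm$chain
  rows <- list()
  for (i in seq_len(nrow(pssm$scores))) {
    if (!(wt[i] %in% AA_ALPHABET)) next
    hits <- AA_ALPHABET[pssm$scores[i, ] > threshold & AA_ALPHABET != wt[i]]
    if (length(hits)) {
      rows[[length(rows) + 1]] <- data.frame(
        chain = chain, position = pssm$positions[i], wt = wt[i], mut = hits,
        source = "pssm", pssm_score = pssm$scores[i, hits],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_pool()
  rownames(out) <- NULL
  out
}

read_curated_table <- function(path) {
  if (!file.exists(path)) stop("cannot read curated table: ", path)
  if (file.size(path) == 0) return(NULL)
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      colClasses = "character", stringsAsFactors = FALSE),
    error = function(e) stop("format error in '", path, "': ",
                             conditionMessage(e)))
  required <- c("chain", "position", "wt", "mut")
  if (!all(required %in% names(tab)))
    stop("format error in '", path, "': expected columns ",
         paste(required, collapse = ", "))
  for (i in seq_len(nrow(tab))) {
    pos <- suppressWarnings(as.integer(tab$position[i]))
    if (is.na(pos) || !(toupper(tab$wt[i]) %in% AA_ALPHABET) ||
        !(toupper(tab$mut[i]) %in% AA_ALPHABET) ||
        toupper(tab$wt[i]) == toupper(tab$mut[i]))
      stop("format error in '", path, "' at line ", i + 1,
           ": chain/position/wt/mut row invalid")
  }
  tab$position <- as.integer(tab$position)
  tab$wt <- toupper(tab$wt)
  tab$mut <- toupper(tab$mut)
  tab
}

#' Merge the PSSM pool with a curated thermostable-mutation table
#'
#' The curated table (TSV, columns chain/position/wt/mut with optional
#' ddg_pred) typically carries literature or database mutations not found by
#' the conservation scan. The union is deduplicated on (chain, position,
#' mutant); duplicates keep the PSSM provenance. When a reference sequence is
#' supplied, curated rows whose claimed wild type disagrees with it are
#' rejected and reported via the "rejected" attribute of the result.
#'
#' @param pssm_pool data.frame from [positive_mutations()]
#' @param curated_table path to the curated TSV (empty file allowed)
#' @param reference_seq optional wild-type sequence used to verify curated
#'   wild-type claims
#' @param positions author numbering of `reference_seq` (default 1..L)
#' @param chain chain the reference belongs to
#' @return merged pool data.frame; attribute "rejected" lists refused rows
#' @export
merge_candidate_pool <- function(pssm_pool, curated_table,
                                 reference_seq = NULL, positions = NULL,
                                 chain = "A") {
  cur <- read_curated_table(curated_table)
  rejected <- data.frame(chain = character(), position = integer(),
                         wt = character(), mut = character(),
                         reason = character(), stringsAsFactors = FALSE)
  if (is.null(cur) || !nrow(cur)) {
    attr(pssm_pool, "rejected") <- rejected
    return(pssm_pool)
  }
  if (!is.null(reference_seq)) {
    ref <- strsplit(toupper(reference_seq), "")[[1]]
    if (is.null(positions)) positions <- seq_along(ref)
    ok <- rep(TRUE, nrow(cur))
    reason <- character(nrow(cur))
    for (i in seq_len(nrow(cur))) {
      if (cur$chain[i] != chain) next  # other chains pass through unchecked
      j <- match(cur$position[i], positions)
      if (is.na(j)) {
        ok[i] <- FALSE; reason[i] <- "position not in reference sequence"
      } else if (ref[j] != cur$wt[i]) {
        ok[i] <- FALSE
        reason[i] <- paste0("wild-type mismatch: reference has ", ref[j])
      }
    }
    if (any(!ok)) {
      rejected <- data.frame(cur[!ok, c("chain", "position", "wt", "mut")],
                             reason = reason[!ok], stringsAsFactors = FALSE)
      message("merge_candidate_pool: rejected ", sum(!ok),
              " curated row(s) failing the wild-type check")
      cur <- cur[ok, , drop = FALSE]
    }
  }
  if (!nrow(cur)) {
    attr(pssm_pool, "rejected") <- rejected
    return(pssm_pool)
  }
  cur_pool <- data.frame(chain = cur$chain, position = cur$position,
                         wt = cur$wt, mut = cur$mut, source = "curated",
                         pssm_score = NA_real_, stringsAsFactors = FALSE)
  merged <- rbind(pssm_pool[, names(empty_pool())], cur_pool)
  key <- paste(merged$chain, merged$position, merged$mut, sep = ":")
  merged <- merged[!duplicated(key), , drop = FALSE]  # pssm rows come first
  rownames(merged) <- NULL
  attr(merged, "rejected") <- rejected
  merged
}

#' Export a PSSM as TSV (position, wt, one column per amino acid)
#' @param pssm a PSSM
#' @param path output path
#' @export
write_pssm <- function(pssm, path) {
  out <- data.frame(position = pssm$positions,
                    wt = strsplit(pssm$reference_seq, "")[[1]],
                    round(pssm$scores, 6), check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
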