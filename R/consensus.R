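#' Consensus-calling parameters
#'
#' Coverage thresholds for per-position amino-acid consensus calls: a residue
#' qualifies at a position when supported by at least `min_reads` reads that
#' also represent at least `min_frac` of the reads contributing a residue to
#' that position. Both thresholds are closed ("at least").
#'
#' @param min_reads Minimum supporting reads (default 4).
#' @param min_frac Minimum fraction of position coverage (default 0.30).
#' @export
consensus_params <- function(min_reads = 4L, min_frac = 0.30) {
  if (min_reads < 1L) stop("min_reads must be >= 1")
  if (min_frac <= 0 || min_frac > 1) stop("min_frac must be in (0, 1]")
  structure(list(min_reads = as.integer(min_reads), min_frac = min_frac),
            class = "consensus_params")
}

#' Stack translated reads onto a reference protein
#'
#' Aligns each peptide (a read's matched reading frame) locally against the
#' family reference protein and stacks the aligned residues at their
#' reference coordinates, producing per-column residue counts. Peptide
#' insertions relative to the reference are dropped; deletions leave the
#' column uncovered for that read.
#'
#' @param peptides Named character vector of peptides.
#' @param reference_protein Reference protein sequence.
#' @param params A [homology_params()].
#' @return Object of class `protein_stack`: `reference`, `mat`
#'   (reads x positions residue matrix), `coverage`.
#' @export
align_reads_to_protein <- function(peptides, reference_protein,
                                   params = homology_params()) {
  L <- nchar(reference_protein)
  ids <- names(peptides) %||% sprintf("pep%04d", seq_along(peptides))
  if (length(peptides) == 0L) {
    return(structure(list(reference = reference_protein,
                          mat = matrix(NA_character_, 0L, L),
                          coverage = integer(L)),
                     class = "protein_stack"))
  }
  st <- .stack_onto_subject(peptides, reference_protein, params,
                            protein = TRUE)
  mat <- st$mat
  mat[mat == "X"] <- NA_character_     # ambiguous codons carry no evidence
  rownames(mat) <- ids
  keep <- rowSums(!is.na(mat)) > 0L
  mat <- mat[keep, , drop = FALSE]
  structure(list(reference = reference_protein, mat = mat,
                 coverage = as.integer(colSums(!is.na(mat)))),
            class = "protein_stack")
}

#' Call a coverage-thresholded consensus sequence
#'
#' Per reference position with `n` contributing reads, a residue qualifies
#' iff its count is at least `min_reads` AND at least `min_frac` of `n`.
#' Exactly one qualifying residue gives a fixed (uppercase) call; two or more
#' give a variable position (annotated set, suggesting allelic isoforms);
#' none, with `n >= 1`, gives a low-confidence lowercase plurality call
#' (ties broken alphabetically); positions never sequenced are unknown.
#'
#' @param stack A [align_reads_to_protein()] result.
#' @param params A [consensus_params()].
#' @param family,species Optional labels stored on the result.
#' @return Object of class `consensus_sequence`: `calls` (data frame `pos`,
#'   `coverage`, `class`, `residues`), `display` (string; variable positions
#'   as `[..]`, low-confidence lowercase, unknown `-`), `representative`
#'   (character vector: fixed residue or first variable residue, `NA` at
#'   low-confidence/unknown positions — the form used for concatenation and
#'   distances).
#' @export
call_consensus <- function(stack, params = consensus_params(),
                           family = NA_character_, species = NA_character_) {
  L <- nchar(stack$reference)
  cls <- character(L); res <- character(L)
  disp <- character(L); rep_res <- rep(NA_character_, L)
  for (j in seq_len(L)) {
    col <- stack$mat[, j]
    col <- col[!is.na(col)]
    n <- length(col)
    if (n == 0L) {
      cls[j] <- "unknown"; res[j] <- ""; disp[j] <- "-"
      next
    }
    tab <- sort(table(col), decreasing = TRUE)
    qual <- names(tab)[tab >= params$min_reads & tab / n >= params$min_frac]
    qual <- sort(qual)
    if (length(qual) == 1L) {
      cls[j] <- "fixed"; res[j] <- qual
      disp[j] <- qual; rep_res[j] <- qual
    } else if (length(qual) >= 2L) {
      cls[j] <- "variable"; res[j] <- paste(qual, collapse = "")
      disp[j] <- paste0("[", paste(qual, collapse = ""), "]")
      rep_res[j] <- qual[1L]
    } else {
      top <- sort(names(tab)[tab == max(tab)])[1L]
      cls[j] <- "low_confidence"; res[j] <- top
      disp[j] <- tolower(top)
    }
  }
  structure(
    list(family = family, species = species,
         calls = data.frame(pos = seq_len(L) - 1L,
                            coverage = unname(stack$coverage),
                            class = cls, residues = res,
                            stringsAsFactors = FALSE),
         display = paste(disp, collapse = ""),
         representative = rep_res),
    class = "consensus_sequence")
}

#' @export
print.consensus_sequence <- function(x, ...) {
  tab <- table(factor(x$calls$class,
                      levels = c("fixed", "variable", "low_confidence", "unknown")))
  cat(sprintf("<consensus_sequence>%s%s %d positions: %d fixed, %d variable, %d low-confidence, %d unknown\n",
              if (is.na(x$species)) "" else paste0(" ", x$species),
              if (is.na(x$family)) "" else paste0("/", x$family),
              nrow(x$calls), tab[1], tab[2], tab[3], tab[4]))
  cat("  ", substr(x$display, 1L, 60L),
      if (nchar(x$display) > 60L) "..." else "", "\n", sep = "")
  invisible(x)
}

#' One-shot consensus from peptides
#'
#' Convenience wrapper: [align_reads_to_protein()] then [call_consensus()].
#'
#' @inheritParams align_reads_to_protein
#' @inheritParams call_consensus
#' @param align_params A [homology_params()].
#' @export
build_consensus <- function(peptides, reference_protein,
                            params = consensus_params(),
                            align_params = homology_params(),
                            family = NA_character_, species = NA_character_) {
  call_consensus(align_reads_to_protein(peptides, reference_protein,
                                        align_params),
                 params, family = family, species = species)
}

#' Best-frame peptides of ORF-coding reads
#'
#' Translates each read in all six frames, aligns every frame against the
#' family reference protein, and returns the highest-scoring frame's peptide
#' per read (reads with no positive-scoring frame are dropped). This is the
#' translated-search step that feeds the consensus stack.
#'
#' @param reads Named character vector of nucleotide reads.
#' @param reference_protein Family reference protein.
#' @param params A [homology_params()].
#' @return Named character vector of peptides (one per retained read).
#' @export
best_frame_peptides <- function(reads, reference_protein,
                                params = homology_params()) {
  if (length(reads) == 0L) return(stats::setNames(character(0), character(0)))
  ids <- names(reads) %||% sprintf("read%04d", seq_along(reads))
  frames <- lapply(reads, six_frame_translate)
  peps <- unlist(lapply(frames, unname), use.names = FALSE)
  sc <- .batch_scores(peps, reference_protein, .blosum62(),
                      params$gap_open, params$gap_ext, protein = TRUE)
  scm <- matrix(sc, nrow = 6L)
  best <- apply(scm, 2L, which.max)
  keep <- scm[cbind(best, seq_along(reads))] > 0
  out <- vapply(which(keep), function(i) frames[[i]][[best[i]]], "")
  stats::setNames(out, ids[keep])
}

#' Mean variability of a consensus sequence
#'
#' Number of variable residues divided by sequence length, in percent.
#'
#' @param cons A `consensus_sequence`.
#' @export
consensus_variability <- function(cons) {
  100 * sum(cons$calls$class == "variable") / nrow(cons$calls)
}

#' Write consensus sequences as annotated FASTA plus per-position TSV
#'
#' The FASTA uses the display convention: uppercase fixed calls, bracketed
#' variable sets, lowercase low-confidence calls, `-` for unknown positions.
#'
#' @param cons_list Named list of `consensus_sequence` objects.
#' @param fasta_path,tsv_path Output files (`tsv_path` optional).
#' @export
write_consensus <- function(cons_list, fasta_path, tsv_path = NULL) {
  lines <- unlist(lapply(names(cons_list), function(nm)
    c(paste0(">", nm), cons_list[[nm]]$display)))
  writeLines(lines %||% character(0), fasta_path)
  if (!is.null(tsv_path) && length(cons_list)) {
    tab <- do.call(rbind, lapply(names(cons_list), function(nm)
      cbind(id = nm, cons_list[[nm]]$calls)))
    utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(fasta_path)
}
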