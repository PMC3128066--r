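#' Homology-search parameters
#'
#' Scoring scheme and statistics for the exhaustive local-alignment search
#' against the reference panel: BLOSUM62 with affine gaps for translated
#' searches, match/mismatch scoring for nucleotide searches, and bundled
#' Karlin-Altschul constants (gapped values for the default schemes) used to
#' convert raw scores into E-values.
#'
#' @param evalue_cutoff Expectation-value cutoff for reporting a hit.
#' @param matrix Protein scoring matrix name (only `"BLOSUM62"` is bundled).
#' @param gap_open,gap_ext Affine gap penalties for protein alignment
#'   (positive costs).
#' @param nt_match,nt_mismatch Nucleotide match/mismatch scores.
#' @param nt_gap_open,nt_gap_ext Affine gap penalties for nucleotide alignment.
#' @param lambda_prot,K_prot Karlin-Altschul constants for the protein scheme.
#' @param lambda_nt,K_nt Karlin-Altschul constants for the nucleotide scheme.
#' @return Object of class `homology_params`.
#' @export
homology_params <- function(evalue_cutoff = 1e-3, matrix = "BLOSUM62",
                            gap_open = 11, gap_ext = 1,
                            nt_match = 2, nt_mismatch = -3,
                            nt_gap_open = 5, nt_gap_ext = 2,
                            lambda_prot = 0.267, K_prot = 0.041,
                            lambda_nt = 0.56, K_nt = 0.21) {
  if (evalue_cutoff <= 0) stop("evalue_cutoff must be > 0")
  if (matrix != "BLOSUM62") stop("only BLOSUM62 is bundled")
  structure(list(evalue_cutoff = evalue_cutoff, matrix = matrix,
                 gap_open = gap_open, gap_ext = gap_ext,
                 nt_match = nt_match, nt_mismatch = nt_mismatch,
                 nt_gap_open = nt_gap_open, nt_gap_ext = nt_gap_ext,
                 lambda_prot = lambda_prot, K_prot = K_prot,
                 lambda_nt = lambda_nt, K_nt = K_nt),
            class = "homology_params")
}

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

.nt_matrix <- function(params) {
  Biostrings::nucleotideSubstitutionMatrix(match = params$nt_match,
                                           mismatch = params$nt_mismatch,
                                           baseOnly = FALSE)
}

#' Six-frame translation
#'
#' Translates a nucleotide sequence in frames +1..+3 (forward strand) and
#' -1..-3 (reverse complement). Codons containing N translate to `X`; stop
#' codons are rendered as `*`.
#'
#' @param seq Nucleotide string.
#' @return Named character vector of six peptides
#'   (`"+1"`, `"+2"`, `"+3"`, `"-1"`, `"-2"`, `"-3"`).
#' @export
#' @examples
#' six_frame_translate("ATGGCC")[["+1"]]
six_frame_translate <- function(seq) {
  seq <- toupper(seq)
  rc <- revcomp(seq)
  one <- function(s, f) {
    L <- nchar(s) - f + 1L
    if (L < 3L) return("")
    translate_dna(substr(s, f, f + (L %/% 3L) * 3L - 1L))
  }
  c("+1" = one(seq, 1L), "+2" = one(seq, 2L), "+3" = one(seq, 3L),
    "-1" = one(rc, 1L), "-2" = one(rc, 2L), "-3" = one(rc, 3L))
}

#' Optimal local alignment (Smith-Waterman, affine gaps)
#'
#' Exact local alignment of two sequences under the configured scoring
#' scheme. Intervals are 0-based, half-open.
#'
#' @param query,target Sequences (character).
#' @param params A [homology_params()].
#' @param mode `"protein"` (BLOSUM62) or `"nucleotide"` (match/mismatch).
#' @return List with `score`, `query_iv`, `target_iv`, `query_aln`,
#'   `target_aln` (aligned strings with `-` for gaps).
#' @export
local_align <- function(query, target, params = homology_params(),
                        mode = c("protein", "nucleotide")) {
  mode <- match.arg(mode)
  if (nchar(query) == 0L || nchar(target) == 0L)
    stop("sequences must be nonempty")
  if (mode == "protein") {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(query), Biostrings::AAString(target),
      type = "local", substitutionMatrix = .blosum62(),
      gapOpening = params$gap_open, gapExtension = params$gap_ext)
  } else {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(query), Biostrings::DNAString(target),
      type = "local", substitutionMatrix = .nt_matrix(params),
      gapOpening = params$nt_gap_open, gapExtension = params$nt_gap_ext)
  }
  sc <- Biostrings::score(aln)
  if (sc <= 0)
    return(list(score = 0, query_iv = c(0L, 0L), target_iv = c(0L, 0L),
                query_aln = "", target_aln = ""))
  p <- Biostrings::pattern(aln); s <- Biostrings::subject(aln)
  list(score = sc,
       query_iv = c(Biostrings::start(p) - 1L, Biostrings::end(p)),
       target_iv = c(Biostrings::start(s) - 1L, Biostrings::end(s)),
       query_aln = as.character(Biostrings::alignedPattern(aln)),
       target_aln = as.character(Biostrings::alignedSubject(aln)))
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * score)` with the bundled constants for the
#' configured scoring scheme.
#'
#' @param score Raw alignment score (>= 0).
#' @param m Query length.
#' @param n Search-space length (summed panel length).
#' @param params A [homology_params()].
#' @param mode `"protein"` or `"nucleotide"`.
#' @export
estimate_evalue <- function(score, m, n, params = homology_params(),
                            mode = c("protein", "nucleotide")) {
  mode <- match.arg(mode)
  if (any(m <= 0) || any(n <= 0)) stop("m and n must be positive")
  if (mode == "protein") params$K_prot * m * n * exp(-params$lambda_prot * score)
  else params$K_nt * m * n * exp(-params$lambda_nt * score)
}

#' Score threshold attaining a given E-value
#'
#' Closed-form inversion of [estimate_evalue()]:
#' `S = log(K * m * n / E) / lambda`.
#'
#' @param evalue Target E-value.
#' @inheritParams estimate_evalue
#' @export
evalue_score_threshold <- function(evalue, m, n, params = homology_params(),
                                   mode = c("protein", "nucleotide")) {
  mode <- match.arg(mode)
  if (m <= 0 || n <= 0) stop("m and n must be positive")
  if (mode == "protein") log(params$K_prot * m * n / evalue) / params$lambda_prot
  else log(params$K_nt * m * n / evalue) / params$lambda_nt
}

#' Classify a hit's reference region
#'
#' Region of the reference mRNA a hit belongs to: `microsatellite` when the
#' read is microsatellite-dominated (masked fraction >= `microsat_threshold`);
#' otherwise `ORF` when more than half of the aligned reference interval
#' overlaps the CDS; otherwise `UTR5`/`UTR3` by which side of the CDS holds
#' the majority of the non-CDS overlap (ties fall to `UTR3`, consistent with
#' a 3'-enriched library).
#'
#' @param ref_iv Aligned reference interval, 0-based half-open (length 2).
#' @param cds CDS interval on the reference mRNA (length 2), or `NA` for
#'   non-coding references (returns `NA`).
#' @param mrna_len Reference mRNA length.
#' @param microsat_frac Fraction of the read masked as microsatellite.
#' @param microsat_threshold Domination cutoff (default 0.5).
#' @export
partition_region <- function(ref_iv, cds, mrna_len, microsat_frac = 0,
                             microsat_threshold = 0.5) {
  if (ref_iv[1] < 0 || ref_iv[2] > mrna_len || ref_iv[1] >= ref_iv[2])
    stop("hit interval outside mRNA bounds")
  if (any(is.na(cds))) return(NA_character_)
  if (microsat_frac >= microsat_threshold) return("microsatellite")
  w <- ref_iv[2] - ref_iv[1]
  in_cds <- iv_overlap(ref_iv[1], ref_iv[2], cds[1], cds[2])
  if (in_cds > 0.5 * w) return("ORF")
  u5 <- iv_overlap(ref_iv[1], ref_iv[2], 0L, cds[1])
  u3 <- iv_overlap(ref_iv[1], ref_iv[2], cds[2], mrna_len)
  if (u5 > u3) "UTR5" else "UTR3"
}

#' Scan translated frames for cysteine-rich stretches
#'
#' Reports maximal stop-free windows of 50-100 residues containing at least
#' 10% cysteines, the structural signature shared by many toxin scaffolds.
#'
#' @param peptides Named character vector of peptides (e.g. the output of
#'   [six_frame_translate()]).
#' @param min_len,max_len Window length bounds (residues).
#' @param min_frac Minimum cysteine fraction.
#' @return Data frame `frame`, `start`, `end` (0-based half-open on the
#'   peptide), `n_cys`.
#' @export
cysteine_rich_scan <- function(peptides, min_len = 50L, max_len = 100L,
                               min_frac = 0.10) {
  out <- NULL
  for (fr in names(peptides) %||% as.character(seq_along(peptides))) {
    x <- strsplit(peptides[[fr]], "")[[1]]
    L <- length(x)
    if (L < min_len) next
    csC <- c(0L, cumsum(x == "C"))
    csS <- c(0L, cumsum(x == "*"))
    wins <- NULL
    for (len in min_len:min(max_len, L)) {
      s <- seq_len(L - len + 1L)
      nC <- csC[s + len] - csC[s]
      nS <- csS[s + len] - csS[s]
      ok <- which(nS == 0L & nC / len >= min_frac)
      if (length(ok))
        wins <- rbind(wins, cbind(start = ok - 1L, end = ok - 1L + len,
                                  n_cys = nC[ok]))
    }
    if (is.null(wins)) next
    wins <- wins[order(wins[, "start"], -wins[, "end"]), , drop = FALSE]
    max_end <- -1L; keep <- logical(nrow(wins))
    for (k in seq_len(nrow(wins))) {
      if (wins[k, "end"] > max_end) { keep[k] <- TRUE; max_end <- wins[k, "end"] }
    }
    wins <- wins[keep, , drop = FALSE]
    out <- rbind(out, data.frame(frame = fr, start = wins[, "start"],
                                 end = wins[, "end"], n_cys = wins[, "n_cys"],
                                 stringsAsFactors = FALSE))
  }
  out %||% data.frame(frame = character(0), start = integer(0),
                      end = integer(0), n_cys = integer(0))
}

# Batch-align sequences locally onto one subject and express each aligned
# sequence in subject coordinates (insertions relative to the subject are
# dropped; deletions are NA). Returns the per-sequence character matrix plus
# scores and subject spans. Workhorse of pileups and consensus stacking.
.stack_onto_subject <- function(seqs, subject, params, protein) {
  n <- length(seqs)
  L <- nchar(subject)
  out <- list(mat = matrix(NA_character_, n, L), scores = rep(0, n),
              t_start = integer(n), t_end = integer(n))
  ok <- which(nchar(seqs) > 0L)
  if (length(ok) == 0L) return(out)
  if (protein) {
    set <- Biostrings::AAStringSet(unname(seqs[ok]))
    subj <- Biostrings::AAString(subject)
    smat <- .blosum62(); go <- params$gap_open; ge <- params$gap_ext
  } else {
    set <- Biostrings::DNAStringSet(unname(seqs[ok]))
    subj <- Biostrings::DNAString(subject)
    smat <- .nt_matrix(params); go <- params$nt_gap_open; ge <- params$nt_gap_ext
  }
  aln <- Biostrings::pairwiseAlignment(set, subj, type = "local",
                                       substitutionMatrix = smat,
                                       gapOpening = go, gapExtension = ge)
  sc <- Biostrings::score(aln)
  ts <- Biostrings::start(Biostrings::subject(aln)) - 1L
  te <- Biostrings::end(Biostrings::subject(aln))
  v <- as.character(Biostrings::aligned(Biostrings::pattern(aln)))
  for (q in seq_along(ok)) {
    i <- ok[q]
    out$scores[i] <- sc[q]
    if (sc[q] <= 0) next
    out$t_start[i] <- ts[q]; out$t_end[i] <- te[q]
    chars <- strsplit(v[q], "")[[1]]
    if (length(chars) != te[q] - ts[q]) {
      # rare insertion relative to the subject: re-walk this one alignment
      a <- local_align(seqs[[i]], subject, params,
                       if (protein) "protein" else "nucleotide")
      qa <- strsplit(a$query_aln, "")[[1]]
      ta <- strsplit(a$target_aln, "")[[1]]
      chars <- qa[ta != "-"]
    }
    chars[chars == "-"] <- NA_character_
    out$mat[i, (ts[q] + 1L):te[q]] <- chars
  }
  out
}

# batch score of a set of sequences against one subject, local alignment
.batch_scores <- function(seqs, subject, mat, gap_open, gap_ext, protein) {
  out <- rep(-Inf, length(seqs))
  ok <- which(nchar(seqs) > 0L)
  if (length(ok) == 0L) return(out)
  set <- if (protein) Biostrings::AAStringSet(seqs[ok])
         else Biostrings::DNAStringSet(seqs[ok])
  subj <- if (protein) Biostrings::AAString(subject)
          else Biostrings::DNAString(subject)
  out[ok] <- Biostrings::pairwiseAlignment(
    set, subj, type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_ext, scoreOnly = TRUE)
  out
}

#' Assign reads to toxin families by exhaustive panel search
#'
#' Every read is aligned against every panel entry in both modes: translated
#' (all six reading frames against the entry protein, BLOSUM62) and
#' nucleotide (against the entry mRNA). The best hit over all entries, modes
#' and frames is the one with the lowest E-value (ties broken by higher raw
#' score, then lexicographic `ref_id`); reads whose best E-value exceeds the
#' cutoff are reported as no-hits. Toxin hits with nucleotide coordinates on
#' the reference are partitioned into ORF / UTR5 / UTR3 / microsatellite
#' regions.
#'
#' @param reads Named character vector of (masked, MID-trimmed) reads.
#' @param panel A [reference_panel()].
#' @param params A [homology_params()].
#' @param microsat_frac Optional named numeric vector: fraction of each read
#'   masked as microsatellite (from [mask_run()]), used for region calls.
#' @return Data frame of class `family_hits`, one row per read: `read_id`,
#'   `category` (`toxin`/`non_toxin`/`no_hit`), `ref_id`, `family`, `mode`,
#'   `frame`, `score`, `evalue`, `read_start`, `read_end`, `ref_start`,
#'   `ref_end` (nucleotide coordinates on the reference mRNA), `region`.
#' @export
assign_families <- function(reads, panel, params = homology_params(),
                            microsat_frac = NULL) {
  if (length(panel$sequences) == 0L) stop("panel is empty")
  n <- length(reads)
  ids <- names(reads) %||% as.character(seq_len(n))
  if (is.null(microsat_frac)) microsat_frac <- stats::setNames(numeric(n), ids)
  frames <- lapply(reads, six_frame_translate)
  frame_names <- c("+1", "+2", "+3", "-1", "-2", "-3")
  peps <- unlist(lapply(frames, function(f) f[frame_names]), use.names = FALSE)
  pep_len <- nchar(peps)
  n_nt <- sum(nchar(panel$sequences))
  n_aa <- sum(nchar(panel$proteins))
  ntmat <- .nt_matrix(params)
  b62 <- .blosum62()

  best <- data.frame(evalue = rep(Inf, n), score = rep(-Inf, n),
                     ref_id = NA_character_, mode = NA_character_,
                     frame = NA_integer_, stringsAsFactors = FALSE)
  better <- function(e, s, r, eb, sb, rb) {
    ifelse(e < eb, TRUE,
           ifelse(e > eb, FALSE,
                  ifelse(s > sb, TRUE, ifelse(s < sb, FALSE, r < rb))))
  }
  for (k in seq_len(nrow(panel$table))) {
    rid <- panel$table$ref_id[k]
    sc <- .batch_scores(unname(reads), panel$sequences[[rid]], ntmat,
                        params$nt_gap_open, params$nt_gap_ext, protein = FALSE)
    ev <- ifelse(is.finite(sc) & sc > 0,
                 estimate_evalue(pmax(sc, 0), nchar(reads), n_nt, params,
                                 "nucleotide"), Inf)
    upd <- better(ev, sc, rid, best$evalue, best$score,
                  ifelse(is.na(best$ref_id), "zzzz~", best$ref_id))
    best$evalue[upd] <- ev[upd]; best$score[upd] <- sc[upd]
    best$ref_id[upd] <- rid; best$mode[upd] <- "nucleotide"
    best$frame[upd] <- NA_integer_
    prot <- panel$proteins[rid]
    if (!is.na(prot) && nzchar(prot) && n_aa > 0) {
      psc <- .batch_scores(peps, prot, b62, params$gap_open, params$gap_ext,
                           protein = TRUE)
      pev <- ifelse(is.finite(psc) & psc > 0,
                    estimate_evalue(pmax(psc, 0), pmax(pep_len, 1L), n_aa,
                                    params, "protein"), Inf)
      m <- matrix(pev, nrow = 6L)
      msc <- matrix(psc, nrow = 6L)
      fbest <- apply(rbind(m, msc), 2L, function(col) {
        e <- col[1:6]; s <- col[7:12]
        o <- order(e, -s)[1L]
        c(e[o], s[o], o)
      })
      fr_codes <- c(1L, 2L, 3L, -1L, -2L, -3L)
      upd <- better(fbest[1L, ], fbest[2L, ], rid, best$evalue, best$score,
                    ifelse(is.na(best$ref_id), "zzzz~", best$ref_id))
      best$evalue[upd] <- fbest[1L, upd]; best$score[upd] <- fbest[2L, upd]
      best$ref_id[upd] <- rid; best$mode[upd] <- "translated"
      best$frame[upd] <- fr_codes[fbest[3L, upd]]
    }
  }

  out <- data.frame(read_id = ids, category = "no_hit",
                    ref_id = NA_character_, family = NA_character_,
                    mode = NA_character_, frame = NA_integer_,
                    score = NA_real_, evalue = NA_real_,
                    read_start = NA_integer_, read_end = NA_integer_,
                    ref_start = NA_integer_, ref_end = NA_integer_,
                    region = NA_character_, stringsAsFactors = FALSE)
  hit <- which(best$evalue <= params$evalue_cutoff)
  for (i in hit) {
    rid <- best$ref_id[i]
    row <- match(rid, panel$table$ref_id)
    cds <- c(panel$table$cds_start[row], panel$table$cds_end[row])
    mlen <- panel$table$length[row]
    if (best$mode[i] == "nucleotide") {
      a <- local_align(reads[[i]], panel$sequences[[rid]], params, "nucleotide")
      read_iv <- a$query_iv; ref_iv <- a$target_iv
    } else {
      f <- best$frame[i]
      pep <- frames[[i]][[frame_names[match(f, c(1L, 2L, 3L, -1L, -2L, -3L))]]]
      a <- local_align(pep, panel$proteins[[rid]], params, "protein")
      # peptide coords -> read nucleotide coords
      L <- nchar(reads[[i]])
      off <- abs(f) - 1L
      nt_s <- off + 3L * a$query_iv[1]
      nt_e <- off + 3L * a$query_iv[2]
      read_iv <- if (f > 0L) c(nt_s, nt_e) else c(L - nt_e, L - nt_s)
      # protein coords -> reference mRNA coords
      ref_iv <- c(cds[1] + 3L * a$target_iv[1], cds[1] + 3L * a$target_iv[2])
    }
    mf <- unname(microsat_frac[ids[i]])
    if (length(mf) != 1L || is.na(mf)) mf <- 0
    region <- if (ref_iv[2] > ref_iv[1])
      partition_region(ref_iv, cds, mlen, mf)
    else NA_character_
    out$category[i] <- ifelse(panel$table$class[row] == "toxin",
                              "toxin", "non_toxin")
    out$ref_id[i] <- rid
    out$family[i] <- panel$table$family[row]
    out$mode[i] <- best$mode[i]
    out$frame[i] <- best$frame[i]
    out$score[i] <- best$score[i]
    out$evalue[i] <- best$evalue[i]
    out$read_start[i] <- read_iv[1]; out$read_end[i] <- read_iv[2]
    out$ref_start[i] <- ref_iv[1]; out$ref_end[i] <- ref_iv[2]
    out$region[i] <- region
  }
  class(out) <- c("family_hits", "data.frame")
  out
}

#' Assign a single read (convenience wrapper over [assign_families()])
#' @inheritParams assign_families
#' @param read A single sequence.
#' @export
assign_family <- function(read, panel, params = homology_params(),
                          microsat_frac = 0) {
  r <- stats::setNames(read, "read1")
  assign_families(r, panel, params,
                  microsat_frac = stats::setNames(microsat_frac, "read1"))
}

#' Write family hits as TSV
#' @param hits A `family_hits` data frame.
#' @param path Output file.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
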