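#' Read a FASTA file as a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(s)), names(s))
}

#' Write a named character vector as FASTA
#' @param seqs Named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 80L)
  invisible(path)
}

#' Read a FASTQ file
#' @param path FASTQ file.
#' @return Named character vector of sequences with the per-read quality
#'   strings in attribute `"qual"`.
#' @export
read_fastq <- function(path) {
  s <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  out <- stats::setNames(as.character(s), names(s))
  attr(out, "qual") <- as.character(S4Vectors::mcols(s)$qualities)
  out
}

#' Demultiplex reads by terminal MID barcode
#'
#' A read is assigned to a species iff its 3'-terminal 10-mer exactly matches
#' that species' MID; the MID is trimmed from assigned reads. Exact matching
#' means any sequencing error within the barcode leaves the read unassigned,
#' which is how run-level barcode error rates are estimated.
#'
#' @param reads Named character vector of read sequences (MID at 3' end).
#' @param mid_set Named character vector of distinct 10-base MIDs
#'   (names are species labels).
#' @return List with `assigned` (list of named character vectors per species),
#'   `unassigned` (named character vector), and `stats` (class `run_stats`:
#'   `n_total`, `n_assigned`, `n_unassigned`, `error_rate_mid` in percent,
#'   per-species counts).
#' @export
demultiplex <- function(reads, mid_set) {
  validate_mid_set(mid_set)
  n <- nchar(reads)
  tail10 <- substr(reads, n - 9L, n)
  tail10[n < 10L] <- ""
  hit <- match(tail10, mid_set)
  assigned <- lapply(seq_along(mid_set), function(k) {
    sel <- which(hit == k)
    stats::setNames(substr(reads[sel], 1L, n[sel] - 10L), names(reads)[sel])
  })
  names(assigned) <- names(mid_set)
  unassigned <- reads[is.na(hit)]
  stats <- structure(
    list(n_total = length(reads),
         n_assigned = sum(!is.na(hit)),
         n_unassigned = sum(is.na(hit)),
         error_rate_mid = if (length(reads)) 100 * sum(is.na(hit)) / length(reads) else 0,
         per_species = vapply(assigned, length, 0L)),
    class = "run_stats")
  list(assigned = assigned, unassigned = unassigned, stats = stats)
}

#' @export
print.run_stats <- function(x, ...) {
  cat(sprintf("<run_stats> %d reads: %d assigned, %d unassigned (MID error rate %.2f%%)\n",
              x$n_total, x$n_assigned, x$n_unassigned, x$error_rate_mid))
  if (!is.null(x$per_species))
    cat("  per species:", paste(sprintf("%s=%d", names(x$per_species),
                                        x$per_species), collapse = ", "), "\n")
  invisible(x)
}

# microsatellite tract detection: maximal perfect tandem runs, motif 1..motif_max
find_tandem_tracts <- function(x, min_tract_nt, min_copies, motif_max) {
  L <- length(x)
  iv <- NULL
  for (m in seq_len(min(motif_max, max(0L, L - 1L)))) {
    eq <- x[(1L + m):L] == x[1L:(L - m)] & x[(1L + m):L] != "N"
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      total <- r$lengths[k] + m          # tract width in nt
      if (total >= min_tract_nt && total / m >= min_copies) {
        s <- starts[k]                   # 1-based index into eq
        iv <- rbind(iv, c(s - 1L, s - 1L + total))  # 0-based half-open
      }
    }
  }
  iv
}

# low-complexity windows: Shannon entropy of A/C/G/T composition below cutoff
find_low_entropy <- function(x, entropy_min, window) {
  L <- length(x)
  if (L < window) return(NULL)
  ind <- lapply(c(DNA_BASES, "N"), function(b) cumsum(x == b))
  n_win <- L - window + 1L
  cnt <- vapply(ind, function(cs) cs[window:L] - c(0L, cs)[1:n_win],
                integer(n_win))
  nn <- cnt[, 5L]
  acgt <- cnt[, 1:4, drop = FALSE]
  tot <- rowSums(acgt)
  p <- acgt / pmax(tot, 1L)
  H <- -rowSums(ifelse(p > 0, p * log2(p), 0))
  low <- which(H < entropy_min & nn == 0L & tot > 0L)
  if (length(low) == 0L) return(NULL)
  cbind(low - 1L, low - 1L + window)
}

#' Mask microsatellite and low-complexity sequence
#'
#' Self-contained repeat masking: perfect tandem repeats of motif length 1-6
#' with at least `min_copies` copies and `min_tract_nt` total nucleotides are
#' classed `microsatellite`; windows whose A/C/G/T Shannon entropy falls below
#' `entropy_min` bits are classed `low_complexity`. Masked positions are
#' replaced by `N`. Intervals are maximal, non-overlapping and half-open
#' (0-based); where the two classes overlap, `microsatellite` wins.
#'
#' @param seq A single nucleotide string over A/C/G/T/N.
#' @param min_tract_nt Minimum tandem tract width (nt).
#' @param min_copies Minimum number of motif copies.
#' @param motif_max Maximum motif length.
#' @param entropy_min Entropy cutoff in bits.
#' @param entropy_window Sliding-window width for the entropy scan.
#' @return Object of class `masked_read`: list with `seq` (masked sequence)
#'   and `intervals` (data frame `start`, `end`, `class`).
#' @export
#' @examples
#' mask_repeats(strrep("AC", 7))$intervals
mask_repeats <- function(seq, min_tract_nt = 12L, min_copies = 3L,
                         motif_max = 6L, entropy_min = 1.0,
                         entropy_window = 25L) {
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L == 0L)
    return(structure(list(seq = seq,
                          intervals = data.frame(start = integer(0),
                                                 end = integer(0),
                                                 class = character(0))),
                     class = "masked_read"))
  x <- strsplit(seq, "")[[1]]
  if (any(!x %in% c(DNA_BASES, "N"))) stop("sequence must be over A/C/G/T/N")
  ms <- find_tandem_tracts(x, min_tract_nt, min_copies, motif_max)
  lc <- find_low_entropy(x, entropy_min, entropy_window)
  is_ms <- logical(L); is_lc <- logical(L)
  if (!is.null(ms)) for (k in seq_len(nrow(ms))) is_ms[(ms[k, 1] + 1L):ms[k, 2]] <- TRUE
  if (!is.null(lc)) for (k in seq_len(nrow(lc))) is_lc[(lc[k, 1] + 1L):lc[k, 2]] <- TRUE
  cls <- ifelse(is_ms, "microsatellite", ifelse(is_lc, "low_complexity", ""))
  r <- rle(cls)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values != "")
  intervals <- data.frame(start = starts[keep] - 1L, end = ends[keep],
                          class = r$values[keep], stringsAsFactors = FALSE)
  x[is_ms | is_lc] <- "N"
  structure(list(seq = paste(x, collapse = ""), intervals = intervals),
            class = "masked_read")
}

#' @export
print.masked_read <- function(x, ...) {
  w <- sum(x$intervals$end - x$intervals$start)
  cat(sprintf("<masked_read> %d nt, %d nt masked in %d interval(s)\n",
              nchar(x$seq), w, nrow(x$intervals)))
  invisible(x)
}

#' Fraction of a read masked as microsatellite
#'
#' @param masked A `masked_read` from [mask_repeats()].
#' @return Value in \[0, 1\].
#' @export
microsat_fraction <- function(masked) {
  stopifnot(inherits(masked, "masked_read"))
  L <- nchar(masked$seq)
  if (L == 0L) return(0)
  ms <- masked$intervals[masked$intervals$class == "microsatellite", , drop = FALSE]
  sum(ms$end - ms$start) / L
}

#' Is a read microsatellite-dominated?
#'
#' A read is classed microsatellite-dominated when at least `threshold` of its
#' bases are masked as microsatellite (default 50%, a conservative cut given
#' that such reads are typically masked almost entirely).
#'
#' @param masked A `masked_read`.
#' @param threshold Fraction cutoff.
#' @export
is_microsat_dominated <- function(masked, threshold = 0.5) {
  microsat_fraction(masked) >= threshold
}

#' Mask a whole set of reads
#'
#' Applies [mask_repeats()] to every read and aggregates run-level masking
#' statistics.
#'
#' @param reads Named character vector.
#' @inheritParams mask_repeats
#' @return List with `reads` (masked named character vector), `masked`
#'   (list of `masked_read` objects), `intervals` (data frame with `read_id`),
#'   and `stats` (`masked_nt`, `total_nt`, `masked_pct`).
#' @export
mask_run <- function(reads, min_tract_nt = 12L, min_copies = 3L,
                     motif_max = 6L, entropy_min = 1.0, entropy_window = 25L) {
  masked <- lapply(reads, mask_repeats, min_tract_nt = min_tract_nt,
                   min_copies = min_copies, motif_max = motif_max,
                   entropy_min = entropy_min, entropy_window = entropy_window)
  iv <- do.call(rbind, lapply(names(masked), function(id) {
    d <- masked[[id]]$intervals
    if (nrow(d) == 0L) return(NULL)
    cbind(read_id = id, d)
  }))
  if (is.null(iv))
    iv <- data.frame(read_id = character(0), start = integer(0),
                     end = integer(0), class = character(0))
  total_nt <- sum(nchar(reads))
  masked_nt <- sum(iv$end - iv$start)
  list(reads = stats::setNames(vapply(masked, `[[`, "", "seq"), names(reads)),
       masked = masked, intervals = iv,
       stats = list(masked_nt = masked_nt, total_nt = total_nt,
                    masked_pct = if (total_nt) 100 * masked_nt / total_nt else 0))
}

#' Write masked intervals as BED
#'
#' BED3+1 with the read id as chromosome and the interval class as name.
#'
#' @param intervals Data frame with `read_id`, `start`, `end`, `class`.
#' @param path Output file.
#' @export
write_intervals_bed <- function(intervals, path) {
  utils::write.table(intervals[, c("read_id", "start", "end", "class")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
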