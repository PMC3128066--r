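# Shared helpers: independent oracles and fixture builders.

# Quadratic-space affine-gap local-alignment DP (Gotoh), independent of the
# implementation path: a gap of length k costs gap_open + k * gap_ext.
sw_oracle <- function(q, t, smat, gap_open, gap_ext) {
  qs <- strsplit(q, "")[[1]]
  ts <- strsplit(t, "")[[1]]
  n <- length(qs); m <- length(ts)
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)
  F <- matrix(-Inf, n + 1L, m + 1L)
  best <- 0
  for (i in 2:(n + 1L)) for (j in 2:(m + 1L)) {
    E[i, j] <- max(H[i, j - 1L] - gap_open - gap_ext, E[i, j - 1L] - gap_ext)
    F[i, j] <- max(H[i - 1L, j] - gap_open - gap_ext, F[i - 1L, j] - gap_ext)
    H[i, j] <- max(0, H[i - 1L, j - 1L] + smat[qs[i - 1L], ts[j - 1L]],
                   E[i, j], F[i, j])
    best <- max(best, H[i, j])
  }
  best
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
rand_aa <- function(n) {
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  paste(sample(aas, n, TRUE), collapse = "")
}

# permute a sequence at dinucleotide granularity (preserves composition)
dinucleotide_shuffle <- function(seq) {
  x <- strsplit(seq, "")[[1]]
  if (length(x) %% 2L == 1L) x <- x[-length(x)]
  pairs <- paste0(x[c(TRUE, FALSE)], x[c(FALSE, TRUE)])
  paste(sample(pairs), collapse = "")
}

# protein stack with prescribed residue columns, for consensus unit tests:
# `columns` is a list of character vectors (the residues observed per column)
stack_from_columns <- function(columns, reference = NULL) {
  L <- length(columns)
  n <- max(vapply(columns, length, 0L))
  mat <- matrix(NA_character_, n, L)
  for (j in seq_len(L)) {
    res <- columns[[j]]
    if (length(res)) mat[seq_along(res), j] <- res
  }
  structure(list(reference = reference %||% strrep("A", L), mat = mat,
                 coverage = colSums(!is.na(mat))),
            class = "protein_stack")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal contig_cluster stand-ins for trim_clusters tests
fake_clusters <- function(counts) {
  lapply(seq_along(counts), function(k)
    structure(list(cluster_id = sprintf("c%03d", k), members = character(0),
                   n_reads = as.integer(counts[k]),
                   signature = data.frame(pos = integer(0), base = character(0),
                                          support = integer(0)),
                   span = c(0L, 1L)),
              class = "contig_cluster"))
}

# evolve a protein along a tree given as nested lists; returns tip sequences.
# Each branch substitutes residues with the given per-site probability.
evolve_protein <- function(seq, rate) {
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  x <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(x)) < rate)
  for (i in hit) x[i] <- sample(setdiff(aas, x[i]), 1L)
  paste(x, collapse = "")
}
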