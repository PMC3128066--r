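# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# run `code` under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Shannon entropy (bits) of the A/C/G/T composition of a character vector
base_entropy <- function(chars) {
  counts <- tabulate(match(chars, DNA_BASES), nbins = 4L)
  n <- sum(counts)
  if (n == 0L) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

# merge overlapping/adjacent half-open intervals given as a 2-column matrix
merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0L) return(iv)
  iv <- iv[order(iv[, 1L], iv[, 2L]), , drop = FALSE]
  out <- iv[1L, , drop = FALSE]
  if (nrow(iv) > 1L) for (k in 2L:nrow(iv)) {
    last <- nrow(out)
    if (iv[k, 1L] <= out[last, 2L]) {
      out[last, 2L] <- max(out[last, 2L], iv[k, 2L])
    } else {
      out <- rbind(out, iv[k, , drop = FALSE])
    }
  }
  out
}

stopifnot_scalar_prob <- function(x, name, open_right = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 &&
    (if (open_right) x < 1 else x <= 1)
  if (!ok) stop(sprintf("`%s` must be a single value in [0, %s", name,
                        if (open_right) "1)" else "1]"), call. = FALSE)
  invisible(x)
}

# half-open interval overlap width
iv_overlap <- function(s1, e1, s2, e2) max(0L, min(e1, e2) - max(s1, s2))
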