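#' @importFrom stats rbinom rlnorm runif uniroot pnorm qnorm
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

# codon lookup built once from the standard genetic code; codons containing
# N (or anything else non-ACGT) translate to X
.codon_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- Biostrings::GENETIC_CODE
    cache
  }
})

translate_dna <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return("")
  starts <- 3L * seq_len(n) - 2L
  aa <- unname(.codon_table()[substring(seq, starts, starts + 2L)])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Construct a toxin gene model
#'
#' A gene model is one (simulated or reference) full-length transcript: the
#' mRNA sequence, its CDS as a 0-based half-open interval, any microsatellite
#' tracts, and the encoded protein. All coordinate invariants are checked.
#'
#' @param gene_id Unique identifier.
#' @param family Toxin family acronym (see [toxin_families()]) or a non-toxin
#'   label such as `"PDI"`.
#' @param paralog_id Integer paralog index within the family.
#' @param mrna Nucleotide sequence (A/C/G/T/N).
#' @param cds Integer length-2 vector, 0-based half-open CDS interval on
#'   `mrna`; its width must be divisible by 3.
#' @param microsat_tracts List of 0-based half-open intervals within the mRNA.
#' @return An object of class `toxin_gene_model`.
#' @export
toxin_gene_model <- function(gene_id, family, paralog_id, mrna, cds,
                             microsat_tracts = list()) {
  mrna <- toupper(mrna)
  L <- nchar(mrna)
  if (!(cds[1] >= 0 && cds[1] < cds[2] && cds[2] <= L))
    stop("CDS interval out of mRNA bounds")
  if ((cds[2] - cds[1]) %% 3L != 0L)
    stop("CDS length must be divisible by 3")
  aa <- translate_dna(substr(mrna, cds[1] + 1L, cds[2]))
  if (substring(aa, nchar(aa)) == "*") aa <- substr(aa, 1L, nchar(aa) - 1L)
  if (grepl("*", aa, fixed = TRUE))
    stop("CDS translation contains an internal stop codon")
  for (tr in microsat_tracts)
    if (tr[1] < 0 || tr[2] > L) stop("microsatellite tract out of bounds")
  structure(
    list(gene_id = gene_id, family = family, paralog_id = as.integer(paralog_id),
         mrna = mrna, cds = as.integer(cds),
         microsat_tracts = microsat_tracts, protein = aa),
    class = "toxin_gene_model")
}

#' @export
print.toxin_gene_model <- function(x, ...) {
  cat(sprintf("<toxin_gene_model> %s (family %s, paralog %d)\n",
              x$gene_id, x$family, x$paralog_id))
  cat(sprintf("  mRNA %d nt; CDS [%d, %d); protein %d aa; %d microsatellite tract(s)\n",
              nchar(x$mrna), x$cds[1], x$cds[2], nchar(x$protein),
              length(x$microsat_tracts)))
  invisible(x)
}

# random CDS: ATG + stop-free codons + one stop codon
random_cds <- function(cds_len) {
  stopifnot(cds_len %% 3 == 0, cds_len >= 9)
  n_mid <- cds_len / 3L - 2L
  codons <- apply(matrix(sample(DNA_BASES, 3L * n_mid, replace = TRUE), nrow = 3L),
                  2L, paste, collapse = "")
  bad <- codons %in% STOP_CODONS
  while (any(bad)) {
    codons[bad] <- apply(matrix(sample(DNA_BASES, 3L * sum(bad), replace = TRUE),
                                nrow = 3L), 2L, paste, collapse = "")
    bad <- codons %in% STOP_CODONS
  }
  paste0("ATG", paste(codons, collapse = ""), sample(STOP_CODONS, 1L))
}

# Mutate `seq` at ~divergence of sites (binomial per site) while keeping the
# CDS free of internal stops. Retries are per affected codon, bounded.
mutate_stop_free <- function(seq, cds, divergence, max_tries = 50L) {
  x <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(x)) < divergence)
  for (i in hit) x[i] <- sample(setdiff(DNA_BASES, x[i]), 1L)
  # repair internal stop codons introduced by mutation
  n_codon <- (cds[2] - cds[1]) / 3L
  anc <- strsplit(seq, "")[[1]]
  for (ci in seq_len(n_codon - 1L)) {        # last codon may be a stop
    idx <- cds[1] + 3L * (ci - 1L) + 1:3
    tries <- 0L
    while (paste(x[idx], collapse = "") %in% STOP_CODONS) {
      mutated <- idx[x[idx] != anc[idx]]
      if (length(mutated) == 0L)
        stop("ancestor CDS contains an internal stop codon")
      for (i in mutated) x[i] <- sample(setdiff(DNA_BASES, anc[i]), 1L)
      tries <- tries + 1L
      if (tries > max_tries)
        stop("stop-free mutation failed: divergence parameters infeasible")
    }
  }
  paste(x, collapse = "")
}

#' Simulate a multigene toxin family
#'
#' Generates `n_paralogs` gene models for one toxin family under an
#' ancestor-based star phylogeny: paralog 1 is the ancestor, and every other
#' paralog differs from it at approximately `divergence` of sites (binomially
#' sampled substitutions; no internal stop codons are introduced in the CDS).
#'
#' @param family Family acronym.
#' @param n_paralogs Number of gene copies (>= 1).
#' @param divergence Per-site substitution fraction from the ancestor, in
#'   \[0, 0.2\].
#' @param cds_len CDS length in nucleotides (divisible by 3, includes start
#'   and stop codon).
#' @param utr3_len 3'UTR length in nucleotides.
#' @param microsat If `TRUE`, a tandem-repeat tract is embedded in the 3'UTR
#'   and recorded in `microsat_tracts`.
#' @param seed Integer seed; results are deterministic given the seed.
#' @param utr5_len 5'UTR length in nucleotides.
#' @param ancestor Optional `toxin_gene_model` to use as paralog 1 (e.g. a
#'   reference-panel exemplar) instead of a randomly generated ancestor.
#' @return List of [toxin_gene_model()] objects.
#' @export
#' @examples
#' fam <- simulate_gene_family("PLA2", 2, 0.05, cds_len = 414, utr3_len = 200,
#'                             seed = 7)
#' length(fam)
simulate_gene_family <- function(family, n_paralogs, divergence,
                                 cds_len = 450L, utr3_len = 300L,
                                 microsat = FALSE, seed = 1L,
                                 utr5_len = 60L, ancestor = NULL) {
  if (n_paralogs < 1L) stop("n_paralogs must be >= 1")
  if (!is.numeric(divergence) || divergence < 0 || divergence > 0.2)
    stop("divergence must lie in [0, 0.2]")
  set.seed(seed)
  if (is.null(ancestor)) {
    utr5 <- random_dna(utr5_len)
    cds_seq <- random_cds(cds_len)
    utr3 <- random_dna(utr3_len)
    tracts <- list()
    if (microsat) {
      motif <- sample(c("AC", "AG", "AT", "CA", "GA", "TA", "CAA", "AAT"), 1L)
      ncopy <- sample(10:18, 1L)
      tract <- strrep(motif, ncopy)
      tw <- nchar(tract)
      if (tw > utr3_len) stop("utr3_len too short for a microsatellite tract")
      pos <- sample.int(utr3_len - tw + 1L, 1L) - 1L   # 0-based within UTR3
      substr(utr3, pos + 1L, pos + tw) <- tract
      tracts <- list(c(utr5_len + cds_len + pos, utr5_len + cds_len + pos + tw))
    }
    anc_mrna <- paste0(utr5, cds_seq, utr3)
    cds <- c(utr5_len, utr5_len + cds_len)
  } else {
    anc_mrna <- ancestor$mrna
    cds <- ancestor$cds
    tracts <- ancestor$microsat_tracts
  }
  out <- vector("list", n_paralogs)
  out[[1L]] <- toxin_gene_model(paste0(family, "-1"), family, 1L, anc_mrna,
                                cds, tracts)
  if (n_paralogs > 1L) for (p in 2:n_paralogs) {
    m <- if (divergence > 0) mutate_stop_free(anc_mrna, cds, divergence)
         else anc_mrna
    out[[p]] <- toxin_gene_model(paste0(family, "-", p), family, p, m, cds, tracts)
  }
  out
}

#' Read-simulation configuration
#'
#' Parameters of the 454-style read simulator. Read lengths are drawn from a
#' log-normal distribution truncated at `max_len`, with `meanlog`/`sdlog`
#' solved at construction so that the truncated mean equals `mean_len` and the
#' fraction of reads shorter than 50 nt equals `frac_short`. Start positions
#' are 3'-weighted (probability proportional to `((start+1)/length)^bias`),
#' emulating a 3'-end-enriched cDNA library. A 10-base MID barcode is appended
#' at the 3' end of every read; a fraction `mid_corruption_rate` of reads
#' carry an unrecognizable MID.
#'
#' @param mean_len Mean read length in nucleotides.
#' @param max_len Maximum read length.
#' @param frac_short Target fraction of reads shorter than 50 nt.
#' @param error_rate Per-base substitution probability.
#' @param three_prime_bias Exponent (>= 0) of the start-position weighting;
#'   0 gives uniform starts.
#' @param mid_set Named character vector of distinct 10-base MIDs; names are
#'   species labels.
#' @param mid_corruption_rate Probability that a read's MID is corrupted into
#'   a barcode matching no entry of `mid_set`.
#' @param seed Integer seed used by [simulate_reads()].
#' @return An object of class `read_sim_config`.
#' @export
read_sim_config <- function(mean_len = 186.6, max_len = 645L,
                            frac_short = 0.0327, error_rate = 0.0135,
                            three_prime_bias = 2, mid_set = default_mid_set(1L),
                            mid_corruption_rate = 0.0135, seed = 1L) {
  stopifnot_scalar_prob(error_rate, "error_rate")
  stopifnot_scalar_prob(mid_corruption_rate, "mid_corruption_rate")
  if (mean_len >= max_len) stop("mean_len must be smaller than max_len")
  if (frac_short <= 0 || frac_short >= 1) stop("frac_short must be in (0, 1)")
  if (three_prime_bias < 0) stop("three_prime_bias must be >= 0")
  validate_mid_set(mid_set)
  # solve truncated log-normal parameters from (mean, max, frac < 50)
  trunc_mean <- function(sig) {
    mu <- log(50) - sig * qnorm(frac_short)
    exp(mu + sig^2 / 2) * pnorm((log(max_len) - mu - sig^2) / sig) /
      pnorm((log(max_len) - mu) / sig) - mean_len
  }
  sdlog <- uniroot(trunc_mean, c(0.05, 2.5))$root
  meanlog <- log(50) - sdlog * qnorm(frac_short)
  structure(
    list(mean_len = mean_len, max_len = as.integer(max_len),
         frac_short = frac_short, error_rate = error_rate,
         three_prime_bias = three_prime_bias, mid_set = mid_set,
         mid_corruption_rate = mid_corruption_rate, seed = as.integer(seed),
         meanlog = meanlog, sdlog = sdlog),
    class = "read_sim_config")
}

validate_mid_set <- function(mid_set) {
  if (any(nchar(mid_set) != 10L)) stop("all MIDs must be 10 bases long")
  if (anyDuplicated(mid_set)) stop("MIDs must be pairwise distinct")
  if (is.null(names(mid_set)) || any(names(mid_set) == ""))
    stop("mid_set must be named by species")
  invisible(mid_set)
}

#' Standard 10-base MID barcodes
#'
#' The first `n` barcodes of the standard GS FLX MID set, named
#' `species1 ... speciesN` (rename as needed).
#'
#' @param n Number of barcodes (1-8).
#' @export
default_mid_set <- function(n = 8L) {
  mids <- c("ACGAGTGCGT", "ACGCTCGACA", "AGACGCACTC", "AGCACTGTAG",
            "ATCAGACACG", "ATATCGCGAG", "CGTGTCTCTA", "CTCGCGTGTC")
  if (n < 1L || n > length(mids)) stop("n must be between 1 and 8")
  stats::setNames(mids[seq_len(n)], paste0("species", seq_len(n)))
}

#' Expression profile for simulation
#'
#' Per-gene transcript weights (relative mRNA abundance) and translational
#' efficiencies (used by [simulate_proteome()] to emulate species-dependent
#' translational control).
#'
#' @param models List of gene models.
#' @param weights Non-negative numeric vector, one per model (default equal).
#' @param efficiencies Non-negative numeric vector, one per model (default 1).
#' @return Data frame of class `expression_profile` with columns `gene_id`,
#'   `family`, `weight`, `efficiency`.
#' @export
expression_profile <- function(models, weights = NULL, efficiencies = NULL) {
  n <- length(models)
  if (n == 0L) stop("models must be nonempty")
  weights <- weights %||% rep(1, n)
  efficiencies <- efficiencies %||% rep(1, n)
  if (length(weights) != n || length(efficiencies) != n)
    stop("weights and efficiencies must have one entry per model")
  if (any(weights < 0) || any(efficiencies < 0))
    stop("weights and efficiencies must be >= 0")
  if (all(weights == 0)) stop("at least one weight must be positive")
  structure(
    data.frame(gene_id = vapply(models, `[[`, "", "gene_id"),
               family = vapply(models, `[[`, "", "family"),
               weight = weights, efficiency = efficiencies,
               stringsAsFactors = FALSE),
    class = c("expression_profile", "data.frame"))
}

# a corrupted barcode: mutate until it matches no MID in the set
corrupt_mid <- function(mid, mid_set) {
  repeat {
    x <- strsplit(mid, "")[[1]]
    for (i in sample.int(10L, 3L)) x[i] <- sample(setdiff(DNA_BASES, x[i]), 1L)
    out <- paste(x, collapse = "")
    if (!out %in% mid_set) return(out)
  }
}

draw_read_lengths <- function(n, cfg) {
  out <- integer(0)
  while (length(out) < n) {
    x <- round(rlnorm(max(2L * n, 100L), cfg$meanlog, cfg$sdlog))
    out <- c(out, x[x <= cfg$max_len & x >= 20L])
  }
  out[seq_len(n)]
}

#' Simulate a multiplexed 454-style read run
#'
#' Draws reads from the supplied gene models according to an expression
#' profile: each read's source gene is sampled proportionally to
#' `weight * transcript length` (shotgun semantics: a transcript's read
#' yield scales with both its molar abundance and its length, which is the
#' length bias that mol% normalization later removes), with 3'-biased start
#' positions, truncated log-normal lengths, per-base substitution errors at
#' `cfg$error_rate` (applied to the insert), and a 10-base species MID
#' appended at the 3' end, corrupted with probability
#' `cfg$mid_corruption_rate`. A complete ground-truth table maps every read
#' to its source gene, source interval and introduced errors.
#'
#' @param models List of gene models.
#' @param profile An [expression_profile()] covering every model.
#' @param cfg A [read_sim_config()].
#' @param n_reads Number of reads to simulate.
#' @param species Optional named character vector `gene_id -> species`
#'   selecting which MID each gene's reads receive; defaults to the first
#'   species of `cfg$mid_set` for all genes.
#' @return An object of class `sim_run`: list with `reads` (named character
#'   vector, MID included), `truth` (data frame: `read_id`, `gene_id`,
#'   `family`, `species`, `start`, `end`, `n_errors`, `mid_ok`), and `config`.
#' @export
simulate_reads <- function(models, profile, cfg, n_reads, species = NULL) {
  if (length(models) == 0L) stop("models must be nonempty")
  ids <- vapply(models, `[[`, "", "gene_id")
  if (!all(ids %in% profile$gene_id))
    stop("profile must define a weight for every model")
  w <- profile$weight[match(ids, profile$gene_id)]
  if (all(w == 0)) stop("all model weights are zero")
  if (is.null(species)) {
    species <- stats::setNames(rep(names(cfg$mid_set)[1L], length(ids)), ids)
  }
  if (!all(ids %in% names(species))) stop("species assignment missing for some genes")
  if (!all(species[ids] %in% names(cfg$mid_set)))
    stop("species assignment refers to species absent from mid_set")

  set.seed(cfg$seed)
  glen <- vapply(models, function(m) nchar(m$mrna), 0L)
  src <- sample.int(length(models), n_reads, replace = TRUE, prob = w * glen)
  lens <- draw_read_lengths(n_reads, cfg)
  b <- cfg$three_prime_bias
  u <- runif(n_reads)
  reads <- character(n_reads)
  starts <- integer(n_reads)
  n_err <- integer(n_reads)
  len_i <- pmin(lens, glen[src])
  # inverse-CDF draw from weights ((s+1)/L)^b over valid starts 0..L-len
  span <- glen[src] - len_i + 1L
  starts <- pmin(span - 1L, pmax(0L, as.integer(ceiling(span * u^(1 / (b + 1)))) - 1L))
  for (i in seq_len(n_reads)) {
    m <- models[[src[i]]]
    insert <- substr(m$mrna, starts[i] + 1L, starts[i] + len_i[i])
    k <- rbinom(1L, len_i[i], cfg$error_rate)
    if (k > 0L) {
      pos <- sample.int(len_i[i], k)
      x <- strsplit(insert, "")[[1]]
      for (p in pos) x[p] <- sample(setdiff(DNA_BASES, x[p]), 1L)
      insert <- paste(x, collapse = "")
    }
    n_err[i] <- k
    reads[i] <- insert
  }
  sp <- unname(species[ids[src]])
  mids <- unname(cfg$mid_set[sp])
  corrupted <- runif(n_reads) < cfg$mid_corruption_rate
  for (i in which(corrupted)) mids[i] <- corrupt_mid(mids[i], cfg$mid_set)
  reads <- paste0(reads, mids)
  read_id <- sprintf("read%06d", seq_len(n_reads))
  names(reads) <- read_id
  truth <- data.frame(
    read_id = read_id, gene_id = ids[src],
    family = vapply(models, `[[`, "", "family")[src],
    species = sp, start = starts, end = starts + len_i,
    n_errors = n_err, mid_ok = !corrupted, stringsAsFactors = FALSE)
  structure(list(reads = reads, truth = truth, config = cfg),
            class = "sim_run")
}

#' @export
print.sim_run <- function(x, ...) {
  cat(sprintf("<sim_run> %d reads from %d genes across %d species\n",
              length(x$reads), length(unique(x$truth$gene_id)),
              length(unique(x$truth$species))))
  cat(sprintf("  mean length %.1f nt (insert), error rate %.4f, MID corruption %.4f\n",
              mean(x$truth$end - x$truth$start), x$config$error_rate,
              x$config$mid_corruption_rate))
  invisible(x)
}

#' Simulate a matched venom proteome
#'
#' Family-level protein abundances implied by the expression profile:
#' each family's share is the sum of `weight * efficiency` over its genes,
#' normalized to 100%. Families whose genes all have zero efficiency are
#' reported as 0% (absent from the venom).
#'
#' @param models List of gene models.
#' @param profile An [expression_profile()].
#' @return Named numeric vector of family percentages summing to 100.
#' @export
simulate_proteome <- function(models, profile) {
  ids <- vapply(models, `[[`, "", "gene_id")
  p <- profile[match(ids, profile$gene_id), ]
  if (any(is.na(p$weight))) stop("profile must cover every model")
  contrib <- p$weight * p$efficiency
  by_fam <- tapply(contrib, p$family, sum)
  if (sum(by_fam) == 0) stop("all weight x efficiency products are zero")
  pct <- 100 * as.vector(by_fam) / sum(by_fam)
  stats::setNames(pct, names(by_fam))
}

## ---- writers ---------------------------------------------------------------

#' Write simulated reads as FASTA
#' @param x A `sim_run` or named character vector of sequences.
#' @param path Output file.
#' @export
write_reads_fasta <- function(x, path) {
  reads <- if (inherits(x, "sim_run")) x$reads else x
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reads), path, width = 80L)
  invisible(path)
}

#' Write simulated reads as FASTQ with constant quality
#'
#' The per-base quality is the Sanger-scaled Phred score implied by the
#' configured substitution rate, `Q = round(-10 log10(error_rate))` (Q40 when
#' the rate is zero).
#'
#' @param run A `sim_run`.
#' @param path Output file.
#' @export
write_reads_fastq <- function(run, path) {
  stopifnot(inherits(run, "sim_run"))
  q <- if (run$config$error_rate <= 0) 40L
       else min(40L, as.integer(round(-10 * log10(run$config$error_rate))))
  qchar <- rawToChar(as.raw(q + 33L))
  quals <- Biostrings::BStringSet(strrep(qchar, nchar(run$reads)))
  names(quals) <- names(run$reads)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(run$reads), path,
                              format = "fastq", qualities = quals)
  invisible(path)
}

#' Write the ground-truth table as TSV
#' @param run A `sim_run` (or its `truth` data frame).
#' @param path Output file.
#' @export
write_truth_tsv <- function(run, path) {
  truth <- if (inherits(run, "sim_run")) run$truth else run
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write gene models as FASTA plus annotation TSV
#'
#' The annotation table has columns `gene_id`, `family`, `cds_start`,
#' `cds_end` (0-based, half-open) and `microsat_tracts`
#' (semicolon-separated `start-end` pairs).
#'
#' @param models List of gene models.
#' @param fasta_path,tsv_path Output files.
#' @export
write_gene_models <- function(models, fasta_path, tsv_path) {
  seqs <- stats::setNames(vapply(models, `[[`, "", "mrna"),
                          vapply(models, `[[`, "", "gene_id"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta_path,
                              width = 80L)
  ann <- data.frame(
    gene_id = names(seqs),
    family = vapply(models, `[[`, "", "family"),
    cds_start = vapply(models, function(m) m$cds[1], 0L),
    cds_end = vapply(models, function(m) m$cds[2], 0L),
    microsat_tracts = vapply(models, function(m)
      paste(vapply(m$microsat_tracts, function(t) paste(t, collapse = "-"), ""),
            collapse = ";"), ""),
    stringsAsFactors = FALSE)
  utils::write.table(ann, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fasta_path)
}
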