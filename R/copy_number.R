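#' Parameters of the gene-copy distinctness test
#'
#' Controls the error-rate-aware clustering that estimates the minimum number
#' of genes per toxin family: two read clusters are considered transcripts of
#' different genes only when their sequences disagree at more positions than
#' sequencing error can plausibly explain, and every variant must be carried
#' by a minimum number of reads.
#'
#' @param epsilon Per-base sequencing error rate; defaults to the run-level
#'   barcode-derived estimate of 1.35%.
#' @param alpha One-sided binomial test level: clusters stay separate iff
#'   `P(X >= m | X ~ Bin(L, epsilon)) < alpha`, where `m` is the number of
#'   discordant validated sites over `L` overlapping columns.
#' @param min_support Number of *additional* reads that must carry the same
#'   variant base for it to be validated (total support `1 + min_support`).
#' @param trim_fraction Clusters are retained largest-first until they account
#'   for at least this fraction of all placed reads.
#' @return Object of class `distinctness_params`.
#' @export
distinctness_params <- function(epsilon = 0.0135, alpha = 0.01,
                                min_support = 2L, trim_fraction = 0.95) {
  stopifnot_scalar_prob(epsilon, "epsilon")
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (min_support < 1L) stop("min_support must be >= 1")
  if (trim_fraction <= 0 || trim_fraction > 1)
    stop("trim_fraction must be in (0, 1]")
  structure(list(epsilon = epsilon, alpha = alpha,
                 min_support = as.integer(min_support),
                 trim_fraction = trim_fraction),
            class = "distinctness_params")
}

#' Reference-guided read pileup
#'
#' Places each read on the family reference by optimal local alignment and
#' records, for every reference column, which base each read contributes.
#' Read insertions relative to the reference are skipped; deletions leave the
#' column uncovered for that read. Reads whose alignment does not reach the
#' E-value cutoff (against the reference alone) are reported as unplaced.
#'
#' @param reads Named character vector of ORF-coding reads for one family.
#' @param reference The family reference mRNA (character) or a gene model.
#' @param params A [homology_params()] providing the nucleotide scoring.
#' @return Object of class `pileup`: list with `reference`, `ref_base`
#'   (character vector), `mat` (reads x positions base matrix), `counts`
#'   (4 x positions A/C/G/T counts), `coverage`, `placements` (data frame),
#'   `unplaced` (read ids).
#' @export
build_pileup <- function(reads, reference, params = homology_params()) {
  if (inherits(reference, "toxin_gene_model")) reference <- reference$mrna
  L <- nchar(reference)
  ref_base <- strsplit(toupper(reference), "")[[1]]
  empty <- function() structure(
    list(reference = reference, ref_base = ref_base,
         mat = matrix(NA_character_, 0L, L),
         counts = matrix(0L, 4L, L, dimnames = list(DNA_BASES, NULL)),
         coverage = integer(L),
         placements = data.frame(read_id = character(0), ref_start = integer(0),
                                 ref_end = integer(0), score = numeric(0)),
         unplaced = character(0)),
    class = "pileup")
  if (length(reads) == 0L) return(empty())
  ids <- names(reads) %||% sprintf("read%04d", seq_along(reads))
  st <- .stack_onto_subject(reads, reference, params, protein = FALSE)
  ev <- ifelse(st$scores > 0,
               estimate_evalue(pmax(st$scores, 0), nchar(reads), L, params,
                               "nucleotide"), Inf)
  placed <- ev <= params$evalue_cutoff
  if (!any(placed)) { e <- empty(); e$unplaced <- ids; return(e) }
  mat <- st$mat
  rownames(mat) <- ids
  mat <- mat[placed, , drop = FALSE]
  counts <- vapply(seq_len(L), function(j)
    tabulate(match(mat[, j], DNA_BASES), nbins = 4L), integer(4L))
  dimnames(counts) <- list(DNA_BASES, NULL)
  structure(
    list(reference = reference, ref_base = ref_base, mat = mat,
         counts = counts, coverage = as.integer(colSums(counts)),
         placements = data.frame(read_id = ids[placed],
                                 ref_start = st$t_start[placed],
                                 ref_end = st$t_end[placed],
                                 score = st$scores[placed],
                                 stringsAsFactors = FALSE),
         unplaced = ids[!placed]),
    class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> %d reads placed on %d nt reference (%d unplaced); mean coverage %.1f\n",
              nrow(x$mat), length(x$ref_base), length(x$unplaced),
              mean(x$coverage)))
  invisible(x)
}

#' Call validated variants from a pileup
#'
#' A variant (position, non-reference base) is validated iff at least
#' `1 + min_support` reads carry that identical base at that position, i.e.
#' the mutation is seen in the read and at least `min_support` other reads.
#'
#' @param pileup A [build_pileup()] result.
#' @param params A [distinctness_params()].
#' @return Data frame `pos` (0-based), `base`, `support`.
#' @export
call_validated_variants <- function(pileup, params = distinctness_params()) {
  need <- 1L + params$min_support
  out <- NULL
  for (j in seq_along(pileup$ref_base)) {
    alt <- setdiff(DNA_BASES, pileup$ref_base[j])
    sup <- pileup$counts[alt, j]
    ok <- which(sup >= need)
    if (length(ok))
      out <- rbind(out, data.frame(pos = j - 1L, base = alt[ok],
                                   support = unname(sup[ok]),
                                   stringsAsFactors = FALSE))
  }
  out %||% data.frame(pos = integer(0), base = character(0),
                      support = integer(0))
}

# majority call per site from a site x base count matrix (NA where uncovered);
# ties resolved toward the reference base, then alphabetically
.majority_calls <- function(cnt, ref_site_base) {
  tot <- rowSums(cnt)
  out <- rep(NA_character_, nrow(cnt))
  for (s in which(tot > 0L)) {
    top <- DNA_BASES[cnt[s, ] == max(cnt[s, ])]
    out[s] <- if (ref_site_base[s] %in% top) ref_site_base[s] else top[1L]
  }
  out
}

#' Cluster reads into putative gene copies
#'
#' Reads are first grouped by their signature over the validated-variant
#' sites they cover (reads covering no validated site join the
#' reference-signature cluster), then merged agglomeratively: two clusters
#' remain separate iff, over the `L` reference columns where their spans
#' overlap, with `m` discordant validated sites, the binomial tail
#' `P(X >= m | X ~ Bin(L, epsilon))` falls below `alpha`. Merging proceeds in
#' descending cluster size (ties by id) to a fixpoint, making the result
#' independent of read input order.
#'
#' @param pileup A [build_pileup()] result.
#' @param params A [distinctness_params()].
#' @param variants Optional precomputed [call_validated_variants()] table.
#' @return List of `contig_cluster` objects (`cluster_id`, `members`,
#'   `n_reads`, `signature`, `span`), ordered by decreasing size.
#' @export
cluster_reads <- function(pileup, params = distinctness_params(),
                          variants = NULL) {
  if (nrow(pileup$mat) == 0L) return(list())
  variants <- variants %||% call_validated_variants(pileup, params)
  sites <- sort(unique(variants$pos))
  ns <- length(sites)
  mat <- pileup$mat
  ids <- rownames(mat)
  ref_site_base <- pileup$ref_base[sites + 1L]
  rs <- stats::setNames(pileup$placements$ref_start, pileup$placements$read_id)
  re <- stats::setNames(pileup$placements$ref_end, pileup$placements$read_id)

  # per-read calls at validated sites: validated alt bases stand, anything
  # else (unvalidated alt = presumed error) counts as the reference base
  callmat <- matrix(NA_character_, length(ids), ns, dimnames = list(ids, NULL))
  if (ns > 0L) {
    smat <- mat[, sites + 1L, drop = FALSE]
    valid <- split(variants$base, factor(variants$pos, levels = sites))
    for (s in seq_len(ns)) {
      col <- smat[, s]
      cov <- col %in% DNA_BASES
      callmat[cov, s] <- ifelse(col[cov] %in% valid[[s]], col[cov],
                                ref_site_base[s])
    }
  }
  # Seed haplotype groups greedily: reads in decreasing covered-site order.
  # A read joins the best group it is statistically compatible with (the
  # read-vs-group discordance at shared validated sites is explainable by
  # sequencing error at rate epsilon over the columns the read shares with
  # the group); "best" maximizes agreeing sites, then minimizes discordance,
  # then prefers the larger, earlier group. Incompatible reads found new
  # groups; reads covering no validated site form the reference-signature
  # group. Statistical merging below consolidates the groups.
  base_idx <- stats::setNames(1:4, DNA_BASES)
  covmat <- !is.na(mat)                       # read x column coverage
  n_cov <- if (ns > 0L) rowSums(!is.na(callmat)) else rep(0L, length(ids))
  tail_p <- function(m, L) stats::pbinom(m - 1L, L, params$epsilon,
                                         lower.tail = FALSE)
  groups <- list()     # each: members, cnt (ns x 4), colcov (column counts)
  orphans <- character(0)
  for (i in order(-n_cov, ids)) {
    id <- ids[i]
    cov <- if (ns > 0L) which(!is.na(callmat[id, ])) else integer(0)
    if (length(cov) == 0L) { orphans <- c(orphans, id); next }
    best <- NULL
    for (g in seq_along(groups)) {
      gc <- groups[[g]]$cnt
      shared <- cov[rowSums(gc)[cov] > 0L]
      if (length(shared) == 0L) next
      maj <- .majority_calls(gc[shared, , drop = FALSE], ref_site_base[shared])
      m <- sum(callmat[id, shared] != maj)
      if (m > 0L) {
        Lsh <- sum(covmat[id, ] & groups[[g]]$colcov > 0L)
        if (tail_p(m, max(Lsh, 1L)) < params$alpha) next   # incompatible
      }
      agree <- length(shared) - m
      cand <- c(agree, -m, length(groups[[g]]$members), -g)
      if (is.null(best)) best <- list(g = g, key = cand)
      else {
        q <- which(cand != best$key)[1L]
        if (!is.na(q) && cand[q] > best$key[q]) best <- list(g = g, key = cand)
      }
    }
    if (!is.null(best)) {
      g <- best$g
      groups[[g]]$members <- c(groups[[g]]$members, id)
      for (s in cov) groups[[g]]$cnt[s, base_idx[[callmat[id, s]]]] <-
          groups[[g]]$cnt[s, base_idx[[callmat[id, s]]]] + 1L
      groups[[g]]$colcov <- groups[[g]]$colcov + covmat[id, ]
    } else {
      cnt <- matrix(0L, ns, 4L)
      for (s in cov) cnt[s, base_idx[[callmat[id, s]]]] <- 1L
      groups[[length(groups) + 1L]] <- list(members = id, cnt = cnt,
                                            colcov = as.integer(covmat[id, ]))
    }
  }
  if (length(orphans)) {
    groups[[length(groups) + 1L]] <- list(
      members = orphans, cnt = matrix(0L, ns, 4L),
      colcov = as.integer(colSums(covmat[orphans, , drop = FALSE])))
  }
  cl <- lapply(groups, function(g) {
    list(members = g$members, size = length(g$members), cnt = g$cnt,
         colcov = g$colcov, maj = NULL)
  })
  maj_of <- function(x) {
    if (is.null(x$maj)) x$maj <- .majority_calls(x$cnt, ref_site_base)
    x
  }
  site_col <- sites + 1L
  distinct <- function(a, b) {
    both_cov <- a$colcov > 0L & b$colcov > 0L
    Lov <- sum(both_cov)
    if (Lov == 0L) return(FALSE)
    m <- 0L
    if (ns > 0L) {
      ca <- a$maj; cb <- b$maj
      both <- both_cov[site_col] & !is.na(ca) & !is.na(cb)
      m <- sum(ca[both] != cb[both])
    }
    tail_p(m, Lov) < params$alpha
  }
  cl <- lapply(cl, maj_of)
  repeat {
    k <- length(cl)
    if (k <= 1L) break
    sizes <- vapply(cl, `[[`, 0L, "size")
    first <- vapply(cl, function(x) sort(x$members)[1L], "")
    ord <- order(-sizes, first)
    merged <- FALSE
    for (ii in seq_len(k - 1L)) {
      a <- ord[ii]
      for (jj in (ii + 1L):k) {
        b <- ord[jj]
        if (!distinct(cl[[a]], cl[[b]])) {
          cl[[a]]$members <- c(cl[[a]]$members, cl[[b]]$members)
          cl[[a]]$size <- cl[[a]]$size + cl[[b]]$size
          cl[[a]]$cnt <- cl[[a]]$cnt + cl[[b]]$cnt
          cl[[a]]$colcov <- cl[[a]]$colcov + cl[[b]]$colcov
          cl[[a]]$maj <- NULL
          cl[[a]] <- maj_of(cl[[a]])
          cl[[b]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }

  ord <- order(-vapply(cl, `[[`, 0L, "size"),
               vapply(cl, function(x) sort(x$members)[1L], ""))
  cl <- cl[ord]
  lapply(seq_along(cl), function(k) {
    x <- cl[[k]]
    mem <- sort(x$members)
    calls <- .majority_calls(x$cnt, ref_site_base)
    non_ref <- which(!is.na(calls) & calls != ref_site_base)
    sig <- data.frame(
      pos = sites[non_ref], base = calls[non_ref],
      support = vapply(non_ref, function(s)
        x$cnt[s, base_idx[[calls[s]]]], 0L),
      stringsAsFactors = FALSE)
    structure(list(cluster_id = sprintf("c%03d", k), members = mem,
                   n_reads = x$size, signature = sig,
                   span = c(min(rs[mem]), max(re[mem]))),
              class = "contig_cluster")
  })
}

#' @export
print.contig_cluster <- function(x, ...) {
  cat(sprintf("<contig_cluster> %s: %d reads, %d signature site(s), span [%d, %d)\n",
              x$cluster_id, x$n_reads, nrow(x$signature), x$span[1], x$span[2]))
  invisible(x)
}

#' Retain the clusters accounting for ~95% of assembled reads
#'
#' Clusters are sorted by read count (descending, ties by id) and the
#' shortest prefix whose cumulative share of placed reads reaches
#' `trim_fraction` is retained. This removes sparsely supported clusters
#' whose apparent sequence differences are most plausibly orphan sequencing
#' errors.
#'
#' @param clusters List of clusters from [cluster_reads()].
#' @param params A [distinctness_params()].
#' @return The retained clusters, in the sorted order.
#' @export
trim_clusters <- function(clusters, params = distinctness_params()) {
  if (length(clusters) == 0L) return(clusters)
  n <- vapply(clusters, `[[`, 0L, "n_reads")
  id <- vapply(clusters, `[[`, "", "cluster_id")
  ord <- order(-n, id)
  cum <- cumsum(n[ord]) / sum(n)
  keep <- seq_len(which(cum >= params$trim_fraction)[1L])
  clusters[ord[keep]]
}

#' Estimate the minimum number of gene copies for one toxin family
#'
#' Full copy-number procedure for the ORF-coding reads of one family in one
#' species: reference-guided pileup, variant validation, error-rate-aware
#' clustering, and retention of the clusters holding ~95% of placed reads.
#' The number of retained clusters is a lower bound on the number of distinct
#' genes of the family transcribed in the venom gland.
#'
#' @param reads Named character vector of ORF-coding reads (possibly empty).
#' @param reference Family reference mRNA (character or gene model).
#' @param params A [distinctness_params()].
#' @param align_params A [homology_params()].
#' @return Object of class `min_gene_estimate`: `count`, `clusters` (all),
#'   `retained` (ids), `distribution` (data frame `cluster_id`, `n_reads`,
#'   `retained`), `n_placed`, `n_unplaced`.
#' @export
estimate_min_genes <- function(reads, reference,
                               params = distinctness_params(),
                               align_params = homology_params()) {
  if (length(reads) == 0L)
    return(structure(list(count = 0L, clusters = list(), retained = character(0),
                          distribution = data.frame(cluster_id = character(0),
                                                    n_reads = integer(0),
                                                    retained = logical(0)),
                          n_placed = 0L, n_unplaced = 0L, params = params),
                     class = "min_gene_estimate"))
  pile <- build_pileup(reads, reference, align_params)
  clusters <- cluster_reads(pile, params)
  retained <- trim_clusters(clusters, params)
  rid <- vapply(retained, `[[`, "", "cluster_id")
  dist <- data.frame(
    cluster_id = vapply(clusters, `[[`, "", "cluster_id"),
    n_reads = vapply(clusters, `[[`, 0L, "n_reads"),
    stringsAsFactors = FALSE)
  dist$retained <- dist$cluster_id %in% rid
  structure(list(count = length(retained), clusters = clusters,
                 retained = rid, distribution = dist,
                 n_placed = nrow(pile$mat),
                 n_unplaced = length(pile$unplaced), params = params),
            class = "min_gene_estimate")
}

#' @export
print.min_gene_estimate <- function(x, ...) {
  cat(sprintf("<min_gene_estimate> %d gene cop%s (%d cluster(s) before trimming; %d reads placed)\n",
              x$count, if (x$count == 1L) "y" else "ies",
              length(x$clusters), x$n_placed))
  if (nrow(x$distribution))
    print(utils::head(x$distribution, 10L), row.names = FALSE)
  invisible(x)
}

#' Write a cluster report TSV
#'
#' One row per cluster: species, family, cluster id, read count, number of
#' signature sites, and whether the cluster survived the 95% trimming. Backs
#' "reads per contig vs number of contigs" plots.
#'
#' @param estimates Named list (or list of lists) of `min_gene_estimate`
#'   objects; names like `"species|family"`, or provide `species`/`family`.
#' @param species,family Character vectors parallel to `estimates`.
#' @param path Output file.
#' @export
write_cluster_report <- function(estimates, species, family, path) {
  rows <- NULL
  for (k in seq_along(estimates)) {
    est <- estimates[[k]]
    for (cl in est$clusters) {
      rows <- rbind(rows, data.frame(
        species = species[k], family = family[k],
        cluster_id = cl$cluster_id, n_reads = cl$n_reads,
        n_signature_sites = nrow(cl$signature),
        retained = cl$cluster_id %in% est$retained,
        stringsAsFactors = FALSE))
    }
  }
  rows <- rows %||% data.frame(species = character(0), family = character(0),
                               cluster_id = character(0), n_reads = integer(0),
                               n_signature_sites = integer(0),
                               retained = logical(0))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
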