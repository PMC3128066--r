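#' Family read percentages
#'
#' Share of venom-protein reads per toxin family: `100 * R_i / sum(R)`.
#' Scale-invariant in the counts.
#'
#' @param counts Named non-negative numeric vector of per-family read counts.
#' @param digits Optional rounding (report tables use 1 decimal).
#' @return Named numeric vector of percentages summing to 100.
#' @export
#' @examples
#' reads_percent(c(SVMP = 300, PLA2 = 100))
reads_percent <- function(counts, digits = NULL) {
  if (any(counts < 0)) stop("counts must be >= 0")
  if (sum(counts) == 0) stop("all counts are zero")
  pct <- 100 * counts / sum(counts)
  if (!is.null(digits)) pct <- round(pct, digits)
  pct
}

#' Family mol percentages (length-normalized abundance)
#'
#' Molar share of each family: read counts are divided by the full-length
#' reference transcript length (`ntREF`, nucleotides) before normalization,
#' so that long transcripts, which attract more reads per mRNA molecule, are
#' not over-weighted. The default (`normalized = TRUE`) reports
#' `100 * (R_i/ntREF_i) / sum_j (R_j/ntREF_j)`, which sums to 100 across
#' families; `normalized = FALSE` gives the literal per-family form
#' `100 * (R_i/ntREF_i) / sum_j R_j`, which does not.
#'
#' @param counts Named per-family read counts.
#' @param ntref Named reference transcript lengths (nt), covering every
#'   family with a positive count.
#' @param normalized Report the normalized (sums-to-100) form?
#' @export
#' @examples
#' mol_percent(c(A = 100, B = 100), c(A = 500, B = 1000))
mol_percent <- function(counts, ntref, normalized = TRUE) {
  if (any(counts < 0)) stop("counts must be >= 0")
  if (sum(counts) == 0) stop("all counts are zero")
  need <- names(counts)[counts > 0]
  miss <- setdiff(need, names(ntref))
  if (length(miss))
    stop("missing ntREF for counted families: ", paste(miss, collapse = ", "))
  if (any(ntref[need] <= 0)) stop("ntREF lengths must be > 0")
  w <- counts
  w[need] <- counts[need] / ntref[need]
  w[setdiff(names(counts), need)] <- 0
  if (normalized) 100 * w / sum(w) else 100 * w / sum(counts)
}

#' Per-species family abundance table
#'
#' Bundles the raw count matrix with its reads% and mol% views.
#'
#' @param counts Species x family matrix of read counts.
#' @param ntref Named reference lengths per family.
#' @return Object of class `abundance_table`: `counts`, `reads_pct`,
#'   `mol_pct` (row-wise percentages), `ntref`.
#' @export
abundance_table <- function(counts, ntref) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have species rownames and family colnames")
  reads_pct <- t(apply(counts, 1L, reads_percent))
  mol_pct <- t(apply(counts, 1L, mol_percent, ntref = ntref))
  structure(list(counts = counts, reads_pct = reads_pct, mol_pct = mol_pct,
                 ntref = ntref[colnames(counts)]),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d species x %d families (%d reads)\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  print(round(x$reads_pct, 1))
  invisible(x)
}

#' Run-level annotation statistics
#'
#' Summarizes an annotation run: how many masked reads produced significant
#' hits, how many of those hits are venom proteins, and the ORF/UTR/
#' microsatellite region breakdown of the toxin hits.
#'
#' @param n_masked_reads Number of masked reads searched.
#' @param n_hits Number of reads with a significant hit.
#' @param n_venom Number of hits to documented venom proteins.
#' @param n_serpentes Optional number of snake-taxon hits.
#' @param region_tally Optional named vector of toxin-hit region counts.
#' @return Object of class `annotation_stats` with the tallies and the
#'   derived percentages `pct_hits` (of masked reads) and
#'   `pct_venom_of_hits`.
#' @export
#' @examples
#' annotation_stats(330010, 100394, 62433)
annotation_stats <- function(n_masked_reads, n_hits, n_venom = NA,
                             n_serpentes = NA, region_tally = NULL) {
  structure(
    list(n_masked_reads = n_masked_reads, n_hits = n_hits,
         n_serpentes = n_serpentes, n_venom = n_venom,
         pct_hits = if (n_masked_reads > 0) 100 * n_hits / n_masked_reads else 0,
         pct_venom_of_hits = if (!is.na(n_venom) && n_hits > 0)
           100 * n_venom / n_hits else NA_real_,
         region_tally = region_tally),
    class = "annotation_stats")
}

#' @export
print.annotation_stats <- function(x, ...) {
  cat(sprintf("<annotation_stats> %s of %s masked reads hit (%.1f%%)",
              format(x$n_hits, big.mark = ","),
              format(x$n_masked_reads, big.mark = ","), x$pct_hits))
  if (!is.na(x$n_venom))
    cat(sprintf("; %s venom-protein reads (%.0f%% of hits)",
                format(x$n_venom, big.mark = ","), x$pct_venom_of_hits))
  cat("\n")
  if (!is.null(x$region_tally)) {
    cat("  regions:", paste(sprintf("%s=%d", names(x$region_tally),
                                    x$region_tally), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Compare a transcriptome with a proteome
#'
#' Three aligned abundance views for one species: (b) mol% over all toxin
#' families; (c) mol% renormalized over the families actually detected in the
#' venom proteome; (d) reads% of all venom-protein hits; plus the per-family
#' difference between view (c) and the proteome. Discordance between (c) and
#' the proteome is the footprint of family-specific translational control.
#'
#' @param counts Named per-family transcriptome read counts.
#' @param ntref Named reference lengths.
#' @param proteome Named numeric vector of proteome family percentages
#'   (families absent from the venom may be omitted or set to 0).
#' @return Object of class `proteome_comparison`: `mol_all` (view b),
#'   `mol_proteome_families` (view c), `reads_pct` (view d), `proteome`,
#'   `difference` (view c minus proteome over its families).
#' @export
compare_with_proteome <- function(counts, ntref, proteome) {
  unknown <- setdiff(names(proteome), names(counts))
  if (length(unknown))
    stop("proteome families not in the transcriptome table: ",
         paste(unknown, collapse = ", "))
  b <- mol_percent(counts, ntref)
  present <- names(proteome)[proteome > 0]
  cc <- counts[intersect(names(counts), present)]
  if (sum(cc) == 0) stop("no transcriptome reads in proteome-present families")
  c_view <- mol_percent(cc, ntref)
  d <- reads_percent(counts)
  prot_al <- proteome[names(c_view)]
  structure(list(mol_all = b, mol_proteome_families = c_view, reads_pct = d,
                 proteome = proteome,
                 difference = c_view - 100 * prot_al / sum(prot_al)),
            class = "proteome_comparison")
}

#' @export
print.proteome_comparison <- function(x, ...) {
  cat("<proteome_comparison>\n")
  fams <- names(x$mol_proteome_families)
  tab <- data.frame(family = fams,
                    mol_pct = round(x$mol_proteome_families, 1),
                    proteome_pct = round(x$proteome[fams], 1),
                    difference = round(x$difference, 1))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' PCA of a family-abundance matrix
#'
#' Principal component analysis of a species x family percentage (or count)
#' matrix. Columns are centered and, by default, scaled to unit variance
#' (autoscaling), so rare families contribute on the same footing as
#' dominant ones; `scale = FALSE` analyzes the covariance structure instead.
#' Zero-variance columns are dropped before autoscaling.
#'
#' @param x Matrix with at least 3 rows (species) and 2 columns (families).
#' @param scale Autoscale columns to unit variance?
#' @return Object of class `abundance_pca`: `scores` (species x PC),
#'   `loadings` (families x PC), `variance_explained` (percent per PC,
#'   summing to 100), `scaled`.
#' @export
pca_abundance <- function(x, scale = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 3L || ncol(x) < 2L)
    stop("need at least 3 rows and 2 columns")
  v <- apply(x, 2L, stats::var)
  if (all(v == 0)) stop("matrix is constant: no variance to decompose")
  if (scale) x <- x[, v > 0, drop = FALSE]
  p <- stats::prcomp(x, center = TRUE, scale. = scale)
  ve <- 100 * p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = p$x, loadings = p$rotation,
                 variance_explained = ve, scaled = scale),
            class = "abundance_pca")
}

#' @export
print.abundance_pca <- function(x, ...) {
  cat(sprintf("<abundance_pca> %d components (%sscaled); variance explained: %s\n",
              length(x$variance_explained), if (x$scaled) "auto" else "un",
              paste(sprintf("PC%d=%.1f%%", seq_len(min(4, length(x$variance_explained))),
                            x$variance_explained[seq_len(min(4, length(x$variance_explained)))]),
                    collapse = ", ")))
  invisible(x)
}
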