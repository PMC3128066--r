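#' Concatenate per-family consensus sequences for one species
#'
#' Joins the five shared-family consensus sequences in the canonical order
#' (BPP, LAO, PLA2, SVMP, SP) regardless of input order. Fixed positions
#' contribute their residue; variable positions contribute their first listed
#' residue (the full set is kept as an annotation); low-confidence and
#' unknown positions are marked missing.
#'
#' @param cons_list Named list of [call_consensus()] results, keyed by family
#'   acronym; must contain every family of `order`.
#' @param species Species label.
#' @param order Family order (default [concatenation_order()]).
#' @return Object of class `concat_sequence`: `species`, `residues`
#'   (character vector, `NA` = missing), `boundaries` (named end offsets per
#'   segment, half-open), `variable_sites` (data frame `family`, `pos`,
#'   `residues`).
#' @export
concatenate_consensus <- function(cons_list, species = NA_character_,
                                  order = concatenation_order()) {
  missing_fams <- setdiff(order, names(cons_list))
  if (length(missing_fams))
    stop("missing consensus for famil",
         if (length(missing_fams) > 1) "ies: " else "y: ",
         paste(missing_fams, collapse = ", "))
  residues <- character(0)
  bounds <- integer(0)
  varsites <- NULL
  for (fam in order) {
    cons <- cons_list[[fam]]
    residues <- c(residues, cons$representative)
    bounds[fam] <- length(residues)
    vs <- cons$calls[cons$calls$class == "variable", , drop = FALSE]
    if (nrow(vs))
      varsites <- rbind(varsites, data.frame(family = fam, pos = vs$pos,
                                             residues = vs$residues,
                                             stringsAsFactors = FALSE))
  }
  structure(list(species = species, residues = residues, boundaries = bounds,
                 variable_sites = varsites %||%
                   data.frame(family = character(0), pos = integer(0),
                              residues = character(0))),
            class = "concat_sequence")
}

#' @export
print.concat_sequence <- function(x, ...) {
  cat(sprintf("<concat_sequence> %s: %d positions (%d missing) over segments %s\n",
              x$species, length(x$residues), sum(is.na(x$residues)),
              paste(names(x$boundaries), collapse = "+")))
  invisible(x)
}

# coerce to residue vector with NA for missing (lowercase/gap/X)
.as_residues <- function(x) {
  if (inherits(x, "concat_sequence")) return(x$residues)
  if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "")[[1]]
  x[x %in% c("-", ".", "X", "x")] <- NA_character_
  low <- !is.na(x) & x %in% letters
  x[low] <- NA_character_
  x
}

#' Poisson-corrected pairwise distance
#'
#' Proportion of differing residues `p` over the positions comparable in both
#' sequences (pairwise deletion of missing positions and gaps), corrected for
#' multiple hits as `d = -ln(1 - p)`, so that `d = 0.1` corresponds to ~10%
#' sequence divergence. Sequences of unequal length are first aligned
#' globally (Needleman-Wunsch, BLOSUM62, affine gaps).
#'
#' @param a,b `concat_sequence` objects, residue vectors, or strings
#'   (lowercase and `-`/`.`/`X` treated as missing).
#' @param params A [homology_params()] (used only when global alignment is
#'   required).
#' @return Non-negative distance; 0 for identical sequences.
#' @export
#' @examples
#' pairwise_distance("AAAAAAAAAA", "AAAAAAAAAC")   # p = 0.1
pairwise_distance <- function(a, b, params = homology_params()) {
  ra <- .as_residues(a); rb <- .as_residues(b)
  if (length(ra) != length(rb)) {
    sa <- paste(ifelse(is.na(ra), "X", ra), collapse = "")
    sb <- paste(ifelse(is.na(rb), "X", rb), collapse = "")
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(sa), Biostrings::AAString(sb), type = "global",
      substitutionMatrix = .blosum62(),
      gapOpening = params$gap_open, gapExtension = params$gap_ext)
    ra <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    rb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    ra[ra %in% c("-", "X")] <- NA_character_
    rb[rb %in% c("-", "X")] <- NA_character_
  }
  comp <- !is.na(ra) & !is.na(rb)
  if (!any(comp)) stop("no comparable positions between the two sequences")
  p <- mean(ra[comp] != rb[comp])
  if (p >= 1) stop("sequences are saturated (p = 1); distance undefined")
  -log(1 - p)
}

#' Distance matrix over concatenated consensus sequences
#'
#' @param concats Named list of `concat_sequence` objects (or residue
#'   vectors/strings).
#' @param params A [homology_params()].
#' @return Symmetric matrix with zero diagonal, labelled by names.
#' @export
distance_matrix <- function(concats, params = homology_params()) {
  n <- length(concats)
  labs <- names(concats) %||% paste0("taxon", seq_len(n))
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    D[i, j] <- D[j, i] <- pairwise_distance(concats[[i]], concats[[j]], params)
  }
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a symmetric distance matrix. Negative
#' branch lengths are clamped to zero with the deficit moved to the adjacent
#' branch of the joined pair (total pair distance preserved). Ties in the
#' Q-criterion are broken by taxon label order, making the topology
#' deterministic and invariant under input permutation.
#'
#' @param D Symmetric numeric matrix with taxon labels as dimnames and zero
#'   diagonal; at least 3 taxa.
#' @return An unrooted `phylo` tree (ape) with branch lengths.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("diagonal must be zero")
  labs <- rownames(D) %||% paste0("t", seq_len(n))
  # working state: newick fragment and sort key per active node
  frag <- stats::setNames(labs, labs)
  key <- stats::setNames(labs, labs)
  rownames(D) <- colnames(D) <- labs
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  while (nrow(D) > 3L) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    ck <- apply(cand, 1L, function(ij) {
      ks <- sort(c(key[rownames(D)[ij[1]]], key[rownames(D)[ij[2]]]))
      paste(ks, collapse = "\r")
    })
    pick <- cand[order(ck)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    d_ij <- D[i, j]
    vi <- 0.5 * d_ij + (R[i] - R[j]) / (2 * (r - 2))
    vj <- d_ij - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    li <- rownames(D)[i]; lj <- rownames(D)[j]
    new_lab <- paste0("(", frag[li], ":", fmt(vi), ",",
                      frag[lj], ":", fmt(vj), ")")
    new_key <- min(key[li], key[lj])
    du <- 0.5 * (D[i, ] + D[j, ] - d_ij)
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    nid <- paste0("node", r)
    rownames(D2) <- colnames(D2) <- c(rownames(D)[keep], nid)
    D <- D2
    frag <- c(frag[rownames(D)[seq_len(r - 2L)]], stats::setNames(new_lab, nid))
    key <- c(key[rownames(D)[seq_len(r - 2L)]], stats::setNames(new_key, nid))
  }
  l3 <- rownames(D)
  va <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  vb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  vc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  ord <- order(key[l3])
  parts <- paste0(frag[l3], ":", vapply(c(va, vb, vc), fmt, ""))
  nwk <- paste0("(", paste(parts[ord], collapse = ","), ");")
  ape::read.tree(text = nwk)
}

#' Write a distance matrix in square PHYLIP format
#' @param D Labelled symmetric matrix.
#' @param path Output file.
#' @export
write_phylip_dist <- function(D, path) {
  labs <- sprintf("%-10s", substr(rownames(D), 1L, 10L))
  lines <- c(sprintf("%5d", nrow(D)),
             vapply(seq_len(nrow(D)), function(i)
               paste0(labs[i], paste(sprintf("%.6f", D[i, ]), collapse = "  ")),
               ""))
  writeLines(lines, path)
  invisible(path)
}
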