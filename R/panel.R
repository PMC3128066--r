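# Bundled synthetic toxin reference panel.
#
# One full-length exemplar mRNA per toxin family (plus coding and non-coding
# non-toxin entries), generated deterministically in code. The sequences are
# synthetic stand-ins for database references: CDS lengths are chosen near the
# precursor lengths typical of each family, and the families that in real
# venom-gland data are dominated by microsatellite-bearing transcripts carry a
# tandem-repeat tract in their 3'UTR.

.panel_family_spec <- function() {
  data.frame(
    family = c("BPP", "CRISP", "CTL", "GF", "LAO", "PLA2", "SVMP", "SP",
               "5NTase", "PDE", "GC", "CVF", "CRO", "SARA", "WAP", "KUN",
               "KAZ", "HYA", "OHA", "3FTx"),
    cds_len = c(750L, 723L, 462L, 390L, 1548L, 414L, 1833L, 783L,
                1734L, 1800L, 1089L, 1800L, 198L, 186L, 300L, 270L,
                255L, 1356L, 564L, 273L),
    utr3_len = c(250L, 300L, 250L, 350L, 250L, 300L, 300L, 350L,
                 250L, 250L, 250L, 300L, 350L, 350L, 250L, 250L,
                 250L, 250L, 400L, 400L),
    microsat = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE,
                 FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE,
                 FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

#' Build the bundled reference panel
#'
#' Constructs the synthetic reference panel used for homology assignment: one
#' full-length exemplar per toxin family (deterministic; identical on every
#' call), optionally restricted to a subset of families, plus non-toxin
#' entries (protein disulphide isomerase and two rRNAs) so that non-toxin
#' reads are representable without external databases.
#'
#' @param families Character vector of family acronyms (default: all 20).
#' @param include_nontoxin Include the non-toxin entries?
#' @return Object of class `reference_panel`: list with `table` (data frame
#'   `ref_id`, `family`, `description`, `class`, `length`, `cds_start`,
#'   `cds_end`), `sequences` and `proteins` (named character vectors), and
#'   `models` (the underlying gene models for coding entries).
#' @export
#' @examples
#' panel <- reference_panel(c("SVMP", "PLA2"))
#' panel$table
reference_panel <- function(families = NULL, include_nontoxin = TRUE) {
  spec <- .panel_family_spec()
  families <- families %||% spec$family
  bad <- setdiff(families, spec$family)
  if (length(bad)) stop("unknown families: ", paste(bad, collapse = ", "))
  spec <- spec[match(families, spec$family), ]
  fam_names <- toxin_families()
  models <- list(); rows <- NULL
  for (k in seq_len(nrow(spec))) {
    fam <- spec$family[k]
    idx <- match(fam, .panel_family_spec()$family)
    g <- simulate_gene_family(fam, 1L, 0, cds_len = spec$cds_len[k],
                              utr3_len = spec$utr3_len[k],
                              microsat = spec$microsat[k],
                              seed = 9000L + idx, utr5_len = 60L)[[1L]]
    g$gene_id <- paste0(fam, "_ref1")
    models[[g$gene_id]] <- g
    rows <- rbind(rows, data.frame(
      ref_id = g$gene_id, family = fam,
      description = fam_names$description[match(fam, fam_names$family)],
      class = "toxin", length = nchar(g$mrna),
      cds_start = g$cds[1], cds_end = g$cds[2], stringsAsFactors = FALSE))
  }
  if (include_nontoxin) {
    pdi <- simulate_gene_family("PDI", 1L, 0, cds_len = 1527L, utr3_len = 150L,
                                microsat = FALSE, seed = 9100L, utr5_len = 60L)[[1L]]
    pdi$gene_id <- "PDI_ref1"
    models[["PDI_ref1"]] <- pdi
    rows <- rbind(rows, data.frame(
      ref_id = "PDI_ref1", family = "PDI",
      description = "Protein disulphide isomerase", class = "non_toxin",
      length = nchar(pdi$mrna), cds_start = pdi$cds[1], cds_end = pdi$cds[2],
      stringsAsFactors = FALSE))
    rrna <- with_seed(9200L, list(rRNA12S = random_dna(950L),
                                  rRNA16S = random_dna(1550L)))
    for (id in names(rrna)) {
      rows <- rbind(rows, data.frame(
        ref_id = id, family = sub("^rRNA", "", id),
        description = paste(sub("^rRNA", "", id), "ribosomal RNA"),
        class = "non_toxin", length = nchar(rrna[[id]]),
        cds_start = NA_integer_, cds_end = NA_integer_,
        stringsAsFactors = FALSE))
    }
  } else rrna <- list()
  sequences <- c(stats::setNames(vapply(models, `[[`, "", "mrna"), names(models)),
                 unlist(rrna))
  proteins <- stats::setNames(vapply(models, `[[`, "", "protein"), names(models))
  structure(list(table = rows, sequences = sequences[rows$ref_id],
                 proteins = proteins, models = models),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("<reference_panel> %d entries (%d toxin, %d non-toxin), %d nt total\n",
              nrow(x$table), sum(x$table$class == "toxin"),
              sum(x$table$class != "toxin"), sum(x$table$length)))
  invisible(x)
}

#' Reference transcript lengths per toxin family
#'
#' Full-length reference transcript length (nucleotides) of each toxin
#' family's exemplar, used to length-normalize read counts into mol%.
#'
#' @param panel A [reference_panel()].
#' @return Named integer vector, one entry per toxin family in the panel.
#' @export
ntref <- function(panel) {
  tox <- panel$table[panel$table$class == "toxin", ]
  tox <- tox[!duplicated(tox$family), ]
  stats::setNames(tox$length, tox$family)
}

#' Write a reference panel as FASTA plus annotation TSV
#' @param panel A `reference_panel`.
#' @param fasta_path,tsv_path Output files.
#' @export
write_panel <- function(panel, fasta_path, tsv_path) {
  write_fasta(panel$sequences, fasta_path)
  utils::write.table(panel$table, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(fasta_path)
}

#' Read a reference panel from FASTA plus annotation TSV
#'
#' The annotation TSV must carry `ref_id`, `family`, `class`, `cds_start`,
#' `cds_end` (0-based half-open; NA for non-coding entries). Proteins are
#' re-derived by translating the CDS.
#'
#' @param fasta_path,tsv_path Input files, as written by [write_panel()].
#' @return A `reference_panel`.
#' @export
read_panel <- function(fasta_path, tsv_path) {
  seqs <- read_fasta(fasta_path)
  tab <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  if (!all(tab$ref_id %in% names(seqs)))
    stop("annotation refers to sequences absent from the FASTA")
  tab$length <- nchar(seqs[tab$ref_id])
  proteins <- character(0); models <- list()
  for (k in which(!is.na(tab$cds_start))) {
    id <- tab$ref_id[k]
    g <- toxin_gene_model(id, tab$family[k], 1L, seqs[[id]],
                          c(tab$cds_start[k], tab$cds_end[k]))
    models[[id]] <- g
    proteins[id] <- g$protein
  }
  structure(list(table = tab, sequences = seqs[tab$ref_id],
                 proteins = proteins, models = models),
            class = "reference_panel")
}
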