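#' Toxin family catalogue
#'
#' The twenty venom-protein family classes used throughout the package, with
#' their full names. Family acronyms are the standard snake-venom abbreviations
#' (SVMP, PLA2, BPP, ...). `"5NTase"` and `"3FTx"` stand for 5'-nucleotidase and
#' three-finger toxin.
#'
#' @return A data frame with columns `family` (acronym) and `description`.
#' @export
#' @examples
#' toxin_families()
toxin_families <- function() {
  data.frame(
    family = c("BPP", "CRISP", "CTL", "GF", "LAO", "PLA2", "SVMP", "SP",
               "5NTase", "PDE", "GC", "CVF", "CRO", "SARA", "WAP", "KUN",
               "KAZ", "HYA", "OHA", "3FTx"),
    description = c(
      "Bradykinin potentiating peptide",
      "Cysteine-rich secretory peptide",
      "C-type lectin-like protein",
      "Growth factor",
      "L-amino acid oxidase",
      "Phospholipase A2",
      "Metalloproteinase",
      "Serine proteinase",
      "5'-nucleotidase",
      "Phosphodiesterase",
      "Glutaminyl cyclase",
      "Cobra venom factor",
      "Crotamine",
      "Sarafotoxin",
      "Waprin",
      "Kunitz-type inhibitor",
      "Kazal-type inhibitor",
      "Hyaluronidase",
      "Ohanin",
      "Three-finger toxin"),
    stringsAsFactors = FALSE
  )
}

# acronym vector, used internally for validation
.toxin_family_labels <- function() toxin_families()$family

#' Concatenation order of the major shared toxin families
#'
#' The five toxin families present in every venom-gland transcriptome, in the
#' fixed order used when building species-level concatenated consensus
#' sequences for cladistic analysis.
#'
#' @return Character vector `c("BPP", "LAO", "PLA2", "SVMP", "SP")`.
#' @export
concatenation_order <- function() c("BPP", "LAO", "PLA2", "SVMP", "SP")
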