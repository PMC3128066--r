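# Bundled survey tables: venom-protein read tallies from a multiplexed 454
# venom-gland transcriptome survey of eight Costa Rican pitviper taxa
# (Crotalus simus, Bothrops asper Caribbean/Pacific, Cerrophidion godmani,
# Atropoides picadoi, A. mexicanus, Bothriechis schlegelii, B. lateralis).
# These are inputs for abundance/PCA computations, not package results.

#' Whole-run venom-protein read counts per toxin family
#'
#' Read tallies (and the published percentage column) for the twenty toxin
#' families across the pooled eight-species venom-gland run.
#'
#' @return Data frame `family`, `reads`, `pct`.
#' @export
run_family_read_counts <- function() {
  utils::read.delim(system.file("extdata", "run_family_read_counts.tsv",
                                package = "venomgland454"),
                    stringsAsFactors = FALSE)
}

#' Per-species venom-protein read counts per toxin family
#'
#' Long-format read tallies and published percentage columns for each of the
#' eight species.
#'
#' @return Data frame `species`, `family`, `reads`, `pct`.
#' @export
species_family_read_counts <- function() {
  utils::read.delim(system.file("extdata", "species_family_read_counts.tsv",
                                package = "venomgland454"),
                    stringsAsFactors = FALSE)
}

#' Species x family matrix view of the per-species table
#'
#' @param value `"pct"` (published percentages) or `"reads"` (counts).
#' @return 8 x 20 matrix, species as rows.
#' @export
species_family_matrix <- function(value = c("pct", "reads")) {
  value <- match.arg(value)
  long <- species_family_read_counts()
  sp <- unique(long$species); fam <- unique(long$family)
  m <- matrix(NA_real_, length(sp), length(fam), dimnames = list(sp, fam))
  m[cbind(match(long$species, sp), match(long$family, fam))] <- long[[value]]
  m
}
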