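---
title: "Methods: venom-gland transcriptome analysis on 454-style reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: venom-gland transcriptome analysis on 454-style reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameters and design decisions behind
the package, in the spirit of a methods supplement: what each stage assumes,
which knobs matter, why the defaults are what they are, and what the
simulation-based tests do and do not establish about real data.

## The analysis problem

Venom glands of pitvipers transcribe a few dozen multigene toxin families
(metalloproteinases, phospholipases A2, serine proteinases, bradykinin
potentiating peptides, ...). A multiplexed pyrosequencing run of
non-normalized, 3'-enriched cDNA libraries yields short (mean ~187 nt),
error-prone (~1.35% substitutions) reads tagged with 10-base MID barcodes.
From such a run one wants: per-species family abundances, a lower bound on
the number of distinct gene copies per family, per-family consensus protein
sequences, and a distance-based picture of how the species' transcriptomes
relate. Because reads are short and coverage is uneven, every stage must be
explicit about what sequencing error can and cannot explain.

## Demultiplexing and the error-rate proxy

A read is assigned iff its terminal 10-mer **exactly** matches one MID.
Exact matching is deliberate: any sequencing error inside the barcode makes
the read unassignable, so the unassigned fraction of a run directly
estimates the per-base error rate (10 bases per read; at a true rate of
1.35% per base roughly 1 in 75 barcodes carries an error). This run-level
estimate is the same ε used downstream by the copy-number test, which keeps
the pipeline's error model self-consistent. Edit-distance rescue of
barcodes would break that interpretation and is intentionally not offered.

## Repeat masking

RepeatMasker-with-Repbase is replaced by a self-contained detector because
the downstream analysis needs only two calls: *microsatellite* (perfect
tandem repeats, motif length 1–6, at least `min_copies = 3` copies and
`min_tract_nt = 12` total nucleotides) and *low complexity* (sliding
windows of `entropy_window = 25` nt whose A/C/G/T Shannon entropy falls
below `entropy_min = 1.0` bits). Masked positions become `N`; intervals are
maximal, half-open, 0-based, and microsatellite takes precedence where the
two classes overlap. Masking is idempotent at the sequence level: `N`
positions are excluded from both detectors. Interspersed repeats
(retroelements, DNA transposons) are out of scope; on real data the
masked fraction will therefore be lower than a full RepeatMasker run would
produce.

A read is *microsatellite-dominated* when ≥50% of its bases are masked as
microsatellite. Reads of that class that do align to a toxin reference are
reported under the `microsatellite` region rather than ORF/UTR. The 50%
threshold is conservative: such reads in real data are typically ~90–100%
repeat.

## Homology assignment

The panel search is exhaustive Smith–Waterman (affine gaps) rather than a
heuristic seeded search: the panel is tens of entries, so exactness is
affordable and removes the aligner as a source of variance. Scoring follows
BLAST conventions — BLOSUM62 with gap open 11 / extend 1 for translated
comparisons; +2/−3 with gap open 5 / extend 2 for nucleotide comparisons —
and raw scores are converted to E-values with bundled gapped
Karlin–Altschul constants (λ = 0.267, K = 0.041 for the protein scheme;
λ = 0.56, K = 0.21 for the nucleotide scheme), using the read (or frame
peptide) length as *m* and the summed panel length as *n*. The accepted
approximations: no sum statistics, no per-query λ fitting, and edge-effect
corrections are omitted. At the default cutoff `E ≤ 10⁻³` a shuffled read
has ~10⁻³ probability of a spurious hit, which the test suite verifies
empirically on dinucleotide shuffles.

The best hit is the minimum E-value over entries × modes × frames, ties
broken by higher raw score, then lexicographic reference id — a total order,
so assignment is deterministic. ORF vs UTR partitioning uses a majority
rule (>50% of the aligned reference interval inside the CDS → ORF;
otherwise the UTR side holding most of the non-CDS overlap, ties falling to
UTR3 in keeping with the 3'-biased library). A cysteine-rich scan (maximal
stop-free windows of 50–100 aa with ≥10% Cys, the structural signature
shared by many toxin scaffolds) is available as a second-round filter for
unassigned reads.

## Minimum gene copies

This is the package's core procedure and the place where the error model
does real work.

1. **Pileup.** ORF-coding reads of one family are placed on the family
   reference by local alignment; insertions relative to the reference are
   dropped and deletions leave columns uncovered. Reads not reaching the
   E-value cutoff against the reference are reported unplaced.
2. **Variant validation.** A (position, base) variant is validated iff
   ≥ `1 + min_support = 3` reads carry that identical base — i.e. the
   mutation is seen in a read *and at least two other reads*. At ε = 1.35%
   (≈ ε/3 per specific alternative base) the chance of three coincident
   identical errors at 20× coverage is ~10⁻³ per column, so validated sites
   are overwhelmingly genuine.
3. **Signature grouping.** Reads are grouped greedily in decreasing order
   of covered validated sites; a read joins the best group whose majority
   calls it matches up to statistically tolerable discordance (the same
   binomial test as below, applied read-vs-group), preferring the group
   with the most shared sites, then least discordance, then size. Reads
   covering no validated site form a reference-signature group. The greedy
   pass is deterministic and input-order-independent (reads are processed
   in a canonical order).
4. **Distinctness test.** Two clusters remain separate iff, over the `L`
   reference columns covered by both, their majority calls disagree at `m`
   validated sites with `P(X ≥ m | X ~ Binomial(L, ε)) < α` (defaults
   ε = 0.0135, α = 0.01). Merging proceeds pairwise in descending cluster
   size (ties by id) to a fixpoint. `L` counts columns actually covered in
   both clusters, not the span union — with 3'-biased coverage the two can
   differ substantially, and using covered columns matches what was
   actually compared.
5. **Trimming.** Clusters are sorted by read count and the shortest prefix
   holding ≥95% (`trim_fraction`) of placed reads is retained. This is what
   makes the estimate a *minimum*: sparsely supported clusters — orphan
   reads whose apparent differences are most plausibly error — do not
   count, and genuinely rare paralogs are knowingly sacrificed.

Two directional facts are worth stating explicitly. Raising α makes
separation *easier*, so the cluster count is non-decreasing in α; the test
suite asserts that direction. And the binomial test is conservative by
construction: it treats cluster-level majority calls as if they were single
error-bearing sequences, so paralog pairs whose true divergence is near
ε (≲ 3–4% over the compared span) are merged, lowering the count — the
correct behaviour for a lower-bound estimator.

Parameter recovery: the test suite simulates k ∈ {1..5} paralogs at 3–10%
divergence under the default gene geometry (60 nt 5'UTR, 450 nt CDS, 300 nt
3'UTR), ~20× per-paralog coverage and ε = 1.35%, and requires the estimate
to equal k in ≥90% of 50 seeded replicates per k. Observed failures are
concentrated at the 3% divergence edge, where the distinctness test merges
by design.

## Consensus calling

Per reference-protein position with `n` contributing residues, a residue
qualifies iff its count ≥ `min_reads = 4` **and** its share ≥
`min_frac = 0.30`; both thresholds are closed (count = 4 and share = 30%
qualify). One qualifying residue → fixed (uppercase); two or more →
variable (annotated as a bracketed set, suggesting allelic isoforms); none
→ lowercase plurality call (ties alphabetical; lowercase preserves the
observation while flagging low confidence); uncovered → unknown (`-`).
Only reads contributing a residue to a column count toward `n`: a read
spanning the column with a deletion or ambiguous (X) codon carries no
evidence for any residue there, so it does not dilute the shares of reads
that do. Frame choice per read is by best translated alignment against the
reference protein across all six frames.

## Abundance, mol% and PCA

reads% is the family share of venom-protein reads. mol% divides counts by
the family reference transcript length (ntREF, nucleotides) before
normalizing:

mol%ᵢ = 100·(Rᵢ/ntREFᵢ) / Σⱼ(Rⱼ/ntREFⱼ)

The normalized form is the default because it sums to 100 across families
and matches the molar-composition reading of abundance pie charts. The
literal unnormalized variant `100·(Rᵢ/ntREFᵢ)/ΣⱼRⱼ` — which does not sum
to 100 — is available behind `normalized = FALSE` for comparability.
Transcriptome–proteome comparison offers three aligned views: mol% over all
families, mol% renormalized over proteome-detected families only, and
reads% of all hits; the second view is the one to compare against the
proteome, and its per-family differences are the footprint of
family-specific translational control.

PCA treats species as observations and families as variables. Column
centering plus unit scaling (autoscaling) is the default so rare families
contribute on the same footing as the dominant ones; covariance PCA
(`scale = FALSE`) is the documented alternative and is dominated by the
high-variance SVMP/SP/BPP columns. Zero-variance columns are dropped before
autoscaling; a wholly constant matrix is an error, as is one with fewer
than 3 rows or 2 columns.

## Cladistics

Species-level sequences are the concatenation of the five shared-family
consensuses in the fixed order BPP, LAO, PLA2, SVMP, SP (the order is
canonical, not input-dependent). Variable positions contribute their first
listed residue; lowercase and unknown positions are missing data. Distances
are Poisson-corrected p-distances, `d = −ln(1−p)` with `p` computed under
pairwise deletion, chosen over a JTT/ProtDist-style matrix because it is
monotone in p, closed-form, and reads directly in "0.1 ≈ 10% divergence"
units; a full multiple alignment is unnecessary because the distance needs
only pairwise comparisons (sequences of equal length compare
position-by-position; unequal lengths are aligned globally first). The
tree is Saitou–Nei neighbor joining with two determinism guarantees:
Q-criterion ties are broken by taxon label order, and negative branch
lengths are clamped to zero with the deficit moved to the sibling branch
(preserving the pair distance). On additive matrices the implementation
recovers the generating topology and branch lengths exactly; the test
suite cross-checks topologies against an independent NJ implementation.

## The read simulator

The simulator exists so that every downstream stage can be tested against
known truth. It emulates: multigene families as an ancestor-based star
phylogeny (paralog 1 is the ancestor; others differ at a binomially
sampled fraction of sites, with stop codons repaired so the CDS stays
open); truncated log-normal read lengths with `meanlog`/`sdlog` solved at
configuration time from the three published summaries (mean 186.6, max
645, 3.27% < 50 nt); substitution errors at ε = 1.35%; 3'-weighted start
positions with density ∝ ((start+1)/length)^b, default exponent b = 2 — the
enrichment strength is not published, so the exponent is a free parameter
chosen to give visibly 3'-dominated coverage while leaving the 5' end
reachable; a 10-base MID appended at the read 3' end, corrupted to an
unrecognizable barcode with probability 1.35%; and shotgun sampling of
source transcripts ∝ weight × length, so that mol% normalization is
genuinely needed to recover molar composition. Expression profiles carry a
per-gene translational efficiency used only by the matched-proteome
generator (family share ∝ Σ weight × efficiency), making
transcriptome–proteome discordance a controllable simulation knob.

What it does **not** emulate — and therefore what green tests do not
establish about real data: homopolymer indel errors (the signature 454
error mode; the copy-number procedure reasons in substitution space only),
quality-score dynamics, chimeric reads, mobile-element sequence,
paralog-count and abundance distributions as skewed as real venom glands,
and real inter-species divergence structure. Indel-free simulation means
the pileup's insertion/deletion handling is exercised only lightly.

## Numerical and degenerate-input choices

* Seeds: every simulation entry point takes an explicit seed; the pipeline
  derives per-stage seeds from the master seed, and identical
  configurations reproduce byte-identical output files (MD5 manifest).
* The truncated log-normal fit solves the 3.27%-below-50-nt quantile
  condition analytically and the truncated-mean condition by `uniroot` on
  σ ∈ [0.05, 2.5]; infeasible (mean, max, short-fraction) triples error at
  configuration time.
* Local alignments with non-positive score are treated as "no placement";
  terminal mismatches are clipped by local alignment by construction, so
  variant sites at the extreme ends of a reference are systematically
  under-covered (visible only when variants sit within ~3 nt of an end).
* Empty inputs: empty read sets give empty pileups and a copy-number of 0;
  a consensus over an empty stack is all-unknown; `trim_clusters(list())`
  is empty; PCA on constant matrices errors rather than returning 0%.
* Distance saturation (p = 1) and fully-missing overlaps are errors, not
  silent NAs.
* Test problem sizes: simulation-backed tests run at 10⁴–2×10⁴ reads for
  calibration checks, ~300–500 reads per copy-number replicate, and a
  three-species demo of ~350 reads per species for end-to-end checks —
  sizes chosen to keep sampling error well inside the 3-SD acceptance
  bands while the full suite stays interactive.

## Known limitations

Substitutions-only error model; no indel variants in the copy-number
signature space; exhaustive alignment scales linearly in panel size and is
not intended for genome-scale references; Karlin–Altschul constants are
bundled for the two default scoring schemes only; the bundled reference
panel is synthetic (one exemplar per family, realistic lengths and UTR
structure but not real toxin sequences), so family assignments on real
reads require supplying a real panel via `read_panel()`.
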