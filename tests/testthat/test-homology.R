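test_that("six-frame translation covers both strands and handles N", {
  fr <- six_frame_translate("ATGGCC")
  expect_identical(fr[["+1"]], "MA")
  expect_identical(six_frame_translate("ATGNNN")[["+1"]], "MX")
  set.seed(11)
  for (r in 1:5) {
    s <- rand_dna(sample(30:60, 1))
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    fr <- six_frame_translate(s)
    expect_identical(fr[["-1"]], six_frame_translate(rc)[["+1"]])
    expect_identical(fr[["-2"]], six_frame_translate(rc)[["+2"]])
  }
})

test_that("local alignment equals the brute-force DP oracle", {
  params <- homology_params()
  b62 <- blosum62()
  ntmat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                    baseOnly = TRUE)
  set.seed(12)
  for (r in 1:20) {
    q <- rand_aa(sample(15:40, 1)); t <- rand_aa(sample(15:40, 1))
    a <- local_align(q, t, params, "protein")
    expect_equal(a$score, sw_oracle(q, t, b62, params$gap_open, params$gap_ext))
  }
  for (r in 1:20) {
    q <- rand_dna(sample(20:50, 1)); t <- rand_dna(sample(20:50, 1))
    a <- local_align(q, t, params, "nucleotide")
    expect_equal(a$score,
                 sw_oracle(q, t, ntmat, params$nt_gap_open, params$nt_gap_ext))
  }
})

test_that("self-alignment score is the BLOSUM62 diagonal sum", {
  b62 <- blosum62()
  pep <- "MKVLANCW"
  a <- local_align(pep, pep)
  expect_equal(a$score, sum(diag(b62[strsplit(pep, "")[[1]],
                                     strsplit(pep, "")[[1]]])))
  expect_identical(a$query_iv, c(0L, 8L))
})

test_that("E-values behave like Karlin-Altschul statistics", {
  p <- homology_params()
  e1 <- estimate_evalue(50, 100, 1e4, p, "protein")
  e2 <- estimate_evalue(60, 100, 1e4, p, "protein")
  expect_lt(e2, e1)
  expect_equal(estimate_evalue(50, 100, 2e4, p, "protein"), 2 * e1)
  expect_error(estimate_evalue(50, 0, 1e4, p), "positive")
  # closed-form threshold matches a numerically inverted oracle
  for (mode in c("protein", "nucleotide")) {
    s_star <- evalue_score_threshold(1e-3, 186, 1e4, p, mode)
    s_num <- stats::uniroot(function(s)
      estimate_evalue(s, 186, 1e4, p, mode) - 1e-3, c(0, 500))$root
    expect_equal(s_star, s_num, tolerance = 1e-6)
    expect_equal(estimate_evalue(s_star, 186, 1e4, p, mode), 1e-3,
                 tolerance = 1e-9)
  }
})

test_that("exact substrings of a panel mRNA are assigned to their family", {
  panel <- reference_panel(c("SVMP", "PLA2", "LAO"))
  mrna <- panel$sequences[["SVMP_ref1"]]
  read <- substr(mrna, 301, 450)
  h <- assign_family(read, panel)
  expect_identical(h$family, "SVMP")
  expect_identical(h$category, "toxin")
  expect_lt(h$evalue, 1e-3)
})

test_that("dinucleotide-shuffled reads produce no hits", {
  panel <- reference_panel(c("SVMP", "PLA2", "LAO"))
  read <- substr(panel$sequences[["SVMP_ref1"]], 301, 450)
  set.seed(13)
  shuffles <- stats::setNames(replicate(50, dinucleotide_shuffle(read)),
                              sprintf("shuf%02d", 1:50))
  h <- assign_families(shuffles, panel)
  expect_identical(sum(h$category != "no_hit"), 0L)
})

test_that("family assignment is >=99% accurate on simulated reads", {
  panel <- reference_panel(c("SVMP", "PLA2", "LAO"))
  models <- c(
    simulate_gene_family("SVMP", 2, 0.06, seed = 14,
                         ancestor = panel$models[["SVMP_ref1"]]),
    simulate_gene_family("PLA2", 2, 0.06, seed = 15,
                         ancestor = panel$models[["PLA2_ref1"]]))
  cfg <- read_sim_config(seed = 16, mid_corruption_rate = 0)
  run <- simulate_reads(models, expression_profile(models), cfg, 150)
  reads <- stats::setNames(substr(run$reads, 1, nchar(run$reads) - 10),
                           names(run$reads))
  keep <- run$truth$end - run$truth$start >= 60
  h <- assign_families(reads[run$truth$read_id[keep]], panel)
  acc <- mean(h$family == run$truth$family[keep], na.rm = FALSE)
  expect_gte(acc, 0.99)
})

test_that("region partitioning follows the majority-overlap rule", {
  cds <- c(100L, 400L)
  expect_identical(partition_region(c(150L, 250L), cds, 600L), "ORF")
  expect_identical(partition_region(c(450L, 550L), cds, 600L), "UTR3")
  expect_identical(partition_region(c(10L, 80L), cds, 600L), "UTR5")
  # straddling the CDS end with 40% CDS overlap -> UTR3
  expect_identical(partition_region(c(360L, 460L), cds, 600L), "UTR3")
  # microsatellite domination overrides
  expect_identical(partition_region(c(150L, 250L), cds, 600L,
                                    microsat_frac = 0.6), "microsatellite")
  expect_identical(partition_region(c(150L, 250L), c(NA, NA), 600L),
                   NA_character_)
  expect_error(partition_region(c(500L, 700L), cds, 600L), "bounds")
})

test_that("cysteine-rich scan applies the 10% threshold on stop-free windows", {
  base <- strrep("AGKLVTMPRS", 6)                       # 60 aa, no C
  with_six <- paste0(substr(base, 1, 54), "CCCCCC")     # 6 C in 60 aa
  hit <- cysteine_rich_scan(c(f = with_six))
  expect_gte(nrow(hit), 1)
  expect_true(all(hit$n_cys / (hit$end - hit$start) >= 0.10))
  # five cysteines spread so that no 50-100 residue window reaches 10%
  spread <- strsplit(base, "")[[1]]
  spread[c(1, 20, 30, 40, 60)] <- "C"
  with_five <- paste(spread, collapse = "")
  expect_identical(nrow(cysteine_rich_scan(c(f = with_five))), 0L)
  expect_identical(nrow(cysteine_rich_scan(c(f = base))), 0L)
  # a stop codon inside the window disqualifies it
  stopped <- paste0(substr(base, 1, 30), "*",
                    substr(base, 32, 54), "CCCCCC")
  expect_identical(nrow(cysteine_rich_scan(c(f = stopped))), 0L)
})

test_that("every read gets exactly one category and ties are deterministic", {
  panel <- reference_panel(c("SVMP", "PLA2"))
  set.seed(17)
  reads <- c(hit1 = substr(panel$sequences[["PLA2_ref1"]], 101, 260),
             junk = rand_dna(160))
  h1 <- assign_families(reads, panel)
  h2 <- assign_families(reads, panel)
  expect_identical(h1, h2)
  expect_true(all(h1$category %in% c("toxin", "non_toxin", "no_hit")))
  expect_identical(nrow(h1), 2L)
})
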