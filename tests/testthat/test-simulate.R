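test_that("zero divergence yields identical paralogs", {
  fam <- simulate_gene_family("SVMP", 3, 0, cds_len = 900, utr3_len = 300,
                              seed = 11)
  expect_length(fam, 3)
  expect_identical(fam[[1]]$mrna, fam[[2]]$mrna)
  expect_identical(fam[[1]]$mrna, fam[[3]]$mrna)
  expect_identical(fam[[2]]$protein, fam[[3]]$protein)
})

test_that("paralog divergence follows the binomial target", {
  fam <- simulate_gene_family("PLA2", 2, 0.05, cds_len = 414, utr3_len = 200,
                              seed = 21)
  cds <- fam[[1]]$cds
  a <- strsplit(substr(fam[[1]]$mrna, cds[1] + 1, cds[2]), "")[[1]]
  b <- strsplit(substr(fam[[2]]$mrna, cds[1] + 1, cds[2]), "")[[1]]
  h <- sum(a != b)
  expect_lt(abs(h - 414 * 0.05), 3 * sqrt(414 * 0.05 * 0.95))
})

test_that("single-paralog family with microsatellite records its tract", {
  fam <- simulate_gene_family("BPP", 1, 0.1, cds_len = 300, utr3_len = 100,
                              microsat = TRUE, seed = 31)
  expect_length(fam, 1)
  expect_gte(length(fam[[1]]$microsat_tracts), 1)
  tr <- fam[[1]]$microsat_tracts[[1]]
  expect_true(tr[1] >= 0 && tr[2] <= nchar(fam[[1]]$mrna))
})

test_that("gene models satisfy their invariants across generated families", {
  for (s in 1:5) {
    fam <- simulate_gene_family("SP", 3, 0.15, cds_len = 312, utr3_len = 150,
                                microsat = TRUE, seed = 100 + s)
    for (g in fam) {
      expect_true(g$cds[1] >= 0 && g$cds[1] < g$cds[2] &&
                    g$cds[2] <= nchar(g$mrna))
      expect_identical((g$cds[2] - g$cds[1]) %% 3L, 0L)
      expect_false(grepl("*", g$protein, fixed = TRUE))
    }
  }
})

test_that("infeasible divergence parameters error", {
  expect_error(simulate_gene_family("SVMP", 2, 0.5, seed = 1), "divergence")
  expect_error(simulate_gene_family("SVMP", 0, 0.1, seed = 1), "n_paralogs")
})

test_that("gene-family simulation is deterministic given the seed", {
  a <- simulate_gene_family("CTL", 3, 0.08, seed = 7)
  b <- simulate_gene_family("CTL", 3, 0.08, seed = 7)
  expect_identical(lapply(a, `[[`, "mrna"), lapply(b, `[[`, "mrna"))
  c <- simulate_gene_family("CTL", 3, 0.08, seed = 8)
  expect_false(identical(a[[2]]$mrna, c[[2]]$mrna))
})

test_that("error-free reads are exact substrings of their source mRNA", {
  fam <- simulate_gene_family("PLA2", 2, 0.05, seed = 41)
  cfg <- read_sim_config(error_rate = 0, mid_corruption_rate = 0, seed = 42)
  run <- simulate_reads(fam, expression_profile(fam), cfg, 200)
  mrnas <- stats::setNames(vapply(fam, `[[`, "", "mrna"),
                           vapply(fam, `[[`, "", "gene_id"))
  for (i in seq_len(nrow(run$truth))) {
    tr <- run$truth[i, ]
    insert <- substr(run$reads[[tr$read_id]], 1,
                     nchar(run$reads[[tr$read_id]]) - 10)
    expect_identical(insert,
                     substr(mrnas[[tr$gene_id]], tr$start + 1, tr$end))
  }
})

test_that("the truth table is complete and consistent", {
  fam <- simulate_gene_family("SVMP", 3, 0.05, seed = 51)
  cfg <- read_sim_config(seed = 52)
  run <- simulate_reads(fam, expression_profile(fam), cfg, 500)
  expect_identical(sort(names(run$reads)), sort(run$truth$read_id))
  expect_false(anyDuplicated(run$truth$read_id) > 0)
  expect_true(all(run$truth$end - run$truth$start ==
                    nchar(run$reads[run$truth$read_id]) - 10L))
})

test_that("simulator calibration: error rate, lengths and MID corruption", {
  # long transcript so read lengths are rarely truncated by transcript ends
  fam <- simulate_gene_family("SVMP", 1, 0, cds_len = 1800, utr3_len = 600,
                              seed = 61)
  cfg <- read_sim_config(seed = 62)
  n <- 2e4
  run <- simulate_reads(fam, expression_profile(fam), cfg, n)
  len <- run$truth$end - run$truth$start
  # substitution rate
  total_nt <- sum(len)
  eps_hat <- sum(run$truth$n_errors) / total_nt
  expect_lt(abs(eps_hat - 0.0135), 3 * sqrt(0.0135 * 0.9865 / total_nt))
  # length summaries
  expect_lte(max(len), 645)
  expect_lt(abs(mean(len) - 186.6), 3 * stats::sd(len) / sqrt(n))
  p_short <- mean(len < 50)
  expect_lt(abs(p_short - 0.0327), 3 * sqrt(0.0327 * 0.9673 / n))
  # MID corruption
  p_bad <- mean(!run$truth$mid_ok)
  expect_lt(abs(p_bad - 0.0135), 3 * sqrt(0.0135 * 0.9865 / n))
})

test_that("3' bias shifts read starts toward the transcript end", {
  fam <- simulate_gene_family("SVMP", 1, 0, cds_len = 1800, utr3_len = 600,
                              seed = 71)
  prof <- expression_profile(fam)
  biased <- simulate_reads(fam, prof, read_sim_config(seed = 72,
                                                      three_prime_bias = 2),
                           3000)
  uniform <- simulate_reads(fam, prof, read_sim_config(seed = 72,
                                                       three_prime_bias = 0),
                            3000)
  expect_gt(mean(biased$truth$start), mean(uniform$truth$start))
})

test_that("proteome simulation follows the weight x efficiency rule", {
  fam <- c(simulate_gene_family("SVMP", 1, 0, seed = 81),
           simulate_gene_family("PLA2", 1, 0, seed = 82))
  # equal efficiencies: proteome equals mRNA-weight shares
  p1 <- simulate_proteome(fam, expression_profile(fam, weights = c(3, 1)))
  expect_equal(unname(p1[c("SVMP", "PLA2")]), c(75, 25))
  # zero-efficiency family drops to 0 and the rest renormalizes
  p2 <- simulate_proteome(fam, expression_profile(fam, weights = c(3, 1),
                                                  efficiencies = c(0, 1)))
  expect_equal(unname(p2["SVMP"]), 0)
  expect_equal(unname(p2["PLA2"]), 100)
  # forced arithmetic: weights (1,1), efficiencies (2,1) -> 66.7/33.3
  p3 <- simulate_proteome(fam, expression_profile(fam,
                                                  efficiencies = c(2, 1)))
  expect_equal(unname(p3[c("SVMP", "PLA2")]), c(200, 100) / 3)
  expect_error(simulate_proteome(fam, expression_profile(fam, weights = c(1, 1),
                                                         efficiencies = c(0, 0))),
               "zero")
})

test_that("identical seeds give byte-identical FASTA/FASTQ output", {
  fam <- simulate_gene_family("CRISP", 2, 0.05, seed = 91)
  cfg <- read_sim_config(seed = 92)
  prof <- expression_profile(fam)
  r1 <- simulate_reads(fam, prof, cfg, 300)
  r2 <- simulate_reads(fam, prof, cfg, 300)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_reads_fastq(r1, f1); write_reads_fastq(r2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  a1 <- tempfile(fileext = ".fasta"); a2 <- tempfile(fileext = ".fasta")
  write_reads_fasta(r1, a1); write_reads_fasta(r2, a2)
  expect_identical(readLines(a1), readLines(a2))
})
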