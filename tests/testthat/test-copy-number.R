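# shared reference for constructed pileups: repeat-free, fixed
ref300 <- function() {
  set.seed(2024)
  rand_dna(300)
}

mutate_at <- function(seq, pos, base = NULL) {
  x <- strsplit(seq, "")[[1]]
  for (p in pos) {
    x[p] <- if (is.null(base)) setdiff(c("A", "C", "G", "T"), x[p])[1] else base
  }
  paste(x, collapse = "")
}

test_that("pileup of error-free reference reads has zero variant counts", {
  ref <- ref300()
  reads <- stats::setNames(
    vapply(seq(1, 201, by = 20), function(s) substr(ref, s, s + 99), ""),
    sprintf("r%02d", 1:11))
  p <- build_pileup(reads, ref)
  expect_identical(nrow(p$mat), 11L)
  for (j in seq_len(300)) {
    alt <- setdiff(c("A", "C", "G", "T"), p$ref_base[j])
    expect_identical(sum(p$counts[alt, j]), 0L)
  }
  expect_equal(sum(vapply(1:300, function(j)
    p$counts[p$ref_base[j], j], 0L)), sum(p$coverage))
})

test_that("a single substitution yields exactly one count-1 variant column", {
  ref <- ref300()
  reads <- c(clean = substr(ref, 1, 150),
             mut = mutate_at(substr(ref, 1, 150), 75))
  p <- build_pileup(reads, ref)
  nonref <- vapply(seq_len(300), function(j)
    sum(p$counts[setdiff(c("A", "C", "G", "T"), p$ref_base[j]), j]), 0L)
  expect_identical(sum(nonref), 1L)
  expect_identical(which(nonref == 1L), 75L)
})

test_that("pileup mismatch rate matches the configured error rate", {
  fam <- simulate_gene_family("SVMP", 1, 0, cds_len = 450, utr3_len = 300,
                              seed = 21)
  cfg <- read_sim_config(seed = 22, mid_corruption_rate = 0)
  run <- simulate_reads(fam, expression_profile(fam), cfg, 1000)
  reads <- stats::setNames(substr(run$reads, 1, nchar(run$reads) - 10),
                           names(run$reads))
  p <- build_pileup(reads, fam[[1]]$mrna)
  total <- sum(p$coverage)
  nonref <- total - sum(vapply(seq_along(p$ref_base), function(j)
    p$counts[p$ref_base[j], j], 0L))
  eps_hat <- nonref / total
  expect_lt(abs(eps_hat - 0.0135), 3 * sqrt(0.0135 * 0.9865 / total))
})

test_that("variant validation needs three identical supporting reads", {
  ref <- ref300()
  two <- c(a = mutate_at(ref, 50, "A"), b = mutate_at(ref, 50, "A"),
           c = ref, d = ref)
  if (substr(ref, 50, 50) == "A") two <- c(a = mutate_at(ref, 50, "C"),
                                           b = mutate_at(ref, 50, "C"),
                                           c = ref, d = ref)
  p2 <- build_pileup(two, ref)
  expect_identical(nrow(call_validated_variants(p2)), 0L)
  three <- c(two[1], two[2], e = two[[1]], c = ref, d = ref)
  names(three) <- c("a", "b", "e", "c", "d")
  p3 <- build_pileup(three, ref)
  v <- call_validated_variants(p3)
  expect_identical(nrow(v), 1L)
  expect_identical(v$pos, 49L)
  expect_identical(v$support, 3L)
})

test_that("false validations at coverage 20 match the binomial oracle", {
  ref <- ref300()
  set.seed(23)
  eps <- 0.05   # inflated rate so the expectation is testable at 300 columns
  reads <- stats::setNames(replicate(20, {
    x <- strsplit(ref, "")[[1]]
    hit <- which(stats::runif(300) < eps)
    for (i in hit) x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1)
    paste(x, collapse = "")
  }), sprintf("r%02d", 1:20))
  p <- build_pileup(reads, ref, homology_params())
  v <- call_validated_variants(p, distinctness_params(epsilon = eps))
  p3 <- stats::pbinom(2, 20, eps / 3, lower.tail = FALSE)
  expected <- 300 * 3 * p3
  expect_lt(abs(nrow(v) - expected), 3 * sqrt(expected) + 1)
})

test_that("clustering separates divergent paralogs and merges near-identical ones", {
  ref <- ref300()
  # single haplotype, error-free -> one cluster
  reads <- stats::setNames(rep(ref, 10), sprintf("r%02d", 1:10))
  p <- build_pileup(reads, ref)
  expect_length(cluster_reads(p), 1L)
  # two paralogs at 5% divergence, full-length error-free reads -> 2 clusters
  set.seed(24)
  alt <- mutate_at(ref, sample(300, 15))
  reads2 <- stats::setNames(c(rep(ref, 50), rep(alt, 50)),
                            sprintf("r%03d", 1:100))
  p2 <- build_pileup(reads2, ref)
  cl2 <- cluster_reads(p2)
  expect_length(cl2, 2L)
  expect_setequal(vapply(cl2, `[[`, 0L, "n_reads"), c(50L, 50L))
  # paralogs differing at exactly one site over a 300 nt overlap merge:
  # P(X >= 1 | Bin(300, 0.0135)) ~ 0.98 >> alpha
  alt1 <- mutate_at(ref, 150)
  reads3 <- stats::setNames(c(rep(ref, 25), rep(alt1, 25)),
                            sprintf("r%03d", 1:50))
  p3 <- build_pileup(reads3, ref)
  expect_length(cluster_reads(p3), 1L)
})

test_that("cluster sizes partition the placed reads", {
  fam <- simulate_gene_family("SP", 3, 0.08, seed = 25)
  cfg <- read_sim_config(seed = 26, mid_corruption_rate = 0)
  run <- simulate_reads(fam, expression_profile(fam), cfg, 300)
  reads <- stats::setNames(substr(run$reads, 1, nchar(run$reads) - 10),
                           names(run$reads))
  p <- build_pileup(reads, fam[[1]]$mrna)
  cl <- cluster_reads(p)
  expect_identical(sum(vapply(cl, `[[`, 0L, "n_reads")), nrow(p$mat))
  expect_false(anyDuplicated(unlist(lapply(cl, `[[`, "members"))) > 0)
})

test_that("error-free full-length reads recover the exact haplotype count", {
  fam <- simulate_gene_family("LAO", 3, 0.08, cds_len = 300, utr3_len = 100,
                              seed = 27)
  seqs <- vapply(fam, `[[`, "", "mrna")
  reads <- stats::setNames(rep(seqs, each = 12), sprintf("r%03d", 1:36))
  p <- build_pileup(reads, fam[[1]]$mrna)
  expect_length(cluster_reads(p), 3L)
})

test_that("trimming keeps the shortest prefix reaching the read-share target", {
  cl <- fake_clusters(c(90, 5, 3, 1, 1))
  kept <- trim_clusters(cl)
  expect_identical(vapply(kept, `[[`, 0L, "n_reads"), c(90L, 5L))
  expect_length(trim_clusters(fake_clusters(10)), 1L)
  expect_identical(vapply(trim_clusters(fake_clusters(c(50, 50))),
                          `[[`, 0L, "n_reads"), c(50L, 50L))
  expect_length(trim_clusters(list()), 0L)
})

test_that("copy-number estimation handles empty input and skewed profiles", {
  expect_identical(estimate_min_genes(character(0), ref300())$count, 0L)
  # one dominant paralog and four rare ones: trimming drops the rare genes,
  # demonstrating the lower-bound semantics
  fam <- simulate_gene_family("SVMP", 5, 0.08, seed = 28)
  cfg <- read_sim_config(seed = 29, mid_corruption_rate = 0)
  prof <- expression_profile(fam, weights = c(95, 1.25, 1.25, 1.25, 1.25))
  run <- simulate_reads(fam, prof, cfg, 400)
  reads <- stats::setNames(substr(run$reads, 1, nchar(run$reads) - 10),
                           names(run$reads))
  est <- estimate_min_genes(reads, fam[[1]]$mrna)
  expect_lt(est$count, 5L)
  expect_gte(est$count, 1L)
})

test_that("cluster count is monotone in alpha and retention in trim fraction", {
  fam <- simulate_gene_family("SVMP", 3, 0.06, seed = 30)
  cfg <- read_sim_config(seed = 31, mid_corruption_rate = 0)
  run <- simulate_reads(fam, expression_profile(fam), cfg, 300)
  reads <- stats::setNames(substr(run$reads, 1, nchar(run$reads) - 10),
                           names(run$reads))
  p <- build_pileup(reads, fam[[1]]$mrna)
  # larger alpha makes separation easier: counts never decrease
  counts <- vapply(c(1e-4, 1e-2, 0.2), function(a)
    length(cluster_reads(p, distinctness_params(alpha = a))), 0L)
  expect_true(all(diff(counts) >= 0))
  # larger trim fraction retains at least as many clusters
  cl <- cluster_reads(p)
  kept <- vapply(c(0.5, 0.8, 0.95, 1), function(tf)
    length(trim_clusters(cl, distinctness_params(trim_fraction = tf))), 0L)
  expect_true(all(diff(kept) >= 0))
})
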