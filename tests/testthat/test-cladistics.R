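fake_consensus <- function(seq) {
  # a consensus whose representative is the given residue vector
  res <- strsplit(seq, "")[[1]]
  res[res == "-"] <- NA
  structure(list(family = NA, species = NA,
                 calls = data.frame(pos = seq_along(res) - 1L,
                                    coverage = 10L, class = "fixed",
                                    residues = ifelse(is.na(res), "", res)),
                 display = seq, representative = res),
            class = "consensus_sequence")
}

test_that("concatenation uses the canonical family order", {
  set.seed(51)
  segs <- stats::setNames(lapply(1:5, function(i) fake_consensus(rand_aa(10))),
                          c("SVMP", "BPP", "SP", "LAO", "PLA2"))
  cc <- concatenate_consensus(segs, species = "sp1")
  expect_length(cc$residues, 50)
  expect_identical(unname(cc$boundaries),
                   as.integer(c(10, 20, 30, 40, 50)))
  expect_identical(names(cc$boundaries), c("BPP", "LAO", "PLA2", "SVMP", "SP"))
  # permuted input gives the identical concatenation
  cc2 <- concatenate_consensus(segs[c(3, 1, 5, 2, 4)], species = "sp1")
  expect_identical(cc$residues, cc2$residues)
  expect_error(concatenate_consensus(segs[c("SVMP", "BPP")]), "LAO")
})

test_that("Poisson-corrected distance matches closed form and counting oracle", {
  expect_equal(pairwise_distance("AAAAAAAAAA", "AAAAAAAAAA"), 0)
  # p = 0.1 -> -ln(0.9)
  a <- strrep("A", 20)
  b <- paste0(strrep("A", 18), "CC")
  expect_equal(pairwise_distance(a, b), -log(1 - 0.1))
  set.seed(52)
  for (r in 1:20) {
    x <- strsplit(rand_aa(60), "")[[1]]
    y <- strsplit(rand_aa(60), "")[[1]]
    keep <- stats::runif(60) > 0.2            # the rest set to missing in x
    x[!keep] <- NA
    comp <- which(!is.na(x))
    p_oracle <- sum(x[comp] != y[comp]) / length(comp)
    if (p_oracle >= 1) next
    expect_equal(pairwise_distance(x, y), -log(1 - p_oracle))
  }
  expect_error(pairwise_distance(rep(NA_character_, 5), strsplit("AAAAA", "")[[1]]),
               "comparable")
})

test_that("lowercase and gap positions are treated as missing data", {
  d <- pairwise_distance("AAAaaAAAAA", "AAACCAAAAC")
  # lowercase positions drop out: 8 compared, 1 mismatch
  expect_equal(d, -log(1 - 1 / 8))
})

test_that("distance of globally aligned unequal-length sequences is sane", {
  set.seed(53)
  a <- rand_aa(60)
  b <- paste0(substr(a, 1, 25), substr(a, 31, 60))   # 5-residue deletion
  d <- pairwise_distance(a, b)
  expect_gte(d, 0)
  expect_lt(d, 0.1)
})

test_that("neighbor joining solves the 3-taxon case in closed form", {
  D <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  expect_s3_class(tr, "phylo")
  cd <- stats::cophenetic(tr)[c("a", "b", "c"), c("a", "b", "c")]
  expect_equal(unname(cd), unname(D))
  # branch lengths: va = (dab + dac - dbc)/2 = 2, vb = 3, vc = 7
  el <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(el[c("a", "b", "c")]), c(2, 3, 7))
})

test_that("NJ recovers additive trees exactly", {
  skip_if_not_installed("phangorn")
  set.seed(54)
  for (r in 1:20) {
    n <- sample(5:10, 1)
    true <- ape::rtree(n, br = stats::runif)
    true$edge.length <- true$edge.length + 0.05
    D <- stats::cophenetic(true)
    tr <- neighbor_joining(D)
    expect_equal(phangorn::RF.dist(ape::unroot(true), tr), 0, ignore_attr = TRUE)
    expect_equal(max(abs(stats::cophenetic(tr)[rownames(D), colnames(D)] - D)),
                 0, tolerance = 1e-8)
  }
})

test_that("NJ agrees with the independent ape implementation", {
  skip_if_not_installed("phangorn")
  set.seed(55)
  for (r in 1:10) {
    n <- 7
    true <- ape::rtree(n); true$edge.length <- true$edge.length + 0.1
    D <- stats::cophenetic(true)
    noise <- matrix(stats::runif(n * n, 0, 0.02), n)
    noise <- (noise + t(noise)) / 2; diag(noise) <- 0
    Dn <- D + noise
    expect_equal(phangorn::RF.dist(neighbor_joining(Dn), ape::nj(Dn)), 0, ignore_attr = TRUE)
  }
})

test_that("identical taxa form a zero-length cherry", {
  D <- matrix(c(0, 0, 4, 6,
                0, 0, 4, 6,
                4, 4, 0, 6,
                6, 6, 6, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(D)
  el <- stats::setNames(tr$edge.length, c(tr$tip.label, "")[tr$edge[, 2]])
  expect_equal(unname(el["a"]), 0)
  expect_equal(unname(el["b"]), 0)
})

test_that("the tree is invariant under taxon permutation", {
  set.seed(56)
  true <- ape::rtree(8); true$edge.length <- true$edge.length + 0.05
  D <- stats::cophenetic(true)
  perm <- sample(8)
  t1 <- neighbor_joining(D)
  t2 <- neighbor_joining(D[perm, perm])
  expect_equal(sum(t1$edge.length), sum(t2$edge.length), tolerance = 1e-9)
  skip_if_not_installed("phangorn")
  expect_equal(phangorn::RF.dist(t1, t2), 0, ignore_attr = TRUE)
})

test_that("asymmetric or tiny matrices are rejected", {
  D <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(neighbor_joining(D), "3 taxa")
  D3 <- matrix(c(0, 1, 2, 1.5, 0, 1, 2, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighbor_joining(D3), "symmetric")
})

test_that("NJ on Poisson-evolved consensus proteins recovers the species tree", {
  skip_if_not_installed("phangorn")
  set.seed(57)
  # fixed 5-taxon topology ((A,B),(C,D),E); per-branch substitution ~ 6%
  success <- 0
  for (r in 1:20) {
    root <- rand_aa(250)
    ab <- evolve_protein(root, 0.06); cd <- evolve_protein(root, 0.06)
    tips <- list(A = evolve_protein(ab, 0.06), B = evolve_protein(ab, 0.06),
                 C = evolve_protein(cd, 0.06), D = evolve_protein(cd, 0.06),
                 E = evolve_protein(root, 0.12))
    D <- distance_matrix(tips)
    tr <- neighbor_joining(D)
    truth <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1,E:2);")
    if (phangorn::RF.dist(tr, truth) == 0) success <- success + 1
  }
  expect_gte(success, 18)
})

test_that("PHYLIP distance output is well formed", {
  D <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("aa", "bb"), NULL))
  f <- tempfile()
  write_phylip_dist(D, f)
  lines <- readLines(f)
  expect_identical(trimws(lines[1]), "2")
  expect_length(lines, 3)
})
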