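pair_aln <- function(a, b) nuc_alignment(c(a = a, b = b))

test_that("count_differences applies pairwise deletion and Ti/Tv typing", {
  cnt <- count_differences(pair_aln("ACGT", "ACGT"), c("a", "b"))
  expect_equal(cnt$compared_sites, 4)
  expect_equal(cnt$differences, 0)

  cnt2 <- count_differences(pair_aln("A-GT", "AAGT"), c("a", "b"))
  expect_equal(cnt2$compared_sites, 3)

  cnt3 <- count_differences(pair_aln("AG", "GA"), c("a", "b"))
  expect_equal(cnt3$transitions, 2)
  expect_equal(cnt3$transversions, 0)

  cnt4 <- count_differences(pair_aln("ANGT", "ACGT"), c("a", "b"))
  expect_equal(cnt4$compared_sites, 3)    # N removed pairwise
  expect_error(count_differences(pair_aln("---", "AAA"), c("a", "b")),
               "zero comparable")
})

test_that("K2p closed form, saturation and JC coincidence", {
  expect_equal(k2p(list(compared_sites = 100, transitions = 0,
                        transversions = 0)), 0)
  expect_equal(round(k2p(list(compared_sites = 10000, transitions = 1000,
                              transversions = 500)), 4), 0.1702)
  expect_error(k2p(list(compared_sites = 10, transitions = 5,
                        transversions = 1)), "saturation")

  # P = Q/2 (uniform substitution): K2p equals the Jukes-Cantor distance
  for (Q in c(0.05, 0.1, 0.2)) {
    counts <- list(compared_sites = 1000, transitions = 500 * Q,
                   transversions = 1000 * Q)
    p <- (counts$transitions + counts$transversions) / 1000
    jc <- -0.75 * log(1 - 4 * p / 3)
    expect_equal(k2p(counts), jc, tolerance = 1e-12)
  }

  # small-p limit: |K - p| < p^2 with balanced Ti/Tv
  for (p in c(0.01, 0.03, 0.045)) {
    counts <- list(compared_sites = 1e6, transitions = 5e5 * p,
                   transversions = 5e5 * p)
    expect_lt(abs(k2p(counts) - p), p^2)
  }
})

test_that("per-position K2p recovers planted per-position rates", {
  aln0 <- codon_alignment(c(a = "ATGAAA", b = "ATGAAA"))
  expect_equal(k2p_by_position(aln0, c("a", "b")), c(0, 0, 0))

  set.seed(10)
  n <- 4000
  planted <- c(0.05, 0.02, 0.3)
  prs <- lapply(planted, function(d) simulate_k2p_pair(n, d))
  weave <- function(i) {
    m <- sapply(prs, function(p) strsplit(p[[i]], "")[[1]])
    paste(as.vector(t(m)), collapse = "")
  }
  aln <- codon_alignment(c(a = weave("a"), b = weave("b")))
  got <- k2p_by_position(aln, c("a", "b"))
  for (pos in 1:3) {
    se <- sqrt(planted[pos] / n) + 0.004
    expect_lt(abs(got[pos] - planted[pos]), 2 * se)
  }
  expect_true(got[3] > got[1] && got[1] > got[2])
})

test_that("Dayhoff expected-identity curve matches a series-expansion oracle", {
  mdl <- utils::getFromNamespace(".Dayhoff", "phangorn")
  bf <- mdl$bf / sum(mdl$bf)
  S <- matrix(0, 20, 20)
  S[lower.tri(S)] <- mdl$Q
  S <- S + t(S)
  Q <- S * rep(bf, each = 20)
  diag(Q) <- -rowSums(Q)
  Q <- Q / (-sum(bf * diag(Q)))
  # matrix exponential by scaling-and-squaring on the plain series
  series_expm <- function(M) {
    k <- 20
    Ms <- M / 2^k
    P <- diag(20); term <- diag(20)
    for (j in 1:12) { term <- term %*% Ms / j; P <- P + term }
    for (j in 1:k) P <- P %*% P
    P
  }
  for (d in c(0.3, 1, 2)) {
    oracle <- sum(bf * diag(series_expm(Q * d)))
    expect_equal(mitocomp:::dayhoff_expected_identity(d), oracle,
                 tolerance = 1e-8)
  }
})

test_that("PAM distance inverts observed identity and is monotone", {
  rows <- c(a = "MKVLIN", b = "MKVLIN")
  expect_equal(pam_distance(rows, c("a", "b")), 0)

  # constructed pair at the PAM-100 expected identity
  n <- 5000
  target <- mitocomp:::dayhoff_expected_identity(1)
  n_match <- round(target * n)
  a <- paste(rep("A", n), collapse = "")
  b <- paste(c(rep("A", n_match), rep("R", n - n_match)), collapse = "")
  d <- pam_distance(c(a = a, b = b), c("a", "b"))
  expect_equal(d, 1, tolerance = 0.01)

  # monotonicity: lower identity never yields a smaller distance
  ident <- seq(0.9, 0.2, by = -0.1)
  dists <- vapply(ident, function(f) {
    nm <- round(f * n)
    bb <- paste(c(rep("A", nm), rep("R", n - nm)), collapse = "")
    pam_distance(c(a = a, b = bb), c("a", "b"))
  }, numeric(1))
  expect_true(all(diff(dists) > 0))
  expect_error(pam_distance(c(a = a, b = paste(rep("R", n), collapse = "")),
                            c("a", "b")), "saturation")
})

test_that("Nei-Gojobori counts match the hand-enumerated path oracle", {
  # identical sequences
  kk0 <- ka_ks(codon_alignment(c(a = "ATGAAA", b = "ATGAAA")), c("a", "b"))
  expect_equal(kk0$ka, 0)
  expect_equal(kk0$ks, 0)
  expect_true(is.na(kk0$ka_ks))

  # GTT -> GTC is synonymous (padded so pS < 0.75)
  pad <- strrep("ATG", 6)
  kk1 <- ka_ks(codon_alignment(c(a = paste0(pad, "GTT"),
                                 b = paste0(pad, "GTC"))), c("a", "b"))
  expect_equal(kk1$ka, 0)
  expect_gt(kk1$ks, 0)

  # mixed codon TTT <-> GTA: both orderings of the two changes are
  # stop-free, so averaging gives sd = (1 + 0)/2, nd = (1 + 2)/2;
  # sites: S(TTT) = 1/3 (third position TTC), S(GTA) = 1 (fourfold),
  # S(AAA) = 1/3 (AAG; the pos-1 change to the TAA stop is skipped)
  cnt <- ng_counts(codon_alignment(c(a = "AAATTT", b = "AAAGTA")),
                   c("a", "b"))
  expect_equal(cnt$syn_sites, (2 / 3 + 4 / 3) / 2)
  expect_equal(cnt$nonsyn_sites, 6 - 1)
  expect_equal(cnt$syn_diffs, 0.5)
  expect_equal(cnt$nonsyn_diffs, 1.5)
})

test_that("Ka/Ks < 1 under simulated purifying selection", {
  set.seed(12)
  pr <- simulate_codon_pair(3000, 0.1, nonsyn_scaling = 0.1)
  kk <- ka_ks(codon_alignment(c(a = pr$a, b = pr$b)), c("a", "b"))
  expect_lt(kk$ka_ks, 1)
  expect_lt(kk$ka_ks, 0.35)   # scaled 0.1x; counting puts it well below 1
})

test_that("group averages pool pairs and flag saturation", {
  aln <- nuc_alignment(c(a = strrep("ACGT", 50),
                         b = strrep("ACGT", 50)))
  d <- gene_distances(aln)
  expect_equal(nrow(d), 1)
  expect_equal(group_average(d)$k2p, d$k2p)

  set.seed(13)
  # 5-taxon star with branch 0.1: every pairwise expected distance 0.2
  anc <- mitocomp:::sample_bases(4000, rep(0.25, 4))
  P <- mitocomp:::hky_pmat(0.1, 3, rep(0.25, 4))
  rows <- vapply(1:5, function(i)
    mitocomp:::chars_seq(mitocomp:::evolve_chars(anc, P)), character(1))
  names(rows) <- paste0("t", 1:5)
  d5 <- gene_distances(nuc_alignment(rows))
  expect_equal(nrow(d5), 10)
  avg <- group_average(d5)
  expect_lt(abs(avg$k2p - 0.2), 2 * sqrt(0.2 / 4000) + 0.01)
  expect_equal(avg$n_saturated, 0)
})

test_that("saturation scan relates p and K2p as expected", {
  set.seed(14)
  # near-identical pair: K2p ~ p
  pr <- simulate_k2p_pair(5000, 0.01)
  aln <- nuc_alignment(c(a = pr$a, b = pr$b))
  d <- gene_distances(aln)
  expect_lt(abs(d$k2p - d$p), d$p^2 + 1e-4)

  # low-divergence set: near-perfect linearity
  alns <- lapply(1:6, function(i) {
    pr <- simulate_k2p_pair(3000, stats::runif(1, 0.02, 0.09))
    nuc_alignment(c(a = pr$a, b = pr$b), region = paste0("g", i))
  })
  sc <- saturation_scan(alns)
  expect_gt(attr(sc, "linearity"), 0.99)

  # closed-form inflation at p = 0.3 with transition-rich differences
  counts <- list(compared_sites = 1000, transitions = 200,
                 transversions = 100)
  expect_gt(k2p(counts) / 0.3, 1.3)
})

test_that("concatenation pools sites before distances", {
  a1 <- nuc_alignment(c(a = "AAAA", b = "AAAA"), region = "g1")
  a2 <- nuc_alignment(c(a = "CCCC", b = "CCCA"), region = "g2")
  cc <- concat_alignments(list(a1, a2), region = "tot")
  d <- gene_distances(cc)
  expect_equal(d$sites, 8)
  expect_equal(d$p, 1 / 8)
})
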