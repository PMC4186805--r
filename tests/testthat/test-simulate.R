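test_that("simulation is deterministic in the seed", {
  s1 <- simulate_genomes(sim_config(seed = 5, n_taxa = 2))
  s2 <- simulate_genomes(sim_config(seed = 5, n_taxa = 2))
  expect_identical(s1$ancestor$sequence, s2$ancestor$sequence)
  expect_identical(lapply(s1$genomes, `[[`, "sequence"),
                   lapply(s2$genomes, `[[`, "sequence"))
  expect_identical(s1$truth, s2$truth)

  s3 <- simulate_genomes(sim_config(seed = 6, n_taxa = 2))
  expect_false(identical(s1$ancestor$sequence, s3$ancestor$sequence))
})

test_that("zero branch lengths reproduce the ancestor exactly", {
  zero <- list(pos1 = 0, pos2 = 0, pos3 = 0, trna_J = 0, trna_N = 0,
               rrna = 0, atrich = 0, element = 0)
  sim <- simulate_genomes(sim_config(seed = 3, n_taxa = 3, branch = zero))
  for (g in sim$genomes) {
    # poly(N) runs are re-stamped per taxon (permuted bases), so compare
    # everything outside the poly(N) zone
    pz <- sim$truth$atrich$polyn
    at_start <- g$features$start[g$features$name == "AT_rich"]
    mask <- rep(TRUE, nchar(g$sequence))
    for (r in seq_len(nrow(pz))) {
      span <- (at_start + pz$start[r] - 1):(at_start + pz$start[r] +
                                              pz$length[r] - 2)
      mask[span] <- FALSE
    }
    a <- strsplit(g$sequence, "")[[1]]
    b <- strsplit(sim$ancestor$sequence, "")[[1]]
    expect_identical(a[mask], b[mask])
  }
})

test_that("K2p process pairs hit their planted distance", {
  set.seed(31)
  est <- replicate(25, {
    pr <- simulate_k2p_pair(10000, 0.3)
    k2p_pair(nuc_alignment(c(a = pr$a, b = pr$b)), c("a", "b"))
  })
  expect_lt(abs(mean(est) - 0.3) / 0.3, 0.02)
})

test_that("third-position branch length 0.3 is recovered within 2 SE", {
  uni <- matrix(1, 13, 3,
                dimnames = list(rownames(mitocomp:::SIM_GENE_POS_SCALE),
                                NULL))
  br <- list(pos1 = 0.02, pos2 = 0.01, pos3 = 0.3, trna_J = 0.03,
             trna_N = 0.03, rrna = 0.03, atrich = 0.1, element = 0.01)
  sim <- simulate_genomes(sim_config(seed = 8, n_taxa = 2, branch = br,
                                     gene_scale = uni, gc_coupling = 0))
  g <- sim$genomes
  pcgJ <- g[[1]]$features$name[g[[1]]$features$kind == "PCG" &
                                 g[[1]]$features$strand == "J"]
  total <- concat_alignments(lapply(pcgJ, function(x)
    gene_alignment(g, x)), "tJ")
  got <- k2p_by_position(total, names(g))[3]
  want <- sim$truth$pairwise$pos3[["k2p_expected"]]
  n3 <- nchar(total$rows[[1]]) / 3
  se <- sqrt(want * (1 + want) / n3)
  expect_lt(abs(got - want), 2 * se + 0.01)
})

test_that("descendant composition stays at the planted stationary state", {
  suite <- sim_suite()
  anc <- base_composition(suite$ancestor$sequence)
  for (g in suite$genomes) {
    d <- base_composition(g$sequence)
    expect_lt(abs(d$pct_AT - anc$pct_AT), 0.5)
    expect_lt(abs(d$at_skew - anc$at_skew), 0.02)
  }
})

test_that("suite has study-like scale and structure", {
  suite <- sim_suite()
  n <- nchar(suite$ancestor$sequence)
  expect_gt(n, 15000)
  expect_lt(n, 16000)
  expect_true("AT_rich" %in% suite$ancestor$features$name)
  expect_equal(length(suite$genomes), 5)
  expect_gt(suite$truth$atrich_length, 600)
})

test_that("planted codon indels exercise the aligner", {
  sim <- simulate_genomes(sim_config(seed = 9, n_taxa = 3,
                                     indel_codons = 1,
                                     indel_genes = "cox2"))
  lens <- vapply(sim$genomes, function(g) nchar(extract_gene(g, "cox2")),
                 numeric(1))
  expect_equal(unname(lens[2]), unname(lens[1]) - 3)
  aln <- gene_alignment(sim$genomes, "cox2")
  expect_true(grepl("---", aln$rows[[2]], fixed = TRUE))
  d <- gene_distances(aln)
  expect_true(all(is.finite(d$k2p)))
})

test_that("fixture suite writes deterministic, re-readable files", {
  d1 <- file.path(tempdir(), "fx1")
  d2 <- file.path(tempdir(), "fx2")
  make_fixture_suite(d1, seed = 11)
  make_fixture_suite(d2, seed = 11)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  for (i in seq_along(f1)) {
    expect_identical(readLines(f1[i]), readLines(f2[i]),
                     info = basename(f1[i]))
  }
  g <- read_genbank(file.path(d1, "sim1.gb"))
  expect_equal(sum(g$features$kind != "region"), 37)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("codon-pair simulator respects the genetic code", {
  set.seed(33)
  pr <- simulate_codon_pair(500, 0.08)
  for (s in c(pr$a, pr$b)) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    aa <- unname(mito_code()[cods])
    expect_false(any(aa == "*"))
  }
})
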