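test_that("trivial nucleotide alignments behave", {
  a <- align_nuc(c(x = "ACGT", y = "ACGT"))
  expect_equal(unname(a$rows), c("ACGT", "ACGT"))

  a2 <- align_nuc(c(x = "ACGT", y = "AGT"))
  cols <- cbind(strsplit(a2$rows[[1]], "")[[1]],
                strsplit(a2$rows[[2]], "")[[1]])
  gaps <- sum(cols == "-")
  matches <- sum(cols[, 1] == cols[, 2] & cols[, 1] != "-")
  expect_equal(gaps, 1)
  expect_equal(matches, 3)
  expect_error(align_nuc(c(x = "", y = "ACGT")), "empty")
})

test_that("pairwise optimum equals brute-force enumeration on tiny inputs", {
  set.seed(5)
  for (i in 1:12) {
    a <- random_dna(sample(3:8, 1))
    b <- random_dna(sample(3:8, 1))
    got <- mitocomp:::align_pair_raw(a, b)$score
    want <- brute_align_score(a, b)
    expect_equal(got, want, info = paste(a, b))
    # score is symmetric in input order
    expect_equal(mitocomp:::align_pair_raw(b, a)$score, got)
  }
})

test_that("degapping inverts alignment", {
  set.seed(6)
  seqs <- c(a = random_dna(60), b = random_dna(55), c = random_dna(62))
  aln <- align_nuc(seqs)
  for (tx in names(seqs)) expect_equal(degap(aln$rows[[tx]]), seqs[[tx]])
})

test_that("codon alignment is protein-guided and frame-preserving", {
  cds <- c(t1 = "ATGAAATTTCCCGGGTAA", t2 = "ATGAAATTTCCCGGGTAA")
  aln <- align_codon(cds, gene = "demo")
  expect_equal(unname(nchar(aln$rows)), c(15L, 15L))   # stop dropped
  expect_equal(unname(aln$rows[1]), "ATGAAATTTCCCGGG")

  # one codon removed from t2: exactly one gap triplet, frame intact
  cds2 <- c(t1 = "ATGAAATTTCCCGGGTAA", t2 = "ATGAAACCCGGGTAA")
  aln2 <- align_codon(cds2, gene = "demo")
  expect_equal(nchar(aln2$rows[["t1"]]) %% 3, 0)
  gap_runs <- gregexpr("-+", aln2$rows[["t2"]])[[1]]
  expect_equal(length(gap_runs), 1)
  expect_equal(attr(gap_runs, "match.length"), 3)
  expect_equal(degap(aln2$rows[["t2"]]), "ATGAAACCCGGG")
  expect_error(align_codon(c(a = "ATGTAGAAA", b = "ATGAAAAAA")),
               "not translatable")
})

test_that("indel-free simulated pairs align site-wise", {
  set.seed(8)
  pr <- simulate_k2p_pair(900, 0.1)
  aln <- align_nuc(c(a = pr$a, b = pr$b))
  expect_false(grepl("-", aln$rows[[1]], fixed = TRUE))
  expect_false(grepl("-", aln$rows[[2]], fixed = TRUE))
  cols1 <- strsplit(aln$rows[[1]], "")[[1]]
  cols2 <- strsplit(aln$rows[[2]], "")[[1]]
  expect_gt(mean(cols1 == cols2), 0.85)   # planted ~90% identity
})

test_that("center-star alignment handles a planted indel in 4 taxa", {
  set.seed(9)
  base <- random_dna(90)
  seqs <- c(a = base, b = base,
            c = paste0(substr(base, 1, 40), substr(base, 47, 90)),
            d = base)
  aln <- align_nuc(seqs)
  lens <- unique(nchar(aln$rows))
  expect_length(lens, 1)
  for (tx in names(seqs)) expect_equal(degap(aln$rows[[tx]]), seqs[[tx]])
})

test_that("position masks and protein rows are consistent", {
  cds <- c(t1 = "ATGAAATTTTAA", t2 = "ATGAAATTCTAA")
  aln <- align_codon(cds)
  expect_equal(position_mask(aln), rep(1:3, 3))
  pr <- protein_rows(aln)
  expect_equal(unname(pr["t1"]), "MKF")
  expect_equal(unname(pr["t2"]), "MKF")
})

test_that("FASTA round-trip preserves an alignment", {
  aln <- align_nuc(c(x = "ACGTACGT", y = "ACGAACGT"))
  p <- tempfile(fileext = ".fasta")
  write_alignment_fasta(aln, p)
  aln2 <- read_alignment_fasta(p)
  expect_equal(aln2$rows, aln$rows)
})
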