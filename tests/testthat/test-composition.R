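test_that("base_composition computes percentages and skews", {
  r <- base_composition("AATT")
  expect_equal(r$at_skew, 0)
  expect_equal(r$pct_AT, 100)

  # counts A=429, T=281 reproduce a printed AT-skew of 0.21 at 2 dp
  s <- paste0(strrep("A", 429), strrep("T", 281), strrep("G", 100),
              strrep("C", 100))
  expect_equal(round(base_composition(s)$at_skew, 2), 0.21)

  # counts G=17, C=121 reproduce a printed GC-skew of -0.75 at 2 dp
  s2 <- paste0(strrep("G", 17), strrep("C", 121), strrep("A", 500))
  expect_equal(round(base_composition(s2)$gc_skew, 2), -0.75)

  expect_error(base_composition("NNN"), "empty|all-N")
  expect_true(is.na(base_composition("AATT")$gc_skew))   # 0 denominator
})

test_that("skews flip sign under reverse complement; rotation/case safe", {
  set.seed(11)
  for (i in 1:20) {
    s <- random_dna(200, freqs = c(0.4, 0.1, 0.1, 0.4))
    a <- base_composition(s)
    b <- base_composition(revcomp(s))
    expect_equal(b$at_skew, -a$at_skew, tolerance = 1e-12)
    expect_equal(b$gc_skew, -a$gc_skew, tolerance = 1e-12)
    r <- base_composition(mitocomp:::rotate_seq(s, 37))
    expect_equal(r$pct_AT, a$pct_AT)
    expect_equal(base_composition(tolower(s))$pct_A, a$pct_A)
  }
})

test_that("codon-position composition on a single codon is degenerate", {
  g <- mito_genome("c", "ATGAAATTTCATTAA",
                   data.frame(name = "cox1", kind = "PCG", start = 1,
                              end = 15, strand = "J"))
  # single gene; drop to one codon genome: use explicit tiny CDS
  g1 <- mito_genome("c1", "ATGTAA",
                    data.frame(name = "cox1", kind = "PCG", start = 1,
                               end = 6, strand = "J"))
  cp <- codon_position_composition(g1, "J")   # stop dropped -> ATG only
  expect_equal(cp$pct_A, c(100, 0, 0))
  expect_equal(cp$pct_T, c(0, 100, 0))
  expect_equal(cp$pct_G, c(0, 0, 100))
  expect_error(codon_position_composition(g1, "N"), "no PCGs")
})

test_that("planted positional frequencies are recovered", {
  sim <- simulate_genomes(sim_config(seed = 7, gc_coupling = 0))
  cp <- codon_position_composition(sim$genomes, "J")
  # the generator's truth is the realized ancestral composition (the
  # open-reading-frame constraint conditions it slightly away from the
  # raw stationary table)
  planted <- sim$truth$ancestral_composition
  for (pos in 1:3) {
    got <- unlist(cp[pos, c("pct_A", "pct_C", "pct_G", "pct_T")]) / 100
    want <- planted[[paste0("pos", pos)]][c("A", "C", "G", "T")]
    expect_true(all(abs(got - want) < 0.015),
                info = paste("pos", pos))
    # and the raw stationary table is matched loosely
    raw <- mitocomp:::SIM_FREQS$J[[pos]][c("A", "C", "G", "T")]
    expect_true(all(abs(got - raw) < 0.04), info = paste("raw pos", pos))
  }
})

test_that("amino-acid frequencies: degenerate cases and study-style top-5", {
  g1 <- mito_genome("m", "ATGATGATG",
                    data.frame(name = "cox1", kind = "PCG", start = 1,
                               end = 9, strand = "J"))
  aa <- amino_acid_frequencies(g1)
  expect_equal(aa$pct[aa$aa == "M"], 100)

  # uniform codon soup: frequencies proportional to code degeneracy
  code <- mito_code()
  sense <- names(code)[code != "*"]
  soup <- paste0("ATG", paste(sense, collapse = ""), "TAA")
  g2 <- mito_genome("u", soup,
                    data.frame(name = "cox1", kind = "PCG", start = 1,
                               end = nchar(soup), strand = "J"))
  aa2 <- amino_acid_frequencies(g2)
  deg <- table(unname(code[sense]))
  deg["M"] <- deg["M"] + 1          # the extra ATG start codon
  want <- 100 * as.numeric(deg[aa2$aa]) / sum(deg)
  expect_equal(aa2$pct, want, tolerance = 1e-9)

  aa3 <- amino_acid_frequencies(sim_suite()$genomes)
  expect_setequal(attr(aa3, "top"), c("L", "I", "S", "F", "M"))
  expect_gt(attr(aa3, "top_share"), 50)
})

test_that("fourfold-degenerate usage: NNA most common, NNG rarest", {
  # one pure family: 4 GGA codons -> NNA proportion 1 for Gly
  g <- mito_genome("f", paste0("ATG", strrep("GGA", 4), "TAA"),
                   data.frame(name = "cox1", kind = "PCG", start = 1,
                              end = 18, strand = "J"))
  ff <- fourfold_family_usage(g)
  expect_equal(ff$NNA[ff$family == "GG"], 1)

  ff2 <- fourfold_family_usage(sim_suite()$genomes)
  pooled <- unlist(ff2[ff2$family == "all", c("NNA", "NNC", "NNG", "NNT")])
  expect_equal(names(which.max(pooled)), "NNA")
  expect_equal(names(which.min(pooled)), "NNG")
})

test_that("whole-genome summaries match the ancestor within 0.5 points", {
  suite <- sim_suite()
  anc <- base_composition(suite$ancestor$sequence)
  gs <- genome_summary(suite$genomes)
  expect_true(all(abs(gs$at_pct - anc$pct_AT) < 0.5))
})

test_that("second codon position is T-dominated as in real mitogenomes", {
  cp <- codon_position_composition(sim_suite()$genomes, "both")
  expect_equal(names(which.max(unlist(
    cp[2, c("pct_A", "pct_C", "pct_G", "pct_T")]))), "pct_T")
  expect_gt(cp$pct_T[2], 40)
})
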