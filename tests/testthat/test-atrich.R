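test_that("tandem repeats: exact repeat, boundaries, canonical period", {
  r <- find_tandem_repeats("ACGTACGTACGT", min_unit = 4, min_copies = 3,
                           min_identity = 0.9)
  expect_equal(nrow(r), 1)
  expect_equal(r$unit_length, 4)
  expect_equal(r$copy_number, 3.0)
  expect_equal(r$start, 1)
  expect_equal(r$end, 12)

  # a period-8 call on a period-4 repeat canonicalizes to 4
  r2 <- find_tandem_repeats(strrep("ACGTTCGG", 6), min_unit = 8,
                            min_copies = 2, min_identity = 0.9)
  expect_equal(r2$unit_length, 8)
  r3 <- find_tandem_repeats(strrep("ACGT", 12), min_unit = 8,
                            min_copies = 2, min_identity = 0.9)
  expect_true(all(r3$unit_length == 4))
})

test_that("random sequences yield no repeat calls at defaults", {
  set.seed(20)
  hits <- 0
  for (i in 1:100) {
    s <- random_dna(1000, freqs = c(0.44, 0.11, 0.07, 0.38))
    hits <- hits + nrow(find_tandem_repeats(s))
  }
  expect_equal(hits, 0)
})

test_that("planted 144-bp repeat is recovered with unit within 2 bp", {
  set.seed(21)
  pr <- plant_repeat_region(unit_length = 144, copies = 3.6,
                            unit_identity = 0.97)
  r <- find_tandem_repeats(pr$region)
  expect_equal(nrow(r), 1)
  expect_lte(abs(r$unit_length - 144), 2)
  expect_lt(abs(r$copy_number - 3.6), 0.25)
  expect_lt(abs(r$start - pr$truth$start), 6)
  expect_lt(abs(r$end - pr$truth$end), 6)
})

test_that("repeat detection is rotation-covariant", {
  set.seed(22)
  pr <- plant_repeat_region(unit_length = 60, copies = 4, flank = 150)
  r1 <- find_tandem_repeats(pr$region)
  # shift the repeat phase by slicing 20 bp off the front
  r2 <- find_tandem_repeats(substr(pr$region, 21, nchar(pr$region)))
  expect_equal(r2$unit_length, r1$unit_length)
  expect_lt(abs(r2$copy_number - r1$copy_number),
            1 + 1 / r1$unit_length)
})

test_that("conserved segments: identical copies give one near-full span", {
  set.seed(23)
  s <- random_dna(600, freqs = c(0.44, 0.11, 0.07, 0.38))
  regions <- stats::setNames(rep(list(s), 5), paste0("t", 1:5))
  sg <- find_conserved_segments(regions)
  expect_equal(nrow(sg), 1)
  expect_gt(sg$length, 0.95 * 600)
})

test_that("planted blocks are recovered at correct coordinates", {
  set.seed(24)
  ps <- plant_conserved_set(identity = 0.95)
  sg <- find_conserved_segments(ps$regions)
  expect_equal(nrow(sg), 4)
  for (tx in paste0("t", 1:5)) {
    tr <- ps$truth[ps$truth$taxon == tx, ]
    for (b in 1:4) {
      expect_lt(abs(sg[[paste0("start_", tx)]][b] - tr$start[b]), 4)
      expect_lt(abs(sg[[paste0("end_", tx)]][b] - tr$end[b]), 4)
    }
  }
})

test_that("segment finder needs two taxa and respects exclusions", {
  expect_error(find_conserved_segments(list(a = "ACGT")), "two taxa")
  set.seed(25)
  ps <- plant_conserved_set(n_blocks = 2, identity = 0.98)
  tr1 <- ps$truth[ps$truth$taxon == "t1", ]
  sg <- find_conserved_segments(
    ps$regions, exclude = data.frame(start = tr1$start[1],
                                     end = tr1$end[1]))
  expect_equal(nrow(sg), 1)
  expect_gt(sg$start_t1[1], tr1$end[1])
})

test_that("poly(N) runs are exact maximal runs", {
  expect_equal(poly_n_runs("AAAAA", 5),
               data.frame(base = "A", start = 1L, length = 5L,
                          stringsAsFactors = FALSE))
  expect_equal(nrow(poly_n_runs("AAAA", 5)), 0)
  r <- poly_n_runs("TTTTTTCGGGGG", 5)
  expect_equal(r$base, c("T", "G"))
  expect_equal(r$start, c(1L, 8L))
  expect_equal(r$length, c(6L, 5L))
  expect_error(poly_n_runs("AAAA", 1), "min_len")
})

test_that("hairpins: palindrome, poly-A, and brute-force equality", {
  h <- find_hairpins("GGGGAAAACCCC", min_stem = 4, max_loop = 8)
  expect_equal(nrow(h), 1)
  expect_equal(h$stem_length, 4)
  expect_equal(h$loop_length, 4)
  expect_equal(h$start, 1)
  expect_equal(h$end, 12)

  expect_equal(nrow(find_hairpins(strrep("A", 30))), 0)

  set.seed(26)
  for (i in 1:15) {
    s <- random_dna(sample(20:40, 1))
    got <- find_hairpins(s)
    want <- brute_hairpins(s)
    if (is.null(want)) {
      expect_equal(nrow(got), 0, info = s)
    } else {
      expect_equal(got[, c("start", "end", "stem_length", "loop_length")],
                   want[, c("start", "end", "stem_length", "loop_length")],
                   info = s)
    }
  }
})

test_that("suite control regions contain the planted structure", {
  suite <- sim_suite()
  regions <- lapply(suite$genomes, extract_gene, name = "AT_rich")
  tr_truth <- suite$truth$atrich

  reps1 <- find_tandem_repeats(regions[[1]])
  expect_equal(reps1$unit_length, tr_truth$repeat_region$unit_length)
  expect_lt(abs(reps1$copy_number - tr_truth$repeat_region$copy_number),
            0.3)

  sg <- find_conserved_segments(regions,
                                exclude = reps1[, c("start", "end")])
  expect_equal(nrow(sg), 4)
  for (b in seq_len(4)) {
    expect_true(any(sg$start_sim1 <= tr_truth$segments$end[b] &
                      sg$end_sim1 >= tr_truth$segments$start[b]))
  }

  # per-taxon planted poly(N) runs are all present
  for (tx in names(regions)) {
    pn <- poly_n_runs(regions[[tx]], min_len = 5)
    truth <- suite$truth$polyn_by_taxon[[tx]]
    for (r in seq_len(nrow(truth))) {
      hit <- any(pn$base == truth$base[r] &
                   pn$start <= truth$start[r] + truth$length[r] - 1 &
                   pn$start + pn$length - 1 >= truth$start[r])
      expect_true(hit, info = paste(tx, "run", r))
    }
  }

  # every conserved segment folds into at least one hairpin candidate
  seg2 <- tr_truth$segments
  s2 <- substr(regions[[1]], seg2$start[2], seg2$end[2])
  expect_gt(nrow(find_hairpins(s2)), 0)
})

test_that("self-match matrix export matches direct comparison", {
  s <- "ACGTACGTA"
  m <- self_match_matrix(s, max_period = 4)
  expect_equal(unname(m[1, "lag4"]), 1L)   # A vs A at lag 4
  expect_equal(unname(m[2, "lag1"]), 0L)   # C vs G
  expect_true(all(is.na(m[6:9, "lag4"])))
})
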