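# Shared fixtures: a tiny handmade genome and a cached simulated suite.

# hand-built circular toy genome: 4 genes + inferable AT-rich tail
toy_genome <- function() {
  trnI <- "ACGTACGTAC"                         # J, 1..10
  cox1 <- "ATGAAATTTCATTAA"                    # J CDS, complete stop
  nad1_coding <- "ATGCCCATTTAA"                # N strand: store revcomp
  rrnS <- "TTAACCGGTT"                         # N
  at_tail <- strrep("AT", 30)                  # 60 bp non-coding
  seq <- paste0(trnI, cox1, revcomp(nad1_coding), rrnS, at_tail)
  feats <- data.frame(
    name = c("trnI", "cox1", "nad1", "rrnS"),
    kind = c("tRNA", "PCG", "PCG", "rRNA"),
    start = c(1, 11, 26, 38),
    end = c(10, 25, 37, 47),
    strand = c("J", "J", "N", "N"),
    stringsAsFactors = FALSE)
  mito_genome("toy1", seq, feats, circular = TRUE, taxon = "toy taxon")
}

revcomp <- mitocomp:::revcomp

# default simulated 5-taxon suite, computed once per test run
.suite_env <- new.env()
sim_suite <- function() {
  if (is.null(.suite_env$suite))
    .suite_env$suite <- simulate_genomes(sim_config(seed = 42))
  .suite_env$suite
}

# rotate a circular genome so position offset+1 becomes position 1,
# shifting all feature coordinates accordingly (wraps allowed)
rotate_genome <- function(genome, offset) {
  n <- nchar(genome$sequence)
  seq2 <- mitocomp:::rotate_seq(genome$sequence, offset)
  sh <- function(x) ((x - offset - 1) %% n) + 1
  f <- genome$features
  f$start <- sh(f$start)
  f$end <- sh(f$end)
  mito_genome(paste0(genome$id, "_rot"), seq2, f, circular = TRUE,
              taxon = genome$taxon)
}

# brute-force global alignment score with affine gaps (open + ext * len),
# written as plain recursion independent of the package's aligner
brute_align_score <- function(a, b, match = 1, mismatch = -1,
                              gap_open = 2, gap_ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, state) {
    # state: 0 none, 1 gap in b (deletion), 2 gap in a (insertion)
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, 0))
    }
    if (i <= length(av)) {
      cost <- gap_ext + if (state == 1) 0 else gap_open
      best <- max(best, -cost + rec(i + 1, j, 1))
    }
    if (j <= length(bv)) {
      cost <- gap_ext + if (state == 2) 0 else gap_open
      best <- max(best, -cost + rec(i, j + 1, 2))
    }
    best
  }
  rec(1, 1, 0)
}

random_dna <- function(n, freqs = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = freqs),
        collapse = "")
}

# independent exhaustive hairpin enumeration: every (a, b, s) triple is
# checked directly, then the same deterministic best-first selection
brute_hairpins <- function(segment, min_stem = 4, max_loop = 30) {
  chars <- strsplit(toupper(segment), "")[[1]]
  L <- length(chars)
  pair_ok <- function(x, y) {
    paste0(x, y) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  }
  cand <- NULL
  for (a in seq_len(L)) {
    for (b in seq_len(L)) {
      if (b <= a) next
      for (s in min_stem:floor((b - a + 1) / 2)) {
        loop <- (b - a + 1) - 2 * s
        if (loop < 3 || loop > max_loop) next
        ok <- all(vapply(0:(s - 1), function(t)
          pair_ok(chars[a + t], chars[b - t]), logical(1)))
        if (!ok) next
        # outward-maximal: stem cannot be extended past a..b
        if (a > 1 && b < L && pair_ok(chars[a - 1], chars[b + 1])) next
        # s is the maximal run from the innermost pair outward
        inner_ok <- s == sum(cumprod(vapply(0:(s - 1), function(t)
          pair_ok(chars[a + t], chars[b - t]), logical(1))))
        if (!inner_ok) next
        cand <- rbind(cand, data.frame(start = a, end = b,
                                       stem_length = s,
                                       loop_length = loop,
                                       score = s))
      }
    }
  }
  if (is.null(cand)) return(cand)
  cand <- unique(cand)
  cand <- cand[order(-cand$score, cand$start, cand$loop_length), ]
  occupied <- rep(FALSE, L)
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    span <- cand$start[r]:cand$end[r]
    if (any(occupied[span])) next
    occupied[span] <- TRUE
    keep[r] <- TRUE
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}


# analytic expected pooled-site K2p total per gene under the generator's
# default world (positions mixed before the K2p transform, as the
# pipeline pools sites)
expected_gene_totals <- function(truth) {
  br <- c(truth$branch$pos1, truth$branch$pos2, truth$branch$pos3)
  sc <- truth$gene_scale
  n_strand <- c("nad1", "nad4", "nad4l", "nad5")
  vapply(rownames(sc), function(g) {
    fr <- mitocomp:::SIM_FREQS[[if (g %in% n_strand) "N" else "J"]]
    PQ <- sapply(1:3, function(p) {
      e <- expected_k2p_hky(2 * br[p] * sc[g, p], truth$kappa, fr[[p]])
      c(e$P, e$Q)
    })
    P <- mean(PQ[1, ]); Q <- mean(PQ[2, ])
    -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
  }, numeric(1))
}
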