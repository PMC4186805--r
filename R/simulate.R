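# Synthetic mitogenome generator with planted ground truth.
#
# The ancestral genome follows the putative ancestral insect gene order
# (37 genes: 13 PCGs, 22 tRNAs, 2 rRNAs; 23 on the J strand, 14 on the
# N strand) with the control (AT-rich) region between rrnS and trnI.
# Descendant taxa evolve independently from the ancestor (star tree)
# under a per-site substitution process with the K2p
# transition/transversion structure and the planted stationary base
# frequencies (i.e. HKY), so composition is preserved while the expected
# number of substitutions per site equals the planted branch length.
# Within-genome tandem-repeat copies are kept homogenized (concerted
# evolution): the unit evolves at the full control-region rate and is
# re-tiled per taxon.

# ancestral insect mitogenome gene order; J-strand coordinates
SIM_GENE_ORDER <- data.frame(
  name = c("trnI", "trnQ", "trnM", "nad2", "trnW", "trnC", "trnY",
           "cox1", "trnL2", "cox2", "trnK", "trnD", "atp8", "atp6",
           "cox3", "trnG", "nad3", "trnA", "trnR", "trnN", "trnS1",
           "trnE", "trnF", "nad5", "trnH", "nad4", "nad4l", "trnT",
           "trnP", "nad6", "cytb", "trnS2", "nad1", "trnL1", "rrnL",
           "trnV", "rrnS"),
  kind = c("tRNA", "tRNA", "tRNA", "PCG", "tRNA", "tRNA", "tRNA",
           "PCG", "tRNA", "PCG", "tRNA", "tRNA", "PCG", "PCG",
           "PCG", "tRNA", "PCG", "tRNA", "tRNA", "tRNA", "tRNA",
           "tRNA", "tRNA", "PCG", "tRNA", "PCG", "PCG", "tRNA",
           "tRNA", "PCG", "PCG", "tRNA", "PCG", "tRNA", "rRNA",
           "tRNA", "rRNA"),
  strand = c("J", "N", "J", "J", "J", "N", "N",
             "J", "J", "J", "J", "J", "J", "J",
             "J", "J", "J", "J", "J", "J", "J",
             "J", "N", "N", "N", "N", "N", "J",
             "N", "J", "J", "J", "N", "N", "N",
             "N", "N"),
  stringsAsFactors = FALSE)

# cox1/cox2 lengths are 1 and 2 mod 3: they end in incomplete stops
SIM_PCG_LENGTHS <- c(nad2 = 1023, cox1 = 1537, cox2 = 686, atp8 = 156,
                     atp6 = 678, cox3 = 789, nad3 = 354, nad5 = 1719,
                     nad4 = 1344, nad4l = 288, nad6 = 522, cytb = 1137,
                     nad1 = 942)

# relative rate multipliers per PCG and codon position (gene rate over
# the all-PCG rate at that position); fastest atp8, slowest cox1, with
# the second position spreading most between genes
SIM_GENE_POS_SCALE <- matrix(c(
  # pos1 / 0.120, pos2 / 0.057, pos3 / 0.330
  0.176, 0.141, 0.434,   # atp8
  0.135, 0.061, 0.307,   # atp6
  0.076, 0.011, 0.355,   # cox1
  0.093, 0.026, 0.346,   # cox2
  0.101, 0.049, 0.342,   # cox3
  0.116, 0.039, 0.385,   # cytb
  0.197, 0.098, 0.307,   # nad2
  0.123, 0.074, 0.320,   # nad3
  0.140, 0.119, 0.303,   # nad6
  0.105, 0.045, 0.339,   # nad1
  0.097, 0.058, 0.286,   # nad4
  0.161, 0.049, 0.350,   # nad4l
  0.147, 0.084, 0.321),  # nad5
  ncol = 3, byrow = TRUE,
  dimnames = list(c("atp8", "atp6", "cox1", "cox2", "cox3", "cytb",
                    "nad2", "nad3", "nad6", "nad1", "nad4", "nad4l",
                    "nad5"), NULL))
SIM_GENE_POS_SCALE <- sweep(SIM_GENE_POS_SCALE, 2,
                            c(0.120, 0.057, 0.330), "/")

# six start-codon kinds (ATN, GTG, TTG) distributed over the 13 PCGs
SIM_START_CODONS <- c(nad2 = "ATT", cox1 = "ATG", cox2 = "ATG",
                      atp8 = "ATC", atp6 = "ATG", cox3 = "ATG",
                      nad3 = "ATA", nad5 = "GTG", nad4 = "ATG",
                      nad4l = "ATG", nad6 = "TTG", cytb = "ATG",
                      nad1 = "ATA")

# genes whose CDS ends with an incomplete stop (completed by
# polyadenylation); all others end with complete TAA
SIM_INCOMPLETE_STOPS <- c(cox1 = "T", cox2 = "TA")

# PCG-PCG overlap pairs share 7 nt: in coding space the upstream
# neighbour ends ...ATA TGA TAA and the downstream one starts ATG ATA A,
# so both frames read the ATGATAA motif. For the J-strand pairs
# (atp8/atp6, nad6/cytb) the downstream-in-J gene is also downstream in
# coding space; for the N-strand pair nad4/nad4l the coding order is
# reversed: nad4 carries the head motif and nad4l the tail motif, while
# in J coordinates nad4l still starts 7 nt before nad4 ends.
SIM_OVERLAP_PAIRS <- list(c("atp8", "atp6"), c("nad4", "nad4l"),
                          c("nad6", "cytb"))
SIM_TAIL_MOTIF_GENES <- c("atp8", "nad6", "nad4l")
SIM_HEAD_MOTIF_GENES <- c("atp6", "cytb", "nad4")

stationary_freqs <- function(vec_tcag) {
  # tables print T, C, A, G percentages; internally A, C, G, T
  p <- c(A = vec_tcag[3], C = vec_tcag[2], G = vec_tcag[4],
         T = vec_tcag[1])
  p / sum(p)
}

SIM_FREQS <- list(
  J = list(stationary_freqs(c(28.1, 13.2, 42.9, 15.8)),
           stationary_freqs(c(45.3, 20.3, 21.4, 13.0)),
           stationary_freqs(c(26.5, 12.1, 59.6, 1.7))),
  N = list(stationary_freqs(c(47.0, 7.4, 27.1, 18.4)),
           stationary_freqs(c(50.6, 13.8, 18.9, 16.7)),
           stationary_freqs(c(62.2, 2.0, 24.8, 11.0))),
  trna = stationary_freqs(c(35.6, 9.5, 44.4, 10.4)),
  rrna = stationary_freqs(c(49.7, 7.0, 30.0, 13.3)),
  atrich = stationary_freqs(c(37.8, 11.1, 43.6, 7.4)))

#' Simulation configuration
#'
#' Branch lengths are per-branch expected substitutions per site on a
#' star tree, so every pairwise planted distance is twice the branch
#' length; per-gene multipliers scale the positional PCG rates.
#'
#' @param n_taxa number of descendant taxa.
#' @param seed integer seed fixing all outputs.
#' @param branch named list of per-branch rates (pos1, pos2, pos3,
#'   trna_J, trna_N, rrna, atrich, element).
#' @param kappa transition/transversion rate ratio of the substitution
#'   process.
#' @param gene_scale named per-PCG rate multipliers.
#' @param nonsyn_scaling acceptance probability of nonsynonymous
#'   proposals in \code{simulate_codon_pair} (purifying selection).
#' @param atrich_plan control-region plan, see
#'   \code{default_atrich_plan}.
#' @param gc_coupling strength of the planted per-gene GC/rate coupling
#'   (negative at positions 1-2, positive at position 3).
#' @param indel_codons number of codons deleted from the second taxon's
#'   copy of each gene in \code{indel_genes} (exercises the aligner).
#' @param indel_genes genes receiving the planted deletion.
#' @param length_scale multiplier applied to gene lengths (PCGs, tRNAs,
#'   rRNAs); used by recovery tests that need more sites per partition.
#' @return SimulationConfig list.
#' @export
sim_config <- function(n_taxa = 5, seed = 1,
                       branch = list(pos1 = 0.060, pos2 = 0.0285,
                                     pos3 = 0.165, trna_J = 0.037,
                                     trna_N = 0.0675, rrna = 0.045,
                                     atrich = 0.45, element = 0.02),
                       kappa = 3,
                       gene_scale = SIM_GENE_POS_SCALE,
                       nonsyn_scaling = 0.1,
                       atrich_plan = default_atrich_plan(),
                       gc_coupling = 0.25,
                       indel_codons = 0,
                       indel_genes = "cox2",
                       length_scale = 1) {
  stopifnot(n_taxa >= 2, all(unlist(branch) >= 0), length_scale >= 1)
  structure(list(n_taxa = n_taxa, seed = as.integer(seed),
                 branch = branch, kappa = kappa, gene_scale = gene_scale,
                 nonsyn_scaling = nonsyn_scaling,
                 atrich_plan = atrich_plan, gc_coupling = gc_coupling,
                 indel_codons = indel_codons, indel_genes = indel_genes,
                 length_scale = length_scale),
            class = "SimulationConfig")
}

#' Default control-region plan
#'
#' A tandem-repeat area (unit 144 bp, about 3.6 copies), four conserved
#' segments (two short terminal, two longer central, segment 2 carrying
#' a planted hairpin), and a poly(N) zone between segments 3 and 4 with
#' run lengths 5-9, inside an AT-rich background; total about 826 bp.
#'
#' @param repeat_unit repeat unit length (bp).
#' @param repeat_copies planted copy number (fractional).
#' @param segment_lengths lengths of the conserved segments.
#' @param polyn named run lengths (base -> length).
#' @return plan list.
#' @export
default_atrich_plan <- function(repeat_unit = 144, repeat_copies = 3.58,
                                segment_lengths = c(25, 40, 35, 20),
                                polyn = c(T = 9, A = 7, C = 6, G = 5)) {
  list(repeat_unit = repeat_unit, repeat_copies = repeat_copies,
       segment_lengths = segment_lengths, polyn = polyn,
       gap_lengths = c(30, 40, 28, 24))
}

# ---- substitution process ------------------------------------------------

# HKY transition-probability matrix: K2p transition/transversion
# structure with stationary frequencies pi, scaled so the expected
# number of substitutions per site equals d
hky_pmat <- function(d, kappa, pi) {
  pi <- pi / sum(pi)
  is_ti <- matrix(FALSE, 4, 4, dimnames = list(BASES, BASES))
  is_ti["A", "G"] <- is_ti["G", "A"] <- TRUE
  is_ti["C", "T"] <- is_ti["T", "C"] <- TRUE
  Q <- matrix(rep(pi, each = 4), 4, 4, dimnames = list(BASES, BASES))
  Q[is_ti] <- Q[is_ti] * kappa
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  sq <- sqrt(pi)
  B <- (sq * Q) %*% diag(1 / sq)
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  P <- diag(1 / sq) %*% eg$vectors %*% diag(exp(eg$values * d)) %*%
    t(eg$vectors) %*% diag(sq)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(BASES, BASES)
  P
}

#' Expected K2p statistic under the simulation process
#'
#' Closed-form expectation of the observed transition and transversion
#' proportions after d substitutions per site under the HKY process,
#' plugged into the K2p formula. This is the analytic target for
#' end-to-end pipeline recovery tests (the K2p estimator itself is only
#' unbiased under the symmetric K2p process).
#'
#' @param d true distance (expected substitutions/site along the path).
#' @param kappa transition/transversion rate ratio.
#' @param pi stationary base frequencies (A, C, G, T).
#' @param pi0 base composition of the common ancestor (defaults to the
#'   stationary frequencies); both descendants evolve d/2 from it.
#' @return list (P, Q, k2p).
#' @export
expected_k2p_hky <- function(d, kappa, pi, pi0 = NULL) {
  pi <- pi / sum(pi)
  if (is.null(pi0)) {
    pi0 <- pi
  } else {
    if (is.null(names(pi0))) names(pi0) <- BASES
    pi0 <- pi0[BASES] / sum(pi0)
  }
  M <- hky_pmat(d / 2, kappa, pi)
  joint <- t(M) %*% (pi0 * M)    # P(x at tip 1, y at tip 2)
  purine <- c("A", "G")
  Pexp <- 0; Qexp <- 0
  for (x in BASES) for (y in BASES) {
    if (x == y) next
    if ((x %in% purine) == (y %in% purine)) Pexp <- Pexp + joint[x, y]
    else Qexp <- Qexp + joint[x, y]
  }
  list(P = Pexp, Q = Qexp,
       k2p = -0.5 * log((1 - 2 * Pexp - Qexp) * sqrt(1 - 2 * Qexp)))
}

sample_bases <- function(n, pi) {
  sample(BASES, n, replace = TRUE, prob = pi / sum(pi))
}

# evolve a character vector one branch: each site substitutes according
# to the row of the transition matrix for its current base
evolve_chars <- function(chars, P) {
  out <- chars
  for (b in BASES) {
    idx <- which(chars == b)
    if (length(idx))
      out[idx] <- sample(BASES, length(idx), replace = TRUE,
                         prob = P[b, ])
  }
  out
}

evolve_seq <- function(seq, d, kappa, pi) {
  if (d <= 0) return(seq)
  chars_seq(evolve_chars(seq_chars(seq), hky_pmat(d, kappa, pi)))
}

#' Simulate one sequence pair under the strict K2p (K80) process
#'
#' Equal base frequencies; used for estimator-recovery properties where
#' the generating model must be exactly the one the estimator assumes.
#' Total path distance d is split over the two branches.
#'
#' @param n_sites number of sites.
#' @param d true pairwise distance (substitutions/site).
#' @param kappa transition/transversion rate ratio.
#' @return list of two DNA strings (a, b).
#' @export
simulate_k2p_pair <- function(n_sites, d, kappa = 3) {
  pi <- rep(0.25, 4)
  anc <- sample_bases(n_sites, pi)
  P <- hky_pmat(d / 2, kappa, pi)
  list(a = chars_seq(evolve_chars(anc, P)),
       b = chars_seq(evolve_chars(anc, P)))
}

#' Simulate a codon-sequence pair under purifying selection
#'
#' Substitutions are proposed per site under the K2p kernel at proposal
#' distance \code{d_prop}; a proposal whose amino acid differs from the
#' current codon's is accepted with probability \code{nonsyn_scaling},
#' and proposals creating stop codons are rejected. Truth: synonymous
#' changes accrue at roughly the proposal rate, nonsynonymous ones at
#' \code{nonsyn_scaling} times it.
#'
#' @param n_codons number of codons.
#' @param d_prop proposal distance per branch (two branches total).
#' @param kappa transition/transversion ratio.
#' @param nonsyn_scaling acceptance probability for nonsynonymous
#'   proposals.
#' @return list of two CDS strings (a, b).
#' @export
simulate_codon_pair <- function(n_codons, d_prop, kappa = 3,
                                nonsyn_scaling = 0.1) {
  code <- mito_code()
  sense <- names(code)[code != "*"]
  anc <- sample(sense, n_codons, replace = TRUE)
  evolve_branch <- function(cods) {
    # expected proposals per site ~ d_prop; one sweep of per-site
    # Bernoulli proposals is adequate at the small d_prop used in tests
    chars <- seq_chars(paste(cods, collapse = ""))
    n <- length(chars)
    hit <- which(stats::runif(n) < d_prop)
    for (i in hit) {
      cur <- chars[i]
      others <- setdiff(BASES, cur)
      w <- ifelse(vapply(others, function(b) {
        (cur %in% c("A", "G") && b %in% c("A", "G")) ||
          (cur %in% c("C", "T") && b %in% c("C", "T"))
      }, logical(1)), kappa, 1)
      prop <- sample(others, 1, prob = w)
      ci <- (i - 1) %/% 3
      cod <- chars_seq(chars[(ci * 3 + 1):(ci * 3 + 3)])
      newc <- chars
      newc[i] <- prop
      ncod <- chars_seq(newc[(ci * 3 + 1):(ci * 3 + 3)])
      if (unname(code[ncod]) == "*") next
      accept <- code[ncod] == code[cod] ||
        stats::runif(1) < nonsyn_scaling
      if (accept) chars[i] <- prop
    }
    n3 <- length(chars)
    substring(paste(chars, collapse = ""), seq(1, n3, 3), seq(3, n3, 3))
  }
  a <- evolve_branch(anc)
  b <- evolve_branch(anc)
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

# ---- ancestral genome construction ---------------------------------------

# shift G+C mass of a frequency vector by `factor`, renormalized
adjust_gc <- function(pi, factor) {
  p <- pi
  p[c("C", "G")] <- p[c("C", "G")] * max(factor, 0.05)
  p / sum(p)
}

# positional frequency vectors for one gene, with the planted GC/rate
# coupling: genes fast at positions 1-2 get less GC there, genes fast at
# position 3 get slightly more
gene_freqs <- function(gene, strand, scale, gc_coupling) {
  base <- SIM_FREQS[[strand]]
  list(adjust_gc(base[[1]], 1 - gc_coupling * (scale[1] - 1)),
       adjust_gc(base[[2]], 1 - gc_coupling * (scale[2] - 1)),
       adjust_gc(base[[3]], 1 + gc_coupling * (scale[3] - 1)))
}

# sample n codons from positional frequencies, rejecting stop codons
sample_codons <- function(n, freqs, code) {
  stops <- names(code)[code == "*"]
  p1 <- sample(BASES, n, TRUE, freqs[[1]])
  p2 <- sample(BASES, n, TRUE, freqs[[2]])
  p3 <- sample(BASES, n, TRUE, freqs[[3]])
  cods <- paste0(p1, p2, p3)
  bad <- which(cods %in% stops)
  while (length(bad)) {
    cods[bad] <- paste0(sample(BASES, length(bad), TRUE, freqs[[1]]),
                        sample(BASES, length(bad), TRUE, freqs[[2]]),
                        sample(BASES, length(bad), TRUE, freqs[[3]]))
    bad <- bad[cods[bad] %in% stops]
  }
  cods
}

# ancestral CDS in coding orientation honouring start/stop/overlap motifs
make_ancestral_pcg <- function(gene, strand, scale, gc_coupling, code,
                               length_scale = 1) {
  # scale: length-3 per-position rate multipliers
  len <- SIM_PCG_LENGTHS[[gene]]
  if (length_scale > 1)
    len <- len + 3L * round(len * (length_scale - 1) / 3)
  inc <- SIM_INCOMPLETE_STOPS[gene]
  tail_len <- if (!is.na(inc)) nchar(inc) else 3L
  freqs <- gene_freqs(gene, strand, scale, gc_coupling)
  is_tail_overlap <- gene %in% SIM_TAIL_MOTIF_GENES
  is_head_overlap <- gene %in% SIM_HEAD_MOTIF_GENES
  n_body <- (len - 3L - tail_len) %/% 3L   # codons between start and tail
  cods <- sample_codons(n_body, freqs, code)
  if (is_tail_overlap) {
    # coding tail ...ATA TGA TAA so the last 7 nt read ATGATAA
    cods[(n_body - 1):n_body] <- c("ATA", "TGA")
    tail_cod <- "TAA"
  } else {
    tail_cod <- if (!is.na(inc)) inc else "TAA"
  }
  head <- SIM_START_CODONS[[gene]]
  if (is_head_overlap) {
    # head reads ATG ATA A.. (shares ATGATAA with the upstream tail)
    head <- "ATG"
    cods[1] <- "ATA"
    repeat {
      c3 <- paste0("A", sample(BASES, 1, prob = freqs[[2]]),
                   sample(BASES, 1, prob = freqs[[3]]))
      if (unname(code[c3]) != "*") break
    }
    cods[2] <- c3
  }
  paste0(head, paste(cods, collapse = ""), tail_cod)
}

# clamped positions of a PCG (start codon, stop tail, overlap motifs):
# these sites are restored after evolution so all taxa share them
pcg_clamp_idx <- function(gene, len) {
  inc <- SIM_INCOMPLETE_STOPS[gene]
  tail_len <- if (!is.na(inc)) nchar(inc) else 3L
  idx <- c(1:3, (len - tail_len + 1):len)
  if (gene %in% SIM_TAIL_MOTIF_GENES) idx <- c(idx, (len - 8):len)
  if (gene %in% SIM_HEAD_MOTIF_GENES) idx <- c(idx, 1:9)
  sort(unique(idx))
}

# internal stops are disallowed: codons that evolved into TAA/TAG are
# re-evolved from their ancestral state until non-stop (rejection keeps
# the realized per-position substitution rates unbiased to first order)
fix_internal_stops <- function(chars, anc_chars, pmats) {
  n <- length(chars)
  ncod <- n %/% 3
  if (ncod < 3) return(chars)
  for (ci in 2:(ncod - 1)) {
    i <- (ci - 1) * 3 + 1
    for (tries in 1:25) {
      cod <- paste0(chars[i], chars[i + 1], chars[i + 2])
      if (!cod %in% c("TAA", "TAG")) break
      for (pos in 1:3)
        chars[i + pos - 1] <- sample(BASES, 1,
                                     prob = pmats[[pos]][anc_chars[i + pos - 1], ])
    }
    if (paste0(chars[i], chars[i + 1], chars[i + 2]) %in% c("TAA", "TAG"))
      chars[(i):(i + 2)] <- anc_chars[(i):(i + 2)]
  }
  chars
}

# ---- AT-rich region construction -----------------------------------------

build_atrich <- function(plan, element_pi = SIM_FREQS$atrich) {
  unit <- chars_seq(sample_bases(plan$repeat_unit, element_pi))
  rep_len_total <- round(plan$repeat_unit * plan$repeat_copies)
  seg_len <- plan$segment_lengths
  gaps <- plan$gap_lengths
  mkbg <- function(n) chars_seq(sample_bases(n, element_pi))
  seg1 <- mkbg(seg_len[1])
  stem <- chars_seq(sample(BASES, 8, TRUE, prob = c(.2, .3, .3, .2)))
  loop <- mkbg(6)
  seg2_core <- paste0(stem, loop, revcomp(stem))
  seg2 <- paste0(seg2_core, mkbg(seg_len[2] - nchar(seg2_core)))
  seg3 <- mkbg(seg_len[3])
  seg4 <- mkbg(seg_len[4])
  rep_area <- substr(paste(rep(unit, ceiling(plan$repeat_copies) + 1),
                           collapse = ""), 1, rep_len_total)
  pn <- plan$polyn
  polyzone <- paste0(strrep("T", pn[["T"]]), mkbg(4),
                     strrep("A", pn[["A"]]), mkbg(5),
                     strrep("C", pn[["C"]]), mkbg(4),
                     strrep("G", pn[["G"]]))
  parts <- list(seg1 = seg1, gap1 = mkbg(gaps[1]), rep = rep_area,
                seg2 = seg2, gap2 = mkbg(gaps[2]), seg3 = seg3,
                polyzone = polyzone, gap3 = mkbg(gaps[3]), seg4 = seg4,
                tail = mkbg(gaps[4]))
  lens <- vapply(parts, nchar, integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  names(starts) <- names(ends) <- names(parts)
  polyn_truth <- local({
    off <- starts[["polyzone"]] - 1L
    pos <- c(0, pn[["T"]] + 4, pn[["T"]] + 4 + pn[["A"]] + 5,
             pn[["T"]] + 4 + pn[["A"]] + 5 + pn[["C"]] + 4)
    data.frame(base = c("T", "A", "C", "G"),
               start = off + pos + 1L,
               length = as.integer(pn[c("T", "A", "C", "G")]),
               stringsAsFactors = FALSE)
  })
  list(sequence = paste(unlist(parts), collapse = ""),
       unit = unit, parts = parts, starts = starts, ends = ends,
       truth = list(
         repeat_region = data.frame(start = starts[["rep"]],
                                    end = ends[["rep"]],
                                    unit_length = plan$repeat_unit,
                                    copy_number = round(plan$repeat_copies, 1)),
         segments = data.frame(
           segment_id = 1:4,
           start = unname(starts[c("seg1", "seg2", "seg3", "seg4")]),
           end = unname(ends[c("seg1", "seg2", "seg3", "seg4")])),
         polyn = polyn_truth,
         hairpin_segment = 2L))
}

# evolve one taxon's control region: background at the atrich rate,
# conserved segments at the element rate, repeat area homogenized from a
# unit evolved at the atrich rate (concerted evolution), and poly(N)
# runs re-stamped with a per-taxon permutation of the run bases (runs
# are a shared structural motif but not column-wise homologous, so the
# zone is not itself a conserved segment). Returns the sequence plus the
# taxon's poly(N) truth rows.
evolve_atrich <- function(anc, branch, kappa, plan) {
  slow_parts <- c("seg1", "seg2", "seg3", "seg4")
  out <- seq_chars(anc$sequence)
  P_fast <- hky_pmat(branch$atrich, kappa, SIM_FREQS$atrich)
  P_slow <- hky_pmat(branch$element, kappa, SIM_FREQS$atrich)
  out <- evolve_chars(out, P_fast)
  for (p in slow_parts) {
    span <- anc$starts[[p]]:anc$ends[[p]]
    out[span] <- evolve_chars(seq_chars(anc$parts[[p]]), P_slow)
  }
  unit_t <- evolve_chars(seq_chars(anc$unit), P_fast)
  span <- anc$starts[["rep"]]:anc$ends[["rep"]]
  tiled <- rep(unit_t, length.out = length(span))
  out[span] <- evolve_chars(tiled, hky_pmat(branch$element / 2, kappa,
                                            SIM_FREQS$atrich))
  # zero-rate control: no shuffling, descendants stay identical
  perm <- if (branch$atrich > 0) sample(c("T", "A", "C", "G")) else
    c("T", "A", "C", "G")
  polyn <- anc$truth$polyn
  polyn$base <- perm[match(polyn$base, c("T", "A", "C", "G"))]
  for (r in seq_len(nrow(polyn))) {
    span <- polyn$start[r]:(polyn$start[r] + polyn$length[r] - 1L)
    out[span] <- polyn$base[r]
  }
  list(sequence = chars_seq(out), polyn = polyn)
}

# ---- genome assembly and top-level simulation ----------------------------

# assemble one taxon's genome from per-gene coding sequences; spacers
# are shared across taxa, overlapping genes drop their first 7 J-bases
assemble_genome <- function(id, gene_seqs, atrich_seq, spacers) {
  order_tbl <- SIM_GENE_ORDER
  head_overlap <- vapply(SIM_OVERLAP_PAIRS, `[`, character(1), 2)
  seq_parts <- character(0)
  feats <- list()
  cur <- 0L
  for (i in seq_len(nrow(order_tbl))) {
    g <- order_tbl$name[i]
    strand <- order_tbl$strand[i]
    coding <- gene_seqs[[g]]
    jrep <- if (strand == "N") revcomp(coding) else coding
    if (g %in% head_overlap) {
      start <- cur - 6L
      seq_parts <- c(seq_parts, substr(jrep, 8, nchar(jrep)))
      cur <- start + nchar(jrep) - 1L
    } else {
      sp <- spacers[[g]]
      if (nchar(sp)) seq_parts <- c(seq_parts, sp)
      start <- cur + nchar(sp) + 1L
      seq_parts <- c(seq_parts, jrep)
      cur <- start + nchar(jrep) - 1L
    }
    feats[[i]] <- data.frame(name = g, kind = order_tbl$kind[i],
                             start = start, end = cur, strand = strand,
                             stringsAsFactors = FALSE)
  }
  at_start <- cur + 1L
  seq_parts <- c(seq_parts, atrich_seq)
  cur <- cur + nchar(atrich_seq)
  feats[[length(feats) + 1]] <- data.frame(
    name = "AT_rich", kind = "region", start = at_start, end = cur,
    strand = "J", stringsAsFactors = FALSE)
  mito_genome(id, paste(seq_parts, collapse = ""),
              do.call(rbind, feats), circular = TRUE, taxon = id)
}

#' Simulate a set of annotated mitogenomes with ground truth
#'
#' Builds a 37-gene ancestral insect-order mitogenome and evolves
#' \code{n_taxa} descendants on a star tree under per-partition HKY
#' substitution (K2p transition/transversion structure, planted
#' stationary composition). The control region carries a planted tandem
#' repeat (kept homogenized within each genome, emulating concerted
#' evolution), four conserved segments, and poly(N) runs.
#'
#' @param config SimulationConfig from \code{sim_config}.
#' @return list (ancestor, genomes, truth); truth holds planted pairwise
#'   distances per partition (both the process distance and the analytic
#'   expectation of the K2p statistic), element coordinates within the
#'   AT-rich region, planted composition and per-gene rate scales.
#' @export
simulate_genomes <- function(config = sim_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  code <- mito_code()
  br <- config$branch
  order_tbl <- SIM_GENE_ORDER
  trna_len <- as.integer(66 * config$length_scale)
  rrna_len <- as.integer(c(rrnL = 1253, rrnS = 777) * config$length_scale)
  names(rrna_len) <- c("rrnL", "rrnS")

  anc_seqs <- list()
  for (i in seq_len(nrow(order_tbl))) {
    g <- order_tbl$name[i]
    kind <- order_tbl$kind[i]
    strand <- order_tbl$strand[i]
    anc_seqs[[g]] <- switch(
      kind,
      PCG = make_ancestral_pcg(g, strand, config$gene_scale[g, ],
                               config$gc_coupling, code,
                               config$length_scale),
      tRNA = chars_seq(sample_bases(trna_len, SIM_FREQS$trna)),
      rRNA = chars_seq(sample_bases(rrna_len[[g]], SIM_FREQS$rrna)))
  }
  at <- build_atrich(config$atrich_plan)
  head_overlap <- vapply(SIM_OVERLAP_PAIRS, `[`, character(1), 2)
  spacers <- list()
  for (g in order_tbl$name) {
    spacers[[g]] <- if (g %in% head_overlap) "" else
      chars_seq(sample_bases(sample(0:4, 1), SIM_FREQS$atrich))
  }

  ancestor <- assemble_genome("ancestor", anc_seqs, at$sequence, spacers)

  taxa_ids <- paste0("sim", seq_len(config$n_taxa))
  genomes <- list()
  polyn_by_taxon <- list()
  for (tx in taxa_ids) {
    gene_seqs <- list()
    for (i in seq_len(nrow(order_tbl))) {
      g <- order_tbl$name[i]
      kind <- order_tbl$kind[i]
      strand <- order_tbl$strand[i]
      anc <- anc_seqs[[g]]
      if (kind == "PCG") {
        scale <- config$gene_scale[g, ]
        freqs <- gene_freqs(g, strand, scale, config$gc_coupling)
        chars <- seq_chars(anc)
        len <- length(chars)
        pmats <- list()
        for (pos in 1:3) {
          idx <- seq(pos, len - len %% 3, by = 3)
          idx <- idx[idx <= len]
          d <- br[[paste0("pos", pos)]] * scale[pos]
          pmats[[pos]] <- hky_pmat(d, config$kappa, freqs[[pos]])
          chars[idx] <- evolve_chars(chars[idx], pmats[[pos]])
        }
        if (len %% 3) {  # incomplete terminal codon evolves at pos rates
          extra <- (len - len %% 3 + 1):len
          chars[extra] <- seq_chars(anc)[extra]
        }
        chars <- fix_internal_stops(chars, seq_chars(anc), pmats)
        clamp <- pcg_clamp_idx(g, len)
        chars[clamp] <- seq_chars(anc)[clamp]
        gene_seqs[[g]] <- chars_seq(chars)
      } else if (kind == "tRNA") {
        d <- if (strand == "J") br$trna_J else br$trna_N
        gene_seqs[[g]] <- evolve_seq(anc, d, config$kappa,
                                     SIM_FREQS$trna)
      } else {
        gene_seqs[[g]] <- evolve_seq(anc, br$rrna, config$kappa,
                                     SIM_FREQS$rrna)
      }
    }
    at_evo <- evolve_atrich(at, br, config$kappa, config$atrich_plan)
    at_seq <- at_evo$sequence
    polyn_by_taxon[[tx]] <- at_evo$polyn
    if (config$indel_codons > 0 && tx == taxa_ids[2]) {
      for (g in intersect(config$indel_genes, names(gene_seqs))) {
        s <- gene_seqs[[g]]
        ncod <- nchar(s) %/% 3
        cut <- (ncod %/% 2) * 3
        gene_seqs[[g]] <- paste0(substr(s, 1, cut),
                                 substr(s, cut + 3 * config$indel_codons + 1,
                                        nchar(s)))
      }
    }
    genomes[[tx]] <- assemble_genome(tx, gene_seqs, at_seq, spacers)
  }

  # realized ancestral compositions (stop-codon rejection and sampling
  # noise move the ancestor slightly off stationarity, and the analytic
  # expectation accounts for that)
  comp_of <- function(strings) {
    ch <- unlist(lapply(strings, seq_chars))
    tab <- table(factor(ch, levels = BASES))
    as.numeric(tab) / sum(tab) -> p
    names(p) <- BASES
    p
  }
  pcgJ <- order_tbl$name[order_tbl$kind == "PCG" & order_tbl$strand == "J"]
  pos_chars <- function(genes, pos) {
    vapply(genes, function(g) {
      s <- anc_seqs[[g]]
      len <- nchar(s) - nchar(s) %% 3
      paste(seq_chars(s)[seq(pos, len, by = 3)], collapse = "")
    }, character(1))
  }
  pi0 <- list(
    pos1 = comp_of(pos_chars(pcgJ, 1)),
    pos2 = comp_of(pos_chars(pcgJ, 2)),
    pos3 = comp_of(pos_chars(pcgJ, 3)),
    trna_J = comp_of(anc_seqs[order_tbl$name[order_tbl$kind == "tRNA" &
                                             order_tbl$strand == "J"]]),
    trna_N = comp_of(anc_seqs[order_tbl$name[order_tbl$kind == "tRNA" &
                                             order_tbl$strand == "N"]]),
    rrna = comp_of(anc_seqs[c("rrnL", "rrnS")]))
  pair_dist <- function(d, pi, pi0_part) {
    e <- expected_k2p_hky(2 * d, config$kappa, pi, pi0 = pi0_part)
    c(true = 2 * d, k2p_expected = e$k2p)
  }
  truth <- list(
    branch = br, kappa = config$kappa, gene_scale = config$gene_scale,
    ancestral_composition = pi0,
    pairwise = list(
      pos1 = pair_dist(br$pos1, SIM_FREQS$J[[1]], pi0$pos1),
      pos2 = pair_dist(br$pos2, SIM_FREQS$J[[2]], pi0$pos2),
      pos3 = pair_dist(br$pos3, SIM_FREQS$J[[3]], pi0$pos3),
      trna_J = pair_dist(br$trna_J, SIM_FREQS$trna, pi0$trna_J),
      trna_N = pair_dist(br$trna_N, SIM_FREQS$trna, pi0$trna_N),
      rrna = pair_dist(br$rrna, SIM_FREQS$rrna, pi0$rrna)),
    composition = SIM_FREQS,
    atrich = at$truth,
    polyn_by_taxon = polyn_by_taxon,
    atrich_length = nchar(at$sequence))
  list(ancestor = ancestor, genomes = genomes, truth = truth)
}

# ---- constructed (non-evolved) structure fixtures ------------------------

#' Plant conserved blocks in unrelated random backgrounds
#'
#' Builds one region per taxon consisting of independent random
#' background with \code{n_blocks} shared blocks inserted at the same
#' relative order (random per-taxon offsets); each taxon's copy of a
#' block differs from the block consensus by independent per-base
#' mutation, calibrated so the expected pairwise identity between any
#' two copies is \code{identity} (each copy is mutated at rate
#' \code{(1 - identity) / 2} relative to the consensus).
#'
#' @param n_taxa taxa count.
#' @param n_blocks number of planted blocks.
#' @param block_len_range length range of the blocks.
#' @param identity expected pairwise identity between block copies.
#' @param region_len approximate background length per taxon.
#' @return list (regions: named list of strings, truth: data.frame of
#'   per-taxon block coordinates).
#' @export
plant_conserved_set <- function(n_taxa = 5, n_blocks = 4,
                                block_len_range = c(20, 40),
                                identity = 0.95, region_len = 600) {
  pi <- SIM_FREQS$atrich
  blocks <- lapply(seq_len(n_blocks), function(i) {
    len <- sample(block_len_range[1]:block_len_range[2], 1)
    sample_bases(len, pi)
  })
  gap <- max(10L, (region_len - sum(lengths(blocks))) %/% (n_blocks + 1))
  taxa <- paste0("t", seq_len(n_taxa))
  regions <- list()
  truth <- list()
  for (tx in taxa) {
    parts <- character(0)
    pos <- 0L
    rows <- list()
    for (b in seq_len(n_blocks)) {
      glen <- gap + sample(-5:5, 1)
      parts <- c(parts, chars_seq(sample_bases(glen, pi)))
      pos <- pos + glen
      copy <- blocks[[b]]
      mut <- which(stats::runif(length(copy)) < (1 - identity) / 2)
      for (m in mut) copy[m] <- sample(setdiff(BASES, copy[m]), 1)
      parts <- c(parts, chars_seq(copy))
      rows[[b]] <- data.frame(taxon = tx, block = b, start = pos + 1L,
                              end = pos + length(copy),
                              stringsAsFactors = FALSE)
      pos <- pos + length(copy)
    }
    glen <- gap + sample(-5:5, 1)
    parts <- c(parts, chars_seq(sample_bases(glen, pi)))
    regions[[tx]] <- paste(parts, collapse = "")
    truth[[tx]] <- do.call(rbind, rows)
  }
  list(regions = regions, truth = do.call(rbind, truth))
}

#' Plant a tandem repeat in a random background
#'
#' @param unit_length repeat unit length (bp).
#' @param copies copy number (fractional allowed).
#' @param flank background length on each side.
#' @param unit_identity per-base identity of each copy to the unit.
#' @return list (region, truth = start/end/unit_length/copy_number).
#' @export
plant_repeat_region <- function(unit_length = 144, copies = 3.6,
                                flank = 200, unit_identity = 1) {
  pi <- SIM_FREQS$atrich
  unit <- sample_bases(unit_length, pi)
  total <- round(unit_length * copies)
  tiled <- rep(unit, length.out = total)
  if (unit_identity < 1) {
    mut <- which(stats::runif(total) > unit_identity)
    for (m in mut) tiled[m] <- sample(setdiff(BASES, tiled[m]), 1)
  }
  left <- chars_seq(sample_bases(flank, pi))
  right <- chars_seq(sample_bases(flank, pi))
  list(region = paste0(left, chars_seq(tiled), right),
       truth = data.frame(start = flank + 1L, end = flank + total,
                          unit_length = unit_length,
                          copy_number = round(copies, 1)))
}

#' Write the deterministic fixture suite used by the unit tests
#'
#' Emits, under \code{out_dir}: the default 5-taxon simulated genome set
#' as GenBank flat files, the ancestor, a truth JSON, and a small toy
#' genome exercising overlap and AT-rich inference.
#'
#' @param out_dir output directory (created if absent).
#' @param seed integer seed.
#' @return invisible character vector of written paths.
#' @export
make_fixture_suite <- function(out_dir, seed = 42) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genomes(sim_config(seed = seed))
  paths <- character(0)
  for (g in c(list(sim$ancestor), sim$genomes)) {
    p <- file.path(out_dir, paste0(g$id, ".gb"))
    write_genbank(g, p)
    paths <- c(paths, p)
  }
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(sim$truth, truth_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths <- c(paths, truth_path)
  invisible(paths)
}
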