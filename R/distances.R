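# Substitution-rate statistics: p-distance, Kimura two-parameter (total
# and per codon position), observed Ti/Tv, Dayhoff/PAM amino-acid
# distance, Nei-Gojobori Ka/Ks, group averages and saturation scans.
#
# Gap and N columns are removed pairwise (pairwise deletion), matching
# common distance-software defaults.

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Pairwise difference counts
#'
#' Compares two rows of an alignment after pairwise deletion of columns
#' holding a gap or N in either row. A purine-purine or
#' pyrimidine-pyrimidine difference is a transition, the rest are
#' transversions.
#'
#' @param aln NucAlignment (or CodonAlignment).
#' @param pair character vector of two taxon names.
#' @return list (compared_sites, differences, transitions,
#'   transversions) of class PairCounts.
#' @export
count_differences <- function(aln, pair) {
  rows <- alignment_pair(aln, pair)
  a <- seq_chars(rows[[1]]); b <- seq_chars(rows[[2]])
  keep <- a %in% BASES & b %in% BASES
  a <- a[keep]; b <- b[keep]
  if (!length(a)) stop("zero comparable sites for pair ",
                       paste(pair, collapse = "/"), call. = FALSE)
  diff <- a != b
  ti <- diff & ((a %in% PURINES & b %in% PURINES) |
                  (a %in% PYRIMIDINES & b %in% PYRIMIDINES))
  structure(list(compared_sites = length(a),
                 differences = sum(diff),
                 transitions = sum(ti),
                 transversions = sum(diff & !ti)),
            class = "PairCounts")
}

alignment_pair <- function(aln, pair) {
  if (length(pair) != 2) stop("pair must name two taxa", call. = FALSE)
  miss <- setdiff(pair, names(aln$rows))
  if (length(miss)) stop("taxa not in alignment: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  aln$rows[pair]
}

#' Uncorrected p-distance
#' @param counts PairCounts.
#' @return proportion of differing sites.
#' @export
p_distance <- function(counts) counts$differences / counts$compared_sites

#' Observed transition/transversion ratio
#' @param counts PairCounts.
#' @return transitions / transversions (NA when no transversions).
#' @export
ti_tv <- function(counts) {
  if (counts$transversions == 0) return(NA_real_)
  counts$transitions / counts$transversions
}

#' Kimura two-parameter distance
#'
#' K = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q)) with P and Q the observed
#' transition and transversion proportions.
#'
#' @param counts PairCounts (or a list with compared_sites, transitions,
#'   transversions).
#' @return substitutions per site.
#' @export
k2p <- function(counts) {
  P <- counts$transitions / counts$compared_sites
  Q <- counts$transversions / counts$compared_sites
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop("K2p saturation: log argument not positive (P=",
         signif(P, 3), ", Q=", signif(Q, 3), ")", call. = FALSE)
  -0.5 * log(w1 * sqrt(w2))
}

#' K2p between two alignment rows
#' @param aln NucAlignment.
#' @param pair two taxon names.
#' @return substitutions per site.
#' @export
k2p_pair <- function(aln, pair) k2p(count_differences(aln, pair))

#' Per-codon-position K2p distances
#'
#' Applies \code{count_differences} and \code{k2p} to the three
#' codon-position masks of a codon alignment independently.
#'
#' @param aln CodonAlignment.
#' @param pair two taxon names.
#' @return numeric vector c(pos1, pos2, pos3).
#' @export
k2p_by_position <- function(aln, pair) {
  stopifnot(inherits(aln, "CodonAlignment"))
  rows <- alignment_pair(aln, pair)
  mask <- position_mask(aln)
  vapply(1:3, function(pos) {
    sub <- lapply(rows, function(r)
      chars_seq(seq_chars(r)[mask == pos]))
    names(sub) <- names(rows)
    k2p_pair(new_nuc_alignment(aln$region, unlist(sub)), names(rows))
  }, numeric(1))
}

# ---- Dayhoff / PAM amino-acid distance -----------------------------------

.mitocomp_cache <- new.env(parent = emptyenv())

# eigen-decomposed Dayhoff rate matrix (exchangeabilities and equilibrium
# frequencies from phangorn), normalized to 1 expected substitution per
# site per unit distance; identity(d) = sum_k w_k exp(lambda_k d)
dayhoff_spectral <- function() {
  if (!is.null(.mitocomp_cache$dayhoff)) return(.mitocomp_cache$dayhoff)
  mdl <- utils::getFromNamespace(".Dayhoff", "phangorn")
  bf <- mdl$bf / sum(mdl$bf)
  S <- matrix(0, 20, 20)
  S[lower.tri(S)] <- mdl$Q
  S <- S + t(S)
  Q <- S * rep(bf, each = 20)      # Q[i, j] = S[i, j] * bf[j]
  diag(Q) <- -rowSums(Q)
  mu <- -sum(bf * diag(Q))
  Q <- Q / mu
  d <- sqrt(bf)
  B <- (d * Q) %*% diag(1 / d)     # symmetric form
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  # P(d) = D^-1 U exp(Ld) U' D with D = diag(sqrt(bf)), so
  # P_ii(d) = sum_k U_ik^2 exp(l_k d) and
  # identity(d) = sum_i bf_i P_ii(d) = sum_k w_k exp(l_k d)
  U <- eg$vectors
  w <- as.numeric(t(U^2) %*% bf)
  .mitocomp_cache$dayhoff <- list(lambda = eg$values, w = w,
                                  eq_identity = sum(bf^2))
  .mitocomp_cache$dayhoff
}

# expected fraction of identical residues after d substitutions/site
dayhoff_expected_identity <- function(d) {
  sp <- dayhoff_spectral()
  vapply(d, function(x) sum(sp$w * exp(sp$lambda * x)), numeric(1))
}

#' Dayhoff (PAM) amino-acid distance
#'
#' Matches the observed proportion of identical residues (after pairwise
#' gap deletion) against the expected identity of the Dayhoff
#' mutation-probability matrix family and returns the distance t/100
#' where PAM-t is the matching matrix power, i.e. amino-acid
#' substitutions per site under the Dayhoff model.
#'
#' @param protein_rows named character vector of aligned protein strings
#'   (e.g. \code{protein_rows(aln)}), or a CodonAlignment.
#' @param pair two taxon names.
#' @param max_pam saturation bound in PAM units (default 2000).
#' @return substitutions per site.
#' @export
pam_distance <- function(protein_rows, pair, max_pam = 2000) {
  if (inherits(protein_rows, "CodonAlignment"))
    protein_rows <- protein_rows(protein_rows)
  rows <- protein_rows[pair]
  if (anyNA(rows)) stop("taxa not found in protein rows", call. = FALSE)
  a <- seq_chars(rows[[1]]); b <- seq_chars(rows[[2]])
  keep <- a != "-" & b != "-" & a != "X" & b != "X"
  a <- a[keep]; b <- b[keep]
  if (!length(a)) stop("zero comparable residues", call. = FALSE)
  obs <- mean(a == b)
  if (obs >= 1) return(0)
  dmax <- max_pam / 100
  if (obs <= dayhoff_expected_identity(dmax))
    stop(sprintf("PAM saturation: identity %.3f below PAM-%d expectation",
                 obs, max_pam), call. = FALSE)
  stats::uniroot(function(d) dayhoff_expected_identity(d) - obs,
                 lower = 0, upper = dmax, tol = 1e-9)$root
}

# ---- Nei-Gojobori Ka/Ks --------------------------------------------------

# synonymous site fraction of one codon: at each position, the fraction
# of the three possible changes that are synonymous; changes to stop
# codons count as neither (original Nei-Gojobori 1986 convention, the
# per-codon site total stays 3)
ng_codon_sites <- function(codon, code) {
  s <- 0
  chars <- seq_chars(codon)
  for (pos in 1:3) {
    for (alt in setdiff(BASES, chars[pos])) {
      mut <- chars
      mut[pos] <- alt
      mutc <- chars_seq(mut)
      if (unname(code[mutc]) == "*") next
      if (code[mutc] == code[codon]) s <- s + 1 / 3
    }
  }
  s
}

# path-averaged synonymous/nonsynonymous differences between two codons;
# paths through stop codons are discarded (all paths kept if none valid)
ng_codon_diffs <- function(c1, c2, code) {
  pos <- which(seq_chars(c1) != seq_chars(c2))
  k <- length(pos)
  if (k == 0) return(c(sd = 0, nd = 0))
  perms <- all_permutations(pos)
  path_sd <- numeric(0); path_nd <- numeric(0)
  all_sd <- numeric(0); all_nd <- numeric(0)
  for (ord in perms) {
    cur <- seq_chars(c1)
    tgt <- seq_chars(c2)
    sd <- 0; nd <- 0; valid <- TRUE
    for (p in ord) {
      nxt <- cur
      nxt[p] <- tgt[p]
      aa1 <- unname(code[chars_seq(cur)])
      aa2 <- unname(code[chars_seq(nxt)])
      if (aa2 == "*") valid <- FALSE
      if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    all_sd <- c(all_sd, sd); all_nd <- c(all_nd, nd)
    if (valid) { path_sd <- c(path_sd, sd); path_nd <- c(path_nd, nd) }
  }
  if (length(path_sd)) c(sd = mean(path_sd), nd = mean(path_nd))
  else c(sd = mean(all_sd), nd = mean(all_nd))
}

ng_sites_table <- function(code) {
  if (!is.null(.mitocomp_cache$ng_sites)) return(.mitocomp_cache$ng_sites)
  sense <- names(code)[code != "*"]
  tab <- vapply(sense, ng_codon_sites, numeric(1), code = code)
  .mitocomp_cache$ng_sites <- tab
  tab
}

ng_diffs_cached <- function(c1, c2, code) {
  if (is.null(.mitocomp_cache$ng_diffs))
    .mitocomp_cache$ng_diffs <- new.env(parent = emptyenv())
  key <- paste0(c1, c2)
  hit <- .mitocomp_cache$ng_diffs[[key]]
  if (!is.null(hit)) return(hit)
  val <- ng_codon_diffs(c1, c2, code)
  .mitocomp_cache$ng_diffs[[key]] <- val
  val
}

all_permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in all_permutations(x[-i]))
      out[[length(out) + 1]] <- c(x[i], rest)
  out
}

#' Nei-Gojobori synonymous/nonsynonymous counts
#'
#' @param aln CodonAlignment.
#' @param pair two taxon names.
#' @return list (codons, syn_sites, nonsyn_sites, syn_diffs,
#'   nonsyn_diffs).
#' @export
ng_counts <- function(aln, pair) {
  stopifnot(inherits(aln, "CodonAlignment"))
  rows <- alignment_pair(aln, pair)
  code <- mito_code()
  nc <- nchar(rows[[1]])
  c1 <- substring(rows[[1]], seq(1, nc, 3), seq(3, nc, 3))
  c2 <- substring(rows[[2]], seq(1, nc, 3), seq(3, nc, 3))
  ok <- !grepl("[^ACGT]", c1) & !grepl("[^ACGT]", c2)
  c1 <- c1[ok]; c2 <- c2[ok]
  if (!length(c1)) stop("zero comparable codons", call. = FALSE)
  # memoized per-codon site fractions and per-pair path-averaged diffs
  # (61 sense codons, so both caches are tiny)
  sites_tab <- ng_sites_table(code)
  S <- (sum(sites_tab[c1]) + sum(sites_tab[c2])) / 2
  N <- 3 * length(c1) - S
  sd <- 0; nd <- 0
  diff_idx <- which(c1 != c2)
  if (length(diff_idx)) {
    keys <- paste(c1[diff_idx], c2[diff_idx])
    tab <- table(keys)
    for (kk in names(tab)) {
      cc <- strsplit(kk, " ", fixed = TRUE)[[1]]
      d <- ng_diffs_cached(cc[1], cc[2], code)
      sd <- sd + d[["sd"]] * tab[[kk]]
      nd <- nd + d[["nd"]] * tab[[kk]]
    }
  }
  list(codons = length(c1), syn_sites = S, nonsyn_sites = N,
       syn_diffs = sd, nonsyn_diffs = nd)
}

#' Ka and Ks (Nei-Gojobori with Jukes-Cantor correction)
#'
#' Synonymous and nonsynonymous sites and differences are counted with
#' equal weighting of mutational paths, proportions pS and pN are
#' Jukes-Cantor corrected, and the Ka/Ks ratio is reported (NA when
#' Ks = 0).
#'
#' @param aln CodonAlignment.
#' @param pair two taxon names.
#' @return list (ka, ks, ka_ks, counts).
#' @export
ka_ks <- function(aln, pair) {
  cnt <- ng_counts(aln, pair)
  pS <- cnt$syn_diffs / cnt$syn_sites
  pN <- cnt$nonsyn_diffs / cnt$nonsyn_sites
  if (pS >= 0.75 || pN >= 0.75)
    stop("Ka/Ks saturation: corrected proportion undefined", call. = FALSE)
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  ks <- jc(pS); ka <- jc(pN)
  list(ka = ka, ks = ks,
       ka_ks = if (ks > 0) ka / ks else NA_real_,
       counts = cnt)
}

# ---- per-gene tables, group averages, saturation -------------------------

#' All-pairs distance table for one alignment
#'
#' One row per (unordered) taxon pair carrying p, K2p, Ti/Tv and, for
#' codon alignments, per-position K2p, Ka/Ks and the Dayhoff/PAM
#' protein distance. A pair for which K2p (or another statistic) is
#' saturated gets NA there and \code{saturated = TRUE}.
#'
#' @param aln NucAlignment or CodonAlignment.
#' @param pairs optional list of character(2) pairs; default all pairs.
#' @return data.frame of class DistanceResult rows.
#' @export
gene_distances <- function(aln, pairs = NULL) {
  taxa <- names(aln$rows)
  if (is.null(pairs)) {
    pairs <- list()
    for (i in seq_along(taxa)[-length(taxa)])
      for (j in (i + 1):length(taxa))
        pairs[[length(pairs) + 1]] <- c(taxa[i], taxa[j])
  }
  is_codon <- inherits(aln, "CodonAlignment")
  prows <- if (is_codon) protein_rows(aln) else NULL
  out <- lapply(pairs, function(pr) {
    cnt <- count_differences(aln, pr)
    k <- tryCatch(k2p(cnt), error = function(e) NA_real_)
    row <- data.frame(label = aln$region, taxon_a = pr[1], taxon_b = pr[2],
                      sites = cnt$compared_sites, p = p_distance(cnt),
                      k2p = k, ti_tv = ti_tv(cnt),
                      saturated = is.na(k), stringsAsFactors = FALSE)
    if (is_codon) {
      kp <- tryCatch(k2p_by_position(aln, pr),
                     error = function(e) rep(NA_real_, 3))
      kk <- tryCatch(ka_ks(aln, pr),
                     error = function(e) list(ka = NA_real_, ks = NA_real_,
                                              ka_ks = NA_real_))
      pm <- tryCatch(pam_distance(prows, pr),
                     error = function(e) NA_real_)
      row$k2p_pos1 <- kp[1]; row$k2p_pos2 <- kp[2]; row$k2p_pos3 <- kp[3]
      row$ka <- kk$ka; row$ks <- kk$ks; row$ka_ks <- kk$ka_ks
      row$pam <- pm
      row$saturated <- row$saturated | anyNA(kp)
    }
    row
  })
  do.call(rbind, out)
}

#' Group average of pairwise distances
#'
#' Arithmetic mean over all pairwise rows of \code{gene_distances};
#' saturated pairs are excluded from the means and flagged.
#'
#' @param results data.frame from \code{gene_distances}.
#' @return one-row data.frame with the averaged numeric columns,
#'   \code{n_pairs}, \code{n_saturated} and attribute
#'   \code{saturated_pairs}.
#' @export
group_average <- function(results) {
  ok <- !results$saturated
  num_cols <- setdiff(names(results)[vapply(results, is.numeric,
                                            logical(1))],
                      c("sites"))
  avg <- lapply(num_cols, function(cl) mean(results[[cl]][ok], na.rm = TRUE))
  names(avg) <- num_cols
  out <- data.frame(label = results$label[1], avg, n_pairs = nrow(results),
                    n_saturated = sum(!ok), stringsAsFactors = FALSE)
  attr(out, "saturated_pairs") <-
    results[!ok, c("taxon_a", "taxon_b"), drop = FALSE]
  out
}

#' Concatenate alignments over the same taxa
#'
#' Used for "Total" rows: sites are pooled before distances are
#' computed. All alignments must share the taxon set; the result is a
#' CodonAlignment only if every input is one.
#'
#' @param alns list of alignments.
#' @param region label for the concatenation.
#' @return NucAlignment or CodonAlignment.
#' @export
concat_alignments <- function(alns, region = "concat") {
  taxa <- names(alns[[1]]$rows)
  rows <- vapply(taxa, function(tx) {
    paste(vapply(alns, function(a) {
      if (!tx %in% names(a$rows))
        stop("taxon ", tx, " missing from alignment ", a$region,
             call. = FALSE)
      a$rows[[tx]]
    }, character(1)), collapse = "")
  }, character(1))
  if (all(vapply(alns, inherits, logical(1), "CodonAlignment")))
    new_codon_alignment(region, rows)
  else
    new_nuc_alignment(region, rows)
}

#' Saturation scan: p versus K2p over genes and pairs
#'
#' @param alns named list of alignments.
#' @return data.frame (gene, taxon_a, taxon_b, p, k2p) with attribute
#'   \code{linearity} = Pearson correlation of p and K2p over
#'   non-saturated rows.
#' @export
saturation_scan <- function(alns) {
  rows <- do.call(rbind, lapply(alns, function(a) {
    d <- gene_distances(a)
    data.frame(gene = d$label, taxon_a = d$taxon_a, taxon_b = d$taxon_b,
               p = d$p, k2p = d$k2p, stringsAsFactors = FALSE)
  }))
  ok <- !is.na(rows$k2p)
  attr(rows, "linearity") <-
    if (sum(ok) >= 3 && stats::sd(rows$p[ok]) > 0)
      stats::cor(rows$p[ok], rows$k2p[ok])
    else NA_real_
  rows
}
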