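# Structure discovery in the AT-rich (control) region: tandem repeats,
# cross-taxon conserved segments, poly(N) runs and simplified stem-loop
# (hairpin) detection.
#
# All coordinates are 1-based inclusive and relative to the region
# passed in.

#' Find tandem repeats by period scan
#'
#' For every candidate period p the sequence is compared against itself
#' at lag p; maximal intervals over which the lagged identity stays at
#' or above \code{min_identity} and that contain at least
#' \code{min_copies} copies are reported. The period is canonicalized to
#' its smallest divisor that still meets the identity threshold, and
#' overlapping candidates are resolved best-first by span.
#'
#' @param region DNA string.
#' @param min_unit smallest repeat unit length considered (bp).
#' @param min_copies minimum (possibly fractional) copy number.
#' @param min_identity minimum mean identity between consecutive copies.
#' @return data.frame (start, end, unit_length, copy_number,
#'   unit_consensus, mean_unit_identity); zero rows when none found.
#' @export
find_tandem_repeats <- function(region, min_unit = 20, min_copies = 2,
                                min_identity = 0.85) {
  region <- toupper(region)
  L <- nchar(region)
  chars <- seq_chars(region)
  empty <- data.frame(start = integer(), end = integer(),
                      unit_length = integer(), copy_number = numeric(),
                      unit_consensus = character(),
                      mean_unit_identity = numeric(),
                      stringsAsFactors = FALSE)
  pmax_period <- floor(L / min_copies)
  if (pmax_period < min_unit) return(empty)
  cands <- list()
  for (p in min_unit:pmax_period) {
    m <- chars[seq_len(L - p)] == chars[seq_len(L - p) + p]
    # windowed identity between copy starting at i and the next one
    cs <- cumsum(c(0, m))
    win_ident <- (cs[(p + 1):(L - p + 1)] - cs[1:(L - 2 * p + 1)]) / p
    good <- win_ident >= min_identity
    if (!any(good)) next
    r <- rle(good)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      a <- starts[k]                       # first good window start
      b <- ends[k]                         # last good window start
      # full-period windows straddling the boundary still pass the
      # threshold, so refine both ends with a short rolling window on
      # the per-position lag-p matches
      w <- min(p, 24L)
      mm <- m[a:(b + p - 1)]
      cs2 <- cumsum(c(0, mm))
      nroll <- length(mm) - w + 1
      roll <- (cs2[(w + 1):(w + nroll)] - cs2[1:nroll]) / w
      okw <- which(roll >= min_identity)
      if (!length(okw)) next
      span_start <- a + okw[1] - 1
      span_end <- a + okw[length(okw)] - 1 + w - 1 + p
      len <- span_end - span_start + 1
      copies <- len / p
      if (copies < min_copies) next
      ident <- mean(m[span_start:(span_end - p)])
      if (ident < min_identity) next
      cands[[length(cands) + 1]] <- list(start = span_start,
                                         end = span_end, p = p,
                                         copies = copies, ident = ident)
    }
  }
  if (!length(cands)) return(empty)
  # best-first non-overlapping selection by span, then identity
  ord <- order(-vapply(cands, function(x) x$end - x$start, numeric(1)),
               -vapply(cands, `[[`, numeric(1), "ident"),
               vapply(cands, `[[`, numeric(1), "p"))
  chosen <- list()
  occupied <- rep(FALSE, L)
  for (i in ord) {
    cd <- cands[[i]]
    span <- cd$start:cd$end
    if (mean(occupied[span]) > 0.2) next   # mostly novel territory only
    occupied[span] <- TRUE
    chosen[[length(chosen) + 1]] <- cd
  }
  rows <- lapply(chosen, function(cd) {
    cd <- canonical_period(chars, cd, min_identity)
    unit <- repeat_consensus(chars, cd$start, cd$end, cd$p)
    data.frame(start = cd$start, end = cd$end, unit_length = cd$p,
               copy_number = round(cd$copies, 1),
               unit_consensus = unit,
               mean_unit_identity = cd$ident, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

# replace the period by its smallest divisor whose lagged identity over
# the interval still meets the threshold
canonical_period <- function(chars, cd, min_identity) {
  p <- cd$p
  divisors <- which(p %% seq_len(p) == 0)
  for (q in divisors) {
    if (q == p) break
    idx <- cd$start:(cd$end - q)
    ident <- mean(chars[idx] == chars[idx + q])
    if (ident >= min_identity) {
      cd$p <- q
      cd$ident <- ident
      break
    }
  }
  cd$copies <- (cd$end - cd$start + 1) / cd$p
  cd
}

# majority-vote consensus of the unit across full copies
repeat_consensus <- function(chars, start, end, p) {
  n_full <- (end - start + 1) %/% p
  if (n_full < 1) return(chars_seq(chars[start:min(end, start + p - 1)]))
  mat <- matrix(chars[start:(start + n_full * p - 1)], nrow = p)
  cons <- apply(mat, 1, function(col) {
    tb <- table(col)
    names(tb)[which.max(tb)]
  })
  chars_seq(cons)
}

#' Find segments conserved across all taxa
#'
#' Exact k-mers present in every taxon's region seed candidate loci;
#' each anchor is extended in both directions while the mean column
#' identity (majority-base consensus fraction across taxa) stays at or
#' above \code{min_identity}. Overlapping candidates are merged,
#' filtered by \code{min_len} and numbered along the first taxon's
#' coordinates.
#'
#' @param regions_by_taxon named list of DNA strings (>= 2 taxa).
#' @param k seed k-mer length.
#' @param min_len minimum segment length (bp).
#' @param min_identity minimum mean cross-taxon column identity.
#' @param exclude optional data.frame with start/end columns (reference
#'   taxon coordinates); candidates overlapping these intervals are
#'   dropped (used to mask tandem-repeat areas).
#' @return data.frame with segment_id, per-taxon start/end columns
#'   (\code{start_<taxon>}, \code{end_<taxon>}), consensus,
#'   min_pairwise_identity.
#' @export
find_conserved_segments <- function(regions_by_taxon, k = 10,
                                    min_len = 12, min_identity = 0.90,
                                    exclude = NULL) {
  regions <- lapply(regions_by_taxon, toupper)
  taxa <- names(regions)
  if (length(regions) < 2) stop("need at least two taxa", call. = FALSE)
  if (min(vapply(regions, nchar, integer(1))) < k)
    return(empty_segments(taxa))
  charsets <- lapply(regions, seq_chars)
  lens <- vapply(regions, nchar, integer(1))
  cands <- list()
  seen <- character(0)
  max_mm <- max(1L, floor(k * (1 - min_identity) * 2))
  # seed from every taxon in turn: a block copy carrying private
  # mutations in one taxon can still be seeded from the others
  for (ridx in seq_along(regions)) {
    refseq <- regions[[ridx]]
    Lr <- nchar(refseq)
    kmers <- substring(refseq, seq_len(Lr - k + 1),
                       seq_len(Lr - k + 1) + k - 1)
    for (i in seq_along(kmers)) {
      km <- kmers[i]
      if (km %in% seen) next
      seen <- c(seen, km)
      pos <- vapply(regions, function(r) {
        m <- regexpr(km, r, fixed = TRUE)
        as.integer(m)
      }, integer(1))
      # anchor must be exact in a majority of taxa; the rest are placed
      # at their best approximate occurrence, and the identity filters
      # below reject chance placements
      n_exact <- sum(pos > 0)
      if (n_exact < ceiling(length(regions) / 2) || n_exact < 2) next
      if (any(pos < 0)) {
        kmc <- seq_chars(km)
        prior <- as.integer(stats::median(pos[pos > 0]))
        for (t in which(pos < 0)) {
          hit <- best_kmer_match(charsets[[t]], kmc, max_mm, prior = prior)
          if (is.na(hit)) { pos[t] <- -1L; break }
          pos[t] <- hit
        }
        if (any(pos < 0)) next
      }
      cand <- extend_anchor(charsets, pos, k, lens, min_identity)
      info <- segment_identity(charsets, cand$start, cand$end)
      if (is.null(info) || info$col_identity < min_identity) next
      if (cand$end[1] - cand$start[1] + 1 < min_len) next
      cand$anchor <- pos
      cands[[length(cands) + 1]] <- cand
    }
  }
  if (!length(cands)) return(empty_segments(taxa))
  # candidates inside excluded reference intervals (e.g. detected tandem
  # repeats, whose internal conservation is annotated separately) are
  # dropped
  if (!is.null(exclude) && nrow(exclude)) {
    keep <- vapply(cands, function(cd) {
      ov <- pmin(cd$end[1], exclude$end) - pmax(cd$start[1], exclude$start) + 1
      max(ov, 0) <= 0.5 * (cd$end[1] - cd$start[1] + 1)
    }, logical(1))
    cands <- cands[keep]
    if (!length(cands)) return(empty_segments(taxa))
  }
  # cluster candidates by reference-interval overlap (allowing a short
  # gap, so fragments split by one weak column rejoin), then keep the
  # union when it still meets the identity threshold, else the longest
  # passing candidate of the cluster
  merge_gap <- 8L
  starts <- vapply(cands, function(x) as.integer(x$start[1]), integer(1))
  ords <- order(starts)
  clusters <- list()
  cur <- list(cands[[ords[1]]])
  cur_end <- as.integer(cands[[ords[1]]]$end[1])
  for (i in ords[-1]) {
    cd <- cands[[i]]
    if (as.integer(cd$start[1]) <= cur_end + merge_gap) {
      cur[[length(cur) + 1]] <- cd
      cur_end <- max(cur_end, as.integer(cd$end[1]))
    } else {
      clusters[[length(clusters) + 1]] <- cur
      cur <- list(cd)
      cur_end <- as.integer(cd$end[1])
    }
  }
  clusters[[length(clusters) + 1]] <- cur
  rows <- list()
  for (cl in clusters) {
    lens_cl <- vapply(cl, function(x) x$end[1] - x$start[1] + 1,
                      numeric(1))
    longest <- cl[[which.max(lens_cl)]]
    u_start <- Reduce(pmin, lapply(cl, `[[`, "start"))
    u_end <- Reduce(pmax, lapply(cl, `[[`, "end"))
    info <- segment_identity(charsets, u_start, u_end)
    pick <- NULL
    if (!is.null(info) && info$col_identity >= min_identity) {
      pick <- list(start = u_start, end = u_end, info = info,
                   anchor = longest$anchor)
    } else {
      for (j in order(-lens_cl)) {
        inf <- segment_identity(charsets, cl[[j]]$start, cl[[j]]$end)
        if (!is.null(inf) && inf$col_identity >= min_identity) {
          pick <- list(start = cl[[j]]$start, end = cl[[j]]$end,
                       info = inf, anchor = cl[[j]]$anchor)
          break
        }
      }
    }
    if (is.null(pick)) next
    len <- pick$end[1] - pick$start[1] + 1
    if (len < min_len) next
    # a real conserved locus is seeded by several overlapping k-mers; a
    # single chance anchor is not corroborated
    if (length(cl) < 2) next
    # chimera guard: a taxon whose anchor was placed at a non-homologous
    # locus agrees with the consensus only inside the (exact-by-
    # construction) anchor columns, so judge agreement outside them
    na_ident <- nonanchor_agreement(charsets, pick$start, pick$end,
                                    pick$anchor, k)
    if (!is.na(na_ident) && na_ident < 0.70) next
    # second guard: homologous control-region segments are roughly
    # collinear, so the segment's relative position within each taxon's
    # region must agree (true segments vary by a few percent)
    frac <- (pick$start - 1) / lens
    if (max(frac) - min(frac) > 0.35) next
    row <- data.frame(segment_id = NA_integer_, stringsAsFactors = FALSE)
    for (t in seq_along(taxa)) {
      row[[paste0("start_", taxa[t])]] <- pick$start[t]
      row[[paste0("end_", taxa[t])]] <- pick$end[t]
    }
    row$length <- len
    row$consensus <- pick$info$consensus
    row$min_pairwise_identity <- pick$info$min_pairwise
    rows[[length(rows) + 1]] <- row
  }
  if (!length(rows)) return(empty_segments(taxa))
  out <- do.call(rbind, rows)
  # one locus in one taxon belongs to at most one homologous segment:
  # when two rows overlap in any taxon, keep the longer one
  if (nrow(out) > 1) {
    ord2 <- order(-out$length, -out$min_pairwise_identity)
    keep <- logical(nrow(out))
    for (i in ord2) {
      clash <- FALSE
      for (j in which(keep)) {
        for (t in taxa) {
          si <- out[[paste0("start_", t)]][i]
          ei <- out[[paste0("end_", t)]][i]
          sj <- out[[paste0("start_", t)]][j]
          ej <- out[[paste0("end_", t)]][j]
          if (si <= ej && ei >= sj) { clash <- TRUE; break }
        }
        if (clash) break
      }
      keep[i] <- !clash
    }
    out <- out[keep, , drop = FALSE]
  }
  out <- out[order(out[[paste0("start_", taxa[1])]]), , drop = FALSE]
  out$segment_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# best approximate occurrence of a k-mer. Regions of homologous control
# regions are roughly collinear, so placements near the prior (median
# position of the exactly matched taxa) are preferred and granted one
# extra mismatch; otherwise the global minimum-Hamming position is used
# (ties to the leftmost). NA when nothing acceptable exists.
best_kmer_match <- function(chars, kmc, max_mm, prior = NA_integer_,
                            prior_window = 40L) {
  k <- length(kmc)
  L <- length(chars)
  if (L < k) return(NA_integer_)
  n_off <- L - k + 1L
  mism <- integer(n_off)
  for (j in seq_len(k))
    mism <- mism + (chars[seq_len(n_off) + j - 1L] != kmc[j])
  if (!is.na(prior)) {
    near <- which(abs(seq_len(n_off) - prior) <= prior_window)
    if (length(near)) {
      nb <- near[order(mism[near], abs(near - prior))][1]
      if (mism[nb] <= max_mm + 1L) return(nb)
    }
  }
  best <- which.min(mism)
  if (mism[best] > max_mm) return(NA_integer_)
  best
}

# minimum per-taxon agreement with the column consensus over segment
# columns outside the seeding anchor; NA when fewer than 4 such columns
nonanchor_agreement <- function(charsets, start, end, anchor, k) {
  lens <- end - start + 1
  if (length(unique(lens)) != 1) return(NA_real_)
  nt <- length(charsets)
  mat <- vapply(seq_len(nt), function(t) charsets[[t]][start[t]:end[t]],
                character(lens[1]))
  if (lens[1] == 1) mat <- matrix(mat, nrow = 1)
  cons <- apply(mat, 1, function(col) {
    tb <- table(col); names(tb)[which.max(tb)]
  })
  # anchor columns relative to each taxon's own span (offsets coincide
  # for consistent candidates; use the reference taxon's offsets)
  a_off <- anchor[1] - start[1] + 1L
  keep <- setdiff(seq_len(lens[1]), a_off:(a_off + k - 1L))
  if (length(keep) < 4) return(NA_real_)
  min(vapply(seq_len(nt), function(t) mean(mat[keep, t] == cons[keep]),
             numeric(1)))
}

empty_segments <- function(taxa) {
  out <- data.frame(segment_id = integer(), stringsAsFactors = FALSE)
  for (t in taxa) {
    out[[paste0("start_", t)]] <- integer()
    out[[paste0("end_", t)]] <- integer()
  }
  out$length <- integer()
  out$consensus <- character()
  out$min_pairwise_identity <- numeric()
  out
}

# extend an exact anchor left/right column by column; a new column is
# accepted while the mean consensus of the most recent window (its side)
# stays at or above the threshold, which keeps boundaries local and
# prevents a long perfect anchor from absorbing background columns
extend_anchor <- function(charsets, pos, k, lens, min_identity,
                          window = 8L) {
  nt <- length(charsets)
  start <- pos
  end <- pos + k - 1L
  col_ident <- function(at) {
    col <- vapply(seq_len(nt), function(t) charsets[[t]][at[t]],
                  character(1))
    max(table(col)) / nt
  }
  right_hist <- rep(1, k)   # anchor columns are exact
  repeat {
    if (!all(end < lens)) break
    ci <- col_ident(end + 1L)
    recent <- c(utils::tail(right_hist, window - 1L), ci)
    if (mean(recent) < min_identity) break
    end <- end + 1L
    right_hist <- c(right_hist, ci)
  }
  left_hist <- rep(1, k)
  repeat {
    if (!all(start > 1)) break
    ci <- col_ident(start - 1L)
    recent <- c(utils::tail(left_hist, window - 1L), ci)
    if (mean(recent) < min_identity) break
    start <- start - 1L
    left_hist <- c(left_hist, ci)
  }
  # trim ragged ends: terminal columns must themselves be conserved
  while (end[1] > pos[1] + k - 1L && col_ident(end) < min_identity)
    end <- end - 1L
  while (start[1] < pos[1] && col_ident(start) < min_identity)
    start <- start + 1L
  list(start = start, end = end)
}

# consensus, mean column identity and minimum pairwise identity of a
# cross-taxon segment (NULL when spans differ in length)
segment_identity <- function(charsets, start, end) {
  lens <- end - start + 1
  if (length(unique(lens)) != 1) return(NULL)
  mat <- vapply(seq_along(charsets),
                function(t) charsets[[t]][start[t]:end[t]],
                character(lens[1]))
  if (lens[1] == 1) mat <- matrix(mat, nrow = 1)
  nt <- ncol(mat)
  cons <- apply(mat, 1, function(col) {
    tb <- table(col); names(tb)[which.max(tb)]
  })
  col_ident <- mean(apply(mat, 1, function(col) max(table(col)) / nt))
  pw <- c()
  for (i in seq_len(nt - 1))
    for (j in (i + 1):nt)
      pw <- c(pw, mean(mat[, i] == mat[, j]))
  taxon_ident <- vapply(seq_len(nt), function(t) mean(mat[, t] == cons),
                        numeric(1))
  list(consensus = chars_seq(cons), col_identity = col_ident,
       min_pairwise = min(pw), min_taxon = min(taxon_ident))
}

#' Maximal single-base runs
#'
#' @param region DNA string.
#' @param min_len minimum run length (>= 2).
#' @return data.frame (base, start, length).
#' @export
poly_n_runs <- function(region, min_len = 5) {
  if (min_len < 2) stop("min_len must be >= 2", call. = FALSE)
  chars <- seq_chars(toupper(region))
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$lengths >= min_len & r$values %in% BASES
  data.frame(base = r$values[keep], start = starts[keep],
             length = r$lengths[keep], stringsAsFactors = FALSE)
}

base_pairs_ok <- function(x, y) {
  (x == "A" & y == "T") | (x == "T" & y == "A") |
    (x == "G" & y == "C") | (x == "C" & y == "G") |
    (x == "G" & y == "T") | (x == "T" & y == "G")   # G.U wobble allowed
}

#' Find hairpin (stem-loop) candidates
#'
#' Enumerates all inverted-repeat pairings with Watson-Crick and G.U
#' pairs, stem length at least \code{min_stem} and loop length between 3
#' and \code{max_loop}; maximal stems are scored by paired-base count
#' and selected best-first without overlap. This is a combinatorial
#' pair-count finder, not a thermodynamic folder.
#'
#' @param segment DNA string.
#' @param min_stem minimum stem length (bp).
#' @param max_loop maximum loop length (bp).
#' @return data.frame (start, end, stem_length, loop_length,
#'   paired_fraction, score) ordered by decreasing score.
#' @export
find_hairpins <- function(segment, min_stem = 4, max_loop = 30) {
  chars <- seq_chars(toupper(segment))
  L <- length(chars)
  empty <- data.frame(start = integer(), end = integer(),
                      stem_length = integer(), loop_length = integer(),
                      paired_fraction = numeric(), score = integer(),
                      stringsAsFactors = FALSE)
  if (L < 2 * min_stem + 3) return(empty)
  cands <- list()
  # i = last base of 5' stem arm, j = first base of 3' arm
  for (i in seq_len(L - 1)) {
    for (loop in 3:max_loop) {
      j <- i + loop + 1L
      if (j > L) break
      # extend stem outward from (i, j)
      s <- 0L
      while (i - s >= 1 && j + s <= L &&
             base_pairs_ok(chars[i - s], chars[j + s])) {
        s <- s + 1L
      }
      if (s >= min_stem) {
        cands[[length(cands) + 1]] <- data.frame(
          start = i - s + 1L, end = j + s - 1L, stem_length = s,
          loop_length = loop,
          paired_fraction = 2 * s / (2 * s + loop), score = s,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(cands)) return(empty)
  cand <- unique(do.call(rbind, cands))
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

#' Lagged self-identity matrix export for dot-plot style visualization
#'
#' @param region DNA string.
#' @param max_period largest lag.
#' @return matrix of 0/1 matches, rows = positions, cols = lags.
#' @export
self_match_matrix <- function(region, max_period = NULL) {
  chars <- seq_chars(toupper(region))
  L <- length(chars)
  if (is.null(max_period)) max_period <- floor(L / 2)
  mat <- matrix(NA_integer_, nrow = L, ncol = max_period)
  for (p in seq_len(max_period)) {
    idx <- seq_len(L - p)
    mat[idx, p] <- as.integer(chars[idx] == chars[idx + p])
  }
  colnames(mat) <- paste0("lag", seq_len(max_period))
  mat
}
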