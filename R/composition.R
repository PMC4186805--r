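# Nucleotide composition, AT/GC skew, codon-position partitioned
# composition, codon usage and amino-acid frequencies.
#
# All percentages are computed on the non-N length. Whole-genome values
# are computed on the J strand as given.

#' Invertebrate mitochondrial genetic code (NCBI table 5)
#'
#' @return named character vector codon -> amino acid (stops as "*").
#' @export
mito_code <- function() {
  Biostrings::getGeneticCode("5")
}

#' Base composition and skew statistics
#'
#' Percentages of T, C, A, G on the non-N length, the A+T percentage and
#' the strand-asymmetry skews AT-skew = (A - T)/(A + T) and
#' GC-skew = (G - C)/(G + C). A skew whose denominator is zero is
#' reported as NA.
#'
#' @param seq DNA string (case-insensitive; N ignored).
#' @param label partition label carried into the output row.
#' @return one-row data.frame (label, pct_T, pct_C, pct_A, pct_G, pct_AT,
#'   at_skew, gc_skew, n_sites).
#' @export
base_composition <- function(seq, label = "seq") {
  seq <- toupper(seq)
  cnt <- vapply(BASES, function(b) {
    lengths(regmatches(seq, gregexpr(b, seq, fixed = TRUE)))
  }, numeric(1))
  total <- sum(cnt)
  if (total == 0) stop("sequence is empty or all N", call. = FALSE)
  a <- cnt[["A"]]; t <- cnt[["T"]]; g <- cnt[["G"]]; c <- cnt[["C"]]
  data.frame(label = label,
             pct_T = 100 * t / total, pct_C = 100 * c / total,
             pct_A = 100 * a / total, pct_G = 100 * g / total,
             pct_AT = 100 * (a + t) / total,
             at_skew = if (a + t > 0) (a - t) / (a + t) else NA_real_,
             gc_skew = if (g + c > 0) (g - c) / (g + c) else NA_real_,
             n_sites = total, stringsAsFactors = FALSE)
}

# coding-orientation codons of one PCG: incomplete terminal codon dropped,
# terminal complete stop dropped, internal stops optionally kept
pcg_codons <- function(genome, gene, drop_internal_stops = FALSE) {
  s <- extract_gene(genome, gene)
  len <- nchar(s) - nchar(s) %% 3
  cods <- substring(s, seq(1, len, by = 3), seq(3, len, by = 3))
  nc <- length(cods)
  if (nc && cods[nc] %in% c("TAA", "TAG")) cods <- cods[-nc]
  if (drop_internal_stops) {
    code <- mito_code()
    aa <- unname(code[cods])
    stops <- !is.na(aa) & aa == "*"
    if (any(stops)) {
      warning(sprintf("%s/%s: %d internal stop codon(s) skipped",
                      genome$id, gene, sum(stops)), call. = FALSE)
      cods <- cods[!stops]
    }
  }
  cods
}

pcg_features <- function(genome, strand_group = "both") {
  f <- genome$features[genome$features$kind == "PCG", ]
  if (strand_group %in% c("J", "N")) f <- f[f$strand == strand_group, ]
  f
}

#' Codon-position composition of pooled protein-coding genes
#'
#' Pools all PCG codons of the requested strand group across genomes
#' (stop codons excluded) and returns one composition row per codon
#' position. Pooling is by nucleotide counts, i.e. length-weighted.
#'
#' @param genomes list of AnnotatedGenome (or a single one).
#' @param strand_group "J", "N" or "both".
#' @return data.frame of three rows (positions 1-3).
#' @export
codon_position_composition <- function(genomes, strand_group = "J") {
  if (inherits(genomes, "AnnotatedGenome")) genomes <- list(genomes)
  cods <- unlist(lapply(genomes, function(g) {
    unlist(lapply(pcg_features(g, strand_group)$name,
                  function(nm) pcg_codons(g, nm)))
  }))
  if (!length(cods))
    stop("no PCGs on strand group ", strand_group, call. = FALSE)
  rows <- lapply(1:3, function(pos) {
    base_composition(paste(substr(cods, pos, pos), collapse = ""),
                     label = sprintf("%s_pos%d", strand_group, pos))
  })
  do.call(rbind, rows)
}

#' Amino-acid frequencies of the mitochondrial proteome
#'
#' Translates all PCGs of each genome under the invertebrate
#' mitochondrial code, computes per-genome amino-acid percentages and
#' averages them across genomes (each genome weighted equally).
#'
#' @param genomes list of AnnotatedGenome.
#' @param top_k how many top amino acids to summarize.
#' @return data.frame (aa, pct) sorted by decreasing pct, with attributes
#'   \code{top} (the top_k amino acids) and \code{top_share} (their
#'   cumulative percentage).
#' @export
amino_acid_frequencies <- function(genomes, top_k = 5) {
  if (inherits(genomes, "AnnotatedGenome")) genomes <- list(genomes)
  code <- mito_code()
  aas <- sort(setdiff(unique(code), "*"))
  per_genome <- vapply(genomes, function(g) {
    cods <- unlist(lapply(pcg_features(g)$name, function(nm)
      pcg_codons(g, nm, drop_internal_stops = TRUE)))
    aa <- unname(code[cods])
    aa <- aa[!is.na(aa) & aa != "*"]
    tab <- table(factor(aa, levels = aas))
    100 * as.numeric(tab) / sum(tab)
  }, numeric(length(aas)))
  pct <- rowMeans(per_genome)
  out <- data.frame(aa = aas, pct = pct, stringsAsFactors = FALSE)
  out <- out[order(-out$pct, out$aa), ]
  rownames(out) <- NULL
  attr(out, "top") <- out$aa[seq_len(top_k)]
  attr(out, "top_share") <- sum(out$pct[seq_len(top_k)])
  out
}

#' Fourfold-degenerate codon family usage
#'
#' For each codon family whose third position is fully degenerate under
#' the invertebrate mitochondrial code, the proportion of NNA, NNT, NNC
#' and NNG codons pooled over all PCGs of all genomes; plus a pooled row
#' over all families.
#'
#' @param genomes list of AnnotatedGenome.
#' @return data.frame (family, aa, NNA, NNT, NNC, NNG, n); final row
#'   "all" pools every family.
#' @export
fourfold_family_usage <- function(genomes) {
  if (inherits(genomes, "AnnotatedGenome")) genomes <- list(genomes)
  code <- mito_code()
  fams <- fourfold_families(code)
  cods <- unlist(lapply(genomes, function(g) {
    unlist(lapply(pcg_features(g)$name, function(nm)
      pcg_codons(g, nm, drop_internal_stops = TRUE)))
  }))
  prefix <- substr(cods, 1, 2)
  third <- substr(cods, 3, 3)
  rows <- lapply(names(fams), function(fam) {
    sel <- prefix == fam
    tab <- table(factor(third[sel], levels = BASES))
    n <- sum(tab)
    props <- if (n > 0) as.numeric(tab) / n else rep(NA_real_, 4)
    data.frame(family = fam, aa = fams[[fam]],
               NNA = props[1], NNC = props[2], NNG = props[3],
               NNT = props[4], n = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  pooled_sel <- prefix %in% names(fams)
  tab <- table(factor(third[pooled_sel], levels = BASES))
  n <- sum(tab)
  out <- rbind(out, data.frame(family = "all", aa = "",
                               NNA = as.numeric(tab[["A"]]) / n,
                               NNC = as.numeric(tab[["C"]]) / n,
                               NNG = as.numeric(tab[["G"]]) / n,
                               NNT = as.numeric(tab[["T"]]) / n, n = n,
                               stringsAsFactors = FALSE))
  out
}

# families (first two codon bases) where any third base gives the same
# amino acid, derived from the code rather than hard-coded
fourfold_families <- function(code = mito_code()) {
  prefixes <- unique(substr(names(code), 1, 2))
  fams <- list()
  for (p in prefixes) {
    aa <- unique(unname(code[paste0(p, BASES)]))
    if (length(aa) == 1 && aa != "*") fams[[p]] <- aa
  }
  fams
}

#' Codon usage table
#'
#' Counts and per-thousand frequencies of all sense codons pooled over
#' the PCGs of the given genomes.
#'
#' @param genomes list of AnnotatedGenome.
#' @return data.frame (codon, aa, count, per_thousand).
#' @export
codon_usage <- function(genomes) {
  if (inherits(genomes, "AnnotatedGenome")) genomes <- list(genomes)
  code <- mito_code()
  sense <- names(code)[code != "*"]
  cods <- unlist(lapply(genomes, function(g) {
    unlist(lapply(pcg_features(g)$name, function(nm)
      pcg_codons(g, nm, drop_internal_stops = TRUE)))
  }))
  tab <- table(factor(cods, levels = sense))
  data.frame(codon = sense, aa = unname(code[sense]),
             count = as.integer(tab),
             per_thousand = 1000 * as.integer(tab) / sum(tab),
             stringsAsFactors = FALSE)
}

#' Translate a coding sequence under the invertebrate mitochondrial code
#'
#' Drops an incomplete terminal codon and a terminal stop before
#' translating.
#'
#' @param cds DNA string in coding orientation.
#' @return amino-acid string.
#' @export
translate_cds <- function(cds) {
  code <- mito_code()
  len <- nchar(cds) - nchar(cds) %% 3
  if (len < 3) stop("CDS shorter than one codon", call. = FALSE)
  cods <- substring(cds, seq(1, len, by = 3), seq(3, len, by = 3))
  if (cods[length(cods)] %in% names(code)[code == "*"])
    cods <- cods[-length(cods)]
  aa <- unname(code[cods])
  if (anyNA(aa)) stop("untranslatable codon (ambiguity) in CDS",
                      call. = FALSE)
  paste(aa, collapse = "")
}
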