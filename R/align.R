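# Protein-guided codon alignment of PCGs and plain nucleotide alignment
# of RNAs and AT-rich regions.
#
# Pairwise global alignment (Needleman-Wunsch, affine gaps) is delegated
# to Biostrings::pairwiseAlignment; multiple sequences are combined by
# center-star merging ("once a gap, always a gap"), which is exact for
# the indel-free alignments the simulator produces by default and a
# standard approximation otherwise. Scoring constants are fixed so
# outputs are bit-reproducible: nucleotides match +1 / mismatch -1, gap
# open 2 / extend 1; proteins PAM120, gap open 10 / extend 1.

NUC_MATCH <- 1
NUC_MISMATCH <- -1
NUC_GAP_OPEN <- 2
NUC_GAP_EXT <- 1
PROT_MATRIX <- "PAM120"
PROT_GAP_OPEN <- 10
PROT_GAP_EXT <- 1

new_nuc_alignment <- function(region, rows) {
  stopifnot(length(unique(nchar(rows))) == 1)
  structure(list(region = region, taxa = names(rows), rows = rows),
            class = "NucAlignment")
}

new_codon_alignment <- function(gene, rows) {
  stopifnot(all(nchar(rows) %% 3 == 0))
  structure(list(region = gene, gene = gene, taxa = names(rows),
                 rows = rows),
            class = c("CodonAlignment", "NucAlignment"))
}

#' @export
print.NucAlignment <- function(x, ...) {
  cat(sprintf("%s alignment of %s: %d taxa, %d columns\n",
              if (inherits(x, "CodonAlignment")) "Codon" else "Nucleotide",
              x$region, length(x$rows), nchar(x$rows[[1]])))
  invisible(x)
}

#' Construct a nucleotide alignment from pre-aligned rows
#'
#' @param rows named character vector of equal-length aligned strings.
#' @param region label.
#' @return NucAlignment.
#' @export
nuc_alignment <- function(rows, region = "region") {
  new_nuc_alignment(region, rows)
}

#' Construct a codon alignment from pre-aligned rows
#'
#' Rows must be gap-tripled (lengths multiples of three).
#'
#' @param rows named character vector of aligned coding strings.
#' @param gene label.
#' @return CodonAlignment.
#' @export
codon_alignment <- function(rows, gene = "gene") {
  new_codon_alignment(gene, rows)
}

#' Remove gaps from an alignment row
#' @param x aligned string.
#' @return ungapped string.
#' @export
degap <- function(x) gsub("-", "", x, fixed = TRUE)

align_pair_raw <- function(a, b, protein = FALSE) {
  if (protein) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = PROT_MATRIX,
      gapOpening = PROT_GAP_OPEN, gapExtension = PROT_GAP_EXT)
  } else {
    mat <- Biostrings::nucleotideSubstitutionMatrix(
      match = NUC_MATCH, mismatch = NUC_MISMATCH, baseOnly = FALSE)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
      substitutionMatrix = mat,
      gapOpening = NUC_GAP_OPEN, gapExtension = NUC_GAP_EXT)
  }
  list(a = as.character(Biostrings::alignedPattern(pa)),
       b = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

# center-star merge: align every sequence to the center and pad so all
# rows share the center's gap profile
star_align <- function(seqs, protein = FALSE) {
  k <- length(seqs)
  if (k < 2) stop("need at least two sequences to align", call. = FALSE)
  if (any(!nzchar(unlist(seqs)))) stop("empty sequence", call. = FALSE)
  if (k == 2) {
    pw <- align_pair_raw(seqs[[1]], seqs[[2]], protein)
    rows <- c(pw$a, pw$b)
    names(rows) <- names(seqs)
    return(rows)
  }
  # center = sequence with the greatest total alignment score to the rest
  scores <- numeric(k)
  pair_cache <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      pw <- align_pair_raw(seqs[[i]], seqs[[j]], protein)
      scores[i] <- scores[i] + pw$score
      scores[j] <- scores[j] + pw$score
      pair_cache[[paste(i, j)]] <- pw
    }
  }
  c_idx <- which.max(scores)
  n_center <- nchar(seqs[[c_idx]])
  others <- setdiff(seq_len(k), c_idx)
  aligned <- list()
  ins <- integer(n_center + 1)        # insertions in slot 0..n_center
  per_seq_ins <- list()
  for (i in others) {
    key <- paste(min(i, c_idx), max(i, c_idx))
    pw <- pair_cache[[key]]
    if (i < c_idx) pw <- list(a = pw$b, b = pw$a, score = pw$score)
    # now pw$a is the center row
    ca <- seq_chars(pw$a); cb <- seq_chars(pw$b)
    slot <- integer(length(ca))
    pos <- 0L
    for (t in seq_along(ca)) {
      if (ca[t] != "-") pos <- pos + 1L
      slot[t] <- pos
    }
    ins_i <- integer(n_center + 1)
    gapcols <- ca == "-"
    if (any(gapcols)) {
      tb <- table(slot[gapcols])
      ins_i[as.integer(names(tb)) + 1L] <- as.integer(tb)
    }
    per_seq_ins[[as.character(i)]] <- list(chars = cb, slot = slot,
                                           gapcols = gapcols)
    ins <- pmax(ins, ins_i)
  }
  # rebuild rows on the merged column grid
  # insertions of slot p-1 sit between center residues p-1 and p; the
  # trailing slot n_center comes after the last residue
  center_chars <- seq_chars(seqs[[c_idx]])
  center_row <- character(0)
  for (p in seq_len(n_center)) {
    center_row <- c(center_row, rep("-", ins[p]), center_chars[p])
  }
  center_row <- c(center_row, rep("-", ins[n_center + 1]))
  rows <- list()
  rows[[c_idx]] <- chars_seq(center_row)
  for (i in others) {
    info <- per_seq_ins[[as.character(i)]]
    out <- character(0)
    for (p in seq_len(n_center + 1)) {
      slot_sel <- info$slot == (p - 1) & info$gapcols
      slot_chars <- info$chars[slot_sel]
      out <- c(out, slot_chars, rep("-", ins[p] - length(slot_chars)))
      if (p <= n_center) {
        res_sel <- info$slot == p & !info$gapcols
        out <- c(out, info$chars[res_sel])
      }
    }
    rows[[i]] <- chars_seq(out)
  }
  rows <- unlist(rows)
  names(rows) <- names(seqs)
  stopifnot(length(unique(nchar(rows))) == 1)
  rows
}

#' Global nucleotide alignment
#'
#' Aligns two or more sequences globally (match +1, mismatch -1, gap
#' open 2, extend 1); with more than two sequences a center-star merge
#' is used.
#'
#' @param seqs_by_taxon named list or character vector of DNA strings.
#' @param region label for the alignment.
#' @return NucAlignment.
#' @export
align_nuc <- function(seqs_by_taxon, region = "region") {
  seqs <- as.list(seqs_by_taxon)
  if (is.null(names(seqs)))
    names(seqs) <- paste0("t", seq_along(seqs))
  rows <- star_align(seqs, protein = FALSE)
  new_nuc_alignment(region, rows)
}

#' Protein-guided codon alignment
#'
#' Each CDS is translated under the invertebrate mitochondrial code
#' (incomplete terminal codon and terminal stop dropped), the proteins
#' are globally aligned (PAM120, affine gaps), and the protein alignment
#' is back-translated to codons, so every gap is a whole gap triplet and
#' reading frame is preserved in all rows.
#'
#' @param cds_by_taxon named list/vector of coding-orientation CDS.
#' @param gene gene label.
#' @return CodonAlignment.
#' @export
align_codon <- function(cds_by_taxon, gene = "gene") {
  seqs <- as.list(cds_by_taxon)
  if (is.null(names(seqs)))
    names(seqs) <- paste0("t", seq_along(seqs))
  code <- mito_code()
  prot <- list()
  codons <- list()
  for (tx in names(seqs)) {
    s <- toupper(seqs[[tx]])
    len <- nchar(s) - nchar(s) %% 3
    if (len < 3)
      stop(sprintf("CDS for %s/%s shorter than one codon", tx, gene),
           call. = FALSE)
    cods <- substring(s, seq(1, len, by = 3), seq(3, len, by = 3))
    if (unname(code[cods[length(cods)]]) %in% "*")
      cods <- cods[-length(cods)]
    aa <- unname(code[cods])
    if (anyNA(aa) || any(aa == "*"))
      stop(sprintf("CDS for %s/%s not translatable (internal stop or ambiguity)",
                   tx, gene), call. = FALSE)
    prot[[tx]] <- paste(aa, collapse = "")
    codons[[tx]] <- cods
  }
  prot_rows <- star_align(prot, protein = TRUE)
  rows <- vapply(names(seqs), function(tx) {
    chars <- seq_chars(prot_rows[[tx]])
    cods <- codons[[tx]]
    out <- character(length(chars))
    ci <- 0L
    for (t in seq_along(chars)) {
      if (chars[t] == "-") out[t] <- "---"
      else { ci <- ci + 1L; out[t] <- cods[ci] }
    }
    chars_seq(out)
  }, character(1))
  new_codon_alignment(gene, rows)
}

#' Codon-position mask of a codon alignment
#'
#' @param aln CodonAlignment.
#' @return integer vector (1,2,3,1,2,3,...) over alignment columns.
#' @export
position_mask <- function(aln) {
  stopifnot(inherits(aln, "CodonAlignment"))
  rep_len(1:3, nchar(aln$rows[[1]]))
}

#' Protein rows of a codon alignment
#'
#' @param aln CodonAlignment.
#' @return named character vector of aligned amino-acid strings.
#' @export
protein_rows <- function(aln) {
  stopifnot(inherits(aln, "CodonAlignment"))
  code <- mito_code()
  vapply(aln$rows, function(r) {
    nc <- nchar(r)
    cods <- substring(r, seq(1, nc, by = 3), seq(3, nc, by = 3))
    aa <- ifelse(cods == "---", "-", unname(code[cods]))
    paste(aa, collapse = "")
  }, character(1))
}

#' Write an alignment to FASTA
#' @param aln NucAlignment or CodonAlignment.
#' @param path output path.
#' @export
write_alignment_fasta <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tx in names(aln$rows)) {
    writeLines(paste0(">", tx), con)
    writeLines(aln$rows[[tx]], con)
  }
  invisible(path)
}

#' Read a FASTA alignment
#' @param path FASTA file of equal-length aligned sequences.
#' @param region label.
#' @return NucAlignment.
#' @export
read_alignment_fasta <- function(path, region = "region") {
  dna <- Biostrings::readBStringSet(path)
  rows <- as.character(dna)
  names(rows) <- vapply(strsplit(names(dna), "\\s+"), `[`, character(1), 1)
  new_nuc_alignment(region, rows)
}
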