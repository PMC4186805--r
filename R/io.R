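# Annotated mitogenome container and GenBank flat-file input/output.
#
# Coordinates are 1-based inclusive on the J strand (GenBank convention).
# A feature wrapping the circular origin is stored with end < start and
# spans start..length then 1..end.

PCG_NAMES <- c("atp6", "atp8", "cox1", "cox2", "cox3", "cytb",
               "nad1", "nad2", "nad3", "nad4", "nad4l", "nad5", "nad6")

TRNA_NAMES <- c("trnA", "trnR", "trnN", "trnD", "trnC", "trnE", "trnQ",
                "trnG", "trnH", "trnI", "trnL1", "trnL2", "trnK", "trnM",
                "trnF", "trnP", "trnS1", "trnS2", "trnT", "trnW", "trnV",
                "trnY")

RRNA_NAMES <- c("rrnL", "rrnS")

# Amino-acid letter for each tRNA symbol, used when reading GenBank
# "tRNA-Xxx" products.
TRNA_AA <- c(trnA = "Ala", trnR = "Arg", trnN = "Asn", trnD = "Asp",
             trnC = "Cys", trnE = "Glu", trnQ = "Gln", trnG = "Gly",
             trnH = "His", trnI = "Ile", trnL1 = "Leu", trnL2 = "Leu",
             trnK = "Lys", trnM = "Met", trnF = "Phe", trnP = "Pro",
             trnS1 = "Ser", trnS2 = "Ser", trnT = "Thr", trnW = "Trp",
             trnV = "Val", trnY = "Tyr")

# explicit synonym table; keys are lower-case with punctuation stripped
GENE_SYNONYMS <- c(
  atp6 = "atp6", atpase6 = "atp6", atp8 = "atp8", atpase8 = "atp8",
  cox1 = "cox1", coi = "cox1", co1 = "cox1", coxi = "cox1",
  cox2 = "cox2", coii = "cox2", co2 = "cox2", coxii = "cox2",
  cox3 = "cox3", coiii = "cox3", co3 = "cox3", coxiii = "cox3",
  cytb = "cytb", cob = "cytb", cytochromeb = "cytb",
  nad1 = "nad1", nd1 = "nad1", nad2 = "nad2", nd2 = "nad2",
  nad3 = "nad3", nd3 = "nad3", nad4 = "nad4", nd4 = "nad4",
  nad4l = "nad4l", nd4l = "nad4l", nad5 = "nad5", nd5 = "nad5",
  nad6 = "nad6", nd6 = "nad6",
  rrnl = "rrnL", lrrna = "rrnL", `16s` = "rrnL", `16srrna` = "rrnL",
  `16sribosomalrna` = "rrnL", lsu = "rrnL",
  rrns = "rrnS", srrna = "rrnS", `12s` = "rrnS", `12srrna` = "rrnS",
  `12sribosomalrna` = "rrnS", ssu = "rrnS",
  atrich = "AT_rich", at_rich = "AT_rich", atrichregion = "AT_rich",
  dloop = "AT_rich", controlregion = "AT_rich"
)

#' Canonicalize a gene name
#'
#' Maps the many spellings found in GenBank records (COI, ND4L, 16S rRNA,
#' tRNA-Leu(UUR), ...) onto the canonical symbols used throughout the
#' package (cox1, nad4l, rrnL, trnL2, ...). Leucine and serine tRNA
#' duplicates are disambiguated by anticodon or codon-family tag when one
#' is present; otherwise the caller must resolve them by genomic order
#' (see \code{read_genbank}).
#'
#' @param name raw gene or product name.
#' @param anticodon optional anticodon string (e.g. "taa") used to split
#'   trnL1/trnL2 and trnS1/trnS2.
#' @return canonical symbol, or NA if the name is not recognized.
#' @export
canonical_gene_name <- function(name, anticodon = NULL) {
  raw <- name
  key <- tolower(gsub("[^0-9A-Za-z_]", "", name))
  if (key %in% names(GENE_SYNONYMS)) return(unname(GENE_SYNONYMS[[key]]))
  if (key %in% c(PCG_NAMES, tolower(RRNA_NAMES), "at_rich"))
    return(if (key == "rrnl") "rrnL" else if (key == "rrns") "rrnS" else key)

  # tRNAs: trnX, trnL1, tRNA-Leu, tRNA-Ser(AGN) ...
  m <- regmatches(raw, regexec("^t[rR][nN][aA]?[-_ ]?([A-Za-z]{1,3}[12]?)",
                               raw))[[1]]
  if (length(m) == 2) {
    tag <- m[2]
    if (grepl("^[A-Za-z][12]$", tag)) {      # trnL1 style
      sym <- paste0("trn", toupper(substr(tag, 1, 1)), substr(tag, 2, 2))
      if (sym %in% TRNA_NAMES) return(sym)
    }
    if (nchar(tag) == 1) {                   # trnW style
      sym <- paste0("trn", toupper(tag))
      if (sym %in% TRNA_NAMES) return(sym)
      if (toupper(tag) %in% c("L", "S"))
        return(resolve_ls_trna(toupper(tag), raw, anticodon))
    }
    if (nchar(tag) == 3) {                   # tRNA-Leu style
      aa3 <- paste0(toupper(substr(tag, 1, 1)), tolower(substr(tag, 2, 3)))
      hits <- names(TRNA_AA)[TRNA_AA == aa3]
      if (length(hits) == 1) return(hits)
      if (length(hits) == 2)
        return(resolve_ls_trna(substr(hits[1], 4, 4), raw, anticodon))
    }
  }
  NA_character_
}

# Split the duplicated Leu/Ser tRNAs. trnL1 reads CUN codons (anticodon
# UAG), trnL2 reads UUR (anticodon UAA); trnS1 reads AGN (UCU/GCU),
# trnS2 reads UCN (UGA). Returns NA when no tag decides it.
resolve_ls_trna <- function(letter, raw, anticodon = NULL) {
  txt <- toupper(paste(raw, anticodon %||% ""))
  txt <- gsub("U", "T", txt)
  if (letter == "L") {
    if (grepl("CTN|TAG|L1", txt)) return("trnL1")
    if (grepl("TTR|TAA|L2", txt)) return("trnL2")
  } else {
    if (grepl("AGN|TCT|GCT|S1", txt)) return("trnS1")
    if (grepl("TCN|TGA|S2", txt)) return("trnS2")
  }
  NA_character_
}

#' Construct an annotated mitogenome
#'
#' @param id genome identifier (accession or fixture name).
#' @param sequence J-strand DNA string over A,C,G,T,N.
#' @param features data.frame with columns name, kind (PCG/tRNA/rRNA/region),
#'   start, end, strand (J/N); 1-based inclusive J-strand coordinates, a
#'   feature wrapping the origin has end < start.
#' @param circular logical, genome topology.
#' @param taxon taxon label (defaults to id).
#' @return object of class AnnotatedGenome.
#' @export
mito_genome <- function(id, sequence, features, circular = TRUE,
                        taxon = id) {
  sequence <- validate_dna(sequence, sprintf("genome %s", id))
  n <- nchar(sequence)
  if (n == 0) stop("empty genome sequence", call. = FALSE)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  need <- c("name", "kind", "start", "end", "strand")
  if (!all(need %in% names(features)))
    stop("features need columns ", paste(need, collapse = ", "), call. = FALSE)
  features <- features[need]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (any(features$start < 1 | features$start > n |
          features$end < 1 | features$end > n))
    stop("feature coordinates outside [1, genome length]", call. = FALSE)
  if (any(!features$strand %in% c("J", "N")))
    stop("strand must be J or N", call. = FALSE)
  if (anyDuplicated(features$name))
    stop("duplicate feature names: ",
         paste(unique(features$name[duplicated(features$name)]),
               collapse = ", "), call. = FALSE)
  if (any(features$end < features$start & !circular))
    stop("wrapping feature in a linear genome", call. = FALSE)
  structure(list(id = id, taxon = taxon, sequence = sequence,
                 circular = circular, features = features),
            class = "AnnotatedGenome")
}

#' @export
print.AnnotatedGenome <- function(x, ...) {
  cat(sprintf("AnnotatedGenome %s (%s): %d bp, %s, %d features (%d J / %d N)\n",
              x$id, x$taxon, nchar(x$sequence),
              if (x$circular) "circular" else "linear",
              nrow(x$features), sum(x$features$strand == "J"),
              sum(x$features$strand == "N")))
  invisible(x)
}

feature_length <- function(genome, feat) {
  n <- nchar(genome$sequence)
  ifelse(feat$end >= feat$start, feat$end - feat$start + 1L,
         n - feat$start + 1L + feat$end)
}

# J-strand slice of [start, end] with origin wrap when end < start
slice_region <- function(sequence, start, end) {
  if (end >= start) return(substr(sequence, start, end))
  paste0(substr(sequence, start, nchar(sequence)), substr(sequence, 1, end))
}

#' Extract a gene sequence in coding orientation
#'
#' Returns the 5'->3' coding-strand sequence of a named feature:
#' N-strand features are reverse-complemented, origin-wrapping features
#' are concatenated across the junction.
#'
#' @param genome AnnotatedGenome.
#' @param name canonical gene symbol (canonicalized if needed).
#' @return DNA string.
#' @export
extract_gene <- function(genome, name) {
  feat <- locate_feature(genome, name)
  s <- slice_region(genome$sequence, feat$start, feat$end)
  if (feat$strand == "N") s <- revcomp(s)
  s
}

locate_feature <- function(genome, name) {
  i <- match(name, genome$features$name)
  if (is.na(i)) {
    canon <- canonical_gene_name(name)
    if (!is.na(canon)) i <- match(canon, genome$features$name)
  }
  if (is.na(i))
    stop(sprintf("gene '%s' not found in genome %s", name, genome$id),
         call. = FALSE)
  genome$features[i, ]
}

#' Find overlapping features
#'
#' Reports every pair of features whose J-strand coordinate ranges
#' intersect, with the shared J-strand sequence. PCG-PCG overlaps carry
#' \code{pcg_pcg = TRUE}.
#'
#' @param genome AnnotatedGenome.
#' @return data.frame (gene_a, gene_b, overlap_length, shared_sequence,
#'   pcg_pcg); zero rows when no features overlap.
#' @export
find_overlaps <- function(genome) {
  fts <- genome$features
  n <- nchar(genome$sequence)
  # unroll wrapping features onto 1..2n so interval logic is linear
  lo <- fts$start
  hi <- ifelse(fts$end >= fts$start, fts$end, fts$end + n)
  out <- list()
  nf <- nrow(fts)
  if (nf >= 2) {
    for (i in seq_len(nf - 1)) {
      for (j in (i + 1):nf) {
        ov <- overlap_span(lo[i], hi[i], lo[j], hi[j], n,
                           genome$circular)
        if (is.null(ov)) next
        len <- ov[2] - ov[1] + 1L
        a <- ((ov[1] - 1L) %% n) + 1L
        b <- ((ov[2] - 1L) %% n) + 1L
        out[[length(out) + 1L]] <- data.frame(
          gene_a = fts$name[i], gene_b = fts$name[j],
          overlap_length = len,
          shared_sequence = slice_region(genome$sequence, a, b),
          pcg_pcg = fts$kind[i] == "PCG" && fts$kind[j] == "PCG",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(gene_a = character(), gene_b = character(),
                      overlap_length = integer(),
                      shared_sequence = character(), pcg_pcg = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# intersection of two arcs given on the unrolled line; considers the
# +/- n shifts a circular genome allows; returns c(lo, hi) or NULL
overlap_span <- function(a1, a2, b1, b2, n, circular) {
  shifts <- if (circular) c(-n, 0L, n) else 0L
  best <- NULL
  for (s in shifts) {
    lo <- max(a1, b1 + s); hi <- min(a2, b2 + s)
    if (hi >= lo && (is.null(best) || hi - lo > best[2] - best[1]))
      best <- c(lo, hi)
  }
  best
}

#' Start and stop codons of all protein-coding genes
#'
#' The start codon is the first triplet of the coding-orientation CDS.
#' The stop is complete when the final in-frame triplet is TAA or TAG;
#' a CDS whose length is not a multiple of three is classified as having
#' an incomplete stop (the trailing T or TA, completed to TAA by
#' polyadenylation in vivo). Internal in-frame stops are flagged in the
#' \code{warning} column rather than raising an error.
#'
#' @param genome AnnotatedGenome.
#' @return data.frame (gene, start_codon, stop_codon, stop_complete,
#'   warning).
#' @export
start_stop_table <- function(genome) {
  pcg <- genome$features[genome$features$kind == "PCG", ]
  rows <- lapply(pcg$name, function(g) {
    s <- extract_gene(genome, g)
    len <- nchar(s)
    rem <- len %% 3
    start <- substr(s, 1, 3)
    if (rem == 0) {
      last <- substr(s, len - 2, len)
      complete <- last %in% c("TAA", "TAG")
      stop_codon <- if (complete) last else ""
    } else {
      complete <- FALSE
      stop_codon <- substr(s, len - rem + 1, len)
    }
    ncod <- (len - rem) %/% 3
    internal <- 0L
    if (ncod > 2) {
      cods <- substring(s, seq(4, by = 3, length.out = ncod - 2), # skip start
                        seq(6, by = 3, length.out = ncod - 2))
      cods <- cods[seq_len(ncod - 2)]
      internal <- sum(cods %in% c("TAA", "TAG"))
    }
    data.frame(gene = g, start_codon = start, stop_codon = stop_codon,
               stop_complete = complete,
               warning = if (internal > 0)
                 sprintf("%d internal stop codon(s)", internal) else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summary table of one or more genomes
#'
#' @param genomes list of AnnotatedGenome.
#' @return data.frame (id, taxon, length, n_features, n_genes, n_J, n_N,
#'   at_pct, at_skew, gc_skew); gene counts exclude region features such
#'   as AT_rich.
#' @export
genome_summary <- function(genomes) {
  if (inherits(genomes, "AnnotatedGenome")) genomes <- list(genomes)
  rows <- lapply(genomes, function(g) {
    comp <- base_composition(g$sequence, label = g$id)
    genes <- g$features[g$features$kind != "region", ]
    data.frame(id = g$id, taxon = g$taxon, length = nchar(g$sequence),
               n_features = nrow(g$features),
               n_genes = nrow(genes),
               n_J = sum(genes$strand == "J"),
               n_N = sum(genes$strand == "N"),
               at_pct = comp$pct_AT, at_skew = comp$at_skew,
               gc_skew = comp$gc_skew, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ---- GenBank flat-file reader/writer -------------------------------------

#' Read an annotated mitogenome from a GenBank flat file
#'
#' Parses LOCUS, FEATURES (CDS, tRNA, rRNA, misc_feature/D-loop) and
#' ORIGIN of a single-record flat file. Gene names are canonicalized via
#' the synonym table; unresolvable features raise an error listing them.
#' When no control-region feature is annotated, the non-coding stretch
#' between the rrnS end and the trnI start (wrapping the origin if
#' necessary) is labeled AT_rich.
#'
#' @param path file path.
#' @return AnnotatedGenome.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("not a GenBank flat file: no LOCUS line",
                           call. = FALSE)
  toks <- strsplit(trimws(locus[1]), "\\s+")[[1]]
  id <- toks[2]
  circular <- any(grepl("circular", locus[1], ignore.case = TRUE))

  org <- grep("^\\s+ORGANISM", lines, value = TRUE)
  taxon <- if (length(org)) trimws(sub("^\\s+ORGANISM\\s+", "", org[1])) else id

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (!length(fstart) || !length(ostart))
    stop("GenBank file lacks FEATURES or ORIGIN block", call. = FALSE)

  seq_lines <- lines[(ostart[1] + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  sequence <- validate_dna(sequence, sprintf("genome %s", id))

  feat_lines <- lines[(fstart[1] + 1):(ostart[1] - 1)]
  feats <- parse_genbank_features(feat_lines)

  resolved <- resolve_feature_names(feats, id)
  genome <- mito_genome(id, sequence, resolved, circular = circular,
                        taxon = taxon)
  ensure_at_rich(genome)
}

# split the FEATURES block into (key, location, qualifiers) entries
parse_genbank_features <- function(feat_lines) {
  is_key <- grepl("^ {5}\\S", feat_lines)
  idx <- which(is_key)
  entries <- list()
  for (k in seq_along(idx)) {
    from <- idx[k]
    to <- if (k < length(idx)) idx[k + 1] - 1 else length(feat_lines)
    block <- feat_lines[from:to]
    head <- strsplit(trimws(block[1]), "\\s+")[[1]]
    key <- head[1]
    if (!key %in% c("CDS", "tRNA", "rRNA", "misc_feature", "D-loop")) next
    rest <- paste(trimws(block[-1]), collapse = "\n")
    # location may continue before the first qualifier
    qual_at <- regexpr("/", rest, fixed = TRUE)
    loc_extra <- if (qual_at > 0) substr(rest, 1, qual_at - 1) else rest
    loc <- gsub("[\n ]", "", paste0(paste(head[-1], collapse = ""), loc_extra))
    quals <- if (qual_at > 0) substr(rest, qual_at, nchar(rest)) else ""
    getq <- function(name) {
      m <- regmatches(quals,
                      regexec(sprintf('/%s="?([^"/\n]+)"?', name), quals))[[1]]
      if (length(m) == 2) trimws(m[2]) else NA_character_
    }
    parsed <- parse_genbank_location(loc)
    entries[[length(entries) + 1]] <- list(
      key = key, start = parsed$start, end = parsed$end,
      strand = parsed$strand, gene = getq("gene"), product = getq("product"),
      note = getq("note"), anticodon = getq("anticodon"))
  }
  entries
}

# location strings: 123..456, complement(...), join(a..L,1..b) for wraps
parse_genbank_location <- function(loc) {
  strand <- "J"
  if (grepl("^complement\\(", loc)) {
    strand <- "N"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  nums <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", p))[[1]]
    if (length(m) != 3) stop("unsupported GenBank location: ", loc,
                             call. = FALSE)
    as.integer(m[2:3])
  })
  start <- nums[[1]][1]
  end <- nums[[length(nums)]][2]
  list(start = start, end = end, strand = strand)
}

resolve_feature_names <- function(entries, id) {
  unresolved <- character()
  rows <- list()
  for (e in entries) {
    kind <- switch(e$key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                   "region")
    label <- e$gene %||% NA_character_
    canon <- NA_character_
    for (cand in c(e$gene, e$product, e$note)) {
      if (is.na(cand) || !nzchar(cand)) next
      canon <- canonical_gene_name(cand, anticodon = e$anticodon)
      if (!is.na(canon)) break
    }
    if (kind == "region" && is.na(canon)) canon <- "AT_rich"
    if (is.na(canon)) {
      unresolved <- c(unresolved,
                      sprintf("%s at %d..%d (%s)", e$key, e$start, e$end,
                              e$gene %||% e$product %||% "?"))
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      name = canon, kind = kind, start = e$start, end = e$end,
      strand = e$strand, stringsAsFactors = FALSE)
  }
  if (length(unresolved))
    stop(sprintf("genome %s: unresolved feature names:\n  %s", id,
                 paste(unresolved, collapse = "\n  ")), call. = FALSE)
  feats <- do.call(rbind, rows)
  # duplicated Leu/Ser without anticodon tags: ancestral order has trnL2
  # before trnL1 and trnS1 before trnS2 along the J strand
  feats
}

# label the non-coding stretch between rrnS end and trnI start AT_rich
ensure_at_rich <- function(genome) {
  if ("AT_rich" %in% genome$features$name) return(genome)
  f <- genome$features
  if (!all(c("rrnS", "trnI") %in% f$name)) return(genome)
  n <- nchar(genome$sequence)
  rs <- f[f$name == "rrnS", ]
  ti <- f[f$name == "trnI", ]
  start <- (max(rs$start, rs$end) %% n) + 1L
  end <- ti$start - 1L
  if (end == 0L) end <- n
  len <- if (end >= start) end - start + 1L else n - start + 1L + end
  if (len < 50L) return(genome)   # no meaningful control region
  genome$features <- rbind(f, data.frame(
    name = "AT_rich", kind = "region", start = start, end = end,
    strand = "J", stringsAsFactors = FALSE))
  genome
}

#' Write an AnnotatedGenome as a GenBank flat file
#'
#' Emits a minimal single-record flat file (LOCUS, FEATURES, ORIGIN) that
#' \code{read_genbank} round-trips exactly.
#'
#' @param genome AnnotatedGenome.
#' @param path output file path.
#' @export
write_genbank <- function(genome, path) {
  n <- nchar(genome$sequence)
  con <- file(path, "w")
  on.exit(close(con))
  # fixed date: outputs are byte-reproducible under a fixed seed
  writeLines(sprintf(
    "LOCUS       %s %d bp    DNA     %s MIT 01-JAN-2000",
    genome$id, n, if (genome$circular) "circular" else "linear"), con)
  writeLines(sprintf("DEFINITION  %s mitochondrion.", genome$taxon), con)
  writeLines("SOURCE      synthetic", con)
  writeLines(sprintf("  ORGANISM  %s", genome$taxon), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", n), con)
  for (i in seq_len(nrow(genome$features))) {
    ft <- genome$features[i, ]
    span <- if (ft$end >= ft$start)
      sprintf("%d..%d", ft$start, ft$end)
    else
      sprintf("join(%d..%d,1..%d)", ft$start, n, ft$end)
    if (ft$strand == "N") span <- sprintf("complement(%s)", span)
    key <- switch(ft$kind, PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  "misc_feature")
    writeLines(sprintf("     %-15s %s", key, span), con)
    writeLines(sprintf('                     /gene="%s"', ft$name), con)
    if (ft$name == "AT_rich")
      writeLines('                     /note="AT-rich region"', con)
  }
  writeLines("ORIGIN", con)
  lower <- tolower(genome$sequence)
  for (off in seq(1, n, by = 60)) {
    chunk <- substr(lower, off, min(off + 59, n))
    groups <- substring(chunk, seq(1, nchar(chunk), by = 10),
                        pmin(seq(10, nchar(chunk) + 9, by = 10),
                             nchar(chunk)))
    writeLines(sprintf("%9d %s", off, paste(groups, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read a genome from FASTA plus a feature table
#'
#' Alternative input route: a single-sequence FASTA file and a
#' tab-separated table with columns name, kind, start, end, strand.
#'
#' @param fasta_path FASTA file with one sequence.
#' @param table_path TSV feature table.
#' @param circular logical.
#' @return AnnotatedGenome.
#' @export
read_feature_table <- function(fasta_path, table_path, circular = TRUE) {
  dna <- Biostrings::readDNAStringSet(fasta_path)
  if (length(dna) != 1) stop("FASTA must contain exactly one sequence",
                             call. = FALSE)
  id <- strsplit(names(dna)[1], "\\s+")[[1]][1]
  feats <- utils::read.delim(table_path, stringsAsFactors = FALSE)
  genome <- mito_genome(id, as.character(dna[[1]]), feats,
                        circular = circular)
  ensure_at_rich(genome)
}
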