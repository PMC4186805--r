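# Cross-gene synthesis: per-gene rate rows, GC-content versus
# substitution-rate regression per codon position, rate rankings and
# relative-rate ratios.

#' Per-gene rate table
#'
#' Builds one row per protein-coding gene from a set of annotated
#' genomes: strand, per-position GC content of the pooled (all-taxon)
#' sequences, group-average K2p (total and per position), Dayhoff/PAM
#' protein distance and Ka/Ks.
#'
#' @param genomes list of AnnotatedGenome sharing the gene set.
#' @param genes gene symbols (default: all 13 PCGs present).
#' @return data.frame with class GeneRateRow rows.
#' @export
gene_rate_table <- function(genomes, genes = NULL) {
  if (is.null(genes))
    genes <- intersect(PCG_NAMES, genomes[[1]]$features$name)
  taxa <- vapply(genomes, function(g) g$id, character(1))
  rows <- lapply(genes, function(gn) {
    cds <- lapply(genomes, extract_gene, name = gn)
    names(cds) <- taxa
    aln <- align_codon(cds, gene = gn)
    avg <- group_average(gene_distances(aln))
    gc <- vapply(1:3, function(pos) {
      pooled <- paste(vapply(genomes, function(g) {
        cods <- pcg_codons(g, gn)
        paste(substr(cods, pos, pos), collapse = "")
      }, character(1)), collapse = "")
      cmp <- base_composition(pooled)
      cmp$pct_C + cmp$pct_G
    }, numeric(1))
    strand <- genomes[[1]]$features$strand[
      match(gn, genomes[[1]]$features$name)]
    data.frame(gene = gn, strand = strand,
               gc_pos1 = gc[1], gc_pos2 = gc[2], gc_pos3 = gc[3],
               k2p_total = avg$k2p, k2p_pos1 = avg$k2p_pos1,
               k2p_pos2 = avg$k2p_pos2, k2p_pos3 = avg$k2p_pos3,
               pam = avg$pam, ka_ks = avg$ka_ks,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' GC content versus substitution rate regression
#'
#' Ordinary least squares of group-average per-position K2p on
#' per-position GC content across genes.
#'
#' @param rows data.frame from \code{gene_rate_table}.
#' @param position codon position 1, 2 or 3.
#' @return list (slope, intercept, correlation, n).
#' @export
gc_rate_regression <- function(rows, position) {
  stopifnot(position %in% 1:3)
  x <- rows[[paste0("gc_pos", position)]]
  y <- rows[[paste0("k2p_pos", position)]]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 genes", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate GC variance", call. = FALSE)
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       correlation = stats::cor(x, y), n = length(x))
}

#' Relative substitution rate of two regions
#'
#' @param numerator,denominator one-row DistanceResult data.frames (or
#'   anything with a \code{k2p} column/element) for the same taxon pair.
#' @return K2p ratio.
#' @export
relative_rate <- function(numerator, denominator) {
  num <- if (is.data.frame(numerator)) numerator$k2p[1] else numerator$k2p
  den <- if (is.data.frame(denominator)) denominator$k2p[1] else denominator$k2p
  if (is.na(den) || den == 0) stop("zero or undefined denominator rate",
                                   call. = FALSE)
  num / den
}

#' Rank genes by total substitution rate
#'
#' @param rows data.frame from \code{gene_rate_table}.
#' @return the input rows sorted by decreasing k2p_total (ties broken
#'   alphabetically by gene).
#' @export
rate_ranking <- function(rows) {
  out <- rows[order(-rows$k2p_total, rows$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
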