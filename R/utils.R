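# Internal sequence helpers shared across modules.

BASES <- c("A", "C", "G", "T")

# reverse complement of an uppercase DNA character scalar (N allowed)
revcomp <- function(seq) {
  if (!nzchar(seq)) return(seq)
  comp <- chartr("ACGTN", "TGCAN", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

chars_seq <- function(x) paste(x, collapse = "")

validate_dna <- function(seq, what = "sequence") {
  bad <- gsub("[ACGTN]", "", toupper(seq))
  if (nzchar(bad)) {
    stop(sprintf("%s contains non-nucleotide characters: %s", what,
                 paste(unique(seq_chars(bad)), collapse = ",")), call. = FALSE)
  }
  toupper(seq)
}

# rotate a circular sequence so that position `offset + 1` becomes position 1
rotate_seq <- function(seq, offset) {
  n <- nchar(seq)
  offset <- offset %% n
  if (offset == 0) return(seq)
  paste0(substr(seq, offset + 1, n), substr(seq, 1, offset))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
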