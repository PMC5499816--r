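#' Reverse complement of DNA strings
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences (A/C/G/T, IUPAC codes allowed).
#' @return Character vector of reverse complements, names preserved.
#' @export
#' @examples
#' revcomp("CACGTG")
revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

# Coerce sequence input (character vector, DNAStringSet, or list) to a named
# character vector of uppercase sequences.
as_dna_character <- function(sequences) {
  if (methods::is(sequences, "XStringSet")) {
    seqs <- as.character(sequences)
  } else if (is.list(sequences)) {
    seqs <- vapply(sequences, as.character, character(1))
  } else {
    seqs <- sequences
    storage.mode(seqs) <- "character"   # as.character() would drop names
  }
  seqs <- toupper(seqs)
  names(seqs) <- names(sequences)
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")) {
    names(seqs) <- if (is.null(names(seqs))) paste0("seq", seq_along(seqs)) else
      ifelse(is.na(names(seqs)) | names(seqs) == "", paste0("seq", seq_along(seqs)), names(seqs))
  }
  seqs
}

# Integer encoding A=1,C=2,G=3,T=4; anything else becomes NA.
dna_to_int <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1]], DNA_BASES)
}

assert_acgt <- function(seqs, what = "sequence") {
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    stop(sprintf("%s contains non-A/C/G/T characters: %s",
                 what, paste(head(names(seqs)[bad], 3), collapse = ", ")),
         call. = FALSE)
  }
  invisible(seqs)
}

# Empirical mononucleotide frequencies of a sequence set.
empirical_background <- function(sequences) {
  seqs <- as_dna_character(sequences)
  counts <- colSums(Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(seqs), baseOnly = TRUE)[, DNA_BASES, drop = FALSE])
  if (sum(counts) == 0) stop("no A/C/G/T characters in sequences", call. = FALSE)
  counts / sum(counts)
}
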