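#' Construct a motif probability matrix object
#'
#' A `motif_matrix` holds per-position nucleotide probabilities for a
#' fixed-width motif together with the background model against which
#' log-odds bit scores are computed. The CATAC element is a width-29 motif
#' whose residues are numbered 1-29 (1-based), with the conserved core at
#' residues 8-17 and the E-box-like region at residues 19-24.
#'
#' @param probs Numeric matrix, 4 rows named A,C,G,T, one column per motif
#'   position; each column must sum to 1 and (for scoring) be strictly
#'   positive.
#' @param background Named numeric vector of background frequencies for
#'   A,C,G,T (default uniform).
#' @param name Motif name used in MEME-format serialization.
#' @param pseudocount Pseudocount weight recorded for provenance.
#' @param nsites Number of sites the matrix was estimated from, if known.
#' @return An object of class `motif_matrix`.
#' @export
motif_matrix <- function(probs, background = NULL, name = "motif",
                         pseudocount = NA_real_, nsites = NA_integer_) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4) stop("probs must have 4 rows (A,C,G,T)", call. = FALSE)
  if (is.null(rownames(probs))) rownames(probs) <- DNA_BASES
  probs <- probs[DNA_BASES, , drop = FALSE]
  if (is.null(background)) background <- setNames(rep(0.25, 4), DNA_BASES)
  background <- background[DNA_BASES]
  if (any(is.na(background)) || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-6) {
    stop("background must be positive A,C,G,T frequencies summing to 1",
         call. = FALSE)
  }
  csums <- colSums(probs)
  if (any(abs(csums - 1) > 1e-9)) {
    stop("each motif position's probabilities must sum to 1", call. = FALSE)
  }
  if (any(probs < 0)) stop("negative probabilities", call. = FALSE)
  structure(
    list(probs = probs, background = background, name = name,
         pseudocount = pseudocount, nsites = nsites),
    class = "motif_matrix")
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat(sprintf("motif_matrix '%s': width %d, consensus %s\n",
              x$name, motif_width(x), motif_consensus(x)))
  cat(sprintf("background: %s\n",
              paste(sprintf("%s=%.3f", DNA_BASES, x$background), collapse = " ")))
  invisible(x)
}

#' Motif width (number of positions)
#' @param matrix A `motif_matrix`.
#' @return Integer width.
#' @export
motif_width <- function(matrix) ncol(matrix$probs)

#' Consensus string (argmax base per position)
#' @param matrix A `motif_matrix`.
#' @return Character scalar of length `motif_width(matrix)`.
#' @export
motif_consensus <- function(matrix) {
  paste(DNA_BASES[apply(matrix$probs, 2, which.max)], collapse = "")
}

#' Per-position information content
#'
#' Relative entropy of each motif position against the background,
#' `sum(p * log2(p / b))`; non-negative, and zero only where the position
#' matches the background exactly.
#'
#' @param matrix A `motif_matrix`.
#' @return Numeric vector of bits per position.
#' @export
motif_information <- function(matrix) {
  p <- matrix$probs
  b <- matrix$background
  ic <- colSums(ifelse(p > 0, p * log2(p / b), 0))
  unname(ic)
}

#' Estimate a motif matrix from aligned sites
#'
#' Per-position probabilities are `(count + pseudocount * background) /
#' (n + pseudocount)`: Laplace-style smoothing that keeps every probability
#' strictly positive whenever `pseudocount > 0`, so log-odds scores stay
#' finite.
#'
#' @param aligned_sites Character vector (or `DNAStringSet`) of equal-length
#'   A/C/G/T sequences, at least two.
#' @param pseudocount Total pseudocount weight distributed according to the
#'   background (default 0.5).
#' @param background Background frequencies (default uniform).
#' @param name Motif name.
#' @return A `motif_matrix`.
#' @export
#' @examples
#' m <- build_motif_matrix(c("CACGTG", "CACGTG", "CGCGTG"), pseudocount = 0)
#' motif_consensus(m)
build_motif_matrix <- function(aligned_sites, pseudocount = 0.5,
                               background = NULL, name = "motif") {
  sites <- as_dna_character(aligned_sites)
  if (length(sites) < 2) stop("need at least 2 aligned sites", call. = FALSE)
  w <- unique(nchar(sites))
  if (length(w) != 1) stop("aligned sites must all have the same length", call. = FALSE)
  if (w < 1) stop("empty sites", call. = FALSE)
  assert_acgt(sites, "aligned site")
  if (is.null(background)) background <- setNames(rep(0.25, 4), DNA_BASES)
  background <- background[DNA_BASES]
  n <- length(sites)
  counts <- matrix(0, nrow = 4, ncol = w, dimnames = list(DNA_BASES, NULL))
  codes <- matrix(vapply(sites, dna_to_int, integer(w)), nrow = w)  # w x n
  for (b in 1:4) counts[b, ] <- rowSums(codes == b)
  probs <- sweep(counts + pseudocount * background, 2, n + pseudocount, "/")
  motif_matrix(probs, background = background, name = name,
               pseudocount = pseudocount, nsites = n)
}

#' Log-odds bit score of subsequences under a motif matrix
#'
#' The bit score of a window `x[1..w]` is
#' `sum_i log2(probs[i, x[i]] / background[x[i]])`: the log base-2 odds of
#' the window under the motif model versus the background model. Scores are
#' additive over positions.
#'
#' @param matrix A `motif_matrix`.
#' @param subseq Character vector of sequences, each exactly the motif width.
#' @return Numeric vector of bit scores.
#' @export
#' @examples
#' m <- build_motif_matrix(c("CACGTG", "CACGTG"), pseudocount = 0.5)
#' motif_bit_score(m, "CACGTG")
motif_bit_score <- function(matrix, subseq) {
  stopifnot(inherits(matrix, "motif_matrix"))
  seqs <- as_dna_character(subseq)
  w <- motif_width(matrix)
  if (any(nchar(seqs) != w)) {
    stop(sprintf("subsequences must have length %d (motif width)", w),
         call. = FALSE)
  }
  assert_acgt(seqs, "subsequence")
  lo <- log2(matrix$probs / matrix$background)   # 4 x w log-odds
  unname(vapply(seqs, function(s) {
    idx <- dna_to_int(s)
    sum(lo[cbind(idx, seq_len(w))])
  }, numeric(1)))
}

# Score every window of one integer-encoded sequence; returns numeric vector
# of length length(codes) - w + 1 (or length 0 when too short). NA where a
# window covers a non-ACGT character.
score_windows <- function(lo, codes) {
  w <- ncol(lo)
  nwin <- length(codes) - w + 1
  if (nwin < 1) return(numeric(0))
  s <- numeric(nwin)
  for (j in seq_len(w)) {
    s <- s + lo[cbind(codes[j:(j + nwin - 1)], j)]
  }
  s
}

#' Scan sequences for motif hits above a bit-score threshold
#'
#' Every window scoring strictly above `threshold_bits` on either strand is
#' reported on forward-strand coordinates (0-based, half-open). Overlapping
#' hits on the same strand are resolved greedily by descending score
#' (ties: leftmost window wins).
#'
#' @param matrix A `motif_matrix`.
#' @param sequences Named character vector or `DNAStringSet`.
#' @param threshold_bits Strict lower bound on reported scores (default 5,
#'   the CATAC site-calling threshold).
#' @param both_strands Scan the reverse complement too (default TRUE).
#' @param background Either `"matrix"` (use the matrix's stored background)
#'   or `"empirical"` (mononucleotide frequencies of `sequences`).
#' @return Data frame with columns `seq_id`, `start`, `end`, `strand`,
#'   `score_bits`. Sequences shorter than the motif width are skipped with a
#'   warning.
#' @export
scan_motif <- function(matrix, sequences, threshold_bits = 5,
                       both_strands = TRUE, background = c("matrix", "empirical")) {
  stopifnot(inherits(matrix, "motif_matrix"))
  background <- match.arg(background)
  seqs <- as_dna_character(sequences)
  if (length(seqs) == 0) stop("no sequences to scan", call. = FALSE)
  if (background == "empirical") {
    matrix <- motif_matrix(matrix$probs, empirical_background(seqs),
                           name = matrix$name, pseudocount = matrix$pseudocount,
                           nsites = matrix$nsites)
  }
  w <- motif_width(matrix)
  lo <- log2(matrix$probs / matrix$background)
  too_short <- nchar(seqs) < w
  if (any(too_short)) {
    warning(sprintf("skipping %d sequence(s) shorter than motif width",
                    sum(too_short)))
    seqs <- seqs[!too_short]
  }
  hits <- lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    len <- nchar(s)
    out <- list()
    fwd <- score_windows(lo, dna_to_int(s))
    keep <- which(!is.na(fwd) & fwd > threshold_bits)
    if (length(keep)) {
      out$fwd <- data.frame(seq_id = id, start = keep - 1L, end = keep - 1L + w,
                            strand = "+", score_bits = fwd[keep])
    }
    if (both_strands) {
      rev <- score_windows(lo, dna_to_int(revcomp(s)))
      keep <- which(!is.na(rev) & rev > threshold_bits)
      if (length(keep)) {
        # window at 0-based offset i on the reverse strand maps to forward
        # coordinates [len - i - w, len - i)
        i0 <- keep - 1L
        out$rev <- data.frame(seq_id = id, start = len - i0 - w,
                              end = len - i0, strand = "-",
                              score_bits = rev[keep])
      }
    }
    if (length(out)) do.call(rbind, out) else NULL
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits) || nrow(hits) == 0) {
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      score_bits = numeric(0)))
  }
  hits <- resolve_overlaps(hits, same_strand_only = TRUE)
  rownames(hits) <- NULL
  hits
}

# Greedy overlap resolution: order by descending score then ascending start,
# keep a hit unless it overlaps an already kept hit (optionally only on the
# same strand within the same sequence).
resolve_overlaps <- function(hits, same_strand_only = TRUE) {
  ord <- order(-hits$score_bits, hits$start, hits$strand)
  hits <- hits[ord, , drop = FALSE]
  keep <- logical(nrow(hits))
  for (grp in split(seq_len(nrow(hits)), hits$seq_id)) {
    kept <- integer(0)
    for (i in grp) {
      over <- FALSE
      for (k in kept) {
        if (same_strand_only && hits$strand[k] != hits$strand[i]) next
        if (hits$start[i] < hits$end[k] && hits$start[k] < hits$end[i]) {
          over <- TRUE
          break
        }
      }
      if (!over) {
        keep[i] <- TRUE
        kept <- c(kept, i)
      }
    }
  }
  out <- hits[keep, , drop = FALSE]
  out[order(out$seq_id, out$start), , drop = FALSE]
}
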