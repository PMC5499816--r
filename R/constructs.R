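#' IUPAC consensus patterns of the CATAC element
#'
#' A `consensus_pattern` names an IUPAC pattern and its 1-based offset in
#' the 29-residue CATAC motif. The built-ins are the conserved core
#' `TRCGCATACG` (residues 8-17), the CATAC E-box-like consensus `CRCGTG`
#' (residues 19-24), and the canonical bHLH E-box `CACGTG` at the same
#' offset.
#'
#' @param name Pattern label.
#' @param iupac IUPAC pattern string.
#' @param offset 1-based motif residue at which the pattern starts.
#' @return A `consensus_pattern` object.
#' @export
consensus_pattern <- function(name, iupac, offset = 1L) {
  iupac <- toupper(iupac)
  chars <- strsplit(iupac, "", fixed = TRUE)[[1]]
  if (!all(chars %in% names(IUPAC_CODES))) {
    stop("pattern contains non-IUPAC characters", call. = FALSE)
  }
  offset <- as.integer(offset)
  if (offset < 1 || offset + nchar(iupac) - 1 > 29) {
    stop("pattern must fit within motif residues 1..29", call. = FALSE)
  }
  structure(list(name = name, iupac = iupac, offset = offset),
            class = "consensus_pattern")
}

#' @rdname consensus_pattern
#' @export
catac_core <- function() consensus_pattern("core", "TRCGCATACG", 8L)

#' @rdname consensus_pattern
#' @export
catac_ebox <- function() consensus_pattern("ebox", "CRCGTG", 19L)

#' @rdname consensus_pattern
#' @export
canonical_ebox <- function() consensus_pattern("canonical_ebox", "CACGTG", 19L)

#' Count mismatches of a subsequence against an IUPAC pattern
#'
#' A position matches when the base belongs to the IUPAC class of the
#' pattern character (e.g. both A and G match R), and counts as a mismatch
#' otherwise.
#'
#' @param pattern A `consensus_pattern` or plain IUPAC string.
#' @param subseq Character vector of sequences, each the pattern's length.
#' @return Integer vector of mismatch counts.
#' @export
#' @examples
#' iupac_mismatches("CRCGTG", c("CACGTG", "CGCGTG", "CTCGTG"))
iupac_mismatches <- function(pattern, subseq) {
  pat <- if (inherits(pattern, "consensus_pattern")) pattern$iupac else toupper(pattern)
  pchars <- strsplit(pat, "", fixed = TRUE)[[1]]
  if (!all(pchars %in% names(IUPAC_CODES))) {
    stop("pattern contains non-IUPAC characters", call. = FALSE)
  }
  seqs <- toupper(as.character(subseq))
  if (any(nchar(seqs) != length(pchars))) {
    stop("subsequence length must equal pattern length", call. = FALSE)
  }
  vapply(seqs, function(s) {
    x <- strsplit(s, "", fixed = TRUE)[[1]]
    sum(!mapply(function(p, b) b %in% IUPAC_CODES[[p]], pchars, x))
  }, integer(1), USE.NAMES = FALSE)
}

# Extract the pattern's residue range from 29-base element strings.
pattern_region <- function(element_seq, pattern) {
  substr(element_seq, pattern$offset, pattern$offset + nchar(pattern$iupac) - 1L)
}

#' Locate CATAC elements in an enhancer sequence
#'
#' Slides a 29-base window over both strands and keeps windows whose core
#' region (motif residues 8-17) has at most `max_core_mismatch` mismatches
#' against the core consensus. Candidate windows are reduced to disjoint
#' elements greedily by ascending core mismatch count (ties: leftmost
#' forward-strand coordinate). Because an element is a double-stranded
#' site, overlap resolution here operates across strands, unlike
#' [scan_motif()].
#'
#' @param enhancer_seq A single DNA string of length >= 29.
#' @param core A `consensus_pattern` for the core (default [catac_core()]).
#' @param max_core_mismatch Maximum core mismatches (default 2; recovers
#'   all wild-type construct elements while rejecting elements carrying the
#'   four core transversion mutations).
#' @return Data frame with one row per element: `element_seq` (29 bases in
#'   motif orientation), `start` (0-based forward-strand offset), `end`,
#'   `orientation` (strand of the motif in the enhancer), `core_mismatches`.
#' @export
find_elements <- function(enhancer_seq, core = catac_core(),
                          max_core_mismatch = 2) {
  seq <- toupper(as.character(enhancer_seq)[1])
  W <- 29L
  if (nchar(seq) < W) stop("enhancer shorter than 29 bp", call. = FALSE)
  len <- nchar(seq)
  cand <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (i in seq_len(nchar(s) - W + 1)) {
      w <- substr(s, i, i + W - 1)
      if (grepl("[^ACGT]", w)) next
      mm <- iupac_mismatches(core$iupac, pattern_region(w, core))
      if (mm <= max_core_mismatch) {
        fwd_start <- if (strand == "+") i - 1L else len - (i - 1L) - W
        cand[[length(cand) + 1]] <- data.frame(
          element_seq = w, start = fwd_start, end = fwd_start + W,
          orientation = strand, core_mismatches = mm)
      }
    }
  }
  if (!length(cand)) {
    return(data.frame(element_seq = character(0), start = integer(0),
                      end = integer(0), orientation = character(0),
                      core_mismatches = integer(0)))
  }
  cand <- do.call(rbind, cand)
  ord <- order(cand$core_mismatches, cand$start, cand$orientation)
  cand <- cand[ord, , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(cand))) {
    over <- any(cand$start[i] < cand$end[kept] & cand$start[kept] < cand$end[i])
    if (!over) kept <- c(kept, i)
  }
  out <- cand[kept, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score a four-element CATAC construct
#'
#' Tallies, over the four 29-base elements, matches of the core region
#' (residues 8-17, 40 residues total) against the core consensus and of the
#' E-box region (residues 19-24, 24 residues total) against the CATAC E-box
#' consensus `CRCGTG` and the canonical E-box `CACGTG`. The "core" and
#' "E-box" scores are the matching fractions.
#'
#' @param elements Character vector of exactly four 29-base element
#'   sequences in motif orientation, or a data frame from
#'   [find_elements()].
#' @return One-row data frame with `core_matches` (of 40), `ebox_matches`
#'   (of 24, vs `CRCGTG`), `core_score`, `ebox_score`,
#'   `canonical_mismatches` and `catac_ebox_mismatches` (both of 24).
#' @export
score_construct <- function(elements) {
  if (is.data.frame(elements)) elements <- elements$element_seq
  elements <- toupper(as.character(elements))
  if (length(elements) != 4) stop("a construct has exactly 4 elements", call. = FALSE)
  if (any(nchar(elements) != 29)) stop("elements must be 29 bases", call. = FALSE)
  core <- catac_core(); ebox <- catac_ebox(); can <- canonical_ebox()
  core_mm <- sum(iupac_mismatches(core$iupac, pattern_region(elements, core)))
  ebox_mm <- sum(iupac_mismatches(ebox$iupac, pattern_region(elements, ebox)))
  can_mm <- sum(iupac_mismatches(can$iupac, pattern_region(elements, can)))
  n_core <- 4L * nchar(core$iupac)
  n_ebox <- 4L * nchar(ebox$iupac)
  data.frame(core_matches = n_core - core_mm, ebox_matches = n_ebox - ebox_mm,
             core_score = (n_core - core_mm) / n_core,
             ebox_score = (n_ebox - ebox_mm) / n_ebox,
             canonical_mismatches = can_mm, catac_ebox_mismatches = ebox_mm)
}

#' Apply the CATAC transversion mutation operator
#'
#' Swaps A<->T and C<->G at the given 1-based motif residues, leaving all
#' other residues unchanged. The default positions are the six residues
#' mutated in the mt4xCATAC constructs: 8, 10, 14 and 16 in the core and 21
#' and 23 in the E-box region. The operator is an involution: applying it
#' twice restores the input.
#'
#' @param element A 29-base element sequence (motif orientation).
#' @param positions Integer vector of 1-based residues to mutate.
#' @return The mutated element sequence.
#' @export
#' @examples
#' apply_transversions("AGCACATTACGCATACGTCACGTGTTGCA")
apply_transversions <- function(element, positions = c(8, 10, 14, 16, 21, 23)) {
  element <- toupper(as.character(element)[1])
  positions <- as.integer(positions)
  if (any(positions < 1 | positions > nchar(element))) {
    stop("positions out of range", call. = FALSE)
  }
  chars <- strsplit(element, "", fixed = TRUE)[[1]]
  swap <- c(A = "T", T = "A", C = "G", G = "C")
  chars[positions] <- swap[chars[positions]]
  if (anyNA(chars)) stop("element contains non-A/C/G/T characters", call. = FALSE)
  paste(chars, collapse = "")
}

#' Assemble a double-stranded enhancer from ordered oligonucleotides
#'
#' Reconstructs the top strand of an enhancer from the oligos of its
#' annealed duplexes, in printed order. Each subsequent oligo is joined by
#' the maximal exact suffix-prefix overlap between the current assembly and
#' the oligo or its reverse complement (whichever overlaps more), mirroring
#' sticky-end duplex assembly. Two oligos that are exact reverse
#' complements collapse onto a single strand.
#'
#' @param oligos Character vector of at least two oligo sequences, 5'->3',
#'   in their annealing order.
#' @param min_overlap Minimum acceptable complementary overlap in bp
#'   (default 10); assembly fails with an error below this.
#' @return The assembled top strand, with attribute `overlaps` recording
#'   the overlap length used at each junction.
#' @export
assemble_enhancer <- function(oligos, min_overlap = 10) {
  oligos <- toupper(as.character(oligos))
  if (length(oligos) < 2) stop("need at least 2 oligos", call. = FALSE)
  cur <- oligos[1]
  overlaps <- integer(0)
  for (o in oligos[-1]) {
    cand <- c(o, revcomp(o))
    ks <- vapply(cand, function(b) max_exact_overlap(cur, b, min_overlap),
                 integer(1), USE.NAMES = FALSE)
    i <- which.max(ks)
    if (ks[i] < min_overlap) {
      stop(sprintf("no complementary overlap >= %d bp with oligo %s...",
                   min_overlap, substr(o, 1, 12)), call. = FALSE)
    }
    cur <- paste0(cur, substr(cand[i], ks[i] + 1, nchar(cand[i])))
    overlaps <- c(overlaps, ks[i])
  }
  attr(cur, "overlaps") <- overlaps
  cur
}

# Longest k >= minov with suffix(a, k) == prefix(b, k); 0 if none.
max_exact_overlap <- function(a, b, minov) {
  if (min(nchar(a), nchar(b)) < minov) return(0L)
  for (k in seq(min(nchar(a), nchar(b)), minov)) {
    if (substr(a, nchar(a) - k + 1, nchar(a)) == substr(b, 1, k)) return(k)
  }
  0L
}

#' Packaged 4xCATAC construct oligonucleotide sets
#'
#' Returns the synthetic oligo sequences of the five multimerized CATAC
#' reporter enhancers (wild-type and mutant Slob and Pdp1 4xCATAC, and the
#' Pdp1-with-Slob-like-E-boxes variant, "PSE"), as designed against the
#' native promoter occurrences. Each element of the returned list is a
#' character vector of four oligos in annealing order.
#'
#' @return Named list of character vectors.
#' @export
catac_constructs <- function() {
  path <- system.file("extdata", "catac_oligos.fa", package = "catac")
  seqs <- as.character(Biostrings::readDNAStringSet(path))
  construct <- sub("\\|[0-9]+$", "", names(seqs))
  idx <- as.integer(sub("^.*\\|", "", names(seqs)))
  out <- lapply(split(seq_along(seqs), construct), function(i) {
    unname(seqs[i][order(idx[i])])
  })
  out[c("slob_4x", "slob_mt4x", "pdp1_4x", "pdp1_mt4x", "pdp1_pse")]
}

#' Elements of the wild-type 4xCATAC enhancers
#'
#' Assembles the named construct's oligos ([assemble_enhancer()]) and
#' extracts its CATAC elements ([find_elements()]).
#'
#' @param construct One of `"slob_4x"`, `"pdp1_4x"`, `"pdp1_pse"` (the
#'   mutant constructs carry four core transversions per element and yield
#'   no elements at the default mismatch cutoff).
#' @param ... Passed to [find_elements()].
#' @return Data frame of elements as from [find_elements()].
#' @export
catac_elements <- function(construct = c("slob_4x", "pdp1_4x", "pdp1_pse",
                                         "slob_mt4x", "pdp1_mt4x"), ...) {
  construct <- match.arg(construct)
  oligos <- catac_constructs()[[construct]]
  find_elements(assemble_enhancer(oligos), ...)
}

#' CATAC position weight matrix from the printed construct elements
#'
#' Builds a width-29 motif matrix from the eight wild-type elements of the
#' Slob and Pdp1 4xCATAC enhancers. This is the packaged stand-in for a
#' matrix trained on genome-wide aligned sites; it reproduces the element's
#' conserved core and E-box-like structure.
#'
#' @param pseudocount Passed to [build_motif_matrix()] (default 0.5).
#' @return A `motif_matrix` named "CATAC".
#' @export
catac_matrix <- function(pseudocount = 0.5) {
  sites <- c(catac_elements("slob_4x")$element_seq,
             catac_elements("pdp1_4x")$element_seq)
  build_motif_matrix(sites, pseudocount = pseudocount, name = "CATAC")
}
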