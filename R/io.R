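#' Read and write long-format trace tables
#'
#' Traces are exchanged as tidy CSV with columns `fly_id`, `time_h`,
#' `counts`, `regime` (LD/DD) and optionally `genotype`.
#'
#' @param path File path.
#' @param traces Data frame to write.
#' @return `read_traces` returns the data frame; `write_traces` returns
#'   `path` invisibly.
#' @export
read_traces <- function(path) {
  tr <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("fly_id", "time_h", "counts", "regime")
  if (!all(need %in% names(tr))) {
    stop(sprintf("%s: trace CSV needs columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  tr
}

#' @rdname read_traces
#' @export
write_traces <- function(traces, path) {
  write.csv(traces, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write Ct tables
#'
#' Ct tables are CSV with columns `gene`, `timepoint`, `replicate`, `ct`.
#'
#' @param path File path.
#' @param ct Data frame to write.
#' @return `read_ct_table` returns the data frame; `write_ct_table`
#'   returns `path` invisibly.
#' @export
read_ct_table <- function(path) {
  ct <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "timepoint", "replicate", "ct")
  if (!all(need %in% names(ct))) {
    stop(sprintf("%s: Ct CSV needs columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  ct
}

#' @rdname read_ct_table
#' @export
write_ct_table <- function(ct, path) {
  write.csv(ct, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write motif hits as BED6
#'
#' Coordinates are 0-based half-open on the forward strand; the BED score
#' column is the bit score times 100, rounded (BED integer-score
#' convention).
#'
#' @param hits Hit data frame from [scan_motif()].
#' @param path Output file.
#' @param name Feature name prefix (default the motif-hit index).
#' @return `path`, invisibly.
#' @export
write_bed_hits <- function(hits, path, name = "catac") {
  gr <- GenomicRanges::GRanges(
    seqnames = hits$seq_id,
    ranges = IRanges::IRanges(start = hits$start + 1L, end = hits$end),
    strand = hits$strand)
  gr$name <- sprintf("%s_%d", name, seq_len(nrow(hits)))
  gr$score <- as.integer(round(hits$score_bits * 100))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED6 file of motif hits
#'
#' @param path BED file written by [write_bed_hits()] (or any BED6 file).
#' @return Data frame with `seq_id`, `start`, `end`, `strand`,
#'   `score_bits` (BED score / 100) and `name`.
#' @export
read_bed_hits <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(seq_id = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             score_bits = if (!is.null(gr$score)) gr$score / 100 else NA_real_,
             name = if (!is.null(gr$name)) gr$name else NA_character_)
}

#' Serialize a motif matrix in MEME minimal motif format
#'
#' Writes (and reads back) the plain-text MEME minimal format: alphabet,
#' background letter frequencies, and the letter-probability matrix with
#' one row per motif position.
#'
#' @param matrix A `motif_matrix`.
#' @param path File path.
#' @return `write_meme_motif` returns `path` invisibly; `read_meme_motif`
#'   returns a `motif_matrix`.
#' @export
write_meme_motif <- function(matrix, path) {
  stopifnot(inherits(matrix, "motif_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  nsites <- if (is.na(matrix$nsites)) 20L else matrix$nsites
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    paste(sprintf("%s %.6f", DNA_BASES, matrix$background), collapse = " "),
    "",
    sprintf("MOTIF %s", matrix$name),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
            motif_width(matrix), nsites)), con)
  writeLines(apply(matrix$probs, 2, function(p)
    paste(sprintf("%.6f", p), collapse = "  ")), con)
  invisible(path)
}

#' @rdname write_meme_motif
#' @export
read_meme_motif <- function(path) {
  lines <- readLines(path)
  bg_i <- grep("^Background letter frequencies", lines)
  background <- setNames(rep(0.25, 4), DNA_BASES)
  if (length(bg_i)) {
    tok <- strsplit(trimws(lines[bg_i[1] + 1]), "\\s+")[[1]]
    background <- setNames(as.numeric(tok[c(2, 4, 6, 8)]), tok[c(1, 3, 5, 7)])[DNA_BASES]
    background <- background / sum(background)
  }
  m_i <- grep("^MOTIF ", lines)
  if (!length(m_i)) stop("no MOTIF record in ", path, call. = FALSE)
  name <- strsplit(lines[m_i[1]], "\\s+")[[1]][2]
  lp_i <- grep("^letter-probability matrix", lines)
  w <- as.integer(sub(".* w= *([0-9]+).*", "\\1", lines[lp_i[1]]))
  nsites <- suppressWarnings(
    as.integer(sub(".* nsites= *([0-9]+).*", "\\1", lines[lp_i[1]])))
  rows <- lines[(lp_i[1] + 1):(lp_i[1] + w)]
  probs <- t(vapply(rows, function(r)
    as.numeric(strsplit(trimws(r), "\\s+")[[1]]), numeric(4),
    USE.NAMES = FALSE))
  probs <- sweep(probs, 1, rowSums(probs), "/")   # renormalize rounding
  dimnames(probs) <- NULL
  motif_matrix(t(probs), background = background, name = name,
               nsites = nsites)
}

#' Write Figure-1B-style construct scores as CSV
#'
#' @param scores Named list or data frame of [score_construct()] rows, one
#'   per construct.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_construct_scores <- function(scores, path) {
  if (is.list(scores) && !is.data.frame(scores)) {
    scores <- do.call(rbind, Map(function(nm, s) cbind(construct = nm, s),
                                 names(scores), scores))
  }
  write.csv(scores, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
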