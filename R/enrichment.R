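#' Promoter windows around transcription start sites
#'
#' Builds fixed-width promoter windows (default 2.5 kb) centered on TSS
#' coordinates, clipped at contig ends and flagged when clipping occurs.
#'
#' @param tss Data frame with columns `gene_id`, `chrom`, `pos` (0-based TSS
#'   coordinate) and optionally `strand`.
#' @param window_bp Total window width in bp (default 2500).
#' @param chrom_sizes Optional named vector of contig lengths used for
#'   clipping.
#' @return Data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `clipped`.
#' @export
promoter_windows <- function(tss, window_bp = 2500, chrom_sizes = NULL) {
  stopifnot(all(c("gene_id", "chrom", "pos") %in% names(tss)))
  half <- window_bp / 2
  start <- floor(tss$pos - half)
  end <- floor(tss$pos + half)
  clipped <- start < 0
  start <- pmax(start, 0)
  if (!is.null(chrom_sizes)) {
    lim <- unname(chrom_sizes[as.character(tss$chrom)])
    clipped <- clipped | end > lim
    end <- pmin(end, lim)
  }
  data.frame(gene_id = tss$gene_id, chrom = tss$chrom,
             start = as.integer(start), end = as.integer(end),
             strand = if ("strand" %in% names(tss)) tss$strand else "+",
             clipped = clipped)
}

#' Hypergeometric enrichment of motif hits in a gene set
#'
#' A gene counts as hit when at least one motif hit overlaps its promoter
#' window by >= 1 bp. The p-value is the one-sided hypergeometric tail:
#' the probability of observing at least `set_hits` hit genes when drawing
#' `set_size` genes from a background of `background_size` genes of which
#' `background_hits` are hit. Fold enrichment is the ratio of hit fractions.
#'
#' @param hits Data frame of motif hits as returned by [scan_motif()]
#'   (`seq_id` is matched against window `chrom`).
#' @param windows Data frame of promoter windows as returned by
#'   [promoter_windows()] (columns `gene_id`, `chrom`, `start`, `end`).
#' @param gene_set Character vector of gene ids, a subset of the window
#'   gene ids.
#' @return A one-row data frame with `set_size`, `set_hits`,
#'   `background_size`, `background_hits`, `fold`, `p_value`. When no
#'   background gene is hit but set genes are (impossible when the set is
#'   drawn from the background), `fold` is `Inf`.
#' @export
promoter_enrichment <- function(hits, windows, gene_set) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(windows)))
  gene_set <- unique(as.character(gene_set))
  if (length(gene_set) == 0) stop("empty gene set", call. = FALSE)
  if (!all(gene_set %in% windows$gene_id)) {
    stop("gene_set contains ids without promoter windows", call. = FALSE)
  }
  hit_genes <- genes_with_hit(hits, windows)
  bg_genes <- unique(windows$gene_id)
  background_size <- length(bg_genes)
  background_hits <- length(hit_genes)
  set_size <- length(gene_set)
  set_hits <- sum(gene_set %in% hit_genes)
  p <- phyper(set_hits - 1, background_hits, background_size - background_hits,
              set_size, lower.tail = FALSE)
  bg_frac <- background_hits / background_size
  fold <- if (bg_frac == 0) {
    if (set_hits > 0) Inf else NaN
  } else {
    (set_hits / set_size) / bg_frac
  }
  data.frame(set_size = set_size, set_hits = set_hits,
             background_size = background_size,
             background_hits = background_hits,
             fold = fold, p_value = p)
}

# Gene ids whose promoter window overlaps >= 1 motif hit by >= 1 bp.
genes_with_hit <- function(hits, windows) {
  if (is.null(hits) || nrow(hits) == 0) return(character(0))
  hit_gr <- GenomicRanges::GRanges(
    seqnames = hits$seq_id,
    ranges = IRanges::IRanges(start = hits$start + 1L, end = hits$end))
  win_gr <- GenomicRanges::GRanges(
    seqnames = windows$chrom,
    ranges = IRanges::IRanges(start = windows$start + 1L, end = windows$end))
  ov <- GenomicRanges::findOverlaps(win_gr, hit_gr, minoverlap = 1L)
  unique(as.character(windows$gene_id[S4Vectors::queryHits(ov)]))
}
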