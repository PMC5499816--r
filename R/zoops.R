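#' ZOOPS posterior placement probabilities
#'
#' Under the zero-or-one-occurrence-per-sequence (ZOOPS) model a sequence
#' either contains no motif occurrence (prior probability `1 - gamma`) or
#' exactly one occurrence (prior `gamma`) at a position drawn uniformly from
#' the valid forward-strand placements. Bases outside the occurrence, and
#' the whole sequence in the no-occurrence case, follow the background
#' model. This function performs the E-step: for each sequence it returns
#' the posterior probability of "no occurrence" and of each placement.
#'
#' @param matrix A `motif_matrix` (current motif estimate).
#' @param sequences Character vector or `DNAStringSet`; sequences shorter
#'   than the motif width are assigned no-occurrence probability 1.
#' @param gamma Prior probability that a sequence contains an occurrence.
#' @return A list with one element per sequence, each a list with `z0`
#'   (posterior no-occurrence probability) and `z` (numeric vector of
#'   placement posteriors, 0-based start offsets as names), plus an
#'   attribute `loglik`, the total data log-likelihood.
#' @export
zoops_posterior <- function(matrix, sequences, gamma = 0.5) {
  stopifnot(inherits(matrix, "motif_matrix"), gamma > 0, gamma < 1)
  seqs <- as_dna_character(sequences)
  assert_acgt(seqs, "sequence")
  w <- motif_width(matrix)
  lo <- log(matrix$probs / matrix$background)   # natural log for likelihoods
  logbg <- log(matrix$background)
  total_ll <- 0
  out <- lapply(seqs, function(s) {
    codes <- dna_to_int(s)
    bg_ll <- sum(logbg[codes])
    m <- length(codes) - w + 1
    if (m < 1) {
      total_ll <<- total_ll + bg_ll
      return(list(z0 = 1, z = numeric(0)))
    }
    # log likelihood-ratio of each placement relative to all-background
    llr <- score_windows(lo, codes)
    # posterior over {none} U placements
    lw <- c(log(1 - gamma), log(gamma) - log(m) + llr)
    mx <- max(lw)
    p <- exp(lw - mx)
    p <- p / sum(p)
    total_ll <<- total_ll + bg_ll + mx + log(sum(exp(lw - mx)))
    list(z0 = p[1], z = setNames(p[-1], 0:(m - 1)))
  })
  attr(out, "loglik") <- total_ll
  out
}

#' Refine a motif matrix by ZOOPS expectation maximization
#'
#' Starting from a seed matrix, alternates the ZOOPS E-step
#' ([zoops_posterior()]) with an M-step that re-estimates the per-position
#' probabilities from posterior-weighted base counts (with the same
#' pseudocount smoothing as [build_motif_matrix()]) and the occurrence
#' prior `gamma` from the mean posterior occurrence probability. The data
#' log-likelihood is non-decreasing across iterations; iteration stops when
#' its increase falls below `tol` or after `max_iter` iterations (the last
#' iterate is returned with `converged = FALSE` in that case).
#'
#' @param seed A `motif_matrix` to start from.
#' @param sequences Character vector or `DNAStringSet` of training
#'   sequences; at least one must be at least as long as the motif.
#' @param max_iter Maximum EM iterations (default 100).
#' @param tol Stop when the log-likelihood improves by less than this
#'   (default 1e-6).
#' @param gamma Initial occurrence prior (default 0.5).
#' @param pseudocount Pseudocount weight for the M-step (default: the
#'   seed's, or 0.5 if unrecorded).
#' @return A `motif_matrix` with attributes `iterations`, `converged`,
#'   `loglik` (trajectory) and `gamma` (final occurrence prior).
#' @export
refine_motif_matrix <- function(seed, sequences, max_iter = 100, tol = 1e-6,
                                gamma = 0.5, pseudocount = NULL) {
  stopifnot(inherits(seed, "motif_matrix"))
  seqs <- as_dna_character(sequences)
  w <- motif_width(seed)
  if (!any(nchar(seqs) >= w)) {
    stop("no sequence is at least as long as the motif", call. = FALSE)
  }
  if (is.null(pseudocount)) {
    pseudocount <- if (is.na(seed$pseudocount)) 0.5 else seed$pseudocount
  }
  if (pseudocount <= 0) {
    stop("refinement requires a positive pseudocount (keeps log-odds finite)",
         call. = FALSE)
  }
  bg <- seed$background
  cur <- seed
  ll_trace <- numeric(0)
  converged <- FALSE
  codes_list <- lapply(seqs, dna_to_int)
  for (it in seq_len(max_iter)) {
    post <- zoops_posterior(cur, seqs, gamma = gamma)
    ll <- attr(post, "loglik")
    if (length(ll_trace) && ll - ll_trace[length(ll_trace)] < tol) {
      ll_trace <- c(ll_trace, ll)
      converged <- TRUE
      break
    }
    ll_trace <- c(ll_trace, ll)
    # M-step: posterior-weighted counts
    counts <- matrix(0, nrow = 4, ncol = w, dimnames = list(DNA_BASES, NULL))
    occ <- 0
    for (i in seq_along(seqs)) {
      z <- post[[i]]$z
      if (!length(z)) next
      occ <- occ + (1 - post[[i]]$z0)
      codes <- codes_list[[i]]
      for (j in seq_along(z)) {
        if (z[j] < 1e-12) next
        idx <- codes[j:(j + w - 1)]
        counts[cbind(idx, seq_len(w))] <- counts[cbind(idx, seq_len(w))] + z[j]
      }
    }
    n_eff <- sum(counts[, 1])
    probs <- sweep(counts + pseudocount * bg, 2, n_eff + pseudocount, "/")
    cur <- motif_matrix(probs, background = bg, name = seed$name,
                        pseudocount = pseudocount, nsites = seed$nsites)
    gamma <- min(max(occ / length(seqs), 1e-6), 1 - 1e-6)
  }
  if (!converged) {
    warning("EM did not converge within max_iter; returning last iterate")
  }
  attr(cur, "iterations") <- length(ll_trace)
  attr(cur, "converged") <- converged
  attr(cur, "loglik") <- ll_trace
  attr(cur, "gamma") <- gamma
  cur
}
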