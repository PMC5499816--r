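# Shared fixtures built in code.

# A realized CATAC consensus element: core TACGCATACG (residues 8-17) and a
# canonical E-box CACGTG (residues 19-24); flanks taken from the first
# wild-type Pdp1 element so that all 29 residues are defined.
consensus_element <- function() {
  paste0("AGCACAT", "TACGCATACG", "T", "CACGTG", "TTGCA")
}

# Deterministic toy matrix: probability 1 on each base of `consensus`.
deterministic_matrix <- function(consensus, background = NULL) {
  bases <- strsplit(consensus, "")[[1]]
  probs <- vapply(bases, function(b) as.numeric(c("A", "C", "G", "T") == b),
                  numeric(4))
  rownames(probs) <- c("A", "C", "G", "T")
  motif_matrix(probs, background = background, name = "toy")
}

# All DNA k-mers (for exhaustive-enumeration oracles; keep k small).
all_kmers <- function(k) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                              stringsAsFactors = FALSE))
}

# Random A/C/G/T string.
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# Single synthetic cosine trace on a uniform hourly grid (no simulator),
# for rhythm-analysis unit tests that should not depend on simulate_traces.
cosine_trace <- function(duration_h = 96, dt = 1, period = 24, amp = 50,
                         phase = 0, baseline = 0, noise_sd = 0) {
  t <- seq(0, duration_h, by = dt)
  y <- baseline + amp * cos(2 * pi * (t - phase) / period) +
    rnorm(length(t), 0, noise_sd)
  data.frame(time_h = t, counts = y, regime = "DD")
}

# Brute-force ZOOPS posterior: explicit per-base probability products over
# every placement, independent of the package's vectorized log-space code.
brute_posterior <- function(matrix, seqs, gamma) {
  bases <- c("A", "C", "G", "T")
  lapply(seqs, function(s) {
    x <- strsplit(s, "")[[1]]
    w <- ncol(matrix$probs)
    m <- length(x) - w + 1
    p_bg <- prod(matrix$background[x])
    p_place <- vapply(seq_len(m), function(j) {
      p <- 1
      for (i in seq_along(x)) {
        p <- p * if (i >= j && i < j + w) matrix$probs[x[i], i - j + 1]
                 else matrix$background[x[i]]
      }
      p
    }, numeric(1))
    un <- c((1 - gamma) * p_bg, gamma / m * p_place)
    post <- un / sum(un)
    list(z0 = post[1], z = post[-1])
  })
}

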