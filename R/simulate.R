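#' Specification for synthetic bioluminescence traces
#'
#' Describes a cohort of simulated single-fly luciferase traces emulating a
#' TopCount-style assay: an exponentially settling baseline (fresh-luciferin
#' excess decaying with time constant `settle_tau`), a circadian cosine, a
#' 12-h ultradian component modelled as the second harmonic phase-locked to
#' the circadian component, and Gaussian noise, sampled roughly hourly on a
#' jittered grid. Recording starts in the light phase; samples before
#' `ld_head_h` hours are labelled LD, the remainder DD.
#'
#' @param n_flies Number of flies.
#' @param duration_h Recording length in hours (> 48).
#' @param sampling_interval_h Mean sampling interval in hours.
#' @param jitter_frac Uniform sampling jitter as a fraction of the interval
#'   (default 0.2, i.e. +/-20%).
#' @param period_24 Circadian period in hours (default 24).
#' @param amp_24 Circadian amplitude in counts.
#' @param phase_24 Circadian peak phase in hours.
#' @param amp_12 Amplitude of the 12-h second-harmonic component in counts.
#' @param baseline Initial baseline level in counts.
#' @param settle_tau Time constant (hours) of the exponential settling of
#'   the baseline; `Inf` keeps the baseline constant.
#' @param noise_sd Gaussian noise standard deviation in counts.
#' @param ld_head_h Hours of LD at the start of the recording (default 12).
#' @param seed Integer seed; identical specs give identical output.
#' @return A `trace_sim_spec` list.
#' @export
trace_sim_spec <- function(n_flies = 20, duration_h = 120,
                           sampling_interval_h = 1, jitter_frac = 0.2,
                           period_24 = 24, amp_24 = 50, phase_24 = 2,
                           amp_12 = 10, baseline = 600, settle_tau = 96,
                           noise_sd = 10, ld_head_h = 12, seed = 1) {
  spec <- list(n_flies = n_flies, duration_h = duration_h,
               sampling_interval_h = sampling_interval_h,
               jitter_frac = jitter_frac, period_24 = period_24,
               amp_24 = amp_24, phase_24 = phase_24, amp_12 = amp_12,
               baseline = baseline, settle_tau = settle_tau,
               noise_sd = noise_sd, ld_head_h = ld_head_h,
               seed = as.integer(seed))
  num <- unlist(spec[setdiff(names(spec), "settle_tau")])
  if (any(!is.finite(num))) stop("non-finite trace parameters", call. = FALSE)
  if (is.na(spec$settle_tau) || spec$settle_tau <= 0) {
    stop("settle_tau must be positive (possibly Inf)", call. = FALSE)
  }
  if (spec$duration_h <= 48) stop("duration_h must exceed 48", call. = FALSE)
  if (spec$sampling_interval_h <= 0) stop("sampling_interval_h must be positive", call. = FALSE)
  if (spec$amp_24 < 0 || spec$amp_12 < 0 || spec$noise_sd < 0) {
    stop("amplitudes and noise_sd must be non-negative", call. = FALSE)
  }
  if (spec$n_flies < 1) stop("need at least one fly", call. = FALSE)
  structure(spec, class = "trace_sim_spec")
}

#' Simulate single-fly luminescence traces
#'
#' Each fly's expected signal at time `t` (hours) is
#' `baseline * exp(-t / settle_tau) + amp_24 * cos(2*pi*(t - phase_24) /
#' period_24) + amp_12 * cos(4*pi*(t - phase_24) / period_24)`, with
#' independent Gaussian noise per sample; counts are floored at zero.
#' Sampling times are an hourly-ish grid with uniform jitter.
#'
#' @param spec A [trace_sim_spec()].
#' @return A list with `traces` (long data frame: `fly_id`, `time_h`,
#'   `counts`, `regime`) and `truth` (the spec, as the generating ground
#'   truth).
#' @export
simulate_traces <- function(spec) {
  stopifnot(inherits(spec, "trace_sim_spec"))
  withr_seed(spec$seed, {
    dt <- spec$sampling_interval_h
    n_t <- floor(spec$duration_h / dt) + 1
    traces <- lapply(seq_len(spec$n_flies), function(f) {
      t <- (seq_len(n_t) - 1) * dt +
        runif(n_t, -spec$jitter_frac * dt, spec$jitter_frac * dt)
      t <- sort(pmax(t, 0))
      mu <- spec$baseline * exp(-t / spec$settle_tau) +
        spec$amp_24 * cos(2 * pi * (t - spec$phase_24) / spec$period_24) +
        spec$amp_12 * cos(4 * pi * (t - spec$phase_24) / spec$period_24)
      y <- pmax(mu + rnorm(n_t, 0, spec$noise_sd), 0)
      data.frame(fly_id = sprintf("fly%03d", f), time_h = t, counts = y,
                 regime = ifelse(t < spec$ld_head_h, "LD", "DD"))
    })
    list(traces = do.call(rbind, traces), truth = unclass(spec))
  })
}

# Evaluate expr under a local RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification for synthetic promoter sequences with planted motifs
#'
#' @param n_seqs Number of sequences.
#' @param seq_length_bp Length of each sequence.
#' @param gc_fraction Background GC fraction (strictly between 0 and 1).
#' @param motif A `motif_matrix` whose distribution planted instances are
#'   drawn from.
#' @param inserts_per_seq Planted instances per sequence.
#' @param seed Integer seed.
#' @return A `promoter_sim_spec` list.
#' @export
promoter_sim_spec <- function(n_seqs = 100, seq_length_bp = 1000,
                              gc_fraction = 0.43, motif = catac_matrix(),
                              inserts_per_seq = 1, seed = 1) {
  stopifnot(inherits(motif, "motif_matrix"))
  if (gc_fraction <= 0 || gc_fraction >= 1) {
    stop("gc_fraction must be in (0, 1)", call. = FALSE)
  }
  if (seq_length_bp < motif_width(motif) * inserts_per_seq) {
    stop("sequences too short for the requested inserts", call. = FALSE)
  }
  structure(list(n_seqs = n_seqs, seq_length_bp = seq_length_bp,
                 gc_fraction = gc_fraction, motif = motif,
                 inserts_per_seq = inserts_per_seq, seed = as.integer(seed)),
            class = "promoter_sim_spec")
}

#' Simulate promoter sequences with planted motif instances
#'
#' Background bases are i.i.d. with the given GC fraction; each planted
#' instance is drawn position-wise from the motif's probability matrix,
#' placed uniformly at random without overlapping other instances, on a
#' random strand. The returned `sites` table records the true coordinates
#' (BED-style 0-based half-open) and strands.
#'
#' @param spec A [promoter_sim_spec()].
#' @return List with `sequences` (named character vector) and `sites`
#'   (data frame: `seq_id`, `start`, `end`, `name`, `score_bits`, `strand`,
#'   `planted_seq`).
#' @export
simulate_promoters <- function(spec) {
  stopifnot(inherits(spec, "promoter_sim_spec"))
  motif <- spec$motif
  w <- motif_width(motif)
  base_p <- c(A = (1 - spec$gc_fraction) / 2, C = spec$gc_fraction / 2,
              G = spec$gc_fraction / 2, T = (1 - spec$gc_fraction) / 2)
  withr_seed(spec$seed, {
    seqs <- character(spec$n_seqs)
    sites <- list()
    for (i in seq_len(spec$n_seqs)) {
      chars <- sample(DNA_BASES, spec$seq_length_bp, replace = TRUE, prob = base_p)
      starts <- integer(0)
      for (k in seq_len(spec$inserts_per_seq)) {
        placed <- FALSE
        for (try in seq_len(1000)) {
          s0 <- sample.int(spec$seq_length_bp - w + 1, 1) - 1L  # 0-based
          if (!any(s0 < starts + w & starts < s0 + w)) {
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop("could not place inserts without overlap; sequences too dense",
               call. = FALSE)
        }
        inst <- vapply(seq_len(w), function(j) {
          sample(DNA_BASES, 1, prob = motif$probs[, j])
        }, character(1))
        strand <- sample(c("+", "-"), 1)
        inst_seq <- paste(inst, collapse = "")
        genomic <- if (strand == "+") inst else strsplit(revcomp(inst_seq), "")[[1]]
        chars[(s0 + 1):(s0 + w)] <- genomic
        starts <- c(starts, s0)
        sites[[length(sites) + 1]] <- data.frame(
          seq_id = sprintf("promoter%03d", i), start = s0, end = s0 + w,
          name = sprintf("planted_%03d_%d", i, k),
          score_bits = motif_bit_score(motif, inst_seq), strand = strand,
          planted_seq = inst_seq)
      }
      seqs[i] <- paste(chars, collapse = "")
    }
    names(seqs) <- sprintf("promoter%03d", seq_len(spec$n_seqs))
    sites <- if (length(sites)) do.call(rbind, sites) else
      data.frame(seq_id = character(0), start = integer(0), end = integer(0),
                 name = character(0), score_bits = numeric(0),
                 strand = character(0), planted_seq = character(0))
    list(sequences = seqs, sites = sites)
  })
}

#' Specification for synthetic qRT-PCR Ct tables
#'
#' Emulates a circadian time-course design: groups of flies harvested at
#' CT0, CT6, CT12, CT18 and CT24, a flat reference gene and a rhythmic
#' target whose Ct oscillates sinusoidally (lower Ct = higher expression,
#' so the Ct trough falls at `peak_ct_hour`).
#'
#' @param timepoints CT hours (default `c(0, 6, 12, 18, 24)`).
#' @param n_replicates Independent replicate groups per timepoint (>= 2).
#' @param reference_mean_ct Mean reference-gene Ct.
#' @param target_mean_ct Mean target-gene Ct.
#' @param rhythm_amplitude_ct Peak-to-mean Ct amplitude of the target.
#' @param peak_ct_hour CT hour of peak expression (Ct minimum).
#' @param replicate_sd Replicate noise SD in cycles.
#' @param target_gene,reference_gene Gene labels in the output table.
#' @param seed Integer seed.
#' @return A `ct_sim_spec` list.
#' @export
ct_sim_spec <- function(timepoints = c(0, 6, 12, 18, 24), n_replicates = 4,
                        reference_mean_ct = 18, target_mean_ct = 24,
                        rhythm_amplitude_ct = 1.5, peak_ct_hour = 6,
                        replicate_sd = 0.3, target_gene = "target",
                        reference_gene = "reference", seed = 1) {
  if (n_replicates < 2) stop("need >= 2 replicates", call. = FALSE)
  if (replicate_sd < 0) stop("replicate_sd must be >= 0", call. = FALSE)
  structure(list(timepoints = timepoints, n_replicates = n_replicates,
                 reference_mean_ct = reference_mean_ct,
                 target_mean_ct = target_mean_ct,
                 rhythm_amplitude_ct = rhythm_amplitude_ct,
                 peak_ct_hour = peak_ct_hour, replicate_sd = replicate_sd,
                 target_gene = target_gene, reference_gene = reference_gene,
                 seed = as.integer(seed)),
            class = "ct_sim_spec")
}

#' Simulate a comparative-Ct qRT-PCR table
#'
#' Target Ct at CT hour `t` is `target_mean_ct - rhythm_amplitude_ct *
#' cos(2*pi*(t - peak_ct_hour)/24)` plus replicate noise; the reference
#' gene is flat at `reference_mean_ct` plus noise.
#'
#' @param spec A [ct_sim_spec()].
#' @return List with `ct` (data frame: `gene`, `timepoint`, `replicate`,
#'   `ct`) and `truth` (the spec).
#' @export
simulate_ct_table <- function(spec) {
  stopifnot(inherits(spec, "ct_sim_spec"))
  withr_seed(spec$seed, {
    grid <- expand.grid(timepoint = spec$timepoints,
                        replicate = seq_len(spec$n_replicates))
    target_mu <- spec$target_mean_ct - spec$rhythm_amplitude_ct *
      cos(2 * pi * (grid$timepoint - spec$peak_ct_hour) / 24)
    tab <- rbind(
      data.frame(gene = spec$target_gene, grid,
                 ct = target_mu + rnorm(nrow(grid), 0, spec$replicate_sd)),
      data.frame(gene = spec$reference_gene, grid,
                 ct = spec$reference_mean_ct +
                   rnorm(nrow(grid), 0, spec$replicate_sd)))
    rownames(tab) <- NULL
    list(ct = tab, truth = unclass(spec))
  })
}
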