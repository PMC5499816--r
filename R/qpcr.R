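#' Relative expression by the comparative Ct method
#'
#' Computes `2^-(Ct_target - Ct_reference)` per replicate, pairing target
#' and reference measurements by `(timepoint, replicate)` — each replicate
#' index corresponds to one independent group of flies whose RNA was
#' assayed for both genes. Adding a constant to every Ct (target and
#' reference alike) leaves the result unchanged.
#'
#' @param target,reference Data frames with columns `timepoint`,
#'   `replicate`, `ct` (and optionally `gene`) for the target and reference
#'   genes; replicate structure must match exactly.
#' @return Data frame with `timepoint`, `replicate`, `rel_expr`.
#' @export
relative_expression <- function(target, reference) {
  need <- c("timepoint", "replicate", "ct")
  stopifnot(all(need %in% names(target)), all(need %in% names(reference)))
  key <- function(d) paste(d$timepoint, d$replicate, sep = "|")
  target <- target[order(target$timepoint, target$replicate), , drop = FALSE]
  reference <- reference[order(reference$timepoint, reference$replicate), , drop = FALSE]
  if (nrow(target) != nrow(reference) ||
      !all(key(target) == key(reference))) {
    stop("target and reference replicate structure does not match", call. = FALSE)
  }
  data.frame(timepoint = target$timepoint, replicate = target$replicate,
             rel_expr = 2^(-(target$ct - reference$ct)))
}

#' Normalize a relative-expression time course to its time-course average
#'
#' Divides all values by the mean of the per-timepoint means, so that the
#' normalized per-timepoint means average exactly 1. SEMs are scaled by the
#' same factor; the profile is invariant to global rescaling of the input.
#'
#' @param levels Data frame from [relative_expression()] (`timepoint`,
#'   `replicate`, `rel_expr`) with at least two timepoints.
#' @return List with `profile` (data frame: `timepoint`, `mean`, `sem`) and
#'   `replicates` (the input with a `norm_expr` column).
#' @export
normalize_profile <- function(levels) {
  stopifnot(all(c("timepoint", "replicate", "rel_expr") %in% names(levels)))
  tps <- sort(unique(levels$timepoint))
  if (length(tps) < 2) stop("need >= 2 timepoints", call. = FALSE)
  means <- vapply(tps, function(tp) mean(levels$rel_expr[levels$timepoint == tp]),
                  numeric(1))
  grand <- mean(means)
  if (grand <= 0) stop("non-positive grand mean", call. = FALSE)
  sems <- vapply(tps, function(tp) {
    x <- levels$rel_expr[levels$timepoint == tp]
    if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  }, numeric(1))
  reps <- levels
  reps$norm_expr <- levels$rel_expr / grand
  list(profile = data.frame(timepoint = tps, mean = means / grand,
                            sem = sems / grand),
       replicates = reps)
}

#' Kruskal-Wallis rhythm test and peak-phase call for one profile
#'
#' Tests for timed regulation across the circadian timepoints with the
#' Kruskal-Wallis rank test on replicate-level normalized expression
#' (standard tie correction), and calls the peak as the timepoint with the
#' highest mean (leftmost on ties). When every value is tied the statistic
#' is 0 and p = 1.
#'
#' @param normalized Output of [normalize_profile()], or a data frame with
#'   `timepoint` and `norm_expr` columns.
#' @return List with `statistic` (H), `p_value`, `df`, `peak` (CT hour).
#' @export
rhythm_test <- function(normalized) {
  reps <- if (is.list(normalized) && !is.data.frame(normalized))
    normalized$replicates else normalized
  stopifnot(all(c("timepoint", "norm_expr") %in% names(reps)))
  tps <- sort(unique(reps$timepoint))
  counts <- table(reps$timepoint)
  if (any(counts < 2)) stop("need >= 2 replicates per timepoint", call. = FALSE)
  means <- vapply(tps, function(tp) mean(reps$norm_expr[reps$timepoint == tp]),
                  numeric(1))
  peak <- tps[which.max(means)]
  if (length(unique(reps$norm_expr)) == 1) {
    return(list(statistic = 0, p_value = 1, df = length(tps) - 1, peak = peak))
  }
  kw <- kruskal.test(reps$norm_expr, factor(reps$timepoint))
  list(statistic = unname(kw$statistic), p_value = kw$p.value,
       df = unname(kw$parameter), peak = peak)
}

#' Full comparative-Ct time-course analysis for one or more target genes
#'
#' For each target gene: per-replicate relative expression against the
#' reference gene ([relative_expression()]), normalization to the
#' time-course average ([normalize_profile()]), and the Kruskal-Wallis
#' rhythm test with peak call ([rhythm_test()]).
#'
#' @param ct Long Ct table (`gene`, `timepoint`, `replicate`, `ct`).
#' @param targets Character vector of target gene names (default: every
#'   gene except the reference).
#' @param reference Reference gene name.
#' @return List with `profiles` (named list of normalized profiles) and
#'   `summary` (data frame: `gene`, `kw_p`, `peak`).
#' @export
qpcr_pipeline <- function(ct, targets = NULL, reference = "reference") {
  stopifnot(all(c("gene", "timepoint", "replicate", "ct") %in% names(ct)))
  if (!reference %in% ct$gene) stop("reference gene not in table", call. = FALSE)
  if (is.null(targets)) targets <- setdiff(unique(ct$gene), reference)
  ref <- ct[ct$gene == reference, , drop = FALSE]
  profiles <- lapply(targets, function(g) {
    lv <- relative_expression(ct[ct$gene == g, , drop = FALSE], ref)
    norm <- normalize_profile(lv)
    norm$test <- rhythm_test(norm)
    norm
  })
  names(profiles) <- targets
  summary <- data.frame(
    gene = targets,
    kw_p = vapply(profiles, function(p) p$test$p_value, numeric(1)),
    peak = vapply(profiles, function(p) p$test$peak, numeric(1)))
  rownames(summary) <- NULL
  list(profiles = profiles, summary = summary)
}
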