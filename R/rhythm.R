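#' Preprocess a luminescence trace for rhythm analysis
#'
#' Drops the initial transient (flies on fresh luciferin media carry excess
#' luciferase, so the first 24 h are excluded by default) and, optionally,
#' all samples not recorded in constant darkness. A trace retaining less
#' than 48 h of data is flagged fit-ineligible.
#'
#' @param trace Data frame for one fly with columns `time_h`, `counts` and
#'   (if `dd_only`) `regime` with values `"LD"`/`"DD"`.
#' @param exclude_initial_h Hours removed from the start (default 24).
#' @param dd_only Keep only DD samples (default TRUE).
#' @return The filtered data frame with attribute `fit_eligible` (TRUE when
#'   >= 48 h of data remain).
#' @export
preprocess_trace <- function(trace, exclude_initial_h = 24, dd_only = TRUE) {
  stopifnot(all(c("time_h", "counts") %in% names(trace)))
  if (is.unsorted(trace$time_h, strictly = TRUE)) {
    stop("trace times must be strictly increasing", call. = FALSE)
  }
  keep <- trace$time_h >= exclude_initial_h
  if (dd_only) {
    if (!"regime" %in% names(trace)) stop("dd_only requires a regime column", call. = FALSE)
    keep <- keep & trace$regime == "DD"
  }
  out <- trace[keep, , drop = FALSE]
  span <- if (nrow(out) > 1) diff(range(out$time_h)) else 0
  attr(out, "fit_eligible") <- span >= 48
  out
}

#' Detrend a trace by subtracting a centered running mean
#'
#' For each sample the mean of all samples within `window_h / 2` hours
#' (edge-truncated window) is subtracted. A 24-h window removes the slow
#' settling trend and any constant offset to first order while passing
#' circadian-period components nearly unattenuated (a centered full-period
#' mean of a cosine is approximately zero).
#'
#' Within half a window of either end the running mean is truncated and
#' asymmetric, which distorts both amplitude and phase there; `trim_edges`
#' drops those samples, which removes a small systematic period bias in
#' downstream cosine fits at the cost of `window_h` hours of data.
#'
#' @param trace Data frame with `time_h` and `counts`.
#' @param window_h Window width in hours (default 24).
#' @param trim_edges Drop samples within `window_h / 2` of either end after
#'   detrending (default FALSE; the fitting pipeline trims).
#' @return The data frame with detrended `counts` (and the removed trend in
#'   column `trend`).
#' @export
detrend_trace <- function(trace, window_h = 24, trim_edges = FALSE) {
  stopifnot(all(c("time_h", "counts") %in% names(trace)))
  t <- trace$time_h
  if (length(t) < 2 || diff(range(t)) < window_h) {
    stop("trace shorter than the detrending window", call. = FALSE)
  }
  half <- window_h / 2
  trend <- vapply(t, function(ti) {
    mean(trace$counts[abs(t - ti) <= half])
  }, numeric(1))
  out <- trace
  out$trend <- trend
  out$counts <- trace$counts - trend
  if (trim_edges) {
    out <- out[t >= min(t) + half & t <= max(t) - half, , drop = FALSE]
  }
  out
}

# Dominant periodogram period of (possibly irregular) samples: linear
# interpolation onto a uniform grid, FFT, max-power frequency. Returns the
# period in hours, plus the cosine/sine coefficients at that frequency as a
# seed for the least-squares refit.
dominant_period <- function(t, y) {
  dt <- median(diff(t))
  grid <- seq(min(t), max(t), by = dt)
  yg <- approx(t, y, xout = grid)$y
  yg <- yg - mean(yg)
  m <- length(yg)
  z <- fft(yg)
  k <- seq_len(floor((m - 1) / 2))
  periods <- m * dt / k
  ok <- periods <= diff(range(t)) & periods >= 2 * dt
  if (!any(ok)) return(NULL)
  k <- k[ok]
  power <- Mod(z[k + 1])^2
  kbest <- k[which.max(power)]
  zb <- z[kbest + 1]
  # y ~ b cos(2 pi t / T) + c sin(2 pi t / T)
  list(period = m * dt / kbest, b = 2 * Re(zb) / m, c = -2 * Im(zb) / m,
       n_freq = length(k), n_grid = m)
}

cosine_model <- function(par, t) {
  ncomp <- (length(par) - 1) / 3
  y <- rep(par[1], length(t))
  for (i in seq_len(ncomp)) {
    T <- par[1 + 3 * (i - 1) + 1]
    b <- par[1 + 3 * (i - 1) + 2]
    cc <- par[1 + 3 * (i - 1) + 3]
    w <- 2 * pi / T
    y <- y + b * cos(w * t) + cc * sin(w * t)
  }
  y
}

# Central-difference Jacobian of cosine_model at par.
cosine_jacobian <- function(par, t) {
  p <- length(par)
  J <- matrix(0, nrow = length(t), ncol = p)
  h <- pmax(abs(par) * 1e-6, 1e-8)
  for (j in seq_len(p)) {
    up <- par; up[j] <- up[j] + h[j]
    dn <- par; dn[j] <- dn[j] - h[j]
    J[, j] <- (cosine_model(up, t) - cosine_model(dn, t)) / (2 * h[j])
  }
  J
}

# Summarize fitted components: amplitude, phase, 95% CIs via the linearized
# covariance at the optimum.
component_table <- function(par, vc, df) {
  ncomp <- (length(par) - 1) / 3
  tcrit <- if (df > 0) qt(0.975, df) else Inf
  if (ncomp == 0) return(empty_component_table())
  out <- lapply(seq_len(ncomp), function(i) {
    j <- 1 + 3 * (i - 1)
    T <- par[j + 1]; b <- par[j + 2]; cc <- par[j + 3]
    amp <- sqrt(b^2 + cc^2)
    grad <- if (amp > 0) c(b, cc) / amp else c(1, 0)
    var_amp <- drop(t(grad) %*% vc[c(j + 2, j + 3), c(j + 2, j + 3)] %*% grad)
    se_amp <- sqrt(max(var_amp, 0))
    se_T <- sqrt(max(vc[j + 1, j + 1], 0))
    phase <- (atan2(cc, b) / (2 * pi)) * T
    phase <- phase %% T
    data.frame(period = T, amplitude = amp, phase = phase,
               amplitude_se = se_amp,
               amplitude_ci95_half_width = tcrit * se_amp,
               period_ci95_half_width = tcrit * se_T)
  })
  do.call(rbind, out)
}

#' Iterative FFT-seeded multicomponent cosine fit (FFT-NLLS)
#'
#' Fits a sum of cosine components to a (preprocessed, detrended) trace by
#' the iterative coupled procedure: the dominant periodogram peak of the
#' current residuals (computed on a linearly interpolated uniform grid)
#' seeds a new component's period, all components plus a constant are then
#' jointly refit by nonlinear least squares on the native timestamps, and
#' the iteration stops when the newest component's amplitude is no longer
#' distinguishable from zero at 95% confidence or `max_components` is
#' reached. Because the seed frequency is chosen as the periodogram
#' maximum, the acceptance test is Bonferroni-corrected over the number of
#' candidate frequencies searched; without that correction pure noise
#' routinely produces nominally significant components. Amplitude and
#' period confidence intervals (and hence the RAE) are the usual unadjusted
#' 95% intervals from the linearized covariance at the optimum.
#'
#' The circadian component is the highest-amplitude accepted component with
#' period inside `period_range`; its relative amplitude error (RAE) is the
#' ratio of the amplitude's 95% confidence-interval half-width to the
#' amplitude estimate. Classification: RAE < 0.7 rhythmic, 0.7 <= RAE <= 1
#' weakly rhythmic, RAE > 1 (or no circadian component, or optimizer
#' failure) arrhythmic.
#'
#' @param trace Data frame with `time_h` and `counts` (or numeric `times`
#'   plus `counts` vectors via `time_h`/`counts` columns).
#' @param max_components Maximum number of cosine components (default 4).
#' @param period_range Circadian period range in hours (default `c(15, 35)`).
#' @return An object of class `rhythm_result`: list with `components`
#'   (data frame), `circadian` (row index or NA), `period`, `amplitude`,
#'   `rae`, `classification`, and fit diagnostics.
#' @export
fft_nlls <- function(trace, max_components = 4, period_range = c(15, 35)) {
  stopifnot(all(c("time_h", "counts") %in% names(trace)))
  t <- trace$time_h
  y <- trace$counts
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  if (length(t) < 12 || diff(range(t)) < 48) {
    return(empty_rhythm_result("insufficient data"))
  }
  par <- mean(y)
  fit <- NULL
  repeat {
    resid <- y - cosine_model(par, t)
    ncomp <- (length(par) - 1) / 3
    if (ncomp >= max_components) break
    seedc <- dominant_period(t, resid)
    if (is.null(seedc)) break
    cand_par <- c(par, seedc$period, seedc$b, seedc$c)
    cand_fit <- tryCatch(
      minpack.lm::nls.lm(par = cand_par,
                         fn = function(p) y - cosine_model(p, t),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(cand_fit)) break
    p <- cand_fit$par
    dfree <- length(t) - length(p)
    if (dfree <= 0) break
    J <- cosine_jacobian(p, t)
    sigma2 <- sum(cand_fit$fvec^2) / dfree
    vc <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
    if (is.null(vc)) break
    comps <- component_table(p, vc, dfree)
    newest <- nrow(comps)
    # Accept only a component whose amplitude differs from zero at overall
    # 95% confidence. Under the null the amplitude is Rayleigh (cosine and
    # sine coefficients jointly zero: a 2-df test, amp^2 / (2 se^2) ~ F),
    # and the seed frequency is the periodogram MAXIMUM refined
    # continuously by least squares, so the test is Bonferroni-corrected
    # over ~one effective independent frequency per grid sample. An
    # unadjusted single-frequency test would let pure noise routinely
    # produce "significant" components.
    se_new <- comps$amplitude_se[newest]
    n_eff <- max(seedc$n_grid, seedc$n_freq, 1)
    f_crit <- qf(1 - 0.05 / n_eff, 2, dfree)
    if (!is.finite(comps$amplitude[newest]) || se_new <= 0 &&
          comps$amplitude[newest] == 0 ||
        comps$amplitude[newest]^2 <= 2 * se_new^2 * f_crit) break
    par <- p
    fit <- list(par = p, vcov = vc, df = dfree, sigma = sqrt(sigma2),
                components = comps,
                converged = cand_fit$info %in% 1:4)
    if (sum(cand_fit$fvec^2) < 1e-20) break  # numerically perfect fit
  }
  if (is.null(fit)) return(empty_rhythm_result("no significant component"))
  comps <- fit$components
  in_range <- which(comps$period >= period_range[1] &
                      comps$period <= period_range[2])
  result <- list(components = comps, n = length(t), sigma = fit$sigma,
                 converged = fit$converged, note = NA_character_)
  if (length(in_range) == 0) {
    result$circadian <- NA_integer_
    result$period <- NA_real_
    result$amplitude <- NA_real_
    result$rae <- NA_real_
    result$classification <- "arrhythmic"
  } else {
    ci <- in_range[which.max(comps$amplitude[in_range])]
    rae <- comps$amplitude_ci95_half_width[ci] / comps$amplitude[ci]
    result$circadian <- ci
    result$period <- comps$period[ci]
    result$amplitude <- comps$amplitude[ci]
    result$rae <- rae
    result$classification <- classify_rae(rae)
  }
  structure(result, class = "rhythm_result")
}

empty_component_table <- function() {
  data.frame(period = numeric(0), amplitude = numeric(0), phase = numeric(0),
             amplitude_se = numeric(0),
             amplitude_ci95_half_width = numeric(0),
             period_ci95_half_width = numeric(0))
}

empty_rhythm_result <- function(note) {
  structure(list(components = empty_component_table(),
                 n = 0L, sigma = NA_real_, converged = FALSE, note = note,
                 circadian = NA_integer_, period = NA_real_,
                 amplitude = NA_real_, rae = NA_real_,
                 classification = "arrhythmic"),
            class = "rhythm_result")
}

#' @export
print.rhythm_result <- function(x, ...) {
  cat(sprintf("rhythm_result: %s", x$classification))
  if (!is.na(x$rae)) {
    cat(sprintf(" (period %.2f h, amplitude %.1f, RAE %.3f)", x$period,
                x$amplitude, x$rae))
  }
  cat(sprintf("\n%d fitted component(s), n = %d samples\n",
              nrow(x$components), x$n))
  invisible(x)
}

#' Relative amplitude error of a cosine component
#'
#' The ratio of the amplitude's 95% confidence-interval half-width to the
#' amplitude estimate ("amplitude error over most probable amplitude").
#' Lower values indicate stronger rhythms.
#'
#' @param component One row of a `rhythm_result` component table (or any
#'   list with `amplitude` and `amplitude_ci95_half_width`).
#' @return The RAE ratio; `NA` (propagating to an arrhythmic call) when the
#'   amplitude is zero.
#' @export
relative_amplitude_error <- function(component) {
  amp <- component$amplitude
  if (is.na(amp) || amp <= 0) return(NA_real_)
  component$amplitude_ci95_half_width / amp
}

#' Classify a trace by relative amplitude error
#'
#' @param rae RAE value (or NA for fit failure).
#' @return `"rhythmic"` (RAE < 0.7), `"weakly_rhythmic"` (0.7 <= RAE <= 1)
#'   or `"arrhythmic"` (RAE > 1, or no RAE available).
#' @export
classify_rae <- function(rae) {
  vapply(rae, function(r) {
    if (is.na(r)) "arrhythmic"
    else if (r < 0.7) "rhythmic"
    else if (r <= 1) "weakly_rhythmic"
    else "arrhythmic"
  }, character(1))
}

#' Run the per-fly rhythm analysis pipeline
#'
#' Preprocesses ([preprocess_trace()]), detrends ([detrend_trace()]) and
#' fits ([fft_nlls()]) every fly in a long trace table. Flies with too
#' little usable data are classified arrhythmic.
#'
#' @param traces Long data frame with `fly_id`, `time_h`, `counts`,
#'   `regime`.
#' @param exclude_initial_h,dd_only Passed to [preprocess_trace()].
#' @param window_h Passed to [detrend_trace()].
#' @param max_components,period_range Passed to [fft_nlls()].
#' @return List with `results` (named list of `rhythm_result`) and `flies`
#'   (data frame: `fly_id`, `classification`, `rae`, `period`,
#'   `amplitude`).
#' @export
rhythm_pipeline <- function(traces, exclude_initial_h = 24, dd_only = TRUE,
                            window_h = 24, max_components = 4,
                            period_range = c(15, 35)) {
  stopifnot(all(c("fly_id", "time_h", "counts") %in% names(traces)))
  results <- lapply(split(traces, traces$fly_id), function(tr) {
    tr <- tr[order(tr$time_h), , drop = FALSE]
    pp <- preprocess_trace(tr, exclude_initial_h, dd_only)
    if (!attr(pp, "fit_eligible")) return(empty_rhythm_result("ineligible"))
    dt <- tryCatch(detrend_trace(pp, window_h, trim_edges = TRUE),
                   error = function(e) NULL)
    if (is.null(dt)) return(empty_rhythm_result("too short to detrend"))
    fft_nlls(dt, max_components = max_components, period_range = period_range)
  })
  flies <- data.frame(
    fly_id = names(results),
    classification = vapply(results, `[[`, character(1), "classification"),
    rae = vapply(results, `[[`, numeric(1), "rae"),
    period = vapply(results, `[[`, numeric(1), "period"),
    amplitude = vapply(results, `[[`, numeric(1), "amplitude"))
  rownames(flies) <- NULL
  list(results = results, flies = flies)
}

#' Average trace with its fitted cosine overlay
#'
#' Interpolates every fly onto a common uniform grid spanning the
#' intersection of their time ranges, averages pointwise, and fits the
#' averaged trace with [fft_nlls()] to produce the theoretical overlay.
#'
#' @param traces Long data frame with `fly_id`, `time_h`, `counts` (and
#'   `regime` when `detrended = TRUE`, since detrending follows
#'   preprocessing).
#' @param detrended Detrend each fly ([detrend_trace()]) before averaging
#'   (default TRUE).
#' @param ... Passed to [fft_nlls()].
#' @return List with `time_h`, `mean_counts`, `overlay` (fitted values on
#'   the grid) and `fit` (the `rhythm_result` of the averaged trace).
#' @export
average_trace <- function(traces, detrended = TRUE, ...) {
  flies <- split(traces, traces$fly_id)
  if (length(flies) < 1) stop("no traces", call. = FALSE)
  flies <- lapply(flies, function(tr) {
    tr <- tr[order(tr$time_h), , drop = FALSE]
    if (detrended) tr <- detrend_trace(tr, trim_edges = TRUE) else tr
  })
  lo <- max(vapply(flies, function(x) min(x$time_h), numeric(1)))
  hi <- min(vapply(flies, function(x) max(x$time_h), numeric(1)))
  if (hi <= lo) stop("trace time ranges are disjoint", call. = FALSE)
  dt <- median(unlist(lapply(flies, function(x) diff(x$time_h))))
  grid <- seq(lo, hi, by = dt)
  mat <- vapply(flies, function(x) approx(x$time_h, x$counts, xout = grid)$y,
                numeric(length(grid)))
  mean_counts <- rowMeans(as.matrix(mat))
  fit <- fft_nlls(data.frame(time_h = grid, counts = mean_counts), ...)
  overlay <- if (nrow(fit$components) > 0) {
    par <- c(mean(mean_counts))
    # rebuild parameter vector from the component table
    for (i in seq_len(nrow(fit$components))) {
      T <- fit$components$period[i]
      A <- fit$components$amplitude[i]
      ph <- fit$components$phase[i]
      par <- c(par, T, A * cos(2 * pi * ph / T), A * sin(2 * pi * ph / T))
    }
    cosine_model(par, grid)
  } else rep(mean(mean_counts), length(grid))
  list(time_h = grid, mean_counts = mean_counts, overlay = overlay, fit = fit)
}

#' Summarize rhythmicity over a cohort of flies
#'
#' Percentages of rhythmic / weakly rhythmic / arrhythmic flies over the
#' whole cohort; mean and SEM of RAE and of the circadian period are
#' computed over rhythmic and weakly rhythmic flies only.
#'
#' @param results List of `rhythm_result` objects (or the `flies` data
#'   frame from [rhythm_pipeline()]).
#' @return One-row data frame with `n_flies`, `pct_r`, `pct_wr`, `pct_ar`,
#'   `mean_rae`, `sem_rae`, `mean_period`, `sem_period`.
#' @export
summarize_group <- function(results) {
  flies <- if (is.data.frame(results)) results else data.frame(
    classification = vapply(results, `[[`, character(1), "classification"),
    rae = vapply(results, `[[`, numeric(1), "rae"),
    period = vapply(results, `[[`, numeric(1), "period"))
  if (nrow(flies) == 0) stop("no results", call. = FALSE)
  n <- nrow(flies)
  cls <- factor(flies$classification,
                levels = c("rhythmic", "weakly_rhythmic", "arrhythmic"))
  pct <- 100 * as.numeric(table(cls)) / n
  rhythmic <- flies[flies$classification != "arrhythmic", , drop = FALSE]
  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  data.frame(
    n_flies = n, pct_r = pct[1], pct_wr = pct[2], pct_ar = pct[3],
    mean_rae = if (nrow(rhythmic)) mean(rhythmic$rae) else NA_real_,
    sem_rae = sem(rhythmic$rae),
    mean_period = if (nrow(rhythmic)) mean(rhythmic$period, na.rm = TRUE) else NA_real_,
    sem_period = sem(rhythmic$period[!is.na(rhythmic$period)]))
}

#' Compare groups of flies or measurements
#'
#' `"chi_square"` compares rhythmicity class distributions (three classes)
#' between two cohorts with Pearson's chi-square (no continuity
#' correction); classes empty in both cohorts are dropped with a warning.
#' `"mann_whitney"` compares two numeric samples (e.g. expression levels)
#' with the Mann-Whitney U / Wilcoxon rank-sum test. `"welch_anova_tamhane"`
#' compares two or more numeric groups (e.g. RAE or period values) with
#' Welch's ANOVA followed by Tamhane's T2 post-hoc procedure (pairwise
#' Welch t tests with Sidak-adjusted p-values).
#'
#' @param a,b Two groups: lists of `rhythm_result` objects or class-label
#'   vectors for `"chi_square"`, numeric vectors otherwise. For
#'   `"welch_anova_tamhane"`, `groups` may supply a named list of more than
#'   two numeric vectors instead.
#' @param test One of `"chi_square"`, `"mann_whitney"`,
#'   `"welch_anova_tamhane"`.
#' @param groups Optional named list of numeric vectors (ANOVA only).
#' @return List with `test`, `statistic`, `p_value`, plus test-specific
#'   detail (`table` for chi-square, `pairwise` for Tamhane T2).
#' @export
compare_groups <- function(a = NULL, b = NULL,
                           test = c("chi_square", "mann_whitney",
                                    "welch_anova_tamhane"),
                           groups = NULL) {
  test <- match.arg(test)
  if (test == "chi_square") {
    classes <- function(x) {
      if (is.list(x) && !is.data.frame(x))
        vapply(x, `[[`, character(1), "classification")
      else as.character(x)
    }
    lv <- c("rhythmic", "weakly_rhythmic", "arrhythmic")
    tab <- rbind(a = table(factor(classes(a), levels = lv)),
                 b = table(factor(classes(b), levels = lv)))
    empty <- colSums(tab) == 0
    if (any(empty)) {
      warning("dropping class(es) with zero counts in both groups: ",
              paste(colnames(tab)[empty], collapse = ", "))
      tab <- tab[, !empty, drop = FALSE]
    }
    if (all(tab["a", ] == tab["b", ])) {
      # identical distributions: statistic is exactly 0
      return(list(test = test, statistic = 0, p_value = 1, table = tab))
    }
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    list(test = test, statistic = unname(ct$statistic),
         p_value = ct$p.value, table = tab)
  } else if (test == "mann_whitney") {
    wt <- wilcox.test(a, b, exact = FALSE)
    list(test = test, statistic = unname(wt$statistic), p_value = wt$p.value)
  } else {
    if (is.null(groups)) groups <- list(a = a, b = b)
    if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
    vals <- unlist(groups, use.names = FALSE)
    grp <- factor(rep(names(groups), lengths(groups)))
    an <- oneway.test(vals ~ grp, var.equal = FALSE)
    pairs <- utils::combn(names(groups), 2, simplify = FALSE)
    m <- length(pairs)
    pairwise <- do.call(rbind, lapply(pairs, function(pr) {
      tt <- t.test(groups[[pr[1]]], groups[[pr[2]]], var.equal = FALSE)
      data.frame(group1 = pr[1], group2 = pr[2],
                 t = unname(tt$statistic), p_raw = tt$p.value,
                 p_sidak = min(1, 1 - (1 - tt$p.value)^m))
    }))
    list(test = test, statistic = unname(an$statistic),
         p_value = an$p.value, pairwise = pairwise)
  }
}

#' Reporter expression level early in constant darkness
#'
#' For each fly, the raw (non-detrended) counts at the sample closest to
#' `at_h` hours after DD onset; flies with no sample within +/- 1 h are
#' excluded with a warning.
#'
#' @param traces Long data frame with `fly_id`, `time_h`, `counts`,
#'   `regime`.
#' @param at_h Hours into DD at which to read the level (default 6).
#' @return Data frame with `fly_id`, `time_h` (sample used) and `level`.
#' @export
expression_level <- function(traces, at_h = 6) {
  stopifnot(all(c("fly_id", "time_h", "counts", "regime") %in% names(traces)))
  out <- lapply(split(traces, traces$fly_id), function(tr) {
    dd <- tr[tr$regime == "DD", , drop = FALSE]
    if (nrow(dd) == 0) return(NULL)
    target <- min(dd$time_h) + at_h
    i <- which.min(abs(dd$time_h - target))
    if (abs(dd$time_h[i] - target) > 1) return(NULL)
    data.frame(fly_id = dd$fly_id[1], time_h = dd$time_h[i],
               level = dd$counts[i])
  })
  dropped <- sum(vapply(out, is.null, logical(1)))
  if (dropped > 0) {
    warning(sprintf("%d fly/flies had no sample within 1 h of the target time",
                    dropped))
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
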