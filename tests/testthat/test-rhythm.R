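test_that("preprocessing removes exactly the transient and LD samples", {
  spec <- trace_sim_spec(n_flies = 1, duration_h = 96, seed = 3)
  tr <- simulate_traces(spec)$traces
  pp <- preprocess_trace(tr)
  expect_equal(nrow(pp), sum(tr$time_h >= 24 & tr$regime == "DD"))
  expect_true(attr(pp, "fit_eligible"))

  # a trace entirely inside the excluded window is empty and flagged
  early <- data.frame(time_h = seq(0, 20), counts = 1, regime = "LD")
  pe <- preprocess_trace(early)
  expect_equal(nrow(pe), 0L)
  expect_false(attr(pe, "fit_eligible"))

  # LD head: output starts at max(24 h, DD onset)
  tr2 <- data.frame(time_h = seq(0, 96), counts = 1,
                    regime = ifelse(seq(0, 96) < 12, "LD", "DD"))
  expect_equal(min(preprocess_trace(tr2)$time_h), 24)
  tr3 <- data.frame(time_h = seq(0, 96), counts = 1,
                    regime = ifelse(seq(0, 96) < 36, "LD", "DD"))
  expect_equal(min(preprocess_trace(tr3)$time_h), 36)

  expect_error(preprocess_trace(data.frame(time_h = c(1, 1), counts = 1:2,
                                           regime = "DD")), "increasing")
})

test_that("detrending removes polynomial trends and preserves cosines", {
  t <- seq(0, 96)
  # constant input -> identically zero
  con <- detrend_trace(data.frame(time_h = t, counts = 7))
  expect_equal(con$counts, rep(0, length(t)))
  # linear ramp -> zero away from the edges
  ramp <- detrend_trace(data.frame(time_h = t, counts = 2 * t))
  interior <- t >= 12 & t <= 84
  expect_equal(ramp$counts[interior], rep(0, sum(interior)))
  expect_false(all(ramp$counts == 0))  # edges carry the truncation artifact

  # pure cosine: the 25-point moving-average gain at period 24 h is
  # sin(25*pi/24) / (25*sin(pi/24)) = -1/25, so the detrended interior is
  # exactly (1 + 1/25) times the input cosine
  y <- 50 * cos(2 * pi * t / 24)
  det <- detrend_trace(data.frame(time_h = t, counts = y), trim_edges = TRUE)
  gain <- sin(25 * pi / 24) / (25 * sin(pi / 24))
  expect_equal(gain, -1 / 25, tolerance = 1e-12)
  co <- coef(lm(det$counts ~ cos(2 * pi * det$time_h / 24) +
                  sin(2 * pi * det$time_h / 24)))
  expect_equal(sqrt(co[2]^2 + co[3]^2), 50 * (1 - gain),
               tolerance = 1e-9, ignore_attr = TRUE)

  expect_error(detrend_trace(data.frame(time_h = 0:10, counts = 1)),
               "shorter than")
})

test_that("a noiseless circadian cosine is recovered essentially exactly", {
  set.seed(90)
  tr <- cosine_trace(duration_h = 96, period = 24, amp = 50, phase = 2,
                     baseline = 100)
  r <- fft_nlls(tr)
  expect_s3_class(r, "rhythm_result")
  expect_equal(r$classification, "rhythmic")
  expect_lt(abs(r$period - 24), 0.05)
  expect_lt(abs(r$amplitude - 50), 0.01)
  expect_lt(r$rae, 0.05)
  expect_equal(r$components$phase[r$circadian] %% 24, 2, tolerance = 1e-6)
})

test_that("two phase-locked components are both recovered", {
  spec <- trace_sim_spec(n_flies = 1, amp_24 = 50, amp_12 = 20, noise_sd = 5,
                         seed = 2)
  tr <- simulate_traces(spec)$traces
  r <- fft_nlls(detrend_trace(preprocess_trace(tr), trim_edges = TRUE))
  per <- sort(r$components$period)
  expect_equal(length(per), 2L)
  expect_lt(abs(per[1] - 12), 0.5)
  expect_lt(abs(per[2] - 24), 0.5)
})

test_that("fits are equivariant under time shift and scale", {
  set.seed(91)
  tr <- cosine_trace(duration_h = 96, amp = 40, phase = 5, noise_sd = 3)
  r0 <- fft_nlls(tr)
  shifted <- transform(tr, time_h = time_h + 5)
  r1 <- fft_nlls(shifted)
  expect_equal(r1$period, r0$period, tolerance = 1e-3)
  expect_equal(r1$amplitude, r0$amplitude, tolerance = 1e-3)
  expect_equal((r0$components$phase[r0$circadian] + 5) %% r0$period,
               r1$components$phase[r1$circadian] %% r1$period,
               tolerance = 0.01)

  scaled <- transform(tr, counts = counts * 10)
  r10 <- fft_nlls(scaled)
  expect_equal(r10$amplitude, 10 * r0$amplitude, tolerance = 1e-6)
  expect_equal(r10$rae, r0$rae, tolerance = 1e-8)
})

test_that("RAE definition and classification boundaries are exact", {
  expect_equal(relative_amplitude_error(
    list(amplitude = 10, amplitude_ci95_half_width = 1)), 0.1)
  expect_true(is.na(relative_amplitude_error(
    list(amplitude = 0, amplitude_ci95_half_width = 1))))
  expect_equal(classify_rae(c(0.69, 0.70, 1.0, 1.01, NA)),
               c("rhythmic", "weakly_rhythmic", "weakly_rhythmic",
                 "arrhythmic", "arrhythmic"))
})

test_that("median RAE grows with noise", {
  meds <- vapply(c(1, 5, 10, 20), function(sigma) {
    spec <- trace_sim_spec(n_flies = 50, amp_24 = 50, amp_12 = 0,
                           noise_sd = sigma, seed = 100 + sigma)
    pipe <- rhythm_pipeline(simulate_traces(spec)$traces)
    median(pipe$flies$rae, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(meds) >= 0))
})

test_that("pure-noise traces are almost never called rhythmic", {
  spec <- trace_sim_spec(n_flies = 100, amp_24 = 0, amp_12 = 0,
                         noise_sd = 10, baseline = 100, settle_tau = Inf,
                         seed = 4)
  pipe <- rhythm_pipeline(simulate_traces(spec)$traces)
  not_rhythmic <- mean(pipe$flies$classification != "rhythmic")
  expect_gte(not_rhythmic, 0.9)
})

test_that("averaging preserves identical traces and cancels antiphase pairs", {
  t <- seq(24, 120)
  one <- data.frame(fly_id = "a", time_h = t,
                    counts = 100 + 30 * cos(2 * pi * t / 24), regime = "DD")
  two <- one; two$fly_id <- "b"
  av <- average_trace(rbind(one, two), detrended = FALSE)
  expect_equal(av$mean_counts, one$counts[t %in% av$time_h])

  anti <- one; anti$fly_id <- "b"; anti$counts <- 100 - 30 * cos(2 * pi * t / 24)
  av2 <- average_trace(rbind(one, anti), detrended = FALSE)
  expect_lt(max(abs(av2$mean_counts - 100)), 1e-9)

  disjoint <- one; disjoint$fly_id <- "b"; disjoint$time_h <- t + 300
  expect_error(average_trace(rbind(one, disjoint)), "disjoint")
})

test_that("cohort averages recover the generating amplitude", {
  spec <- trace_sim_spec(n_flies = 26, amp_24 = 50, noise_sd = 10, seed = 6)
  av <- average_trace(simulate_traces(spec)$traces, detrended = TRUE)
  expect_equal(av$fit$classification, "rhythmic")
  expect_lt(abs(av$fit$amplitude - 50) / 50, 0.1)
  expect_equal(length(av$overlay), length(av$time_h))
})

test_that("group summaries tally classes and restrict means correctly", {
  flies <- data.frame(
    classification = c("rhythmic", "rhythmic", "weakly_rhythmic", "arrhythmic"),
    rae = c(0.3, 0.5, 0.8, NA), period = c(24, 23, 25, NA))
  gs <- summarize_group(flies)
  expect_equal(gs$pct_r, 50)
  expect_equal(gs$pct_wr, 25)
  expect_equal(gs$pct_ar, 25)
  expect_equal(gs$pct_r + gs$pct_wr + gs$pct_ar, 100)
  # means over rhythmic + weakly rhythmic only
  expect_equal(gs$mean_rae, mean(c(0.3, 0.5, 0.8)))
  expect_equal(gs$mean_period, mean(c(24, 23, 25)))

  all_ar <- data.frame(classification = rep("arrhythmic", 3),
                       rae = NA_real_, period = NA_real_)
  gs2 <- summarize_group(all_ar)
  expect_equal(gs2$pct_ar, 100)
  expect_true(is.na(gs2$mean_rae) || is.nan(gs2$mean_rae))
})

test_that("group comparisons match hand-computed statistics", {
  # identical groups: chi-square statistic exactly 0, p = 1
  cls <- c("rhythmic", "weakly_rhythmic", "arrhythmic")
  same <- compare_groups(rep(cls, 5), rep(cls, 5), test = "chi_square")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # textbook 2x3 table
  a <- rep(cls, times = c(10, 5, 5))
  b <- rep(cls, times = c(2, 4, 14))
  got <- compare_groups(a, b, test = "chi_square")
  O <- rbind(c(10, 5, 5), c(2, 4, 14))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(got$statistic, sum((O - E)^2 / E), tolerance = 1e-12)

  # a class absent from both groups is dropped with a warning
  expect_warning(
    compare_groups(rep("rhythmic", 4), rep("arrhythmic", 4),
                   test = "chi_square"),
    "zero counts")

  mw <- compare_groups(rnorm(20, 10), rnorm(20, 10), test = "mann_whitney")
  expect_true(mw$p_value > 0 && mw$p_value <= 1)

  set.seed(92)
  gl <- list(a = rnorm(15, 0.5, 0.1), b = rnorm(15, 0.8, 0.2),
             c = rnorm(15, 0.5, 0.1))
  wa <- compare_groups(test = "welch_anova_tamhane", groups = gl)
  expect_equal(nrow(wa$pairwise), 3L)
  expect_true(all(wa$pairwise$p_sidak >= wa$pairwise$p_raw - 1e-12))
  # Sidak adjustment formula
  expect_equal(wa$pairwise$p_sidak,
               pmin(1, 1 - (1 - wa$pairwise$p_raw)^3))
})

test_that("cohorts with and without rhythm separate by chi-square", {
  n_sig <- 0
  for (rep_i in 1:20) {
    sa <- trace_sim_spec(n_flies = 15, amp_24 = 50, noise_sd = 10,
                         seed = 200 + rep_i)
    sb <- trace_sim_spec(n_flies = 15, amp_24 = 0, amp_12 = 0, noise_sd = 10,
                         seed = 300 + rep_i)
    pa <- rhythm_pipeline(simulate_traces(sa)$traces)
    pb <- rhythm_pipeline(simulate_traces(sb)$traces)
    ct <- suppressWarnings(compare_groups(pa$flies$classification,
                                          pb$flies$classification,
                                          test = "chi_square"))
    n_sig <- n_sig + (ct$p_value < 0.01)
  }
  expect_gte(n_sig / 20, 0.9)
})

test_that("expression levels read the sample nearest 6 h into DD", {
  t <- seq(0, 96)
  tr <- data.frame(fly_id = "a", time_h = t, counts = 100,
                   regime = ifelse(t < 12, "LD", "DD"))
  lev <- expression_level(tr)
  expect_equal(lev$level, 100)
  expect_equal(lev$time_h, 18)   # DD onset 12 + 6

  # cohorts with different baselines separate by Mann-Whitney
  sa <- trace_sim_spec(n_flies = 20, baseline = 200, settle_tau = Inf,
                       amp_24 = 0, amp_12 = 0, noise_sd = 10, seed = 13)
  sb <- trace_sim_spec(n_flies = 20, baseline = 100, settle_tau = Inf,
                       amp_24 = 0, amp_12 = 0, noise_sd = 10, seed = 14)
  la <- expression_level(simulate_traces(sa)$traces)
  lb <- expression_level(simulate_traces(sb)$traces)
  mw <- compare_groups(la$level, lb$level, test = "mann_whitney")
  expect_lt(mw$p_value, 0.001)

  # flies without a sample near the target are dropped with a warning
  sparse <- data.frame(fly_id = "b", time_h = c(0, 40, 80), counts = 1,
                       regime = "DD")
  expect_warning(expression_level(rbind(tr, sparse)), "within 1 h")
})
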