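test_that("ratio computation is elementwise and rejects bad 380 samples", {
  expect_equal(compute_ratio(c(2, 4), c(1, 2)), c(2, 2))
  x <- runif(10, 1, 2)
  expect_equal(compute_ratio(x, x), rep(1, 10))
  expect_error(compute_ratio(c(1, 1), c(1, 0)), "index 2")
  expect_error(compute_ratio(1:3, 1:2), "length mismatch")

  set.seed(4)
  a <- runif(50, 10, 100); b <- runif(50, 10, 100)
  expect_equal(compute_ratio(a, b), a / b)
})

test_that("baseline normalisation uses the five pre-stimulus samples", {
  t <- seq(0, 58, by = 2)
  expect_equal(normalize_baseline(rep(0.8, 30), t, 20), rep(1, 30))

  r <- rep(0.5, 30); r[20] <- 1.0
  expect_equal(normalize_baseline(r, t, 20)[20], 2.0)

  expect_error(normalize_baseline(r, t, 6), "at least 5")

  set.seed(6)
  r <- runif(30, 0.4, 1.2)
  rel <- normalize_baseline(r, t, 20)
  pre5 <- tail(which(t < 20), 5)
  expect_equal(mean(rel[pre5]), 1, tolerance = 1e-12)
  # invariant to scaling both raw channels by a constant
  f340 <- runif(30, 20, 40); f380 <- runif(30, 20, 40)
  rel1 <- normalize_baseline(compute_ratio(f340, f380), t, 20)
  rel2 <- normalize_baseline(compute_ratio(7 * f340, 7 * f380), t, 20)
  expect_equal(rel1, rel2)
})

test_that("ratio-to-calcium calibration follows the ratiometric relation", {
  p <- calibration_params(Rmin = 0.3, Rmax = 2.5, Kd = 224, beta = 1)
  expect_equal(calibrate_ca(p$Rmin, p), 0)
  expect_equal(calibrate_ca((p$Rmin + p$Rmax) / 2, p), p$Kd)
  expect_error(calibrate_ca(2.5, p), "saturated")

  # round-trip through the algebraic inverse recovers R
  set.seed(8)
  for (i in 1:20) {
    p <- calibration_params(Rmin = runif(1, 0.1, 0.5),
                            Rmax = runif(1, 2, 4),
                            Kd = runif(1, 100, 300), beta = runif(1, 0.5, 3))
    r <- runif(1, p$Rmin, p$Rmax - 1e-6)
    ca <- calibrate_ca(r, p)
    r_back <- (ca * p$Rmax + p$Kd * p$beta * p$Rmin) / (ca + p$Kd * p$beta)
    expect_equal(r_back, r, tolerance = 1e-9)
  }

  # strictly increasing on [Rmin, Rmax)
  grid <- seq(0.3, 2.49, length.out = 50)
  p <- calibration_params(0.3, 2.5, 224, 2)
  expect_true(all(diff(calibrate_ca(grid, p)) > 0))
})

test_that("amplitude fold is the windowed maximum of the relative trace", {
  t <- seq(0, 100, by = 2)
  expect_equal(amplitude_fold(rep(1, length(t)), t, c(20, 60)), 1)
  r <- rep(1, length(t)); r[t == 40] <- 1.59
  expect_equal(amplitude_fold(r, t, c(20, 60)), 1.59)
  expect_error(amplitude_fold(r, t, c(200, 300)), "empty")

  set.seed(10)
  r <- 1 + abs(rnorm(length(t), 0, 0.2))
  expect_equal(amplitude_fold(r, t, c(20, 60)),
               max(r[t >= 20 & t <= 60]))
})

test_that("responder cutoff is mean plus three sample SDs", {
  expect_equal(responder_threshold(c(1, 1, 1, 1)), 1)
  expect_error(responder_threshold(1.0), "at least 2")

  set.seed(12)
  peaks <- rnorm(100, 1, 0.05)
  expect_equal(responder_threshold(peaks), mean(peaks) + 3 * sd(peaks))
  # translation equivariance
  expect_equal(responder_threshold(peaks + 0.2),
               responder_threshold(peaks) + 0.2, tolerance = 1e-12)
})

test_that("data-driven cutoff derivation isolates the sub-cutoff mode", {
  set.seed(14)
  peaks <- c(rnorm(150, 1, 0.05), rnorm(50, 1.5, 0.1))
  out <- derive_threshold(peaks, provisional = 1.15)
  expect_true(out$cutoff > 1.05 && out$cutoff < 1.3)
  expect_true(all(out$nonresponder_peaks < out$cutoff))
})

test_that("responder classification is inclusive at the cutoff", {
  calls <- data.frame(amplitude_fold = c(1.20, 1.15, 1.00))
  out <- classify_responders(calls, cutoff = 1.15)
  expect_identical(out$is_responder, c(TRUE, TRUE, FALSE))
})

test_that("desensitization flags traces that fail to recover", {
  sch <- data.frame(label = c("low", "high", "KCl"),
                    onset = c(60, 150, 240), offset = c(90, 180, 270),
                    washout_end = c(150, 240, 300))
  t <- seq(0, 300, by = 2)

  recovered <- rep(1, length(t))
  recovered[t >= 60 & t <= 90] <- 1.6   # transient fully back by 150 s
  expect_false(flag_desensitized(recovered, t, sch)[["high"]])

  stuck <- rep(1, length(t))
  stuck[t >= 60] <- 1.6                 # never recovers
  expect_true(flag_desensitized(stuck, t, sch)[["high"]])

  # planted recovery levels straddling the criterion: pre-high level of
  # 1 + f*(peak-1) with f above/below recovery_fraction = 0.5
  for (f in c(0.2, 0.45, 0.55, 0.9)) {
    tr <- rep(1, length(t))
    tr[t >= 60 & t <= 90] <- 1.6
    tr[t > 90 & t < 150] <- 1 + f * 0.6
    expect_equal(unname(flag_desensitized(tr, t, sch)[["high"]]), f > 0.5)
  }
})

test_that("generated desensitized responders are flagged, recovered are not", {
  sim <- gen_traces(2, 40, responder_fraction = 1, desensitize_prob = 0.5,
                    noise_sd = 0.002, seed = 77)
  calls <- analyze_traces(sim$traces, sim$schedule)
  high <- calls[calls$stimulus == "AITC_high", ]
  high <- high[order(high$neuron_id), ]
  truth <- sim$truth[order(sim$truth$neuron_id), ]
  expect_identical(high$excluded_desensitized, truth$desensitized)
  expect_true(all(is.na(high$amplitude_fold[high$excluded_desensitized])))
})

test_that("per-mouse responder percentages normalise to KCl responders", {
  mk_calls <- function(n, n_kcl_resp, n_aitc_resp, mouse = "m1") {
    ids <- sprintf("n%03d", seq_len(n))
    kcl_resp <- seq_len(n) <= n_kcl_resp
    aitc_resp <- seq_len(n) <= n_aitc_resp   # nested in KCl responders
    rbind(
      data.frame(neuron_id = ids, mouse_id = mouse, stimulus = "AITC_low",
                 amplitude_fold = ifelse(aitc_resp, 1.5, 1.0),
                 peak_fold = ifelse(aitc_resp, 1.5, 1.0),
                 excluded_desensitized = FALSE, is_responder = aitc_resp),
      data.frame(neuron_id = ids, mouse_id = mouse, stimulus = "KCl",
                 amplitude_fold = ifelse(kcl_resp, 2, 1.0),
                 peak_fold = ifelse(kcl_resp, 2, 1.0),
                 excluded_desensitized = FALSE, is_responder = kcl_resp))
  }
  s <- percent_responders(mk_calls(30, 20, 10))
  expect_equal(s$pct_responders[s$stimulus == "AITC_low"], 50)
  expect_equal(s$n_kcl_responders, c(20L, 20L))

  s0 <- percent_responders(mk_calls(30, 20, 0))
  expect_equal(s0$pct_responders[s0$stimulus == "AITC_low"], 0)

  expect_warning(sNA <- percent_responders(mk_calls(10, 0, 0)),
                 "no KCl responders")
  expect_true(is.na(sNA$pct_responders[sNA$stimulus == "AITC_low"]))
})

test_that("gated percentages never exceed 100", {
  set.seed(19)
  for (i in 1:10) {
    sim <- gen_traces(3, 30, responder_fraction = runif(1),
                      kcl_fraction = runif(1, 0.5, 1), seed = 1000 + i)
    calls <- analyze_traces(sim$traces, sim$schedule)
    suppressWarnings(s <- percent_responders(calls))
    expect_true(all(s$pct_responders[!is.na(s$pct_responders)] <= 100))
  }
})

test_that("group comparison wrappers match hand calculations", {
  same <- c(3.1, 3.3, 2.9, 3.0)
  out <- group_compare(same, same)
  expect_equal(out$statistic, 0)

  a <- c(1, 2); b <- c(3, 5)
  out <- group_compare(a, b)
  expect_equal(out$statistic, oracle_student_t(a, b))
  expect_equal(out$statistic, -2.2360679, tolerance = 1e-6)

  # one-way ANOVA with two groups: F = t^2
  out_f <- group_compare(a, b, test = "oneway_anova")
  expect_equal(out_f$statistic, oracle_student_t(a, b)^2, tolerance = 1e-9)
  expect_equal(out_f$p_value, out$p_value, tolerance = 1e-9)
})

test_that("trace reader computes ratios and schedule reader validates", {
  tf <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(neuron_id = "n1", mouse_id = "m1",
                   time = c(0, 2, 4), f340 = c(2, 4, 6), f380 = c(2, 2, 2))
  write.csv(df, tf, row.names = FALSE)
  tr <- read_traces(tf)
  expect_equal(tr$ratio, c(1, 2, 3))

  sf <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(label = c("low", "KCl"), onset = c(10, 60),
                       offset = c(20, 70), washout_end = c(50, 80)),
            sf, row.names = FALSE)
  expect_equal(nrow(read_schedule(sf)), 2L)
  write.csv(data.frame(label = c("KCl", "low"), onset = c(10, 60),
                       offset = c(20, 70), washout_end = c(50, 80)),
            sf, row.names = FALSE)
  expect_error(read_schedule(sf), "KCl")
})
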