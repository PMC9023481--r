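# P search windows, dissociation rules, verification, and the full pipeline

test_that("P window matches direct arithmetic; degenerate cases are NULL", {
  cfg <- detector_config()
  # R(i-1) = 0, R(i) = 360 (RR = 1 s): 0.71*360 = 255.6 -> 256;
  # 360 - (0.07*360 + 0.06*360 = 46.8 -> 47) = 313
  expect_identical(p_search_window(360L, 1.0, 360, cfg), c(256L, 313L))
  # first beat: fixed window R - 300 ms to R - 80 ms (28.8 -> 29)
  expect_identical(p_search_window(720L, NA_real_, 360, cfg), c(612L, 691L))
  # very short RR: right edge crosses the left -> no window
  expect_null(p_search_window(72L, 0.2, 360, cfg))
  # clipping
  expect_identical(p_search_window(360L, 1.0, 360, cfg, sig_len = 300L),
                   c(256L, 300L))
})

test_that("conducted P candidates hit the true apex; ties and zeros behave", {
  fs <- 360
  cfg <- detector_config()
  g <- sinus_fixture(fs = fs, duration = 30, hr = 60)
  xc <- clean_ecg(g$record, cfg)
  beats <- beats_from_r(g$truth$r_peaks, fs)
  for (i in 2:10) {
    cand <- detect_normal_p(xc, beats, i, cfg)
    expect_lte(abs(cand$position - g$beats$p[i]), 1)
    expect_equal(cand$kind, "normal")
  }
  # all-zero window: candidate sits at the window start (earliest tie)
  z <- structure(list(samples = numeric(10 * fs), fs = fs, kind = "cleaned"),
                 class = "filtered_signal")
  bz <- beats_from_r(c(2L * fs, 3L * fs), fs)
  cz <- detect_normal_p(z, bz, 2, cfg)
  expect_identical(cz$position,
                   p_search_window(3L * fs, 1.0, fs, cfg, sig_len = 10L * fs)[1])
  # two bumps in the window: the taller one wins
  x <- numeric(10 * fs)
  w <- p_search_window(3L * fs, 1.0, fs, cfg, sig_len = 10L * fs)
  x[w[1] + 10] <- 0.1
  x[w[1] + 30] <- 0.2
  s2 <- structure(list(samples = x, fs = fs, kind = "cleaned"),
                  class = "filtered_signal")
  c2 <- detect_normal_p(s2, bz, 2, cfg)
  expect_identical(c2$position, w[1] + 30L)
})

test_that("dissociation gate applies the printed criteria", {
  cfg <- detector_config()
  # fresh pause: all three criteria required
  expect_true(dissociation_gate(2.0, 1.0, FALSE, FALSE, cfg))
  expect_false(dissociation_gate(2.0, 1.0, TRUE, FALSE, cfg))   # PVC vetoes
  expect_false(dissociation_gate(1.5, 1.0, FALSE, FALSE, cfg))  # not > 1.6 s
  expect_false(dissociation_gate(1.7, 1.2, FALSE, FALSE, cfg))  # ratio fails
  # previous interval had a dissociated P: single relaxed criterion
  expect_true(dissociation_gate(0.9, 1.0, FALSE, TRUE, cfg))
  expect_false(dissociation_gate(0.7, 1.0, FALSE, TRUE, cfg))
})

test_that("verification applies voltage then position, in that order", {
  cfg <- detector_config()
  cand <- data.frame(beat_index = 2L, position = 500L, amplitude = 0.1,
                     kind = "normal", accepted = FALSE,
                     rejection_reason = "none", stringsAsFactors = FALSE)
  ok <- verify_p(cand, u_qrs = 1.0, t_prev = 400L, cfg)
  expect_true(ok$accepted)
  expect_identical(ok$rejection_reason, "none")

  weak <- cand; weak$amplitude <- 0.04
  out <- verify_p(weak, 1.0, 400L, cfg)
  expect_false(out$accepted)
  expect_identical(out$rejection_reason, "low_voltage")

  early <- cand; early$position <- 390L
  out2 <- verify_p(early, 1.0, 400L, cfg)
  expect_false(out2$accepted)
  expect_identical(out2$rejection_reason, "behind_T")

  # low voltage is checked first even when both criteria fail
  both <- cand; both$amplitude <- 0.01; both$position <- 390L
  expect_identical(verify_p(both, 1.0, 400L, cfg)$rejection_reason,
                   "low_voltage")
  # first beat: no previous T, position criterion passes vacuously
  expect_true(verify_p(cand, 1.0, NA_integer_, cfg)$accepted)
})

test_that("pipeline recovers every P on noiseless sinus at all rates", {
  for (fs in c(128, 250, 360)) {
    g <- sinus_fixture(fs = fs, duration = 40, hr = 60)
    res <- run_pipeline(g$record)
    expect_length(res$p_accepted, length(g$truth$p_peaks))
    expect_lte(localization_error(res$p_accepted, g$truth$p_peaks), 1)
    expect_true(all(res$candidates$accepted))
    expect_false(any(res$beats$pvc))
    expect_false(any(res$beats$afib))
  }
})

test_that("pipeline is deterministic", {
  g <- sinus_fixture(fs = 250, duration = 30, hr = 75, rr_jitter = 0.05)
  r1 <- run_pipeline(g$record)
  r2 <- run_pipeline(g$record)
  expect_identical(r1$p_accepted, r2$p_accepted)
  expect_identical(r1$beats$r_peaks, r2$beats$r_peaks)
  expect_identical(r1$candidates, r2$candidates)
})

test_that("PVC beats get no P search; neighbours are unaffected", {
  g <- sinus_fixture(fs = 360, duration = 60, hr = 60,
                     events = list(list(type = "pvc", beats = c(10L, 25L, 40L))))
  res <- run_pipeline(g$record)
  pvc_i <- which(g$beats$label == "pvc")
  expect_identical(which(res$beats$pvc), pvc_i)
  skip_rows <- res$candidates[res$candidates$rejection_reason == "pvc_skip", ]
  expect_identical(sort(skip_rows$beat_index), pvc_i)
  expect_length(res$p_accepted, length(g$truth$p_peaks))
  expect_lte(localization_error(res$p_accepted, g$truth$p_peaks), 1)
})

test_that("AFIB region yields zero accepted P; flags cover its interior", {
  g <- sinus_fixture(fs = 250, duration = 220, hr = 70, seed = 7,
                     events = list(list(type = "afib_segment",
                                        beats = c(40L, 160L), rr_jitter = 0.30)))
  res <- run_pipeline(g$record)
  af_truth <- range(which(g$beats$label == "afib"))
  interior <- (af_truth[1] + 10):(af_truth[2] - 10)
  expect_gt(mean(res$beats$afib[interior]), 0.9)
  expect_true(all(is.na(res$beats$p_peaks[res$beats$afib])))
  # no accepted P inside the flagged region
  flagged_r <- res$beats$r_peaks[res$beats$afib]
  if (length(flagged_r) >= 2) {
    inside <- res$p_accepted > min(flagged_r) & res$p_accepted < max(flagged_r)
    expect_equal(sum(inside), 0)
  }
})

test_that("AVB II pause yields exactly one dissociated P at the true apex", {
  fs <- 360
  g <- sinus_fixture(fs = fs, duration = 40, hr = 60,
                     events = list(list(type = "avb2_drop", beats = 20L)))
  res <- run_pipeline(g$record)
  dtrue <- g$beats$p[g$beats$label == "dropped"]
  dc <- res$candidates[res$candidates$kind == "dissociated" &
                       res$candidates$accepted, ]
  expect_equal(nrow(dc), 1)
  expect_lte(abs(dc$position - dtrue), 1)
  # conducted P detection elsewhere unharmed
  expect_length(res$p_accepted, length(g$truth$p_peaks))
  expect_lte(localization_error(res$p_accepted, g$truth$p_peaks), 1)
})

test_that("two consecutive dropped beats both recover their P (relaxed gate)", {
  fs <- 360
  g <- sinus_fixture(fs = fs, duration = 50, hr = 60,
                     events = list(list(type = "avb2_drop", beats = c(20L, 22L))))
  res <- run_pipeline(g$record)
  dtrue <- sort(g$beats$p[g$beats$label == "dropped"])
  dc <- res$candidates[res$candidates$kind == "dissociated" &
                       res$candidates$accepted, ]
  expect_equal(nrow(dc), 2)
  expect_lte(localization_error(sort(dc$position), dtrue), 1)
})

test_that("accepted P waves always satisfy both verification criteria post hoc", {
  cfg <- detector_config()
  fixtures <- list(
    sinus_fixture(fs = 360, duration = 40, hr = 60),
    sinus_fixture(fs = 360, duration = 40, hr = 60,
                  events = list(list(type = "pvc", beats = c(8L, 16L)))),
    sinus_fixture(fs = 360, duration = 40, hr = 60,
                  events = list(list(type = "avb2_drop", beats = 15L)))
  )
  for (g in fixtures) {
    res <- run_pipeline(g$record, cfg)
    xc <- clean_ecg(g$record, cfg)
    acc <- res$candidates[res$candidates$accepted, ]
    for (k in seq_len(nrow(acc))) {
      i <- acc$beat_index[k]
      u_qrs <- xc$samples[res$beats$r_peaks[i]]
      expect_gt(abs(acc$amplitude[k]), cfg$up_factor * abs(u_qrs))
      if (i >= 2 && !is.na(res$beats$t_peaks[i - 1])) {
        expect_gt(acc$position[k], res$beats$t_peaks[i - 1])
      }
      # and no accepted P inside the refractory zone of a PVC beat
      if (res$beats$pvc[i]) {
        expect_lt(acc$position[k],
                  res$beats$r_peaks[i] - sec_to_samples(cfg$refractory, 360))
      }
    }
  }
})
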