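# generator construction guarantees and determinism

test_that("default sinus construction has one P per beat, counts as expected", {
  g <- sinus_fixture(fs = 360, duration = 60, hr = 60)
  nb <- nrow(g$beats)
  expect_true(abs(nb - 59) <= 1) # 60 s at 60 bpm minus edge margins
  expect_length(g$truth$p_peaks, nb)
  expect_length(g$truth$r_peaks, nb)
  expect_identical(g$truth$p_peaks, sort(g$beats$p))
})

test_that("event surrogates shape the truth as constructed", {
  g <- sinus_fixture(fs = 250, duration = 120, hr = 70, seed = 3,
                     events = list(list(type = "afib_segment",
                                        beats = c(30L, 80L), rr_jitter = 0.3)))
  af <- g$beats$label == "afib"
  expect_true(any(af))
  expect_true(all(is.na(g$beats$p[af])))
  # truth has zero P peaks inside the afib beat range
  rng <- range(g$beats$r[af])
  expect_false(any(g$truth$p_peaks > rng[1] & g$truth$p_peaks < rng[2]))

  g2 <- sinus_fixture(fs = 360, duration = 30, hr = 60,
                      events = list(list(type = "avb2_drop", beats = 10L)))
  drop <- g2$beats$label == "dropped"
  expect_true(all(is.na(g2$beats$r[drop])))
  expect_false(anyNA(g2$beats$p[drop]))
  # a P with no R in the pause: more P than R in the truth
  expect_gt(length(g2$truth$p_peaks), length(g2$truth$r_peaks))

  g3 <- sinus_fixture(fs = 360, duration = 20, hr = 60,
                      events = list(list(type = "pvc", beats = 5L)))
  expect_true(is.na(g3$beats$p[5]))
  expect_identical(g3$beats$label[5], "pvc")
})

test_that("same spec and seed reproduce the record exactly", {
  s <- synth_ecg(fs = 250, duration = 30, hr_bpm = 80, rr_jitter = 0.1, seed = 9)
  g1 <- generate_ecg(s)
  g2 <- generate_ecg(s)
  expect_identical(g1$record$samples, g2$record$samples)
  expect_identical(g1$truth$p_peaks, g2$truth$p_peaks)
  g3 <- generate_ecg(synth_ecg(fs = 250, duration = 30, hr_bpm = 80,
                               rr_jitter = 0.1, seed = 10))
  expect_false(identical(g1$record$samples, g3$record$samples))
})

test_that("invalid specs and events are rejected", {
  expect_error(synth_ecg(rr_jitter = 1.2))
  expect_error(synth_ecg(hr_bpm = 5))
  expect_error(synth_ecg(events = list(list(type = "nonsense", beats = 1L))),
               "unknown event type")
})

test_that("add_noise is seeded, reproducible, and the identity at level 0", {
  g <- sinus_fixture(fs = 250, duration = 10)
  expect_identical(add_noise(g$record, "gaussian", 0)$samples,
                   g$record$samples)
  n1 <- add_noise(g$record, "gaussian", 0.05, seed = 4)
  n2 <- add_noise(g$record, "gaussian", 0.05, seed = 4)
  expect_identical(n1$samples, n2$samples)
  expect_false(identical(n1$samples,
                         add_noise(g$record, "gaussian", 0.05, seed = 5)$samples))
})

test_that("cleaning removes most injected baseline drift power", {
  fs <- 250
  g <- sinus_fixture(fs = fs, duration = 40)
  noisy <- add_noise(g$record, "baseline_drift", level = 0.2, freq = 0.2)
  cleaned <- clean_ecg(noisy)$samples
  mid <- (5 * fs):(35 * fs)
  drift_before <- noisy$samples[mid] - g$record$samples[mid]
  drift_after <- cleaned[mid] - clean_ecg(g$record)$samples[mid]
  expect_lt(sum(drift_after^2) / sum(drift_before^2), 0.2)
})
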