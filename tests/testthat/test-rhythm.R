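# QRS area, PVC rule, symbolic dynamics / entropy, AFIB rule, pathology gate

test_that("QRS area matches the closed form for a rectangular pulse", {
  fs <- 360
  cfg <- detector_config()
  half <- sec_to_samples(cfg$pvc_win, fs)
  n <- 10 * fs
  x <- numeric(n)
  r <- 5L * fs
  x[(r - half):(r + half)] <- 1 # 1 mV across the full +/-150 ms window
  sig <- structure(list(samples = x, fs = fs, kind = "baseline_free"),
                   class = "filtered_signal")
  beats <- beats_from_r(c(2L * fs, r), fs)
  auc <- compute_auc(sig, beats, cfg)
  expect_lt(abs(auc$auc[2] - 0.3), 2 / fs) # 0.3 mV*s up to edge quantization
  expect_equal(auc$auc[1], 0)

  # linearity under positive scaling
  sig2 <- structure(list(samples = 2 * x, fs = fs, kind = "baseline_free"),
                    class = "filtered_signal")
  auc2 <- compute_auc(sig2, beats, cfg)
  expect_equal(auc2$auc, 2 * auc$auc)

  # running median uses strictly previous beats only
  expect_true(is.na(auc$running_median[1]))
  expect_equal(auc$running_median[2], auc$auc[1])
})

test_that("PVC rule flags exactly the outlier and respects the 75% override", {
  expect_identical(detect_pvc(auc_from_values(c(1, 1, 1, 2, 1))),
                   c(FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_identical(detect_pvc(auc_from_values(rep(1, 6))), rep(FALSE, 6))
  # naive flags F,T,T,T = exactly 75%: not "more than 75%", flags kept
  expect_identical(detect_pvc(auc_from_values(c(1, 2, 2, 2))),
                   c(FALSE, TRUE, TRUE, TRUE))
  # above 75%: all flags cleared (bundle branch block interpretation)
  expect_identical(detect_pvc(auc_from_values(c(1, 2, 2, 2, 2))),
                   rep(FALSE, 5))
  # scale-free: positive rescaling leaves flags unchanged
  a <- c(1, 1.1, 0.9, 2.2, 1, 1.05)
  expect_identical(detect_pvc(auc_from_values(a)),
                   detect_pvc(auc_from_values(37.5 * a)))
})

test_that("entropy matches closed forms on constructed RR sequences", {
  fs <- 250
  cfg <- detector_config()
  # metronomic: single repeated word -> sh = 0
  r <- cumsum(rep(fs, 120))
  ent <- symbolic_entropy(beats_from_r(r, fs), cfg)
  mid <- ent$sh[!is.na(ent$sh)]
  expect_true(length(mid) > 0)
  expect_equal(unname(mid), rep(0, length(mid)))

  # two-word alternation, 30/29 split inside the 59-word window
  # hr alternates between two symbols -> words alternate between two values
  rr <- rep(c(fs, round(fs * 60 / 80)), 70)[1:140] # 60 and 80 bpm
  r2 <- cumsum(rr)
  ent2 <- symbolic_entropy(beats_from_r(r2, fs), cfg)
  sh_expect <- -(30 / 59 * log(30 / 59) + 29 / 59 * log(29 / 59)) / log(59)
  mid2 <- ent2$sh[!is.na(ent2$sh)]
  expect_true(all(abs(mid2 - sh_expect) < 1e-9))

  # sh depends only on the word distribution, not the word order
  w <- c(rep(1L, 30), rep(2L, 29))
  p1 <- pwaved:::shannon_entropy_norm(w, 59)
  p2 <- pwaved:::shannon_entropy_norm(sample(w), 59)
  expect_equal(p1, p2)
  # 59 distinct words: uniform over 59 -> sh = 1
  expect_equal(pwaved:::shannon_entropy_norm(seq_len(59), 59), 1)
})

test_that("entropy is undefined near edges and for short records", {
  fs <- 250
  r <- cumsum(rep(fs, 40)) # fewer beats than the 59-word window
  ent <- symbolic_entropy(beats_from_r(r, fs))
  expect_true(all(is.na(ent$sh)))
  expect_identical(detect_afib(ent, rep(FALSE, 40)), rep(FALSE, 40))
})

test_that("AFIB flags fire on irregular RR, stay off on metronomic RR", {
  fs <- 250
  cfg <- detector_config()
  set.seed(11)
  rr <- round(fs * pmax(60 / 70 * (1 + 0.30 * rnorm(200)), 0.3))
  ent <- symbolic_entropy(beats_from_r(cumsum(rr), fs), cfg)
  flags <- detect_afib(ent, rep(FALSE, 200), cfg)
  mid <- 60:140 # interior, full windows available
  expect_gt(mean(flags[mid]), 0.9)

  reg <- symbolic_entropy(beats_from_r(cumsum(rep(fs, 200)), fs), cfg)
  expect_false(any(detect_afib(reg, rep(FALSE, 200), cfg)))
})

test_that("more than 30 PVCs inside the entropy window suppress AFIB", {
  n <- 120
  sh <- rep(0.9, n) # nominally above threshold wherever defined
  sh[c(1:29, (n - 28):n)] <- NA # no full word window at the edges
  ent <- entropy_from_sh(sh)
  defined <- !is.na(sh)
  pvc_heavy <- rep(c(TRUE, TRUE, FALSE), length.out = n) # ~39 per 59-window
  expect_false(any(detect_afib(ent, pvc_heavy)))
  pvc_light <- rep(FALSE, n)
  expect_true(all(detect_afib(ent, pvc_light)[defined]))
  expect_false(any(detect_afib(ent, pvc_light)[!defined]))
  # threshold is strict: sh exactly at the threshold is not AFIB
  at <- entropy_from_sh(ifelse(defined, detector_config()$sh_thresh, NA))
  expect_false(any(detect_afib(at, pvc_light)))
})

test_that("pathology gate checks AFIB before PVC", {
  b <- beats_from_r(c(100, 400, 700), 360)
  b$afib <- c(TRUE, FALSE, FALSE)
  b$pvc <- c(TRUE, TRUE, FALSE)
  expect_identical(pathology_check(b, 1), "skip_afib")
  expect_identical(pathology_check(b, 2), "skip_pvc")
  expect_identical(pathology_check(b, 3), "proceed")
})
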