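test_that("the interval model matches its closed form", {
  sp <- scenario_spec("c", 10, mean_nni_ms = 1000, amp_lf_ms = 0,
                      amp_hf_ms = 0)
  expect_equal(generate_tachogram(sp, c(0, 1, 2)), c(1000, 1000, 1000))

  sp <- scenario_spec("lf", 10, mean_nni_ms = 1000, amp_lf_ms = 50,
                      freq_lf_hz = 0.1, amp_hf_ms = 0)
  expect_equal(generate_tachogram(sp, 2.5), 1000 + 50 * sin(pi / 2))

  # two-tone closed form on a dense grid
  sp <- scenario_spec("2t", 60, mean_nni_ms = 900, amp_lf_ms = 40,
                      freq_lf_hz = 0.08, amp_hf_ms = 25, freq_hf_hz = 0.3)
  t <- seq(0, 60, by = 0.25)
  expect_equal(generate_tachogram(sp, t),
               900 + 40 * sin(2 * pi * 0.08 * t) + 25 * sin(2 * pi * 0.3 * t))
})

test_that("noisy generation is reproducible under a seed and leaves the caller's RNG alone", {
  sp <- scenario_spec("n", 30, mean_nni_ms = 1000, amp_lf_ms = 50,
                      freq_lf_hz = 0.1, amp_hf_ms = 0, noise_sd_ms = 20)
  t <- seq(0, 30, by = 0.5)
  a <- generate_tachogram(sp, t, seed = 7)
  b <- generate_tachogram(sp, t, seed = 7)
  expect_identical(a, b)
  expect_gt(stats::sd(a - 1000 - 50 * sin(2 * pi * 0.1 * t)), 5)

  set.seed(123)
  x1 <- rnorm(3)
  set.seed(123)
  invisible(generate_tachogram(sp, t, seed = 7))
  expect_identical(rnorm(3), x1)
})

test_that("grid validation rejects out-of-segment and unordered times", {
  sp <- scenario_spec("c", 10, mean_nni_ms = 1000, amp_lf_ms = 0, amp_hf_ms = 0)
  expect_error(generate_tachogram(sp, c(0, 11)), "within")
  expect_error(generate_tachogram(sp, c(1, 1)), "increasing")
})

test_that("beat accumulation yields the expected counts and spans", {
  b <- tachogram_to_beats(scenario_spec("c", 10, 1000, amp_lf_ms = 0,
                                        amp_hf_ms = 0))
  expect_equal(b$beat_s, 0:10)

  b <- tachogram_to_beats(scenario_spec("c", 10, 500, amp_lf_ms = 0,
                                        amp_hf_ms = 0))
  expect_equal(nrow(b), 21)

  # modulated: emitted intervals must accumulate to just under the duration
  sp <- scenario_spec("m", 120, 1000, amp_lf_ms = 50, freq_lf_hz = 0.1,
                      amp_hf_ms = 0)
  b <- tachogram_to_beats(sp)
  iv <- nn_intervals(b)$nni_ms
  expect_equal(sum(iv) / 1000, b$beat_s[nrow(b)])
  expect_lte(b$beat_s[nrow(b)], 120)
  expect_gt(b$beat_s[nrow(b)], 120 - max(iv) / 1000)
})

test_that("zero-noise tachogram variance obeys Parseval over whole periods", {
  # 0.08 and 0.32 Hz share a 12.5 s period; 8 periods = 100 s
  sp <- scenario_spec("p", 100, 900, amp_lf_ms = 40, freq_lf_hz = 0.08,
                      amp_hf_ms = 25, freq_hf_hz = 0.32)
  t <- seq(0, 100 - 0.05, by = 0.05)
  v <- generate_tachogram(sp, t)
  expected <- 40^2 / 2 + 25^2 / 2
  expect_equal(mean((v - mean(v))^2), expected, tolerance = 0.01)
})

test_that("deep-breath artifacts add a unimodal excursion of the stated peak", {
  b <- tachogram_to_beats(scenario_spec("c", 60, 1000, amp_lf_ms = 0,
                                        amp_hf_ms = 0))
  art <- artifact_spec("deep_breath", onset_s = 20, duration_s = 10,
                       magnitude_ms = 300)
  out <- inject_artifact(b, art)
  iv0 <- nn_intervals(b)
  iv1 <- nn_intervals(out)
  expect_equal(max(iv1$nni_ms), 1300)
  # outside the window nothing changes
  outside <- iv0$t_mid_s < 20 | iv0$t_mid_s > 30
  expect_equal(iv1$nni_ms[outside][1:10], iv0$nni_ms[outside][1:10])
  # unimodal inside: increases then decreases
  inside <- iv1$nni_ms[!outside]
  peak <- which.max(inside)
  expect_true(all(diff(inside[1:peak]) >= 0))
  expect_true(all(diff(inside[peak:length(inside)]) <= 0))
})

test_that("ectopic artifacts rescale one interval pair and conserve its sum", {
  b <- tachogram_to_beats(scenario_spec("c", 30, 1000, amp_lf_ms = 0,
                                        amp_hf_ms = 0))
  out <- inject_artifact(b, artifact_spec("ectopic", onset_s = 10.5))
  iv <- nn_intervals(out)$nni_ms
  k <- which(iv < 999)
  expect_length(k, 1)
  expect_equal(iv[k], 600)
  expect_equal(iv[k + 1], 1400)
  expect_equal(iv[k] + iv[k + 1], 2000)
  expect_equal(sum(abs(iv - 1000) > 1e-9), 2)
})

test_that("zero-magnitude injection is the identity and bad onsets error", {
  b <- tachogram_to_beats(scenario_spec("c", 30, 1000, amp_lf_ms = 0,
                                        amp_hf_ms = 0))
  out <- inject_artifact(b, artifact_spec("bradycardia", onset_s = 10,
                                          magnitude_ms = 0))
  expect_equal(out$beat_s, b$beat_s)
  expect_error(inject_artifact(b, artifact_spec("deep_breath", onset_s = 99)),
               "beyond")
})

test_that("protocols concatenate segments with a correct label track", {
  mk <- function(lbl) scenario_spec(lbl, 300, 1000, amp_lf_ms = 0,
                                    amp_hf_ms = 0)
  rec <- generate_protocol(protocol_spec(list(mk("A"), mk("B"), mk("C")),
                                         seed = 4))
  expect_equal(rec$segments$label, c("A", "B", "C"))
  expect_equal(rec$segments$start_s, c(0, 300, 600))
  expect_equal(rec$segments$end_s, c(300, 600, 900))
  expect_true(all(diff(rec$beats$beat_s) > 0))
  expect_lte(rec$beats$beat_s[nrow(rec$beats)], 900)
})

test_that("the part1 preset emits the rest/math/rest/exercise/rest ordering", {
  pr <- part1_protocol(seed = 0)
  expect_equal(vapply(pr$segments, `[[`, character(1), "label"),
               c("Rest 1", "Math", "Rest 2", "Exercise", "Rest 3"))
  # effect directions: math raises LF and lowers HF amp; exercise lowers
  # HF amp and mean NNI relative to rest
  amp <- function(i, f) pr$segments[[i]][[f]]
  expect_gt(amp(2, "amp_lf_ms"), amp(1, "amp_lf_ms"))
  expect_lt(amp(2, "amp_hf_ms"), amp(1, "amp_hf_ms"))
  expect_lt(amp(4, "amp_hf_ms"), amp(1, "amp_hf_ms"))
  expect_lte(amp(4, "amp_lf_ms"), amp(1, "amp_lf_ms"))
  expect_lt(amp(4, "mean_nni_ms"), amp(1, "mean_nni_ms"))
})

test_that("protocol generation is byte-identical under the same seed", {
  r1 <- generate_protocol(part1_protocol(seed = 11, segment_s = 120,
                                         rest3_bradycardia = FALSE))
  r2 <- generate_protocol(part1_protocol(seed = 11, segment_s = 120,
                                         rest3_bradycardia = FALSE))
  expect_identical(r1$beats$beat_s, r2$beats$beat_s)
  expect_identical(r1$segments, r2$segments)
})

test_that("scenario invariants are enforced", {
  expect_error(scenario_spec("x", -1, 1000), "duration")
  expect_error(scenario_spec("x", 10, 1000, freq_lf_hz = 0.2), "0.15")
  expect_error(scenario_spec("x", 10, 1000, freq_hf_hz = 0.1), "0.15")
  expect_error(scenario_spec("x", 10, 500, amp_lf_ms = 300, amp_hf_ms = 100,
                             noise_sd_ms = 30), "positive")
  expect_error(protocol_spec(list()), "non-empty")
})

test_that("cohort simulation is reproducible and carries subject effects", {
  c1 <- simulate_part1_cohort(n_subjects = 2, seed = 5, segment_s = 60)
  c2 <- simulate_part1_cohort(n_subjects = 2, seed = 5, segment_s = 60)
  expect_identical(c1$beats[[1]]$beat_s, c2$beats[[1]]$beat_s)
  expect_identical(c1$lf_mult, c2$lf_mult)
  expect_false(identical(c1$beats[[1]]$beat_s, c1$beats[[2]]$beat_s))
})
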