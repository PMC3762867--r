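mk_trials <- function(video, audio, response) {
  data.frame(trial_id = seq_along(video), video_phoneme = video,
             audio_phoneme = audio, response = response,
             category = NA_character_, audio_onset = 0,
             stringsAsFactors = FALSE)
}

test_that("categorization applies the exact binomial rule per combination", {
  ## 10 of 12 video reports: P(X >= 10 | n = 12, p = .25) well under .05
  tail_p <- sum(dbinom(10:12, 12, 0.25))
  expect_lt(tail_p, 0.05)
  ph4 <- c("BA", "GA", "VA", "THA")
  tr <- mk_trials(rep("VA", 12), rep("BA", 12),
                  c(rep("VA", 10), "BA", "GA"))
  out <- categorize_trials(tr, phonemes = ph4)
  expect_true(all(out$category == "mcgurk"))

  ## uniform responses over 4 labels: neither test significant
  tr2 <- mk_trials(rep("VA", 12), rep("BA", 12), rep(ph4, 3))
  expect_true(all(categorize_trials(tr2, phonemes = ph4)$category ==
                    "unclassified"))

  ## audio-dominant reports
  tr3 <- mk_trials(rep("VA", 12), rep("BA", 12),
                   c(rep("BA", 10), "VA", "VA"))
  expect_true(all(categorize_trials(tr3)$category == "unmatched"))

  ## matched combinations are matched regardless of responses
  tr4 <- mk_trials(rep("GA", 6), rep("GA", 6),
                   c("BA", "BA", "BA", "VA", "VA", "THA"))
  expect_true(all(categorize_trials(tr4, phonemes = ph4)$category ==
                    "matched"))

  expect_error(categorize_trials(mk_trials("VA", "BA", "XX")),
               "label set")
})

test_that("categorization is invariant to trial order", {
  ds <- tiny_sim()
  out1 <- categorize_trials(ds$trials)
  perm <- rev(seq_len(nrow(ds$trials)))
  out2 <- categorize_trials(ds$trials[perm, ])
  expect_equal(out2$category[match(out1$trial_id, out2$trial_id)],
               out1$category)
})

test_that("per-category performance reports audio-report fractions and counts", {
  tr <- rbind(
    mk_trials(rep("BA", 4), rep("BA", 4), rep("BA", 4)),
    mk_trials(rep("VA", 12), rep("BA", 12), rep("VA", 12)))
  out <- categorize_trials(tr)
  perf <- performance_by_category(out)
  expect_equal(sort(perf$category), c("matched", "mcgurk"))
  expect_equal(perf$audio_accuracy[perf$category == "matched"], 1)
  expect_equal(perf$audio_accuracy[perf$category == "mcgurk"], 0)
  expect_equal(perf$n[perf$category == "mcgurk"], 12L)
  ## absent categories are absent, not zero
  expect_false("unmatched" %in% perf$category)
  expect_error(performance_by_category(tr), "categorized")
})

test_that("high-gamma electrode selection recovers the planted coding set", {
  sel_cfg <- spectrogram_config(step_s = 0.1, fmin = 75, fmax = 200)
  hits <- sapply(1:3, function(sd) {
    cfg <- sim_config(n_electrodes = 8L, n_trials_per_combo = 2L,
                      role_electrodes = c(posterior = 2L, middle = 5L,
                                          anterior = 7L), seed = 600 + sd)
    ds <- simulate_dataset(cfg)
    sel <- select_electrodes(ds$epochs, spec_cfg = sel_cfg)
    setequal(sel, c(2, 5, 7))
  })
  expect_true(all(hits))
})

test_that("a dominant electrode ranks first and ties break to lower index", {
  set.seed(8)
  t <- seq(-2, 1.5 - 1e-3, by = 1e-3)
  burst <- exp(-(t - 0.3)^2 / (2 * 0.1^2)) * sin(2 * pi * 140 * t)
  epochs <- lapply(1:4, function(i) {
    X <- matrix(rnorm(length(t) * 3, sd = 0.5), ncol = 3)
    X[, 2] <- X[, 2] + 10 * burst
    epoch_array(X, fs = 1000, t0 = -2)
  })
  sel <- select_electrodes(epochs, n_select = 2,
                           spec_cfg = spectrogram_config(step_s = 0.1,
                                                         fmin = 75,
                                                         fmax = 200))
  expect_equal(sel[1], 2L)
  expect_error(select_electrodes(epochs, n_select = 5), "fewer")
  expect_error(select_electrodes(epochs, n_select = 3,
                                 stg_mask = c(TRUE, TRUE, FALSE)),
               "fewer")
})
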