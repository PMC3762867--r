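## gaussian two-class toy features: rows = trials
toy_features <- function(n_per, d, sep, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * d), n_per, d),
             matrix(rnorm(n_per * d, mean = sep / sqrt(d)), n_per, d))
  list(X = X, labels = rep(c("A", "B"), each = n_per))
}

test_that("feature rows concatenate voltage and spectrogram cells per electrode", {
  ds <- tiny_sim()
  cfg <- feature_cfg()
  sub <- ds$trials[1:4, ]
  eps <- ds$epochs[1:4]
  fm <- build_features(eps, sub, electrodes = c(1, 2), spec_cfg = cfg)
  nv <- length(epoch_window_idx(eps[[1]], -1, 0.5))
  sp <- multitaper_spectrogram(eps[[1]], 1, cfg)
  nt <- sum(sp$times >= -1 & sp$times <= 0.5)
  expect_equal(ncol(fm$X), 2 * (nv + nt * length(sp$freqs)))
  expect_equal(nrow(fm$X), 4L)
  expect_equal(nrow(fm$catalog), ncol(fm$X))
  expect_equal(sum(fm$catalog$kind == "voltage"), 2 * nv)

  ## identical epochs give identical rows; permuting trials permutes rows
  eps2 <- eps; eps2[[2]] <- eps[[1]]
  fm2 <- build_features(eps2, sub, c(1, 2), spec_cfg = cfg)
  expect_identical(fm2$X[1, ], fm2$X[2, ])
  perm <- c(3, 1, 4, 2)
  fm3 <- build_features(eps[perm], sub[perm, ], c(1, 2), spec_cfg = cfg)
  expect_equal(fm3$X, fm$X[perm, ], ignore_attr = TRUE)

  eps_na <- eps; eps_na[2] <- list(NULL)
  expect_error(build_features(eps_na, sub, c(1, 2), spec_cfg = cfg),
               "missing epochs.*2")
})

test_that("well-separated classes classify perfectly, null classes near chance", {
  toy <- toy_features(10, 40, sep = 10)
  cm <- fit_predict_pairwise(toy$X, toy$labels, c("A", "B"), seed = 2)
  expect_equal(cm$accuracy, 1)
  expect_equal(rowSums(cm$counts), c(A = 10, B = 10))

  ## identical distributions: accuracy inside the binomial 95% band
  toy0 <- toy_features(20, 40, sep = 0, seed = 4)
  cm0 <- fit_predict_pairwise(toy0$X, toy0$labels, c("A", "B"), seed = 2)
  band <- qbinom(c(0.025, 0.975), 40, 0.5) / 40
  expect_gte(cm0$accuracy, band[1])
  expect_lte(cm0$accuracy, band[2])
})

test_that("label permutation yields chance-level accuracy on average", {
  toy <- toy_features(20, 30, sep = 6, seed = 6)
  set.seed(9)
  accs <- replicate(60, {
    fit_predict_pairwise(toy$X, sample(toy$labels), c("A", "B"),
                         seed = sample.int(1e6, 1))$accuracy
  })
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 2.576 * se + 0.02)
})

test_that("transforms are computed on the training fold only (no leakage)", {
  toy <- toy_features(10, 25, sep = 3, seed = 7)
  cm <- fit_predict_pairwise(toy$X, toy$labels, c("A", "B"), seed = 5)
  test_rows_fold1 <- cm$predictions$row[cm$predictions$fold == 1]
  X2 <- toy$X
  X2[test_rows_fold1, ] <- matrix(rnorm(length(test_rows_fold1) * 25,
                                        mean = 100),
                                  length(test_rows_fold1), 25)
  cm2 <- fit_predict_pairwise(X2, toy$labels, c("A", "B"), seed = 5)
  ## fold 1 is trained on the untouched fold-2 rows: identical transform
  expect_identical(cm$transforms[[1]], cm2$transforms[[1]])
  ## while the other fold's training data did change
  expect_false(identical(cm$transforms[[2]], cm2$transforms[[2]]))
})

test_that("degenerate inputs are rejected and dead columns dropped", {
  toy <- toy_features(6, 10, sep = 4, seed = 8)
  Xz <- cbind(toy$X, 0, 1)
  cm <- fit_predict_pairwise(Xz, toy$labels, c("A", "B"), seed = 1)
  expect_gte(cm$n_dropped_columns, 2L)
  expect_error(fit_predict_pairwise(toy$X[1:7, ], toy$labels[1:7],
                                    c("A", "B")),
               "at least 2 trials")
  expect_error(fit_predict_pairwise(toy$X, toy$labels[-1], c("A", "B")),
               "match")
})

## trials with a video-driven gaussian code and reciprocal McGurk structure
video_coded_set <- function(n_per_combo = 6, d = 30, sep = 6, seed = 10) {
  set.seed(seed)
  ph <- c("BA", "GA")
  combos <- expand.grid(video_phoneme = ph, audio_phoneme = ph,
                        stringsAsFactors = FALSE)
  trials <- combos[rep(1:4, each = n_per_combo), ]
  trials$trial_id <- seq_len(nrow(trials))
  trials$response <- trials$video_phoneme
  trials$category <- ifelse(trials$video_phoneme == trials$audio_phoneme,
                            "matched", "mcgurk")
  trials$audio_onset <- 0
  mu <- list(BA = rnorm(d), GA = rnorm(d))
  X <- t(sapply(trials$video_phoneme,
                function(v) sep * mu[[v]] / sqrt(d) + rnorm(d)))
  list(trials = trials, X = X)
}

test_that("McGurk cross-decoding follows the video code and inverts the audio score", {
  vs <- video_coded_set()
  dec <- decode_mcgurk_identity(vs$X, vs$trials)
  expect_gt(dec$video_accuracy, 0.5)
  expect_lt(dec$audio_accuracy, 0.5)
  ## the two scorings are exactly complementary on reciprocal trials
  expect_equal(dec$pair_accuracies$video_accuracy +
                 dec$pair_accuracies$audio_accuracy,
               rep(1, nrow(dec$pair_accuracies)))
})

test_that("confound balancing removes the incongruent-design audio leak", {
  vs <- video_coded_set(n_per_combo = 10, seed = 12)
  mk <- vs$trials$category == "mcgurk"
  dv <- decode_stimulus_identity(vs$X[mk, ], vs$trials[mk, ], "video",
                                 pair_scheme = "all", seed = 3)
  expect_gt(dv$mean_accuracy, 0.8)
  ## with only reciprocal incongruent trials the audio labels are a
  ## deterministic function of the video labels, so the un-balanced audio
  ## decoder rides the video code
  da_all <- decode_stimulus_identity(vs$X[mk, ], vs$trials[mk, ], "audio",
                                     pair_scheme = "all", seed = 3)
  expect_gt(da_all$mean_accuracy, 0.8)
  ## balancing leaves nothing: the balanced subset is empty here, which is
  ## the correct refusal for fully confounded designs
  expect_error(suppressWarnings(
    decode_stimulus_identity(vs$X[mk, ], vs$trials[mk, ], "audio",
                             pair_scheme = "balanced", seed = 3)),
    "no decodable pairs")
})

test_that("the regularized discriminant agrees with a reference LDA when well-conditioned", {
  set.seed(31)
  n <- 40; d <- 5
  X <- rbind(matrix(rnorm(n * d), n, d),
             matrix(rnorm(n * d, mean = 0.8), n, d))
  y <- rep(c("A", "B"), each = n)
  cm <- fit_predict_pairwise(X, y, c("A", "B"), seed = 3, ridge = 0.01)
  agree <- vapply(1:2, function(f) {
    pr <- cm$predictions[cm$predictions$fold == f, ]
    tr <- cm$predictions[cm$predictions$fold != f, ]
    fit <- MASS::lda(X[tr$row, ], grouping = tr$truth)
    ref <- as.character(predict(fit, X[pr$row, ])$class)
    mean(ref == pr$predicted)
  }, numeric(1))
  expect_gte(mean(agree), 0.95)
})
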