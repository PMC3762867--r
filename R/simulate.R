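#' Configuration for the synthetic ECoG generator
#'
#' The generator emulates a four-alternative audiovisual phoneme task: a
#' video of mouth articulation starts 1 s before a 500 ms audio phoneme, and
#' recording continues for 1 s after audio offset, so every epoch covers
#' [-2.0, +1.5] s around audio onset. Four video phonemes crossed with four
#' audio phonemes give 16 stimulus combinations, each presented
#' `n_trials_per_combo` times in randomized order.
#'
#' Each epoch contains, per electrode, unit-variance 1/f-shaped background
#' noise. Three designated electrodes (`role_electrodes`: posterior, middle,
#' anterior) additionally carry (i) a phoneme-specific spectro-temporal burst
#' pattern in the 75-200 Hz high-gamma band spanning video onset to phoneme
#' offset, whose identity follows the video or the audio stimulus per
#' `code_carrier`, and (ii) a phoneme-unspecific audio-onset-locked evoked
#' burst. During `coupling_interval` an extra copy of the coupling source's
#' pattern, delayed by `coupling_lag` and scaled by `coupling_gain`, is
#' injected into the coupling destination electrode, so that electrode
#' becomes the better-decoded site in that interval - the planted signature
#' that the directed information-tendency analysis recovers.
#'
#' Behavioral responses follow the audio identity on congruent trials (with
#' accuracy `congruent_accuracy`); on incongruent trials the video identity
#' is reported with probability `mcgurk_prob` (the McGurk regime), otherwise
#' the audio identity apart from a small `lapse` spread over the remaining
#' labels.
#'
#' @param n_electrodes number of electrodes (>= 3).
#' @param n_trials_per_combo trials per stimulus combination.
#' @param fs sampling rate in Hz; must satisfy Nyquist for the 200 Hz band.
#' @param phonemes character vector of phoneme labels (>= 2).
#' @param snr amplitude ratio of the phoneme-specific burst pattern to the
#'   unit-SD background noise.
#' @param evoked_snr amplitude ratio of the phoneme-unspecific audio-evoked
#'   burst to the background; evoked responses dominate stimulus-locked
#'   power in auditory cortex, and this is the signal the electrode
#'   selection criterion keys on.
#' @param code_carrier `"video"` or `"audio"`: which stimulus identity the
#'   neural pattern follows on incongruent trials.
#' @param coupling_lag delay (s) of the injected copy.
#' @param coupling_gain scale of the injected copy (>= 0; 0 disables
#'   coupling).
#' @param coupling_interval `"baseline"`, `"video_only"` or `"audio_video"`.
#' @param coupling_edge length-2 character vector (source role, destination
#'   role) among `"posterior"`, `"middle"`, `"anterior"`.
#' @param mcgurk_prob probability an incongruent trial's response follows the
#'   video identity.
#' @param congruent_accuracy probability a congruent trial's response is the
#'   (shared) stimulus identity.
#' @param lapse on incongruent non-McGurk outcomes, probability mass spread
#'   uniformly over the two labels that are neither video nor audio identity.
#' @param role_electrodes named integer vector giving the posterior, middle
#'   and anterior electrode indices.
#' @param epoch_window epoch extent (s) relative to audio onset.
#' @param seed integer master seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_electrodes = 8L,
                       n_trials_per_combo = 10L,
                       fs = 1000,
                       phonemes = c("BA", "GA", "VA", "THA"),
                       snr = 0.12,
                       evoked_snr = 0.5,
                       code_carrier = c("video", "audio"),
                       coupling_lag = 0.05,
                       coupling_gain = 1,
                       coupling_interval = c("video_only", "baseline",
                                             "audio_video"),
                       coupling_edge = c("posterior", "middle"),
                       mcgurk_prob = 0.8,
                       congruent_accuracy = 0.75,
                       lapse = 0.1,
                       role_electrodes = c(posterior = 3L, middle = 5L,
                                           anterior = 7L),
                       epoch_window = c(-2.0, 1.5),
                       seed = 1L) {
  cfg <- list(
    n_electrodes = as.integer(n_electrodes),
    n_trials_per_combo = as.integer(n_trials_per_combo),
    fs = fs,
    phonemes = as.character(phonemes),
    snr = snr,
    evoked_snr = evoked_snr,
    code_carrier = match.arg(code_carrier),
    coupling_lag = coupling_lag,
    coupling_gain = coupling_gain,
    coupling_interval = match.arg(coupling_interval),
    coupling_edge = coupling_edge,
    mcgurk_prob = mcgurk_prob,
    congruent_accuracy = congruent_accuracy,
    lapse = lapse,
    role_electrodes = role_electrodes,
    epoch_window = epoch_window,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

## highest frequency the burst templates may contain
.template_fmax <- 195

validate_sim_config <- function(cfg) {
  if (cfg$n_electrodes < 3L) stop_stgflow("n_electrodes must be >= 3")
  if (length(cfg$phonemes) < 2L) stop_stgflow("need at least 2 phonemes")
  if (cfg$fs < 2 * .template_fmax)
    stop_stgflow("fs = ", cfg$fs, " Hz violates Nyquist for the 75-200 Hz ",
                 "burst band (need fs >= ", 2 * .template_fmax, " Hz)")
  if (cfg$mcgurk_prob < 0 || cfg$mcgurk_prob > 1)
    stop_stgflow("mcgurk_prob must lie in [0, 1]")
  if (cfg$coupling_gain < 0) stop_stgflow("coupling_gain must be >= 0")
  dur <- diff(cfg$epoch_window)
  if (cfg$coupling_lag >= dur)
    stop_stgflow("coupling_lag must be shorter than the epoch (", dur, " s)")
  if (dur < 3.5 - 1e-9)
    stop_stgflow("epoch_window must cover at least [-2.0, +1.5] s")
  roles <- cfg$role_electrodes
  if (!all(c("posterior", "middle", "anterior") %in% names(roles)))
    stop_stgflow("role_electrodes must name posterior, middle and anterior")
  if (any(roles < 1L) || any(roles > cfg$n_electrodes) ||
      anyDuplicated(roles))
    stop_stgflow("role_electrodes must be distinct indices in 1..n_electrodes")
  if (!all(cfg$coupling_edge %in% names(roles)) ||
      length(cfg$coupling_edge) != 2L ||
      cfg$coupling_edge[1] == cfg$coupling_edge[2])
    stop_stgflow("coupling_edge must be two distinct roles")
  invisible(cfg)
}

#' Task interval bounds
#'
#' The three one-second analysis intervals of the task: `baseline`
#' ([-2, -1] s, no stimulus), `video_only` ([-1, 0] s, mouth articulation
#' only) and `audio_video` ([0, 1] s, concurrent audio and video).
#'
#' @param name interval name.
#' @return numeric length-2 vector (start, end) in seconds re audio onset.
#' @export
interval_bounds <- function(name = c("baseline", "video_only", "audio_video")) {
  switch(match.arg(name),
         baseline    = c(-2, -1),
         video_only  = c(-1, 0),
         audio_video = c(0, 1))
}

## 1/f-amplitude-shaped Gaussian noise, unit SD. Spectral shaping of white
## noise; power floor below `floor_hz` avoids the DC singularity.
one_over_f_noise <- function(n, fs, floor_hz = 1) {
  one_over_f_noise_matrix(n, fs, 1L, floor_hz)[, 1]
}

## matrix version: one independent noise column per electrode
one_over_f_noise_matrix <- function(n, fs, ncols, floor_hz = 1) {
  white <- matrix(rnorm(n * ncols), n, ncols)
  k <- 0:(n - 1)
  f <- k * fs / n
  f <- pmin(f, fs - f)                      # two-sided frequency magnitude
  shape <- 1 / sqrt(pmax(f, floor_hz))
  x <- Re(mvfft(mvfft(white) * shape, inverse = TRUE)) / n
  sweep(x, 2L, apply(x, 2L, sd), `/`)
}

## One fixed random spectro-temporal template per phoneme, drawn once per
## dataset: the (frequency, time-center, width, amplitude) envelope of a sum
## of Gabor-like components in the high-gamma band between video onset and
## phoneme offset. The envelope is the phoneme code; carrier phases are
## randomized per trial (high-gamma is not phase-locked), so identity
## information lives in spectro-temporal power, not in the raw waveform.
draw_templates <- function(phonemes, n_comp = 6L) {
  tpl <- lapply(phonemes, function(p) {
    data.frame(freq  = runif(n_comp, 80, .template_fmax),
               tc    = runif(n_comp, -0.85, 0.30),
               width = runif(n_comp, 0.08, 0.20),
               amp   = runif(n_comp, 0.5, 1.0))
  })
  names(tpl) <- phonemes
  tpl
}

## Precompute the phase-independent parts of a template on a time axis:
## component envelopes (zeroed outside the active span [-1, 0.5] s), carrier
## phase arguments, and the RMS normalization constant (expected RMS over
## the active span under random phases).
template_basis <- function(tpl, t) {
  active <- t >= -1 & t <= 0.5
  E <- matrix(0, length(t), nrow(tpl))
  S <- matrix(0, length(t), nrow(tpl))
  for (i in seq_len(nrow(tpl))) {
    E[, i] <- tpl$amp[i] * exp(-(t - tpl$tc[i])^2 / (2 * tpl$width[i]^2))
    S[, i] <- 2 * pi * tpl$freq[i] * t
  }
  E[!active, ] <- 0
  r <- sqrt(mean(rowSums(E[active, , drop = FALSE]^2)) / 2)
  list(E = E, S = S, norm = r)
}

## Single-trial realization of a template: random carrier phases, shared
## trial gain; unit expected RMS over the active span.
template_wave <- function(basis, phases, gain = 1) {
  w <- rowSums(basis$E * sin(sweep(basis$S, 2L, phases, `+`)))
  gain * w / basis$norm
}

## Phoneme-unspecific audio-onset-locked evoked burst (unit RMS over
## [0, 0.4] s); carries the 75-200 Hz power used for electrode selection but
## no identity information.
evoked_wave <- function(t) {
  w <- exp(-(t - 0.15)^2 / (2 * 0.06^2)) * sin(2 * pi * 120 * t)
  act <- t >= 0 & t <= 0.4
  r <- sqrt(mean(w[act]^2))
  w / r
}

## response model, see sim_config()
draw_response <- function(video, audio, phonemes, cfg) {
  if (video == audio) {
    if (runif(1) < cfg$congruent_accuracy) return(audio)
    return(sample(setdiff(phonemes, audio), 1L))
  }
  u <- runif(1)
  if (u < cfg$mcgurk_prob) return(video)
  others <- setdiff(phonemes, c(video, audio))
  if (length(others) > 0L && runif(1) < cfg$lapse)
    return(sample(others, 1L))
  audio
}

#' Simulate a trial-structured ECoG dataset with known ground truth
#'
#' See [sim_config()] for the generative model. Identical seeds yield
#' bit-identical datasets.
#'
#' @param cfg a [sim_config()].
#' @return A list of class `ecog_dataset` with elements `trials` (data.frame:
#'   trial_id, video_phoneme, audio_phoneme, response, category [NA until
#'   categorized], audio_onset), `epochs` (list of [epoch_array()], one per
#'   trial row), `templates` (the per-phoneme burst templates) and `config`.
#' @export
simulate_dataset <- function(cfg) {
  validate_sim_config(cfg)
  with_seed(cfg$seed, {
    ph <- cfg$phonemes
    templates <- draw_templates(ph)

    combos <- expand.grid(video_phoneme = ph, audio_phoneme = ph,
                          stringsAsFactors = FALSE)
    trials <- combos[rep(seq_len(nrow(combos)), each = cfg$n_trials_per_combo), ]
    trials <- trials[sample.int(nrow(trials)), , drop = FALSE]
    rownames(trials) <- NULL
    trials$trial_id <- seq_len(nrow(trials))
    trials$response <- NA_character_
    trials$category <- NA_character_
    trials$audio_onset <- 0

    n <- round(diff(cfg$epoch_window) * cfg$fs)
    t <- cfg$epoch_window[1] + (seq_len(n) - 1) / cfg$fs
    roles <- cfg$role_electrodes
    src <- roles[[cfg$coupling_edge[1]]]
    dst <- roles[[cfg$coupling_edge[2]]]
    cwin <- interval_bounds(cfg$coupling_interval)
    cmask <- as.numeric(t >= cwin[1] & t < cwin[2])
    evk <- evoked_wave(t)
    ## phase-independent template parts are fixed per dataset; per-trial
    ## randomness enters through carrier phases and a shared trial gain
    basis_by_ph <- lapply(templates, template_basis, t = t)
    basis_lag_by_ph <- lapply(templates, template_basis,
                              t = t - cfg$coupling_lag)
    n_comp <- nrow(templates[[1]])

    epochs <- vector("list", nrow(trials))
    for (i in seq_len(nrow(trials))) {
      vid <- trials$video_phoneme[i]
      aud <- trials$audio_phoneme[i]
      trials$response[i] <- draw_response(vid, aud, ph, cfg)

      carrier <- if (cfg$code_carrier == "video") vid else aud
      phases <- runif(n_comp, 0, 2 * pi)
      gain_t <- exp(rnorm(1, 0, 0.2) - 0.02)   # mild trial-to-trial gain
      pat <- template_wave(basis_by_ph[[carrier]], phases, gain_t)

      X <- one_over_f_noise_matrix(n, cfg$fs, cfg$n_electrodes)
      for (r in roles)
        X[, r] <- X[, r] + cfg$snr * pat + cfg$evoked_snr * evk
      if (cfg$coupling_gain > 0) {
        ## coherent delayed copy of the source burst (same phases and gain)
        lagged <- template_wave(basis_lag_by_ph[[carrier]], phases, gain_t)
        X[, dst] <- X[, dst] + cfg$snr * cfg$coupling_gain * lagged * cmask
      }
      epochs[[i]] <- epoch_array(X, fs = cfg$fs, t0 = cfg$epoch_window[1])
    }
    structure(list(trials = trials, epochs = epochs, templates = templates,
                   config = cfg),
              class = "ecog_dataset")
  })
}

#' Machine-readable summary of the effects planted by a configuration
#'
#' Used by parameter-recovery tests: which stimulus identity the neural code
#' follows, the coupling edge/interval/lag/gain, the designated electrode
#' roles, and the expected video-report rate on incongruent trials.
#'
#' @param cfg a [sim_config()].
#' @return a list of planted effects.
#' @export
ground_truth <- function(cfg) {
  validate_sim_config(cfg)
  list(
    code_carrier = cfg$code_carrier,
    coupling = list(source = cfg$coupling_edge[1],
                    destination = cfg$coupling_edge[2],
                    interval = cfg$coupling_interval,
                    lag = cfg$coupling_lag,
                    gain = cfg$coupling_gain,
                    present = cfg$coupling_gain > 0),
    roles = cfg$role_electrodes,
    expected_mcgurk_rate = cfg$mcgurk_prob,
    expected_video_gt_audio_decoding = cfg$code_carrier == "video",
    expected_positive_tendency =
      if (cfg$coupling_gain > 0)
        list(edge = paste(cfg$coupling_edge, collapse = "->"),
             interval = cfg$coupling_interval)
      else NULL
  )
}

#' @export
print.ecog_dataset <- function(x, ...) {
  cat(sprintf("<ecog_dataset> %d trials x %d electrodes, fs = %g Hz\n",
              nrow(x$trials), x$config$n_electrodes, x$config$fs))
  invisible(x)
}
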