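#' Rule for behavioral trial categorization
#'
#' "More often than chance" is operationalized as a one-sided exact binomial
#' test against the chance level, per stimulus combination.
#'
#' @param chance_level probability of a given report under guessing
#'   (1/number of alternatives; 0.25 for the four-button task).
#' @param alpha significance level of the exact binomial test.
#' @return a `category_rule` list.
#' @export
category_rule <- function(chance_level = 0.25, alpha = 0.05) {
  if (chance_level <= 0 || chance_level >= 1) stop_stgflow("chance_level must be in (0,1)")
  if (alpha <= 0 || alpha >= 1) stop_stgflow("alpha must be in (0,1)")
  structure(list(chance_level = chance_level, alpha = alpha),
            class = "category_rule")
}

#' Categorize trials into matched / McGurk / unmatched / unclassified
#'
#' Combinations with identical video and audio identity are `matched`.
#' Incongruent combinations are labeled `mcgurk` when the video identity is
#' reported more often than chance (one-sided exact binomial test),
#' `unmatched` when the audio identity is, and `unclassified` when neither
#' criterion is met. Combinations meeting both criteria are resolved by the
#' larger report fraction (ties fall to `unmatched`). All trials of a
#' combination share its category; the result is invariant to trial order.
#'
#' @param trials data.frame with `video_phoneme`, `audio_phoneme`,
#'   `response`.
#' @param rule a [category_rule()].
#' @param phonemes the task's phoneme label set; defaults to every label
#'   appearing as a video or audio stimulus.
#' @return `trials` with the `category` column filled.
#' @export
categorize_trials <- function(trials, rule = category_rule(),
                              phonemes = NULL) {
  ph <- phonemes %||%
    sort(unique(c(trials$video_phoneme, trials$audio_phoneme)))
  if (anyNA(trials$response) || !all(trials$response %in% ph))
    stop_stgflow("responses must all be drawn from the phoneme label set")
  key <- paste(trials$video_phoneme, trials$audio_phoneme, sep = "|")
  trials$category <- NA_character_
  for (k in unique(key)) {
    idx <- which(key == k)
    vid <- trials$video_phoneme[idx[1]]
    aud <- trials$audio_phoneme[idx[1]]
    if (vid == aud) {
      trials$category[idx] <- "matched"
      next
    }
    n <- length(idx)
    kv <- sum(trials$response[idx] == vid)
    ka <- sum(trials$response[idx] == aud)
    pv <- binom.test(kv, n, p = rule$chance_level,
                     alternative = "greater")$p.value
    pa <- binom.test(ka, n, p = rule$chance_level,
                     alternative = "greater")$p.value
    sig_v <- pv < rule$alpha
    sig_a <- pa < rule$alpha
    trials$category[idx] <-
      if (sig_v && sig_a) (if (kv > ka) "mcgurk" else "unmatched")
      else if (sig_v) "mcgurk"
      else if (sig_a) "unmatched"
      else "unclassified"
  }
  trials
}

#' Per-category behavioral performance
#'
#' Fraction of trials whose response equals the audio identity, per category
#' present in the data; on McGurk trials this is the rate of (non-illusory)
#' correct audio reports. Absent categories are absent from the result, not
#' zero.
#'
#' @param trials categorized trials.
#' @return data.frame with `category`, `n`, `audio_accuracy`.
#' @export
performance_by_category <- function(trials) {
  if (anyNA(trials$category))
    stop_stgflow("trials must be categorized first (see categorize_trials)")
  cats <- intersect(c("matched", "mcgurk", "unmatched", "unclassified"),
                    unique(trials$category))
  out <- do.call(rbind, lapply(cats, function(cc) {
    sub <- trials[trials$category == cc, ]
    data.frame(category = cc, n = nrow(sub),
               audio_accuracy = mean(sub$response == sub$audio_phoneme))
  }))
  rownames(out) <- NULL
  out
}

#' Data-driven electrode selection by high-gamma power
#'
#' Selects the `n_select` electrodes with the largest trial-averaged mean
#' 75-200 Hz spectral power during the 1 s auditory stimulus window, in rank
#' order; ties break toward the lower electrode index. When a logical
#' `stg_mask` is supplied (the simulation stand-in for the anatomical
#' superior-temporal-gyrus constraint) only flagged electrodes compete.
#'
#' @param epochs list of [epoch_array()] at the analysis sampling rate.
#' @param n_select number of electrodes to pick.
#' @param band frequency band (Hz).
#' @param window time window (s re audio onset).
#' @param spec_cfg [spectrogram_config()] used for the power estimate; the
#'   default uses a coarser 50 ms step, which is sufficient for a windowed
#'   mean.
#' @param stg_mask optional logical vector flagging candidate electrodes.
#' @return integer vector of selected electrode indices, best first, with the
#'   per-electrode mean band power as the `"band_power"` attribute.
#' @export
select_electrodes <- function(epochs, n_select = 3L, band = c(75, 200),
                              window = c(0, 1),
                              spec_cfg = spectrogram_config(step_s = 0.05,
                                                            fmin = band[1],
                                                            fmax = band[2]),
                              stg_mask = NULL) {
  ne <- ncol(epochs[[1]]$data)
  cand <- seq_len(ne)
  if (!is.null(stg_mask)) {
    if (length(stg_mask) != ne)
      stop_stgflow("stg_mask must have one entry per electrode")
    cand <- which(stg_mask)
  }
  if (length(cand) < n_select)
    stop_stgflow("fewer candidate electrodes (", length(cand),
                 ") than n_select (", n_select, ")")
  pow <- sapply(cand, function(e) {
    mean(vapply(epochs, function(ep) {
      band_power(multitaper_spectrogram(ep, e, spec_cfg),
                 band[1], band[2], window[1], window[2])
    }, numeric(1)))
  })
  ord <- order(-pow, cand)
  sel <- cand[ord][seq_len(n_select)]
  attr(sel, "band_power") <- setNames(pow, cand)
  sel
}

#' Assign posterior / middle / anterior roles to selected electrodes
#'
#' For simulated data the generator's designated roles are used when they are
#' a subset of the selection. Otherwise the middle electrode (the one
#' proximal to primary auditory cortex) is identified physiologically as the
#' selected electrode with the largest audio-evoked potential (mean absolute
#' trial-averaged voltage in the 0-0.4 s window), and the remaining two keep
#' their selection rank order as posterior then anterior.
#'
#' @param dataset an `ecog_dataset` (or any list with `epochs` and optional
#'   `config$role_electrodes`).
#' @param selected integer vector of selected electrode indices.
#' @return named integer vector with entries posterior, middle, anterior.
#' @export
assign_roles <- function(dataset, selected) {
  truth <- dataset$config$role_electrodes
  if (!is.null(truth) && all(truth %in% selected)) return(truth)
  if (length(selected) != 3L) stop_stgflow("role assignment needs 3 electrodes")
  evoked <- sapply(selected, function(e) {
    m <- rowMeans(sapply(dataset$epochs, function(ep) ep$data[, e]))
    idx <- epoch_window_idx(dataset$epochs[[1]], 0, 0.4)
    mean(abs(m[idx]))
  })
  middle <- selected[which.max(evoked)]
  rest <- setdiff(selected, middle)
  c(posterior = rest[1], middle = middle, anterior = rest[2])
}
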