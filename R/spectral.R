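## Multitaper spectrogram estimation and the difference-spectrogram statistic.

.spectral_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed from the standard symmetric-tridiagonal eigenproblem for the
#' Slepian sequences, with the usual sign convention (symmetric tapers have
#' positive mean, antisymmetric tapers start with a positive lobe). Tapers
#' are orthonormal columns. Results are cached per (n, nw, k).
#'
#' @param n taper length in samples.
#' @param nw time-bandwidth product.
#' @param k number of leading tapers; must satisfy `k <= 2 * nw - 1`.
#' @return an `n x k` matrix of tapers.
#' @export
dpss_tapers <- function(n, nw, k) {
  if (k > 2 * nw - 1)
    stop_stgflow("n_tapers = ", k, " exceeds the Slepian bound 2*NW-1 = ",
                 2 * nw - 1)
  key <- paste(n, nw, k, sep = "_")
  if (!is.null(.spectral_cache[[key]])) return(.spectral_cache[[key]])
  w <- nw / n
  tt <- 0:(n - 1)
  d <- ((n - 1 - 2 * tt) / 2)^2 * cos(2 * pi * w)
  e <- tt[-1] * (n - tt[-1]) / 2
  A <- diag(d)
  A[cbind(2:n, 1:(n - 1))] <- e
  A[cbind(1:(n - 1), 2:n)] <- e
  v <- eigen(A, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    s <- sum(v[, j])
    if (abs(s) > 1e-10) v[, j] <- v[, j] * sign(s)
    else v[, j] <- v[, j] * sign(v[2, j])
  }
  .spectral_cache[[key]] <- v
  v
}

#' Spectrogram estimation parameters
#'
#' Defaults: 500 ms moving window, 10 ms step, time-bandwidth product 7 with
#' the 11 leading Slepian tapers (K = 11 satisfies K <= 2NW - 1).
#'
#' @param window_s moving-window length (s).
#' @param step_s window step (s); must not exceed `window_s`.
#' @param time_bandwidth Slepian time-bandwidth product NW.
#' @param n_tapers number of leading tapers K.
#' @param fmin,fmax frequency band retained (Hz).
#' @return a `spectrogram_config` list.
#' @export
spectrogram_config <- function(window_s = 0.5, step_s = 0.010,
                               time_bandwidth = 7, n_tapers = 11,
                               fmin = 0, fmax = Inf) {
  if (step_s > window_s) stop_stgflow("step_s must be <= window_s")
  if (n_tapers > 2 * time_bandwidth - 1)
    stop_stgflow("n_tapers must be <= 2 * time_bandwidth - 1")
  structure(list(window_s = window_s, step_s = step_s,
                 time_bandwidth = time_bandwidth, n_tapers = n_tapers,
                 fmin = fmin, fmax = fmax),
            class = "spectrogram_config")
}

#' Spectrogram container
#'
#' @param power time x frequency matrix of power spectral density
#'   (microvolt^2/Hz before normalization, z-units after).
#' @param times window-center times (s re audio onset), strictly increasing.
#' @param freqs frequencies (Hz).
#' @param normalized has [normalize_by_band()] been applied?
#' @return a `spectrogram` object.
#' @export
spectrogram <- function(power, times, freqs, normalized = FALSE) {
  if (!is.matrix(power) || nrow(power) != length(times) ||
      ncol(power) != length(freqs))
    stop_stgflow("power must be a time x frequency matrix matching axes")
  if (any(diff(times) <= 0)) stop_stgflow("times must be strictly increasing")
  if (!normalized && any(power < 0))
    stop_stgflow("unnormalized power must be non-negative")
  structure(list(power = power, times = times, freqs = freqs,
                 normalized = normalized),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d windows x %d freqs, t = [%.3f, %.3f] s, f = [%g, %g] Hz%s\n",
              nrow(x$power), ncol(x$power), min(x$times), max(x$times),
              min(x$freqs), max(x$freqs),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Multitaper spectrogram of one electrode
#'
#' Each time-frequency cell is the average over `n_tapers` Slepian-tapered
#' periodograms of the corresponding window. Only windows fully inside the
#' epoch are used (no padding); window centers define the time axis. Power is
#' one-sided spectral density scaled so that the integral over frequency
#' equals the signal variance (Parseval).
#'
#' @param epoch an [epoch_array()].
#' @param electrode electrode (column) index.
#' @param cfg a [spectrogram_config()].
#' @return a [spectrogram()].
#' @export
multitaper_spectrogram <- function(epoch, electrode, cfg = spectrogram_config()) {
  x <- epoch$data[, electrode]
  fs <- epoch$fs
  n <- round(cfg$window_s * fs)
  step <- max(1L, round(cfg$step_s * fs))
  if (length(x) < n)
    stop_stgflow("epoch too short for a single ", cfg$window_s, " s window")
  starts <- seq(1L, length(x) - n + 1L, by = step)
  centers <- epoch$t0 + (starts - 1 + (n - 1) / 2) / fs
  tapers <- dpss_tapers(n, cfg$time_bandwidth, cfg$n_tapers)
  W <- matrix(x[outer(0:(n - 1L), starts, `+`)], nrow = n)
  nf <- n %/% 2L + 1L
  P <- matrix(0, length(starts), nf)
  for (k in seq_len(cfg$n_tapers)) {
    Xf <- mvfft(W * tapers[, k])
    P <- P + t(Mod(Xf[seq_len(nf), , drop = FALSE])^2)
  }
  P <- P / cfg$n_tapers
  onesided <- rep(2, nf)
  onesided[1] <- 1
  if (n %% 2L == 0L) onesided[nf] <- 1
  P <- sweep(P, 2L, onesided, `*`) / fs
  freqs <- (seq_len(nf) - 1) * fs / n
  keep <- freqs >= cfg$fmin & freqs <= cfg$fmax
  if (!any(keep)) stop_stgflow("no frequencies inside [fmin, fmax]")
  spectrogram(P[, keep, drop = FALSE], times = centers, freqs = freqs[keep])
}

#' Per-frequency-band z-normalization against a baseline interval
#'
#' Each frequency band (column over time) is converted to z-units using that
#' band's mean and SD over the baseline interval. The default baseline is the
#' pre-video segment (t <= -1 s), the only stimulus-free part of the epoch.
#'
#' @param spec an unnormalized [spectrogram()].
#' @param baseline length-2 interval (s) of baseline window centers.
#' @return the normalized [spectrogram()].
#' @export
normalize_by_band <- function(spec, baseline = c(-Inf, -1)) {
  if (spec$normalized) stop_stgflow("spectrogram already normalized")
  bidx <- spec$times >= baseline[1] & spec$times <= baseline[2]
  if (!any(bidx))
    stop_stgflow("baseline interval [", baseline[1], ", ", baseline[2],
                 "] contains no spectrogram windows")
  B <- spec$power[bidx, , drop = FALSE]
  mu <- colMeans(B)
  sdv <- apply(B, 2L, sd)
  Z <- spec$power
  for (j in seq_along(spec$freqs)) {
    if (sdv[j] == 0) {
      if (all(spec$power[, j] == mu[j])) {
        Z[, j] <- 0               # constant band: z of a constant is 0
      } else {
        stop_stgflow("zero baseline variance in frequency band ",
                     spec$freqs[j], " Hz")
      }
    } else {
      Z[, j] <- (spec$power[, j] - mu[j]) / sdv[j]
    }
  }
  spectrogram(Z, spec$times, spec$freqs, normalized = TRUE)
}

#' Mean power over a time-frequency rectangle
#'
#' @param spec an unnormalized [spectrogram()].
#' @param f_lo,f_hi frequency bounds (Hz, inclusive).
#' @param t_lo,t_hi time bounds (s, inclusive of window centers).
#' @return scalar mean power.
#' @export
band_power <- function(spec, f_lo, f_hi, t_lo, t_hi) {
  if (spec$normalized)
    stop_stgflow("band_power is defined on un-normalized power")
  fi <- spec$freqs >= f_lo & spec$freqs <= f_hi
  ti <- spec$times >= t_lo & spec$times <= t_hi
  if (!any(fi) || !any(ti))
    stop_stgflow("empty time-frequency selection")
  mean(spec$power[ti, fi])
}

#' Mean of the absolute difference between two spectrograms
#'
#' The difference-spectrogram statistic: the mean over all cells in
#' [t_lo, t_hi] of |A - B|. Symmetric in its arguments, zero iff the
#' spectrograms agree on the window.
#'
#' @param spec_a,spec_b two spectrograms on identical time/frequency grids,
#'   both covering the window.
#' @param t_lo,t_hi comparison window (s), default -1 to +1 s around audio
#'   onset.
#' @return scalar statistic.
#' @export
difference_spectrogram_stat <- function(spec_a, spec_b, t_lo = -1, t_hi = 1) {
  if (!isTRUE(all.equal(spec_a$times, spec_b$times)) ||
      !isTRUE(all.equal(spec_a$freqs, spec_b$freqs)))
    stop_stgflow("spectrograms are on different time/frequency grids")
  ti <- spec_a$times >= t_lo & spec_a$times <= t_hi
  if (!any(ti)) stop_stgflow("no windows inside the comparison interval")
  if (min(spec_a$times) > t_lo || max(spec_a$times) < t_hi)
    stop_stgflow("spectrograms do not cover [", t_lo, ", ", t_hi, "] s")
  mean(abs(spec_a$power[ti, , drop = FALSE] -
           spec_b$power[ti, , drop = FALSE]))
}

#' Average spectrograms across trials
#'
#' @param specs list of spectrograms on a common grid.
#' @return the element-wise mean [spectrogram()].
#' @export
average_spectrograms <- function(specs) {
  if (length(specs) == 0L) stop_stgflow("no spectrograms to average")
  ref <- specs[[1L]]
  for (s in specs[-1L]) {
    if (!isTRUE(all.equal(s$times, ref$times)) ||
        !isTRUE(all.equal(s$freqs, ref$freqs)) ||
        s$normalized != ref$normalized)
      stop_stgflow("spectrograms must share grids and normalization state")
  }
  P <- Reduce(`+`, lapply(specs, `[[`, "power")) / length(specs)
  spectrogram(P, ref$times, ref$freqs, normalized = ref$normalized)
}
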