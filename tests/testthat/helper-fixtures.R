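## shared fixtures, built in code and memoized across test files

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  hit <- get0(key, envir = .fixture_env, ifnotfound = NULL)
  if (!is.null(hit)) return(hit)
  val <- force(expr)
  assign(key, val, envir = .fixture_env)
  val
}

## small, fast configuration: 3 electrodes, 3 trials/combination
tiny_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_electrodes = 3L, n_trials_per_combo = 3L,
         role_electrodes = c(posterior = 1L, middle = 2L, anterior = 3L)),
    list(...))
  do.call(sim_config, args)
}

tiny_sim <- function() memo("tiny_sim", simulate_dataset(tiny_cfg(seed = 5)))

## default-condition dataset shared by heavier tests
default_sim <- function() memo("default_sim",
                               simulate_dataset(sim_config(seed = 1)))

feature_cfg <- function() spectrogram_config(fmin = 75, fmax = 200,
                                             step_s = 0.05)

## a deterministic toy spectrogram for arithmetic checks
toy_spectrogram <- function(power, t0 = -2, dt = 0.25) {
  spectrogram(power, times = t0 + (seq_len(nrow(power)) - 1) * dt,
              freqs = seq_len(ncol(power)) * 10)
}

## random probability array over (S, Rx, Ry)
random_joint <- function(nl = 2L) {
  p <- array(rexp(nl^3), dim = c(nl, nl, nl))
  p <- p / sum(p)
  structure(p, class = c("joint_sr", "array"))
}

## independent reference for I(S;Rx|Ry): direct plug-in double sum over the
## definition, no entropy decomposition
cmi_direct <- function(p) {
  p <- unclass(p)
  py <- apply(p, 3, sum)
  psy <- apply(p, c(1, 3), sum)
  pxy <- apply(p, c(2, 3), sum)
  tot <- 0
  for (s in seq_len(dim(p)[1])) for (x in seq_len(dim(p)[2]))
    for (y in seq_len(dim(p)[3])) {
      if (p[s, x, y] > 0)
        tot <- tot + p[s, x, y] *
          log2(p[s, x, y] * py[y] / (psy[s, y] * pxy[x, y]))
    }
  tot
}
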