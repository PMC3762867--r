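## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `code` under a fixed RNG state without clobbering the caller's
## stream. All package-level randomness funnels through here.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## Deterministic per-component sub-seeds below 2^31, so independent stages
## draw from decorrelated streams under one master seed.
sub_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

stop_stgflow <- function(...) stop(..., call. = FALSE)
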