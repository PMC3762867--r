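## Shared settings for the numbered analysis scripts. Every script can be
## run from the repository root with Rscript analysis/<nn>_<name>.R; they
## chain through files under results/.

library(stgflow)

SEED <- 1L
DATA_DIR <- "results/dataset"
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

feature_config <- function() spectrogram_config(fmin = 75, fmax = 200,
                                                step_s = 0.05)

load_prepped <- function() {
  ds <- read_dataset(DATA_DIR)
  ds$config <- ds$config %||% NULL
  ds <- structure(ds, class = "ecog_dataset")
  ds$trials <- categorize_trials(ds$trials)
  ds
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_table <- function(df, name) {
  path <- file.path(RESULTS_DIR, name)
  write.csv(df, path, row.names = FALSE)
  message("  wrote ", path)
}
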