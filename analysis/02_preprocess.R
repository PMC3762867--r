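## Preprocess (common-average reference; anti-alias filtering/decimation
## would apply for >1 kHz recordings) and categorize trials behaviorally
## into matched / McGurk / unmatched combinations.

source("analysis/00_common.R")

ds <- read_dataset(DATA_DIR)
ds <- structure(ds, class = "ecog_dataset")
ds <- preprocess_dataset(ds)
ds$trials <- categorize_trials(ds$trials)
write_dataset(ds, DATA_DIR)

perf <- performance_by_category(ds$trials)
write_table(ds$trials, "trials.csv")
write_table(perf, "performance.csv")

message("per-category audio-report accuracy:")
for (i in seq_len(nrow(perf)))
  message(sprintf("  %-12s %5.1f%%  (N = %d)", perf$category[i],
                  100 * perf$audio_accuracy[i], perf$n[i]))
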