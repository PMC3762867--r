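## Behavioral hypothesis tests: one-way ANOVA of per-trial audio-report
## correctness across categories, with Tukey-Kramer pairwise contrasts.
## McGurk trials should show a large deficit relative to matched trials.

source("analysis/00_common.R")

ds <- load_prepped()
tests <- anova_tukey(ds$trials$response == ds$trials$audio_phoneme,
                     ds$trials$category)
write_table(tests, "behavior_tests.csv")

message("behavioral tests:")
for (i in seq_len(nrow(tests)))
  message(sprintf("  %-14s %-28s stat %8.3f  p %.3g", tests$test[i],
                  tests$comparison[i], tests$statistic[i], tests$p_value[i]))
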