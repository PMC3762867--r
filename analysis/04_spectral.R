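## Difference-spectrogram analysis: are McGurk-condition spectrograms closer
## to the matched condition sharing their video identity or the one sharing
## their audio identity? Mean |difference| over [-1, 1] s per electrode and
## combination, compared with a Mann-Whitney U test.

source("analysis/00_common.R")

ds <- load_prepped()
roles <- ds$config$role_electrodes
dsp <- diffspec_comparison(ds, electrodes = unname(roles))
mw <- mannwhitney_diffspec(dsp$same_video, dsp$same_audio)
write_table(dsp, "diffspec.csv")
write_table(mw, "diffspec_test.csv")

message(sprintf("same-video difference %.2f vs same-audio %.2f (z-units), Mann-Whitney p = %.3g",
                mean(dsp$same_video), mean(dsp$same_audio), mw$p_value))
message(if (mean(dsp$same_video) < mean(dsp$same_audio))
  "-> McGurk spectrograms track the VIDEO identity" else
  "-> McGurk spectrograms track the AUDIO identity")
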