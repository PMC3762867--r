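## Single-trial decoding. Electrodes are selected by 75-200 Hz power during
## the audio window; discriminants trained on matched trials are applied to
## reciprocal McGurk trials and scored against the video and the audio
## labeling; per-attribute decodability is also estimated with the
## confound-balanced scheme. Wilcoxon signed-rank tests compare per-pair
## accuracies with the 50% chance level.

source("analysis/00_common.R")

ds <- load_prepped()
selected <- select_electrodes(ds$epochs)
roles <- assign_roles(ds, selected)
role_vec <- unname(roles[c("posterior", "middle", "anterior")])
write_table(data.frame(rank = seq_along(selected), electrode = selected,
                       role = names(roles)[match(selected, roles)]),
            "selection.csv")
message(sprintf("selected electrodes (by high-gamma power): %s",
                paste(selected, collapse = ", ")))

fc <- feature_config()
spectro <- compute_spectrograms(ds$epochs, role_vec, fc)
features <- build_features(ds$epochs, ds$trials, role_vec, spec_cfg = fc,
                           spectrograms = spectro)

dec <- decode_mcgurk_identity(features, ds$trials)
write_table(dec$pair_accuracies, "decoding_accuracy.csv")
tests <- rbind(wilcoxon_vs_chance(dec$pair_accuracies$video_accuracy),
               wilcoxon_vs_chance(dec$pair_accuracies$audio_accuracy))
tests$comparison <- paste(c("video-identity", "audio-identity"),
                          tests$comparison)
write_table(tests, "decoding_tests.csv")
message(sprintf("McGurk trials: video-identity %.1f%%, audio-identity %.1f%% (chance 50%%)",
                100 * dec$video_accuracy, 100 * dec$audio_accuracy))

by_target <- lapply(c(video = "video", audio = "audio"), function(tg)
  decode_stimulus_identity(features, ds$trials, target = tg,
                           category = "mcgurk", seed = SEED))
bt <- do.call(rbind, lapply(names(by_target), function(tg) {
  d <- by_target[[tg]]$pair_accuracies; d$target <- tg; d
}))
write_table(bt, "decoding_by_target.csv")
message(sprintf("confound-balanced decoding: video %.1f%%, audio %.1f%%",
                100 * by_target$video$mean_accuracy,
                100 * by_target$audio$mean_accuracy))
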