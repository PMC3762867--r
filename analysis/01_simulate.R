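## Generate the synthetic audiovisual ECoG dataset used by all later
## scripts: 4 video x 4 audio phonemes, 10 trials per combination, video
## onset 1 s before a 500 ms audio phoneme, high-gamma phoneme codes on
## three designated electrodes following the video identity, and a lagged
## posterior-to-middle coupling during the video-only interval.

source("analysis/00_common.R")

cfg <- sim_config(seed = SEED)
ds <- simulate_dataset(cfg)
write_dataset(ds, DATA_DIR)

message(sprintf("simulated %d trials x %d electrodes at %g Hz -> %s",
                nrow(ds$trials), cfg$n_electrodes, cfg$fs, DATA_DIR))
gt <- ground_truth(cfg)
message(sprintf("planted: %s-driven code; coupling %s during %s (gain %g, lag %g s)",
                gt$code_carrier, gt$expected_positive_tendency$edge,
                gt$coupling$interval, gt$coupling$gain, gt$coupling$lag))
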