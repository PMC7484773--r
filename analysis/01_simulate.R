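#!/usr/bin/env Rscript
# Step 1 — generate the two synthetic study trials.
#
# Neither of the motivating text-messaging trials has public participant
# data, so the whole workflow runs on synthetic stand-ins that copy only the
# designs: a 535-participant two-arm smoking-cessation trial with heavy
# follow-up attrition, and a 560-participant nested experiment with a null
# effect on pressing a link in a text message.

suppressPackageStartupMessages(library(seqmonitor))
dir.create("results", showWarnings = FALSE)

for (preset in c("smoking_trial", "alcohol_message_experiment")) {
  run <- synthetic_trial_preset(preset)
  csv <- file.path("results", paste0(preset, ".csv"))
  write_trial_csv(run$records, csv)
  write_run_manifest(file.path("results", paste0(preset, "_manifest.json")),
                     step = "simulate",
                     config = unclass(run$config)[c("n", "p_control", "true_or",
                                                    "allocation",
                                                    "attrition_prob", "seed")],
                     seeds = list(trial = run$config$seed),
                     outputs = csv)
  cat(sprintf("%s: %d participants, %d responders, true OR %.2f -> %s\n",
              preset, nrow(run$records), sum(run$records$responded),
              run$config$true_or, csv))
}
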