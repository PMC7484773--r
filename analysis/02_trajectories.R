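#!/usr/bin/env Rscript
# Step 2 — the P value line dance: recompute OR / CI / P at every responder
# and find each crossing of the significance line.
#
# Run after analysis/01_simulate.R.

suppressPackageStartupMessages(library(seqmonitor))
dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

for (preset in c("smoking_trial", "alcohol_message_experiment")) {
  records <- read_trial_csv(file.path("results", paste0(preset, ".csv")))
  traj <- trajectory(records)  # a look at every responder, alpha = .05
  write_trajectory_csv(traj, file.path("results", paste0(preset, "_trajectory.csv")))
  crossings <- find_crossings(traj)
  utils::write.csv(crossings,
                   file.path("results", paste0(preset, "_crossings.csv")),
                   row.names = FALSE)
  naive <- stop_at_first_crossing(traj)
  final <- traj[nrow(traj), ]
  cat(sprintf("\n%s: %d looks, %d significance-line crossings\n",
              preset, nrow(traj), nrow(crossings)))
  cat(sprintf("  final look (n=%d): OR %.2f, P=%.3f\n", final$n, final$or, final$p))
  if (is.null(naive)) {
    cat("  naive peeking never stops: P never crosses .05\n")
  } else {
    cat(sprintf("  naive peeking would stop at n=%d with OR %.2f (P=%.3f)\n",
                naive$n, naive$or, naive$p))
  }
  fig <- plot_trajectory(traj)
  ggplot2::ggsave(file.path("results/figures", paste0(preset, "_trajectory.png")),
                  fig, width = 7, height = 6, dpi = 150)
}
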