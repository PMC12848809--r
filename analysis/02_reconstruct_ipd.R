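#!/usr/bin/env Rscript

# Stage 2: Guyot reconstruction. Reads each digitized curve/risk pair,
# rebuilds pseudo individual-patient data, writes the IPD CSVs and a QC
# table of reconstruction fidelity. The CSV dialect carries no reported
# event totals, so reconstruction runs without the final-interval
# event-count adjustment — the situation of a trial whose median OS was
# not reached.

library(pd1cea)

cfg <- read_config("results/config.yaml")
dir.create("results/ipd", recursive = TRUE, showWarnings = FALSE)

qc <- NULL
for (s in names(cfg$strategies)) {
  for (e in c("PFS", "OS")) {
    curve <- read_digitized_curve("results/curves", s, e)
    rec <- validate_reconstruction(curve, reconstruct_ipd(curve))
    write_ipd(rec$ipd, sprintf("results/ipd/%s_%s_ipd.csv", s, e))
    qc <- rbind(qc, data.frame(strategy = s, endpoint = e,
                               n = nrow(rec$ipd),
                               events = rec$events_reconstructed,
                               rmse_survival = rec$rmse_survival,
                               max_abs_dev = rec$max_abs_dev,
                               clamped = rec$clamped))
  }
}
write.csv(qc, "results/reconstruction_qc.csv", row.names = FALSE)
cat("Reconstruction fidelity (KM of pseudo-IPD vs digitized coordinates):\n")
print(qc, row.names = FALSE, digits = 3)
stopifnot(all(qc$max_abs_dev <= 0.02))
cat("All curves reconstructed within 0.02 absolute survival deviation.\n")
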