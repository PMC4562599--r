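#!/usr/bin/env Rscript
# Simulates dilution-potential recording sets for an anion-selective channel
# (P_Cl/P_Na = 18.8) and a cation-selective channel (P_Cl/P_Na = 0.19):
# 5 replicates x 7 holding potentials x 3 NaCl dilutions each, with
# desensitizing kinetics, lognormal replicate amplitudes and trace noise.
# Writes tidy trace CSVs with provenance sidecars under results/.
suppressPackageStartupMessages(library(ghkselect))

seed <- 42L
expt <- default_dilution_experiment()
conds <- lapply(expt$externals, function(sol) {
  list(sol_out = sol, sol_in = expt$internal)
})

for (spec in list(list(tag = "anion", ratio = 18.8),
                  list(tag = "cation", ratio = 0.19))) {
  ch <- channel_model(c(Na = 1, Cl = spec$ratio), conductance_scale = 0.07)
  rs <- simulate_experiment(
    ch, conds,
    protocol = voltage_protocol(),
    kinetics = kinetics_spec(tau_d_ms = 100, plateau_fraction = 0.3),
    noise = noise_spec(trace_sd = 5, amplitude_cv = 0.2,
                       seed = seed + match(spec$tag, c("anion", "cation"))),
    n_replicates = 5)
  dir.create(file.path("results", spec$tag), showWarnings = FALSE,
             recursive = TRUE)
  path <- file.path("results", spec$tag, "traces.csv")
  write_traces_csv(rs, path)
  cat(sprintf("%s channel (P_Cl/P_Na = %g): %d sweeps -> %s\n", spec$tag,
              spec$ratio,
              nrow(unique(as.data.frame(rs)[, c("condition_id",
                                                "replicate_id",
                                                "holding_mV")])), path))
}
cat("Each sweep: 50 ms baseline + 250 ms agonist window at 1 ms sampling.\n")
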