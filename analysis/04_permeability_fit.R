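#!/usr/bin/env Rscript
# Builds reversal-potential shift curves against external Cl- activity and
# fits the GHK voltage equation for P_Cl/P_Na with bootstrap confidence
# intervals. Writes permeability_fit.json per channel.
suppressPackageStartupMessages(library(ghkselect))

expt <- default_dilution_experiment()
truths <- c(anion = 18.8, cation = 0.19)

for (tag in names(truths)) {
  doc <- jsonlite::read_json(file.path("results", tag, "erev.json"),
                             simplifyVector = FALSE)
  erev <- lapply(doc$erev, function(e) e$value)
  curve <- build_dilution_curve(expt, erev)
  fit <- fit_pcl_pna(expt, curve, n_boot = 1000, boot_seed = 42L)
  fit_to_json(fit, file.path("results", tag, "permeability_fit.json"))
  cat(sprintf(
    "%s channel: true P_Cl/P_Na %g -> fitted %.3g [95%% CI %.3g, %.3g], %s\n",
    tag, truths[[tag]], fit$p_cl_over_p_na, fit$ci_low, fit$ci_high,
    fit$classification))
  cat(sprintf("  residual rmse %.2f mV over %d dilution points\n",
              fit$residual_rmse, fit$n_points))
}
cat("\nThe fitted ratios carry the ~20 mV-grid interpolation bias of the\n",
    "7-point protocol; the classification margins are unaffected.\n", sep = "")
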