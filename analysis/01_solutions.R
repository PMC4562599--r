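#!/usr/bin/env Rscript
# Solution accounting for all recording solutions: per-ion totals, ionic
# strength, and Davies activities. Writes results/solution_table.csv.
suppressPackageStartupMessages(library(ghkselect))

reg <- solution_registry()
davies <- activity_model("davies")

rows <- lapply(names(reg), function(nm) {
  s <- reg[[nm]]
  act <- function(ion) {
    if (ion %in% names(s$ion_totals)) ion_activity(s, ion, davies) else NA
  }
  data.frame(
    solution = nm, side = s$side,
    Na_mM = ion_total(s, "Na"), K_mM = ion_total(s, "K"),
    Ca_mM = ion_total(s, "Ca"), Cl_mM = ion_total(s, "Cl"),
    ionic_strength_M = ionic_strength(s),
    aCl_davies_mM = act("Cl")
  )
})
tab <- do.call(rbind, rows)

dir.create("results", showWarnings = FALSE)
write.csv(tab, "results/solution_table.csv", row.names = FALSE)

cat("Recording solutions (totals in mM):\n")
print(tab, digits = 4, row.names = FALSE)
cat("\nKey checks: standard (ES1) and low-Na (ES2) externals both carry",
    ion_total(reg$ES1, "Cl"), "mM Cl-; the low-Cl- external is shipped in",
    "two variants because the printed recipe (45 mM) and the printed summary",
    "(30 mM) disagree.\n")
cat("Dilution series externals: ",
    paste(sprintf("%s = %g mM NaCl", c("1NaCl", "0.5NaCl", "0.25NaCl"),
                  sapply(c("1NaCl", "0.5NaCl", "0.25NaCl"),
                         function(nm) ion_total(reg[[nm]], "Na"))),
          collapse = ", "), "\n", sep = "")
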