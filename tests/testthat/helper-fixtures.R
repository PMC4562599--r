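# Shared fixtures: built-in solutions, a room-temperature context, and small
# deterministic channels used across the suite.

ctx22 <- physical_context(22)
REG <- solution_registry()

anion_channel <- function(ratio = 18.8, scale = 500) {
  channel_model(c(Na = 1, Cl = ratio), conductance_scale = scale)
}

cation_channel <- function(scale = 500) {
  channel_model(c(Na = 1, K = 1, Ca = 0), conductance_scale = scale)
}

# Independent brute-force accumulator for ion totals: walks every component's
# stoichiometry with plain loops, no shared code path with build_solution.
brute_force_totals <- function(solution) {
  totals <- list()
  for (comp in solution$components) {
    st <- comp$stoichiometry
    for (i in seq_along(st)) {
      ion <- names(st)[i]
      prev <- if (is.null(totals[[ion]])) 0 else totals[[ion]]
      totals[[ion]] <- prev + comp$mM * st[[i]]
    }
  }
  unlist(totals)
}
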