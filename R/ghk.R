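# Goldman-Hodgkin-Katz computations: Nernst potentials, the two-ion voltage
# equation, constant-field flux currents, and multi-ion reversal potentials.

#' Physical context (temperature and constants)
#'
#' @param temperature_C Temperature in degrees Celsius; default 22 C (room
#'   temperature). RT/F is computed, never hard-coded (~25.4 mV at 22 C).
#' @return Object of class `physical_context` with `T_K`, `R`
#'   (J mol^-1 K^-1) and `F` (C mol^-1).
#' @export
physical_context <- function(temperature_C = 22) {
  structure(list(T_K = temperature_C + 273.15,
                 R = 8.31446261815324,
                 F = 96485.33212),
            class = "physical_context")
}

#' RT/F in millivolts
#'
#' @param ctx A [physical_context()].
#' @return RT/F in mV.
#' @export
rtf_mV <- function(ctx = physical_context()) {
  1000 * ctx$R * ctx$T_K / ctx$F
}

#' Nernst equilibrium potential
#'
#' E = (RT/zF) ln(a_out/a_in), the limiting case of the GHK voltage equation
#' for a single permeant ion.
#'
#' @param a_out,a_in Outside/inside activities (mM), both > 0.
#' @param charge Ion valence (non-zero signed integer).
#' @param ctx A [physical_context()].
#' @return Potential in mV (inside minus outside convention).
#' @export
nernst <- function(a_out, a_in, charge, ctx = physical_context()) {
  if (any(a_out <= 0) || any(a_in <= 0)) {
    stop("Nernst potential requires positive activities on both sides")
  }
  if (charge == 0) stop("Nernst potential undefined for a neutral species")
  (rtf_mV(ctx) / charge) * log(a_out / a_in)
}

#' Channel model: relative permeability map
#'
#' @param permeabilities Named non-negative numeric vector of relative
#'   permeabilities, e.g. `c(Na = 1, Cl = 18.8)`. At least one must be > 0.
#'   Reversal potentials are invariant under joint rescaling of the map;
#'   currents scale linearly with it.
#' @param reference_ion Ion whose permeability defines the ratio scale for
#'   reporting (default `"Na"`).
#' @param conductance_scale Amplitude factor mapping GHK flux to simulated
#'   current (arbitrary current units); used only by the simulator.
#' @return Object of class `channel_model`.
#' @export
channel_model <- function(permeabilities, reference_ion = "Na",
                          conductance_scale = 1) {
  if (is.null(names(permeabilities)) || any(permeabilities < 0) ||
      !any(permeabilities > 0)) {
    stop("permeabilities must be a named non-negative vector with at least ",
         "one positive entry")
  }
  ion_charge(names(permeabilities))  # validate species
  structure(list(permeabilities = permeabilities,
                 reference_ion = reference_ion,
                 conductance_scale = conductance_scale),
            class = "channel_model")
}

#' @export
print.channel_model <- function(x, ...) {
  p <- x$permeabilities
  cat("<channel_model> P(", paste(names(p), collapse = ","), ") = ",
      paste(format(p), collapse = " : "),
      "  [ref ", x$reference_ion, ", scale ", x$conductance_scale, "]\n",
      sep = "")
  invisible(x)
}

#' Reversal-potential estimate record
#'
#' @param value E_rev in mV.
#' @param method One of `"closed_form"`, `"root_find"`, `"interpolated"`.
#' @param standard_error Optional SE in mV (absent for closed form).
#' @param n_replicates Number of replicates behind the estimate.
#' @param flags Character vector of analysis flags.
#' @return Object of class `erev_estimate`.
#' @export
erev_estimate <- function(value,
                          method = c("closed_form", "root_find",
                                     "interpolated"),
                          standard_error = NA_real_, n_replicates = 1L,
                          flags = character(0)) {
  method <- match.arg(method)
  if (method == "closed_form") standard_error <- NA_real_
  structure(list(value = value, standard_error = standard_error,
                 method = method, n_replicates = n_replicates, flags = flags),
            class = "erev_estimate")
}

#' @export
print.erev_estimate <- function(x, ...) {
  cat(sprintf("<erev_estimate> %.3f mV (%s%s)\n", x$value, x$method,
              if (is.finite(x$standard_error))
                sprintf(", se %.3f", x$standard_error) else ""))
  invisible(x)
}

#' Two-ion GHK reversal potential (Na+/Cl-)
#'
#' E_rev = (RT/F) ln[(P_Na (a_Na)_o + (a_Cl)_i P_Cl) /
#'                   (P_Na (a_Na)_i + (a_Cl)_o P_Cl)].
#' Note the anion terms: intracellular Cl- activity in the numerator,
#' extracellular in the denominator. Depends on the permeabilities only through
#' their ratio `p_ratio` = P_Cl/P_Na.
#'
#' @param p_ratio P_Cl/P_Na, >= 0 (finite); `Inf` is accepted and returns the
#'   Nernst Cl- limit.
#' @param aNa_o,aNa_i,aCl_o,aCl_i Activities in mM, all > 0.
#' @param ctx A [physical_context()].
#' @return E_rev in mV.
#' @export
ghk_erev_two_ion <- function(p_ratio, aNa_o, aNa_i, aCl_o, aCl_i,
                             ctx = physical_context()) {
  if (any(c(aNa_o, aNa_i, aCl_o, aCl_i) <= 0)) {
    stop("all activities must be positive")
  }
  if (is.na(p_ratio) || p_ratio < 0) stop("p_ratio must be >= 0")
  if (is.infinite(p_ratio)) return(nernst(aCl_o, aCl_i, -1L, ctx))
  rtf_mV(ctx) * log((aNa_o + p_ratio * aCl_i) / (aNa_i + p_ratio * aCl_o))
}

# Dimensionless GHK flux kernel: h(u) = u (a_in - a_out e^{-u}) / (1 - e^{-u}),
# u = zFV/RT. The removable singularity at u = 0 is patched with the series
# u/(1-e^{-u}) = 1 + u/2 + u^2/12 + O(u^4), accurate to ~1e-12 at |u| < 1e-4.
.ghk_flux_kernel <- function(u, a_in, a_out) {
  ifelse(abs(u) < 1e-4,
         (a_in - a_out * exp(-u)) * (1 + u / 2 + u^2 / 12),
         u * (a_in - a_out * exp(-u)) / (1 - exp(-u)))
}

#' GHK constant-field current density
#'
#' Sums the per-ion GHK flux terms
#' P_ion z^2 (V F^2 / RT) (a_in - a_out e^{-zVF/RT}) / (1 - e^{-zVF/RT})
#' over the channel's permeant ions, with the singularity at V = 0 handled by
#' series expansion. Conventions: membrane potential is inside minus outside;
#' outward current positive. Units are arbitrary (proportional to mM); the
#' simulator's `conductance_scale` sets the amplitude.
#'
#' @param channel A [channel_model()].
#' @param V_mV Membrane potential(s) in mV (vectorised).
#' @param sol_out,sol_in Extracellular / intracellular `ghk_solution`.
#' @param model An [activity_model()].
#' @param ctx A [physical_context()].
#' @return Signed current density (arbitrary units), same length as `V_mV`.
#' @export
ghk_current_density <- function(channel, V_mV, sol_out, sol_in,
                                model = activity_model("unity"),
                                ctx = physical_context()) {
  stopifnot(inherits(channel, "channel_model"))
  p <- channel$permeabilities
  ions <- names(p)[p > 0]
  ions <- ions[ion_charge(ions) != 0]
  act <- function(sol, ion) {
    if (ion %in% names(sol$ion_totals)) ion_activity(sol, ion, model) else 0
  }
  shared <- vapply(ions, function(ion) {
    act(sol_out, ion) > 0 || act(sol_in, ion) > 0
  }, logical(1))
  if (!any(shared)) {
    stop("no permeant ion of the channel is present in either solution")
  }
  rtf <- rtf_mV(ctx)  # mV
  total <- numeric(length(V_mV))
  for (ion in ions[shared]) {
    z <- ion_charge(ion)
    u <- z * V_mV / rtf
    # z * h(u) == z^2 (V/rtf) g(u): matches the z^2 flux form and keeps
    # outward current positive for both carrier signs
    total <- total + p[[ion]] * z *
      .ghk_flux_kernel(u, act(sol_in, ion), act(sol_out, ion))
  }
  total
}

#' Multi-ion reversal potential by root finding
#'
#' Finds the zero of the summed GHK current on [-150, +150] mV by bracketing
#' root search (needed when divalents are permeant and no closed form exists).
#' For monovalent-only channels this agrees with [ghk_erev_two_ion()] to well
#' under 0.01 mV.
#'
#' @inheritParams ghk_current_density
#' @param interval Search bracket in mV.
#' @return An [erev_estimate()] with method `"root_find"`.
#' @export
ghk_erev_multi <- function(channel, sol_out, sol_in,
                           model = activity_model("unity"),
                           ctx = physical_context(),
                           interval = c(-150, 150)) {
  f <- function(v) ghk_current_density(channel, v, sol_out, sol_in, model, ctx)
  lo <- f(interval[1]); hi <- f(interval[2])
  if (sign(lo) == sign(hi) && lo != 0 && hi != 0) {
    stop(sprintf(
      "no zero-current crossing in [%g, %g] mV (currents %.4g and %.4g)",
      interval[1], interval[2], lo, hi))
  }
  root <- stats::uniroot(f, interval, tol = 1e-10)$root
  erev_estimate(root, method = "root_find")
}

#' Serialize a channel model to YAML
#' @param channel A [channel_model()].
#' @param path Output path.
#' @export
channel_to_yaml <- function(channel, path) {
  yaml::write_yaml(list(reference_ion = channel$reference_ion,
                        permeabilities = as.list(channel$permeabilities),
                        conductance_scale = channel$conductance_scale),
                   path)
  invisible(path)
}

#' Read a channel model from YAML
#' @param path File written by [channel_to_yaml()].
#' @return A [channel_model()].
#' @export
channel_from_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  channel_model(unlist(doc$permeabilities),
                reference_ion = doc$reference_ion,
                conductance_scale = doc$conductance_scale)
}
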