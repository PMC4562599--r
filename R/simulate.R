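# Synthetic whole-cell macrocurrent generator: seeded simulation of
# agonist-evoked currents across holding potentials, replicates and solutions.

#' Voltage-step protocol
#'
#' @param holding_mV Strictly increasing holding potentials; default
#'   -60 to +60 mV in 20 mV steps (7 sweeps).
#' @param agonist_ms Agonist application window (default 250 ms).
#' @param sample_ms Sampling interval (default 1 ms).
#' @param baseline_ms Pre-agonist baseline (default 50 ms).
#' @return Object of class `voltage_protocol`.
#' @export
voltage_protocol <- function(holding_mV = seq(-60, 60, by = 20),
                             agonist_ms = 250, sample_ms = 1,
                             baseline_ms = 50) {
  if (is.unsorted(holding_mV, strictly = TRUE)) {
    stop("holding potentials must be strictly increasing")
  }
  stopifnot(agonist_ms > 0, sample_ms > 0, baseline_ms >= 0)
  structure(list(holding_mV = holding_mV, agonist_ms = agonist_ms,
                 sample_ms = sample_ms, baseline_ms = baseline_ms),
            class = "voltage_protocol")
}

#' Macroscopic desensitization kinetics
#'
#' The current decays from its peak as I(t) = I_o exp(-t/tau_d) + I_inf.
#' `plateau_fraction` is I_inf relative to the peak amplitude. Defaults
#' (tau_d = 100 ms, plateau 0.3) are plausible for a desensitizing Cys-loop
#' receptor but are configuration values, not measured constants.
#'
#' @param tau_d_ms Decay time constant (> 0).
#' @param plateau_fraction I_inf / peak, in [0, 1].
#' @param rise_ms Linear rise time to peak at agonist onset (0 = step).
#' @return Object of class `kinetics_spec`.
#' @export
kinetics_spec <- function(tau_d_ms = 100, plateau_fraction = 0.3,
                          rise_ms = 0) {
  stopifnot(tau_d_ms > 0, plateau_fraction >= 0, plateau_fraction <= 1,
            rise_ms >= 0)
  structure(list(tau_d_ms = tau_d_ms, plateau_fraction = plateau_fraction,
                 rise_ms = rise_ms),
            class = "kinetics_spec")
}

#' Noise model for simulated recordings
#'
#' @param trace_sd Additive Gaussian noise SD per sample (current units).
#' @param amplitude_cv Replicate-to-replicate coefficient of variation of the
#'   peak amplitude; realised as a lognormal factor with mean 1 (keeps peak
#'   signs consistent). Default 0.2.
#' @param seed Integer seed; identical seed and spec give bit-identical
#'   recordings.
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(trace_sd = 0, amplitude_cv = 0.2, seed = 1L) {
  stopifnot(trace_sd >= 0, amplitude_cv >= 0)
  structure(list(trace_sd = trace_sd, amplitude_cv = amplitude_cv,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

# Deterministic noiseless waveform at one holding potential.
.trace_template <- function(peak, time_ms, protocol, kinetics) {
  t0 <- protocol$baseline_ms
  s <- time_ms - t0
  i <- numeric(length(time_ms))
  pf <- kinetics$plateau_fraction
  rise <- kinetics$rise_ms
  on <- s >= 0
  if (rise > 0) {
    ramp <- on & s < rise
    i[ramp] <- peak * s[ramp] / rise
    dec <- on & s >= rise
    sd_ <- s[dec] - rise
    i[dec] <- peak * ((1 - pf) * exp(-sd_ / kinetics$tau_d_ms) + pf)
  } else {
    i[on] <- peak * ((1 - pf) * exp(-s[on] / kinetics$tau_d_ms) + pf)
  }
  i
}

#' Simulate one voltage-clamp sweep
#'
#' Baseline at zero current; at agonist onset the current rises (step or linear
#' ramp over `rise_ms`) to a peak equal to
#' `conductance_scale * ghk_current_density(V) * amp_factor`, then decays
#' single-exponentially to the plateau. Gaussian noise of SD `trace_sd` is
#' added per sample using the current RNG state.
#'
#' @param channel A [channel_model()].
#' @param V_mV Holding potential.
#' @param sol_out,sol_in Solutions.
#' @param protocol A [voltage_protocol()].
#' @param kinetics A [kinetics_spec()].
#' @param amp_factor Replicate amplitude factor (default 1).
#' @param trace_sd Per-sample noise SD (default 0).
#' @param model Activity model.
#' @param ctx Physical context.
#' @return data.frame with `time_ms` and `current`.
#' @export
simulate_trace <- function(channel, V_mV, sol_out, sol_in,
                           protocol = voltage_protocol(),
                           kinetics = kinetics_spec(),
                           amp_factor = 1, trace_sd = 0,
                           model = activity_model("unity"),
                           ctx = physical_context()) {
  time_ms <- seq(0, protocol$baseline_ms + protocol$agonist_ms,
                 by = protocol$sample_ms)
  peak <- channel$conductance_scale * amp_factor *
    ghk_current_density(channel, V_mV, sol_out, sol_in, model, ctx)
  current <- .trace_template(peak, time_ms, protocol, kinetics)
  if (trace_sd > 0) {
    current <- current + stats::rnorm(length(current), sd = trace_sd)
  }
  data.frame(time_ms = time_ms, current = current)
}

#' Simulate a full recording set
#'
#' Generates replicates at every holding potential for each named condition.
#' One lognormal amplitude factor is drawn per (condition, replicate) — the
#' whole-cell expression level — shared across that replicate's sweeps; trace
#' noise is drawn per sample. Fully deterministic under `noise$seed`.
#'
#' @param channel A [channel_model()].
#' @param conditions Named list; each element a list with `sol_out` and
#'   `sol_in` (`ghk_solution` objects).
#' @param protocol,kinetics,noise Protocol, kinetics and noise specs.
#' @param n_replicates Replicates per condition (default 4, matching typical
#'   n = 4-5 experiments).
#' @param model Activity model.
#' @param ctx Physical context.
#' @return Object of class `recording_set`: a tidy data.frame
#'   (`condition_id`, `replicate_id`, `holding_mV`, `time_ms`, `current_pA`)
#'   with a `provenance` attribute recording channel, solutions, protocol,
#'   kinetics, noise and seed.
#' @export
simulate_experiment <- function(channel, conditions,
                                protocol = voltage_protocol(),
                                kinetics = kinetics_spec(),
                                noise = noise_spec(),
                                n_replicates = 4,
                                model = activity_model("unity"),
                                ctx = physical_context()) {
  stopifnot(n_replicates >= 1, length(conditions) >= 1,
            !is.null(names(conditions)))
  set.seed(noise$seed)
  cv <- noise$amplitude_cv
  sdlog <- sqrt(log(1 + cv^2))
  out <- vector("list", length(conditions) * n_replicates *
                  length(protocol$holding_mV))
  k <- 0L
  for (cid in names(conditions)) {
    cond <- conditions[[cid]]
    for (rep_i in seq_len(n_replicates)) {
      amp <- if (cv > 0) {
        stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      } else 1
      for (v in protocol$holding_mV) {
        tr <- simulate_trace(channel, v, cond$sol_out, cond$sol_in,
                             protocol, kinetics, amp_factor = amp,
                             trace_sd = noise$trace_sd, model = model,
                             ctx = ctx)
        k <- k + 1L
        out[[k]] <- data.frame(condition_id = cid, replicate_id = rep_i,
                               holding_mV = v, time_ms = tr$time_ms,
                               current_pA = tr$current)
      }
    }
  }
  rs <- do.call(rbind, out)
  attr(rs, "provenance") <- list(
    channel = list(permeabilities = as.list(channel$permeabilities),
                   reference_ion = channel$reference_ion,
                   conductance_scale = channel$conductance_scale),
    solutions = lapply(conditions, function(cond) {
      list(out = cond$sol_out$name, `in` = cond$sol_in$name)
    }),
    protocol = unclass(protocol), kinetics = unclass(kinetics),
    noise = unclass(noise), n_replicates = n_replicates,
    activity_model = unclass(model), temperature_K = ctx$T_K
  )
  class(rs) <- c("recording_set", "data.frame")
  rs
}

#' Write a recording set to CSV with a JSON provenance sidecar
#'
#' @param rs A `recording_set`.
#' @param path CSV output path; provenance goes to `<path>.provenance.json`.
#' @export
write_traces_csv <- function(rs, path) {
  utils::write.csv(as.data.frame(rs), path, row.names = FALSE)
  prov <- attr(rs, "provenance")
  if (!is.null(prov)) {
    jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a recording set from CSV
#'
#' @param path CSV written by [write_traces_csv()].
#' @return A `recording_set` (provenance attached if the sidecar exists).
#' @export
read_traces_csv <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  rs <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition_id", "replicate_id", "holding_mV", "time_ms",
            "current_pA")
  miss <- setdiff(need, names(rs))
  if (length(miss)) {
    stop("malformed trace CSV; missing columns: ", paste(miss, collapse = ", "))
  }
  if (nrow(rs) == 0) stop("empty trace file: ", path)
  sidecar <- paste0(path, ".provenance.json")
  if (file.exists(sidecar)) {
    attr(rs, "provenance") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  class(rs) <- c("recording_set", "data.frame")
  rs
}
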