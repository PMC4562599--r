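# End-to-end orchestration: configuration, seed substreams, and the
# simulate -> I-V analysis -> permeability-fit pipeline.

#' Pipeline configuration
#'
#' A fully serializable description of one in-silico selectivity experiment.
#' A stored config plus its master seed reproduces every output.
#'
#' @param p_cl_over_p_na True P_Cl/P_Na of the simulated channel.
#' @param conductance_scale Current amplitude factor; the default 0.07 maps
#'   the GHK flux of the wild-type-like channel to ~500 pA peaks at +/-60 mV
#'   in the symmetric dilution condition.
#' @param n_replicates Replicates per condition.
#' @param trace_sd,amplitude_cv Noise parameters (see [noise_spec()]).
#' @param tau_d_ms,plateau_fraction,rise_ms Kinetics (see [kinetics_spec()]).
#' @param n_avg Replicates averaged per potential.
#' @param qc_threshold Replicate-QC discard threshold.
#' @param erev_method `"interp"` or `"quad"`.
#' @param n_boot Bootstrap resamples for the permeability CI.
#' @param activity_mode `"unity"` or `"davies"`.
#' @param temperature_C Recording temperature.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return Object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(p_cl_over_p_na = 18.8, conductance_scale = 0.07,
                            n_replicates = 5, trace_sd = 5,
                            amplitude_cv = 0.2, tau_d_ms = 100,
                            plateau_fraction = 0.3, rise_ms = 0, n_avg = 3,
                            qc_threshold = 0.8, erev_method = "interp",
                            n_boot = 1000, activity_mode = "unity",
                            temperature_C = 22, seed = 1L) {
  cfg <- list(p_cl_over_p_na = p_cl_over_p_na,
              conductance_scale = conductance_scale,
              n_replicates = n_replicates, trace_sd = trace_sd,
              amplitude_cv = amplitude_cv, tau_d_ms = tau_d_ms,
              plateau_fraction = plateau_fraction, rise_ms = rise_ms,
              n_avg = n_avg, qc_threshold = qc_threshold,
              erev_method = erev_method, n_boot = n_boot,
              activity_mode = activity_mode, temperature_C = temperature_C,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write pipeline configs as YAML
#' @param cfg A [pipeline_config()].
#' @param path File path.
#' @export
config_to_yaml <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname config_to_yaml
#' @export
config_from_yaml <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Derive per-stage seeds from a master seed
#'
#' Draws `n` independent 31-bit seeds from the master seed so each pipeline
#' stage is individually reproducible.
#'
#' @param master Master seed (integer).
#' @param n Number of substream seeds.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(master, n) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, n)
}

# Stable fingerprint of a config for provenance blocks.
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Run a full dilution-potential study on synthetic recordings
#'
#' Simulates tyramine-evoked macrocurrents for a channel with the configured
#' P_Cl/P_Na in the dilution-potential conditions (I2 pipette solution vs the
#' 1 / 0.5 / 0.25 NaCl external series), extracts peaks, applies replicate QC,
#' averages and normalizes I-V curves, interpolates reversal potentials,
#' builds the shift-vs-Cl-activity curve and refits the GHK voltage equation
#' for P_Cl/P_Na.
#'
#' @param cfg A [pipeline_config()].
#' @param outdir Optional directory; when given, traces CSV, I-V CSV, E_rev
#'   JSON and fit JSON are written there with a provenance block naming the
#'   config hash and seed.
#' @return List with `recordings`, `analysis`, `curve`, `fit`, `config`,
#'   `seeds`.
#' @export
run_dilution_study <- function(cfg = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  seeds <- derive_seeds(cfg$seed, 2)
  ctx <- physical_context(cfg$temperature_C)
  model <- activity_model(cfg$activity_mode)
  channel <- channel_model(c(Na = 1, Cl = cfg$p_cl_over_p_na),
                           conductance_scale = cfg$conductance_scale)
  expt <- default_dilution_experiment()
  conditions <- lapply(expt$externals, function(sol) {
    list(sol_out = sol, sol_in = expt$internal)
  })
  rs <- simulate_experiment(
    channel, conditions,
    protocol = voltage_protocol(),
    kinetics = kinetics_spec(cfg$tau_d_ms, cfg$plateau_fraction, cfg$rise_ms),
    noise = noise_spec(cfg$trace_sd, cfg$amplitude_cv, seed = seeds[1]),
    n_replicates = cfg$n_replicates, model = model, ctx = ctx)
  analysis <- analyze_recording_set(rs, n_avg = cfg$n_avg,
                                    qc_threshold = cfg$qc_threshold,
                                    erev_method = cfg$erev_method)
  miss <- setdiff(names(expt$externals), names(analysis$erev))
  if (length(miss)) {
    stop("conditions discarded or without E_rev: ",
         paste(miss, collapse = ", "), " (",
         paste(unlist(analysis$discarded), collapse = "; "), ")")
  }
  curve <- build_dilution_curve(expt, analysis$erev, model)
  fit <- fit_pcl_pna(expt, curve, model = model, ctx = ctx,
                     n_boot = cfg$n_boot, boot_seed = seeds[2])
  res <- list(recordings = rs, analysis = analysis, curve = curve, fit = fit,
              config = cfg, seeds = seeds)
  if (!is.null(outdir)) write_study_outputs(res, outdir)
  res
}

#' Write the outputs of a dilution study to a directory
#'
#' @param study Result of [run_dilution_study()].
#' @param outdir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_study_outputs <- function(study, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  prov <- list(config = unclass(study$config),
               config_hash = config_hash(study$config),
               seed = study$config$seed, stage_seeds = study$seeds)
  write_traces_csv(study$recordings, file.path(outdir, "traces.csv"))
  write_iv_csv(study$analysis$iv_curves, file.path(outdir, "iv_curves.csv"))
  erev_doc <- list(
    provenance = prov,
    erev = lapply(study$analysis$erev, unclass),
    discarded = study$analysis$discarded
  )
  jsonlite::write_json(erev_doc, file.path(outdir, "erev.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  fit_to_json(study$fit, file.path(outdir, "permeability_fit.json"))
  report <- c(
    sprintf("dilution-potential study (config %s, seed %d)",
            prov$config_hash, study$config$seed),
    sprintf("true P_Cl/P_Na: %g", study$config$p_cl_over_p_na),
    sprintf("fitted P_Cl/P_Na: %.4g  [%s]", study$fit$p_cl_over_p_na,
            study$fit$classification),
    if (is.finite(study$fit$ci_low)) {
      sprintf("bootstrap 95%% CI: [%.4g, %.4g]", study$fit$ci_low,
              study$fit$ci_high)
    },
    sprintf("residual rmse: %.3g mV", study$fit$residual_rmse),
    if (length(study$analysis$discarded)) {
      paste("discarded:", paste(names(study$analysis$discarded),
                                unlist(study$analysis$discarded),
                                sep = ": ", collapse = "; "))
    } else "discarded: none"
  )
  writeLines(report, file.path(outdir, "report.txt"))
  invisible(outdir)
}

#' Monovalent/divalent shift study (K+ and Ca2+ swaps)
#'
#' Computes model reversal potentials (multi-ion GHK root finding) for a
#' channel in the low-Na (ES2), high-K (ES4) and high-Ca (ES5) external
#' solutions against the K-rich I1 pipette solution, and reports the E_rev
#' shifts ES2 -> ES4 and ES2 -> ES5.
#'
#' @param channel A [channel_model()]; default is a nonselective monovalent
#'   cation channel (P_K = P_Na, P_Ca = 0) emulating the engineered
#'   cation-selective receptor.
#' @param model An [activity_model()].
#' @param ctx A [physical_context()].
#' @return List with `erev` (per solution, mV) and `shifts` (list of
#'   [shift_analysis()] records).
#' @export
run_shift_study <- function(channel = channel_model(c(Na = 1, K = 1, Ca = 0)),
                            model = activity_model("unity"),
                            ctx = physical_context()) {
  reg <- solution_registry()
  erev <- vapply(c("ES2", "ES4", "ES5"), function(nm) {
    ghk_erev_multi(channel, reg[[nm]], reg$I1, model, ctx)$value
  }, numeric(1))
  list(
    erev = erev,
    shifts = list(
      high_K = shift_analysis(erev["ES2"], erev["ES4"], analytic = TRUE),
      high_Ca = shift_analysis(erev["ES2"], erev["ES5"], analytic = TRUE)
    )
  )
}
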