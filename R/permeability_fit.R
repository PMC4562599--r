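# Dilution-potential permeability inference: assemble reversal-potential
# shift curves, fit the GHK voltage equation for P_Cl/P_Na, classify
# selectivity, and quantify E_rev shifts across solution swaps.

#' Assemble a dilution-potential experiment
#'
#' @param internal Intracellular `ghk_solution` (the NaCl-based pipette
#'   solution).
#' @param externals Named list of extracellular `ghk_solution`s, one per
#'   dilution factor; names are condition ids.
#' @param factors Numeric vector of dilution factors aligned with `externals`.
#' @param reference Condition id of the symmetric (factor 1) external.
#' @return Object of class `dilution_experiment`.
#' @export
dilution_experiment <- function(internal, externals, factors,
                                reference = names(externals)[factors == 1]) {
  stopifnot(length(externals) == length(factors),
            !is.null(names(externals)))
  if (!length(reference) || !(reference %in% names(externals))) {
    stop("reference (factor 1) condition missing from externals")
  }
  structure(list(internal = internal, externals = externals,
                 factors = factors, reference = reference),
            class = "dilution_experiment")
}

#' Build the default dilution-potential experiment
#'
#' The I2 NaCl pipette solution against the 1 / 0.5 / 0.25 NaCl external
#' series (145, 72.5, 36.25 mM NaCl).
#'
#' @return A [dilution_experiment()].
#' @export
default_dilution_experiment <- function() {
  reg <- solution_registry()
  dilution_experiment(
    internal = reg$I2,
    externals = list(`1NaCl` = reg[["1NaCl"]], `0.5NaCl` = reg[["0.5NaCl"]],
                     `0.25NaCl` = reg[["0.25NaCl"]]),
    factors = c(1, 0.5, 0.25),
    reference = "1NaCl"
  )
}

# Pooled monovalent-cation and Cl- activities for the two-ion GHK equation.
# `cations` lists the ions pooled with equal permeability (P_K = P_Na when K
# is included, the standard treatment for K-rich internals).
.two_ion_activities <- function(sol, model, cations = "Na") {
  a_cat <- sum(vapply(cations, function(ion) {
    if (ion %in% names(sol$ion_totals)) ion_activity(sol, ion, model) else 0
  }, numeric(1)))
  a_cl <- if ("Cl" %in% names(sol$ion_totals)) {
    ion_activity(sol, "Cl", model)
  } else 0
  c(cat = a_cat, Cl = a_cl)
}

# Predicted E_rev shifts (each external minus the reference external) for a
# candidate ratio; the reference solution is passed explicitly so curves that
# omit the reference point can still be fitted.
.predict_delta_erev <- function(p_ratio, internal, externals, ref_sol, model,
                                ctx, cations = "Na") {
  a_in <- .two_ion_activities(internal, model, cations)
  erev_for <- function(sol) {
    a_out <- .two_ion_activities(sol, model, cations)
    ghk_erev_two_ion(p_ratio, a_out[["cat"]], a_in[["cat"]],
                     a_out[["Cl"]], a_in[["Cl"]], ctx)
  }
  vapply(externals, erev_for, numeric(1)) - erev_for(ref_sol)
}

#' Build a dilution curve: reversal-potential shift vs external Cl- activity
#'
#' Delta E_rev = E_rev(dilution) - E_rev(reference); the x coordinate is the
#' external Cl- activity under the chosen activity model. The activity model
#' moves the x coordinates only; measured shifts are unchanged.
#'
#' @param experiment A [dilution_experiment()].
#' @param erev Named list (by condition id) of [erev_estimate()] objects or
#'   numeric E_rev values (mV).
#' @param model An [activity_model()].
#' @return data.frame with `condition_id`, `factor`, `aCl_o`, `dErev_mV`,
#'   `se_mV`.
#' @export
build_dilution_curve <- function(experiment, erev,
                                 model = activity_model("unity")) {
  stopifnot(inherits(experiment, "dilution_experiment"))
  ids <- names(experiment$externals)
  miss <- setdiff(ids, names(erev))
  if (length(miss)) {
    stop("missing E_rev estimate(s) for: ", paste(miss, collapse = ", "))
  }
  if (!(experiment$reference %in% names(erev))) {
    stop("missing E_rev estimate for reference condition ",
         experiment$reference)
  }
  val <- function(e) if (inherits(e, "erev_estimate")) e$value else as.numeric(e)
  se <- function(e) if (inherits(e, "erev_estimate")) e$standard_error else NA_real_
  e_ref <- val(erev[[experiment$reference]])
  data.frame(
    condition_id = ids,
    factor = experiment$factors,
    aCl_o = vapply(experiment$externals, ion_activity, numeric(1),
                   ion = "Cl", model = model),
    dErev_mV = vapply(ids, function(id) val(erev[[id]]) - e_ref, numeric(1)),
    se_mV = vapply(ids, function(id) se(erev[[id]]), numeric(1)),
    row.names = NULL
  )
}

#' Fit P_Cl/P_Na to a dilution curve by the GHK voltage equation
#'
#' Nonlinear least squares in log(P_Cl/P_Na) (positivity enforced, the search
#' symmetric between anion- and cation-favouring ratios), minimizing the sum
#' of squared differences between observed and GHK-predicted reversal
#' potential shifts. The objective is scanned on a coarse log-ratio grid over
#' ratios 1e-5 .. 1e5 and polished with Brent optimization around the grid
#' minimum, which guards against the flat Nernst limits. Confidence limits are
#' from a parametric bootstrap: E_rev shifts are resampled from Gaussians with
#' the per-point standard errors (or the residual RMSE when none are given)
#' and refit.
#'
#' @param experiment A [dilution_experiment()].
#' @param curve Output of [build_dilution_curve()] (observed shifts).
#' @param model An [activity_model()] used for the GHK predictions.
#' @param ctx A [physical_context()].
#' @param cations Monovalent cations pooled with equal permeability
#'   (default `"Na"`, appropriate for the NaCl dilution experiments).
#' @param n_boot Bootstrap resamples (default 1000); 0 disables the CI.
#' @param boot_seed Seed for the bootstrap.
#' @param thresholds Classification thresholds `c(lo, hi)`; see
#'   [classify_selectivity()].
#' @return Object of class `permeability_fit`: `p_cl_over_p_na`, `log_ratio`,
#'   `ci_low`, `ci_high`, `residual_rmse` (mV), `n_points`, `classification`,
#'   `curve` (with fitted shifts), `limits` (hypothetical shift curves for
#'   ratio -> Inf and -> 0), `boot_ratios`.
#' @export
fit_pcl_pna <- function(experiment, curve,
                        model = activity_model("unity"),
                        ctx = physical_context(), cations = "Na",
                        n_boot = 1000, boot_seed = 1L,
                        thresholds = c(0.5, 5)) {
  stopifnot(inherits(experiment, "dilution_experiment"),
            nrow(curve) >= 2)
  obs <- curve$dErev_mV
  ids <- curve$condition_id
  fit_externals <- experiment$externals[ids]
  ref_sol <- experiment$externals[[experiment$reference]]

  # activities are fixed across the optimization; precompute once
  a_in <- .two_ion_activities(experiment$internal, model, cations)
  a_out <- vapply(fit_externals, .two_ion_activities, numeric(2),
                  model = model, cations = cations)
  a_ref <- .two_ion_activities(ref_sol, model, cations)
  rtf <- rtf_mV(ctx)
  predict_shifts <- function(r) {
    rtf * (log((a_out["cat", ] + r * a_in[["Cl"]]) /
                 (a_in[["cat"]] + r * a_out["Cl", ])) -
             log((a_ref[["cat"]] + r * a_in[["Cl"]]) /
                   (a_in[["cat"]] + r * a_ref[["Cl"]])))
  }
  objective <- function(logr, y) sum((y - predict_shifts(exp(logr)))^2)
  fit_once <- function(y) {
    grid <- seq(log(1e-5), log(1e5), length.out = 81)
    vals <- vapply(grid, objective, numeric(1), y = y)
    i <- which.min(vals)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    opt <- stats::optimize(objective, c(lo, hi), y = y, tol = 1e-12)
    # widen once if the optimum sits on the bracket edge (flat limit)
    if (min(abs(opt$minimum - c(lo, hi))) < 1e-8) {
      opt2 <- stats::optimize(objective, range(grid), y = y, tol = 1e-12)
      if (opt2$objective < opt$objective) opt <- opt2
    }
    opt$minimum
  }
  logr_hat <- fit_once(obs)
  pred <- predict_shifts(exp(logr_hat))
  rmse <- sqrt(mean((obs - pred)^2))

  se <- curve$se_mV
  if (all(!is.finite(se))) se <- rep(max(rmse, 1e-6), length(obs))
  se[!is.finite(se)] <- max(rmse, 1e-6)
  boot_ratios <- numeric(0)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    set.seed(boot_seed)
    is_ref <- ids == experiment$reference
    boot_ratios <- vapply(seq_len(n_boot), function(b) {
      y <- obs + stats::rnorm(length(obs), sd = se)
      y[is_ref] <- 0  # the reference shift is identically zero
      exp(fit_once(y))
    }, numeric(1))
    ci <- unname(stats::quantile(boot_ratios, c(0.025, 0.975)))
  }

  a_in <- .two_ion_activities(experiment$internal, model, cations)
  nernst_shift <- function(ion, z) {
    one <- function(sol) {
      nernst(ion_activity(sol, ion, model),
             a_in[[if (ion == "Cl") "Cl" else "cat"]], z, ctx)
    }
    vapply(fit_externals, one, numeric(1)) - one(ref_sol)
  }
  limits <- data.frame(
    condition_id = ids,
    aCl_o = curve$aCl_o,
    dErev_inf = nernst_shift("Cl", -1L),   # P_Cl/P_Na -> Inf
    dErev_zero = nernst_shift("Na", +1L),  # P_Cl/P_Na -> 0
    row.names = NULL
  )
  curve$fitted_mV <- pred
  ratio <- exp(logr_hat)
  structure(list(
    p_cl_over_p_na = ratio, log_ratio = logr_hat,
    ci_low = ci[1], ci_high = ci[2],
    residual_rmse = rmse, n_points = nrow(curve),
    classification = classify_selectivity(ratio, lo = thresholds[1],
                                          hi = thresholds[2]),
    curve = curve, limits = limits, boot_ratios = boot_ratios,
    activity_model = model$mode, cations = cations, n_boot = n_boot,
    boot_seed = boot_seed
  ), class = "permeability_fit")
}

#' @export
print.permeability_fit <- function(x, ...) {
  cat(sprintf("<permeability_fit> P_Cl/P_Na = %.4g", x$p_cl_over_p_na))
  if (is.finite(x$ci_low)) {
    cat(sprintf(" [95%% CI %.4g, %.4g]", x$ci_low, x$ci_high))
  }
  cat(sprintf("\n  %s; rmse %.3g mV over %d points (activity model: %s)\n",
              x$classification, x$residual_rmse, x$n_points,
              x$activity_model))
  invisible(x)
}

#' Classify channel selectivity from a permeability ratio
#'
#' Anion-selective above `hi`, cation-selective below `lo`, otherwise
#' nonselective. Defaults (0.5 and 5) put the wild-type-like ratio 18.8 and
#' the engineered cation-channel ratio 0.19 on their respective sides with a
#' wide margin.
#'
#' @param ratio P_Cl/P_Na (or a `permeability_fit`).
#' @param lo,hi Thresholds.
#' @return `"anion_selective"`, `"cation_selective"` or `"nonselective"`.
#' @export
classify_selectivity <- function(ratio, lo = 0.5, hi = 5) {
  if (inherits(ratio, "permeability_fit")) ratio <- ratio$p_cl_over_p_na
  stopifnot(ratio >= 0, lo < hi)
  if (ratio > hi) "anion_selective"
  else if (ratio < lo) "cation_selective"
  else "nonselective"
}

#' Reversal-potential shift between two conditions
#'
#' Difference of mean E_rev (condition B minus condition A) with a percentile
#' bootstrap confidence interval when both sides have at least two estimates.
#' The direction is labelled `positive` / `negative` when the CI excludes
#' zero (or, for single analytic values, by the sign of the difference),
#' `none` when it does not, and `undetermined` when no CI can be formed from
#' single noisy estimates.
#'
#' @param erev_a,erev_b Numeric vectors of E_rev values (mV), or lists of
#'   [erev_estimate()] objects.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Bootstrap seed.
#' @param analytic Set TRUE when single values are exact model computations,
#'   so a direction can be assigned without a CI.
#' @return List with `delta_mV`, `ci_low`, `ci_high`, `direction`, `n_a`,
#'   `n_b`.
#' @export
shift_analysis <- function(erev_a, erev_b, n_boot = 1000, seed = 1L,
                           analytic = FALSE) {
  num <- function(x) {
    if (is.list(x)) vapply(x, function(e) {
      if (inherits(e, "erev_estimate")) e$value else as.numeric(e)
    }, numeric(1)) else as.numeric(x)
  }
  a <- num(erev_a); b <- num(erev_b)
  delta <- mean(b) - mean(a)
  if (length(a) >= 2 && length(b) >= 2 && n_boot > 0) {
    set.seed(seed)
    boots <- vapply(seq_len(n_boot), function(i) {
      mean(sample(b, replace = TRUE)) - mean(sample(a, replace = TRUE))
    }, numeric(1))
    ci <- unname(stats::quantile(boots, c(0.025, 0.975)))
    direction <- if (ci[1] > 0) "positive" else if (ci[2] < 0) "negative"
    else "none"
    list(delta_mV = delta, ci_low = ci[1], ci_high = ci[2],
         direction = direction, n_a = length(a), n_b = length(b))
  } else if (analytic) {
    direction <- if (delta > 0) "positive" else if (delta < 0) "negative"
    else "none"
    list(delta_mV = delta, ci_low = NA_real_, ci_high = NA_real_,
         direction = direction, n_a = length(a), n_b = length(b))
  } else {
    list(delta_mV = delta, ci_low = NA_real_, ci_high = NA_real_,
         direction = "undetermined", n_a = length(a), n_b = length(b))
  }
}

#' Analytic dilution curve for a given permeability ratio
#'
#' Evaluates the GHK voltage equation at each external of a dilution
#' experiment to produce the noise-free shift curve a channel with the given
#' P_Cl/P_Na would show.
#'
#' @param experiment A [dilution_experiment()].
#' @param p_ratio True P_Cl/P_Na (`Inf` and 0 give the Nernst limit curves).
#' @param model,ctx Activity model and physical context.
#' @param cations Pooled monovalent cations (see [fit_pcl_pna()]).
#' @return data.frame in the layout of [build_dilution_curve()].
#' @export
analytic_dilution_curve <- function(experiment, p_ratio,
                                    model = activity_model("unity"),
                                    ctx = physical_context(),
                                    cations = "Na") {
  ref_sol <- experiment$externals[[experiment$reference]]
  d <- .predict_delta_erev(p_ratio, experiment$internal,
                           experiment$externals, ref_sol, model, ctx, cations)
  data.frame(
    condition_id = names(experiment$externals),
    factor = experiment$factors,
    aCl_o = vapply(experiment$externals, ion_activity, numeric(1),
                   ion = "Cl", model = model),
    dErev_mV = unname(d), se_mV = NA_real_, row.names = NULL
  )
}

#' Monte-Carlo recovery study for the permeability fit
#'
#' For each true ratio and each seed, perturbs the analytic reversal-potential
#' shifts with the mean of `n_experiments` iid Gaussian errors of SD
#' `sd_mV` (mimicking averaging E_rev over independent experiments), refits,
#' and records the fitted ratio; optionally a bootstrap CI per fit for
#' coverage studies.
#'
#' @param truths True P_Cl/P_Na values.
#' @param n_experiments Independent experiments averaged per point.
#' @param sd_mV Per-experiment E_rev noise SD in mV.
#' @param n_seeds Monte-Carlo repetitions per truth.
#' @param seed Master seed.
#' @param experiment A [dilution_experiment()].
#' @param n_boot Bootstrap resamples per fit (0 = no CI, fastest).
#' @param model,ctx Activity model and physical context.
#' @return data.frame with `truth`, `rep`, `ratio_hat`, `log_err`, and (when
#'   `n_boot > 0`) `ci_low`, `ci_high`, `covered`.
#' @export
recovery_study <- function(truths = c(0.19, 1, 18.8), n_experiments = 5,
                           sd_mV = 1.5, n_seeds = 50, seed = 1L,
                           experiment = default_dilution_experiment(),
                           n_boot = 0,
                           model = activity_model("unity"),
                           ctx = physical_context()) {
  seeds <- derive_seeds(seed, length(truths) * n_seeds + 1)
  sem <- sd_mV / sqrt(n_experiments)
  rows <- list(); k <- 0L
  for (truth in truths) {
    base <- analytic_dilution_curve(experiment, truth, model, ctx)
    is_ref <- base$condition_id == experiment$reference
    for (r in seq_len(n_seeds)) {
      k <- k + 1L
      set.seed(seeds[k])
      cur <- base
      # reference shift is a self-difference and stays 0; noise enters the
      # dilution points as the SEM of n_experiments measurements
      cur$dErev_mV <- cur$dErev_mV +
        ifelse(is_ref, 0, stats::rnorm(nrow(cur), sd = sem))
      cur$se_mV <- ifelse(is_ref, 0, sem)
      fit <- fit_pcl_pna(experiment, cur, model = model, ctx = ctx,
                         n_boot = n_boot, boot_seed = seeds[k])
      row <- data.frame(truth = truth, rep = r,
                        ratio_hat = fit$p_cl_over_p_na,
                        log_err = fit$log_ratio - log(truth))
      if (n_boot > 0) {
        row$ci_low <- fit$ci_low
        row$ci_high <- fit$ci_high
        row$covered <- fit$ci_low <= truth & truth <= fit$ci_high
      }
      rows[[k]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Write a permeability fit to JSON
#'
#' @param fit A `permeability_fit`.
#' @param path Output path.
#' @export
fit_to_json <- function(fit, path) {
  out <- list(
    p_cl_over_p_na = fit$p_cl_over_p_na,
    ci_low = fit$ci_low, ci_high = fit$ci_high,
    residual_rmse_mV = fit$residual_rmse, n_points = fit$n_points,
    classification = fit$classification,
    activity_model = fit$activity_model, cations = fit$cations,
    n_boot = fit$n_boot, boot_seed = fit$boot_seed,
    curve = fit$curve, limits = fit$limits
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, na = "null")
  invisible(path)
}
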