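# I-V analysis: peak extraction, single-exponential desensitization fits,
# replicate QC, normalized I-V curves and reversal-potential estimation.

#' Peak current of a sweep
#'
#' Baseline (mean of all pre-agonist samples) is subtracted; the signed
#' extremum of the baseline-subtracted current within the agonist window is
#' returned (the sample with the largest absolute value, keeping its sign).
#'
#' @param trace data.frame with `time_ms` and `current` (or `current_pA`).
#' @param protocol A [voltage_protocol()] defining baseline and agonist
#'   windows.
#' @return Signed peak current.
#' @export
peak_current <- function(trace, protocol = voltage_protocol()) {
  cur <- if ("current" %in% names(trace)) trace$current else trace$current_pA
  t <- trace$time_ms
  in_window <- t >= protocol$baseline_ms &
    t <= protocol$baseline_ms + protocol$agonist_ms
  if (!any(in_window)) stop("agonist window contains no samples")
  baseline <- if (any(t < protocol$baseline_ms)) {
    mean(cur[t < protocol$baseline_ms])
  } else 0
  w <- cur[in_window] - baseline
  w[which.max(abs(w))]
}

#' Fit a single-exponential desensitization decay
#'
#' Fits I(t) = I_o exp(-t/tau_d) + I_inf by nonlinear least squares to the
#' post-peak segment of the agonist window, with time re-zeroed at the peak.
#' Starting values come from the tail mean (I_inf), the peak offset (I_o) and
#' a log-linear slope estimate (tau_d); `stats::nls` (port) is tried first and
#' `minpack.lm::nlsLM` used as fallback.
#'
#' @param trace data.frame with `time_ms` and `current` (or `current_pA`).
#' @param protocol A [voltage_protocol()].
#' @return Object of class `decay_fit`: list with `I_o`, `I_inf`, `tau_d`
#'   (ms), `rmse`.
#' @export
fit_decay <- function(trace, protocol = voltage_protocol()) {
  cur <- if ("current" %in% names(trace)) trace$current else trace$current_pA
  t <- trace$time_ms
  in_window <- t >= protocol$baseline_ms &
    t <= protocol$baseline_ms + protocol$agonist_ms
  baseline <- if (any(t < protocol$baseline_ms)) {
    mean(cur[t < protocol$baseline_ms])
  } else 0
  tw <- t[in_window]
  iw <- cur[in_window] - baseline
  pk <- which.max(abs(iw))
  ts <- tw[pk:length(tw)] - tw[pk]
  is <- iw[pk:length(iw)]
  if (length(ts) < 10) stop("need at least 10 samples after the peak")
  if (stats::sd(is) < 1e-12 * (abs(mean(is)) + 1e-12) ||
      stats::sd(is) == 0) {
    stop("decay unidentifiable: post-peak current is constant")
  }
  n_tail <- max(3L, ceiling(length(is) * 0.1))
  iinf0 <- mean(utils::tail(is, n_tail))
  io0 <- is[1] - iinf0
  if (abs(io0) < 1e-12) stop("decay unidentifiable: no amplitude above plateau")
  # log-linear slope on the early decaying part for tau start
  frac <- (is - iinf0) / io0
  ok <- which(frac > 0.05)
  tau0 <- if (length(ok) >= 3) {
    fit0 <- stats::lm(log(frac[ok]) ~ ts[ok])
    sl <- stats::coef(fit0)[2]
    if (is.finite(sl) && sl < 0) -1 / sl else max(ts) / 3
  } else max(ts) / 3
  tau0 <- min(max(tau0, protocol$sample_ms), 10 * max(ts))
  df <- data.frame(ts = ts, is = is)
  start <- list(I_o = io0, tau_d = tau0, I_inf = iinf0)
  fit <- tryCatch(
    stats::nls(is ~ I_o * exp(-ts / tau_d) + I_inf, data = df, start = start,
               algorithm = "port",
               lower = c(I_o = -Inf, tau_d = protocol$sample_ms / 10,
                         I_inf = -Inf)),
    error = function(e) {
      tryCatch(
        minpack.lm::nlsLM(is ~ I_o * exp(-ts / tau_d) + I_inf, data = df,
                          start = start,
                          lower = c(-Inf, protocol$sample_ms / 10, -Inf)),
        error = function(e2) {
          stop("decay fit did not converge (starts I_o=", signif(io0, 4),
               ", tau_d=", signif(tau0, 4), ", I_inf=", signif(iinf0, 4),
               "): ", conditionMessage(e2))
        })
    })
  cf <- stats::coef(fit)
  structure(list(I_o = unname(cf["I_o"]), I_inf = unname(cf["I_inf"]),
                 tau_d = unname(cf["tau_d"]),
                 rmse = sqrt(mean(stats::resid(fit)^2))),
            class = "decay_fit")
}

#' Replicate quality control
#'
#' Implements the discard rule for replicate peak currents: the maximum
#' pairwise relative difference |p_i - p_j| / max(|p_i|, |p_j|) is computed
#' and the experiment is discarded when it exceeds `threshold` (default 0.80).
#' All-zero peaks are discarded as "no response"; a single replicate is kept
#' with a warning flag (the rule is vacuous).
#'
#' @param peaks Numeric vector of replicate peak currents for one condition.
#' @param threshold Relative-difference threshold (default 0.8).
#' @return List with `keep` (logical), `max_rel_diff`, `reason`, `flags`.
#' @export
qc_replicates <- function(peaks, threshold = 0.8) {
  stopifnot(is.numeric(peaks), length(peaks) >= 1)
  if (all(peaks == 0)) {
    return(list(keep = FALSE, max_rel_diff = NA_real_,
                reason = "no response", flags = character(0)))
  }
  if (length(peaks) == 1) {
    return(list(keep = TRUE, max_rel_diff = NA_real_, reason = "kept",
                flags = "single replicate: QC rule not applicable"))
  }
  mx <- 0
  for (i in seq_along(peaks)[-length(peaks)]) {
    for (j in seq((i + 1), length(peaks))) {
      denom <- max(abs(peaks[i]), abs(peaks[j]))
      d <- if (denom == 0) 0 else abs(peaks[i] - peaks[j]) / denom
      mx <- max(mx, d)
    }
  }
  if (mx > threshold) {
    list(keep = FALSE, max_rel_diff = mx,
         reason = sprintf("max pairwise relative difference %.1f%% > %.0f%%",
                          100 * mx, 100 * threshold),
         flags = character(0))
  } else {
    list(keep = TRUE, max_rel_diff = mx, reason = "kept", flags = character(0))
  }
}

#' Average replicate peaks and normalize to I_max
#'
#' Per holding potential, the mean of the first `n_avg` replicate peaks (in
#' replicate order) is taken; all means are then divided by
#' I_max = max |mean peak| over potentials. Fewer than `n_avg` replicates at a
#' potential are all used and flagged.
#'
#' @param peaks data.frame with columns `holding_mV`, `replicate_id`, `peak`.
#' @param n_avg Number of replicates to average (default 3).
#' @return Object of class `iv_curve`: data.frame (`holding_mV`, `mean_peak`,
#'   `norm_peak`, `n_used`) with attributes `I_max` and `flags`.
#' @export
average_normalize <- function(peaks, n_avg = 3) {
  stopifnot(all(c("holding_mV", "replicate_id", "peak") %in% names(peaks)))
  flags <- character(0)
  pots <- sort(unique(peaks$holding_mV))
  rows <- lapply(pots, function(v) {
    sub <- peaks[peaks$holding_mV == v, ]
    sub <- sub[order(sub$replicate_id), ]
    use <- utils::head(sub$peak, n_avg)
    if (nrow(sub) < n_avg) {
      flags <<- c(flags, sprintf("only %d replicate(s) at %g mV (wanted %d)",
                                 nrow(sub), v, n_avg))
    }
    data.frame(holding_mV = v, mean_peak = mean(use), n_used = length(use))
  })
  iv <- do.call(rbind, rows)
  i_max <- max(abs(iv$mean_peak))
  if (i_max <= 0) stop("I_max is zero: no response at any potential")
  iv$norm_peak <- iv$mean_peak / i_max
  attr(iv, "I_max") <- i_max
  attr(iv, "flags") <- flags
  class(iv) <- c("iv_curve", "data.frame")
  iv
}

#' Estimate the reversal potential from an I-V curve
#'
#' E_rev is the potential where the current is zero, located by linear
#' interpolation between the bracketing pair of holding potentials with
#' opposite current signs. With multiple sign changes the pair nearest 0 mV is
#' used and flagged. `method = "quad"` refines the estimate with a local
#' quadratic through the bracketing pair and its nearest neighbour.
#'
#' @param iv An [average_normalize()] `iv_curve` (or any data.frame with
#'   `holding_mV` and `norm_peak` or `mean_peak`).
#' @param method `"interp"` (default) or `"quad"`.
#' @return An [erev_estimate()] with method `"interpolated"`.
#' @export
estimate_erev <- function(iv, method = c("interp", "quad")) {
  method <- match.arg(method)
  v <- iv$holding_mV
  y <- if ("norm_peak" %in% names(iv)) iv$norm_peak else iv$mean_peak
  stopifnot(length(v) >= 2, !is.unsorted(v))
  flags <- character(0)
  exact <- which(y == 0)
  if (length(exact)) {
    return(erev_estimate(v[exact[which.min(abs(v[exact]))]],
                         method = "interpolated", flags = "exact zero sample"))
  }
  ssign <- sign(y)
  cross <- which(ssign[-length(ssign)] * ssign[-1] < 0)
  if (!length(cross)) {
    stop(sprintf(
      "no zero crossing: currents span [%.4g, %.4g] (E_rev outside protocol)",
      min(y), max(y)))
  }
  if (length(cross) > 1) {
    flags <- c(flags, "multiple sign changes; using pair nearest 0 mV")
    mid <- (v[cross] + v[cross + 1]) / 2
    cross <- cross[which.min(abs(mid))]
  }
  i <- cross
  e_lin <- v[i] - y[i] * (v[i + 1] - v[i]) / (y[i + 1] - y[i])
  if (method == "interp" || length(v) < 3) {
    return(erev_estimate(e_lin, method = "interpolated", flags = flags))
  }
  # local quadratic through the bracket plus its nearest neighbour
  idx <- if (i == 1) 1:3 else if (i + 1 == length(v)) (i - 1):(i + 1)
  else if (abs(y[i - 1]) < abs(y[i + 2])) (i - 1):(i + 1) else i:(i + 2)
  qf <- stats::lm(y[idx] ~ v[idx] + I(v[idx]^2))
  cf <- stats::coef(qf)
  roots <- if (abs(cf[3]) < 1e-12) -cf[1] / cf[2] else {
    disc <- cf[2]^2 - 4 * cf[3] * cf[1]
    if (disc < 0) e_lin else {
      (-cf[2] + c(-1, 1) * sqrt(disc)) / (2 * cf[3])
    }
  }
  e_q <- roots[which.min(abs(roots - e_lin))]
  if (!is.finite(e_q) || e_q < v[i] - 20 || e_q > v[i + 1] + 20) e_q <- e_lin
  erev_estimate(e_q, method = "interpolated", flags = flags)
}

#' Analyze a recording set: peaks, QC, averaging, E_rev per condition
#'
#' Runs the full chain peak extraction -> replicate QC -> averaging and
#' normalization -> reversal-potential interpolation for every condition in a
#' recording set. The replicate-consistency rule compares response peaks, so
#' it is evaluated per holding potential only where there is a substantial
#' response: mean |peak| at least `qc_floor_frac` (default 0.5) of the
#' condition's maximum. Sweeps near E_rev carry little current and their
#' peaks are noise-dominated, which would make any relative-difference rule
#' fire spuriously. Any failing responsive potential discards the whole
#' condition.
#'
#' @param rs A `recording_set` (see [simulate_experiment()]).
#' @param protocol A [voltage_protocol()]; defaults to the protocol recorded
#'   in the set's provenance when present.
#' @param n_avg Replicates averaged per potential (default 3).
#' @param qc_threshold Relative-difference discard threshold (default 0.8).
#' @param qc_floor_frac Responsiveness floor as a fraction of the maximum mean
#'   |peak| (default 0.5).
#' @param erev_method Passed to [estimate_erev()].
#' @return List with `peaks` (data.frame), `iv_curves` (named list of
#'   `iv_curve`), `erev` (named list of [erev_estimate()]), `discarded`
#'   (named list of reasons).
#' @export
analyze_recording_set <- function(rs, protocol = NULL, n_avg = 3,
                                  qc_threshold = 0.8, qc_floor_frac = 0.5,
                                  erev_method = "interp") {
  if (is.null(protocol)) {
    prov <- attr(rs, "provenance")
    protocol <- if (!is.null(prov$protocol)) {
      voltage_protocol(prov$protocol$holding_mV, prov$protocol$agonist_ms,
                       prov$protocol$sample_ms, prov$protocol$baseline_ms)
    } else voltage_protocol()
  }
  key <- interaction(rs$condition_id, rs$replicate_id, rs$holding_mV,
                     drop = TRUE)
  pieces <- split(seq_len(nrow(rs)), key)
  peaks <- do.call(rbind, lapply(pieces, function(idx) {
    sub <- rs[idx, ]
    data.frame(condition_id = sub$condition_id[1],
               replicate_id = sub$replicate_id[1],
               holding_mV = sub$holding_mV[1],
               peak = peak_current(sub, protocol))
  }))
  rownames(peaks) <- NULL
  iv_curves <- list(); erev <- list(); discarded <- list()
  for (cid in unique(peaks$condition_id)) {
    pc <- peaks[peaks$condition_id == cid, ]
    mean_abs <- tapply(pc$peak, pc$holding_mV, function(p) abs(mean(p)))
    floor_amp <- qc_floor_frac * max(mean_abs)
    fail <- NULL
    for (v in names(mean_abs)) {
      if (mean_abs[[v]] < floor_amp) next
      qc <- qc_replicates(pc$peak[pc$holding_mV == as.numeric(v)],
                          threshold = qc_threshold)
      if (!qc$keep) {
        fail <- sprintf("at %s mV: %s", v, qc$reason)
        break
      }
    }
    if (!is.null(fail)) {
      discarded[[cid]] <- fail
      next
    }
    iv <- average_normalize(pc[, c("holding_mV", "replicate_id", "peak")],
                            n_avg = n_avg)
    iv_curves[[cid]] <- iv
    erev[[cid]] <- tryCatch(estimate_erev(iv, method = erev_method),
                            error = function(e) {
                              discarded[[cid]] <<- conditionMessage(e)
                              NULL
                            })
    if (is.null(erev[[cid]])) {
      erev[[cid]] <- NULL
      iv_curves[[cid]] <- NULL
    }
  }
  list(peaks = peaks, iv_curves = iv_curves, erev = erev,
       discarded = discarded)
}

#' Write I-V curves to CSV
#'
#' @param iv_curves Named list of `iv_curve` objects.
#' @param path Output CSV (condition_id, holding_mV, mean_norm_peak, n_used).
#' @export
write_iv_csv <- function(iv_curves, path) {
  tab <- do.call(rbind, lapply(names(iv_curves), function(cid) {
    iv <- iv_curves[[cid]]
    data.frame(condition_id = cid, holding_mV = iv$holding_mV,
               mean_norm_peak = iv$norm_peak, n_used = iv$n_used)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
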