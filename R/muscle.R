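#' Muscle cross-sectional area from mass and optimal length
#'
#' Physiological CSA assuming cylindrical geometry and a muscle density of
#' 1.06 g/cm^3: \eqn{CSA = m / (L_0 \rho)}. A specific-tension closure is
#' returned that divides force (mN) by the CSA in mm^2.
#'
#' @param mass_g muscle mass (g).
#' @param L0_cm optimal muscle length (cm).
#' @param density_g_cm3 muscle density (g/cm^3), default 1.06.
#' @return A `muscle_geometry` list: `csa_cm2`, `csa_mm2`, `csa_um2`, the
#'   inputs, and `specific_tension(force_mN)` returning mN/mm^2.
#' @export
csa_from_mass <- function(mass_g, L0_cm, density_g_cm3 = 1.06) {
  if (mass_g <= 0 || L0_cm <= 0 || density_g_cm3 <= 0)
    stop("mass, length and density must be positive")
  csa_cm2 <- mass_g / (L0_cm * density_g_cm3)
  csa_mm2 <- csa_cm2 * 100          # 1 cm^2 = 100 mm^2
  structure(list(mass_g = mass_g, L0_cm = L0_cm, density_g_cm3 = density_g_cm3,
                 csa_cm2 = csa_cm2, csa_mm2 = csa_mm2, csa_um2 = csa_cm2 * 1e8,
                 specific_tension = function(force_mN) force_mN / csa_mm2),
            class = "muscle_geometry")
}

moving_average <- function(x, w) {
  if (w <= 1) return(x)
  k <- rep(1 / w, w)
  y <- stats::filter(x, k, sides = 2)
  y <- as.numeric(y)
  # pad the filter edges with the nearest defined value
  first <- which(!is.na(y))[1]
  last <- tail(which(!is.na(y)), 1)
  y[seq_len(first - 1)] <- y[first]
  y[seq(last + 1, length.out = length(y) - last)] <- y[last]
  y
}

smoothed_derivative <- function(value, fs, smooth_ms = 5) {
  w <- max(1L, round(smooth_ms * fs / 1000))
  v <- moving_average(value, w)
  n <- length(v)
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) * fs / 2   # central differences
  d[1] <- (v[2] - v[1]) * fs
  d[n] <- (v[n] - v[n - 1]) * fs
  d
}

#' Force-frequency feature extraction
#'
#' Per-stimulation-frequency features of isometric tetanic force traces:
#' peak force above baseline, maximal rate of contraction (+dF/dT, the
#' maximum of the smoothed derivative during the rise) and maximal rate of
#' relaxation (-dF/dT, the minimum after the peak). Optionally normalized by
#' muscle CSA to give specific tension.
#'
#' @param traces named list of force [mech_trace]s, names = stimulation
#'   frequencies in Hz.
#' @param onset_s stimulus onset time (s); required.
#' @param baseline_s length of the pre-onset baseline window (s), default
#'   0.1.
#' @param smooth_ms moving-average width applied before differentiation
#'   (ms), default 5.
#' @param geometry optional [csa_from_mass()] result; when supplied, forces
#'   and rates are also reported as specific tension (per mm^2).
#' @return data.frame with one row per frequency: `freq_hz`, `peak_force`,
#'   `dfdt_max`, `dfdt_min`, and `_specific` columns when `geometry` is
#'   given.
#' @export
force_frequency_features <- function(traces, onset_s, baseline_s = 0.1,
                                     smooth_ms = 5, geometry = NULL) {
  if (missing(onset_s) || is.null(onset_s)) stop("stimulus onset marker required")
  stopifnot(length(traces) >= 1)
  rows <- lapply(names(traces), function(nm) {
    tr <- traces[[nm]]
    fs <- trace_fs(tr)
    base <- mean(tr$value[tr$time < onset_s & tr$time >= onset_s - baseline_s])
    v <- tr$value - base
    post <- tr$time >= onset_s
    peak <- max(v[post])
    if (peak <= 0) return(data.frame(freq_hz = as.numeric(nm), peak_force = 0,
                                     dfdt_max = 0, dfdt_min = 0))
    i_peak <- which(post)[which.max(v[post])]
    d <- smoothed_derivative(v, fs, smooth_ms)
    rise <- which(post & seq_along(v) <= i_peak)
    relax <- which(seq_along(v) > i_peak)
    data.frame(freq_hz = as.numeric(nm), peak_force = peak,
               dfdt_max = max(d[rise]), dfdt_min = min(d[relax]))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$freq_hz), , drop = FALSE]
  if (!is.null(geometry)) {
    out$peak_force_specific <- geometry$specific_tension(out$peak_force)
    out$dfdt_max_specific <- geometry$specific_tension(out$dfdt_max)
    out$dfdt_min_specific <- geometry$specific_tension(out$dfdt_min)
  }
  rownames(out) <- NULL
  out
}

#' Calcium-transient kinetics from a fluorescence trace
#'
#' Baseline fluorescence \eqn{F_0} is the mean over a pre-stimulus window;
#' the transient is expressed as \eqn{\Delta F / F_0 = (F - F_0)/F_0}
#' (invariant to multiplicative gain). Reported parameters: magnitude of
#' release (peak \eqn{\Delta F/F_0}), maximal rate of release (max smoothed
#' \eqn{d(\Delta F/F_0)/dt} during the stimulus), and the uptake time
#' constant from a single-exponential fit to the post-stimulus decay,
#' starting where the transient has fallen to 90% of its peak (avoiding the
#' shoulder at train cessation).
#'
#' @param trace a fluorescence [mech_trace].
#' @param stim_window numeric `c(start, end)` of the stimulus (s).
#' @param baseline_s pre-stimulus baseline window length (s), default 0.1.
#' @param smooth_ms derivative smoothing (ms), default 5.
#' @param decay_start_frac fraction of peak at which the decay fit begins
#'   (default 0.9).
#' @return A `calcium_transient` list: `F0`, `peak_dFF0`, `max_rise_rate`,
#'   `tau_decay`, `decay_converged`, plus the `dFF0` trace.
#' @export
calcium_transient_metrics <- function(trace, stim_window, baseline_s = 0.1,
                                      smooth_ms = 5, decay_start_frac = 0.9) {
  if (!identical(trace_channel(trace), "fluorescence"))
    stop("calcium_transient_metrics expects a fluorescence trace")
  t <- trace$time; f <- trace$value
  fs <- trace_fs(trace)
  base_sel <- t < stim_window[1] & t >= stim_window[1] - baseline_s
  if (!any(base_sel)) stop("no pre-stimulus baseline window available")
  F0 <- mean(f[base_sel])
  if (F0 <= 0) stop("baseline fluorescence F0 must be positive")
  dff <- (f - F0) / F0
  peak <- max(dff)
  if (peak <= 1e-12) {
    return(structure(list(F0 = F0, peak_dFF0 = 0, max_rise_rate = 0,
                          tau_decay = NA_real_, decay_converged = FALSE,
                          dFF0 = data.frame(time = t, dFF0 = dff)),
                     class = "calcium_transient"))
  }
  d <- smoothed_derivative(dff, fs, smooth_ms)
  stim <- t >= stim_window[1] & t <= stim_window[2]
  max_rise <- max(d[stim])

  post <- which(t > stim_window[2])
  tau <- NA_real_; conv <- FALSE
  if (length(post) > 10) {
    below <- post[dff[post] <= decay_start_frac * peak]
    i0 <- if (length(below)) below[1] else post[1]
    td <- t[i0:length(t)] - t[i0]
    yd <- dff[i0:length(t)]
    if (max(yd) > 1e-9) {
      fit <- tryCatch(
        minpack.lm::nlsLM(yd ~ A * exp(-td / tau),
                          start = list(A = max(yd), tau = max(td) / 3),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit)) { tau <- unname(coef(fit)["tau"]); conv <- TRUE }
    }
  }
  structure(list(F0 = F0, peak_dFF0 = peak, max_rise_rate = max_rise,
                 tau_decay = tau, decay_converged = conv,
                 dFF0 = data.frame(time = t, dFF0 = dff)),
            class = "calcium_transient")
}
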