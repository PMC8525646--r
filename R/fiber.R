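#' Fit the rate of force redevelopment (k_tr)
#'
#' Nonlinear least-squares fit of the single-exponential force redevelopment
#' following a slack-restretch maneuver,
#' \deqn{F(t) = F_{res} + (F_{max} - F_{res}) (1 - e^{-k_{tr} t}),}
#' where \eqn{F_{max}} is maximal force, \eqn{k_{tr}} the rate constant of
#' force development and \eqn{F_{res}} the residual tension immediately after
#' the maneuver. `t = 0` must be the restretch instant. Initialization takes
#' \eqn{k_{tr}} from the 63% rise time; the fit is unconstrained and
#' `F_res < 0` is reported with a flag rather than clipped.
#'
#' @param trace a [mech_trace] on the force channel with >= 20 samples.
#' @return A `ktr_fit` list: `F_max`, `k_tr`, `F_res` (trace units / s^-1),
#'   `rss`, `converged`, `negative_residual` flag.
#' @export
fit_ktr <- function(trace) {
  if (!identical(trace_channel(trace), "force"))
    stop("fit_ktr expects a force-channel trace")
  t <- trace$time; f <- trace$value
  if (length(t) < 20) stop("need at least 20 samples")
  if (sd(f) < 1e-12 * max(abs(f), 1)) stop("constant trace: k_tr unidentifiable")

  f0 <- mean(head(f, 3)); fmax0 <- mean(tail(f, round(length(f) / 10)))
  target <- f0 + 0.632 * (fmax0 - f0)
  i63 <- which(f >= target)[1]
  k0 <- if (is.na(i63) || t[i63] <= 0) 1 / (max(t) / 3) else 1 / t[i63]

  fit <- tryCatch(
    minpack.lm::nlsLM(f ~ F_res + (F_max - F_res) * (1 - exp(-k_tr * t)),
                      start = list(F_max = fmax0, k_tr = k0, F_res = f0),
                      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(F_max = NA_real_, k_tr = NA_real_, F_res = NA_real_,
                          rss = NA_real_, converged = FALSE,
                          negative_residual = NA), class = "ktr_fit"))
  }
  cf <- coef(fit)
  structure(list(F_max = unname(cf["F_max"]), k_tr = unname(cf["k_tr"]),
                 F_res = unname(cf["F_res"]),
                 rss = sum(stats::resid(fit)^2), converged = TRUE,
                 negative_residual = unname(cf["F_res"]) < 0),
            class = "ktr_fit")
}

#' Normalize steady-state tensions to maximal activation
#'
#' Submaximal tensions are expressed as a fraction of maximal
#' Ca2+-activated tension, with the normalizing value taken as the mean of
#' the maximal activations recorded at the beginning and end of the
#' protocol.
#'
#' @param pCa vector of pCa values of the submaximal activations.
#' @param tension corresponding steady tensions (any consistent unit).
#' @param p0_initial,p0_final maximal tensions at protocol start and end.
#' @return data.frame `(pCa, tension)` with tension on the \eqn{P/P_0}
#'   scale; attribute `P0` records the normalizing tension.
#' @export
normalize_tension <- function(pCa, tension, p0_initial, p0_final = p0_initial) {
  stopifnot(p0_initial > 0, p0_final > 0, length(pCa) == length(tension))
  P0 <- mean(c(p0_initial, p0_final))
  out <- data.frame(pCa = pCa, tension = tension / P0)
  attr(out, "P0") <- P0
  out
}

#' Fit the tension-pCa relationship
#'
#' Three pCa50 estimates are produced: (i) a Hill sigmoid fit
#' \deqn{P/P_0 = \frac{[Ca]^{n_H}}{[Ca]^{n_H} + K^{n_H}}
#'   = \frac{1}{1 + 10^{\,n_H (pCa - pCa_{50})}},}
#' giving `pCa50_hill` and the Hill coefficient `n_H`; and (ii, iii) the
#' x-intercepts of two straight lines fitted to the linearizing transform
#' \eqn{\log_{10}[(P/P_0)/(1 - P/P_0)]} versus pCa over the high-activation
#' (\eqn{P/P_0 >} split) and low-activation (\eqn{P/P_0 <} split) subsets.
#' Points with \eqn{P/P_0 \notin (0, 1)} are excluded from the
#' linearization.
#'
#' @param d data.frame with columns `pCa` and `tension` (normalized
#'   \eqn{P/P_0}); at least 5 pCa levels spanning the transition.
#' @param split activation level dividing the two linearized branches
#'   (default 0.5).
#' @return A `pca_fit` list: `pCa50_hill`, `n_H`, `pCa50_linearized_high`,
#'   `pCa50_linearized_low` (NA with `linearized_defined = FALSE` when all
#'   usable points fall on one side of the split), `rss`, `converged`.
#' @export
fit_tension_pca <- function(d, split = 0.5) {
  stopifnot(all(c("pCa", "tension") %in% names(d)))
  if (length(unique(d$pCa)) < 5)
    stop("need at least 5 pCa levels spanning the transition")
  pCa <- d$pCa; P <- d$tension

  i50 <- which.min(abs(P - 0.5))
  start <- list(pCa50 = pCa[i50], n_H = 2)
  fit <- tryCatch(
    minpack.lm::nlsLM(P ~ 1 / (1 + 10^(n_H * (pCa - pCa50))), start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10)),
    error = function(e) NULL)
  converged <- !is.null(fit)
  cf <- if (converged) coef(fit) else c(pCa50 = NA_real_, n_H = NA_real_)

  ok <- P > 0 & P < 1
  y <- log10(P[ok] / (1 - P[ok]))
  x <- pCa[ok]
  hi <- P[ok] > split; lo <- P[ok] < split
  xint <- function(sel) {
    if (sum(sel) < 2 || length(unique(x[sel])) < 2) return(NA_real_)
    cfl <- coef(lm(y[sel] ~ x[sel]))
    -cfl[1] / cfl[2]      # pCa at which log-odds crosses zero
  }
  p_hi <- unname(xint(hi)); p_lo <- unname(xint(lo))
  structure(list(pCa50_hill = unname(cf["pCa50"]), n_H = unname(cf["n_H"]),
                 pCa50_linearized_high = p_hi, pCa50_linearized_low = p_lo,
                 linearized_defined = !is.na(p_hi) && !is.na(p_lo),
                 rss = if (converged) sum(stats::resid(fit)^2) else NA_real_,
                 converged = converged),
            class = "pca_fit")
}

#' Fit loaded-shortening velocity from a force-clamp length trace
#'
#' The length trace during the force clamp is fit to a single decaying
#' exponential \eqn{L(t) = A e^{-kt} + C}; shortening velocity at any time is
#' the slope of the tangent to the fitted curve, and the reported velocity is
#' the extrapolation to clamp onset, \eqn{V(0) = A k} (positive =
#' shortening).
#'
#' @param trace a [mech_trace] on the length channel restricted to the clamp
#'   window, with `t = 0` at clamp onset.
#' @return A `shortening_fit` list: `A`, `k`, `C`, `velocity_t0` (= `A * k`),
#'   `velocity(t)` closure, `rss`, `converged`, `non_decaying` flag
#'   (TRUE when `A * k <= 0`).
#' @export
fit_shortening_velocity <- function(trace) {
  if (!identical(trace_channel(trace), "length"))
    stop("fit_shortening_velocity expects a length-channel trace")
  t <- trace$time; l <- trace$value
  if (length(t) < 10) stop("need at least 10 samples")
  flagged <- function(A, k, C, rss, conv) {
    structure(list(A = A, k = k, C = C,
                   velocity_t0 = if (is.na(A) || is.na(k)) NA_real_ else A * k,
                   velocity = function(tt) A * k * exp(-k * tt),
                   rss = rss, converged = conv,
                   non_decaying = is.na(A) || is.na(k) || A * k <= 0),
              class = "shortening_fit")
  }
  if (sd(l) < 1e-12 * max(abs(l), 1)) return(flagged(0, NA_real_, mean(l), 0, TRUE))

  C0 <- min(l) - 0.05 * diff(range(l))
  A0 <- l[1] - C0
  k0 <- {
    z <- l - C0
    pos <- z > 0
    if (sum(pos) > 3) max(1e-3, unname(-coef(lm(log(z[pos]) ~ t[pos]))[2])) else 1 / max(t)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(l ~ A * exp(-k * t) + C,
                      start = list(A = A0, k = k0, C = C0),
                      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit)) return(flagged(NA_real_, NA_real_, NA_real_, NA_real_, FALSE))
  cf <- coef(fit)
  flagged(unname(cf["A"]), unname(cf["k"]), unname(cf["C"]),
          sum(stats::resid(fit)^2), TRUE)
}

#' Fit the Hill force-velocity hyperbola and the power-load curve
#'
#' Least-squares fit of the Hill relation
#' \deqn{(P + a)(V + b) = (P_0 + a) b}
#' to (load, velocity) pairs, i.e. \eqn{V(P) = b (P_0 - P) / (P + a)} with
#' \eqn{P_0} fixed at the measured isometric force. The power-load curve is
#' \eqn{W(P) = P \cdot V(P)}; its maximum has the closed form
#' \eqn{P_{opt} = \sqrt{a (a + P_0)} - a}.
#'
#' @param points data.frame with columns `load` and `velocity`; loads on the
#'   same scale as `P0` (use `P0 = 1` for relative loads \eqn{P/P_0}).
#'   At least 5 distinct load levels.
#' @param P0 peak isometric force.
#' @return A `hill_fv_fit` list: `a`, `b`, `P0`, `V_max` (= `b P0 / a`),
#'   `P_opt`, `peak_power`, `velocity(P)` and `power(P)` closures, `rss`,
#'   `converged`, `invalid_params` flag (fitted `a` or `b` <= 0).
#' @export
fit_force_velocity_power <- function(points, P0 = 1) {
  stopifnot(all(c("load", "velocity") %in% names(points)), P0 > 0)
  p <- points$load; v <- points$velocity
  if (length(unique(p)) < 2) stop("loads are all equal; hyperbola unidentifiable")
  if (length(unique(p)) < 5) stop("need at least 5 distinct load levels")

  a0 <- 0.25 * P0
  b0 <- max(v) * a0 / P0
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ b * (P0 - p) / (p + a),
                      start = list(a = a0, b = max(b0, 1e-6)),
                      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(a = NA_real_, b = NA_real_, P0 = P0, V_max = NA_real_,
                          P_opt = NA_real_, peak_power = NA_real_,
                          rss = NA_real_, converged = FALSE, invalid_params = NA),
                     class = "hill_fv_fit"))
  }
  cf <- coef(fit)
  a <- unname(cf["a"]); b <- unname(cf["b"])
  vel <- function(P) b * (P0 - P) / (P + a)
  pow <- function(P) P * vel(P)
  P_opt <- sqrt(a * (a + P0)) - a
  structure(list(a = a, b = b, P0 = P0, V_max = b * P0 / a,
                 P_opt = P_opt, peak_power = pow(P_opt),
                 velocity = vel, power = pow,
                 rss = sum(stats::resid(fit)^2), converged = TRUE,
                 invalid_params = a <= 0 || b <= 0),
            class = "hill_fv_fit")
}

#' Passive sarcomere length-tension relation
#'
#' Straight-line least-squares fit of passive force against sarcomere
#' length; the slope serves as a passive stiffness surrogate.
#'
#' @param pairs data.frame with columns `sarcomere_length` (um) and `force`;
#'   at least 3 length levels.
#' @return list with `slope`, `intercept`, `slope_se`, `fit` (the `lm`
#'   object).
#' @export
passive_tension_relation <- function(pairs) {
  stopifnot(all(c("sarcomere_length", "force") %in% names(pairs)))
  if (length(unique(pairs$sarcomere_length)) < 2)
    stop("need more than one sarcomere length level")
  if (nrow(pairs) < 3) stop("need at least 3 observations")
  fit <- lm(force ~ sarcomere_length, data = pairs)
  cf <- coef(fit)
  x <- pairs$sarcomere_length
  se <- sqrt(sum(stats::resid(fit)^2) / (nrow(pairs) - 2) / sum((x - mean(x))^2))
  list(slope = unname(cf[2]), intercept = unname(cf[1]),
       slope_se = se, fit = fit)
}
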