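#' Uniformly sampled time-series trace
#'
#' Container for a single-channel recording on a uniform time grid, the input
#' to every trace-fitting operation (force redevelopment, loaded shortening,
#' tetanic force, fluorescence transients, platform vibration).
#'
#' @param time numeric vector of sample times (s), strictly increasing and
#'   uniformly spaced.
#' @param value numeric vector of samples, same length as `time`.
#' @param fs sampling rate (Hz); must match the time grid.
#' @param channel one of `"force"`, `"length"`, `"fluorescence"`,
#'   `"vibration"`.
#' @return An object of class `mech_trace`: a data.frame with columns
#'   `time` and `value` and attributes `fs` and `channel`.
#' @export
mech_trace <- function(time, value, fs, channel = c("force", "length", "fluorescence", "vibration")) {
  channel <- match.arg(channel)
  stopifnot(length(time) == length(value), length(time) >= 2)
  if (any(!is.finite(time)) || any(diff(time) <= 0))
    stop("time grid must be finite and strictly increasing")
  dt <- diff(time)
  if (max(abs(dt - 1 / fs)) > 1e-6 / fs)
    stop("sampling rate fs inconsistent with time grid")
  out <- data.frame(time = time, value = value)
  attr(out, "fs") <- fs
  attr(out, "channel") <- channel
  class(out) <- c("mech_trace", "data.frame")
  out
}

trace_fs <- function(trace) attr(trace, "fs")
trace_channel <- function(trace) attr(trace, "channel")

hex_lattice_sites <- function(d, width_nm, height_nm, theta, margin) {
  # basis vectors of a hexagonal (triangular) lattice rotated by theta
  a1 <- d * c(cos(theta), sin(theta))
  a2 <- d * c(cos(theta + pi / 3), sin(theta + pi / 3))
  nmax <- ceiling((sqrt(width_nm^2 + height_nm^2) + 2 * margin) / d) + 2
  ij <- expand.grid(i = -nmax:nmax, j = -nmax:nmax)
  cx <- width_nm / 2 + ij$i * a1[1] + ij$j * a2[1]
  cy <- height_nm / 2 + ij$i * a1[2] + ij$j * a2[2]
  keep <- cx >= -margin & cx <= width_nm + margin &
    cy >= -margin & cy <= height_nm + margin
  cbind(x = cx[keep], y = cy[keep])
}

rasterize_disk_area <- function(cx, cy, r, nm_per_pixel, nx, ny) {
  # pixel-center convention: pixel (ix, iy) has centre ((ix-.5), (iy-.5))*scale
  ix <- max(1L, floor((cx - r) / nm_per_pixel)):min(nx, ceiling((cx + r) / nm_per_pixel) + 1L)
  iy <- max(1L, floor((cy - r) / nm_per_pixel)):min(ny, ceiling((cy + r) / nm_per_pixel) + 1L)
  if (!length(ix) || !length(iy)) return(NULL)
  px <- (ix - 0.5) * nm_per_pixel
  py <- (iy - 0.5) * nm_per_pixel
  inside <- outer((px - cx)^2, (py - cy)^2, "+") <= r^2
  list(ix = ix, iy = iy, inside = inside, n_px = sum(inside))
}

#' Generate a synthetic cross-sectional electron micrograph
#'
#' Renders bright disks (thick-filament cross sections) at jittered hexagonal
#' lattice sites on a noisy darker background, and returns the image together
#' with the ground-truth filament table. The lattice orientation is drawn from
#' the seed unless fixed via `orientation`, so segmentation is exercised at
#' arbitrary rotations. Deterministic given identical arguments.
#'
#' @param size_px integer vector `c(nx, ny)`, image size in pixels.
#' @param d_nm centre-to-centre lattice spacing (nm); must exceed `2 * r_nm`.
#' @param r_nm filament radius (nm).
#' @param nm_per_pixel physical scale (nm per pixel), > 0.
#' @param jitter_sd isotropic Gaussian jitter of each lattice site (nm).
#' @param noise_sd additive Gaussian pixel noise on the \eqn{[0, 1]} scale.
#' @param seed integer seed; all randomness (orientation, jitter, noise) flows
#'   from it.
#' @param orientation lattice rotation in radians, or `NULL` (default) to draw
#'   it uniformly from the seed.
#' @param centers optional two-column matrix of filament centres (nm) that
#'   bypasses lattice generation (used for hand-built configurations).
#' @param bg,fg background and filament mean intensities on \eqn{[0, 1]}.
#' @param id micrograph identifier carried into downstream tables.
#' @return A `micrograph` list: `image` (matrix indexed `[x, y]`),
#'   `nm_per_pixel`, `id`, and `truth`, a data.frame of true centres
#'   (`cx_nm`, `cy_nm`), rasterized areas (`area_nm2`, pixel count times
#'   squared scale) and a `border` flag for disks clipped by the image edge.
#' @export
gen_em_micrograph <- function(size_px, d_nm = 40, r_nm = 9, nm_per_pixel = 1,
                              jitter_sd = 0, noise_sd = 0, seed = 1,
                              orientation = NULL, centers = NULL,
                              bg = 0.3, fg = 0.7, id = "synthetic") {
  stopifnot(length(size_px) == 2, all(size_px >= 8), nm_per_pixel > 0, r_nm > 0)
  if (d_nm <= 2 * r_nm)
    stop("lattice spacing d must exceed the filament diameter 2r (overlapping filaments)")
  nx <- as.integer(size_px[1]); ny <- as.integer(size_px[2])
  width_nm <- nx * nm_per_pixel; height_nm <- ny * nm_per_pixel

  withr::with_seed(seed, {
    if (is.null(centers)) {
      theta <- if (is.null(orientation)) stats::runif(1, 0, pi / 3) else orientation
      centers <- hex_lattice_sites(d_nm, width_nm, height_nm, theta, margin = r_nm)
      if (jitter_sd > 0)
        centers <- centers + matrix(rnorm(length(centers), 0, jitter_sd), ncol = 2)
    } else {
      theta <- if (is.null(orientation)) 0 else orientation
      centers <- as.matrix(centers)
      colnames(centers) <- c("x", "y")
    }
    # drop sites whose disk lies entirely outside the frame
    keep <- centers[, 1] > -r_nm & centers[, 1] < width_nm + r_nm &
      centers[, 2] > -r_nm & centers[, 2] < height_nm + r_nm
    centers <- centers[keep, , drop = FALSE]
    if (nrow(centers) < 7)
      stop("image too small: fewer than 7 lattice sites fall inside the frame")

    img <- matrix(bg, nx, ny)
    area <- numeric(nrow(centers))
    border <- logical(nrow(centers))
    for (k in seq_len(nrow(centers))) {
      dsk <- rasterize_disk_area(centers[k, 1], centers[k, 2], r_nm, nm_per_pixel, nx, ny)
      if (is.null(dsk) || dsk$n_px == 0) { area[k] <- 0; border[k] <- TRUE; next }
      img[dsk$ix, dsk$iy][dsk$inside] <- fg
      area[k] <- dsk$n_px * nm_per_pixel^2
      border[k] <- centers[k, 1] < r_nm || centers[k, 1] > width_nm - r_nm ||
        centers[k, 2] < r_nm || centers[k, 2] > height_nm - r_nm
    }
    if (noise_sd > 0)
      img <- img + matrix(rnorm(nx * ny, 0, noise_sd), nx, ny)

    truth <- data.frame(label = seq_len(nrow(centers)),
                        cx_nm = centers[, 1], cy_nm = centers[, 2],
                        area_nm2 = area, border = border)
    truth <- truth[truth$area_nm2 > 0, , drop = FALSE]
    structure(list(image = img, nm_per_pixel = nm_per_pixel, id = id,
                   truth = truth, orientation = theta, seed = seed),
              class = "micrograph")
  })
}

#' Generate synthetic contractile-mechanics data with known parameters
#'
#' Forward models for the four fitting procedures of the skinned-fiber
#' protocol plus the calcium transient:
#' \describe{
#'   \item{ktr}{force redevelopment after a slack-restretch,
#'     \eqn{F(t) = F_{res} + (F_{max} - F_{res})(1 - e^{-k_{tr} t})}.}
#'   \item{shortening}{isotonic length during a force clamp,
#'     \eqn{L(t) = A e^{-kt} + C}.}
#'   \item{pca}{normalized steady tension from a Hill sigmoid at the
#'     requested pCa values, \eqn{P/P_0 = 1 / (1 + 10^{n_H (pCa - pCa_{50})})}.}
#'   \item{force_velocity}{shortening velocity from the Hill hyperbola
#'     \eqn{V = b (P_0 - P) / (P + a)} at the requested loads.}
#'   \item{calcium}{a fluorescence transient: baseline `F0`, saturating rise
#'     to `peak_dFF0` during the stimulus, then single-exponential decay with
#'     `tau_decay`.}
#' }
#'
#' @param kind one of `"ktr"`, `"shortening"`, `"pca"`, `"force_velocity"`,
#'   `"calcium"`.
#' @param params named list of model parameters (see Details above); rate and
#'   shape parameters must be strictly positive.
#' @param noise_sd additive Gaussian noise SD in signal units.
#' @param fs sampling rate (Hz) for trace kinds.
#' @param duration trace duration (s) for trace kinds.
#' @param pca_values pCa grid for `kind = "pca"`.
#' @param loads relative loads \eqn{P/P_0} for `kind = "force_velocity"`.
#' @param seed integer seed.
#' @return For trace kinds, a [mech_trace] with a `truth` attribute holding
#'   the generating parameters; for `"pca"` a data.frame `(pCa, tension)`;
#'   for `"force_velocity"` a data.frame `(load, velocity)` (loads on the
#'   \eqn{P/P_0} scale).
#' @export
gen_mechanics_data <- function(kind, params, noise_sd = 0, fs = 1000,
                               duration = 1,
                               pca_values = seq(7.0, 4.5, by = -0.25),
                               loads = seq(0.05, 0.95, by = 0.1), seed = 1) {
  kind <- match.arg(kind, c("ktr", "shortening", "pca", "force_velocity", "calcium"))
  check_pos <- function(nms) {
    missing <- setdiff(nms, names(params))
    if (length(missing)) stop("missing parameters: ", paste(missing, collapse = ", "))
  }
  rates <- switch(kind,
    ktr = "k_tr", shortening = "k", pca = "n_H",
    force_velocity = c("a", "b", "P0"), calcium = "tau_decay")
  check_pos(rates)
  if (any(unlist(params[rates]) <= 0))
    stop("rate/shape parameters must be strictly positive: ",
         paste(rates, collapse = ", "))

  withr::with_seed(seed, {
    switch(kind,
      ktr = {
        check_pos(c("F_max", "F_res"))
        t <- seq(0, duration, by = 1 / fs)
        f <- params$F_res + (params$F_max - params$F_res) * (1 - exp(-params$k_tr * t))
        tr <- mech_trace(t, f + rnorm(length(t), 0, noise_sd), fs, "force")
        attr(tr, "truth") <- params
        tr
      },
      shortening = {
        check_pos(c("A", "C"))
        t <- seq(0, duration, by = 1 / fs)
        l <- params$A * exp(-params$k * t) + params$C
        tr <- mech_trace(t, l + rnorm(length(t), 0, noise_sd), fs, "length")
        attr(tr, "truth") <- params
        tr
      },
      pca = {
        check_pos("pCa50")
        p <- 1 / (1 + 10^(params$n_H * (pca_values - params$pCa50)))
        out <- data.frame(pCa = pca_values,
                          tension = p + rnorm(length(p), 0, noise_sd))
        attr(out, "truth") <- params
        out
      },
      force_velocity = {
        p <- loads * params$P0
        v <- params$b * (params$P0 - p) / (p + params$a)
        out <- data.frame(load = loads,
                          velocity = v + rnorm(length(v), 0, noise_sd))
        attr(out, "truth") <- params
        out
      },
      calcium = {
        check_pos(c("F0", "peak_dFF0"))
        tau_rise <- if (is.null(params$tau_rise)) 0.01 else params$tau_rise
        stim_on <- if (is.null(params$stim_onset)) 0.2 else params$stim_onset
        stim_dur <- if (is.null(params$stim_dur)) 0.5 else params$stim_dur
        t <- seq(0, duration, by = 1 / fs)
        dff <- numeric(length(t))
        rise <- t >= stim_on & t <= stim_on + stim_dur
        dff[rise] <- params$peak_dFF0 * (1 - exp(-(t[rise] - stim_on) / tau_rise))
        after <- t > stim_on + stim_dur
        peak_end <- params$peak_dFF0 * (1 - exp(-stim_dur / tau_rise))
        dff[after] <- peak_end * exp(-(t[after] - stim_on - stim_dur) / params$tau_decay)
        f <- params$F0 * (1 + dff)
        tr <- mech_trace(t, f + rnorm(length(t), 0, noise_sd), fs, "fluorescence")
        attr(tr, "truth") <- c(params, list(tau_rise = tau_rise, stim_onset = stim_on,
                                            stim_dur = stim_dur))
        tr
      })
  })
}

#' Generate a synthetic tremor-plate recording
#'
#' White-noise platform baseline with sinusoidal bursts of the stated
#' frequency inserted at the stated times, emulating the vibration signal of
#' an anesthetized animal on a force-plate (1 kHz sampling, minutes-long
#' recordings). The ground-truth event list is returned alongside the signal.
#'
#' @param fs sampling rate (Hz), default 1000; must exceed `2 * f0`.
#' @param duration recording length (s).
#' @param f0 burst frequency (Hz); 55--65 Hz is the band of interest.
#' @param burst_times numeric vector of burst start times (s).
#' @param burst_dur burst duration (s), scalar or per-burst.
#' @param amp burst amplitude (V); `amp = 0` yields pure noise and an empty
#'   event list.
#' @param noise_sd baseline noise SD (V).
#' @param seed integer seed.
#' @param animal_id,genotype labels carried into downstream summaries.
#' @return A `tremor_recording` list: `signal`, `fs`, `duration`, `f0`,
#'   `events` (data.frame `start_s`, `end_s`), `animal_id`, `genotype`.
#' @export
gen_tremor_signal <- function(fs = 1000, duration = 360, f0 = 60,
                              burst_times = numeric(0), burst_dur = 0.5,
                              amp = 0.5, noise_sd = 0.05, seed = 1,
                              animal_id = "animal", genotype = "WT") {
  stopifnot(fs > 2 * f0, duration > 0, noise_sd >= 0, amp >= 0)
  burst_dur <- rep_len(burst_dur, length(burst_times))
  if (length(burst_times) && any(burst_times < 0 | burst_times + burst_dur > duration))
    stop("burst windows exceed the recording duration")
  n <- round(fs * duration)
  t <- (seq_len(n) - 1) / fs
  withr::with_seed(seed, {
    x <- rnorm(n, 0, noise_sd)
    if (amp > 0) {
      for (k in seq_along(burst_times)) {
        idx <- which(t >= burst_times[k] & t < burst_times[k] + burst_dur[k])
        x[idx] <- x[idx] + amp * sin(2 * pi * f0 * (t[idx] - burst_times[k]))
      }
    }
    events <- if (amp > 0 && length(burst_times)) {
      data.frame(start_s = burst_times, end_s = burst_times + burst_dur)
    } else data.frame(start_s = numeric(0), end_s = numeric(0))
    structure(list(signal = x, fs = fs, duration = duration, f0 = f0,
                   events = events[order(events$start_s), , drop = FALSE],
                   animal_id = animal_id, genotype = genotype, seed = seed),
              class = "tremor_recording")
  })
}

#' Generate synthetic droplet digital PCR counts
#'
#' Two-channel Poisson partitioning: each droplet is positive with
#' probability \eqn{1 - e^{-c v}} for channel concentration \eqn{c}
#' (copies/uL) and droplet volume \eqn{v} (uL). The VIC channel reports the
#' wild-type allele and the FAM channel the variant allele.
#'
#' @param conc_wt,conc_var channel concentrations (copies/uL), >= 0.
#' @param n_droplets number of droplets analyzed.
#' @param droplet_vol droplet volume (uL); default 8.5e-4 (0.85 nL).
#' @param seed integer seed.
#' @param sample_id,genotype labels carried into the counts table.
#' @return A one-row data.frame with columns `sample_id`, `genotype`,
#'   `vic_pos`, `vic_total`, `fam_pos`, `fam_total`, `droplet_vol`.
#' @export
gen_ddpcr_counts <- function(conc_wt, conc_var, n_droplets = 20000,
                             droplet_vol = 0.00085, seed = 1,
                             sample_id = "sample", genotype = "WT") {
  stopifnot(conc_wt >= 0, conc_var >= 0, n_droplets >= 1)
  if (droplet_vol <= 0) stop("droplet_vol must be positive")
  withr::with_seed(seed, {
    p_wt <- 1 - exp(-conc_wt * droplet_vol)
    p_var <- 1 - exp(-conc_var * droplet_vol)
    data.frame(sample_id = sample_id, genotype = genotype,
               vic_pos = rbinom(1, n_droplets, p_wt), vic_total = n_droplets,
               fam_pos = rbinom(1, n_droplets, p_var), fam_total = n_droplets,
               droplet_vol = droplet_vol)
  })
}

#' Generate a synthetic tetanic force trace
#'
#' Saturating-exponential rise during the stimulus train followed by
#' exponential relaxation, the standard shape of an isometric tetanus; used
#' to exercise force--frequency feature extraction.
#'
#' @param F_peak plateau force above baseline (mN).
#' @param tau_rise,tau_decay rise and relaxation time constants (s).
#' @param onset stimulus onset (s).
#' @param train_dur stimulus train duration (s), default 0.25.
#' @param fs sampling rate (Hz).
#' @param duration trace length (s).
#' @param baseline resting force (mN).
#' @param noise_sd additive Gaussian noise SD (mN).
#' @param seed integer seed.
#' @return A [mech_trace] (force channel) with a `truth` attribute.
#' @export
gen_tetanus_trace <- function(F_peak, tau_rise = 0.02, tau_decay = 0.04,
                              onset = 0.1, train_dur = 0.25, fs = 1000,
                              duration = 1, baseline = 0, noise_sd = 0, seed = 1) {
  stopifnot(F_peak >= 0, tau_rise > 0, tau_decay > 0, onset >= 0,
            onset + train_dur < duration)
  t <- seq(0, duration, by = 1 / fs)
  f <- rep(baseline, length(t))
  rise <- t >= onset & t <= onset + train_dur
  f[rise] <- baseline + F_peak * (1 - exp(-(t[rise] - onset) / tau_rise))
  end_val <- F_peak * (1 - exp(-train_dur / tau_rise))
  after <- t > onset + train_dur
  f[after] <- baseline + end_val * exp(-(t[after] - onset - train_dur) / tau_decay)
  withr::with_seed(seed, {
    tr <- mech_trace(t, f + rnorm(length(t), 0, noise_sd), fs, "force")
    attr(tr, "truth") <- list(F_peak = F_peak, tau_rise = tau_rise,
                              tau_decay = tau_decay, onset = onset,
                              train_dur = train_dur, baseline = baseline)
    tr
  })
}
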