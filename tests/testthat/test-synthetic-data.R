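test_that("EM generator renders a perfect 7-site lattice with known geometry", {
  ctr <- hex7_centers(d = 40, origin = c(80, 80))
  m <- gen_em_micrograph(c(160, 160), d_nm = 40, r_nm = 9, nm_per_pixel = 1,
                         jitter_sd = 0, noise_sd = 0, centers = ctr, seed = 1)
  expect_equal(nrow(m$truth), 7)
  # 6-NN distance of the central site is exactly the lattice constant
  d <- sqrt((m$truth$cx_nm[-1] - m$truth$cx_nm[1])^2 +
              (m$truth$cy_nm[-1] - m$truth$cy_nm[1])^2)
  expect_equal(mean(sort(d)[1:6]), 40, tolerance = 1e-12)
})

test_that("EM generator is deterministic and rejects overlapping filaments", {
  m1 <- gen_em_micrograph(c(128, 128), 40, 9, 1, jitter_sd = 1, noise_sd = 0.05, seed = 5)
  m2 <- gen_em_micrograph(c(128, 128), 40, 9, 1, jitter_sd = 1, noise_sd = 0.05, seed = 5)
  expect_identical(m1$image, m2$image)
  expect_identical(m1$truth, m2$truth)
  m3 <- gen_em_micrograph(c(128, 128), 40, 9, 1, jitter_sd = 1, noise_sd = 0.05, seed = 6)
  expect_false(identical(m1$image, m3$image))
  expect_error(gen_em_micrograph(c(128, 128), d_nm = 17, r_nm = 9), "overlap")
})

test_that("rasterized disk area matches the analytic circle area within 2%", {
  # independent oracle: count pixel centres inside the circle directly
  r <- 9; cx <- 40.5
  px <- (1:80) - 0.5
  oracle <- sum(outer((px - cx)^2, (px - cx)^2, "+") <= r^2)
  m <- gen_em_micrograph(c(160, 160), 40, 9, 1, jitter_sd = 0, noise_sd = 0,
                         centers = hex7_centers(40, c(80, 80)), seed = 1)
  expect_equal(oracle, 253)   # frozen from the oracle above
  expect_true(all(abs(m$truth$area_nm2 - pi * 81) / (pi * 81) < 0.02))
})

test_that("mechanics forward models match their closed forms", {
  tr <- gen_mechanics_data("ktr", list(F_max = 1, k_tr = 10, F_res = 0), fs = 1000)
  expect_equal(tr$value[tr$time == 0.1], 1 - exp(-1), tolerance = 1e-12)

  d <- gen_mechanics_data("pca", list(pCa50 = 6, n_H = 4), pca_values = c(7, 6.5, 6, 5.5, 5))
  expect_equal(d$tension[d$pCa == 6], 0.5, tolerance = 1e-12)

  fv <- gen_mechanics_data("force_velocity", list(a = 0.25, b = 0.5, P0 = 1),
                           loads = c(0, 0.2, 0.5, 0.8, 1))
  expect_equal(fv$velocity[fv$load == 1], 0, tolerance = 1e-12)
  expect_equal(fv$velocity[fv$load == 0], 0.5 * 1 / 0.25, tolerance = 1e-12)

  sh <- gen_mechanics_data("shortening", list(A = 0.1, k = 20, C = 0.9))
  expect_equal(sh$value[1], 1.0, tolerance = 1e-12)
  expect_error(gen_mechanics_data("ktr", list(F_max = 1, k_tr = -1, F_res = 0)),
               "strictly positive")
  expect_error(gen_mechanics_data("wiggle", list()), "arg")
})

test_that("tremor generator places bursts as stated and is band-limited", {
  r0 <- gen_tremor_signal(duration = 30, amp = 0, noise_sd = 0.05, seed = 2)
  expect_equal(nrow(r0$events), 0)

  bt <- c(2, 7, 12, 17, 22)
  r <- gen_tremor_signal(duration = 30, f0 = 60, burst_times = bt, burst_dur = 0.5,
                         amp = 0.5, noise_sd = 0.05, seed = 2)
  expect_equal(nrow(r$events), 5)
  expect_identical(r$signal,
                   gen_tremor_signal(duration = 30, f0 = 60, burst_times = bt,
                                     burst_dur = 0.5, amp = 0.5, noise_sd = 0.05,
                                     seed = 2)$signal)

  # noiseless burst: discrete-Fourier oracle puts the peak at 60 Hz, and
  # out-of-band power within f0 +/- 2 Hz is < 1% of in-band power
  rn <- gen_tremor_signal(duration = 30, f0 = 60, burst_times = 5, burst_dur = 1,
                          amp = 0.5, noise_sd = 0, seed = 1)
  seg <- rn$signal[5001:6000]
  pw <- Mod(fft(seg))^2
  freq <- (seq_along(seg) - 1) * 1000 / length(seg)
  half <- freq > 0 & freq <= 500
  pk <- freq[half][which.max(pw[half])]
  expect_lt(abs(pk - 60), 1.0)    # within the 1 Hz frequency resolution
  inb <- half & freq >= 58 & freq <= 62
  expect_lt(sum(pw[half & !inb]) / sum(pw[inb]), 0.01)

  expect_error(gen_tremor_signal(duration = 10, burst_times = 9.8, burst_dur = 0.5),
               "exceed")
})

test_that("ddPCR generator follows the Poisson partitioning model", {
  z <- gen_ddpcr_counts(conc_wt = 1000, conc_var = 0, n_droplets = 20000, seed = 3)
  expect_equal(z$fam_pos, 0)

  # c * v = ln 2 gives 50% positive droplets in expectation
  v <- 0.00085
  z2 <- gen_ddpcr_counts(conc_wt = log(2) / v, conc_var = 0,
                         n_droplets = 20000, seed = 4)
  p_hat <- z2$vic_pos / z2$vic_total
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / 20000))

  # concentration recovery within 3 SE (delta-method SE of the inversion)
  conc <- 800
  z3 <- gen_ddpcr_counts(conc, 0, n_droplets = 20000, seed = 5)
  p <- z3$vic_pos / z3$vic_total
  lam <- -log(1 - p) / v
  se <- sqrt(p * (1 - p) / 20000) / ((1 - p) * v)
  expect_lt(abs(lam - conc), 3 * se)
  expect_error(gen_ddpcr_counts(100, 100, droplet_vol = 0), "positive")
})

test_that("every generator is a pure function of its parameters and seed", {
  a <- gen_mechanics_data("ktr", list(F_max = 1, k_tr = 10, F_res = 0.05),
                          noise_sd = 0.02, seed = 11)
  b <- gen_mechanics_data("ktr", list(F_max = 1, k_tr = 10, F_res = 0.05),
                          noise_sd = 0.02, seed = 11)
  expect_identical(a$value, b$value)
  expect_identical(gen_ddpcr_counts(500, 500, seed = 12),
                   gen_ddpcr_counts(500, 500, seed = 12))
  expect_identical(gen_tetanus_trace(10, noise_sd = 0.1, seed = 13)$value,
                   gen_tetanus_trace(10, noise_sd = 0.1, seed = 13)$value)
})

test_that("noiseless generation then fitting round-trips each model kind", {
  tr <- gen_mechanics_data("ktr", list(F_max = 1, k_tr = 10, F_res = 0.05))
  kf <- fit_ktr(tr)
  expect_equal(kf$k_tr, 10, tolerance = 1e-6)

  d <- gen_mechanics_data("pca", list(pCa50 = 6, n_H = 4))
  pf <- fit_tension_pca(d)
  expect_equal(pf$pCa50_hill, 6, tolerance = 1e-6)

  sh <- gen_mechanics_data("shortening", list(A = 0.1, k = 20, C = 0.9), duration = 0.25)
  sf <- fit_shortening_velocity(sh)
  expect_equal(sf$velocity_t0, 2, tolerance = 1e-6)

  fv <- gen_mechanics_data("force_velocity", list(a = 0.25, b = 0.5, P0 = 1))
  hf <- fit_force_velocity_power(fv, P0 = 1)
  expect_equal(c(hf$a, hf$b), c(0.25, 0.5), tolerance = 1e-6)

  ca <- gen_mechanics_data("calcium", list(F0 = 100, peak_dFF0 = 2, tau_decay = 0.15),
                           duration = 2, fs = 2000)
  cm <- calcium_transient_metrics(ca, c(0.2, 0.7))
  expect_equal(cm$peak_dFF0, 2, tolerance = 1e-3)
  expect_equal(cm$tau_decay, 0.15, tolerance = 1e-3)
})
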