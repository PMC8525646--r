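test_that("k_tr fit recovers noiseless parameters and flags degenerate traces", {
  tr <- gen_mechanics_data("ktr", list(F_max = 1, k_tr = 10, F_res = 0.05))
  kf <- fit_ktr(tr)
  expect_true(kf$converged)
  expect_equal(kf$F_max, 1, tolerance = 1e-6)
  expect_equal(kf$k_tr, 10, tolerance = 1e-6)
  expect_equal(kf$F_res, 0.05, tolerance = 1e-6)
  expect_false(kf$negative_residual)

  flat <- mech_trace(seq(0, 1, by = 0.01), rep(0.5, 101), 100, "force")
  expect_error(fit_ktr(flat), "unidentifiable")
  expect_error(fit_ktr(gen_mechanics_data("shortening",
                                          list(A = 0.1, k = 20, C = 0.9))),
               "force")
})

test_that("k_tr estimates on noisy traces agree with a grid-search SSE oracle", {
  errs <- sapply(1:25, function(s) {
    tr <- gen_mechanics_data("ktr", list(F_max = 1, k_tr = 10, F_res = 0.05),
                             noise_sd = 0.95 / 20, seed = s)
    kf <- fit_ktr(tr)
    if (s <= 3) {
      # independent oracle: profile SSE over a fine k grid, least squares in
      # the linear parameters at each k
      sse <- sapply(seq(5, 20, by = 0.01), function(k) {
        X <- cbind(1, 1 - exp(-k * tr$time))
        sum(lm.fit(X, tr$value)$residuals^2)
      })
      k_grid <- seq(5, 20, by = 0.01)[which.min(sse)]
      expect_lt(abs(kf$k_tr - k_grid), 0.011)
    }
    abs(kf$k_tr - 10) / 10
  })
  expect_lt(median(errs), 0.02)
})

test_that("k_tr is invariant to uniform force rescaling", {
  tr <- gen_mechanics_data("ktr", list(F_max = 1, k_tr = 12, F_res = 0.05),
                           noise_sd = 0.02, seed = 3)
  tr2 <- tr; tr2$value <- tr$value * 37.5
  attr(tr2, "fs") <- attr(tr, "fs"); attr(tr2, "channel") <- "force"
  class(tr2) <- class(tr)
  k1 <- fit_ktr(tr); k2 <- fit_ktr(tr2)
  expect_equal(k2$k_tr, k1$k_tr, tolerance = 1e-8)
  expect_equal(k2$F_max, k1$F_max * 37.5, tolerance = 1e-6)
})

test_that("tension normalization averages initial and final maximal activations", {
  d <- normalize_tension(c(6.4, 6.0, 5.6), c(10, 25, 45), p0_initial = 52, p0_final = 48)
  expect_equal(attr(d, "P0"), 50)
  expect_equal(d$tension, c(0.2, 0.5, 0.9))
})

test_that("tension-pCa fit returns three coincident pCa50 values on pure Hill data", {
  d <- gen_mechanics_data("pca", list(pCa50 = 6, n_H = 4))
  pf <- fit_tension_pca(d)
  expect_equal(pf$pCa50_hill, 6, tolerance = 1e-4)
  expect_equal(pf$pCa50_linearized_high, 6, tolerance = 1e-4)
  expect_equal(pf$pCa50_linearized_low, 6, tolerance = 1e-4)
  expect_equal(pf$n_H, 4, tolerance = 1e-4)
  # Hill estimate lies between (or within 0.01 of) the linearized intercepts
  lo <- min(pf$pCa50_linearized_high, pf$pCa50_linearized_low) - 0.01
  hi <- max(pf$pCa50_linearized_high, pf$pCa50_linearized_low) + 0.01
  expect_true(pf$pCa50_hill >= lo && pf$pCa50_hill <= hi)
})

test_that("noisy tension-pCa data recover pCa50 within 0.02 units (median)", {
  errs <- sapply(1:25, function(s) {
    d <- gen_mechanics_data("pca", list(pCa50 = 6, n_H = 4), noise_sd = 0.03, seed = s)
    abs(fit_tension_pca(d)$pCa50_hill - 6)
  })
  expect_lt(median(errs), 0.02)
  # spot-check against a fine grid search over (pCa50, n_H)
  d <- gen_mechanics_data("pca", list(pCa50 = 6, n_H = 4), noise_sd = 0.03, seed = 1)
  grid <- expand.grid(pCa50 = seq(5.9, 6.1, by = 0.001), n_H = seq(3, 5, by = 0.02))
  sse <- mapply(function(p50, nh) sum((d$tension - 1 / (1 + 10^(nh * (d$pCa - p50))))^2),
                grid$pCa50, grid$n_H)
  best <- grid$pCa50[which.min(sse)]
  expect_lt(abs(fit_tension_pca(d)$pCa50_hill - best), 0.0015)
})

test_that("one-sided tension-pCa data flag the linearized intercepts", {
  d <- data.frame(pCa = c(7, 6.8, 6.6, 6.4, 6.2), tension = c(0.01, 0.02, 0.05, 0.1, 0.2))
  pf <- fit_tension_pca(d)
  expect_false(pf$linearized_defined)
  expect_true(is.na(pf$pCa50_linearized_high))
  expect_error(fit_tension_pca(data.frame(pCa = c(7, 6, 5), tension = c(0, 0.5, 1))),
               "5 pCa levels")
})

test_that("shortening fit extrapolates velocity to clamp onset", {
  sh <- gen_mechanics_data("shortening", list(A = 0.1, k = 20, C = 0.9), duration = 0.25)
  sf <- fit_shortening_velocity(sh)
  expect_equal(sf$velocity_t0, 2.0, tolerance = 1e-6)
  expect_false(sf$non_decaying)

  # tangent slope against a central-difference oracle at three time points
  fitted_L <- function(t) sf$A * exp(-sf$k * t) + sf$C
  h <- 1e-6
  for (t0 in c(0.02, 0.08, 0.15)) {
    num <- -(fitted_L(t0 + h) - fitted_L(t0 - h)) / (2 * h)
    expect_equal(sf$velocity(t0), num, tolerance = 1e-4)
  }

  flat <- mech_trace(seq(0, 0.25, by = 0.001), rep(0.9, 251), 1000, "length")
  expect_true(fit_shortening_velocity(flat)$non_decaying)
})

test_that("Hill force-velocity fit recovers exact hyperbola and peak power", {
  fv <- gen_mechanics_data("force_velocity", list(a = 0.25, b = 0.5, P0 = 1),
                           loads = c(0.02, seq(0.1, 0.9, by = 0.1), 0.98))
  hf <- fit_force_velocity_power(fv, P0 = 1)
  expect_equal(hf$a, 0.25, tolerance = 1e-6)
  expect_equal(hf$b, 0.5, tolerance = 1e-6)
  expect_equal(hf$V_max, 2, tolerance = 1e-6)
  expect_equal(hf$velocity(1), 0, tolerance = 1e-12)

  # closed-form optimum load against dense numerical maximization
  grid <- seq(1e-5, 1 - 1e-5, length.out = 2e5)
  p_num <- grid[which.max(hf$power(grid))]
  expect_lt(abs(hf$P_opt - p_num) / p_num, 0.001)
  expect_false(hf$invalid_params)

  expect_error(fit_force_velocity_power(
    data.frame(load = rep(0.5, 6), velocity = 1:6), P0 = 1), "equal")
})

test_that("force-velocity fit is consistent between relative and absolute loads", {
  P0_abs <- 30
  fv_rel <- gen_mechanics_data("force_velocity", list(a = 0.25, b = 0.5, P0 = 1),
                               noise_sd = 0.01, seed = 5)
  fv_abs <- fv_rel
  fv_abs$load <- fv_rel$load * P0_abs
  h_rel <- fit_force_velocity_power(fv_rel, P0 = 1)
  h_abs <- fit_force_velocity_power(fv_abs, P0 = P0_abs)
  expect_equal(h_abs$a / P0_abs, h_rel$a, tolerance = 1e-6)
  expect_equal(h_abs$V_max, h_rel$V_max, tolerance = 1e-6)
  expect_equal(h_abs$P_opt / P0_abs, h_rel$P_opt, tolerance = 1e-6)
})

test_that("passive length-tension relation is a least-squares line", {
  d <- data.frame(sarcomere_length = c(2.4, 2.6, 2.8, 3.0), force = c(0.8, 1.2, 1.6, 2.0))
  pt <- passive_tension_relation(d)
  expect_equal(pt$slope, 2, tolerance = 1e-12)
  d0 <- data.frame(sarcomere_length = c(2.4, 2.6, 2.8), force = c(0, 0, 0))
  expect_equal(passive_tension_relation(d0)$slope, 0)
  expect_error(passive_tension_relation(
    data.frame(sarcomere_length = rep(2.5, 4), force = 1:4)), "length level")

  # noisy line: slope within 3 analytic SEs of truth, matching the
  # closed-form simple-regression solution
  withr::with_seed(8, {
    x <- seq(2.2, 3.2, by = 0.1)
    y <- 2 * x - 3 + rnorm(length(x), 0, 0.05)
  })
  pt2 <- passive_tension_relation(data.frame(sarcomere_length = x, force = y))
  slope_cf <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(pt2$slope, slope_cf, tolerance = 1e-12)
  expect_lt(abs(pt2$slope - 2), 3 * pt2$slope_se)
})
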