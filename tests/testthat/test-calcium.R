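# Calcium module: trace extraction, per-beat kinetics, and the tau fit.

test_that("extract_trace recovers a uniform cell on a flat background", {
  frames <- array(10, dim = c(3, 40, 40))
  for (ti in 1:3) frames[ti, 10:30, 10:30] <- 100
  tr <- extract_trace(ca_stack(frames, frame_rate = 50))
  expect_equal(tr$value, rep(90, 3), tolerance = 1e-12)
  expect_true(tr$background_corrected)
  expect_error(extract_trace(ca_stack(array(0, c(3, 20, 20)), 50)),
               "no foreground")
})

test_that("extraction matches the ground-truth-mask oracle", {
  sim <- gen_imaging("WT_12D_GlcFA",
                     noise = noise_model("gaussian", sd = 0.5, seed = 2))
  tr <- extract_trace(sim$stack)
  oracle <- oracle_trace_from_truth(sim)
  # same mask modulo edge pixels, so traces agree within the noise scale
  expect_lt(max(abs(tr$value - oracle)), 0.5)
  expect_gt(cor(tr$value, sim$truth$trace$value), 0.999)
})

test_that("triangular transient yields closed-form kinetics", {
  # F0 = 1, peak 2 at 0.5 s after onset, linear return to baseline over 1 s:
  # crossings of the linear decay give T50R = 0.5 s, T90R = 0.9 s
  dt <- 0.005
  t <- seq(0, 12, by = dt)
  one_beat <- function(t0) {
    w <- numeric(length(t)); s <- t - t0
    up <- s >= 0 & s < 0.5; w[up] <- s[up] / 0.5
    dn <- s >= 0.5 & s <= 1.5; w[dn] <- 1 - (s[dn] - 0.5)
    w
  }
  v <- 1 + one_beat(1) + one_beat(3.5) + one_beat(6) + one_beat(8.5)
  m <- transient_metrics(fluor_trace(t, v, TRUE))
  expect_equal(nrow(m), 4)
  avg <- summary(m)
  # the 5%-of-amplitude onset rule places the upstroke 0.05 * rise after
  # the geometric corner, so T_peak is shorter by up to 0.025 s here
  expect_equal(unname(avg["fold"]), 2.0, tolerance = 0.02)
  expect_equal(unname(avg["T_peak"]), 0.5, tolerance = 0.06)
  expect_equal(unname(avg["T50R"]), 0.5, tolerance = 0.01)
  expect_equal(unname(avg["T90R"]), 0.9, tolerance = 0.01)
  expect_equal(unname(avg["R_peak"]), 1 / 0.5, tolerance = 0.06)
  expect_equal(unname(avg["R50R"]), 0.5 / 0.5, tolerance = 0.02)
  expect_equal(unname(avg["R90R"]), 0.9 / 0.9, tolerance = 0.02)
})

test_that("degenerate traces error and short trains warn", {
  t <- seq(0, 5, by = 0.02)
  expect_error(transient_metrics(fluor_trace(t, rep(1, length(t)), TRUE)),
               "no transients")
  v <- 1 + exp(-((t - 2.5) / 0.1)^2)  # single bump
  expect_warning(transient_metrics(fluor_trace(t, v, TRUE)),
                 "fewer than 4")
})

test_that("tau fit is exact on noiseless decays and matches a grid oracle", {
  t <- seq(0, 4, by = 0.01)
  v <- 2 * exp(-t / 1.0) + 1
  fit <- fit_tau(list(time = t, value = v), f0 = 1)
  expect_equal(fit$tau, 1.0, tolerance = 1e-6)
  expect_error(fit_tau(list(time = t, value = rev(v)), f0 = 1),
               "does not decay")
  # noisy segment: within 2% of the dense grid-search oracle
  set.seed(9)
  vn <- v + rnorm(length(v), sd = 0.05 * 2)
  fitn <- fit_tau(list(time = t, value = vn), f0 = 1)
  sel <- {
    rel <- (vn[1] - vn) / (vn[1] - 1)
    which(rel >= 0.1 & rel <= 0.9)
  }
  oracle <- oracle_tau_grid(t[sel] - t[1], vn[sel])
  expect_equal(fitn$tau, oracle, tolerance = 0.02)
})

test_that("fold is scale-invariant and rate identities hold", {
  sim <- gen_imaging("Mut_12D_GlcFA")
  tr <- extract_trace(sim$stack)
  m1 <- transient_metrics(tr, pacing_hz = 0.5)
  scaled <- fluor_trace(tr$time, 3.7 * tr$value, TRUE)
  m2 <- transient_metrics(scaled, pacing_hz = 0.5)
  expect_equal(m2$fold, m1$fold, tolerance = 1e-9)
  expect_true(all(m1$T50R <= m1$T90R, na.rm = TRUE))
  # R90R / R50R = (0.9 / 0.5) * (T50R / T90R)
  expect_equal(m1$R90R / m1$R50R, 1.8 * m1$T50R / m1$T90R, tolerance = 1e-9)
})

test_that("metrics converge to ground truth as noise shrinks", {
  errs <- vapply(c(1.0, 0.25, 0.05), function(sd) {
    sim <- gen_imaging("WT_12D_GlcFA",
                       noise = noise_model("gaussian", sd = sd, seed = 31))
    m <- transient_metrics(extract_trace(sim$stack), pacing_hz = 0.5)
    abs(unname(summary(m)["fold"]) - 2.03)
  }, numeric(1))
  expect_lt(errs[3], 0.01)
  expect_lt(errs[3], errs[1] + 1e-9)
})

test_that("end-to-end noiseless recovery hits every calcium preset target", {
  for (p in c("WT_12D_GlcFA", "Mut_12D_GlcFA")) {
    sim <- gen_imaging(p)
    tr <- extract_trace(sim$stack)
    m <- transient_metrics(tr, pacing_hz = 0.5)
    expect_equal(unname(summary(m)["fold"]), preset_value(p, "ca_fold"),
                 tolerance = 0.01)
    fit <- fit_tau(relaxation_window(tr, m, 1), f0 = m$F0[1])
    expect_equal(fit$tau, preset_value(p, "ca_tau"), tolerance = 1e-3)
  }
})
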