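# The fits start away from the generator truth throughout (the model handed
# to the fitter carries the starting estimate).

start_at <- function(model, log_K) set_free_constants(model, log_K)

test_that("variable projection reproduces the normal-equations solution", {
  sim <- gen_spectral_titration(log_K = 4, snr = Inf, seed = 1)
  C <- anionbind:::design_matrix(sim$schedule, sim$model, "spectral")
  S_pkg <- anionbind:::solve_molar_response(sim$series$values, C)
  S_orc <- oracle_molar_response(sim$series$values, C)
  expect_equal(unname(S_pkg), unname(S_orc), tolerance = 1e-9)
})

test_that("zero-noise spectral fit recovers the constant exactly", {
  sim <- gen_spectral_titration(log_K = 4, snr = Inf, seed = 1)
  fit <- fit_spectral(sim$series, sim$schedule, start_at(sim$model, 3.3))
  expect_equal(fit$log_beta$log_beta, 4, tolerance = 1e-6)
  expect_lt(sqrt(fit$ss), 1e-10 * max(abs(sim$series$values)))
  expect_lt(fit$log_beta$se, 1e-6)
})

test_that("noisy spectral recovery is within the documented tolerance", {
  sim <- gen_spectral_titration(log_K = 4, snr = 100, seed = 7)
  fit <- fit_spectral(sim$series, sim$schedule, start_at(sim$model, 3))
  expect_lt(abs(fit$log_beta$log_beta - 4), 0.05)
})

test_that("residual at the optimum is orthogonal to the design space", {
  sim <- gen_spectral_titration(log_K = 3.5, snr = 50, seed = 11)
  fit <- fit_spectral(sim$series, sim$schedule, start_at(sim$model, 3))
  C <- anionbind:::design_matrix(sim$schedule, fit$model, "spectral")
  ortho <- t(C) %*% t(fit$residuals)
  expect_lt(max(abs(ortho)) / max(abs(t(C) %*% t(sim$series$values))), 1e-8)
})

test_that("degenerate designs are flagged as ill-conditioned", {
  sim <- gen_spectral_titration(log_K = 4, snr = Inf, seed = 1)
  flat <- sim$series
  flat$values[] <- 5
  expect_error(fit_spectral(flat, sim$schedule, sim$model),
               "ill-conditioned")
})

test_that("NMR fast-exchange limits hold and fits recover the constant", {
  m <- model_1to1(8)
  sch <- titration_schedule(V0 = 5e-4, c_L_initial = 1e-3,
                            c_A_titrant = 2e-2,
                            cumulative_added_volumes = c(0, 1e-5),
                            mode = "constant-ligand")
  C <- anionbind:::design_matrix(sch, m, "shift")
  # zero anion: all receptor is free, observed shift = delta_L
  expect_equal(unname(C[1, ]), c(1, 0))

  # composition where [LA] = total_L / 2: population-average shift
  K <- 1e4; tL <- 1e-3
  tA_half <- tL / 2 + (tL / 2) / (K * tL / 2)  # free A + bound A
  s <- solve_speciation(tL, tA_half, model_1to1(4))
  frac <- s$concentrations[["LA"]] / tL
  expect_equal(frac, 0.5, tolerance = 1e-9)
  delta <- c(L = 7.6, LA = 8.1)
  expect_equal(frac * delta["LA"] + (1 - frac) * delta["L"],
               c(LA = (7.6 + 8.1) / 2), tolerance = 1e-9)

  nmr <- gen_nmr_titration(log_K = 2, delta_shift = c(0.5, 0.12),
                           noise_sd = 0.002, seed = 3)
  fit <- fit_nmr_shifts(nmr$series, nmr$schedule, start_at(nmr$model, 2.7))
  expect_lt(abs(fit$log_beta$log_beta - 2), 0.1)

  noiseless <- gen_nmr_titration(log_K = 2, noise_sd = 0, seed = 3)
  fit0 <- fit_nmr_shifts(noiseless$series, noiseless$schedule,
                         start_at(noiseless$model, 2.7))
  expect_equal(fit0$log_beta$log_beta, 2, tolerance = 1e-6)
})

test_that("blank correction subtracts interpolated titrant background", {
  sim <- gen_spectral_titration(log_K = 4, snr = Inf, seed = 2)
  # series identical to its blank -> zero
  zeroed <- blank_correct(sim$series, sim$series)
  expect_equal(max(abs(zeroed$values)), 0)

  # background linear in titrant volume; blank recorded at the endpoints
  bg <- outer(exp(-(sim$series$channels - 300)^2 / 200),
              sim$series$volumes / max(sim$series$volumes)) * 1e5
  contaminated <- sim$series
  contaminated$values <- sim$series$values + bg
  blank <- response_series(sim$series$channels,
                           range(sim$series$volumes),
                           bg[, c(1, ncol(bg))],
                           kind = "fluorescence")
  corrected <- blank_correct(contaminated, blank)
  expect_equal(corrected$values, sim$series$values, tolerance = 1e-9)

  bad_blank <- response_series(sim$series$channels + 5,
                               range(sim$series$volumes),
                               bg[, c(1, ncol(bg))])
  expect_error(blank_correct(contaminated, bad_blank), "channel axes")
})

test_that("uncertainties: replicates, zero-noise, and Monte-Carlo scale", {
  sim0 <- gen_spectral_titration(log_K = 4, snr = Inf, seed = 1)
  fit0 <- fit_spectral(sim0$series, sim0$schedule, start_at(sim0$model, 3.5))
  u <- estimate_uncertainties(fit0, replicates = list(fit0, fit0))
  expect_equal(u$sd_rep, 0)
  expect_lt(u$se_asymptotic, 1e-6)

  fits <- lapply(1:60, function(s) {
    sim <- gen_spectral_titration(log_K = 4, snr = 100, seed = 100 + s)
    fit_spectral(sim$series, sim$schedule, start_at(sim$model, 3.6),
                 multistart = 1L)
  })
  est <- vapply(fits, function(f) f$log_beta$log_beta, numeric(1))
  se_mean <- mean(vapply(fits, function(f) f$log_beta$se, numeric(1)))
  ratio <- sd(est) / se_mean
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("recovery uncertainty grows as the signal-to-noise ratio falls", {
  ses <- vapply(c(1000, 100, 20, 5), function(snr) {
    sim <- gen_spectral_titration(log_K = 4, snr = snr, seed = 5)
    fit_spectral(sim$series, sim$schedule, start_at(sim$model, 3.5),
                 multistart = 1L)$log_beta$se
  }, numeric(1))
  expect_true(all(diff(ses) > 0))
})

test_that("fixing the dimerization constant at truth changes nothing at zero noise", {
  m_free <- equilibrium_model(data.frame(l = c(1, 0), a = c(1, 2),
                                         log_beta = c(4, 2)))
  sim <- gen_spectral_titration(model = m_free, snr = Inf, seed = 4)
  m_fixed <- equilibrium_model(data.frame(l = c(1, 0), a = c(1, 2),
                                          log_beta = c(3.4, 2),
                                          fixed = c(FALSE, TRUE)))
  fit_fixed <- fit_spectral(sim$series, sim$schedule, m_fixed)
  start_free <- set_free_constants(m_free, c(3.4, 2))
  fit_free <- fit_spectral(sim$series, sim$schedule, start_free)
  b11_fixed <- fit_fixed$log_beta$log_beta[fit_fixed$log_beta$l == 1]
  b11_free <- fit_free$log_beta$log_beta[fit_free$log_beta$l == 1]
  expect_equal(b11_fixed, 4, tolerance = 1e-5)
  expect_equal(b11_free, b11_fixed, tolerance = 1e-5)
})
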