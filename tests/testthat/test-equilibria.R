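test_that("closed-form 1:1 oracle values and limits", {
  expect_equal(closed_form_1to1(1e-4, 1e-4, 1e4), 3.81966e-5,
               tolerance = 1e-5)
  expect_equal(closed_form_1to1(1e-4, 0, 1e4), 0)
  # saturation: K -> infinity with limiting anion
  expect_equal(closed_form_1to1(2e-4, 1e-4, 1e12), 1e-4, tolerance = 1e-6)
})

test_that("speciation matches the spec examples", {
  m <- model_1to1(4)
  s0 <- solve_speciation(1e-4, 0, m)
  expect_equal(s0$free_L, 1e-4)
  expect_equal(unname(s0$concentrations["LA"]), 0)

  s <- solve_speciation(1e-4, 1e-4, m)
  expect_equal(unname(s$concentrations["LA"]), 3.81966e-5, tolerance = 1e-5)
  expect_equal(s$free_L, 6.18034e-5, tolerance = 1e-5)
  expect_equal(s$free_A, 6.18034e-5, tolerance = 1e-5)

  md <- equilibrium_model(data.frame(l = 0, a = 2, log_beta = 2))
  sd_ <- solve_speciation(0, 1e-3, md)
  expect_equal(sd_$free_A, 8.5410e-4, tolerance = 1e-4)
  expect_equal(unname(sd_$concentrations["A2"]), 7.295e-5, tolerance = 1e-3)
})

test_that("mass balance closes and solver agrees with quadratic oracles", {
  set.seed(42)
  for (i in 1:200) {
    logK <- runif(1, 1, 8)
    tL <- 10^runif(1, -6, -2); tA <- 10^runif(1, -6, -2)
    s <- solve_speciation(tL, tA, model_1to1(logK))
    conc <- s$concentrations
    expect_lt(abs(conc["L"] + conc["LA"] - tL) / tL, 1e-10)
    expect_lt(abs(conc["A"] + conc["LA"] - tA) / tA, 1e-10)
    la <- closed_form_1to1(tL, tA, 10^logK)
    expect_lt(abs(conc["LA"] - la) / max(la, 1e-300), 1e-10)
  }
  # dimer-only model against its own quadratic
  for (i in 1:200) {
    lb <- runif(1, 1, 6); tA <- 10^runif(1, -5, -2)
    s <- solve_speciation(0, tA, equilibrium_model(
      data.frame(l = 0, a = 2, log_beta = lb)))
    a_free <- oracle_dimer_free_A(tA, 10^lb)
    expect_lt(abs(s$free_A - a_free) / a_free, 1e-10)
  }
})

test_that("three-species model agrees with the elimination-bisection oracle", {
  set.seed(7)
  for (i in 1:50) {
    b11 <- runif(1, 2, 6); b02 <- runif(1, 1, 4)
    b12 <- b11 + b02 + runif(1, -1, 1)
    m <- equilibrium_model(data.frame(l = c(1, 0, 1), a = c(1, 2, 2),
                                      log_beta = c(b11, b02, b12)))
    tL <- 10^runif(1, -5, -3); tA <- 10^runif(1, -5, -2.5)
    s <- solve_speciation(tL, tA, m)
    orc <- oracle_three_species(tL, tA, 10^b11, 10^b02, 10^b12)
    expect_equal(unname(s$concentrations[c("L", "A", "LA", "A2", "LA2")]),
                 unname(orc), tolerance = 1e-8)
  }
})

test_that("1:1 complex concentration is monotone in total anion", {
  m <- model_1to1(4.5)
  tA <- seq(0, 5e-4, length.out = 40)
  la <- vapply(tA, function(a)
    solve_speciation(1e-4, a, m)$concentrations[["LA"]], numeric(1))
  expect_true(all(diff(la) >= -1e-15))
})

test_that("schedule arithmetic follows the dilution model", {
  sch <- titration_schedule(V0 = 2e-3, c_L_initial = 1e-4,
                            c_A_titrant = 2e-3,
                            cumulative_added_volumes = c(0, 2e-4))
  comp <- schedule_to_compositions(sch)
  expect_equal(comp$total_L, c(1e-4, 9.0909e-5), tolerance = 1e-4)
  expect_equal(comp$total_A, c(0, 1.8182e-4), tolerance = 1e-4)

  schc <- titration_schedule(V0 = 5e-4, c_L_initial = 1e-3,
                             c_A_titrant = 1e-2,
                             cumulative_added_volumes = c(0, 1e-5, 5e-5),
                             mode = "constant-ligand")
  compc <- schedule_to_compositions(schc)
  expect_equal(compc$total_L, rep(1e-3, 3))
})

test_that("model and schedule validation rejects bad inputs", {
  expect_error(equilibrium_model(data.frame(l = 1, a = 0, log_beta = 1)),
               "implicit")
  expect_error(equilibrium_model(data.frame(l = c(1, 1), a = c(1, 1),
                                            log_beta = c(2, 3))),
               "duplicate")
  expect_error(equilibrium_model(data.frame(l = 0, a = 0, log_beta = 1)))
  expect_error(solve_speciation(-1e-4, 0, model_1to1()), ">= 0")
  expect_error(titration_schedule(2e-3, 1e-4, 1e-3, c(0, 1e-5, 1e-5)),
               "increasing")
  expect_error(titration_schedule(5e-4, 1e-3, 1e-2, c(0, 1e-5),
                                  mode = "constant-ligand",
                                  c_L_titrant = 2e-3),
               "constant-ligand")
})

test_that("speciation handles stiff constants and trace totals", {
  m <- equilibrium_model(data.frame(l = c(1, 0), a = c(1, 2),
                                    log_beta = c(10, 8)))
  s <- solve_speciation(1e-6, 1e-2, m)
  expect_lt(s$residual, 1e-10)
  s2 <- solve_speciation(1e-2, 1e-8, m)
  expect_lt(s2$residual, 1e-10)
})
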