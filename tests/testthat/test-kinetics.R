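test_that("zero analyte concentration gives an identically zero sensorgram", {
  p <- kinetic_params()
  s <- simulate_bivalent(p, 0)
  expect_true(all(s$response == 0))
})

test_that("the reduced model matches the closed-form Langmuir solution", {
  grid <- seq(0, 420, by = 1)
  for (conc in c(50e-9, 400e-9, 1600e-9)) {
    p <- kinetic_params(k_on = 1.2e5, k_off = 2e-3, k_on2 = 0, k_off2 = 0,
                        R_max = 120)
    sim <- simulate_bivalent(p, conc, grid, 120)
    cf <- langmuir_closed_form(p, conc, grid, 120)
    expect_lt(max(abs(sim$response - cf$response)) / max(cf$response), 0.005)
  }
})

test_that("long association with k_on2 = 0 plateaus at the Langmuir level", {
  p <- kinetic_params(k_on = 1e5, k_off = 1e-3, k_on2 = 0, k_off2 = 0,
                      R_max = 100)
  conc <- 800e-9
  s <- simulate_bivalent(p, conc, grid = seq(0, 2100, by = 5),
                         t_assoc_end = 2000)
  plateau <- p$R_max * 2 * p$k_on * conc / (2 * p$k_on * conc + p$k_off)
  expect_lt(abs(max(s$response) - plateau) / plateau, 0.005)
})

test_that("dissociation with k_on2 = 0 is log-linear with slope -k_off", {
  p <- kinetic_params(k_on = 1e5, k_off = 2.5e-3, k_on2 = 0, k_off2 = 0,
                      R_max = 100)
  s <- simulate_bivalent(p, 400e-9, seq(0, 420, by = 1), 120)
  diss <- s[s$time >= 130 & s$time <= 400, ]
  slope <- stats::coef(stats::lm(log(response) ~ time, data = diss))[2]
  expect_lt(abs(slope + p$k_off) / p$k_off, 0.01)
})

test_that("simulated responses stay within [0, R_max] and associate monotonically", {
  set.seed(19)
  for (i in 1:8) {
    p <- kinetic_params(k_on = 10^stats::runif(1, 4, 6),
                        k_off = 10^stats::runif(1, -4, -2),
                        k_on2 = 10^stats::runif(1, -6, -3),
                        k_off2 = 10^stats::runif(1, -4, -2),
                        R_max = stats::runif(1, 50, 200))
    s <- simulate_bivalent(p, 10^stats::runif(1, -8, -6))
    expect_true(all(s$response >= -1e-9))
    expect_true(all(s$response <= p$R_max * (1 + 1e-9)))
  }
  # no dissociation at all: association is monotone non-decreasing
  p0 <- kinetic_params(k_on = 1e5, k_off = 0, k_on2 = 1e-4, k_off2 = 0,
                       R_max = 100)
  s0 <- simulate_bivalent(p0, 200e-9, seq(0, 120, by = 1), t_assoc_end = 119)
  expect_true(all(diff(s0$response[s0$time <= 119]) >= -1e-9))
})

test_that("a noiseless global fit recovers the generating rates within 1%", {
  p <- kinetic_params(k_on = 1.09e5, k_off = 1.25e-3, k_on2 = 1e-4,
                      k_off2 = 1e-3, R_max = 100)
  b <- make_assay_bundle(kinetics = p)
  expect_length(b$sensorgrams, 6)
  fit <- fit_bivalent(b$sensorgrams)
  expect_lt(abs(fit$params$k_on - p$k_on) / p$k_on, 0.01)
  expect_lt(abs(fit$params$k_off - p$k_off) / p$k_off, 0.01)
  expect_true(all(is.finite(fit$se[c("k_on", "k_off")])))
  expect_lt(fit$rss, 1e-6)
})

test_that("degenerate sensorgram sets are rejected, not crashed on", {
  grid <- seq(0, 420, by = 2)
  flat <- sensorgram(grid, rep(0, length(grid)), 100e-9, 120)
  flat2 <- sensorgram(grid, rep(0, length(grid)), 800e-9, 120)
  expect_error(fit_bivalent(list(flat, flat2)), "non-convergence")
  one <- simulate_bivalent(kinetic_params(), 100e-9, grid, 120)
  expect_error(fit_bivalent(list(one)), "4-fold")
  expect_error(sensorgram(c(0, 1, 1), 1:3, 1e-9, 0.5),
               "strictly increasing")
})

test_that("K_D derivation reproduces the published rate-constant table", {
  expect_equal(equilibrium_kd(kinetic_params(k_on = 1.09e5, k_off = 1.25e-3)),
               11.5)
  expect_equal(equilibrium_kd(kinetic_params(k_on = 1.73e5, k_off = 3.30e-3)),
               19.1)
  expect_equal(equilibrium_kd(kinetic_params(k_on = 1e5, k_off = 0)), 0)
  expect_error(equilibrium_kd(kinetic_params(k_on = 0, k_off = 1e-3)),
               "k_on")
})
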