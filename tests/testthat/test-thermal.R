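test_that("simulated melt curves have the constructed shape", {
  # amplitude 0: baseline only
  flat <- simulate_melt(data.frame(tm = 70, amplitude = 0, slope = 1),
                        baseline = c(5, 0.1))
  expect_equal(flat$fluorescence, 5 + 0.1 * flat$temperature,
               tolerance = 1e-12)
  # two transitions 8 degrees apart give two local maxima in dF/dT
  two <- simulate_melt(data.frame(tm = c(66, 74), amplitude = c(100, 80),
                                  slope = c(1, 1)))
  d <- diff(two$fluorescence) / diff(two$temperature)
  locmax <- which(diff(sign(diff(d))) < 0)
  expect_gte(length(locmax), 2)
  # same seed, same curve
  a <- simulate_melt(data.frame(tm = 70, amplitude = 50, slope = 1),
                     noise_sd = 2, seed = 5)
  b <- simulate_melt(data.frame(tm = 70, amplitude = 50, slope = 1),
                     noise_sd = 2, seed = 5)
  expect_identical(a$fluorescence, b$fluorescence)
})

test_that("derivative-method Tm recovers the generating inflection", {
  cv <- simulate_melt(data.frame(tm = 73.6, amplitude = 100, slope = 1),
                      baseline = c(10, 0.05))
  pk <- tm_derivative(cv)
  expect_equal(nrow(pk), 1)
  grid_step <- diff(cv$temperature)[1]
  expect_lt(abs(pk$tm[1] - 73.6), grid_step / 2)
})

test_that("flat curves yield an empty peak list, not an error", {
  flat <- melt_curve(seq(25, 99, by = 0.5), rep(1, 149))
  expect_equal(nrow(tm_derivative(flat)), 0)
  expect_error(tm_derivative(melt_curve(1:10, 1:10)), "20 grid points")
})

test_that("multi-transition peaks order by height and filter by range", {
  cv <- simulate_melt(data.frame(tm = c(65, 73.6), amplitude = c(40, 100),
                                 slope = c(1, 1)))
  pk <- tm_derivative(cv)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$peak_rank, 1:2)
  expect_gt(pk$peak_height[1], pk$peak_height[2])
  expect_lt(abs(pk$tm[1] - 73.6), 0.3)   # larger transition ranks first
  # Fab-window filter isolates one peak
  fab <- tm_derivative(cv, range = c(70, 85))
  expect_equal(nrow(fab), 1)
  expect_lt(abs(fab$tm - 73.6), 0.3)
})

test_that("Tm recovery stays under half the grid spacing across a sweep", {
  tms <- seq(55, 90, length.out = 10)
  for (tm in tms) {
    cv <- simulate_melt(data.frame(tm = tm, amplitude = 100, slope = 1.2),
                        baseline = c(3, 0.02))
    pk <- tm_derivative(cv)
    expect_lt(abs(pk$tm[1] - tm), 0.25)
  }
})

test_that("delta-Tm reproduces the published shifts and p-values", {
  d <- delta_tm_summary(3, 75.4, 0.5, 3, 73.6, 0.3)
  expect_equal(d$delta_tm, 1.8)
  expect_equal(round(d$p_value, 3), 0.006)
  expect_equal(d$df, 4)
  expect_equal(d$t, 5.35, tolerance = 0.01)

  d5 <- delta_tm_summary(3, 64.5, 0.3, 3, 73.6, 0.3)
  expect_equal(d5$delta_tm, -9.1)
  expect_lt(d5$p_value, 0.001)
})

test_that("delta_tm is antisymmetric and identical groups give p = 1", {
  a <- c(75.1, 75.6, 75.5); b <- c(73.4, 73.8, 73.6)
  expect_equal(delta_tm(a, b)$delta_tm, -delta_tm(b, a)$delta_tm)
  same <- delta_tm(c(70, 71, 72), c(70, 71, 72))
  expect_equal(same$delta_tm, 0)
  expect_equal(same$p_value, 1)
  expect_error(delta_tm(70, c(70, 71)), "replicates")
})

test_that("summary-statistic and raw-replicate t tests agree", {
  a <- c(75.0, 75.4, 75.8); b <- c(73.3, 73.6, 73.9)
  raw <- delta_tm(a, b)
  summ <- delta_tm_summary(3, mean(a), stats::sd(a), 3, mean(b), stats::sd(b))
  expect_equal(raw$p_value, summ$p_value, tolerance = 1e-6)
  # independent route: base R's pooled t test
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(raw$p_value, tt$p.value, tolerance = 1e-9)
  expect_equal(raw$t, unname(tt$statistic), tolerance = 1e-9)
})
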