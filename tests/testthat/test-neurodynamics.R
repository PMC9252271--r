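# independent oracle for the binding stage: integrate the ODE by brute
# force with tiny forward-Euler steps
binding_euler <- function(b, d, u, t_end_s, n = 50000) {
  dt <- t_end_s / n
  x <- 0
  for (i in seq_len(n)) x <- x + dt * (b * u * (1 - x) - d * x)
  x
}

test_that("binding stage reaches its closed-form fixed point", {
  set.seed(7)
  p <- al_params()$otp
  for (i in 1:20) {
    b <- runif(1, 0.5, 50); d <- runif(1, 0.5, 50); u <- runif(1, 0, 20)
    # settle over many binding time constants
    t_end <- 12 / (b * u + d)                       # seconds
    s <- otp_state()
    dt_ms <- t_end * 1000 / 400
    for (k in 1:400) s <- otp_step(s, b, d, u, dt_ms, p)
    expect_equal(s$x, b * u / (b * u + d), tolerance = 1e-4)
    expect_equal(s$x, binding_euler(b, d, u, t_end), tolerance = 1e-3)
  }
})

test_that("bound fraction stays in [0,1] and is inert without odorant", {
  p <- al_params()$otp
  s <- otp_state()
  for (k in 1:100) {
    s <- otp_step(s, b = 100, d = 1, u = 50, dt = 5, p)
    expect_gte(s$x, 0); expect_lte(s$x, 1)
  }
  expect_gt(s$x, 0.99)
  z <- otp_state()
  for (k in 1:50) z <- otp_step(z, b = 100, d = 1, u = 0, dt = 5, p)
  expect_equal(z$x, 0)
  expect_equal(z$current, 0)
  # symmetric case: b*u = d gives x* = 1/2
  s2 <- otp_state()
  for (k in 1:500) s2 <- otp_step(s2, b = 2, d = 10, u = 5, dt = 5, p)
  expect_equal(s2$x, 0.5, tolerance = 1e-6)
  expect_error(otp_step(otp_state(), 1, 1, 1, dt = 0), "positive")
})

test_that("steady transduction current is monotone and saturating", {
  p <- al_params()$otp
  # oracle: integrate otp_step to convergence at two affinities
  settle <- function(A) {
    s <- otp_state()
    for (k in 1:6000) s <- otp_step(s, b = A, d = 1, u = 1, dt = 2, p)
    s$current
  }
  i1 <- settle(1); i10 <- settle(10)
  expect_lt(i1, i10)
  expect_equal(i1, otp_steady_current(1, 1, 1, p), tolerance = 1e-3)
  expect_equal(i10, otp_steady_current(10, 1, 1, p), tolerance = 1e-3)
  expect_equal(otp_steady_current(1, 1, 0, p), 0)
  # saturation at large inputs
  expect_gt(otp_steady_current(1e4, 1, 1, p) /
              otp_steady_current(1e5, 1, 1, p), 0.95)
  # strictly increasing along a wide grid
  grid <- otp_steady_current(10^seq(-3, 5, by = 0.5), 1, 1, p)
  expect_true(all(diff(grid) > 0))
})

test_that("Connor-Stevens rests without input and is deterministic", {
  r <- connor_stevens_integrate(0, dt = 0.01, duration = 1000)
  expect_length(r$spike_times, 0)
  tail_v <- r$v[r$t > 900]
  expect_lt(diff(range(tail_v)), 0.01)   # settled at rest
  expect_lt(abs(mean(tail_v) + 68), 5)   # near canonical rest

  a <- connor_stevens_integrate(15, dt = 0.01, duration = 500)
  b <- connor_stevens_integrate(15, dt = 0.01, duration = 500)
  expect_identical(a$spike_times, b$spike_times)
  expect_identical(a$v, b$v)
})

test_that("the f-I curve is monotone and type-I near rheobase", {
  fi <- connor_stevens_fi(c(9, 12, 16, 25), duration = 1000)
  expect_true(all(diff(fi$rate_hz) > 0))
  # bisect the rheobase, then confirm low rates just above it
  lo <- 5; hi <- 12
  for (i in 1:12) {
    mid <- (lo + hi) / 2
    r <- connor_stevens_integrate(mid, dt = 0.02, duration = 800,
                                  record_v = FALSE)
    if (length(r$spike_times) > 1) hi <- mid else lo <- mid
  }
  r <- connor_stevens_integrate(hi + 0.02, dt = 0.02, duration = 1000,
                                record_v = FALSE)
  rate <- steady_state_rate(r$spike_times / 1000, 0.5, 1)
  expect_lt(rate, 10)
})

test_that("spike detection respects the 2 ms lockout", {
  r <- connor_stevens_integrate(100, dt = 0.01, duration = 500,
                                record_v = FALSE)
  expect_gt(length(r$spike_times), 10)
  expect_true(all(diff(r$spike_times) >= 2))
})

test_that("alpha synapse peaks at tau with value g_max and is linear", {
  tg <- seq(0, 50, by = 0.01)
  g <- alpha_synapse_conductance(10, tg, g_max = 0.5, tau = 6)
  expect_equal(tg[which.max(g)], 16, tolerance = 0.02)
  expect_equal(max(g), 0.5, tolerance = 1e-4)
  expect_true(all(g[tg < 10] == 0))

  expect_equal(alpha_synapse_conductance(numeric(0), tg, 1, 5),
               rep(0, length(tg)))

  g1 <- alpha_synapse_conductance(c(5, 12), tg, 1, 5)
  g2 <- alpha_synapse_conductance(sort(rep(c(5, 12), 2)), tg, 1, 5)
  expect_equal(g2, 2 * g1, tolerance = 1e-12)

  expect_error(alpha_synapse_conductance(c(12, 5), tg, 1, 5), "sorted")
  expect_error(alpha_synapse_conductance(5, tg, -1, 5), "g_max")
})

test_that("alpha conductance is invariant to grid refinement", {
  pts <- c(3.7, 8.1, 21.9)
  coarse <- alpha_synapse_conductance(c(2, 9), pts, 0.8, 4)
  fine_grid <- sort(c(pts, seq(0, 30, by = 0.001)))
  fine <- alpha_synapse_conductance(c(2, 9), fine_grid, 0.8, 4)
  expect_equal(coarse, fine[match(pts, fine_grid)], tolerance = 1e-12)
})

test_that("presynaptic gain is divisive, bounded and monotone", {
  expect_equal(presynaptic_gain(0, 3.7), 1)
  expect_equal(presynaptic_gain(12.3, 0), 1)
  s <- seq(0, 1000, length.out = 50)
  g <- presynaptic_gain(s, 0.5)
  expect_true(all(diff(g) < 0))
  expect_true(all(g > 0 & g <= 1))
  expect_lt(presynaptic_gain(1e6, 1), 1e-5)
  expect_error(presynaptic_gain(-1, 1), "nonnegative")
  expect_error(presynaptic_gain(1, -1), "nonnegative")
})
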