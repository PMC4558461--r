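# dynamics of the four-population microcircuit: activation function,
# state derivatives, equilibria and linearisation

test_that("centred sigmoid is odd, bounded, monotone with slope gamma/4", {
  g <- 0.67
  v <- seq(-50, 50, length.out = 401)
  s <- cmc_sigmoid(v, g)
  expect_equal(s, -rev(cmc_sigmoid(rev(-v), g)))
  expect_true(all(diff(s) > 0))
  expect_true(all(abs(s) <= 0.5))
  expect_equal(cmc_sigmoid(0, g), 0)
  expect_equal(cmc_sigmoid(1e4, g), 0.5, tolerance = 1e-12)
  expect_equal(cmc_sigmoid(-1e4, g), -0.5, tolerance = 1e-12)
  h <- 1e-6
  expect_equal((cmc_sigmoid(h, g) - cmc_sigmoid(-h, g)) / (2 * h),
               g / 4, tolerance = 1e-6)
  expect_equal(g / 4, 0.1675)
  expect_error(cmc_sigmoid(NaN, g), "finite")
  expect_error(cmc_sigmoid(0, -1), "gamma")
})

test_that("the origin is a fixed point and input reaches only the granular cells", {
  p <- cmc_parameters()
  expect_equal(cmc_state_derivative(rep(0, 8), rep(0, 8), 0, p), rep(0, 8))
  dx <- cmc_state_derivative(rep(0, 8), rep(0, 8), 1e-3, p)
  expect_true(abs(dx[5]) > 0)            # granular current responds
  expect_equal(dx[c(1:4, 6:8)], rep(0, 7))
  expect_error(cmc_state_derivative(rep(0, 7), rep(0, 8), 0, p), "length 8")
})

test_that("state derivative matches an independently hand-expanded oracle", {
  p <- cmc_parameters()
  set.seed(11)
  for (rep in 1:5) {
    x <- rnorm(8, sd = 2); xd <- rnorm(8, sd = 2); u <- rnorm(1)
    expect_equal(cmc_state_derivative(x, xd, u, p),
                 oracle_state_derivative(x, xd, u, p), tolerance = 1e-12)
  }
})

test_that("equilibria are exact, residual-checked and continuous in the input", {
  p <- cmc_parameters()
  expect_equal(cmc_equilibrium(p, 0), rep(0, 8), ignore_attr = TRUE)
  x1 <- cmc_equilibrium(p, 0.1)
  res <- cmc_state_derivative(x1, x1, 0.1, p)
  expect_lt(sqrt(sum(res^2)), 1e-9)
  deltas <- c(1e-2, 1e-3, 1e-4)
  gaps <- vapply(deltas, function(d)
    sqrt(sum((cmc_equilibrium(p, 0.1 + d) - x1)^2)), numeric(1))
  expect_true(all(diff(gaps) < 0))       # shrinks as delta -> 0
  expect_lt(gaps[3], 1e-3)
})

test_that("analytic and finite-difference Jacobians agree", {
  p <- cmc_parameters()
  Ja <- cmc_jacobian(p)
  Jf <- cmc_jacobian(p, method = "fd")
  scale <- max(abs(Ja$J0))
  expect_lt(max(abs(Ja$J0 - Jf$J0)) / scale, 1e-6)
  expect_lt(max(abs(Ja$Jd - Jf$Jd)) / max(abs(Ja$Jd)), 1e-6)
  # away from the origin too
  x0 <- cmc_equilibrium(p, 0.2)
  Ja2 <- cmc_jacobian(p, x0)
  Jf2 <- cmc_jacobian(p, x0, method = "fd")
  expect_lt(max(abs(Ja2$J0 - Jf2$J0)) / max(abs(Ja2$J0)), 1e-6)
})

test_that("the resting linearisation is stable at prior means", {
  J <- cmc_jacobian(cmc_parameters())
  expect_lt(max(Re(eigen(J$J0 + J$Jd, only.values = TRUE)$values)), 0)
})

test_that("removing all coupling decouples the populations", {
  p <- cmc_parameters()
  p[5:14] <- 1e-12          # g ~ 0
  J <- cmc_jacobian(p)
  tot <- J$J0 + J$Jd
  # current equations may only reference their own population's states
  for (k in 1:4) {
    other <- setdiff(1:4, k)
    expect_true(all(abs(tot[4 + k, c(other, 4 + other)]) < 1e-6))
  }
})

test_that("the inhibitory sign convention is exercised by the spectrum", {
  p <- cmc_parameters()
  s0 <- predicted_spectrum(p)$density
  for (gi in c("g3", "g4", "g9")) {
    p2 <- p; p2[gi] <- p2[gi] * exp(0.3)
    expect_gt(max(abs(predicted_spectrum(p2)$density - s0) / s0), 1e-3)
  }
})
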