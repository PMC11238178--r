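# PQN neuron model: parameter derivation, piecewise functions, input
# transform, Euler steps, spike detection, homeostasis.

test_that("derived coefficients make f, g, h continuous and smooth", {
  p <- pqn_params(tau = 0.01, phi = 1, epsilon = 0.1, I_b0 = 0, k_I = 1,
                  m0 = -1, m1 = 1,
                  a_fn = 1, b_fn = -1, c_fn = 0, a_fp = 2,
                  a_gn = 1, b_gn = 0, c_gn = 0, a_gp = 1, r_g = 0.5,
                  a_hn = 0.5, b_hn = -1, c_hn = 0, a_hp = 0.5, r_h = 0,
                  variant = "single")
  # hand-derived values for the f branch
  expect_equal(p$b_fp, -0.5)
  expect_equal(p$c_fp, 0.5)
  expect_equal(eval_piecewise("f", 0, p), 1)
  # slope match at v = 0: f'(0-) = -2*a_fn*b_fn = 2, f'(0+) = -2*a_fp*b_fp
  expect_equal(-2 * p$a_fp * p$b_fp, 2)
  # hand-derived g branch at r_g = 0.5
  expect_equal(p$b_gp, 0)
  expect_equal(p$c_gp, 0)
  # identical curvatures give identical branches
  p2 <- pqn_params(tau = 0.01, phi = 1, epsilon = 0, I_b0 = 0, k_I = 1,
                   m0 = 0, m1 = 1,
                   a_fn = 1.3, b_fn = -0.7, c_fn = 0.2, a_fp = 1.3,
                   a_gn = 1, b_gn = 0, c_gn = 0, a_gp = 1, r_g = 0,
                   variant = "single")
  expect_equal(p2$b_fp, p2$b_fn)
  expect_equal(p2$c_fp, p2$c_fn)
})

test_that("C1 continuity at branch points holds for random parameter draws", {
  withr::with_seed(7, {
    for (rep in 1:50) {
      p <- random_pqn_params()
      eps <- 1e-9
      for (spec in list(list("f", 0), list(c("g"), p$r_g), list("h", p$r_h))) {
        w <- spec[[1]]; r <- spec[[2]]
        lo <- eval_piecewise(w, r - eps, p)
        hi <- eval_piecewise(w, r + eps, p)
        expect_equal(lo, hi, tolerance = 1e-6)
        # first derivative via symmetric secants on each side
        d_lo <- (eval_piecewise(w, r - eps, p) - eval_piecewise(w, r - 2 * eps, p)) / eps
        d_hi <- (eval_piecewise(w, r + 2 * eps, p) - eval_piecewise(w, r + eps, p)) / eps
        expect_equal(d_lo, d_hi, tolerance = 1e-4)
      }
    }
  })
})

test_that("zero curvature on a p-branch is rejected", {
  expect_error(
    pqn_params(tau = 0.01, phi = 1, epsilon = 0, I_b0 = 0, k_I = 1,
               m0 = 0, m1 = 1,
               a_fn = 1, b_fn = 0, c_fn = 0, a_fp = 0,
               a_gn = 1, b_gn = 0, c_gn = 0, a_gp = 1, r_g = 0,
               variant = "single"),
    "nonzero")
})

test_that("piecewise evaluation picks the correct branch", {
  p <- spiking_params()
  expect_equal(eval_piecewise("f", -1, pqn_params(
    tau = 0.01, phi = 1, epsilon = 0, I_b0 = 0, k_I = 1, m0 = 0, m1 = 1,
    a_fn = 1, b_fn = 0, c_fn = 0, a_fp = 1,
    a_gn = 1, b_gn = 0, c_gn = 0, a_gp = 1, r_g = 0, variant = "single")), 1)
  # h at its branch point equals the left-branch limit
  expect_equal(eval_piecewise("h", p$r_h, p),
               p$a_hn * (p$r_h - p$b_hn)^2 + p$c_hn)
})

test_that("input transform clamps and scales", {
  p <- pqn_params(tau = 0.01, phi = 1, epsilon = 0, I_b0 = 0, k_I = 0.5,
                  m0 = -1, m1 = 2,
                  a_fn = 1, b_fn = 0, c_fn = 0, a_fp = 1,
                  a_gn = 1, b_gn = 0, c_gn = 0, a_gp = 1, r_g = 0,
                  variant = "single")
  expect_equal(transform_input(1, p), 0.5)
  expect_equal(transform_input(-3, p), -0.5)
  expect_equal(transform_input(p$m1, p), 0.5 * 2)
  # monotone nondecreasing, constant outside [m0, m1]
  I_grid <- seq(-5, 5, by = 0.1)
  out <- transform_input(I_grid, p)
  expect_true(all(diff(out) >= 0))
  expect_true(all(out >= p$k_I * p$m0 & out <= p$k_I * p$m1))
})

test_that("m0 > m1 is rejected", {
  expect_error(spiking_params(m0 = 3, m1 = -3), "m0")
})

test_that("single-compartment Euler step matches hand calculation", {
  p <- pqn_params(tau = 1, phi = 1, epsilon = 1, I_b0 = 0, k_I = 1,
                  m0 = 0, m1 = 0,
                  a_fn = 1, b_fn = 0, c_fn = 0, a_fp = 1,
                  a_gn = 0.5, b_gn = 0, c_gn = 0, a_gp = 0.5, r_g = 0,
                  a_hn = 0.25, b_hn = 0, c_hn = 0, a_hp = 0.25, r_h = 0,
                  variant = "single")
  st <- pqn_state(1, "single")
  st$v <- -1
  st2 <- step_single(st, p, I = 0, dt = 0.001)
  expect_equal(st2$v, -1 + 0.001 * 1) # f(-1) = 1
  expect_equal(st2$n, 0.001 * 0.5)    # g(-1) = 0.5
  expect_equal(st2$q, 0.001 * 0.25)   # h(-1) = 0.25
  # dt = 0 leaves the state unchanged
  st3 <- step_single(st, p, I = 0, dt = 0)
  expect_equal(st3$v, st$v)
  expect_equal(st3$n, st$n)
})

test_that("a fixed point of the dynamics stays fixed", {
  p <- spiking_params()
  # find the rest state numerically, then verify one step leaves it be
  tr <- simulate_trace(p, rep(0, 3000))
  v0 <- tail(tr$v, 1)
  st <- pqn_state(1, "single")
  st$v <- v0
  st$n <- eval_piecewise("g", v0, p)
  st$q <- eval_piecewise("h", v0, p)
  resid <- eval_piecewise("f", v0, p) - st$n - st$q + p$I_b0 + transform_input(0, p)
  st2 <- step_single(st, p, I = 0, dt = 0.001)
  expect_lt(abs(st2$v - st$v), 1e-3 * abs(resid) + 1e-8)
})

test_that("all-zero coefficients and input keep every variant at zero", {
  z <- pqn_params(tau = 1, phi = 1, epsilon = 1, I_b0 = 0, k_I = 1,
                  m0 = 0, m1 = 0,
                  a_fn = 0, b_fn = 0, c_fn = 0, a_fp = 1,
                  a_gn = 0, b_gn = 0, c_gn = 0, a_gp = 1, r_g = 0,
                  a_hn = 0, b_hn = 0, c_hn = 0, a_hp = 1, r_h = 0,
                  variant = "single")
  tr <- simulate_trace(z, rep(0, 100))
  expect_true(all(tr$v == 0))
  z2 <- pqn_params(tau = 1, phi = 1, epsilon = 0, I_b0 = 0, k_I = 1,
                   m0 = 0, m1 = 0,
                   a_fn = 0, b_fn = 0, c_fn = 0, a_fp = 1,
                   a_gn = 0, b_gn = 0, c_gn = 0, a_gp = 1, r_g = 0,
                   variant = "two_comp", theta = 1, alpha_leak = 1,
                   I_b1 = 0, k_0 = 1, k_r = 1)
  tr2 <- simulate_trace(z2, rep(0, 100), route = "soma")
  expect_true(all(tr2$v == 0))
  expect_true(all(tr2$v_s == 0))
})

test_that("two-compartment step handles coupling and the soma fixed point", {
  p <- two_comp_params(k_0 = 1)
  st <- pqn_state(1, "two_comp")
  st$v <- 1; st$v_s <- 0
  st2 <- step_two_comp(st, p, I = 0, dt = 0.001)
  # I_c = k_0 (v - v_s) = 1 is subtracted from dv and added to dv_s
  dv_expected <- 0.001 * (p$phi / p$tau) *
    (eval_piecewise("f", 1, p) - 0 + p$I_b0 + transform_input(0, p) - 1)
  expect_equal(st2$v - 1, dv_expected)
  dvs_expected <- 0.001 * (p$theta / p$tau) * (0 + p$I_b1 + 1)
  expect_equal(st2$v_s, dvs_expected)
  # v = v_s gives zero coupling current
  st$v <- 0.5; st$v_s <- 0.5
  st3 <- step_two_comp(st, p, I = 0, dt = 0.001)
  expect_equal(st3$v_s - 0.5, 0.001 * (p$theta / p$tau) * (-p$alpha_leak * 0.5 + p$I_b1))
})

test_that("decoupled soma relaxes to its closed-form fixed point", {
  p <- two_comp_params(k_0 = 0, alpha_leak = 2, I_b1 = 1, theta = 1)
  # with k_0 = 0 the soma is a pure linear ODE: v_s -> I_b1 / alpha = 0.5
  tr <- simulate_trace(p, rep(0, 2000), route = "soma")
  expect_equal(tail(tr$v_s, 1), 0.5, tolerance = 1e-3)
  # Euler trajectory tracks the analytic exponential within O(dt)
  rate <- p$theta * p$alpha_leak / p$tau
  t_s <- tr$t_ms / 1000
  analytic <- 0.5 * (1 - exp(-rate * t_s))
  expect_lt(max(abs(tr$v_s - analytic)), 0.05)
})

test_that("Euler solution converges to the closed form as dt shrinks", {
  p <- two_comp_params(k_0 = 0, alpha_leak = 2, I_b1 = 1, theta = 1)
  rate <- p$theta * p$alpha_leak / p$tau
  errs <- sapply(c(1e-3, 5e-4, 2.5e-4), function(dt) {
    n <- round(0.5 / dt)
    tr <- simulate_trace(p, rep(0, n), dt = dt, route = "soma")
    t_s <- seq_len(n) * dt
    max(abs(tr$v_s - 0.5 * (1 - exp(-rate * t_s))))
  })
  expect_true(all(diff(errs) < 0))      # error decreases with dt
  expect_lt(errs[3], errs[1] / 2)       # roughly first-order convergence
})

test_that("PN variant gates the drive by u and counts spikes", {
  p <- spiking_params(variant = "pn", theta = 0.1, alpha_leak = 1, I_b1 = 0,
                      k_0 = 0.2, k_r = 1, kappa = 1e-4, F_t = 10)
  st1 <- pqn_state(3, "pn", u0 = 1)
  st0 <- pqn_state(3, "pn", u0 = 0)
  # u = 1 matches the plain two-compartment update
  p2 <- spiking_params(variant = "two_comp", theta = 0.1, alpha_leak = 1,
                       I_b1 = 0, k_0 = 0.2, k_r = 1)
  st2 <- pqn_state(3, "two_comp")
  a <- step_pn(st1, p, I = c(2, 0, -1), dt = 0.001)
  b <- step_two_comp(st2, p2, I = c(2, 0, -1), dt = 0.001)
  expect_equal(a$v, b$v)
  expect_equal(a$n, b$n)
  expect_equal(a$v_s, b$v_s)
  # u = 0 removes the synaptic drive entirely
  c0 <- step_pn(st0, p, I = c(2, 0, -1), dt = 0.001)
  d0 <- step_two_comp(st2, p2, I = c(0, 0, 0), dt = 0.001)
  expect_equal(c0$v, d0$v)
  # u = 0.5 halves the transformed drive
  st5 <- pqn_state(1, "pn", u0 = 0.5)
  e <- step_pn(st5, p, I = 2, dt = 0.001)
  f <- step_two_comp(pqn_state(1, "two_comp"), p2, I = 1, dt = 0.001)
  expect_equal(e$v, f$v)
})

test_that("homeostatic gain update follows the rate error and clamps", {
  p <- spiking_params(variant = "pn", theta = 0.1, alpha_leak = 1, I_b1 = 0,
                      k_0 = 0.2, k_r = 1, kappa = 0.01 * 0.008, F_t = 10)
  # kappa / tau = 0.01; F = 0 -> du = 0.1
  st <- pqn_state(1, "pn", u0 = 0.5)
  st$spike_count_window <- 0L
  st2 <- update_homeostasis(st, p)
  expect_equal(st2$u, 0.6)
  expect_equal(st2$F, 0)
  expect_equal(st2$spike_count_window, 0L)
  # F = F_t leaves u unchanged
  st$spike_count_window <- 10L
  expect_equal(update_homeostasis(st, p)$u, 0.5)
  # clamped at 1
  st$u <- 1; st$spike_count_window <- 0L
  expect_equal(update_homeostasis(st, p)$u, 1)
  # clamped at 0 with F far above target
  st$u <- 0; st$spike_count_window <- 200L
  expect_equal(update_homeostasis(st, p)$u, 0)
})

test_that("u stays in [0, 1] and decreases monotonically when F > F_t", {
  p <- spiking_params(variant = "pn", theta = 0.1, alpha_leak = 1, I_b1 = 0,
                      k_0 = 0.2, k_r = 1, kappa = 0.005 * 0.008, F_t = 10)
  st <- pqn_state(1, "pn", u0 = 1)
  us <- numeric(30)
  withr::with_seed(3, {
    for (k in 1:30) {
      st$spike_count_window <- as.integer(15 + sample(0:10, 1)) # F > F_t always
      st <- update_homeostasis(st, p)
      us[k] <- st$u
    }
  })
  expect_true(all(us >= 0 & us <= 1))
  expect_true(all(diff(us) <= 0))
})

test_that("spike detection fires on negative-to-nonnegative crossings only", {
  expect_true(detect_spike(-0.1, 0))
  expect_false(detect_spike(0.1, 0.2))
  expect_false(detect_spike(-0.2, -0.1))
  expect_false(detect_spike(0, 0.5)) # was already at threshold
})

test_that("stepping spike count equals the post-hoc trace-scan oracle", {
  p <- spiking_params()
  withr::with_seed(11, {
    for (I in c(1.2, 1.8, 2.4)) {
      I_series <- I + stats::rnorm(2000, sd = 0.2)
      tr <- simulate_trace(p, I_series)
      expect_equal(sum(tr$spike), count_spikes_in_trace(tr$v))
    }
  })
})

test_that("repetitive firing appears above threshold drive, silence below", {
  p <- spiking_params()
  quiet <- simulate_trace(p, rep(0, 2000))
  expect_equal(sum(quiet$spike), 0)
  firing <- simulate_trace(p, rep(2, 2000))
  expect_gt(sum(firing$spike), 20)
})

test_that("constant-input trace is causal: longer run extends the shorter", {
  p <- spiking_params()
  a <- simulate_trace(p, rep(2, 500))
  b <- simulate_trace(p, rep(2, 1000))
  expect_equal(a$v, b$v[1:500])
})

test_that("non-finite state reports the offending neuron index", {
  p <- spiking_params()
  st <- pqn_state(3, "single")
  st$v[2] <- Inf
  expect_error(step_single(st, p, I = 0, dt = 1e-3), "neuron index 2")
})
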