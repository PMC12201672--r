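test_that("gating steady states have the documented half-points and monotonicity", {
  expect_equal(gating_steady_states(-53)$h_inf, 0.5)
  expect_equal(gating_steady_states(-30)$n_inf, 0.5)
  expect_equal(gating_steady_states(-30)$m_inf, 0.5)
  expect_equal(gating_steady_states(-39)$z_inf, 0.5)
  v <- seq(-120, 60, by = 0.5)
  ss <- gating_steady_states(v)
  expect_true(all(ss >= 0 & ss <= 1))
  expect_true(all(diff(ss$m_inf) > 0))
  expect_true(all(diff(ss$n_inf) > 0))
  expect_true(all(diff(ss$z_inf) > 0))
  expect_true(all(diff(ss$h_inf) < 0))
  expect_error(gating_steady_states(NaN), "finite")
})

test_that("gating time constants hit their half-points and limits", {
  expect_equal(gating_time_constants(-40.5)$tau_h, 0.37 + 2.78 / 2)
  expect_equal(gating_time_constants(-27)$tau_n, 0.37 + 1.85 / 2)
  tc <- gating_time_constants(seq(-120, 80, by = 1))
  expect_true(all(tc$tau_h > 0.37 & tc$tau_h < 3.15))
  expect_true(all(tc$tau_n > 0.37 & tc$tau_n < 2.22))
  far <- gating_time_constants(500)
  expect_equal(far$tau_h, 0.37, tolerance = 1e-6)
  expect_equal(far$tau_n, 0.37, tolerance = 1e-6)
})

test_that("membrane derivatives satisfy leak-only and fixed-point identities", {
  # all active conductances off, no drive: the cell rests at VL
  p <- neuron_params(gNa = 0, gKdr = 0, gKs = 0, Idrive = 0)
  st <- neuron_state(-60)
  expect_equal(membrane_derivatives(st, p)$dV, 0)
  # gating at steady state has zero gating derivatives
  p2 <- neuron_params()
  st2 <- neuron_state(-48)
  d <- membrane_derivatives(st2, p2)
  expect_equal(d$dh, 0, tolerance = 1e-12)
  expect_equal(d$dn, 0, tolerance = 1e-12)
  expect_equal(d$dz, 0, tolerance = 1e-12)
})

test_that("root-found rest point agrees with simulated relaxation", {
  p <- neuron_params(gKs = 1.5, Idrive = 0)
  v_star <- hh_rest(p)
  d <- membrane_derivatives(neuron_state(v_star), p)
  expect_equal(d$dV, 0, tolerance = 1e-8)
  r <- simulate_neuron(p, duration = 2000, v0 = v_star + 5)
  expect_equal(r$final_state$V, v_star, tolerance = 1e-4)
})

test_that("rest point is reached from dispersed initial conditions", {
  p <- neuron_params(gKs = 1.5, Idrive = 0.5)
  v_star <- hh_rest(p)
  set.seed(11)
  finals <- vapply(runif(20, -75, -50), function(v0)
    simulate_neuron(p, duration = 1500, v0 = v0)$final_state$V, numeric(1))
  expect_true(all(abs(finals - v_star) < 1e-4))
})

test_that("spike detection fires once per pulse and the quiet regime is quiet", {
  p <- neuron_params(gKs = 1.5, Idrive = 0.5)
  # the network background regime is subthreshold without noise
  expect_length(simulate_neuron(p, duration = 10000)$spikes, 0)
  # one 80 uA/cm2, 1 ms pulse from rest elicits exactly one spike
  r <- simulate_neuron(p, duration = 400,
                       pulses = data.frame(time = 100, amp = 80, width = 1))
  expect_length(r$spikes, 1)
  expect_gt(r$spikes, 100)
  expect_lt(r$spikes, 110)
})

test_that("gating variables stay in [0, 1] through a spiking run", {
  p <- neuron_params(gKs = 0, Idrive = 2)
  r <- simulate_neuron(p, duration = 1000)
  st <- r$final_state
  expect_true(all(c(st$h, st$n, st$z) >= 0 & c(st$h, st$n, st$z) <= 1))
  expect_gt(length(r$spikes), 10)
})

test_that("halving dt shifts spike times by less than 0.1 ms per spike", {
  p <- neuron_params(gKs = 1.5, Idrive = 2.5)
  s1 <- simulate_neuron(p, duration = 1000, dt = 0.05)$spikes
  s2 <- simulate_neuron(p, duration = 1000, dt = 0.025)$spikes
  expect_equal(length(s1), length(s2))
  expect_lt(max(abs(s1 - s2)), 0.1)
})

test_that("F-I curve is zero below rheobase and non-decreasing", {
  p <- neuron_params(gKs = 1.5)
  fi <- fi_curve(p, I_range = c(0.5, 1, 2, 3, 4), T = 2000, discard = 500)
  expect_equal(fi$rate_hz[1], 0)
  expect_true(all(diff(fi$rate_hz) >= 0))
})

test_that("PRC machinery: zero pulse gives zero shift, silence is an error", {
  p <- neuron_params(gKs = 0)
  prc0 <- phase_response_curve(p, I_tonic = 1, pulse_amp = 0, n_phases = 6)
  expect_true(all(abs(prc0$shift) < 1e-6))
  expect_error(phase_response_curve(neuron_params(gKs = 1.5), I_tonic = 0.5),
               "no limit cycle")
})

test_that("PRC minimum crosses from non-negative to negative as gKs rises", {
  mins <- vapply(c(0, 0.5, 1, 1.5), function(g)
    min(phase_response_curve(neuron_params(gKs = g), I_tonic = 2.5,
                             n_phases = 12)$shift),
    numeric(1))
  expect_gte(mins[1], -1e-6)
  expect_lt(mins[4], 0)
  # one transition: once the minimum goes negative it stays negative
  neg <- mins < -1e-6
  expect_true(all(diff(neg) >= 0))
})

test_that("excitability type follows the M-current conductance", {
  # Type 1 (gKs = 0): PRC non-negative at every phase
  prc1 <- phase_response_curve(neuron_params(gKs = 0), I_tonic = 1)
  expect_true(all(prc1$shift >= -1e-6))
  # Type 2 (gKs = 1.5): early-phase delays, late-phase advances
  prc2 <- phase_response_curve(neuron_params(gKs = 1.5), I_tonic = 2.5)
  expect_lt(min(prc2$shift[prc2$phase < 0.5]), 0)
  expect_gt(max(prc2$shift[prc2$phase > 0.5]), 0)
})
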