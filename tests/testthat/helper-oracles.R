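# Independent oracles used across the test files.

# Brute-force AMD: all-pairs nearest distance, no sorting tricks.
amd_brute <- function(s_i, s_j) {
  mean(vapply(s_i, function(t) min(abs(t - s_j)), numeric(1)))
}

# Monte-Carlo null for the nearest-spike distance of a uniformly placed
# point within the span of a reference train (brute-force minimum over
# every spike, vectorized over the sample points).
amd_null_mc <- function(s_ref, n = 3e5) {
  x <- runif(n, min(s_ref), max(s_ref))
  d <- rep(Inf, n)
  for (t in s_ref) d <- pmin(d, abs(x - t))
  c(mu = mean(d), sigma = sd(d))
}

# Explicit double-sum evaluation of an exponentially decaying synaptic
# drive (the spike-sum form of the trace).
syn_sum <- function(spike_times, increments, tau, times) {
  increments <- rep_len(increments, length(spike_times))
  vapply(times, function(t) {
    past <- spike_times <= t
    sum(increments[past] * exp(-(t - spike_times[past]) / tau))
  }, numeric(1))
}

# Plain-R RK4 reference integrator for a two-neuron microcircuit
# (neuron 1 drives neuron 2 through one excitatory edge), used to
# cross-check the compiled engine.  Mirrors the engine's conventions:
# analytic trace decay within a step, delivery at the end of the step in
# which the presynaptic spike was detected.
ref_two_neuron <- function(duration, dt, idrive, gks, amp, tau_f = 0.5,
                           v0 = c(-65, -65)) {
  p <- neuron_params()
  nst <- round(duration / dt)
  V <- v0
  ss <- gating_steady_states(V)
  h <- ss$h_inf; n <- ss$n_inf; z <- ss$z_inf
  gE <- c(0, 0)
  latch <- c(FALSE, FALSE)
  spikes1 <- numeric(0)
  vtrace2 <- numeric(nst)
  f <- function(V, h, n, z, gE, I) {
    ss <- gating_steady_states(V)
    tc <- gating_time_constants(V)
    list(
      dV = (-p$gNa * ss$m_inf^3 * h * (V - p$VNa) -
              p$gKdr * n^4 * (V - p$VK) -
              p$gL * (V - p$VL) - gks * z * (V - p$VK) +
              I - gE * V) / p$C,
      dh = (ss$h_inf - h) / tc$tau_h,
      dn = (ss$n_inf - n) / tc$tau_n,
      dz = (ss$z_inf - z) / p$tau_z)
  }
  dh_ <- exp(-0.5 * dt / tau_f); df_ <- dh_^2
  for (s in seq_len(nst)) {
    k1 <- f(V, h, n, z, gE, idrive)
    k2 <- f(V + dt / 2 * k1$dV, h + dt / 2 * k1$dh, n + dt / 2 * k1$dn,
            z + dt / 2 * k1$dz, gE * dh_, idrive)
    k3 <- f(V + dt / 2 * k2$dV, h + dt / 2 * k2$dh, n + dt / 2 * k2$dn,
            z + dt / 2 * k2$dz, gE * dh_, idrive)
    k4 <- f(V + dt * k3$dV, h + dt * k3$dh, n + dt * k3$dn,
            z + dt * k3$dz, gE * df_, idrive)
    Vn <- V + dt / 6 * (k1$dV + 2 * k2$dV + 2 * k3$dV + k4$dV)
    h <- pmin(pmax(h + dt / 6 * (k1$dh + 2 * k2$dh + 2 * k3$dh + k4$dh), 0), 1)
    n <- pmin(pmax(n + dt / 6 * (k1$dn + 2 * k2$dn + 2 * k3$dn + k4$dn), 0), 1)
    z <- pmin(pmax(z + dt / 6 * (k1$dz + 2 * k2$dz + 2 * k3$dz + k4$dz), 0), 1)
    gE <- gE * df_
    fired1 <- !latch[1] && V[1] < 5 && Vn[1] >= 5
    latch <- (latch & Vn >= 5) | (Vn >= 5 & V < 5)
    if (fired1) {
      spikes1 <- c(spikes1, s * dt)
      gE[2] <- gE[2] + amp
    }
    V <- Vn
    vtrace2[s] <- V[2]
  }
  list(spikes1 = spikes1, v2 = vtrace2, t = seq_len(nst) * dt)
}
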