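#' Biophysical parameters of a model neuron
#'
#' Single-compartment Hodgkin-Huxley cell with a fast sodium current, a
#' delayed-rectifier potassium current, a leak, and a slow M-type potassium
#' current whose maximal conductance `gKs` is the acetylcholine proxy
#' (`gKs = 1.5` low-ACh/NREM-like, `gKs = 0` high-ACh/REM-like).  Defaults are
#' the values used in all network simulations; excitatory and inhibitory
#' neurons share every parameter except the constant drive `Idrive`.
#'
#' @param gKs M-current maximal conductance, mS/cm2 (0 to 1.5).
#' @param Idrive constant driving current, uA/cm2 (0.5 excitatory, -0.1
#'   inhibitory by convention).
#' @param C membrane capacitance, uF/cm2.
#' @param gNa,gKdr,gL maximal conductances, mS/cm2.
#' @param VNa,VK,VL reversal potentials, mV.
#' @param tau_z M-current activation time constant, ms.
#' @param v_thresh spike-detection threshold, mV (upward crossing).
#' @return An object of class `neuron_params` (named list).
#' @export
#' @examples
#' p <- neuron_params(gKs = 1.5)
#' hh_rest(p)
neuron_params <- function(gKs = 1.5, Idrive = 0.5,
                          C = 1, gNa = 24, gKdr = 3, gL = 0.02,
                          VNa = 55, VK = -90, VL = -60,
                          tau_z = 75, v_thresh = 5) {
  stopifnot(C > 0, gNa >= 0, gKdr >= 0, gKs >= 0, gL >= 0, tau_z > 0)
  structure(list(C = C, gNa = gNa, gKdr = gKdr, gKs = gKs, gL = gL,
                 VNa = VNa, VK = VK, VL = VL, Idrive = Idrive,
                 tau_z = tau_z, v_thresh = v_thresh),
            class = "neuron_params")
}

#' Steady-state gating curves
#'
#' Sigmoid activation/inactivation curves of the four gating variables.
#' `m` (Na activation, instantaneous), `n` (delayed-rectifier activation) and
#' `z` (M-current activation) increase with voltage with half-points at
#' -30, -30 and -39 mV; `h` (Na inactivation) decreases with half-point
#' -53 mV.
#'
#' @param V membrane voltage, mV (vectorized).
#' @return Data frame with columns `m_inf`, `h_inf`, `n_inf`, `z_inf`.
#' @export
gating_steady_states <- function(V) {
  if (!is.numeric(V) || any(!is.finite(V)))
    stop("V must be finite numeric")
  data.frame(
    m_inf = 1 / (1 + exp(-(V + 30) / 9.5)),
    h_inf = 1 / (1 + exp((V + 53) / 7)),
    n_inf = 1 / (1 + exp(-(V + 30) / 10)),
    z_inf = 1 / (1 + exp(-(V + 39) / 5))
  )
}

#' Voltage-dependent gating time constants
#'
#' Time constants of Na inactivation (`tau_h`, between 0.37 and 3.15 ms) and
#' delayed-rectifier activation (`tau_n`, between 0.37 and 2.22 ms); both
#' approach 0.37 ms at strongly depolarized voltages.  The M-current time
#' constant is voltage-independent (75 ms) and lives in [neuron_params()].
#'
#' @param V membrane voltage, mV (vectorized).
#' @return Data frame with columns `tau_h`, `tau_n` (ms).
#' @export
gating_time_constants <- function(V) {
  if (!is.numeric(V) || any(!is.finite(V)))
    stop("V must be finite numeric")
  data.frame(
    tau_h = 0.37 + 2.78 / (1 + exp((V + 40.5) / 6)),
    tau_n = 0.37 + 1.85 / (1 + exp((V + 27) / 15))
  )
}

#' Neuron state constructor
#'
#' @param V membrane voltage, mV.
#' @param h,n,z gating variables in \[0, 1\]; default to their steady-state
#'   values at `V`.
#' @return Named list of class `neuron_state`.
#' @export
neuron_state <- function(V, h = NULL, n = NULL, z = NULL) {
  ss <- gating_steady_states(V)
  h <- if (is.null(h)) ss$h_inf else h
  n <- if (is.null(n)) ss$n_inf else n
  z <- if (is.null(z)) ss$z_inf else z
  stopifnot(all(c(h, n, z) >= 0), all(c(h, n, z) <= 1), is.finite(V))
  structure(list(V = V, h = h, n = n, z = z), class = "neuron_state")
}

#' Membrane and gating derivatives
#'
#' Right-hand side of the single-cell dynamics: the voltage derivative sums
#' the fast Na, delayed-rectifier K, leak, and M currents with the constant
#' drive, noise input and (subtracted) synaptic current, divided by the
#' capacitance; gating variables relax first-order to their steady states.
#'
#' @param state a [neuron_state()].
#' @param params a [neuron_params()].
#' @param I_syn synaptic current, uA/cm2 (positive = outward by the driving
#'   force convention; enters with a minus sign).
#' @param I_noise additive noise current, uA/cm2.
#' @return Named list `dV`, `dh`, `dn`, `dz` (mV/ms, 1/ms).
#' @export
membrane_derivatives <- function(state, params, I_syn = 0, I_noise = 0) {
  stopifnot(inherits(state, "neuron_state"), inherits(params, "neuron_params"))
  V <- state$V
  ss <- gating_steady_states(V)
  tc <- gating_time_constants(V)
  with(params, {
    I_ion <- -gNa * ss$m_inf^3 * state$h * (V - VNa) -
      gKdr * state$n^4 * (V - VK) -
      gL * (V - VL) -
      gKs * state$z * (V - VK)
    list(
      dV = (I_ion + Idrive + I_noise - I_syn) / C,
      dh = (ss$h_inf - state$h) / tc$tau_h,
      dn = (ss$n_inf - state$n) / tc$tau_n,
      dz = (ss$z_inf - state$z) / tau_z
    )
  })
}

#' Resting potential by root finding
#'
#' Solves the steady-state current balance (all gating variables at their
#' voltage-dependent steady states, no synaptic or noise input) for the
#' membrane voltage at which `dV/dt = 0`.
#'
#' @param params a [neuron_params()].
#' @param interval search interval in mV.
#' @return Resting voltage, mV.
#' @export
hh_rest <- function(params, interval = c(-90, -20)) {
  f <- function(V) {
    ss <- gating_steady_states(V)
    with(params,
      -gNa * ss$m_inf^3 * ss$h_inf * (V - VNa) -
        gKdr * ss$n_inf^4 * (V - VK) -
        gL * (V - VL) -
        gKs * ss$z_inf * (V - VK) + Idrive)
  }
  stats::uniroot(f, interval, tol = 1e-10)$root
}

#' Simulate one isolated neuron
#'
#' Fixed-step RK4 integration of a single cell with optional square current
#' pulses and the per-millisecond Bernoulli noise process.  Spike times are
#' interpolated at the 5 mV upward crossing; a latch prevents re-triggering
#' while the voltage stays above threshold.
#'
#' @param params a [neuron_params()].
#' @param duration simulation length, ms.
#' @param dt integration step, ms (must divide 1 ms).
#' @param pulses optional data frame with columns `time`, `amp`, `width`
#'   (ms, uA/cm2, ms) of additive square pulses.
#' @param noise_p per-neuron, per-millisecond pulse probability (0 disables
#'   the noise process).
#' @param noise_amp,noise_dur noise pulse amplitude (uA/cm2) and width (ms).
#' @param v0 initial voltage (defaults to the resting point); gating starts
#'   at steady state for `v0`.
#' @param record_v record the voltage trace (logical).
#' @param seed optional RNG seed for the noise process.
#' @return List with `spikes` (ms), and if requested `v` / `t` traces.
#' @export
simulate_neuron <- function(params, duration, dt = 0.05, pulses = NULL,
                            noise_p = 0, noise_amp = 80, noise_dur = 1,
                            v0 = NULL, record_v = FALSE, seed = NULL) {
  stopifnot(inherits(params, "neuron_params"), duration > 0, dt > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(v0)) v0 <- hh_rest(params)
  ss <- gating_steady_states(v0)

  # build the drive timeline: constant Idrive plus square pulses
  bounds <- duration
  if (!is.null(pulses) && nrow(pulses) > 0) {
    stopifnot(all(c("time", "amp", "width") %in% names(pulses)))
    bounds <- sort(unique(c(pulses$time, pulses$time + pulses$width, duration)))
    bounds <- bounds[bounds > 0 & bounds <= duration]
    if (bounds[length(bounds)] < duration) bounds <- c(bounds, duration)
  }
  n_seg <- length(bounds)
  starts <- c(0, bounds[-n_seg])
  add <- numeric(n_seg)
  if (!is.null(pulses) && nrow(pulses) > 0) {
    for (k in seq_len(nrow(pulses))) {
      on <- starts >= pulses$time[k] - 1e-9 &
        starts < pulses$time[k] + pulses$width[k] - 1e-9
      add[on] <- add[on] + pulses$amp[k]
    }
  }

  res <- .sim_network(
    v0 = v0, h0 = ss$h_inf, n0 = ss$n_inf, z0 = ss$z_inf,
    idrive = params$Idrive,
    cell = params[c("C", "gNa", "gKdr", "gL", "VNa", "VK", "VL",
                    "tau_z", "v_thresh")],
    e_pre = integer(0), e_post = integer(0),
    e_amp_fast = numeric(0), e_amp_slow = numeric(0),
    e_exc = integer(0), e_w = numeric(0), e_px = numeric(0),
    seg_end = bounds, seg_gks = rep(params$gKs, n_seg),
    seg_plastic = rep(0L, n_seg),
    seg_drive = matrix(add, nrow = 1),
    stdp = list(a_plus = 0, a_minus = 0, tau_plus = 1, tau_minus = 1, wmax = 5),
    syn = list(tau_f = 0.5, tau_s = 50, erev_e = 0, erev_i = -75),
    noise_p = noise_p, noise_amp = noise_amp, noise_dur = noise_dur,
    dt = dt, snap_times = numeric(0),
    record_idx = if (record_v) 0L else integer(0),
    record_stride = if (record_v) 1L else 0L)

  out <- list(spikes = res$spike_t,
              final_state = neuron_state(res$v_final, res$h_final,
                                         res$n_final, res$z_final))
  if (record_v) {
    out$t <- res$v_trace_t
    out$v <- as.numeric(res$v_trace)
  }
  out
}

#' Steady-state F-I curve
#'
#' Firing rate as a function of constant drive, computed from spike counts
#' after a transient discard window.  With `gKs = 0` the onset is continuous
#' (Type 1 excitability: arbitrarily low rates above rheobase); with
#' `gKs = 1.5` the onset jumps discontinuously to a finite frequency
#' (Type 2).
#'
#' @param params a [neuron_params()]; its `Idrive` is ignored.
#' @param I_range drive values to scan, uA/cm2.
#' @param T simulated time per drive value, ms.
#' @param discard transient discarded before counting, ms.
#' @param dt integration step, ms.
#' @return Data frame with columns `I` (uA/cm2) and `rate_hz`.
#' @export
fi_curve <- function(params, I_range, T = 3000, discard = 500, dt = 0.05) {
  stopifnot(T > discard)
  rate <- vapply(I_range, function(I) {
    p <- params
    p$Idrive <- I
    sp <- simulate_neuron(p, duration = T, dt = dt)$spikes
    sum(sp > discard) / (T - discard) * 1000
  }, numeric(1))
  data.frame(I = I_range, rate_hz = rate)
}

#' Phase response curve by direct perturbation
#'
#' For a tonically firing cell, delivers a brief current pulse at a set of
#' phases of the limit cycle and reports the normalized shift of the next
#' spike, `(T0 - T_perturbed) / T0` (positive = phase advance).  At
#' `gKs = 0` the PRC is non-negative at all phases (Type 1); at `gKs = 1.5`
#' inputs arriving shortly after a spike delay the next one, making the PRC
#' biphasic (Type 2).
#'
#' @param params a [neuron_params()]; its `Idrive` is ignored.
#' @param I_tonic constant drive placing the cell above rheobase, uA/cm2.
#' @param pulse_amp,pulse_width perturbation amplitude (uA/cm2) and width (ms).
#' @param n_phases number of equally spaced phases in \[0, 1).
#' @param n_settle cycles discarded while converging to the limit cycle.
#' @param dt integration step, ms.
#' @return Data frame with columns `phase` and `shift`.
#' @export
phase_response_curve <- function(params, I_tonic, pulse_amp = 1,
                                 pulse_width = 1, n_phases = 20,
                                 n_settle = 20, dt = 0.05) {
  p <- params
  p$Idrive <- I_tonic
  probe <- simulate_neuron(p, duration = 4000, dt = dt)$spikes
  if (length(probe) < n_settle + 6)
    stop("no limit cycle: cell does not fire periodically at I_tonic = ",
         I_tonic)
  isi <- diff(probe)
  T0 <- mean(utils::tail(isi, 5))
  if (stats::sd(utils::tail(isi, 5)) / T0 > 1e-3)
    stop("no limit cycle: inter-spike intervals have not converged")
  t_ref <- probe[length(probe) - 3]
  t_next0 <- probe[length(probe) - 2]  # unperturbed next spike
  # midpoint phase sampling avoids placing the pulse exactly on the spike
  phases <- (seq_len(n_phases) - 0.5) / n_phases
  shift <- vapply(phases, function(ph) {
    pert <- simulate_neuron(
      p, duration = t_ref + 3 * T0, dt = dt,
      pulses = data.frame(time = t_ref + ph * T0, amp = pulse_amp,
                          width = pulse_width))$spikes
    nxt <- pert[pert > t_ref + 1e-6][1]
    (t_next0 - nxt) / T0
  }, numeric(1))
  data.frame(phase = phases, shift = shift)
}
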