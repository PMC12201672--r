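#' Synaptic kinetics and relative efficacies
#'
#' Postsynaptic currents are linear combinations of exponentially decaying
#' fast excitatory, fast inhibitory (GABA-A-like) and slow inhibitory
#' (GABA-B-like) components.  Relative amplitudes depend on the postsynaptic
#' class: excitatory input is stronger onto excitatory cells (0.15) than
#' onto interneurons (0.08); fast inhibition targets only interneurons
#' (0.15) while excitatory cells receive only the slow component (0.05).
#'
#' @param R_E_exc,R_E_inh excitatory amplitude onto excitatory / inhibitory
#'   targets.
#' @param R_fI_exc,R_fI_inh fast inhibitory amplitude onto excitatory /
#'   inhibitory targets.
#' @param R_sI_exc,R_sI_inh slow inhibitory amplitude onto excitatory /
#'   inhibitory targets.
#' @param tau_f,tau_s fast and slow decay time constants, ms.
#' @param erev_e,erev_i excitatory and inhibitory reversal potentials, mV.
#' @return Named list of class `synapse_params`.
#' @export
synapse_params <- function(R_E_exc = 0.15, R_E_inh = 0.08,
                           R_fI_exc = 0, R_fI_inh = 0.15,
                           R_sI_exc = 0.05, R_sI_inh = 0,
                           tau_f = 0.5, tau_s = 50,
                           erev_e = 0, erev_i = -75) {
  amps <- c(R_E_exc, R_E_inh, R_fI_exc, R_fI_inh, R_sI_exc, R_sI_inh)
  stopifnot(all(amps >= 0), tau_f > 0, tau_s > 0)
  structure(list(R_E_exc = R_E_exc, R_E_inh = R_E_inh,
                 R_fI_exc = R_fI_exc, R_fI_inh = R_fI_inh,
                 R_sI_exc = R_sI_exc, R_sI_inh = R_sI_inh,
                 tau_f = tau_f, tau_s = tau_s,
                 erev_e = erev_e, erev_i = erev_i),
            class = "synapse_params")
}

#' STDP rule parameters
#'
#' Additive, bounded spike-timing-dependent plasticity: potentiation
#' `Px * A_plus * exp(-|dt|/tau_plus)` when the presynaptic spike precedes
#' the postsynaptic one, depression `-Px * A_minus * exp(-|dt|/tau_minus)`
#' otherwise.  `Px` scales the rate per (presynaptic, postsynaptic) group
#' pair; it is zero for every pair involving inhibitory neurons and for
#' engram-backbone-internal connections, whose weights are fixed.
#'
#' @param a_plus,a_minus maximal potentiation / depression step.
#' @param tau_plus,tau_minus exponential time constants, ms.
#' @param wmax upper weight bound (weights live in \[0, wmax\]).
#' @return Named list of class `stdp_params`.
#' @export
stdp_params <- function(a_plus = 0.07, a_minus = 0.025,
                        tau_plus = 14, tau_minus = 34, wmax = 5) {
  stopifnot(a_plus >= 0, a_minus >= 0, tau_plus > 0, tau_minus > 0, wmax > 0)
  structure(list(a_plus = a_plus, a_minus = a_minus,
                 tau_plus = tau_plus, tau_minus = tau_minus, wmax = wmax),
            class = "stdp_params")
}

#' STDP weight change for a spike-time offset
#'
#' @param dt_post_pre postsynaptic minus presynaptic spike time, ms
#'   (vectorized).  Positive values potentiate, negative values depress;
#'   exactly simultaneous spikes produce no change.
#' @param px plasticity-rate multiplier for the group pair.
#' @param params an [stdp_params()].
#' @return Weight increments (same length as `dt_post_pre`).
#' @export
#' @examples
#' stdp_delta(14, px = 1)    # 0.07 * exp(-1)
stdp_delta <- function(dt_post_pre, px = 1, params = stdp_params()) {
  ifelse(dt_post_pre > 0,
         px * params$a_plus * exp(-abs(dt_post_pre) / params$tau_plus),
         ifelse(dt_post_pre < 0,
                -px * params$a_minus * exp(-abs(dt_post_pre) / params$tau_minus),
                0))
}

#' Synchrony boundary of the STDP rule
#'
#' The positive offset at which the potentiation magnitude at `+t` equals
#' the depression magnitude at `-t`; spike pairs closer than this are net
#' potentiating when encountered symmetrically, pairs further apart are net
#' depressing.  Closed form:
#' `t = log(a_plus/a_minus) / (1/tau_plus - 1/tau_minus)`.
#'
#' @param params an [stdp_params()].
#' @return Offset in ms (about 24.5 ms at the default parameters).
#' @export
stdp_synchrony_boundary <- function(params = stdp_params()) {
  log(params$a_plus / params$a_minus) /
    (1 / params$tau_plus - 1 / params$tau_minus)
}

#' Apply nearest-preceding-spike STDP to a weight over paired spike trains
#'
#' Reference (pure R) implementation of the online pairing rule used by the
#' network engine: on each postsynaptic spike the weight is potentiated
#' against the most recent earlier presynaptic spike, and on each
#' presynaptic spike it is depressed against the most recent earlier
#' postsynaptic spike; the weight is clipped to \[0, wmax\] after every
#' update.  Useful for single-edge experiments and as a cross-check of the
#' compiled engine.
#'
#' @param pre,post presynaptic and postsynaptic spike times, ms (sorted).
#' @param w0 initial weight.
#' @param px plasticity-rate multiplier.
#' @param params an [stdp_params()].
#' @return Final weight.
#' @export
apply_stdp_edge <- function(pre, post, w0 = 1, px = 1,
                            params = stdp_params()) {
  ev <- rbind(data.frame(t = pre, is_post = FALSE),
              data.frame(t = post, is_post = TRUE))
  ev <- ev[order(ev$t), , drop = FALSE]
  w <- w0
  last_pre <- -Inf
  last_post <- -Inf
  for (k in seq_len(nrow(ev))) {
    t <- ev$t[k]
    if (ev$is_post[k]) {
      if (is.finite(last_pre) && t > last_pre)
        w <- w + stdp_delta(t - last_pre, px, params)
      last_post <- t
    } else {
      if (is.finite(last_post) && t > last_post)
        w <- w + stdp_delta(last_post - t, px, params)
      last_pre <- t
    }
    w <- min(max(w, 0), params$wmax)
  }
  w
}

#' Exponentially decaying synaptic trace
#'
#' Evaluates a per-target synaptic drive trace that decays with time
#' constant `tau` and jumps by `increments[k]` at `spike_times[k]`, at the
#' requested times.  This trace representation is mathematically identical
#' to summing `increment * exp(-(t - t_k)/tau)` over all past spikes.
#'
#' @param spike_times presynaptic spike times, ms (sorted).
#' @param increments jump size per spike (recycled).
#' @param tau decay time constant, ms.
#' @param times evaluation times, ms.
#' @return Trace values at `times`.
#' @export
syn_trace <- function(spike_times, increments, tau, times) {
  stopifnot(tau > 0, !is.unsorted(spike_times))
  increments <- rep_len(increments, length(spike_times))
  vapply(times, function(t) {
    past <- spike_times <= t
    sum(increments[past] * exp(-(t - spike_times[past]) / tau))
  }, numeric(1))
}

#' Bernoulli noise pulse process
#'
#' Every millisecond each neuron independently receives, with probability
#' `p_per_ms`, a square current pulse of `amp` uA/cm2 lasting `dur` ms.
#' At the default `p_per_ms = 0.002` and 80 uA/cm2 this drives synaptically
#' isolated neurons at roughly 2 Hz (one spike per pulse).
#'
#' @param n_neurons number of neurons.
#' @param duration ms.
#' @param p_per_ms per-neuron, per-millisecond pulse probability.
#' @param amp pulse amplitude, uA/cm2.
#' @param seed optional RNG seed.
#' @return Data frame with columns `neuron_id`, `time_ms` (pulse onsets).
#' @export
noise_process <- function(n_neurons, duration, p_per_ms = 0.002, amp = 80,
                          seed = NULL) {
  stopifnot(p_per_ms >= 0, p_per_ms <= 1, duration > 0, n_neurons >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_ms <- floor(duration)
  hits <- which(matrix(runif(n_neurons * n_ms), n_neurons) < p_per_ms,
                arr.ind = TRUE)
  out <- data.frame(neuron_id = as.integer(hits[, 1]),
                    time_ms = as.numeric(hits[, 2] - 1))
  out <- out[order(out$neuron_id, out$time_ms), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "amp") <- amp
  out
}
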