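# Synthetic spike-train generators.  These emulate the statistical
# structure the analysis metrics assume — independent trains, synchronous
# pairs, oscillatory populations, and state-dependent synchrony changes —
# so every statistic is testable without running the network simulator.

.raster_df <- function(neuron_id, time_ms, group, window) {
  ord <- order(neuron_id, time_ms)
  out <- data.frame(neuron_id = as.integer(neuron_id[ord]),
                    group = group[ord], time_ms = time_ms[ord])
  attr(out, "window") <- window
  out
}

#' Homogeneous Poisson raster
#'
#' Independent Poisson spike trains at a common rate.
#'
#' @param n_neurons number of neurons.
#' @param rate firing rate, Hz.
#' @param duration ms.
#' @param seed RNG seed.
#' @param group group label.
#' @return Spike raster data frame (`neuron_id`, `group`, `time_ms`).
#' @export
fixture_poisson <- function(n_neurons, rate, duration, seed = 1,
                            group = "POP") {
  stopifnot(rate >= 0, duration > 0, n_neurons >= 1)
  set.seed(seed)
  counts <- rpois(n_neurons, rate * duration / 1000)
  id <- rep(seq_len(n_neurons), counts)
  .raster_df(id, runif(sum(counts), 0, duration),
             rep(group, sum(counts)), c(0, duration))
}

#' Jittered-synchronous pair
#'
#' Neuron 1 fires as a Poisson process; neuron 2 emits one spike per
#' neuron-1 spike, displaced by Gaussian jitter.  With zero jitter the two
#' trains coincide exactly (maximal functional connectivity); increasing
#' jitter degrades the locking smoothly.
#'
#' @param rate Hz.
#' @param duration ms.
#' @param jitter_sd Gaussian jitter SD, ms.
#' @param seed RNG seed.
#' @return Spike raster with neurons 1 (reference) and 2 (jittered copy).
#' @export
fixture_jittered_pair <- function(rate, duration, jitter_sd, seed = 1) {
  stopifnot(rate > 0, duration > 0, jitter_sd >= 0)
  set.seed(seed)
  n1 <- rpois(1, rate * duration / 1000)
  s1 <- sort(runif(n1, 0, duration))
  s2 <- s1 + rnorm(n1, 0, jitter_sd)
  s2 <- sort(s2[s2 >= 0 & s2 <= duration])
  .raster_df(c(rep(1L, length(s1)), rep(2L, length(s2))), c(s1, s2),
             rep("PAIR", length(s1) + length(s2)), c(0, duration))
}

#' Periodically bursting population
#'
#' Every neuron emits a burst around each multiple of the period, with
#' per-spike Gaussian jitter — a caricature of the synchronized population
#' oscillations seen in the high-ACh network state.
#'
#' @param n_neurons number of neurons.
#' @param period burst period, ms (125 ms gives an 8 Hz population peak).
#' @param duration ms.
#' @param spikes_per_burst spikes each neuron fires per cycle.
#' @param jitter_sd within-burst jitter SD, ms.
#' @param seed RNG seed.
#' @return Spike raster data frame.
#' @export
fixture_periodic_burster <- function(n_neurons, period, duration,
                                     spikes_per_burst = 1, jitter_sd = 3,
                                     seed = 1) {
  stopifnot(period > 0, duration > period)
  set.seed(seed)
  centers <- seq(period / 2, duration, by = period)
  per <- length(centers) * spikes_per_burst
  id <- rep(seq_len(n_neurons), each = per)
  t <- rep(rep(centers, each = spikes_per_burst), n_neurons) +
    rnorm(n_neurons * per, 0, jitter_sd)
  keep <- t >= 0 & t <= duration
  .raster_df(id[keep], t[keep], rep("BURST", sum(keep)), c(0, duration))
}

#' Alternating NREM/REM bouts with state-dependent synchrony
#'
#' Generates a population raster plus a matching bout-annotation table in
#' which NREM-labelled bouts contain synchronous firing (all neurons are
#' jittered copies of a common mother train) while REM-labelled bouts
#' contain independent Poisson firing at the same rate.  The paired-bout
#' functional-connectivity change on this fixture is therefore negative by
#' construction (locking is lost from NREM to REM), mirroring the
#' empirical baseline observation that average functional connectivity is
#' lower in REM than in the preceding NREM.
#'
#' @param n_neurons number of neurons.
#' @param n_pairs number of NREM/REM bout pairs.
#' @param nrem_dur,rem_dur bout durations, ms.
#' @param gap gap between bouts, ms (must stay below the pairing cutoff
#'   for the pairs to qualify).
#' @param rate firing rate in both states, Hz.
#' @param nrem_jitter_sd jitter of the synchronous NREM spikes, ms.
#' @param rem_sync if `TRUE`, REM bouts are synchronous too (null
#'   construction: the delta-z distribution is then centred at zero).
#' @param seed RNG seed.
#' @return List with `raster` and `bouts`.
#' @export
fixture_rate_switching_bouts <- function(n_neurons = 20, n_pairs = 3,
                                         nrem_dur = 60000, rem_dur = 20000,
                                         gap = 2000, rate = 5,
                                         nrem_jitter_sd = 3,
                                         rem_sync = FALSE, seed = 1) {
  set.seed(seed)
  id <- integer(0); tm <- numeric(0)
  bouts <- list()
  t0 <- 0
  sync_bout <- function(start, dur) {
    n_m <- rpois(1, rate * dur / 1000)
    mother <- sort(runif(n_m, 0, dur))
    tt <- rep(mother, n_neurons) + rnorm(n_m * n_neurons, 0, nrem_jitter_sd)
    ii <- rep(seq_len(n_neurons), each = n_m)
    keep <- tt >= 0 & tt <= dur
    list(id = ii[keep], t = start + tt[keep])
  }
  pois_bout <- function(start, dur) {
    counts <- rpois(n_neurons, rate * dur / 1000)
    list(id = rep(seq_len(n_neurons), counts),
         t = start + runif(sum(counts), 0, dur))
  }
  for (k in seq_len(n_pairs)) {
    b <- sync_bout(t0, nrem_dur)
    id <- c(id, b$id); tm <- c(tm, b$t)
    bouts[[length(bouts) + 1]] <- data.frame(state = "NREM", start = t0,
                                             end = t0 + nrem_dur)
    t0 <- t0 + nrem_dur + gap
    b <- if (rem_sync) sync_bout(t0, rem_dur) else pois_bout(t0, rem_dur)
    id <- c(id, b$id); tm <- c(tm, b$t)
    bouts[[length(bouts) + 1]] <- data.frame(state = "REM", start = t0,
                                             end = t0 + rem_dur)
    t0 <- t0 + rem_dur + gap
  }
  list(raster = .raster_df(id, tm, rep("POP", length(id)), c(0, t0)),
       bouts = do.call(rbind, bouts))
}
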