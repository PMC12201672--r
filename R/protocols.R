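#' Simulation epoch
#'
#' One entry of a state schedule: a labelled stretch of simulated time with
#' its own M-current conductance (the acetylcholine proxy), plasticity flag
#' and optional stimulation directive.  Conventions: the low-ACh NREM-like
#' state (`ACh_minus`) uses `gKs = 1.5`, the high-ACh REM-like state
#' (`ACh_plus`) `gKs = 0`, and memory-recall test epochs `gKs = 0.1` with
#' plasticity off.
#'
#' @param label epoch label (free text; `ACh_minus`, `ACh_plus`, `test_*`
#'   and `baseline` are the conventional ones).
#' @param duration ms (non-negative).
#' @param gks M-current conductance during the epoch, mS/cm2.
#' @param plasticity logical; whether STDP runs during the epoch.
#' @param stim `NULL`, or a stimulation directive created by
#'   [stim_constant()] or [stim_alternating()].
#' @return Named list of class `sim_epoch`.
#' @export
epoch <- function(label, duration, gks, plasticity = FALSE, stim = NULL) {
  if (!is.numeric(duration) || duration < 0)
    stop("epoch duration must be non-negative")
  stopifnot(gks >= 0)
  structure(list(label = label, duration = duration, gks = gks,
                 plasticity = isTRUE(plasticity), stim = stim),
            class = "sim_epoch")
}

#' Constant-drive stimulation directive
#'
#' Adds a constant current to every neuron of the named groups for the
#' whole epoch (used for test bouts, where one backbone is activated while
#' the other is suppressed).
#'
#' @param drive named numeric vector: added `Idrive` (uA/cm2) per group.
#' @return Stimulation directive.
#' @export
stim_constant <- function(drive) {
  stopifnot(is.numeric(drive), !is.null(names(drive)))
  list(mode = "constant", drive = drive)
}

#' Alternating-reactivation stimulation directive
#'
#' Reactivates the target groups one at a time in repeating bouts: while
#' one backbone receives `drive_on`, the other receives `drive_suppress`,
#' mimicking temporally segregated offline replay of distinct memories;
#' bouts may be separated by quiet gaps.
#'
#' @param targets character vector of exactly two group names.
#' @param bout_length bout duration in ms; length 1 or 2 (per target, for
#'   saliency-bias protocols).
#' @param gap quiet time between bouts, ms.
#' @param drive_on added drive to the active target, uA/cm2; length 1 or 2.
#' @param drive_suppress added drive to the inactive target, uA/cm2.
#' @return Stimulation directive.
#' @export
stim_alternating <- function(targets, bout_length = 200, gap = 0,
                             drive_on = 2, drive_suppress = -6) {
  stopifnot(length(targets) == 2, all(bout_length > 0), gap >= 0)
  list(mode = "alternating", targets = targets,
       bout_length = rep_len(bout_length, 2), gap = gap,
       drive_on = rep_len(drive_on, 2), drive_suppress = drive_suppress)
}

#' Sleep-cycle schedule
#'
#' Builds the epoch list for `n_cycles` repetitions of the NREM-like
#' `ACh_minus` state followed by the REM-like `ACh_plus` state (or the
#' reversed order), with alternating backbone reactivation during sleep
#' epochs and optional interleaved memory tests in which each backbone is
#' activated in turn under low `gKs` and frozen weights.
#'
#' @param n_cycles number of sleep cycles.
#' @param dur_minus,dur_plus durations of the two states per cycle, ms.
#' @param reversed if `TRUE`, each cycle runs `ACh_plus` before `ACh_minus`.
#' @param tests one of `"states"` (test pair at baseline and after every
#'   state — the two-memory consolidation protocol), `"cycles"` (test pair
#'   at baseline and after every full cycle — the cycling protocol), or
#'   `"none"`.
#' @param test_duration duration of each single-backbone test bout, ms.
#' @param test_gks M-current conductance during tests.
#' @param test_drive constant drive added to the activated backbone during
#'   a test, uA/cm2.
#' @param stim_minus,stim_plus `NULL` for unstimulated sleep epochs, or
#'   [stim_alternating()] directives applied to the `ACh_minus` /
#'   `ACh_plus` epochs.  The defaults drive the active backbone near its
#'   Type 2 rheobase in the low-ACh state (so it fires in synchronized
#'   bursts that recruit plastic neurons) and harder in the high-ACh state
#'   (where inhibition is strong and tonic backbone firing drives
#'   competitive depression of weak inputs).
#' @param targets backbone group names (used for tests and the default
#'   stimulation directive).
#' @param suppress added drive to the non-activated backbone during tests,
#'   uA/cm2.
#' @return List of [epoch()] objects.
#' @export
make_sleep_schedule <- function(n_cycles = 1, dur_minus = 30000,
                                dur_plus = 30000, reversed = FALSE,
                                tests = c("states", "cycles", "none"),
                                test_duration = 3000, test_gks = 0.1,
                                test_drive = 2,
                                stim_minus = stim_alternating(
                                  c("EB1", "EB2"), drive_on = 1),
                                stim_plus = stim_alternating(
                                  c("EB1", "EB2"), drive_on = 3),
                                targets = c("EB1", "EB2"),
                                suppress = -6) {
  tests <- match.arg(tests)
  stopifnot(n_cycles >= 1)
  test_pair <- function(tag) {
    lapply(seq_along(targets), function(k) {
      drive <- stats::setNames(c(test_drive, rep(suppress, length(targets) - 1)),
                               c(targets[k], targets[-k]))
      epoch(paste0("test_", targets[k], "_", tag), test_duration, test_gks,
            plasticity = FALSE, stim = stim_constant(drive))
    })
  }
  sleep_pair <- function(cyc) {
    minus <- epoch(paste0("ACh_minus_", cyc), dur_minus, 1.5,
                   plasticity = TRUE, stim = stim_minus)
    plus <- epoch(paste0("ACh_plus_", cyc), dur_plus, 0,
                  plasticity = TRUE, stim = stim_plus)
    if (reversed) list(plus, minus) else list(minus, plus)
  }
  sched <- if (tests == "none") list() else test_pair("baseline")
  for (cyc in seq_len(n_cycles)) {
    pair <- sleep_pair(cyc)
    if (tests == "states") {
      sched <- c(sched, pair[1], test_pair(paste0("s1c", cyc)),
                 pair[2], test_pair(paste0("s2c", cyc)))
    } else if (tests == "cycles") {
      sched <- c(sched, pair, test_pair(paste0("c", cyc)))
    } else {
      sched <- c(sched, pair)
    }
  }
  sched
}

# Expand a schedule into the engine's segment timeline: per segment an end
# time, gKs, plasticity flag, and per-neuron added drive.
.compile_schedule <- function(network, schedule) {
  groups <- network$neurons$group
  n <- nrow(network$neurons)
  seg_end <- numeric(0); seg_gks <- numeric(0); seg_pl <- integer(0)
  drives <- list()
  ep_log <- data.frame(label = character(0), start = numeric(0),
                       end = numeric(0), gks = numeric(0),
                       plasticity = logical(0))
  t <- 0
  group_drive <- function(drv) {
    out <- numeric(n)
    for (gname in names(drv)) {
      hit <- groups == gname
      if (!any(hit)) stop("stimulation targets unknown group: ", gname)
      out[hit] <- out[hit] + drv[[gname]]
    }
    out
  }
  push <- function(len, gks, pl, dr) {
    if (len <= 0) return(invisible())
    seg_end <<- c(seg_end, t + len); t <<- t + len
    seg_gks <<- c(seg_gks, gks); seg_pl <<- c(seg_pl, as.integer(pl))
    drives[[length(drives) + 1]] <<- dr
  }
  for (ep in schedule) {
    stopifnot(inherits(ep, "sim_epoch"))
    t0 <- t
    if (ep$duration > 0) {
      if (is.null(ep$stim)) {
        push(ep$duration, ep$gks, ep$plasticity, numeric(n))
      } else if (ep$stim$mode == "constant") {
        push(ep$duration, ep$gks, ep$plasticity, group_drive(ep$stim$drive))
      } else if (ep$stim$mode == "alternating") {
        st <- ep$stim
        left <- ep$duration
        k <- 1L
        while (left > 1e-9) {
          dr <- stats::setNames(c(st$drive_on[k], st$drive_suppress),
                                c(st$targets[k], st$targets[-k]))
          b <- min(st$bout_length[k], left)
          push(b, ep$gks, ep$plasticity, group_drive(dr))
          left <- left - b
          if (st$gap > 0 && left > 1e-9) {
            g <- min(st$gap, left)
            push(g, ep$gks, ep$plasticity, numeric(n))
            left <- left - g
          }
          k <- if (k == 1L) 2L else 1L
        }
      } else stop("unknown stimulation mode: ", ep$stim$mode)
    }
    ep_log <- rbind(ep_log, data.frame(label = ep$label, start = t0, end = t,
                                       gks = ep$gks,
                                       plasticity = ep$plasticity))
  }
  list(seg_end = seg_end, seg_gks = seg_gks, seg_plastic = seg_pl,
       seg_drive = if (length(drives)) do.call(cbind, drives)
                   else matrix(0, n, 0),
       epochs = ep_log, total = t)
}

#' Run a network simulation under a state schedule
#'
#' Integrates the full network (RK4, fixed step) across the schedule's
#' epochs: `gKs` of every neuron follows the epoch, STDP runs only in
#' epochs with plasticity on, and the Bernoulli noise process is active
#' throughout.  Deterministic given (network, schedule, seed).  Initial
#' voltages are drawn uniformly from \[-70, -55\] mV with gating at steady
#' state, which avoids artificial network-wide synchrony at t = 0.
#'
#' @param network an `engram_network` from the builders.
#' @param schedule list of [epoch()] objects.
#' @param seed RNG seed for initial conditions and the noise process.
#' @param dt integration step, ms.
#' @param syn a [synapse_params()].
#' @param stdp an [stdp_params()].
#' @param noise_p per-neuron, per-ms noise pulse probability.
#' @param noise_amp,noise_dur noise pulse amplitude (uA/cm2) and width (ms).
#' @param record record voltage traces for these neuron ids (or `NULL`).
#' @param record_stride steps between recorded samples.
#' @return An `engram_sim` object: `raster` (neuron_id, group, time_ms,
#'   epoch), `epochs` log, `weights` (edge-by-snapshot matrix, one column
#'   per epoch boundary including t = 0), `snap_times`, the `network`,
#'   `seed` and `dt`.
#' @export
run_network <- function(network, schedule, seed = 1, dt = 0.05,
                        syn = synapse_params(), stdp = stdp_params(),
                        noise_p = 0.002, noise_amp = 80, noise_dur = 1,
                        record = NULL, record_stride = 20L) {
  stopifnot(inherits(network, "engram_network"), length(schedule) >= 1)
  cs <- .compile_schedule(network, schedule)
  neurons <- network$neurons
  edges <- network$edges
  n <- nrow(neurons)

  post_exc <- neurons$role[edges$post] == "E"
  is_exc <- edges$type == "E"
  amp_fast <- ifelse(is_exc,
                     edges$M * ifelse(post_exc, syn$R_E_exc, syn$R_E_inh),
                     edges$M * ifelse(post_exc, syn$R_fI_exc, syn$R_fI_inh))
  amp_slow <- ifelse(is_exc, 0,
                     edges$M * ifelse(post_exc, syn$R_sI_exc, syn$R_sI_inh))

  set.seed(seed)
  v0 <- runif(n, -70, -55)
  ss <- gating_steady_states(v0)

  snap_times <- c(0, cs$epochs$end)
  cell <- neuron_params()  # shared biophysics; gKs comes from the schedule
  if (cs$total <= 0) {
    empty <- data.frame(neuron_id = integer(0), group = character(0),
                        time_ms = numeric(0), epoch = character(0))
    w0 <- matrix(edges$w0, ncol = length(snap_times),
                 nrow = nrow(edges))
    return(structure(list(raster = empty, epochs = cs$epochs, weights = w0,
                          snap_times = snap_times, network = network,
                          seed = seed, dt = dt),
                     class = "engram_sim"))
  }

  res <- .sim_network(
    v0 = v0, h0 = ss$h_inf, n0 = ss$n_inf, z0 = ss$z_inf,
    idrive = neurons$idrive,
    cell = cell[c("C", "gNa", "gKdr", "gL", "VNa", "VK", "VL",
                  "tau_z", "v_thresh")],
    e_pre = as.integer(edges$pre - 1L), e_post = as.integer(edges$post - 1L),
    e_amp_fast = amp_fast, e_amp_slow = amp_slow,
    e_exc = as.integer(is_exc), e_w = edges$w0, e_px = edges$px,
    seg_end = cs$seg_end, seg_gks = cs$seg_gks,
    seg_plastic = cs$seg_plastic, seg_drive = cs$seg_drive,
    stdp = stdp[c("a_plus", "a_minus", "tau_plus", "tau_minus", "wmax")],
    syn = syn[c("tau_f", "tau_s", "erev_e", "erev_i")],
    noise_p = noise_p, noise_amp = noise_amp, noise_dur = noise_dur,
    dt = dt, snap_times = snap_times,
    record_idx = if (is.null(record)) integer(0) else as.integer(record - 1L),
    record_stride = if (is.null(record)) 0L else as.integer(record_stride))

  id <- res$spike_id + 1L
  ep_idx <- findInterval(res$spike_t, cs$epochs$start,
                         rightmost.closed = FALSE)
  raster <- data.frame(neuron_id = id, group = neurons$group[id],
                       time_ms = res$spike_t,
                       epoch = cs$epochs$label[pmax(ep_idx, 1L)])
  weights <- do.call(cbind, res$snapshots)
  out <- structure(list(raster = raster, epochs = cs$epochs,
                        weights = weights, snap_times = snap_times,
                        network = network, seed = seed, dt = dt,
                        final_weights = res$w_final),
                   class = "engram_sim")
  if (!is.null(record)) {
    out$v_trace <- res$v_trace
    out$v_trace_t <- res$v_trace_t
    out$v_trace_ids <- record
  }
  out
}

#' @export
print.engram_sim <- function(x, ...) {
  cat("engram simulation: ", nrow(x$epochs), " epochs, ",
      max(x$epochs$end), " ms, ", nrow(x$raster), " spikes\n", sep = "")
  invisible(x)
}

#' Mean firing rates by group
#'
#' @param sim an `engram_sim`.
#' @param epoch_label restrict to one epoch label (or `NULL` for all).
#' @param per_neuron if `TRUE`, return one row per neuron instead of group
#'   means (silent neurons included at 0 Hz).
#' @return Data frame with columns `group`, `rate_hz` (and `neuron_id` if
#'   per-neuron).
#' @export
firing_rates <- function(sim, epoch_label = NULL, per_neuron = FALSE) {
  ep <- sim$epochs
  r <- sim$raster
  if (!is.null(epoch_label)) {
    ep <- ep[ep$label %in% epoch_label, , drop = FALSE]
    if (nrow(ep) == 0) stop("unknown epoch label")
    r <- r[r$epoch %in% epoch_label, , drop = FALSE]
  }
  dur <- sum(ep$end - ep$start)
  counts <- tabulate(r$neuron_id, nbins = nrow(sim$network$neurons))
  per <- data.frame(neuron_id = sim$network$neurons$id,
                    group = sim$network$neurons$group,
                    rate_hz = counts / dur * 1000)
  if (per_neuron) return(per)
  agg <- stats::aggregate(rate_hz ~ group, per, mean)
  agg[order(agg$group), , drop = FALSE]
}

#' Run the two-memory consolidation experiment
#'
#' Builds a two-memory network, runs the sleep/test schedule, and computes
#' the recruitment read-outs at every test phase: SF-group firing rates
#' under activation of each backbone, activation and segregation indices,
#' mean backbone-to-SF weights, and the functional-connectivity overlap of
#' the blue/green SF subnetwork between the two backbone activations.
#'
#' @param seed master seed; wiring, initial conditions and noise derive
#'   from it deterministically.
#' @param order `"forward"` (`ACh_minus` then `ACh_plus` per cycle — the
#'   stereotypic NREM-before-REM architecture) or `"reversed"`.
#' @param n_cycles number of sleep cycles.
#' @param tests `"states"` (test after every sleep state) or `"cycles"`
#'   (test after every full cycle).
#' @param dur_minus,dur_plus,test_duration epoch durations, ms.
#' @param bout_length,gap,drive_suppress alternating-reactivation
#'   parameters (see [stim_alternating()]).
#' @param drive_minus,drive_plus reactivation drive to the active backbone
#'   during the `ACh_minus` / `ACh_plus` states, uA/cm2.  The low-ACh
#'   default sits just below the Type 2 rheobase so the backbone fires in
#'   synchronized bursts; the high-ACh default is stronger, giving
#'   sustained backbone firing against the elevated inhibition.
#' @param test_gks,test_drive test-epoch conductance and backbone drive.
#' @param bias,suppress_drive,scale network construction parameters (see
#'   [build_two_memory()]).
#' @param violet_drive optional override of the violet quartile's `Idrive`.
#' @param fc_threshold significance threshold on |z| for overlap.
#' @param fc_null,fc_jitter_sd null model for the test-epoch
#'   functional-connectivity matrices (see [fc_matrix()]); the surrogate
#'   null is the default because test epochs carry a network-wide rhythm
#'   that the analytic null would count as locking.
#' @param dt,noise_p integration step and noise probability.
#' @return List of class `two_memory_experiment` with elements `rates`
#'   (phase x backbone x SF-group firing rates), `summary` (activation,
#'   segregation, overlap per phase), `weight_means` (mean EB1/EB2 input
#'   weight per SF group per phase), `fc` (z-matrices per phase and
#'   backbone), `sim`, and `phases`.
#' @export
run_two_memory_experiment <- function(seed = 1, order = c("forward", "reversed"),
                                      n_cycles = 1,
                                      tests = c("states", "cycles"),
                                      dur_minus = 30000, dur_plus = 30000,
                                      test_duration = 3000,
                                      bout_length = 200, gap = 0,
                                      drive_minus = 1, drive_plus = 3,
                                      drive_suppress = -6,
                                      test_gks = 0.1, test_drive = 2,
                                      bias = 1.2, suppress_drive = -6,
                                      scale = 1, violet_drive = NULL,
                                      fc_threshold = 2,
                                      fc_null = "jitter", fc_jitter_sd = 20,
                                      dt = 0.05, noise_p = 0.002) {
  order <- match.arg(order)
  tests <- match.arg(tests)
  net <- build_two_memory(seed = seed, scale = scale, bias = bias,
                          suppress_drive = suppress_drive)
  if (!is.null(violet_drive))
    net$neurons$idrive[net$neurons$group == "SF_violet"] <- violet_drive
  sched <- make_sleep_schedule(
    n_cycles = n_cycles, dur_minus = dur_minus, dur_plus = dur_plus,
    reversed = (order == "reversed"), tests = tests,
    test_duration = test_duration, test_gks = test_gks,
    test_drive = test_drive,
    stim_minus = stim_alternating(c("EB1", "EB2"),
                                  bout_length = bout_length, gap = gap,
                                  drive_on = drive_minus,
                                  drive_suppress = drive_suppress),
    stim_plus = stim_alternating(c("EB1", "EB2"),
                                 bout_length = bout_length, gap = gap,
                                 drive_on = drive_plus,
                                 drive_suppress = drive_suppress))
  sim <- run_network(net, sched, seed = seed + 1L, dt = dt,
                     noise_p = noise_p)
  analyze_two_memory(sim, fc_threshold = fc_threshold, fc_null = fc_null,
                     fc_jitter_sd = fc_jitter_sd)
}

#' Analyze a two-memory simulation's test epochs
#'
#' Computes the per-phase read-outs from an `engram_sim` whose schedule
#' contains `test_EB1_*` / `test_EB2_*` epoch pairs (as produced by
#' [make_sleep_schedule()]).
#'
#' @param sim an `engram_sim` of a two-memory network.
#' @param fc_threshold significance threshold on |z| for the overlap.
#' @param fc_null,fc_jitter_sd null model for the functional-connectivity
#'   matrices (see [fc_matrix()]).
#' @return See [run_two_memory_experiment()].
#' @export
analyze_two_memory <- function(sim, fc_threshold = 2, fc_null = "jitter",
                               fc_jitter_sd = 20) {
  ep <- sim$epochs
  neurons <- sim$network$neurons
  sf_groups <- c("SF_blue", "SF_green", "SF_pink", "SF_violet")
  tl <- ep$label[grepl("^test_", ep$label)]
  phase_of <- sub("^test_EB[12]_", "", tl)
  phases <- unique(phase_of)

  rates <- do.call(rbind, lapply(phases, function(ph) {
    do.call(rbind, lapply(c("EB1", "EB2"), function(eb) {
      lab <- paste0("test_", eb, "_", ph)
      fr <- firing_rates(sim, epoch_label = lab, per_neuron = TRUE)
      fr <- fr[fr$group %in% sf_groups, , drop = FALSE]
      agg <- stats::aggregate(rate_hz ~ group, fr, mean)
      data.frame(phase = ph, eb = eb, agg)
    }))
  }))

  g_rate <- function(ph, eb, grp) {
    v <- rates$rate_hz[rates$phase == ph & rates$eb == eb &
                         rates$group %in% grp]
    mean(v)
  }
  bg <- c("SF_blue", "SF_green")
  quiet <- c("SF_pink", "SF_violet")

  fc <- list()
  summary <- do.call(rbind, lapply(phases, function(ph) {
    a <- mean(c(activation(g_rate(ph, "EB1", bg), g_rate(ph, "EB1", quiet)),
                activation(g_rate(ph, "EB2", bg), g_rate(ph, "EB2", quiet))))
    s <- mean(c(segregation(g_rate(ph, "EB1", "SF_blue"),
                            g_rate(ph, "EB2", "SF_blue")),
                segregation(g_rate(ph, "EB1", "SF_green"),
                            g_rate(ph, "EB2", "SF_green"))))
    sub <- neurons$id[neurons$group %in% bg]
    z1 <- fc_matrix(sim$raster, neurons = sub,
                    window = .epoch_window(ep, paste0("test_EB1_", ph)),
                    null = fc_null, jitter_sd = fc_jitter_sd)
    z2 <- fc_matrix(sim$raster, neurons = sub,
                    window = .epoch_window(ep, paste0("test_EB2_", ph)),
                    null = fc_null, jitter_sd = fc_jitter_sd)
    fc[[ph]] <<- list(EB1 = z1, EB2 = z2)
    ov <- fc_overlap(z1, z2, threshold = fc_threshold)
    data.frame(phase = ph, activation = a, segregation = s,
               overlap = ov, overlap_cos = attr(ov, "cosine"))
  }))
  rownames(summary) <- NULL

  # mean backbone-to-quartile weights at the snapshot opening each phase's
  # first test epoch (weights are frozen across the test pair)
  first_test <- vapply(phases, function(ph)
    which(ep$label == paste0("test_EB1_", ph))[1], integer(1))
  snap_col <- vapply(ep$start[first_test], function(s)
    which(abs(sim$snap_times - s) < 1e-6)[1], integer(1))
  e <- sim$network$edges
  gpre <- neurons$group[e$pre]; gpost <- neurons$group[e$post]
  weight_means <- do.call(rbind, lapply(seq_along(phases), function(k) {
    w <- sim$weights[, snap_col[k]]
    do.call(rbind, lapply(sf_groups, function(grp) {
      data.frame(phase = phases[k], group = grp,
                 w_eb1 = mean(w[gpre == "EB1" & gpost == grp]),
                 w_eb2 = mean(w[gpre == "EB2" & gpost == grp]))
    }))
  }))
  structure(list(rates = rates, summary = summary,
                 weight_means = weight_means, fc = fc, phases = phases,
                 sim = sim),
            class = "two_memory_experiment")
}

.epoch_window <- function(epochs, label) {
  row <- epochs[epochs$label == label, , drop = FALSE]
  if (nrow(row) != 1) stop("epoch label not found: ", label)
  c(row$start, row$end)
}

#' Parameter sweep over repeated two-memory experiments
#'
#' Runs the full two-memory consolidation experiment at each value of one
#' named parameter of [run_two_memory_experiment()], over several seeds
#' (offset deterministically from `seed`), and tabulates the final-phase
#' activation and segregation.
#'
#' @param param parameter name (e.g. `"gap"`, `"bout_length"`,
#'   `"violet_drive"`).
#' @param values values to scan.
#' @param n_seeds repeats per value.
#' @param seed base seed.
#' @param ... fixed arguments forwarded to [run_two_memory_experiment()].
#' @return Data frame with columns `value`, `metric`, `mean`, `sem`.
#' @export
sweep_two_memory <- function(param, values, n_seeds = 4, seed = 1, ...) {
  fixed <- list(...)
  if (!param %in% names(formals(run_two_memory_experiment)))
    stop("unknown parameter: ", param, "; valid parameters are: ",
         paste(setdiff(names(formals(run_two_memory_experiment)), "seed"),
               collapse = ", "))
  rows <- list()
  for (v in values) {
    finals <- vapply(seq_len(n_seeds), function(k) {
      args <- c(list(seed = seed + 1000L * k), fixed)
      args[[param]] <- v
      res <- do.call(run_two_memory_experiment, args)
      last <- res$summary[nrow(res$summary), ]
      c(activation = last$activation, segregation = last$segregation)
    }, numeric(2))
    for (m in rownames(finals)) {
      x <- finals[m, ]
      rows[[length(rows) + 1]] <-
        data.frame(value = v, metric = m, mean = mean(x),
                   sem = stats::sd(x) / sqrt(length(x)))
    }
  }
  do.call(rbind, rows)
}
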