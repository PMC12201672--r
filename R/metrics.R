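# Spike-train statistics: AMD functional connectivity with an analytic
# uniform-placement null, engram activation/segregation indices, overlap
# of significant-connectivity patterns, weight-change vectors, delta-z
# histograms, population spectra, and the paired NREM/REM bout comparison.

.check_train <- function(s, name, min_n = 1) {
  if (!is.numeric(s) || length(s) < min_n)
    stop("spike train ", name, " needs at least ", min_n, " spikes")
  if (is.unsorted(s)) stop("spike train ", name, " must be sorted")
  invisible(s)
}

#' Average minimal distance between two spike trains
#'
#' Mean, over the spikes of `s_i`, of the absolute temporal distance to the
#' nearest spike of `s_j` in either direction.  Spikes of `s_i` lying
#' before the first or after the last spike of `s_j` use the single
#' available neighbour.  Zero if and only if every spike of `s_i` coincides
#' with a spike of `s_j`.
#'
#' @param s_i spike times whose distances are measured, ms (sorted).
#' @param s_j reference spike train, ms (sorted, at least 2 spikes).
#' @return AMD in ms.
#' @export
amd <- function(s_i, s_j) {
  .check_train(s_i, "s_i", 1)
  .check_train(s_j, "s_j", 2)
  idx <- findInterval(s_i, s_j)
  nj <- length(s_j)
  left <- ifelse(idx >= 1, s_i - s_j[pmax(idx, 1)], Inf)
  right <- ifelse(idx < nj, s_j[pmin(idx + 1, nj)] - s_i, Inf)
  mean(pmin(left, right))
}

#' Analytic null moments of the nearest-spike distance
#'
#' For a point placed uniformly at random within the span of a reference
#' spike train, the distance to the nearest spike has mean
#' `mu1 = sum(L^2) / (4 T)` and second moment `mu2 = sum(L^3) / (12 T)`,
#' where `L` runs over the inter-spike intervals and `T = sum(L)` is the
#' train's span.  These are exact: a point falling in an interval of
#' length L is uniform there, and its nearest-spike distance is the
#' distance to the closer endpoint.
#'
#' @param s_ref reference spike train, ms (sorted, at least 2 spikes).
#' @return Named vector `mu` (ms) and `sigma` (ms).
#' @export
amd_null_moments <- function(s_ref) {
  .check_train(s_ref, "s_ref", 2)
  L <- diff(s_ref)
  T <- sum(L)
  if (T <= 0) stop("degenerate reference train (zero span)")
  mu1 <- sum(L^2) / (4 * T)
  mu2 <- sum(L^3) / (12 * T)
  var <- mu2 - mu1^2
  if (var < 0) {
    if (var < -1e-9 * mu2) stop("negative null variance: numerical error")
    var <- 0
  }
  c(mu = mu1, sigma = sqrt(var))
}

#' AMD functional-connectivity z-score
#'
#' Standardizes the AMD of `s_i` against `s_j` by the analytic null of
#' uniformly placed points on the reference train `s_j`:
#' `z = sqrt(N_i) * (mu - AMD) / sigma`, where (`mu`, `sigma`) are the
#' single-point null moments of [amd_null_moments()] and `N_i` the number
#' of spikes in `s_i` — the AMD is a mean of `N_i` distances, so its null
#' SD is `sigma / sqrt(N_i)`.  Without this scaling the positive z range
#' is bounded by `mu/sigma <= sqrt(3)` and no degree of coincidence could
#' reach a two-SD significance threshold.  The sign convention makes
#' tighter-than-chance temporal locking positive; `literal_sign = TRUE`
#' flips it to the raw-distance orientation (large AMD positive).
#'
#' @inheritParams amd
#' @param literal_sign use the raw-distance sign convention.
#' @return z-score (dimensionless).
#' @export
fc_zscore <- function(s_i, s_j, literal_sign = FALSE) {
  mom <- amd_null_moments(s_j)
  if (mom["sigma"] <= 0) return(NA_real_)
  # the null describes points inside the reference train's span; spikes
  # outside it would bias the statistic through the one-neighbour rule
  s_i <- s_i[s_i >= s_j[1] & s_i <= s_j[length(s_j)]]
  if (length(s_i) == 0) return(NA_real_)
  a <- amd(s_i, s_j)
  z <- sqrt(length(s_i)) * (mom[["mu"]] - a) / mom[["sigma"]]
  if (literal_sign) -z else z
}

#' Pairwise functional-connectivity matrix
#'
#' z-scores for all ordered neuron pairs of a raster within a time window.
#' Entry `[i, j]` measures the spikes of neuron `i` against the reference
#' train of neuron `j`.  Pairs whose trains fail the preconditions (fewer
#' than `min_spikes` spikes in the window, or a degenerate null) are `NA`,
#' not zero; the diagonal is `NA`.
#'
#' @param raster data frame with columns `neuron_id`, `time_ms` (a `group`
#'   column is carried along if present).
#' @param neurons neuron ids to include (default: all in the raster).
#' @param window `c(start, end)` in ms (default: full raster range).
#' @param min_spikes minimum spikes per train within the window.
#' @param literal_sign see [fc_zscore()].
#' @param null `"analytic"` standardizes against the closed-form
#'   uniform-placement null of the reference train; `"jitter"` against a
#'   surrogate ensemble in which the reference train's spikes are
#'   Gaussian-jittered, which absorbs slow common rate modulation (e.g. a
#'   network-wide rhythm) into the null so that only locking finer than
#'   `jitter_sd` is significant.
#' @param jitter_sd surrogate jitter SD, ms.
#' @param n_surrogates surrogate ensemble size.
#' @return Square matrix of class `fc_matrix` with neuron ids as dimnames
#'   and the window as an attribute.
#' @export
fc_matrix <- function(raster, neurons = NULL, window = NULL,
                      min_spikes = 2, literal_sign = FALSE,
                      null = c("analytic", "jitter"), jitter_sd = 20,
                      n_surrogates = 30) {
  stopifnot(all(c("neuron_id", "time_ms") %in% names(raster)))
  null <- match.arg(null)
  if (is.null(neurons)) neurons <- sort(unique(raster$neuron_id))
  if (is.null(window)) window <- range(raster$time_ms)
  r <- raster[raster$time_ms >= window[1] & raster$time_ms <= window[2] &
                raster$neuron_id %in% neurons, , drop = FALSE]
  trains <- split(r$time_ms, factor(r$neuron_id, levels = neurons))
  z <- .fc_zmat(unname(trains), as.integer(min_spikes), literal_sign,
                null == "jitter", jitter_sd, as.integer(n_surrogates))
  dimnames(z) <- list(neurons, neurons)
  structure(z, window = window, null = null,
            class = c("fc_matrix", "matrix", "array"))
}

#' Overlap of two functional-connectivity patterns
#'
#' Zeroes every entry with `|z|` at or below the significance threshold
#' (and every `NA`), flattens the remaining entries and takes the dot
#' product.  The cosine-normalized value (dot product divided by the
#' product of the masked matrices' norms) is attached as attribute
#' `"cosine"`.  Disjoint significance masks give 0; identical matrices
#' give the squared norm of their significant entries.
#'
#' @param fc_a,fc_b matrices from [fc_matrix()] over the same neuron set
#'   and ordering.
#' @param threshold significance threshold on `|z|`.
#' @return Overlap (dimensionless, signed) with attribute `cosine`.
#' @export
fc_overlap <- function(fc_a, fc_b, threshold = 2) {
  if (!identical(dim(fc_a), dim(fc_b)) ||
      !identical(dimnames(fc_a), dimnames(fc_b)))
    stop("functional-connectivity matrices are not aligned")
  mask <- function(z) {
    z[is.na(z) | abs(z) <= threshold] <- 0
    z
  }
  a <- mask(unclass(fc_a)); b <- mask(unclass(fc_b))
  raw <- sum(a * b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  cosv <- if (na > 0 && nb > 0) raw / (na * nb) else 0
  structure(raw, cosine = cosv)
}

#' Engram activation index
#'
#' Normalized contrast of a recruited group's firing rate against the
#' background rate: `(f_act - f_bg) / (f_act + f_bg)`, in \[-1, 1\].  One
#' means the background is silent while the group fires; zero means no
#' activation above background.
#'
#' @param f_act mean rate of the activated (recruitable) group, Hz.
#' @param f_bg mean rate of the non-participating background groups, Hz.
#' @return Activation index.
#' @export
activation <- function(f_act, f_bg) {
  stopifnot(f_act >= 0, f_bg >= 0)
  if (f_act + f_bg == 0) stop("activation undefined: both rates are zero")
  (f_act - f_bg) / (f_act + f_bg)
}

#' Engram segregation index
#'
#' Normalized rate difference `|f1 - f2| / (f1 + f2)`, in \[0, 1\].  A value
#' near one indicates almost complete silence of a group under one
#' backbone's activation while it is active under the other's.  For the
#' two-memory experiment it is computed separately for each recruited SF
#' group across the two backbone tests and then averaged.
#'
#' @param f1,f2 mean firing rates of the group under the two conditions, Hz.
#' @return Segregation index.
#' @export
segregation <- function(f1, f2) {
  stopifnot(f1 >= 0, f2 >= 0)
  if (f1 + f2 == 0) stop("segregation undefined: both rates are zero")
  abs(f1 - f2) / (f1 + f2)
}

#' Mean synaptic-strength change vectors per SF group
#'
#' For each SF group, the mean weight of its inputs from each backbone
#' before and after an interval, and the change — the vector
#' representation of engram recruitment (tail at the before-means, head at
#' the after-means).
#'
#' @param network the `engram_network` the weights belong to.
#' @param w_before,w_after edge-weight vectors aligned with
#'   `network$edges` (e.g. columns of an `engram_sim`'s `weights`).
#' @param groups SF group labels to report.
#' @param sources backbone group labels.
#' @return Data frame with one row per (group, source): columns `group`,
#'   `source`, `w_before`, `w_after`, `dw`.
#' @export
weight_vectors <- function(network, w_before, w_after,
                           groups = c("SF_blue", "SF_green", "SF_pink",
                                      "SF_violet"),
                           sources = c("EB1", "EB2")) {
  e <- network$edges
  stopifnot(length(w_before) == nrow(e), length(w_after) == nrow(e))
  g <- network$neurons$group
  out <- list()
  for (grp in groups) {
    if (!any(g == grp)) stop("group absent from network: ", grp)
    for (src in sources) {
      sel <- g[e$pre] == src & g[e$post] == grp
      out[[length(out) + 1]] <- data.frame(
        group = grp, source = src,
        w_before = mean(w_before[sel]), w_after = mean(w_after[sel]),
        dw = mean(w_after[sel]) - mean(w_before[sel]))
    }
  }
  do.call(rbind, out)
}

#' Pairwise functional-connectivity changes
#'
#' Per-pair `z_after - z_before` between two aligned
#' functional-connectivity matrices.  Pairs missing (`NA`) in either matrix
#' are excluded and counted; pairs non-significant (`|z|` at or below
#' `threshold`) in both matrices are excluded from the headline
#' distribution unless `keep_nonsignificant = TRUE`.
#'
#' @param fc_before,fc_after matrices from [fc_matrix()], same neurons.
#' @param threshold significance threshold on `|z|`.
#' @param keep_nonsignificant keep pairs non-significant in both states.
#' @return List with `dz` (numeric vector), `n_missing`,
#'   `n_nonsignificant` (excluded counts).
#' @export
dz_distribution <- function(fc_before, fc_after, threshold = 2,
                            keep_nonsignificant = FALSE) {
  if (!identical(dim(fc_before), dim(fc_after)) ||
      !identical(dimnames(fc_before), dimnames(fc_after)))
    stop("functional-connectivity matrices are not aligned")
  a <- unclass(fc_before); b <- unclass(fc_after)
  off <- row(a) != col(a)
  ok <- off & !is.na(a) & !is.na(b)
  n_missing <- sum(off & (is.na(a) | is.na(b)))
  sig <- abs(a) > threshold | abs(b) > threshold
  keep <- if (keep_nonsignificant) ok else (ok & sig)
  list(dz = (b - a)[keep],
       n_missing = n_missing,
       n_nonsignificant = sum(ok & !sig))
}

#' Population power spectrum of a spike raster
#'
#' Bins the population spike count (1 ms bins by default), subtracts the
#' mean, and averages modified periodograms over Hann-tapered segments
#' (2 s long, 50% overlap) — a Welch estimate.  Useful for detecting the
#' network oscillations that emerge in the high-ACh state.
#'
#' @param raster data frame with `neuron_id`, `time_ms`.
#' @param window `c(start, end)` ms; default full range.
#' @param groups restrict to these groups (needs a `group` column).
#' @param bin bin width, ms.
#' @param seg_len Welch segment length, ms.
#' @return Data frame with columns `freq_hz`, `power` (arbitrary units).
#' @export
spike_spectrum <- function(raster, window = NULL, groups = NULL, bin = 1,
                           seg_len = 2000) {
  stopifnot(all(c("neuron_id", "time_ms") %in% names(raster)))
  if (!is.null(groups)) {
    stopifnot("group" %in% names(raster))
    raster <- raster[raster$group %in% groups, , drop = FALSE]
  }
  if (is.null(window)) window <- range(raster$time_ms)
  if (diff(window) < 2000) stop("window must span at least 2 s")
  t <- raster$time_ms
  t <- t[t >= window[1] & t < window[2]]
  edges <- seq(window[1], window[2], by = bin)
  counts <- tabulate(findInterval(t, edges), nbins = length(edges) - 1)
  x <- counts - mean(counts)
  nseg <- floor(seg_len / bin)
  hop <- floor(nseg / 2)
  if (length(x) < nseg) stop("window shorter than one Welch segment")
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  starts <- seq(1, length(x) - nseg + 1, by = hop)
  acc <- 0
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)] * taper
    acc <- acc + Mod(fft(seg))^2
  }
  p <- acc / length(starts)
  fs <- 1000 / bin
  k <- seq_len(floor(nseg / 2))
  data.frame(freq_hz = k * fs / nseg, power = p[k + 1])
}

#' Validate a sleep-bout annotation table
#'
#' @param bouts data frame with columns `state` (NREM/REM/WAKE), `start`,
#'   `end` in ms.
#' @return The table, invisibly, or an error naming offending rows.
#' @export
validate_bouts <- function(bouts) {
  stopifnot(all(c("state", "start", "end") %in% names(bouts)))
  bad <- which(bouts$end <= bouts$start)
  if (length(bad))
    stop("bout end <= start at row(s): ", paste(bad, collapse = ", "))
  if (nrow(bouts) > 1) {
    ov <- which(bouts$start[-1] < bouts$end[-nrow(bouts)])
    if (length(ov))
      stop("overlapping/unordered bouts at row(s): ",
           paste(ov + 1, collapse = ", "))
  }
  invisible(bouts)
}

#' Paired NREM-to-REM functional-connectivity change
#'
#' For every NREM bout whose immediately following bout is REM with onset
#' within `max_gap` of the NREM offset, compares pairwise functional
#' connectivity between the two bouts.  To offset duration differences,
#' only the final segment of the NREM bout matching the paired REM bout's
#' duration is analyzed.  Per qualifying pair of neurons, reports
#' `dz = z_REM - z_NREM`; pairs non-significant in both states are excluded
#' unless `keep_nonsignificant = TRUE`.
#'
#' @param raster spike table with `neuron_id`, `time_ms`.
#' @param bouts bout annotation table (see [validate_bouts()]).
#' @param max_gap maximum NREM-offset-to-REM-onset gap, ms.
#' @param threshold significance threshold on `|z|`.
#' @param keep_nonsignificant see [dz_distribution()].
#' @param min_spikes minimum spikes per train and bout.
#' @return List with `pairs` (data frame: bout_pair, i, j, z_nrem, z_rem,
#'   dz), `bout_pairs` (the qualifying bout windows), and exclusion
#'   counts.  Empty (with a warning) if no bout pair qualifies.
#' @export
paired_bout_fc_change <- function(raster, bouts, max_gap = 10000,
                                  threshold = 2,
                                  keep_nonsignificant = FALSE,
                                  min_spikes = 2) {
  validate_bouts(bouts)
  nb <- nrow(bouts)
  sel <- which(bouts$state[-nb] == "NREM" & bouts$state[-1] == "REM" &
                 (bouts$start[-1] - bouts$end[-nb]) < max_gap)
  if (length(sel) == 0) {
    warning("no qualifying NREM-REM bout pairs")
    return(list(pairs = data.frame(), bout_pairs = data.frame(),
                n_missing = 0L, n_nonsignificant = 0L))
  }
  neurons <- sort(unique(raster$neuron_id))
  all_pairs <- list(); bp <- list()
  n_missing <- 0L; n_nonsig <- 0L
  for (k in seq_along(sel)) {
    i_n <- sel[k]; i_r <- sel[k] + 1L
    rem_dur <- bouts$end[i_r] - bouts$start[i_r]
    nrem_win <- c(max(bouts$start[i_n], bouts$end[i_n] - rem_dur),
                  bouts$end[i_n])
    rem_win <- c(bouts$start[i_r], bouts$end[i_r])
    zn <- fc_matrix(raster, neurons = neurons, window = nrem_win,
                    min_spikes = min_spikes)
    zr <- fc_matrix(raster, neurons = neurons, window = rem_win,
                    min_spikes = min_spikes)
    d <- dz_distribution(zn, zr, threshold = threshold,
                         keep_nonsignificant = keep_nonsignificant)
    keepm <- !is.na(zn) & !is.na(zr) & row(zn) != col(zn)
    if (!keep_nonsignificant)
      keepm <- keepm & (abs(zn) > threshold | abs(zr) > threshold)
    idx <- which(keepm, arr.ind = TRUE)
    all_pairs[[k]] <- if (nrow(idx) == 0) NULL else data.frame(
      bout_pair = k,
      i = neurons[idx[, 1]], j = neurons[idx[, 2]],
      z_nrem = zn[keepm], z_rem = zr[keepm], dz = zr[keepm] - zn[keepm])
    bp[[k]] <- data.frame(bout_pair = k,
                          nrem_start = nrem_win[1], nrem_end = nrem_win[2],
                          rem_start = rem_win[1], rem_end = rem_win[2])
    n_missing <- n_missing + d$n_missing
    n_nonsig <- n_nonsig + d$n_nonsignificant
  }
  pairs <- do.call(rbind, all_pairs)
  if (is.null(pairs)) pairs <- data.frame()
  list(pairs = pairs, bout_pairs = do.call(rbind, bp),
       n_missing = n_missing, n_nonsignificant = n_nonsig)
}
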