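test_that("AMD matches definitional examples and the brute-force oracle", {
  expect_equal(amd(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(amd(5, c(0, 10)), 5)
  # boundary spikes use the single available neighbour
  expect_equal(amd(c(-3, 12), c(0, 10)), mean(c(3, 2)))
  set.seed(21)
  for (k in 1:100) {
    s_i <- sort(runif(sample(1:30, 1), 0, 1000))
    s_j <- sort(runif(sample(2:30, 1), 0, 1000))
    expect_equal(amd(s_i, s_j), amd_brute(s_i, s_j), tolerance = 1e-12)
  }
  expect_error(amd(numeric(0), c(1, 2)), "at least")
  expect_error(amd(1, 5), "at least")
})

test_that("analytic null moments: regular-train closed form and scaling", {
  # regular train, ISI = L: mu = L/4, sigma = L / (4 sqrt(3))
  L <- 8
  s <- seq(0, 800, by = L)
  m <- amd_null_moments(s)
  expect_equal(m[["mu"]], L / 4)
  expect_equal(m[["sigma"]], L / (4 * sqrt(3)))
  # doubling all intervals doubles both moments
  set.seed(3)
  s2 <- sort(runif(50, 0, 1000))
  m1 <- amd_null_moments(s2)
  m2 <- amd_null_moments(s2 * 2)
  expect_equal(m2[["mu"]], 2 * m1[["mu"]])
  expect_equal(m2[["sigma"]], 2 * m1[["sigma"]])
})

test_that("analytic null moments match the uniform-placement Monte Carlo oracle", {
  set.seed(17)
  for (k in 1:20) {
    s <- sort(runif(sample(10:80, 1), 0, 5000))
    m <- amd_null_moments(s)
    mc <- amd_null_mc(s)
    expect_equal(m[["mu"]], mc[["mu"]], tolerance = 0.01)
    expect_equal(m[["sigma"]], mc[["sigma"]], tolerance = 0.01)
  }
})

test_that("z-score sign convention: locking positive, identical trains maximal", {
  set.seed(4)
  s <- sort(runif(100, 0, 10000))
  m <- amd_null_moments(s)
  expect_equal(fc_zscore(s, s), 10 * m[["mu"]] / m[["sigma"]])
  expect_equal(fc_zscore(s, s, literal_sign = TRUE),
               -10 * m[["mu"]] / m[["sigma"]])
  # tightly jittered copies are strongly locked
  s2 <- sort(s + rnorm(100, 0, 1))
  expect_gt(fc_zscore(s2, s), 2)
})

test_that("z-score null is centred for independent Poisson pairs", {
  set.seed(42)
  z <- vapply(1:300, function(k) {
    fc_zscore(sort(runif(60, 0, 30000)), sort(runif(60, 0, 30000)))
  }, numeric(1))
  expect_lt(abs(mean(z)), 0.1)
})

test_that("z-score is invariant to common shifts and rescaling", {
  set.seed(9)
  a <- sort(runif(50, 0, 5000))
  b <- sort(runif(70, 0, 5000))
  z0 <- fc_zscore(a, b)
  expect_equal(fc_zscore(a + 137.5, b + 137.5), z0)
  expect_equal(fc_zscore(a * 3, b * 3), z0, tolerance = 1e-12)
})

test_that("fc_matrix flags underpopulated trains as missing, not zero", {
  r <- rbind(
    data.frame(neuron_id = 1, time_ms = sort(runif(40, 0, 1000))),
    data.frame(neuron_id = 2, time_ms = sort(runif(40, 0, 1000))),
    data.frame(neuron_id = 3, time_ms = 500))  # a single spike
  z <- fc_matrix(r)
  expect_true(all(is.na(diag(z))))
  expect_true(all(is.na(z[3, ])))
  expect_true(all(is.na(z[, 3])))
  expect_false(anyNA(z[1:2, 1:2][row(z[1:2, 1:2]) != col(z[1:2, 1:2])]))
})

test_that("independent population has a near-nominal significant-pair rate", {
  r <- fixture_poisson(40, rate = 4, duration = 30000, seed = 31)
  z <- fc_matrix(r)
  frac <- mean(abs(z) > 2, na.rm = TRUE)
  # |z| > 2 two-sided on a roughly standardized statistic: ~5% nominal
  expect_lt(frac, 0.10)
  expect_gt(frac, 0.005)
})

test_that("jitter-surrogate null absorbs common rate modulation but keeps
           fine locking", {
  # all neurons share a slow on/off firing envelope (200 ms on, 200 ms
  # off) with no spike-level coordination inside the on-windows: the
  # analytic uniform-placement null flags the co-modulation, while the
  # 20 ms jitter surrogate retains the envelope and treats it as chance
  set.seed(5)
  windows <- seq(0, 29800, by = 400)
  r <- do.call(rbind, lapply(1:12, function(id) {
    t <- rep(windows, each = 3) + runif(3 * length(windows), 0, 200)
    data.frame(neuron_id = id, time_ms = sort(t))
  }))
  za <- fc_matrix(r)
  set.seed(6)
  zj <- fc_matrix(r, null = "jitter", jitter_sd = 20)
  expect_gt(mean(abs(za) > 2, na.rm = TRUE), 0.5)
  expect_lt(mean(abs(zj) > 2, na.rm = TRUE), 0.15)
  # locking finer than the surrogate timescale (1 ms) survives it
  r2 <- fixture_periodic_burster(12, period = 125, duration = 30000,
                                 jitter_sd = 1, seed = 7)
  set.seed(8)
  zj2 <- fc_matrix(r2, null = "jitter", jitter_sd = 20)
  expect_gt(mean(abs(zj2) > 2, na.rm = TRUE), 0.5)
})

test_that("overlap obeys its algebraic identities", {
  m <- matrix(c(NA, 3, -4, 1,
                2.5, NA, 0.5, -3,
                0, 1, NA, 5,
                -1, 6, 2, NA), 4, 4, byrow = TRUE,
              dimnames = list(1:4, 1:4))
  class(m) <- c("fc_matrix", "matrix", "array")
  self <- fc_overlap(m, m)
  sig <- m[!is.na(m) & abs(m) > 2]
  expect_equal(as.numeric(self), sum(sig^2))
  expect_gte(as.numeric(self), 0)
  expect_equal(attr(self, "cosine"), 1)
  # symmetry
  m2 <- m[4:1, 4:1]
  dimnames(m2) <- dimnames(m)
  class(m2) <- class(m)
  expect_equal(as.numeric(fc_overlap(m, m2)),
               as.numeric(fc_overlap(m2, m)))
  # disjoint significance masks
  a <- m; a[abs(a) > 2 | is.na(a)] <- 0; a[1, 2] <- 3
  b <- m; b[] <- 0; b[2, 1] <- 4
  class(a) <- class(b) <- class(m)
  expect_equal(as.numeric(fc_overlap(a, b)), 0)
  expect_error(fc_overlap(m, m[1:3, 1:3]), "aligned")
})

test_that("activation and segregation indices are correct and bounded", {
  expect_equal(activation(3, 1), 0.5)
  expect_equal(activation(1, 1), 0)
  expect_equal(activation(1, 0), 1)
  expect_equal(segregation(3, 1), 0.5)
  expect_equal(segregation(1, 1), 0)
  expect_equal(segregation(1, 0), 1)
  expect_error(activation(0, 0), "undefined")
  expect_error(segregation(0, 0), "undefined")
  set.seed(2)
  f <- matrix(rexp(400), ncol = 2)
  a <- apply(f, 1, function(x) activation(x[1], x[2]))
  s <- apply(f, 1, function(x) segregation(x[1], x[2]))
  expect_true(all(a >= -1 & a <= 1))
  expect_true(all(s >= 0 & s <= 1))
})

test_that("weight vectors report per-group mean changes", {
  net <- build_two_memory(seed = 1)
  w0 <- net$edges$w0
  w1 <- w0
  g <- net$neurons$group
  sel <- g[net$edges$pre] == "EB1" & g[net$edges$post] == "SF_blue"
  w1[sel] <- w1[sel] + 0.5
  wv <- weight_vectors(net, w0, w1)
  expect_equal(wv$dw[wv$group == "SF_blue" & wv$source == "EB1"], 0.5)
  expect_true(all(wv$dw[!(wv$group == "SF_blue" & wv$source == "EB1")] == 0))
  expect_error(weight_vectors(net, w0, w1, groups = "SF_orange"), "absent")
})

test_that("delta-z distribution handles point masses and exclusions", {
  z <- matrix(rnorm(25, sd = 3), 5, 5, dimnames = list(1:5, 1:5))
  diag(z) <- NA
  class(z) <- c("fc_matrix", "matrix", "array")
  d0 <- dz_distribution(z, z, keep_nonsignificant = TRUE)
  expect_true(all(d0$dz == 0))
  zp <- z + 1
  class(zp) <- class(z)
  d1 <- dz_distribution(z, zp, keep_nonsignificant = TRUE)
  expect_true(all(abs(d1$dz - 1) < 1e-12))
  # pairs non-significant in both states are excluded by default
  za <- z; za[] <- 0.5; diag(za) <- NA; za[1, 2] <- 4
  zb <- za; zb[1, 2] <- 1
  class(za) <- class(zb) <- class(z)
  d2 <- dz_distribution(za, zb)
  expect_equal(d2$dz, -3)
  expect_equal(d2$n_nonsignificant, 19)
})

test_that("spectrum finds a constructed peak and no spurious ones", {
  r <- fixture_periodic_burster(30, period = 125, duration = 20000,
                                jitter_sd = 3, seed = 12)
  sp <- spike_spectrum(r)
  peak <- sp$freq_hz[which.max(sp$power)]
  expect_equal(peak, 8, tolerance = 0.5)
  rp <- fixture_poisson(30, rate = 8, duration = 20000, seed = 13)
  spp <- spike_spectrum(rp)
  expect_lt(max(spp$power), 5 * stats::median(spp$power))
  expect_error(spike_spectrum(rp, window = c(0, 1500)), "at least 2 s")
})

test_that("bout validation reports offending rows", {
  good <- data.frame(state = c("NREM", "REM"), start = c(0, 70),
                     end = c(60, 100))
  expect_silent(validate_bouts(good))
  bad <- data.frame(state = c("NREM", "REM"), start = c(0, 50),
                    end = c(60, 100))
  expect_error(validate_bouts(bad), "row\\(s\\): 2")
  rev_bad <- data.frame(state = "NREM", start = 10, end = 5)
  expect_error(validate_bouts(rev_bad), "row\\(s\\): 1")
})

test_that("paired bout analysis pairs, truncates and excludes correctly", {
  fx <- fixture_rate_switching_bouts(n_neurons = 12, n_pairs = 2, seed = 2,
                                     rem_sync = TRUE)
  res <- paired_bout_fc_change(fx$raster, fx$bouts)
  expect_equal(nrow(res$bout_pairs), 2)
  # NREM analysis window is its final segment matching the REM duration
  expect_equal(res$bout_pairs$nrem_end - res$bout_pairs$nrem_start,
               res$bout_pairs$rem_end - res$bout_pairs$rem_start)
  # a 15 s gap excludes the pair
  b <- data.frame(state = c("NREM", "REM"), start = c(0, 75000),
                  end = c(60000, 95000))
  expect_warning(out <- paired_bout_fc_change(fx$raster, b),
                 "no qualifying")
  expect_equal(nrow(out$pairs), 0)
})

test_that("paired bout delta-z is centred when both states share statistics", {
  fx <- fixture_rate_switching_bouts(n_neurons = 15, n_pairs = 3, seed = 4,
                                     rem_sync = TRUE)
  res <- paired_bout_fc_change(fx$raster, fx$bouts)
  expect_gt(nrow(res$pairs), 50)
  expect_lt(abs(mean(res$pairs$dz)), 1)
})

test_that("losing synchrony from NREM to REM shifts delta-z negative", {
  fx <- fixture_rate_switching_bouts(n_neurons = 15, n_pairs = 3, seed = 6,
                                     rem_sync = FALSE)
  res <- paired_bout_fc_change(fx$raster, fx$bouts)
  expect_lt(mean(res$pairs$dz), -2)
})
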