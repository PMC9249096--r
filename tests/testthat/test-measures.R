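# Spike-train statistics: MPC, cross-correlation, AMD / AMD-Z, region
# deltas, firing rates, LFP spectra.

test_that("mean phase coherence recognizes perfect and absent locking", {
  ti <- seq(0, 1000, by = 100)
  expect_equal(mean_phase_coherence(ti, ti + 25), 1)      # constant pi/2 phase
  expect_equal(mean_phase_coherence(ti, ti[-length(ti)] + 1e-9), 1)
  # uniform phases: resultant length near zero
  set.seed(1)
  tj <- sort(runif(10000, 0, 1000))
  expect_lt(mean_phase_coherence(ti, tj), 0.03)
  # degenerate pairs are masked
  expect_true(is.na(mean_phase_coherence(c(1), c(2))))
  expect_true(is.na(mean_phase_coherence(c(1, 2), c(5))))
})

test_that("MPC is invariant under a global time shift and 1 on the diagonal", {
  set.seed(2)
  trains <- lapply(1:4, function(i) sort(runif(40, 0, 2000)))
  sd0 <- spike_data(trains, 0, 2000)
  sd1 <- spike_data(lapply(trains, `+`, 500), 500, 2500)
  M0 <- mpc_matrix(sd0, window = c(0, 2000))
  M1 <- mpc_matrix(sd1, window = c(500, 2500))
  expect_equal(M0, M1)
  expect_equal(diag(M0), rep(1, 4))
})

test_that("network MPC averages ordered pairs and recombines over blocks", {
  ti <- seq(1000, 2000, by = 100)
  sdp <- spike_data(list(ti, ti + 10, ti + 37), 0, 2100)
  M <- mpc_matrix(sdp)
  diag(M) <- NA
  nm <- network_mpc(sdp)
  expect_equal(nm$global, mean(M, na.rm = TRUE))
  # two-neuron network: mean of the two ordered values
  sd2 <- spike_data(list(ti, ti + 10), 0, 2100)
  nm2 <- network_mpc(sd2)
  expect_equal(nm2$global,
               mean(c(mean_phase_coherence(ti, ti + 10),
                      mean_phase_coherence(ti + 10, ti))))
  # block decomposition recombines with pair weighting
  hub <- 1:2
  blocks <- network_mpc(sdp, hub = hub)
  n_hub_pairs <- sum(!is.na(M[hub, hub]))
  n_non_pairs <- sum(!is.na(M[3, 3, drop = FALSE]))
  expect_equal(blocks$hub, mean(M[hub, hub], na.rm = TRUE))
  expect_equal(blocks$hub_minus_nonhub, blocks$hub - blocks$nonhub)
  expect_error(network_mpc(spike_data(list(c(1500), c(1600)), 0, 2100)),
               "insufficient spiking")
})

test_that("cross-correlation is 1 for identical trains and matches a dense oracle", {
  ti <- seq(100, 1900, by = 50)
  expect_equal(cross_correlation(ti, ti), 1)

  # offset 25 ms >> sigma with 50 ms period: anti-correlated; check against
  # an independently coded dense inner product
  tj <- ti + 25
  got <- cross_correlation(ti, tj, sigma_gauss = 1, dt = 0.1,
                           window = c(0, 2000))
  dtg <- 0.1
  grid <- seq(dtg / 2, 2000, by = dtg)
  dense <- function(tr) {
    x <- numeric(length(grid))
    for (tk in tr) x <- x + dnorm(grid, mean = tk, sd = 1)
    x - mean(x)
  }
  xi <- dense(ti); xj <- dense(tj)
  want <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  expect_lt(got, 0)
  expect_equal(got, want, tolerance = 0.02)

  # independent Poisson trains decorrelate
  set.seed(4)
  cc <- replicate(20, {
    a <- sort(runif(400, 0, 10000)); b <- sort(runif(400, 0, 10000))
    cross_correlation(a, b, window = c(0, 10000))
  })
  expect_lt(stats::quantile(abs(cc), 0.95), 0.05)
  expect_true(is.na(cross_correlation(numeric(0), ti)))
})

test_that("cc_matrix masks silent neurons and is symmetric with unit diagonal", {
  set.seed(5)
  trains <- list(sort(runif(60, 1000, 2000)), sort(runif(60, 1000, 2000)),
                 numeric(0))
  M <- cc_matrix(spike_data(trains, 0, 2000))
  expect_equal(diag(M)[1:2], c(1, 1))
  expect_true(all(is.na(M[3, ])))
  expect_equal(M[1, 2], M[2, 1])
})

test_that("AMD measures the mean distance to the most recent preceding spike", {
  ti <- c(10, 20, 30)
  expect_equal(amd(ti, ti), 0)
  expect_equal(amd(ti + 3, ti), 3)
  # uniform spikes against a periodic reference: expectation L/2
  set.seed(6)
  tj <- seq(0, 10000, by = 100)
  ti_u <- sort(runif(20000, 0, 10000))
  expect_equal(amd(ti_u, tj), 50, tolerance = 0.02)
  expect_true(is.na(amd(c(1), c(5))))   # nothing precedes
})

test_that("interval-based null moments calibrate the preceding distance", {
  # gamma-distributed ISIs; random test spikes; empirical mean and SD of the
  # preceding distance must match mu1 = sum(L^2)/(2T), sd = sqrt(mu2 - mu1^2)
  set.seed(7)
  isi <- rgamma(4000, shape = 2, rate = 0.05)
  ref <- cumsum(isi)
  t0 <- ref[1]; t1 <- ref[length(ref)]
  L <- diff(ref); Tt <- sum(L)
  mu1 <- sum(L^2) / (2 * Tt)
  mu2 <- sum(L^3) / (3 * Tt)
  sd_null <- sqrt(mu2 - mu1^2)
  probes <- runif(1e5, t0, t1)
  k <- findInterval(probes, ref)
  d <- probes - ref[k]
  expect_equal(mean(d), mu1, tolerance = 0.02)
  expect_equal(stats::sd(d), sd_null, tolerance = 0.02)
})

test_that("AMD Z-scores flag locking with the documented sign and antisymmetry", {
  set.seed(8)
  ref <- seq(1000, 2000, by = 100)            # j: periodic, 100 ms
  locked <- ref[-1] + 1                        # i: 1 ms after every j spike
  rnd <- sort(runif(60, 1000, 2000))
  sdz <- spike_data(list(ref, locked, rnd), 0, 2100)
  z <- amd_zscore(sdz, window = c(1000, 2100))
  expect_lt(z$z[2, 1], -2)                     # locked follower: strongly negative
  expect_equal(z$amd[2, 1], 1)
  expect_equal(z$mu[1], 50, tolerance = 1e-6)
  A <- z$asymmetry
  expect_equal(A, -t(A))
  # random placement stays within |Z| < 2 most of the time
  zr <- replicate(40, {
    rr <- sort(runif(200, 0, 20000))
    probe <- sort(runif(200, 0, 20000))
    sdx <- spike_data(list(rr, probe), 0, 20000)
    amd_zscore(sdx, window = c(0, 20000))$z[2, 1]
  })
  expect_gte(mean(abs(zr) < 2), 0.9)
})

test_that("region deltas normalize summed change per synapse and initial weight", {
  set.seed(9)
  topo <- build_network(30, 3, 0.5, seed = 91)
  W <- topo$weights
  hub <- topo$hub
  z0 <- region_delta(W, W, hub, w0 = 0.04)
  expect_true(all(z0$delta[z0$n_synapses > 0] == 0))
  dbl <- region_delta(W, 2 * W, hub, w0 = 0.04)
  expect_true(all(abs(dbl$delta[dbl$n_synapses > 0] - 1) < 1e-12))
  # cancellation in a toy two-synapse region
  wb <- matrix(0, 4, 4); wb[2, 1] <- wb[3, 1] <- 0.04
  wa <- wb; wa[2, 1] <- wa[2, 1] + 0.002; wa[3, 1] <- wa[3, 1] - 0.002
  rd <- region_delta(wb, wa, hub = 1, w0 = 0.04)
  expect_equal(rd$delta[rd$region == "hub_to_nonhub"], 0)
  expect_error(region_delta(W, W[1:10, 1:10], hub), "mismatched")
  # region synapse counts partition the synapse set
  expect_equal(sum(z0$n_synapses), sum(W != 0))
})

test_that("firing frequency counts spikes per window and sums to the total", {
  sdf <- spike_data(list(seq(100, 2000, by = 100), c(500), numeric(0)),
                    0, 2000)
  f <- firing_frequency(sdf, c(0, 2000))
  expect_equal(f[3], 0)
  expect_equal(f[1], 10)            # 20 spikes / 2 s
  expect_equal(sum(f) * 2, sum(lengths(sdf$trains)))
})

test_that("LFP spectrum finds an injected tone and rejects white noise peaks", {
  dt <- 0.5
  tt <- seq(0, 4000 - dt, by = dt)
  v <- sin(2 * pi * 7 * tt / 1000)
  sp <- lfp_spectrum(v, dt = dt)
  expect_equal(sp$dominant_freq, 7, tolerance = 0.05)
  # white noise: dominant frequency scatters across seeds
  doms <- sapply(1:8, function(s) {
    set.seed(s)
    lfp_spectrum(rnorm(length(tt)), dt = dt)$dominant_freq
  })
  expect_gt(length(unique(doms)), 4)
  expect_warning(lfp_spectrum(rnorm(100), dt = 0.5), "2 s")
})

test_that("spike data round-trips through event files", {
  set.seed(10)
  trains <- list(sort(runif(30, 0, 1000)), numeric(0), c(500.5))
  sdd <- spike_data(trains, 0, 1000)
  f <- tempfile(fileext = ".spk")
  write_spike_events(sdd, f)
  back <- read_spike_events(f, n_neurons = 3)
  expect_equal(back$trains, sdd$trains, tolerance = 1e-9)
  expect_equal(back$t_start, 0)
  expect_equal(back$t_end, 1000)
  unlink(f)
})
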