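# Membrane model: gating curves, derivatives, RK4 stepping, noise process,
# spike detection, f-I characterization and drive selection.

test_that("gating functions hit their sigmoid midpoints and derived values", {
  g <- gating_functions(-30)
  expect_equal(g$m_inf, 0.5)
  expect_equal(g$n_inf, 0.5)
  expect_equal(gating_functions(-39)$z_inf, 0.5)
  expect_equal(gating_functions(-53)$h_inf, 0.5)
  expect_equal(gating_functions(-40.5)$tau_h, 0.37 + 2.78 / 2)
  expect_equal(gating_functions(-27)$tau_n, 0.37 + 1.85 / 2)
  expect_equal(gating_functions(-14)$z_inf, 1 / (1 + exp(-5)))
  # saturation is overflow-safe
  ext <- gating_functions(c(-1e4, 1e4))
  expect_true(all(vapply(ext, function(x) all(is.finite(x)), logical(1))))
  expect_equal(ext$m_inf, c(0, 1))
})

test_that("membrane derivatives reduce to forced limits", {
  p0 <- neuron_params()
  p0$g_Na <- p0$g_Kdr <- p0$g_Ks <- p0$g_L <- 0
  st <- list(V = 0, h = 0.5, n = 0.5, z = 0.5)
  expect_equal(membrane_derivatives(st, p0, I_drive = 1)$dV, 1)

  # V = E_K with closed sodium and I = 0: only the leak term remains
  p <- neuron_params()
  st <- list(V = -90, h = 0, n = 0.5, z = 0)
  expect_equal(membrane_derivatives(st, p)$dV, -0.02 * (-90 + 60))
  expect_equal(membrane_derivatives(st, p)$dV, 0.6)

  expect_error(membrane_derivatives(list(V = NaN, h = 1, n = 0, z = 0), p),
               "neuron 1")
})

test_that("all derivatives vanish at the subthreshold fixed point", {
  p <- neuron_params(g_Ks = 1.5)
  st <- achnet:::rest_state(p)          # root-finding on the full nullcline
  d <- membrane_derivatives(st, p, I_drive = 0)
  for (dd in d) expect_lt(abs(dd), 1e-7)
})

test_that("RK4 is exact for drift and matches the leak-only closed form", {
  p0 <- neuron_params()
  p0$g_Na <- p0$g_Kdr <- p0$g_Ks <- p0$g_L <- 0
  st <- list(V = -50, h = 0.5, n = 0.5, z = 0.5)
  expect_equal(rk4_step(st, p0, 0.1, I_drive = 2)$V, -50 + 0.2)

  # leak only: V(t) = E_L + (V0 - E_L) exp(-g_L t / C)
  pl <- neuron_params()
  pl$g_Na <- pl$g_Kdr <- pl$g_Ks <- 0
  st <- list(V = 0, h = 0, n = 0, z = 0)
  V <- st$V
  for (k in 1:100) {
    st <- rk4_step(st, pl, 0.1)
  }
  exact <- -60 + 60 * exp(-0.02 * 10)
  expect_lt(abs(st$V - exact) / abs(exact), 1e-8)
})

test_that("compiled engine agrees with the pure-R stepper to 1e-12", {
  p <- neuron_params(g_Ks = 0.8)
  st <- list(V = -55, h = 0.7, n = 0.1, z = 0.05)
  res <- achnet:::integrate_uncoupled(st, p, I_drive = 1.3, duration = 100,
                                      dt = 0.1)
  st_r <- st
  for (k in 1:1000) st_r <- rk4_step(st_r, p, 0.1, I_drive = 1.3)
  expect_lt(abs(res$V - st_r$V), 1e-12)
  expect_lt(abs(res$h - st_r$h), 1e-12)
  expect_lt(abs(res$n - st_r$n), 1e-12)
  expect_lt(abs(res$z - st_r$z), 1e-12)
})

test_that("gates stay in [0, 1] and voltage stays bounded during network runs", {
  sim <- cached_sim(1.5, 0.5, seed = 301, duration = 500, n = 60,
                    z_passes = 4, record_v = TRUE)
  expect_true(all(sim$vtrace >= -110 & sim$vtrace <= 75))
  fs <- sim$final_state
  for (gate in c("h", "n_gate", "z"))
    expect_true(all(fs[[gate]] >= 0 & fs[[gate]] <= 1))
})

test_that("halving the step size moves spike times by less than 0.1 ms", {
  p <- neuron_params(g_Ks = 1.5)
  st <- achnet:::rest_state(p)
  r1 <- achnet:::integrate_uncoupled(st, p, I_drive = 2, duration = 2000,
                                     dt = 0.1)
  r2 <- achnet:::integrate_uncoupled(st, p, I_drive = 2, duration = 2000,
                                     dt = 0.05)
  n <- min(length(r1$spike_times), length(r2$spike_times))
  expect_gt(n, 5)
  expect_equal(length(r1$spike_times), length(r2$spike_times))
  # the firing period converges below the coarse resolution; the absolute
  # spike-time offset carries the quantized onset transient (< 3 dt)
  expect_lt(max(abs(diff(r1$spike_times) - diff(r2$spike_times))), 0.1)
  expect_lt(max(abs(r1$spike_times[1:n] - r2$spike_times[1:n])), 0.3)
})

test_that("pulse noise has the configured rate, duration and restart rule", {
  cfg <- stimulus_config()
  set.seed(5)
  nz <- generate_noise(3, 5000, stimulus_config(noise_prob_per_step = 0))
  expect_true(all(nz == 0))
  nz <- generate_noise(2, 200, stimulus_config(noise_prob_per_step = 1))
  expect_true(all(nz == 0.7))        # always retriggered: constant current
  # pulses hold 20 steps at amplitude 0.7
  set.seed(8)
  nz <- generate_noise(1, 1e5, cfg)
  expect_true(all(nz %in% c(0, 0.7)))
  runs <- rle(as.vector(nz))
  on_runs <- runs$lengths[runs$values == 0.7]
  if (runs$values[length(runs$values)] == 0.7)  # final pulse may be truncated
    on_runs <- on_runs[-length(on_runs)]
  expect_true(all(on_runs >= 20))
})

test_that("spike detection marks upward zero crossings only", {
  expect_length(detect_spikes(rep(-30, 100), 0.1), 0)
  expect_length(detect_spikes(rep(10, 100), 0.1), 0)   # no crossing
  # 10 Hz sine sampled at 1 kHz: upward crossings at t = 0.1 s intervals
  tt <- seq(0, 0.9999, by = 0.001)
  v <- sin(2 * pi * 10 * tt)
  spk <- detect_spikes(v, dt = 1, t0 = 0)   # ms units: dt = 1 ms
  expect_length(spk, 10)
  analytic <- seq(0, 900, by = 100)
  expect_true(all(abs(spk - analytic) <= 1 + 1e-9))
})

test_that("f-I curves separate Type I and Type II excitability", {
  fi0 <- f_i_curve(neuron_params(g_Ks = 0), seq(-0.3, 0.3, by = 0.01),
                   duration = 2000)
  fi15 <- f_i_curve(neuron_params(g_Ks = 1.5), seq(0.8, 1.8, by = 0.01),
                    duration = 2000)
  on0 <- fi0$rate_hz[fi0$rate_hz > 0]
  on15 <- fi15$rate_hz[fi15$rate_hz > 0]
  expect_gt(length(on0), 0)
  expect_gt(length(on15), 0)
  expect_lt(min(on0), 5)                     # continuous onset from 0 Hz
  expect_gt(min(on15), min(on0))             # finite jump at onset
  # rheobase ordering and flatter suprathreshold slope at high g_Ks
  rheo0 <- min(fi0$I[fi0$rate_hz > 0])
  rheo15 <- min(fi15$I[fi15$rate_hz > 0])
  expect_gt(rheo15, rheo0)
  slope0 <- diff(range(fi0$rate_hz)) / diff(range(fi0$I))
  slope15 <- diff(range(fi15$rate_hz)) / diff(range(fi15$I))
  expect_lt(slope15, slope0)
  expect_error(f_i_curve(neuron_params(), numeric(0)), "empty")
})

test_that("drive selection returns the largest quiet current consistently", {
  p <- neuron_params(g_Ks = 1.5)
  coarse <- select_drive(p, seq(0, 2, by = 0.04), duration = 1000)
  fine <- select_drive(p, seq(0, 2, by = 0.02), duration = 1000)
  fi <- f_i_curve(p, seq(0, 2, by = 0.04), duration = 1000)
  expect_lt(coarse, min(fi$I[fi$rate_hz > 0]))
  expect_lte(abs(fine - coarse), 0.04)       # refinement consistency
  expect_error(select_drive(p, c(4, 5), duration = 500),
               "grid below rheobase")
  # the selected drive sustains no steady-state firing from rest
  st <- achnet:::rest_state(p)
  r <- achnet:::integrate_uncoupled(st, p, coarse, 1000, 0.1)
  expect_length(r$spike_times[r$spike_times > 500], 0)
})

test_that("a zero-amplitude perturbation leaves the phase response flat", {
  prc <- compute_prc(neuron_params(g_Ks = 1.5), I_drive = 1.3,
                     perturbation = 0, n_phases = 6)
  # shifts vanish up to spike-time quantization (one dt over one period)
  expect_true(all(abs(prc$shift) < 2 * 0.1 / attr(prc, "T0")))
})
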