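#' Biophysical neuron parameters
#'
#' Conductance-based membrane model with transient sodium, delayed-rectifier
#' potassium, leak, and a slow non-inactivating M-type potassium current whose
#' maximal conductance \code{g_Ks} serves as an inverse proxy for
#' acetylcholine level: \code{g_Ks = 0} mS/cm2 models high ACh (Type I
#' excitability), \code{g_Ks = 1.5} mS/cm2 models low ACh (Type II).
#'
#' @param g_Ks M-type potassium conductance (mS/cm2), in \code{[0, 1.5]} for
#'   the standard protocols.
#' @param C membrane capacitance (uF/cm2).
#' @param g_Na,g_Kdr,g_L sodium, delayed-rectifier and leak conductances
#'   (mS/cm2).
#' @param E_Na,E_K,E_L reversal potentials (mV).
#' @param tau_z time constant of the M-current gate (ms).
#' @return A list of class \code{"neuron_params"}.
#' @export
neuron_params <- function(g_Ks = 0, C = 1.0, g_Na = 24.0, g_Kdr = 3.0,
                          g_L = 0.02, E_Na = 55.0, E_K = -90.0, E_L = -60.0,
                          tau_z = 75.0) {
  stopifnot(g_Ks >= 0, g_Na >= 0, g_Kdr >= 0, g_L >= 0, C > 0, tau_z > 0,
            E_K < E_L, E_L < E_Na)
  structure(list(g_Ks = g_Ks, C = C, g_Na = g_Na, g_Kdr = g_Kdr, g_L = g_L,
                 E_Na = E_Na, E_K = E_K, E_L = E_L, tau_z = tau_z),
            class = "neuron_params")
}

#' Stimulus configuration: constant drive plus random pulse noise
#'
#' Background noise is a train of rectangular current pulses: at every
#' integration step each neuron independently initiates a pulse with
#' probability \code{noise_prob_per_step}; a pulse holds
#' \code{noise_amplitude} for \code{noise_duration}, and a new initiation
#' during an active pulse restarts its clock (amplitudes do not stack).
#' The defaults (0.7 uA/cm2, 2 ms, 2\% per 0.1 ms step) give an initiation
#' rate of 200 Hz per neuron.
#'
#' @param I_drive constant applied current (uA/cm2); \code{NULL} selects the
#'   highest subthreshold current for the simulation's \code{g_Ks} at run
#'   time (see [select_drive()]).
#' @param noise_amplitude pulse amplitude (uA/cm2).
#' @param noise_duration pulse duration (ms).
#' @param noise_prob_per_step initiation probability per integration step.
#' @param dt integration step (ms).
#' @return A list of class \code{"stimulus_config"}.
#' @export
stimulus_config <- function(I_drive = NULL, noise_amplitude = 0.7,
                            noise_duration = 2.0, noise_prob_per_step = 0.02,
                            dt = 0.1) {
  stopifnot(dt > 0, noise_duration >= dt,
            noise_prob_per_step >= 0, noise_prob_per_step <= 1)
  structure(list(I_drive = I_drive, noise_amplitude = noise_amplitude,
                 noise_duration = noise_duration,
                 noise_prob_per_step = noise_prob_per_step, dt = dt),
            class = "stimulus_config")
}

#' Steady-state activation curves and time constants
#'
#' Evaluates the six gating functions of the membrane model at voltage
#' \code{V}: instantaneous sodium activation \code{m_inf}, sodium
#' inactivation steady state \code{h_inf} and time constant \code{tau_h},
#' delayed-rectifier steady state \code{n_inf} and time constant
#' \code{tau_n}, and the M-current gate steady state \code{z_inf}.
#' Evaluation is overflow-safe at extreme voltages (sigmoids saturate to
#' exactly 0 or 1).
#'
#' @param V membrane voltage (mV), vectorized.
#' @return A list of numeric vectors \code{m_inf}, \code{h_inf},
#'   \code{tau_h}, \code{n_inf}, \code{tau_n}, \code{z_inf}.
#' @export
gating_functions <- function(V) {
  list(m_inf = 1 / (1 + exp(-(V + 30) / 9.5)),
       h_inf = 1 / (1 + exp((V + 53) / 7)),
       tau_h = 0.37 + 2.78 / (1 + exp((V + 40.5) / 6)),
       n_inf = 1 / (1 + exp(-(V + 30) / 10)),
       tau_n = 0.37 + 1.85 / (1 + exp((V + 27) / 15)),
       z_inf = 1 / (1 + exp(-(V + 39) / 5)))
}

#' Membrane equation right-hand side
#'
#' Time derivatives of the state \code{(V, h, n, z)} under external currents.
#' All current arguments are in uA/cm2 and follow the sign convention of the
#' membrane equation: drive and noise depolarize when positive, while
#' \code{I_syn} is subtracted (an excitatory synaptic current computed as
#' \code{g * (V - E_syn)} with \code{E_syn = 0} is negative at rest and so
#' depolarizes).
#'
#' @param state list with numeric vectors \code{V}, \code{h}, \code{n},
#'   \code{z} (equal lengths).
#' @param params a [neuron_params()] object.
#' @param I_drive,I_noise,I_syn per-neuron currents (uA/cm2), recycled.
#' @return List of derivatives \code{dV}, \code{dh}, \code{dn}, \code{dz}
#'   (mV/ms and 1/ms).
#' @export
membrane_derivatives <- function(state, params, I_drive = 0, I_noise = 0,
                                 I_syn = 0) {
  V <- state$V
  if (anyNA(V) || any(!is.finite(V)))
    stop("non-finite voltage for neuron ", which(!is.finite(V))[1])
  g <- gating_functions(V)
  dV <- (-params$g_Na * g$m_inf^3 * state$h * (V - params$E_Na) -
           params$g_Kdr * state$n^4 * (V - params$E_K) -
           params$g_Ks * state$z * (V - params$E_K) -
           params$g_L * (V - params$E_L) +
           I_drive + I_noise - I_syn) / params$C
  list(dV = dV,
       dh = (g$h_inf - state$h) / g$tau_h,
       dn = (g$n_inf - state$n) / g$tau_n,
       dz = (g$z_inf - state$z) / params$tau_z)
}

#' One classical fourth-order Runge-Kutta step
#'
#' Advances the full membrane state by \code{dt} with external currents held
#' constant across the four substages. Gating variables are clipped to
#' \code{[0, 1]} after the update. This is the pure-R reference stepper; the
#' network simulator uses an equivalent compiled path.
#'
#' @inheritParams membrane_derivatives
#' @param dt step size (ms).
#' @return The state list advanced to \code{t + dt}.
#' @export
rk4_step <- function(state, params, dt, I_drive = 0, I_noise = 0, I_syn = 0) {
  stopifnot(dt > 0)
  k1 <- membrane_derivatives(state, params, I_drive, I_noise, I_syn)
  s2 <- list(V = state$V + dt / 2 * k1$dV, h = state$h + dt / 2 * k1$dh,
             n = state$n + dt / 2 * k1$dn, z = state$z + dt / 2 * k1$dz)
  k2 <- membrane_derivatives(s2, params, I_drive, I_noise, I_syn)
  s3 <- list(V = state$V + dt / 2 * k2$dV, h = state$h + dt / 2 * k2$dh,
             n = state$n + dt / 2 * k2$dn, z = state$z + dt / 2 * k2$dz)
  k3 <- membrane_derivatives(s3, params, I_drive, I_noise, I_syn)
  s4 <- list(V = state$V + dt * k3$dV, h = state$h + dt * k3$dh,
             n = state$n + dt * k3$dn, z = state$z + dt * k3$dz)
  k4 <- membrane_derivatives(s4, params, I_drive, I_noise, I_syn)
  clip <- function(x) pmin(pmax(x, 0), 1)
  list(V = state$V + dt / 6 * (k1$dV + 2 * k2$dV + 2 * k3$dV + k4$dV),
       h = clip(state$h + dt / 6 * (k1$dh + 2 * k2$dh + 2 * k3$dh + k4$dh)),
       n = clip(state$n + dt / 6 * (k1$dn + 2 * k2$dn + 2 * k3$dn + k4$dn)),
       z = clip(state$z + dt / 6 * (k1$dz + 2 * k2$dz + 2 * k3$dz + k4$dz)))
}

#' Random pulse-noise current time series
#'
#' Draws the background noise process explicitly: per neuron and step, with
#' probability \code{noise_prob_per_step} a rectangular pulse of
#' \code{noise_amplitude} starts and holds for \code{noise_duration};
#' re-initiation during an active pulse restarts the clock.
#'
#' @param n_neurons,n_steps dimensions of the draw.
#' @param config a [stimulus_config()].
#' @return An \code{n_steps x n_neurons} matrix of currents (uA/cm2) with
#'   attribute \code{"initiations"} holding the per-neuron initiation counts.
#' @export
generate_noise <- function(n_neurons, n_steps, config = stimulus_config()) {
  p <- config$noise_prob_per_step
  hold <- max(1L, as.integer(round(config$noise_duration / config$dt)))
  out <- matrix(0, n_steps, n_neurons)
  inits <- integer(n_neurons)
  if (p > 0) {
    for (j in seq_len(n_neurons)) {
      start <- stats::runif(n_steps) < p
      inits[j] <- sum(start)
      if (inits[j] > 0) {
        count <- 0L
        act <- logical(n_steps)
        for (k in seq_len(n_steps)) {
          if (start[k]) count <- hold
          if (count > 0L) {
            act[k] <- TRUE
            count <- count - 1L
          }
        }
        out[act, j] <- config$noise_amplitude
      }
    }
  }
  attr(out, "initiations") <- inits
  out
}

#' Detect spikes as upward zero crossings of a voltage trace
#'
#' A spike is recorded whenever the trace crosses 0 mV from below
#' (\code{V[k-1] <= 0 < V[k]}), with the spike time assigned to sample
#' \code{k}; one spike per crossing regardless of how long the trace stays
#' above threshold.
#'
#' @param V_trace numeric vector, uniformly sampled membrane voltage (mV).
#' @param dt sampling step (ms).
#' @param t0 time of sample 0 (ms); sample \code{k} is at \code{t0 + k * dt}.
#' @return Numeric vector of spike times (ms).
#' @export
detect_spikes <- function(V_trace, dt, t0 = 0) {
  k <- which(V_trace[-length(V_trace)] <= 0 & V_trace[-1] > 0)
  t0 + (k + 1 - 1) * dt  # crossing assigned to the later sample, 1-based
}

# resting state under a given applied current: gates at steady state,
# dV/dt = 0. Low-g_Ks cells can lack a subthreshold fixed point at I = 0
# (they are spontaneously active); a hyperpolarized start is used then.
rest_state <- function(params, n = 1, I_drive = 0) {
  f <- function(V) {
    g <- gating_functions(V)
    -params$g_Na * g$m_inf^3 * g$h_inf * (V - params$E_Na) -
      params$g_Kdr * g$n_inf^4 * (V - params$E_K) -
      params$g_Ks * g$z_inf * (V - params$E_K) -
      params$g_L * (V - params$E_L) + I_drive
  }
  V <- tryCatch(stats::uniroot(f, c(params$E_K + 1, -35), tol = 1e-10)$root,
                error = function(e) -70)
  g <- gating_functions(V)
  list(V = rep(V, n), h = rep(g$h_inf, n), n = rep(g$n_inf, n),
       z = rep(g$z_inf, n))
}

# integrate n_grid uncoupled neurons through the compiled engine
integrate_uncoupled <- function(state, params, I_drive, duration, dt = 0.1,
                                record_v = FALSE) {
  m <- length(I_drive)
  W <- matrix(0, m, m)
  res <- engine_run(W, matrix(FALSE, m, m), rep(FALSE, m),
                    state$V, state$h, state$n, state$z,
                    numeric(m), numeric(m), integer(m),
                    as.numeric(I_drive), unclass(params), dt,
                    as.integer(round(duration / dt)), 0,
                    0, 0, 0L, 0.5, 0.2, 0, -75,
                    FALSE, 0, 10, 0.08, 40, numeric(0), integer(0),
                    FALSE, record_v)
  res
}

#' Steady-state frequency-current (f-I) curve of an isolated neuron
#'
#' Integrates one noiseless, uncoupled neuron from rest for each current on
#' the grid and reports the firing rate over the second half of the run
#' (the first half is discarded as transient). At \code{g_Ks = 0} the rate
#' rises continuously from 0 Hz above rheobase (Type I); at
#' \code{g_Ks = 1.5} it jumps discontinuously to a finite rate (Type II).
#'
#' @param params a [neuron_params()] object.
#' @param current_grid applied currents (uA/cm2).
#' @param duration run length per current (ms).
#' @param dt integration step (ms).
#' @return A data frame with columns \code{I} and \code{rate_hz}, classed
#'   \code{"fi_curve"}.
#' @export
f_i_curve <- function(params, current_grid = seq(-1, 5, by = 0.05),
                      duration = 2000, dt = 0.1) {
  if (length(current_grid) == 0) stop("empty current grid")
  state <- rest_state(params, length(current_grid))
  res <- integrate_uncoupled(state, params, current_grid, duration, dt)
  half <- duration / 2
  keep <- res$spike_times > half
  counts <- tabulate(res$spike_neurons[keep], nbins = length(current_grid))
  structure(data.frame(I = as.numeric(current_grid),
                       rate_hz = counts / (half / 1000)),
            class = c("fi_curve", "data.frame"), g_Ks = params$g_Ks)
}

drive_cache <- new.env(parent = emptyenv())

#' Highest subthreshold applied current for a given g_Ks
#'
#' Scans the current grid with an isolated noiseless neuron and returns the
#' largest current that elicits no spikes over \code{duration}. The result is
#' cached per parameter set within the session.
#'
#' @inheritParams f_i_curve
#' @param current_grid ascending currents (uA/cm2) spanning rheobase.
#' @return The selected drive (uA/cm2).
#' @export
select_drive <- function(params, current_grid = seq(-1, 5, by = 0.01),
                         duration = 2000, dt = 0.1) {
  key <- paste(unlist(params), collapse = "|")
  key <- paste(key, paste(range(current_grid), collapse = ":"),
               length(current_grid), duration, dt, sep = "|")
  hit <- drive_cache[[key]]
  if (!is.null(hit)) return(hit)
  fi <- f_i_curve(params, current_grid, duration, dt)
  quiet <- fi$I[fi$rate_hz == 0]
  if (length(quiet) == 0) stop("grid below rheobase exhausted")
  if (all(fi$rate_hz == 0))
    warning("no suprathreshold current on grid; rheobase not bracketed")
  drive <- max(quiet)
  drive_cache[[key]] <- drive
  drive
}

#' Phase response curve under a synaptic-like perturbation
#'
#' The neuron fires periodically under constant suprathreshold drive; at each
#' of \code{n_phases} equally spaced phases of its cycle a brief excitatory
#' conductance pulse (double-exponential kernel, reversal 0 mV) is delivered
#' and the normalized shift of the next spike, \code{(T0 - T_perturbed)/T0},
#' is reported (positive = phase advance). Type I cells (\code{g_Ks = 0})
#' give a strictly positive curve; Type II cells (\code{g_Ks = 1.5}) give a
#' biphasic curve with delays at early phases.
#'
#' @param params a [neuron_params()] object.
#' @param I_drive constant suprathreshold current (uA/cm2); \code{NULL}
#'   selects the smallest grid current firing in (or nearest above) 5-10 Hz.
#' @param perturbation peak synaptic conductance of the probe (mS/cm2).
#' @param n_phases number of equally spaced phases.
#' @param dt integration step (ms).
#' @return Data frame with columns \code{phase} and \code{shift}, classed
#'   \code{"prc_curve"}.
#' @export
compute_prc <- function(params, I_drive = NULL, perturbation = 0.04,
                        n_phases = 50, dt = 0.1) {
  if (is.null(I_drive)) {
    fi <- f_i_curve(params, seq(-1, 5, by = 0.02), duration = 2000, dt = dt)
    band <- fi$I[fi$rate_hz >= 5 & fi$rate_hz <= 10]
    I_drive <- if (length(band) > 0) min(band) else {
      up <- fi$I[fi$rate_hz > 0]
      if (length(up) == 0) stop("neuron not periodic under grid drive")
      min(up)
    }
  }
  # settle on the limit cycle, then measure the unperturbed period
  st <- rest_state(params, 1)
  settle <- integrate_uncoupled(st, params, I_drive, 3000, dt, record_v = TRUE)
  spk <- settle$spike_times[settle$spike_times > 1500]
  if (length(spk) < 4) stop("neuron not periodic under given drive")
  isi <- diff(spk)
  if (stats::sd(isi) / mean(isi) > 1e-3)
    stop("neuron not periodic under given drive")
  T0 <- mean(isi)
  # state at the last observed spike: re-integrate from the recorded state
  # (settle returned only the final state; step count to last spike)
  k_last <- round(spk[length(spk)] / dt)
  ref <- integrate_uncoupled(st, params, I_drive, k_last * dt, dt)
  state0 <- list(V = ref$V, h = ref$h, n = ref$n, z = ref$z)

  phases <- (seq_len(n_phases) - 1) / n_phases
  shifts <- vapply(phases, function(phi) {
    t_pert <- phi * T0
    horizon <- ceiling((t_pert + 2.5 * T0) / dt)
    res <- integrate_perturbed(state0, params, I_drive, horizon, dt,
                               t_pert, perturbation)
    nxt <- res$spikes
    if (length(nxt) == 0) return(NA_real_)
    (T0 - nxt[1]) / T0
  }, numeric(1))
  structure(data.frame(phase = phases, shift = shifts),
            class = c("prc_curve", "data.frame"),
            g_Ks = params$g_Ks, I_drive = I_drive, T0 = T0)
}

# scalar integration with one synaptic conductance pulse at t_pert;
# pure R, used by the PRC probe and as an engine cross-check
integrate_perturbed <- function(state, params, I_drive, n_steps, dt,
                                t_pert = Inf, w_pert = 0,
                                tau_d = 0.5, tau_r = 0.2, E_syn = 0) {
  V <- state$V[1]; h <- state$h[1]; n <- state$n[1]; z <- state$z[1]
  spikes <- numeric(0)
  st <- list(V = V, h = h, n = n, z = z)
  for (k in seq_len(n_steps)) {
    t_now <- (k - 1) * dt
    Isyn <- 0
    if (w_pert > 0 && t_now >= t_pert) {
      el <- t_now - t_pert
      Isyn <- w_pert * (exp(-el / tau_d) - exp(-el / tau_r)) * (st$V - E_syn)
    }
    new <- rk4_step(st, params, dt, I_drive = I_drive, I_syn = Isyn)
    if (st$V <= 0 && new$V > 0) spikes <- c(spikes, k * dt)
    st <- new
  }
  list(spikes = spikes, state = st)
}
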