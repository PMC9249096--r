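#' Simulation configuration
#'
#' Bundles network, stimulus, synapse and plasticity settings for a network
#' simulation. \code{g_syn} is the initial conductance of every excitatory
#' synapse (it is the network's \code{w0}); \code{g_Ks} sets the ACh state
#' (0 = high ACh / wake-like, 1.5 = low ACh / slow-wave-sleep-like).
#'
#' @param n,z_passes,p_in,inhibitory_fraction,w_inh,hub_fraction network
#'   settings, see [build_network()].
#' @param g_Ks M-current conductance (mS/cm2).
#' @param g_syn initial excitatory synaptic conductance (mS/cm2).
#' @param duration simulated time (ms); protocols using second-half analysis
#'   need >= 1000 ms.
#' @param dt integration step (ms).
#' @param stimulus a [stimulus_config()]; its \code{I_drive = NULL} default
#'   auto-selects the highest subthreshold drive for \code{g_Ks}.
#' @param synapse a [synapse_params()].
#' @param plasticity a [plasticity_params()]; \code{enabled = FALSE} freezes
#'   weights.
#' @param n_trials number of independent repetitions used by the experiment
#'   drivers (fresh topology and initial conditions per trial).
#' @param record_vsum record the summed excitatory voltage (LFP proxy).
#' @param record_v record full voltage traces (memory-heavy).
#' @param seed RNG seed; trial \code{k} of an experiment uses
#'   \code{seed + k - 1}.
#' @return A list of class \code{"simulation_config"}.
#' @export
simulation_config <- function(n = 250, z_passes = 15, p_in = 0.5,
                              inhibitory_fraction = 0, g_Ks = 0,
                              g_syn = 0.04, w_inh = 0.01, hub_fraction = 0.1,
                              duration = 2000, dt = 0.1,
                              stimulus = stimulus_config(dt = dt),
                              synapse = synapse_params(),
                              plasticity = plasticity_params(
                                w_max = 2 * g_syn, enabled = FALSE),
                              n_trials = 10, record_vsum = FALSE,
                              record_v = FALSE, seed = 1) {
  stopifnot(duration > 0, n_trials >= 1, g_Ks >= 0, g_syn >= 0)
  structure(list(n = n, z_passes = z_passes, p_in = p_in,
                 inhibitory_fraction = inhibitory_fraction, g_Ks = g_Ks,
                 g_syn = g_syn, w_inh = w_inh, hub_fraction = hub_fraction,
                 duration = duration, dt = dt, stimulus = stimulus,
                 synapse = synapse, plasticity = plasticity,
                 n_trials = n_trials, record_vsum = record_vsum,
                 record_v = record_v, seed = seed),
            class = "simulation_config")
}

# default drive grid used when auto-selecting the subthreshold drive
auto_drive <- function(g_Ks, dt = 0.1) {
  select_drive(neuron_params(g_Ks = g_Ks), seq(-1, 5, by = 0.01),
               duration = 2000, dt = dt)
}

# mutable simulation bundle: everything the engine needs to resume
init_sim_bundle <- function(topo, config) {
  n <- nrow(topo$weights)
  list(topo = topo,
       W = topo$weights,
       adj_plastic = topo$weights > 0 & !matrix(topo$is_inhibitory, n, n,
                                                byrow = TRUE),
       V = stats::runif(n, -70, 0), h = rep(1, n), n_gate = rep(0, n),
       z = rep(0, n), sd = numeric(n), sr = numeric(n),
       noise_count = integer(n), hist_t = numeric(0), hist_id = integer(0),
       t_now = 0, spike_times = numeric(0), spike_neurons = integer(0),
       vsum = numeric(0))
}

# advance one protocol segment (fixed g_Ks / plasticity flag) in place
advance_segment <- function(b, config, duration, g_Ks, stdp_on,
                            I_drive = NULL) {
  if (is.null(I_drive)) {
    I_drive <- config$stimulus$I_drive
    if (is.null(I_drive)) I_drive <- auto_drive(g_Ks, config$dt)
  }
  n <- length(b$V)
  np <- neuron_params(g_Ks = g_Ks)
  st <- config$stimulus
  sy <- config$synapse
  pl <- config$plasticity
  res <- engine_run(b$W, b$adj_plastic, b$topo$is_inhibitory,
                    b$V, b$h, b$n_gate, b$z, b$sd, b$sr, b$noise_count,
                    rep_len(I_drive, n), unclass(np), config$dt,
                    as.integer(round(duration / config$dt)), b$t_now,
                    st$noise_amplitude, st$noise_prob_per_step,
                    as.integer(round(st$noise_duration / st$dt)),
                    sy$tau_d, sy$tau_r, sy$E_syn_exc, sy$E_syn_inh,
                    stdp_on, pl$A_L, pl$tau_STDP, pl$w_max,
                    pl$pairing_window, b$hist_t, b$hist_id,
                    config$record_vsum, config$record_v)
  b$W <- res$W
  b$V <- res$V; b$h <- res$h; b$n_gate <- res$n; b$z <- res$z
  b$sd <- res$sd; b$sr <- res$sr; b$noise_count <- res$noise_count
  b$hist_t <- res$hist_t; b$hist_id <- res$hist_id
  b$spike_times <- c(b$spike_times, res$spike_times)
  b$spike_neurons <- c(b$spike_neurons, res$spike_neurons)
  b$vsum <- c(b$vsum, res$vsum)
  b$vtrace <- if (config$record_v) rbind(b$vtrace, res$vtrace) else NULL
  b$t_now <- res$t_end
  b$I_drive <- I_drive
  b
}

bundle_spikes <- function(b, t_start = 0) {
  trains <- split(b$spike_times, factor(b$spike_neurons,
                                        levels = seq_along(b$V)))
  spike_data(unname(trains), t_start, b$t_now)
}

#' Run one network simulation
#'
#' Builds a fresh topology from the configuration, draws initial conditions
#' (voltage uniform on [-70, 0] mV, gates at 0 except sodium inactivation at
#' 1), auto-selects the per-g_Ks subthreshold drive unless overridden, and
#' integrates for \code{config$duration} with RK4 at \code{config$dt},
#' accumulating synaptic currents and (if enabled) STDP. Identical
#' configuration and seed give identical output.
#'
#' @param config a [simulation_config()].
#' @param topology optionally, a pre-built \code{"sf_topology"} to reuse
#'   (the configuration's network settings are then ignored).
#' @return An object of class \code{"achnet_sim"}: list with \code{spikes}
#'   ([spike_data()]), \code{topology}, \code{w_before}, \code{w_after},
#'   \code{I_drive}, \code{vsum} (if recorded), \code{config}, and the final
#'   integrator state.
#' @export
run_simulation <- function(config = simulation_config(), topology = NULL) {
  set.seed(config$seed)
  if (is.null(topology))
    topology <- build_network(config$n, config$z_passes, config$p_in,
                              config$inhibitory_fraction, config$g_syn,
                              config$w_inh, config$hub_fraction)
  b <- init_sim_bundle(topology, config)
  w_before <- b$W
  b <- advance_segment(b, config, config$duration, config$g_Ks,
                       config$plasticity$enabled)
  structure(list(spikes = bundle_spikes(b), topology = topology,
                 w_before = w_before, w_after = b$W,
                 adj_plastic = b$adj_plastic,
                 I_drive = b$I_drive,
                 vsum = if (config$record_vsum) b$vsum else NULL,
                 vtrace = b$vtrace,
                 config = config, final_state = b[c("V", "h", "n_gate", "z")]),
            class = "achnet_sim")
}

#' @export
print.achnet_sim <- function(x, ...) {
  cfg <- x$config
  cat("Network simulation: n =", cfg$n, ", g_Ks =", cfg$g_Ks,
      "mS/cm2, p_in =", cfg$p_in, ",", cfg$duration, "ms\n")
  print(x$spikes)
  invisible(x)
}

#' @export
summary.achnet_sim <- function(object, ...) {
  sdw <- object$spikes
  hub <- object$topology$hub
  rates <- firing_frequency(sdw, c((sdw$t_start + sdw$t_end) / 2, sdw$t_end))
  m <- tryCatch(network_mpc(sdw, hub), error = function(e) NULL)
  cc <- tryCatch(network_cc(sdw, hub), error = function(e) NULL)
  out <- list(mean_rate = mean(rates), sd_rate = stats::sd(rates),
              mpc = m, cc = cc, n_spikes = sum(lengths(sdw$trains)))
  class(out) <- "summary.achnet_sim"
  out
}

#' @export
print.summary.achnet_sim <- function(x, ...) {
  cat("Second-half mean rate:", round(x$mean_rate, 2), "Hz ( SD",
      round(x$sd_rate, 2), ")\n")
  if (!is.null(x$mpc)) cat("Network MPC:", round(x$mpc$global, 3), "\n")
  if (!is.null(x$cc)) cat("Network CC: ", round(x$cc$global, 3), "\n")
  invisible(x)
}

#' Raster plot of a simulation
#'
#' @param x an \code{"achnet_sim"}.
#' @param order_by_degree sort neurons by descending total degree (hubs at
#'   the bottom).
#' @param ... passed to [graphics::plot()].
#' @export
plot.achnet_sim <- function(x, order_by_degree = TRUE, ...) {
  sdw <- x$spikes
  n <- length(sdw$trains)
  ord <- if (order_by_degree) x$topology$degree_rank else seq_len(n)
  pos <- integer(n)
  pos[ord] <- seq_len(n)
  t_all <- unlist(sdw$trains, use.names = FALSE)
  y <- rep(pos, lengths(sdw$trains))
  graphics::plot(t_all, y, pch = ".", cex = 1.5, xlab = "time (ms)",
                 ylab = "neuron (by degree rank)", ...)
  invisible(x)
}
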