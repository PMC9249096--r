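#' Synaptic kinetics parameters
#'
#' Double-exponential conductance kernel
#' \code{K(s) = exp(-s/tau_d) - exp(-s/tau_r)} triggered by each presynaptic
#' spike; excitatory synapses reverse at 0 mV, inhibitory at -75 mV.
#'
#' @param tau_d decay time constant (ms).
#' @param tau_r rise time constant (ms); must satisfy \code{tau_d > tau_r}.
#' @param E_syn_exc,E_syn_inh reversal potentials (mV).
#' @param kernel_cutoff age (ms) beyond which a spike's kernel contribution
#'   is treated as zero in the event-driven sum; at the default 10*tau_d the
#'   truncated tail is below 5e-5 of the kernel peak.
#' @return A list of class \code{"synapse_params"}.
#' @export
synapse_params <- function(tau_d = 0.5, tau_r = 0.2, E_syn_exc = 0,
                           E_syn_inh = -75, kernel_cutoff = 10 * tau_d) {
  stopifnot(tau_d > tau_r, tau_r > 0, kernel_cutoff >= 5 * tau_d)
  structure(list(tau_d = tau_d, tau_r = tau_r, E_syn_exc = E_syn_exc,
                 E_syn_inh = E_syn_inh, kernel_cutoff = kernel_cutoff),
            class = "synapse_params")
}

#' Plasticity (STDP) parameters
#'
#' Fully asymmetric pair-based rule: a presynaptic spike preceding a
#' postsynaptic spike by \code{0 < dt <= pairing_window} potentiates the
#' synapse by \code{A_L * exp(-dt/tau_STDP)}; the reverse order depresses by
#' the same magnitude. Weights are clipped to \code{[0, w_max]} and synapses
#' absent at initialization are never created.
#'
#' @param A_L maximal weight change per pairing (mS/cm2). The default 0.002
#'   follows the model description; 0.0002 (an alternative stated elsewhere
#'   in the source material's parameter table) is also supported.
#' @param tau_STDP exponential decay constant of the pairing window (ms).
#' @param w_max upper weight bound (mS/cm2), conventionally \code{2 * w0}.
#' @param pairing_window maximal |spike-time difference| that contributes (ms).
#' @param enabled logical flag.
#' @return A list of class \code{"plasticity_params"}.
#' @export
plasticity_params <- function(A_L = 0.002, tau_STDP = 10, w_max = 0.08,
                              pairing_window = 40, enabled = TRUE) {
  stopifnot(A_L >= 0, tau_STDP > 0, w_max >= 0, pairing_window > 0)
  structure(list(A_L = A_L, tau_STDP = tau_STDP, w_max = w_max,
                 pairing_window = pairing_window, enabled = enabled),
            class = "plasticity_params")
}

#' Double-exponential synaptic kernel
#'
#' @param s time since the presynaptic spike (ms), vectorized; negative ages
#'   return 0.
#' @param params a [synapse_params()].
#' @return Kernel values (dimensionless conductance gate).
#' @export
synaptic_kernel <- function(s, params = synapse_params()) {
  ifelse(s >= 0, exp(-s / params$tau_d) - exp(-s / params$tau_r), 0)
}

#' Event-driven synaptic current
#'
#' Total synaptic current onto each neuron at time \code{t}:
#' \code{I_i = sum_j w_ij * sum_k K(t - t_jk) * (V_i - E_syn(j))}, summing
#' over presynaptic neurons \code{j} and their spikes \code{t_jk <= t};
#' contributions older than the kernel cutoff are dropped.
#'
#' @param weights n x n weight matrix (entry \code{[i, j]}: presynaptic j to
#'   postsynaptic i, mS/cm2).
#' @param spike_history list of per-neuron spike-time vectors (ms).
#' @param V per-neuron membrane voltage at \code{t} (mV).
#' @param t current time (ms).
#' @param params a [synapse_params()].
#' @param is_inhibitory per-neuron logical (presynaptic class).
#' @return Per-neuron current (uA/cm2), positive outward.
#' @export
synaptic_current <- function(weights, spike_history, V, t,
                             params = synapse_params(),
                             is_inhibitory = rep(FALSE, nrow(weights))) {
  n <- nrow(weights)
  kern <- numeric(n)
  for (j in seq_len(n)) {
    s <- t - spike_history[[j]]
    s <- s[s >= 0 & s <= params$kernel_cutoff]
    if (length(s)) kern[j] <- sum(synaptic_kernel(s, params))
  }
  E <- ifelse(is_inhibitory, params$E_syn_inh, params$E_syn_exc)
  # I_i = sum_j w_ij kern_j (V_i - E_j)
  V * drop(weights %*% kern) - drop(weights %*% (kern * E))
}

#' Pair-based STDP weight update at spike events
#'
#' Applies the asymmetric pairing rule for the spikes emitted in the current
#' integration step against the recent spike history (all-to-all pairing
#' within the window; simultaneous spikes contribute nothing). For each
#' neuron \code{i} spiking now, every existing synapse \code{w[i, j]} is
#' potentiated by \code{A_L * sum_k exp(-(t - t_jk)/tau_STDP)} over j's
#' recent spikes; for each neuron \code{j} spiking now, every existing
#' synapse \code{w[i, j]} is depressed analogously over i's recent spikes.
#' Updates are applied sequentially (all potentiations, then all
#' depressions), each clipped to \code{[0, w_max]}; zero synapses in
#' \code{adjacency} are never created.
#'
#' @param weights n x n weight matrix (post x pre, mS/cm2).
#' @param adjacency n x n logical matrix of synapses existing at
#'   initialization.
#' @param new_spikes integer indices of neurons spiking at time \code{t}.
#' @param t spike-event time (ms).
#' @param spike_history list of per-neuron spike-time vectors strictly
#'   before \code{t}.
#' @param params a [plasticity_params()].
#' @return The updated weight matrix.
#' @export
stdp_update <- function(weights, adjacency, new_spikes, t, spike_history,
                        params = plasticity_params()) {
  if (!params$enabled || params$A_L == 0 || length(new_spikes) == 0)
    return(weights)
  n <- nrow(weights)
  r <- vapply(seq_len(n), function(j) {
    d <- t - spike_history[[j]]
    d <- d[d > 0 & d <= params$pairing_window]
    sum(exp(-d / params$tau_STDP))
  }, numeric(1))
  for (i in new_spikes) {  # post spiked now: potentiate w[i, ]
    upd <- adjacency[i, ] & r > 0
    weights[i, upd] <- pmin(weights[i, upd] + params$A_L * r[upd],
                            params$w_max)
  }
  for (j in new_spikes) {  # pre spiked now: depress w[, j]
    upd <- adjacency[, j] & r > 0
    weights[upd, j] <- pmax(weights[upd, j] - params$A_L * r[upd], 0)
  }
  weights
}
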