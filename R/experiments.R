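# Protocol drivers. Every experiment repeats its condition over n_trials
# fully independent realizations (fresh topology, fresh initial conditions,
# fresh noise; trial k uses seed + k - 1) and reports trial means with
# standard errors, mirroring the ensemble statistics of the study design.

se <- function(x) stats::sd(x) / sqrt(length(x))

trial_config <- function(base, trial, ...) {
  dots <- list(...)
  for (nm in names(dots)) base[[nm]] <- dots[[nm]]
  base$seed <- base$seed + trial - 1
  class(base) <- "simulation_config"
  base
}

# second-half MPC/CC summaries restricted to a neuron subset
pair_summaries <- function(sim, neurons = NULL) {
  sdw <- sim$spikes
  hub <- sim$topology$hub
  if (is.null(neurons)) neurons <- seq_along(sdw$trains)
  hub <- intersect(hub, neurons)
  nonhub <- setdiff(neurons, hub)
  M <- mpc_matrix(sdw)
  Cc <- cc_matrix(sdw)
  diag(M) <- NA
  diag(Cc) <- NA
  avg <- function(X, a, b) {
    v <- X[a, b, drop = FALSE]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  rates <- firing_frequency(sdw, c((sdw$t_start + sdw$t_end) / 2, sdw$t_end))
  data.frame(mpc = avg(M, neurons, neurons),
             mpc_hub = avg(M, hub, hub),
             mpc_nonhub = avg(M, nonhub, nonhub),
             cc = avg(Cc, neurons, neurons),
             cc_hub = avg(Cc, hub, hub),
             cc_nonhub = avg(Cc, nonhub, nonhub),
             mean_rate = mean(rates[neurons]),
             sd_rate = stats::sd(rates[neurons]))
}

summarize_trials <- function(df, by) {
  num <- setdiff(names(df), c(by, "trial"))
  agg <- stats::aggregate(df[num], df[by], function(x) mean(x, na.rm = TRUE))
  ses <- stats::aggregate(df[num], df[by],
                          function(x) se(x[!is.na(x)]))
  names(ses)[match(num, names(ses))] <- paste0(num, "_se")
  merge(agg, ses, by = by)
}

#' Sweep M-current conductance and hub-orientation bias
#'
#' Runs \code{n_trials} independent simulations for every combination of
#' \code{g_Ks} and \code{p_in} and reports network MPC, CC, their hub /
#' non-hub block averages, and firing statistics (second-half analysis).
#'
#' @param base_config a [simulation_config()] supplying everything except
#'   the swept values.
#' @param gks_list M-current conductances (mS/cm2).
#' @param pin_list hub in-degree orientation probabilities.
#' @return List of class \code{"achnet_sweep"} with \code{trials} (one row
#'   per condition x trial) and \code{summary} (trial means and standard
#'   errors).
#' @export
gks_sweep <- function(base_config = simulation_config(),
                      gks_list = c(0, 0.5, 1, 1.5),
                      pin_list = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  rows <- list()
  for (pin in pin_list) for (gks in gks_list)
    for (tr in seq_len(base_config$n_trials)) {
      sim <- run_simulation(trial_config(base_config, tr, g_Ks = gks,
                                         p_in = pin))
      rows[[length(rows) + 1]] <-
        cbind(data.frame(g_Ks = gks, p_in = pin, trial = tr),
              pair_summaries(sim))
    }
  trials <- do.call(rbind, rows)
  structure(list(trials = trials,
                 summary = summarize_trials(trials, c("g_Ks", "p_in"))),
            class = "achnet_sweep")
}

#' Robustness sweeps over synaptic strength and noise amplitude
#'
#' Repeats the g_Ks sweep at several uniform synaptic conductances
#' (\code{gsyn_list}) and, separately, at several noise-pulse amplitudes
#' delivered sparsely (initiation probability 0.001 per step, the
#' high-amplitude low-rate noise paradigm).
#'
#' @inheritParams gks_sweep
#' @param gsyn_list synaptic conductances (mS/cm2).
#' @param noise_list noise pulse amplitudes (uA/cm2).
#' @param noise_prob initiation probability per step for the noise grid.
#' @param gks_list conductances crossed with both grids.
#' @return List with two \code{"achnet_sweep"} objects, \code{gsyn} and
#'   \code{noise}.
#' @export
robustness_sweeps <- function(base_config = simulation_config(),
                              gsyn_list = c(0.02, 0.04, 0.06, 0.08),
                              noise_list = c(1.5, 2.5, 3.0, 4.0),
                              noise_prob = 0.001,
                              gks_list = c(0, 0.5, 1, 1.5)) {
  g_rows <- list()
  for (gs in gsyn_list) for (gks in gks_list)
    for (tr in seq_len(base_config$n_trials)) {
      cfg <- trial_config(base_config, tr, g_Ks = gks, g_syn = gs)
      cfg$plasticity$w_max <- 2 * gs
      sim <- run_simulation(cfg)
      g_rows[[length(g_rows) + 1]] <-
        cbind(data.frame(g_syn = gs, g_Ks = gks, trial = tr),
              pair_summaries(sim))
    }
  n_rows <- list()
  for (na in noise_list) for (gks in gks_list)
    for (tr in seq_len(base_config$n_trials)) {
      cfg <- trial_config(base_config, tr, g_Ks = gks)
      cfg$stimulus$noise_amplitude <- na
      cfg$stimulus$noise_prob_per_step <- noise_prob
      sim <- run_simulation(cfg)
      n_rows[[length(n_rows) + 1]] <-
        cbind(data.frame(noise_amp = na, g_Ks = gks, trial = tr),
              pair_summaries(sim))
    }
  gt <- do.call(rbind, g_rows)
  nt <- do.call(rbind, n_rows)
  list(gsyn = structure(list(trials = gt,
                             summary = summarize_trials(gt, c("g_syn", "g_Ks"))),
                        class = "achnet_sweep"),
       noise = structure(list(trials = nt,
                              summary = summarize_trials(nt, c("noise_amp", "g_Ks"))),
                         class = "achnet_sweep"))
}

#' Excitatory-only versus mixed E-I network comparison
#'
#' For each inhibitory fraction and g_Ks, runs matched pairs of simulations
#' (excitatory-only and mixed, same trial seed) and reports the E-minus-E-I
#' differences of MPC and CC within the excitatory hub and non-hub blocks.
#'
#' @inheritParams gks_sweep
#' @param inhibitory_fractions fractions of inhibitory cells.
#' @return \code{"achnet_sweep"} with difference columns
#'   (\code{d_mpc_hub}, \code{d_mpc_nonhub}, \code{d_cc_hub},
#'   \code{d_cc_nonhub}).
#' @export
ei_comparison <- function(base_config = simulation_config(),
                          inhibitory_fractions = 0.10,
                          gks_list = c(0, 0.5, 1, 1.5)) {
  rows <- list()
  for (fr in inhibitory_fractions) for (gks in gks_list)
    for (tr in seq_len(base_config$n_trials)) {
      sim_e <- run_simulation(trial_config(base_config, tr, g_Ks = gks,
                                           inhibitory_fraction = 0))
      sim_ei <- run_simulation(trial_config(base_config, tr, g_Ks = gks,
                                            inhibitory_fraction = fr))
      exc <- which(!sim_ei$topology$is_inhibitory)
      s_e <- pair_summaries(sim_e)
      s_ei <- pair_summaries(sim_ei, neurons = exc)
      rows[[length(rows) + 1]] <- data.frame(
        inhibitory_fraction = fr, g_Ks = gks, trial = tr,
        d_mpc_hub = s_e$mpc_hub - s_ei$mpc_hub,
        d_mpc_nonhub = s_e$mpc_nonhub - s_ei$mpc_nonhub,
        d_cc_hub = s_e$cc_hub - s_ei$cc_hub,
        d_cc_nonhub = s_e$cc_nonhub - s_ei$cc_nonhub)
    }
  trials <- do.call(rbind, rows)
  structure(list(trials = trials,
                 summary = summarize_trials(trials,
                                            c("inhibitory_fraction", "g_Ks"))),
            class = "achnet_sweep")
}

#' Hub-removal experiment
#'
#' Simulates 2 s with the intact network, then zeroes every synapse incoming
#' to or outgoing from the hub neurons and continues for 2 more seconds
#' (state variables carry over). MPC and CC among the surviving (non-hub)
#' neurons are compared between the second halves of the two segments.
#'
#' @inheritParams gks_sweep
#' @param segment_ms duration of each segment (ms).
#' @return \code{"achnet_sweep"} with pre, post and pre-minus-post columns.
#' @export
hub_removal_experiment <- function(base_config = simulation_config(),
                                   gks_list = c(0, 1.5),
                                   segment_ms = 2000) {
  rows <- list()
  for (gks in gks_list) for (tr in seq_len(base_config$n_trials)) {
    cfg <- trial_config(base_config, tr, g_Ks = gks)
    set.seed(cfg$seed)
    topo <- build_network(cfg$n, cfg$z_passes, cfg$p_in,
                          cfg$inhibitory_fraction, cfg$g_syn, cfg$w_inh,
                          cfg$hub_fraction)
    b <- init_sim_bundle(topo, cfg)
    b <- advance_segment(b, cfg, segment_ms, gks, FALSE)
    removed <- remove_hub(topo)
    b$W <- removed$weights
    b <- advance_segment(b, cfg, segment_ms, gks, FALSE)
    sdw <- bundle_spikes(b)
    nonhub <- setdiff(which(!topo$is_inhibitory), topo$hub)
    win_pre <- c(segment_ms / 2, segment_ms)
    win_post <- c(segment_ms * 1.5, segment_ms * 2)
    avg <- function(win, fn) {
      X <- fn(sdw, window = win)
      diag(X) <- NA
      v <- X[nonhub, nonhub]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }
    mpc_pre <- avg(win_pre, mpc_matrix); mpc_post <- avg(win_post, mpc_matrix)
    cc_pre <- avg(win_pre, cc_matrix); cc_post <- avg(win_post, cc_matrix)
    rows[[length(rows) + 1]] <- data.frame(
      g_Ks = gks, trial = tr, mpc_pre = mpc_pre, mpc_post = mpc_post,
      cc_pre = cc_pre, cc_post = cc_post,
      d_mpc = mpc_pre - mpc_post, d_cc = cc_pre - cc_post)
  }
  trials <- do.call(rbind, rows)
  structure(list(trials = trials, summary = summarize_trials(trials, "g_Ks")),
            class = "achnet_sweep")
}

#' STDP-driven synaptic reorganization by network region
#'
#' Runs plastic simulations (default 3 s) and reports the normalized
#' synaptic change ([region_delta()]) in the four hub-defined regions,
#' averaged over trials.
#'
#' @inheritParams gks_sweep
#' @param duration plastic simulation length (ms).
#' @return List of class \code{"achnet_sweep"}; \code{trials} has one row
#'   per (g_Ks, p_in, trial, region).
#' @export
stdp_reorganization <- function(base_config = simulation_config(),
                                gks_list = c(0, 1.5),
                                pin_list = c(0.1, 0.5, 0.9),
                                duration = 3000) {
  rows <- list()
  for (pin in pin_list) for (gks in gks_list)
    for (tr in seq_len(base_config$n_trials)) {
      cfg <- trial_config(base_config, tr, g_Ks = gks, p_in = pin,
                          duration = duration)
      cfg$plasticity$enabled <- TRUE
      sim <- run_simulation(cfg)
      rd <- region_delta(sim$w_before, sim$w_after, sim$topology$hub,
                         w0 = cfg$g_syn, adjacency = sim$adj_plastic)
      rows[[length(rows) + 1]] <-
        cbind(data.frame(g_Ks = gks, p_in = pin, trial = tr), rd)
    }
  trials <- do.call(rbind, rows)
  structure(list(trials = trials,
                 summary = summarize_trials(trials,
                                            c("g_Ks", "p_in", "region"))),
            class = "achnet_sweep")
}

#' Wake-sleep-wake protocol: frequency renormalization by plasticity
#'
#' Nine seconds per trial: 3 s at \code{g_Ks = 0} with frozen weights
#' (wake), 3 s at \code{g_Ks = 1.5} with STDP enabled (slow-wave sleep),
#' 3 s back at \code{g_Ks = 0} with frozen weights. Firing frequency is
#' measured over the latter 2 s of each wake segment; the per-neuron change
#' \code{df = f_post - f_pre} is regressed on \code{f_pre}. Slope and R2 are
#' reported per trial, and pooled from per-neuron points averaged across
#' trials after aligning neurons by descending-degree rank (each trial has a
#' fresh topology, so ranks are the comparable unit).
#'
#' @inheritParams gks_sweep
#' @param wake_gks,sleep_gks conductances of the wake and sleep states.
#' @param segment_ms segment duration (ms).
#' @return List of class \code{"wsw_result"}: \code{per_trial} (slope, R2,
#'   mean df per trial), \code{points} (rank-averaged f_pre, df),
#'   \code{slope}, \code{r_squared} (pooled fit), \code{slope_trial_mean},
#'   \code{slope_trial_se}.
#' @export
wake_sleep_wake <- function(base_config = simulation_config(),
                            wake_gks = 0, sleep_gks = 1.5,
                            segment_ms = 3000) {
  n_tr <- base_config$n_trials
  per_trial <- list()
  fpre_mat <- NULL
  df_mat <- NULL
  for (tr in seq_len(n_tr)) {
    cfg <- trial_config(base_config, tr)
    set.seed(cfg$seed)
    topo <- build_network(cfg$n, cfg$z_passes, cfg$p_in,
                          cfg$inhibitory_fraction, cfg$g_syn, cfg$w_inh,
                          cfg$hub_fraction)
    b <- init_sim_bundle(topo, cfg)
    b <- advance_segment(b, cfg, segment_ms, wake_gks, FALSE)
    b <- advance_segment(b, cfg, segment_ms, sleep_gks, TRUE)
    b <- advance_segment(b, cfg, segment_ms, wake_gks, FALSE)
    sdw <- bundle_spikes(b)
    f_pre <- firing_frequency(sdw, c(segment_ms - 2000, segment_ms))
    f_post <- firing_frequency(sdw, c(3 * segment_ms - 2000, 3 * segment_ms))
    df <- f_post - f_pre
    fit <- stats::lm(df ~ f_pre)
    per_trial[[tr]] <- data.frame(trial = tr,
                                  slope = unname(stats::coef(fit)[2]),
                                  r_squared = summary(fit)$r.squared,
                                  mean_df = mean(df))
    ord <- topo$degree_rank
    fpre_mat <- cbind(fpre_mat, f_pre[ord])
    df_mat <- cbind(df_mat, df[ord])
  }
  pts <- data.frame(f_pre = rowMeans(fpre_mat), df = rowMeans(df_mat))
  pooled <- stats::lm(df ~ f_pre, data = pts)
  per_trial <- do.call(rbind, per_trial)
  structure(list(per_trial = per_trial, points = pts,
                 slope = unname(stats::coef(pooled)[2]),
                 r_squared = summary(pooled)$r.squared,
                 slope_trial_mean = mean(per_trial$slope),
                 slope_trial_se = se(per_trial$slope)),
            class = "wsw_result")
}

#' @export
print.achnet_sweep <- function(x, ...) {
  cat("Experiment sweep:", nrow(x$trials), "trial rows\n")
  print(utils::head(x$summary, 20))
  if (nrow(x$summary) > 20) cat("...\n")
  invisible(x)
}

#' @export
print.wsw_result <- function(x, ...) {
  cat("Wake-sleep-wake experiment (", nrow(x$per_trial), "trials )\n")
  cat("  pooled fit on rank-averaged points: slope =",
      round(x$slope, 3), ", R2 =", round(x$r_squared, 4), "\n")
  cat("  per-trial slope:", round(x$slope_trial_mean, 3), "+/-",
      round(x$slope_trial_se, 3), "(SE)\n")
  invisible(x)
}

#' @export
plot.wsw_result <- function(x, ...) {
  graphics::plot(x$points$f_pre, x$points$df,
                 xlab = "initial frequency (Hz)",
                 ylab = "frequency change (Hz)", pch = 16, cex = 0.6, ...)
  graphics::abline(stats::lm(df ~ f_pre, data = x$points), col = 2)
  invisible(x)
}
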