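#' Spike data container
#'
#' Per-neuron sorted spike-time lists over a recording window.
#'
#' @param trains list of strictly increasing numeric vectors (ms).
#' @param t_start,t_end recording window (ms).
#' @return A list of class \code{"spike_data"}.
#' @export
spike_data <- function(trains, t_start, t_end) {
  stopifnot(is.list(trains), t_end > t_start)
  for (tr in trains) {
    if (is.unsorted(tr, strictly = TRUE)) stop("spike trains must be strictly increasing")
    if (length(tr) && (tr[1] < t_start || tr[length(tr)] > t_end))
      stop("spike times outside the recording window")
  }
  structure(list(trains = trains, t_start = t_start, t_end = t_end),
            class = "spike_data")
}

# restrict to a window; default analysis window is the second half of the
# recording (transients from initial conditions are discarded)
window_spikes <- function(sd, window = NULL) {
  if (is.null(window)) window <- c((sd$t_start + sd$t_end) / 2, sd$t_end)
  trains <- lapply(sd$trains, function(tr) tr[tr >= window[1] & tr <= window[2]])
  spike_data(trains, window[1], window[2])
}

#' @export
print.spike_data <- function(x, ...) {
  n_spk <- sum(lengths(x$trains))
  cat("Spike data:", length(x$trains), "neurons,", n_spk, "spikes in [",
      x$t_start, ",", x$t_end, "] ms ( mean rate",
      round(n_spk / length(x$trains) / ((x$t_end - x$t_start) / 1000), 2),
      "Hz )\n")
  invisible(x)
}

#' Pairwise mean phase coherence
#'
#' Phase-locks train j against the interspike intervals of reference train i:
#' each spike of j falling inside i's span is assigned the phase
#' \code{2*pi*(t_jk - t_ik)/(t_ik+1 - t_ik)} within the enclosing interval of
#' i, and the coherence is the resultant length of \code{exp(1i*phase)}.
#' 1 = perfect phase locking, near 0 = no phase relation.
#'
#' @param train_i reference spike train (>= 2 spikes).
#' @param train_j test spike train.
#' @return Coherence in \code{[0, 1]}, or \code{NA} if undefined (too few
#'   spikes of i, or no spike of j inside i's span).
#' @export
mean_phase_coherence <- function(train_i, train_j) {
  if (length(train_i) < 2 || length(train_j) < 1) return(NA_real_)
  k <- findInterval(train_j, train_i)
  ok <- k >= 1 & k < length(train_i)
  if (!any(ok)) return(NA_real_)
  k <- k[ok]
  phi <- 2 * pi * (train_j[ok] - train_i[k]) / (train_i[k + 1] - train_i[k])
  sqrt(mean(cos(phi))^2 + mean(sin(phi))^2)
}

#' Pairwise mean-phase-coherence matrix
#'
#' Entry \code{[i, j]} is [mean_phase_coherence()] with i as reference,
#' computed on the analysis window (default: second half of the recording).
#' Neurons with fewer than \code{min_spikes} spikes in the window are masked
#' (NA rows/columns).
#'
#' @param sd a [spike_data()] object.
#' @param window analysis window \code{c(t0, t1)} in ms, or \code{NULL} for
#'   the second half of the recording.
#' @param min_spikes minimal spike count for a neuron to enter the matrix.
#' @return An n x n matrix with NA on undefined pairs.
#' @export
mpc_matrix <- function(sd, window = NULL, min_spikes = 2) {
  sdw <- window_spikes(sd, window)
  trains <- sdw$trains
  n <- length(trains)
  keep <- lengths(trains) >= min_spikes
  all_t <- unlist(trains[keep], use.names = FALSE)
  all_id <- rep(which(keep), lengths(trains[keep]))
  M <- matrix(NA_real_, n, n)
  for (i in which(keep)) {
    ti <- trains[[i]]
    k <- findInterval(all_t, ti)
    ok <- k >= 1 & k < length(ti)
    if (!any(ok)) next
    kk <- k[ok]
    phi <- 2 * pi * (all_t[ok] - ti[kk]) / (ti[kk + 1] - ti[kk])
    cs <- rowsum(cbind(cos(phi), sin(phi), 1), all_id[ok])
    j <- as.integer(rownames(cs))
    M[i, j] <- sqrt(cs[, 1]^2 + cs[, 2]^2) / cs[, 3]
  }
  M
}

# average a pairwise matrix over ordered pairs i != j, optionally by blocks
block_average <- function(M, hub) {
  n <- nrow(M)
  diag(M) <- NA
  nonhub <- setdiff(seq_len(n), hub)
  avg <- function(idx_i, idx_j) {
    v <- M[idx_i, idx_j, drop = FALSE]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  list(global = avg(seq_len(n), seq_len(n)),
       hub = avg(hub, hub),
       nonhub = avg(nonhub, nonhub),
       hub_minus_nonhub = avg(hub, hub) - avg(nonhub, nonhub))
}

#' Network-average mean phase coherence
#'
#' Mean of defined ordered-pair coherences, with within-hub and
#' within-non-hub block averages and their difference.
#'
#' @inheritParams mpc_matrix
#' @param hub integer indices of hub neurons.
#' @return List \code{global}, \code{hub}, \code{nonhub},
#'   \code{hub_minus_nonhub}.
#' @export
network_mpc <- function(sd, hub = integer(0), window = NULL) {
  M <- mpc_matrix(sd, window)
  diag(M) <- NA
  if (all(is.na(M))) stop("insufficient spiking: no defined pairs")
  block_average(M, hub)
}

# Gaussian-smoothed, mean-subtracted binned spike trains on a window
smooth_trains <- function(trains, t0, t1, dt = 0.1, sigma = 1) {
  nb <- max(1L, floor((t1 - t0) / dt))
  n <- length(trains)
  Mx <- matrix(0, nb, n)
  for (j in seq_len(n)) {
    tr <- trains[[j]]
    tr <- tr[tr >= t0 & tr <= t1]
    if (length(tr)) {
      b <- pmin(pmax(floor((tr - t0) / dt) + 1L, 1L), nb)
      cnt <- tabulate(b, nbins = nb)
      Mx[, j] <- cnt
    }
  }
  half <- ceiling(5 * sigma / dt)
  kern <- stats::dnorm(seq(-half, half) * dt, sd = sigma)
  kern <- kern / sum(kern * dt) * dt  # unit area at resolution dt
  pad <- matrix(0, half, n)
  Mp <- rbind(pad, Mx, pad)
  sm <- stats::filter(Mp, kern, method = "convolution", sides = 2)
  sm <- sm[(half + 1):(half + nb), , drop = FALSE]
  sweep(sm, 2, colMeans(sm))
}

#' Zero-lag cross-correlation of two spike trains
#'
#' Both trains are binned at \code{dt}, convolved with a unit-area Gaussian
#' of width \code{sigma_gauss}, mean-subtracted, and correlated at zero lag
#' (normalized inner product). This is the network "synchrony" measure.
#'
#' @param train_i,train_j spike-time vectors (ms).
#' @param sigma_gauss Gaussian width (ms).
#' @param dt bin size (ms).
#' @param window analysis window \code{c(t0, t1)}; defaults to the joint
#'   span of the two trains.
#' @return Correlation in \code{[-1, 1]}, or NA for a zero-variance trace.
#' @export
cross_correlation <- function(train_i, train_j, sigma_gauss = 1, dt = 0.1,
                              window = NULL) {
  if (length(train_i) == 0 || length(train_j) == 0) return(NA_real_)
  if (is.null(window)) window <- range(c(train_i, train_j)) + c(-1, 1) * 5 * sigma_gauss
  S <- smooth_trains(list(train_i, train_j), window[1], window[2], dt,
                     sigma_gauss)
  den <- sqrt(sum(S[, 1]^2) * sum(S[, 2]^2))
  if (den == 0) return(NA_real_)
  sum(S[, 1] * S[, 2]) / den
}

#' Pairwise zero-lag cross-correlation matrix
#'
#' @inheritParams mpc_matrix
#' @param sigma_gauss Gaussian width (ms).
#' @param dt bin size (ms).
#' @return An n x n symmetric matrix; zero-variance neurons and neurons with
#'   fewer than \code{min_spikes} spikes are masked.
#' @export
cc_matrix <- function(sd, window = NULL, sigma_gauss = 1, dt = 0.1,
                      min_spikes = 2) {
  sdw <- window_spikes(sd, window)
  n <- length(sdw$trains)
  keep <- lengths(sdw$trains) >= min_spikes
  M <- matrix(NA_real_, n, n)
  if (!any(keep)) return(M)
  S <- smooth_trains(sdw$trains[keep], sdw$t_start, sdw$t_end, dt, sigma_gauss)
  nrm <- sqrt(colSums(S^2))
  ok <- nrm > 0
  if (any(ok)) {
    idx <- which(keep)[ok]
    Sn <- sweep(S[, ok, drop = FALSE], 2, nrm[ok], `/`)
    M[idx, idx] <- crossprod(Sn)
  }
  M
}

#' Network-average zero-lag cross-correlation
#'
#' @inheritParams network_mpc
#' @return List \code{global}, \code{hub}, \code{nonhub},
#'   \code{hub_minus_nonhub}.
#' @export
network_cc <- function(sd, hub = integer(0), window = NULL) {
  M <- cc_matrix(sd, window)
  diag(M) <- NA
  if (all(is.na(M))) stop("insufficient spiking: no defined pairs")
  block_average(M, hub)
}

#' Average minimal distance (AMD) to the preceding spikes of another train
#'
#' Mean, over the spikes of train i, of the time elapsed since the most
#' recent preceding spike of train j; spikes of i before j's first spike are
#' dropped from the average.
#'
#' @param train_i,train_j spike-time vectors (ms).
#' @return Mean preceding distance (ms), or NA if no usable spikes.
#' @export
amd <- function(train_i, train_j) {
  if (length(train_i) == 0 || length(train_j) == 0) return(NA_real_)
  k <- findInterval(train_i, train_j)
  ok <- k >= 1
  if (!any(ok)) return(NA_real_)
  mean(train_i[ok] - train_j[k[ok]])
}

#' AMD Z-scores and asymmetry matrix
#'
#' Z-scores each pairwise AMD against the analytic null of spikes placed
#' uniformly at random on the reference train's interval structure: with
#' interspike intervals L of train j spanning total time T, the preceding
#' distance has mean \code{mu1 = sum(L^2)/(2T)} and SD
#' \code{sqrt(mu2 - mu1^2)} with \code{mu2 = sum(L^3)/(3T)}. AMD is the
#' mean over the N usable spikes of i, so its null standard error is
#' \code{sd_j/sqrt(N)} and \code{Z[i, j] = (AMD[i, j] - mu1_j)/(sd_j/
#' sqrt(N))}. (The single-distance normalization without the sqrt(N)
#' factor cannot exceed |Z| = sqrt(3): the preceding-distance density is
#' non-increasing, bounding sd/mu from below at 1/sqrt(3); the +/-2
#' significance threshold only makes sense on the standard-error scale.)
#' \code{Z[i, j] < -2} flags significant locking of i shortly after j.
#' The asymmetry matrix \code{Z - t(Z)} quantifies which train reliably
#' leads.
#'
#' @inheritParams mpc_matrix
#' @return List with matrices \code{amd}, \code{z}, \code{asymmetry} and the
#'   per-neuron null moments \code{mu}, \code{sd}.
#' @export
amd_zscore <- function(sd, window = NULL, min_spikes = 2) {
  sdw <- window_spikes(sd, window)
  trains <- sdw$trains
  n <- length(trains)
  keep <- lengths(trains) >= min_spikes
  mu <- s <- rep(NA_real_, n)
  for (j in which(keep)) {
    L <- diff(trains[[j]])
    Tt <- sum(L)
    m1 <- sum(L^2) / (2 * Tt)
    m2 <- sum(L^3) / (3 * Tt)
    v <- m2 - m1^2
    if (is.finite(v) && v > 0) {
      mu[j] <- m1
      s[j] <- sqrt(v)
    }
  }
  A <- Nm <- matrix(NA_real_, n, n)
  all_t <- unlist(trains[keep], use.names = FALSE)
  all_id <- rep(which(keep), lengths(trains[keep]))
  for (j in which(keep)) {
    tj <- trains[[j]]
    k <- findInterval(all_t, tj)
    ok <- k >= 1
    if (!any(ok)) next
    dsum <- rowsum(cbind(all_t[ok] - tj[k[ok]], 1), all_id[ok])
    i <- as.integer(rownames(dsum))
    A[i, j] <- dsum[, 1] / dsum[, 2]
    Nm[i, j] <- dsum[, 2]
  }
  Z <- sweep(sweep(A, 2, mu), 2, s, `/`) * sqrt(Nm)
  list(amd = A, z = Z, asymmetry = Z - t(Z), mu = mu, sd = s, n_used = Nm)
}

#' Region-resolved normalized synaptic weight change
#'
#' Compares two weight matrices over the four regions defined by hub
#' membership of the pre- and postsynaptic cell, normalizing the summed
#' change by (number of synapses in the region) x (initial weight):
#' \code{delta = sum(w_after - w_before) / (A * w0)}. A value of 1 means the
#' average synapse in the region doubled from \code{w0}.
#'
#' @param w_before,w_after n x n weight matrices (post x pre).
#' @param hub hub neuron indices.
#' @param w0 initial synaptic weight (mS/cm2).
#' @param adjacency logical matrix of existing synapses; defaults to the
#'   union of the nonzero patterns of the two matrices.
#' @return Data frame with columns \code{region}, \code{delta},
#'   \code{n_synapses}, classed \code{"region_delta"}. Regions with no
#'   synapses report NA.
#' @export
region_delta <- function(w_before, w_after, hub, w0 = 0.04,
                         adjacency = NULL) {
  if (!all(dim(w_before) == dim(w_after))) stop("mismatched matrices")
  stopifnot(w0 > 0)
  if (is.null(adjacency)) adjacency <- w_before != 0 | w_after != 0
  if (!all(dim(adjacency) == dim(w_before)))
    stop("mismatched sparsity pattern")
  n <- nrow(w_before)
  in_hub <- seq_len(n) %in% hub
  post_hub <- matrix(in_hub, n, n)        # row index = postsynaptic
  pre_hub <- matrix(in_hub, n, n, byrow = TRUE)
  regions <- list(hub_hub = post_hub & pre_hub,
                  hub_to_nonhub = !post_hub & pre_hub,
                  nonhub_to_hub = post_hub & !pre_hub,
                  nonhub_nonhub = !post_hub & !pre_hub)
  d <- w_after - w_before
  out <- data.frame(region = names(regions),
                    delta = NA_real_,
                    n_synapses = NA_integer_)
  for (k in seq_along(regions)) {
    sel <- regions[[k]] & adjacency
    A <- sum(sel)
    out$n_synapses[k] <- A
    if (A > 0) out$delta[k] <- sum(d[sel]) / (A * w0)
  }
  class(out) <- c("region_delta", "data.frame")
  out
}

#' Per-neuron firing frequency
#'
#' @param sd a [spike_data()] object.
#' @param window measurement window \code{c(t0, t1)} in ms; defaults to the
#'   full recording.
#' @return Numeric vector of rates (Hz).
#' @export
firing_frequency <- function(sd, window = NULL) {
  if (is.null(window)) window <- c(sd$t_start, sd$t_end)
  len_s <- (window[2] - window[1]) / 1000
  vapply(sd$trains,
         function(tr) sum(tr >= window[1] & tr <= window[2]) / len_s,
         numeric(1))
}

#' Spectrum of the simulated local field potential
#'
#' The LFP proxy is the summed membrane voltage of the (excitatory) neurons.
#' The signal is z-scored, Fourier transformed, and the one-sided power
#' spectrum returned together with the dominant frequency over 1-100 Hz.
#'
#' @param v either a numeric vector (pre-summed signal) or a time x neuron
#'   matrix of voltage traces, uniformly sampled.
#' @param dt sampling step (ms).
#' @return List of class \code{"lfp_spectrum"} with \code{freq} (Hz),
#'   \code{power}, and \code{dominant_freq} (Hz).
#' @export
lfp_spectrum <- function(v, dt = 0.1) {
  if (is.matrix(v)) v <- rowSums(v)
  N <- length(v)
  if (N * dt < 2000) warning("signal shorter than 2 s: poor frequency resolution")
  x <- (v - mean(v)) / stats::sd(v)
  P <- Mod(stats::fft(x))^2 / N
  fs <- 1000 / dt
  freq <- (seq_len(N) - 1) * fs / N
  half <- seq_len(floor(N / 2) + 1)
  freq <- freq[half]
  P <- P[half]
  band <- freq >= 1 & freq <= 100
  dom <- if (any(band)) freq[band][which.max(P[band])] else NA_real_
  structure(list(freq = freq, power = P, dominant_freq = dom),
            class = "lfp_spectrum")
}

#' @export
print.lfp_spectrum <- function(x, ...) {
  cat("LFP spectrum:", length(x$freq), "frequency bins, dominant frequency",
      round(x$dominant_freq, 2), "Hz\n")
  invisible(x)
}

#' @export
print.region_delta <- function(x, ...) {
  cat("Normalized synaptic change (delta_g_syn) by region:\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
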