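#' Write / read spike events as delimited text
#'
#' Two-column tab-separated event file (neuron index, spike time in ms) with
#' a comment header carrying the recording window.
#'
#' @param sd a [spike_data()] object.
#' @param path file path.
#' @export
write_spike_events <- function(sd, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# t_start=%.10g t_end=%.10g", sd$t_start, sd$t_end), con)
  writeLines("neuron\ttime_ms", con)
  df <- data.frame(neuron = rep(seq_along(sd$trains), lengths(sd$trains)),
                   time_ms = unlist(sd$trains, use.names = FALSE))
  df <- df[order(df$time_ms, df$neuron), ]
  utils::write.table(df, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
}

#' @rdname write_spike_events
#' @param n_neurons number of neurons (trains beyond the largest index seen
#'   are empty); defaults to the largest index in the file.
#' @return \code{read_spike_events}: a [spike_data()] object.
#' @export
read_spike_events <- function(path, n_neurons = NULL) {
  hdr <- readLines(path, n = 1)
  t_start <- as.numeric(sub(".*t_start=([^ ]+).*", "\\1", hdr))
  t_end <- as.numeric(sub(".*t_end=([^ ]+).*", "\\1", hdr))
  df <- utils::read.table(path, sep = "\t", skip = 2,
                          col.names = c("neuron", "time_ms"))
  if (is.null(n_neurons)) n_neurons <- max(df$neuron, 1)
  trains <- lapply(seq_len(n_neurons),
                   function(i) sort(df$time_ms[df$neuron == i]))
  spike_data(trains, t_start, t_end)
}

#' Write / read a dense weight matrix as tab-separated text
#'
#' Rows are postsynaptic neurons, columns presynaptic (entry \code{[i, j]} =
#' conductance of the synapse j -> i in mS/cm2).
#'
#' @param W numeric matrix.
#' @param path file path.
#' @export
write_weight_matrix <- function(W, path) {
  utils::write.table(W, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
}

#' @rdname write_weight_matrix
#' @return \code{read_weight_matrix}: a numeric matrix.
#' @export
read_weight_matrix <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}

#' Write the neuron companion table of a topology
#'
#' Tab-separated table with one row per neuron: index, class
#' (excitatory/inhibitory), hub membership and total degree.
#'
#' @param topology an \code{"sf_topology"}.
#' @param path file path.
#' @export
write_neuron_table <- function(topology, path) {
  n <- nrow(topology$weights)
  df <- data.frame(index = seq_len(n),
                   class = ifelse(topology$is_inhibitory, "inhibitory",
                                  "excitatory"),
                   is_hub = seq_len(n) %in% topology$hub,
                   degree = topology$degree)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}
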