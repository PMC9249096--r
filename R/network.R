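#' Multi-pass preferential-attachment scale-free graph
#'
#' Grows a simple undirected graph on \code{n} nodes by executing a
#' linearized-chord-diagram style growth process \code{z_passes} times over
#' the same node set, accumulating the union of edges. Within each pass nodes
#' enter one at a time and the new node attaches to one existing node chosen
#' with probability proportional to its degree accumulated across all passes
#' so far (the entering node in an empty graph attaches uniformly). No
#' self-connections or duplicate edges are created: draws that hit an
#' existing neighbour are redrawn, and a node already connected to every
#' earlier node falls back to a degree-weighted draw over the remaining
#' non-neighbours so that every pass contributes exactly \code{n - 1} edges.
#'
#' @param n number of nodes (>= 2).
#' @param z_passes number of growth passes; the resulting mean total degree
#'   is \code{2 * z_passes * (n - 1) / n}, i.e. about twice the target mean
#'   in-degree after orientation.
#' @param seed optional RNG seed set before growth.
#' @return A list of class \code{"sf_graph"} with elements \code{n},
#'   \code{edges} (two-column matrix, each row one undirected edge
#'   \code{i < j}) and \code{degree}.
#' @export
build_scale_free <- function(n = 250, z_passes = 15, seed = NULL) {
  if (n < 2) stop("invalid config: n must be >= 2")
  if (z_passes < 1) stop("invalid config: z_passes must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  deg <- numeric(n)
  # adjacency as a logical matrix: n is small (hundreds) in all protocols
  adj <- matrix(FALSE, n, n)
  e_from <- integer(z_passes * (n - 1))
  e_to <- integer(z_passes * (n - 1))
  n_e <- 0L
  for (pass in seq_len(z_passes)) {
    for (u in 2:n) {
      earlier <- seq_len(u - 1)
      nbr <- adj[earlier, u]
      if (all(nbr)) {
        # already tied to every earlier node: degree-weighted fallback over
        # all remaining non-neighbours, preserving the per-pass edge budget
        cand <- which(!adj[, u])
        cand <- cand[cand != u]
        if (length(cand) == 0L) next
        w <- deg[cand]
        if (sum(w) == 0) w <- w + 1
      } else {
        cand <- earlier[!nbr]
        w <- deg[cand]
        if (sum(w) == 0) w <- w + 1
      }
      # one uniform per attachment, inverse-CDF over candidates in index order
      tgt <- cand[findInterval(stats::runif(1) * sum(w), cumsum(w),
                               left.open = TRUE) + 1L]
      adj[u, tgt] <- adj[tgt, u] <- TRUE
      deg[u] <- deg[u] + 1
      deg[tgt] <- deg[tgt] + 1
      n_e <- n_e + 1L
      e_from[n_e] <- min(u, tgt)
      e_to[n_e] <- max(u, tgt)
    }
  }
  edges <- cbind(from = e_from[seq_len(n_e)], to = e_to[seq_len(n_e)])
  structure(list(n = n, edges = edges, degree = deg), class = "sf_graph")
}

#' Orient an undirected graph into a directed synaptic weight matrix
#'
#' Neurons are ranked by descending total degree (rank 1 = highest degree,
#' ties broken by lower index). For each undirected edge, a uniform draw
#' decides its direction: with probability \code{p_in} the edge points INTO
#' its higher-ranked (higher-degree) endpoint, otherwise out of it. Each
#' undirected edge becomes exactly one directed synapse of conductance
#' \code{w0}. \code{p_in} therefore tunes the in/out balance of the hubs:
#' 0.1 = "strong hub outgoing" ... 0.9 = "strong hub incoming".
#'
#' @param graph an \code{"sf_graph"} from [build_scale_free()].
#' @param p_in probability that an edge is oriented into its higher-degree
#'   endpoint.
#' @param w0 initial excitatory synaptic conductance (mS/cm2).
#' @param hub_fraction fraction of neurons labelled as hub (by total degree).
#' @param seed optional RNG seed set before the orientation draws.
#' @return An \code{"sf_topology"}: list with \code{weights} (n x n matrix,
#'   entry \code{[i, j]} = conductance of the synapse from presynaptic j onto
#'   postsynaptic i), \code{is_inhibitory}, \code{hub} (indices),
#'   \code{degree_rank} (permutation sorting neurons by descending degree)
#'   and \code{degree}.
#' @export
orient_edges <- function(graph, p_in, w0 = 0.04, hub_fraction = 0.1,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!inherits(graph, "sf_graph")) stop("invalid input: expected sf_graph")
  if (anyDuplicated(graph$edges) || any(graph$edges[, 1] == graph$edges[, 2]))
    stop("invalid input: graph must be simple")
  stopifnot(p_in >= 0, p_in <= 1, w0 >= 0)
  n <- graph$n
  rank_of <- integer(n)
  degree_rank <- order(-graph$degree, seq_len(n))
  rank_of[degree_rank] <- seq_len(n)
  W <- matrix(0, n, n)
  a <- graph$edges[, 1]
  b <- graph$edges[, 2]
  swap <- rank_of[b] < rank_of[a]  # ensure a = higher-ranked (lower rank no.)
  hi <- ifelse(swap, b, a)
  lo <- ifelse(swap, a, b)
  into_hi <- stats::runif(nrow(graph$edges)) < p_in
  pre <- ifelse(into_hi, lo, hi)
  post <- ifelse(into_hi, hi, lo)
  W[cbind(post, pre)] <- w0
  topo <- structure(list(weights = W, is_inhibitory = rep(FALSE, n),
                         hub = integer(0), degree_rank = degree_rank,
                         degree = graph$degree, w0 = w0),
                    class = "sf_topology")
  topo$hub <- identify_hub(topo, hub_fraction)
  topo
}

#' Identify hub neurons
#'
#' Hubs are the top \code{fraction} (default 10\%) of excitatory neurons by
#' total degree (in + out), i.e. \code{round(fraction * n_excitatory)} cells;
#' ties at the boundary are broken in favour of the lower neuron index.
#'
#' @param topology an \code{"sf_topology"}.
#' @param fraction fraction of excitatory neurons labelled hub, in (0, 1).
#' @return Integer vector of hub indices (sorted).
#' @export
identify_hub <- function(topology, fraction = 0.1) {
  if (fraction <= 0 || fraction >= 1)
    stop("invalid config: fraction must be in (0, 1)")
  exc <- which(!topology$is_inhibitory)
  if (length(exc) < 1) stop("no excitatory neurons")
  deg <- topology$degree[exc]
  k <- round(fraction * length(exc))
  ord <- order(-deg, exc)
  sort(exc[ord[seq_len(k)]])
}

#' Build a network topology (excitatory scale-free, optionally mixed E-I)
#'
#' The excitatory population forms an oriented scale-free network
#' ([build_scale_free()] then [orient_edges()]). With
#' \code{inhibitory_fraction > 0}, that population shrinks to
#' \code{n - round(inhibitory_fraction * n)} cells and the remaining cells
#' are inhibitory, wired uniformly at random: each inhibitory neuron receives
#' \code{K = z_passes} directed inputs from distinct excitatory neurons and
#' sends \code{K} directed outputs (conductance \code{w_inh}) to distinct
#' neurons of any class.
#'
#' @param n total neuron count.
#' @param z_passes growth passes of the scale-free builder.
#' @param p_in hub in-degree orientation probability.
#' @param inhibitory_fraction fraction of inhibitory cells in \code{[0, 1)}.
#' @param w0_exc initial excitatory conductance (mS/cm2).
#' @param w_inh inhibitory conductance (mS/cm2).
#' @param hub_fraction fraction of excitatory cells labelled hub.
#' @param seed optional RNG seed set before construction.
#' @return An \code{"sf_topology"} (see [orient_edges()]); inhibitory cells
#'   occupy the trailing indices and have no scale-free rank.
#' @export
build_network <- function(n = 250, z_passes = 15, p_in = 0.5,
                          inhibitory_fraction = 0, w0_exc = 0.04,
                          w_inh = 0.01, hub_fraction = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inhibitory_fraction < 0 || inhibitory_fraction >= 1)
    stop("invalid config: inhibitory_fraction must be in [0, 1)")
  stopifnot(w0_exc >= 0, w_inh >= 0)
  n_inh <- round(inhibitory_fraction * n)
  n_exc <- n - n_inh
  g <- build_scale_free(n_exc, z_passes)
  topo <- orient_edges(g, p_in, w0 = w0_exc, hub_fraction = hub_fraction)
  if (n_inh == 0) return(topo)
  W <- matrix(0, n, n)
  W[seq_len(n_exc), seq_len(n_exc)] <- topo$weights
  K <- z_passes
  for (ii in (n_exc + 1):n) {
    pre <- sample(seq_len(n_exc), min(K, n_exc))      # inputs: excitatory only
    W[ii, pre] <- w0_exc
    tgt <- sample(setdiff(seq_len(n), ii), min(K, n - 1)) # outputs: any class
    W[tgt, ii] <- w_inh
  }
  structure(list(weights = W,
                 is_inhibitory = c(rep(FALSE, n_exc), rep(TRUE, n_inh)),
                 hub = topo$hub,
                 degree_rank = c(topo$degree_rank, (n_exc + 1):n),
                 degree = c(topo$degree, rep(NA_real_, n_inh)),
                 w0 = w0_exc),
            class = "sf_topology")
}

#' Disconnect the hub neurons
#'
#' Returns a copy of the topology with every synapse incoming to or outgoing
#' from a hub neuron set to zero. Hub neurons stay in the state vector (they
#' keep receiving drive and noise) but are isolated from the network.
#'
#' @param topology an \code{"sf_topology"}.
#' @return The modified topology.
#' @export
remove_hub <- function(topology) {
  W <- topology$weights
  if (length(topology$hub) > 0) {
    W[topology$hub, ] <- 0
    W[, topology$hub] <- 0
  }
  topology$weights <- W
  topology
}

#' @export
print.sf_graph <- function(x, ...) {
  cat("Undirected scale-free graph:", x$n, "nodes,", nrow(x$edges),
      "edges\n  degree: median", stats::median(x$degree), "max",
      max(x$degree), "\n")
  invisible(x)
}

#' @export
print.sf_topology <- function(x, ...) {
  n <- nrow(x$weights)
  cat("Directed network topology:", n, "neurons (",
      sum(x$is_inhibitory), "inhibitory ),",
      sum(x$weights != 0), "synapses\n")
  cat("  mean in-degree:", round(sum(x$weights != 0) / n, 2),
      "| hub neurons:", length(x$hub), "\n")
  invisible(x)
}
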