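#' Social-network specifications
#'
#' The experiment linked the 50 participants by one of 8 topologies:
#' ring lattices where each node connects to all nodes within lattice
#' distance 1, 2, or 3 (uniform degree 2, 4, 6), and random graphs realizing
#' a fixed degree sequence with mean degree 4.
#'
#' @param kind `"ring_lattice"` or `"degree_sequence"`.
#' @param lattice_distance ring-lattice neighbourhood radius (1, 2, or 3).
#' @param degree_sequence integer degrees, one per node; defaults to the
#'   experiment's sequence \{1x10, 2x8, 3x7, 4x6, 5x5, 6x4, 7x4, 8x3, 9x2,
#'   10x1\} (sum 200, mean 4).
#' @param n_nodes number of participants (50).
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(kind = c("ring_lattice", "degree_sequence"),
                         lattice_distance = 1L,
                         degree_sequence = default_degree_sequence(),
                         n_nodes = 50L) {
  kind <- match.arg(kind)
  if (kind == "ring_lattice") {
    if (!lattice_distance %in% 1:3) stop("`lattice_distance` must be 1, 2, or 3")
  } else {
    degree_sequence <- as.integer(degree_sequence)
    if (length(degree_sequence) != n_nodes)
      stop("degree sequence length must equal `n_nodes`")
    if (sum(degree_sequence) %% 2L != 0L)
      stop("degree sequence must have an even sum")
    if (!igraph::is_graphical(degree_sequence))
      stop("degree sequence is not graphical")
  }
  structure(list(kind = kind, lattice_distance = as.integer(lattice_distance),
                 degree_sequence = degree_sequence, n_nodes = as.integer(n_nodes)),
            class = "network_spec")
}

#' @rdname network_spec
#' @export
default_degree_sequence <- function() {
  rep.int(1:10, c(10L, 8L, 7L, 6L, 5L, 4L, 4L, 3L, 2L, 1L))
}

#' Build a participant network
#'
#' Realizes a [network_spec()] as a simple undirected graph on the
#' participant set. Degree-sequence graphs are sampled by edge-switching
#' Markov chain over simple realizations of the exact sequence.
#'
#' @param spec a [network_spec()].
#' @param seed optional integer seed (degree-sequence sampling only).
#' @return An [igraph::graph] with `n_nodes` vertices.
#' @export
build_network <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  if (!is.null(seed)) set.seed(seed)
  if (spec$kind == "ring_lattice") {
    n <- spec$n_nodes
    d <- spec$lattice_distance
    ends <- do.call(rbind, lapply(seq_len(n), function(i) {
      j <- ((i - 1L + seq_len(d)) %% n) + 1L   # forward neighbours only
      cbind(i, j)
    }))
    igraph::graph_from_edgelist(ends, directed = FALSE)
  } else {
    igraph::sample_degseq(spec$degree_sequence, method = "edge.switching.simple")
  }
}

#' Default set of experiment networks
#'
#' The 8 topologies used across runs: lattices at distance 1-3 and five
#' independent degree-sequence realizations.
#'
#' @return A list of `network_spec` objects of length 8.
#' @export
default_network_specs <- function() {
  c(lapply(1:3, function(d) network_spec("ring_lattice", lattice_distance = d)),
    rep(list(network_spec("degree_sequence")), 5L))
}
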