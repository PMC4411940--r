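#' Construct a protein interaction network
#'
#' Builds a normalized undirected simple graph over protein identifiers.
#' Self-loops are dropped and duplicate or reversed pairs are collapsed to a
#' single undirected edge; the number of dropped/merged lines is recorded and
#' reported via [message()].
#'
#' Identifiers are case-sensitive opaque strings; no symbol mapping is
#' attempted. Nodes are stored in sorted order, which is the deterministic
#' node order used for every tie-break in the package.
#'
#' @param edges A two-column character matrix or data frame of interacting
#'   pairs. May be empty.
#' @param nodes Optional character vector of node identifiers; the node set is
#'   the union of `nodes` and all edge endpoints, so isolated proteins can be
#'   declared here.
#' @param name Free-text label for the network.
#' @param quiet If `TRUE`, suppress the normalization message.
#' @return An object of class `protein_network` with components `nodes`
#'   (sorted character vector), `edges` (integer matrix, one row per
#'   undirected edge, column 1 < column 2, indices into `nodes`), `adj`
#'   (adjacency list of integer vectors) and `name`.
#' @examples
#' net <- protein_network(rbind(c("A", "B"), c("B", "C")))
#' partners(net, "B")
#' @export
protein_network <- function(edges, nodes = NULL, name = "", quiet = FALSE) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2L)
  }
  if (ncol(edges) != 2L) stop("`edges` must have exactly two columns")
  storage.mode(edges) <- "character"
  all_nodes <- sort(unique(c(as.character(nodes), edges[, 1L], edges[, 2L])))
  i <- match(edges[, 1L], all_nodes)
  j <- match(edges[, 2L], all_nodes)
  self <- i == j
  n_self <- sum(self)
  i2 <- pmin(i[!self], j[!self])
  j2 <- pmax(i[!self], j[!self])
  key <- (i2 - 1) * length(all_nodes) + j2
  keep <- !duplicated(key)
  n_dup <- sum(!keep)
  em <- cbind(i2[keep], j2[keep])
  em <- em[order(em[, 1L], em[, 2L]), , drop = FALSE]
  adj <- rep(list(integer(0)), length(all_nodes))
  if (nrow(em) > 0L) {
    nb <- split(c(em[, 2L], em[, 1L]), c(em[, 1L], em[, 2L]))
    idx <- as.integer(names(nb))
    adj[idx] <- lapply(nb, function(x) sort(as.integer(x)))
  }
  if (!quiet && (n_self > 0L || n_dup > 0L)) {
    message(sprintf("normalized network '%s': dropped %d self-loop(s), merged %d duplicate edge(s)",
                    name, n_self, n_dup))
  }
  structure(
    list(nodes = all_nodes, edges = em, adj = adj, name = name),
    n_self_loops = n_self, n_duplicates = n_dup,
    class = "protein_network"
  )
}

#' @export
print.protein_network <- function(x, ...) {
  cat(sprintf("Protein interaction network%s\n",
              if (nzchar(x$name)) paste0(" '", x$name, "'") else ""))
  cat(sprintf("  %d proteins, %d interactions\n", length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Number of nodes / edges of a protein network
#' @param net A `protein_network`.
#' @return An integer count.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

#' Interaction partners of a protein
#'
#' Returns the neighborhood Gamma(v): the set of interaction partners of `v`.
#' Adjacency is symmetric by construction.
#'
#' @param net A `protein_network`.
#' @param v A single protein identifier present in the network.
#' @return Character vector of partner identifiers (sorted).
#' @export
partners <- function(net, v) {
  i <- match(v, net$nodes)
  if (is.na(i)) stop(sprintf("unknown protein '%s'", v))
  net$nodes[net$adj[[i]]]
}

#' Degree of every protein
#' @param net A `protein_network`.
#' @return Named integer vector of interaction counts, in node order.
#' @export
node_degree <- function(net) {
  d <- lengths(net$adj)
  names(d) <- net$nodes
  d
}

#' Convert a protein network to an igraph object
#'
#' @param net A `protein_network`.
#' @return An undirected simple [igraph::graph] whose vertex names are the
#'   protein identifiers, including isolated proteins.
#' @export
as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = length(net$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = net$nodes)
  if (nrow(net$edges) > 0L) {
    g <- igraph::add_edges(g, t(net$edges))
  }
  g
}

#' Summary statistics of a network
#'
#' Reports node count, edge count and mean degree (interactions per protein),
#' `mean_degree = 2 * n_edges / n_nodes`.
#'
#' @param net A `protein_network` with at least one node.
#' @return A `network_summary` list with `n_nodes`, `n_edges`, `mean_degree`.
#' @examples
#' net <- protein_network(rbind(c("A", "B"), c("B", "C"), c("C", "A")))
#' network_summary(net)$mean_degree # 2 for a triangle
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "protein_network"))
  if (length(net$nodes) == 0L) stop("cannot summarize an empty network")
  structure(
    list(n_nodes = length(net$nodes), n_edges = nrow(net$edges),
         mean_degree = 2 * nrow(net$edges) / length(net$nodes)),
    class = "network_summary"
  )
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("%d proteins, %d interactions, mean degree %.2f\n",
              x$n_nodes, x$n_edges, x$mean_degree))
  invisible(x)
}

#' Connected components of a network
#'
#' Every node belongs to exactly one component; isolated nodes form singleton
#' components.
#'
#' @param net A `protein_network`.
#' @return A list with `membership` (named integer vector of component ids),
#'   `n` (number of components) and `sizes` (integer vector of sizes).
#' @export
network_components <- function(net) {
  if (length(net$nodes) == 0L) {
    return(list(membership = integer(0), n = 0L, sizes = integer(0)))
  }
  comp <- igraph::components(as_igraph(net))
  list(membership = comp$membership, n = comp$no, sizes = as.integer(comp$csize))
}
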