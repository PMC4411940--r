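# Independent reference implementations used as oracles. These deliberately
# avoid the package's own code paths (and igraph) for the quantity they
# check: plain-R flood fill, geodesic enumeration and exact hypergeometric
# sums.

# Erdos-Renyi-style random network over sprintf-coded node names.
rand_net <- function(n, p, seed, prefix = "v") {
  set.seed(seed)
  nodes <- sprintf(paste0(prefix, "%03d"), seq_len(n))
  if (n >= 2) {
    em <- t(utils::combn(n, 2))
    em <- em[stats::runif(nrow(em)) < p, , drop = FALSE]
  } else {
    em <- matrix(integer(0), ncol = 2)
  }
  protein_network(cbind(nodes[em[, 1]], nodes[em[, 2]]), nodes = nodes,
                  quiet = TRUE)
}

# adjacency as a named list of character vectors
adj_list <- function(net) {
  setNames(lapply(net$adj, function(ix) net$nodes[ix]), net$nodes)
}

# Breadth-first flood fill component count (oracle for component queries).
flood_fill_components <- function(nodes, adj) {
  seen <- setNames(rep(FALSE, length(nodes)), nodes)
  ncomp <- 0L
  sizes <- integer(0)
  for (v in nodes) {
    if (seen[[v]]) next
    ncomp <- ncomp + 1L
    queue <- v
    size <- 0L
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      if (seen[[u]]) next
      seen[[u]] <- TRUE
      size <- size + 1L
      queue <- c(queue, adj[[u]][!seen[adj[[u]]]])
    }
    sizes <- c(sizes, size)
  }
  list(n = ncomp, sizes = sizes)
}

# Brute-force betweenness: BFS geodesic counts from every source, then the
# pair-sum sigma_st(v)/sigma_st over unordered pairs with v not an endpoint.
brute_betweenness <- function(net) {
  n <- length(net$nodes)
  adj <- net$adj
  dist <- matrix(Inf, n, n)
  nsp <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n); sig <- rep(0, n)
    d[s] <- 0; sig[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (u in frontier) {
        for (w in adj[[u]]) {
          if (is.infinite(d[w])) { d[w] <- d[u] + 1; nxt <- c(nxt, w) }
          if (d[w] == d[u] + 1) sig[w] <- sig[w] + sig[u]
        }
      }
      frontier <- unique(nxt)
    }
    dist[s, ] <- d; nsp[s, ] <- sig
  }
  cb <- setNames(rep(0, n), net$nodes)
  for (s in seq_len(n - 1)) for (t in seq((s + 1), n)) {
    if (is.infinite(dist[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (dist[s, v] + dist[v, t] == dist[s, t]) {
        cb[v] <- cb[v] + nsp[s, v] * nsp[v, t] / nsp[s, t]
      }
    }
  }
  cb
}

# Exact upper-tail hypergeometric probability by explicit enumeration over
# 2x2 tables with fixed margins.
enum_fisher_tail <- function(n_nodes, n_a, n_b, overlap) {
  xmax <- min(n_a, n_b)
  xmin <- max(0, n_a + n_b - n_nodes)
  xs <- xmin:xmax
  mass <- choose(n_b, xs) * choose(n_nodes - n_b, n_a - xs) / choose(n_nodes, n_a)
  sum(mass[xs >= overlap])
}

path_net <- function(k, prefix = "n") {
  nodes <- sprintf(paste0(prefix, "%d"), seq_len(k))
  protein_network(cbind(nodes[-k], nodes[-1]), quiet = TRUE)
}

cycle_net <- function(k, prefix = "c") {
  nodes <- sprintf(paste0(prefix, "%d"), seq_len(k))
  protein_network(cbind(nodes, nodes[c(2:k, 1)]), quiet = TRUE)
}

complete_net <- function(k, prefix = "k") {
  nodes <- sprintf(paste0(prefix, "%d"), seq_len(k))
  protein_network(t(utils::combn(nodes, 2)), quiet = TRUE)
}

star_net <- function(leaves = 5) {
  protein_network(cbind("hub", sprintf("leaf%d", seq_len(leaves))), quiet = TRUE)
}
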