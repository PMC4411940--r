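#' @keywords internal
as_member_vector <- function(s) {
  if (inherits(s, "dominating_set")) s$members else as.character(s)
}

new_dominating_set <- function(members, status, solver_info, ordering = "sorted") {
  structure(
    list(members = sort(members), objective = length(members), status = status,
         solver_info = solver_info, ordering = ordering),
    class = "dominating_set"
  )
}

#' @export
print.dominating_set <- function(x, ...) {
  cat(sprintf("Dominating set: %d proteins (status: %s)\n", x$objective, x$status))
  cat(sprintf("  %s\n", x$solver_info))
  invisible(x)
}

#' Check whether a set dominates a network
#'
#' A set S dominates G when every node is either in S or adjacent to a member
#' of S (the domination constraint of the binary program).
#'
#' @param net A `protein_network`.
#' @param s Character vector of protein identifiers (or a `dominating_set`);
#'   must all be network nodes.
#' @return A list with `ok` (logical) and `undominated` (character vector of
#'   violating nodes, empty when `ok`).
#' @examples
#' p3 <- protein_network(rbind(c("A", "B"), c("B", "C")))
#' verify_dominating(p3, "B")$ok   # TRUE
#' @export
verify_dominating <- function(net, s) {
  s <- as_member_vector(s)
  idx <- match(s, net$nodes)
  if (anyNA(idx)) {
    stop(sprintf("unknown identifiers in candidate set: %s",
                 paste(s[is.na(idx)], collapse = ", ")))
  }
  covered <- logical(length(net$nodes))
  covered[idx] <- TRUE
  covered[unlist(net$adj[idx])] <- TRUE
  list(ok = all(covered), undominated = net$nodes[!covered])
}

#' Minimum dominating set by exhaustive enumeration
#'
#' Enumerates node subsets in increasing cardinality (lexicographic within a
#' cardinality) and returns the first dominating one, which is therefore a
#' true minimum. Intended as a reference for small graphs only.
#'
#' @param net A `protein_network` with at most 20 nodes.
#' @return A `dominating_set` with status `"brute-forced"`.
#' @export
brute_force_mdset <- function(net) {
  n <- length(net$nodes)
  if (n > 20L) stop(sprintf("brute force refused: %d nodes exceeds the 20-node guard", n))
  closed <- lapply(seq_len(n), function(v) c(v, net$adj[[v]]))
  for (size in 0:n) {
    if (size == 0L) {
      if (n == 0L) return(new_dominating_set(character(0), "brute-forced", "empty graph"))
      next
    }
    combos <- utils::combn(n, size)
    for (j in seq_len(ncol(combos))) {
      sel <- combos[, j]
      if (length(unique(unlist(closed[sel]))) == n) {
        return(new_dominating_set(net$nodes[sel], "brute-forced",
                                  sprintf("enumeration over subsets of size <= %d", size)))
      }
    }
  }
  stop("internal error: full node set must dominate") # nocov
}

#' Greedy dominating set
#'
#' Repeatedly selects the node covering the most still-uncovered nodes
#' (itself plus its neighbors), ties broken by sorted node order. The result
#' always dominates the network; it is an upper bound on the domination
#' number and serves as the branch-and-bound incumbent.
#'
#' @param net A `protein_network`.
#' @return A `dominating_set` with status `"feasible-upper-bound"`.
#' @export
greedy_mdset <- function(net) {
  n <- length(net$nodes)
  closed <- lapply(seq_len(n), function(v) c(v, net$adj[[v]]))
  covered <- logical(n)
  cov_cnt <- lengths(closed)
  sel <- integer(0)
  while (!all(covered)) {
    v <- which.max(cov_cnt) # first max = lowest index on ties
    sel <- c(sel, v)
    newly <- closed[[v]][!covered[closed[[v]]]]
    covered[newly] <- TRUE
    for (e in newly) cov_cnt[closed[[e]]] <- cov_cnt[closed[[e]]] - 1L
  }
  new_dominating_set(net$nodes[sel], "feasible-upper-bound", "greedy max-coverage")
}

#' Solve the minimum dominating set binary program
#'
#' Solves `min sum_v x_v` subject to `x_v + sum_{w in Gamma(v)} x_w >= 1`
#' for every node v, with binary x, by branch-and-bound (greedy incumbent,
#' set-cover branching, packing lower bound). An isolated node's constraint
#' degenerates to `x_v >= 1`, so isolated nodes are always members. With the
#' default sorted node ordering the solution is fully deterministic: the same
#' network always yields the same set. Because optimal dominating sets are
#' generically non-unique, `order = "random"` re-solves under a seeded random
#' node permutation to probe the sensitivity of downstream statistics to the
#' particular optimum returned.
#'
#' @param net A `protein_network` with at least one node.
#' @param time_limit Wall-clock budget in seconds. If the search is not
#'   exhausted in time the incumbent is returned with status
#'   `"feasible-upper-bound"` and the proven lower bound in `solver_info`.
#' @param order `"sorted"` (default, deterministic) or `"random"`.
#' @param seed Integer seed used when `order = "random"`.
#' @return A `dominating_set`; status `"optimal"` when optimality was proven.
#' @examples
#' star <- protein_network(cbind("hub", paste0("leaf", 1:5)))
#' solve_mdset(star)$objective  # 1
#' @export
solve_mdset <- function(net, time_limit = 60, order = c("sorted", "random"),
                        seed = NULL) {
  order <- match.arg(order)
  n <- length(net$nodes)
  if (n < 1L) stop("cannot solve an empty network")
  perm <- seq_len(n)
  if (order == "random") {
    perm <- with_seed(if (is.null(seed)) 1L else seed, sample.int(n))
  }
  inv <- integer(n)
  inv[perm] <- seq_len(n)
  # adjacency in permuted 0-based labels
  adj0 <- lapply(net$adj[perm], function(nb) as.integer(sort(inv[nb]) - 1L))
  res <- .mdset_bb(adj0, as.double(time_limit))
  members <- net$nodes[perm[res$members]]
  status <- if (res$optimal) "optimal" else "feasible-upper-bound"
  info <- sprintf("branch-and-bound: %s nodes explored, objective %d, lower bound %d%s",
                  format(res$nodes_explored, big.mark = ","), res$objective,
                  res$lower_bound,
                  if (res$optimal) "" else sprintf(" (gap %d, time limit reached)",
                                                   res$objective - res$lower_bound))
  ds <- new_dominating_set(members, status, info, ordering = order)
  chk <- verify_dominating(net, ds$members)
  if (!chk$ok) stop("internal error: solver returned a non-dominating set") # nocov
  ds
}

#' Stratify network proteins into essential / MDSet / e-MDSet sets
#'
#' The e-MDSet is the intersection of the computed MDSet with the essential
#' proteins present in the network. All overlap counts use the intersection
#' of the essential list with the network's nodes, since genome-wide
#' essential gene lists typically exceed the network.
#'
#' @param net A `protein_network`.
#' @param mdset A `dominating_set` (or character vector); members must be
#'   network nodes.
#' @param essential Character vector of essential protein identifiers (may
#'   contain identifiers absent from the network).
#' @return An `mdset_strata` list with `mdset`, `essential_in_network`,
#'   `e_mdset`, `non_mdset` (all sorted character vectors) and `sizes`.
#' @export
stratify <- function(net, mdset, essential) {
  members <- as_member_vector(mdset)
  if (!all(members %in% net$nodes)) stop("MDSet members must be network nodes")
  ess_in <- sort(intersect(as.character(essential), net$nodes))
  e_mdset <- sort(intersect(members, ess_in))
  strata <- list(
    mdset = sort(members),
    essential_in_network = ess_in,
    e_mdset = e_mdset,
    non_mdset = sort(setdiff(net$nodes, members))
  )
  strata$sizes <- lengths(strata[1:4])
  structure(strata, class = "mdset_strata")
}

#' @export
print.mdset_strata <- function(x, ...) {
  cat("Protein strata:\n")
  cat(sprintf("  MDSet:                %d\n", x$sizes[["mdset"]]))
  cat(sprintf("  essential in network: %d\n", x$sizes[["essential_in_network"]]))
  cat(sprintf("  e-MDSet (overlap):    %d\n", x$sizes[["e_mdset"]]))
  cat(sprintf("  non-MDSet:            %d\n", x$sizes[["non_mdset"]]))
  invisible(x)
}
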