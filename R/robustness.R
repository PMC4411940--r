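#' Degree-ordered deletion trajectory
#'
#' Sorts the victim proteins by their degree in the intact network
#' (descending, ties by sorted node order) and deletes them one at a time,
#' recording after each step the number of connected components of the
#' remaining graph (isolated nodes count as singleton components) and the
#' cumulative number of removed interactions. Degrees are, by default, NOT
#' recomputed as the graph shrinks; `recompute = TRUE` switches to an
#' adaptive order that always deletes the currently most connected
#' remaining victim.
#'
#' @param net A `protein_network`.
#' @param victims Nonempty character vector of proteins to delete (subset of
#'   the nodes).
#' @param recompute Recompute degrees after every deletion (default FALSE).
#' @return A `robustness_trajectory` data frame with columns `step`,
#'   `protein`, `initial_degree`, `n_components`, `removed_edges_cum`,
#'   `n_remaining_nodes`.
#' @export
deletion_trajectory <- function(net, victims, recompute = FALSE) {
  victims <- as.character(victims)
  if (length(victims) == 0L) stop("victims is empty")
  if (!all(victims %in% net$nodes)) stop("victims contains non-network proteins")
  deg0 <- lengths(net$adj); names(deg0) <- net$nodes
  g <- as_igraph(net)
  e0 <- nrow(net$edges)
  if (!recompute) {
    ord <- victims[order(-deg0[victims], victims)]
  } else {
    ord <- character(0)
    pool <- victims
  }
  steps <- length(victims)
  out <- data.frame(step = seq_len(steps), protein = NA_character_,
                    initial_degree = NA_integer_, n_components = NA_integer_,
                    removed_edges_cum = NA_integer_, n_remaining_nodes = NA_integer_)
  for (t in seq_len(steps)) {
    if (recompute) {
      dcur <- igraph::degree(g)[pool]
      v <- pool[order(-dcur, pool)][1L]
      pool <- setdiff(pool, v)
    } else {
      v <- ord[t]
    }
    g <- igraph::delete_vertices(g, v)
    out$protein[t] <- v
    out$initial_degree[t] <- deg0[[v]]
    out$n_components[t] <- igraph::components(g)$no
    out$removed_edges_cum[t] <- e0 - igraph::ecount(g)
    out$n_remaining_nodes[t] <- igraph::vcount(g)
  }
  structure(out, class = c("robustness_trajectory", "data.frame"),
            ordering = if (recompute) "adaptive" else "static")
}

#' @export
plot.robustness_trajectory <- function(x, ...) {
  graphics::plot(x$step, x$n_components, type = "s",
                 xlab = "deletion step", ylab = "connected components", ...)
  invisible(x)
}

#' Compare deletion trajectories of two equally sized protein sets
#'
#' Deletes `set_a` (e.g. the e-MDSet) and, for comparison, the equally sized
#' set of highest-degree proteins drawn from `pool` (e.g. the most connected
#' essential proteins), with ties broken by sorted node order. Both runs use
#' [deletion_trajectory()] on the intact network.
#'
#' @param net A `protein_network`.
#' @param set_a Nonempty character vector of proteins.
#' @param pool Character vector from which the comparison set is drawn; its
#'   intersection with the network must contain at least `length(set_a)`
#'   proteins.
#' @return A `trajectory_comparison` list with `a`, `b` (trajectories),
#'   `set_b` (the chosen comparison proteins) and `diff` (per-step
#'   differences a - b in components and removed edges).
#' @export
compare_trajectories <- function(net, set_a, pool) {
  set_a <- as.character(set_a)
  pool_in <- intersect(as.character(pool), net$nodes)
  if (length(pool_in) < length(set_a)) {
    stop(sprintf("pool has %d network proteins; need at least %d",
                 length(pool_in), length(set_a)))
  }
  deg <- lengths(net$adj); names(deg) <- net$nodes
  set_b <- pool_in[order(-deg[pool_in], pool_in)][seq_along(set_a)]
  ta <- deletion_trajectory(net, set_a)
  tb <- deletion_trajectory(net, set_b)
  structure(
    list(a = ta, b = tb, set_b = sort(set_b),
         diff = data.frame(step = ta$step,
                           d_components = ta$n_components - tb$n_components,
                           d_removed_edges = ta$removed_edges_cum - tb$removed_edges_cum)),
    class = "trajectory_comparison"
  )
}

#' @export
print.trajectory_comparison <- function(x, ...) {
  k <- nrow(x$a)
  cat(sprintf("Deletion of %d proteins per set:\n", k))
  cat(sprintf("  set A: final components %d, removed interactions %d\n",
              x$a$n_components[k], x$a$removed_edges_cum[k]))
  cat(sprintf("  set B: final components %d, removed interactions %d\n",
              x$b$n_components[k], x$b$removed_edges_cum[k]))
  invisible(x)
}
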