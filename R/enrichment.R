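# Resampling enrichment machinery shared by the bottleneck, complex and
# functional-class analyses. All empirical p-values use the plus-one rule
# p = (1 + #draws at least as extreme) / (1 + R), so p is in (0, 1] and a
# reported p of 1/(R+1) means no null draw reached the observed value.

#' @keywords internal
new_enrichment_result <- function(observed, null_draws, reps, seed) {
  nm <- mean(null_draws)
  structure(
    list(
      observed = observed,
      null_mean = nm,
      null_sd = stats::sd(null_draws),
      ratio = if (nm > 0) observed / nm else NA_real_,
      p_ge = (1 + sum(null_draws >= observed)) / (1 + reps),
      p_le = (1 + sum(null_draws <= observed)) / (1 + reps),
      n_randomizations = reps,
      seed = seed
    ),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Enrichment: observed %s, null %.2f +/- %.2f (R = %d)\n",
              format(x$observed), x$null_mean, x$null_sd, x$n_randomizations))
  cat(sprintf("  ratio %.3f, p_ge = %.4g, p_le = %.4g\n", x$ratio, x$p_ge, x$p_le))
  invisible(x)
}

#' Betweenness centrality of every protein
#'
#' Unnormalized shortest-path betweenness c_B(v): the sum over unordered node
#' pairs s != t (both distinct from v) of the fraction of shortest paths
#' between s and t that pass through v. Paths are unweighted and undirected;
#' pairs in different components contribute zero.
#'
#' @param net A `protein_network`.
#' @return Named numeric vector of c_B scores in node order.
#' @export
betweenness_centrality <- function(net) {
  g <- as_igraph(net)
  b <- igraph::betweenness(g, directed = FALSE, weights = NULL, normalized = FALSE)
  b[net$nodes]
}

#' Bottleneck proteins (top betweenness quantile)
#'
#' The `ceiling(quantile * n)` proteins with highest betweenness centrality;
#' ties at the cut are broken by sorted node order.
#'
#' @param scores Named numeric vector of betweenness scores (as returned by
#'   [betweenness_centrality()]), or a `protein_network` (scores computed).
#' @param quantile Fraction of proteins to keep, in (0, 1); default 0.20.
#' @return Character vector of bottleneck protein identifiers (sorted).
#' @export
bottleneck_set <- function(scores, quantile = 0.20) {
  if (inherits(scores, "protein_network")) scores <- betweenness_centrality(scores)
  stopifnot(quantile > 0, quantile < 1)
  n <- length(scores)
  k <- ceiling(quantile * n)
  ord <- order(-scores, names(scores))
  sort(names(scores)[ord[seq_len(k)]])
}

#' Degree-threshold enrichment curve
#'
#' For each threshold k, proteins are grouped into the bin of all proteins
#' with at least k interactions (size `n_geq_k`) and the marked proteins
#' among them are counted (`n_marked_geq_k`). The null resamples
#' `|marked in network|` proteins uniformly without replacement R times and
#' recounts. The enrichment E at each k is, by default, the observed count
#' divided by the mean null count; `stat = "mean-of-ratios"` instead averages
#' the per-draw ratio observed/null, skipping (and counting) draws with a
#' zero null count, for which the ratio is undefined.
#'
#' @param net A `protein_network`.
#' @param marked Character vector of marked proteins (e.g. essential genes);
#'   the intersection with network nodes must be nonempty.
#' @param k_values Integer thresholds; default `1:max(degree)` restricted to
#'   thresholds with at least `min_bin` proteins.
#' @param reps Number of randomizations R (default 10000).
#' @param seed Integer seed; fixed seed gives bit-identical results.
#' @param stat `"ratio-of-means"` (default) or `"mean-of-ratios"`.
#' @param min_bin Smallest bin size reported when `k_values` is defaulted.
#' @return A `degree_enrichment_curve`: a data frame with one row per k
#'   (`k`, `n_geq_k`, `n_marked_geq_k`, `null_mean`, `null_sd`, `enrichment`,
#'   `p_ge`, `p_le`), with the call parameters in attributes. Thresholds with
#'   an empty bin are reported with `NA` enrichment rather than an error.
#' @export
degree_enrichment_curve <- function(net, marked, k_values = NULL, reps = 10000,
                                    seed = NULL, stat = c("ratio-of-means", "mean-of-ratios"),
                                    min_bin = 10) {
  stat <- match.arg(stat)
  stopifnot(reps >= 1)
  deg <- lengths(net$adj)
  n <- length(deg)
  marked_in <- intersect(as.character(marked), net$nodes)
  m <- length(marked_in)
  if (m == 0L) stop("no marked proteins present in the network")
  maxdeg <- max(deg)
  tab_all <- tabulate(deg + 1L, nbins = maxdeg + 1L)
  geq_all <- rev(cumsum(rev(tab_all)))             # index k+1 -> N_{>=k}
  if (is.null(k_values)) {
    k_values <- seq_len(maxdeg)
    k_values <- k_values[geq_all[k_values + 1L] >= min_bin]
  }
  k_values <- sort(unique(as.integer(k_values)))
  n_geq <- ifelse(k_values <= maxdeg, geq_all[pmin(k_values, maxdeg) + 1L], 0L)
  deg_marked <- deg[match(marked_in, net$nodes)]
  tab_m <- tabulate(deg_marked + 1L, nbins = maxdeg + 1L)
  geq_m <- rev(cumsum(rev(tab_m)))
  obs <- ifelse(k_values <= maxdeg, geq_m[pmin(k_values, maxdeg) + 1L], 0L)

  null_counts <- with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      ds <- deg[sample.int(n, m)]
      tb <- tabulate(ds + 1L, nbins = maxdeg + 1L)
      gq <- rev(cumsum(rev(tb)))
      ifelse(k_values <= maxdeg, gq[pmin(k_values, maxdeg) + 1L], 0L)
    }, numeric(length(k_values)))
  })
  null_counts <- matrix(null_counts, nrow = length(k_values))
  null_mean <- rowMeans(null_counts)
  null_sd <- apply(null_counts, 1L, stats::sd)
  n_zero_null <- rowSums(null_counts == 0)
  enr <- if (stat == "ratio-of-means") {
    ifelse(null_mean > 0, obs / null_mean, NA_real_)
  } else {
    vapply(seq_along(k_values), function(i) {
      nz <- null_counts[i, ] > 0
      if (!any(nz)) NA_real_ else mean(obs[i] / null_counts[i, nz])
    }, 0)
  }
  p_ge <- (1 + rowSums(null_counts >= obs)) / (1 + reps)
  p_le <- (1 + rowSums(null_counts <= obs)) / (1 + reps)
  undefined <- n_geq == 0L
  enr[undefined] <- NA_real_
  out <- data.frame(
    k = k_values, n_geq_k = n_geq, n_marked_geq_k = obs,
    null_mean = null_mean, null_sd = null_sd, enrichment = enr,
    p_ge = p_ge, p_le = p_le
  )
  structure(out, class = c("degree_enrichment_curve", "data.frame"),
            n_randomizations = reps, seed = seed, stat = stat,
            n_marked = m, n_zero_null = n_zero_null)
}

#' @export
plot.degree_enrichment_curve <- function(x, ...) {
  graphics::plot(x$k, x$enrichment, type = "b", pch = 16,
                 xlab = "degree threshold k", ylab = expression(E[i >= k]), ...)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' Fractions over logarithmic degree bins
#'
#' Groups proteins of degree >= 1 into bins of logarithmically increasing
#' degree, `[2^j, 2^(j+1))` for j >= 0, and reports the fraction of the
#' denominator set falling in the numerator set within each bin (e.g. the
#' fraction of essential proteins that are also MDSet members). Degree-0
#' proteins are excluded; a bin with an empty denominator is reported as
#' `NA`.
#'
#' @param net A `protein_network`.
#' @param numerator,denominator Character vectors of protein identifiers with
#'   `numerator` a subset of `denominator`, both subsets of the nodes.
#' @return Data frame with `bin_lo`, `bin_hi` (inclusive), `n_denominator`,
#'   `n_numerator`, `fraction`.
#' @export
log_degree_bin_fractions <- function(net, numerator, denominator) {
  numerator <- as.character(numerator); denominator <- as.character(denominator)
  if (!all(denominator %in% net$nodes)) stop("denominator contains non-network proteins")
  if (!all(numerator %in% denominator)) stop("numerator must be a subset of denominator")
  deg <- lengths(net$adj); names(deg) <- net$nodes
  pos <- deg[deg >= 1L]
  if (length(pos) == 0L) stop("network has no interacting proteins")
  jmax <- floor(log2(max(pos)))
  bins <- lapply(0:jmax, function(j) c(2^j, 2^(j + 1) - 1))
  res <- lapply(bins, function(b) {
    in_bin <- names(pos)[pos >= b[1] & pos <= b[2]]
    den <- sum(denominator %in% in_bin)
    num <- sum(numerator %in% in_bin)
    data.frame(bin_lo = b[1], bin_hi = b[2], n_denominator = den,
               n_numerator = num,
               fraction = if (den > 0) num / den else NA_real_)
  })
  do.call(rbind, res)
}

#' Overlap enrichment of a fixed target set by label resampling
#'
#' Observed statistic: the number of network proteins lying in both `target`
#' and `marked`. The null resamples `|marked in network|` node labels
#' uniformly without replacement R times and recounts the intersection with
#' `target` (the null count is hypergeometric, and draws are generated from
#' that exact distribution). Used for the bottleneck-protein enrichment and
#' any other fixed-set overlap null.
#'
#' @param net A `protein_network`.
#' @param target Nonempty character vector of network proteins (e.g. the
#'   bottleneck set).
#' @param marked Character vector of marked proteins (e.g. essential genes).
#' @param reps Number of randomizations (default 10000).
#' @param seed Integer seed.
#' @return An `enrichment_result`.
#' @export
set_overlap_enrichment <- function(net, target, marked, reps = 10000, seed = NULL) {
  target <- as.character(target)
  if (length(target) == 0L) stop("target set is empty")
  if (!all(target %in% net$nodes)) stop("target contains non-network proteins")
  n <- length(net$nodes)
  marked_in <- intersect(as.character(marked), net$nodes)
  m <- length(marked_in)
  observed <- length(intersect(target, marked_in))
  null_draws <- with_seed(seed, {
    stats::rhyper(reps, m = length(target), n = n - length(target), k = m)
  })
  new_enrichment_result(observed, null_draws, reps, seed)
}

#' One-sided Fisher's exact test for set overlap
#'
#' Upper-tail probability of observing at least `n_overlap` proteins in the
#' intersection of two sets of the given sizes drawn from `n_nodes` network
#' proteins — the hypergeometric tail behind the one-sided Fisher's exact
#' test for enrichment.
#'
#' @param n_nodes Total number of network proteins.
#' @param n_mdset Size of the first set (e.g. the MDSet).
#' @param n_marked_in_net Size of the second set intersected with the network
#'   (e.g. essential proteins in the network).
#' @param n_overlap Observed intersection size.
#' @return The one-sided p-value, P(X >= n_overlap).
#' @export
fisher_overlap <- function(n_nodes, n_mdset, n_marked_in_net, n_overlap) {
  stopifnot(n_nodes >= 0, n_mdset >= 0, n_marked_in_net >= 0, n_overlap >= 0)
  if (n_mdset > n_nodes || n_marked_in_net > n_nodes) {
    stop("set sizes exceed the number of network proteins")
  }
  if (n_overlap > min(n_mdset, n_marked_in_net)) {
    stop("overlap exceeds the smaller set")
  }
  if (n_overlap < n_mdset + n_marked_in_net - n_nodes) {
    stop("overlap below the minimum forced by the margins")
  }
  stats::phyper(n_overlap - 1, m = n_marked_in_net, n = n_nodes - n_marked_in_net,
                k = n_mdset, lower.tail = FALSE)
}
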