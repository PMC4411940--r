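#' @keywords internal
membership_index <- function(catalog, universe = NULL) {
  # protein -> integer vector of complex indices
  all_members <- unlist(catalog, use.names = FALSE)
  cx <- rep(seq_along(catalog), lengths(catalog))
  idx <- split(cx, all_members)
  if (!is.null(universe)) idx <- idx[intersect(names(idx), universe)]
  idx
}

#' Protein complex participation coefficients
#'
#' For each protein i with at least one interaction partner belonging to a
#' complex, `n_is` counts the links of i to proteins in complex s (a partner
#' belonging to several complexes increments each of them), and
#' `P_i = sum_s (n_is / sum_s n_is)^2`. P tends to 1 when a protein
#' predominantly interacts with partners of a single complex and towards 1/N
#' when its links spread evenly over many complexes. Proteins with no
#' complexed partner have no defined coefficient and are reported as `NA`.
#'
#' @param net A `protein_network`.
#' @param catalog A nonempty `complex_catalog`.
#' @return A `participation_result` list: `p` (named numeric, `NA` where
#'   undefined), `n_complexed_links` (named integer: partners belonging to
#'   at least one complex), `n_complexes` (N).
#' @examples
#' net <- protein_network(rbind(c("i", "a"), c("i", "b")))
#' cat1 <- complex_catalog(list(c1 = c("a", "b")))
#' participation_coefficients(net, cat1)$p[["i"]] # 1
#' @export
participation_coefficients <- function(net, catalog) {
  stopifnot(inherits(catalog, "complex_catalog"))
  if (length(catalog) == 0L) stop("catalog is empty")
  memb <- membership_index(catalog)
  p <- rep(NA_real_, length(net$nodes))
  ncl <- integer(length(net$nodes))
  names(p) <- names(ncl) <- net$nodes
  for (v in seq_along(net$nodes)) {
    prt <- net$nodes[net$adj[[v]]]
    cxs <- memb[intersect(prt, names(memb))]
    ncl[v] <- length(cxs)
    if (length(cxs) == 0L) next
    n_is <- table(unlist(cxs, use.names = FALSE))
    frac <- as.numeric(n_is) / sum(n_is)
    p[v] <- sum(frac^2)
  }
  structure(list(p = p, n_complexed_links = ncl, n_complexes = length(catalog)),
            class = "participation_result")
}

#' @export
print.participation_result <- function(x, ...) {
  def <- x$p[!is.na(x$p)]
  cat(sprintf("Participation coefficients: %d/%d proteins defined, N = %d complexes\n",
              length(def), length(x$p), x$n_complexes))
  if (length(def)) {
    cat(sprintf("  median P = %.3f, range [%.3f, %.3f]\n",
                stats::median(def), min(def), max(def)))
  }
  invisible(x)
}

#' Compare participation coefficients between two protein groups
#'
#' Two-sided Wilcoxon rank-sum test on the defined participation
#' coefficients of two groups (e.g. e-MDSet versus essential proteins).
#' Exact enumeration is used when both groups have at most 20 defined values
#' and no ties; otherwise the normal approximation with tie correction.
#'
#' @param result A `participation_result`.
#' @param group_a,group_b Character vectors of protein identifiers.
#' @param labels Length-2 character vector naming the groups.
#' @return A list with `statistic` (rank-sum W), `p_value`, per-group sample
#'   sizes and medians.
#' @export
compare_participation <- function(result, group_a, group_b,
                                  labels = c("group_a", "group_b")) {
  pa <- result$p[intersect(as.character(group_a), names(result$p))]
  pb <- result$p[intersect(as.character(group_b), names(result$p))]
  pa <- pa[!is.na(pa)]; pb <- pb[!is.na(pb)]
  if (length(pa) == 0L || length(pb) == 0L) {
    stop("each group needs at least one protein with a defined coefficient")
  }
  exact <- length(pa) <= 20L && length(pb) <= 20L
  wt <- suppressWarnings(stats::wilcox.test(pa, pb, exact = exact, correct = !exact))
  structure(
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         n = c(length(pa), length(pb)),
         medians = c(stats::median(pa), stats::median(pb)),
         labels = labels),
    class = "participation_comparison"
  )
}

#' @export
print.participation_comparison <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum: %s (n=%d, median %.3f) vs %s (n=%d, median %.3f)\n",
              x$labels[1], x$n[1], x$medians[1], x$labels[2], x$n[2], x$medians[2]))
  cat(sprintf("  W = %g, p = %.4g\n", x$statistic, x$p_value))
  invisible(x)
}

#' Classify interactions of a focal set as intra- or inter-complex
#'
#' Considers only interactions with both endpoints in `focal`. An interaction
#' is intra-complex when its endpoints share at least one complex,
#' inter-complex when both endpoints belong to complexes but share none, and
#' excluded when at least one endpoint belongs to no complex.
#'
#' @param net A `protein_network`.
#' @param catalog A `complex_catalog`.
#' @param focal Character vector of proteins (subset of network nodes).
#' @return A `complex_interaction_counts` list: `intra`, `inter`, `excluded`,
#'   `total` (total = intra + inter + excluded = focal-set interactions).
#' @export
count_complex_interactions <- function(net, catalog, focal) {
  focal <- as.character(focal)
  if (!all(focal %in% net$nodes)) stop("focal contains non-network proteins")
  memb <- membership_index(catalog)
  e <- focal_edges(net, focal)
  cls <- classify_edges(net$nodes[e[, 1L]], net$nodes[e[, 2L]], memb)
  structure(list(intra = as.integer(cls[["intra"]]), inter = as.integer(cls[["inter"]]),
                 excluded = as.integer(cls[["excluded"]]), total = nrow(e)),
            class = "complex_interaction_counts")
}

#' @keywords internal
focal_edges <- function(net, focal) {
  fidx <- match(focal, net$nodes)
  in_focal <- logical(length(net$nodes)); in_focal[fidx] <- TRUE
  keep <- in_focal[net$edges[, 1L]] & in_focal[net$edges[, 2L]]
  net$edges[keep, , drop = FALSE]
}

#' @keywords internal
classify_edges <- function(a, b, memb) {
  ma <- memb[a]; mb <- memb[b]
  ca <- !vapply(ma, is.null, TRUE)
  cb <- !vapply(mb, is.null, TRUE)
  both <- ca & cb
  share <- logical(length(a))
  share[both] <- mapply(function(x, y) any(x %in% y), ma[both], mb[both])
  c(intra = sum(share), inter = sum(both & !share), excluded = sum(!both))
}

#' @export
print.complex_interaction_counts <- function(x, ...) {
  cat(sprintf("Focal-set interactions: %d intra-complex, %d inter-complex, %d excluded (total %d)\n",
              x$intra, x$inter, x$excluded, x$total))
  invisible(x)
}

#' Intra/inter-complex interaction enrichment under complex reassignment
#'
#' Null model: each of R draws rebuilds the catalog with the same complex
#' sizes, filling every complex independently by uniform sampling without
#' replacement (within that complex) from the universe of proteins appearing
#' in at least one real complex, then recounts the focal set's intra- and
#' inter-complex interactions. Empirical tails use the plus-one rule.
#'
#' @inheritParams count_complex_interactions
#' @param reps Number of null catalogs (default 10000).
#' @param seed Integer seed.
#' @return A list with elements `intra` and `inter`, each an
#'   `enrichment_result`, plus `observed` (the real
#'   `complex_interaction_counts`). With an empty focal set all counts are
#'   zero and the ratios are `NA`.
#' @export
complex_null_enrichment <- function(net, catalog, focal, reps = 10000, seed = NULL) {
  focal <- as.character(focal)
  if (!all(focal %in% net$nodes)) stop("focal contains non-network proteins")
  universe <- sort(unique(unlist(catalog, use.names = FALSE)))
  sizes <- lengths(catalog)
  if (any(sizes > length(universe))) {
    stop("a complex is larger than the complexed-protein universe")
  }
  observed <- count_complex_interactions(net, catalog, focal)
  e <- focal_edges(net, focal)
  # only edges with both endpoints in the universe can ever be classified
  ea <- net$nodes[e[, 1L]]; eb <- net$nodes[e[, 2L]]
  in_u <- ea %in% universe & eb %in% universe
  ia <- match(ea[in_u], universe); ib <- match(eb[in_u], universe)
  nu <- length(universe); nc <- length(catalog)
  cx_of_slot <- rep(seq_len(nc), sizes)
  draws <- with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      slots <- unlist(lapply(sizes, function(s) sample.int(nu, s)), use.names = FALSE)
      M <- matrix(FALSE, nu, nc)
      M[cbind(slots, cx_of_slot)] <- TRUE
      if (length(ia) == 0L) return(c(0, 0))
      Ma <- M[ia, , drop = FALSE]; Mb <- M[ib, , drop = FALSE]
      shared <- rowSums(Ma & Mb) > 0
      compl_a <- rowSums(Ma) > 0; compl_b <- rowSums(Mb) > 0
      c(sum(shared), sum(compl_a & compl_b & !shared))
    }, numeric(2))
  })
  intra <- new_enrichment_result(unname(observed$intra), draws[1L, ], reps, seed)
  inter <- new_enrichment_result(unname(observed$inter), draws[2L, ], reps, seed)
  list(intra = intra, inter = inter, observed = observed)
}
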