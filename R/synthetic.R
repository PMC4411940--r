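# Seeded generator of complete synthetic studies: a scale-free interaction
# network with planted essentiality (degree-coupled), overlapping protein
# complexes with elevated intra-complex wiring, and COG-style class labels
# with per-class degree bias. One global seed feeds a deterministic
# sub-stream per planter, so adding a planter never perturbs earlier draws.

#' Configuration of a synthetic study
#'
#' Defaults emulate the regime of a bacterial yeast-two-hybrid interactome:
#' about a thousand proteins, mean degree around four with a heavy-tailed
#' degree distribution, roughly a third of network proteins essential with a
#' moderate positive coupling between log-degree and the odds of
#' essentiality, a few dozen partially overlapping complexes with elevated
#' intra-complex edge density, and twenty COG-style single-letter classes
#' with the translation class (`J`) biased towards high-degree proteins.
#'
#' @param n_nodes Number of proteins (>= 10).
#' @param topology `"preferential-attachment"` or `"configuration"`.
#' @param m Edges attached per new node (preferential attachment).
#' @param gamma Power-law exponent (configuration model).
#' @param essential_fraction Target fraction of network proteins essential,
#'   in (0, 1).
#' @param essential_degree_coupling Log-odds of essentiality per unit
#'   log-degree (beta); 0 gives uniform labels.
#' @param n_complexes Number of complexes.
#' @param complex_size_range Integer `c(min, max)` complex sizes.
#' @param intra_complex_edge_boost Probability of adding an interaction
#'   between two complex co-members.
#' @param focal_intra_bias Additional probability for co-members that are
#'   both essential.
#' @param class_alphabet Character vector of single-letter class codes.
#' @param class_degree_bias Named numeric vector (names in
#'   `class_alphabet`) of per-class log-degree biases; unnamed classes get 0.
#' @param seed Integer seed; identical config implies identical study.
#' @return A `study_config` list.
#' @export
study_config <- function(n_nodes = 1200,
                         topology = c("preferential-attachment", "configuration"),
                         m = 2, gamma = 2.5,
                         essential_fraction = 0.3,
                         essential_degree_coupling = 1.0,
                         n_complexes = 40,
                         complex_size_range = c(3, 20),
                         intra_complex_edge_boost = 0.10,
                         focal_intra_bias = 0.15,
                         class_alphabet = c("J", "K", "L", "D", "O", "M", "N",
                                            "P", "T", "C", "G", "E", "F", "H",
                                            "I", "Q", "R", "S", "U", "V"),
                         class_degree_bias = c(J = 1.0),
                         seed = 1L) {
  topology <- match.arg(topology)
  stopifnot(n_nodes >= 10, essential_fraction > 0, essential_fraction < 1,
            length(complex_size_range) == 2L,
            complex_size_range[1] >= 2, complex_size_range[1] <= complex_size_range[2],
            intra_complex_edge_boost >= 0, intra_complex_edge_boost <= 1,
            focal_intra_bias >= 0)
  if (topology == "preferential-attachment" && m >= n_nodes) {
    stop("m must be smaller than n_nodes")
  }
  bias <- stats::setNames(rep(0, length(class_alphabet)), class_alphabet)
  if (length(class_degree_bias)) {
    unknown <- setdiff(names(class_degree_bias), class_alphabet)
    if (length(unknown)) stop("class_degree_bias names outside the alphabet")
    bias[names(class_degree_bias)] <- class_degree_bias
  }
  structure(
    list(n_nodes = as.integer(n_nodes), topology = topology, m = as.integer(m),
         gamma = gamma, essential_fraction = essential_fraction,
         essential_degree_coupling = essential_degree_coupling,
         n_complexes = as.integer(n_complexes),
         complex_size_range = as.integer(complex_size_range),
         intra_complex_edge_boost = intra_complex_edge_boost,
         focal_intra_bias = focal_intra_bias,
         class_alphabet = class_alphabet, class_degree_bias = bias,
         seed = as.integer(seed)),
    class = "study_config"
  )
}

#' Generate a synthetic scale-free interaction network
#'
#' Preferential attachment (undirected, `m` links per new node) gives
#' heavy-tailed degrees with mean degree close to `2m`; the configuration
#' model draws degrees from a discrete power law with exponent `gamma`
#' (minimum degree 1) and simplifies the resulting multigraph. Nodes are
#' named `P0001`, `P0002`, ... so that sorted node order equals generation
#' order.
#'
#' @param config A `study_config`.
#' @return A `protein_network`.
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "study_config"))
  n <- config$n_nodes
  g <- with_seed(sub_seed(config$seed, 1L), {
    if (config$topology == "preferential-attachment") {
      igraph::sample_pa(n, m = config$m, directed = FALSE)
    } else {
      kmax <- floor(sqrt(n))
      ks <- 1:kmax
      degs <- sample(ks, n, replace = TRUE, prob = ks^(-config$gamma))
      if (sum(degs) %% 2 == 1) degs[1L] <- degs[1L] + 1L
      igraph::simplify(igraph::sample_degseq(degs, method = "configuration"))
    }
  })
  width <- nchar(as.character(n))
  nodes <- sprintf(paste0("P%0", width, "d"), seq_len(n))
  el <- igraph::as_edgelist(g, names = FALSE)
  protein_network(cbind(nodes[el[, 1L]], nodes[el[, 2L]]), nodes = nodes,
                  name = sprintf("synthetic-%s-n%d", config$topology, n),
                  quiet = TRUE)
}

#' Plant degree-coupled essentiality labels
#'
#' Each protein is labelled essential independently with probability
#' `plogis(alpha + beta * log(max(degree, 1)))`; the intercept alpha is
#' calibrated by root finding so the expected essential fraction matches the
#' target within 0.01. `beta = 0` reduces to uniform labels.
#'
#' @param net A `protein_network`.
#' @param fraction Target essential fraction, in (0, 1).
#' @param beta Log-odds of essentiality per unit log-degree.
#' @param seed Integer seed.
#' @return Character vector of essential protein identifiers (class
#'   `gene_set`), with the calibrated `alpha` as an attribute.
#' @export
plant_essentiality <- function(net, fraction, beta, seed) {
  stopifnot(fraction > 0, fraction < 1)
  lk <- log(pmax(lengths(net$adj), 1L))
  f <- function(a) mean(stats::plogis(a + beta * lk)) - fraction
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0) {
    stop(sprintf("essential fraction %.3f unattainable for beta = %.2f on this degree sequence (range [%.4f, %.4f])",
                 fraction, beta, fraction + f(lo), fraction + f(hi)))
  }
  alpha <- stats::uniroot(f, c(lo, hi), tol = 1e-6)$root
  if (abs(f(alpha)) > 0.01) stop("intercept calibration did not converge") # nocov
  prob <- stats::plogis(alpha + beta * lk)
  ess <- with_seed(seed, net$nodes[stats::runif(length(prob)) < prob])
  structure(ess, label = "essential", alpha = alpha,
            class = c("gene_set", "character"))
}

#' Plant overlapping protein complexes with elevated intra-complex wiring
#'
#' Complex sizes are drawn uniformly from `complex_size_range`; members are
#' sampled without replacement within a complex with probability
#' proportional to degree + 1 (so participation analyses have nondegenerate
#' support), and overlap between complexes is permitted. Each co-member pair
#' then gains an interaction with probability `intra_complex_edge_boost`,
#' plus `focal_intra_bias` when both members are essential; the returned
#' network stays simple.
#'
#' @param net A `protein_network`.
#' @param config A `study_config`.
#' @param essential Character vector of essential proteins.
#' @param seed Integer seed.
#' @return A list with `network` (augmented `protein_network`) and `catalog`
#'   (`complex_catalog`).
#' @export
plant_complexes <- function(net, config, essential, seed) {
  n <- length(net$nodes)
  rng <- config$complex_size_range
  if (rng[2] > n) stop("complex sizes exceed the network")
  w <- lengths(net$adj) + 1
  is_ess <- net$nodes %in% essential
  res <- with_seed(seed, {
    sizes <- sample(seq(rng[1], rng[2]), config$n_complexes, replace = TRUE)
    cx <- lapply(sizes, function(s) sort(sample.int(n, s, prob = w)))
    new_edges <- list()
    for (members in cx) {
      prs <- utils::combn(members, 2L)
      p_add <- config$intra_complex_edge_boost +
        config$focal_intra_bias * (is_ess[prs[1L, ]] & is_ess[prs[2L, ]])
      add <- stats::runif(ncol(prs)) < pmin(p_add, 1)
      if (any(add)) new_edges[[length(new_edges) + 1L]] <- prs[, add, drop = FALSE]
    }
    list(cx = cx, new_edges = new_edges)
  })
  catalog <- complex_catalog(stats::setNames(
    lapply(res$cx, function(ix) net$nodes[ix]),
    sprintf("cpx%03d", seq_along(res$cx))
  ))
  if (length(res$new_edges)) {
    extra <- do.call(cbind, res$new_edges)
    all_e <- rbind(net$edges,
                   cbind(pmin(extra[1L, ], extra[2L, ]), pmax(extra[1L, ], extra[2L, ])))
    net2 <- protein_network(cbind(net$nodes[all_e[, 1L]], net$nodes[all_e[, 2L]]),
                            nodes = net$nodes, name = net$name, quiet = TRUE)
  } else {
    net2 <- net
  }
  list(network = net2, catalog = catalog)
}

#' @keywords internal
plant_classes <- function(net, config, seed) {
  lk <- log(pmax(lengths(net$adj), 1L))
  bias <- config$class_degree_bias
  with_seed(seed, {
    codes <- lapply(seq_along(net$nodes), function(v) {
      wts <- exp(bias * lk[v])
      primary <- sample(config$class_alphabet, 1L, prob = wts)
      if (length(config$class_alphabet) > 1L && stats::runif(1) < 0.1) {
        extra <- sample(setdiff(config$class_alphabet, primary), 1L)
        c(primary, extra)
      } else primary
    })
    structure(stats::setNames(codes, net$nodes), class = "class_annotation")
  })
}

#' Generate a complete synthetic study
#'
#' Runs the network generator and the three planters (essentiality,
#' complexes with intra-complex wiring, class labels — the labels use a
#' softmax over the per-class degree biases evaluated at each protein's
#' log-degree) and optionally writes every artifact in the package's file
#' dialects. Output is fully determined by the config (including its seed):
#' the same config writes byte-identical files.
#'
#' @param config A `study_config`.
#' @param dir Optional directory; when given, writes `network.tsv`
#'   (edge list), `essential.txt`, `complexes.tsv` (long dialect),
#'   `classes.tsv` and `truth.json`.
#' @return A `synthetic_study` list: `network`, `essential`, `catalog`,
#'   `annotation`, `truth` (the planted parameters, including the calibrated
#'   essentiality intercept).
#' @export
generate_study <- function(config, dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  net0 <- generate_network(config)
  essential <- plant_essentiality(net0, config$essential_fraction,
                                  config$essential_degree_coupling,
                                  sub_seed(config$seed, 2L))
  pc <- plant_complexes(net0, config, essential, sub_seed(config$seed, 3L))
  annotation <- plant_classes(pc$network, config, sub_seed(config$seed, 4L))
  study <- structure(
    list(network = pc$network, essential = essential, catalog = pc$catalog,
         annotation = annotation,
         truth = c(config[setdiff(names(config), "class_degree_bias")],
                   list(class_degree_bias = config$class_degree_bias,
                        alpha = attr(essential, "alpha"),
                        n_essential = length(essential)))),
    class = "synthetic_study"
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_edge_list(study$network, file.path(dir, "network.tsv"))
    write_gene_set(study$essential, file.path(dir, "essential.txt"))
    write_complex_catalog(study$catalog, file.path(dir, "complexes.tsv"), "long")
    write_class_annotation(study$annotation, file.path(dir, "classes.tsv"))
    jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  study
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic study:\n  ")
  print(x$network)
  cat(sprintf("  %d essential proteins, %d complexes, %d annotated proteins\n",
              length(x$essential), length(x$catalog), length(x$annotation)))
  invisible(x)
}
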