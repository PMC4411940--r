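test_that("preferential attachment hits the target mean degree and is heavy-tailed", {
  cfg <- study_config(n_nodes = 1000, m = 2, seed = 1)
  net <- generate_network(cfg)
  md <- network_summary(net)$mean_degree
  expect_gte(md, 3.6)
  expect_lte(md, 4.4)
  deg <- node_degree(net)
  expect_gt(max(deg), 10 * mean(deg) / 4) # hubs far above the mean
})

test_that("generation is deterministic in the config seed", {
  cfg <- study_config(n_nodes = 300, seed = 5)
  a <- generate_network(cfg)
  b <- generate_network(cfg)
  expect_identical(a$edges, b$edges)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$network$edges, s2$network$edges)
  expect_identical(as.character(s1$essential), as.character(s2$essential))
  expect_identical(unclass(s1$catalog), unclass(s2$catalog))
  expect_identical(unclass(s1$annotation), unclass(s2$annotation))
})

test_that("configuration model recovers the requested power-law tail", {
  cfg <- study_config(n_nodes = 2000, topology = "configuration", gamma = 2.5, seed = 8)
  net <- generate_network(cfg)
  deg <- node_degree(net)
  deg <- deg[deg >= 1]
  # maximum-likelihood exponent under the truncated discrete power law
  ks <- 1:floor(sqrt(2000))
  nll <- function(g) g * sum(log(deg)) + length(deg) * log(sum(ks^(-g)))
  gamma_hat <- stats::optimize(nll, c(1.2, 5))$minimum
  expect_lt(abs(gamma_hat - 2.5), 0.3)
})

test_that("planted essentiality calibrates the fraction and couples to degree", {
  cfg <- study_config(n_nodes = 1500, seed = 3)
  net <- generate_network(cfg)
  # beta = 0: realized fraction within binomial 99% bounds of the target
  ess0 <- plant_essentiality(net, 0.3, 0, seed = 11)
  n <- length(net$nodes)
  bounds <- qbinom(c(0.005, 0.995), n, 0.3) / n
  frac <- length(ess0) / n
  expect_gte(frac, bounds[1])
  expect_lte(frac, bounds[2])
  # positive coupling raises the mean degree of essential proteins
  hits <- 0L
  for (r in 1:20) {
    ess <- plant_essentiality(net, 0.3, 1.5, seed = 100 + r)
    deg <- node_degree(net)
    if (mean(deg[ess]) > mean(deg)) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
  expect_error(plant_essentiality(net, 0.999999, -50, seed = 1), "unattainable")
})

test_that("intra-complex boost adds co-member edges; zero boost leaves the network intact", {
  cfg0 <- study_config(n_nodes = 200, intra_complex_edge_boost = 0,
                       focal_intra_bias = 0, seed = 6)
  net <- generate_network(cfg0)
  ess <- plant_essentiality(net, 0.3, 1, seed = 2)
  pc0 <- plant_complexes(net, cfg0, ess, seed = 3)
  expect_identical(pc0$network$edges, net$edges)
  cfg1 <- study_config(n_nodes = 200, intra_complex_edge_boost = 1,
                       focal_intra_bias = 0, seed = 6)
  pc1 <- plant_complexes(net, cfg1, ess, seed = 3)
  # boost = 1: every complex induces a clique
  for (cx in pc1$catalog) {
    prs <- utils::combn(cx, 2)
    for (j in seq_len(ncol(prs))) {
      expect_true(prs[2, j] %in% partners(pc1$network, prs[1, j]))
    }
  }
})

test_that("generated studies cross-reference and round trip through the readers", {
  cfg <- study_config(n_nodes = 250, seed = 10)
  dir <- withr::local_tempdir()
  study <- generate_study(cfg, dir = dir)
  expect_true(all(unlist(study$catalog) %in% study$network$nodes))
  expect_true(all(as.character(study$essential) %in% study$network$nodes))
  expect_true(all(names(study$annotation) %in% study$network$nodes))
  back <- list(
    network = read_edge_list(file.path(dir, "network.tsv"), quiet = TRUE),
    essential = read_gene_set(file.path(dir, "essential.txt")),
    catalog = read_complex_catalog(file.path(dir, "complexes.tsv"), "long"),
    annotation = read_class_annotation(file.path(dir, "classes.tsv"))
  )
  expect_identical(back$network$nodes, study$network$nodes)
  expect_identical(back$network$edges, study$network$edges)
  expect_setequal(as.character(back$essential), as.character(study$essential))
  expect_identical(lapply(back$catalog, sort)[sort(names(back$catalog))],
                   lapply(study$catalog, sort)[sort(names(study$catalog))])
  ord <- names(study$annotation)
  expect_identical(unclass(back$annotation)[ord], unclass(study$annotation)[ord])
})

test_that("study files are byte-identical across runs with the same config", {
  cfg <- study_config(n_nodes = 120, seed = 14)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_study(cfg, dir = d1)
  generate_study(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("infeasible configs are rejected", {
  expect_error(study_config(n_nodes = 5), "n_nodes")
  expect_error(study_config(n_nodes = 20, m = 25), "smaller")
  expect_error(study_config(n_nodes = 100, essential_fraction = 0), "essential_fraction")
  expect_error(study_config(n_nodes = 100, class_degree_bias = c(ZZ = 1)), "alphabet")
})
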