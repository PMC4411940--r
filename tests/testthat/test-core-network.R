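test_that("edge lists are normalized: self-loops dropped, duplicates merged, adjacency symmetric", {
  path <- withr::local_tempfile()
  writeLines(c("A\tB", "B\tA", "C\tC", "A\tB"), path)
  expect_message(net <- read_edge_list(path), "1 self-loop.*2 duplicate")
  expect_setequal(net$nodes, c("A", "B", "C"))
  expect_equal(n_edges(net), 1L)
  expect_equal(partners(net, "A"), "B")
  expect_equal(partners(net, "B"), "A")
  expect_equal(partners(net, "C"), character(0))

  path2 <- withr::local_tempfile()
  writeLines(c("# a comment", "A\tB", "", "B\tC"), path2)
  net2 <- read_edge_list(path2, quiet = TRUE)
  expect_setequal(partners(net2, "B"), c("A", "C"))
})

test_that("SIF dialect parses and the relation column is ignored", {
  path <- withr::local_tempfile()
  writeLines(c("A\tpp\tB", "B\tpp\tC"), path)
  net <- read_edge_list(path, format = "sif", quiet = TRUE)
  expect_setequal(partners(net, "B"), c("A", "C"))
})

test_that("malformed and empty edge lists raise informative errors", {
  path <- withr::local_tempfile()
  writeLines(c("A\tB", "oops"), path)
  expect_error(read_edge_list(path, quiet = TRUE), "line 2")
  empty <- withr::local_tempfile()
  writeLines("# only a comment", empty)
  expect_error(read_edge_list(empty, quiet = TRUE), "no interactions")
})

test_that("normalization is idempotent", {
  net <- rand_net(40, 0.1, seed = 11)
  renorm <- protein_network(cbind(net$nodes[net$edges[, 1]], net$nodes[net$edges[, 2]]),
                            nodes = net$nodes, quiet = TRUE)
  expect_identical(renorm$nodes, net$nodes)
  expect_identical(renorm$edges, net$edges)
})

test_that("edge list round trip preserves node and edge sets", {
  for (seed in 1:5) {
    net <- rand_net(100, 0.04, seed = seed)
    net <- protein_network(cbind(net$nodes[net$edges[, 1]], net$nodes[net$edges[, 2]]),
                           quiet = TRUE) # drop isolates: edge lists cannot carry them
    path <- withr::local_tempfile()
    write_edge_list(net, path)
    back <- read_edge_list(path, quiet = TRUE)
    expect_identical(back$nodes, net$nodes)
    expect_identical(back$edges, net$edges)
  }
})

test_that("gene sets collapse duplicates, survive round trips, and warn when empty", {
  path <- withr::local_tempfile()
  writeLines(c("g1", "g2", "g1"), path)
  expect_setequal(as.character(read_gene_set(path)), c("g1", "g2"))

  empty <- withr::local_tempfile()
  writeLines(character(0), empty)
  expect_warning(gs <- read_gene_set(empty), "empty")
  expect_length(gs, 0L)

  rt <- withr::local_tempfile()
  ids <- sprintf("prot%02d", sample(1:50, 30))
  write_gene_set(ids, rt)
  expect_setequal(as.character(read_gene_set(rt)), unique(ids))
})

test_that("complex catalogs parse both dialects and round trip equally", {
  long <- withr::local_tempfile()
  writeLines(c("c1\tA", "c1\tB", "c2\tB"), long)
  cat_l <- read_complex_catalog(long, "long")
  expect_length(cat_l, 2L)
  expect_setequal(cat_l$c1, c("A", "B"))
  expect_equal(cat_l$c2, "B")

  wide <- withr::local_tempfile()
  writeLines("c1\tA;B;C", wide)
  expect_length(read_complex_catalog(wide, "wide")$c1, 3L)

  catalog <- complex_catalog(list(x = c("A", "B", "C"), y = c("B", "D")))
  for (fmt in c("long", "wide")) {
    path <- withr::local_tempfile()
    write_complex_catalog(catalog, path, fmt)
    back <- read_complex_catalog(path, fmt)
    expect_identical(lapply(back, sort), lapply(catalog, sort))
  }
  expect_error(complex_catalog(list(bad = character(0))), "nonempty")
})

test_that("class annotations split letter strings and round trip", {
  path <- withr::local_tempfile()
  writeLines(c("p1\tKLT", "p2\tJ"), path)
  ann <- read_class_annotation(path)
  expect_setequal(ann$p1, c("K", "L", "T"))
  expect_equal(ann$p2, "J")
  rt <- withr::local_tempfile()
  write_class_annotation(ann, rt)
  expect_identical(read_class_annotation(rt), ann)
})

test_that("network summary follows mean_degree = 2E/N and rejects empty networks", {
  tri <- cycle_net(3)
  expect_equal(network_summary(tri)$mean_degree, 2)
  star <- star_net(4)
  expect_equal(network_summary(star)$mean_degree, 1.6)
  expect_error(network_summary(protein_network(matrix(character(0), ncol = 2))),
               "empty")
})

test_that("component counts match a flood-fill oracle and sizes sum to n", {
  two <- protein_network(rbind(c("A", "B"), c("C", "D")), quiet = TRUE)
  expect_equal(network_components(two)$n, 2L)
  pth <- protein_network(rbind(c("A", "B"), c("B", "C")), nodes = c("A", "B", "C", "D"),
                         quiet = TRUE)
  expect_equal(network_components(pth)$n, 2L)
  for (seed in 1:6) {
    net <- rand_net(50, 0.03, seed = seed)
    got <- network_components(net)
    oracle <- flood_fill_components(net$nodes, adj_list(net))
    expect_equal(got$n, oracle$n)
    expect_equal(sum(got$sizes), length(net$nodes))
    expect_setequal(got$sizes, oracle$sizes)
  }
})
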