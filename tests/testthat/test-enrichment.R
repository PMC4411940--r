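test_that("betweenness matches hand values and the geodesic-enumeration oracle", {
  p3 <- path_net(3)
  cb <- betweenness_centrality(p3)
  expect_equal(unname(cb[c("n1", "n2", "n3")]), c(0, 1, 0))
  st <- star_net(5)
  expect_equal(unname(betweenness_centrality(st)["hub"]), choose(5, 2))
  for (seed in 1:8) {
    net <- rand_net(sample(15:30, 1), runif(1, 0.08, 0.2), seed = 300 + seed)
    expect_equal(betweenness_centrality(net), brute_betweenness(net), tolerance = 1e-10)
  }
})

test_that("bottleneck set takes the top ceiling(q*n) scores with deterministic ties", {
  scores <- setNames(c(5, 4, 3, 2, 1, 1, 1, 1, 1, 1), sprintf("p%02d", 1:10))
  expect_setequal(bottleneck_set(scores, 0.2), c("p01", "p02"))
  tied <- setNames(rep(2, 10), sprintf("p%02d", 1:10))
  expect_equal(bottleneck_set(tied, 0.2), c("p01", "p02"))
  net <- rand_net(100, 0.05, seed = 9)
  sc <- betweenness_centrality(net)
  got <- bottleneck_set(sc, 0.2)
  ord <- order(-sc, names(sc))
  expect_setequal(got, names(sc)[ord[1:20]])
  expect_length(got, ceiling(0.2 * 100))
})

test_that("degree enrichment is exactly 1 when every protein is marked", {
  net <- rand_net(80, 0.06, seed = 12)
  cur <- degree_enrichment_curve(net, net$nodes, reps = 50, seed = 1)
  expect_true(all(abs(cur$enrichment - 1) < 1e-12))
  expect_true(all(cur$p_ge == 1))
})

test_that("degree enrichment curves are reproducible and monotone in bin sizes", {
  net <- rand_net(150, 0.04, seed = 13)
  marked <- sample(net$nodes, 40)
  a <- degree_enrichment_curve(net, marked, reps = 200, seed = 7)
  b <- degree_enrichment_curve(net, marked, reps = 200, seed = 7)
  expect_identical(a, b)
  expect_true(all(diff(a$n_geq_k) <= 0))
  expect_true(all(a$n_marked_geq_k <= a$n_geq_k))
  c2 <- degree_enrichment_curve(net, marked, reps = 200, seed = 8)
  expect_false(identical(a$null_mean, c2$null_mean))
})

test_that("mean-of-ratios variant skips zero null draws but stays close to the default", {
  net <- rand_net(120, 0.05, seed = 21)
  marked <- sample(net$nodes, 50)
  a <- degree_enrichment_curve(net, marked, k_values = 1:3, reps = 500, seed = 2)
  m <- degree_enrichment_curve(net, marked, k_values = 1:3, reps = 500, seed = 2,
                               stat = "mean-of-ratios")
  expect_equal(a$n_marked_geq_k, m$n_marked_geq_k)
  expect_true(all(abs(a$enrichment - m$enrichment) < 0.5))
})

test_that("log-degree bin fractions match a direct recount", {
  net <- rand_net(120, 0.05, seed = 14)
  deg <- node_degree(net)
  den <- names(deg)[deg >= 1][1:60]
  num <- den[seq(1, 60, by = 3)]
  tab <- log_degree_bin_fractions(net, num, den)
  # direct recount with independent binning
  for (i in seq_len(nrow(tab))) {
    in_bin <- names(deg)[deg >= tab$bin_lo[i] & deg <= tab$bin_hi[i] & deg >= 1]
    expect_equal(tab$n_denominator[i], length(intersect(den, in_bin)))
    expect_equal(tab$n_numerator[i], length(intersect(num, in_bin)))
    if (tab$n_denominator[i] > 0) {
      expect_equal(tab$fraction[i], tab$n_numerator[i] / tab$n_denominator[i])
    } else {
      expect_true(is.na(tab$fraction[i]))
    }
  }
  expect_true(all(log_degree_bin_fractions(net, den, den)$fraction %in% c(1, NA)))
  expect_true(all(log_degree_bin_fractions(net, character(0), den)$fraction %in% c(0, NA)))
  expect_error(log_degree_bin_fractions(net, "not-in-den", den), "subset")
})

test_that("set overlap null mean matches the hypergeometric expectation", {
  net <- rand_net(20, 0.2, seed = 15)
  target <- net$nodes[1:5]
  marked <- net$nodes[8:15]
  res <- set_overlap_enrichment(net, target, marked, reps = 4000, seed = 3)
  expect_equal(res$observed, length(intersect(target, marked)))
  expect_lt(abs(res$null_mean - 5 * 8 / 20), 3 * res$null_sd / sqrt(4000) + 0.05)
  # marked = all nodes forces ratio 1, p_ge 1
  all_res <- set_overlap_enrichment(net, target, net$nodes, reps = 100, seed = 1)
  expect_equal(all_res$observed, length(target))
  expect_equal(all_res$ratio, 1)
  expect_equal(all_res$p_ge, 1)
  expect_error(set_overlap_enrichment(net, character(0), marked), "empty")
})

test_that("empirical p-values respect the plus-one rule bounds", {
  net <- rand_net(50, 0.1, seed = 16)
  res <- set_overlap_enrichment(net, net$nodes[1:10], net$nodes[20:40],
                                reps = 99, seed = 2)
  expect_gte(res$p_ge, 1 / 100)
  expect_lte(res$p_ge, 1)
  expect_gte(res$p_le, 1 / 100)
})

test_that("fisher_overlap equals exhaustive fixed-margin enumeration", {
  grid <- expand.grid(N = c(10, 20, 35), a = c(3, 8), b = c(2, 5))
  for (i in seq_len(nrow(grid))) {
    N <- grid$N[i]; a <- grid$a[i]; b <- grid$b[i]
    for (x in max(0, a + b - N):min(a, b)) {
      expect_equal(fisher_overlap(N, a, b, x), enum_fisher_tail(N, a, b, x),
                   tolerance = 1e-12)
    }
  }
  expect_equal(fisher_overlap(20, 20, 5, 5), 1)
  expect_error(fisher_overlap(20, 8, 5, 6), "overlap")
  expect_error(fisher_overlap(20, 25, 5, 2), "exceed")
})

test_that("fisher_overlap agrees with fisher.test's one-sided alternative", {
  p1 <- fisher_overlap(20, 8, 5, 4)
  tab <- matrix(c(4, 8 - 4, 5 - 4, 20 - 8 - 5 + 4), 2)
  p2 <- stats::fisher.test(tab, alternative = "greater")$p.value
  expect_equal(p1, p2, tolerance = 1e-12)
})
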