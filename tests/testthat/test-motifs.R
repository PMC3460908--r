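test_that("the shipped triad dictionary is a valid 13-class taxonomy", {
  dict <- motif_dictionary()
  expect_equal(nrow(dict), 13)
  expect_equal(sort(dict$n_edges), c(2, 2, 2, 3, 3, 3, 3, 4, 4, 4, 4, 5, 6))
  expect_identical(which(dict$is_apex_class), c(4L, 6L, 9L))
  # class 9 is the doubly reciprocal apex, 13 the full reciprocal triangle
  expect_equal(dict$n_edges[9], 4)
  expect_equal(dict$n_edges[13], 6)
})

test_that("census matches fixtures exactly", {
  star <- fixture_library()$reciprocal_star_5
  cen <- triad_census(star)
  expect_equal(unname(cen$class_count["M9"]), choose(5, 2))
  expect_equal(sum(cen$class_count), choose(5, 2))       # only M9 triads
  expect_equal(unname(cen$node_apex_count["hub", "M9"]), choose(5, 2))
  cyc <- triad_census(fixture_library()$cycle_3)
  expect_equal(unname(cyc$class_count["M7"]), 1)
  expect_equal(sum(cyc$class_count), 1)
  full <- triad_census(fixture_library()$reciprocal_triangle)
  expect_equal(unname(full$class_count["M13"]), 1)
})

test_that("census equals a brute-force permutation-matching oracle", {
  set.seed(37)
  for (rep in 1:40) {
    net <- rand_digraph(sample(4:6, 1), runif(1, 0.15, 0.75))
    got <- triad_census(net)
    expect_equal(unname(got$class_count), as.numeric(oracle_triad_census(net)))
    # participation sums: each instance involves 3 nodes
    expect_equal(colSums(got$node_participation),
                 3 * got$class_count, ignore_attr = TRUE)
    expect_true(all(got$node_apex_count <= got$node_participation))
  }
})

test_that("census class totals agree with igraph's triad census", {
  # igraph orders triads by the MAN classification; compare via sorted counts
  set.seed(41)
  for (rep in 1:10) {
    net <- rand_digraph(10, 0.3)
    ours <- triad_census(net)$class_count
    ig <- igraph::triad_census(as_igraph(net))[-(1:3)]   # drop disconnected
    expect_equal(sort(as.numeric(ours)), sort(as.numeric(ig)))
    expect_equal(sum(ours), sum(ig))
  }
})

test_that("apex ratio separates star centres from leaves", {
  cen <- triad_census(fixture_library()$reciprocal_star_5)
  ar <- apex_ratio(cen, classes = 9)
  expect_equal(unname(ar["hub"]), 1)
  expect_equal(unname(ar["leaf1"]), 0)
  expect_true(all(apex_ratio(cen) >= 0 & apex_ratio(cen) <= 1))
})

test_that("motif z-scores flag zero-spread classes and planted stars", {
  net <- fixture_library()$two_clique_bridge
  frozen <- structure(list(members = rep(list(net), 3), model = "randomized",
                           seed = 0, swaps_per_edge = 0), class = "null_ensemble")
  frozen_l <- structure(list(members = rep(list(net), 3), model = "latticized",
                             seed = 0, swaps_per_edge = 0), class = "null_ensemble")
  z <- motif_zscores(net, frozen, frozen_l)
  expect_true(all(z$sd_zero))
  expect_true(all(is.na(z$z_random)))

  # planted macaque-like core: the doubly reciprocal apex class beats
  # degree-matched randomized nulls across seeds
  for (s in 1:3) {
    g <- generate_network(synthetic_spec(n_nodes = 100, rc_size = 8,
                                         rc2_size = 12, seed = s))
    rand <- build_ensemble(g$net, "randomized", 30, seed = s + 50)
    latt <- build_ensemble(g$net, "latticized", 30, seed = s + 60)
    z <- motif_zscores(g$net, rand, latt)
    expect_gt(z$z_random[z$class == "M9"], 3)
  }
})

test_that("star centres combine high apex ratios with low clustering", {
  # planted stars over background noise: 5 hubs, 8 exclusive leaves each,
  # leaves mutually unconnected
  set.seed(61)
  n <- 60
  a <- matrix(as.integer(runif(n * n) < 0.05), n, n)
  diag(a) <- 0L
  hubs <- seq(1, 5)
  leaves <- split(5 + seq_len(40), rep(1:5, each = 8))
  for (h in hubs) {
    lv <- leaves[[h]]
    a[h, lv] <- a[lv, h] <- 1L
    a[lv, lv] <- 0L
  }
  net <- connection_matrix(a)
  cen <- triad_census(net)
  ar <- apex_ratio(cen)
  cc <- clustering_directed(net)
  expect_gt(mean(ar[hubs]), mean(ar[-hubs]))
  expect_lt(mean(cc[hubs]), mean(cc[-hubs]))
})

test_that("star search is exact on small graphs and respects the constraints", {
  star <- fixture_library()$reciprocal_star_5
  res <- largest_star(star, "hub", seed = 1)
  expect_setequal(res$leaves, paste0("leaf", 1:5))
  # reciprocal clique centre: only one leaf can be kept
  a <- matrix(1L, 5, 5); diag(a) <- 0L
  res2 <- largest_star(connection_matrix(a), 1, seed = 1)
  expect_equal(attr(res2, "size"), 1)
  # no reciprocal neighbour: size 0
  res3 <- largest_star(fixture_library()$cycle_3, "A")
  expect_equal(attr(res3, "size"), 0)

  set.seed(43)
  for (rep in 1:25) {
    net <- rand_digraph(sample(6:11, 1), runif(1, 0.3, 0.7))
    a <- net$adjacency
    for (centre in seq_len(n_nodes(net))) {
      got <- largest_star(net, centre, seed = rep)
      recips <- setdiff(which(a[centre, ] == 1 & a[, centre] == 1), centre)
      conflict <- (a[recips, recips, drop = FALSE] +
                     t(a[recips, recips, drop = FALSE])) > 0
      expect_equal(attr(got, "size"), oracle_max_independent_set(conflict))
      # validity: all leaves reciprocal to centre, no edges among leaves
      lv <- match(got$leaves, net$labels)
      expect_true(all(a[centre, lv] == 1 & a[lv, centre] == 1))
      if (length(lv) > 1) {
        expect_equal(sum(a[lv, lv]), 0)
      }
    }
  }
})

test_that("planted club nodes carry larger stars than the periphery", {
  g <- generate_network(synthetic_spec(seed = 2))
  sz <- star_sizes(g$net, restarts = 5, seed = 1)
  in_rc <- g$net$labels %in% g$truth$rc_nodes
  expect_gt(median(sz[in_rc]), median(sz[!in_rc]))
  wt <- wilcox.test(sz[in_rc], sz[!in_rc], alternative = "greater")
  expect_lt(wt$p.value, 0.001)
})
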