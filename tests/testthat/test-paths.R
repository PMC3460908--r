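test_that("path counts match fixtures and the enumeration oracle", {
  grid <- fixture_library()$grid_2x2
  ps <- count_shortest_paths(grid)
  expect_equal(ps$sigma["s", "t"], 2)
  comp <- count_shortest_paths(fixture_library()$complete_5)
  expect_equal(comp$total_paths, 5 * 4)

  set.seed(47)
  for (rep in 1:20) {
    net <- rand_digraph(sample(3:6, 1), runif(1, 0.2, 0.7))
    got <- count_shortest_paths(net)
    oracle <- oracle_path_stats(net)
    expect_equal(unname(got$sigma), oracle$sigma)
    expect_equal(got$total_paths, oracle$total)
    eu <- got$edge_usage
    for (r in seq_len(nrow(eu))) {
      i <- match(eu$source[r], net$labels)
      j <- match(eu$target[r], net$labels)
      expect_equal(eu$usage[r], oracle$edge_usage[i, j])
    }
    expect_equal(unname(got$node_usage), oracle$node_usage)
  }
})

test_that("edge usage conservation: summed usage equals summed path lengths", {
  for (s in 1:3) {
    net <- generate_network(synthetic_spec(n_nodes = 60, rc_size = 6,
                                           rc2_size = 8, seed = s))$net
    ps <- count_shortest_paths(net)
    d <- shortest_distances(net)
    conn <- is.finite(d) & row(d) != col(d)
    expect_equal(sum(ps$edge_usage$usage), sum(ps$sigma[conn] * d[conn]))
    expect_gte(ps$total_paths, ps$n_connected_pairs)
  }
})

test_that("rc participation by complement equals enumeration on fixtures", {
  enum_touch <- function(net, rc_labels) {
    rc <- match(rc_labels, net$labels)
    paths <- oracle_all_shortest_paths(net$adjacency)
    tot <- 0; touch <- 0; travel <- 0
    for (key in names(paths)) {
      st <- as.integer(strsplit(key, " ")[[1]])
      if (any(st %in% rc)) next
      for (p in paths[[key]]) {
        tot <- tot + 1
        if (any(p[-c(1, length(p))] %in% rc)) touch <- touch + 1
        if (length(p) > 1) {
          steps <- cbind(p[-length(p)], p[-1])
          if (any(steps[, 1] %in% rc & steps[, 2] %in% rc)) travel <- travel + 1
        }
      }
    }
    c(touch = touch / tot, travel = travel / tot)
  }
  set.seed(53)
  for (rep in 1:12) {
    net <- rand_digraph(sample(5:7, 1), runif(1, 0.25, 0.6))
    rc <- sample(net$labels, 2)
    got <- rc_participation(net, rc)
    want <- enum_touch(net, rc)
    expect_equal(got$frac_touch_node, unname(want["touch"]), tolerance = 1e-12)
    expect_equal(got$frac_travel_edge, unname(want["travel"]), tolerance = 1e-12)
    expect_lte(got$frac_travel_edge, got$frac_touch_node + 1e-12)
  }
  # empty club: zero by convention
  z <- rc_participation(fixture_library()$complete_5, character(0))
  expect_equal(z$frac_touch_node, 0)
  expect_equal(z$frac_travel_edge, 0)
})

test_that("planted club dominates path participation beyond its size", {
  g <- generate_network(synthetic_spec(seed = 3))
  rp <- rc_participation(g$net, g$truth$rc_nodes)
  expect_gt(rp$frac_touch_node, 0.3)        # 5% of nodes touch >30% of paths
  expect_gt(rp$frac_travel_edge, 0.05)
  cm <- cross_module_paths(g$net, g$truth$module_of, g$truth$rc_nodes)
  expect_gt(cm$frac_overall, rp$frac_touch_node * 0.8)
  expect_true(all(cm$per_pair$frac_rc >= 0 & cm$per_pair$frac_rc <= 1,
                  na.rm = TRUE))
  # all nodes in the club: 100% involvement
  cm_all <- cross_module_paths(g$net, g$truth$module_of, g$net$labels)
  expect_equal(cm_all$frac_overall, 1)
})

test_that("degree profiles are flat on a degree-regular lattice and rise-then-fall on planted cores", {
  # reciprocal ring lattice: all degrees equal
  n <- 30
  a <- matrix(0L, n, n)
  for (i in seq_len(n)) for (s in 1:2) {
    j <- ((i + s - 1) %% n) + 1
    a[i, j] <- a[j, i] <- 1L
  }
  ring <- connection_matrix(a)
  prof <- degree_profile_along_paths(ring, character(0))
  expect_true(all(prof$median_degree$median_degree == 8))

  g <- generate_network(synthetic_spec(seed = 4))
  pr <- degree_profile_along_paths(g$net, g$truth$rc2_nodes)
  for (L in unique(pr$median_degree$length)) {
    md <- pr$median_degree[pr$median_degree$length == L, ]
    md <- md[order(md$position), ]
    expect_gt(max(md$median_degree), md$median_degree[1])
    expect_gt(max(md$median_degree), md$median_degree[nrow(md)])
  }
  # touch probability peaks strictly inside the path
  tp <- pr$touch_prob[pr$touch_prob$length == 3, ]
  expect_equal(tp$prob[tp$position == 0], 0)
  expect_equal(tp$prob[tp$position == 3], 0)
  expect_gt(max(tp$prob), 0.2)
})

test_that("flow asymmetry is zero on symmetric graphs and +/-1 at boundaries", {
  # fully reciprocal synthetic network
  spec <- synthetic_spec(n_nodes = 60, rc_size = 6, rc2_size = 8,
                         reciprocity_target = 1, seed = 5)
  g <- generate_network(spec)
  expect_equal(reciprocity(g$net), 1)
  fa <- flow_asymmetry(g$net, g$truth$rc_nodes)
  expect_true(all(abs(fa$ratio[!is.na(fa$ratio)]) < 1e-12))

  # boundary cases: a club node crossed only inward has ratio +1, one
  # crossed only outward has ratio -1
  lab <- c("s1", "s2", "w", "x", "t")
  a <- matrix(0L, 5, 5, dimnames = list(lab, lab))
  a["s1", "w"] <- a["s2", "w"] <- 1L   # feeders into w
  a["w", "x"] <- 1L                    # club edge
  a["x", "t"] <- 1L                    # feeder out of x
  net <- connection_matrix(a, lab)
  fa2 <- flow_asymmetry(net, c("w", "x"))
  expect_equal(fa2$ratio[fa2$label == "w"], 1)     # only entries
  expect_equal(fa2$ratio[fa2$label == "x"], -1)    # only exits
  expect_equal(fa2$in_paths[fa2$label == "w"], 2)  # s1->t and s2->t
})

test_that("planted one-way bias is flagged against degree-preserving nulls", {
  # 200 nulls: the smallest attainable two-sided add-one p is 2/201 < 0.01
  flags <- sapply(1:3, function(s) {
    b <- make_biased_feeder_net(s)
    ens <- build_ensemble(b$net, "randomized", 200, seed = s + 300)
    fa <- flow_asymmetry(b$net, b$club, ens)
    biased_sig <- fa$significant[fa$label == b$biased]
    others <- fa$significant[fa$label != b$biased]
    c(biased = biased_sig, fp = mean(others, na.rm = TRUE))
  })
  expect_gte(mean(flags["biased", ]), 2 / 3)
  expect_lt(mean(flags["fp", ]), 0.3)
})

test_that("communication cost composes usage and Euclidean length", {
  g <- generate_network(synthetic_spec(n_nodes = 80, rc_size = 6, rc2_size = 10,
                                       seed = 7))
  coords <- g$truth$coords
  cc <- communication_cost(g$net, coords, g$truth$rc_nodes)
  expect_equal(sum(cc$shares$density_share), 1)
  expect_equal(sum(cc$shares$cost_share), 1, tolerance = 1e-12)
  expect_equal(cc$n_covered, 80)
  # planted club spans modules: club edges should be longer than local ones
  expect_gt(median(cc$edges$length[cc$edges$class == "rich_club"]),
            median(cc$edges$length[cc$edges$class == "local"]))
  expect_lt(cc$tests$p_value[cc$tests$comparison == "cost rich_club > local"], 0.01)
  # cost share exceeds density share for the club
  sh <- cc$shares
  expect_gt(sh$cost_to_density[sh$class == "rich_club"], 1)
  # coordinates restricted to a subset: analysis restricted accordingly
  cc2 <- communication_cost(g$net, coords[1:50, ], g$truth$rc_nodes)
  expect_equal(cc2$n_covered, 50)
  expect_equal(length(cc2$missing_coords), 30)
  expect_error(communication_cost(g$net, coords[1, , drop = FALSE],
                                  g$truth$rc_nodes), "fewer than 2")
})
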