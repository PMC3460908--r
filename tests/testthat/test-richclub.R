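test_that("phi equals the density of the high-degree subgraph", {
  comp <- fixture_library()$complete_5
  expect_equal(phi(comp, 2), 1)
  # 4 qualifying nodes with 6 directed edges among them: 6/12
  a <- matrix(0L, 8, 8)
  a[1, 2] <- a[2, 3] <- a[3, 4] <- a[4, 1] <- a[1, 3] <- a[2, 4] <- 1L
  for (h in 1:4) {
    a[h, 4 + h] <- 1L
    a[4 + h, h] <- 1L
  }
  net <- connection_matrix(a)
  kt <- degrees(net)$k               # nodes 1-4 have k = 5, nodes 5-8 have k = 2
  expect_equal(phi(net, 4), 6 / 12)
  expect_true(is.na(phi(net, max(kt))))
})

test_that("BH step-up matches hand-worked cases", {
  expect_true(all(fdr_correct(rep(0, 5))$significant))
  expect_false(any(fdr_correct(rep(1, 5))$significant))
  # thresholds q*i/m = .0125, .025, .0375, .05: p3 = 0.04 > 0.0375,
  # so exactly the first two survive
  res <- fdr_correct(c(0.01, 0.02, 0.04, 0.8), q = 0.05)
  expect_identical(res$significant, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(res$p_adjusted, p.adjust(c(0.01, 0.02, 0.04, 0.8), "BH"))
  # a case where the step-up rescues an earlier p
  res2 <- fdr_correct(c(0.04, 0.04, 0.04, 0.05), q = 0.05)
  expect_true(all(res2$significant))
})

test_that("planted rich club is detected as a nested hierarchy", {
  g <- generate_network(synthetic_spec(seed = 3))
  ens <- build_ensemble(g$net, "randomized", 300, seed = 77)
  res <- rich_club_curve(g$net, ens)
  expect_gt(length(res$levels), 3)
  # nestedness: level j strictly contained in level j+1
  for (j in seq_len(length(res$levels) - 1)) {
    expect_true(all(res$levels[[j]] %in% res$levels[[j + 1]]))
    expect_lt(length(res$levels[[j]]), length(res$levels[[j + 1]]))
  }
  # every member of a level has degree above the level's defining k
  kt <- setNames(degrees(g$net)$k, g$net$labels)
  for (lev in res$levels) {
    expect_true(all(kt[lev] > attr(lev, "k")))
  }
  # phi column is a brute-force density recomputation at every k
  for (row in sample(nrow(res$curve), 12)) {
    expect_equal(res$curve$phi[row], phi(g$net, res$curve$k[row]))
  }
  # phi_norm elevated across the planted core's range
  in_core <- res$curve$n_nodes >= 12 & res$curve$n_nodes <= 46
  expect_true(all(res$curve$phi_norm[in_core] > 1))
})

test_that("edge classification partitions all edges", {
  g <- generate_network(synthetic_spec(n_nodes = 80, rc_size = 6, rc2_size = 10,
                                       seed = 9))
  net <- g$net
  expect_true(all(classify_edges(net, character(0))$edges$class == "local"))
  expect_true(all(classify_edges(net, net$labels)$edges$class == "rich_club"))
  cls <- classify_edges(net, g$truth$rc_nodes)
  expect_equal(sum(cls$counts), n_edges(net))
  # rich-club edges both ends in club, feeder exactly one, local none
  in_rc <- cls$edges$source %in% g$truth$rc_nodes
  out_rc <- cls$edges$target %in% g$truth$rc_nodes
  expect_identical(cls$edges$class == "rich_club", in_rc & out_rc)
  expect_identical(cls$edges$class == "feeder", xor(in_rc, out_rc))
})

test_that("k-core levels match igraph coreness; subshells cover the network", {
  # complete reciprocal graph: every node at core level 2(n-1)
  n <- 6
  a <- matrix(1L, n, n); diag(a) <- 0L
  cd <- kcore_decompose(connection_matrix(a))
  expect_true(all(cd$core_level == 2 * (n - 1)))
  set.seed(31)
  for (rep in 1:10) {
    net <- rand_digraph(sample(8:20, 1), runif(1, 0.1, 0.4))
    cd <- kcore_decompose(net)
    expect_equal(unname(cd$core_level),
                 unname(igraph::coreness(as_igraph(net), mode = "all")))
    expect_equal(cd$disintegration_k, cd$k_max + 1)
    expect_true(all(cd$subshell_rank >= 1))
    expect_true(all(cd$core_level <= degrees(net)$k))
  }
})

test_that("subshell ranks track rich-club levels on the planted network", {
  g <- generate_network(synthetic_spec(seed = 1))
  cd <- kcore_decompose(g$net)
  ens <- build_ensemble(g$net, "randomized", 200, seed = 41)
  res <- rich_club_curve(g$net, ens)
  rc_level <- rep(NA_real_, n_nodes(g$net))
  names(rc_level) <- g$net$labels
  for (j in rev(seq_along(res$levels))) {
    rc_level[res$levels[[j]]] <- j
  }
  on_rc <- !is.na(rc_level)
  # deeper club membership <-> later detachment from the core
  expect_gt(cor(rc_level[on_rc], -cd$subshell_rank[names(rc_level)[on_rc]]), 0.3)
})
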