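test_that("directed clustering matches hand-computed fixture values", {
  fx <- fixture_library()
  expect_equal(unname(clustering_directed(fx$cycle_3)), rep(0.5, 3))
  expect_equal(unname(clustering_directed(fx$reciprocal_triangle)), rep(1, 3))
  star <- clustering_directed(fx$reciprocal_star_5)
  expect_equal(unname(star["hub"]), 0)
  # nodes with fewer than two neighbours get 0
  expect_equal(unname(clustering_directed(fx$chain_4)), rep(0, 4))
})

test_that("clustering triangle counts agree with exhaustive enumeration", {
  # t_i from the formula vs naive count of directed triangles through i
  naive_triangles <- function(a) {
    n <- nrow(a)
    s <- (a + t(a))
    t_i <- numeric(n)
    for (i in 1:n) for (j in 1:n) for (k in 1:n) {
      if (i != j && j != k && i != k) {
        t_i[i] <- t_i[i] + s[i, j] * s[j, k] * s[k, i]
      }
    }
    t_i / 2
  }
  set.seed(11)
  for (rep in 1:15) {
    net <- rand_digraph(5, runif(1, 0.2, 0.7))
    a <- net$adjacency
    k <- rowSums(a) + colSums(a)
    krec <- diag(a %*% a)
    denom <- k * (k - 1) - 2 * krec
    expected <- ifelse(denom > 0, naive_triangles(a) / denom, 0)
    expect_equal(unname(clustering_directed(net)), unname(expected))
  }
})

test_that("path length and efficiency fixtures", {
  fx <- fixture_library()
  expect_equal(characteristic_path_length(shortest_distances(fx$cycle_4)), 2)
  expect_equal(characteristic_path_length(shortest_distances(fx$complete_5)), 1)
  expect_equal(global_efficiency(shortest_distances(fx$complete_5)), 1)
  # local efficiency of a reciprocal star is 0: neighbourhoods are edgeless
  expect_equal(unname(local_efficiency(fx$reciprocal_star_5)), rep(0, 6))
})

test_that("global efficiency is monotone under edge deletion", {
  set.seed(13)
  for (rep in 1:10) {
    net <- rand_digraph(8, 0.4)
    if (n_edges(net) < 2) next
    e <- which(net$adjacency == 1, arr.ind = TRUE)
    drop <- e[sample(nrow(e), 1), ]
    a2 <- net$adjacency
    a2[drop[1], drop[2]] <- 0L
    e_full <- global_efficiency(shortest_distances(net))
    e_less <- global_efficiency(shortest_distances(connection_matrix(a2)))
    expect_gte(e_full, e_less)
  }
})

test_that("self-normalization yields gamma = lambda = sigma = 1", {
  net <- fixture_library()$two_clique_bridge
  self_rand <- structure(list(members = list(net), model = "randomized",
                              seed = 0, swaps_per_edge = 0),
                         class = "null_ensemble")
  self_latt <- structure(list(members = list(net), model = "latticized",
                              seed = 0, swaps_per_edge = 0),
                         class = "null_ensemble")
  sw <- small_world_indices(net, self_rand, self_latt)
  expect_equal(sw$gamma, 1)
  expect_equal(sw$lambda, 1)
  expect_equal(sw$sigma, 1)
  expect_error(small_world_indices(net, self_latt, self_latt), "randomized")
  expect_error(small_world_indices(net, self_rand, self_rand), "latticized")
})

test_that("ring lattice with rewiring shows the small-world regime", {
  # reciprocal ring lattice, 40 nodes, 4 neighbours each side
  ring <- function(n = 40, half = 4) {
    a <- matrix(0L, n, n)
    for (i in seq_len(n)) for (s in seq_len(half)) {
      j <- ((i + s - 1) %% n) + 1
      a[i, j] <- a[j, i] <- 1L
    }
    connection_matrix(a)
  }
  net0 <- ring()
  set.seed(17)
  rewire_frac <- function(net, frac) {
    randomize(net, swaps_per_edge = frac)   # partial swaps = partial rewiring
  }
  mid <- rewire_frac(net0, 0.2)
  rand_ens <- build_ensemble(mid, "randomized", 8, seed = 3)
  latt_ens <- build_ensemble(mid, "latticized", 8, seed = 4)
  sw <- small_world_indices(mid, rand_ens, latt_ens)
  expect_gt(sw$sigma, 1)                    # clustered yet short paths
  expect_lt(abs(sw$omega), 0.5)             # between lattice (-) and random (+)
  # unrewired ring: omega clearly negative (lattice-like)
  sw0 <- small_world_indices(net0, build_ensemble(net0, "randomized", 8, seed = 5),
                             build_ensemble(net0, "latticized", 8, seed = 6))
  expect_lt(sw0$omega, sw$omega)
})
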