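# Independent brute-force oracles. Everything here is deliberately naive and
# shares no code path with the package: Floyd-Warshall distances, explicit
# path enumeration, permutation-matching triad classification, exhaustive
# set-partition search, exhaustive independent-set search.

rand_digraph <- function(n, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- matrix(as.integer(runif(n * n) < p), n, n)
  diag(a) <- 0L
  connection_matrix(a, labels = sprintf("v%02d", seq_len(n)))
}

oracle_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  d[a == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
    }
  }
  d
}

# all shortest paths per ordered pair, as lists of node index vectors
oracle_all_shortest_paths <- function(a) {
  n <- nrow(a)
  d <- oracle_distances(a)
  out <- list()
  walk <- function(path, target) {
    v <- path[length(path)]
    if (v == target) return(list(path))
    nxt <- which(a[v, ] == 1 & d[v, target] == d[, target] + 1)
    unlist(lapply(nxt, function(u) walk(c(path, u), target)), recursive = FALSE)
  }
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s != t && is.finite(d[s, t])) {
      out[[paste(s, t)]] <- walk(s, t)
    }
  }
  out
}

oracle_path_stats <- function(net) {
  a <- net$adjacency
  n <- nrow(a)
  paths <- oracle_all_shortest_paths(a)
  sigma <- matrix(0, n, n)
  edge_usage <- matrix(0, n, n)
  node_usage <- numeric(n)
  bc <- numeric(n)
  for (key in names(paths)) {
    pl <- paths[[key]]
    st <- as.integer(strsplit(key, " ")[[1]])
    sigma[st[1], st[2]] <- length(pl)
    through <- numeric(n)
    for (p in pl) {
      if (length(p) > 1) {
        for (i in seq_len(length(p) - 1)) {
          edge_usage[p[i], p[i + 1]] <- edge_usage[p[i], p[i + 1]] + 1
        }
      }
      if (length(p) > 2) {
        mid <- p[-c(1, length(p))]
        node_usage[mid] <- node_usage[mid] + 1
        through[mid] <- through[mid] + 1
      }
    }
    bc <- bc + through / length(pl)
  }
  list(sigma = sigma, edge_usage = edge_usage, node_usage = node_usage,
       betweenness = bc, total = sum(sigma))
}

# --- triads -----------------------------------------------------------------
# The 13 canonical classes written out by hand (edges among nodes 1,2,3),
# numbered per the documented convention: edge count ascending, then sorted
# per-node (out, in) signature; apex classes are 4 (reciprocal + outgoing),
# 6 (reciprocal + incoming), 9 (doubly reciprocal).
triad_reps <- local({
  e <- function(...) {
    m <- matrix(0L, 3, 3)
    for (ed in list(...)) m[ed[1], ed[2]] <- 1L
    m
  }
  list(
    `1` = e(c(1, 2), c(1, 3)),                                    # out-star
    `2` = e(c(1, 2), c(2, 3)),                                    # path
    `3` = e(c(2, 1), c(3, 1)),                                    # in-star
    `4` = e(c(1, 2), c(2, 1), c(1, 3)),                           # recip + out
    `5` = e(c(1, 2), c(2, 3), c(1, 3)),                           # transitive
    `6` = e(c(1, 2), c(2, 1), c(3, 1)),                           # recip + in
    `7` = e(c(1, 2), c(2, 3), c(3, 1)),                           # cycle
    `8` = e(c(1, 2), c(2, 1), c(1, 3), c(2, 3)),
    `9` = e(c(1, 2), c(2, 1), c(1, 3), c(3, 1)),                  # double recip
    `10` = e(c(1, 2), c(2, 1), c(1, 3), c(3, 2)),
    `11` = e(c(1, 2), c(2, 1), c(3, 1), c(3, 2)),
    `12` = e(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3)),
    `13` = e(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2))
  )
})

perms3 <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))

oracle_classify_triple <- function(m) {
  # m: 3x3 induced adjacency; 0 if not weakly connected
  und <- (m + t(m)) > 0
  # three nodes are weakly connected iff at least two dyads carry an edge
  if (sum(und[upper.tri(und)]) < 2) return(0L)
  for (id in seq_along(triad_reps)) {
    rep <- triad_reps[[id]]
    for (p in perms3) {
      if (all(m[p, p] == rep)) return(id)
    }
  }
  stop("unclassifiable connected triple")
}

oracle_triad_census <- function(net) {
  a <- net$adjacency
  n <- nrow(a)
  counts <- integer(13)
  if (n >= 3) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      id <- oracle_classify_triple(a[c(i, j, k), c(i, j, k)])
      if (id > 0) counts[id] <- counts[id] + 1L
    }
  }
  counts
}

# --- partitions and independent sets ---------------------------------------
all_set_partitions <- function(n) {
  if (n == 1) return(list(1L))
  smaller <- all_set_partitions(n - 1)
  out <- list()
  for (p in smaller) {
    for (g in seq_len(max(p) + 1)) {
      out[[length(out) + 1]] <- c(p, g)
    }
  }
  out
}

oracle_best_partition <- function(net) {
  best_q <- -Inf
  best <- NULL
  for (p in all_set_partitions(n_nodes(net))) {
    q <- modularity_q(net, p)
    if (q > best_q) {
      best_q <- q
      best <- p
    }
  }
  list(assignment = best, Q = best_q)
}

oracle_max_independent_set <- function(conflict) {
  n <- nrow(conflict)
  best <- 0L
  if (n == 0) return(0L)
  for (mask in 0:(2^n - 1)) {
    memb <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(memb) <= best) next
    if (length(memb) < 2 || !any(conflict[memb, memb])) best <- length(memb)
  }
  best
}

# planted directional bias: relocate every outgoing feeder edge of one club
# node into the club via degree-preserving swaps, so the node's shortest-path
# boundary crossings become entries while every in/out degree is unchanged
# (the bias is then invisible to the degree sequence and must be detected
# from path structure)
make_biased_feeder_net <- function(seed, n_nodes = 80, rc_size = 6,
                                   rc2_size = 20) {
  g <- generate_network(synthetic_spec(n_nodes = n_nodes, rc_size = rc_size,
                                       rc2_size = rc2_size, seed = seed))
  a <- g$net$adjacency
  # analyse flow over the full planted core so it can absorb every relocated
  # edge of the biased node; bias the lowest-degree club member (most
  # capacity headroom)
  rc <- match(g$truth$rc2_nodes, g$net$labels)
  w <- match(g$truth$rc_nodes[length(g$truth$rc_nodes)], g$net$labels)
  nr <- setdiff(seq_len(nrow(a)), rc)
  set.seed(seed + 77)
  for (pass in 1:2) {
    # point w's outgoing feeders into the core
    for (x in intersect(which(a[w, ] == 1), nr)) {
      for (c2 in sample(setdiff(rc, w))) {
        if (a[w, c2] == 1) next
        c1s <- intersect(which(a[, c2] == 1), setdiff(nr, x))
        c1s <- c1s[a[c1s, x] == 0]
        if (length(c1s)) {
          c1 <- c1s[sample.int(length(c1s), 1)]
          a[w, x] <- 0L; a[c1, c2] <- 0L
          a[w, c2] <- 1L; a[c1, x] <- 1L
          break
        }
      }
    }
    # re-source w's core-incoming edges from outside, boosting entries
    for (c2 in intersect(which(a[, w] == 1), rc)) {
      for (c1 in sample(nr)) {
        if (a[c1, w] == 1) next
        ys <- which(a[c1, ] == 1 & a[c2, ] == 0)
        ys <- setdiff(ys, c(w, c2))
        if (length(ys)) {
          y <- ys[sample.int(length(ys), 1)]
          a[c2, w] <- 0L; a[c1, y] <- 0L
          a[c1, w] <- 1L; a[c2, y] <- 1L
          break
        }
      }
    }
  }
  list(net = connection_matrix(a, g$net$labels),
       club = g$truth$rc2_nodes, biased = g$net$labels[w])
}
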