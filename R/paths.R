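# Shortest-path machinery.
#
# All counts use the fact that in an unweighted digraph every walk whose
# length equals the endpoint distance is automatically a simple path, and all
# shortest paths arise this way. Hence sigma_st = (A^d(s,t))[s, t], and
# positional counts factor through matrix powers: the number of shortest
# paths from s to t passing node v at position p is A^p[s, v] * A^(L-p)[v, t]
# for L = d(s, t). Counts are exact integers held in doubles (well below
# 2^53 at the network sizes in play).

sp_core <- function(net) {
  a <- net$adjacency
  storage.mode(a) <- "double"
  d <- shortest_distances(net)
  diam <- attr(d, "diameter")
  if (is.na(diam)) diam <- 0
  pow <- vector("list", max(diam, 1))
  pow[[1]] <- a
  if (diam >= 2) for (L in 2:diam) pow[[L]] <- pow[[L - 1]] %*% a
  n <- nrow(a)
  sig <- matrix(0, n, n)
  diag(sig) <- 1
  for (L in seq_len(diam)) {
    at <- which(d == L)
    sig[at] <- pow[[L]][at]
  }
  list(a = a, d = d, diam = diam, pow = pow, sig = sig, n = n)
}

# identity-padded power lookup: P_0 = I
sp_pow <- function(core, L) {
  if (L == 0) diag(core$n) else core$pow[[L]]
}

#' Exhaustive shortest-path counts and usage
#'
#' Counts every distinct shortest path between all connected ordered node
#' pairs, the number of shortest paths traversing each edge, and the number
#' passing through each node as an intermediate.
#'
#' @param net a [connection_matrix()]
#' @return list of class `path_stats`: `sigma` (pair-wise count matrix),
#'   `total_paths`, `n_connected_pairs`, `diameter`, `edge_usage`
#'   (data.frame source/target/usage), `node_usage` (named vector,
#'   intermediate appearances).
#' @export
count_shortest_paths <- function(net) {
  core <- sp_core(net)
  d <- core$d; sig <- core$sig; n <- core$n
  off <- row(d) != col(d)
  conn <- off & is.finite(d)
  edges <- which(core$a == 1, arr.ind = TRUE)
  usage <- numeric(nrow(edges))
  node_usage <- numeric(n)
  for (s in seq_len(n)) {
    ds <- d[s, ]
    reach <- which(is.finite(ds) & seq_len(n) != s)
    if (!length(reach)) next
    # g[v] = number of shortest-path continuations from v consistent with
    # source s (including termination at v itself)
    tmat <- outer(-ds, ds, "+")        # tmat[v, t] = d(s,t) - d(s,v)
    ind <- is.finite(tmat) & (d == tmat)
    ind[is.infinite(ds), ] <- FALSE
    g <- rowSums(core$sig * ind)
    eu <- edges[, 1]; ev <- edges[, 2]
    ok <- is.finite(ds[eu]) & (ds[ev] == ds[eu] + 1)
    usage[ok] <- usage[ok] + sig[s, eu[ok]] * g[ev[ok]]
    mid <- is.finite(ds) & seq_len(n) != s
    node_usage[mid] <- node_usage[mid] + sig[s, mid] * (g[mid] - 1)
  }
  structure(list(
    sigma = sig * conn,
    total_paths = sum(sig[conn]),
    n_connected_pairs = sum(conn),
    diameter = core$diam,
    edge_usage = data.frame(source = net$labels[edges[, 1]],
                            target = net$labels[edges[, 2]],
                            usage = usage, stringsAsFactors = FALSE),
    node_usage = setNames(node_usage, net$labels)
  ), class = "path_stats")
}

#' Betweenness centrality (directed, shortest-path fractions)
#'
#' For every ordered pair (s, t) the fraction of s->t shortest paths passing
#' through node i as an intermediate, summed over pairs.
#' @param net a [connection_matrix()]
#' @return named numeric vector
#' @export
betweenness_directed <- function(net) {
  core <- sp_core(net)
  d <- core$d; sig <- core$sig; n <- core$n
  bc <- numeric(n)
  for (s in seq_len(n)) {
    ds <- d[s, ]
    if (!any(is.finite(ds[-s]))) next
    tmat <- outer(-ds, ds, "+")
    ind <- is.finite(tmat) & (d == tmat)
    ind[is.infinite(ds), ] <- FALSE
    diag(ind) <- FALSE                 # exclude t == v (termination)
    ind[, s] <- FALSE
    ind[s, ] <- FALSE                  # v == s is not an intermediate
    w <- (sig[s, ] * sig) * ind        # w[v, t] = sigma_sv * sigma_vt
    denom <- sig[s, ]
    denom[denom == 0] <- 1
    bc <- bc + rowSums(sweep(w, 2, denom, "/"))
  }
  setNames(bc, net$labels)
}

rc_index <- function(net, rc_nodes) {
  if (is.character(rc_nodes)) {
    idx <- match(rc_nodes, net$labels)
    if (anyNA(idx)) stop("unknown region labels: ",
                         paste(rc_nodes[is.na(idx)], collapse = ", "))
    idx
  } else {
    as.integer(rc_nodes)
  }
}

# per ordered pair (s,t): number of shortest paths (at full-graph length)
# avoiding RC nodes as intermediates, and avoiding RC-RC edges.
sp_avoid_counts <- function(core, rc) {
  n <- core$n
  nr <- setdiff(seq_len(n), rc)
  avoid_node <- matrix(0, n, n)
  avoid_edge <- matrix(0, n, n)
  if (core$diam >= 1) {
    avoid_node[core$d == 1] <- 1       # length-1 paths have no intermediates
    b <- core$a
    b[rc, rc] <- 0
    bl <- b
    avoid_edge[core$d == 1] <- bl[core$d == 1]
    kpow <- diag(length(nr))
    if (core$diam >= 2) {
      for (L in 2:core$diam) {
        vn <- core$a[, nr, drop = FALSE] %*% kpow %*% core$a[nr, , drop = FALSE]
        at <- which(core$d == L)
        avoid_node[at] <- vn[at]
        bl <- bl %*% b
        avoid_edge[at] <- bl[at]
        kpow <- kpow %*% core$a[nr, nr, drop = FALSE]
      }
    }
  }
  list(avoid_node = avoid_node, avoid_edge = avoid_edge)
}

#' Rich-club participation of shortest paths
#'
#' Over all shortest paths whose endpoints both lie outside the rich-club
#' set: the fraction touching at least one RC node (as an intermediate) and
#' the fraction traveling across at least one RC edge (an edge between two
#' RC nodes). Computed by complement: paths avoiding the club are counted by
#' dynamic programming restricted to non-RC intermediates (resp. the graph
#' minus RC-RC edges) at unchanged path length.
#'
#' @param net a [connection_matrix()]
#' @param rc_nodes rich-club node set (labels or indices)
#' @return list with `frac_touch_node`, `frac_travel_edge`, `total_paths`
#'   (paths between non-RC pairs), `n_pairs`.
#' @export
rc_participation <- function(net, rc_nodes) {
  rc <- rc_index(net, rc_nodes)
  core <- sp_core(net)
  n <- core$n
  nr <- setdiff(seq_len(n), rc)
  if (!length(rc)) {
    return(list(frac_touch_node = 0, frac_travel_edge = 0,
                total_paths = NA_real_, n_pairs = NA_integer_))
  }
  conn <- is.finite(core$d) & row(core$d) != col(core$d)
  mask <- matrix(FALSE, n, n)
  mask[nr, nr] <- TRUE
  mask <- mask & conn
  total <- sum(core$sig[mask])
  av <- sp_avoid_counts(core, rc)
  list(frac_touch_node = 1 - sum(av$avoid_node[mask]) / total,
       frac_travel_edge = 1 - sum(av$avoid_edge[mask]) / total,
       total_paths = total, n_pairs = sum(mask))
}

#' Rich-club involvement of module-crossing paths
#'
#' For shortest paths whose endpoints lie in different modules: the fraction
#' involving at least one rich-club node anywhere on the path (endpoints
#' included), overall and per ordered module pair.
#'
#' @param net a [connection_matrix()]
#' @param partition `modular_partition` or assignment vector
#' @param rc_nodes rich-club node set (labels or indices)
#' @return list with `frac_overall` and `per_pair` (data.frame)
#' @export
cross_module_paths <- function(net, partition, rc_nodes) {
  cl <- partition_assignment(partition, net)
  rc <- rc_index(net, rc_nodes)
  if (length(unique(cl)) < 2) {
    return(list(frac_overall = NA_real_,
                per_pair = data.frame(module_from = integer(0), module_to = integer(0),
                                      paths = numeric(0), frac_rc = numeric(0))))
  }
  core <- sp_core(net)
  n <- core$n
  conn <- is.finite(core$d) & row(core$d) != col(core$d)
  cross <- outer(cl, cl, "!=") & conn
  av <- sp_avoid_counts(core, rc)
  # endpoints inside the club involve it trivially
  endpoint_rc <- matrix(FALSE, n, n)
  endpoint_rc[rc, ] <- TRUE
  endpoint_rc[, rc] <- TRUE
  involved <- ifelse(endpoint_rc, core$sig, core$sig - av$avoid_node)
  mods <- sort(unique(cl))
  rows <- list()
  for (g1 in mods) for (g2 in mods) {
    if (g1 == g2) next
    m <- cross & outer(cl == g1, cl == g2, "&")
    tot <- sum(core$sig[m])
    rows[[length(rows) + 1]] <- data.frame(
      module_from = g1, module_to = g2, paths = tot,
      frac_rc = if (tot > 0) sum(involved[m]) / tot else NA_real_)
  }
  list(frac_overall = sum(involved[cross]) / sum(core$sig[cross]),
       per_pair = do.call(rbind, rows))
}

#' Node degrees encountered along shortest paths
#'
#' For each path length L between non-rich-club endpoints, the weighted
#' distribution of node total degrees at every path position 0..L, the
#' probability that the node at each position belongs to the rich club, and
#' the probability that each step travels a rich-club edge.
#'
#' @param net a [connection_matrix()]
#' @param rc_nodes rich-club node set (labels or indices)
#' @param lengths path lengths to profile (default 2 up to the diameter)
#' @return list of class `degree_profile`: `profiles` (long data.frame with
#'   length, position, degree, weight), `median_degree` (data.frame),
#'   `touch_prob` (length, position, prob), `travel_prob` (length, step,
#'   prob).
#' @export
degree_profile_along_paths <- function(net, rc_nodes, lengths = NULL) {
  rc <- rc_index(net, rc_nodes)
  core <- sp_core(net)
  n <- core$n
  nr <- setdiff(seq_len(n), rc)
  if (is.null(lengths)) lengths <- seq(2, max(core$diam, 2))
  lengths <- lengths[lengths <= core$diam & lengths >= 1]
  k <- rowSums(core$a) + colSums(core$a)
  arc <- core$a
  arc[nr, ] <- 0
  arc[, nr] <- 0                        # RC-RC edges only
  prof <- list(); med <- list(); touch <- list(); travel <- list()
  for (L in lengths) {
    ml <- matrix(0, n, n)
    sel <- which(core$d == L)
    ml[sel] <- 1
    ml[rc, ] <- 0; ml[, rc] <- 0        # non-RC endpoints only
    npaths <- sum(ml * core$sig)
    if (npaths == 0) next
    for (p in 0:L) {
      w <- rowSums((t(sp_pow(core, p)) %*% ml) * sp_pow(core, L - p))
      prof[[length(prof) + 1]] <- data.frame(
        length = L, position = p, degree = k[w > 0], weight = w[w > 0])
      med[[length(med) + 1]] <- data.frame(
        length = L, position = p,
        median_degree = weighted_median(k, w), n_paths = sum(w))
      touch[[length(touch) + 1]] <- data.frame(
        length = L, position = p, prob = sum(w[rc]) / sum(w))
    }
    for (j in 1:L) {
      q <- sum(ml * (sp_pow(core, j - 1) %*% arc %*% sp_pow(core, L - j)))
      travel[[length(travel) + 1]] <- data.frame(
        length = L, step = j, prob = q / npaths)
    }
  }
  structure(list(profiles = do.call(rbind, prof),
                 median_degree = do.call(rbind, med),
                 touch_prob = do.call(rbind, touch),
                 travel_prob = do.call(rbind, travel)),
            class = "degree_profile")
}

weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}

# entry/exit counts of shortest paths (between non-RC endpoints) crossing
# the rich-club boundary at each RC node; every crossing counts.
flow_counts <- function(core, rc) {
  n <- core$n
  nr <- setdiff(seq_len(n), rc)
  a_in <- core$a; a_in[rc, ] <- 0       # step from non-RC source into any node
  a_out <- core$a; a_out[, rc] <- 0     # step from any node onto non-RC target
  ins <- numeric(n); outs <- numeric(n)
  for (L in 2:max(core$diam, 2)) {
    if (L > core$diam) break
    ml <- matrix(0, n, n)
    ml[core$d == L] <- 1
    ml[rc, ] <- 0; ml[, rc] <- 0
    if (!any(ml > 0)) next
    for (j in 1:(L - 1)) {
      x <- sp_pow(core, j - 1) %*% a_in
      ins <- ins + rowSums((t(x) %*% ml) * sp_pow(core, L - j))
      y <- a_out %*% sp_pow(core, L - j - 1)
      outs <- outs + rowSums((t(sp_pow(core, j)) %*% ml) * y)
    }
  }
  list(in_paths = ins[rc], out_paths = outs[rc])
}

#' Directional flow of shortest paths into and out of the rich club
#'
#' Counts, for each rich-club node, the entry events (a path step from a
#' non-RC node into that node) and exit events (a step from that node onto a
#' non-RC node) over all shortest paths between non-RC endpoints, and the
#' in-out ratio (in - out)/(in + out). Per-node significance is an empirical
#' two-sided p-value against a degree-preserving randomized ensemble
#' (add-one corrected, computed on the absolute deviation from the null
#' mean; reported uncorrected). p-values are computed both for the ratio
#' and for the raw count imbalance in - out; the flag uses the count
#' statistic, since the ratio saturates at +-1 where null ties make its p
#' conservative.
#'
#' @param net a [connection_matrix()]
#' @param rc_nodes rich-club node set (labels or indices)
#' @param ensemble a randomized `null_ensemble` (or `NULL` to skip the
#'   significance comparison)
#' @param alpha flag threshold on the uncorrected p-value (default 0.01)
#' @return data.frame of class `flow_asymmetry` with per-RC-node `in_paths`,
#'   `out_paths`, `ratio`, `null_mean`, `null_sd`, `p_ratio`, `p_count`,
#'   `significant`.
#' @export
flow_asymmetry <- function(net, rc_nodes, ensemble = NULL, alpha = 0.01) {
  rc <- rc_index(net, rc_nodes)
  core <- sp_core(net)
  obs <- flow_counts(core, rc)
  tot <- obs$in_paths + obs$out_paths
  ratio <- ifelse(tot > 0, (obs$in_paths - obs$out_paths) / tot, NA_real_)
  out <- data.frame(label = net$labels[rc],
                    in_paths = obs$in_paths, out_paths = obs$out_paths,
                    ratio = ratio, stringsAsFactors = FALSE)
  if (!is.null(ensemble)) {
    if (ensemble$model != "randomized") {
      stop("flow asymmetry requires a randomized ensemble")
    }
    null_stats <- lapply(ensemble$members, function(mbr) {
      fc <- flow_counts(sp_core(mbr), rc)
      t2 <- fc$in_paths + fc$out_paths
      list(ratio = ifelse(t2 > 0, (fc$in_paths - fc$out_paths) / t2, NA_real_),
           diff = fc$in_paths - fc$out_paths)
    })
    emp_p <- function(obs, nulls) {
      nn <- rowSums(!is.na(nulls))
      mu <- rowMeans(nulls, na.rm = TRUE)
      dev_obs <- abs(obs - mu)
      extreme <- rowSums(abs(nulls - mu) >= dev_obs - 1e-12, na.rm = TRUE)
      list(p = (1 + extreme) / (1 + nn), mu = mu,
           s = apply(nulls, 1, sd, na.rm = TRUE))
    }
    nr_ratio <- matrix(vapply(null_stats, `[[`, numeric(length(rc)), "ratio"),
                       nrow = length(rc))
    nr_diff <- matrix(vapply(null_stats, `[[`, numeric(length(rc)), "diff"),
                      nrow = length(rc))
    pr <- emp_p(ratio, nr_ratio)
    pd <- emp_p(obs$in_paths - obs$out_paths, nr_diff)
    out$null_mean <- pr$mu
    out$null_sd <- pr$s
    out$p_ratio <- pr$p
    out$p_count <- pd$p
    # the ratio saturates at +-1 (ties with occasional extreme null ratios
    # make its p conservative); the path-count imbalance carries the flag
    out$significant <- tot > 0 & pd$p < alpha
  }
  class(out) <- c("flow_asymmetry", "data.frame")
  out
}

#' Communication cost of edges by class
#'
#' Edge cost = (number of shortest paths using the edge) x (Euclidean length
#' between the endpoint centroids). The analysis is restricted to the
#' subnetwork of nodes with coordinates. Returns per-edge data, class-wise
#' shares of density and cost, and one-sided Wilcoxon rank-sum comparisons
#' (rich-club vs local, feeder vs local) for both length and cost.
#'
#' @param net a [connection_matrix()]
#' @param coords data.frame with columns `label`, `x`, `y`, `z`
#' @param rc_nodes rich-club node set (labels or indices into `net`)
#' @return list of class `communication_cost`: `edges` (data.frame),
#'   `shares` (data.frame by class), `tests` (data.frame), `n_covered`.
#' @export
communication_cost <- function(net, coords, rc_nodes) {
  stopifnot(all(c("label", "x", "y", "z") %in% names(coords)))
  covered <- intersect(net$labels, coords$label)
  missing <- setdiff(net$labels, covered)
  if (length(covered) < 2) stop("fewer than 2 nodes have coordinates")
  idx <- match(covered, net$labels)
  sub <- connection_matrix(net$adjacency[idx, idx, drop = FALSE], labels = covered)
  rc_labels <- net$labels[rc_index(net, rc_nodes)]
  cls <- classify_edges(sub, intersect(rc_labels, covered))
  ps <- count_shortest_paths(sub)
  ed <- merge(cls$edges, ps$edge_usage, by = c("source", "target"))
  xyz <- as.matrix(coords[match(covered, coords$label), c("x", "y", "z")])
  rownames(xyz) <- covered
  dvec <- sqrt(rowSums((xyz[ed$source, , drop = FALSE] -
                          xyz[ed$target, , drop = FALSE])^2))
  ed$length <- unname(dvec)
  ed$cost <- ed$usage * ed$length
  shares <- do.call(rbind, lapply(c("rich_club", "feeder", "local"), function(cl) {
    sel <- ed$class == cl
    data.frame(class = cl, n_edges = sum(sel),
               density_share = mean(sel),
               cost_share = sum(ed$cost[sel]) / sum(ed$cost),
               length_share = sum(ed$length[sel]) / sum(ed$length))
  }))
  shares$cost_to_density <- shares$cost_share / shares$density_share
  cmp <- function(var, c1, c2) {
    x <- ed[[var]][ed$class == c1]; y <- ed[[var]][ed$class == c2]
    if (!length(x) || !length(y)) return(NA_real_)
    suppressWarnings(wilcox.test(x, y, alternative = "greater")$p.value)
  }
  tests <- data.frame(
    comparison = c("length rich_club > local", "length feeder > local",
                   "cost rich_club > local", "cost feeder > local"),
    p_value = c(cmp("length", "rich_club", "local"), cmp("length", "feeder", "local"),
                cmp("cost", "rich_club", "local"), cmp("cost", "feeder", "local")))
  structure(list(edges = ed, shares = shares, tests = tests,
                 n_covered = length(covered), missing_coords = missing),
            class = "communication_cost")
}
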