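# The 13 connected directed triads. A triple's dyad configuration is encoded
# in 6 bits (edge i->j, j->i, i->k, k->i, j->k, k->j for i < j < k); classes
# are isomorphism classes of connected configurations. For 3-node digraphs
# the sorted multiset of per-node (out-degree, in-degree) pairs is a complete
# isomorphism invariant, which the classifier exploits. Class ids are
# assigned by edge count ascending, then lexicographically by the sorted
# per-node signature; this places the three apex classes (an apex node
# adjacent to two mutually unconnected leaves) at ids 4 (reciprocal +
# outgoing), 6 (reciprocal + incoming) and 9 (doubly reciprocal), and the
# fully reciprocal triangle at 13, matching the canonical triad chart of the
# motif literature at the ids this analysis relies on.

triad_tables <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    codes <- 0:63
    decode <- function(code) {
      b <- as.integer(intToBits(code)[1:6])
      m <- matrix(0L, 3, 3)
      m[1, 2] <- b[1]; m[2, 1] <- b[2]; m[1, 3] <- b[3]
      m[3, 1] <- b[4]; m[2, 3] <- b[5]; m[3, 2] <- b[6]
      m
    }
    sig_of <- function(m) paste(sort(10 * rowSums(m) + colSums(m)), collapse = ".")
    n_dyads <- function(m) sum((m + t(m))[upper.tri(m)] > 0)
    mats <- lapply(codes, decode)
    connected <- vapply(mats, n_dyads, 0L) >= 2
    sigs <- vapply(mats, sig_of, "")
    edges <- vapply(mats, sum, 0L)
    canon <- unique(data.frame(sig = sigs[connected], n_edges = edges[connected]))
    canon <- canon[order(canon$n_edges, canon$sig), ]
    ord <- order(canon$n_edges,
                 vapply(strsplit(canon$sig, ".", fixed = TRUE), function(s) {
                   sum(as.numeric(s) * c(1e8, 1e4, 1))
                 }, 0))
    canon <- canon[ord, ]
    canon$id <- seq_len(nrow(canon))
    stopifnot(nrow(canon) == 13)
    class_of <- integer(64)
    class_of[connected] <- canon$id[match(sigs[connected], canon$sig)]
    apex_slot <- rep(-1L, 64)
    for (i in which(connected)) {
      id <- class_of[i]
      if (!id %in% c(4L, 6L, 9L)) next
      m <- mats[[i]]
      s <- m + t(m)
      # apex = the node not in the empty dyad
      for (v in 1:3) {
        others <- setdiff(1:3, v)
        if (s[others[1], others[2]] == 0) { apex_slot[i] <- v - 1L; break }
      }
    }
    cache <<- list(class_of = class_of, apex_slot = apex_slot, canon = canon,
                   mats = mats, connected = connected)
    cache
  }
})

#' Dictionary of the 13 connected directed triad classes
#'
#' One row per class: id, edge count, the sorted per-node
#' (out-degree, in-degree) signature, a representative edge list, and
#' whether the class is an apex class (ids 4, 6, 9). Ships so the numbering
#' convention is auditable.
#' @return data.frame with 13 rows
#' @export
motif_dictionary <- function() {
  tt <- triad_tables()
  rep_edges <- vapply(tt$canon$id, function(id) {
    code <- which(tt$class_of == id)[1]
    m <- tt$mats[[code]]
    e <- which(m == 1L, arr.ind = TRUE)
    paste(sprintf("%s>%s", c("a", "b", "c")[e[, 1]], c("a", "b", "c")[e[, 2]]),
          collapse = " ")
  }, "")
  data.frame(id = tt$canon$id, n_edges = tt$canon$n_edges,
             signature = tt$canon$sig, example = rep_edges,
             is_apex_class = tt$canon$id %in% c(4, 6, 9))
}

#' Exact 13-class triad census with per-node apex statistics
#'
#' Enumerates every connected induced 3-node subgraph (induced counting: a
#' reciprocal triangle is one class-13 instance, not several lower-class
#' ones) and classifies it. For the apex classes 4, 6 and 9 the apex
#' occupancy of each node is tallied.
#'
#' @param net a [connection_matrix()]
#' @return list of class `motif_census`: `class_count` (length-13 vector),
#'   `node_participation` and `node_apex_count` (N x 13 matrices, rows named
#'   by label).
#' @export
triad_census <- function(net) {
  tt <- triad_tables()
  res <- triad_census_cpp(net$adjacency, tt$class_of, tt$apex_slot)
  cc <- setNames(as.numeric(res$class_count), paste0("M", 1:13))
  part <- res$participation
  apex <- res$apex_count
  dimnames(part) <- dimnames(apex) <- list(net$labels, paste0("M", 1:13))
  structure(list(class_count = cc, node_participation = part,
                 node_apex_count = apex),
            class = "motif_census")
}

#' Motif z-scores against randomized and latticized ensembles
#'
#' z = (count_real - mean_null) / sd_null per class and null model, with
#' empirical one-sided p-values (add-one corrected). Classes with zero null
#' spread get `NA` z-scores and are flagged. A class is called
#' over-represented when its empirical p-value is below `alpha` under both
#' null models.
#'
#' @param net a [connection_matrix()]
#' @param rand_ensemble randomized `null_ensemble`
#' @param latt_ensemble latticized `null_ensemble`
#' @param alpha significance level for the over-representation call
#' @return data.frame with per-class counts, z and p against both nulls,
#'   `sd_zero` flags and `overrepresented_both`.
#' @export
motif_zscores <- function(net, rand_ensemble, latt_ensemble, alpha = 0.05) {
  if (rand_ensemble$model != "randomized" || latt_ensemble$model != "latticized") {
    stop("need one randomized and one latticized ensemble, in that order")
  }
  real <- triad_census(net)$class_count
  null_counts <- function(ens) {
    m <- vapply(ens$members, function(x) triad_census(x)$class_count, numeric(13))
    matrix(m, nrow = 13)
  }
  zp <- function(nc) {
    mu <- rowMeans(nc); s <- apply(nc, 1, sd)
    z <- ifelse(s > 0, (real - mu) / s, NA_real_)
    p <- (1 + rowSums(nc >= real)) / (1 + ncol(nc))
    list(z = z, p = p, sd_zero = s == 0)
  }
  r <- zp(null_counts(rand_ensemble))
  l <- zp(null_counts(latt_ensemble))
  data.frame(class = paste0("M", 1:13), count = as.numeric(real),
             z_random = r$z, p_random = r$p,
             z_lattice = l$z, p_lattice = l$p,
             sd_zero = r$sd_zero | l$sd_zero,
             overrepresented_both = r$p < alpha & l$p < alpha)
}

#' Apex ratio per node
#'
#' Fraction of a node's apex-class motif instances in which it occupies the
#' apex position, over the given class set (default all three apex classes).
#' Nodes with no participation in those classes get 0.
#'
#' @param census a `motif_census`
#' @param classes apex class ids, subset of c(4, 6, 9)
#' @return named numeric vector
#' @export
apex_ratio <- function(census, classes = c(4, 6, 9)) {
  stopifnot(all(classes %in% c(4, 6, 9)))
  cols <- paste0("M", classes)
  ap <- rowSums(census$node_apex_count[, cols, drop = FALSE])
  pa <- rowSums(census$node_participation[, cols, drop = FALSE])
  ifelse(pa > 0, ap / pa, 0)
}

#' Heuristic largest star motif around a node
#'
#' A star is a centre reciprocally connected to leaves that have no edges
#' among themselves in either direction. Finding the largest one is a
#' maximum-independent-set problem over the centre's reciprocal neighbours;
#' the heuristic greedily adds neighbours in ascending-degree order and takes
#' the best of `restarts` additional random insertion orders.
#'
#' @param net a [connection_matrix()]
#' @param center node label or index
#' @param restarts number of random-order restarts (default 20)
#' @param seed optional seed for the restart orders
#' @return list with `center` (label) and `leaves` (character vector,
#'   possibly empty); `size` attribute = number of leaves.
#' @export
largest_star <- function(net, center, restarts = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  c_idx <- rc_index(net, center)
  a <- net$adjacency
  recips <- which(a[c_idx, ] == 1L & a[, c_idx] == 1L)
  recips <- setdiff(recips, c_idx)
  best <- integer(0)
  if (length(recips)) {
    conflict <- (a[recips, recips, drop = FALSE] +
                   t(a[recips, recips, drop = FALSE])) > 0
    kt <- rowSums(a) + colSums(a)
    greedy <- function(ord) {
      chosen <- logical(length(recips))
      for (i in ord) {
        if (!any(conflict[i, chosen])) chosen[i] <- TRUE
      }
      which(chosen)
    }
    best <- greedy(order(kt[recips]))
    for (r in seq_len(restarts)) {
      cand <- greedy(sample.int(length(recips)))
      if (length(cand) > length(best)) best <- cand
    }
  }
  out <- list(center = net$labels[c_idx], leaves = net$labels[recips[best]])
  attr(out, "size") <- length(best)
  out
}

#' Largest-star size for every node
#' @inheritParams largest_star
#' @return named integer vector of star sizes (leaf counts)
#' @export
star_sizes <- function(net, restarts = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n_nodes(net)), function(i) {
    attr(largest_star(net, i, restarts = restarts), "size")
  }, integer(1)) |> setNames(net$labels)
}
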