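#' Rich-club coefficient at degree k
#'
#' Phi(k) is the connection density of the directed subgraph induced by the
#' nodes with total degree > k: E_k / (N_k (N_k - 1)).
#'
#' @param net a [connection_matrix()]
#' @param k degree threshold
#' @return Phi(k), or `NA` when fewer than 2 nodes qualify.
#' @export
phi <- function(net, k) {
  kt <- degrees(net)$k
  idx <- which(kt > k)
  if (length(idx) < 2) return(NA_real_)
  sum(net$adjacency[idx, idx]) / (length(idx) * (length(idx) - 1))
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up procedure at level q (delegates the adjustment to
#' [stats::p.adjust()]).
#' @param p_values numeric vector of p-values
#' @param q false-discovery level (default 0.05)
#' @return list with `significant` (logical flags) and `p_adjusted`.
#' @export
fdr_correct <- function(p_values, q = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  adj <- p.adjust(p_values, method = "BH")
  list(significant = !is.na(adj) & adj <= q, p_adjusted = adj)
}

#' Rich-club curve with permutation significance and nested levels
#'
#' Sweeps the degree threshold k from the lowest total degree to the second
#' highest, computing Phi(k), the null distribution of Phi over a
#' degree-preserving randomized ensemble, the normalized coefficient
#' Phi_norm(k) = Phi(k) / <Phi_random(k)>, a one-sided permutation p-value
#' per k (with add-one correction), and Benjamini-Hochberg FDR flags.
#' Because the nulls preserve the degree sequence, the node set at every k
#' is identical across members and only the edge counts differ.
#'
#' Rich-club levels are extracted from the rich-club regime: the longest
#' contiguous run of significant k values. Within it, consecutive k values yielding the same node set
#' collapse into one level; levels are ordered innermost (highest defining
#' k) first and are nested by construction. Isolated significant k values
#' beyond a gap (typically small-subgraph density fluctuations at the top of
#' the degree sequence) remain flagged in the curve but do not define
#' levels.
#'
#' @param net a [connection_matrix()]
#' @param ensemble a randomized `null_ensemble`
#' @param q FDR level (default 0.05)
#' @return list of class `richclub_result`: data.frame `curve` (k, n_nodes,
#'   phi, phi_random_mean, phi_norm, p_raw, p_adjusted, significant) and
#'   `levels`, a list of label vectors, innermost first, each with
#'   attributes `k` (innermost defining k) and `p_adjusted`.
#' @export
rich_club_curve <- function(net, ensemble, q = 0.05) {
  if (ensemble$model != "randomized") {
    stop("rich-club calibration requires a randomized ensemble")
  }
  kt <- degrees(net)$k
  kmax2 <- sort(kt, decreasing = TRUE)[2]
  ks <- seq(min(kt), kmax2)
  ks <- ks[vapply(ks, function(k) sum(kt > k) >= 2, logical(1))]
  if (!length(ks)) stop("no degree threshold leaves >= 2 qualifying nodes")

  phi_of <- function(a) {
    # edge counts among {k > ks[i]} for the whole sweep at once
    idx <- which(a == 1L, arr.ind = TRUE)
    mn <- pmin(kt[idx[, 1]], kt[idx[, 2]])
    vapply(ks, function(k) sum(mn > k), numeric(1))
  }
  nsub <- vapply(ks, function(k) sum(kt > k), numeric(1))
  pairs <- nsub * (nsub - 1)
  phi_emp <- phi_of(net$adjacency) / pairs
  null_mat <- vapply(ensemble$members, function(m) phi_of(m$adjacency) / pairs,
                     numeric(length(ks)))
  null_mat <- matrix(null_mat, nrow = length(ks))
  nnull <- ncol(null_mat)
  phi_rand <- rowMeans(null_mat)
  p_raw <- (1 + rowSums(null_mat >= phi_emp)) / (1 + nnull)
  fdr <- fdr_correct(p_raw, q)

  curve <- data.frame(k = ks, n_nodes = nsub, phi = phi_emp,
                      phi_random_mean = phi_rand,
                      phi_norm = phi_emp / phi_rand,
                      p_raw = p_raw, p_adjusted = fdr$p_adjusted,
                      significant = fdr$significant)
  levels <- list()
  sig_ks <- ks[fdr$significant]
  if (length(sig_ks)) {
    # dominant contiguous run over the swept k grid = the rich-club regime
    pos <- which(fdr$significant)
    runs <- split(pos, cumsum(c(1, diff(pos) != 1)))
    sig_ks <- ks[runs[[which.max(lengths(runs))]]]
  }
  sig_ks <- rev(sig_ks)                       # descending k: innermost first
  seen <- character(0)
  for (k in sig_ks) {
    memb <- sort(net$labels[kt > k])
    key <- paste(memb, collapse = "\r")
    if (key %in% seen) next
    seen <- c(seen, key)
    lev <- net$labels[kt > k]
    attr(lev, "k") <- k
    attr(lev, "p_adjusted") <- curve$p_adjusted[match(k, ks)]
    levels[[length(levels) + 1]] <- lev
  }
  structure(list(curve = curve, levels = levels), class = "richclub_result")
}

#' @export
print.richclub_result <- function(x, ...) {
  ns <- sum(x$curve$significant)
  cat(sprintf("<richclub_result> %d k values swept, %d significant, %d unique levels\n",
              nrow(x$curve), ns, length(x$levels)))
  if (length(x$levels)) {
    cat(sprintf("  level sizes (innermost first): %s\n",
                paste(lengths(x$levels), collapse = " ")))
  }
  invisible(x)
}

#' Classify edges as rich-club, feeder or local
#'
#' Rich-club edges join two rich-club nodes, feeder edges join a rich-club
#' node to a non-rich-club node (either direction), local edges join two
#' non-rich-club nodes. The three classes partition the edge set.
#'
#' @param net a [connection_matrix()]
#' @param rc_nodes rich-club node set (labels or indices)
#' @return list with `edges` (data.frame source/target/class) and `counts`.
#' @export
classify_edges <- function(net, rc_nodes) {
  rc <- rc_index(net, rc_nodes)
  in_rc <- seq_len(n_nodes(net)) %in% rc
  idx <- which(net$adjacency == 1L, arr.ind = TRUE)
  n_ends <- in_rc[idx[, 1]] + in_rc[idx[, 2]]
  cls <- c("local", "feeder", "rich_club")[n_ends + 1]
  edges <- data.frame(source = net$labels[idx[, 1]], target = net$labels[idx[, 2]],
                      class = cls, stringsAsFactors = FALSE)
  list(edges = edges,
       counts = c(rich_club = sum(cls == "rich_club"),
                  feeder = sum(cls == "feeder"),
                  local = sum(cls == "local")))
}

#' k-core decomposition on total degree, with subshell ranks
#'
#' The k-core is the maximal subgraph in which every node keeps total
#' (in + out) degree >= k within the subgraph. `core_level` is the largest k
#' at which a node survives. At the disintegration degree (the first k whose
#' core is empty) nodes detach in rounds of simultaneous removal;
#' `subshell_rank` records the round in which each node detached.
#'
#' @param net a [connection_matrix()]
#' @return list of class `core_decomposition`: `core_level` (named vector),
#'   `k_max` (highest non-empty core), `peak_size` (its node count),
#'   `disintegration_k`, `subshell_rank` (named vector).
#' @export
kcore_decompose <- function(net) {
  a <- net$adjacency
  n <- nrow(a)
  core <- integer(n)
  alive <- rep(TRUE, n)
  k <- 0L
  while (any(alive)) {
    k <- k + 1L
    repeat {
      sub <- a[alive, alive, drop = FALSE]
      deg <- rowSums(sub) + colSums(sub)
      drop_now <- which(deg < k)
      if (!length(drop_now)) break
      core[which(alive)[drop_now]] <- k - 1L
      alive[which(alive)[drop_now]] <- FALSE
      if (!any(alive)) break
    }
    if (any(alive)) core[alive] <- k
  }
  k_max <- max(core)
  kd <- k_max + 1L
  # subshell: simultaneous removal rounds at the disintegration degree
  alive <- rep(TRUE, n)
  rank <- integer(n)
  round <- 0L
  while (any(alive)) {
    round <- round + 1L
    deg <- rowSums(a[alive, alive, drop = FALSE]) +
      colSums(a[alive, alive, drop = FALSE])
    gone <- deg < kd
    if (!any(gone)) {                 # cannot happen at the disintegration k
      rank[alive] <- round
      break
    }
    rank[which(alive)[gone]] <- round
    alive[which(alive)[gone]] <- FALSE
  }
  structure(list(core_level = setNames(core, net$labels),
                 k_max = k_max,
                 peak_size = sum(core == k_max),
                 disintegration_k = kd,
                 subshell_rank = setNames(rank, net$labels)),
            class = "core_decomposition")
}
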