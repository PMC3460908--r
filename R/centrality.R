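#' Closeness centrality (mean of in- and out-closeness)
#'
#' Out-closeness of node i is the inverse mean directed distance from i to
#' all other nodes; in-closeness is the inverse mean distance to i. On
#' inputs with unreachable pairs the harmonic variant (mean of inverse
#' distances) is used instead, which degrades gracefully to the same value
#' on strongly connected graphs only when all distances are finite.
#'
#' @param net a [connection_matrix()]
#' @return named numeric vector, the average of in- and out-closeness.
#' @export
closeness_centrality <- function(net) {
  d <- shortest_distances(net)
  n <- nrow(d)
  one_way <- function(dd) {
    # dd: rows = from-node, values = distances to others
    apply(dd, 1, function(x) {
      x <- x[!is.na(x)]
      if (all(is.finite(x))) (n - 1) / sum(x) else mean(1 / x)
    })
  }
  diag(d) <- NA
  (one_way(d) + one_way(t(d))) / 2
}

#' Vulnerability: efficiency loss under node deletion
#'
#' V(i) = E_glob(net) - E_glob(net minus node i), with the efficiency of the
#' reduced network computed over its remaining N - 1 nodes. The sign is
#' retained: peripheral nodes whose removal raises mean efficiency get
#' negative values.
#'
#' @param net a [connection_matrix()]
#' @return named numeric vector
#' @export
vulnerability <- function(net) {
  e0 <- global_efficiency(shortest_distances(net))
  n <- n_nodes(net)
  v <- vapply(seq_len(n), function(i) {
    sub <- connection_matrix(net$adjacency[-i, -i, drop = FALSE],
                             labels = net$labels[-i])
    e0 - global_efficiency(shortest_distances(sub))
  }, numeric(1))
  setNames(v, net$labels)
}

# dominant adjacency eigenvalue (largest real part; real and maximal in
# modulus for strongly connected binary nets by Perron-Frobenius)
dominant_eigenvalue <- function(a) {
  if (nrow(a) == 0) return(0)
  ev <- eigen(a, only.values = TRUE)$values
  max(Re(ev))
}

#' Dynamical importance: spectral impact of node deletion
#'
#' I(i) = (lambda_max - lambda_max^(-i)) / lambda_max, the relative drop of
#' the dominant adjacency eigenvalue when node i is deleted.
#'
#' @param net a [connection_matrix()]
#' @return named numeric vector
#' @export
dynamical_importance <- function(net) {
  a <- net$adjacency
  storage.mode(a) <- "double"
  lam <- dominant_eigenvalue(a)
  if (lam <= 0) stop("adjacency has no positive dominant eigenvalue")
  v <- vapply(seq_len(nrow(a)), function(i) {
    (lam - dominant_eigenvalue(a[-i, -i, drop = FALSE])) / lam
  }, numeric(1))
  setNames(v, net$labels)
}

#' All four centrality measures plus the global consistency score
#'
#' Computes betweenness, closeness, vulnerability and dynamical importance,
#' then scores each node by the number of measures in which it reaches the
#' 90th percentile (quantile with midpoint interpolation; ties at the
#' threshold are all included).
#'
#' @param net a [connection_matrix()]
#' @param top_quantile percentile defining "top" nodes (default 0.9)
#' @return data.frame of class `centrality_table` with the four measures and
#'   `global_score` (0-4), ordered as the input labels.
#' @export
centrality_table <- function(net, top_quantile = 0.9) {
  tab <- data.frame(
    label = net$labels,
    betweenness = unname(betweenness_directed(net)),
    closeness = unname(closeness_centrality(net)),
    vulnerability = unname(vulnerability(net)),
    dyn_importance = unname(dynamical_importance(net)),
    stringsAsFactors = FALSE)
  tab$global_score <- global_centrality_score(tab, top_quantile)
  class(tab) <- c("centrality_table", "data.frame")
  tab
}

#' @rdname centrality_table
#' @param table a data.frame with columns `betweenness`, `closeness`,
#'   `vulnerability`, `dyn_importance`
#' @export
global_centrality_score <- function(table, top_quantile = 0.9) {
  measures <- c("betweenness", "closeness", "vulnerability", "dyn_importance")
  stopifnot(all(measures %in% names(table)))
  rowSums(vapply(measures, function(m) {
    x <- table[[m]]
    x >= quantile(x, top_quantile, names = FALSE)
  }, logical(nrow(table))))
}
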