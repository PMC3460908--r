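#' Directed clustering coefficient (Fagiolo)
#'
#' Per-node directed clustering: with S = A + t(A), the number of directed
#' triangles around node i is t_i = (S^3)_ii / 2, and
#' C_i = t_i / (k_i (k_i - 1) - 2 k_i^rec), where k_i is total degree and
#' k_i^rec the number of reciprocal neighbours. The denominator discounts the
#' "false triangles" formed by reciprocal dyads. Nodes with fewer than two
#' neighbours get 0 by convention.
#'
#' @param net a [connection_matrix()]
#' @return named numeric vector of per-node coefficients; the network-level
#'   coefficient is their mean.
#' @export
clustering_directed <- function(net) {
  a <- net$adjacency
  storage.mode(a) <- "double"
  s <- a + t(a)
  tri <- diag(s %*% s %*% s) / 2
  k <- rowSums(a) + colSums(a)
  krec <- diag(a %*% a)
  denom <- k * (k - 1) - 2 * krec
  cc <- ifelse(denom > 0, tri / denom, 0)
  names(cc) <- net$labels
  cc
}

#' Characteristic path length
#'
#' Mean of the finite off-diagonal entries of the distance matrix
#' (self-distances and unreachable pairs excluded).
#' @param dist a distance matrix from [shortest_distances()]
#' @export
characteristic_path_length <- function(dist) {
  off <- dist[row(dist) != col(dist)]
  mean(off[is.finite(off)])
}

#' Global efficiency
#'
#' Mean over ordered node pairs of the inverse distance, with unreachable
#' pairs contributing zero.
#' @param dist a distance matrix from [shortest_distances()]
#' @export
global_efficiency <- function(dist) {
  n <- nrow(dist)
  if (n < 2) return(0)
  off <- dist[row(dist) != col(dist)]
  sum(1 / off[off > 0]) / (n * (n - 1))
}

#' Local efficiency
#'
#' For each node, the global efficiency of the directed subgraph induced on
#' its neighbourhood (union of in- and out-neighbours, node itself excluded).
#' @param net a [connection_matrix()]
#' @return named numeric vector; the network value is its mean.
#' @export
local_efficiency <- function(net) {
  a <- net$adjacency
  n <- nrow(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] == 1L | a[, i] == 1L)
    nb <- setdiff(nb, i)
    if (length(nb) < 2) next
    sub <- connection_matrix(a[nb, nb, drop = FALSE], labels = net$labels[nb])
    out[i] <- global_efficiency(shortest_distances(sub))
  }
  names(out) <- net$labels
  out
}

#' Small-world indices against randomized and latticized ensembles
#'
#' gamma = C / <C_rand>, lambda = L / <L_rand>, sigma = gamma / lambda, and
#' omega = <L_rand> / L - C / <C_latt>. sigma > 1 indicates high clustering at
#' a short path length relative to randomized nulls; omega near 0 indicates
#' lattice-like clustering combined with random-like path length.
#'
#' @param net a [connection_matrix()]
#' @param rand_ensemble a `null_ensemble` with `model == "randomized"`
#' @param latt_ensemble a `null_ensemble` with `model == "latticized"`
#' @return list of class `smallworld_report` with fields `C`, `L`, `E_glob`,
#'   `E_loc`, `C_rand`, `L_rand`, `C_latt`, `gamma`, `lambda`, `sigma`,
#'   `omega`.
#' @export
small_world_indices <- function(net, rand_ensemble, latt_ensemble) {
  if (rand_ensemble$model != "randomized") {
    stop("rand_ensemble must have model 'randomized', got ", rand_ensemble$model)
  }
  if (latt_ensemble$model != "latticized") {
    stop("latt_ensemble must have model 'latticized', got ", latt_ensemble$model)
  }
  dist <- shortest_distances(net)
  C <- mean(clustering_directed(net))
  L <- characteristic_path_length(dist)
  c_rand <- ensemble_apply(rand_ensemble, function(m) mean(clustering_directed(m)),
                           simplify = TRUE)
  l_rand <- ensemble_apply(rand_ensemble, function(m) {
    characteristic_path_length(shortest_distances(m))
  }, simplify = TRUE)
  c_latt <- ensemble_apply(latt_ensemble, function(m) mean(clustering_directed(m)),
                           simplify = TRUE)
  gamma <- C / mean(c_rand)
  lambda <- L / mean(l_rand)
  structure(list(
    C = C, L = L,
    E_glob = global_efficiency(dist), E_loc = mean(local_efficiency(net)),
    C_rand = mean(c_rand), L_rand = mean(l_rand), C_latt = mean(c_latt),
    gamma = gamma, lambda = lambda, sigma = gamma / lambda,
    omega = mean(l_rand) / L - C / mean(c_latt)
  ), class = "smallworld_report")
}

#' @export
print.smallworld_report <- function(x, ...) {
  cat(sprintf("C = %.3f  L = %.3f  E_glob = %.3f  E_loc = %.3f\n",
              x$C, x$L, x$E_glob, x$E_loc))
  cat(sprintf("gamma = %.3f  lambda = %.3f  sigma = %.3f  omega = %.3f\n",
              x$gamma, x$lambda, x$sigma, x$omega))
  invisible(x)
}
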