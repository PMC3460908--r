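#' Directed modularity of a partition
#'
#' Q = (1/m) * sum_ij (a_ij - k_i^out k_j^in / m) delta(c_i, c_j), the
#' directed generalization of Newman modularity.
#'
#' @param net a [connection_matrix()]
#' @param assignment integer module id per node
#' @export
modularity_q <- function(net, assignment) {
  a <- net$adjacency
  m <- sum(a)
  if (m == 0) return(0)
  kout <- rowSums(a); kin <- colSums(a)
  q <- 0
  for (g in unique(assignment)) {
    idx <- which(assignment == g)
    q <- q + sum(a[idx, idx]) / m - sum(kout[idx]) * sum(kin[idx]) / m^2
  }
  q
}

#' Spectral optimization of directed modularity
#'
#' Recursive spectral bisection on the symmetrized directed modularity matrix
#' (B + t(B))/2, with B = A - k_out k_in^T / m, followed at each split by a
#' greedy node-moving (Kernighan-Lin style) refinement pass. A split is
#' retained only if it increases Q. Deterministic given `seed` (the seed only
#' matters for degenerate sign ties in the leading eigenvector).
#'
#' @param net a [connection_matrix()]
#' @param seed integer seed for degenerate tie-breaking
#' @param tol numerical tolerance on eigenvalues and Q gains
#' @return list of class `modular_partition`: `assignment` (integer per node,
#'   1-based, named by label), `Q`, `n_modules`.
#' @export
optimize_modularity_directed <- function(net, seed = 1L, tol = 1e-10) {
  set.seed(seed)
  a <- net$adjacency
  storage.mode(a) <- "double"
  n <- nrow(a)
  m <- sum(a)
  if (m == 0 || n < 2) {
    return(finish_partition(net, rep(1L, n)))
  }
  kout <- rowSums(a); kin <- colSums(a)
  B <- a - tcrossprod(kout, kin) / m
  S <- (B + t(B)) / 2

  assignment <- rep(1L, n)
  queue <- list(seq_len(n))
  next_id <- 2L
  while (length(queue) > 0) {
    g <- queue[[1]]; queue <- queue[-1]
    if (length(g) < 2) next
    Bg <- S[g, g, drop = FALSE]
    diag(Bg) <- diag(Bg) - rowSums(Bg)
    es <- eigen(Bg, symmetric = TRUE)
    if (es$values[1] <= tol) next
    v <- es$vectors[, 1]
    s <- ifelse(v >= 0, 1, -1)
    if (all(v == 0)) s <- sample(c(-1, 1), length(g), replace = TRUE)
    s <- kl_refine(Bg, s, tol)
    if (all(s == s[1])) next
    dq <- drop(crossprod(s, Bg %*% s)) / (4 * m)
    if (dq <= tol) next
    g2 <- g[s < 0]
    assignment[g2] <- next_id
    next_id <- next_id + 1L
    queue <- c(queue, list(g[s > 0]), list(g2))
  }
  assignment <- global_refine(S, m, assignment, tol)
  # escape local optima: perturb-and-refine restarts, keep the best Q
  q_of <- function(asg) {
    memb <- outer(asg, sort(unique(asg)), "==") + 0
    sum(diag(crossprod(memb, S %*% memb))) / (2 * m)
  }
  best <- assignment
  best_q <- q_of(best)
  for (t in seq_len(5)) {
    pert <- best
    flip <- sample(n, max(2, round(0.1 * n)))
    pert[flip] <- sample(unique(best), length(flip), replace = TRUE)
    pert <- global_refine(S, m, pert, tol)
    qq <- q_of(pert)
    if (qq > best_q + tol) {
      best <- pert
      best_q <- qq
    }
  }
  finish_partition(net, best)
}

# final refinement over the full partition: greedy single-node moves to any
# module, interleaved with module merges, until neither improves Q
global_refine <- function(S, m, assignment, tol) {
  repeat {
    changed <- FALSE
    # node moves
    repeat {
      mods <- sort(unique(assignment))
      memb <- outer(assignment, mods, "==") + 0
      M <- S %*% memb
      cur <- M[cbind(seq_along(assignment), match(assignment, mods))]
      gain <- (M - cur + diag(S)) / m          # delta-Q of moving node i
      gain[cbind(seq_along(assignment), match(assignment, mods))] <- 0
      i <- arrayInd(which.max(gain), dim(gain))
      if (gain[i] <= tol) break
      assignment[i[1]] <- mods[i[2]]
      changed <- TRUE
    }
    # merges
    mods <- sort(unique(assignment))
    if (length(mods) > 1) {
      memb <- outer(assignment, mods, "==") + 0
      G <- crossprod(memb, S %*% memb) / m     # delta-Q of merging two modules
      diag(G) <- -Inf
      i <- arrayInd(which.max(G), dim(G))
      if (G[i] > tol) {
        assignment[assignment == mods[i[2]]] <- mods[i[1]]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  assignment
}

# Greedy single-node moves maximizing s' Bg s; terminates because each
# accepted move strictly increases the objective.
kl_refine <- function(Bg, s, tol) {
  repeat {
    bs <- Bg %*% s
    gain <- -4 * s * (bs - diag(Bg) * s)
    i <- which.max(gain)
    if (gain[i] <= tol) break
    s[i] <- -s[i]
  }
  s
}

finish_partition <- function(net, assignment) {
  assignment <- as.integer(factor(assignment))
  names(assignment) <- net$labels
  structure(list(assignment = assignment,
                 Q = modularity_q(net, assignment),
                 n_modules = length(unique(assignment))),
            class = "modular_partition")
}

#' @export
print.modular_partition <- function(x, ...) {
  cat(sprintf("<modular_partition> %d modules, Q = %.4f, sizes: %s\n",
              x$n_modules, x$Q, paste(table(x$assignment), collapse = " ")))
  invisible(x)
}

#' Within/between-module connection densities
#'
#' Realized over possible directed edges within versus between modules, plus
#' the fraction of all edges that are intra-modular.
#' @param net a [connection_matrix()]
#' @param partition a `modular_partition` (or bare assignment vector)
#' @return list with `within_density`, `between_density`,
#'   `intra_edge_fraction`.
#' @export
partition_densities <- function(net, partition) {
  cl <- partition_assignment(partition, net)
  a <- net$adjacency
  same <- outer(cl, cl, "==")
  diag(same) <- NA
  e_within <- sum(a[same & !is.na(same)])
  e_between <- sum(a[!same & !is.na(same)])
  p_within <- sum(same, na.rm = TRUE)
  p_between <- sum(!same, na.rm = TRUE)
  list(within_density = if (p_within > 0) e_within / p_within else NA_real_,
       between_density = if (p_between > 0) e_between / p_between else NA_real_,
       intra_edge_fraction = e_within / sum(a))
}

partition_assignment <- function(partition, net) {
  cl <- if (inherits(partition, "modular_partition")) partition$assignment else partition
  stopifnot(length(cl) == n_nodes(net))
  as.integer(cl)
}

#' Participation coefficient, within-module degree z-score, connector hubs
#'
#' Participation P_i = 1 - sum_s (kappa_is / k_i)^2, where kappa_is is node
#' i's total (in + out) degree into module s. The within-module z-score
#' standardizes each node's total degree into its own module across that
#' module's members. Connector hubs satisfy z > `z_thresh` and
#' P > `p_thresh`. Nodes in singleton modules get z = 0 (with a warning).
#'
#' @param net a [connection_matrix()]
#' @param partition a `modular_partition` or assignment vector
#' @param z_thresh,p_thresh connector-hub thresholds (defaults 2 and 0.5)
#' @return data.frame with `label`, `module`, `participation`, `z_within`,
#'   `is_connector_hub`.
#' @export
node_roles <- function(net, partition, z_thresh = 2, p_thresh = 0.5) {
  cl <- partition_assignment(partition, net)
  a <- net$adjacency
  mods <- sort(unique(cl))
  memb <- outer(cl, mods, "==") + 0           # n x n_mod indicator
  kappa <- (a + t(a)) %*% memb                # total degree into each module
  k <- rowSums(kappa)
  p <- 1 - rowSums((kappa / pmax(k, 1))^2)
  p[k == 0] <- 0
  within <- kappa[cbind(seq_along(cl), match(cl, mods))]
  z <- numeric(length(cl))
  singleton <- FALSE
  for (g in mods) {
    idx <- which(cl == g)
    if (length(idx) < 2) { z[idx] <- 0; singleton <- TRUE; next }
    s <- sd(within[idx])
    z[idx] <- if (s > 0) (within[idx] - mean(within[idx])) / s else 0
  }
  if (singleton) warning("singleton module: within-module z-score set to 0")
  data.frame(label = net$labels, module = cl, participation = unname(p),
             z_within = z, is_connector_hub = z > z_thresh & p > p_thresh,
             stringsAsFactors = FALSE)
}
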