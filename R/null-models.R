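#' Degree-preserving randomization (Markov edge switching)
#'
#' Repeated double-edge swaps (a->b, c->d) => (a->d, c->b), rejecting swaps
#' that would create self-loops or duplicate edges. Every swap conserves each
#' node's in-degree and out-degree exactly, so the null network preserves
#' size, density and the full in/out-degree sequence while losing global
#' structure.
#'
#' @param net a [connection_matrix()]
#' @param swaps_per_edge number of attempted swaps per edge (default 10;
#'   convergence can be checked via the `"swaps"` attribute).
#' @param seed optional integer seed applied via [set.seed()].
#' @return a rewired `connection_matrix`; attribute `"swaps"` records
#'   attempted and accepted swap counts. If the degree sequence admits no
#'   rewiring a warning is raised and an unchanged copy returned.
#' @export
randomize <- function(net, swaps_per_edge = 10, seed = NULL) {
  rewire_net(net, swaps_per_edge, lattice = FALSE, seed = seed)
}

#' Degree-preserving latticization
#'
#' Same swap mechanics as [randomize()], but a swap is accepted only if the
#' combined distance of the two rewired edges from the matrix diagonal does
#' not increase (with `strict = TRUE`, only if it strictly decreases), under a
#' node ordering drawn at random per instantiation. This concentrates edges
#' in a band around the diagonal, an approximate ring lattice embodying
#' cost-efficient wiring.
#'
#' @inheritParams randomize
#' @param strict require a strict decrease of the combined diagonal distance.
#' @param ordering optional integer permutation of nodes to use as the imposed
#'   ordering; drawn uniformly at random when `NULL`.
#' @export
latticize <- function(net, swaps_per_edge = 10, seed = NULL, strict = FALSE,
                      ordering = NULL) {
  rewire_net(net, swaps_per_edge, lattice = TRUE, seed = seed, strict = strict,
             ordering = ordering)
}

rewire_net <- function(net, swaps_per_edge, lattice, seed = NULL,
                       strict = FALSE, ordering = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- n_edges(net)
  if (lattice && is.null(ordering)) ordering <- sample.int(n_nodes(net))
  if (is.null(ordering)) ordering <- seq_len(n_nodes(net))
  res <- rewire_swaps_cpp(net$adjacency, as.integer(ceiling(swaps_per_edge * m)),
                          lattice, as.integer(ordering), strict)
  if (m >= 2 && res$accepted == 0) {
    warning("degree sequence admits no rewiring; returning an unchanged copy")
  }
  out <- connection_matrix(res$adjacency, labels = net$labels, module = net$module)
  attr(out, "swaps") <- list(attempts = res$attempts, accepted = res$accepted)
  if (lattice) attr(out, "ordering") <- ordering
  out
}

#' Build a seeded ensemble of null networks
#'
#' Member i is generated under a sub-seed derived deterministically from the
#' master seed (SplitMix-style multiplicative hashing), so ensembles are
#' reproducible member-by-member.
#'
#' @param net a [connection_matrix()]
#' @param model `"randomized"` or `"latticized"`
#' @param size number of members (>= 1)
#' @param swaps_per_edge attempted swaps per edge per member
#' @param seed master integer seed
#' @param ... passed to [latticize()] (e.g. `strict`)
#' @return an object of class `null_ensemble`: list with `members` (list of
#'   `connection_matrix`), `model`, `seed`, `swaps_per_edge`.
#' @export
build_ensemble <- function(net, model = c("randomized", "latticized"), size,
                           swaps_per_edge = 10, seed = 1L, ...) {
  model <- match.arg(model)
  if (size < 1) stop("ensemble size must be >= 1")
  members <- vector("list", size)
  for (i in seq_len(size)) {
    si <- member_seed(seed, i)
    members[[i]] <- if (model == "randomized") {
      randomize(net, swaps_per_edge, seed = si)
    } else {
      latticize(net, swaps_per_edge, seed = si, ...)
    }
  }
  structure(list(members = members, model = model, seed = seed,
                 swaps_per_edge = swaps_per_edge),
            class = "null_ensemble")
}

# SplitMix-style sub-seed: deterministic, well spread, < 2^31.
member_seed <- function(seed, i) {
  x <- (as.double(seed) %% 2147483647) + 0x9E37 * as.double(i)
  x <- (x * 48271) %% 2147483647
  as.integer((x * 16807) %% 2147483629)
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> %s, %d members, seed %d, %g swaps/edge\n",
              x$model, length(x$members), x$seed, x$swaps_per_edge))
  invisible(x)
}

#' Apply a function over ensemble members
#' @param ensemble a `null_ensemble`
#' @param f function of a `connection_matrix`
#' @param simplify passed to [sapply()] semantics; if `TRUE` results are
#'   simplified via `vapply` when scalar.
#' @export
ensemble_apply <- function(ensemble, f, simplify = FALSE) {
  out <- lapply(ensemble$members, f)
  if (simplify && all(vapply(out, length, 1L) == 1L)) unlist(out) else out
}
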