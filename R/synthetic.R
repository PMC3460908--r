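#' Specification for a synthetic directed network with planted structure
#'
#' Defaults emulate a macaque-cortex-like connectome: 242 nodes, 5 modules,
#' within-module directed density 0.191 versus between-module 0.037 (overall
#' around 0.07), edge-wise reciprocity 0.507, an exponential degree
#' propensity producing a broad (exponential-like) degree tail, and a
#' 12-node rich club spread over all modules and wired among itself at
#' density 0.64. Coordinates place each module in its own 3D Gaussian
#' cluster, so the module-spanning rich-club edges are long.
#'
#' @param n_nodes,n_modules network size and module count
#' @param within_density,between_density directed edge densities inside and
#'   between modules
#' @param rc_size,rc_density planted (innermost) rich-club size and its
#'   internal directed density (must exceed `rc2_density`)
#' @param rc2_size,rc2_density size and density of the outer planted shell:
#'   the `rc2_size` highest-propensity non-club nodes are wired, among
#'   themselves and with the club, at `rc2_density`. Real connectomes show a
#'   nested rich-club hierarchy, and without such an outer shell the
#'   innermost club is statistically invisible after FDR (at club-level
#'   degrees a degree-preserving null already concentrates edges among the
#'   club, so the boundary z-score alone cannot carry the step-up). Set
#'   `rc2_size = 0` to plant a single bare club.
#' @param rc_per_module allocation of rich-club nodes across modules
#'   (defaults to an even spread over all modules)
#' @param reciprocity_target edge-wise reciprocity in `[0, 1]`
#' @param degree_tail_rate rate of the exponential per-node propensity
#' @param propensity_mix weight of the propensity in the edge probability
#'   (0 = homogeneous block model)
#' @param club_propensity absolute propensity level of club members (on the
#'   scale of the bulk propensities, whose mean is 1). An absolute level —
#'   rather than one pinned to the realized bulk maximum — keeps club
#'   degrees, and hence the null density at the club boundary, stable
#'   across seeds. A slight descending ladder (6% spread) gives the club a
#'   reproducible internal degree order, so degree-threshold subsets of the
#'   club are fixed sets with unbiased realized density rather than
#'   luck-selected ones.
#' @param shell_propensity_cap upper bound on shell members' bulk
#'   propensity; keeps shell degrees below club degrees so degree
#'   thresholds separate the two tiers.
#' @param cluster_sd,cluster_spread coordinate dispersion within a module and
#'   distance scale between module centres, in mm
#' @param seed integer seed
#' @return list of class `synthetic_spec`
#' @export
synthetic_spec <- function(n_nodes = 242, n_modules = 5,
                           within_density = 0.191, between_density = 0.037,
                           rc_size = 12, rc_density = 0.64,
                           rc2_size = 34, rc2_density = 0.43,
                           rc_per_module = NULL,
                           reciprocity_target = 0.507,
                           degree_tail_rate = 1, propensity_mix = 0.6,
                           club_propensity = 3.1, shell_propensity_cap = 1.2,
                           cluster_sd = 4, cluster_spread = 25, seed = 1L) {
  if (!(rc_density > within_density && within_density > between_density)) {
    stop("need rc_density > within_density > between_density")
  }
  if (rc2_size > 0 && !(rc_density > rc2_density && rc2_density > within_density)) {
    stop("need rc_density > rc2_density > within_density")
  }
  if (rc_size + rc2_size > n_nodes) stop("planted shells exceed n_nodes")
  if (is.null(rc_per_module)) {
    rc_per_module <- diff(round(seq(0, rc_size, length.out = n_modules + 1)))
  }
  stopifnot(sum(rc_per_module) == rc_size, length(rc_per_module) == n_modules)
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Generate a synthetic network with planted modules and rich club
#'
#' Dyad-level sampling: each unordered pair receives both edges with
#' probability rho * d and a single edge in either direction with
#' probability d * (1 - rho) each, where d is the pair's target density and
#' rho the reciprocity target; this realizes the target reciprocity exactly
#' in expectation. Pair densities combine (a) baseline block densities
#' modulated multiplicatively by per-node propensities, rescaled so the
#' network's overall expected density equals the block-implied value with
#' the planted core included, and (b) a nested density gradient over the
#' planted core (club plus shell): a core pair's density is set by the
#' outermore of its two members, interpolating from `rc_density` at the
#' club boundary to `rc2_density` at the shell edge — the nested-hierarchy
#' signature of empirical connectomes. Core dyad states are drawn with
#' exact (probabilistically rounded) stratified counts, so planted
#' densities are realized with minimal seed-to-seed fluctuation; the
#' detectability of the planted club is then governed by the design, not by
#' sampling luck. Club members carry the highest degrees by construction.
#'
#' @param spec a [synthetic_spec()]
#' @return list with `net` (a [connection_matrix()] with `module` set) and
#'   `truth` (list: `module_of`, `rc_nodes` and `rc2_nodes` labels,
#'   `coords` data.frame).
#' @export
generate_network <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_nodes
  labels <- sprintf("R%03d", seq_len(n))
  module_of <- rep(seq_len(spec$n_modules), length.out = n)
  module_of <- sort(module_of)
  # rich-club nodes: the first rc_per_module[g] slots of each module
  rc <- unlist(lapply(seq_len(spec$n_modules), function(g) {
    which(module_of == g)[seq_len(spec$rc_per_module[g])]
  }))
  # bulk propensities (exponential tail); club levels absolute and laddered;
  # shell = highest-propensity non-club nodes, capped
  w <- rexp(n - length(rc), rate = spec$degree_tail_rate)
  w <- spec$propensity_mix * w + (1 - spec$propensity_mix)
  v <- numeric(n)
  v[-rc] <- w
  v[rc] <- spec$club_propensity * seq(1.06, 0.98, length.out = length(rc))
  rc2 <- integer(0)
  if (spec$rc2_size > 0) {
    nonclub <- setdiff(seq_len(n), rc)
    rc2 <- nonclub[order(v[nonclub], decreasing = TRUE)[seq_len(spec$rc2_size)]]
    v[rc2] <- pmin(v[rc2], spec$shell_propensity_cap)
  }
  v <- v / mean(v)

  rho <- spec$reciprocity_target
  dcap <- 1 / (2 - rho) - 1e-9
  core_rank <- rep(NA_real_, n)
  core_rank[rc] <- seq_along(rc)
  if (length(rc2)) core_rank[rc2] <- length(rc) + seq_along(rc2)
  core_order <- order(core_rank)[seq_len(length(rc) + length(rc2))]
  n_core <- length(core_order)
  core_density <- function(r) {
    f <- pmin(1, pmax(0, r - spec$rc_size) / max(spec$rc2_size, 1))
    spec$rc_density - (spec$rc_density - spec$rc2_density) * f
  }
  # baseline block densities, rescaled separately for within- and
  # between-module pairs so the network's REALIZED within/between densities
  # (planted core included) match the targets — the empirical block
  # densities of a connectome subsume its core, so the baselines must make
  # room for it
  base <- matrix(spec$between_density, n, n)
  same <- outer(module_of, module_of, "==")
  base[same] <- spec$within_density
  base <- base * tcrossprod(v)
  diag(base) <- 0
  in_core <- !is.na(core_rank)
  coremask <- outer(in_core, in_core, "&")
  diag(coremask) <- FALSE
  offdiag <- row(base) != col(base)
  dcore <- outer(core_rank, core_rank, function(a, b) core_density(pmax(a, b)))
  # at small n the planted core can exceed a block's density budget; the
  # baseline is then floored at 15% of nominal and the realized block
  # density overshoots its target (flagged via the "rebalanced" attribute)
  rebalanced <- FALSE
  beta_for <- function(mask, target_density) {
    pairs_all <- mask & offdiag
    b <- (target_density * sum(pairs_all) - sum(dcore[pairs_all & coremask])) /
      sum(base[pairs_all & !coremask])
    if (is.nan(b) || b < 0.15) {
      rebalanced <<- TRUE
      b <- 0.15
    }
    b
  }
  beta <- ifelse(same, beta_for(same, spec$within_density),
                 beta_for(!same, spec$between_density))

  a <- matrix(0L, n, n)
  # non-core dyads: independent dyad-state draws
  pair_up <- which(upper.tri(base) & !coremask, arr.ind = TRUE)
  d <- pmin((base * beta)[pair_up], dcap)
  u <- runif(nrow(pair_up))
  both <- u < rho * d
  fwd <- !both & u < rho * d + d * (1 - rho)
  bwd <- !both & !fwd & u < d * (2 - rho)
  a[pair_up[both | fwd, , drop = FALSE]] <- 1L
  a[pair_up[both | bwd, c(2, 1), drop = FALSE]] <- 1L
  # core dyads: stratified by nesting rank with exact dyad-state counts
  # (largest-remainder apportionment of the state probabilities, which sum
  # to the dyad count exactly; random tie-break)
  alloc_states <- function(targets, nd) {
    fl <- floor(targets)
    r <- nd - sum(fl)
    if (r > 0) {
      frac <- targets - fl
      ord <- order(frac + runif(3) * 1e-9, decreasing = TRUE)
      fl[ord[seq_len(r)]] <- fl[ord[seq_len(r)]] + 1
    }
    fl
  }
  for (r in 2:n_core) {
    node <- core_order[r]
    partners <- core_order[seq_len(r - 1)]
    nd <- length(partners)
    dr <- min(core_density(r), dcap)
    cnt <- alloc_states(nd * c(rho * dr, 2 * dr * (1 - rho),
                               1 - dr * (2 - rho)), nd)
    st <- rep(c(2L, 1L, 0L), cnt)[sample.int(nd)]
    bothp <- partners[st == 2L]
    a[node, bothp] <- 1L; a[bothp, node] <- 1L
    singp <- partners[st == 1L]
    if (length(singp)) {
      dir_out <- runif(length(singp)) < 0.5
      a[node, singp[dir_out]] <- 1L
      a[cbind(singp[!dir_out], node)] <- 1L
    }
  }
  centers <- matrix(rnorm(spec$n_modules * 3, sd = spec$cluster_spread / 2),
                    spec$n_modules, 3)
  coords <- centers[module_of, ] + matrix(rnorm(n * 3, sd = spec$cluster_sd), n, 3)
  net <- connection_matrix(a, labels = labels, module = module_of)
  attr(net, "density_rebalanced") <- rebalanced
  truth <- list(module_of = setNames(module_of, labels),
                rc_nodes = labels[rc],
                rc2_nodes = labels[sort(c(rc, rc2))],
                coords = data.frame(label = labels, x = coords[, 1],
                                    y = coords[, 2], z = coords[, 3]))
  list(net = net, truth = truth)
}

#' Library of small hand-analyzable fixtures
#'
#' Named `connection_matrix` objects with exactly known metric values, used
#' across the test suite: `cycle_3`, `cycle_4`, `chain_4`,
#' `reciprocal_star_5` (centre `hub` with 5 mutually unconnected leaves),
#' `two_clique_bridge` (two reciprocal 4-cliques joined by one reciprocal
#' bridge), `grid_2x2` (two equal-length routes), `complete_5`,
#' `reciprocal_triangle`.
#' @return named list of `connection_matrix`
#' @export
fixture_library <- function() {
  from_edges <- function(labels, edges, reciprocal = FALSE) {
    m <- matrix(0L, length(labels), length(labels),
                dimnames = list(labels, labels))
    for (e in edges) {
      m[e[1], e[2]] <- 1L
      if (reciprocal) m[e[2], e[1]] <- 1L
    }
    connection_matrix(m, labels)
  }
  cyc <- function(k) {
    lab <- LETTERS[seq_len(k)]
    from_edges(lab, lapply(seq_len(k), function(i) c(lab[i], lab[i %% k + 1])))
  }
  star <- from_edges(c("hub", paste0("leaf", 1:5)),
                     lapply(paste0("leaf", 1:5), function(l) c("hub", l)),
                     reciprocal = TRUE)
  clq <- matrix(0L, 8, 8, dimnames = rep(list(letters[1:8]), 2))
  clq[1:4, 1:4] <- 1L; clq[5:8, 5:8] <- 1L
  diag(clq) <- 0L
  clq["d", "e"] <- clq["e", "d"] <- 1L
  comp5 <- matrix(1L, 5, 5, dimnames = rep(list(LETTERS[1:5]), 2))
  diag(comp5) <- 0L
  list(
    cycle_3 = cyc(3),
    cycle_4 = cyc(4),
    chain_4 = from_edges(LETTERS[1:4], list(c("A", "B"), c("B", "C"), c("C", "D"))),
    reciprocal_star_5 = star,
    two_clique_bridge = connection_matrix(clq, letters[1:8]),
    grid_2x2 = from_edges(c("s", "u", "v", "t"),
                          list(c("s", "u"), c("s", "v"), c("u", "t"), c("v", "t"))),
    complete_5 = connection_matrix(comp5, LETTERS[1:5]),
    reciprocal_triangle = from_edges(LETTERS[1:3],
                                     list(c("A", "B"), c("B", "C"), c("A", "C")),
                                     reciprocal = TRUE)
  )
}
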