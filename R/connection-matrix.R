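#' Connection matrix: the binary directed graph container
#'
#' A `connection_matrix` holds an N x N binary adjacency matrix of directed
#' projections (`a[i, j] = 1` iff region i projects to region j; rows are
#' sources, columns are targets), together with unique region labels and,
#' optionally, a module assignment. Self-connections are disallowed.
#'
#' @param adjacency numeric/integer N x N matrix with entries in \{0, 1\} and a
#'   zero diagonal.
#' @param labels character vector of N unique region names. If `NULL`,
#'   dimnames of `adjacency` are used, or labels `"n001"...` are generated.
#' @param module optional integer vector of length N with a community id per
#'   node.
#' @return An object of class `connection_matrix`: a list with elements
#'   `adjacency` (integer matrix with labels as dimnames), `labels`, and
#'   optionally `module`.
#' @examples
#' a <- matrix(0, 3, 3); a[1, 2] <- a[2, 3] <- a[3, 1] <- 1
#' net <- connection_matrix(a, labels = c("A", "B", "C"))
#' n_edges(net)
#' @export
connection_matrix <- function(adjacency, labels = NULL, module = NULL) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency)) {
    stop("adjacency must be square, got ", nrow(adjacency), " x ", ncol(adjacency))
  }
  n <- nrow(adjacency)
  if (is.null(labels)) {
    labels <- rownames(adjacency)
    if (is.null(labels)) labels <- sprintf("n%03d", seq_len(n))
  }
  labels <- as.character(labels)
  if (length(labels) != n) {
    stop("label count (", length(labels), ") does not match matrix size (", n, ")")
  }
  if (anyDuplicated(labels)) stop("region labels must be unique")
  if (any(is.na(adjacency)) || !all(adjacency %in% c(0, 1))) {
    stop("adjacency entries must be binary (0/1)")
  }
  if (n > 0 && any(diag(adjacency) != 0)) {
    stop("self-loop present: the matrix must contain no self-connections")
  }
  storage.mode(adjacency) <- "integer"
  dimnames(adjacency) <- list(labels, labels)
  out <- list(adjacency = adjacency, labels = labels)
  if (!is.null(module)) {
    stopifnot(length(module) == n)
    out$module <- as.integer(module)
  }
  structure(out, class = "connection_matrix")
}

#' @export
print.connection_matrix <- function(x, ...) {
  cat(sprintf(
    "<connection_matrix> %d nodes, %d directed edges (density %.4f)\n",
    n_nodes(x), n_edges(x),
    if (n_nodes(x) > 1) n_edges(x) / (n_nodes(x) * (n_nodes(x) - 1)) else NA_real_
  ))
  invisible(x)
}

#' Number of nodes / directed edges
#' @param net a `connection_matrix`
#' @export
n_nodes <- function(net) length(net$labels)

#' @rdname n_nodes
#' @export
n_edges <- function(net) sum(net$adjacency)

#' Convert to an igraph object
#'
#' Used internally for breadth-first distances; exported because it is handy
#' for plotting and ad-hoc queries.
#' @param net a `connection_matrix`
#' @export
as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "directed")
}

#' Load a directed binary network from text files
#'
#' Reads either a dense whitespace/comma-delimited 0/1 matrix or a two-column
#' edge list (source label, target label), plus a label file with one region
#' name per line (its order defines the matrix order). Validates binarity, the
#' absence of self-loops and the matrix/label dimension match.
#'
#' @param adjacency_path path to the matrix or edge-list file.
#' @param labels_path path to the label file (one name per line). Optional for
#'   dense files that carry dimnames.
#' @param format `"auto"` (default), `"matrix"` or `"edgelist"`.
#' @param transpose if `TRUE`, the dense input is transposed on load (for
#'   files stored column = source).
#' @return a validated [connection_matrix()].
#' @export
load_network <- function(adjacency_path, labels_path = NULL, format = "auto",
                         transpose = FALSE) {
  labels <- NULL
  if (!is.null(labels_path)) {
    labels <- trimws(readLines(labels_path, warn = FALSE))
    labels <- labels[nzchar(labels)]
  }
  first <- readLines(adjacency_path, n = 1L, warn = FALSE)
  if (format == "auto") {
    toks <- strsplit(trimws(first), "[,\t ]+")[[1]]
    format <- if (all(grepl("^[01]$", toks))) "matrix" else "edgelist"
  }
  if (format == "matrix") {
    sep <- if (grepl(",", first)) "," else ""
    m <- as.matrix(read.table(adjacency_path, sep = sep, header = FALSE))
    dimnames(m) <- NULL
    if (transpose) m <- t(m)
    connection_matrix(m, labels = labels)
  } else {
    toks <- tolower(strsplit(trimws(first), "[,\t ]+")[[1]])
    has_header <- identical(toks[1:2], c("source", "target"))
    el <- read.table(adjacency_path, header = has_header, stringsAsFactors = FALSE)
    if (ncol(el) < 2) stop("edge list needs at least two columns")
    if (is.null(labels)) labels <- sort(unique(c(el[[1]], el[[2]])))
    bad <- setdiff(unique(c(el[[1]], el[[2]])), labels)
    if (length(bad)) stop("edge list labels missing from label file: ", paste(bad, collapse = ", "))
    m <- matrix(0L, length(labels), length(labels))
    i <- match(el[[1]], labels); j <- match(el[[2]], labels)
    if (any(i == j)) stop("self-loop present: the matrix must contain no self-connections")
    m[cbind(i, j)] <- 1L
    connection_matrix(m, labels = labels)
  }
}

#' Write a network as an edge list keyed by region label
#' @param net a `connection_matrix`
#' @param path output path (tab-separated, columns source/target)
#' @export
write_edgelist <- function(net, path) {
  idx <- which(net$adjacency == 1L, arr.ind = TRUE)
  df <- data.frame(source = net$labels[idx[, 1]], target = net$labels[idx[, 2]])
  df <- df[order(df$source, df$target), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Prune to the subnetwork where every node keeps in- and out-connections
#'
#' Iteratively removes nodes with zero in-degree or zero out-degree until none
#' remain (removal of a node can strip another node's last afferent or
#' efferent, hence the iteration). `single_pass = TRUE` applies the rule once.
#'
#' @param net a `connection_matrix`
#' @param single_pass apply the removal rule only once instead of to a fixed
#'   point.
#' @return the surviving `connection_matrix`, with attribute `"removed"`
#'   holding the labels dropped, in removal order (per sweep).
#' @export
prune_to_connected <- function(net, single_pass = FALSE) {
  a <- net$adjacency
  keep <- seq_len(nrow(a))
  removed <- character(0)
  repeat {
    sub <- a[keep, keep, drop = FALSE]
    bad <- which(rowSums(sub) == 0 | colSums(sub) == 0)
    if (length(bad) == 0) break
    removed <- c(removed, net$labels[keep[bad]])
    keep <- keep[-bad]
    if (length(keep) == 0 || single_pass) break
  }
  if (length(keep) == 0) {
    stop("pruning removed every node: no subnetwork with both afferents and efferents exists")
  }
  out <- connection_matrix(a[keep, keep, drop = FALSE], labels = net$labels[keep],
                           module = net$module[keep])
  attr(out, "removed") <- removed
  out
}

#' In-, out- and total degree per node
#'
#' Total degree k is the sum of in-degree and out-degree, the convention used
#' throughout the rich-club sweep.
#' @param net a `connection_matrix`
#' @return data.frame with columns `label`, `k_in`, `k_out`, `k`.
#' @export
degrees <- function(net) {
  a <- net$adjacency
  data.frame(label = net$labels,
             k_in = unname(colSums(a)),
             k_out = unname(rowSums(a)),
             k = unname(colSums(a) + rowSums(a)),
             stringsAsFactors = FALSE)
}

#' Fraction of edges lying in a reciprocal pair
#'
#' Number of directed edges whose opposite edge also exists, divided by the
#' total edge count (equivalently 2 x reciprocal dyads / |E|).
#' @param net a `connection_matrix` with at least one edge
#' @export
reciprocity <- function(net) {
  e <- sum(net$adjacency)
  if (e == 0) stop("reciprocity is undefined on an empty graph")
  sum(net$adjacency * t(net$adjacency)) / e
}

#' Directed hop-distance matrix
#'
#' Breadth-first shortest-path lengths between all ordered node pairs;
#' unreachable pairs are `Inf`. The attribute `"diameter"` holds the largest
#' finite off-diagonal entry.
#' @param net a `connection_matrix`
#' @export
shortest_distances <- function(net) {
  if (n_nodes(net) == 0) stop("empty network")
  d <- igraph::distances(as_igraph(net), mode = "out")
  dimnames(d) <- list(net$labels, net$labels)
  off <- d[row(d) != col(d)]
  attr(d, "diameter") <- if (any(is.finite(off))) max(off[is.finite(off)]) else NA_real_
  d
}
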