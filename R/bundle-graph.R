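#' Build a bundle graph from a filament system
#'
#' Collapses a bead-level configuration into the spatial graph of bundle
#' spines that the ring classifier operates on. Beads on different filaments
#' that lie within `bundling_distance` of each other *transversely* (their
#' separation projected on either bead's local tangent must not exceed half a
#' bond length, so merging happens across a bundle, not along it) are merged
#' by single-linkage into spine points; spine points inherit the bond
#' connectivity of their member beads. Isolated filaments remain as their own
#' paths.
#'
#' @param sys a [filament_system()].
#' @param bundling_distance merge radius (um); the cross-link capture range
#'   is the natural choice.
#' @return An object of class `bundle_graph`: list with `nodes` (m x 3 um),
#'   `edges` (data.frame `from`, `to`, `length`), `total_contour` (um) and
#'   `bundling_distance`.
#' @export
build_bundle_graph <- function(sys, bundling_distance = 0.15) {
  pos <- sys$positions
  n <- nrow(pos)
  if (n == 0) {
    return(structure(list(nodes = matrix(numeric(0), 0, 3),
                          edges = data.frame(from = integer(0),
                                             to = integer(0),
                                             length = numeric(0)),
                          total_contour = 0,
                          bundling_distance = bundling_distance),
                     class = "bundle_graph"))
  }
  fil <- sys$filament
  bonded <- which(fil[-1] == fil[-n])  # bond i -- i+1

  # local unit tangents
  tan <- matrix(0, n, 3)
  dvec <- pos[bonded + 1, , drop = FALSE] - pos[bonded, , drop = FALSE]
  tan[bonded, ] <- tan[bonded, ] + dvec
  tan[bonded + 1, ] <- tan[bonded + 1, ] + dvec
  nt <- sqrt(rowSums(tan^2))
  nt[nt < 1e-12] <- 1
  tan <- tan / nt

  # median bond length sets the transverse window
  bl <- sqrt(rowSums(dvec^2))
  half_l0 <- 0.5 * stats::median(bl)

  pr <- cross_pairs_cpp(pos, fil, bundling_distance)
  if (nrow(pr) > 0) {
    dd <- pos[pr[, 2], , drop = FALSE] - pos[pr[, 1], , drop = FALSE]
    ti <- abs(rowSums(dd * tan[pr[, 1], , drop = FALSE]))
    tj <- abs(rowSums(dd * tan[pr[, 2], , drop = FALSE]))
    pr <- pr[ti <= half_l0 & tj <= half_l0, , drop = FALSE]
  }

  # single-linkage union-find over the transverse pairs
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  if (nrow(pr) > 0)
    for (k in seq_len(nrow(pr))) {
      ra <- find(pr[k, 1]); rb <- find(pr[k, 2])
      if (ra != rb) parent[ra] <- rb
    }
  root <- vapply(seq_len(n), find, integer(1))
  cl <- match(root, unique(root))
  m <- max(cl)

  nodes <- matrix(0, m, 3)
  for (j in 1:3) nodes[, j] <- tapply(pos[, j], cl, mean)

  ef <- cl[bonded]
  et <- cl[bonded + 1]
  keep <- ef != et
  a <- pmin(ef[keep], et[keep])
  b <- pmax(ef[keep], et[keep])
  key <- paste(a, b)
  dup <- duplicated(key)
  a <- a[!dup]; b <- b[!dup]
  len <- sqrt(rowSums((nodes[a, , drop = FALSE] - nodes[b, , drop = FALSE])^2))
  edges <- data.frame(from = a, to = b, length = len)
  structure(list(nodes = nodes, edges = edges,
                 total_contour = sum(len),
                 bundling_distance = bundling_distance),
            class = "bundle_graph")
}

#' Construct a bundle graph directly from nodes and edges
#'
#' Mostly used to build hand-made topology fixtures: circles, gapped arcs,
#' branched rings.
#'
#' @param nodes m x 3 matrix (um); @param from,to 1-based node indices;
#' @param bundling_distance stored merge radius (um).
#' @return a `bundle_graph`.
#' @export
bundle_graph <- function(nodes, from, to, bundling_distance = 0.15) {
  nodes <- as.matrix(nodes)
  stopifnot(ncol(nodes) == 3, length(from) == length(to))
  if (any(from < 1 | from > nrow(nodes) | to < 1 | to > nrow(nodes)))
    stop("edge endpoint out of range")
  len <- sqrt(rowSums((nodes[from, , drop = FALSE] -
                       nodes[to, , drop = FALSE])^2))
  if (any(!is.finite(nodes))) stop("node coordinates must be finite")
  structure(list(nodes = nodes,
                 edges = data.frame(from = as.integer(from),
                                    to = as.integer(to), length = len),
                 total_contour = sum(len),
                 bundling_distance = bundling_distance),
            class = "bundle_graph")
}

#' @export
print.bundle_graph <- function(x, ...) {
  cat(sprintf("bundle_graph: %d nodes, %d edges, contour %.2f um\n",
              nrow(x$nodes), nrow(x$edges), x$total_contour))
  invisible(x)
}

.as_igraph <- function(graph) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = graph$edges$from, to = graph$edges$to),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(graph$nodes))))
  igraph::E(g)$weight <- graph$edges$length
  g
}
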