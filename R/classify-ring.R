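#' Classify a bundle graph as ring / ring-like / none
#'
#' Implements the topology scoring used for the ring-formation statistics:
#'
#' * `ring`: the graph contains a single closed cycle carrying at least
#'   `f_min` of the total contour, with no side branches.
#' * `ring_like`: either (a) an open path carrying at least `f_min` of the
#'   contour whose endpoint gap is smaller than `g_max` of its would-be
#'   circumference (a ring with a small gap), or (b) a closed cycle carrying
#'   at least `f_min` of the contour that has one or more side branches.
#' * `none`: everything else.
#'
#' Side branches shorter than `branch_min` (default twice the bundling
#' distance) are treated as reconstruction noise: they are neither counted
#' nor allowed to break the path test. The largest cycle is found exactly:
#' degree-2 chains of the graph's 2-core are contracted to a junction
#' multigraph and simple cycles are enumerated by depth-first search (the
#' search is capped at 2e5 expansions; graphs from bundles reduce to a
#' handful of junctions, so the cap is never near in practice -- if it is
#' hit, `details$cycle_search_capped` reports it).
#'
#' @param graph a [bundle_graph()].
#' @param f_min minimum fraction of total contour in the cycle (or path).
#' @param g_max maximum endpoint gap, as a fraction of the would-be
#'   circumference, for the gapped-ring case.
#' @param branch_min side-branch contour threshold (um).
#' @return An object of class `ring_report`: `classification`,
#'   `cycle_fraction`, `gap_fraction`, `n_side_branches`, and `details`
#'   (thresholds and intermediate measurements).
#' @export
classify_ring <- function(graph, f_min = 0.8, g_max = 0.1,
                          branch_min = 2 * graph$bundling_distance) {
  stopifnot(inherits(graph, "bundle_graph"))
  empty <- function(cls) {
    structure(list(classification = cls, cycle_fraction = 0,
                   gap_fraction = 0, n_side_branches = 0L,
                   details = list(f_min = f_min, g_max = g_max,
                                  branch_min = branch_min,
                                  total_contour = graph$total_contour,
                                  largest_cycle = 0,
                                  cycle_search_capped = FALSE)),
              class = "ring_report")
  }
  if (nrow(graph$edges) == 0) return(empty("none"))

  g <- .as_igraph(graph)
  g <- .prune_noise_spurs(g, branch_min)
  total <- sum(igraph::E(g)$weight)
  if (!is.finite(total) || total <= 0) return(empty("none"))

  cyc <- .largest_cycle(g)
  wc <- cyc$weight

  gap_fraction <- 0
  n_branch <- 0L
  cls <- "none"
  path_fraction <- 0

  if (wc >= f_min * total) {
    comp <- igraph::components(g)
    cid <- comp$membership[cyc$vertex]
    vids <- which(comp$membership == cid)
    sub <- igraph::induced_subgraph(g, vids)
    wcomp <- sum(igraph::E(sub)$weight)
    n_branch <- .count_branches(sub, branch_min)
    cls <- if (n_branch == 0L && (wcomp - wc) <= branch_min) "ring"
           else "ring_like"
  } else {
    # gapped-ring test on the dominant open path
    comp <- igraph::components(g)
    for (cid in order(tabulate(comp$membership), decreasing = TRUE)) {
      vids <- which(comp$membership == cid)
      sub <- igraph::induced_subgraph(g, vids)
      deg <- igraph::degree(sub)
      if (any(deg > 2)) next
      if (igraph::gsize(sub) >= igraph::gorder(sub)) next  # has a cycle
      w <- sum(igraph::E(sub)$weight)
      if (w < f_min * total) next
      ends <- as.integer(igraph::V(sub)$name[deg == 1])
      if (length(ends) != 2) next
      gap <- sqrt(sum((graph$nodes[ends[1], ] - graph$nodes[ends[2], ])^2))
      gap_fraction <- gap / (w + gap)
      path_fraction <- w / total
      if (gap_fraction < g_max) cls <- "ring_like"
      break
    }
  }

  structure(list(classification = cls,
                 cycle_fraction = if (total > 0) wc / total else 0,
                 gap_fraction = gap_fraction,
                 n_side_branches = n_branch,
                 details = list(f_min = f_min, g_max = g_max,
                                branch_min = branch_min,
                                total_contour = total,
                                largest_cycle = wc,
                                path_fraction = path_fraction,
                                cycle_search_capped = cyc$capped)),
            class = "ring_report")
}

#' @export
print.ring_report <- function(x, ...) {
  cat(sprintf(paste0("ring_report: %s (cycle %.2f of contour, gap %.3f,",
                     " %d side branches)\n"),
              x$classification, x$cycle_fraction, x$gap_fraction,
              x$n_side_branches))
  invisible(x)
}

# remove leaf chains shorter than branch_min that hang off a junction
.prune_noise_spurs <- function(g, branch_min) {
  repeat {
    ch <- .leaf_chains(g)
    drop <- character(0)
    for (c1 in ch) {
      if (c1$weight > branch_min) next
      if (!c1$at_junction) next  # whole path: keep
      drop <- c(drop, c1$chain)
    }
    if (length(drop) == 0) return(g)
    g <- igraph::delete_vertices(g, unique(drop))
  }
}

# maximal chains from each leaf to the first vertex of degree != 2
.leaf_chains <- function(g) {
  deg <- igraph::degree(g)
  nm <- igraph::V(g)$name
  leaves <- nm[deg == 1]
  out <- list()
  for (lf in leaves) {
    chain <- lf
    w <- 0
    cur <- lf
    prev <- NA_character_
    repeat {
      nb <- setdiff(nm[igraph::neighbors(g, cur)], prev)
      if (length(nb) == 0) break
      nxt <- nb[1]
      eid <- igraph::get_edge_ids(g, c(cur, nxt))
      w <- w + igraph::E(g)$weight[eid]
      if (deg[match(nxt, nm)] != 2) {
        out[[length(out) + 1]] <-
          list(chain = chain, weight = w,
               at_junction = deg[match(nxt, nm)] >= 3, end = nxt)
        break
      }
      chain <- c(chain, nxt)
      prev <- cur
      cur <- nxt
    }
  }
  out
}

# leaf-branches longer than branch_min = side branches
.count_branches <- function(sub, branch_min) {
  ch <- .leaf_chains(sub)
  sum(vapply(ch, function(c1) c1$weight > branch_min, logical(1)))
}

# 2-core (cycle-carrying part) via coreness
.two_core <- function(g) {
  igraph::induced_subgraph(g, igraph::V(g)[igraph::coreness(g) >= 2])
}

# exact max-weight simple cycle; returns weight, one vertex name on the
# cycle, and whether the DFS budget was hit
.largest_cycle <- function(g, budget = 2e5) {
  core <- .two_core(g)
  if (igraph::gorder(core) == 0)
    return(list(weight = 0, vertex = NA_character_, capped = FALSE))
  best <- 0
  best_v <- NA_character_
  capped <- FALSE
  comp <- igraph::components(core)
  for (cid in seq_len(comp$no)) {
    sub <- igraph::induced_subgraph(core, which(comp$membership == cid))
    deg <- igraph::degree(sub)
    w <- sum(igraph::E(sub)$weight)
    if (all(deg == 2)) {  # the component is itself a simple cycle
      if (w > best) { best <- w; best_v <- igraph::V(sub)$name[1] }
      next
    }
    cm <- .contract_chains(sub)
    res <- .dfs_max_cycle(cm, budget)
    capped <- capped || res$capped
    if (res$weight > best) { best <- res$weight; best_v <- res$vertex }
  }
  list(weight = best, vertex = best_v, capped = capped)
}

# contract degree-2 chains of a 2-core into a junction multigraph
# returns list(vnames, edges = data.frame(u, v, w)) with u, v vertex names
.contract_chains <- function(sub) {
  deg <- igraph::degree(sub)
  nm <- igraph::V(sub)$name
  junc <- nm[deg >= 3]
  el <- igraph::as_edgelist(sub)
  ew <- igraph::E(sub)$weight
  used <- rep(FALSE, nrow(el))
  edge_lookup <- new.env()
  for (k in seq_len(nrow(el))) {
    for (key in c(paste0(el[k, 1], "|", el[k, 2]),
                  paste0(el[k, 2], "|", el[k, 1]))) {
      lst <- edge_lookup[[key]]
      edge_lookup[[key]] <- c(lst, k)
    }
  }
  out_u <- character(0); out_v <- character(0); out_w <- numeric(0)
  for (j in junc) {
    # walk every unused edge incident to j to the next junction
    repeat {
      inc <- NULL
      for (nb in nm[igraph::neighbors(sub, j)]) {
        cand <- edge_lookup[[paste0(j, "|", nb)]]
        cand <- cand[!used[cand]]
        if (length(cand) > 0) { inc <- c(cand[1], match(nb, nm)); break }
      }
      if (is.null(inc)) break
      k <- inc[1]
      used[k] <- TRUE
      w <- ew[k]
      prev <- j
      cur <- nm[inc[2]]
      while (!(cur %in% junc)) {
        nxts <- nm[igraph::neighbors(sub, cur)]
        step_k <- NULL
        for (nb in nxts) {
          cand <- edge_lookup[[paste0(cur, "|", nb)]]
          cand <- cand[!used[cand]]
          if (length(cand) > 0) { step_k <- cand[1]; break }
        }
        if (is.null(step_k)) break
        used[step_k] <- TRUE
        w <- w + ew[step_k]
        prev <- cur
        cur <- if (el[step_k, 1] == cur) el[step_k, 2] else el[step_k, 1]
      }
      out_u <- c(out_u, j); out_v <- c(out_v, cur); out_w <- c(out_w, w)
    }
  }
  list(vnames = junc,
       edges = data.frame(u = out_u, v = out_v, w = out_w,
                          stringsAsFactors = FALSE))
}

# DFS over the junction multigraph for the max-weight simple cycle
.dfs_max_cycle <- function(cm, budget) {
  ed <- cm$edges
  if (nrow(ed) == 0)
    return(list(weight = 0, vertex = NA_character_, capped = FALSE))
  verts <- unique(c(ed$u, ed$v))
  nv <- length(verts)
  ui <- match(ed$u, verts); vi <- match(ed$v, verts)
  adj <- vector("list", nv)
  for (k in seq_len(nrow(ed))) {
    adj[[ui[k]]] <- rbind(adj[[ui[k]]], c(k, vi[k]))
    if (ui[k] != vi[k]) adj[[vi[k]]] <- rbind(adj[[vi[k]]], c(k, ui[k]))
  }
  best <- 0; best_v <- NA_character_; capped <- FALSE
  expansions <- 0L
  visited <- rep(FALSE, nv)
  used_e <- rep(FALSE, nrow(ed))
  dfs <- function(v, s, acc) {
    if (expansions > budget) { capped <<- TRUE; return() }
    for (r in seq_len(NROW(adj[[v]]))) {
      k <- adj[[v]][r, 1]; u <- adj[[v]][r, 2]
      if (used_e[k]) next
      expansions <<- expansions + 1L
      if (u == s) {
        if (acc + ed$w[k] > best) { best <<- acc + ed$w[k]; best_v <<- verts[s] }
      } else if (!visited[u]) {
        used_e[k] <<- TRUE; visited[u] <<- TRUE
        dfs(u, s, acc + ed$w[k])
        used_e[k] <<- FALSE; visited[u] <<- FALSE
      }
    }
  }
  for (s in seq_len(nv)) {
    visited[s] <- TRUE
    dfs(s, s, 0)
    visited[s] <- FALSE
    if (capped) break
  }
  list(weight = best, vertex = best_v, capped = capped)
}
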