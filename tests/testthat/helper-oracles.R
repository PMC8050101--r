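# Independent oracles and small fixture builders shared across tests.

# central finite-difference gradient of a scalar energy function
fd_gradient <- function(efun, sys, params, h = 1e-6) {
  g <- matrix(0, nrow(sys$positions), 3)
  for (i in seq_len(nrow(sys$positions))) {
    for (j in 1:3) {
      sp <- sys; sm <- sys
      sp$positions[i, j] <- sp$positions[i, j] + h
      sm$positions[i, j] <- sm$positions[i, j] - h
      g[i, j] <- (efun(sp, params) - efun(sm, params)) / (2 * h)
    }
  }
  g
}

# relative agreement between analytic forces and -grad(E)
force_gradient_error <- function(ffun, efun, sys, params) {
  f <- ffun(sys, params)
  g <- fd_gradient(efun, sys, params)
  max(abs(f + g)) / max(max(abs(f)), 1e-10)
}

# random smooth open chain (single filament)
random_chain <- function(n, seed, step = 0.08, origin = c(0, 0, 0)) {
  set.seed(seed)
  dirs <- matrix(rnorm(3 * (n - 1)), n - 1, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  # correlated walk: keeps angles away from the degenerate 180 degree kink
  for (i in seq_len(nrow(dirs) - 1))
    dirs[i + 1, ] <- (dirs[i + 1, ] + 2 * dirs[i, ]) /
      sqrt(sum(((dirs[i + 1, ] + 2 * dirs[i, ]))^2))
  pos <- rbind(origin, origin + apply(dirs * step, 2, cumsum))
  pos
}

# brute-force maximum-weight simple cycle by edge-subset enumeration:
# a simple cycle is exactly an edge subset that is connected with every
# vertex of degree 2. Exponential, so only for graphs with <= 22 edges.
oracle_max_cycle <- function(graph) {
  ed <- graph$edges
  m <- nrow(ed)
  stopifnot(m <= 16)
  best <- 0
  nv <- max(ed$from, ed$to)
  pow <- 2^(seq_len(m) - 1)
  for (mask in seq_len(2^m - 1)) {
    sel <- which(bitwAnd(mask, pow) > 0)
    if (length(sel) < 2) next
    vs <- c(ed$from[sel], ed$to[sel])
    deg <- tabulate(vs, nv)
    if (any(deg != 0 & deg != 2)) next
    # connectivity of the selected subgraph (label propagation)
    comp <- seq_len(nv)
    repeat {
      changed <- FALSE
      for (k in sel) {
        a <- comp[ed$from[k]]; b <- comp[ed$to[k]]
        if (a != b) {
          comp[c(ed$from[k], ed$to[k])] <- min(a, b)
          comp[comp == max(a, b)] <- min(a, b)
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    if (length(unique(comp[deg > 0])) != 1) next
    w <- sum(ed$length[sel])
    if (w > best) best <- w
  }
  best
}

# closed circle as a bundle graph (n nodes, radius r, plane xy + offset)
circle_graph <- function(n = 40, r = 5, gap = 0, offset = c(0, 0, 0),
                         bundling_distance = 0.15) {
  th <- seq(0, 2 * pi * (1 - gap), length.out = n)
  if (gap == 0) th <- th[-n]
  nodes <- sweep(cbind(r * cos(th), r * sin(th), 0), 2, offset, "+")
  m <- nrow(nodes)
  if (gap == 0) bundle_graph(nodes, seq_len(m), c(2:m, 1),
                             bundling_distance)
  else bundle_graph(nodes, 1:(m - 1), 2:m, bundling_distance)
}

# straight filament system along +x
straight_filament <- function(n, l0 = 0.1, origin = c(0, 0, 0), fid = 1L) {
  pos <- cbind(origin[1] + (seq_len(n) - 1) * l0, origin[2], origin[3])
  filament_system(pos, rep(fid, n))
}

# stack two filament systems into one
combine_systems <- function(...) {
  ss <- list(...)
  pos <- do.call(rbind, lapply(ss, function(s) s$positions))
  fil <- unlist(lapply(seq_along(ss), function(i)
    ss[[i]]$filament + 1000L * (i - 1L)))
  filament_system(pos, match(fil, unique(fil)))
}

# quick small-system params for integrator tests (no confinement effects)
free_params <- function(..., R = 500, kT = 4.1e-3) {
  args <- list(...)
  if (is.null(args$L)) args$L <- 1
  do.call(sim_params, c(args, list(R = R, kT = kT, c = 1e-4,
                                   total_time = 1,
                                   polymerization_rate = 1e-9)))
}

# hand fixture set: name, builder, expected class
fixture_graphs <- function() {
  mk_path <- function(nodes, bd = 0.15) {
    m <- nrow(nodes)
    bundle_graph(nodes, 1:(m - 1), 2:m, bd)
  }
  arc <- function(r, from, to, n = 12, off = c(0, 0, 0)) {
    th <- seq(from, to, length.out = n)
    sweep(cbind(r * cos(th), r * sin(th), 0), 2, off, "+")
  }
  list(
    closed_ring = list(g = circle_graph(16), class = "ring"),
    small_ring_offset = list(g = circle_graph(12, r = 2,
                                              offset = c(3, -1, 2)),
                             class = "ring"),
    gap5 = list(g = circle_graph(16, gap = 0.05), class = "ring_like"),
    gap25 = list(g = circle_graph(16, gap = 0.25), class = "none"),
    ring_plus_branch = list(g = {
      n <- 10
      th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
      nodes <- rbind(cbind(5 * cos(th), 5 * sin(th), 0),
                     cbind(5 + seq(0.5, 2.5, by = 0.5), 0, 0))
      bundle_graph(nodes, c(seq_len(n), n, n + 1:4),
                   c(2:n, 1, n + 1:5), 0.15)
    }, class = "ring_like"),
    two_loops = list(g = {
      n <- 8
      th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
      nodes <- rbind(cbind(5 * cos(th), 5 * sin(th), 0),
                     cbind(2 * cos(th) + 12, 2 * sin(th), 0))
      bundle_graph(nodes, c(seq_len(n), n + seq_len(n)),
                   c(2:n, 1, n + c(2:n, 1)), 0.15)
    }, class = "none"),
    disjoint_arcs = list(g = {
      a1 <- arc(5, 0, 0.8 * pi, n = 8)
      a2 <- arc(5, pi, 1.8 * pi, n = 8, off = c(12, 0, 0))
      nodes <- rbind(a1, a2)
      m <- nrow(a1)
      bundle_graph(nodes, c(1:(m - 1), m + 1:(m - 1)),
                   c(2:m, m + 2:m), 0.15)
    }, class = "none"),
    star_tree = list(g = {
      nodes <- rbind(c(0, 0, 0), c(2, 0, 0), c(-2, 0, 0), c(0, 2, 0),
                     c(0, -2, 0), c(0, 0, 2))
      bundle_graph(nodes, rep(1, 5), 2:6, 0.15)
    }, class = "none"),
    random_tree = list(g = {
      set.seed(8)
      nodes <- matrix(runif(30, -5, 5), 10, 3)
      bundle_graph(nodes, 1:9, sapply(2:10, function(i)
        sample(i - 1, 1)), 0.15)
    }, class = "none"),
    theta_graph = list(g = {
      # circle plus a chord: largest cycle < 80% of total contour
      n <- 16
      th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
      ring <- cbind(5 * cos(th), 5 * sin(th), 0)
      chord <- cbind(seq(-4, 4, length.out = 7), 0.3, 0)
      nodes <- rbind(ring, chord)
      bundle_graph(nodes,
                   c(seq_len(n), n + 1:6, 13, n + 7),
                   c(2:n, 1, n + 2:7, n + 1, 5), 0.15)
    }, class = "none"),
    ring_with_noise_spur = list(g = {
      # spur shorter than 2 x bundling distance: ignored -> still a ring
      n <- 12
      th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
      nodes <- rbind(cbind(5 * cos(th), 5 * sin(th), 0), c(5.2, 0, 0))
      bundle_graph(nodes, c(seq_len(n), 1), c(2:n, 1, n + 1), 0.15)
    }, class = "ring"),
    dominant_ring_plus_small_arc = list(g = {
      n <- 12
      th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
      ring <- cbind(8 * cos(th), 8 * sin(th), 0)
      a2 <- arc(1.2, 0, pi, n = 5, off = c(20, 0, 0))
      nodes <- rbind(ring, a2)
      bundle_graph(nodes, c(seq_len(n), n + 1:4),
                   c(2:n, 1, n + 2:5), 0.15)
    }, class = "ring")
  )
}

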