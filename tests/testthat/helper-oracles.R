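# Independent brute-force oracles used across the suite.  These deliberately
# re-derive every quantity from first principles (defining sums, exhaustive
# enumeration) rather than calling package internals.

# entropies straight from the defining sums
oracle_h_plugin <- function(counts) {
  n <- sum(counts)
  s <- 0
  for (c in counts) if (c > 0) s <- s - (c / n) * log(c / n)
  s
}
oracle_h_mm <- function(counts) {
  oracle_h_plugin(counts) + (sum(counts > 0) - 1) / (2 * sum(counts))
}
# MM MI of a 2x2 table given as c(n00, n01, n10, n11) (x varies fastest)
oracle_mi_mm <- function(cells) {
  x_marg <- c(cells[1] + cells[2], cells[3] + cells[4])
  y_marg <- c(cells[1] + cells[3], cells[2] + cells[4])
  oracle_h_mm(x_marg) + oracle_h_mm(y_marg) - oracle_h_mm(cells)
}
oracle_mi_plugin <- function(cells) {
  x_marg <- c(cells[1] + cells[2], cells[3] + cells[4])
  y_marg <- c(cells[1] + cells[3], cells[2] + cells[4])
  oracle_h_plugin(x_marg) + oracle_h_plugin(y_marg) - oracle_h_plugin(cells)
}

# all simple paths between two nodes of an edge data.frame (from, to, length)
oracle_shortest_distance <- function(edges, a, b) {
  best <- Inf
  walk <- function(node, visited, d) {
    if (d >= best) return(invisible(NULL))
    if (node == b) { best <<- d; return(invisible(NULL)) }
    inc <- which(edges$from == node | edges$to == node)
    for (e in inc) {
      nxt <- if (edges$from[e] == node) edges$to[e] else edges$from[e]
      if (!nxt %in% visited) walk(nxt, c(visited, nxt), d + edges$length[e])
    }
  }
  walk(a, a, 0)
  best
}

# edge-centric DPI oracle: an edge dies iff some triangle marks it, where the
# marked edge of a triangle is its (mi, lexicographic-key)-minimum and the
# mark applies only under the strict tolerance inequality
oracle_dpi_survivors <- function(edges, eps = 0) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  ek <- key(edges$from, edges$to)
  mi <- stats::setNames(edges$mi, ek)
  dead <- rep(FALSE, nrow(edges))
  for (e in seq_len(nrow(edges))) {
    u <- min(edges$from[e], edges$to[e]); v <- max(edges$from[e], edges$to[e])
    others <- setdiff(unique(c(edges$from, edges$to)), c(u, v))
    for (w in others) {
      k1 <- key(u, v); k2 <- key(u, w); k3 <- key(v, w)
      if (is.na(mi[k2]) || is.na(mi[k3])) next
      tri <- c(k1, k2, k3)
      marked <- tri[order(mi[tri], tri)][1]
      if (marked == k1 && mi[k1] < (1 - eps) * min(mi[k2], mi[k3])) {
        dead[e] <- TRUE
      }
    }
  }
  edges[!dead, , drop = FALSE]
}

# exhaustive minimum of the two-level map equation over all set partitions
oracle_best_partition <- function(net) {
  n <- igraph::vcount(net)
  best_L <- Inf
  best <- NULL
  assign_next <- function(mem, i, nblocks) {
    if (i > n) {
      L <- minprog::map_equation(net, mem)
      if (L < best_L - 1e-12) { best_L <<- L; best <<- mem }
      return(invisible(NULL))
    }
    for (b in seq_len(nblocks + 1)) {
      mem[i] <- b
      assign_next(mem, i + 1, max(nblocks, b))
    }
  }
  assign_next(integer(n), 1L, 0L)
  list(membership = best, codelength = best_L)
}

# unweighted betweenness by explicit enumeration of all shortest paths
oracle_betweenness_unweighted <- function(edges, nodes) {
  bc <- stats::setNames(rep(0, length(nodes)), nodes)
  all_paths <- function(a, b) {
    out <- list()
    walk <- function(node, path) {
      if (node == b) { out[[length(out) + 1]] <<- path; return(invisible(NULL)) }
      inc <- which(edges$from == node | edges$to == node)
      for (e in inc) {
        nxt <- if (edges$from[e] == node) edges$to[e] else edges$from[e]
        if (!nxt %in% path) walk(nxt, c(path, nxt))
      }
    }
    walk(a, a)
    out
  }
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (i >= j) next
      ps <- all_paths(nodes[i], nodes[j])
      if (!length(ps)) next
      lens <- vapply(ps, length, 1L)
      sps <- ps[lens == min(lens)]
      for (p in sps) {
        inner <- setdiff(p, c(nodes[i], nodes[j]))
        for (v in inner) bc[v] <- bc[v] + 1 / length(sps)
      }
    }
  }
  bc
}

# random weighted graph as an edge data.frame, for path/DPI property tests
random_edge_graph <- function(n_nodes, p_edge = 0.45) {
  nodes <- LETTERS[seq_len(n_nodes)]
  pairs <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  pairs <- pairs[keep, , drop = FALSE]
  data.frame(from = pairs[, 1], to = pairs[, 2],
             mi = stats::runif(nrow(pairs), 0.05, 1),
             stringsAsFactors = FALSE)
}

# Cox partial likelihood (Breslow) from the defining product, for 1-D grid
# maximization
oracle_cox_loglik <- function(beta, time, status, x) {
  ll <- 0
  for (t in sort(unique(time[status == 1]))) {
    ev <- which(time == t & status == 1)
    risk <- which(time >= t)
    ll <- ll + sum(beta * x[ev]) - length(ev) * log(sum(exp(beta * x[risk])))
  }
  ll
}

# planted-edge recovery of a pipeline run against its cohort's ground truth
edge_recovery <- function(bundle) {
  truth <- apply(bundle$cohort$truth$direct_edges, 1, paste, collapse = "|")
  found <- paste(bundle$edges_pruned$from, bundle$edges_pruned$to, sep = "|")
  list(recall = if (length(truth)) mean(truth %in% found) else NA_real_,
       precision = if (length(found)) mean(found %in% truth) else NA_real_,
       n_found = length(found))
}

# every 2x2 table (as c(n00, n01, n10, n11)) with total n
all_tables_n <- function(n) {
  out <- list()
  for (a in 0:n) for (b in 0:(n - a)) for (c in 0:(n - a - b)) {
    out[[length(out) + 1]] <- c(a, b, c, n - a - b - c)
  }
  out
}

# 0/1 vectors realizing a 2x2 table given as c(n00, n01, n10, n11),
# where nxy counts observations with X = x and Y = y
vectors_from_table <- function(cells) {
  x <- rep(c(0, 0, 1, 1), cells)
  y <- rep(c(0, 1, 0, 1), cells)
  list(x = x, y = y)
}
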