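#' Shortest prognostic paths to a target node
#'
#' Single-source shortest paths over the inverse-MI edge lengths, by
#' Dijkstra's algorithm.  Ties between equal-length paths are broken
#' deterministically: during relaxation, an equal-distance alternative is
#' adopted only if it routes through a lexicographically smaller
#' predecessor, so the reported node sequences are reproducible.
#'
#' @param net An `igraph` network from [build_network()] with a `length`
#'   edge attribute.
#' @param target Node name of the endpoint (e.g. `"death"`).
#' @return A data.frame of class `path_report`: one row per non-target
#'   node with `variable`, `distance` (sum of 1/MI; `Inf` when
#'   unreachable), `path` (node sequence from the variable to the target,
#'   collapsed with `" -> "`), `reachable`.
#' @export
shortest_paths_to <- function(net, target) {
  nodes <- igraph::V(net)$name
  if (!target %in% nodes) stop(sprintf("unknown target '%s'", target), call. = FALSE)
  el <- igraph::as_data_frame(net, what = "edges")
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (e in seq_len(nrow(el))) {
    adj[[el$from[e]]] <- rbind(adj[[el$from[e]]],
                               data.frame(to = el$to[e], len = el$length[e]))
    adj[[el$to[e]]] <- rbind(adj[[el$to[e]]],
                             data.frame(to = el$from[e], len = el$length[e]))
  }
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  prev <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  done <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  dist[target] <- 0
  repeat {
    open <- names(dist)[!done & is.finite(dist)]
    if (!length(open)) break
    u <- open[order(dist[open], open)][1]  # lexicographic tie-break
    done[u] <- TRUE
    nb <- adj[[u]]
    for (e in seq_len(NROW(nb))) {
      v <- nb$to[e]
      cand <- dist[u] + nb$len[e]
      if (cand < dist[v] - 1e-15 ||
          (abs(cand - dist[v]) <= 1e-15 && !is.na(prev[v]) && u < prev[v])) {
        dist[v] <- cand
        prev[v] <- u
      }
    }
  }
  vars <- setdiff(nodes, target)
  paths <- vapply(vars, function(v) {
    if (!is.finite(dist[v])) return(NA_character_)
    seq <- v
    while (seq[length(seq)] != target) seq <- c(seq, prev[seq[length(seq)]])
    paste(seq, collapse = " -> ")
  }, character(1))
  structure(
    data.frame(variable = vars, distance = unname(dist[vars]),
               path = unname(paths), reachable = is.finite(unname(dist[vars])),
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("path_report", "data.frame"), target = target
  )
}

#' Node centralities of the mutual information network
#'
#' Degree, betweenness and PageRank for every node.  Betweenness uses the
#' inverse-MI lengths (consistent with the network's distance definition),
#' with fractional credit split among equal-length shortest paths and
#' endpoints excluded.  PageRank runs on the MI edge weights with damping
#' 0.85 and uniform teleportation.
#'
#' @param net An `igraph` network from [build_network()].
#' @param damping PageRank damping factor (default 0.85).
#' @return A data.frame: `variable`, `degree`, `betweenness`, `pagerank`
#'   (sums to 1).
#' @export
centralities <- function(net, damping = 0.85) {
  if (igraph::vcount(net) == 0) stop("empty graph", call. = FALSE)
  has_edges <- igraph::ecount(net) > 0
  bw <- if (has_edges) {
    igraph::betweenness(net, weights = igraph::E(net)$length, directed = FALSE)
  } else {
    rep(0, igraph::vcount(net))
  }
  pr <- igraph::page_rank(net, damping = damping,
                          weights = if (has_edges) igraph::E(net)$weight else NULL)$vector
  data.frame(variable = igraph::V(net)$name,
             degree = unname(igraph::degree(net)),
             betweenness = unname(bw),
             pagerank = unname(pr),
             stringsAsFactors = FALSE, row.names = NULL)
}

# ---- two-level map equation ------------------------------------------------

plogp <- function(p) ifelse(p > 0, p * log2(p), 0)

#' Two-level map equation of a partition
#'
#' Computes the description length (bits) of a random walk on the weighted
#' undirected network under a two-level coding with the given module
#' partition: \eqn{L(M) = q H(Q) + \sum_m p_m H(P_m)}, with node visit
#' probabilities proportional to weighted degree and module exit
#' probabilities proportional to the cut weight.
#'
#' @param net An `igraph` network with `weight` edge attribute and at least
#'   one edge.
#' @param membership Integer or character vector of module labels, one per
#'   node (in `V(net)` order).
#' @return Code length in bits.
#' @export
map_equation <- function(net, membership) {
  if (igraph::ecount(net) == 0) stop("map equation needs at least one edge", call. = FALSE)
  if (length(membership) != igraph::vcount(net)) {
    stop("membership must label every node", call. = FALSE)
  }
  w <- igraph::E(net)$weight
  tot2 <- 2 * sum(w)
  p_node <- igraph::strength(net, weights = w) / tot2
  mem <- as.character(membership)
  mods <- unique(mem)
  el <- igraph::as_edgelist(net, names = FALSE)
  # cut weight per module: edges with exactly one endpoint inside
  q_m <- vapply(mods, function(m) {
    inm <- mem == m
    sum(w[xor(inm[el[, 1]], inm[el[, 2]])]) / tot2
  }, numeric(1))
  q <- sum(q_m)
  index_term <- if (q > 0) q * (-sum(plogp(q_m / q))) else 0
  module_term <- 0
  for (i in seq_along(mods)) {
    pa <- p_node[mem == mods[i]]
    pm <- q_m[i] + sum(pa)
    if (pm <= 0) next
    probs <- c(pa, q_m[i]) / pm
    module_term <- module_term + pm * (-sum(plogp(probs)))
  }
  index_term + module_term
}

#' Detect network modules by minimizing the two-level map equation
#'
#' Greedy agglomerative optimization in the style of the Infomap method:
#' starting from singleton modules, the pair merge that most decreases the
#' map equation is applied repeatedly; a node-level refinement pass then
#' moves individual nodes between neighbouring modules while improvements
#' remain.  The best partition over `restarts` seeded random scan orders is
#' returned.  Isolated nodes carry no flow and are reported as singleton
#' modules.
#'
#' @param net An `igraph` network with at least one edge.
#' @param restarts Number of seeded restarts (default 10).
#' @param seed Integer seed for the restart scan orders.
#' @return A list of class `module_partition`: `membership` (named integer
#'   vector, labels 1..m), `n_modules`, `codelength` (bits).
#' @export
detect_modules <- function(net, restarts = 10, seed = 1) {
  if (igraph::vcount(net) == 0 || igraph::ecount(net) == 0) {
    stop("module detection needs a graph with at least one edge", call. = FALSE)
  }
  n <- igraph::vcount(net)
  best <- NULL
  best_L <- Inf
  for (r in seq_len(restarts)) {
    set.seed(derive_seed(seed, "infomap-restart", r))
    mem <- optimize_map_once(net)
    L <- map_equation(net, mem)
    if (L < best_L - 1e-12) {
      best_L <- L
      best <- mem
    }
  }
  labels <- match(best, unique(best))
  names(labels) <- igraph::V(net)$name
  structure(list(membership = labels, n_modules = length(unique(labels)),
                 codelength = best_L),
            class = "module_partition")
}

# One greedy merge + node-move optimization pass (uses the current RNG
# state for scan-order randomization).
optimize_map_once <- function(net) {
  n <- igraph::vcount(net)
  mem <- seq_len(n)
  L <- map_equation(net, mem)
  el <- igraph::as_edgelist(net, names = FALSE)
  repeat {
    improved <- FALSE
    # merge phase: best connected-module merge
    repeat {
      mods <- unique(mem)
      # candidate merges: module pairs joined by at least one edge
      mpairs <- unique(t(apply(cbind(mem[el[, 1]], mem[el[, 2]]), 1, sort)))
      mpairs <- mpairs[mpairs[, 1] != mpairs[, 2], , drop = FALSE]
      if (!nrow(mpairs)) break
      mpairs <- mpairs[sample.int(nrow(mpairs)), , drop = FALSE]
      best_dL <- -1e-12
      best_mem <- NULL
      for (i in seq_len(nrow(mpairs))) {
        cand <- mem
        cand[cand == mpairs[i, 2]] <- mpairs[i, 1]
        dL <- map_equation(net, cand) - L
        if (dL < best_dL) {
          best_dL <- dL
          best_mem <- cand
        }
      }
      if (is.null(best_mem)) break
      mem <- best_mem
      L <- L + best_dL
      improved <- TRUE
    }
    # move phase: single-node moves to neighbouring modules
    moved <- TRUE
    while (moved) {
      moved <- FALSE
      for (v in sample.int(n)) {
        nbr <- unique(c(el[el[, 1] == v, 2], el[el[, 2] == v, 1]))
        if (!length(nbr)) next
        targets <- setdiff(unique(mem[nbr]), mem[v])
        for (m in targets) {
          cand <- mem
          cand[v] <- m
          dL <- map_equation(net, cand) - L
          if (dL < -1e-12) {
            mem <- cand
            L <- L + dL
            moved <- TRUE
            improved <- TRUE
          }
        }
      }
    }
    if (!improved) break
  }
  mem
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("Map-equation partition: %d modules, codelength %.4f bits\n",
              x$n_modules, x$codelength))
  invisible(x)
}

#' Classify edges by MI strength quintile-style bins
#'
#' Each edge's MI is converted to a mid-rank percentile
#' `(rank - 0.5) / n_edges` (ties share the mean rank) and binned:
#' `top20` for \[0.8, 1\], `p60_80` for \[0.6, 0.8), `p40_60` for
#' \[0.4, 0.6) and `below40` for \[0, 0.4) -- the colour classes used to
#' draw association strength in MIN figures.
#'
#' @param net An `igraph` network with >= 1 edge.
#' @return A data.frame: `from`, `to`, `mi`, `percentile`, `class`.
#' @export
classify_edge_strength <- function(net) {
  if (igraph::ecount(net) == 0) stop("network has no edges", call. = FALSE)
  el <- igraph::as_data_frame(net, what = "edges")
  pct <- (rank(el$weight, ties.method = "average") - 0.5) / nrow(el)
  cls <- cut(pct, breaks = c(-Inf, 0.4, 0.6, 0.8, Inf), right = FALSE,
             labels = c("below40", "p40_60", "p60_80", "top20"))
  data.frame(from = el$from, to = el$to, mi = el$weight,
             percentile = pct, class = as.character(cls),
             stringsAsFactors = FALSE)
}
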