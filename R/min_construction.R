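#' Network pruning configuration
#'
#' @param T Significance level applied to Bonferroni-adjusted permutation
#'   p-values (default 0.05).
#' @param D Minimum MI an edge must reach (default 0; edges with MI exactly
#'   0 are always dropped since their inverse distance is undefined).
#' @param epsilon DPI tolerance in \[0, 1): the weakest edge of a triangle
#'   is removed only when its MI is below `(1 - epsilon)` times the smaller
#'   of the other two (default 0).
#' @return A list of class `prune_config`.
#' @export
prune_config <- function(T = 0.05, D = 0, epsilon = 0) {
  if (T <= 0 || T > 1) stop("T must lie in (0, 1]", call. = FALSE)
  if (D < 0) stop("D must be >= 0", call. = FALSE)
  if (epsilon < 0 || epsilon >= 1) stop("epsilon must lie in [0, 1)", call. = FALSE)
  structure(list(T = T, D = D, epsilon = epsilon), class = "prune_config")
}

#' Select statistically significant edge candidates
#'
#' Keeps exactly the variable pairs whose Bonferroni-adjusted permutation
#' p-value is at most `T` and whose MM MI is at least `D` and strictly
#' positive (a zero-MI edge has no defined inverse-MI length).
#'
#' @param mi A `mi_matrix` from [pairwise_mi()].
#' @param sig A `mi_significance` from [mi_significance()] /
#'   [bonferroni_adjust()], over the same variables.
#' @param cfg A [prune_config()].
#' @return A data.frame of edge candidates: `from`, `to` (with
#'   `from < to` lexicographically), `mi`, `adjusted_p`.
#' @export
significant_edges <- function(mi, sig, cfg = prune_config()) {
  stopifnot(inherits(mi, "mi_matrix"), inherits(sig, "mi_significance"))
  ids <- mi$variable_ids
  if (!identical(ids, rownames(sig$adjusted_p))) {
    stop("MI and significance matrices cover different variables", call. = FALSE)
  }
  k <- length(ids)
  out <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      m <- mi$values[i, j]; p <- sig$adjusted_p[i, j]
      if (is.na(m) || is.na(p)) next
      if (p <= cfg$T && m >= cfg$D && m > 0) {
        pr <- sort(c(ids[i], ids[j]))
        out[[length(out) + 1L]] <- data.frame(from = pr[1], to = pr[2],
                                              mi = m, adjusted_p = p,
                                              stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(from = character(0), to = character(0),
                      mi = numeric(0), adjusted_p = numeric(0)))
  }
  do.call(rbind, out)
}

#' Data-processing-inequality (DPI) triangle pruning
#'
#' For every triangle present in the candidate graph, the edge with the
#' smallest MI is marked for removal when its MI is strictly below
#' `(1 - epsilon)` times the smaller of the other two MIs.  All marks are
#' computed against the pre-pruning graph and applied simultaneously, so
#' the result does not depend on edge order.  Ties on the triangle minimum
#' are broken by lexicographic pair order: the lexicographically smallest
#' `(from, to)` pair among the joint minima is the one marked.
#'
#' @param edges Edge-candidate data.frame from [significant_edges()] (no
#'   duplicate pairs).
#' @param epsilon DPI tolerance in \[0, 1).
#' @return The surviving subset of `edges`.
#' @export
dpi_prune <- function(edges, epsilon = 0) {
  if (epsilon < 0 || epsilon >= 1) stop("epsilon must lie in [0, 1)", call. = FALSE)
  if (!nrow(edges)) return(edges)
  key <- paste(edges$from, edges$to, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate edges in candidate list", call. = FALSE)
  mi_of <- stats::setNames(edges$mi, key)
  nodes <- sort(unique(c(edges$from, edges$to)))
  pair_key <- function(a, b) {
    ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  }
  drop <- character(0)
  if (length(nodes) >= 3) {
    triples <- utils::combn(nodes, 3)
    for (t in seq_len(ncol(triples))) {
      ks <- c(pair_key(triples[1, t], triples[2, t]),
              pair_key(triples[1, t], triples[3, t]),
              pair_key(triples[2, t], triples[3, t]))
      vals <- mi_of[ks]
      if (any(is.na(vals))) next  # not a triangle
      o <- order(vals, ks)  # weakest first; lexicographic tie-break
      weakest <- o[1]
      second <- min(vals[-weakest])
      if (vals[weakest] < (1 - epsilon) * second) {
        drop <- c(drop, ks[weakest])
      }
    }
  }
  edges[!key %in% drop, , drop = FALSE]
}

#' Assemble the weighted mutual information network
#'
#' Builds an undirected `igraph` graph whose edge weights are the MI
#' values and whose edge lengths are their exact reciprocals 1/MI.  All
#' declared variables become nodes; variables without surviving edges stay
#' as isolated nodes.
#'
#' @param edges Edge data.frame (`from`, `to`, `mi`), e.g. from
#'   [dpi_prune()].
#' @param variables Character vector of node IDs to declare (defaults to
#'   the nodes occurring in `edges`).
#' @return An `igraph` object with edge attributes `weight` (MI, nats) and
#'   `length` (1/MI).
#' @export
build_network <- function(edges, variables = NULL) {
  if (is.null(variables)) variables <- sort(unique(c(edges$from, edges$to)))
  if (!all(c(edges$from, edges$to) %in% variables)) {
    stop("edge references an undeclared variable", call. = FALSE)
  }
  if (anyDuplicated(paste(pmin(edges$from, edges$to),
                          pmax(edges$from, edges$to)))) {
    stop("duplicate edge", call. = FALSE)
  }
  if (nrow(edges) && any(edges$mi <= 0)) {
    stop("edge weights must be strictly positive", call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(edges[, c("from", "to"), drop = FALSE],
                                     directed = FALSE,
                                     vertices = data.frame(name = variables))
  if (nrow(edges)) {
    igraph::E(g)$weight <- edges$mi
    igraph::E(g)$length <- 1 / edges$mi
  }
  g
}

#' Export a network as a weighted edge list or GraphML
#'
#' The edge list is three-column delimited text (`from`, `to`, `mi`);
#' GraphML carries `weight`, `length` and, when present, the
#' `strength_class` edge attribute from [classify_edge_strength()].
#'
#' @param net An `igraph` network from [build_network()].
#' @param path Output file.
#' @param format `"edgelist"` or `"graphml"`.
#' @param sep Separator for the edge list.
#' @export
export_network <- function(net, path, format = c("edgelist", "graphml"),
                           sep = "\t") {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(net, what = "edges")
    out <- data.frame(from = el$from, to = el$to, mi = el$weight)
    utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
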