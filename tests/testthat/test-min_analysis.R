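test_that("shortest prognostic paths follow inverse-MI lengths and prefer
           multi-step routes over weak direct edges", {
  chain <- build_network(data.frame(from = c("A", "B"), to = c("B", "C"),
                                    mi = c(0.5, 0.25)))
  rep1 <- shortest_paths_to(chain, "C")
  expect_equal(rep1$distance[rep1$variable == "A"], 2 + 4)
  expect_equal(rep1$path[rep1$variable == "A"], "A -> B -> C")

  # adding a weak direct edge (length 10) must not change the path
  tri <- build_network(data.frame(from = c("A", "B", "A"),
                                  to = c("B", "C", "C"),
                                  mi = c(0.5, 0.25, 0.1)))
  rep2 <- shortest_paths_to(tri, "C")
  expect_equal(rep2$distance[rep2$variable == "A"], 6)
  expect_equal(rep2$path[rep2$variable == "A"], "A -> B -> C")

  # unreachable nodes get an infinite sentinel
  iso <- build_network(data.frame(from = "A", to = "B", mi = 1),
                       variables = c("A", "B", "Z"))
  rep3 <- shortest_paths_to(iso, "B")
  expect_false(rep3$reachable[rep3$variable == "Z"])
  expect_equal(rep3$distance[rep3$variable == "Z"], Inf)

  expect_error(shortest_paths_to(chain, "nope"), "unknown target")
})

test_that("path distances equal exhaustive simple-path enumeration on random
           graphs", {
  set.seed(71)
  for (rep in 1:60) {
    g <- random_edge_graph(sample(3:8, 1))
    if (nrow(g) < 1) next
    g$length <- 1 / g$mi
    net <- build_network(g)
    nodes <- igraph::V(net)$name
    target <- sample(nodes, 1)
    repd <- shortest_paths_to(net, target)
    for (i in seq_len(nrow(repd))) {
      expect_equal(repd$distance[i],
                   oracle_shortest_distance(g, repd$variable[i], target),
                   tolerance = 1e-9)
    }
  }
})

test_that("reported path sequences are deterministic and realize the stated
           distance", {
  set.seed(72)
  for (rep in 1:20) {
    g <- random_edge_graph(6, p_edge = 0.6)
    if (nrow(g) < 2) next
    net <- build_network(g)
    target <- igraph::V(net)$name[1]
    r1 <- shortest_paths_to(net, target)
    r2 <- shortest_paths_to(net, target)
    expect_identical(r1, r2)
    len_of <- function(a, b) 1 / g$mi[(g$from == a & g$to == b) |
                                        (g$from == b & g$to == a)]
    for (i in which(r1$reachable)) {
      seqv <- strsplit(r1$path[i], " -> ", fixed = TRUE)[[1]]
      d <- sum(mapply(len_of, seqv[-length(seqv)], seqv[-1]))
      expect_equal(d, r1$distance[i], tolerance = 1e-9)
    }
  }
})

test_that("centralities give textbook values on stars, paths and
           vertex-transitive graphs", {
  star <- build_network(data.frame(from = rep("hub", 4),
                                   to = c("l1", "l2", "l3", "l4"),
                                   mi = rep(1, 4)))
  ce <- centralities(star)
  expect_equal(ce$degree[ce$variable == "hub"], 4)
  expect_equal(ce$betweenness[ce$variable == "hub"], 6)  # C(4,2) leaf pairs
  expect_true(all(ce$degree[ce$variable != "hub"] == 1))
  expect_true(all(ce$betweenness[ce$variable != "hub"] == 0))
  expect_equal(sum(ce$pagerank), 1, tolerance = 1e-9)

  path <- build_network(data.frame(from = c("A", "B"), to = c("B", "C"),
                                   mi = c(1, 1)))
  cp <- centralities(path)
  expect_equal(cp$betweenness[cp$variable == "B"], 1)
  expect_equal(cp$betweenness[cp$variable != "B"], c(0, 0))

  ring <- build_network(data.frame(from = c("A", "B", "C", "D", "E"),
                                   to = c("B", "C", "D", "E", "A"),
                                   mi = rep(0.7, 5)))
  cr <- centralities(ring)
  expect_equal(cr$pagerank, rep(1 / 5, 5), tolerance = 1e-6)
})

test_that("weighted betweenness on equal-MI graphs matches unweighted
           enumeration", {
  set.seed(19)
  for (rep in 1:15) {
    g <- random_edge_graph(sample(4:7, 1), p_edge = 0.5)
    if (nrow(g) < 2) next
    g$mi <- rep(0.5, nrow(g))  # equal weights: shortest = fewest hops
    net <- build_network(g)
    ce <- centralities(net)
    bc <- oracle_betweenness_unweighted(g, igraph::V(net)$name)
    expect_equal(ce$betweenness, unname(bc[ce$variable]), tolerance = 1e-9)
  }
})

test_that("the map equation scores known partitions correctly and module
           detection matches brute force on two cliques and a triangle", {
  clique_edges <- function(nodes, w) {
    p <- t(utils::combn(nodes, 2))
    data.frame(from = p[, 1], to = p[, 2], mi = w)
  }
  two <- rbind(clique_edges(c("a1", "a2", "a3", "a4"), 1),
               clique_edges(c("b1", "b2", "b3", "b4"), 1),
               data.frame(from = "a1", to = "b1", mi = 0.05))
  net <- build_network(two)
  part <- detect_modules(net, restarts = 5, seed = 4)
  oracle <- oracle_best_partition(net)
  expect_equal(part$codelength, oracle$codelength, tolerance = 1e-9)
  expect_equal(part$n_modules, 2)
  mem <- part$membership
  expect_length(unique(mem[c("a1", "a2", "a3", "a4")]), 1)
  expect_length(unique(mem[c("b1", "b2", "b3", "b4")]), 1)
  expect_false(mem[["a1"]] == mem[["b1"]])

  tri <- build_network(clique_edges(c("x", "y", "z"), 1))
  ptri <- detect_modules(tri, restarts = 3, seed = 1)
  otri <- oracle_best_partition(tri)
  expect_equal(ptri$codelength, otri$codelength, tolerance = 1e-9)
  expect_equal(ptri$n_modules, 1)

  # partition never scores worse than all-singletons or one-module
  k <- igraph::vcount(net)
  expect_lte(part$codelength, map_equation(net, seq_len(k)) + 1e-9)
  expect_lte(part$codelength, map_equation(net, rep(1, k)) + 1e-9)
})

test_that("disconnected components form separate modules", {
  g <- rbind(data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"),
                        mi = 1),
             data.frame(from = c("p", "p", "q"), to = c("q", "r", "r"),
                        mi = 1))
  net <- build_network(g)
  part <- detect_modules(net, restarts = 5, seed = 2)
  expect_equal(part$n_modules, 2)
  comp <- igraph::components(net)$membership
  expect_true(all(tapply(part$membership[igraph::V(net)$name],
                         comp, function(v) length(unique(v))) == 1))
})

test_that("edge strength classes follow mid-rank percentiles with shared
           ranks for ties", {
  net5 <- build_network(data.frame(from = letters[1:5], to = letters[2:6],
                                   mi = c(0.1, 0.2, 0.3, 0.4, 0.5)))
  cl5 <- classify_edge_strength(net5)
  expect_equal(sum(cl5$class == "top20"), 1)
  expect_equal(cl5$class[cl5$mi == 0.5], "top20")

  net_tie <- build_network(data.frame(from = letters[1:4], to = letters[2:5],
                                      mi = rep(0.3, 4)))
  cl_tie <- classify_edge_strength(net_tie)
  expect_true(all(cl_tie$percentile == 0.5))
  expect_true(all(cl_tie$class == "p40_60"))

  net10 <- build_network(data.frame(from = paste0("n", 1:10),
                                    to = paste0("n", 2:11),
                                    mi = (1:10) / 10))
  cl10 <- classify_edge_strength(net10)
  expect_setequal(cl10$mi[cl10$class == "top20"], c(0.9, 1.0))
})
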