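mim_from_values <- function(values, mode = "bipartite", h = 0.2, n = 78L) {
  structure(list(values = values, mode = mode, h = h, n_observations = n,
                 deletion = "listwise", dataset_label = "demo"),
            class = "mi_matrix")
}

test_that("reconstruct keeps exactly the entries above the threshold", {
  v <- matrix(c(0.3, 0.1), 1, 2, dimnames = list("p1", c("c1", "c2")))
  net <- reconstruct(mim_from_values(v), 0.2)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 0.3)
  expect_identical(net$edges$source, "p1")
  expect_identical(net$edges$target, "c1")
  # all nodes retained; disconnected ones get provenance "none"
  expect_setequal(net$nodes$name, c("p1", "c1", "c2"))
  expect_identical(net$nodes$provenance[net$nodes$name == "c2"], "none")
  # strict inequality: a tie at the threshold is discarded
  tie <- reconstruct(mim_from_values(v), 0.3)
  expect_equal(nrow(tie$edges), 0)
  # threshold above the maximum gives an edgeless network
  empty <- reconstruct(mim_from_values(v), 0.5)
  expect_equal(nrow(empty$edges), 0)
  expect_equal(nrow(empty$nodes), 3)
})

test_that("edge count is non-increasing in the threshold", {
  gp <- small_planted(seed = 5, n = 150)
  mim <- compute_mim(gp$data, "bipartite", 0.3)
  counts <- sapply(seq(0.01, 0.5, by = 0.01),
                   function(t) nrow(reconstruct(mim, t)$edges))
  expect_true(all(diff(counts) <= 0))
})

test_that("full-mode reconstruction types and flags edges by role", {
  gp <- small_planted(seed = 6, n = 200)
  mim <- compute_mim(gp$data, "full", 0.3)
  net <- reconstruct(mim, 0.05, roles = gp$data$roles)
  expect_true(all(net$edges$edge_type %in%
                    c("input-input", "input-output", "output-output")))
  # no self edges, no duplicate unordered pairs
  expect_false(any(net$edges$source == net$edges$target))
  key <- paste(pmin(net$edges$source, net$edges$target),
               pmax(net$edges$source, net$edges$target))
  expect_false(anyDuplicated(key) > 0)
  # default ranking is input-centric
  if (any(net$edges$edge_type == "output-output"))
    expect_false(any(rank_edges(net)$edge_type == "output-output"))
})

test_that("combining networks unions edges and tracks provenance", {
  vA <- matrix(c(0.4, 0.3, 0.0, 0.0), 2, 2,
               dimnames = list(c("p1", "p2"), c("c1", "c2")))
  vB <- matrix(c(0.4, 0.0, 0.0, 0.5), 2, 2,
               dimnames = list(c("p1", "p2"), c("c1", "c2")))
  netA <- reconstruct(mim_from_values(vA), 0.2, dataset_label = "Toll")
  netB <- reconstruct(mim_from_values(vB), 0.2, dataset_label = "nonToll")
  comb <- combine_networks(netA, netB, c("Toll", "nonToll"))
  expect_equal(nrow(comb$edges), 3)  # p1-c1 shared, p2-c1 A only, p2-c2 B only
  shared <- comb$edges[comb$edges$source == "p1", ]
  expect_identical(shared$provenance, "both")
  expect_equal(shared$weight_Toll, 0.4)
  expect_equal(shared$weight_nonToll, 0.4)
  provs <- setNames(comb$nodes$provenance, comb$nodes$name)
  expect_identical(provs[["p1"]], "both")
  expect_identical(provs[["p2"]], "both")  # edges in both datasets
  expect_identical(provs[["c2"]], "nonToll")
})

test_that("combine is idempotent and commutative up to label swap", {
  gp <- small_planted(seed = 7, n = 150)
  mim <- compute_mim(gp$data, "bipartite", 0.3)
  net <- reconstruct(mim, 0.05, dataset_label = "d1")
  self <- combine_networks(net, net, c("d1", "d1b"))
  expect_equal(nrow(self$edges), nrow(net$edges))
  expect_true(all(self$edges$provenance == "both"))
  expect_true(all(self$nodes$provenance[self$nodes$name %in%
                                          c(net$edges$source,
                                            net$edges$target)] == "both"))
  net2 <- reconstruct(mim, 0.12, dataset_label = "d2")
  ab <- combine_networks(net, net2, c("A", "B"))
  ba <- combine_networks(net2, net, c("B", "A"))
  key <- function(n) sort(paste(n$edges$source, n$edges$target))
  expect_identical(key(ab), key(ba))
})

test_that("combining networks with conflicting roles fails", {
  v <- matrix(0.4, 1, 1, dimnames = list("p1", "c1"))
  netA <- reconstruct(mim_from_values(v), 0.2)
  netB <- netA
  netB$nodes$role <- rev(netB$nodes$role)
  expect_error(combine_networks(netA, netB, c("A", "B")),
               "conflicting roles")
})

test_that("rank_edges sorts by weight with lexicographic tie-breaks", {
  v <- matrix(c(0.3, 0.5, 0.4, 0.4), 2, 2,
              dimnames = list(c("b", "a"), c("c1", "c2")))
  net <- reconstruct(mim_from_values(v), 0.2)
  rk <- rank_edges(net)
  expect_equal(rk$weight, c(0.5, 0.4, 0.4, 0.3))
  expect_identical(rk$source[2:3], c("a", "b"))  # tie broken by source
  expect_error(rank_edges(reconstruct(mim_from_values(v), 0.9)), "no edges")
})

test_that("node-by-node on single-output data equals joint reconstruction", {
  edges <- data.frame(input = 1:2, output = 1, link = "linear",
                      effect_size = 1)
  gp <- generate_planted(planted_network_spec(
    4, 1, 120, edges, noise_sd = 0.4, seed = 8))
  h <- 0.3
  nbn <- node_by_node(gp$data, output_name = "out1", h = h, p_value = 0.005,
                      n_permutations = 30, seed = 5)
  mim <- compute_mim(gp$data, "bipartite", h)
  cal <- calibrate_threshold(gp$data, "bipartite", h, 0.005, 30,
                             seed = kdenet:::stage_seed(5, "null") + 1)
  joint <- reconstruct(mim, cal$threshold)
  expect_equal(nbn$edges[c("source", "target", "weight")],
               joint$edges[c("source", "target", "weight")])
})

test_that("node-by-node union approximates the jointly thresholded network", {
  gp <- small_planted(seed = 12, n = 200)
  h <- 0.3
  nbn <- node_by_node(gp$data, h = h, n_permutations = 30, seed = 3)
  mim <- compute_mim(gp$data, "bipartite", h)
  cal <- calibrate_threshold(gp$data, "bipartite", h, 0.005, 30, seed = 3)
  joint <- reconstruct(mim, cal$threshold)
  key <- function(n) paste(n$edges$source, n$edges$target)
  sym_diff <- union(setdiff(key(nbn), key(joint)),
                    setdiff(key(joint), key(nbn)))
  # disagreements are confined to edges near the calibration threshold
  if (length(sym_diff)) {
    mis <- mim$values[do.call(rbind, strsplit(sym_diff, " "))]
    expect_true(all(abs(mis - cal$threshold) < 0.1))
  }
  expect_gt(length(intersect(key(nbn), key(joint))), 0)
})

test_that("edge lists and GraphML survive export and import", {
  gp <- small_planted(seed = 2, n = 150)
  mim <- compute_mim(gp$data, "bipartite", 0.3)
  net <- reconstruct(mim, 0.05)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, path)
  back <- read_edge_list(path)
  expect_equal(back$edges$weight, net$edges$weight, tolerance = 1e-12)
  expect_identical(back$edges$source, net$edges$source)
  expect_equal(back$metadata$threshold, 0.05, tolerance = 1e-12)
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), nrow(net$nodes))
  expect_equal(igraph::gsize(g), nrow(net$edges))
  expect_setequal(igraph::vertex_attr(g, "role"), unique(net$nodes$role))
})
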