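test_that("gaussian_pair is reproducible with the stated closed-form MI", {
  g1 <- gaussian_pair(0.8, 200, seed = 5)
  g2 <- gaussian_pair(0.8, 200, seed = 5)
  expect_identical(g1, g2)
  expect_equal(attr(g1, "true_mi"), -0.5 * log(1 - 0.64))
  expect_equal(attr(gaussian_pair(0, 10), "true_mi"), 0)
  expect_equal(attr(gaussian_pair(0.8, 10), "true_mi"), 0.510826,
               tolerance = 1e-6)
  expect_error(gaussian_pair(1, 10), "rho")
  expect_error(gaussian_pair(-1.2, 10), "rho")
})

test_that("gaussian_pair has unit-scale marginals and the right correlation", {
  gp <- gaussian_pair(0.6, 5000, seed = 2)
  expect_equal(cor(gp$x, gp$y), 0.6, tolerance = 0.03)
  expect_equal(sd(gp$x), 1, tolerance = 0.05)
  expect_equal(sd(gp$y), 1, tolerance = 0.05)
})

test_that("planted generation is seed-reproducible and marks the truth", {
  edges <- data.frame(input = c(1, 3), output = c(2, 1),
                      link = c("linear", "quadratic"), effect_size = 1)
  spec <- planted_network_spec(4, 2, 150, edges, noise_sd = 0.3, seed = 9)
  g1 <- generate_planted(spec)
  g2 <- generate_planted(spec)
  expect_identical(g1$data$values, g2$data$values)
  expect_equal(sum(g1$adjacency), 2)
  expect_true(g1$adjacency["in01", "out2"])
  expect_true(g1$adjacency["in03", "out1"])
  expect_identical(dim(g1$data$values), c(150L, 6L))
  expect_setequal(unique(g1$data$roles), c("input", "output"))
})

test_that("missing-row masking leaves the expected complete-row count", {
  spec <- planted_network_spec(5, 2, 100, edges = NULL, noise_sd = 1,
                               missing_row_fraction = 0.1, seed = 3)
  gp <- generate_planted(spec)
  n_complete <- sum(complete.cases(gp$data$values))
  expect_lte(n_complete, 90)
  expect_gte(n_complete, 85)  # a few masked rows may coincide
})

test_that("input correlation produces exchangeably correlated inputs", {
  spec <- planted_network_spec(6, 1, 2000, edges = NULL, noise_sd = 1,
                               input_correlation = 0.5, seed = 4)
  gp <- generate_planted(spec)
  cm <- cor(gp$data$values[, 1:6])
  off <- cm[upper.tri(cm)]
  expect_equal(mean(off), 0.5, tolerance = 0.05)
})

test_that("quadratic links decorrelate Pearson but not mutual information", {
  edges <- data.frame(input = 1, output = 1, link = "quadratic",
                      effect_size = 1)
  gp <- generate_planted(planted_network_spec(
    3, 1, 500, edges, noise_sd = 0.3, seed = 17))
  x <- scale(gp$data$values[, "in01"])[, 1]
  y <- scale(gp$data$values[, "out1"])[, 1]
  expect_lt(abs(cor(x, y)), 0.25)
  mi_link <- mutual_information(x, y, 0.25)
  z <- scale(gp$data$values[, "in02"])[, 1]  # no planted link
  expect_gt(mi_link, 5 * max(mutual_information(z, y, 0.25), 0.01))
})

test_that("recovery metrics are exact on hand-built networks", {
  truth <- matrix(FALSE, 2, 2, dimnames = list(c("i1", "i2"), c("o1", "o2")))
  truth["i1", "o1"] <- truth["i2", "o2"] <- TRUE
  make_net <- function(edf) {
    nodes <- data.frame(name = c("i1", "i2", "o1", "o2"),
                        role = c("input", "input", "output", "output"),
                        provenance = "d")
    edf$edge_type <- rep("input-output", nrow(edf))
    edf$provenance <- rep("d", nrow(edf))
    structure(list(nodes = nodes, edges = edf, mode = "bipartite",
                   metadata = list()), class = "mi_network")
  }
  exact <- make_net(data.frame(source = c("i1", "i2"),
                               target = c("o1", "o2"), weight = c(0.3, 0.2)))
  expect_equal(evaluate_recovery(truth, exact),
               c(precision = 1, recall = 1))
  half <- make_net(data.frame(source = "i1", target = "o1", weight = 0.3))
  expect_equal(evaluate_recovery(truth, half),
               c(precision = 1, recall = 0.5))
  wrong <- make_net(data.frame(source = c("i1", "i2"),
                               target = c("o2", "o1"), weight = c(0.3, 0.2)))
  expect_equal(evaluate_recovery(truth, wrong),
               c(precision = 0, recall = 0))
  none <- make_net(data.frame(source = character(), target = character(),
                              weight = numeric()))
  expect_true(is.na(evaluate_recovery(truth, none)[["precision"]]))
})

test_that("planted specs validate their edge lists", {
  expect_error(planted_network_spec(2, 2, 50, data.frame(
    input = 5, output = 1, link = "linear", effect_size = 1)),
    "unknown variables")
  expect_error(planted_network_spec(2, 2, 50, data.frame(
    input = 1, output = 1, link = "cubic", effect_size = 1)), "link")
  expect_error(sample_planted_edges(2, 2, 10), "more edges")
  e <- sample_planted_edges(5, 3, 8, seed = 2)
  expect_equal(nrow(e), 8)
  expect_false(anyDuplicated(e[c("input", "output")]) > 0)
})
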