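# Attribute generation, network simulation, expected edges, and the
# synthetic cemetery fixture.

test_that("attribute quotas are exact", {
  nt <- generate_attributes(300, list(sex = c("1" = 0.5, "2" = 0.5)),
                            seed = 1)
  expect_equal(unname(table(nt$sex)), c(150L, 150L), ignore_attr = TRUE)

  nt2 <- generate_attributes(300, list(sex = c("1" = 0.25, "2" = 0.75)),
                             seed = 1)
  expect_equal(as.integer(table(nt2$sex)), c(75L, 225L))

  nt3 <- generate_attributes(4, list(g = c(a = 0.5, b = 0.5, c = 0)),
                             seed = 1)
  expect_equal(as.integer(table(nt3$g)), c(2L, 2L, 0L))

  expect_error(generate_attributes(2, list(g = c(a = .4, b = .3, c = .3))),
               "smaller than")
  expect_error(generate_attributes(10, list(g = c(a = .5, b = .4))),
               "sum to 1")
})

test_that("simulation respects the dyad probabilities", {
  nodes <- generate_attributes(50, list(sex = c(F = .5, M = .5)), seed = 2)
  # essentially-zero intercept: empty graph
  net <- simulate_network(nodes, model_spec(term_edges()), -30, seed = 1)
  expect_equal(n_edges(net), 0)
  # determinism under the seed
  spec <- model_spec(term_nodematch("sex"))
  n1 <- simulate_network(nodes, spec, c(-2, .5), seed = 99)
  n2 <- simulate_network(nodes, spec, c(-2, .5), seed = 99)
  expect_identical(n1$edges, n2$edges)
  expect_error(simulate_network(nodes, spec, c(-2, .5, .1)), "length")
})

test_that("mean simulated edge count matches the exact expectation", {
  nodes <- generate_attributes(300, list(sex = c("1" = .5, "2" = .5)),
                               seed = 3)
  # intercept-only closed form
  expect_equal(expected_edges(nodes, model_spec(term_edges()), -4),
               choose(300, 2) * plogis(-4), tolerance = 1e-12)
  expect_equal(round(expected_edges(nodes, model_spec(term_edges()), -4), 1),
               806.7)

  # Monte-Carlo check for the match model
  spec <- model_spec(term_nodematch("sex"))
  theta <- c(-4, 0.5)
  mu <- expected_edges(nodes, spec, theta)
  counts <- vapply(1:200, function(r)
    n_edges(simulate_network(nodes, spec, theta, seed = 7000 + r)),
    numeric(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - mu), 3 * se)
})

test_that("expected edges covers every model in the default family", {
  nodes <- generate_attributes(120, default_family_attributes(), seed = 4)
  fam <- default_model_family()
  truths <- default_family_truth(fam, nodes, theta0 = -3)
  for (m in names(fam)) {
    mu <- expected_edges(nodes, fam[[m]], truths[[m]])
    counts <- vapply(1:200, function(r)
      n_edges(simulate_network(nodes, fam[[m]], truths[[m]],
                               seed = 11000 + r)), numeric(1))
    se <- sd(counts) / sqrt(length(counts))
    expect_lt(abs(mean(counts) - mu), 3 * se)
  }
})

test_that("degenerate node counts give zero expected edges", {
  spec <- model_spec(term_edges())
  nt1 <- node_table(data.frame(id = "a", sex = factor("F", c("F", "M"))))
  expect_equal(expected_edges(nt1, spec, -1), 0)
})

test_that("disjoint dyads are uncorrelated", {
  nodes <- generate_attributes(10, list(sex = c(F = .5, M = .5)), seed = 5)
  spec <- model_spec(term_nodematch("sex"))
  # indicators of dyads (1,2) and (3,4) across draws
  y12 <- y34 <- numeric(500)
  for (r in 1:500) {
    net <- simulate_network(nodes, spec, c(-1, .5), seed = 20000 + r)
    key <- paste(net$edges$i, net$edges$j)
    y12[r] <- ("1 2" %in% key) + 0
    y34[r] <- ("3 4" %in% key) + 0
  }
  expect_lt(abs(cor(y12, y34)), 0.05)
})

test_that("node-count inversion finds the smallest sufficient n", {
  spec <- model_spec(term_edges())
  sx <- list(sex = c(F = .5, M = .5))
  expect_equal(nodes_for_expected_edges(806, sx, spec, -4), 300)
  # single dyad at p = 0.5 expects 0.5 < 1; three nodes give 1.5
  expect_equal(nodes_for_expected_edges(1, sx, spec, 0), 3)
  # monotone in the target
  targets <- c(10, 50, 200, 1000)
  ns <- vapply(targets, nodes_for_expected_edges, integer(1),
               attribute_specs = sx, spec = spec, theta = -4)
  expect_true(all(diff(ns) >= 0))
  expect_error(nodes_for_expected_edges(10, sx, spec, -40, max_n = 1e4),
               "unreachable")
})

test_that("the cemetery fixture is reproducible and correctly shaped", {
  fx1 <- make_avar_fixture(seed = 11)
  fx2 <- make_avar_fixture(seed = 11)
  expect_identical(fx1$network$edges, fx2$network$edges)
  expect_identical(fx1$pairs, fx2$pairs)

  expect_equal(nrow(fx1$nodes), 237)
  expect_setequal(levels(fx1$nodes$site), c("HNJ", "KFJ", "KUP", "RK"))
  expect_setequal(levels(fx1$nodes$age), c("Adult", "Subadult"))

  # thresholding the bundled IBD summaries reproduces the simulated edges
  net <- threshold_network(fx1$pairs, fx1$nodes, fx1$rule)
  expect_equal(net$edges[, c("i", "j")], fx1$network$edges[, c("i", "j")])
})

test_that("a single fixture draw estimates near the generating values", {
  fx <- make_avar_fixture(seed = 23)
  fit <- fit_dyad_ergm(build_design(fx$network, fx$spec))
  expect_true(fit$converged)
  expect_false(any(fit$separated))
  zs <- (fit$coefficients - fx$theta) / fit$se
  expect_true(all(abs(zs) < 4.5))
})
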