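# Design-matrix construction for homophily and mixing terms.

test_that("nodematch indicator fires exactly on matching dyads", {
  nt <- make_nodes(sex = c("1", "1", "2"))
  net <- make_net(nt)
  d <- build_design(net, model_spec(term_nodematch("sex")))
  # dyads in order (1,2), (1,3), (2,3)
  expect_equal(unname(d$X[, "nodematch.sex"]), c(1, 0, 0))
  expect_equal(colnames(d$X), c("edges", "nodematch.sex"))
  expect_equal(length(d$y), 3)
})

test_that("differential nodematch gives one per-level indicator", {
  nt <- make_nodes(site = c("A", "A", "B", "B"))
  net <- make_net(nt)
  d <- build_design(net, model_spec(term_nodematch_diff("site")))
  X <- d$X
  # dyads: (1,2) (1,3) (2,3) (1,4) (2,4) (3,4)
  expect_equal(unname(X[, "nodematch_diff.site.A"]), c(1, 0, 0, 0, 0, 0))
  expect_equal(unname(X[, "nodematch_diff.site.B"]), c(0, 0, 0, 0, 0, 1))
})

test_that("parameter counts for the three homophily classes are 1 / 3 / 5", {
  nt <- make_nodes(site = c("A", "A", "B", "B", "C", "C"))
  expect_equal(n_parameters(model_spec(term_nodematch("site")), nt), 2)
  expect_equal(n_parameters(model_spec(term_nodematch_diff("site")), nt), 4)
  # 6 unordered cells minus the base cell, plus intercept
  expect_equal(n_parameters(model_spec(term_nodemix("site")), nt), 6)
  d <- build_design(make_net(nt), model_spec(term_nodemix("site")))
  expect_equal(sum(startsWith(colnames(d$X), "nodemix.")), 5)
  # default base cell is the lexicographically smallest pair (A,A)
  expect_false("nodemix.site.A.A" %in% colnames(d$X))
  d2 <- build_design(make_net(nt),
                     model_spec(term_nodemix("site", base_cell = c("B", "B"))))
  expect_true("nodemix.site.A.A" %in% colnames(d2$X))
  expect_false("nodemix.site.B.B" %in% colnames(d2$X))
})

test_that("nodematch column equals the sum of its nodematch_diff columns", {
  for (seed in 1:5) {
    set.seed(seed)
    nt <- make_nodes(site = sample(LETTERS[1:4], 20, TRUE))
    net <- make_net(nt)
    dm <- build_design(net, model_spec(term_nodematch("site")))
    dd <- build_design(net, model_spec(term_nodematch_diff("site")))
    diff_cols <- dd$X[, startsWith(colnames(dd$X), "nodematch_diff."),
                      drop = FALSE]
    expect_equal(unname(dm$X[, "nodematch.site"]),
                 unname(rowSums(diff_cols)))
  }
})

test_that("the differential-match model is nested in the mixing model", {
  set.seed(7)
  nt <- make_nodes(site = sample(c("A", "B", "C"), 40, TRUE))
  spec_diff <- model_spec(term_nodematch_diff("site"))
  truth <- c(-2, 0.6, 1.1, 1.6)
  for (seed in 1:3) {
    net <- simulate_network(nt, spec_diff, truth, seed = seed)
    f_diff <- fit_dyad_ergm(build_design(net, spec_diff))
    f_mix <- fit_dyad_ergm(build_design(net,
                                        model_spec(term_nodemix("site"))))
    expect_lte(f_mix$deviance, f_diff$deviance + 1e-8)
  }
})

test_that("relabelling nodes leaves fitted coefficients unchanged", {
  set.seed(12)
  nt <- make_nodes(sex = sample(c("F", "M"), 30, TRUE),
                   site = sample(c("A", "B"), 30, TRUE))
  spec <- model_spec(term_nodematch("sex"), term_nodematch("site"))
  net <- simulate_network(nt, spec, c(-1.5, 0.8, 0.5), seed = 3)
  fit <- fit_dyad_ergm(build_design(net, spec))

  perm <- sample(30)
  df <- as.data.frame(nt)[perm, ]
  nt2 <- node_table(df)
  old_pos <- match(nt2$id, nt$id)
  inv <- match(seq_len(30), old_pos)
  net2 <- kin_network(nt2, data.frame(i = inv[net$edges$i],
                                      j = inv[net$edges$j]))
  fit2 <- fit_dyad_ergm(build_design(net2, spec))
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-8)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-10)
})

test_that("missing attribute values error by default, drop on request", {
  df <- data.frame(id = c("a", "b", "c", "d"),
                   sex = c("F", NA, "M", "F"), stringsAsFactors = FALSE)
  nt <- node_table(df, levels = list(sex = c("F", "M")))
  net <- kin_network(nt, data.frame(i = c(1, 3), j = c(3, 4)))
  spec <- model_spec(term_nodematch("sex"))
  expect_error(build_design(net, spec), "b")
  d <- build_design(net, spec, on_missing = "drop")
  expect_equal(d$n_nodes, 3)
  expect_equal(d$dropped_nodes, 1)
  expect_equal(length(d$y), choose(3, 2))
  expect_equal(sum(d$y), 2) # both edges avoided the incomplete node
})

test_that("degenerate attributes and model specs are rejected", {
  nt <- make_nodes(sex = c("F", "F", "F"))
  expect_error(build_design(make_net(nt),
                            model_spec(term_nodematch("sex"))),
               "fewer than 2")
  expect_error(build_design(make_net(nt),
                            model_spec(term_nodematch("height"))),
               "height")
  expect_error(model_spec(term_nodematch("sex"), term_nodematch("sex")),
               "duplicated term")
  expect_error(model_spec(term_edges(), term_edges()), "exactly one edges")
})

test_that("composite attributes are formed by explicit concatenation", {
  nt <- make_nodes(sex = c("F", "M", "F"), age = c("Adult", "Adult", "Sub"))
  nt2 <- combine_attributes(nt, c("age", "sex"), "agesex")
  expect_equal(as.character(nt2$agesex), c("Adult.F", "Adult.M", "Sub.F"))
  expect_true(all(c("Adult.F", "Adult.M", "Sub.F", "Sub.M") %in%
                    levels(nt2$agesex)))
})

test_that("edge covariates enter as raw per-dyad values", {
  nt <- make_nodes(sex = c("F", "M", "F"))
  net <- make_net(nt, i = 1, j = 2)
  w <- c(1.5, 2.5, 3.5)
  d <- build_design(net, model_spec(term_edgecov("dist")),
                    edge_covariates = list(dist = w))
  expect_equal(unname(d$X[, "edgecov.dist"]), w)
  expect_error(build_design(net, model_spec(term_edgecov("dist"))),
               "dist")
})
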