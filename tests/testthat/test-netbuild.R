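# Network construction by IBD thresholding, and file IO.

test_that("two-block rule counts qualifying segments correctly", {
  nt <- make_nodes(sex = c("F", "M", "F"))
  rule <- two_block_rule(L1 = 12, k1 = 2, L2 = 16, k2 = 1)

  # two blocks >= 12 of which one >= 16: edge
  pr <- data.frame(id1 = c("v1", "v1"), id2 = c("v2", "v2"),
                   length_cM = c(13.0, 17.5))
  expect_equal(n_edges(threshold_network(pr, nt, rule)), 1)

  # a single 20 cM block: only one block >= 12, no edge
  pr <- data.frame(id1 = "v1", id2 = "v2", length_cM = 20.0)
  expect_equal(n_edges(threshold_network(pr, nt, rule)), 0)

  # brute force over the 2x2 combinations of (>=2 blocks @12, >=1 block @16)
  seg_sets <- list(
    both = c(13, 17),       # 2 @12, 1 @16 -> edge
    only12 = c(13, 14),     # 2 @12, 0 @16 -> no edge
    only16 = c(17),         # 1 @12, 1 @16 -> no edge
    neither = c(5)          # 0, 0        -> no edge
  )
  want <- c(both = 1L, only12 = 0L, only16 = 0L, neither = 0L)
  for (nm in names(seg_sets)) {
    pr <- data.frame(id1 = "v1", id2 = "v2", length_cM = seg_sets[[nm]])
    expect_equal(n_edges(threshold_network(pr, nt, rule)), want[[nm]],
                 info = nm)
  }
})

test_that("scalar rule boundary is inclusive and weights carry total cM", {
  nt <- make_nodes(sex = c("F", "M"))
  pr <- data.frame(id1 = "v1", id2 = "v2", total_cM = 20)
  net <- threshold_network(pr, nt, scalar_rule(20))
  expect_equal(n_edges(net), 1)
  expect_equal(net$edges$weight, 20)
  expect_equal(n_edges(threshold_network(pr, nt, scalar_rule(20.0001))), 0)
})

test_that("raising the scalar cutoff never adds edges", {
  set.seed(41)
  nt <- make_nodes(sex = sample(c("F", "M"), 12, TRUE))
  d <- combn(12, 2)
  pr <- data.frame(id1 = paste0("v", d[1, ]), id2 = paste0("v", d[2, ]),
                   total_cM = round(runif(ncol(d), 0, 50), 1))
  prev <- Inf
  for (cut in seq(0, 55, by = 5)) {
    m <- n_edges(threshold_network(pr, nt, scalar_rule(cut)))
    expect_lte(m, prev)
    prev <- m
  }
  expect_equal(prev, 0) # cutoff above max sharing leaves an empty graph
})

test_that("non-sharing pairs are zero, isolates are retained", {
  nt <- make_nodes(sex = c("F", "M", "F", "M", "F"))
  net <- threshold_network(data.frame(id1 = character(0), id2 = character(0),
                                      total_cM = numeric(0)),
                           nt, scalar_rule(10))
  expect_equal(n_nodes(net), 5)
  expect_equal(n_edges(net), 0)
})

test_that("unknown ids and duplicate pairs are hard errors", {
  nt <- make_nodes(sex = c("F", "M"))
  expect_error(
    threshold_network(data.frame(id1 = "v1", id2 = "zz", total_cM = 30),
                      nt, scalar_rule(10)),
    "zz")
  dup <- data.frame(id1 = c("v1", "v2"), id2 = c("v2", "v1"),
                    total_cM = c(30, 40))
  expect_error(threshold_network(dup, nt, scalar_rule(10)), "duplicated")
  expect_error(
    threshold_network(data.frame(id1 = "v1", id2 = "v1", total_cM = 3),
                      nt, scalar_rule(1)),
    "self")
})

test_that("rule constructors validate their parameters", {
  expect_error(two_block_rule(L1 = 16, k1 = 2, L2 = 12, k2 = 1), "L2 >= L1")
  expect_error(two_block_rule(k1 = 1, k2 = 2), "k1 >= k2")
  expect_error(scalar_rule(Inf))
})

test_that("networks round-trip through GraphML and edge-list CSV", {
  nt <- make_nodes(sex = c("F", "M", "F"), site = c("A", "A", "B"))
  net <- make_net(nt, i = c(1, 2), j = c(2, 3), weight = c(25.5, 31))

  gpath <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, gpath, format = "graphml")
  back <- read_network(gpath, format = "graphml")
  expect_equal(back$nodes$id, net$nodes$id)
  expect_equal(as.character(back$nodes$sex), as.character(net$nodes$sex))
  expect_equal(levels(back$nodes$sex), c("F", "M"))
  expect_equal(back$edges[, c("i", "j")], net$edges[, c("i", "j")])
  expect_equal(back$edges$weight, net$edges$weight)

  cpath <- withr::local_tempfile(fileext = ".csv")
  write_network(net, cpath, format = "edgelist")
  back2 <- read_network(cpath, format = "edgelist")
  expect_equal(back2$nodes$id, net$nodes$id)
  expect_equal(back2$edges, net$edges)
})

test_that("malformed CSV input is reported with line numbers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id1,id2,total_cM", "a,b,20", "a,c,not_a_number"), path)
  expect_error(read_ibd_pairs(path), "line\\(s\\) 3")

  npath <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,sex", "a,F", "a,M"), npath)
  expect_error(read_nodes(npath), "duplicated node id")
})

test_that("node tables validate structure", {
  expect_error(node_table(data.frame(sex = "F")), "'id' column")
  nt <- node_table(data.frame(id = c("a", "b"), sex = c("F", "M")),
                   levels = list(sex = c("F", "M", "U")))
  expect_equal(levels(nt$sex), c("F", "M", "U"))
  expect_error(node_table(data.frame(id = "a", sex = "X"),
                          levels = list(sex = c("F", "M"))),
               "outside its declared levels")
})
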