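test_that("pruning keeps only links above the out-volume share threshold", {
  net <- build_network(rec(
    origin = "a", destination = c("b", "c", "d"), head = c(80, 15, 5)
  ))
  pruned <- prune_minor_links(net)
  expect_equal(nrow(pruned$links), 1)
  expect_equal(pruned$links$destination, "b")
  expect_setequal(pruned$nodes, c("a", "b"))

  # a single out-link has share 1 and is never pruned
  single <- build_network(rec(origin = c("a", "b"), destination = c("b", "c"),
    head = c(1, 1)))
  expect_equal(nrow(prune_minor_links(single)$links), 2)

  # exact 20% shares fail the strict inequality and are all pruned
  eq <- build_network(rec(
    origin = "a", destination = c("b", "c", "d", "e", "f"), head = 20
  ))
  expect_equal(nrow(prune_minor_links(eq, 0.2)$links), 0)

  expect_error(prune_minor_links(net, 0), "threshold")
  expect_error(prune_minor_links(net, 1), "threshold")
})

test_that("the worked toy decomposition is recovered exactly", {
  # flows a->m:100, b->m:80, m->c:30, c->a:5
  net <- build_network(rec(
    origin = c("a", "b", "m", "c"),
    destination = c("m", "m", "c", "a"),
    head = c(100, 80, 30, 5)
  ))
  forest <- nodal_regions(net)
  expect_equal(forest$dominant_nodes, "m")
  expect_setequal(forest$assignments$node, c("a", "b"))
  expect_equal(unique(forest$assignments$parent), "m")
  expect_equal(forest$regions[["m"]], c("a", "b"))
  expect_equal(nrow(forest$retained_links), 2)
  expect_equal(forest$coverage$volume_fraction, 180 / 215)
  expect_equal(forest$coverage$n_links, 2)

  # inward star: hub dominant, all spokes assigned
  star <- build_network(rec(
    origin = c("s1", "s2", "s3", "s4", "s5"), destination = "hub", head = 10
  ))
  f2 <- nodal_regions(star)
  expect_equal(f2$dominant_nodes, "hub")
  expect_setequal(f2$assignments$node, paste0("s", 1:5))
  expect_equal(f2$coverage$volume_fraction, 1.0)

  # no links at all
  f3 <- nodal_regions(build_network(rec("a", "b")[0, ]))
  expect_equal(length(f3$dominant_nodes), 0)
  expect_equal(nrow(f3$retained_links), 0)
  expect_equal(f3$coverage$volume_fraction, 0)
})

test_that("a flow tree oriented toward a sink has the sink as unique dominant node", {
  # binary tree, volumes grow toward the root so in-volumes increase
  tbl <- rec(
    origin = c("l1", "l2", "l3", "l4", "m1", "m2"),
    destination = c("m1", "m1", "m2", "m2", "root", "root"),
    head = c(10, 12, 11, 13, 40, 44)
  )
  forest <- nodal_regions(build_network(tbl))
  expect_equal(forest$dominant_nodes, "root")
  expect_setequal(forest$assignments$node, c("l1", "l2", "l3", "l4", "m1", "m2"))
})

test_that("assignments form a forest and match brute force on random digraphs", {
  for (seed in 1:120) {
    m <- random_digraph_matrix(seed)
    if (all(m == 0)) next
    net <- build_network(table_from_matrix(m))
    keep <- rownames(m) %in% net$nodes
    m2 <- m[keep, keep, drop = FALSE]
    forest <- nodal_regions(net)
    oracle <- bf_nodal_regions(m2)

    asg <- as.data.frame(forest$assignments)
    asg <- asg[order(asg$node), ]
    rownames(asg) <- NULL
    rownames(oracle$assignments) <- NULL
    expect_equal(asg, oracle$assignments)
    expect_equal(forest$dominant_nodes, oracle$dominant_nodes)

    # forest property: out-degree <= 1 and no cycles
    expect_false(any(duplicated(forest$assignments$node)))
    parent <- stats::setNames(
      forest$assignments$parent, forest$assignments$node
    )
    for (start in names(parent)) {
      seen <- character(0)
      node <- start
      while (node %in% names(parent)) {
        expect_false(node %in% seen)
        seen <- c(seen, node)
        node <- parent[[node]]
      }
    }
  }
})

test_that("reduction stats validate forest/network consistency", {
  net <- build_network(rec(
    origin = c("a", "b"), destination = c("m", "m"), head = c(10, 20)
  ))
  forest <- nodal_regions(net)
  other <- build_network(rec("x", "y", head = 5))
  expect_error(reduction_stats(forest, other), "not present")
})
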