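test_that("worked voting example places the taxon on the central edge", {
  ex <- voting_example_tree()
  out <- voting_example_outcomes(ex)
  sel <- tally_and_select(ex$tree, out)
  expect_equal(sort(sel$edge), sort(unname(ex$nodes[c("u", "v")])))
  expect_equal(sel$votes, 3)
  expect_false(sel$tie)
  # and the printed vote sets match brute-force counting
  bf <- brute_force_votes(ex$tree, out)
  labs <- ex$tree$label
  key_of <- function(x, y) {
    ids <- vapply(c(x, y), function(z) {
      if (z %in% names(ex$nodes)) unname(ex$nodes[z]) else which(labs == z)
    }, 0L)
    inctree:::edge_key(ids[1], ids[2])
  }
  expect_equal(unname(bf[key_of("u", "v")]), 3L)
  expect_equal(unname(bf[key_of("p", "u")]), 2L)
  expect_equal(unname(bf[key_of("u", "c")]), 2L)
  expect_equal(unname(bf[key_of("q", "e")]), 2L)
  expect_equal(unname(bf[key_of("p", "a")]), 1L)
})

test_that("differential tally equals brute-force counting", {
  for (seed in 1:40) {
    t <- random_topology(5 + seed %% 16, seed)
    out <- random_outcomes(t, seed + 1000)
    scores <- tally_votes(t, out)
    bf <- brute_force_votes(t, out)
    got <- stats::setNames(scores$votes,
                           inctree:::edge_key(scores$a, scores$b))
    expect_equal(got[names(bf)], bf, ignore_attr = TRUE,
                 info = paste("seed", seed))
  }
})

test_that("all-abstain tally ties every edge and breaks it with the seed", {
  t <- random_topology(8, 4)
  out <- rep(NA_integer_, length(t$adj))
  pick1 <- withr::with_seed(99, select_edge(tally_votes(t, out)))
  pick2 <- withr::with_seed(99, select_edge(tally_votes(t, out)))
  expect_true(pick1$tie)
  expect_equal(pick1$n_max, nrow(inctree:::tree_edge_matrix(t)))
  expect_identical(pick1$edge, pick2$edge)
})

test_that("inserting into each edge of a quartet gives 5 distinct topologies", {
  q <- parse_newick("((a,b),(c,d));")
  em <- inctree:::tree_edge_matrix(q)
  expect_equal(nrow(em), 5L)
  tops <- vapply(seq_len(nrow(em)), function(r) {
    topology_id(insert_leaf_structural(q, "e", em[r, ]))
  }, "")
  expect_equal(length(unique(tops)), 5L)
})

test_that("trivial sizes return the unique topology", {
  d1 <- matrix(0, 1, 1, dimnames = list("a", "a"))
  expect_equal(tree_leaves(inc_build(d1)), "a")
  d3 <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  t3 <- inc_build(d3)
  expect_equal(tree_leaves(t3), c("a", "b", "c"))
  expect_equal(sum(is.na(t3$label)), 1L)
})

test_that("additive matrices are reconstructed exactly", {
  for (seed in 1:10) {
    inst <- make_instance(10 + 5 * (seed %% 4), 0.05, 0.3, seed)
    t <- inc_build(inst$D, inc_config(seed = seed))
    expect_equal(rf_distance(t, inst$mod$tree), 0L, info = paste("seed", seed))
  }
})

test_that("bounded perturbations below half the shortest edge are harmless", {
  for (seed in 1:10) {
    inst <- make_instance(15, 0.05, 0.3, seed)
    d <- perturb_distances(inst$D, 0.05 / 2 - 1e-6, seed = seed + 40)
    t <- inc_build(d, inc_config(seed = seed))
    expect_equal(rf_distance(t, inst$mod$tree), 0L, info = paste("seed", seed))
  }
})

test_that("runs are deterministic and instrumented", {
  inst <- make_instance(20, 0.05, 0.3, 17)
  d <- perturb_distances(inst$D, 0.02, seed = 5)
  t1 <- inc_build(d, inc_config(seed = 123))
  t2 <- inc_build(d, inc_config(seed = 123))
  expect_identical(write_newick(t1), write_newick(t2))
  st <- attr(t1, "inc_stats")
  expect_equal(st$q, 8 * st$q0)
  # each insertion queries every internal node exactly once: a tree with
  # m leaves has m - 2 internal nodes
  expect_equal(st$queries, seq_len(20 - 3))
  expect_equal(st$fallbacks, 0L)
})

test_that("zero-valid-query fallback widens the radius and still builds", {
  inst <- make_instance(8, 0.05, 0.3, 31)
  cfg <- inc_config(q = 1e-9, seed = 1) # radius far below any diameter
  expect_message(t <- inc_build(inst$D, cfg), "widened")
  expect_setequal(tree_leaves(t), rownames(inst$D))
  expect_gt(attr(t, "inc_stats")$fallbacks, 0L)
})

test_that("an explicit q override bypasses the q0 multiplier", {
  inst <- make_instance(10, 0.05, 0.3, 9)
  t <- inc_build(inst$D, inc_config(q = 50, seed = 1))
  expect_equal(attr(t, "inc_stats")$q, 50)
  expect_equal(rf_distance(t, inst$mod$tree), 0L)
})

test_that("constrained build honors, and reduces without, constraints", {
  inst <- make_instance(20, 0.05, 0.3, 3)
  lv <- tree_leaves(inst$mod$tree)
  # the full true topology as the single constraint forces itself
  t <- constrained_inc_build(inst$D, list(inst$mod$tree),
                             inc_config(seed = 2))
  expect_equal(rf_distance(t, inst$mod$tree), 0L)
  # empty constraint set: identical to the unconstrained run
  t0 <- constrained_inc_build(inst$D, list(), inc_config(seed = 7))
  expect_identical(write_newick(t0),
                   write_newick(inc_build(inst$D, inc_config(seed = 7))))
})

test_that("two disjoint correct subtrees are preserved and recovery holds", {
  for (seed in 1:5) {
    inst <- make_instance(40, 0.05, 0.3, seed + 60)
    lv <- tree_leaves(inst$mod$tree)
    grp <- withr::with_seed(seed, sample(lv, 36))
    c1 <- as_inc_tree(induce_topology(inst$mod$tree, grp[1:18]))
    c2 <- as_inc_tree(induce_topology(inst$mod$tree, grp[19:36]))
    d <- perturb_distances(inst$D, 0.02, seed = seed)
    t <- constrained_inc_build(d, list(c1, c2), inc_config(seed = seed))
    expect_equal(rf_distance(t, inst$mod$tree), 0L)
    for (tc in list(c1, c2)) {
      expect_equal(rf_distance(as_inc_tree(induce_topology(t, tree_leaves(tc))),
                               tc), 0L)
    }
  }
})

test_that("overlapping or unknown constraint leaves are rejected", {
  inst <- make_instance(10, 0.05, 0.3, 2)
  lv <- tree_leaves(inst$mod$tree)
  c1 <- as_inc_tree(induce_topology(inst$mod$tree, lv[1:5]))
  c2 <- as_inc_tree(induce_topology(inst$mod$tree, lv[4:8]))
  expect_error(constrained_inc_build(inst$D, list(c1, c2)),
               class = "inc_validation_error")
  c3 <- three_leaf_tree(c("zz1", "zz2", "zz3"))
  expect_error(constrained_inc_build(inst$D, list(c3)),
               class = "inc_validation_error")
})
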