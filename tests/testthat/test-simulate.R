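test_that("random model trees respect the weight class bounds", {
  mod <- random_model_tree(3, 0.1, 0.1, seed = 1)
  expect_equal(sum(is.na(mod$tree$label)), 1L)
  expect_equal(unname(mod$w), rep(0.1, 3))
  expect_equal(unname(mod$p), rep((1 - exp(-0.2)) / 2, 3), tolerance = 1e-12)
  expect_equal(unname(mod$p)[1], 0.0906, tolerance = 1e-3)

  mod2 <- random_model_tree(20, 0.05, 0.3, seed = 2)
  expect_true(all(mod2$w >= 0.05 & mod2$w <= 0.3))
  # w and p mutually consistent
  expect_equal(mod2$w, -0.5 * log(1 - 2 * mod2$p), tolerance = 1e-12)
  expect_error(random_model_tree(2, 0.05, 0.3), class = "inc_validation_error")
  expect_error(random_model_tree(5, 0.3, 0.05), class = "inc_validation_error")
})

test_that("five-leaf topologies are sampled uniformly", {
  draws <- 15000
  # sub-seeds come from one stream: reseeding with consecutive integers
  # biases the first categorical draw of the twister
  seeds <- withr::with_seed(42, sample.int(1e9, draws))
  ids <- vapply(seeds, function(i) {
    topology_id(random_model_tree(5, 0.1, 0.1, seed = i)$tree)
  }, "")
  tab <- table(ids)
  expect_equal(length(tab), 15L)
  expected <- draws / 15
  sigma <- sqrt(draws * (1 / 15) * (14 / 15))
  expect_true(all(abs(tab - expected) < 3 * sigma))
})

test_that("CFN evolution matches its expected mismatch fractions", {
  # near-zero weights: no change anywhere
  frozen <- random_model_tree(6, 1e-9, 1e-9, seed = 3)
  aln0 <- evolve_cfn(frozen, 200, seed = 4)
  expect_equal(length(unique(apply(aln0, 1, paste, collapse = ""))), 1L)

  # determinism
  mod <- random_model_tree(4, 0.05, 0.3, seed = 5)
  expect_identical(evolve_cfn(mod, 500, seed = 6), evolve_cfn(mod, 500, seed = 6))
  expect_false(identical(evolve_cfn(mod, 500, seed = 6),
                         evolve_cfn(mod, 500, seed = 7)))

  # H_ij concentrates on E_ij = (1 - exp(-2 D_ij)) / 2
  k <- 1e5
  aln <- evolve_cfn(mod, k, seed = 8)
  D <- additive_matrix(mod)
  X <- matrix(as.numeric(aln == "1"), nrow = nrow(aln),
              dimnames = list(rownames(aln), NULL))
  H <- (X %*% t(1 - X) + (1 - X) %*% t(X)) / k
  E <- (1 - exp(-2 * D)) / 2
  taxa <- rownames(D)
  for (i in 1:3) for (j in (i + 1):4) {
    se <- sqrt(E[i, j] * (1 - E[i, j]) / k)
    expect_lt(abs(H[taxa[i], taxa[j]] - E[i, j]), 3 * se + 1e-9)
  }
})

test_that("empirical CFN distances converge to the additive matrix", {
  mod <- random_model_tree(8, 0.05, 0.15, seed = 9)
  D <- additive_matrix(mod)
  errs <- vapply(c(1e3, 1e4, 1e5), function(k) {
    d <- cfn_distance_matrix(evolve_cfn(mod, k, seed = 10))
    max(abs(d - D))
  }, 0)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 5 * errs[1])
})

test_that("GTR models are exactly calibrated through the determinant identity", {
  gm <- random_gtr_model(8, 0.05, 0.2, m = 4, seed = 11)
  expect_true(all(gm$w >= 0.05 & gm$w <= 0.2))
  trQ <- sum(diag(gm$Q))
  for (k in names(gm$M)) {
    expect_equal(rowSums(gm$M[[k]]), rep(1, 4), tolerance = 1e-10)
    # det(expm(tau Q)) = exp(tau trace(Q)), no numerical search involved
    expect_equal(-log(det(gm$M[[k]])), unname(-gm$tau[[k]] * trQ),
                 tolerance = 1e-8)
    expect_equal(unname(gm$w[k]), unname(-gm$tau[[k]] * trQ), tolerance = 1e-12)
  }
  # detailed balance of the sampled generator
  expect_lt(max(abs(gm$pi * gm$Q - t(gm$pi * gm$Q))), 1e-10)
  badQ <- matrix(c(-1, 1, 2, -2), 2, 2, byrow = TRUE)
  expect_error(gtr_model(random_model_tree(3, .1, .1, seed = 1)$tree, badQ,
                         c(0.5, 0.5), stats::setNames(rep(1, 3),
                           inctree:::edge_key(1L, 2:4))),
               class = "inc_validation_error")
})

test_that("the two-state GTR special case reproduces CFN behavior", {
  mod <- random_model_tree(4, 0.08, 0.2, seed = 12)
  Q <- matrix(c(-0.5, 0.5, 0.5, -0.5), 2, 2)
  # -log det expm(tau Q) = tau while a CFN edge of weight w has
  # -log det = 2w, so tau_e = 2 w_e reproduces the same edge process
  gm <- gtr_model(mod$tree, Q, c(0.5, 0.5), tau = 2 * mod$w)
  expect_equal(unname(gm$w), unname(2 * mod$w), tolerance = 1e-12)
  k <- 1e5
  ag <- evolve_gtr(gm, k, seed = 13)
  ac <- evolve_cfn(mod, k, seed = 14)
  D <- additive_matrix(mod)
  E <- (1 - exp(-2 * D)) / 2
  mismatch <- function(a, i, j) mean(a[i, ] != a[j, ])
  taxa <- rownames(D)
  for (i in 1:3) for (j in (i + 1):4) {
    se <- sqrt(E[i, j] * (1 - E[i, j]) / k)
    expect_lt(abs(mismatch(ag, taxa[i], taxa[j]) - E[i, j]), 4 * se)
    expect_lt(abs(mismatch(ac, taxa[i], taxa[j]) - E[i, j]), 4 * se)
  }
})

test_that("GTR site frequencies are stationary at the leaves", {
  gm <- random_gtr_model(5, 0.05, 0.15, m = 4, seed = 15)
  k <- 1e5
  aln <- evolve_gtr(gm, k, seed = 16)
  for (leaf in rownames(aln)) {
    freq <- table(factor(aln[leaf, ], levels = gm$states)) / k
    for (s in 1:4) {
      se <- sqrt(gm$pi[s] * (1 - gm$pi[s]) / k)
      expect_lt(abs(freq[s] - gm$pi[s]), 4 * se)
    }
  }
})

test_that("log-det distances on GTR data satisfy the four point condition", {
  # additivity holds only up to a constant shift, which the four point
  # comparison cancels; check quartets against the generating topology
  gm <- random_gtr_model(8, 0.05, 0.15, m = 4, seed = 17)
  aln <- evolve_gtr(gm, 5e4, seed = 18)
  d <- logdet_distance_matrix(aln)
  wrong <- 0L
  combos <- utils::combn(rownames(d), 4, simplify = FALSE)
  for (s in combos) {
    qt <- four_point_method(d, s)
    if (quartet_key(qt) != induced_quartet(gm$tree, s)) wrong <- wrong + 1L
  }
  expect_lte(wrong, 1L) # allow one sampling-noise miss out of 70 quartets
})

test_that("bounded perturbations stay within their envelope", {
  inst <- make_instance(10, 0.05, 0.3, 19)
  d <- perturb_distances(inst$D, 0.02, seed = 20)
  expect_true(all(abs(d - inst$D)[upper.tri(d)] < 0.02))
  expect_equal(diag(d), diag(inst$D))
  expect_identical(d, perturb_distances(inst$D, 0.02, seed = 20))
})
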