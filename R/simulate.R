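#' Random two-state (CFN) model trees
#'
#' Samples a uniform random binary topology by sequential attachment of
#' each taxon to a uniformly chosen edge, then draws edge weights
#' `w(e) ~ Uniform[f, g]` i.i.d. and sets the per-edge substitution
#' probability `p(e) = (1 - exp(-2 w(e))) / 2`, so every tree lies in the
#' model class with edge weights bounded between `f` and `g`.
#'
#' @param n number of leaves (>= 3).
#' @param f,g lower/upper edge-weight bounds, `0 < f <= g` (units: expected
#'   substitutions per site).
#' @param seed integer seed.
#' @param labels optional taxon labels (default zero-padded `t01`, ...).
#' @return Object of class `cfn_model`: list with `tree` (an `inc_tree`
#'   whose `brlen` carry the weights), `w`, `p` (named by edge key), `f`,
#'   `g`.
#' @export
random_model_tree <- function(n, f, g, seed = 1L, labels = NULL) {
  if (n < 3L) stop_validation("need at least 3 leaves")
  if (!(f > 0 && f <= g)) stop_validation("need 0 < f <= g")
  if (is.null(labels))
    labels <- sprintf("t%0*d", max(2L, nchar(n)), seq_len(n))
  if (length(labels) != n || anyDuplicated(labels))
    stop_validation("labels must be ", n, " distinct strings")
  withr::with_seed(as.integer(seed), {
    t <- three_leaf_tree(labels[1:3])
    if (n > 3L) {
      for (i in 4:n) {
        em <- tree_edge_matrix(t)
        t <- insert_leaf_structural(t, labels[i], em[sample.int(nrow(em), 1L), ])
      }
    }
    em <- tree_edge_matrix(t)
    w <- stats::runif(nrow(em), f, g)
  })
  names(w) <- edge_key(em[, 1L], em[, 2L])
  t$brlen <- w
  structure(list(tree = t, w = w, p = (1 - exp(-2 * w)) / 2, f = f, g = g),
            class = "cfn_model")
}

#' Evolve binary sequences along a CFN model tree
#'
#' Sites evolve i.i.d.: the state at the (arbitrarily chosen) root is 0 or
#' 1 with equal probability and flips along each edge independently with
#' that edge's substitution probability.  The traversal order is fixed, so
#' a seed fully determines the alignment.
#'
#' @param model a `cfn_model`.
#' @param k number of sites (>= 1).
#' @param seed integer seed.
#' @return Character matrix over `{"0","1"}` with taxon rownames and
#'   `states` attribute.
#' @export
evolve_cfn <- function(model, k, seed = 1L) {
  if (k < 1L) stop_validation("k must be at least 1")
  t <- model$tree
  N <- length(t$adj)
  root <- internal_node_ids(t)[1L]
  states <- matrix(NA_integer_, N, k)
  withr::with_seed(as.integer(seed), {
    states[root, ] <- stats::rbinom(k, 1L, 0.5)
    queue <- root
    seen <- logical(N)
    seen[root] <- TRUE
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (u in t$adj[[v]]) {
        if (!seen[u]) {
          seen[u] <- TRUE
          pe <- model$p[[edge_key(v, u)]]
          states[u, ] <- (states[v, ] + stats::rbinom(k, 1L, pe)) %% 2L
          queue <- c(queue, u)
        }
      }
    }
  })
  lids <- leaf_node_ids(t)
  out <- matrix(as.character(states[lids, , drop = FALSE]),
                nrow = length(lids),
                dimnames = list(t$label[lids], NULL))
  attr(out, "states") <- c("0", "1")
  out
}

#' Construct a time-reversible Markov substitution model on a tree
#'
#' @param tree an `inc_tree`.
#' @param Q rate matrix with positive off-diagonal entries, zero row sums,
#'   satisfying detailed balance with respect to `pi`.
#' @param pi stationary distribution (positive, sums to 1).
#' @param tau named per-edge durations (by edge key), all positive.
#' @param states state labels.
#' @return Object of class `gtr_model`: adds per-edge transition matrices
#'   `M = expm(tau * Q)` and edge weights `w = -log det M` (so the additive
#'   matrix of the model is the path sum of log-det edge weights).
#' @export
gtr_model <- function(tree, Q, pi, tau, states = NULL) {
  m <- length(pi)
  if (!is.matrix(Q) || nrow(Q) != m || ncol(Q) != m)
    stop_validation("Q must be ", m, " x ", m)
  if (any(abs(rowSums(Q)) > 1e-10))
    stop_validation("Q rows must sum to zero")
  if (any(Q[upper.tri(Q) | lower.tri(Q)] <= 0))
    stop_validation("off-diagonal rates must be positive")
  if (abs(sum(pi) - 1) > 1e-10 || any(pi <= 0))
    stop_validation("pi must be a positive probability vector")
  db <- pi * Q - t(pi * Q)
  if (max(abs(db)) > 1e-10)
    stop_validation("Q does not satisfy detailed balance with respect to pi")
  if (is.null(states))
    states <- if (m == 2L) c("0", "1")
              else if (m == 4L) c("A", "C", "G", "T")
              else LETTERS[seq_len(m)]
  em <- tree_edge_matrix(tree)
  keys <- edge_key(em[, 1L], em[, 2L])
  if (!all(keys %in% names(tau)))
    stop_validation("tau must name every edge of the tree")
  if (any(tau <= 0)) stop_validation("edge durations must be positive")
  M <- lapply(keys, function(k) ape::matexpo(Q * tau[[k]]))
  names(M) <- keys
  # det(expm(tau * Q)) = exp(tau * trace(Q)), so each edge weight is exactly
  # -tau_e * trace(Q)
  w <- stats::setNames(-tau[keys] * sum(diag(Q)), keys)
  structure(list(tree = tree, Q = Q, pi = pi, tau = tau[keys], M = M, w = w,
                 m = m, states = states),
            class = "gtr_model")
}

#' Random general time-reversible model trees
#'
#' Topology and target edge weights are drawn as in [random_model_tree()].
#' The stationary distribution is sampled from a symmetric Dirichlet
#' (concentration 5), floored at 0.05 and renormalized; exchangeabilities
#' are Uniform(0.5, 2); and each edge duration is calibrated through the
#' exact identity `-log det expm(tau Q) = -tau * trace(Q)` so that every
#' edge's log-det weight lands exactly in `[f, g]` with no numerical
#' search.
#'
#' @inheritParams random_model_tree
#' @param m number of states (>= 2; 4 gives a DNA-like alphabet).
#' @return A `gtr_model`.
#' @export
random_gtr_model <- function(n, f, g, m = 4L, seed = 1L, labels = NULL) {
  if (m < 2L) stop_validation("need at least 2 states")
  if (n < 3L) stop_validation("need at least 3 leaves")
  if (!(f > 0 && f <= g)) stop_validation("need 0 < f <= g")
  if (is.null(labels))
    labels <- sprintf("t%0*d", max(2L, nchar(n)), seq_len(n))
  withr::with_seed(as.integer(seed), {
    t <- three_leaf_tree(labels[1:3])
    if (n > 3L) {
      for (i in 4:n) {
        em <- tree_edge_matrix(t)
        t <- insert_leaf_structural(t, labels[i], em[sample.int(nrow(em), 1L), ])
      }
    }
    em <- tree_edge_matrix(t)
    w <- stats::runif(nrow(em), f, g)
    pi <- stats::rgamma(m, shape = 5)
    pi <- pi / sum(pi)
    pi <- pmax(pi, 0.05)
    pi <- pi / sum(pi)
    rex <- stats::runif(m * (m - 1L) / 2L, 0.5, 2)
  })
  R <- matrix(0, m, m)
  R[lower.tri(R)] <- rex
  R <- R + t(R)
  Q <- R * rep(pi, each = m)
  diag(Q) <- -rowSums(Q)
  tau <- stats::setNames(w / (-sum(diag(Q))), edge_key(em[, 1L], em[, 2L]))
  t$brlen <- stats::setNames(w, names(tau))
  gtr_model(t, Q, pi, tau)
}

#' Evolve sequences along a GTR model tree
#'
#' The root state of each site is drawn from the stationary distribution
#' and propagated down the tree through each edge's transition matrix,
#' i.i.d. across sites; traversal order is fixed so the seed determines
#' the alignment.
#'
#' @param model a `gtr_model`.
#' @param k number of sites.
#' @param seed integer seed.
#' @return Character matrix over `model$states` with a `states` attribute.
#' @export
evolve_gtr <- function(model, k, seed = 1L) {
  if (k < 1L) stop_validation("k must be at least 1")
  t <- model$tree
  N <- length(t$adj)
  m <- model$m
  root <- internal_node_ids(t)[1L]
  states <- matrix(NA_integer_, N, k)
  withr::with_seed(as.integer(seed), {
    states[root, ] <- sample.int(m, k, replace = TRUE, prob = model$pi)
    queue <- root
    seen <- logical(N)
    seen[root] <- TRUE
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (u in t$adj[[v]]) {
        if (!seen[u]) {
          seen[u] <- TRUE
          M <- model$M[[edge_key(v, u)]]
          child <- integer(k)
          for (s in seq_len(m)) {
            idx <- which(states[v, ] == s)
            if (length(idx))
              child[idx] <- sample.int(m, length(idx), replace = TRUE,
                                       prob = M[s, ])
          }
          states[u, ] <- child
          queue <- c(queue, u)
        }
      }
    }
  })
  lids <- leaf_node_ids(t)
  out <- matrix(model$states[states[lids, , drop = FALSE]],
                nrow = length(lids),
                dimnames = list(t$label[lids], NULL))
  attr(out, "states") <- model$states
  out
}

#' Symmetric bounded perturbation of a distance matrix
#'
#' Adds i.i.d. uniform noise in `(-eps, eps)` to every off-diagonal entry
#' (symmetrically), emulating estimation error of known magnitude; used to
#' probe the bounded-error recovery guarantees.
#'
#' @param D dissimilarity matrix.
#' @param eps noise half-width; recovery is guaranteed while `eps` stays
#'   below half the shortest internal edge weight.
#' @param seed integer seed.
#' @return Perturbed matrix (entries floored at 0).
#' @export
perturb_distances <- function(D, eps, seed = 1L) {
  validate_dissimilarity(D)
  n <- nrow(D)
  noise <- withr::with_seed(as.integer(seed),
                            stats::runif(n * (n - 1L) / 2L, -eps, eps))
  E <- matrix(0, n, n, dimnames = dimnames(D))
  E[upper.tri(E)] <- noise
  E <- E + t(E)
  pmax(D + E, 0)
}
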