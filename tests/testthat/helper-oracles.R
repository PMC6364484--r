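# Independent oracles used across the suite.  These deliberately avoid the
# code paths they check: vote counts are accumulated edge by edge from
# component membership, splits are enumerated by brute force, and external
# packages (phangorn, igraph, ape) provide cross-checks.

# Explicit per-edge vote counting: each non-abstaining query at internal
# node u votes for every edge with both endpoints in (chosen component + u).
brute_force_votes <- function(t, outcomes) {
  em <- inctree:::tree_edge_matrix(t)
  counts <- stats::setNames(rep(0L, nrow(em)),
                            inctree:::edge_key(em[, 1], em[, 2]))
  for (u in which(is.na(t$label))) {
    j <- outcomes[u]
    if (is.na(j)) next
    inset <- c(inctree:::reachable_from(t, t$adj[[u]][j], blocked = u), u)
    hit <- em[, 1] %in% inset & em[, 2] %in% inset
    counts[hit] <- counts[hit] + 1L
  }
  counts
}

# Random tree topology for oracle tests (weights irrelevant).
random_topology <- function(n, seed) {
  random_model_tree(n, 0.05, 0.3, seed = seed)$tree
}

# Random query outcomes: abstain with probability p_abstain, otherwise a
# uniformly chosen component slot.
random_outcomes <- function(t, seed, p_abstain = 0.3) {
  withr::with_seed(seed, {
    out <- rep(NA_integer_, length(t$adj))
    for (u in which(is.na(t$label))) {
      if (stats::runif(1) > p_abstain) out[u] <- sample.int(3L, 1L)
    }
    out
  })
}

# Canonical topology fingerprint: sorted non-trivial splits.
topology_id <- function(t) paste(sort(inctree:::tree_splits(t)), collapse = ";")

as_phylo <- function(t) ape::read.tree(text = write_newick(t))

# The quartet split a model tree induces on 4 taxa, via the package's
# induced-topology machinery (used as the FPM oracle).
induced_quartet <- function(tree, taxa4) {
  ti <- as_inc_tree(induce_topology(tree, taxa4))
  s <- inctree:::tree_splits(ti)
  stopifnot(length(s) == 1L)
  s
}

quartet_key <- function(qt) {
  pair <- if (qt$taxa[1] %in% qt$pair1) qt$pair1 else qt$pair2
  paste(sort(pair), collapse = "\r")
}

# The tree t of the voting worked example: internal path p-u-v-q with leaf
# pairs (a,b) at p, c at u, d at v, (e,f) at q; returns the tree plus the
# internal node ids keyed by name.
voting_example_tree <- function() {
  t <- parse_newick("((a,b),c,(d,(e,f)));")
  labs <- t$label
  ints <- which(is.na(labs))
  has <- function(n, who) all(who %in% labs[t$adj[[n]]])
  nodes <- c(p = ints[vapply(ints, has, TRUE, who = c("a", "b"))],
             u = ints[vapply(ints, has, TRUE, who = "c")],
             v = ints[vapply(ints, has, TRUE, who = "d")],
             q = ints[vapply(ints, has, TRUE, who = c("e", "f"))])
  list(tree = t, nodes = nodes)
}

# Outcomes matching the worked example's caption: p pairs x with c (the
# component through u), u with the v side, v with the u side, q abstains.
voting_example_outcomes <- function(ex) {
  t <- ex$tree
  n <- ex$nodes
  out <- rep(NA_integer_, length(t$adj))
  out[n["p"]] <- match(n["u"], t$adj[[n["p"]]])
  out[n["u"]] <- match(n["v"], t$adj[[n["u"]]])
  out[n["v"]] <- match(n["u"], t$adj[[n["v"]]])
  out
}

# A model instance bundle used by several acceptance checks.
make_instance <- function(n, f, g, seed) {
  mod <- random_model_tree(n, f, g, seed = seed)
  list(mod = mod, D = additive_matrix(mod))
}
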