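#' Configuration for incremental tree building
#'
#' @param q_mult multiplier applied to the spanning-tree bottleneck weight
#'   `q0` to obtain the quartet validity radius (default 8; the analysis
#'   uses 8 but notes the constant is likely not optimal).
#' @param q explicit radius overriding `q_mult * q0` when non-`NULL`.
#' @param seed integer seed driving the random tie-break among top-voted
#'   edges; a fixed seed makes the whole run deterministic.
#' @param max_doublings zero-valid-query fallback: when every query
#'   abstains for some taxon, the radius is doubled up to this many times,
#'   after which all queries are forced to vote.  The fallback never fires
#'   in the guaranteed regime (bounded distance error); it exists so a tree
#'   is always returned on arbitrary real data.
#' @return A list of class `inc_config`.
#' @export
inc_config <- function(q_mult = 8, q = NULL, seed = 42L, max_doublings = 10L) {
  if (q_mult <= 0) stop_validation("q_mult must be positive")
  if (!is.null(q) && q <= 0) stop_validation("q must be positive")
  structure(list(q_mult = q_mult, q = q, seed = as.integer(seed),
                 max_doublings = as.integer(max_doublings)),
            class = "inc_config")
}

#' Differential vote tally
#'
#' Each valid query votes for every edge of one subtree, so the vote counts
#' of two adjacent edges sharing node `u` differ only through the query at
#' `u`: by +1/-1 when `u`'s chosen component contains exactly one of the two
#' far endpoints, else 0.  A single BFS from a leaf therefore recovers all
#' edge totals in linear time; the absolute count of the starting leaf edge
#' is obtained directly (a query votes for it exactly when its chosen
#' component contains that leaf), anchoring the scores at true counts.
#'
#' @param t an `inc_tree`.
#' @param outcomes integer vector indexed by node id: for each internal
#'   node, the adjacency slot of the component its query chose, or `NA` if
#'   the query abstained; `NA` for leaves.
#' @return A data.frame with columns `a`, `b` (node ids, `a < b`) and
#'   `votes` (absolute counts).
#' @export
tally_votes <- function(t, outcomes) {
  N <- length(t$adj)
  l0 <- leaf_node_ids(t)[1L]
  # parent pointers rooted at l0
  par <- rep(NA_integer_, N)
  seen <- logical(N)
  seen[l0] <- TRUE
  queue <- l0
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in t$adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        par[w] <- v
        queue <- c(queue, w)
      }
    }
  }
  votes0 <- 0L
  for (u in internal_node_ids(t)) {
    j <- outcomes[u]
    if (!is.na(j) && t$adj[[u]][j] == par[u]) votes0 <- votes0 + 1L
  }
  score <- new.env(parent = emptyenv())
  u0 <- t$adj[[l0]][1L]
  assign(edge_key(l0, u0), votes0, envir = score)
  # BFS over directed edges away from l0
  queue_v <- u0
  queue_p <- l0
  queue_s <- votes0
  while (length(queue_v)) {
    v <- queue_v[1L]; p <- queue_p[1L]; s <- queue_s[1L]
    queue_v <- queue_v[-1L]; queue_p <- queue_p[-1L]; queue_s <- queue_s[-1L]
    if (is.na(t$label[v])) {
      j <- outcomes[v]
      cj <- if (is.na(j)) NA_integer_ else t$adj[[v]][j]
      for (w in t$adj[[v]]) {
        if (w == p) next
        delta <- if (is.na(cj)) 0L else (cj == w) - (cj == p)
        sw <- s + delta
        assign(edge_key(v, w), sw, envir = score)
        queue_v <- c(queue_v, w)
        queue_p <- c(queue_p, v)
        queue_s <- c(queue_s, sw)
      }
    }
  }
  em <- tree_edge_matrix(t)
  data.frame(a = em[, 1L], b = em[, 2L],
             votes = vapply(seq_len(nrow(em)),
                            function(r) get(edge_key(em[r, 1L], em[r, 2L]),
                                            envir = score),
                            numeric(1)))
}

#' Pick the top-voted edge
#'
#' @param scores output of [tally_votes()].
#' @param eligible optional character vector of edge keys (`"a-b"`, smaller
#'   id first) restricting the argmax; votes for other edges are discarded.
#' @return List with `edge` (node id pair), `votes`, `tie` (whether the
#'   argmax was a tie broken by a uniform seeded draw), `n_max`.
#' @export
select_edge <- function(scores, eligible = NULL) {
  if (!is.null(eligible)) {
    keep <- edge_key(scores$a, scores$b) %in% eligible
    if (!any(keep))
      stop("internal invariant violation: no eligible edge in the tree")
    scores <- scores[keep, , drop = FALSE]
  }
  mx <- max(scores$votes)
  cand <- which(scores$votes == mx)
  pick <- if (length(cand) > 1L) cand[sample.int(length(cand), 1L)] else cand
  list(edge = c(scores$a[pick], scores$b[pick]),
       votes = mx, tie = length(cand) > 1L, n_max = length(cand))
}

#' Tally all queries and select the insertion edge
#'
#' Convenience wrapper combining [tally_votes()] and [select_edge()].
#'
#' @inheritParams tally_votes
#' @inheritParams select_edge
#' @return As [select_edge()], plus `scores`.
#' @export
tally_and_select <- function(t, outcomes, eligible = NULL) {
  scores <- tally_votes(t, outcomes)
  out <- select_edge(scores, eligible)
  out$scores <- scores
  out
}

#' Insert a taxon into an edge of the growing tree
#'
#' Subdivides `e`, attaches `x`, and (when a spanning tree is supplied)
#' initializes the new internal node's query triple; the third slot of that
#' triple is `x` itself, witnessed by the spanning-tree edge through which
#' `x` was first reached in the insertion ordering.
#'
#' @param t an `inc_tree`.
#' @param x new taxon label.
#' @param e integer vector of two adjacent node ids.
#' @param S optional `inc_mst` used to build the new node's query triple.
#' @return The grown tree; when `S` is given, the new triple is stored in
#'   `attr(t, "triples")[[as.character(new internal id)]]`.
#' @export
insert_leaf <- function(t, x, e, S = NULL) {
  triples <- attr(t, "triples")
  t2 <- insert_leaf_structural(t, x, e)
  if (!is.null(S)) {
    w <- length(t2$adj) - 1L
    if (is.null(triples)) triples <- list()
    triples[[as.character(w)]] <- build_query_triple(t2, w, S)
    attr(t2, "triples") <- triples
  } else if (!is.null(triples)) {
    attr(t2, "triples") <- triples
  }
  t2
}

# Collect query outcomes for inserting x at radius q; force = ignore diameter.
collect_outcomes <- function(t, triples, x, d, q, force = FALSE) {
  outcomes <- rep(NA_integer_, length(t$adj))
  nvalid <- 0L
  for (u in internal_node_ids(t)) {
    v <- vote_of_query(t, triples[[as.character(u)]], x, d,
                       if (force) Inf else q)
    if (v$valid) {
      outcomes[u] <- v$position
      nvalid <- nvalid + 1L
    }
  }
  list(outcomes = outcomes, nvalid = nvalid)
}

# Eligible edge keys for inserting x under constraint tree tc, or NULL when
# the constraint does not bind yet (fewer than 2 constraint leaves placed).
eligible_edges <- function(t, tc, x) {
  A <- intersect(tree_leaves(tc), t$label[!is.na(t$label)])
  if (length(A) < 2L) return(NULL)
  # attachment edge of x in the induced topology, read off the constraint
  indc <- induce_topology(tc, c(A, x))
  xid <- indc$nodes[which(indc$labels == x)]
  y <- indc$adj[[as.character(xid)]][1L]
  ynbrs <- setdiff(indc$adj[[as.character(y)]], xid)
  B1 <- setdiff(induced_edge_side(indc, y, ynbrs[1L]), x)
  key1 <- paste(sort(B1), collapse = "\r")
  ind <- induce_topology(t, A)
  target <- NULL
  for (r in seq_len(nrow(ind$edges))) {
    s <- induced_edge_side(ind, ind$edges[r, 1L], ind$edges[r, 2L])
    k <- paste(s, collapse = "\r")
    kc <- paste(sort(setdiff(ind$A, s)), collapse = "\r")
    if (k == key1 || kc == key1) {
      target <- ind$edges[r, ]
      break
    }
  }
  if (is.null(target))
    stop("internal invariant violation: constraint attachment edge not found ",
         "for taxon ", x, " (was a constraint violated earlier?)")
  comp <- edge_component(ind, target)
  edge_key(comp$edges[, 1L], comp$edges[, 2L])
}

# Core insertion loop shared by the unconstrained and constrained builders.
# Runs inside a fixed RNG context provided by the caller.
inc_core <- function(d, S, ord, q, cfg, constraints = NULL) {
  sig <- ord$order
  n <- length(sig)
  t <- three_leaf_tree(sig[1:3])
  triples <- list(`1` = build_query_triple(t, 1L, S))
  cmap <- NULL
  if (!is.null(constraints) && length(constraints)) {
    cmap <- stats::setNames(rep(seq_along(constraints),
                                vapply(constraints, n_leaves, 0L)),
                            unlist(lapply(constraints, tree_leaves)))
  }
  queries <- integer(0)
  fallbacks <- 0L
  forced <- 0L
  if (n > 3L) {
    for (x in sig[4:n]) {
      internals <- internal_node_ids(t)
      co <- collect_outcomes(t, triples, x, d, q)
      if (co$nvalid == 0L) {
        fallbacks <- fallbacks + 1L
        qq <- q
        for (dbl in seq_len(cfg$max_doublings)) {
          qq <- 2 * qq
          co <- collect_outcomes(t, triples, x, d, qq)
          if (co$nvalid > 0L) break
        }
        if (co$nvalid == 0L) {
          forced <- forced + 1L
          co <- collect_outcomes(t, triples, x, d, q, force = TRUE)
        }
        message("no valid quartet query for taxon ", x,
                "; widened the validity radius")
      }
      eligible <- NULL
      if (!is.null(cmap) && x %in% names(cmap)) {
        eligible <- eligible_edges(t, constraints[[cmap[[x]]]], x)
      }
      scores <- tally_votes(t, co$outcomes)
      sel <- select_edge(scores, eligible)
      t <- insert_leaf_structural(t, x, sel$edge)
      w <- length(t$adj) - 1L
      triples[[as.character(w)]] <- build_query_triple(t, w, S)
      queries <- c(queries, length(internals))
    }
  }
  attr(t, "triples") <- triples
  attr(t, "inc_stats") <- list(q0 = S$q0, q = q, seed = cfg$seed,
                               queries = queries, fallbacks = fallbacks,
                               forced = forced)
  t
}

finish_small <- function(d) {
  taxa <- sort(rownames(d))
  if (length(taxa) == 1L) return(new_inc_tree(list(integer(0)), taxa))
  new_inc_tree(list(2L, 1L), taxa)
}

#' Incremental tree building from a dissimilarity matrix
#'
#' Builds a binary tree on all taxa by incremental insertion: the insertion
#' ordering is a BFS of a minimum spanning tree of the complete distance
#' graph; each remaining taxon is placed by letting every valid quartet
#' query (one per internal node, using the node's stored leaf triple) vote
#' for the edges of one subtree, and inserting into the top-voted edge
#' (ties broken by a seeded uniform draw).  With an additive input matrix,
#' or one whose short-range error is below half the shortest internal edge
#' weight, the output equals the generating topology.
#'
#' @param d dissimilarity matrix.
#' @param cfg an [inc_config()].
#' @return An `inc_tree` on all taxa of `d`, with an `inc_stats` attribute
#'   recording `q0`, `q`, the per-insertion query counts, and fallback
#'   events.  Fully deterministic given `(d, cfg$seed)`.
#' @export
inc_build <- function(d, cfg = inc_config()) {
  validate_dissimilarity(d)
  if (nrow(d) < 3L) return(finish_small(d))
  S <- minimum_spanning_tree(d)
  ord <- insertion_ordering(S)
  q <- if (!is.null(cfg$q)) cfg$q else cfg$q_mult * S$q0
  withr::with_seed(cfg$seed, inc_core(d, S, ord, q, cfg))
}

#' Constrained incremental tree building
#'
#' As [inc_build()], but honoring a set of leaf-disjoint constraint trees:
#' the output tree induces every constraint exactly on its leaf set.  When
#' inserting a taxon whose constraint tree already shares at least two
#' leaves with the growing tree, the constraint determines an attachment
#' edge in the induced topology, and voting is restricted to the
#' corresponding component of the growing tree (votes elsewhere are
#' discarded).  Constraints with fewer than 3 leaves carry no topological
#' information and are ignored.
#'
#' @param d dissimilarity matrix.
#' @param constraints list of `inc_tree` objects on pairwise disjoint leaf
#'   sets, all leaves present in `d`.
#' @param cfg an [inc_config()].
#' @return An `inc_tree`; constraint preservation is asserted before
#'   returning.
#' @export
constrained_inc_build <- function(d, constraints, cfg = inc_config()) {
  validate_dissimilarity(d)
  if (!is.list(constraints))
    stop_validation("constraints must be a list of trees")
  constraints <- Filter(function(tc) n_leaves(tc) >= 3L, constraints)
  if (length(constraints) >= 2L) {
    lv <- lapply(constraints, tree_leaves)
    all_lv <- unlist(lv)
    if (anyDuplicated(all_lv))
      stop_validation("constraint trees are not leaf-disjoint; shared taxa: ",
                      paste(unique(all_lv[duplicated(all_lv)]), collapse = ", "))
  }
  miss <- setdiff(unlist(lapply(constraints, tree_leaves)), rownames(d))
  if (length(miss))
    stop_validation("constraint leaves missing from the distance matrix: ",
                    paste(miss, collapse = ", "))
  if (nrow(d) < 3L) return(finish_small(d))
  S <- minimum_spanning_tree(d)
  ord <- insertion_ordering(S)
  q <- if (!is.null(cfg$q)) cfg$q else cfg$q_mult * S$q0
  t <- withr::with_seed(cfg$seed,
                        inc_core(d, S, ord, q, cfg,
                                 constraints = if (length(constraints))
                                   constraints else NULL))
  for (tc in constraints) {
    got <- as_inc_tree(induce_topology(t, tree_leaves(tc)))
    if (rf_distance(got, tc) != 0L)
      stop("internal invariant violation: output does not induce a ",
           "constraint tree (leaves ",
           paste(tree_leaves(tc), collapse = ", "), ")")
  }
  t
}
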