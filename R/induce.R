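#' Induced topologies and their edge components
#'
#' `induce_topology(t, A)` restricts `t` to the leaf subset `A`: take the
#' minimal subtree of `t` spanning `A`, then suppress every degree-2 node.
#' The nodes of the induced tree keep their base-tree ids, so each induced
#' edge directly records the two base-tree endpoints of the path it
#' contracts.  `edge_component()` returns the region of the base tree that
#' an induced edge stands for: the path between the two endpoints together
#' with every subtree hanging off the path's interior nodes.  Constrained
#' insertion uses these components as its eligible edge sets.
#'
#' @name induced-topology
NULL

#' Induce the topology of a tree on a leaf subset
#'
#' @param t an `inc_tree`.
#' @param A character vector of leaf labels, a subset of `tree_leaves(t)`.
#' @return An object of class `inc_induced` with elements `nodes` (base ids
#'   kept after suppression), `adj` (adjacency among kept ids, named by id),
#'   `edges` (two-column matrix of base endpoint ids, smaller first),
#'   `labels` (named by id), `A`, and `base` (the base tree).
#' @export
induce_topology <- function(t, A) {
  A <- as.character(A)
  lv <- tree_leaves(t)
  if (!all(A %in% lv))
    stop_validation("not leaves of the tree: ",
                    paste(setdiff(A, lv), collapse = ", "))
  if (anyDuplicated(A)) A <- unique(A)
  N <- length(t$adj)
  aid <- match(A, t$label)
  out <- list(base = t, A = sort(A))
  if (length(A) == 1L) {
    out$nodes <- aid
    out$adj <- stats::setNames(list(), character(0))
    out$edges <- matrix(integer(0), 0L, 2L)
    out$labels <- stats::setNames(t$label[aid], aid)
    return(structure(out, class = "inc_induced"))
  }
  # minimal spanning subtree: iteratively strip non-A leaves
  present <- rep(TRUE, N)
  deg <- lengths(t$adj)
  in_A <- logical(N)
  in_A[aid] <- TRUE
  repeat {
    drop <- which(present & deg <= 1L & !in_A)
    if (!length(drop)) break
    for (v in drop) {
      present[v] <- FALSE
      for (w in t$adj[[v]]) if (present[w]) deg[w] <- deg[w] - 1L
    }
  }
  kept_mask <- logical(N)
  kept_mask[aid] <- TRUE
  kept_mask[present & deg >= 3L & is.na(t$label)] <- TRUE
  kept <- which(kept_mask)
  adj <- stats::setNames(vector("list", length(kept)), as.character(kept))
  edges <- matrix(integer(0), 0L, 2L)
  for (v in kept) {
    for (w0 in t$adj[[v]]) {
      if (!present[w0]) next
      prev <- v; cur <- w0
      while (!kept_mask[cur]) {
        nbrs <- t$adj[[cur]]
        nxt <- nbrs[present[nbrs] & nbrs != prev]
        prev <- cur
        cur <- nxt[1L]
      }
      adj[[as.character(v)]] <- c(adj[[as.character(v)]], cur)
      if (v < cur) edges <- rbind(edges, c(v, cur))
    }
  }
  out$nodes <- kept
  out$adj <- adj
  out$edges <- edges
  out$labels <- stats::setNames(t$label[kept], kept)
  structure(out, class = "inc_induced")
}

#' Materialize an induced topology as a standalone tree
#'
#' @param ind an `inc_induced` with at least 2 leaves.
#' @return An `inc_tree` over the leaf set `ind$A`.
#' @export
as_inc_tree <- function(ind) {
  if (!inherits(ind, "inc_induced")) stop_validation("not an induced topology")
  kept <- ind$nodes
  if (length(kept) < 2L)
    stop_validation("cannot materialize an induced topology with < 2 leaves")
  id <- stats::setNames(seq_along(kept), kept)
  adj <- lapply(as.character(kept), function(v) unname(id[as.character(ind$adj[[v]])]))
  validate_tree(new_inc_tree(adj, unname(ind$labels)))
}

# Leaf labels of A on the `b` side of induced edge (a, b), as a sorted vector.
induced_edge_side <- function(ind, a, b) {
  seen <- character(0)
  queue <- b
  prevs <- a
  visited <- as.character(c(a, b))
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    lab <- ind$labels[[as.character(v)]]
    if (!is.na(lab)) seen <- c(seen, lab)
    for (w in ind$adj[[as.character(v)]]) {
      if (!(as.character(w) %in% visited)) {
        visited <- c(visited, as.character(w))
        queue <- c(queue, w)
      }
    }
  }
  sort(seen)
}

#' Base-tree component corresponding to an induced edge
#'
#' The component of induced edge `e` (base endpoints `u`, `v`) is the set of
#' base-tree edges and vertices reachable on a walk from `u` to `v` that
#' visits neither endpoint twice: the `u`--`v` path plus all subtrees
#' hanging off the path's interior nodes.  `u` and `v` are leaves of the
#' resulting subgraph.
#'
#' @param ind an `inc_induced`.
#' @param e integer vector of two base node ids forming an edge of `ind`.
#' @return A list with `nodes` (sorted base ids), `edges` (two-column matrix
#'   of base ids), `boundary` (the two endpoint ids), and `subgraph_leaves`
#'   (ids of degree-1 nodes of the subgraph).
#' @export
edge_component <- function(ind, e) {
  if (!inherits(ind, "inc_induced")) stop_validation("not an induced topology")
  a <- as.integer(e[1L]); b <- as.integer(e[2L])
  hit <- which(pmin(ind$edges[, 1L], ind$edges[, 2L]) == min(a, b) &
                 pmax(ind$edges[, 1L], ind$edges[, 2L]) == max(a, b))
  if (!length(hit))
    stop_validation("not an edge of the induced topology: (", a, ", ", b, ")")
  t <- ind$base
  # path a..b in the base tree via BFS parents
  N <- length(t$adj)
  par <- rep(NA_integer_, N)
  seen <- logical(N)
  seen[a] <- TRUE
  queue <- a
  while (length(queue) && !seen[b]) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in t$adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        par[w] <- v
        queue <- c(queue, w)
      }
    }
  }
  path <- b
  while (path[1L] != a) path <- c(par[path[1L]], path)
  interior <- path[-c(1L, length(path))]
  if (length(interior)) {
    nodes <- sort(unique(c(a, b, reachable_from(t, interior[1L], blocked = c(a, b)))))
  } else {
    nodes <- sort(c(a, b))
  }
  inset <- logical(N)
  inset[nodes] <- TRUE
  em <- tree_edge_matrix(t)
  edges <- em[inset[em[, 1L]] & inset[em[, 2L]], , drop = FALSE]
  degs <- tabulate(c(edges[, 1L], edges[, 2L]), nbins = N)
  structure(list(nodes = nodes, edges = edges, boundary = c(a, b),
                 subgraph_leaves = nodes[degs[nodes] == 1L]),
            class = "inc_edge_component")
}
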