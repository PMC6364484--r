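#' Four Point Method
#'
#' Infers the split of a quartet from a dissimilarity matrix: the pairing
#' `uv|wz` minimizing `d(u,v) + d(w,z)` wins.  On an exact tie the
#' lexicographically smallest split is returned and the `tie` flag is set
#' (the underlying rule allows an arbitrary topology in that case).  The
#' method is invariant under adding a constant to all off-diagonal entries,
#' since every pairing sum shifts by the same amount.
#'
#' @param d dissimilarity matrix.
#' @param quartet four distinct taxon labels present in `d`.
#' @return An object of class `quartet_topology`: list with `taxa` (sorted),
#'   `pair1`, `pair2` (the winning split, `pair1` holding the smallest
#'   taxon), and `tie`.
#' @export
four_point_method <- function(d, quartet) {
  quartet <- as.character(quartet)
  if (length(quartet) != 4L || anyDuplicated(quartet))
    stop_validation("need 4 distinct taxa, got: ",
                    paste(quartet, collapse = ", "))
  if (!all(quartet %in% rownames(d)))
    stop_validation("taxa missing from matrix: ",
                    paste(setdiff(quartet, rownames(d)), collapse = ", "))
  s <- sort(quartet)
  sums <- c(d[s[1L], s[2L]] + d[s[3L], s[4L]],
            d[s[1L], s[3L]] + d[s[2L], s[4L]],
            d[s[1L], s[4L]] + d[s[2L], s[3L]])
  i <- which.min(sums)
  pairs <- list(list(c(s[1L], s[2L]), c(s[3L], s[4L])),
                list(c(s[1L], s[3L]), c(s[2L], s[4L])),
                list(c(s[1L], s[4L]), c(s[2L], s[3L])))
  structure(list(taxa = s,
                 pair1 = pairs[[i]][[1L]],
                 pair2 = pairs[[i]][[2L]],
                 tie = sum(sums == sums[i]) > 1L),
            class = "quartet_topology")
}

#' Quartet validity (diameter) test
#'
#' A quartet query is valid when its d-diameter (largest pairwise entry) is
#' strictly less than the radius `q`; only valid queries are allowed to
#' vote.  Quartets containing a saturated pair are never valid.
#'
#' @param d dissimilarity matrix.
#' @param quartet four taxon labels.
#' @param q positive radius.
#' @return Logical scalar.
#' @export
is_valid_quartet <- function(d, quartet, q) {
  quartet <- as.character(quartet)
  vals <- d[quartet, quartet]
  vals <- vals[upper.tri(vals)]
  if (any(vals >= MAX_DIST)) return(FALSE)
  max(vals) < q
}

#' Representative leaf triple for an internal node
#'
#' Removing internal node `u` from the growing tree splits it into three
#' components, one per adjacency slot of `u`.  For each component this
#' picks a leaf `u_i` witnessed by a spanning-tree edge `(u_i, v_i)` whose
#' other endpoint lies outside the component (such an edge exists because
#' the inserted taxa always form a connected subtree of the spanning tree).
#' Among eligible leaves the one with the lightest witness edge is chosen,
#' ties by label.  The triple is aligned with `t$adj[[u]]`: `leaves[i]`
#' lies in the component reached through `t$adj[[u]][i]`, an assignment
#' that stays correct as the tree grows because components only ever gain
#' leaves.
#'
#' @param t an `inc_tree`.
#' @param u internal node id.
#' @param S an `inc_mst` over (at least) the current leaf set.
#' @return Object of class `query_triple`: list with `node`, `leaves`
#'   (length 3, slot-aligned), `witness_weight`.
#' @export
build_query_triple <- function(t, u, S) {
  if (!is.na(t$label[u])) stop_validation("node ", u, " is not internal")
  cur <- t$label[!is.na(t$label)]
  comp <- stats::setNames(rep(NA_integer_, length(cur)), cur)
  for (i in 1:3) {
    ids <- reachable_from(t, t$adj[[u]][i], blocked = u)
    comp[t$label[ids[!is.na(t$label[ids])]]] <- i
  }
  best_w <- rep(Inf, 3L)
  best_l <- rep(NA_character_, 3L)
  e <- S$edges
  inside <- e$from %in% cur & e$to %in% cur
  for (r in which(inside)) {
    cf <- comp[[e$from[r]]]
    ct <- comp[[e$to[r]]]
    if (cf == ct) next
    w <- e$weight[r]
    if (w < best_w[cf] || (w == best_w[cf] && e$from[r] < best_l[cf])) {
      best_w[cf] <- w
      best_l[cf] <- e$from[r]
    }
    if (w < best_w[ct] || (w == best_w[ct] && e$to[r] < best_l[ct])) {
      best_w[ct] <- w
      best_l[ct] <- e$to[r]
    }
  }
  if (anyNA(best_l))
    stop("internal invariant violation: no spanning-tree edge crosses out of ",
         "component ", which(is.na(best_l))[1L], " of node ", u,
         "; the insertion ordering lost prefix connectivity")
  structure(list(node = u, leaves = best_l, witness_weight = best_w),
            class = "query_triple")
}

#' Outcome of one quartet query for a pending insertion
#'
#' Forms the quartet `{u_1, u_2, u_3, x}` from the node's stored triple,
#' abstains unless it is valid at radius `q`, and otherwise reports which
#' component the Four Point Method pairs `x` with: the vote goes to every
#' edge of that component plus the edge connecting it to the owner node.
#'
#' @param t an `inc_tree`.
#' @param triple a `query_triple` owned by an internal node of `t`.
#' @param x the taxon being inserted (present in `d`, absent from `t`).
#' @param d dissimilarity matrix.
#' @param q validity radius; `Inf` forces the query to vote regardless of
#'   diameter (the zero-valid-query fallback).
#' @return List with `valid`, `position` (adjacency slot of the chosen
#'   component, `NA` when abstaining), and `tie`.
#' @export
vote_of_query <- function(t, triple, x, d, q) {
  lv <- triple$leaves
  if (!is.finite(q) || q >= MAX_DIST) {
    vals <- d[c(lv, x), c(lv, x)]
    ok <- all(vals[upper.tri(vals)] < MAX_DIST)
  } else {
    ok <- is_valid_quartet(d, c(lv, x), q)
  }
  if (!ok) return(list(valid = FALSE, position = NA_integer_, tie = FALSE))
  qt <- four_point_method(d, c(lv, x))
  partner <- if (x %in% qt$pair1) setdiff(qt$pair1, x) else setdiff(qt$pair2, x)
  list(valid = TRUE, position = match(partner, lv), tie = qt$tie)
}
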