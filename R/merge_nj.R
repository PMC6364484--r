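#' Neighbor joining
#'
#' Classical Saitou--Nei agglomeration (Q-criterion pair selection with the
#' standard distance update), returning the unrooted topology.  Recovers
#' the true tree whenever the input is within L-infinity distance f/2 of an
#' additive matrix, f being the shortest internal edge weight.  Saturated
#' entries are rejected: an undefined distance gives NJ no usable signal.
#'
#' @param d dissimilarity matrix with finite (unsaturated) entries.
#' @return An `inc_tree`.
#' @export
neighbor_joining <- function(d) {
  validate_dissimilarity(d)
  off <- d[upper.tri(d)]
  if (any(off >= MAX_DIST)) {
    bad <- which(d >= MAX_DIST & upper.tri(d), arr.ind = TRUE)[1L, ]
    stop_validation("saturated distance between '", rownames(d)[bad[1L]],
                    "' and '", rownames(d)[bad[2L]],
                    "'; neighbor joining needs finite distances")
  }
  if (nrow(d) < 3L) return(finish_small(d))
  if (nrow(d) == 3L) return(three_leaf_tree(sort(rownames(d))))
  tr <- ape::nj(d)
  from_phylo(ape::unroot(tr))
}

#' Greedy ball-growing decomposition of the threshold graph
#'
#' Repeatedly seeds a ball at the lexicographically smallest unassigned
#' taxon and adds unassigned taxa within distance `q` of the seed in
#' ascending distance (ties by label) until the ball holds `cap` taxa;
#' taxa with no unassigned neighbor within `q` form singletons.  The balls
#' partition the taxon set and are pairwise disjoint by construction.
#'
#' @param d dissimilarity matrix.
#' @param q positive radius.
#' @param cap maximum subset size (>= 1).
#' @return Object of class `inc_decomposition`: list with `subsets` (list
#'   of character vectors), `seeds`, `q`, `cap`.
#' @export
ball_decomposition <- function(d, q, cap) {
  validate_dissimilarity(d)
  if (q <= 0) stop_validation("q must be positive")
  cap <- as.integer(cap)
  if (cap < 1L) stop_validation("cap must be at least 1")
  unassigned <- sort(rownames(d))
  subsets <- list()
  seeds <- character(0)
  while (length(unassigned)) {
    seed <- unassigned[1L]
    unassigned <- unassigned[-1L]
    ball <- seed
    if (cap > 1L && length(unassigned)) {
      dv <- d[seed, unassigned]
      near <- unassigned[dv <= q]
      if (length(near)) {
        near <- near[order(d[seed, near], near)]
        take <- utils::head(near, cap - 1L)
        ball <- c(ball, take)
        unassigned <- setdiff(unassigned, take)
      }
    }
    subsets <- c(subsets, list(ball))
    seeds <- c(seeds, seed)
  }
  structure(list(subsets = subsets, seeds = seeds, q = q, cap = cap),
            class = "inc_decomposition")
}

#' Divide-and-conquer tree building: NJ subset trees merged by constrained
#' incremental insertion
#'
#' The taxa are partitioned into balls of at most `ceiling(sqrt(n))` taxa
#' within threshold-graph radius `q = q_mult * q0`; neighbor joining is run
#' on each ball's induced submatrix; and the resulting leaf-disjoint subset
#' trees are fed to [constrained_inc_build()] as constraint trees.  Balls
#' with fewer than 3 taxa contribute no usable constraint and their taxa
#' are placed by ordinary voting.
#'
#' @param d dissimilarity matrix.
#' @param cfg an [inc_config()].
#' @param cap maximum ball size; default `ceiling(sqrt(n))`.
#' @return An `inc_tree` with attributes `decomposition` and
#'   `constraint_trees`.
#' @export
inc_nj_build <- function(d, cfg = inc_config(), cap = NULL) {
  validate_dissimilarity(d)
  n <- nrow(d)
  if (n < 3L) return(finish_small(d))
  S <- minimum_spanning_tree(d)
  q <- if (!is.null(cfg$q)) cfg$q else cfg$q_mult * S$q0
  if (is.null(cap)) cap <- ceiling(sqrt(n))
  dec <- ball_decomposition(d, q, cap)
  big <- Filter(function(s) length(s) >= 3L, dec$subsets)
  cons <- lapply(big, function(s) neighbor_joining(d[s, s, drop = FALSE]))
  t <- if (length(cons)) constrained_inc_build(d, cons, cfg)
       else inc_build(d, cfg)
  attr(t, "decomposition") <- dec
  attr(t, "constraint_trees") <- cons
  t
}
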