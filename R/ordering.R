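#' Minimum spanning tree of the complete threshold graph
#'
#' Prim's algorithm over the complete graph on the taxa weighted by the
#' dissimilarity matrix, started from the lexicographically smallest taxon;
#' equal-weight choices are broken by the sorted label pair of the candidate
#' edge, so the tree is deterministic.  All minimum spanning trees share the
#' same maximum edge weight `q0`, the smallest threshold at which the
#' thresholded distance graph is connected; `q0` calibrates the quartet
#' validity radius `q = 8 * q0`.
#'
#' Saturated entries ([MAX_DIST]) participate with their sentinel weight; if
#' a sentinel edge is forced into the tree, `q0` is taken as the largest
#' non-sentinel edge weight (with a warning) so the validity radius stays
#' finite.
#'
#' @param d dissimilarity matrix.
#' @return An object of class `inc_mst`: list with `taxa`, `edges` (a
#'   data.frame `from`/`to`/`weight` in label space), and `q0`.
#' @export
minimum_spanning_tree <- function(d) {
  validate_dissimilarity(d)
  lab <- rownames(d)
  n <- length(lab)
  if (n == 1L) {
    return(structure(list(taxa = lab,
                          edges = data.frame(from = character(0),
                                             to = character(0),
                                             weight = numeric(0)),
                          q0 = 0), class = "inc_mst"))
  }
  intree <- logical(n)
  r <- order(lab)[1L]
  intree[r] <- TRUE
  key <- d[r, ]
  parent <- rep(r, n)
  key[r] <- Inf
  from <- to <- character(n - 1L)
  wt <- numeric(n - 1L)
  for (s in seq_len(n - 1L)) {
    cand <- which(!intree)
    pl <- lab[parent[cand]]
    cl <- lab[cand]
    o <- order(key[cand], pmin(pl, cl), pmax(pl, cl))
    v <- cand[o[1L]]
    intree[v] <- TRUE
    from[s] <- lab[parent[v]]
    to[s] <- lab[v]
    wt[s] <- key[v]
    upd <- which(!intree & (d[v, ] < key |
                              (d[v, ] == key & lab[v] < lab[parent])))
    key[upd] <- d[v, upd]
    parent[upd] <- v
  }
  if (any(wt >= MAX_DIST)) {
    finite <- wt[wt < MAX_DIST]
    q0 <- if (length(finite)) max(finite) else 0
    warning("minimum spanning tree contains saturated edges; ",
            "q0 taken from the largest unsaturated edge")
  } else {
    q0 <- max(wt)
  }
  structure(list(taxa = lab,
                 edges = data.frame(from = from, to = to, weight = wt,
                                    stringsAsFactors = FALSE),
                 q0 = q0),
            class = "inc_mst")
}

mst_adjacency <- function(S) {
  adj <- stats::setNames(vector("list", length(S$taxa)), S$taxa)
  for (r in seq_len(nrow(S$edges))) {
    f <- S$edges$from[r]; t <- S$edges$to[r]; w <- S$edges$weight[r]
    adj[[f]] <- rbind(adj[[f]], data.frame(nbr = t, w = w))
    adj[[t]] <- rbind(adj[[t]], data.frame(nbr = f, w = w))
  }
  adj
}

mst_degree <- function(S) {
  tab <- table(c(S$edges$from, S$edges$to))
  stats::setNames(as.integer(tab[S$taxa]), S$taxa)
}

#' Insertion ordering by breadth-first traversal of the spanning tree
#'
#' Starting from a leaf of the spanning tree (by default the
#' lexicographically smallest), taxa are ordered by BFS with neighbors
#' visited in ascending edge weight (ties by label).  Every prefix of the
#' ordering then spans a connected subtree of the spanning tree, which is
#' what guarantees that witness edges exist for every query triple of the
#' growing tree.
#'
#' @param S an `inc_mst`.
#' @param start optional starting taxon; must be a leaf (degree 1) of `S`.
#' @return An object of class `inc_ordering`: list with `order` (the
#'   permutation), `parent` (named BFS parent per taxon, `NA` for the
#'   start), and `parent_weight`.
#' @export
insertion_ordering <- function(S, start = NULL) {
  if (!inherits(S, "inc_mst")) stop_validation("S must be an inc_mst")
  taxa <- S$taxa
  if (length(taxa) == 1L) {
    return(structure(list(order = taxa,
                          parent = stats::setNames(NA_character_, taxa),
                          parent_weight = stats::setNames(NA_real_, taxa)),
                     class = "inc_ordering"))
  }
  deg <- mst_degree(S)
  if (is.null(start)) {
    lv <- sort(names(deg)[deg == 1L])
    start <- lv[1L]
  } else {
    if (!(start %in% taxa))
      stop_validation("start taxon not in the spanning tree: ", start)
    if (deg[[start]] != 1L)
      stop_validation("start taxon is not a leaf of the spanning tree: ", start)
  }
  adj <- mst_adjacency(S)
  parent <- stats::setNames(rep(NA_character_, length(taxa)), taxa)
  pw <- stats::setNames(rep(NA_real_, length(taxa)), taxa)
  seen <- stats::setNames(logical(length(taxa)), taxa)
  seen[start] <- TRUE
  ord <- character(length(taxa))
  ord[1L] <- start
  head <- 1L; tail <- 1L
  while (head <= tail) {
    v <- ord[head]
    head <- head + 1L
    nb <- adj[[v]]
    if (!is.null(nb)) {
      nb <- nb[order(nb$w, nb$nbr), , drop = FALSE]
      for (r in seq_len(nrow(nb))) {
        u <- nb$nbr[r]
        if (!seen[u]) {
          seen[u] <- TRUE
          parent[u] <- v
          pw[u] <- nb$w[r]
          tail <- tail + 1L
          ord[tail] <- u
        }
      }
    }
  }
  structure(list(order = ord, parent = parent, parent_weight = pw),
            class = "inc_ordering")
}
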