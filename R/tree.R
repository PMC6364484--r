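#' Unrooted binary trees
#'
#' Trees are stored as an adjacency list over integer node ids together with
#' a label vector (`NA` for internal nodes).  Node ids are never reused while
#' a tree is grown: inserting a leaf subdivides an edge in place, so edge
#' maps computed on induced topologies remain valid across later insertions.
#' Every internal node has degree 3 and every leaf degree 1; branch lengths,
#' when present, are carried through I/O but ignored by all topological
#' operations.
#'
#' @name inc_tree
#' @keywords internal
NULL

new_inc_tree <- function(adj, label, brlen = NULL) {
  structure(list(adj = adj, label = label, brlen = brlen), class = "inc_tree")
}

#' Build the unique three-leaf tree
#'
#' @param labels character vector of three taxon labels.
#' @return An `inc_tree` with one internal node (id 1) joined to leaves 2:4.
#' @export
three_leaf_tree <- function(labels) {
  if (length(labels) != 3L || anyDuplicated(labels))
    stop_validation("three_leaf_tree() needs 3 distinct labels")
  new_inc_tree(list(c(2L, 3L, 4L), 1L, 1L, 1L),
               c(NA_character_, as.character(labels)))
}

is_inc_tree <- function(x) inherits(x, "inc_tree")

leaf_node_ids <- function(t) which(!is.na(t$label))

internal_node_ids <- function(t) which(is.na(t$label))

#' Leaf labels of a tree
#'
#' @param t an `inc_tree`.
#' @return Sorted character vector of taxon labels.
#' @export
tree_leaves <- function(t) sort(t$label[!is.na(t$label)])

n_leaves <- function(t) sum(!is.na(t$label))

edge_key <- function(a, b) paste0(pmin(a, b), "-", pmax(a, b))

#' All edges of a tree as a two-column matrix of node ids (smaller id first)
#' @keywords internal
tree_edge_matrix <- function(t) {
  from <- rep.int(seq_along(t$adj), lengths(t$adj))
  to <- unlist(t$adj, use.names = FALSE)
  keep <- from < to
  cbind(from[keep], to[keep])
}

validate_tree <- function(t) {
  deg <- lengths(t$adj)
  leaf <- !is.na(t$label)
  if (length(t$adj) != length(t$label))
    stop_validation("corrupt tree: adjacency/label length mismatch")
  if (anyDuplicated(t$label[leaf]))
    stop_validation("duplicate leaf labels: ",
                    paste(unique(t$label[leaf][duplicated(t$label[leaf])]),
                          collapse = ", "))
  if (length(t$adj) >= 4L) {
    bad <- which(!leaf & deg != 3L)
    if (length(bad))
      stop_validation("non-binary internal node(s): ",
                      paste(bad, collapse = ", "))
    if (any(leaf & deg != 1L))
      stop_validation("leaf node(s) of degree != 1: ",
                      paste(which(leaf & deg != 1L), collapse = ", "))
  }
  invisible(t)
}

# Nodes reachable from `start` without passing through any node in `blocked`.
reachable_from <- function(t, start, blocked = integer(0)) {
  n <- length(t$adj)
  seen <- logical(n)
  seen[blocked] <- TRUE
  out <- integer(n)
  out[1L] <- start
  seen[start] <- TRUE
  head <- 1L
  tail <- 1L
  while (head <= tail) {
    v <- out[head]
    head <- head + 1L
    for (w in t$adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        tail <- tail + 1L
        out[tail] <- w
      }
    }
  }
  out[seq_len(tail)]
}

# Labels of the leaves lying on the `b` side of edge (a, b).
side_leaf_labels <- function(t, a, b) {
  ids <- reachable_from(t, b, blocked = a)
  t$label[ids[!is.na(t$label[ids])]]
}

#' Non-trivial bipartitions of a tree
#'
#' Each internal edge is encoded by the sorted leaf set on the side holding
#' the overall smallest taxon, pasted into a single key, so two trees over
#' the same taxa can be compared as sets of strings.
#' @keywords internal
tree_splits <- function(t) {
  all_lv <- tree_leaves(t)
  if (length(all_lv) < 4L) return(character(0))
  em <- tree_edge_matrix(t)
  keys <- character(0)
  for (r in seq_len(nrow(em))) {
    a <- em[r, 1L]; b <- em[r, 2L]
    if (!is.na(t$label[a]) || !is.na(t$label[b])) next
    s <- sort(side_leaf_labels(t, a, b))
    if (!(all_lv[1L] %in% s)) s <- setdiff(all_lv, s)
    keys <- c(keys, paste(s, collapse = "\r"))
  }
  keys
}

#' Robinson–Foulds distance between two unrooted trees
#'
#' Counts the non-trivial bipartitions present in exactly one of the two
#' trees (the symmetric difference of the split sets).
#'
#' @param t1,t2 `inc_tree` objects on identical leaf sets.
#' @return Non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  l1 <- tree_leaves(t1)
  l2 <- tree_leaves(t2)
  if (!identical(l1, l2))
    stop_validation("leaf sets differ; only in first: {",
                    paste(setdiff(l1, l2), collapse = ", "),
                    "}, only in second: {",
                    paste(setdiff(l2, l1), collapse = ", "), "}")
  s1 <- tree_splits(t1)
  s2 <- tree_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

#' Convert an ape phylo object to an inc_tree
#' @keywords internal
from_phylo <- function(tr) {
  nt <- length(tr$tip.label)
  nn <- tr$Nnode
  adj <- vector("list", nt + nn)
  for (r in seq_len(nrow(tr$edge))) {
    a <- tr$edge[r, 1L]; b <- tr$edge[r, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  label <- c(tr$tip.label, rep(NA_character_, nn))
  brlen <- NULL
  if (!is.null(tr$edge.length))
    brlen <- stats::setNames(tr$edge.length,
                             edge_key(tr$edge[, 1L], tr$edge[, 2L]))
  validate_tree(new_inc_tree(adj, label, brlen))
}

#' Parse a Newick string into an unrooted binary tree
#'
#' A rooted binary input has its root bifurcation collapsed; after unrooting
#' all internal nodes must have degree 3.  Branch lengths are retained but
#' ignored by every topological operation.
#'
#' @param text a single Newick string (quoted labels supported).
#' @return An `inc_tree`.
#' @export
parse_newick <- function(text) {
  if (length(text) != 1L || !is.character(text))
    stop_parse("expected a single Newick string")
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  quoted <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") quoted <- !quoted
    if (quoted) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop_parse("unbalanced ')' at position ", i)
    }
  }
  if (depth != 0L) stop_parse("unbalanced '(' (", depth, " unclosed)")
  if (!grepl(";", text, fixed = TRUE)) stop_parse("missing ';' terminator")
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop_parse("could not parse Newick string")
  if (anyDuplicated(tr$tip.label))
    stop_validation("duplicate leaf labels: ",
                    paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
                          collapse = ", "))
  if (length(tr$tip.label) == 2L) {
    return(new_inc_tree(list(2L, 1L), tr$tip.label,
                        if (!is.null(tr$edge.length))
                          stats::setNames(sum(tr$edge.length), "1-2")))
  }
  if (length(tr$tip.label) < 2L)
    stop_validation("trees with fewer than 2 leaves are not supported")
  if (ape::is.rooted(tr)) tr <- ape::unroot(tr)
  from_phylo(tr)
}

quote_label <- function(lab) {
  bad <- grepl("[ ,():;'\\[\\]]", lab)
  lab[bad] <- paste0("'", gsub("'", "''", lab[bad]), "'")
  lab
}

#' Serialize an unrooted binary tree to Newick
#'
#' Deterministic: the trifurcation is placed at the internal node adjacent
#' to the lexicographically smallest leaf and children are ordered by their
#' smallest descendant label, so equal topologies serialize identically.
#' Branch lengths are emitted when the tree carries them.
#'
#' @param t an `inc_tree` with at least 3 leaves.
#' @return A single Newick string.
#' @export
write_newick <- function(t) {
  if (n_leaves(t) < 3L)
    stop_validation("unsupported size: need >= 3 leaves to serialize")
  labs <- t$label
  lids <- leaf_node_ids(t)
  lid <- lids[order(labs[lids])[1L]]
  root <- t$adj[[lid]][1L]
  suffix <- function(node, parent) {
    if (is.null(t$brlen) || parent < 1L) return("")
    k <- edge_key(node, parent)
    if (is.na(match(k, names(t$brlen)))) return("")
    paste0(":", format(unname(t$brlen[k]), digits = 10))
  }
  ser <- function(node, parent) {
    if (!is.na(labs[node])) {
      return(list(str = paste0(quote_label(labs[node]), suffix(node, parent)),
                  min = labs[node]))
    }
    kids <- setdiff(t$adj[[node]], parent)
    parts <- lapply(kids, ser, parent = node)
    parts <- parts[order(vapply(parts, `[[`, "", "min"))]
    list(str = paste0("(",
                      paste(vapply(parts, `[[`, "", "str"), collapse = ","),
                      ")", suffix(node, parent)),
         min = parts[[1L]]$min)
  }
  paste0(ser(root, parent = 0L)$str, ";")
}

#' Subdivide an edge and attach a new leaf
#'
#' Structural half of taxon insertion: edge `e = (a, b)` is replaced by
#' `a - w - b` and the new leaf `x` is attached to the new internal node
#' `w`.  Adjacency positions of existing nodes are updated in place so that
#' component bookkeeping at other nodes stays valid.
#'
#' @param t an `inc_tree`.
#' @param x new taxon label, not yet in the tree.
#' @param e integer vector of two adjacent node ids.
#' @return The grown tree; the new internal node has id `length(t$adj) + 1`
#'   and the new leaf the id after it.
#' @export
insert_leaf_structural <- function(t, x, e) {
  a <- as.integer(e[1L]); b <- as.integer(e[2L])
  if (!(b %in% t$adj[[a]]))
    stop_validation("not an edge of the tree: (", a, ", ", b, ")")
  if (x %in% t$label)
    stop_validation("taxon already in tree: ", x)
  w <- length(t$adj) + 1L
  xid <- w + 1L
  t$adj[[a]][t$adj[[a]] == b] <- w
  t$adj[[b]][t$adj[[b]] == a] <- w
  t$adj[[w]] <- c(a, b, xid)
  t$adj[[xid]] <- w
  t$label <- c(t$label, NA_character_, as.character(x))
  t$brlen <- NULL
  t
}
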