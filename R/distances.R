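#' Saturation sentinel for undefined distances
#'
#' Pairs whose empirical distance transform is undefined (normalized Hamming
#' distance at or above 1/2 under the two-state model, or a non-positive
#' determinant of the divergence matrix under log-det) are stored as this
#' finite sentinel rather than `Inf`, so that spanning-tree computations on
#' the complete weighted graph remain well defined.  The sentinel exceeds
#' any realistic path length, so saturated pairs never enter a minimum
#' spanning tree when an unsaturated alternative exists.
#'
#' @export
MAX_DIST <- 1e6

#' Validate a dissimilarity matrix
#'
#' @param d numeric square matrix with matching row/column taxon names.
#' @param tol symmetry tolerance.
#' @return `d`, invisibly, with rows/cols in their given order.
#' @keywords internal
validate_dissimilarity <- function(d, tol = 1e-6) {
  if (!is.matrix(d) || !is.numeric(d) || nrow(d) != ncol(d))
    stop_validation("dissimilarity matrix must be a square numeric matrix")
  if (is.null(rownames(d)) || is.null(colnames(d)) ||
      !identical(rownames(d), colnames(d)))
    stop_validation("dissimilarity matrix needs identical row and column taxon names")
  if (anyDuplicated(rownames(d)))
    stop_validation("duplicate taxa in dissimilarity matrix")
  if (any(abs(d - t(d)) > tol))
    stop_validation("matrix is not symmetric within tolerance ", tol)
  if (any(diag(d) != 0))
    stop_validation("dissimilarity matrix must have a zero diagonal")
  if (any(d < 0))
    stop_validation("negative dissimilarities are not allowed")
  invisible(d)
}

aln_matrix <- function(aln) {
  if (!is.matrix(aln) || !is.character(aln) || is.null(rownames(aln)))
    stop_validation("alignment must be a character matrix with taxon rownames")
  if (anyDuplicated(rownames(aln)))
    stop_validation("duplicate taxa in alignment")
  if (ncol(aln) < 1L)
    stop_validation("alignment must have at least one site")
  aln
}

#' Empirical CFN distances from a binary alignment
#'
#' For every taxon pair the normalized Hamming distance \eqn{H_{ij}} is
#' mapped through \eqn{d_{ij} = -\frac{1}{2}\ln(1 - 2H_{ij})}, the distance
#' correction of the two-state symmetric (Cavender--Farris--Neyman) model.
#' Pairs with \eqn{H_{ij} \ge 1/2} are saturated and recorded as
#' [MAX_DIST].
#'
#' @param aln character matrix over `{"0","1"}` with taxon rownames.
#' @return Symmetric dissimilarity matrix with zero diagonal.
#' @export
cfn_distance_matrix <- function(aln) {
  aln <- aln_matrix(aln)
  if (!all(aln %in% c("0", "1")))
    stop_validation("CFN distances need a binary {0,1} alignment")
  X <- matrix(as.numeric(aln == "1"), nrow = nrow(aln),
              dimnames = list(rownames(aln), NULL))
  k <- ncol(X)
  H <- (X %*% t(1 - X) + (1 - X) %*% t(X)) / k
  d <- -0.5 * log(pmax(1 - 2 * H, 0))
  d[H >= 0.5] <- MAX_DIST
  diag(d) <- 0
  d <- (d + t(d)) / 2
  dimnames(d) <- list(rownames(aln), rownames(aln))
  d
}

#' Empirical log-det distances from an m-state alignment
#'
#' For each pair the m-by-m relative-frequency (divergence) matrix
#' \eqn{\hat F_{ij}} is tabulated over all sites and the distance is
#' \eqn{d_{ij} = -\log\det \hat F_{ij}}, the paralinear/log-det distance of
#' the general Markov model.  A non-positive determinant saturates the pair
#' to [MAX_DIST].  The diagonal is stored as 0 even though
#' \eqn{-\log\det\hat F_{ii} > 0} in general: no algorithm in the package
#' reads it and the dissimilarity-matrix contract demands a zero diagonal.
#'
#' @param aln character matrix with taxon rownames.
#' @param alphabet state set; defaults to the alignment's `states` attribute
#'   and otherwise to `c("A","C","G","T")`.
#' @return Symmetric dissimilarity matrix with zero diagonal.
#' @export
logdet_distance_matrix <- function(aln, alphabet = NULL) {
  aln <- aln_matrix(aln)
  if (is.null(alphabet)) alphabet <- attr(aln, "states")
  if (is.null(alphabet)) alphabet <- c("A", "C", "G", "T")
  m <- length(alphabet)
  idx <- matrix(match(toupper(aln), toupper(alphabet)), nrow = nrow(aln))
  if (anyNA(idx))
    stop_validation("alignment contains characters outside the declared alphabet {",
                    paste(alphabet, collapse = ","), "}")
  n <- nrow(aln)
  k <- ncol(aln)
  taxa <- rownames(aln)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      Fh <- matrix(tabulate((idx[i, ] - 1L) * m + idx[j, ], nbins = m * m),
                   m, m, byrow = TRUE) / k
      dt <- det(Fh)
      d[i, j] <- d[j, i] <- if (dt <= 0) MAX_DIST else -log(dt)
    }
  }
  d
}

#' Additive (path-sum) distance matrix of a model tree
#'
#' @param model a `cfn_model` or `gtr_model` (anything with a `tree` and a
#'   per-edge weight vector `w` named by edge key), or an `inc_tree` passed
#'   with an explicit `w`.
#' @param w optional named edge weight vector when `model` is a bare tree.
#' @return Matrix of leaf-to-leaf path sums of edge weights.
#' @export
additive_matrix <- function(model, w = NULL) {
  if (is_inc_tree(model)) {
    t <- model
    if (is.null(w)) w <- model$brlen
  } else {
    t <- model$tree
    if (is.null(w)) w <- model$w
  }
  if (is.null(w)) stop_validation("no edge weights available")
  if (any(w <= 0)) stop_validation("edge weights must be positive")
  lids <- leaf_node_ids(t)
  taxa <- t$label[lids]
  ord <- order(taxa)
  lids <- lids[ord]; taxa <- taxa[ord]
  n <- length(lids)
  N <- length(t$adj)
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n)) {
    dist <- rep(NA_real_, N)
    dist[lids[i]] <- 0
    queue <- lids[i]
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (u in t$adj[[v]]) {
        if (is.na(dist[u])) {
          dist[u] <- dist[v] + w[[edge_key(v, u)]]
          queue <- c(queue, u)
        }
      }
    }
    D[i, ] <- dist[lids]
  }
  # per-row path sums can disagree across the diagonal by an ulp; mirror the
  # upper triangle so the matrix is exactly symmetric
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  D
}

#' Maximum short-range deviation between two dissimilarity matrices
#'
#' \eqn{\epsilon(q) = \max\{|d_{ij} - D_{ij}| : d_{ij} \le q
#' \textrm{ or } D_{ij} \le q\}}, the error functional that governs when
#' quartet queries on short distances are reliable; 0 when no pair
#' qualifies.
#'
#' @param d,D dissimilarity matrices over the same taxa in the same order.
#' @param q positive threshold.
#' @return A single non-negative number.
#' @export
epsilon_q <- function(d, D, q) {
  validate_dissimilarity(d)
  validate_dissimilarity(D)
  if (!identical(rownames(d), rownames(D)))
    stop_validation("taxa of the two matrices differ or are ordered differently")
  if (!is.numeric(q) || length(q) != 1L || q <= 0)
    stop_validation("q must be a single positive number")
  off <- upper.tri(d)
  qual <- off & (d <= q | D <= q)
  if (!any(qual)) return(0)
  max(abs(d - D)[qual])
}

#' Read a PHYLIP square distance matrix
#'
#' First line: the number of taxa; then one row per taxon: label followed by
#' n distances.  Rows may wrap across lines.
#'
#' @param path file path, or a character vector of lines via `text`.
#' @param text optional character scalar holding the file contents.
#' @return Validated dissimilarity matrix.
#' @export
read_phylip_dist <- function(path, text = NULL) {
  lines <- if (!is.null(text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    if (!file.exists(path)) stop_io("no such file: ", path)
    readLines(path)
  }
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_parse("empty distance file")
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L)
    stop_parse("line 1: expected the number of taxa, got '", lines[1L], "'")
  tokens <- unlist(strsplit(trimws(lines[-1L]), "[ \t]+"))
  if (length(tokens) != n * (n + 1L))
    stop_parse("expected ", n, " rows of a label plus ", n,
               " values (", n * (n + 1L), " tokens), found ", length(tokens))
  tok <- matrix(tokens, nrow = n, byrow = TRUE)
  taxa <- tok[, 1L]
  vals <- suppressWarnings(matrix(as.numeric(tok[, -1L, drop = FALSE]), nrow = n))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop_parse("row ", bad[1L] + 1L, ": non-numeric distance for taxon '",
               taxa[bad[1L]], "'")
  }
  dimnames(vals) <- list(taxa, taxa)
  validate_dissimilarity(vals)
  vals
}

#' Write a PHYLIP square distance matrix
#'
#' @param d dissimilarity matrix.
#' @param path optional output path; when `NULL` the text is returned.
#' @return The file contents as a single string, invisibly when written.
#' @export
write_phylip_dist <- function(d, path = NULL) {
  validate_dissimilarity(d)
  rows <- vapply(seq_len(nrow(d)), function(i) {
    paste(rownames(d)[i], paste(sprintf("%.6f", d[i, ]), collapse = " "))
  }, "")
  out <- paste0(paste(c(nrow(d), rows), collapse = "\n"), "\n")
  if (is.null(path)) return(out)
  writeLines(out, path, sep = "")
  invisible(out)
}

#' Read a FASTA alignment
#'
#' Wrap-agnostic and case-insensitive; all sequences must share one length.
#'
#' @param path FASTA file.
#' @param alphabet `"binary"` for `{0,1}` data or `"dna"` for `{A,C,G,T}`.
#' @return Character matrix with taxon rownames and a `states` attribute.
#' @export
read_fasta_alignment <- function(path, alphabet = c("dna", "binary")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop_io("no such file: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (!length(seqs)) stop_parse("no sequences in FASTA file: ", path)
  if (length(unique(Biostrings::width(seqs))) != 1L)
    stop_validation("sequences have unequal lengths in ", path)
  chars <- toupper(as.character(seqs))
  mat <- do.call(rbind, strsplit(chars, "", fixed = TRUE))
  rownames(mat) <- names(seqs)
  states <- if (alphabet == "binary") c("0", "1") else c("A", "C", "G", "T")
  if (!all(mat %in% states))
    stop_validation("alignment contains characters outside the ", alphabet,
                    " alphabet")
  attr(mat, "states") <- states
  mat
}

#' Write an alignment to FASTA
#'
#' @param aln character matrix with taxon rownames.
#' @param path output path.
#' @export
write_fasta_alignment <- function(aln, path) {
  aln <- aln_matrix(aln)
  seqs <- Biostrings::BStringSet(apply(aln, 1L, paste, collapse = ""))
  names(seqs) <- rownames(aln)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
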