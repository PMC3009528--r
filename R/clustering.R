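# Cladograms and score histograms. The distance between two binding sites is
# 1 - PM13Score (PMSMin); trees are built by neighbour joining and serialized
# as Newick.

#' Turn a score matrix into a distance matrix
#'
#' Elementwise `1 - score`; the diagonal becomes zero.
#'
#' @param scores A symmetric score matrix with unit diagonal and entries in
#'   `[0, 1]`, or a `pm13_score_matrix` (its PMSMin matrix is used).
#' @return Symmetric numeric distance matrix with zero diagonal.
#' @export
to_distance_matrix <- function(scores) {
  if (inherits(scores, "pm13_score_matrix")) scores <- scores$pms_min
  scores <- as.matrix(scores)
  if (nrow(scores) != ncol(scores) ||
      !isTRUE(all.equal(scores, t(scores), tolerance = 1e-8))) {
    stop("input error: score matrix must be symmetric", call. = FALSE)
  }
  if (any(scores < 0 | scores > 1)) {
    stop("input error: scores must lie in [0, 1]", call. = FALSE)
  }
  if (any(abs(diag(scores) - 1) > 1e-8)) {
    stop("input error: score matrix must have unit diagonal", call. = FALSE)
  }
  d <- 1 - scores
  diag(d) <- 0
  d
}

#' Neighbour-joining cladogram of binding sites
#'
#' Saitou-Nei neighbour joining on a `1 - score` distance matrix. Negative
#' branch lengths (possible on non-additive data) are clamped to zero and the
#' total clamped deficit is reported as an attribute. The input label order is
#' used as the deterministic tie-break.
#'
#' @param d Symmetric distance matrix with zero diagonal (see
#'   [to_distance_matrix()]), at least 3 labels.
#' @return An unrooted `phylo` tree (ape), attribute `clamped` giving the
#'   total negative branch length removed.
#' @export
neighbor_join <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("input error: need at least 3 labels", call. = FALSE)
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  tr <- ape::nj(stats::as.dist(d))
  neg <- tr$edge.length < 0
  clamped <- -sum(tr$edge.length[neg])
  if (any(neg)) {
    message("neighbor_join: clamped ", sum(neg),
            " negative branch length(s), total deficit ",
            signif(clamped, 3))
    tr$edge.length[neg] <- 0
  }
  attr(tr, "clamped") <- clamped
  tr
}

# quote a label when it contains Newick metacharacters
.newick_label <- function(lab) {
  bad <- grepl("[][():;,'\"[:space:]]", lab)
  lab[bad] <- paste0("'", gsub("'", "''", lab[bad]), "'")
  lab
}

# serializer preserving labels verbatim (quoted where needed)
.phylo_to_newick <- function(tr) {
  ntip <- length(tr$tip.label)
  kids <- split(seq_len(nrow(tr$edge)), tr$edge[, 1])
  fmt_node <- function(node, edge_idx) {
    lab <- if (node <= ntip) .newick_label(tr$tip.label[node]) else {
      ch <- kids[[as.character(node)]]
      paste0("(", paste(vapply(ch, function(e) fmt_node(tr$edge[e, 2], e),
                               ""), collapse = ","), ")")
    }
    if (is.na(edge_idx)) lab else
      paste0(lab, ":", format(tr$edge.length[edge_idx], digits = 15))
  }
  root <- ntip + 1L
  paste0(fmt_node(root, NA), ";")
}

#' Serialize a cladogram to Newick
#'
#' Standard Newick with branch lengths, semicolon-terminated; labels with
#' Newick metacharacters are quoted. `ape::read.tree` re-reads the output
#' losslessly.
#'
#' @param tree A `phylo` tree.
#' @param path Optional output file; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string, invisibly when written to `path`.
#' @export
to_newick <- function(tree, path = NULL) {
  if (!inherits(tree, "phylo") || is.null(tree$tip.label) ||
      length(tree$tip.label) == 0) {
    stop("input error: not a non-empty phylo tree", call. = FALSE)
  }
  s <- .phylo_to_newick(tree)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Histogram of similarity scores in ten bins
#'
#' Bins `[0,0.1), [0.1,0.2), ..., [0.9,1.0]`; the top bin is closed so a
#' score of exactly 1 is counted in bin 9.
#'
#' @param scores Numeric vector of scores in `[0, 1]`.
#' @return Named integer vector of 10 counts (`bin-0` ... `bin-9`).
#' @export
#' @examples
#' score_histogram(c(0.55, 0.58, 0.71))
score_histogram <- function(scores) {
  scores <- as.numeric(scores)
  if (length(scores) && any(scores < 0 | scores > 1 | !is.finite(scores))) {
    stop("input error: scores must lie in [0, 1]", call. = FALSE)
  }
  breaks <- seq(0, 1, by = 0.1)
  idx <- findInterval(scores, breaks, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = 10L)
  names(counts) <- paste0("bin-", 0:9)
  counts
}

#' Off-diagonal scores of a score matrix
#'
#' Convenience accessor for histogramming: the upper-triangle PMSMin values.
#'
#' @param m A `pm13_score_matrix` or symmetric score matrix.
#' @return Numeric vector of pairwise scores.
#' @export
pairwise_scores <- function(m) {
  if (inherits(m, "pm13_score_matrix")) m <- m$pms_min
  m <- as.matrix(m)
  m[upper.tri(m)]
}
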