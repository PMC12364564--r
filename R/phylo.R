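#' Phylomorphospace: project a phylogeny into a morphospace
#'
#' Estimates morphospace coordinates (e.g. PC1/PC2 scores) for the internal
#' nodes of a phylogeny by weighted squared-change parsimony - minimising
#' the sum over branches of (squared change) / (branch length) - which
#' coincides with maximum-likelihood Brownian-motion ancestral states.
#' The result is plottable as tip and node coordinates plus the tree edges
#' connecting them.
#'
#' @param tree a rooted `phylo` tree (ape) with branch lengths; its tips
#'   must cover the rows of `tip_scores`. Zero-length branches are replaced
#'   by a small fraction (1e-8) of the tree height.
#' @param tip_scores numeric matrix (or data frame) of morphospace
#'   coordinates with tip labels as row names, one column per axis.
#' @return object of class `phylomorphospace`: `tip_scores` (input,
#'   reordered to the tree's tips), `node_scores` (internal nodes x axes;
#'   row names are ape node numbers), `edges` (data frame: parent, child,
#'   and the from/to coordinates of the first two axes).
#' @export
phylomorphospace <- function(tree, tip_scores) {
  if (!inherits(tree, "phylo")) stopf("`tree` must be an ape 'phylo' object")
  tip_scores <- as.matrix(tip_scores)
  if (is.null(rownames(tip_scores))) {
    stopf("`tip_scores` must have tip labels as row names")
  }
  missing_tips <- setdiff(tree$tip.label, rownames(tip_scores))
  if (length(missing_tips)) {
    tree <- ape::drop.tip(tree, missing_tips)
  }
  if (is.null(tree) || ape::Ntip(tree) < 2L) {
    stopf("fewer than 2 tree tips have scores")
  }
  not_in_tree <- setdiff(rownames(tip_scores), tree$tip.label)
  if (length(not_in_tree)) {
    stopf("tips missing from the tree: %s", paste(not_in_tree, collapse = ", "))
  }
  tip_scores <- tip_scores[tree$tip.label, , drop = FALSE]
  n_tip <- ape::Ntip(tree)
  n_node <- tree$Nnode
  if (is.null(tree$edge.length)) {
    stopf("tree has no branch lengths")
  }
  el <- tree$edge.length
  height <- max(ape::node.depth.edgelength(tree))
  el[el <= 0] <- 1e-8 * max(height, 1)
  w <- 1 / el
  edges <- tree$edge          # parent (node ids > n_tip), child

  # Solve the weighted-Laplacian system for internal-node states, one axis
  # at a time: for each internal node, sum of w * (state - neighbor) = 0.
  L <- matrix(0, n_node, n_node)
  b0 <- matrix(0, n_node, ncol(tip_scores))
  for (e in seq_len(nrow(edges))) {
    p <- edges[e, 1L] - n_tip
    ch <- edges[e, 2L]
    L[p, p] <- L[p, p] + w[e]
    if (ch > n_tip) {
      ci <- ch - n_tip
      L[ci, ci] <- L[ci, ci] + w[e]
      L[p, ci] <- L[p, ci] - w[e]
      L[ci, p] <- L[ci, p] - w[e]
    } else {
      b0[p, ] <- b0[p, ] + w[e] * tip_scores[ch, ]
    }
  }
  node_scores <- solve(L, b0)
  rownames(node_scores) <- as.character(n_tip + seq_len(n_node))
  colnames(node_scores) <- colnames(tip_scores)

  all_scores <- rbind(tip_scores, node_scores)
  coord <- function(ids, axis) {
    out <- numeric(length(ids))
    tipm <- ids <= n_tip
    out[tipm] <- tip_scores[ids[tipm], axis]
    out[!tipm] <- node_scores[as.character(ids[!tipm]), axis]
    out
  }
  ax2 <- min(2L, ncol(tip_scores))
  ed <- data.frame(parent = edges[, 1L], child = edges[, 2L],
                   x0 = coord(edges[, 1L], 1L), y0 = coord(edges[, 1L], ax2),
                   x1 = coord(edges[, 2L], 1L), y1 = coord(edges[, 2L], ax2))
  structure(list(tip_scores = tip_scores, node_scores = node_scores,
                 edges = ed, tree = tree),
            class = "phylomorphospace")
}

#' @export
print.phylomorphospace <- function(x, ...) {
  cat(sprintf("phylomorphospace: %d tips, %d internal nodes, %d axes\n",
              nrow(x$tip_scores), nrow(x$node_scores), ncol(x$tip_scores)))
  invisible(x)
}

#' @export
plot.phylomorphospace <- function(x, xlab = "PC1", ylab = "PC2", ...) {
  xs <- c(x$edges$x0, x$edges$x1)
  ys <- c(x$edges$y0, x$edges$y1)
  graphics::plot(xs, ys, type = "n", xlab = xlab, ylab = ylab, ...)
  graphics::segments(x$edges$x0, x$edges$y0, x$edges$x1, x$edges$y1,
                     col = "grey60")
  ax2 <- min(2L, ncol(x$tip_scores))
  graphics::points(x$node_scores[, 1L], x$node_scores[, ax2], pch = 21,
                   bg = "white", cex = 0.8)
  graphics::points(x$tip_scores[, 1L], x$tip_scores[, ax2], pch = 19)
  graphics::text(x$tip_scores[, 1L], x$tip_scores[, ax2],
                 rownames(x$tip_scores), pos = 3, cex = 0.7)
  invisible(x)
}
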